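#' Correlation distance matrix
#'
#' Distance d = 1 - Pearson r between expression profiles, the metric used
#' for hierarchical clustering of differential features and of samples.
#' Constant profiles (zero variance) are dropped with a warning since their
#' correlation is undefined.
#'
#' @param x Expression tibble or numeric matrix (features x samples).
#' @param axis `"features"` (cluster rows) or `"samples"` (cluster columns).
#' @return Symmetric numeric matrix with zero diagonal and dimnames.
#' @export
correlation_distance <- function(x, axis = c("features", "samples")) {
  axis <- match.arg(axis)
  m <- if (is.data.frame(x)) expr_matrix(x) else x
  if (axis == "features") m <- t(m)
  # items are now columns
  v <- apply(m, 2, sd)
  if (any(v == 0)) {
    warn(paste0("dropping ", sum(v == 0), " constant profile(s)"))
    m <- m[, v > 0, drop = FALSE]
  }
  if (ncol(m) < 2L) abort("need at least 2 non-constant profiles")
  d <- 1 - cor(m)
  diag(d) <- 0
  d
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Agglomerative clustering with average linkage and a deterministic
#' tie-break: among equally close cluster pairs, the pair whose
#' (lexicographically sorted) representative ids come first is merged.
#' Representatives are each cluster's smallest member id, so the procedure
#' is a pure function of the distance matrix and its dimnames.
#'
#' @param d Symmetric distance matrix with dimnames (see
#'   [correlation_distance()]).
#' @return Object of class `lnc_dendrogram`: a list with `merges` (tibble of
#'   `node_a`, `node_b`, `height` in merge order), `labels`, and
#'   `leaf_order`.
#' @export
upgma <- function(d) {
  d <- as.matrix(d)
  if (any(!is.finite(d))) abort("non-finite distances")
  n <- nrow(d)
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (n < 2L) abort("need at least 2 items")

  # active clusters: representative label, member leaf indices, merge-node id
  reps <- labels
  members <- as.list(seq_len(n))
  node <- -seq_len(n) # hclust convention: negative = leaf
  active <- rep(TRUE, n)
  dd <- d
  merges <- matrix(0L, n - 1L, 2L)
  heights <- numeric(n - 1L)
  merge_of <- vector("list", n - 1L)

  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    sub <- dd[idx, idx, drop = FALSE]
    diag(sub) <- Inf
    h <- min(sub)
    cand <- which(sub - h <= .Machine$double.eps * 64, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # tie-break: lexicographically smallest sorted representative pair
    keys <- apply(cand, 1, function(rc) {
      pr <- sort(c(reps[idx[rc[1]]], reps[idx[rc[2]]]))
      paste(pr, collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- idx[pick[1]]
    j <- idx[pick[2]]

    heights[step] <- dd[i, j]
    merges[step, ] <- sort(c(node[i], node[j]))
    merge_of[[step]] <- c(node[i], node[j])

    ni <- length(members[[i]])
    nj <- length(members[[j]])
    other <- setdiff(idx, c(i, j))
    new_d <- (dd[i, other] * ni + dd[j, other] * nj) / (ni + nj)
    dd[i, other] <- new_d
    dd[other, i] <- new_d
    members[[i]] <- c(members[[i]], members[[j]])
    reps[i] <- min(reps[i], reps[j])
    node[i] <- step
    active[j] <- FALSE
  }

  # leaf order by recursive expansion of the final merge
  expand <- function(id) {
    if (id < 0) return(-id)
    c(expand(merge_of[[id]][1]), expand(merge_of[[id]][2]))
  }
  leaf_order <- expand(n - 1L)

  structure(
    list(
      merges = tibble(
        node_a = merges[, 1], node_b = merges[, 2], height = heights
      ),
      labels = labels,
      leaf_order = labels[leaf_order]
    ),
    class = "lnc_dendrogram"
  )
}

#' @export
print.lnc_dendrogram <- function(x, ...) {
  cat("<lnc_dendrogram> ", length(x$labels), " leaves, ",
      nrow(x$merges), " merges\n", sep = "")
  invisible(x)
}

#' Convert an `lnc_dendrogram` to a base `hclust` object
#'
#' Enables [stats::cutree()], plotting and any downstream tooling that
#' expects the standard representation.
#'
#' @param x `lnc_dendrogram` object.
#' @param ... Unused.
#' @return An object of class `hclust`.
#' @export
as.hclust.lnc_dendrogram <- function(x, ...) {
  structure(
    list(
      merge = cbind(x$merges$node_a, x$merges$node_b),
      height = x$merges$height,
      order = match(x$leaf_order, x$labels),
      labels = x$labels,
      method = "average",
      dist.method = "1 - pearson"
    ),
    class = "hclust"
  )
}

#' Cut a dendrogram into k clusters
#'
#' @param dendro `lnc_dendrogram` object.
#' @param k Number of clusters.
#' @return Tibble with columns `id`, `cluster`.
#' @export
cut_dendrogram <- function(dendro, k) {
  cl <- stats::cutree(stats::as.hclust(dendro), k = k)
  tibble(id = names(cl), cluster = unname(cl))
}

#' Export a clustered, z-scored matrix for heatmap display
#'
#' Rows and columns are permuted to the dendrogram leaf orders and each
#' feature row is z-scored (display only; upstream statistics are computed
#' on unscaled values). The output is a CDT-style TSV: first column feature
#' ids, remaining columns samples in leaf order.
#'
#' @param x Expression tibble or numeric matrix (features x samples).
#' @param feature_dendro,sample_dendro `lnc_dendrogram` objects over the
#'   matrix rows and columns (either may be `NULL` to keep the input order).
#' @param path Output TSV path.
#' @return The permuted, z-scored matrix, invisibly.
#' @export
export_heatmap <- function(x, feature_dendro = NULL, sample_dendro = NULL, path) {
  m <- if (is.data.frame(x)) expr_matrix(x) else x
  if (!is.null(feature_dendro)) {
    if (!all(feature_dendro$labels %in% rownames(m))) abort("feature dendrogram ids not in matrix")
    m <- m[feature_dendro$leaf_order, , drop = FALSE]
  }
  if (!is.null(sample_dendro)) {
    if (!all(sample_dendro$labels %in% colnames(m))) abort("sample dendrogram ids not in matrix")
    m <- m[, sample_dendro$leaf_order, drop = FALSE]
  }
  z <- t(apply(m, 1, function(r) {
    s <- sd(r)
    if (s == 0) r * 0 else (r - mean(r)) / s
  }))
  dimnames(z) <- dimnames(m)
  out <- tibble::as_tibble(z, rownames = "feature_id")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(z)
}
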