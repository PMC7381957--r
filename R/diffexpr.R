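#' Convert counts to FPKM
#'
#' FPKM_ij = k_ij * 1e9 / (L_i * N_j) where L_i is the feature's summed exon
#' length in nt and N_j the column total of the quantified matrix. Using the
#' column total as the per-million denominator keeps the transform
#' self-contained and monotone-equivalent to using total mapped reads.
#'
#' @param counts Expression tibble (see [read_counts()]) of raw counts.
#' @param lengths Named numeric vector, feature id -> length in nt.
#' @return Expression tibble of FPKM values with the same design attached.
#' @export
compute_fpkm <- function(counts, lengths) {
  m <- expr_matrix(counts)
  if (!all(rownames(m) %in% names(lengths))) {
    abort("lengths missing for some features")
  }
  L <- lengths[rownames(m)]
  if (any(L <= 0)) abort("feature lengths must be positive")
  N <- colSums(m)
  if (any(N == 0)) {
    abort(paste0("empty sample(s): ", paste(colnames(m)[N == 0], collapse = ", ")))
  }
  fpkm <- sweep(sweep(m, 1, L, "/"), 2, N, "/") * 1e9
  expr_from_matrix(fpkm, counts_design(counts))
}

#' Median-of-ratios size factors
#'
#' Per-sample depth normalisers: for each sample, the median over features
#' (restricted to features with nonzero counts in every sample) of the ratio
#' of its count to the feature's geometric mean across samples. Factors are
#' rescaled to geometric mean 1.
#'
#' @param counts Expression tibble of raw counts.
#' @return Tibble with columns `sample_id`, `size_factor`.
#' @export
estimate_size_factors <- function(counts) {
  m <- expr_matrix(counts)
  keep <- rowSums(m == 0) == 0L
  if (!any(keep)) {
    abort("no feature has nonzero counts in all samples; filter the matrix first")
  }
  lm <- log(m[keep, , drop = FALSE])
  geo <- rowMeans(lm)
  s <- apply(lm, 2, function(col) exp(median(col - geo)))
  s <- s / exp(mean(log(s)))
  tibble(sample_id = colnames(m), size_factor = unname(s))
}

# per-feature NB dispersion: method of moments on normalized counts,
# shrunk 50/50 toward the mean dispersion of the feature's
# expression decile
estimate_dispersions <- function(q, groups) {
  mean_all <- rowMeans(q)
  lev <- unique(groups)
  vs <- matrix(0, nrow(q), length(lev))
  ns <- integer(length(lev))
  for (i in seq_along(lev)) {
    sub <- q[, groups == lev[i], drop = FALSE]
    ns[i] <- ncol(sub)
    vs[, i] <- apply(sub, 1, var) * (ns[i] - 1)
  }
  var_pooled <- rowSums(vs) / max(1L, sum(ns) - length(lev))
  mom <- (var_pooled - mean_all) / mean_all^2
  mom[!is.finite(mom)] <- 0
  raw <- pmax(0, mom)

  # decile prior from the untruncated moment estimates: truncating at zero
  # before averaging would bias the prior low and make the test liberal
  dec <- dplyr::ntile(mean_all, 10)
  prior <- pmax(vapply(split(mom, dec), mean, numeric(1)), 0)
  shrunk <- 0.5 * raw + 0.5 * prior[as.character(dec)]
  unname(shrunk)
}

# conditioned NB exact p-value for one feature (Robinson-Smyth style):
# given group count sums ka, kb, per-group NB means and common dispersion,
# sum the conditional probabilities of all splits of ka+kb that are as or
# less probable than the observed split
nb_exact_p <- function(ka, kb, mu_a, mu_b, size_a, size_b) {
  total <- ka + kb
  if (total == 0) return(1)
  dens <- function(a, mu, size) {
    if (is.finite(size)) dnbinom(a, mu = mu, size = size) else dpois(a, lambda = mu)
  }
  if (total <= 20000) {
    a <- 0:total
  } else {
    # exact up to a negligible (<1e-12) truncated tail mass
    lo <- min(ka, if (is.finite(size_a)) qnbinom(1e-14, mu = mu_a, size = size_a)
              else stats::qpois(1e-14, mu_a))
    hi <- max(ka, if (is.finite(size_a)) qnbinom(1 - 1e-14, mu = mu_a, size = size_a)
              else stats::qpois(1 - 1e-14, mu_a))
    a <- max(0, lo):min(total, hi)
  }
  pa <- dens(a, mu_a, size_a) * dens(total - a, mu_b, size_b)
  p_obs <- dens(ka, mu_a, size_a) * dens(kb, mu_b, size_b)
  denom <- sum(pa)
  if (denom == 0) return(1)
  min(1, sum(pa[pa <= p_obs * (1 + 1e-8)]) / denom)
}

#' Negative-binomial exact differential test
#'
#' Two-group exact test on count data with the NB variance form
#' var = mu + phi * mu^2. Per-feature dispersions are estimated by the method
#' of moments on normalized counts and shrunk 50/50 toward the trimmed-mean
#' dispersion of features in the same expression decile. The p-value
#' conditions on the two-group count total and sums NB probabilities of all
#' splits as or more extreme (less probable) than the observed one. The
#' fold change is log2((mean_b + 0.5) / (mean_a + 0.5)) on normalized group
#' means, so it is finite even for all-zero groups.
#'
#' @param counts Expression tibble of raw counts with attached design.
#' @param group_a,group_b Group labels; the fold change is b over a.
#' @param size_factors Optional tibble from [estimate_size_factors()];
#'   computed on the two groups' samples when omitted.
#' @return A tibble of class `lnc_de` with columns `feature_id`,
#'   `base_mean_a`, `base_mean_b`, `log2fc`, `dispersion`, `p_value`,
#'   `p_adj` (Benjamini-Hochberg, reported but not used for calling) and
#'   `all_zero`.
#' @export
nb_exact_test <- function(counts, group_a, group_b, size_factors = NULL) {
  design <- counts_design(counts)
  sel <- design$group %in% c(group_a, group_b)
  samples <- design$sample_id[sel]
  groups <- design$group[sel]
  if (sum(groups == group_a) < 2L || sum(groups == group_b) < 2L) {
    abort("both groups need at least 2 samples")
  }
  m <- expr_matrix(counts)[, samples, drop = FALSE]
  if (is.null(size_factors)) {
    sub <- as_expr_tbl(
      tibble::as_tibble(cbind(tibble(feature_id = rownames(m)), as.data.frame(m))),
      design[sel, , drop = FALSE]
    )
    size_factors <- estimate_size_factors(sub)
  }
  s <- setNames(size_factors$size_factor, size_factors$sample_id)[samples]
  q <- sweep(m, 2, s, "/")

  ia <- groups == group_a
  ib <- groups == group_b
  mean_a <- rowMeans(q[, ia, drop = FALSE])
  mean_b <- rowMeans(q[, ib, drop = FALSE])
  phi <- estimate_dispersions(q, groups)

  ka <- rowSums(m[, ia, drop = FALSE])
  kb <- rowSums(m[, ib, drop = FALSE])
  sa <- sum(s[ia])
  sb <- sum(s[ib])
  mu0 <- (ka + kb) / (sa + sb) # pooled null mean per unit depth
  na <- sum(ia)
  nb <- sum(ib)

  p <- vapply(seq_along(mu0), function(i) {
    if (ka[i] + kb[i] == 0) return(1)
    size_a <- if (phi[i] > 1e-10) na / phi[i] else Inf
    size_b <- if (phi[i] > 1e-10) nb / phi[i] else Inf
    nb_exact_p(ka[i], kb[i], mu0[i] * sa, mu0[i] * sb, size_a, size_b)
  }, numeric(1))

  res <- tibble(
    feature_id = rownames(m),
    base_mean_a = unname(mean_a),
    base_mean_b = unname(mean_b),
    log2fc = unname(log2((mean_b + 0.5) / (mean_a + 0.5))),
    dispersion = unname(phi),
    p_value = unname(p),
    all_zero = unname(ka + kb == 0)
  ) |>
    mutate(
      log2fc = ifelse(.data$all_zero, 0, .data$log2fc),
      p_value = ifelse(.data$all_zero, 1, .data$p_value),
      p_adj = p.adjust(.data$p_value, method = "BH")
    ) |>
    relocate("p_adj", .after = "p_value")
  class(res) <- c("lnc_de", class(res))
  attr(res, "comparison") <- c(a = group_a, b = group_b)
  res
}

#' Call differential features
#'
#' Applies the raw-p and fold-change filter: p < alpha (strict) and
#' |log2fc| >= min_lfc. No multiple-testing adjustment enters the call; the
#' BH-adjusted p is carried along for reference.
#'
#' @param results `lnc_de` tibble from [nb_exact_test()].
#' @param alpha P-value cutoff (default 0.05, strict `<`).
#' @param min_lfc Absolute log2 fold-change cutoff (default 1, inclusive `>=`).
#' @return Tibble of differential features with a `direction` column
#'   (`"up"`/`"down"` by the sign of `log2fc`).
#' @export
call_de <- function(results, alpha = 0.05, min_lfc = 1) {
  results |>
    filter(.data$p_value < alpha, abs(.data$log2fc) >= min_lfc) |>
    mutate(direction = ifelse(.data$log2fc > 0, "up", "down")) |>
    as_tibble()
}

#' Partition two differential sets into case-specific and common subsets
#'
#' The Venn partition of the two case-versus-control calls: features
#' differential in both comparisons are `common`, the remainder are specific
#' to the comparison that called them.
#'
#' @param de_case1,de_case2 Character vectors of differential feature ids.
#' @return Tibble with columns `feature_id`, `set_label`
#'   (`case1_specific`, `case2_specific`, `common`); labels are pairwise
#'   disjoint by construction.
#' @export
partition_sets <- function(de_case1, de_case2) {
  de_case1 <- unique(de_case1)
  de_case2 <- unique(de_case2)
  common <- intersect(de_case1, de_case2)
  bind_rows(
    tibble(feature_id = setdiff(de_case1, common), set_label = "case1_specific"),
    tibble(feature_id = setdiff(de_case2, common), set_label = "case2_specific"),
    tibble(feature_id = common, set_label = "common")
  )
}
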