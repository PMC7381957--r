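# ---- lncRNA-protein interaction scoring ------------------------------------
#
# Sequence-composition features in the style of the RPISeq family of tools:
# normalised RNA 4-mer frequencies (256 values) paired with protein
# conjoint-triad frequencies over the standard 7-class reduced amino-acid
# alphabet (343 values). Two independent probabilistic classifiers (an SVM
# and a random forest) are trained on labelled pairs; a pair is called
# positive only when both probabilities exceed 0.5.

CT_CLASSES <- c(
  A = 1, G = 1, V = 1,
  I = 2, L = 2, F = 2, P = 2,
  Y = 3, M = 3, T = 3, S = 3,
  H = 4, N = 4, Q = 4, W = 4,
  R = 5, K = 5,
  D = 6, E = 6,
  C = 7
)

rna_kmer_names <- function(k = 4) {
  b <- c("A", "C", "G", "U")
  apply(expand.grid(rep(list(b), k))[, k:1], 1, paste, collapse = "")
}

triad_names <- function() {
  g <- expand.grid(1:7, 1:7, 1:7)[, 3:1]
  paste0("t", g[, 1], g[, 2], g[, 3])
}

#' Sequence-composition features for one lncRNA-protein pair
#'
#' The RNA block holds normalised 4-mer frequencies over {A,C,G,U}; the
#' protein block holds normalised conjoint-triad frequencies over the
#' 7-class reduced alphabet {AGV, ILFP, YMTS, HNQW, RK, DE, C}. Each block
#' sums to 1 (or is all zero when the sequence is shorter than the window).
#' Windows containing unknown residues are skipped with a warning.
#'
#' @param rna_seq RNA string over {A,C,G,U}.
#' @param protein_seq Protein string over the 20-letter alphabet.
#' @return Named numeric vector of length 256 + 343.
#' @export
featurize_pair <- function(rna_seq, protein_seq) {
  kn <- rna_kmer_names()
  rv <- strsplit(toupper(rna_seq), "")[[1]]
  rna_block <- setNames(numeric(256), kn)
  if (length(rv) >= 4L) {
    kmers <- vapply(seq_len(length(rv) - 3L), function(i) {
      paste(rv[i:(i + 3L)], collapse = "")
    }, character(1))
    known <- kmers %in% kn
    if (any(!known)) warn(paste0("skipping ", sum(!known), " RNA window(s) with unknown bases"))
    tab <- table(kmers[known])
    if (sum(tab) > 0) rna_block[names(tab)] <- as.numeric(tab) / sum(tab)
  }

  tn <- triad_names()
  pv <- strsplit(toupper(protein_seq), "")[[1]]
  cl <- CT_CLASSES[pv]
  prot_block <- setNames(numeric(343), tn)
  if (length(cl) >= 3L) {
    triads <- paste0("t", cl[-c(length(cl) - 1L, length(cl))],
                     cl[-c(1L, length(cl))], cl[-(1:2)])
    known <- !grepl("NA", triads, fixed = TRUE)
    if (any(!known)) warn(paste0("skipping ", sum(!known), " protein window(s) with unknown residues"))
    tab <- table(triads[known])
    if (sum(tab) > 0) prot_block[names(tab)] <- as.numeric(tab) / sum(tab)
  }
  c(rna_block, prot_block)
}

# feature matrix for a table of (rna, protein) sequence pairs
featurize_pairs <- function(rna_seqs, protein_seqs) {
  stopifnot(length(rna_seqs) == length(protein_seqs))
  t(vapply(seq_along(rna_seqs), function(i) {
    suppressWarnings(featurize_pair(rna_seqs[[i]], protein_seqs[[i]]))
  }, numeric(256 + 343)))
}

#' Train the two interaction scorers
#'
#' Fits two independent probabilistic classifiers on labelled
#' lncRNA-protein pairs: a linear support vector machine with Platt
#' probability calibration and a random forest, both on features
#' standardized with the training statistics. Deterministic given `seed`.
#'
#' @param labeled_pairs Tibble with columns `rna_seq`, `protein_seq` and
#'   logical `interacts`; needs at least 20 positives and 20 negatives.
#' @param seed Integer training seed.
#' @return Object of class `interaction_scorers` holding both fitted models,
#'   a version stamp and the seed.
#' @export
train_scorers <- function(labeled_pairs, seed = 1L) {
  y <- labeled_pairs$interacts
  if (length(unique(y)) < 2L) abort("training set must contain both classes")
  if (sum(y) < 20L || sum(!y) < 20L) {
    abort("need at least 20 positive and 20 negative training pairs")
  }
  X <- featurize_pairs(labeled_pairs$rna_seq, labeled_pairs$protein_seq)
  # standardize with training statistics; raw frequency features are too
  # small in magnitude for the SVM margin to be informative
  center <- colMeans(X)
  scale_ <- apply(X, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  Xs <- scale(X, center, scale_)
  colnames(Xs) <- paste0("f", seq_len(ncol(Xs)))
  yf <- factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos"))
  withr::with_seed(seed, {
    svm_fit <- e1071::svm(Xs, yf, kernel = "linear", probability = TRUE, scale = FALSE)
    rf_fit <- randomForest::randomForest(Xs, yf, ntree = 300)
  })
  structure(
    list(svm = svm_fit, rf = rf_fit, center = center, scale = scale_,
         seed = seed, version = as.character(utils::packageVersion("lncreg"))),
    class = "interaction_scorers"
  )
}

#' @export
print.interaction_scorers <- function(x, ...) {
  cat("<interaction_scorers> SVM + random forest, version ", x$version,
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' @export
glance.interaction_scorers <- function(x, ...) {
  tibble(
    n_train = length(x$rf$y),
    rf_oob_error = x$rf$err.rate[x$rf$ntree, "OOB"],
    version = x$version,
    seed = x$seed
  )
}

# probabilities from both scorers for a feature matrix
score_pairs <- function(scorers, X) {
  X <- scale(X, scorers$center, scorers$scale)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  pr_svm <- attr(
    stats::predict(scorers$svm, X, probability = TRUE), "probabilities"
  )[, "pos"]
  pr_rf <- stats::predict(scorers$rf, X, type = "prob")[, "pos"]
  tibble(prob_svm = unname(pr_svm), prob_rf = unname(pr_rf))
}

#' Call lncRNA-protein interactions
#'
#' Scores candidate lncRNA-protein pairs under a coexpression prerequisite:
#' only pairs whose (lncRNA, gene) combination passed the coexpression
#' screen are scored at all. A pair is positive when both the SVM and the
#' random forest probability exceed `prob_threshold`.
#'
#' @param candidates Tibble with columns `lncrna_id`, `protein_id` (the
#'   gene id whose protein is considered).
#' @param coexpression_pairs Tibble of passing coexpression pairs (columns
#'   `lncrna_id`, `gene_id`); the prerequisite gate.
#' @param rna_seqs Named character vector of lncRNA sequences.
#' @param protein_seqs Named character vector of protein sequences keyed by
#'   `protein_id`.
#' @param scorers Fitted [train_scorers()] object.
#' @param prob_threshold Dual probability cutoff (default 0.5, strict `>`).
#' @return Tibble with columns `lncrna_id`, `protein_id`, `prob_svm`,
#'   `prob_rf`, `positive`. Gated-out pairs are absent; pairs with missing
#'   sequences are skipped with a warning.
#' @export
call_interactions <- function(candidates, coexpression_pairs, rna_seqs,
                              protein_seqs, scorers, prob_threshold = 0.5) {
  gated <- candidates |>
    semi_join(
      coexpression_pairs |> select(lncrna_id = "lncrna_id", protein_id = "gene_id"),
      by = c("lncrna_id", "protein_id")
    )
  if (nrow(gated) == 0L) {
    return(tibble(lncrna_id = character(), protein_id = character(),
                  prob_svm = numeric(), prob_rf = numeric(), positive = logical()))
  }
  have <- gated$lncrna_id %in% names(rna_seqs) & gated$protein_id %in% names(protein_seqs)
  if (any(!have)) {
    warn(paste0(sum(!have), " pair(s) skipped: missing sequence"))
    gated <- gated[have, , drop = FALSE]
  }
  X <- featurize_pairs(rna_seqs[gated$lncrna_id], protein_seqs[gated$protein_id])
  probs <- score_pairs(scorers, X)
  bind_cols(gated |> select("lncrna_id", "protein_id"), probs) |>
    mutate(positive = .data$prob_svm > prob_threshold & .data$prob_rf > prob_threshold)
}
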