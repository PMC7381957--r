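# ---- PWM motif scanning for RNA-binding proteins ---------------------------

#' Log-odds score matrix from a position frequency matrix
#'
#' Column frequencies are converted to probabilities, mixed with a
#' background-proportional pseudocount, and scored as
#' log2((f + pseudocount * b) / ((1 + pseudocount) * b)).
#'
#' @param pfm 4 x L non-negative matrix with rownames A, C, G, U.
#' @param background Background base probabilities (must sum to 1; default
#'   uniform 0.25).
#' @param pseudocount Pseudocount weight (> 0, default 0.01).
#' @return 4 x L numeric score matrix.
#' @export
pwm_log_odds <- function(pfm, background = rep(0.25, 4), pseudocount = 0.01) {
  if (any(background <= 0)) abort("background probabilities must be positive")
  if (abs(sum(background) - 1) > 1e-8) abort("background must sum to 1")
  if (pseudocount <= 0) abort("pseudocount must be positive")
  if (any(colSums(pfm) == 0)) abort("PFM has an all-zero column")
  f <- sweep(pfm, 2, colSums(pfm), "/")
  log2(sweep(f, 1, pseudocount * background, "+") /
         ((1 + pseudocount) * background))
}

#' Scan an RNA sequence with a PWM
#'
#' Every window of the sequence is scored with the log-odds matrix and
#' rescaled to the matrix's attainable range:
#' relative_score = (score - min_score) / (max_score - min_score), with the
#' per-PWM extremes computed by per-column minimisation/maximisation. Hits
#' are windows with relative_score >= threshold. A degenerate PWM whose
#' maximum equals its minimum scores 1.0 everywhere and the hits are flagged
#' `degenerate`.
#'
#' @param sequence RNA string over {A,C,G,U}.
#' @param pfm 4 x L PFM (see [read_pfm()]).
#' @param threshold Relative-score cutoff in [0, 1] (default 0.8,
#'   inclusive `>=`).
#' @param rbp_id,lncrna_id Ids carried into the result.
#' @param background,pseudocount Passed to [pwm_log_odds()].
#' @return Tibble with columns `rbp_id`, `lncrna_id`, `position` (1-based
#'   window start), `score`, `relative_score`, `degenerate`. Sequences
#'   shorter than the motif give an empty result.
#' @export
scan_motifs <- function(sequence, pfm, threshold = 0.8,
                        rbp_id = "RBP", lncrna_id = "lncRNA",
                        background = rep(0.25, 4), pseudocount = 0.01) {
  sv <- seq_to_vec(sequence, lncrna_id)
  w <- ncol(pfm)
  empty <- tibble(rbp_id = character(), lncrna_id = character(),
                  position = integer(), score = numeric(),
                  relative_score = numeric(), degenerate = logical())
  if (length(sv) < w) return(empty)
  S <- pwm_log_odds(pfm, background, pseudocount)
  smin <- sum(apply(S, 2, min))
  smax <- sum(apply(S, 2, max))
  idx <- match(sv, c("A", "C", "G", "U"))
  n_win <- length(sv) - w + 1L
  scores <- vapply(seq_len(n_win), function(p) {
    sum(S[cbind(idx[p:(p + w - 1L)], seq_len(w))])
  }, numeric(1))
  degenerate <- (smax - smin) < 1e-12
  rel <- if (degenerate) rep(1, n_win) else (scores - smin) / (smax - smin)
  hit <- rel >= threshold
  tibble(
    rbp_id = rbp_id, lncrna_id = lncrna_id,
    position = which(hit),
    score = scores[hit],
    relative_score = rel[hit],
    degenerate = degenerate
  )
}

#' Scan many lncRNAs with many PWMs
#'
#' @param sequences Named character vector of RNA sequences.
#' @param pfms Tibble from [read_pfm()].
#' @param threshold Relative-score cutoff (default 0.8).
#' @param ... Passed to [scan_motifs()].
#' @return Tibble of motif hits across all sequence/PWM combinations.
#' @export
scan_motifs_all <- function(sequences, pfms, threshold = 0.8, ...) {
  res <- list()
  for (i in seq_len(nrow(pfms))) {
    for (id in names(sequences)) {
      res[[length(res) + 1L]] <- scan_motifs(
        sequences[[id]], pfms$pfm[[i]], threshold = threshold,
        rbp_id = pfms$rbp_id[i], lncrna_id = id, ...
      )
    }
  }
  bind_rows(res)
}
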