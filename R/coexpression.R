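#' Pearson coexpression screen between lncRNAs and genes
#'
#' Correlates each differential lncRNA with each differential protein-coding
#' gene across a chosen sample scope. Correlations are computed on
#' log2(FPKM + 1) (callers pass an FPKM-scale matrix), where Pearson r is
#' far less outlier-driven than on the raw scale. The two-sided p-value uses
#' the t transform t = r * sqrt((n - 2) / (1 - r^2)) with n - 2 degrees of
#' freedom.
#'
#' The default scope pools the case group with the controls: with only two
#' samples in case population 1 a within-case correlation is degenerate, so
#' the screen needs the pooled axis of variation to be informative.
#'
#' @param expr Expression tibble on the FPKM scale with attached design.
#' @param lncrna_ids,gene_ids Character vectors of feature ids to pair.
#' @param case_group Case group label used to resolve the scope.
#' @param scope `"case_plus_control"` (default), `"case_only"` or `"all"`.
#' @param control_group Control group label (default `"control"`).
#' @param log_transform Apply log2(x + 1) before correlating (default TRUE).
#' @return Tibble with columns `lncrna_id`, `gene_id`, `r`, `p_value`,
#'   `n_samples`. Pairs with a constant profile are skipped with a warning.
#' @export
correlate_pairs <- function(expr, lncrna_ids, gene_ids,
                            case_group = "case1",
                            scope = c("case_plus_control", "case_only", "all"),
                            control_group = "control",
                            log_transform = TRUE) {
  scope <- match.arg(scope)
  design <- counts_design(expr)
  samples <- switch(scope,
    case_plus_control = design$sample_id[design$group %in% c(case_group, control_group)],
    case_only = design$sample_id[design$group == case_group],
    all = design$sample_id
  )
  if (length(samples) < 3L) abort("need at least 3 samples in scope")
  m <- expr_matrix(expr)[, samples, drop = FALSE]
  if (log_transform) m <- log2(m + 1)
  missing <- setdiff(c(lncrna_ids, gene_ids), rownames(m))
  if (length(missing) > 0L) {
    abort(paste0("feature(s) not in matrix: ", paste(missing, collapse = ", ")))
  }
  lm <- m[lncrna_ids, , drop = FALSE]
  gm <- m[gene_ids, , drop = FALSE]
  const_l <- apply(lm, 1, sd) == 0
  const_g <- apply(gm, 1, sd) == 0
  if (any(const_l) || any(const_g)) {
    warn(paste0("skipping ", sum(const_l), " lncRNA(s) and ", sum(const_g),
                " gene(s) with constant profiles"))
    lm <- lm[!const_l, , drop = FALSE]
    gm <- gm[!const_g, , drop = FALSE]
  }
  if (nrow(lm) == 0L || nrow(gm) == 0L) {
    return(tibble(lncrna_id = character(), gene_id = character(),
                  r = numeric(), p_value = numeric(), n_samples = integer()))
  }
  n <- ncol(m)
  rmat <- cor(t(lm), t(gm))
  r <- as.vector(rmat)
  tstat <- r * sqrt((n - 2) / pmax(1e-300, 1 - r^2))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1 - 1e-12] <- 0
  tibble(
    lncrna_id = rep(rownames(lm), times = nrow(gm)),
    gene_id = rep(rownames(gm), each = nrow(lm)),
    r = r,
    p_value = p,
    n_samples = n
  )
}

#' Filter coexpression pairs on |r| and p
#'
#' Strict thresholds: |r| > r_min and p < alpha, no multiple-testing
#' correction. Set `signed = TRUE` to additionally require r > r_min
#' (positive correlations only).
#'
#' @param pairs Tibble from [correlate_pairs()].
#' @param r_min Correlation magnitude cutoff (default 0.8, strict `>`).
#' @param alpha P-value cutoff (default 0.05, strict `<`).
#' @param signed Keep only positive correlations (default FALSE keeps |r|).
#' @return The passing subset of `pairs`.
#' @export
filter_pairs <- function(pairs, r_min = 0.8, alpha = 0.05, signed = FALSE) {
  crit <- if (signed) pairs$r > r_min else abs(pairs$r) > r_min
  pairs[crit & pairs$p_value < alpha, , drop = FALSE]
}
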