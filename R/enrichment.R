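# ---- over-representation and preranked gene-set enrichment -----------------

#' Over-representation analysis (hypergeometric + BH)
#'
#' For each gene set, the upper-tail hypergeometric probability of drawing
#' at least the observed overlap when `length(selected)` features are drawn
#' without replacement from the universe: P(X >= overlap). Sets are
#' intersected with the universe before testing; p-values are BH-adjusted
#' across the tested sets.
#'
#' @param selected Character vector of selected (e.g. differential)
#'   features; must be a subset of `universe`.
#' @param sets Gene-set tibble from [read_gmt()].
#' @param universe Character vector of all tested features.
#' @return Tibble with columns `set_id`, `description`, `overlap`,
#'   `set_size`, `selected_size`, `universe_size`, `rich_factor`
#'   (overlap / set_size), `p`, `p_adj`, sorted by `p`.
#' @export
ora <- function(selected, sets, universe) {
  selected <- unique(selected)
  universe <- unique(universe)
  if (length(universe) == 0L || length(selected) == 0L) {
    abort("selected and universe must be non-empty")
  }
  if (!all(selected %in% universe)) abort("selected must be a subset of universe")
  res <- sets |>
    mutate(
      members = map(.data$genes, ~ intersect(.x, universe)),
      set_size = map_int(.data$members, length),
      overlap = map_int(.data$members, ~ length(intersect(.x, selected))),
      selected_size = length(selected),
      universe_size = length(universe)
    ) |>
    filter(.data$set_size > 0L) |>
    mutate(
      rich_factor = .data$overlap / .data$set_size,
      # P(X >= overlap), X ~ Hypergeometric(set_size, universe - set_size, selected)
      p = phyper(.data$overlap - 1L, .data$set_size,
                 .data$universe_size - .data$set_size,
                 .data$selected_size, lower.tail = FALSE),
      p_adj = p.adjust(.data$p, method = "BH")
    ) |>
    select("set_id", "description", "overlap", "set_size", "selected_size",
           "universe_size", "rich_factor", "p", "p_adj") |>
    arrange(.data$p)
  res
}

# weighted Kolmogorov-Smirnov running-sum enrichment score of one set along
# a ranked list (scores sorted decreasing); returns the signed extremum
gsea_es <- function(in_set, scores, weight) {
  n <- length(scores)
  nh <- sum(in_set)
  if (nh == 0L || nh == n) return(NA_real_)
  w <- abs(scores)^weight
  hit_sum <- sum(w[in_set])
  if (hit_sum == 0) return(NA_real_)
  incr <- ifelse(in_set, w / hit_sum, -1 / (n - nh))
  run <- cumsum(incr)
  run[which.max(abs(run))]
}

#' Preranked gene-set enrichment
#'
#' Standard preranked GSEA: features are ordered by decreasing score, the
#' running sum increments by |score|^weight (normalised over set members) at
#' set hits and decrements by 1/(N - set_size) at misses, and the enrichment
#' score is the signed extremum. Significance is estimated by permuting
#' feature labels `n_perm` times and comparing against sign-matched
#' permutation scores, giving p in [1/(n_perm + 1), 1]. Sets with no member
#' in the ranking, or covering the whole ranking (the miss decrement is
#' undefined), are skipped with a warning.
#'
#' @param ranked Tibble with columns `feature_id` and `score` (finite, no
#'   duplicated features), or a named numeric vector.
#' @param sets Gene-set tibble from [read_gmt()].
#' @param weight Score-weighting exponent (default 1; 0 gives the classic
#'   unweighted Kolmogorov-Smirnov statistic).
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Integer seed for the permutations.
#' @return Tibble with columns `set_id`, `description`, `set_size`, `es`,
#'   `direction` (sign of ES), `p`, `p_adj`.
#' @export
gsea_preranked <- function(ranked, sets, weight = 1, n_perm = 1000, seed = 1L) {
  if (is.numeric(ranked)) {
    ranked <- tibble(feature_id = names(ranked), score = unname(ranked))
  }
  if (anyDuplicated(ranked$feature_id)) abort("duplicated features in ranking")
  if (any(!is.finite(ranked$score))) abort("scores must be finite")
  ord <- order(ranked$score, decreasing = TRUE)
  ids <- ranked$feature_id[ord]
  scores <- ranked$score[ord]
  n <- length(ids)

  keep <- map_int(sets$genes, ~ length(intersect(.x, ids)))
  skip <- keep < 1L | keep >= n
  if (any(skip)) {
    warn(paste0("skipping ", sum(skip),
                " set(s) with no members in the ranking or covering it entirely"))
  }
  sets <- sets[!skip, , drop = FALSE]
  if (nrow(sets) == 0L) {
    return(tibble(set_id = character(), description = character(),
                  set_size = integer(), es = numeric(),
                  direction = character(), p = numeric(), p_adj = numeric()))
  }

  withr::with_seed(seed, {
    res <- map(seq_len(nrow(sets)), function(i) {
      members <- sets$genes[[i]]
      in_set <- ids %in% members
      nh <- sum(in_set)
      es <- gsea_es(in_set, scores, weight)
      perm <- vapply(seq_len(n_perm), function(b) {
        gsea_es(seq_len(n) %in% sample.int(n, nh), scores, weight)
      }, numeric(1))
      same_sign <- if (es >= 0) perm[perm >= 0] else perm[perm < 0]
      p <- (1 + sum(abs(same_sign) >= abs(es))) / (1 + length(same_sign))
      tibble(
        set_id = sets$set_id[i], description = sets$description[i],
        set_size = nh, es = es,
        direction = ifelse(es >= 0, "up", "down"), p = p
      )
    })
    bind_rows(res) |>
      mutate(p_adj = p.adjust(.data$p, method = "BH")) |>
      arrange(.data$p)
  })
}
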