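# Independent brute-force oracles used to validate the optimised
# implementations. These deliberately share nothing with the package's
# search code beyond the energy/score definitions under test.

RNA_BASES <- c("A", "C", "G", "U")
WC <- c("AU", "UA", "CG", "GC")
ALL_PAIRS <- c(WC, "GU", "UG")

random_rna_str <- function(n) paste(sample(RNA_BASES, n, TRUE), collapse = "")

rna_rc <- function(x) chartr("ACGU", "UGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))

# exhaustive enumeration of all ungapped duplex windows that contain at
# least seed_len consecutive Watson-Crick pairs; returns the minimum energy
# (or NULL when no window qualifies)
oracle_best_ungapped <- function(q, t, model, seed_len = 6) {
  qv <- strsplit(q, "")[[1]]
  rtv <- rev(strsplit(t, "")[[1]])
  n1 <- length(qv)
  n2 <- length(rtv)
  st <- model$stacks
  lp <- model$loop_penalty
  best <- Inf
  for (off in (1 - n1):(n2 - 1)) {
    i0 <- max(1L, 1L - off)
    i1 <- min(n1, n2 - off)
    len <- i1 - i0 + 1L
    if (len < seed_len) next
    pc <- paste0(qv[i0:i1], rtv[(i0 + off):(i1 + off)])
    paired <- pc %in% ALL_PAIRS
    wc <- pc %in% WC
    for (a in seq_len(len)) {
      for (b in a:len) {
        w <- a:b
        # window must contain a WC run of >= seed_len
        r <- rle(wc[w])
        if (!any(r$values & r$lengths >= seed_len)) next
        e <- model$init
        for (k in w) {
          if (!paired[k]) e <- e + 2 * lp
          else if (k > a && paired[k - 1L]) e <- e + st[pc[k - 1L], pc[k]]
        }
        if (e < best) best <- e
      }
    }
  }
  if (is.finite(best)) best else NULL
}

# exact ORA tail probability by full enumeration of all selections
oracle_ora_p <- function(universe_n, set_n, selected_n, overlap) {
  sets <- combn(universe_n, selected_n)
  hits <- colSums(sets <= set_n) # treat 1..set_n as the set members
  mean(hits >= overlap)
}

# direct running-sum ES enumeration (unweighted or weighted)
oracle_gsea_es <- function(in_set, scores, weight = 0) {
  n <- length(scores)
  w <- abs(scores)^weight
  hit <- sum(w[in_set])
  run <- 0
  best <- 0
  for (k in seq_len(n)) {
    run <- run + if (in_set[k]) w[k] / hit else -1 / (n - sum(in_set))
    if (abs(run) > abs(best)) best <- run
  }
  best
}
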