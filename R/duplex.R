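# ---- RNA-RNA duplex scanner -------------------------------------------------
#
# A local seed-and-extend interaction scanner: exact Watson-Crick seeds are
# extended by a banded dynamic program that tolerates mismatches and short
# bulges, scoring with a nearest-neighbour stacking model. Energies are in
# model units of 0.1 kcal/mol (the integer convention RNA-energy software
# uses internally); negative = favourable.

RNA_PAIRS <- c("AU", "UA", "CG", "GC", "GU", "UG")
WC_PAIRS <- c("AU", "UA", "CG", "GC")

#' Default nearest-neighbour energy model
#'
#' Stacking energies for the six RNA pairs (AU, UA, CG, GC, GU, UG) are read
#' from the stacking table shipped with the package
#' (`extdata/stack_energies.tsv`); entry (p1, p2) is the energy of pair p2
#' stacked 3' of pair p1 along the query strand. The shipped table is
#' pair-symmetric, which makes scan energies invariant under swapping query
#' and target. Units are 0.1 kcal/mol: e.g. a CG/CG stack is -32 units
#' (-3.2 kcal/mol).
#'
#' @param loop_penalty Penalty per unpaired nucleotide in a mismatch or
#'   bulge, in model units (default 40).
#' @param init Duplex initiation penalty in model units (default 41).
#' @return Object of class `energy_model`.
#' @export
default_energy_model <- function(loop_penalty = 40, init = 41) {
  path <- system.file("extdata", "stack_energies.tsv", package = "lncreg")
  tab <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
  energy_model(tab, loop_penalty = loop_penalty, init = init)
}

#' Construct and validate an energy model
#'
#' @param stacks 6 x 6 numeric matrix with dimnames over the RNA pairs;
#'   Watson-Crick stack entries must be negative.
#' @param loop_penalty Per-nucleotide loop/bulge penalty (>= 0).
#' @param init Duplex initiation penalty (>= 0).
#' @return Object of class `energy_model`.
#' @export
energy_model <- function(stacks, loop_penalty = 40, init = 41) {
  if (!all(RNA_PAIRS %in% rownames(stacks)) || !all(RNA_PAIRS %in% colnames(stacks))) {
    abort("stack table must cover all six RNA pairs")
  }
  if (any(stacks[WC_PAIRS, WC_PAIRS] >= 0)) abort("Watson-Crick stacks must be negative")
  if (loop_penalty < 0 || init < 0) abort("penalties must be non-negative")
  structure(
    list(stacks = stacks[RNA_PAIRS, RNA_PAIRS], loop_penalty = loop_penalty, init = init),
    class = "energy_model"
  )
}

pair_code <- function(qb, tb) paste0(qb, tb) # query base then target base

seq_to_vec <- function(x, id = "sequence") {
  v <- strsplit(x, "")[[1]]
  if (!all(v %in% c("A", "C", "G", "U"))) {
    abort(paste0(id, " contains characters outside {A,C,G,U}"))
  }
  v
}

# banded extension DP away from a seed edge. qx/tx are the extension
# substrings (first element adjacent to the seed), edge_pair the seed's
# boundary pair. Returns best (most negative) energy delta, the numbers of
# query/target nts consumed, and paired columns added.
extend_duplex <- function(qx, tx, edge_pair, model, max_bulge, max_extend) {
  nq <- min(length(qx), max_extend)
  nt <- min(length(tx), max_extend)
  if (nq == 0L || nt == 0L) return(list(e = 0, dq = 0L, dt = 0L, pairs = 0L))
  st <- model$stacks
  lp <- model$loop_penalty
  band <- max_bulge
  INF <- Inf

  # E_p[x,y]: best energy, last column a pair (the pair at (x,y));
  # E_o[x,y]: best energy, last column mismatch/bulge. 1-based on consumed nts.
  E_p <- matrix(INF, nq + 1L, nt + 1L)
  E_o <- matrix(INF, nq + 1L, nt + 1L)
  P_p <- matrix(0L, nq + 1L, nt + 1L) # paired columns along best path
  P_o <- matrix(0L, nq + 1L, nt + 1L)
  E_p[1L, 1L] <- 0 # virtual seed-edge pair
  best <- list(e = 0, dq = 0L, dt = 0L, pairs = 0L)

  for (x in 1:nq) {
    ylo <- max(1L, x - band)
    yhi <- min(nt, x + band)
    if (ylo > yhi) break
    for (y in ylo:yhi) {
      xi <- x + 1L
      yi <- y + 1L
      pc <- pair_code(qx[x], tx[y])
      pairable <- pc %in% RNA_PAIRS
      ep <- INF; pp <- 0L
      if (pairable) {
        # from previous pair: stack; the previous pair at (x-1, y-1) is the
        # seed edge when x == y == 1
        prev_pair <- if (x == 1L && y == 1L) edge_pair
                     else if (E_p[xi - 1L, yi - 1L] < INF) pair_code(qx[x - 1L], tx[y - 1L])
                     else NA
        if (!is.na(prev_pair) && E_p[xi - 1L, yi - 1L] < INF) {
          cand <- E_p[xi - 1L, yi - 1L] + st[prev_pair, pc]
          if (cand < ep) { ep <- cand; pp <- P_p[xi - 1L, yi - 1L] + 1L }
        }
        if (E_o[xi - 1L, yi - 1L] < ep) {
          ep <- E_o[xi - 1L, yi - 1L] # pair after an interior loop: no stack
          pp <- P_o[xi - 1L, yi - 1L] + 1L
        }
      }
      eo <- INF; po <- 0L
      # mismatch column (consume both, unpaired, 2 nts)
      cand <- min(E_p[xi - 1L, yi - 1L], E_o[xi - 1L, yi - 1L]) + 2 * lp
      if (cand < eo) {
        eo <- cand
        po <- if (E_p[xi - 1L, yi - 1L] <= E_o[xi - 1L, yi - 1L]) P_p[xi - 1L, yi - 1L] else P_o[xi - 1L, yi - 1L]
      }
      if (band > 0L) {
        # bulge in query (consume query nt only)
        cand <- min(E_p[xi - 1L, yi], E_o[xi - 1L, yi]) + lp
        if (cand < eo) {
          eo <- cand
          po <- if (E_p[xi - 1L, yi] <= E_o[xi - 1L, yi]) P_p[xi - 1L, yi] else P_o[xi - 1L, yi]
        }
        # bulge in target
        cand <- min(E_p[xi, yi - 1L], E_o[xi, yi - 1L]) + lp
        if (cand < eo) {
          eo <- cand
          po <- if (E_p[xi, yi - 1L] <= E_o[xi, yi - 1L]) P_p[xi, yi - 1L] else P_o[xi, yi - 1L]
        }
      }
      E_p[xi, yi] <- ep; P_p[xi, yi] <- pp
      E_o[xi, yi] <- eo; P_o[xi, yi] <- po
      # extensions must end on a paired column, and only strict improvements
      # are taken so neutral columns never inflate the reported site
      if (ep < best$e - 1e-9) {
        best <- list(e = ep, dq = x, dt = y, pairs = pp)
      }
    }
  }
  best
}

# maximal runs of exact WC complementarity between q and rt (reversed target),
# as a data.frame of (qi, ui, len): q[qi + k] pairs rt[ui + k]
find_seed_runs <- function(qv, rtv, seed_len) {
  n1 <- length(qv)
  n2 <- length(rtv)
  if (n1 < seed_len || n2 < seed_len) return(NULL)
  wc <- matrix(FALSE, n1, n2)
  for (p in WC_PAIRS) {
    a <- substr(p, 1, 1)
    b <- substr(p, 2, 2)
    na <- sum(qv == a)
    if (na == 0L) next
    wc[qv == a, ] <- wc[qv == a, , drop = FALSE] | matrix(rtv == b, na, n2, byrow = TRUE)
  }
  ok <- wc[1:(n1 - seed_len + 1L), 1:(n2 - seed_len + 1L), drop = FALSE]
  if (seed_len > 1L) {
    for (off in 1:(seed_len - 1L)) {
      ok <- ok & wc[(1L + off):(n1 - seed_len + 1L + off), (1L + off):(n2 - seed_len + 1L + off), drop = FALSE]
    }
  }
  hits <- which(ok, arr.ind = TRUE)
  if (nrow(hits) == 0L) return(NULL)
  # merge overlapping seed starts on each diagonal into maximal runs
  diag_id <- hits[, 2] - hits[, 1]
  out <- list()
  for (d in unique(diag_id)) {
    qi <- sort(hits[diag_id == d, 1])
    brk <- c(TRUE, diff(qi) > 1L)
    run_start <- qi[brk]
    run_id <- cumsum(brk)
    run_len <- tapply(qi, run_id, function(z) max(z) - min(z) + seed_len)
    out[[length(out) + 1L]] <- data.frame(
      qi = run_start, ui = run_start + d, len = as.integer(run_len)
    )
  }
  do.call(rbind, out)
}

#' Scan two RNAs for hybridization sites
#'
#' Seed-and-extend duplex prediction: all maximal exact Watson-Crick
#' complementary runs of at least `seed_len` nt (GU is allowed as a pair
#' during extension but not in seeds) are extended on both sides by a banded
#' dynamic program tolerating mismatches and, when `max_bulge > 0`, bulges.
#' Energy = initiation + sum of nearest-neighbour stacks + per-nucleotide
#' loop penalties, in model units (0.1 kcal/mol). Overlapping candidates are
#' reduced to maximal non-overlapping hits, reported sorted by energy
#' ascending (best first).
#'
#' @param query,target RNA strings over {A,C,G,U}.
#' @param model [energy_model()] object; default [default_energy_model()].
#' @param seed_len Exact-seed length (default 7).
#' @param max_bulge Bulge band width of the extension DP (default 1;
#'   0 restricts extension to mismatches only, i.e. ungapped).
#' @param max_extend Maximum extension length per side (default 60 nt).
#' @param query_id,target_id Ids carried into the result.
#' @return Tibble with columns `query_id`, `target_id`, `query_start`,
#'   `query_end`, `target_start`, `target_end` (1-based inclusive on each
#'   transcript), `site_length` (number of base-paired positions) and
#'   `energy`.
#' @export
duplex_scan <- function(query, target, model = default_energy_model(),
                        seed_len = 7, max_bulge = 1, max_extend = 60,
                        query_id = "query", target_id = "target") {
  qv <- seq_to_vec(query, "query")
  tv <- seq_to_vec(target, "target")
  empty <- tibble(
    query_id = character(), target_id = character(),
    query_start = integer(), query_end = integer(),
    target_start = integer(), target_end = integer(),
    site_length = integer(), energy = numeric()
  )
  if (length(qv) < seed_len || length(tv) < seed_len) return(empty)
  rtv <- rev(tv)
  runs <- find_seed_runs(qv, rtv, seed_len)
  if (is.null(runs)) return(empty)

  st <- model$stacks
  n2 <- length(tv)
  cand <- vector("list", nrow(runs))
  for (r in seq_len(nrow(runs))) {
    qi <- runs$qi[r]
    ui <- runs$ui[r]
    len <- runs$len[r]
    pos <- 0:(len - 1L)
    pairs <- pair_code(qv[qi + pos], rtv[ui + pos])
    seed_e <- if (len > 1L) sum(st[cbind(pairs[-len], pairs[-1L])]) else 0

    left <- extend_duplex(
      rev(qv[seq_len(qi - 1L)]), rev(rtv[seq_len(ui - 1L)]),
      edge_pair = pairs[1L], model = model, max_bulge = max_bulge, max_extend = max_extend
    )
    right <- extend_duplex(
      qv[seq(qi + len, length.out = length(qv) - qi - len + 1L)],
      rtv[seq(ui + len, length.out = length(rtv) - ui - len + 1L)],
      edge_pair = pairs[len], model = model, max_bulge = max_bulge, max_extend = max_extend
    )

    q_start <- qi - left$dq
    q_end <- qi + len - 1L + right$dq
    u_start <- ui - left$dt
    u_end <- ui + len - 1L + right$dt
    cand[[r]] <- tibble(
      query_id = query_id, target_id = target_id,
      query_start = q_start, query_end = q_end,
      target_start = n2 - u_end + 1L, target_end = n2 - u_start + 1L,
      site_length = len + left$pairs + right$pairs,
      energy = model$init + seed_e + left$e + right$e
    )
  }
  hits <- bind_rows(cand) |> arrange(.data$energy, .data$query_start)
  # greedy selection of non-overlapping hits (on either sequence)
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ok <- TRUE
    for (j in which(keep)) {
      if (hits$query_start[i] <= hits$query_end[j] && hits$query_end[i] >= hits$query_start[j]) ok <- FALSE
      if (hits$target_start[i] <= hits$target_end[j] && hits$target_end[i] >= hits$target_start[j]) ok <- FALSE
      if (!ok) break
    }
    keep[i] <- ok
  }
  hits[keep, , drop = FALSE]
}

#' Does a duplex hit pass the binding filter?
#'
#' A hit qualifies when its hybridization site is longer than 20 base-paired
#' positions (strict, i.e. `site_length >= min_len` with the default
#' `min_len = 21`) and its free energy is at least as favourable as the
#' cutoff: `energy <= -|energy_cutoff|` model units.
#'
#' @param hits Tibble from [duplex_scan()] (zero or more rows).
#' @param min_len Minimum site length in paired nt (default 21).
#' @param energy_cutoff Energy magnitude cutoff in model units (default 50,
#'   i.e. -5 kcal/mol).
#' @return Logical vector, one element per hit.
#' @export
passes_binding <- function(hits, min_len = 21, energy_cutoff = 50) {
  hits$site_length >= min_len & hits$energy <= -abs(energy_cutoff)
}
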