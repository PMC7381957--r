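# ---- cis/trans lncRNA target classification --------------------------------

# genomic span of each gene: the span of its longest transcript (one
# location per gene is needed for the proximity rule)
gene_spans <- function(annotation) {
  annotation |>
    group_by(.data$gene_id) |>
    arrange(desc(.data$tx_length), .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select("gene_id", "chrom", "start", "end")
}

# nearest-end distance between two 1-based inclusive spans on the same
# chromosome; 0 when they overlap
span_gap <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s1, s2) - pmin(e1, e2) - 1L)
}

#' Call cis-acting lncRNA targets
#'
#' A passing coexpression pair is a cis pair when lncRNA and gene lie on the
#' same chromosome with a genomic gap below `max_gap`. The gap is the
#' nearest-end distance between the two loci (span of the longest transcript
#' per feature), strand-ignored; overlapping spans have gap 0.
#'
#' @param pairs Tibble of passing coexpression pairs
#'   (columns `lncrna_id`, `gene_id`, `r`, `p_value`).
#' @param annotation Transcript annotation from [read_gtf()].
#' @param max_gap Maximum gap in nt (default 100000, strict `<`).
#' @return Tibble of cis regulation pairs with columns `lncrna_id`,
#'   `gene_id`, `mode` (`"cis"`), `r`, `p_value`, `genomic_gap`.
#' @export
call_cis <- function(pairs, annotation, max_gap = 100000) {
  loc <- gene_spans(annotation)
  ann <- pairs |>
    inner_join(loc, by = c(lncrna_id = "gene_id")) |>
    inner_join(loc, by = "gene_id", suffix = c("_lnc", "_gene"))
  skipped <- nrow(pairs) - nrow(ann)
  if (skipped > 0L) {
    warn(paste0(skipped, " pair(s) skipped: feature(s) missing from annotation"))
  }
  ann |>
    filter(.data$chrom_lnc == .data$chrom_gene) |>
    mutate(genomic_gap = span_gap(.data$start_lnc, .data$end_lnc,
                                  .data$start_gene, .data$end_gene)) |>
    filter(.data$genomic_gap < max_gap) |>
    mutate(mode = "cis") |>
    select("lncrna_id", "gene_id", "mode", "r", "p_value", "genomic_gap")
}

#' Call trans-acting lncRNA targets
#'
#' Implements the two-step trans rule: passing coexpression pairs whose
#' lncRNA and gene lie on the same chromosome are eliminated first; the
#' remaining (different-chromosome) pairs are duplex-scanned and those with
#' a hybridization site passing [passes_binding()] are labelled trans, with
#' the best (lowest-energy) passing hit attached.
#'
#' @param pairs Tibble of passing coexpression pairs.
#' @param annotation Transcript annotation from [read_gtf()].
#' @param sequences Named character vector of spliced RNA sequences.
#' @param min_len,energy_cutoff Binding thresholds (see [passes_binding()]).
#' @param model,seed_len,max_bulge,max_extend Passed to [duplex_scan()].
#' @return Tibble of trans regulation pairs: `lncrna_id`, `gene_id`, `mode`
#'   (`"trans"`), `r`, `p_value`, plus the best hit's coordinates,
#'   `site_length` and `energy`.
#' @export
call_trans <- function(pairs, annotation, sequences,
                       min_len = 21, energy_cutoff = 50,
                       model = default_energy_model(), seed_len = 7,
                       max_bulge = 1, max_extend = 60) {
  loc <- gene_spans(annotation)
  ann <- pairs |>
    inner_join(loc |> select("gene_id", "chrom"), by = c(lncrna_id = "gene_id")) |>
    inner_join(loc |> select("gene_id", "chrom"), by = "gene_id",
               suffix = c("_lnc", "_gene")) |>
    filter(.data$chrom_lnc != .data$chrom_gene)
  # lncRNA and gene sequences: use the feature's longest transcript
  tx_of <- annotation |>
    group_by(.data$gene_id) |>
    arrange(desc(.data$tx_length), .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select("gene_id", "transcript_id")
  seq_of <- setNames(tx_of$transcript_id, tx_of$gene_id)

  out <- vector("list", nrow(ann))
  n_missing <- 0L
  for (i in seq_len(nrow(ann))) {
    pick_seq <- function(feature) {
      for (key in c(seq_of[feature], feature)) {
        if (!is.na(key) && key %in% names(sequences)) return(sequences[[key]])
      }
      NULL
    }
    lseq <- pick_seq(ann$lncrna_id[i])
    gseq <- pick_seq(ann$gene_id[i])
    if (is.null(lseq) || is.null(gseq) || is.na(lseq) || is.na(gseq)) {
      n_missing <- n_missing + 1L
      next
    }
    hits <- duplex_scan(lseq, gseq, model = model, seed_len = seed_len,
                        max_bulge = max_bulge, max_extend = max_extend,
                        query_id = ann$lncrna_id[i], target_id = ann$gene_id[i])
    if (nrow(hits) == 0L) next
    pass <- hits[passes_binding(hits, min_len, energy_cutoff), , drop = FALSE]
    if (nrow(pass) == 0L) next
    best <- pass[1L, ] # already sorted by energy ascending
    out[[i]] <- tibble(
      lncrna_id = ann$lncrna_id[i], gene_id = ann$gene_id[i], mode = "trans",
      r = ann$r[i], p_value = ann$p_value[i],
      query_start = best$query_start, query_end = best$query_end,
      target_start = best$target_start, target_end = best$target_end,
      site_length = best$site_length, energy = best$energy
    )
  }
  if (n_missing > 0L) {
    warn(paste0(n_missing, " pair(s) skipped: missing sequence"))
  }
  res <- bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble(
      lncrna_id = character(), gene_id = character(), mode = character(),
      r = numeric(), p_value = numeric(),
      query_start = integer(), query_end = integer(),
      target_start = integer(), target_end = integer(),
      site_length = integer(), energy = numeric()
    )
  }
  res
}

#' Per-gene regulator counts
#'
#' Counts distinct trans- and cis-acting lncRNAs per gene and formats the
#' display label "n_trans/n_cis" used to annotate network nodes. Genes in
#' `gene_universe` without any regulator get 0/0.
#'
#' @param regulation_pairs Tibble combining [call_cis()] and [call_trans()]
#'   output (columns `lncrna_id`, `gene_id`, `mode`).
#' @param gene_universe Optional character vector of genes to report.
#' @return Tibble with columns `gene_id`, `n_trans`, `n_cis`, `label`.
#' @export
count_regulators <- function(regulation_pairs, gene_universe = NULL) {
  counts <- regulation_pairs |>
    distinct(.data$lncrna_id, .data$gene_id, .data$mode) |>
    count(.data$gene_id, .data$mode) |>
    tidyr::pivot_wider(names_from = "mode", values_from = "n", values_fill = 0L)
  for (col in c("trans", "cis")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  counts <- counts |> rename(n_trans = "trans", n_cis = "cis")
  if (!is.null(gene_universe)) {
    counts <- tibble(gene_id = unique(gene_universe)) |>
      left_join(counts, by = "gene_id") |>
      mutate(across(c("n_trans", "n_cis"), ~ tidyr::replace_na(.x, 0L)))
  }
  counts |>
    mutate(label = paste0(.data$n_trans, "/", .data$n_cis)) |>
    select("gene_id", "n_trans", "n_cis", "label")
}
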