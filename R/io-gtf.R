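#' Read transcript models from a GTF file
#'
#' Parses exon features from a GTF2.2-dialect file into a tidy transcript
#' annotation table. Coordinates follow the GTF convention (1-based,
#' inclusive) throughout the package. The transcript biotype (mRNA versus
#' lncRNA) is taken from the first attribute key in `biotype_attr` present on
#' the transcript's exon records; unknown or absent biotypes default to
#' `"mRNA"` with a warning.
#'
#' @param path Path to a GTF file.
#' @param biotype_attr Character vector of attribute keys to try, in order,
#'   when determining the biotype.
#' @return A tibble with one row per transcript: `transcript_id`, `gene_id`,
#'   `biotype` (`"mRNA"` or `"lncRNA"`), `chrom`, `strand`, `start`, `end`
#'   (transcript span, 1-based inclusive), `exon_starts`, `exon_ends`
#'   (list-columns of sorted, non-overlapping exon coordinates) and
#'   `tx_length` (summed exon length in nt).
#' @export
read_gtf <- function(path, biotype_attr = c("transcript_biotype", "gene_biotype")) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) abort(paste0("failed to parse GTF '", path, "': ", conditionMessage(e)))
  )
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) abort("GTF contains no exon features")
  md <- as.data.frame(S4Vectors::mcols(gr))
  if (is.null(md$transcript_id) || is.null(md$gene_id)) {
    abort("GTF exon features must carry gene_id and transcript_id attributes")
  }

  key <- intersect(biotype_attr, names(md))
  biotype_raw <- rep(NA_character_, length(gr))
  for (k in key) {
    biotype_raw <- dplyr::coalesce(biotype_raw, as.character(md[[k]]))
  }

  exons <- tibble(
    transcript_id = as.character(md$transcript_id),
    gene_id = as.character(md$gene_id),
    biotype_raw = biotype_raw,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr)
  )

  ann <- exons |>
    group_by(.data$transcript_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    summarise(
      gene_id = .data$gene_id[1],
      biotype_raw = .data$biotype_raw[1],
      chrom = .data$chrom[1],
      strand = .data$strand[1],
      exon_starts = list(.data$start),
      exon_ends = list(.data$end),
      .groups = "drop"
    ) |>
    mutate(
      start = map_int(.data$exon_starts, ~ as.integer(min(.x))),
      end = map_int(.data$exon_ends, ~ as.integer(max(.x))),
      tx_length = map2(.data$exon_starts, .data$exon_ends, ~ sum(.y - .x + 1L)) |>
        unlist() |> as.integer()
    )

  unknown <- !ann$biotype_raw %in% c("mRNA", "lncRNA", "protein_coding") & !is.na(ann$biotype_raw)
  if (any(unknown) || anyNA(ann$biotype_raw)) {
    warn(paste0(
      sum(unknown | is.na(ann$biotype_raw)),
      " transcript(s) with unknown or missing biotype; defaulting to mRNA"
    ))
  }
  ann$biotype <- dplyr::case_when(
    ann$biotype_raw == "lncRNA" ~ "lncRNA",
    TRUE ~ "mRNA"
  )

  bad <- map2(ann$exon_starts, ann$exon_ends, function(s, e) {
    any(e < s) || (length(s) > 1L && any(s[-1L] <= e[-length(e)]))
  }) |> unlist()
  if (any(bad)) {
    abort(paste0(
      "overlapping or inverted exons in transcript(s): ",
      paste(ann$transcript_id[bad], collapse = ", ")
    ))
  }

  ann |>
    select(
      "transcript_id", "gene_id", "biotype", "chrom", "strand",
      "start", "end", "exon_starts", "exon_ends", "tx_length"
    )
}

#' Write a transcript annotation table to GTF
#'
#' Inverse of [read_gtf()]: emits one exon feature per exon with `gene_id`,
#' `transcript_id` and `transcript_biotype` attributes.
#'
#' @param annotation Tibble as returned by [read_gtf()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  rows <- annotation |>
    select("transcript_id", "gene_id", "biotype", "chrom", "strand", "exon_starts", "exon_ends") |>
    tidyr::unnest(c("exon_starts", "exon_ends"))
  gr <- GenomicRanges::GRanges(
    seqnames = rows$chrom,
    ranges = IRanges::IRanges(start = rows$exon_starts, end = rows$exon_ends),
    strand = rows$strand,
    type = "exon",
    source = "lncreg",
    gene_id = rows$gene_id,
    transcript_id = rows$transcript_id,
    transcript_biotype = rows$biotype
  )
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}
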