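#' Read sequences from a FASTA file
#'
#' Nucleotide sequences are normalised to the RNA alphabet (T becomes U,
#' everything upper-cased) because the duplex and motif modules operate on
#' RNA; protein sequences are upper-cased only.
#'
#' @param path FASTA file path.
#' @param type `"rna"` (default) or `"protein"`.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("rna", "protein")) {
  type <- match.arg(type)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(paste0(
      "duplicate FASTA id(s): ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  seqs <- toupper(as.character(set))
  if (type == "rna") seqs <- gsub("T", "U", seqs, fixed = TRUE)
  setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (tab-separated: set id, description, member ids).
#' @return Tibble with columns `set_id`, `description` and list-column
#'   `genes`; members are de-duplicated within a set.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- stringr::str_split(lines, "\t")
  bad <- map_int(fields, length) < 3L
  if (any(bad)) {
    abort(paste0("GMT set with no members at line ", which(bad)[1]))
  }
  tibble(
    set_id = map_chr(fields, 1),
    description = map_chr(fields, 2),
    genes = map(fields, ~ unique(.x[-(1:2)][nzchar(.x[-(1:2)])]))
  ) |>
    (\(x) {
      if (any(map_int(x$genes, length) == 0L)) {
        abort(paste0("GMT set with no members: ",
                     paste(x$set_id[map_int(x$genes, length) == 0L], collapse = ", ")))
      }
      x
    })()
}

#' Write gene sets to a GMT file
#'
#' @param sets Tibble as returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- pmap(list(sets$set_id, sets$description, sets$genes), function(id, d, g) {
    paste(c(id, d, g), collapse = "\t")
  })
  readr::write_lines(unlist(lines), path)
  invisible(path)
}

#' Read JASPAR-style position frequency matrices
#'
#' Expects records of the form `>id name` followed by four rows `A [ ... ]`,
#' `C [ ... ]`, `G [ ... ]`, `T [ ... ]` (or `U`). Rows are stored in RNA
#' order A, C, G, U.
#'
#' @param path PFM text file.
#' @return Tibble with columns `rbp_id` and list-column `pfm` (4 x L numeric
#'   matrix with rownames A, C, G, U).
#' @export
read_pfm <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(stringr::str_trim(lines))]
  starts <- which(stringr::str_starts(lines, ">"))
  if (length(starts) == 0L) abort("no PFM records found")
  recs <- map(seq_along(starts), function(i) {
    from <- starts[i]
    to <- if (i < length(starts)) starts[i + 1] - 1L else length(lines)
    block <- lines[from:to]
    id <- stringr::str_split(sub("^>", "", block[1]), "\\s+")[[1]][1]
    rows <- block[-1]
    if (length(rows) != 4L) abort(paste0("PFM '", id, "' must have exactly 4 base rows"))
    vals <- map(rows, function(r) {
      nums <- stringr::str_extract_all(r, "[0-9.eE+-]+")[[1]]
      as.numeric(nums)
    })
    lens <- map_int(vals, length)
    if (length(unique(lens)) != 1L) abort(paste0("PFM '", id, "' has ragged rows"))
    m <- do.call(rbind, vals)
    rownames(m) <- c("A", "C", "G", "U")
    if (any(m < 0)) abort(paste0("PFM '", id, "' has negative entries"))
    if (any(colSums(m) == 0)) abort(paste0("PFM '", id, "' has an all-zero column"))
    list(rbp_id = id, pfm = m)
  })
  tibble(
    rbp_id = map_chr(recs, "rbp_id"),
    pfm = map(recs, "pfm")
  )
}

#' Write position frequency matrices in JASPAR-style text
#'
#' @param pfms Tibble as returned by [read_pfm()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(pfms, path) {
  out <- unlist(map2(pfms$rbp_id, pfms$pfm, function(id, m) {
    c(
      paste0(">", id),
      paste0(c("A", "C", "G", "U"), " [ ",
             apply(m, 1, function(r) paste(r, collapse = " ")), " ]")
    )
  }))
  readr::write_lines(out, path)
  invisible(path)
}
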