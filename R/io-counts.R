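#' Read a count matrix and its sample design
#'
#' Reads a TSV count (or FPKM) matrix with features in rows and samples in
#' columns, together with a two-column design TSV mapping `sample_id` to
#' `group`. Every sample column must appear in the design.
#'
#' @param path TSV file; first column feature ids, remaining columns samples.
#' @param design_path TSV file with columns `sample_id` and `group`.
#' @return A wide tibble (`feature_id` plus one numeric column per sample)
#'   with the design attached as attribute `"design"` (see [counts_design()]).
#' @export
read_counts <- function(path, design_path) {
  mat <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(mat)[1] <- "feature_id"
  design <- readr::read_tsv(design_path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample_id", "group") %in% names(design))) {
    abort("design file must have columns sample_id and group")
  }
  as_expr_tbl(mat, design)
}

#' Assemble an expression table from a matrix-like tibble and a design
#'
#' Validates the invariants of the package's expression container: unique
#' feature and sample ids, non-negative values, and a group for every sample.
#'
#' @param mat Tibble with `feature_id` plus one numeric column per sample.
#' @param design Tibble with columns `sample_id`, `group`.
#' @return `mat` with attribute `"design"` set.
#' @export
as_expr_tbl <- function(mat, design) {
  samples <- setdiff(names(mat), "feature_id")
  if (anyDuplicated(mat$feature_id)) {
    abort(paste0(
      "duplicated feature id(s): ",
      paste(unique(mat$feature_id[duplicated(mat$feature_id)]), collapse = ", ")
    ))
  }
  if (anyDuplicated(samples)) abort("duplicated sample ids in matrix")
  missing <- setdiff(samples, design$sample_id)
  if (length(missing) > 0L) {
    abort(paste0("sample(s) missing from design: ", paste(missing, collapse = ", ")))
  }
  vals <- as.matrix(mat[samples])
  if (!is.numeric(vals)) abort("non-numeric expression values")
  if (anyNA(vals)) abort("missing values in expression matrix")
  if (any(vals < 0)) abort("negative expression values are not allowed")
  design <- design[match(samples, design$sample_id), , drop = FALSE]
  attr(mat, "design") <- tibble::as_tibble(design)
  mat
}

#' Retrieve the design attached to an expression table
#'
#' @param x Expression tibble from [read_counts()] or [as_expr_tbl()].
#' @return Tibble with columns `sample_id`, `group`.
#' @export
counts_design <- function(x) {
  d <- attr(x, "design")
  if (is.null(d)) abort("no design attached; use as_expr_tbl() or read_counts()")
  d
}

#' Write an expression table and its design to TSV
#'
#' @param x Expression tibble with attached design.
#' @param path Counts TSV path.
#' @param design_path Design TSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, design_path = NULL) {
  readr::write_tsv(x, path, progress = FALSE)
  if (!is.null(design_path)) {
    readr::write_tsv(counts_design(x), design_path, progress = FALSE)
  }
  invisible(path)
}

# numeric matrix view (features x samples) of an expression tibble
expr_matrix <- function(x) {
  samples <- setdiff(names(x), "feature_id")
  m <- as.matrix(x[samples])
  rownames(m) <- x$feature_id
  m
}

# rebuild an expression tibble from a matrix, keeping the design
expr_from_matrix <- function(m, design) {
  mat <- tibble::as_tibble(m, rownames = "feature_id")
  as_expr_tbl(mat, design)
}
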