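# ---- broom-style tidiers ----------------------------------------------------

#' Tidy a differential-expression result
#'
#' @param x `lnc_de` tibble from [nb_exact_test()].
#' @param ... Unused.
#' @return A plain tibble (one row per feature).
#' @export
tidy.lnc_de <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a differential-expression result
#'
#' @param x `lnc_de` tibble from [nb_exact_test()].
#' @param alpha,min_lfc Calling thresholds (defaults as in [call_de()]).
#' @param ... Unused.
#' @return Tibble with the comparison, feature counts and DE counts.
#' @export
glance.lnc_de <- function(x, alpha = 0.05, min_lfc = 1, ...) {
  cmp <- attr(x, "comparison")
  called <- call_de(x, alpha, min_lfc)
  tibble(
    group_a = cmp[["a"]], group_b = cmp[["b"]],
    n_features = nrow(x),
    n_de = nrow(called),
    n_up = sum(called$direction == "up"),
    n_down = sum(called$direction == "down")
  )
}

#' Tidy a dendrogram into its merge table
#'
#' @param x `lnc_dendrogram` from [upgma()].
#' @param ... Unused.
#' @return Tibble of merges (`node_a`, `node_b`, `height`); negative node
#'   ids are leaves (indexing `labels`), positive ids earlier merges.
#' @export
tidy.lnc_dendrogram <- function(x, ...) {
  x$merges
}

#' Tidy a network into its edge table
#'
#' @param x `lnc_network` object.
#' @param ... Unused.
#' @return The edge tibble.
#' @export
tidy.lnc_network <- function(x, ...) {
  x$edges
}

#' One-row summary of a network
#'
#' @param x `lnc_network` object.
#' @param ... Unused.
#' @return Tibble with node/edge counts by kind and relation.
#' @export
glance.lnc_network <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_genes = sum(x$nodes$kind == "gene"),
    n_lncrnas = sum(x$nodes$kind == "lncRNA"),
    n_cis_edges = sum(x$edges$relation == "cis"),
    n_trans_edges = sum(x$edges$relation == "trans"),
    n_ppi_edges = sum(x$edges$relation == "ppi")
  )
}
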