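#' Construct an annotated network object
#'
#' The package's network container: a node table and an edge table. Node
#' kinds and edge relations are checked against the endpoints present.
#'
#' @param nodes Tibble with at least columns `id` and `kind`
#'   (one of gene, lncRNA, protein, RBP); further columns become node
#'   attributes (e.g. `direction`, `n_trans`, `n_cis`, `set_label`).
#' @param edges Tibble with at least columns `source`, `target`, `relation`
#'   (ppi, cis, trans, rna_binding, protein_binding); a `weight` column is
#'   kept as an edge attribute.
#' @return Object of class `lnc_network`.
#' @export
lnc_network <- function(nodes, edges) {
  nodes <- tibble::as_tibble(nodes)
  edges <- tibble::as_tibble(edges)
  if (!all(c("id", "kind") %in% names(nodes))) abort("nodes need columns id, kind")
  if (nrow(edges) > 0 && !all(c("source", "target", "relation") %in% names(edges))) {
    abort("edges need columns source, target, relation")
  }
  if (anyDuplicated(nodes$id)) abort("duplicated node ids")
  if (nrow(edges) > 0) {
    missing <- setdiff(c(edges$source, edges$target), nodes$id)
    if (length(missing) > 0L) {
      abort(paste0("edge endpoint(s) not in node table: ", paste(missing, collapse = ", ")))
    }
    kind <- setNames(nodes$kind, nodes$id)
    reg <- edges$relation %in% c("cis", "trans")
    if (any(reg & !(kind[edges$source] == "lncRNA" & kind[edges$target] == "gene"))) {
      abort("cis/trans edges must run lncRNA -> gene")
    }
  }
  structure(list(nodes = nodes, edges = edges), class = "lnc_network")
}

#' @export
print.lnc_network <- function(x, ...) {
  cat("<lnc_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges), " edges\n", sep = "")
  if (nrow(x$edges) > 0) {
    tab <- table(x$edges$relation)
    cat("  relations:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Convert an annotated network to igraph
#'
#' @param net `lnc_network` object.
#' @return Directed `igraph` graph with all node and edge attributes.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "lnc_network"))
  nodes <- net$nodes |> rename(name = "id")
  edges <- net$edges
  if (nrow(edges) == 0L) {
    return(igraph::make_empty_graph(directed = TRUE) +
             igraph::vertices(nodes$name))
  }
  igraph::graph_from_data_frame(
    d = edges |> rename(from = "source", to = "target"),
    directed = TRUE,
    vertices = as.data.frame(nodes)
  )
}

#' Write a network to SIF or GraphML
#'
#' SIF keeps only topology (`source relation target`, one edge per line);
#' GraphML carries every node and edge attribute and round-trips through
#' [read_network()].
#'
#' @param net `lnc_network` object.
#' @param path Output path.
#' @param format `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (format == "sif") {
    lines <- sprintf("%s\t%s\t%s", net$edges$source, net$edges$relation, net$edges$target)
    isolated <- setdiff(net$nodes$id, c(net$edges$source, net$edges$target))
    readr::write_lines(c(lines, isolated), path)
  } else {
    g <- as_igraph(net)
    # igraph's GraphML writer rejects NA logicals/characters; stringify
    for (a in igraph::vertex_attr_names(g)) {
      v <- igraph::vertex_attr(g, a)
      if (!is.numeric(v)) igraph::vertex_attr(g, a) <- ifelse(is.na(v), "NA", as.character(v))
      else igraph::vertex_attr(g, a) <- ifelse(is.na(v), NA_real_, as.numeric(v))
    }
    for (a in igraph::edge_attr_names(g)) {
      v <- igraph::edge_attr(g, a)
      if (!is.numeric(v)) igraph::edge_attr(g, a) <- ifelse(is.na(v), "NA", as.character(v))
      else igraph::edge_attr(g, a) <- ifelse(is.na(v), NA_real_, as.numeric(v))
    }
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a GraphML network written by [write_network()]
#'
#' @param path GraphML file.
#' @return `lnc_network` object.
#' @export
read_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- tibble::as_tibble(igraph::as_data_frame(g, what = "vertices")) |>
    select(-dplyr::any_of("id")) |> # GraphML node ids duplicate the name attribute
    rename(id = "name")
  edges <- tibble::as_tibble(igraph::as_data_frame(g, what = "edges")) |>
    rename(source = "from", target = "to")
  nodes[nodes == "NA"] <- NA
  if (nrow(edges) > 0) edges[edges == "NA"] <- NA
  lnc_network(nodes, edges)
}
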