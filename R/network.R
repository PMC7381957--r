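# ---- annotated network assembly --------------------------------------------

#' Build the lncRNA -> gene regulation network
#'
#' Nodes are the genes and lncRNAs touched by the classified regulation
#' pairs; gene nodes carry the expression direction (sign of log2fc of the
#' differential call), the Venn `set_label`, and the "n_trans/n_cis"
#' regulator-count label; lncRNA nodes carry their own direction and
#' set_label. Edges run lncRNA -> gene with relation cis or trans. Pairs
#' referencing features absent from the differential calls keep their edge
#' but get direction NA, with a warning.
#'
#' @param regulation_pairs Combined [call_cis()] / [call_trans()] tibble.
#' @param de_calls Tibble with columns `feature_id`, `direction` (e.g. the
#'   row-bound output of [call_de()] across comparisons).
#' @param partition Tibble from [partition_sets()].
#' @return `lnc_network` object.
#' @export
build_regulation_network <- function(regulation_pairs, de_calls, partition) {
  dir_map <- de_calls |> distinct(.data$feature_id, .keep_all = TRUE)
  counts <- count_regulators(regulation_pairs)
  lnc_ids <- unique(regulation_pairs$lncrna_id)
  gene_ids <- unique(regulation_pairs$gene_id)

  nodes <- bind_rows(
    tibble(id = gene_ids, kind = "gene"),
    tibble(id = lnc_ids, kind = "lncRNA")
  ) |>
    left_join(dir_map |> select("feature_id", "direction"), by = c(id = "feature_id")) |>
    left_join(partition, by = c(id = "feature_id")) |>
    left_join(counts, by = c(id = "gene_id")) |>
    mutate(
      n_trans = ifelse(.data$kind == "gene", tidyr::replace_na(.data$n_trans, 0L), NA_integer_),
      n_cis = ifelse(.data$kind == "gene", tidyr::replace_na(.data$n_cis, 0L), NA_integer_),
      label = ifelse(.data$kind == "gene", .data$label, NA_character_)
    )
  uncalled <- sum(is.na(nodes$direction))
  if (uncalled > 0L) {
    warn(paste0(uncalled, " node(s) reference features without a differential call; direction set to NA"))
  }

  edges <- regulation_pairs |>
    transmute(
      source = .data$lncrna_id, target = .data$gene_id,
      relation = .data$mode, weight = abs(.data$r)
    )
  lnc_network(nodes, edges)
}

#' Merge protein-protein interaction edges into a network
#'
#' PPI edges are file inputs (confidence-weighted gene pairs), never
#' computed. Edges whose endpoints are unknown to the network are dropped
#' with a warning; duplicate edges collapse to the maximum weight. Node
#' count never decreases.
#'
#' @param net `lnc_network` object.
#' @param ppi_edges Tibble with columns `gene_a`, `gene_b` and optional
#'   `weight`.
#' @return Updated `lnc_network`.
#' @export
merge_ppi <- function(net, ppi_edges) {
  if (nrow(ppi_edges) == 0L) return(net)
  if (!"weight" %in% names(ppi_edges)) ppi_edges$weight <- 1
  known <- ppi_edges$gene_a %in% net$nodes$id & ppi_edges$gene_b %in% net$nodes$id
  if (any(!known)) {
    warn(paste0(sum(!known), " PPI edge(s) dropped: unknown node id"))
  }
  add <- ppi_edges[known, , drop = FALSE] |>
    mutate(
      source = pmin(.data$gene_a, .data$gene_b),
      target = pmax(.data$gene_a, .data$gene_b)
    ) |>
    group_by(.data$source, .data$target) |>
    summarise(weight = max(.data$weight), .groups = "drop") |>
    mutate(relation = "ppi")
  lnc_network(net$nodes, bind_rows(net$edges, add))
}

#' Build a lncRNA-protein (or lncRNA-RBP) binding network
#'
#' @param calls Tibble of positive interaction calls with columns
#'   `lncrna_id` and `protein_id` (or `rbp_id`), plus an optional numeric
#'   column named by `weight_col`.
#' @param relation `"protein_binding"` (scored interactions) or
#'   `"rna_binding"` (motif hits).
#' @param weight_col Optional column to use as edge weight.
#' @return `lnc_network` object.
#' @export
build_binding_network <- function(calls, relation = c("protein_binding", "rna_binding"),
                                  weight_col = NULL) {
  relation <- match.arg(relation)
  part_col <- if ("protein_id" %in% names(calls)) "protein_id" else "rbp_id"
  kind <- if (part_col == "protein_id") "protein" else "RBP"
  nodes <- bind_rows(
    tibble(id = unique(calls$lncrna_id), kind = "lncRNA"),
    tibble(id = unique(calls[[part_col]]), kind = kind)
  )
  edges <- tibble(
    source = calls$lncrna_id,
    target = calls[[part_col]],
    relation = relation,
    weight = if (!is.null(weight_col)) calls[[weight_col]] else 1
  ) |> distinct(.data$source, .data$target, .keep_all = TRUE)
  lnc_network(nodes, edges)
}

#' Attach a subcellular localization table to network nodes
#'
#' Localization predictions are an optional input table (the external
#' predictor is out of scope); values become a `localization` node
#' attribute.
#'
#' @param net `lnc_network` object.
#' @param localization Tibble with columns `id`, `localization`.
#' @return Updated `lnc_network`.
#' @export
annotate_localization <- function(net, localization) {
  nodes <- net$nodes |>
    left_join(localization |> distinct(.data$id, .keep_all = TRUE), by = "id")
  lnc_network(nodes, net$edges)
}
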