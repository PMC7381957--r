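# ---- plots ------------------------------------------------------------------

#' Volcano plot of a differential-expression result
#'
#' @param object `lnc_de` tibble from [nb_exact_test()].
#' @param alpha,min_lfc Thresholds drawn as guide lines (defaults match
#'   [call_de()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lnc_de <- function(object, alpha = 0.05, min_lfc = 1, ...) {
  df <- tibble::as_tibble(object) |>
    mutate(called = .data$p_value < alpha & abs(.data$log2fc) >= min_lfc)
  ggplot2::ggplot(df, ggplot2::aes(.data$log2fc, -log10(.data$p_value), colour = .data$called)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-min_lfc, min_lfc), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p", colour = "differential") +
    ggplot2::theme_minimal()
}

#' Dendrogram plot
#'
#' @param object `lnc_dendrogram` from [upgma()].
#' @param ... Unused.
#' @return A ggplot object (segments of the merge tree).
#' @export
autoplot.lnc_dendrogram <- function(object, ...) {
  hc <- stats::as.hclust(object)
  dend <- stats::dendrapply(stats::as.dendrogram(hc), identity)
  # simple segment extraction
  xy <- list()
  walk_dend <- function(d, x0) {
    if (is.leaf(d)) {
      return(list(x = match(attr(d, "label"), object$leaf_order), h = 0))
    }
    l <- walk_dend(d[[1]])
    r <- walk_dend(d[[2]])
    h <- attr(d, "height")
    xy[[length(xy) + 1L]] <<- tibble(
      x = c(l$x, l$x, r$x), xend = c(l$x, r$x, r$x),
      y = c(l$h, h, h), yend = c(h, h, r$h)
    )
    list(x = (l$x + r$x) / 2, h = h)
  }
  walk_dend(dend)
  seg <- bind_rows(xy)
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = seq_along(object$leaf_order),
                                labels = object$leaf_order) +
    ggplot2::labs(x = NULL, y = "height (1 - r)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1))
}

#' Enrichment dot plot
#'
#' Rich factor against gene set, sized by overlap and coloured by adjusted
#' p, for an [ora()] result.
#'
#' @param result Tibble from [ora()].
#' @param top Number of sets to show (default 15).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(result, top = 15) {
  df <- result |> arrange(.data$p) |> head(top)
  ggplot2::ggplot(df, ggplot2::aes(.data$rich_factor,
                                   stats::reorder(.data$set_id, .data$rich_factor))) +
    ggplot2::geom_point(ggplot2::aes(size = .data$overlap, colour = .data$p_adj)) +
    ggplot2::scale_colour_gradient(low = "firebrick", high = "steelblue") +
    ggplot2::labs(x = "rich factor (overlap / set size)", y = NULL,
                  size = "overlap", colour = "BH p") +
    ggplot2::theme_minimal()
}

#' Expression heatmap of differential features
#'
#' Row-z-scored log2(FPKM + 1) tile map with rows and columns in dendrogram
#' leaf order.
#'
#' @param x Expression tibble or matrix (features x samples).
#' @param feature_dendro,sample_dendro Optional `lnc_dendrogram` objects.
#' @return A ggplot object.
#' @export
plot_heatmap <- function(x, feature_dendro = NULL, sample_dendro = NULL) {
  m <- if (is.data.frame(x)) expr_matrix(x) else x
  if (!is.null(feature_dendro)) m <- m[feature_dendro$leaf_order, , drop = FALSE]
  if (!is.null(sample_dendro)) m <- m[, sample_dendro$leaf_order, drop = FALSE]
  z <- t(apply(m, 1, function(r) if (sd(r) == 0) r * 0 else (r - mean(r)) / sd(r)))
  df <- tibble::as_tibble(z, rownames = "feature_id") |>
    tidyr::pivot_longer(-"feature_id", names_to = "sample_id", values_to = "z") |>
    mutate(
      feature_id = factor(.data$feature_id, levels = rev(rownames(z))),
      sample_id = factor(.data$sample_id, levels = colnames(z))
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_id, .data$feature_id, fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "green4", mid = "black", high = "red3") +
    ggplot2::labs(x = NULL, y = NULL, fill = "row z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 90, hjust = 1))
}
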