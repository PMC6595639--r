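#' Plot a footprinting depth-QC curve
#'
#' Footprints per peak against median peak volume across thinning levels,
#' with the one-footprint-per-peak line marked; the curve's crossing
#' point is the recommended minimum peak volume for reliable footprinting.
#'
#' @param object An `fg_qc` from [qc_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fg_qc <- function(object, ...) {
  df <- tidy(object)
  rec <- attr(object, "recommended_min_volume")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$median_peak_volume,
                                        y = .data$footprints_per_peak)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "median peak volume (cuts / window)",
                  y = "footprints per peak",
                  title = "Footprint detection vs sequencing depth")
  if (!is.na(rec)) {
    p <- p + ggplot2::geom_vline(xintercept = rec, linetype = "dotted")
  }
  p
}

#' Plot a subtype TF network
#'
#' Family nodes and their target genes per subtype, on a seeded
#' force-directed layout; node colour marks family vs target gene,
#' facets separate subtypes.
#'
#' @param object An `fg_network`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fg_network <- function(object, seed = 1L, ...) {
  e <- object$edges
  if (nrow(e) == 0L) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", 0, 0, label = "empty network") +
             ggplot2::theme_void())
  }
  segs <- list()
  pts <- list()
  for (s in unique(e$subtype)) {
    es <- e[e$subtype == s, ]
    g <- igraph::graph_from_data_frame(
      data.frame(from = es$family_id, to = es$target_gene), directed = TRUE)
    lay <- withr::with_seed(as.integer(seed),
                            igraph::layout_with_fr(g))
    v <- tibble(name = igraph::V(g)$name, x = lay[, 1L], y = lay[, 2L],
                role = ifelse(igraph::V(g)$name %in% es$family_id,
                              "TF family", "target gene"),
                subtype = s)
    ix <- match(es$family_id, v$name)
    jx <- match(es$target_gene, v$name)
    segs[[s]] <- tibble(x = v$x[ix], y = v$y[ix], xend = v$x[jx],
                        yend = v$y[jx], subtype = s)
    pts[[s]] <- v
  }
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = dplyr::bind_rows(segs),
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey60",
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::geom_point(data = dplyr::bind_rows(pts),
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$role), size = 3) +
    ggplot2::geom_text(data = dplyr::bind_rows(pts),
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$name),
                       vjust = -1, size = 2.7) +
    ggplot2::facet_wrap(~subtype, scales = "free") +
    ggplot2::theme_void() +
    ggplot2::labs(colour = NULL, title = "Subtype-specific TF networks")
}

#' Plot sample-sample correlation structure of a clustering
#'
#' Tile plot of the pairwise distances (1 - Pearson correlation of
#' log-signal over distal peaks) with samples in dendrogram order.
#'
#' @param object An `fg_clustering`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fg_clustering <- function(object, ...) {
  d <- as.matrix(object$dist)
  ord <- object$hclust$labels[object$hclust$order]
  df <- tidyr::expand_grid(a = ord, b = ord)
  df$distance <- d[cbind(df$a, df$b)]
  df$a <- factor(df$a, levels = ord)
  df$b <- factor(df$b, levels = ord)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(x = NULL, y = NULL, fill = "1 - r",
                  title = "Sample clustering on distal DHS signal") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
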