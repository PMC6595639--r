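#' Tidy a TF network into a flat edge list
#'
#' @param x An `fg_network`.
#' @param ... Unused.
#' @return Tibble: `subtype`, `family_id`, `target_gene`, `n_supporting`,
#'   `supporting_footprints` (semicolon-separated footprint ids).
#' @export
tidy.fg_network <- function(x, ...) {
  e <- x$edges
  tibble(subtype = e$subtype, family_id = e$family_id,
         target_gene = e$target_gene, n_supporting = e$n_supporting,
         supporting_footprints = vapply(e$supporting, function(s) {
           paste(s$fp_id, collapse = ";")
         }, character(1)))
}

#' One-row summary of a TF network
#' @param x An `fg_network`.
#' @param ... Unused.
#' @return Tibble: `n_nodes`, `n_edges`, `n_subtypes`, `n_target_genes`.
#' @export
glance.fg_network <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         n_subtypes = length(unique(x$nodes$subtype)),
         n_target_genes = length(unique(x$edges$target_gene)))
}

#' Tidy sample-clustering groups
#' @param x An `fg_clustering`.
#' @param ... Unused.
#' @return Tibble with `sample_id` and `cluster`.
#' @export
tidy.fg_clustering <- function(x, ...) x$groups

#' One-row summary of a sample clustering
#' @param x An `fg_clustering`.
#' @param ... Unused.
#' @return Tibble with `n_samples`, `k`, `mean_within_distance`.
#' @export
glance.fg_clustering <- function(x, ...) {
  d <- as.matrix(x$dist)
  grp <- setNames(x$groups$cluster, x$groups$sample_id)
  within <- d[outer(grp[rownames(d)], grp[colnames(d)], `==`) &
                upper.tri(d)]
  tibble(n_samples = nrow(x$groups), k = x$k,
         mean_within_distance = if (length(within)) mean(within) else NA_real_)
}

#' Tidy a QC curve
#' @param x An `fg_qc`.
#' @param ... Unused.
#' @return The QC records as a plain tibble.
#' @export
tidy.fg_qc <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("fraction", "total_reads",
                                 "median_peak_volume", "footprints_per_peak")])
}

#' One-row summary of a QC curve
#' @param x An `fg_qc`.
#' @param ... Unused.
#' @return Tibble with `n_depths`, `recommended_min_volume`.
#' @export
glance.fg_qc <- function(x, ...) {
  tibble(n_depths = nrow(x),
         recommended_min_volume = attr(x, "recommended_min_volume"))
}
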