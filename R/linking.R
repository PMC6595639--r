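#' Link distal peaks to genes via promoter-capture interactions
#'
#' A peak is linked to a gene when it overlaps (by at least 1 bp) one
#' anchor of an interaction whose other anchor overlaps the gene's
#' promoter (TSS +/- `promoter_margin_bp`). Anchor pairs are unordered
#' (either end may be the promoter end); one link is reported per
#' (peak, gene) with the number of supporting interactions.
#'
#' @param peaks Tibble of (distal) peaks: `peak_id`, `chrom`, `start`, `end`.
#' @param interactions Tibble in BEDPE column layout: `chrom1`, `start1`,
#'   `end1`, `chrom2`, `start2`, `end2` (0-based half-open).
#' @param annotation Gene annotation with `gene_id`, `chrom`, `tss`.
#' @param promoter_margin_bp Promoter half-width around the TSS (default 2000).
#' @return Tibble of links: `peak_id`, `gene_id`, `method = "hic"`,
#'   `n_supporting_interactions`.
#' @export
link_by_hic <- function(peaks, interactions, annotation,
                        promoter_margin_bp = 2000L) {
  empty <- tibble(peak_id = character(), gene_id = character(),
                  method = character(), n_supporting_interactions = integer())
  if (nrow(interactions) == 0L || nrow(peaks) == 0L || nrow(annotation) == 0L) {
    return(empty)
  }
  gr <- function(chrom, start, end) {
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start + 1L, end = end))
  }
  pk <- gr(peaks$chrom, peaks$start, peaks$end)
  prom <- gr(annotation$chrom,
             pmax(annotation$tss - promoter_margin_bp, 0L),
             annotation$tss + promoter_margin_bp)
  a1 <- gr(interactions$chrom1, interactions$start1, interactions$end1)
  a2 <- gr(interactions$chrom2, interactions$start2, interactions$end2)
  pair_hits <- function(peak_anchor, prom_anchor) {
    op <- GenomicRanges::findOverlaps(pk, peak_anchor)
    og <- GenomicRanges::findOverlaps(prom, prom_anchor)
    dplyr::inner_join(
      tibble(peak = S4Vectors::queryHits(op), ix = S4Vectors::subjectHits(op)),
      tibble(gene = S4Vectors::queryHits(og), ix = S4Vectors::subjectHits(og)),
      by = "ix", relationship = "many-to-many")
  }
  hits <- dplyr::bind_rows(pair_hits(a1, a2), pair_hits(a2, a1))
  if (nrow(hits) == 0L) return(empty)
  hits |>
    dplyr::mutate(peak_id = peaks$peak_id[.data$peak],
                  gene_id = annotation$gene_id[.data$gene]) |>
    dplyr::distinct(.data$peak_id, .data$gene_id, .data$ix) |>
    dplyr::count(.data$peak_id, .data$gene_id,
                 name = "n_supporting_interactions") |>
    dplyr::mutate(method = "hic", .before = "n_supporting_interactions")
}

#' Nearest-gene fallback links
#'
#' Each peak receives exactly one link to the gene whose TSS is closest
#' to the peak summit (ties to the lower-coordinate TSS). Used for distal
#' peaks without any conformation-based link.
#'
#' @param peaks Tibble of peaks with `peak_id`, `chrom`, `summit`.
#' @param annotation Gene annotation with `gene_id`, `chrom`, `tss`.
#' @return Tibble of links with `method = "nearest"` and
#'   `n_supporting_interactions = 0`.
#' @export
nearest_gene_fallback <- function(peaks, annotation) {
  assert_that(nrow(annotation) > 0L, "nearest-gene fallback needs a non-empty annotation")
  if (nrow(peaks) == 0L) {
    return(tibble(peak_id = character(), gene_id = character(),
                  method = character(), n_supporting_interactions = integer()))
  }
  nt <- nearest_tss(peaks$chrom, peaks$summit, annotation)
  tibble(peak_id = peaks$peak_id, gene_id = nt$gene_id, method = "nearest",
         n_supporting_interactions = 0L)
}

#' Link all distal peaks to target genes
#'
#' Promoter-capture links first; any peak without one falls back to its
#' nearest gene, so every peak ends with at least one link. Without an
#' interaction table this reduces to pure nearest-gene assignment.
#'
#' @inheritParams link_by_hic
#' @param peaks Distal peak tibble with `peak_id`, `chrom`, `start`,
#'   `end`, `summit`.
#' @return Tibble of links (`peak_id`, `gene_id`, `method`,
#'   `n_supporting_interactions`).
#' @export
link_targets <- function(peaks, interactions, annotation,
                         promoter_margin_bp = 2000L) {
  hic <- link_by_hic(peaks, interactions, annotation, promoter_margin_bp)
  rest <- peaks[!peaks$peak_id %in% hic$peak_id, , drop = FALSE]
  dplyr::bind_rows(hic, nearest_gene_fallback(rest, annotation))
}

#' Summary statistics of DHS-gene linking
#'
#' Reports the fraction of distal peaks with at least one
#' promoter-capture link, the fraction of promoter-DHS links whose gene
#' is the peak's nearest gene, and — over HiC-linked deregulated peaks —
#' the fraction linked to their nearest gene. Undefined fractions (empty
#' denominators) are returned as `NA`, never as 0.
#'
#' @param links Link tibble from [link_targets()] or [link_by_hic()].
#' @param peaks Distal peak tibble (`peak_id`, `chrom`, `summit`).
#' @param annotation Gene annotation with `gene_id`, `chrom`, `tss`.
#' @param deregulated_ids Optional peak ids of subtype-deregulated DHSs.
#' @return One-row tibble: `fraction_dhs_with_promoter_interaction`,
#'   `fraction_interactions_nearest_gene`,
#'   `fraction_deregulated_dhs_nearest`.
#' @export
link_stats <- function(links, peaks, annotation, deregulated_ids = NULL) {
  hic <- links[links$method == "hic" & links$peak_id %in% peaks$peak_id, ]
  frac_linked <- if (nrow(peaks) > 0L) {
    length(unique(hic$peak_id)) / nrow(peaks)
  } else NA_real_
  nt <- nearest_tss(peaks$chrom, peaks$summit, annotation)
  nearest <- setNames(nt$gene_id, peaks$peak_id)
  frac_nearest <- if (nrow(hic) > 0L) {
    mean(hic$gene_id == nearest[hic$peak_id])
  } else NA_real_
  frac_dereg <- NA_real_
  if (!is.null(deregulated_ids)) {
    dh <- hic[hic$peak_id %in% deregulated_ids, ]
    if (nrow(dh) > 0L) {
      per_peak <- dplyr::summarise(
        dplyr::group_by(dh, .data$peak_id),
        hit = any(.data$gene_id == nearest[.data$peak_id[1L]]), .groups = "drop")
      frac_dereg <- mean(per_peak$hit)
    }
  }
  tibble(fraction_dhs_with_promoter_interaction = frac_linked,
         fraction_interactions_nearest_gene = frac_nearest,
         fraction_deregulated_dhs_nearest = frac_dereg)
}
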