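#' Call DHS peaks on merged cut profiles
#'
#' Profiles are summed position-wise (both strands) into one merged
#' track — pooling all samples before peak calling flattens background
#' noise and maximizes detection sensitivity — and scanned in fixed bins.
#' A bin is a candidate when its merged count exceeds what a Poisson
#' background at the genome-wide mean rate would produce with
#' `p < p_cutoff`; candidates closer than `merge_gap_bp` are merged, and
#' each merged region is reported as one peak whose summit is the argmax
#' of the `smooth_bp`-smoothed merged density (ties to the leftmost
#' position). Fully deterministic.
#'
#' @param profiles List of `fg_profile` objects on one chromosome space.
#' @param bin_bp Scanning bin width (default 50).
#' @param p_cutoff Poisson tail probability cutoff (default 1e-5).
#' @param merge_gap_bp Maximum gap between candidates to merge (default 200).
#' @param smooth_bp Smoothing window for summit placement (default 150).
#' @param lambda_per_bp Background rate per bp; defaults to the
#'   genome-wide mean of the merged track. Supplying a fixed value makes
#'   thresholds comparable across tracks of different depth.
#' @return Atlas tibble: `peak_id`, `chrom`, `start`, `end`, `summit`
#'   (0-based half-open; `start <= summit < end`).
#' @export
call_peaks <- function(profiles, bin_bp = 50L, p_cutoff = 1e-5,
                       merge_gap_bp = 200L, smooth_bp = 150L,
                       lambda_per_bp = NULL) {
  assert_that(length(profiles) >= 1L, "call_peaks needs at least one profile")
  merged <- merge_profiles(profiles)
  lens <- chrom_lengths(merged)
  lambda_per_bp <- lambda_per_bp %||% (total_cuts(merged) / sum(lens))
  rows <- list()
  for (ch in names(lens)) {
    track <- merged$fwd[[ch]] + merged$rev[[ch]]
    n_bins <- length(track) %/% bin_bp
    if (n_bins == 0L) next
    used <- n_bins * bin_bp
    bins <- colSums(matrix(track[seq_len(used)], nrow = bin_bp))
    sig <- which(bins > 0 &
                   stats::ppois(bins - 1, lambda_per_bp * bin_bp,
                                lower.tail = FALSE) < p_cutoff)
    if (!length(sig)) next
    starts <- (sig - 1L) * bin_bp
    ends <- sig * bin_bp
    new_region <- c(TRUE, starts[-1L] - ends[-length(ends)] > merge_gap_bp)
    grp <- cumsum(new_region)
    sm <- running_mean(track, smooth_bp)
    for (g in unique(grp)) {
      s <- min(starts[grp == g])
      e <- max(ends[grp == g])
      summit <- s + which.max(sm[(s + 1L):e]) - 1L
      rows[[length(rows) + 1L]] <- tibble(chrom = ch, start = s, end = e,
                                          summit = summit)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble(peak_id = character(), chrom = character(), start = integer(),
                  end = integer(), summit = integer()))
  }
  out <- dplyr::arrange(out, .data$chrom, .data$start)
  out$peak_id <- sprintf("peak%05d", seq_len(nrow(out)))
  dplyr::select(out, "peak_id", "chrom", "start", "end", "summit")
}

#' Quantify a sample on fixed peak windows
#'
#' Every atlas peak is quantified with the same fixed window: total cuts
#' (both strands) in `[summit - window/2, summit + window/2)`, clipped at
#' chromosome ends, so all samples are measured on identical regions.
#'
#' @param atlas Atlas tibble from [call_peaks()].
#' @param profile An `fg_profile`.
#' @param window_bp Window width in bp (default 400).
#' @return Tibble with `peak_id` and `count`.
#' @export
quantify_peaks <- function(atlas, profile, window_bp = 400L) {
  assert_that(nrow(atlas) >= 1L, "atlas must be non-empty")
  half <- window_bp %/% 2L
  lens <- chrom_lengths(profile)
  counts <- numeric(nrow(atlas))
  for (ch in unique(atlas$chrom)) {
    idx <- which(atlas$chrom == ch)
    cs <- cumsum(c(0, profile$fwd[[ch]] + profile$rev[[ch]]))
    lo <- pmax(atlas$summit[idx] - half, 0L)
    hi <- pmin(atlas$summit[idx] + half, lens[[ch]])
    counts[idx] <- cs[hi + 1L] - cs[lo + 1L]
  }
  tibble(peak_id = atlas$peak_id, count = counts)
}

#' Count matrix over an atlas
#'
#' @param atlas Atlas tibble.
#' @param profiles Named list of `fg_profile`.
#' @param window_bp Fixed quantification window (default 400).
#' @return Tibble with `peak_id` plus one raw-count column per sample;
#'   attribute `normalized` is `FALSE`.
#' @export
build_count_matrix <- function(atlas, profiles, window_bp = 400L) {
  out <- tibble(peak_id = atlas$peak_id)
  for (nm in names(profiles)) {
    out[[nm]] <- quantify_peaks(atlas, profiles[[nm]], window_bp)$count
  }
  attr(out, "normalized") <- FALSE
  out
}

#' Ranked-peak normalization of a count matrix
#'
#' Each sample is rescaled by the value of its r-th largest peak count,
#' where `r = min(norm_rank, floor(n_peaks * norm_rank_fraction))`. With
#' the defaults this is the count of the peak ranked 16 000 by size
#' (close to the median number of peaks per sample in a cohort-scale
#' atlas of ~128 000 peaks; `norm_rank_fraction = 0.125` keeps the same
#' proportion on smaller atlases). The reference value defaults to the
#' across-sample median of the r-th-largest counts, so a typical sample
#' is left roughly unchanged. Normalization is idempotent and invariant
#' to global per-sample rescaling.
#'
#' @param counts Count-matrix tibble (`peak_id` + sample columns).
#' @param norm_rank Rank of the anchor peak (default 16000).
#' @param norm_rank_fraction Fraction used when the atlas is smaller than
#'   `norm_rank` (default 0.125).
#' @param reference_value Target value for the r-th largest count;
#'   default: across-sample median.
#' @return The rescaled tibble; attributes `normalized`, `factors`,
#'   `reference_value`, `effective_rank`.
#' @export
normalize_rank <- function(counts, norm_rank = 16000L, norm_rank_fraction = 0.125,
                           reference_value = NULL) {
  samples <- setdiff(names(counts), "peak_id")
  assert_that(length(samples) >= 1L, "count matrix has no sample columns")
  n <- nrow(counts)
  r <- min(norm_rank, floor(n * norm_rank_fraction))
  assert_that(r >= 1L, "effective normalization rank < 1; atlas too small")
  anchors <- vapply(samples, function(s) {
    sort(counts[[s]], decreasing = TRUE)[r]
  }, numeric(1))
  assert_that(all(anchors > 0),
              paste0("sample too shallow for rank normalization: ",
                     paste(samples[anchors == 0], collapse = ", ")))
  reference_value <- reference_value %||% median(anchors)
  factors <- reference_value / anchors
  out <- counts
  for (s in samples) out[[s]] <- counts[[s]] * factors[[s]]
  attr(out, "normalized") <- TRUE
  attr(out, "factors") <- factors
  attr(out, "reference_value") <- reference_value
  attr(out, "effective_rank") <- r
  out
}

#' Classify atlas peaks as distal or promoter-proximal
#'
#' A peak is distal iff its summit lies more than `promoter_margin_bp`
#' from the nearest TSS (ties in the nearest TSS go to the lower
#' coordinate). With an empty annotation all peaks are distal.
#'
#' @param atlas Atlas tibble.
#' @param annotation Gene annotation tibble with `chrom`, `tss`, `gene_id`.
#' @param promoter_margin_bp Distance cutoff (default 2000).
#' @return `atlas` with added columns `distal` (logical),
#'   `nearest_gene`, `tss_distance`.
#' @export
classify_distal <- function(atlas, annotation, promoter_margin_bp = 2000L) {
  nt <- nearest_tss(atlas$chrom, atlas$summit, annotation)
  atlas$nearest_gene <- nt$gene_id
  atlas$tss_distance <- nt$distance
  atlas$distal <- nt$distance > promoter_margin_bp
  atlas
}

#' Hierarchical clustering of samples on distal peaks
#'
#' Agglomerative clustering with distance `1 - Pearson correlation` of
#' `log2(1 + signal)` over the distal rows of a normalized count matrix,
#' average linkage. Samples are ordered canonically before clustering so
#' the result does not depend on input order, and flat groups are
#' labelled in order of first appearance of the alphabetically sorted
#' sample names.
#'
#' @param counts Normalized count-matrix tibble.
#' @param distal_ids Peak ids to cluster on (default: all rows).
#' @param k Number of flat groups to cut (default 2).
#' @return An object of class `fg_clustering`: `hclust`, `groups` tibble
#'   (`sample_id`, `cluster`), `k`, and the distance matrix.
#' @export
cluster_samples <- function(counts, distal_ids = NULL, k = 2L) {
  samples <- sort(setdiff(names(counts), "peak_id"))
  assert_that(length(samples) >= 2L, "clustering needs at least 2 samples")
  rows <- if (is.null(distal_ids)) seq_len(nrow(counts)) else
    which(counts$peak_id %in% distal_ids)
  m <- log2(1 + as.matrix(counts[rows, samples, drop = FALSE]))
  sds <- apply(m, 2L, stats::sd)
  assert_that(all(sds > 0),
              paste0("constant sample vector(s), correlation undefined: ",
                     paste(samples[sds == 0], collapse = ", ")))
  d <- as.dist(1 - cor(m))
  hc <- hclust(d, method = "average")
  grp <- cutree(hc, k = k)
  canon <- setNames(seq_along(unique(grp[samples])), unique(grp[samples]))
  groups <- tibble(sample_id = samples,
                   cluster = unname(canon[as.character(grp[samples])]))
  structure(list(hclust = hc, groups = groups, k = k, dist = d),
            class = "fg_clustering")
}

#' @export
print.fg_clustering <- function(x, ...) {
  cat("<fg_clustering>", nrow(x$groups), "samples in", x$k, "groups\n")
  print(x$groups)
  invisible(x)
}

#' Subtype-specific DHS subsets
#'
#' A peak is assigned to subtype S when its mean normalized signal in S
#' samples is at least `fold` times the mean over all other samples
#' (controls included) and its signal exceeds `min_signal` in at least
#' `presence_fraction` of the S samples.
#'
#' @param counts Normalized count-matrix tibble.
#' @param metadata Sample sheet with `sample_id`, `subtype`, `is_control`.
#' @param fold Fold-enrichment threshold (default 2).
#' @param presence_fraction Minimum fraction of S samples with signal
#'   (default 0.5).
#' @param min_signal Peak-calling floor the per-sample signal must exceed
#'   (default 1).
#' @return Tibble with `subtype`, `peak_id`; parameters in attributes.
#' @export
subtype_specific_dhs <- function(counts, metadata, fold = 2.0,
                                 presence_fraction = 0.5, min_signal = 1.0) {
  samples <- setdiff(names(counts), "peak_id")
  metadata <- metadata[metadata$sample_id %in% samples, ]
  labels <- unique(metadata$subtype)
  assert_that(length(labels) >= 2L,
              "need at least two subtypes (or a subtype plus controls)")
  subtypes <- unique(metadata$subtype[!metadata$is_control])
  m <- as.matrix(counts[, metadata$sample_id, drop = FALSE])
  rows <- list()
  for (s in subtypes) {
    in_s <- metadata$subtype == s
    assert_that(sum(in_s) >= 1L, paste0("subtype with 0 samples: ", s))
    mean_s <- rowMeans(m[, in_s, drop = FALSE])
    mean_o <- rowMeans(m[, !in_s, drop = FALSE])
    enriched <- mean_s >= fold * mean_o
    enriched[is.na(enriched)] <- FALSE
    present <- rowMeans(m[, in_s, drop = FALSE] > min_signal) >= presence_fraction
    hit <- which(enriched & present)
    if (length(hit)) {
      rows[[s]] <- tibble(subtype = s, peak_id = counts$peak_id[hit])
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) out <- tibble(subtype = character(), peak_id = character())
  attr(out, "fold") <- fold
  attr(out, "presence_fraction") <- presence_fraction
  attr(out, "min_signal") <- min_signal
  out
}
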