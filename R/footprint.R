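#' Footprint detection parameters
#'
#' @param lengths Candidate footprint lengths in bp (default 11-25).
#' @param shoulder_bp Shoulder width on each side (default 35).
#' @param score_threshold Minimum combined score, in -log10 p (default 10).
#' @param strand_mode `"both"` (default) requires both strands to pass
#'   individually — the combined score is the minimum of the two strand
#'   scores, enforcing the bidirectional protection signature;
#'   `"forward"`/`"reverse"` score a single strand.
#' @param max_per_peak Maximum accepted calls per peak (default unlimited).
#' @return A list of class `fg_fp_params`.
#' @export
footprint_params <- function(lengths = 11:25, shoulder_bp = 35L,
                             score_threshold = 10,
                             strand_mode = c("both", "forward", "reverse"),
                             max_per_peak = Inf) {
  assert_that(shoulder_bp > 0L, "shoulder_bp must be positive")
  assert_that(all(lengths >= 6L), "footprint lengths must be >= 6 bp")
  structure(list(lengths = as.integer(lengths),
                 shoulder_bp = as.integer(shoulder_bp),
                 score_threshold = score_threshold,
                 strand_mode = match.arg(strand_mode),
                 max_per_peak = max_per_peak),
            class = "fg_fp_params")
}

#' Binomial shoulder-versus-interior tail score
#'
#' The statistic behind digital footprint detection: a protein bound at a
#' footprint blocks DNase cuts in the interior while cuts pile up in the
#' flanking shoulders. Given `n_shoulder` cuts in a shoulder of width
#' `shoulder_bp` and `n_fp` cuts in a footprint of width `fp_bp`, the
#' score is `-log10 P[X >= n_shoulder]` with
#' `X ~ Binomial(n_shoulder + n_fp, shoulder_bp / (shoulder_bp + fp_bp))`;
#' under no protection the cuts split proportionally to width and the
#' score stays near 0. With zero cuts in both intervals the score is 0.
#'
#' Vectorized over all four count/width arguments.
#'
#' @param n_shoulder,n_fp Cut counts in the shoulder and the footprint.
#' @param shoulder_bp,fp_bp Interval widths in bp.
#' @return Scores in -log10 p units.
#' @export
binomial_shoulder_score <- function(n_shoulder, n_fp, shoulder_bp, fp_bp) {
  n <- n_shoulder + n_fp
  p0 <- shoulder_bp / (shoulder_bp + fp_bp)
  # deep in the upper tail pbeta warns about full precision; the score is
  # then orders of magnitude past any threshold, so the loss is immaterial
  # (accuracy elsewhere is pinned by the brute-force oracle tests)
  logp <- suppressWarnings(
    pbinom(n_shoulder - 1, n, p0, lower.tail = FALSE, log.p = TRUE))
  out <- -logp / log(10)
  out[n_shoulder <= 0] <- 0
  out
}

#' Strand-aware footprint score at one interval
#'
#' The forward-strand test compares forward cuts in the upstream shoulder
#' `[start - S, start)` against forward cuts inside the footprint; the
#' reverse-strand test symmetrically uses the downstream shoulder
#' `[end, end + S)`. The combined score is the minimum of the two strand
#' scores (both strands must individually show protection), or the single
#' strand's score under a one-strand mode.
#'
#' @param profile An `fg_profile`.
#' @param chrom Chromosome name.
#' @param start,end Footprint interval, 0-based half-open; both shoulders
#'   must fit inside the chromosome.
#' @param params An [footprint_params()] object.
#' @return Tibble with `score`, `score_fwd`, `score_rev`.
#' @export
wellington_score <- function(profile, chrom, start, end,
                             params = footprint_params()) {
  S <- params$shoulder_bp
  L <- end - start
  assert_that(L >= 1L, "footprint interval must be non-empty")
  lens <- chrom_lengths(profile)
  assert_that(start - S >= 0L && end + S <= lens[[chrom]],
              "footprint must have shoulder clearance inside the chromosome")
  fwd <- profile$fwd[[chrom]]
  rev <- profile$rev[[chrom]]
  f_sh <- sum(fwd[(start - S + 1L):start])
  f_fp <- sum(fwd[(start + 1L):end])
  r_fp <- sum(rev[(start + 1L):end])
  r_sh <- sum(rev[(end + 1L):(end + S)])
  sf <- binomial_shoulder_score(f_sh, f_fp, S, L)
  sr <- binomial_shoulder_score(r_sh, r_fp, S, L)
  combined <- switch(params$strand_mode,
                     both = pmin(sf, sr),
                     forward = sf,
                     reverse = sr)
  tibble(score = combined, score_fwd = sf, score_rev = sr)
}

#' Detect digital footprints in atlas peaks
#'
#' Every candidate (position, length) pair inside each peak — with full
#' shoulder clearance from the peak edges — is scored with
#' [wellington_score()]'s statistic; candidates at or above
#' `score_threshold` are accepted greedily by descending score with no
#' overlap among accepted calls (ties broken by leftmost start, then
#' shortest length), which makes the output deterministic.
#'
#' @param profile An `fg_profile`.
#' @param atlas Atlas tibble from [call_peaks()].
#' @param params An [footprint_params()] object.
#' @return Tibble of calls: `fp_id`, `peak_id`, `chrom`, `start`, `end`,
#'   `score`, `score_fwd`, `score_rev`.
#' @export
detect_footprints <- function(profile, atlas, params = footprint_params()) {
  assert_that(nrow(atlas) >= 1L, "atlas must be non-empty")
  S <- params$shoulder_bp
  lens <- chrom_lengths(profile)
  cs_f <- lapply(profile$fwd, function(x) cumsum(c(0, x)))
  cs_r <- lapply(profile$rev, function(x) cumsum(c(0, x)))
  accepted <- list()
  for (i in seq_len(nrow(atlas))) {
    ch <- atlas$chrom[i]
    p_start <- max(atlas$start[i], S)
    p_end <- min(atlas$end[i], lens[[ch]] - S)
    cand <- list()
    for (L in params$lengths) {
      if (p_end - S - L < p_start + S) next
      starts <- seq.int(p_start + S, p_end - S - L)
      f <- cs_f[[ch]]
      r <- cs_r[[ch]]
      f_sh <- f[starts + 1L] - f[starts - S + 1L]
      f_fp <- f[starts + L + 1L] - f[starts + 1L]
      r_fp <- r[starts + L + 1L] - r[starts + 1L]
      r_sh <- r[starts + L + S + 1L] - r[starts + L + 1L]
      sf <- binomial_shoulder_score(f_sh, f_fp, S, L)
      sr <- binomial_shoulder_score(r_sh, r_fp, S, L)
      sc <- switch(params$strand_mode,
                   both = pmin(sf, sr), forward = sf, reverse = sr)
      keep <- which(sc >= params$score_threshold)
      if (length(keep)) {
        cand[[length(cand) + 1L]] <- tibble(start = starts[keep], len = L,
                                            score = sc[keep], score_fwd = sf[keep],
                                            score_rev = sr[keep])
      }
    }
    if (!length(cand)) next
    cand <- dplyr::arrange(dplyr::bind_rows(cand),
                           dplyr::desc(.data$score), .data$start, .data$len)
    span <- p_end - p_start
    occ <- logical(span)
    taken <- 0L
    for (j in seq_len(nrow(cand))) {
      if (taken >= params$max_per_peak) break
      rel <- (cand$start[j] - p_start + 1L):(cand$start[j] + cand$len[j] - p_start)
      if (any(occ[rel])) next
      occ[rel] <- TRUE
      taken <- taken + 1L
      accepted[[length(accepted) + 1L]] <-
        tibble(peak_id = atlas$peak_id[i], chrom = ch,
               start = cand$start[j], end = cand$start[j] + cand$len[j],
               score = cand$score[j], score_fwd = cand$score_fwd[j],
               score_rev = cand$score_rev[j])
    }
  }
  out <- dplyr::bind_rows(accepted)
  if (nrow(out) == 0L) {
    return(tibble(fp_id = character(), peak_id = character(), chrom = character(),
                  start = integer(), end = integer(), score = numeric(),
                  score_fwd = numeric(), score_rev = numeric()))
  }
  out <- dplyr::arrange(out, .data$chrom, .data$start, .data$end)
  out$fp_id <- sprintf("call%05d", seq_len(nrow(out)))
  dplyr::select(out, "fp_id", dplyr::everything())
}

#' Sequencing-depth QC curve for footprinting
#'
#' Reliable footprint detection needs deep data, and raw read depth alone
#' is a poor predictor across datasets; the median peak volume (cuts in
#' the fixed peak window) is the better guide. This routine thins a
#' profile to a series of fractions of its depth (binomial thinning with
#' a fixed seed), and reports for each the median peak volume and mean
#' footprints per peak. The recommended minimum volume is the smallest
#' observed median volume that still yields at least one footprint per
#' peak on average.
#'
#' @param profile An `fg_profile`.
#' @param atlas Atlas tibble.
#' @param fractions Thinning fractions in `(0, 1]`.
#' @param params An [footprint_params()] object.
#' @param window_bp Quantification window for peak volume (default 400).
#' @param seed Integer seed for the thinning.
#' @return A tibble of class `fg_qc` with `fraction`, `total_reads`,
#'   `median_peak_volume`, `footprints_per_peak`; the recommended minimum
#'   volume (or `NA` if never reached, or for a single-point curve) is in
#'   attribute `recommended_min_volume`.
#' @export
qc_curve <- function(profile, atlas, fractions = c(0.05, 0.1, 0.25, 0.5, 1.0),
                     params = footprint_params(), window_bp = 400L, seed = 1L) {
  assert_that(all(fractions > 0 & fractions <= 1), "fractions must be in (0, 1]")
  fractions <- sort(fractions)
  rows <- lapply(seq_along(fractions), function(i) {
    thinned <- thin_profile(profile, fractions[i], seed = seed + i)
    vol <- quantify_peaks(atlas, thinned, window_bp)$count
    calls <- detect_footprints(thinned, atlas, params)
    tibble(fraction = fractions[i],
           total_reads = total_cuts(thinned),
           median_peak_volume = median(vol),
           footprints_per_peak = nrow(calls) / nrow(atlas))
  })
  out <- dplyr::bind_rows(rows)
  ok <- out$footprints_per_peak >= 1.0
  rec <- if (length(fractions) >= 2L && any(ok)) {
    min(out$median_peak_volume[ok])
  } else NA_real_
  attr(out, "recommended_min_volume") <- rec
  class(out) <- c("fg_qc", class(out))
  out
}
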