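#' Stranded DNase cut profiles
#'
#' A `fg_profile` holds per-base 5' cut counts for one sample: for every
#' chromosome, one integer vector per strand, indexed by 0-based position
#' (element `i + 1` of the vector is position `i`). This is the unit of
#' data the footprinting statistic consumes; read-level information is
#' never represented.
#'
#' @param sample_id Sample identifier.
#' @param fwd,rev Named lists of non-negative integer vectors, one per
#'   chromosome, with identical names and lengths between strands.
#' @return An object of class `fg_profile`.
#' @export
cut_profile <- function(sample_id, fwd, rev) {
  assert_that(identical(names(fwd), names(rev)),
              "forward and reverse tracks must cover the same chromosomes")
  assert_that(all(vapply(names(fwd), function(ch) length(fwd[[ch]]) == length(rev[[ch]]), logical(1))),
              "per-chromosome strand vectors must have equal length")
  for (ch in names(fwd)) {
    assert_that(all(fwd[[ch]] >= 0) && all(rev[[ch]] >= 0), "cut counts must be non-negative")
  }
  structure(list(sample_id = as.character(sample_id), fwd = fwd, rev = rev),
            class = "fg_profile")
}

#' @export
print.fg_profile <- function(x, ...) {
  cat("<fg_profile> sample:", x$sample_id,
      "| chromosomes:", length(x$fwd),
      "| total cuts:", total_cuts(x), "\n")
  invisible(x)
}

#' Total cut count of a profile (both strands)
#' @param profile An `fg_profile`.
#' @return A single number.
#' @export
total_cuts <- function(profile) {
  sum(vapply(profile$fwd, sum, numeric(1))) +
    sum(vapply(profile$rev, sum, numeric(1)))
}

#' Chromosome lengths of a profile
#' @param profile An `fg_profile`.
#' @return Named integer vector of chromosome lengths.
#' @export
chrom_lengths <- function(profile) {
  vapply(profile$fwd, length, integer(1))
}

#' Sum several cut profiles position-wise
#'
#' Used to pool samples before atlas peak calling (merging flattens
#' background noise and maximizes detection sensitivity) and to pool
#' samples of one subtype before footprinting.
#'
#' @param profiles List of `fg_profile` objects on the same chromosomes.
#' @param sample_id Identifier for the merged profile.
#' @return An `fg_profile`.
#' @export
merge_profiles <- function(profiles, sample_id = "merged") {
  assert_that(length(profiles) >= 1L, "need at least one profile to merge")
  chroms <- names(profiles[[1L]]$fwd)
  for (p in profiles) {
    assert_that(identical(names(p$fwd), chroms), "profiles must share a chromosome space")
  }
  fwd <- lapply(chroms, function(ch) Reduce(`+`, lapply(profiles, function(p) p$fwd[[ch]])))
  rev <- lapply(chroms, function(ch) Reduce(`+`, lapply(profiles, function(p) p$rev[[ch]])))
  names(fwd) <- chroms
  names(rev) <- chroms
  cut_profile(sample_id, fwd, rev)
}

#' Binomial thinning of a cut profile
#'
#' Subsamples a profile to a fraction of its depth by independently
#' keeping each cut with probability `fraction`. This is the count-space
#' equivalent of read subsampling and drives the sequencing-depth QC.
#'
#' @param profile An `fg_profile`.
#' @param fraction Keep probability in `[0, 1]`.
#' @param seed Integer seed; thinning is deterministic given the seed.
#' @return An `fg_profile`.
#' @export
thin_profile <- function(profile, fraction, seed = 1L) {
  assert_that(fraction >= 0 && fraction <= 1, "fraction must be in [0, 1]")
  if (fraction == 1) return(profile)
  withr::with_seed(as.integer(seed), {
    thin1 <- function(x) {
      out <- integer(length(x))
      nz <- which(x > 0L)
      if (length(nz)) out[nz] <- rbinom(length(nz), x[nz], fraction)
      out
    }
    fwd <- lapply(profile$fwd, thin1)
    rev <- lapply(profile$rev, thin1)
  })
  cut_profile(profile$sample_id, fwd, rev)
}

#' Write a stranded profile as a pair of bedGraph files
#'
#' One file per strand, 0-based half-open intervals, zero runs omitted,
#' adjacent equal-count positions collapsed into one record.
#'
#' @param profile An `fg_profile`.
#' @param fwd_path,rev_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_bedgraph <- function(profile, fwd_path, rev_path) {
  write1 <- function(track, path) {
    rows <- lapply(names(track), function(ch) {
      x <- track[[ch]]
      r <- rle(as.integer(x))
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths
      keep <- r$values != 0L
      if (!any(keep)) return(NULL)
      tibble(chrom = ch, start = starts[keep], end = ends[keep], count = r$values[keep])
    })
    df <- dplyr::bind_rows(rows)
    readr::write_tsv(df, path, col_names = FALSE)
    path
  }
  write1(profile$fwd, fwd_path)
  write1(profile$rev, rev_path)
  invisible(c(fwd_path, rev_path))
}

#' Read a stranded profile from a pair of bedGraph files
#'
#' @param sample_id Sample identifier for the resulting profile.
#' @param fwd_path,rev_path bedGraph files (chrom, start, end, count).
#' @param lengths Named integer vector of chromosome lengths.
#' @return An `fg_profile`.
#' @export
read_bedgraph <- function(sample_id, fwd_path, rev_path, lengths) {
  read1 <- function(path) {
    track <- lapply(lengths, function(n) integer(n))
    if (file.size(path) > 0) {
      df <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "count"),
                            col_types = "ciid", progress = FALSE)
      for (ch in unique(df$chrom)) {
        assert_that(ch %in% names(lengths), paste0("unknown chromosome in bedGraph: ", ch))
        sub <- df[df$chrom == ch, ]
        for (i in seq_len(nrow(sub))) {
          track[[ch]][(sub$start[i] + 1L):sub$end[i]] <- as.integer(sub$count[i])
        }
      }
    }
    track
  }
  cut_profile(sample_id, read1(fwd_path), read1(rev_path))
}
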