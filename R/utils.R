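#' @keywords internal
#' @noRd
assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

#' sample() without the scalar-x surprise
#' @keywords internal
#' @noRd
resample <- function(x, size = length(x)) {
  x[sample.int(length(x), size)]
}

#' Running mean with a centered window, edges truncated.
#' @keywords internal
#' @noRd
running_mean <- function(x, width) {
  if (width <= 1L) return(as.numeric(x))
  n <- length(x)
  half <- width %/% 2L
  cs <- cumsum(c(0, as.numeric(x)))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Nearest TSS lookup: distance and index of closest TSS on the same
#' chromosome; ties broken toward the lower genomic coordinate.
#'
#' Positions and TSS are 0-based. Vectorized over query positions.
#' @keywords internal
#' @noRd
nearest_tss <- function(chrom, pos, ann) {
  stopifnot(length(chrom) == length(pos))
  out_gene <- rep(NA_character_, length(pos))
  out_dist <- rep(Inf, length(pos))
  out_tss <- rep(NA_real_, length(pos))
  if (nrow(ann) == 0L) {
    return(tibble(gene_id = out_gene, distance = out_dist, tss = out_tss))
  }
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    ga <- ann[ann$chrom == ch, , drop = FALSE]
    if (nrow(ga) == 0L) next
    ord <- order(ga$tss, ga$gene_id)
    tss <- ga$tss[ord]
    ids <- ga$gene_id[ord]
    # candidate = insertion point and its left neighbour
    idx <- findInterval(pos[sel], tss)
    left <- pmax(idx, 1L)
    right <- pmin(idx + 1L, length(tss))
    dl <- abs(pos[sel] - tss[left])
    dr <- abs(pos[sel] - tss[right])
    # ties go to the lower-coordinate TSS (the left candidate)
    use_left <- (idx >= 1L) & (dl <= dr | idx >= length(tss))
    pick <- ifelse(use_left, left, right)
    out_gene[sel] <- ids[pick]
    out_tss[sel] <- tss[pick]
    out_dist[sel] <- abs(pos[sel] - tss[pick])
  }
  tibble(gene_id = out_gene, distance = out_dist, tss = out_tss)
}
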