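#' Position weight matrices
#'
#' A PWM is stored as a 4 x L probability matrix with rows A, C, G, T;
#' each column sums to 1. `new_pwm()` accepts counts or probabilities and
#' normalizes columns.
#'
#' @param name Motif name.
#' @param mat 4 x L numeric matrix (rows A, C, G, T) of counts or
#'   probabilities.
#' @param source Free-text source tag.
#' @return A list of class `fg_pwm`.
#' @export
new_pwm <- function(name, mat, source = "unknown") {
  mat <- as.matrix(mat)
  assert_that(nrow(mat) == 4L, "a PWM needs 4 rows (A, C, G, T)")
  assert_that(ncol(mat) >= 4L, "a PWM needs length >= 4")
  assert_that(all(mat >= 0), "PWM entries must be non-negative")
  cs <- colSums(mat)
  assert_that(all(cs > 0), "PWM columns must have positive mass")
  mat <- sweep(mat, 2L, cs, "/")
  dimnames(mat) <- list(c("A", "C", "G", "T"), NULL)
  structure(list(name = name, mat = mat, source = source), class = "fg_pwm")
}

#' @export
print.fg_pwm <- function(x, ...) {
  cat("<fg_pwm>", x$name, sprintf("(%d bp, consensus %s)\n", ncol(x$mat), pwm_consensus(x)))
  invisible(x)
}

#' Consensus string of a PWM (most probable base per column)
#' @param pwm An `fg_pwm`.
#' @return A character scalar.
#' @export
pwm_consensus <- function(pwm) {
  paste(rownames(pwm$mat)[apply(pwm$mat, 2L, which.max)], collapse = "")
}

#' Reverse complement of a PWM
#' @param pwm An `fg_pwm`.
#' @return An `fg_pwm` on the opposite strand.
#' @export
pwm_revcomp <- function(pwm) {
  m <- pwm$mat[c("T", "G", "C", "A"), rev(seq_len(ncol(pwm$mat))), drop = FALSE]
  rownames(m) <- c("A", "C", "G", "T")
  new_pwm(pwm$name, m, pwm$source)
}

#' Total information content of a PWM in bits
#' @param pwm An `fg_pwm`.
#' @return A single number.
#' @export
pwm_information <- function(pwm) {
  p <- pwm$mat
  sum(2 + colSums(ifelse(p > 0, p * log2(p), 0)))
}

# Column similarity used by pwm_similarity: Pearson correlation of the two
# 4-vectors; a pair of identical flat columns counts as 1, a flat column
# against an informative one as 0 (correlation is undefined there).
#' @keywords internal
#' @noRd
column_cor <- function(x, y) {
  sx <- sd(x); sy <- sd(y)
  if (sx == 0 && sy == 0) return(as.numeric(max(abs(x - y)) < 1e-9))
  if (sx == 0 || sy == 0) return(0)
  cor(x, y)
}

#' Similarity between two PWMs
#'
#' Maximum over all ungapped alignment offsets and both orientations
#' (the second PWM and its reverse complement) of the mean column-wise
#' Pearson correlation across the overlapping columns. Overlaps shorter
#' than `min_overlap` columns are not considered. The score is symmetric
#' and equals 1 for a PWM against itself or its reverse complement.
#'
#' @param a,b `fg_pwm` objects.
#' @param min_overlap Minimum overlap in columns (default 5).
#' @return A number in `[-1, 1]`.
#' @export
pwm_similarity <- function(a, b, min_overlap = 5L) {
  la <- ncol(a$mat)
  lb <- ncol(b$mat)
  assert_that(min(la, lb) >= min_overlap,
              "PWMs are too short for the required overlap")
  best <- -Inf
  for (bm in list(b$mat, pwm_revcomp(b)$mat)) {
    # offset d: column j of b aligns with column j + d of a
    for (d in seq(-(lb - min_overlap), la - min_overlap)) {
      ja <- max(1L, 1L + d):min(la, lb + d)
      jb <- ja - d
      if (length(ja) < min_overlap) next
      cc <- vapply(seq_along(ja),
                   function(i) column_cor(a$mat[, ja[i]], bm[, jb[i]]),
                   numeric(1))
      best <- max(best, mean(cc))
    }
  }
  best
}

#' Condense a redundant motif library into non-redundant families
#'
#' Whole TF families typically share essentially identical binding
#' motifs, and motif databases carry several PWMs per factor. Network
#' construction therefore uses one representative motif per group of TFs
#' binding the same motif. PWMs are joined by an edge when their
#' similarity is at least `threshold`; families are the connected
#' components; the representative is the member with the highest total
#' information content (ties to the lexicographically first name). A
#' factor with a genuinely distinctive motif (the PU.1 case among ETS
#' factors) falls below the threshold and keeps its own family.
#'
#' @param pwms List of `fg_pwm`.
#' @param tf_annotation Tibble with columns `motif`, `tf_gene`, mapping
#'   every PWM name to at least one TF gene.
#' @param threshold Similarity threshold (default 0.8).
#' @param min_overlap Passed to [pwm_similarity()].
#' @return A tibble of class `fg_catalog` with one row per family:
#'   `family_id`, `representative`, `n_members`, and list-columns
#'   `member_pwms`, `member_tf_genes`. The PWM objects ride along in the
#'   `pwms` attribute, keyed by name.
#' @export
condense_motifs <- function(pwms, tf_annotation, threshold = 0.8, min_overlap = 5L) {
  nm <- vapply(pwms, function(p) p$name, character(1))
  assert_that(!anyDuplicated(nm), "PWM names must be unique")
  missing <- setdiff(nm, tf_annotation$motif)
  assert_that(length(missing) == 0L,
              paste0("PWMs without TF annotation: ", paste(missing, collapse = ", ")))
  n <- length(pwms)
  comp <- integer(0)
  if (n > 0L) {
    adj <- diag(TRUE, n)
    if (n > 1L) {
      for (i in seq_len(n - 1L)) {
        for (j in seq((i + 1L), n)) {
          s <- pwm_similarity(pwms[[i]], pwms[[j]], min_overlap = min_overlap)
          adj[i, j] <- adj[j, i] <- s >= threshold
        }
      }
    }
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
    comp <- igraph::components(g)$membership
  }
  fams <- lapply(unique(comp), function(k) {
    idx <- which(comp == k)
    ic <- vapply(pwms[idx], pwm_information, numeric(1))
    ord <- order(-ic, nm[idx])
    rep_name <- nm[idx][ord[1L]]
    genes <- sort(unique(tf_annotation$tf_gene[tf_annotation$motif %in% nm[idx]]))
    tibble(family_id = rep_name,
           representative = rep_name,
           n_members = length(idx),
           member_pwms = list(sort(nm[idx])),
           member_tf_genes = list(genes))
  })
  out <- dplyr::arrange(dplyr::bind_rows(fams), .data$family_id)
  if (nrow(out) == 0L) {
    out <- tibble(family_id = character(), representative = character(),
                  n_members = integer(), member_pwms = list(),
                  member_tf_genes = list())
  }
  attr(out, "pwms") <- setNames(pwms, nm)
  class(out) <- c("fg_catalog", class(out))
  out
}

#' Flag expressed family members
#'
#' A member TF gene counts as expressed when its maximum FKPM over the
#' given samples is at least `min_fkpm` (inclusive). Families with no
#' expressed member are flagged inactive. Genes missing from the
#' expression table trigger a warning and are treated as unexpressed.
#'
#' @param families An `fg_catalog` tibble from [condense_motifs()].
#' @param expression Tibble with `gene_id` and one numeric column per sample.
#' @param samples Sample columns to consider (default: all).
#' @param min_fkpm Expression floor in FKPM (default 1, inclusive).
#' @return `families` with added list-column `expressed_members` and
#'   logical `active`.
#' @export
filter_expressed <- function(families, expression, samples = NULL, min_fkpm = 1.0) {
  samples <- samples %||% setdiff(names(expression), "gene_id")
  all_genes <- unique(unlist(families$member_tf_genes))
  absent <- setdiff(all_genes, expression$gene_id)
  if (length(absent)) {
    warn(paste0("TF genes absent from expression table (treated unexpressed): ",
                paste(absent, collapse = ", ")))
  }
  mx <- if (nrow(expression)) {
    apply(as.matrix(expression[, samples, drop = FALSE]), 1L, max)
  } else numeric(0)
  expressed <- expression$gene_id[mx >= min_fkpm]
  families$expressed_members <- lapply(families$member_tf_genes,
                                       function(g) intersect(g, expressed))
  families$active <- lengths(families$expressed_members) > 0L
  families
}

#' @keywords internal
#' @noRd
base_frequencies <- function(genome) {
  f <- colSums(Biostrings::letterFrequency(genome, c("A", "C", "G", "T")))
  f / sum(f)
}

#' @keywords internal
#' @noRd
logodds_matrix <- function(pwm, bg, pseudocount = 1e-3) {
  log2(sweep(pwm$mat + pseudocount, 1L, bg + pseudocount, "/"))
}

#' @keywords internal
#' @noRd
scan_sequence <- function(seq_int, lom) {
  L <- ncol(lom)
  P <- length(seq_int) - L + 1L
  if (P < 1L) return(numeric(0))
  idx <- outer(seq_len(P) - 1L, seq_len(L), "+")
  vals <- lom[cbind(as.vector(seq_int[idx]), rep(seq_len(L), each = P))]
  rowSums(matrix(vals, P, L))
}

#' Scan footprints for occupied motifs
#'
#' Each footprint interval, extended by `flank_bp`, is scanned on both
#' strands against each family's representative PWM using log-odds scores
#' against the genome base composition. A hit requires a score of at
#' least `min_logodds_fraction` of the PWM's maximum achievable score;
#' the best hit per (footprint, family) is kept.
#'
#' @param calls Tibble of footprint calls with `fp_id`, `peak_id`,
#'   `chrom`, `start`, `end` (0-based half-open).
#' @param genome A [Biostrings::DNAStringSet].
#' @param families An `fg_catalog` from [condense_motifs()].
#' @param flank_bp Extension of each footprint on both sides (default 5).
#' @param min_logodds_fraction Hit threshold as a fraction of the maximum
#'   achievable log-odds score (default 0.8).
#' @param pseudocount Probability pseudocount in the log-odds (default 1e-3).
#' @param bg Background base frequencies (default: computed from `genome`).
#' @return Tibble of motif occurrences: `fp_id`, `peak_id`, `family_id`,
#'   `chrom`, `start`, `end`, `strand`, `score`.
#' @export
scan_footprints <- function(calls, genome, families, flank_bp = 5L,
                            min_logodds_fraction = 0.8, pseudocount = 1e-3,
                            bg = NULL) {
  empty <- tibble(fp_id = character(), peak_id = character(),
                  family_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character(),
                  score = numeric())
  if (nrow(calls) == 0L) return(empty)
  bg <- bg %||% base_frequencies(genome)
  pwms <- attr(families, "pwms")
  reps <- lapply(families$representative, function(r) pwms[[r]])
  loms <- lapply(reps, logodds_matrix, bg = bg, pseudocount = pseudocount)
  loms_rc <- lapply(reps, function(p) logodds_matrix(pwm_revcomp(p), bg = bg,
                                                     pseudocount = pseudocount))
  maxsc <- vapply(loms, function(m) sum(apply(m, 2L, max)), numeric(1))
  glens <- setNames(Biostrings::width(genome), names(genome))
  base_code <- setNames(1:4, c("A", "C", "G", "T"))

  out <- vector("list", nrow(calls))
  for (i in seq_len(nrow(calls))) {
    ch <- calls$chrom[i]
    assert_that(ch %in% names(glens) && calls$start[i] >= 0 &&
                  calls$end[i] <= glens[[ch]],
                "footprint outside the genome sequence")
    s0 <- max(0L, calls$start[i] - flank_bp)
    e0 <- min(glens[[ch]], calls$end[i] + flank_bp)
    sq <- strsplit(as.character(Biostrings::subseq(genome[[ch]], s0 + 1L, e0)), "")[[1L]]
    si <- unname(base_code[sq])
    hits <- vector("list", nrow(families))
    for (k in seq_len(nrow(families))) {
      L <- ncol(loms[[k]])
      fw <- scan_sequence(si, loms[[k]])
      rc <- scan_sequence(si, loms_rc[[k]])
      if (!length(fw)) next
      sc <- pmax(fw, rc)
      best <- which.max(sc)
      if (sc[best] >= min_logodds_fraction * maxsc[k]) {
        hits[[k]] <- tibble(fp_id = calls$fp_id[i], peak_id = calls$peak_id[i],
                            family_id = families$family_id[k], chrom = ch,
                            start = s0 + best - 1L, end = s0 + best - 1L + L,
                            strand = if (fw[best] >= rc[best]) "+" else "-",
                            score = sc[best])
      }
    }
    out[[i]] <- dplyr::bind_rows(hits)
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) empty else res
}

#' Read a JASPAR-format PFM file
#'
#' Parses the common JASPAR text layout: a `>name` header followed by
#' four base rows (`A [ 1 2 3 ]` or bare numbers). Counts are normalized
#' to column probabilities.
#'
#' @param path File path.
#' @return A list of `fg_pwm`.
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  assert_that(length(heads) > 0L, "no motif headers found")
  lapply(seq_along(heads), function(i) {
    from <- heads[i]
    to <- if (i < length(heads)) heads[i + 1L] - 1L else length(lines)
    name <- sub("^>\\s*", "", lines[from])
    name <- strsplit(name, "\\s+")[[1L]][1L]
    rows <- lines[(from + 1L):to]
    assert_that(length(rows) == 4L, paste0("motif ", name, ": expected 4 base rows"))
    vals <- lapply(rows, function(r) {
      r <- sub("^\\s*[ACGTacgt]\\s*", "", r)
      r <- gsub("[][]", "", r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1L]])
    })
    assert_that(length(unique(lengths(vals))) == 1L,
                paste0("motif ", name, ": base rows differ in length"))
    new_pwm(name, do.call(rbind, vals), source = "jaspar")
  })
}

#' Write PWMs as a JASPAR-format PFM file
#' @param pwms List of `fg_pwm`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_jaspar <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$name), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s [ %s ]", b,
                         paste(format(p$mat[b, ], digits = 6), collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Write a motif-family catalog as TSV
#'
#' Columns: `family_id`, `representative_motif`, `member_tf_genes`
#' (semicolon-separated).
#' @param families An `fg_catalog`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_catalog <- function(families, path) {
  df <- tibble(family_id = families$family_id,
               representative_motif = families$representative,
               member_tf_genes = vapply(families$member_tf_genes,
                                        paste, character(1), collapse = ";"))
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a motif-family catalog from TSV
#'
#' Expects the three-column schema written by [write_catalog()]
#' (family_id, representative_motif, member_tf_genes semicolon-separated).
#' Malformed rows raise an error naming the offending line.
#'
#' @param path File path.
#' @return A tibble with `family_id`, `representative`, and list-column
#'   `member_tf_genes`.
#' @export
read_catalog <- function(path) {
  lines <- readLines(path)
  assert_that(length(lines) >= 1L, "empty catalog file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 3L)
  assert_that(length(bad) == 0L,
              paste0("malformed catalog row at line ", if (length(bad)) bad[1L] else 0L,
                     ": expected 3 tab-separated fields"))
  body <- fields[-1L]
  tibble(family_id = vapply(body, `[`, character(1), 1L),
         representative = vapply(body, `[`, character(1), 2L),
         member_tf_genes = lapply(body, function(f) {
           g <- strsplit(f[3L], ";", fixed = TRUE)[[1L]]
           g[nzchar(g)]
         }))
}

#' Summarize a motif-family catalog
#'
#' @param families An `fg_catalog` tibble or a path to a catalog TSV in
#'   the [write_catalog()] schema.
#' @return A tibble with `n_families` and `n_member_tf_genes` (distinct
#'   gene symbols across all member lists).
#' @export
summarize_catalog <- function(families) {
  if (is.character(families)) families <- read_catalog(families)
  tibble(n_families = nrow(families),
         n_member_tf_genes = length(unique(unlist(families$member_tf_genes))))
}
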