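
test_that("PWM similarity is symmetric, reflexive and orientation-blind", {
  a <- pm_pwm("a", "ACGTACGTAC", p = 0.85)
  b <- pm_pwm("b", "TTTTGGGGCC", p = 0.85)
  expect_equal(pwm_similarity(a, a), 1)
  expect_equal(pwm_similarity(a, pwm_revcomp(a)), 1)
  expect_equal(pwm_similarity(a, b), pwm_similarity(b, a))
  expect_error(pwm_similarity(pm_pwm("s", "ACGT"), a), "overlap")
})

test_that("similarity matches the exhaustive offset/orientation oracle", {
  set.seed(31)
  rand_pwm <- function(name, L) {
    m <- matrix(runif(4 * L), 4)
    new_pwm(name, m)
  }
  cases <- list(
    list(pm_pwm("acgt", "ACGTACGTACGT"), new_pwm("unif", matrix(0.25, 4, 8))),
    list(rand_pwm("r1", 12L), rand_pwm("r2", 9L)),
    list(rand_pwm("r3", 15L), rand_pwm("r4", 15L)),
    list(pm_pwm("c1", "AAACCCGGTTT", p = 0.9), rand_pwm("r5", 7L)))
  for (cs in cases) {
    expect_equal(pwm_similarity(cs[[1]], cs[[2]]),
                 brute_similarity(cs[[1]], cs[[2]]), tolerance = 1e-12)
  }
})

test_that("condensation groups shifted and reverse-complement variants", {
  a <- pm_pwm("A_base", "ACGGATTACCGT", p = 0.9)
  a_shift <- new_pwm("A_shift", cbind(rep(0.25, 4), a$mat[, 1:11]))
  a_rc <- pwm_revcomp(a)
  a_rc$name <- "A_rc"
  b <- pm_pwm("B_other", "CCCCAAAATTGG", p = 0.9)
  ann <- tibble::tibble(motif = c("A_base", "A_shift", "A_rc", "B_other"),
                        tf_gene = c("TF1", "TF2", "TF1", "TF3"))
  fams <- condense_motifs(list(a, a_shift, a_rc, b), ann)
  expect_equal(nrow(fams), 2L)
  grp_a <- fams[vapply(fams$member_pwms, function(m) "A_base" %in% m, logical(1)), ]
  expect_setequal(grp_a$member_pwms[[1]], c("A_base", "A_shift", "A_rc"))
  expect_setequal(grp_a$member_tf_genes[[1]], c("TF1", "TF2"))
  # representative has the highest information content
  expect_equal(grp_a$representative, "A_base")
  # every PWM lands in exactly one family
  expect_setequal(unlist(fams$member_pwms), c("A_base", "A_shift", "A_rc", "B_other"))
  expect_equal(sum(lengths(fams$member_pwms)), 4L)
})

test_that("condensation is invariant to input order and reverse complementation", {
  pwms <- list(pm_pwm("m1", "ACGGATTACCGT", 0.9),
               pm_pwm("m2", "ACGGATTACCGA", 0.8),
               pm_pwm("m3", "GGGGCCCCAAAA", 0.9))
  ann <- tibble::tibble(motif = c("m1", "m2", "m3"), tf_gene = c("a", "b", "c"))
  f1 <- condense_motifs(pwms, ann)
  f2 <- condense_motifs(base::rev(pwms), ann)
  expect_equal(dplyr::select(f1, -dplyr::any_of("n_members")),
               dplyr::select(f2, -dplyr::any_of("n_members")),
               ignore_attr = TRUE)
  flipped <- pwms
  flipped[[2]] <- pwm_revcomp(flipped[[2]])
  f3 <- condense_motifs(flipped, ann)
  expect_equal(f1$family_id, f3$family_id)
  expect_equal(f1$member_pwms, f3$member_pwms)
})

test_that("condensation limits behave", {
  a <- pm_pwm("solo", "ACGTTGCAAC", 0.9)
  ann <- tibble::tibble(motif = "solo", tf_gene = "TF1")
  f <- condense_motifs(list(a), ann)
  expect_equal(nrow(f), 1L)
  expect_equal(f$representative, "solo")
  pwms <- list(a, pm_pwm("twin", "ACGTTGCAAC", 0.9))
  ann2 <- tibble::tibble(motif = c("solo", "twin"), tf_gene = c("x", "y"))
  expect_equal(nrow(condense_motifs(pwms, ann2, threshold = 1.01)), 2L)
  expect_error(condense_motifs(pwms, ann), "annotation")
})

test_that("expression filtering uses an inclusive FKPM floor", {
  fams <- condense_motifs(list(pm_pwm("m", "ACGTTGCAAC", 0.9)),
                          tibble::tibble(motif = "m", tf_gene = c("TF1", "TF2")))
  expr <- tibble::tibble(gene_id = c("TF1", "TF2"), s1 = c(1.0, 0.99))
  out <- filter_expressed(fams, expr)
  expect_equal(out$expressed_members[[1]], "TF1")   # exactly 1.0 counts
  expect_true(out$active)
  zero <- filter_expressed(fams, tibble::tibble(gene_id = c("TF1", "TF2"), s1 = 0))
  expect_false(zero$active)
  expect_warning(
    filter_expressed(fams, tibble::tibble(gene_id = "TF1", s1 = 5)),
    "absent")
})

test_that("footprint scanning recovers embedded consensus sites at full score", {
  sim <- small_sim()
  truth <- sim$truth
  fams <- condense_motifs(truth$motifs$pwms, truth$motifs$tf_annotation)
  fp <- truth$footprints[1:8, ]
  calls <- tibble::tibble(fp_id = fp$fp_id, peak_id = fp$peak_id,
                          chrom = fp$chrom, start = fp$start, end = fp$end)
  occ <- scan_footprints(calls, truth$genome, fams)
  hit <- dplyr::inner_join(occ, fp, by = "fp_id", suffix = c("", ".t"))
  # the planted family is found at its planted spot for every footprint
  found <- hit[hit$family_id == hit$family_id.t, ]
  expect_equal(sort(unique(found$fp_id)), sort(fp$fp_id))
  expect_equal(found$start, found$start.t)
  expect_equal(found$strand, found$strand.t)
  expect_equal(nrow(scan_footprints(calls[0, ], truth$genome, fams)), 0L)
  bad <- calls
  bad$start[1] <- -10L
  expect_error(scan_footprints(bad, truth$genome, fams), "outside")
})

test_that("scanning agrees with a position-by-position brute-force scorer", {
  sim <- small_sim()
  truth <- sim$truth
  fams <- condense_motifs(truth$motifs$pwms, truth$motifs$tf_annotation)
  pwms <- attr(fams, "pwms")
  bg <- rep(0.25, 4)
  call <- tibble::tibble(fp_id = "x", peak_id = "pk", chrom = "chr1",
                         start = 1000L, end = 1012L)
  occ <- scan_footprints(call, truth$genome, fams, bg = bg)
  # brute force: score every window on both strands with plain loops
  seqc <- strsplit(as.character(Biostrings::subseq(truth$genome$chr1,
                                                   996L, 1017L)), "")[[1]]
  code <- setNames(1:4, c("A", "C", "G", "T"))
  for (k in seq_len(nrow(fams))) {
    p <- pwms[[fams$representative[k]]]
    lom <- log2((p$mat + 1e-3) / (bg + 1e-3))
    rcm <- log2((pwm_revcomp(p)$mat + 1e-3) / (bg + 1e-3))
    L <- ncol(lom)
    best <- -Inf
    for (s in seq_len(length(seqc) - L + 1L)) {
      idx <- code[seqc[s:(s + L - 1L)]]
      best <- max(best,
                  sum(lom[cbind(idx, seq_len(L))]),
                  sum(rcm[cbind(idx, seq_len(L))]))
    }
    row <- occ[occ$family_id == fams$family_id[k], ]
    if (nrow(row)) {
      expect_equal(row$score, best, tolerance = 1e-10)
    } else {
      expect_lt(best, 0.8 * sum(apply(lom, 2, max)))
    }
  }
})

test_that("random sequence rarely matches a point-mass 8-mer at 0.8 of max", {
  withr::with_seed(99L, {
    seqc <- paste(sample(c("A", "C", "G", "T"), 1000L, TRUE), collapse = "")
  })
  genome <- Biostrings::DNAStringSet(c(chr1 = seqc))
  fams <- condense_motifs(list(pm_pwm("m8", "ACGTACGT", p = 1)),
                          tibble::tibble(motif = "m8", tf_gene = "TF"))
  call <- tibble::tibble(fp_id = "w", peak_id = "pk", chrom = "chr1",
                         start = 5L, end = 995L)
  occ <- scan_footprints(call, genome, fams, bg = rep(0.25, 4))
  # a hit at 0.8 of max needs a near-exact 8-mer; expected count ~ 2000/4^8
  expect_lte(nrow(occ), 1L)
})

test_that("JASPAR and catalog files round-trip", {
  pwms <- list(pm_pwm("MA0001.1", "ACGTAACC", 0.7), pm_pwm("MA0002.2", "GGGTTTAA", 0.9))
  path <- withr::local_tempfile(fileext = ".pfm")
  write_jaspar(pwms, path)
  back <- read_jaspar(path)
  expect_equal(vapply(back, function(p) p$name, character(1)),
               c("MA0001.1", "MA0002.2"))
  expect_equal(back[[1]]$mat, pwms[[1]]$mat, tolerance = 1e-6)

  fams <- condense_motifs(pwms, tibble::tibble(motif = c("MA0001.1", "MA0002.2"),
                                               tf_gene = c("TFA", "TFB")))
  cpath <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(fams, cpath)
  rt <- read_catalog(cpath)
  expect_equal(rt$family_id, fams$family_id)
  expect_equal(rt$member_tf_genes, fams$member_tf_genes)
})

test_that("catalog summaries count distinct genes with set semantics", {
  fams <- tibble::tibble(family_id = c("f1", "f2"),
                         representative = c("f1", "f2"),
                         member_tf_genes = list(c("TF1", "TF2"), c("TF2", "TF3")))
  s <- summarize_catalog(fams)
  expect_equal(s$n_families, 2L)
  expect_equal(s$n_member_tf_genes, 3L)   # TF2 counted once
  empty <- summarize_catalog(tibble::tibble(family_id = character(),
                                            representative = character(),
                                            member_tf_genes = list()))
  expect_equal(c(empty$n_families, empty$n_member_tf_genes), c(0L, 0L))
  # malformed rows are reported with their line number
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("family_id\trepresentative_motif\tmember_tf_genes",
               "f1\tm1\ta;b", "broken line without tabs"), bad)
  expect_error(read_catalog(bad), "line 3")
})
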