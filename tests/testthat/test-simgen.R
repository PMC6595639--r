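test_that("sim_config validates fractions, capacity and quotas", {
  expect_s3_class(sim_config(), "fg_sim_config")
  expect_error(sim_config(hic_linked_fraction = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(n_peaks = 10000L, chrom_length = 100000L,
                          n_chromosomes = 1L), "fit")
  expect_error(sim_config(subtype_specific_fraction = 0,
                          edges_per_subtype = 3L), "planted edges")
})

test_that("annotation generation respects bounds, distinctness and the empty case", {
  cfg <- small_config()
  ann <- simulate_annotation(cfg)
  expect_equal(nrow(ann$annotation), cfg$n_genes)
  expect_false(anyDuplicated(ann$annotation$tss) > 0)
  expect_true(all(ann$annotation$tss > 0 &
                    ann$annotation$tss < cfg$chrom_length))
  expect_true(all(ann$annotation$start < ann$annotation$end))
  # empty case: no genes, genome still valid
  cfg0 <- sim_config(n_genes = 0L, n_motif_families = 0L, tfs_per_family = 0L,
                     edges_per_subtype = 0L, subtype_specific_fraction = 0,
                     promoter_peak_fraction = 0)
  ann0 <- simulate_annotation(cfg0)
  expect_equal(nrow(ann0$annotation), 0L)
  expect_equal(sum(Biostrings::width(ann0$genome)),
               cfg0$n_chromosomes * cfg0$chrom_length)
})

test_that("the same seed reproduces the genome byte for byte", {
  cfg <- small_config(seed = 123L)
  a <- simulate_annotation(cfg)
  b <- simulate_annotation(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  ta <- plant_landscape(cfg, a)
  tb <- plant_landscape(cfg, b)
  expect_identical(as.character(ta$genome), as.character(tb$genome))
  expect_identical(ta$peaks, tb$peaks)
  expect_identical(ta$edges, tb$edges)
})

test_that("planted landscape satisfies its structural invariants", {
  truth <- small_sim()$truth
  cfg <- truth$config
  # every footprint inside exactly one peak
  pk <- truth$peaks
  n_containing <- vapply(seq_len(nrow(truth$footprints)), function(i) {
    f <- truth$footprints[i, ]
    sum(pk$chrom == f$chrom & pk$start <= f$start & pk$end >= f$end)
  }, integer(1))
  expect_true(all(n_containing == 1L))
  # every edge supported by a footprint in a peak linked to its target
  for (i in seq_len(nrow(truth$edges))) {
    e <- truth$edges[i, ]
    f <- truth$footprints[truth$footprints$fp_id == e$fp_id, ]
    expect_equal(f$peak_id, e$peak_id)
    expect_equal(f$family_id, e$family_id)
    l <- truth$links[truth$links$peak_id == e$peak_id, ]
    expect_true(e$target_gene %in% l$gene_id)
  }
  # subtype partition: private quota exact, one edge family per planted edge
  priv <- table(pk$subtype[pk$subtype != "shared"])
  expect_true(all(priv == round(cfg$subtype_specific_fraction * cfg$n_peaks)))
  expect_equal(nrow(truth$edges), cfg$n_subtypes * cfg$edges_per_subtype)
})

test_that("hic-linked fraction of distal peaks matches the setting exactly", {
  truth <- small_sim()$truth
  cfg <- truth$config
  distal <- truth$peaks$peak_id[truth$peaks$location == "distal"]
  hic_peaks <- unique(truth$links$peak_id[truth$links$via == "hic"])
  frac <- length(hic_peaks) / length(distal)
  expect_lt(abs(frac - cfg$hic_linked_fraction), 1 / cfg$n_peaks + 1e-9)
  near <- truth$links$via == "hic" &
    truth$links$gene_id == nearest_planted_gene(truth)[truth$links$peak_id]
  n_hic <- sum(truth$links$via == "hic")
  expect_lt(abs(sum(near) / n_hic - cfg$nearest_gene_fraction), 1 / n_hic + 1e-9)
})

test_that("all peaks are shared when no private peaks or edges are requested", {
  cfg <- small_config(subtype_specific_fraction = 0, edges_per_subtype = 0L)
  truth <- plant_landscape(cfg, simulate_annotation(cfg))
  expect_true(all(truth$peaks$subtype == "shared"))
  expect_equal(nrow(truth$edges), 0L)
})

test_that("simulated cut totals and footprint depletion match the model", {
  sim <- small_sim()
  cfg <- sim$config
  # totals within 5 SD of the Poisson expectation
  for (p in sim$profiles) {
    expect_lt(abs(total_cuts(p) - cfg$reads_per_sample),
              5 * sqrt(cfg$reads_per_sample))
  }
  # depth 0 gives an all-zero profile
  z <- simulate_cuts(sim$truth, "z", "S1", depth = 0, seed = 1)
  expect_equal(total_cuts(z), 0)
  expect_error(simulate_cuts(sim$truth, "x", "NOPE", 100, 1), "unknown subtype")
  # empirical interior/peak cut-rate ratio converges to footprint_depletion
  deep <- simulate_cuts(sim$truth, "deep", "S1", depth = 1e7, seed = 3)
  truth <- sim$truth
  acc <- truth$peaks[truth$peaks$subtype %in% c("shared", "S1"), ]
  fp <- truth$footprints[truth$footprints$peak_id %in% acc$peak_id, ]
  track <- deep$fwd$chr1 + deep$rev$chr1
  fp_mask <- logical(length(track))
  flank_mask <- logical(length(track))
  for (i in seq_len(nrow(fp))) {
    fp_mask[(fp$start[i] + 1L):fp$end[i]] <- TRUE
    flank_mask[(fp$start[i] - cfg$flank_bp + 1L):(fp$end[i] + cfg$flank_bp)] <- TRUE
  }
  pk_mask <- logical(length(track))
  for (i in seq_len(nrow(acc))) {
    pk_mask[(acc$start[i] + 1L):acc$end[i]] <- TRUE
  }
  rate_fp <- mean(track[fp_mask])
  rate_pk <- mean(track[pk_mask & !flank_mask])
  expect_lt(abs(rate_fp / rate_pk - cfg$footprint_depletion),
            0.1 * cfg$footprint_depletion)
})

test_that("no-depletion settings erase the footprint signal", {
  cfg <- small_config(footprint_depletion = 1, flank_boost = 1)
  truth <- plant_landscape(cfg, simulate_annotation(cfg))
  prof <- simulate_cuts(truth, "s", "S1", depth = 2e6, seed = 5)
  acc <- truth$peaks[truth$peaks$subtype %in% c("shared", "S1"), ]
  fp <- truth$footprints[truth$footprints$peak_id %in% acc$peak_id, ]
  track <- prof$fwd$chr1 + prof$rev$chr1
  fp_mask <- pk_mask <- logical(length(track))
  for (i in seq_len(nrow(fp))) fp_mask[(fp$start[i] + 1L):fp$end[i]] <- TRUE
  for (i in seq_len(nrow(acc))) pk_mask[(acc$start[i] + 1L):acc$end[i]] <- TRUE
  expect_lt(abs(mean(track[fp_mask]) / mean(track[pk_mask & !fp_mask]) - 1), 0.05)
})

test_that("expression planting hits the exact means without noise", {
  cfg <- small_config(expression_noise_cv = 0, tf_upregulation_fold = 3,
                      tf_planted_fold_margin = 1)
  truth <- plant_landscape(cfg, simulate_annotation(cfg))
  md <- simulate_metadata(cfg)
  genes <- sort(truth$annotation$gene_id)
  base <- setNames(rep(2.0, length(genes)), genes)
  expr <- simulate_expression(truth, md, baseline = base)
  up_s1 <- unlist(truth$motifs$families$member_tf_genes[
    truth$motifs$families$family_id %in%
      truth$source_families$family_id[truth$source_families$subtype == "S1"]])
  s1 <- md$sample_id[md$subtype == "S1"][1L]
  ctrl <- md$sample_id[md$is_control][1L]
  expect_equal(unique(expr[[ctrl]]), 2.0)
  expect_equal(expr[[s1]][expr$gene_id %in% up_s1],
               rep(6.0, length(unique(up_s1))))
  expect_equal(expr[[s1]][!expr$gene_id %in% up_s1],
               rep(2.0, sum(!expr$gene_id %in% up_s1)))
  # empty sample sheet gives an empty table; seeded rerun is identical
  expect_equal(names(simulate_expression(truth, md[0, ])), "gene_id")
  full_cfg <- small_config()
  t2 <- plant_landscape(full_cfg, simulate_annotation(full_cfg))
  e1 <- simulate_expression(t2, md)
  e2 <- simulate_expression(t2, md)
  expect_identical(e1, e2)
})

test_that("planted motif consensus sequences are embedded in the genome", {
  truth <- small_sim()$truth
  fams <- truth$motifs$families
  for (i in seq_len(min(10L, nrow(truth$footprints)))) {
    f <- truth$footprints[i, ]
    seq <- as.character(Biostrings::subseq(truth$genome[[f$chrom]],
                                           f$start + 1L, f$end))
    cons <- fams$consensus[fams$family_id == f$family_id]
    if (f$strand == "-") {
      cons <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
    }
    expect_equal(seq, cons)
  }
})
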