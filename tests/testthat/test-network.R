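toy_families <- function() {
  condense_motifs(
    list(pm_pwm("F1", "ACGGATTACCGT", 0.9), pm_pwm("F2", "CCCCAAAATTGG", 0.9)),
    tibble::tibble(motif = c("F1", "F1", "F2", "F2"),
                   tf_gene = c("TFa", "TFb", "TFc", "TFd")))
}

toy_metadata <- tibble::tibble(
  sample_id = c("s1", "s2", "c1"),
  subtype = c("S1", "S1", "control"),
  is_control = c(FALSE, FALSE, TRUE))

test_that("upregulation uses the pseudocount fold rule, inclusively", {
  fams <- toy_families()
  expr <- tibble::tibble(gene_id = c("TFa", "TFb", "TFc", "TFd"),
                         s1 = c(6.0, 2.0, 2.0, 2.0),
                         s2 = c(6.0, 2.0, 2.0, 2.0),
                         c1 = c(2.0, 2.0, 2.0, 2.0))
  # with the 0.1 pseudocount, 6.1/2.1 = 2.905 < 3: not upregulated
  nodes_pc <- upregulated_families(expr, toy_metadata, fams, network_config())
  expect_equal(nrow(nodes_pc), 0L)
  # without the pseudocount the ratio is exactly 3.0 and counts (inclusive)
  nodes0 <- upregulated_families(expr, toy_metadata, fams,
                                 network_config(pseudocount = 0))
  expect_equal(nodes0$family_id, "F1")
  expect_equal(nodes0$upregulated_members[[1]], "TFa")
  # expressed members ride along with their expression bins
  expect_setequal(nodes0$expressed_members[[1]], c("TFa", "TFb"))
  expect_equal(unname(nodes0$expression_bins[[1]]["TFa"]), "moderate")
  expect_equal(unname(nodes0$expression_bins[[1]]["TFb"]), "low")
  # flat expression gives zero nodes; missing controls error
  flat <- expr
  flat$s1 <- flat$s2 <- flat$c1 <- 5
  expect_equal(nrow(upregulated_families(flat, toy_metadata, fams)), 0L)
  md_nc <- toy_metadata
  md_nc$is_control <- FALSE
  expect_error(upregulated_families(expr, md_nc, fams), "control")
})

toy_network_inputs <- function() {
  fams <- toy_families()
  nodes <- tibble::tibble(subtype = c("S1", "S1"), family_id = c("F1", "F2"),
                          upregulated_members = list("TFa", "TFc"),
                          expressed_members = list(c("TFa", "TFb"), "TFc"),
                          expression_bins = list(c(TFa = "high", TFb = "low"),
                                                 c(TFc = "moderate")))
  occurrences <- tibble::tibble(
    fp_id = c("fp1", "fp2", "fp3", "fp4"),
    peak_id = c("p1", "p1", "p2", "p3"),
    family_id = c("F1", "F2", "F1", "F2"),
    chrom = "chr1", start = c(100L, 130L, 500L, 900L),
    end = c(112L, 142L, 512L, 912L), strand = "+", score = 10)
  dhs <- tibble::tibble(subtype = c("S1", "S1"), peak_id = c("p1", "p2"))
  links <- tibble::tibble(peak_id = c("p1", "p2", "p3"),
                          gene_id = c("TFb", "TFd", "TFa"),
                          method = c("hic", "nearest", "hic"),
                          n_supporting_interactions = c(1L, 0L, 1L))
  list(fams = fams, nodes = nodes, occurrences = occurrences,
       dhs = dhs, links = links)
}

test_that("edge assembly equals the exhaustive rule enumeration", {
  x <- toy_network_inputs()
  # by hand: p3 is not S1-specific, so fp4 contributes nothing;
  # p1 carries F1->TFb and F2->TFb; p2 carries F1->TFd
  net <- build_edges(x$nodes, x$occurrences, x$dhs, x$links, x$fams,
                     network_config(targets = "tf_genes_only"))
  got <- dplyr::arrange(tidy(net), family_id, target_gene)
  expect_equal(got$family_id, c("F1", "F1", "F2"))
  expect_equal(got$target_gene, c("TFb", "TFd", "TFb"))
  expect_true(all(got$subtype == "S1"))
  # no nodes -> no edges
  none <- build_edges(x$nodes[0, ], x$occurrences, x$dhs, x$links, x$fams)
  expect_equal(nrow(none$edges), 0L)
  # unknown peak reference errors when an atlas is supplied
  atlas <- tibble::tibble(peak_id = c("p1", "p2"))
  expect_error(build_edges(x$nodes, x$occurrences, x$dhs, x$links, x$fams,
                           atlas = atlas), "unknown peak")
})

test_that("edges are monotone in evidence and respect the target filter", {
  x <- toy_network_inputs()
  base_net <- build_edges(x$nodes, x$occurrences, x$dhs, x$links, x$fams)
  more <- dplyr::bind_rows(x$occurrences, tibble::tibble(
    fp_id = "fp5", peak_id = "p2", family_id = "F2", chrom = "chr1",
    start = 600L, end = 612L, strand = "+", score = 10))
  more_net <- build_edges(x$nodes, more, x$dhs, x$links, x$fams)
  key <- function(n) paste(n$edges$family_id, n$edges$target_gene)
  expect_true(all(key(base_net) %in% key(more_net)))
  expect_gt(nrow(more_net$edges), nrow(base_net$edges))
  # non-TF targets only appear under targets = "all_genes"
  links2 <- x$links
  links2$gene_id[1] <- "geneX"
  tf_only <- build_edges(x$nodes, x$occurrences, x$dhs, links2, x$fams,
                         network_config(targets = "tf_genes_only"))
  all_g <- build_edges(x$nodes, x$occurrences, x$dhs, links2, x$fams,
                       network_config(targets = "all_genes"))
  expect_false("geneX" %in% tf_only$edges$target_gene)
  expect_true("geneX" %in% all_g$edges$target_gene)
})

test_that("co-occupancy counts 50-bp windows and matches the exact null", {
  cfg <- network_config(n_permutations = 4000L)
  # two occurrences 30 bp apart count; 60 bp apart do not
  occ_pair <- function(gap) {
    tibble::tibble(fp_id = c("a", "b"), peak_id = "p1",
                   family_id = c("F1", "F2"), chrom = "chr1",
                   start = c(100L, 100L + gap), end = c(112L, 112L + gap),
                   strand = "+", score = 1)
  }
  r30 <- co_occupancy(occ_pair(30L), cfg, seed = 1L)
  expect_equal(r30$observed, 1)
  r60 <- co_occupancy(occ_pair(60L), cfg, seed = 1L)
  expect_equal(r60$observed, 0)
  # 3 occurrences, 2 families: exact enumeration of label permutations.
  # mids 106, 146, 186; close pairs (1,2) and (2,3); labels A,B,A -> obs 2.
  # null: B in the middle (1/3 of arrangements) also gives 2, else 1,
  # so p converges to (1 + n/3) / (1 + n) ~ 1/3.
  occ3 <- tibble::tibble(fp_id = c("a", "b", "c"), peak_id = "p1",
                         family_id = c("A", "B", "A"), chrom = "chr1",
                         start = c(100L, 140L, 180L), end = c(112L, 152L, 192L),
                         strand = "+", score = 1)
  r3 <- co_occupancy(occ3, cfg, seed = 2L)
  expect_equal(r3$observed, 2)
  expect_equal(r3$p_value, 1 / 3, tolerance = 0.06)
  expect_equal(r3$null_mean, 4 / 3, tolerance = 0.06)
  # symmetric in the pair and invariant to occurrence order
  r3_rev <- co_occupancy(occ3[3:1, ], cfg, seed = 2L)
  expect_equal(r3_rev$observed, r3$observed)
  # fewer than 100 permutations warns; single family errors
  expect_warning(co_occupancy(occ_pair(30L), network_config(n_permutations = 10L)),
                 "permutations")
  solo <- occ_pair(30L)
  solo$family_id <- "F1"
  expect_error(co_occupancy(solo, cfg), "2 families")
})

test_that("GraphML export round-trips and rejects dangling edges", {
  x <- toy_network_inputs()
  net <- build_edges(x$nodes, x$occurrences, x$dhs, x$links, x$fams)
  gpath <- withr::local_tempfile(fileext = ".graphml")
  epath <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, gpath, epath)
  g <- igraph::read_graph(gpath, format = "graphml")
  edf <- igraph::as_data_frame(g, what = "edges")
  expect_equal(nrow(edf), nrow(net$edges))
  got <- tibble::tibble(subtype = edf$subtype,
                        family_id = sub("^.*\\|", "", edf$from),
                        target_gene = sub("^.*\\|", "", edf$to),
                        n_supporting = as.integer(edf$n_supporting)) |>
    dplyr::arrange(family_id, target_gene)
  want <- dplyr::arrange(net$edges, family_id, target_gene)
  expect_equal(got$family_id, want$family_id)
  expect_equal(got$target_gene, want$target_gene)
  expect_equal(got$n_supporting, want$n_supporting)
  # edge list TSV mirrors tidy()
  expect_equal(readr::read_tsv(epath, show_col_types = FALSE)$target_gene,
               tidy(net)$target_gene)
  # empty network still exports valid GraphML
  empty <- build_edges(x$nodes[0, ], x$occurrences[0, ], x$dhs, x$links, x$fams)
  g0 <- withr::local_tempfile(fileext = ".graphml")
  export_network(empty, g0)
  expect_equal(igraph::gorder(igraph::read_graph(g0, format = "graphml")), 0L)
  # dangling edge -> error
  broken <- net
  broken$nodes <- broken$nodes[broken$nodes$family_id != "F1", ]
  expect_error(export_network(broken, withr::local_tempfile()), "absent")
})

test_that("tidiers summarise networks and clusterings", {
  x <- toy_network_inputs()
  net <- build_edges(x$nodes, x$occurrences, x$dhs, x$links, x$fams)
  gl <- glance(net)
  expect_equal(gl$n_nodes, 2L)
  expect_equal(gl$n_edges, nrow(net$edges))
  expect_s3_class(autoplot(net), "ggplot")
  cl <- cluster_samples(small_norm_counts(), k = 3L)
  expect_s3_class(glance(cl), "tbl_df")
  expect_s3_class(autoplot(cl), "ggplot")
})
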