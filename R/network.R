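#' Network construction parameters
#'
#' @param upregulation_fold Minimum subtype/control fold change for a TF
#'   gene to count as upregulated (default 3, inclusive).
#' @param pseudocount Added to both means in the fold change so
#'   zero-control genes stay finite (default 0.1).
#' @param expressed_min_fkpm Expression floor for "expressed" members
#'   (default 1, inclusive).
#' @param bin_breaks FKPM cutpoints between low/moderate/high expression
#'   (default 3 and 20).
#' @param cooccupancy_window_bp Maximum midpoint distance for two motifs
#'   to count as co-occupied (default 50).
#' @param n_permutations Permutations for the co-occupancy null (default 1000).
#' @param fdr_alpha BH significance level (default 0.05).
#' @param targets `"tf_genes_only"` (default) restricts edges to TF-gene
#'   targets; `"all_genes"` allows any linked gene.
#' @return A list of class `fg_net_config`.
#' @export
network_config <- function(upregulation_fold = 3.0, pseudocount = 0.1,
                           expressed_min_fkpm = 1.0, bin_breaks = c(3, 20),
                           cooccupancy_window_bp = 50L, n_permutations = 1000L,
                           fdr_alpha = 0.05,
                           targets = c("tf_genes_only", "all_genes")) {
  assert_that(upregulation_fold > 1, "upregulation_fold must exceed 1")
  assert_that(cooccupancy_window_bp > 0L, "cooccupancy_window_bp must be positive")
  structure(list(upregulation_fold = upregulation_fold, pseudocount = pseudocount,
                 expressed_min_fkpm = expressed_min_fkpm, bin_breaks = bin_breaks,
                 cooccupancy_window_bp = as.integer(cooccupancy_window_bp),
                 n_permutations = as.integer(n_permutations),
                 fdr_alpha = fdr_alpha, targets = match.arg(targets)),
            class = "fg_net_config")
}

#' @keywords internal
#' @noRd
expression_bin <- function(fkpm, breaks) {
  cut(fkpm, c(-Inf, breaks, Inf), labels = c("low", "moderate", "high"),
      right = TRUE) |> as.character()
}

#' Upregulated TF families per subtype
#'
#' A TF gene is upregulated in subtype S when
#' `(mean FKPM in S + pc) / (mean control FKPM + pc) >= upregulation_fold`
#' (inclusive; `pc` is the pseudocount). A node is emitted for every
#' (subtype, family) with at least one upregulated member, and carries
#' all family members expressed in that subtype together with their
#' low/moderate/high expression bins.
#'
#' @param expression Tibble with `gene_id` plus one FKPM column per sample.
#' @param metadata Sample sheet (`sample_id`, `subtype`, `is_control`).
#' @param families An `fg_catalog` from [condense_motifs()].
#' @param config An [network_config()] object.
#' @return Node tibble: `subtype`, `family_id`, list-columns
#'   `upregulated_members`, `expressed_members`, `expression_bins`
#'   (named character vectors).
#' @export
upregulated_families <- function(expression, metadata, families,
                                 config = network_config()) {
  ctrl <- metadata$sample_id[metadata$is_control]
  assert_that(length(ctrl) >= 1L, "no control samples in the metadata")
  pc <- config$pseudocount
  mean_ctrl <- rowMeans(as.matrix(expression[, ctrl, drop = FALSE]))
  subtypes <- unique(metadata$subtype[!metadata$is_control])
  rows <- list()
  for (s in subtypes) {
    sam <- metadata$sample_id[metadata$subtype == s]
    mean_s <- rowMeans(as.matrix(expression[, sam, drop = FALSE]))
    fc <- (mean_s + pc) / (mean_ctrl + pc)
    up_genes <- expression$gene_id[fc >= config$upregulation_fold]
    expr_genes <- expression$gene_id[
      apply(as.matrix(expression[, sam, drop = FALSE]), 1L, max) >=
        config$expressed_min_fkpm]
    bins <- setNames(expression_bin(mean_s, config$bin_breaks), expression$gene_id)
    for (i in seq_len(nrow(families))) {
      members <- families$member_tf_genes[[i]]
      up <- intersect(members, intersect(up_genes, expr_genes))
      if (!length(up)) next
      expr <- intersect(members, expr_genes)
      rows[[length(rows) + 1L]] <- tibble(
        subtype = s, family_id = families$family_id[i],
        upregulated_members = list(up), expressed_members = list(expr),
        expression_bins = list(bins[expr]))
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(subtype = character(), family_id = character(),
                  upregulated_members = list(), expressed_members = list(),
                  expression_bins = list())
  }
  out
}

#' Assemble subtype-specific network edges
#'
#' An edge `family F -> gene G` exists in subtype S when at least one
#' motif occurrence of F lies inside a footprint within an S-specific DHS
#' linked to G, F is a node in S, and (under `targets = "tf_genes_only"`)
#' G is a TF gene. All supporting evidence (footprint, peak, link method)
#' is recorded; adding occurrences can only add edges.
#'
#' @param nodes Node tibble from [upregulated_families()].
#' @param occurrences Motif occurrences from [scan_footprints()]; an
#'   optional `subtype` column restricts each occurrence to the subtype
#'   whose profile it was detected in.
#' @param dhs_sets Subtype-specific DHS tibble from [subtype_specific_dhs()].
#' @param links Link tibble from [link_targets()].
#' @param families The `fg_catalog`, used for the TF-gene universe.
#' @param config An [network_config()] object.
#' @param atlas Optional atlas tibble; when given, occurrences referring
#'   to unknown peaks raise an error.
#' @return An object of class `fg_network`: list with `nodes` and `edges`
#'   (tibble: `subtype`, `family_id`, `target_gene`, `n_supporting`,
#'   list-column `supporting`).
#' @export
build_edges <- function(nodes, occurrences, dhs_sets, links, families,
                        config = network_config(), atlas = NULL) {
  if (!is.null(atlas)) {
    bad <- setdiff(unique(occurrences$peak_id), atlas$peak_id)
    assert_that(length(bad) == 0L,
                paste0("occurrences reference unknown peaks: ",
                       paste(bad, collapse = ", ")))
  }
  tf_genes <- unique(unlist(families$member_tf_genes))
  edges <- list()
  for (s in unique(nodes$subtype)) {
    fams_s <- nodes$family_id[nodes$subtype == s]
    peaks_s <- dhs_sets$peak_id[dhs_sets$subtype == s]
    occ <- occurrences
    if ("subtype" %in% names(occ)) occ <- occ[occ$subtype == s, ]
    occ <- occ[occ$peak_id %in% peaks_s & occ$family_id %in% fams_s, ]
    if (nrow(occ) == 0L) next
    hit <- dplyr::inner_join(occ, links, by = "peak_id",
                             relationship = "many-to-many")
    if (config$targets == "tf_genes_only") {
      hit <- hit[hit$gene_id %in% tf_genes, ]
    }
    if (nrow(hit) == 0L) next
    edges[[s]] <- hit |>
      dplyr::group_by(.data$family_id, .data$gene_id) |>
      dplyr::summarise(
        n_supporting = dplyr::n(),
        supporting = list(tibble(fp_id = fp_id, peak_id = peak_id,
                                 method = method)),
        .groups = "drop") |>
      dplyr::transmute(subtype = s, family_id = .data$family_id,
                       target_gene = .data$gene_id, .data$n_supporting,
                       .data$supporting)
  }
  edges <- dplyr::bind_rows(edges)
  if (nrow(edges) == 0L) {
    edges <- tibble(subtype = character(), family_id = character(),
                    target_gene = character(), n_supporting = integer(),
                    supporting = list())
  }
  structure(list(nodes = nodes, edges = edges, config = config),
            class = "fg_network")
}

#' @export
print.fg_network <- function(x, ...) {
  cat("<fg_network>", nrow(x$nodes), "nodes |", nrow(x$edges), "edges |",
      length(unique(x$nodes$subtype)), "subtype(s)\n")
  invisible(x)
}

#' Score a network against the planted truth
#'
#' Precision and recall of recovered edges against the generator's
#' planted `(family, target gene, subtype)` triples.
#'
#' @param network An `fg_network`.
#' @param truth An `fg_truth`.
#' @return One-row tibble: `n_true`, `n_called`, `n_correct`,
#'   `precision`, `recall`.
#' @export
evaluate_network <- function(network, truth) {
  key <- function(df, f, g, s) paste(df[[f]], df[[g]], df[[s]], sep = "\r")
  true_keys <- unique(key(truth$edges, "family_id", "target_gene", "subtype"))
  call_keys <- unique(key(network$edges, "family_id", "target_gene", "subtype"))
  n_correct <- length(intersect(true_keys, call_keys))
  tibble(n_true = length(true_keys), n_called = length(call_keys),
         n_correct = n_correct,
         precision = if (length(call_keys)) n_correct / length(call_keys) else NA_real_,
         recall = if (length(true_keys)) n_correct / length(true_keys) else NA_real_)
}

#' Motif co-occupancy permutation test
#'
#' TFs that cooperate leave occupied motifs close together: the observed
#' statistic for a family pair is the number of occurrence pairs in the
#' same peak whose midpoints lie within `cooccupancy_window_bp`. The null
#' permutes family labels across occurrences within each peak (preserving
#' per-peak occupancy density and per-family totals); the empirical
#' p-value is `(1 + #null >= observed) / (1 + n_permutations)`, BH-adjusted
#' across pairs. Pairs of distinct families present in the occurrence set
#' are tested; with an occurrence `subtype` column the test runs per
#' subtype.
#'
#' @param occurrences Occurrence tibble (`peak_id`, `family_id`, `start`,
#'   `end`, optional `subtype`).
#' @param config An [network_config()] object.
#' @param seed Integer seed for the permutations.
#' @return Tibble: `subtype`, `family_a`, `family_b`, `observed`,
#'   `null_mean`, `p_value`, `q_value`.
#' @export
co_occupancy <- function(occurrences, config = network_config(), seed = 1L) {
  if (config$n_permutations < 100L) {
    warn("fewer than 100 permutations gives a coarse empirical null")
  }
  if (!"subtype" %in% names(occurrences)) occurrences$subtype <- "all"
  out <- lapply(unique(occurrences$subtype), function(s) {
    occ <- occurrences[occurrences$subtype == s, ]
    fams <- sort(unique(occ$family_id))
    assert_that(length(fams) >= 2L,
                "co-occupancy needs occurrences from at least 2 families")
    mid <- (occ$start + occ$end) / 2
    # positional pairs are fixed; permutations only relabel them
    prs <- list()
    for (pk in unique(occ$peak_id)) {
      idx <- which(occ$peak_id == pk)
      if (length(idx) < 2L) next
      cmb <- utils::combn(idx, 2L)
      close <- abs(mid[cmb[1L, ]] - mid[cmb[2L, ]]) <= config$cooccupancy_window_bp
      if (any(close)) prs[[pk]] <- cmb[, close, drop = FALSE]
    }
    pair_key <- function(f1, f2) paste(pmin(f1, f2), pmax(f1, f2), sep = "\r")
    all_pairs <- utils::combn(fams, 2L)
    keys <- pair_key(all_pairs[1L, ], all_pairs[2L, ])
    count_pairs <- function(labels) {
      cnt <- setNames(numeric(length(keys)), keys)
      for (m in prs) {
        f1 <- labels[m[1L, ]]
        f2 <- labels[m[2L, ]]
        same <- f1 == f2
        if (all(same)) next
        k <- pair_key(f1[!same], f2[!same])
        tb <- table(k)
        cnt[names(tb)] <- cnt[names(tb)] + as.numeric(tb)
      }
      cnt
    }
    obs <- count_pairs(occ$family_id)
    peak_of <- occ$peak_id
    null_ge <- numeric(length(keys))
    null_sum <- numeric(length(keys))
    withr::with_seed(as.integer(seed), {
      for (b in seq_len(config$n_permutations)) {
        perm <- occ$family_id
        for (pk in unique(peak_of)) {
          idx <- which(peak_of == pk)
          if (length(idx) > 1L) perm[idx] <- perm[resample(idx)]
        }
        nc <- count_pairs(perm)
        null_ge <- null_ge + (nc >= obs)
        null_sum <- null_sum + nc
      }
    })
    p <- (1 + null_ge) / (1 + config$n_permutations)
    tibble(subtype = s, family_a = all_pairs[1L, ], family_b = all_pairs[2L, ],
           observed = unname(obs), null_mean = unname(null_sum) / config$n_permutations,
           p_value = unname(p), q_value = p.adjust(unname(p), method = "BH"))
  })
  dplyr::bind_rows(out)
}

#' Export a network as GraphML and a TSV edge list
#'
#' Family nodes carry their subtype, upregulated and expressed members,
#' and per-member expression bins; gene nodes are added per subtype.
#' Edges referencing a family absent from the node table raise an error.
#' The GraphML file round-trips through [igraph::read_graph()].
#'
#' @param network An `fg_network`.
#' @param graphml_path,edgelist_path Output paths (either may be `NULL`).
#' @return Invisibly, the written paths.
#' @export
export_network <- function(network, graphml_path = NULL, edgelist_path = NULL) {
  nodes <- network$nodes
  edges <- network$edges
  dangling <- setdiff(paste(edges$subtype, edges$family_id),
                      paste(nodes$subtype, nodes$family_id))
  assert_that(length(dangling) == 0L,
              paste0("edges reference families absent from the node set: ",
                     paste(dangling, collapse = "; ")))
  if (!is.null(edgelist_path)) {
    readr::write_tsv(tidy(network), edgelist_path)
  }
  if (!is.null(graphml_path)) {
    vfam <- tibble(
      name = paste(nodes$subtype, nodes$family_id, sep = "|"),
      type = "family", subtype = nodes$subtype, label = nodes$family_id,
      upregulated = vapply(nodes$upregulated_members, paste, character(1), collapse = ";"),
      expressed = vapply(nodes$expressed_members, paste, character(1), collapse = ";"),
      expression_bins = vapply(nodes$expression_bins, function(b) {
        paste(names(b), b, sep = ":", collapse = ";")
      }, character(1)))
    vgene <- if (nrow(edges)) {
      dplyr::distinct(tibble(
        name = paste(edges$subtype, edges$target_gene, sep = "|"),
        type = "gene", subtype = edges$subtype, label = edges$target_gene,
        upregulated = "", expressed = "", expression_bins = ""))
    } else vfam[0, ]
    verts <- dplyr::distinct(dplyr::bind_rows(vfam, vgene), .data$name,
                             .keep_all = TRUE)
    edf <- if (nrow(edges)) {
      data.frame(from = paste(edges$subtype, edges$family_id, sep = "|"),
                 to = paste(edges$subtype, edges$target_gene, sep = "|"),
                 subtype = edges$subtype, n_supporting = edges$n_supporting,
                 stringsAsFactors = FALSE)
    } else data.frame(from = character(), to = character(),
                      subtype = character(), n_supporting = integer())
    g <- igraph::graph_from_data_frame(edf, directed = TRUE,
                                       vertices = as.data.frame(verts))
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(c(graphml_path, edgelist_path))
}
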