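#' Pipeline configuration
#'
#' Bundles the per-stage settings of the whole run. Every tunable
#' constant (the 400-bp window, the rank-16000 normalization anchor, the
#' threefold upregulation cutoff, the 50-bp co-occupancy window, ...)
#' lives here, never hard-coded in stage logic.
#'
#' @param seed Global integer seed for the run.
#' @param sim An [sim_config()]; used when `input_dir` is `NULL`.
#' @param input_dir Optional directory of study inputs in the
#'   [write_study()] layout; when given, no data are simulated.
#' @param window_bp Fixed quantification window (default 400).
#' @param norm_rank,norm_rank_fraction Ranked-peak normalization anchor.
#' @param promoter_margin_bp Distal/promoter cutoff and promoter
#'   half-width for linking (default 2000).
#' @param dhs_fold,dhs_presence_fraction,dhs_min_signal Subtype-specific
#'   DHS thresholds.
#' @param cluster_k Flat clusters to cut; default: number of subtypes
#'   plus one for controls.
#' @param footprint An [footprint_params()] object.
#' @param motif_threshold,motif_min_overlap Motif condensation settings.
#' @param scan_flank_bp,scan_min_logodds_fraction Footprint motif-scan
#'   settings.
#' @param network An [network_config()] object.
#' @param run_qc Whether to compute the depth-QC curve (default FALSE).
#' @param qc_fractions Thinning fractions for the QC curve.
#' @return A list of class `fg_pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = sim_config(seed = seed),
                            input_dir = NULL,
                            window_bp = 400L,
                            norm_rank = 16000L,
                            norm_rank_fraction = 0.125,
                            promoter_margin_bp = 2000L,
                            dhs_fold = 2.0,
                            dhs_presence_fraction = 0.5,
                            dhs_min_signal = 1.0,
                            cluster_k = NULL,
                            footprint = footprint_params(),
                            motif_threshold = 0.8,
                            motif_min_overlap = 5L,
                            scan_flank_bp = 5L,
                            scan_min_logodds_fraction = 0.8,
                            network = network_config(),
                            run_qc = FALSE,
                            qc_fractions = c(0.05, 0.1, 0.25, 0.5, 1.0)) {
  structure(as.list(environment()), class = "fg_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; `sim`,
#' `footprint` and `network` may be given as nested maps of their
#' constructor arguments.
#'
#' @param path YAML file.
#' @return An `fg_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (nested in c("sim", "footprint", "network")) {
    if (!is.null(y[[nested]])) {
      ctor <- switch(nested, sim = sim_config, footprint = footprint_params,
                     network = network_config)
      y[[nested]] <- do.call(ctor, y[[nested]])
    }
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  assert_that(length(unknown) == 0L,
              paste0("unknown pipeline config key(s): ", paste(unknown, collapse = ", ")))
  do.call(pipeline_config, y)
}

#' @keywords internal
#' @noRd
run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  })
}

#' Run the full pipeline
#'
#' Executes the stages in dependency order: simulate (or load) the study,
#' call the merged-profile DHS atlas, quantify and normalize on fixed
#' windows, cluster samples on distal peaks, call subtype-specific DHS
#' subsets, footprint each subtype's pooled profile, condense the motif
#' library and scan footprints for occupied motifs, link distal DHSs to
#' genes (promoter-capture first, nearest-gene fallback), and assemble
#' the subtype networks with the co-occupancy test. All outputs are
#' written under `outdir` together with a JSON manifest of file
#' checksums and parameters; a fixed seed makes the run byte-identical.
#'
#' @param config An [pipeline_config()] object.
#' @param outdir Output directory.
#' @return An object of class `fg_pipeline` with all stage results and
#'   the manifest.
#' @export
run_pipeline <- function(config, outdir) {
  assert_that(inherits(config, "fg_pipeline_config"), "config must be a pipeline_config()")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  sim <- NULL
  truth <- NULL
  if (is.null(config$input_dir)) {
    study <- run_stage("simulate", {
      sim <- simulate_study(config$sim)
      write_study(sim, file.path(outdir, "sim"))
      truth <- sim$truth
      list(annotation = sim$annotation, genome = truth$genome,
           metadata = sim$metadata, profiles = sim$profiles,
           expression = sim$expression, interactions = truth$interactions,
           pwms = truth$motifs$pwms, tf_annotation = truth$motifs$tf_annotation)
    })
  } else {
    study <- run_stage("validate-inputs", read_study(config$input_dir))
  }

  atlas <- run_stage("atlas", call_peaks(study$profiles))
  atlas <- run_stage("atlas",
                     classify_distal(atlas, study$annotation,
                                     config$promoter_margin_bp))
  counts <- run_stage("quantify",
                      build_count_matrix(atlas, study$profiles, config$window_bp))
  norm <- run_stage("normalize",
                    normalize_rank(counts, config$norm_rank, config$norm_rank_fraction))
  k <- config$cluster_k %||%
    (length(unique(study$metadata$subtype[!study$metadata$is_control])) +
       as.integer(any(study$metadata$is_control)))
  clustering <- run_stage("cluster",
                          cluster_samples(norm, atlas$peak_id[atlas$distal], k = k))
  dhs_sets <- run_stage("subtype-dhs",
                        subtype_specific_dhs(norm, study$metadata,
                                             fold = config$dhs_fold,
                                             presence_fraction = config$dhs_presence_fraction,
                                             min_signal = config$dhs_min_signal))

  subtypes <- unique(study$metadata$subtype[!study$metadata$is_control])
  calls <- run_stage("footprint", {
    dplyr::bind_rows(lapply(subtypes, function(s) {
      pooled <- merge_profiles(study$profiles[study$metadata$sample_id[
        study$metadata$subtype == s]], sample_id = s)
      cbind_subtype <- detect_footprints(pooled, atlas, config$footprint)
      cbind_subtype$subtype <- s
      cbind_subtype
    }))
  })

  families <- run_stage("motif-catalog", {
    fam <- condense_motifs(study$pwms, study$tf_annotation,
                           threshold = config$motif_threshold,
                           min_overlap = config$motif_min_overlap)
    filter_expressed(fam, study$expression,
                     min_fkpm = config$network$expressed_min_fkpm)
  })

  occurrences <- run_stage("motif-scan", {
    dplyr::bind_rows(lapply(subtypes, function(s) {
      oc <- scan_footprints(calls[calls$subtype == s, ], study$genome, families,
                            flank_bp = config$scan_flank_bp,
                            min_logodds_fraction = config$scan_min_logodds_fraction)
      if (nrow(oc)) oc$subtype <- s
      oc
    }))
  })

  distal <- atlas[atlas$distal, ]
  links <- run_stage("link",
                     link_targets(distal, study$interactions, study$annotation,
                                  config$promoter_margin_bp))
  stats <- run_stage("link-stats",
                     link_stats(links, distal, study$annotation,
                                deregulated_ids = dhs_sets$peak_id))

  nodes <- run_stage("network",
                     upregulated_families(study$expression, study$metadata,
                                          families, config$network))
  network <- run_stage("network",
                       build_edges(nodes, occurrences, dhs_sets, links,
                                   families, config$network, atlas = atlas))
  cooc <- run_stage("co-occupancy", {
    if (nrow(occurrences) && length(unique(occurrences$family_id)) >= 2L) {
      co_occupancy(occurrences, config$network, seed = config$seed)
    } else {
      tibble(subtype = character(), family_a = character(), family_b = character(),
             observed = numeric(), null_mean = numeric(), p_value = numeric(),
             q_value = numeric())
    }
  })

  qc <- NULL
  if (isTRUE(config$run_qc)) {
    qc <- run_stage("qc", {
      pooled <- merge_profiles(study$profiles[study$metadata$sample_id[
        study$metadata$subtype == subtypes[1L]]], sample_id = subtypes[1L])
      qc_curve(pooled, atlas, config$qc_fractions, config$footprint,
               config$window_bp, seed = config$seed)
    })
  }

  manifest <- run_stage("export", {
    p <- function(f) file.path(outdir, f)
    write_bed6(atlas, p("atlas.bed"), name = "peak_id")
    readr::write_tsv(norm, p("count_matrix_normalized.tsv"))
    readr::write_tsv(dhs_sets, p("subtype_dhs.tsv"))
    write_bed6(dplyr::mutate(calls,
                             score = pmin(round(.data$score * 10), 1000)),
               p("footprints.bed"), name = "fp_id", score = "score")
    readr::write_tsv(occurrences, p("occurrences.tsv"))
    readr::write_tsv(links, p("links.tsv"))
    jsonlite::write_json(as.list(stats), p("link_stats.json"),
                         auto_unbox = TRUE, digits = NA)
    write_catalog(families, p("motif_catalog.tsv"))
    export_network(network, p("network.graphml"), p("network_edges.tsv"))
    readr::write_tsv(cooc, p("co_occupancy.tsv"))
    readr::write_tsv(tidy(clustering), p("sample_clusters.tsv"))
    if (!is.null(qc)) readr::write_tsv(tidy(qc), p("qc_curve.tsv"))
    files <- sort(setdiff(list.files(outdir, recursive = TRUE, full.names = TRUE),
                          file.path(outdir, "manifest.json")))
    manifest <- list(
      package = "footgrn",
      version = as.character(utils::packageVersion("footgrn")),
      seed = config$seed,
      parameters = list(window_bp = config$window_bp,
                        norm_rank = config$norm_rank,
                        promoter_margin_bp = config$promoter_margin_bp,
                        upregulation_fold = config$network$upregulation_fold,
                        cooccupancy_window_bp = config$network$cooccupancy_window_bp,
                        footprint_score_threshold = config$footprint$score_threshold),
      files = tibble(path = sub(paste0("^", outdir, "/?"), "", files),
                     md5 = unname(tools::md5sum(files))))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest
  })

  structure(list(config = config, sim = sim, truth = truth, study = study,
                 atlas = atlas, counts = counts, normalized = norm,
                 clustering = clustering, dhs_sets = dhs_sets, calls = calls,
                 families = families, occurrences = occurrences, links = links,
                 link_stats = stats, nodes = nodes, network = network,
                 co_occupancy = cooc, qc = qc, manifest = manifest),
            class = "fg_pipeline")
}

#' @export
print.fg_pipeline <- function(x, ...) {
  cat("<fg_pipeline>", nrow(x$atlas), "atlas peaks |", nrow(x$calls),
      "footprint calls |", nrow(x$network$edges), "network edges\n")
  invisible(x)
}
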