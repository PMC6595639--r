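#' Configuration for the synthetic regulatory landscape generator
#'
#' Returns the generator settings with defaults matching the study
#' conditions the package is tested under: a small genome carrying a
#' planted regulatory landscape whose statistical structure mirrors what
#' the pipeline assumes in real DNase data — peaks of elevated cut
#' density, footprint-shaped strand-imbalanced depletions at planted
#' motif instances, subtype-private peak subsets, at-least-threefold TF
#' upregulation per subtype, and a promoter-capture interaction file
#' covering a configurable fraction of distal peaks.
#'
#' @param seed Global integer seed. Per-sample random streams are derived
#'   deterministically from it, so adding samples never perturbs existing
#'   ones.
#' @param n_chromosomes,chrom_length Genome shape (all chromosomes share
#'   one length, in bp).
#' @param n_genes Number of genes with distinct TSS.
#' @param n_peaks Number of planted accessible regions.
#' @param n_subtypes Number of mutation subtypes.
#' @param samples_per_subtype,n_control_samples Cohort shape.
#' @param reads_per_sample Expected total 5' cuts per sample (both strands).
#' @param peak_width Peak width in bp (default 400, the fixed
#'   quantification window width).
#' @param footprint_depletion Cut-rate multiplier inside a footprint,
#'   in `[0, 1]`; 1 means no footprint signal.
#' @param background_rate Relative cut rate per bp outside peaks; only the
#'   ratio to the peak rate matters because rates are rescaled to
#'   `reads_per_sample`.
#' @param peak_enrichment Peak cut rate as a multiple of `background_rate`.
#' @param flank_boost Multiplier applied to the strand-specific 35-bp
#'   shoulders flanking each footprint (forward cuts pile up in the
#'   upstream flank, reverse cuts in the downstream flank).
#' @param flank_bp Width of the boosted footprint shoulders.
#' @param subtype_specific_fraction Fraction of all peaks private to each
#'   subtype.
#' @param promoter_peak_fraction Fraction of peaks placed at promoters;
#'   the rest are distal (>= 2 kb from any TSS).
#' @param hic_linked_fraction Fraction of distal peaks given a
#'   promoter-capture interaction (default 0.85).
#' @param nearest_gene_fraction Fraction of interactions whose promoter
#'   end is the nearest gene (default 0.5).
#' @param tf_upregulation_fold Minimum fold change of planted upregulated
#'   TF genes over control (default 3).
#' @param tf_planted_fold_margin Multiplier above
#'   `tf_upregulation_fold` at which upregulated TFs are actually planted;
#'   upregulation is "at least" the fold, and planting exactly at the fold
#'   would sit on the detection boundary.
#' @param expression_noise_cv Coefficient of variation of multiplicative
#'   lognormal expression noise.
#' @param n_motif_families,tfs_per_family,motif_length Motif library
#'   shape: families of near-identical PWMs, each annotated to
#'   `tfs_per_family` TF genes.
#' @param edges_per_subtype Planted regulatory edges per subtype.
#' @param footprints_per_peak Planted motif instances per peak (the extra
#'   instances beyond the planted-edge ones use families that can never
#'   generate false edges in that peak's subtype).
#' @return A validated list of class `fg_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length = 500000L,
                       n_genes = 80L,
                       n_peaks = 240L,
                       n_subtypes = 2L,
                       samples_per_subtype = 3L,
                       n_control_samples = 2L,
                       reads_per_sample = 1e6,
                       peak_width = 400L,
                       footprint_depletion = 0.1,
                       background_rate = 0.05,
                       peak_enrichment = 50,
                       flank_boost = 3,
                       flank_bp = 35L,
                       subtype_specific_fraction = 0.25,
                       promoter_peak_fraction = 0.2,
                       hic_linked_fraction = 0.85,
                       nearest_gene_fraction = 0.5,
                       tf_upregulation_fold = 3.0,
                       tf_planted_fold_margin = 1.5,
                       expression_noise_cv = 0.2,
                       n_motif_families = 8L,
                       tfs_per_family = 2L,
                       motif_length = 12L,
                       edges_per_subtype = 3L,
                       footprints_per_peak = 2L) {
  cfg <- structure(as.list(environment()), class = "fg_sim_config")
  validate_sim_config(cfg)
  cfg
}

#' @keywords internal
#' @noRd
validate_sim_config <- function(cfg) {
  fr <- c("footprint_depletion", "subtype_specific_fraction", "promoter_peak_fraction",
          "hic_linked_fraction", "nearest_gene_fraction")
  for (f in fr) {
    assert_that(cfg[[f]] >= 0 && cfg[[f]] <= 1, paste0(f, " must be in [0, 1]"))
  }
  assert_that(cfg$n_peaks * cfg$peak_width < cfg$n_chromosomes * cfg$chrom_length,
              "planted peaks do not fit on the genome")
  assert_that(cfg$peak_width %% 2L == 0L && cfg$peak_width > 0L,
              "peak_width must be even and positive")
  n_private <- round(cfg$subtype_specific_fraction * cfg$n_peaks)
  n_prom <- round(cfg$promoter_peak_fraction * cfg$n_peaks)
  assert_that(cfg$n_subtypes * n_private + n_prom <= cfg$n_peaks,
              "requested private peaks exceed n_peaks")
  assert_that(n_private >= cfg$edges_per_subtype,
              "private peaks per subtype must cover the planted edges")
  n_tf <- cfg$n_motif_families * cfg$tfs_per_family
  assert_that(cfg$n_genes >= n_tf, "n_genes must cover the TF genes")
  assert_that(cfg$reads_per_sample >= 0, "reads_per_sample must be non-negative")
  invisible(cfg)
}

#' @export
print.fg_sim_config <- function(x, ...) {
  cat("<fg_sim_config>",
      sprintf("genome %d x %d bp | %d genes | %d peaks | %d subtypes x %d samples + %d controls | depth %g",
              x$n_chromosomes, x$chrom_length, x$n_genes, x$n_peaks,
              x$n_subtypes, x$samples_per_subtype, x$n_control_samples,
              x$reads_per_sample), "\n")
  invisible(x)
}
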