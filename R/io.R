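#' Write intervals as BED6
#'
#' 0-based half-open coordinates, native BED convention.
#'
#' @param df Tibble with `chrom`, `start`, `end`; optional name, score and
#'   strand sources.
#' @param path Output path.
#' @param name,score,strand Column names to use for BED fields 4-6
#'   (missing ones are written as `.`/`0`).
#' @return Invisibly, `path`.
#' @export
write_bed6 <- function(df, path, name = NULL, score = NULL, strand = NULL) {
  bed <- tibble(chrom = df$chrom, start = df$start, end = df$end,
                name = if (is.null(name)) "." else df[[name]],
                score = if (is.null(score)) 0 else df[[score]],
                strand = if (is.null(strand)) "." else df[[strand]])
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read a BED6 file
#' @param path File path.
#' @return Tibble with `chrom`, `start`, `end`, `name`, `score`, `strand`.
#' @export
read_bed6 <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                      "score", "strand"),
                  col_types = "ciicdc", progress = FALSE)
}

#' Write interactions as BEDPE
#' @param interactions Tibble with `chrom1`, `start1`, `end1`, `chrom2`,
#'   `start2`, `end2`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bedpe <- function(interactions, path) {
  readr::write_tsv(interactions[, c("chrom1", "start1", "end1",
                                    "chrom2", "start2", "end2")],
                   path, col_names = FALSE)
  invisible(path)
}

#' Read a BEDPE file
#' @param path File path.
#' @return Tibble with the six anchor columns.
#' @export
read_bedpe <- function(path) {
  if (file.size(path) == 0) {
    return(tibble(chrom1 = character(), start1 = integer(), end1 = integer(),
                  chrom2 = character(), start2 = integer(), end2 = integer()))
  }
  readr::read_tsv(path, col_names = c("chrom1", "start1", "end1",
                                      "chrom2", "start2", "end2"),
                  col_types = "ciicii", progress = FALSE)
}

#' Write a simulated study to disk
#'
#' Writes genome FASTA, gene annotation TSV, true peaks and footprints as
#' BED6 (name = owning subtype / motif family), interactions as BEDPE,
#' expression and metadata TSVs, the motif library as a JASPAR-format PFM
#' file with its TF-gene annotation TSV, per-sample stranded bedGraph
#' pairs, and the planted truth as JSON.
#'
#' @param sim An `fg_sim` from [simulate_study()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named character vector of written paths.
#' @export
write_study <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  truth <- sim$truth
  Biostrings::writeXStringSet(truth$genome, p("genome.fa"))
  readr::write_tsv(sim$annotation, p("annotation.tsv"))
  write_bed6(truth$peaks, p("true_peaks.bed"), name = "subtype")
  write_bed6(truth$footprints, p("true_footprints.bed"),
             name = "family_id", strand = "strand")
  write_bedpe(truth$interactions, p("interactions.bedpe"))
  readr::write_tsv(sim$expression, p("expression.tsv"))
  readr::write_tsv(sim$metadata, p("metadata.tsv"))
  write_jaspar(truth$motifs$pwms, p("motifs.pfm"))
  readr::write_tsv(truth$motifs$tf_annotation, p("motif_tf_annotation.tsv"))
  for (nm in names(sim$profiles)) {
    write_bedgraph(sim$profiles[[nm]],
                   p(paste0(nm, ".fwd.bedGraph")), p(paste0(nm, ".rev.bedGraph")))
  }
  jsonlite::write_json(
    list(config = unclass(sim$config),
         chrom_lengths = as.list(truth$chrom_lengths),
         peaks = truth$peaks, footprints = truth$footprints,
         edges = truth$edges, links = truth$links,
         source_families = truth$source_families),
    p("truth.json"), auto_unbox = TRUE, digits = NA)
  files <- c(genome = p("genome.fa"), annotation = p("annotation.tsv"),
             true_peaks = p("true_peaks.bed"),
             true_footprints = p("true_footprints.bed"),
             interactions = p("interactions.bedpe"),
             expression = p("expression.tsv"), metadata = p("metadata.tsv"),
             motifs = p("motifs.pfm"),
             motif_tf_annotation = p("motif_tf_annotation.tsv"),
             truth = p("truth.json"))
  invisible(files)
}

#' Read a study written by [write_study()]
#'
#' Validates that every required file exists before reading anything and
#' reconstructs the inputs the pipeline consumes.
#'
#' @param dir Directory written by [write_study()].
#' @return A list with `annotation`, `genome`, `chrom_lengths`,
#'   `metadata`, `profiles`, `expression`, `interactions`, `pwms`,
#'   `tf_annotation`.
#' @export
read_study <- function(dir) {
  req <- c("genome.fa", "annotation.tsv", "interactions.bedpe",
           "expression.tsv", "metadata.tsv", "motifs.pfm",
           "motif_tf_annotation.tsv")
  missing <- req[!file.exists(file.path(dir, req))]
  assert_that(length(missing) == 0L,
              paste0("missing study input file(s): ", paste(missing, collapse = ", ")))
  p <- function(f) file.path(dir, f)
  genome <- Biostrings::readDNAStringSet(p("genome.fa"))
  names(genome) <- sub("\\s.*$", "", names(genome))
  lens <- setNames(Biostrings::width(genome), names(genome))
  metadata <- readr::read_tsv(p("metadata.tsv"), col_types = "ccl", progress = FALSE)
  bgs <- c(paste0(metadata$sample_id, ".fwd.bedGraph"),
           paste0(metadata$sample_id, ".rev.bedGraph"))
  missing_bg <- bgs[!file.exists(file.path(dir, bgs))]
  assert_that(length(missing_bg) == 0L,
              paste0("missing cut-profile file(s): ", paste(missing_bg, collapse = ", ")))
  profiles <- lapply(metadata$sample_id, function(s) {
    read_bedgraph(s, p(paste0(s, ".fwd.bedGraph")), p(paste0(s, ".rev.bedGraph")), lens)
  })
  names(profiles) <- metadata$sample_id
  list(annotation = readr::read_tsv(p("annotation.tsv"), col_types = "cciici",
                                    progress = FALSE),
       genome = genome, chrom_lengths = lens, metadata = metadata,
       profiles = profiles,
       expression = readr::read_tsv(p("expression.tsv"), progress = FALSE,
                                    show_col_types = FALSE),
       interactions = read_bedpe(p("interactions.bedpe")),
       pwms = read_jaspar(p("motifs.pfm")),
       tf_annotation = readr::read_tsv(p("motif_tf_annotation.tsv"),
                                       col_types = "cc", progress = FALSE))
}
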