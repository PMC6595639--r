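#' Simulate a genome and gene annotation
#'
#' Draws a random genome of `n_chromosomes` x `chrom_length` bp and places
#' `n_genes` genes with distinct, well-separated TSS (0-based half-open
#' coordinates, 1-kb gene bodies). Motif instances are embedded later by
#' [plant_landscape()], which returns the updated genome.
#'
#' @param config An [sim_config()] object.
#' @return A list with `annotation` (tibble: gene_id, chrom, start, end,
#'   strand, tss), `genome` (a [Biostrings::DNAStringSet]), and
#'   `chrom_lengths` (named integer vector).
#' @export
simulate_annotation <- function(config) {
  validate_sim_config(config)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  lens <- setNames(rep(config$chrom_length, config$n_chromosomes), chroms)
  withr::with_seed(config$seed, {
    genome <- Biostrings::DNAStringSet(setNames(vapply(chroms, function(ch) {
      paste(sample(c("A", "C", "G", "T"), config$chrom_length, replace = TRUE),
            collapse = "")
    }, character(1)), chroms))
    ann <- tibble(gene_id = character(), chrom = character(), start = integer(),
                  end = integer(), strand = character(), tss = integer())
    if (config$n_genes > 0L) {
      margin <- 5000L
      assert_that(config$chrom_length > 2L * margin + 2000L,
                  "genes do not fit on the genome")
      per_chrom <- tabulate(rep_len(seq_along(chroms), config$n_genes),
                            nbins = length(chroms))
      rows <- list()
      g <- 0L
      for (ci in seq_along(chroms)) {
        k <- per_chrom[ci]
        if (k == 0L) next
        span <- config$chrom_length - 2L * margin
        assert_that(span / k > 4000, "genes do not fit on the genome")
        grid <- margin + (seq_len(k) - 0.5) * span / k
        tss <- as.integer(round(grid + runif(k, -1000, 1000)))
        strand <- sample(c("+", "-"), k, replace = TRUE)
        rows[[ci]] <- tibble(
          gene_id = sprintf("g%03d", g + seq_len(k)),
          chrom = chroms[ci],
          start = ifelse(strand == "+", tss, tss - 1000L),
          end = ifelse(strand == "+", tss + 1000L, tss),
          strand = strand,
          tss = tss)
        g <- g + k
      }
      ann <- dplyr::bind_rows(rows)
    }
  })
  list(annotation = ann, genome = genome, chrom_lengths = lens)
}

#' Simulate a redundant motif library with family structure
#'
#' Generates `n_motif_families` mutually dissimilar consensus motifs. Each
#' family contributes two PWMs on the same consensus — the representative
#' and either a shifted or a reverse-complement variant — plus a TF-gene
#' annotation assigning `tfs_per_family` genes per family, emulating the
#' redundancy that motif-catalog condensation removes.
#'
#' @param config An [sim_config()] object.
#' @param gene_ids Gene identifiers to draw TF genes from (the first
#'   `n_motif_families * tfs_per_family` are used, in order).
#' @return A list with `pwms` (list of `fg_pwm`), `tf_annotation` (tibble
#'   motif/tf_gene), `families` (tibble family_id, consensus, member_motifs,
#'   member_tf_genes), and `tf_genes` (character vector).
#' @export
simulate_motif_library <- function(config, gene_ids) {
  n_tf <- config$n_motif_families * config$tfs_per_family
  assert_that(length(gene_ids) >= n_tf, "not enough genes for the TF families")
  tf_genes <- gene_ids[seq_len(n_tf)]
  withr::with_seed(config$seed + 11L, {
    consensi <- character(0)
    pwms <- list()
    fam_rows <- list()
    ann_rows <- list()
    for (k in seq_len(config$n_motif_families)) {
      # draw a consensus whose family members (representative plus shifted or
      # reverse-complement variant) stay clearly below the condensation
      # threshold against every member of every previous family, so family
      # identity is unambiguous by construction
      for (attempt in 1:500) {
        cons <- paste(sample(c("A", "C", "G", "T"), config$motif_length,
                             replace = TRUE), collapse = "")
        rep_pwm <- consensus_pwm(sprintf("FAM%02d_A", k), cons, 0.85)
        alt_name <- sprintf("FAM%02d_B", k)
        alt <- if (k %% 2L == 0L) {
          p <- pwm_revcomp(consensus_pwm(alt_name, cons, 0.8))
          p$name <- alt_name
          p
        } else {
          # same consensus with one uninformative leading column (a shift)
          m <- cbind(rep(0.25, 4), consensus_pwm(alt_name, cons, 0.8)$mat)
          new_pwm(alt_name, m, source = "simulated")
        }
        ok <- all(vapply(pwms, function(p) {
          pwm_similarity(rep_pwm, p) < 0.75 && pwm_similarity(alt, p) < 0.75
        }, logical(1)))
        if (ok) break
      }
      pwms[[rep_pwm$name]] <- rep_pwm
      pwms[[alt$name]] <- alt
      genes <- tf_genes[(k - 1L) * config$tfs_per_family + seq_len(config$tfs_per_family)]
      ann_rows[[k]] <- tibble(
        motif = rep(c(rep_pwm$name, alt$name), each = length(genes)),
        tf_gene = c(genes, base::rev(genes)))
      fam_rows[[k]] <- tibble(family_id = rep_pwm$name, consensus = cons,
                              member_motifs = list(c(rep_pwm$name, alt$name)),
                              member_tf_genes = list(genes))
      consensi <- c(consensi, cons)
    }
  })
  list(pwms = unname(pwms), tf_annotation = dplyr::bind_rows(ann_rows),
       families = dplyr::bind_rows(fam_rows), tf_genes = tf_genes)
}

#' @keywords internal
#' @noRd
consensus_pwm <- function(name, consensus, p_major) {
  bases <- c("A", "C", "G", "T")
  cols <- strsplit(consensus, "")[[1L]]
  m <- vapply(cols, function(b) {
    v <- rep((1 - p_major) / 3, 4)
    v[match(b, bases)] <- p_major
    v
  }, numeric(4))
  new_pwm(name, m, source = "simulated")
}

#' Plant the ground-truth regulatory landscape
#'
#' Places promoter and distal peaks (distal peaks at least 2 kb from any
#' TSS), partitions peaks into shared and subtype-private sets, plants
#' motif instances (footprints) including one source-family instance per
#' planted regulatory edge, embeds each instance's consensus sequence in
#' the genome, and assigns every distal peak a target gene — an exact
#' count of `hic_linked_fraction` via promoter-capture interactions (of
#' which an exact count of `nearest_gene_fraction` contact the nearest
#' gene) and the rest via the nearest gene.
#'
#' Decoy footprints inside a subtype's private peaks never use that
#' subtype's source families, so planted-truth precision is well defined.
#'
#' @param config An [sim_config()] object.
#' @param ann Result of [simulate_annotation()].
#' @return A list of class `fg_truth`: `config`, `annotation`, `genome`
#'   (with embedded motifs), `chrom_lengths`, `peaks`, `footprints`,
#'   `edges`, `links`, `interactions`, `motifs`, `source_families`.
#' @export
plant_landscape <- function(config, ann) {
  validate_sim_config(config)
  annotation <- ann$annotation
  assert_that(nrow(annotation) > 0L, "plant_landscape needs at least one gene")
  w <- config$peak_width
  half <- w %/% 2L
  subtypes <- paste0("S", seq_len(config$n_subtypes))
  n_edge <- config$n_subtypes * config$edges_per_subtype
  assert_that(config$n_motif_families >= n_edge,
              "need one distinct motif family per planted edge")
  assert_that(config$footprints_per_peak %in% 1:2,
              "footprints_per_peak must be 1 or 2")
  motifs <- simulate_motif_library(config, sort(annotation$gene_id))
  src <- tibble(subtype = rep(subtypes, each = config$edges_per_subtype),
                family_id = motifs$families$family_id[seq_len(n_edge)])

  withr::with_seed(config$seed + 23L, {
    n_prom <- round(config$promoter_peak_fraction * config$n_peaks)
    assert_that(n_prom <= nrow(annotation), "not enough genes for promoter peaks")
    prom_genes <- sample(annotation$gene_id, n_prom)
    pg <- annotation[match(prom_genes, annotation$gene_id), ]
    prom <- tibble(chrom = pg$chrom, start = pg$tss - half, end = pg$tss + half,
                   subtype = "shared", location = "promoter",
                   anchor_gene = NA_character_)

    # planted-edge peaks sit 2.5-3.5 kb from a distinct TF gene's TSS so that
    # gene is provably the nearest (TSS spacing always exceeds 7 kb)
    edge_anchor <- sample(motifs$tf_genes, n_edge)
    ag <- annotation[match(edge_anchor, annotation$gene_id), ]
    off <- sample(c(-1L, 1L), n_edge, replace = TRUE) *
      as.integer(round(runif(n_edge, 2500, 3500)))
    esum <- ag$tss + off
    edge <- tibble(chrom = ag$chrom, start = esum - half, end = esum + half,
                   subtype = rep(subtypes, each = config$edges_per_subtype),
                   location = "distal", anchor_gene = edge_anchor)

    # remaining distal peaks on a candidate grid clear of TSS and other peaks
    n_bg <- config$n_peaks - n_prom - n_edge
    cand <- dplyr::bind_rows(lapply(names(ann$chrom_lengths), function(ch) {
      L <- ann$chrom_lengths[[ch]]
      tibble(chrom = ch, start = seq(1000L, L - 1000L - w, by = w + 400L))
    }))
    cand$summit <- cand$start + half
    nt <- nearest_tss(cand$chrom, cand$summit, annotation)
    cand <- cand[is.na(nt$distance) | nt$distance > 2000L + half + 100L, ]
    taken <- dplyr::bind_rows(prom, edge)
    keep <- vapply(seq_len(nrow(cand)), function(i) {
      t <- taken[taken$chrom == cand$chrom[i], ]
      all(cand$start[i] >= t$end + 400L | cand$start[i] + w <= t$start - 400L)
    }, logical(1))
    cand <- cand[keep, ]
    assert_that(nrow(cand) >= n_bg, "genome too small for the requested peaks")
    bg_idx <- sort(sample(nrow(cand), n_bg))
    bg <- tibble(chrom = cand$chrom[bg_idx], start = cand$start[bg_idx],
                 end = cand$start[bg_idx] + w, subtype = "shared",
                 location = "distal", anchor_gene = NA_character_)

    # private-peak quota per subtype, over and above the edge peaks
    q <- round(config$subtype_specific_fraction * config$n_peaks)
    extra <- q - config$edges_per_subtype
    assert_that(extra >= 0 && config$n_subtypes * extra <= n_bg,
                "requested private peaks exceed n_peaks")
    if (extra > 0L) {
      pick <- sample(nrow(bg), config$n_subtypes * extra)
      bg$subtype[pick] <- rep(subtypes, each = extra)
    }

    peaks <- dplyr::bind_rows(prom, edge, bg)
    peaks <- dplyr::arrange(peaks, .data$chrom, .data$start)
    peaks$peak_id <- sprintf("pk%04d", seq_len(nrow(peaks)))
    peaks$summit <- peaks$start + half
    peaks <- dplyr::select(peaks, "peak_id", "chrom", "start", "end", "summit",
                           "subtype", "location", "anchor_gene")

    # --- target-gene assignment: exact counts, not coin flips -------------
    distal <- peaks[peaks$location == "distal", ]
    nd <- nrow(distal)
    n_link <- round(config$hic_linked_fraction * nd)
    is_edge <- !is.na(distal$anchor_gene)
    ord <- c(resample(which(is_edge)), resample(which(!is_edge)))
    linked_idx <- ord[seq_len(n_link)]
    n_near <- round(config$nearest_gene_fraction * n_link)
    near_flag <- rep(FALSE, n_link)
    if (n_near > 0L) near_flag[sample(n_link, n_near)] <- TRUE

    nt_all <- nearest_tss(distal$chrom, distal$summit, annotation)
    links <- list()
    inter <- list()
    for (j in seq_along(linked_idx)) {
      i <- linked_idx[j]
      nearest <- nt_all$gene_id[i]
      partner <- if (near_flag[j]) {
        nearest
      } else if (is_edge[i]) {
        sample(setdiff(motifs$tf_genes, nearest), 1L)
      } else {
        sample(setdiff(annotation$gene_id, nearest), 1L)
      }
      ptss <- annotation$tss[annotation$gene_id == partner]
      pchr <- annotation$chrom[annotation$gene_id == partner]
      links[[j]] <- tibble(peak_id = distal$peak_id[i], gene_id = partner, via = "hic")
      inter[[j]] <- tibble(chrom1 = distal$chrom[i], start1 = distal$start[i],
                           end1 = distal$end[i], chrom2 = pchr,
                           start2 = max(0L, ptss - 500L), end2 = ptss + 500L)
    }
    unlinked <- setdiff(seq_len(nd), linked_idx)
    for (i in unlinked) {
      links[[length(links) + 1L]] <- tibble(peak_id = distal$peak_id[i],
                                            gene_id = nt_all$gene_id[i],
                                            via = "nearest")
    }
    links <- dplyr::bind_rows(links)
    interactions <- if (length(inter)) dplyr::bind_rows(inter) else
      tibble(chrom1 = character(), start1 = integer(), end1 = integer(),
             chrom2 = character(), start2 = integer(), end2 = integer())

    # --- footprints: one source-family instance per edge peak, decoys
    #     elsewhere; close second instance in alternating peaks ------------
    genome <- ann$genome
    fam_ids <- motifs$families$family_id
    fp_rows <- list()
    edge_rows <- list()
    for (i in seq_len(nrow(peaks))) {
      pk <- peaks[i, ]
      allowed <- if (pk$subtype == "shared") fam_ids else
        setdiff(fam_ids, src$family_id[src$subtype == pk$subtype])
      offs <- c(120L, if (config$footprints_per_peak == 2L) {
        if (i %% 2L == 0L) 160L else 280L
      })
      for (fi in seq_along(offs)) {
        fam <- if (fi == 1L && !is.na(pk$anchor_gene)) {
          # planted edge: the subtype's next source family, round-robin
          srow <- src[src$subtype == pk$subtype, ]
          used <- vapply(edge_rows, function(e) e$family_id, character(1))
          remaining <- setdiff(srow$family_id, used)
          if (length(remaining)) remaining[1L] else sample(srow$family_id, 1L)
        } else {
          sample(allowed, 1L)
        }
        cons <- motifs$families$consensus[motifs$families$family_id == fam]
        s0 <- pk$start + offs[fi]
        e0 <- s0 + nchar(cons)
        strand <- sample(c("+", "-"), 1L)
        seqc <- if (strand == "+") cons else
          as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
        Biostrings::subseq(genome[[pk$chrom]], s0 + 1L, e0) <-
          Biostrings::DNAString(seqc)
        fp_id <- sprintf("fp%05d", length(fp_rows) + 1L)
        fp_rows[[length(fp_rows) + 1L]] <-
          tibble(fp_id = fp_id, peak_id = pk$peak_id, chrom = pk$chrom,
                 start = s0, end = e0, family_id = fam, strand = strand)
        if (fi == 1L && !is.na(pk$anchor_gene)) {
          target <- links$gene_id[links$peak_id == pk$peak_id]
          edge_rows[[length(edge_rows) + 1L]] <-
            tibble(family_id = fam, target_gene = target, subtype = pk$subtype,
                   peak_id = pk$peak_id, fp_id = fp_id)
        }
      }
    }
    footprints <- dplyr::bind_rows(fp_rows)
    edges <- dplyr::bind_rows(edge_rows)
  })

  structure(list(config = config, annotation = annotation, genome = genome,
                 chrom_lengths = ann$chrom_lengths, peaks = peaks,
                 footprints = footprints, edges = edges, links = links,
                 interactions = interactions, motifs = motifs,
                 source_families = src),
            class = "fg_truth")
}

#' @export
print.fg_truth <- function(x, ...) {
  cat("<fg_truth>", nrow(x$peaks), "peaks |", nrow(x$footprints), "footprints |",
      nrow(x$edges), "planted edges |", nrow(x$interactions), "interactions\n")
  invisible(x)
}

#' Sample sheet for a simulated cohort
#' @param config An [sim_config()] object.
#' @return Tibble with `sample_id`, `subtype`, `is_control`.
#' @export
simulate_metadata <- function(config) {
  subtypes <- paste0("S", seq_len(config$n_subtypes))
  dplyr::bind_rows(
    tibble(sample_id = paste0(rep(subtypes, each = config$samples_per_subtype), "_rep",
                              rep(seq_len(config$samples_per_subtype), config$n_subtypes)),
           subtype = rep(subtypes, each = config$samples_per_subtype),
           is_control = FALSE),
    tibble(sample_id = paste0("control_rep", seq_len(config$n_control_samples)),
           subtype = "control",
           is_control = TRUE))
}

#' Simulate a stranded cut profile for one sample
#'
#' Per-base cut counts are drawn from independent Poisson distributions.
#' The rate field is `background_rate` outside peaks, elevated
#' `peak_enrichment`-fold inside peaks accessible to this sample's
#' subtype (shared peaks plus its own private peaks; controls see only
#' shared peaks), boosted `flank_boost`-fold in the strand-specific
#' footprint shoulders (forward upstream, reverse downstream), multiplied
#' by `footprint_depletion` inside footprint interiors, and finally
#' rescaled so the expected total equals `depth`.
#'
#' @param truth An `fg_truth` from [plant_landscape()].
#' @param sample_id Sample identifier.
#' @param subtype The sample's subtype label (or `"control"`).
#' @param depth Expected total cut count (both strands).
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return An `fg_profile`.
#' @export
simulate_cuts <- function(truth, sample_id, subtype, depth, seed) {
  cfg <- truth$config
  subtypes <- paste0("S", seq_len(cfg$n_subtypes))
  assert_that(subtype %in% c(subtypes, "control"),
              paste0("unknown subtype label: ", subtype))
  assert_that(depth >= 0, "depth must be non-negative")
  acc <- truth$peaks$subtype == "shared" |
    (subtype != "control" & truth$peaks$subtype == subtype)
  pk <- truth$peaks[acc, ]
  fp <- truth$footprints[truth$footprints$peak_id %in% pk$peak_id, ]
  S <- cfg$flank_bp
  rate <- list()
  for (ch in names(truth$chrom_lengths)) {
    L <- truth$chrom_lengths[[ch]]
    fw <- rep(cfg$background_rate / 2, L)
    rv <- fw
    p <- pk[pk$chrom == ch, ]
    for (i in seq_len(nrow(p))) {
      idx <- (p$start[i] + 1L):p$end[i]
      fw[idx] <- rv[idx] <- cfg$background_rate * cfg$peak_enrichment / 2
    }
    f <- fp[fp$chrom == ch, ]
    for (i in seq_len(nrow(f))) {       # strand-specific shoulder pile-up
      up <- max(1L, f$start[i] - S + 1L):f$start[i]
      dn <- (f$end[i] + 1L):min(L, f$end[i] + S)
      fw[up] <- fw[up] * cfg$flank_boost
      rv[dn] <- rv[dn] * cfg$flank_boost
    }
    for (i in seq_len(nrow(f))) {       # interiors override any boost
      idx <- (f$start[i] + 1L):f$end[i]
      fw[idx] <- rv[idx] <-
        cfg$background_rate * cfg$peak_enrichment / 2 * cfg$footprint_depletion
    }
    rate[[ch]] <- list(fwd = fw, rev = rv)
  }
  total <- sum(vapply(rate, function(r) sum(r$fwd) + sum(r$rev), numeric(1)))
  scale <- if (depth > 0 && total > 0) depth / total else 0
  withr::with_seed(as.integer(seed), {
    fwd <- lapply(rate, function(r) rpois(length(r$fwd), r$fwd * scale))
    rev <- lapply(rate, function(r) rpois(length(r$rev), r$rev * scale))
  })
  cut_profile(sample_id, fwd, rev)
}

#' Simulate an expression table (FKPM)
#'
#' Every gene gets a control-mean baseline; member TF genes of a
#' subtype's planted source families are raised to
#' `tf_upregulation_fold * tf_planted_fold_margin` times their baseline in
#' that subtype's samples ("at least" the fold). Values carry
#' multiplicative lognormal noise with coefficient of variation
#' `expression_noise_cv` (mean-preserving; `cv = 0` gives the means
#' exactly).
#'
#' @param truth An `fg_truth`.
#' @param metadata Sample sheet from [simulate_metadata()].
#' @param baseline Optional named numeric vector of control means per
#'   gene; defaults to a seeded draw (TF genes uniform on 3-30 FKPM,
#'   other genes lognormal around 5 FKPM).
#' @param seed Integer seed (default derived from the generator seed).
#' @return Tibble with `gene_id` and one numeric column per sample.
#' @export
simulate_expression <- function(truth, metadata, baseline = NULL, seed = NULL) {
  cfg <- truth$config
  seed <- seed %||% (cfg$seed + 29L)
  genes <- sort(truth$annotation$gene_id)
  tf_genes <- truth$motifs$tf_genes
  up_members <- lapply(split(truth$source_families$family_id,
                             truth$source_families$subtype), function(fams) {
    sort(unique(unlist(
      truth$motifs$families$member_tf_genes[truth$motifs$families$family_id %in% fams])))
  })
  withr::with_seed(as.integer(seed), {
    if (is.null(baseline)) {
      baseline <- setNames(numeric(length(genes)), genes)
      is_tf <- genes %in% tf_genes
      baseline[is_tf] <- runif(sum(is_tf), 3, 30)
      baseline[!is_tf] <- rlnorm(sum(!is_tf), log(5), 1)
    } else {
      assert_that(all(genes %in% names(baseline)), "baseline must cover all genes")
      baseline <- baseline[genes]
    }
    out <- tibble(gene_id = genes)
    if (nrow(metadata) > 0L) {
      fold <- cfg$tf_upregulation_fold * cfg$tf_planted_fold_margin
      cv <- cfg$expression_noise_cv
      sdlog <- sqrt(log(1 + cv^2))
      for (i in seq_len(nrow(metadata))) {
        mu <- baseline
        st <- metadata$subtype[i]
        if (st %in% names(up_members)) {
          mu[names(mu) %in% up_members[[st]]] <- mu[names(mu) %in% up_members[[st]]] * fold
        }
        noise <- if (cv > 0) rlnorm(length(mu), -sdlog^2 / 2, sdlog) else 1
        out[[metadata$sample_id[i]]] <- unname(mu * noise)
      }
    }
  })
  out
}

#' Simulate a complete study
#'
#' Runs [simulate_annotation()], [plant_landscape()],
#' [simulate_metadata()], one [simulate_cuts()] per sample (per-sample
#' seeds are `seed + 100 + sample index`, so adding samples never
#' perturbs existing ones), and [simulate_expression()].
#'
#' @param config An [sim_config()] object.
#' @return A list of class `fg_sim`: `config`, `truth`, `annotation`,
#'   `metadata`, `profiles` (named list of `fg_profile`), `expression`.
#' @export
simulate_study <- function(config) {
  ann <- simulate_annotation(config)
  truth <- plant_landscape(config, ann)
  metadata <- simulate_metadata(config)
  profiles <- lapply(seq_len(nrow(metadata)), function(i) {
    simulate_cuts(truth, metadata$sample_id[i], metadata$subtype[i],
                  depth = config$reads_per_sample,
                  seed = config$seed + 100L + i)
  })
  names(profiles) <- metadata$sample_id
  expression <- simulate_expression(truth, metadata)
  structure(list(config = config, truth = truth, annotation = truth$annotation,
                 metadata = metadata, profiles = profiles, expression = expression),
            class = "fg_sim")
}

#' @export
print.fg_sim <- function(x, ...) {
  cat("<fg_sim>", nrow(x$metadata), "samples |", nrow(x$truth$peaks), "peaks |",
      nrow(x$truth$edges), "planted edges\n")
  invisible(x)
}
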