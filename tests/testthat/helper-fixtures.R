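# Shared fixtures, built once per test run and cached.

.fg_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fg_cache)) {
    assign(key, force(expr), envir = .fg_cache)
  }
  get(key, envir = .fg_cache)
}

# A compact study: one 200-kb chromosome, 20 genes, 60 peaks, 2 subtypes x 2
# samples + 1 control, 3e5 cuts/sample. Small enough for unit tests, deep
# enough that every planted feature is recoverable.
small_config <- function(...) {
  defaults <- list(seed = 7L, n_chromosomes = 1L, chrom_length = 200000L,
                   n_genes = 20L, n_peaks = 60L, n_subtypes = 2L,
                   samples_per_subtype = 2L, n_control_samples = 1L,
                   reads_per_sample = 3e5, edges_per_subtype = 2L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

small_sim <- function() cached("small_sim", simulate_study(small_config()))

small_atlas <- function() {
  cached("small_atlas", {
    sim <- small_sim()
    classify_distal(call_peaks(sim$profiles), sim$annotation)
  })
}

small_norm_counts <- function() {
  cached("small_norm", {
    sim <- small_sim()
    normalize_rank(build_count_matrix(small_atlas(), sim$profiles))
  })
}

# A deterministic hand-built profile: one chromosome of `len` bp with
# constant per-strand counts, optionally with rectangular footprints
# (interior zeroed, strand-specific shoulders boosted).
flat_profile <- function(len = 10000L, level = 2L, footprints = NULL,
                         shoulder = 35L, boost = 3L, sample_id = "flat") {
  fwd <- rep(level, len)
  rev <- rep(level, len)
  for (fp in footprints) {
    s <- fp[1L]; e <- fp[2L]
    fwd[(s - shoulder + 1L):s] <- level * boost
    rev[(e + 1L):(e + shoulder)] <- level * boost
    fwd[(s + 1L):e] <- 0L
    rev[(s + 1L):e] <- 0L
  }
  cut_profile(sample_id, list(chr1 = fwd), list(chr1 = rev))
}

# Independent brute-force binomial upper-tail p-value (linear-space sum).
brute_tail_p <- function(n_shoulder, n_fp, S, L) {
  if (n_shoulder <= 0) return(1)
  n <- n_shoulder + n_fp
  sum(dbinom(n_shoulder:n, n, S / (S + L)))
}

# Brute-force nearest gene per planted peak (named by peak_id); independent
# of the package's findInterval-based lookup.
nearest_planted_gene <- function(truth) {
  ann <- truth$annotation
  pk <- truth$peaks
  out <- vapply(seq_len(nrow(pk)), function(i) {
    g <- ann[ann$chrom == pk$chrom[i], ]
    d <- abs(g$tss - pk$summit[i])
    cand <- g[d == min(d), ]
    cand$gene_id[which.min(cand$tss)]
  }, character(1))
  setNames(out, pk$peak_id)
}

# Point-mass PWM from a consensus string.
pm_pwm <- function(name, consensus, p = 1) {
  bases <- c("A", "C", "G", "T")
  cols <- strsplit(consensus, "")[[1L]]
  m <- vapply(cols, function(b) {
    v <- rep((1 - p) / 3, 4)
    v[match(b, bases)] <- p
    v
  }, numeric(4))
  new_pwm(name, m)
}

# Independent brute-force PWM similarity: explicit double loop over every
# offset and both orientations, computing column correlations directly.
brute_similarity <- function(a, b, min_overlap = 5L) {
  rc <- function(m) {
    out <- m[4:1, ncol(m):1, drop = FALSE]
    rownames(out) <- rownames(m)
    out
  }
  colsim <- function(x, y) {
    if (sd(x) == 0 && sd(y) == 0) return(as.numeric(max(abs(x - y)) < 1e-9))
    if (sd(x) == 0 || sd(y) == 0) return(0)
    cor(x, y)
  }
  best <- -Inf
  for (bm in list(b$mat, rc(b$mat))) {
    for (sa in seq_len(ncol(a$mat))) {          # a-column aligned to b-column 1
      for (sb in seq_len(ncol(bm))) {
        if (sa > 1 && sb > 1) next              # only boundary-anchored offsets
        k <- min(ncol(a$mat) - sa + 1L, ncol(bm) - sb + 1L)
        if (k < min_overlap) next
        cc <- vapply(0:(k - 1L), function(j) {
          colsim(a$mat[, sa + j], bm[, sb + j])
        }, numeric(1))
        best <- max(best, mean(cc))
      }
    }
  }
  best
}
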