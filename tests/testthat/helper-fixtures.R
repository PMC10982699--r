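# Shared fixtures and independent oracles, all built in code.

toy_genome <- function(lens = c(chrI = 10000, chrII = 20000)) {
  genome_spec(names(lens), unname(lens))
}

make_frags <- function(genome, chrom, start, end, strand,
                       sample_id = "s1", genotype = "WT", mark = "BrdU") {
  fragment_set(chrom, start, end, strand, genome,
               sample_id = sample_id, genotype_label = genotype, mark = mark)
}

# n random fragments on one chromosome of the genome
random_frags <- function(genome, n, chrom = genome$chrom_names[1],
                         min_len = 50, max_len = 200, ...) {
  len <- unname(genome$chrom_lengths[chrom])
  sizes <- sample(min_len:max_len, n, replace = TRUE)
  start <- sample.int(len - max_len, n, replace = TRUE) - 1
  make_frags(genome, rep(chrom, n), start, start + sizes,
             sample(c("W", "C"), n, replace = TRUE), ...)
}

# Naive per-base decode of one strand of a strand_coverage
decode_strand <- function(cov, chrom, strand) {
  as.numeric(if (strand == "W") cov$w[[chrom]] else cov$c[[chrom]])
}

# Brute-force window sum over a 0-based half-open interval, plain loop
naive_window_sum <- function(vec, start, end) {
  s <- 0
  for (i in (start + 1):end) s <- s + vec[i]
  s
}

# Independent double-loop implementation of the sliding-window bias
naive_windowed_bias <- function(cov, origins, radius, window, step) {
  centers <- seq(-radius, radius, by = step)
  lo <- floor(window / 2); hi <- ceiling(window / 2)
  out <- matrix(NaN, nrow(origins), length(centers),
                dimnames = list(origins$origin_id, centers))
  for (i in seq_len(nrow(origins))) {
    chrom <- origins$chrom[i]
    len <- unname(cov$genome$chrom_lengths[chrom])
    wv <- decode_strand(cov, chrom, "W")
    cv <- decode_strand(cov, chrom, "C")
    for (j in seq_along(centers)) {
      a <- origins$pos[i] + centers[j] - lo
      b <- origins$pos[i] + centers[j] + hi
      if (a < 0 || b > len) next
      W <- naive_window_sum(wv, a, b)
      C <- naive_window_sum(cv, a, b)
      out[i, j] <- if (W + C > 0) (W - C) / (W + C) else NaN
    }
  }
  attr(out, "bin_centers") <- centers
  out
}

# Small simulated experiment for module-level tests (fast, shallow)
small_sim <- function(genotypes, marks = "H3K4me3", n_origins = 12,
                      cells = 40, reads = 0.5, brdu = 0.6, seed = 99, ...) {
  geo <- sim_genome(n_origins = n_origins, origin_spacing = 26000,
                    margin = 13000)
  cfg <- simulation_config(geo$genome, geo$origins,
                           cells_per_sample = cells,
                           reads_per_nucleosome = reads,
                           brdu_reads_per_bp = brdu, seed = seed, ...)
  res <- simulate_experiment(cfg, genotypes, marks = marks)
  covs <- lapply(res$samples, coverage_from_fragments, genome = geo$genome)
  list(geo = geo, cfg = cfg, samples = res$samples, covs = covs,
       manifest = res$manifest)
}

# Brute-force no-intercept least squares over the density bin grid,
# independent of the package's Views-based implementation.
naive_coefficient <- function(espan_cov, brdu_cov, chrom, pos, strand_class,
                              halfwidth = 2500, bin = 100, exclude = 300) {
  starts <- seq(-halfwidth, halfwidth - bin, by = bin)
  num <- 0; den <- 0
  for (s0 in starts) {
    if (!(s0 + bin <= -exclude || s0 >= exclude)) next
    side <- if (s0 >= 0) "right" else "left"
    strand <- nascent_strand_of(strand_class, side)
    ev <- decode_strand(espan_cov, chrom, strand)
    bv <- decode_strand(brdu_cov, chrom, strand)
    e <- naive_window_sum(ev, pos + s0, pos + s0 + bin)
    b <- naive_window_sum(bv, pos + s0, pos + s0 + bin)
    if (b > 0) { num <- num + e * b; den <- den + b * b }
  }
  if (den == 0) NA_real_ else max(0, num / den)
}
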