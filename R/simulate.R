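#' Genotype parameters for histone segregation
#'
#' The segregation model works at the level of H3-H4 tetramers at a
#' nucleosome slot disrupted by a passing replication fork. With
#' probability `r_recycle` the parental tetramer is recycled onto one of
#' the two daughter duplexes: the leading-strand daughter with
#' probability `p_lead`, the lagging-strand daughter otherwise. Each
#' daughter slot that did not receive a parental tetramer is filled by a
#' newly synthesized tetramer, so every slot carries exactly one
#' tetramer per daughter.
#'
#' Per-slot expected occupancies follow in closed form: parental
#' occupancy is `r_recycle * p_lead` on the leading daughter and
#' `r_recycle * (1 - p_lead)` on the lagging daughter; new-histone
#' occupancy is the complement on each daughter.
#'
#' @param label Genotype label.
#' @param p_lead Probability a recycled parental tetramer lands on the
#'   leading-strand daughter (in `[0, 1]`).
#' @param r_recycle Probability a disrupted parental tetramer is
#'   recycled at all (in `[0, 1]`).
#' @param density_scale_new Relative read yield of new-histone
#'   nucleosomes (default 1).
#' @return An object of class `genotype_params`.
#' @export
genotype_params <- function(label, p_lead, r_recycle, density_scale_new = 1) {
  stopifnot(is.character(label), length(label) == 1L)
  if (!is.numeric(p_lead) || p_lead < 0 || p_lead > 1) {
    stop("p_lead must be in [0, 1]")
  }
  if (!is.numeric(r_recycle) || r_recycle < 0 || r_recycle > 1) {
    stop("r_recycle must be in [0, 1]")
  }
  if (!is.numeric(density_scale_new) || density_scale_new < 0) {
    stop("density_scale_new must be >= 0")
  }
  structure(list(label = label, p_lead = p_lead, r_recycle = r_recycle,
                 density_scale_new = density_scale_new),
            class = "genotype_params")
}

#' Shipped genotype presets
#'
#' Qualitative emulations of the strand-partition phenotypes of the
#' chaperone mutants studied with eSPAN: a symmetric wild type, a
#' Mcm2 histone-binding mutant that shifts parental histones to the
#' leading strand, a Dpb3/Dpb4 (pol epsilon subunit) deletion that
#' shifts them to the lagging strand, their double mutant, and a FACT
#' subunit deletion that mainly lowers overall recycling. The values are
#' illustrative ground truths for validating the pipeline, not fitted
#' estimates of the biology.
#'
#' @return Named list of [genotype_params()].
#' @export
genotype_presets <- function() {
  list(
    WT            = genotype_params("WT",            p_lead = 0.50, r_recycle = 1.00),
    mcm2_2A       = genotype_params("mcm2_2A",       p_lead = 0.85, r_recycle = 0.60),
    dpb4d         = genotype_params("dpb4d",         p_lead = 0.25, r_recycle = 0.80),
    mcm2_2A_dpb3d = genotype_params("mcm2_2A_dpb3d", p_lead = 0.55, r_recycle = 0.45),
    pob3d         = genotype_params("pob3d",         p_lead = 0.50, r_recycle = 0.35)
  )
}

#' Build a regular synthetic genome with evenly spaced origins
#'
#' One chromosome with `n_origins` bidirectional origins spaced
#' `origin_spacing` bp apart and `margin` bp of unreplicated DNA at both
#' ends (so fragments near the outermost forks stay on-chromosome and
#' genome-wide BrdU enrichment at origins is > 1).
#'
#' @param n_origins Number of origins (default 200).
#' @param origin_spacing Distance between adjacent origins in bp
#'   (default 30000).
#' @param margin Unreplicated margin at each chromosome end in bp
#'   (default 15000).
#' @param chrom_name Chromosome name.
#' @return List with elements `genome` ([genome_spec()]) and `origins`
#'   ([origin_set()]).
#' @export
sim_genome <- function(n_origins = 200, origin_spacing = 30000,
                       margin = 15000, chrom_name = "chrSim") {
  stopifnot(n_origins >= 1, origin_spacing > 0, margin >= 0)
  pos <- margin + (seq_len(n_origins) - 1) * origin_spacing
  len <- margin + (n_origins - 1) * origin_spacing + margin
  genome <- genome_spec(chrom_name, len)
  list(genome = genome,
       origins = origin_set(rep(chrom_name, n_origins), pos,
                            sprintf("origin_%03d", seq_len(n_origins)),
                            genome, provenance = "sim_genome"))
}

#' Simulation configuration
#'
#' Geometry and sequencing-depth parameters shared by all samples of a
#' simulated experiment. Each origin fires bidirectionally and both
#' forks travel `replicated_halfwidth` bp; nucleosome slots sit every
#' `nucleosome_spacing` bp at offsets `(k + 1/2) * spacing` from the
#' origin. A library pools `cells_per_sample` independent cells, each
#' making its own segregation choices, and sequences an expected
#' `reads_per_nucleosome` fragments per deposited tetramer per daughter.
#' BrdU-input fragments are drawn uniformly over the replicated
#' intervals at `brdu_reads_per_bp` expected fragments per replicated bp
#' (split equally between strands). `strand_recovery_w` is a
#' multiplicative Watson-recovery distortion applied identically to all
#' samples; it exists to test that BrdU-bias subtraction removes shared
#' technical strand asymmetries.
#'
#' @param genome A [genome_spec()].
#' @param origins An [origin_set()].
#' @param replicated_halfwidth Distance each fork travels, bp.
#' @param nucleosome_spacing Nucleosome repeat length, bp.
#' @param fragment_length_mean,fragment_length_sd Normal fragment-length
#'   model, bp; lengths are clamped at >= 50.
#' @param reads_per_nucleosome Expected sequenced fragments per
#'   deposited tetramer per daughter.
#' @param brdu_reads_per_bp Expected BrdU-input fragments per replicated
#'   bp (both strands together).
#' @param cells_per_sample Number of cells pooled into one library.
#' @param strand_recovery_w Watson-strand recovery factor (1 = no
#'   distortion; < 1 thins Watson fragments, > 1 upsamples them).
#' @param seed Master RNG seed; a fixed seed makes all outputs
#'   byte-identical across reruns.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(genome, origins,
                              replicated_halfwidth = 5000,
                              nucleosome_spacing = 160,
                              fragment_length_mean = 150,
                              fragment_length_sd = 15,
                              reads_per_nucleosome = 0.3,
                              brdu_reads_per_bp = 3,
                              cells_per_sample = 1000,
                              strand_recovery_w = 1,
                              seed = 1L) {
  if (!inherits(genome, "genome_spec")) stop("genome must be a genome_spec")
  if (!inherits(origins, "origin_set")) stop("origins must be an origin_set")
  if (nucleosome_spacing <= 0) stop("nucleosome_spacing must be > 0")
  if (replicated_halfwidth <= 0) stop("replicated_halfwidth must be > 0")
  rates <- c(fragment_length_mean, fragment_length_sd, reads_per_nucleosome,
             brdu_reads_per_bp, cells_per_sample, strand_recovery_w)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("all rate parameters must be finite and >= 0")
  }
  if (cells_per_sample < 1 || cells_per_sample != floor(cells_per_sample)) {
    stop("cells_per_sample must be a positive integer")
  }
  structure(list(genome = genome, origins = origins,
                 replicated_halfwidth = replicated_halfwidth,
                 nucleosome_spacing = nucleosome_spacing,
                 fragment_length_mean = fragment_length_mean,
                 fragment_length_sd = fragment_length_sd,
                 reads_per_nucleosome = reads_per_nucleosome,
                 brdu_reads_per_bp = brdu_reads_per_bp,
                 cells_per_sample = cells_per_sample,
                 strand_recovery_w = strand_recovery_w,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Nucleosome slot centers replicated by the two forks of an origin
#'
#' Slots sit at `origin +/- (k + 1/2) * spacing` for `k = 0, 1, ...`
#' while strictly inside the replicated half-width. Deterministic given
#' the configuration.
#'
#' @param config A [simulation_config()].
#' @param origin_pos Origin position (0-based bp).
#' @return Sorted numeric vector of absolute slot centers (empty when
#'   the half-width is smaller than half the spacing).
#' @export
place_nucleosomes <- function(config, origin_pos) {
  s <- config$nucleosome_spacing
  hw <- config$replicated_halfwidth
  offs <- s / 2 + s * (seq_len(max(0, ceiling(hw / s))) - 1)
  offs <- offs[offs < hw]
  if (!length(offs)) return(numeric(0))
  sort(c(origin_pos - offs, origin_pos + offs))
}

#' Strand of the nascent daughter duplex
#'
#' Encodes bidirectional fork geometry: right of the origin the
#' leading-strand daughter is synthesized on the Watson template
#' direction (`W`) and the lagging daughter on Crick (`C`); left of the
#' origin the mapping is mirrored. Pure function, vectorized.
#'
#' @param daughter `"leading"` or `"lagging"`.
#' @param side `"left"` or `"right"` (relative to the origin).
#' @return `"W"` or `"C"`.
#' @export
nascent_strand_of <- function(daughter, side) {
  if (!all(daughter %in% c("leading", "lagging"))) {
    stop("daughter must be 'leading' or 'lagging'")
  }
  if (!all(side %in% c("left", "right"))) {
    stop("side must be 'left' or 'right'")
  }
  ifelse((daughter == "leading") == (side == "right"), "W", "C")
}

#' Segregate parental histones at nucleosome slots of one cell
#'
#' For each slot center, the parental tetramer is recycled with
#' probability `r_recycle`; a recycled tetramer goes to the
#' leading-strand daughter with probability `p_lead`, otherwise to the
#' lagging daughter. Each daughter slot without a parental tetramer
#' receives a new tetramer, so exactly two tetramers (one per daughter)
#' are deposited per center.
#'
#' @param centers Numeric vector of slot centers.
#' @param side `"left"` or `"right"` of the origin (scalar or vector).
#' @param params A [genotype_params()].
#' @return A data.frame with two rows per center and columns `center`,
#'   `side`, `daughter`, `histone_class`.
#' @export
segregate_histones <- function(centers, side, params) {
  n <- length(centers)
  if (length(side) == 1L) side <- rep(side, n)
  stopifnot(length(side) == n)
  if (n == 0L) {
    return(data.frame(center = numeric(0), side = character(0),
                      daughter = character(0), histone_class = character(0),
                      stringsAsFactors = FALSE))
  }
  recycled <- stats::runif(n) < params$r_recycle
  to_lead <- stats::runif(n) < params$p_lead
  lead_class <- ifelse(recycled & to_lead, "parental", "new")
  lag_class <- ifelse(recycled & !to_lead, "parental", "new")
  data.frame(center = rep(centers, each = 2L),
             side = rep(side, each = 2L),
             daughter = rep(c("leading", "lagging"), times = n),
             histone_class = as.vector(rbind(lead_class, lag_class)),
             stringsAsFactors = FALSE)
}

## Population tally: per slot, the number of cells (out of `cells`) whose
## parental tetramer went to each daughter. Binomial sampling here is
## distributionally identical to pooling `cells` independent
## segregate_histones() draws, because fragment emission depends only on
## per-slot tetramer counts by (daughter, class).
segregate_population <- function(centers, side, params, cells) {
  n <- length(centers)
  if (length(side) == 1L) side <- rep(side, n)
  if (n == 0L) {
    return(data.frame(center = numeric(0), side = character(0),
                      daughter = character(0), histone_class = character(0),
                      n_tetramers = numeric(0), stringsAsFactors = FALSE))
  }
  k_rec <- stats::rbinom(n, cells, params$r_recycle)
  k_lead <- stats::rbinom(n, k_rec, params$p_lead)
  k_lag <- k_rec - k_lead
  data.frame(
    center = rep(centers, times = 4L),
    side = rep(side, times = 4L),
    daughter = rep(c("leading", "lagging", "leading", "lagging"), each = n),
    histone_class = rep(c("parental", "parental", "new", "new"), each = n),
    n_tetramers = c(k_lead, k_lag, cells - k_lead, cells - k_lag),
    stringsAsFactors = FALSE)
}

## Depositions for all origins of a genotype: slot tallies plus the
## genomic strand each tetramer's nascent DNA maps to.
build_depositions <- function(config, params) {
  origins <- config$origins
  parts <- vector("list", nrow(origins))
  for (i in seq_len(nrow(origins))) {
    centers <- place_nucleosomes(config, origins$pos[i])
    if (!length(centers)) next
    side <- ifelse(centers < origins$pos[i], "left", "right")
    dep <- segregate_population(centers, side, params, config$cells_per_sample)
    dep$chrom <- origins$chrom[i]
    parts[[i]] <- dep
  }
  dep <- do.call(rbind, parts)
  if (is.null(dep)) {
    stop("no nucleosome slots placed; is replicated_halfwidth < spacing/2?")
  }
  dep$strand <- nascent_strand_of(dep$daughter, dep$side)
  dep
}

## Watson-recovery distortion: thin (w < 1) or upsample (w > 1) Watson
## fragments; applied identically to every sample of an experiment.
apply_strand_recovery <- function(frags_df, w) {
  if (w == 1 || nrow(frags_df) == 0L) return(frags_df)
  is_w <- frags_df$strand == "W"
  if (!any(is_w)) return(frags_df)
  if (w < 1) {
    drop <- is_w & (stats::runif(nrow(frags_df)) >= w)
    frags_df[!drop, , drop = FALSE]
  } else {
    copies <- floor(w - 1) + (stats::runif(sum(is_w)) < (w - 1) %% 1)
    extra <- frags_df[is_w, , drop = FALSE][rep(seq_len(sum(is_w)), copies), , drop = FALSE]
    rbind(frags_df, extra)
  }
}

draw_lengths <- function(n, config) {
  pmax(50, round(stats::rnorm(n, config$fragment_length_mean,
                              config$fragment_length_sd)))
}

## Drop fragments that would extend past a chromosome end (only possible
## when origins sit closer to an end than replicated_halfwidth plus one
## fragment length; sim_genome() leaves a margin so this is rare).
clip_to_genome <- function(df, genome) {
  if (nrow(df) == 0L) return(df)
  len <- genome$chrom_lengths[df$chrom]
  bad <- df$start < 0 | df$end > len
  if (any(bad)) {
    warning(sum(bad), " simulated fragment(s) extended past a chromosome end and were dropped")
    df <- df[!bad, , drop = FALSE]
  }
  df
}

#' Emit sequenced fragments for one sample
#'
#' For a histone-mark sample, each deposition whose histone class
#' matches the mark yields `Poisson(reads_per_nucleosome *
#' n_tetramers)` fragments (times `density_scale_new` for new-histone
#' marks) with Normal(`fragment_length_mean`, `fragment_length_sd`^2)
#' lengths clamped at >= 50, centered on the nucleosome slot, on the
#' strand given by [nascent_strand_of()]. A BrdU sample ignores the
#' depositions and draws fragments uniformly over each origin's
#' replicated interval on both strands at `brdu_reads_per_bp` expected
#' fragments per bp. Finally the Watson-recovery distortion
#' `strand_recovery_w` is applied.
#'
#' @param depositions Deposition table from [segregate_histones()] (plus
#'   a `chrom` column) or from [simulate_experiment()]'s internal
#'   population tally; must have columns `center`, `side`, `daughter`,
#'   `histone_class`, `chrom`, and optionally `n_tetramers` (defaults
#'   to 1).
#' @param config A [simulation_config()].
#' @param mark One of `"BrdU"`, `"H3K4me3"`, `"H3K9me3"`, `"H3K56ac"`.
#' @param params The [genotype_params()] of the sample's genotype.
#' @param sample_id Sample identifier (default `<genotype>.<mark>`).
#' @return A [fragment_set()].
#' @export
emit_fragments <- function(depositions, config, mark, params,
                           sample_id = paste(params$label, mark, sep = ".")) {
  mark <- match.arg(mark, ESPAN_MARKS)
  genome <- config$genome
  if (mark == "BrdU") {
    hw <- config$replicated_halfwidth
    origins <- config$origins
    per_strand_rate <- config$brdu_reads_per_bp / 2
    parts <- vector("list", 2L * nrow(origins))
    for (i in seq_len(nrow(origins))) {
      for (s in c("W", "C")) {
        n <- stats::rpois(1L, 2 * hw * per_strand_rate)
        if (n == 0L) next
        centers <- stats::runif(n, origins$pos[i] - hw, origins$pos[i] + hw)
        lens <- draw_lengths(n, config)
        start <- round(centers - lens / 2)
        parts[[2L * (i - 1L) + (s == "C") + 1L]] <-
          data.frame(chrom = origins$chrom[i], start = start,
                     end = start + lens, strand = s, stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, parts)
    if (is.null(df)) df <- data.frame(chrom = character(0), start = numeric(0),
                                      end = numeric(0), strand = character(0))
  } else {
    cls <- mark_class(mark)
    dep <- depositions[depositions$histone_class == cls, , drop = FALSE]
    if (is.null(dep$n_tetramers)) dep$n_tetramers <- 1
    if (is.null(dep$strand)) dep$strand <- nascent_strand_of(dep$daughter, dep$side)
    rate <- config$reads_per_nucleosome * dep$n_tetramers
    if (cls == "new") rate <- rate * params$density_scale_new
    counts <- stats::rpois(nrow(dep), rate)
    idx <- rep(seq_len(nrow(dep)), counts)
    n <- length(idx)
    lens <- draw_lengths(n, config)
    start <- round(dep$center[idx] - lens / 2)
    df <- data.frame(chrom = dep$chrom[idx], start = start,
                     end = start + lens, strand = dep$strand[idx],
                     stringsAsFactors = FALSE)
  }
  df <- apply_strand_recovery(df, config$strand_recovery_w)
  df <- clip_to_genome(df, genome)
  fragment_set(df$chrom, df$start, df$end, df$strand, genome,
               sample_id = sample_id, genotype_label = params$label, mark = mark)
}

## Deterministic 32-bit seed substream per (genotype, mark) so adding a
## genotype or mark never perturbs the draws of another sample.
substream_seed <- function(master, label) {
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 1048573
  as.integer((as.numeric(master) * 2654435 + h) %% 2147483647)
}

#' Simulate a full eSPAN experiment
#'
#' Generates, for every genotype, a BrdU-input sample plus one eSPAN
#' sample per requested histone mark, all under a single master seed
#' (per-sample substreams keep samples independent and reproducible).
#' The returned manifest records each genotype's ground truth and the
#' closed-form expectations the analysis stages should recover:
#' per-strand parental occupancy `r * p` and `r * (1 - p)`, parental
#' eSPAN bias `2p - 1` on the Watson-leading side, and new-histone bias
#' `r(1 - 2p) / (2 - r)`.
#'
#' @param config A [simulation_config()].
#' @param genotypes List of [genotype_params()] (at least one).
#' @param marks Character vector of histone marks to profile (BrdU is
#'   always generated per genotype and need not be listed).
#' @param analysis_radius Optional bp radius of the downstream bias
#'   window; when larger than `replicated_halfwidth` a warning is raised
#'   and recorded in the manifest, since bins beyond the fork are
#'   unreplicated and will be masked as NaN.
#' @return List with `samples` (named list of [fragment_set()]s, names
#'   `<genotype>.<mark>`) and `manifest` (data.frame of ground truth).
#' @export
simulate_experiment <- function(config, genotypes,
                                marks = c("H3K4me3", "H3K56ac"),
                                analysis_radius = NULL) {
  if (inherits(genotypes, "genotype_params")) genotypes <- list(genotypes)
  if (!length(genotypes)) stop("at least one genotype is required")
  marks <- unique(marks)
  if (!length(marks)) stop("at least one mark is required")
  bad <- setdiff(marks, setdiff(ESPAN_MARKS, "BrdU"))
  if (length(bad)) stop("unknown mark(s): ", paste(bad, collapse = ", "))
  note <- ""
  if (!is.null(analysis_radius) && analysis_radius > config$replicated_halfwidth) {
    note <- sprintf("analysis radius %d exceeds replicated halfwidth %d; outer bins will be NaN",
                    analysis_radius, config$replicated_halfwidth)
    warning(note)
  }
  samples <- list()
  rows <- vector("list", length(genotypes))
  for (gi in seq_along(genotypes)) {
    g <- genotypes[[gi]]
    set.seed(substream_seed(config$seed, paste0(g$label, ".depositions")))
    dep <- build_depositions(config, g)
    for (mk in c("BrdU", marks)) {
      set.seed(substream_seed(config$seed, paste0(g$label, ".", mk)))
      samples[[paste(g$label, mk, sep = ".")]] <-
        emit_fragments(dep, config, mk, g)
    }
    p <- g$p_lead; r <- g$r_recycle
    rows[[gi]] <- data.frame(
      genotype = g$label, p_lead = p, r_recycle = r,
      density_scale_new = g$density_scale_new,
      expected_density_leading = r * p,
      expected_density_lagging = r * (1 - p),
      expected_parental_bias = 2 * p - 1,
      expected_new_bias = r * (1 - 2 * p) / (2 - r),
      note = note, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  attr(manifest, "replicated_halfwidth") <- config$replicated_halfwidth
  list(samples = samples, manifest = manifest)
}
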