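#' Resolve and validate a pipeline run configuration
#'
#' Accepts a YAML file path or a nested list and fills in defaults. Two
#' input modes exist: `simulation` (a simulated experiment defined by
#' geometry plus a genotype table; the default and the one used for
#' validation) and `samples` (already-aligned stranded BED6 fragment
#' files plus `genome`/`origins` paths).
#'
#' @param x YAML path or list.
#' @return A validated list of class `run_config` with all defaults
#'   resolved.
#' @export
run_config <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("config file not found: ", x)
    x <- yaml::read_yaml(x)
  }
  if (!is.list(x)) stop("config must be a YAML file path or a list")
  cfg <- x
  if (is.null(cfg$outdir)) stop("config requires 'outdir'")
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$reference <- cfg$reference %||% "WT"
  an <- cfg$analysis %||% list()
  an$radius <- an$radius %||% 10000
  an$window <- an$window %||% 100
  an$step <- an$step %||% 10
  an$exclude <- an$exclude %||% 300
  an$density_halfwidth <- an$density_halfwidth %||% 2500
  an$density_bin <- an$density_bin %||% 100
  an$filter_halfwidth <- an$filter_halfwidth %||% 1000
  an$filter_threshold <- an$filter_threshold %||% 2
  an$normalization <- an$normalization %||% "none"
  pos_params <- c("radius", "window", "step", "exclude", "density_halfwidth",
                  "density_bin", "filter_halfwidth")
  for (p in pos_params) {
    if (!is.numeric(an[[p]]) || an[[p]] <= 0) {
      stop("analysis parameter '", p, "' must be positive (got ", an[[p]], ")")
    }
  }
  if (!an$normalization %in% c("none", "cpm")) {
    stop("analysis$normalization must be 'none' or 'cpm'")
  }
  cfg$analysis <- an
  cfg$write_bedgraphs <- isTRUE(cfg$write_bedgraphs)
  if (is.null(cfg$simulation) && is.null(cfg$samples)) {
    stop("config requires a 'simulation' or a 'samples' section")
  }
  if (!is.null(cfg$simulation)) {
    sim <- cfg$simulation
    sim$n_origins <- sim$n_origins %||% 200
    sim$origin_spacing <- sim$origin_spacing %||% 30000
    sim$margin <- sim$margin %||% 15000
    sim$replicated_halfwidth <- sim$replicated_halfwidth %||% 5000
    sim$nucleosome_spacing <- sim$nucleosome_spacing %||% 160
    sim$fragment_length_mean <- sim$fragment_length_mean %||% 150
    sim$fragment_length_sd <- sim$fragment_length_sd %||% 15
    sim$reads_per_nucleosome <- sim$reads_per_nucleosome %||% 0.3
    sim$brdu_reads_per_bp <- sim$brdu_reads_per_bp %||% 3
    sim$cells_per_sample <- sim$cells_per_sample %||% 1000
    sim$strand_recovery_w <- sim$strand_recovery_w %||% 1
    sim$marks <- sim$marks %||% c("H3K4me3", "H3K56ac")
    if (is.null(sim$genotypes)) stop("simulation section requires 'genotypes'")
    cfg$simulation <- sim
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Genotype table entries may be preset names or explicit parameter sets.
resolve_genotypes <- function(spec_list) {
  presets <- genotype_presets()
  lapply(spec_list, function(g) {
    if (is.character(g) && length(g) == 1L) {
      if (!g %in% names(presets)) {
        stop("unknown genotype preset '", g, "'; available: ",
             paste(names(presets), collapse = ", "))
      }
      return(presets[[g]])
    }
    genotype_params(g$label, g$p_lead, g$r_recycle,
                    g$density_scale_new %||% 1)
  })
}

#' Run the full eSPAN pipeline
#'
#' Executes simulate (or load) -> coverage -> origin filter -> bias ->
#' density in dependency order, writing every stage artifact plus a run
#' log and the effective configuration into the output directory.
#' Rerunning with an identical configuration and seed reproduces
#' byte-identical tables.
#'
#' Outputs (under `outdir`): `genome.sizes`, `origins.bed`,
#' `origins.filtered.bed`, `manifest.tsv` (simulation ground truth),
#' one BED6 per sample, per eSPAN sample `<sample>.bias.tsv` (heatmap
#' matrix, origins sorted by folded bias), `<sample>.aggregate.tsv` and
#' `<sample>.folded.tsv`, per mark `<mark>.density.tsv` and
#' `<mark>.tests.tsv`, `config_used.yaml`, and `run.log`.
#'
#' @param config A [run_config()], YAML path, or list.
#' @return The output directory path, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  outdir <- cfg$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }
  an <- cfg$analysis
  say("pipeline start; seed=", cfg$seed, "; reference=", cfg$reference)
  say("parameters: radius=", an$radius, " window=", an$window, " step=", an$step,
      " exclude=", an$exclude, " density_halfwidth=", an$density_halfwidth,
      " density_bin=", an$density_bin, " filter_threshold=", an$filter_threshold,
      " normalization=", an$normalization)

  ## --- stage: inputs (simulate or load) ---------------------------------
  if (!is.null(cfg$simulation)) {
    sim <- cfg$simulation
    geo <- sim_genome(sim$n_origins, sim$origin_spacing, sim$margin)
    genome <- geo$genome
    origins <- geo$origins
    scfg <- simulation_config(
      genome, origins,
      replicated_halfwidth = sim$replicated_halfwidth,
      nucleosome_spacing = sim$nucleosome_spacing,
      fragment_length_mean = sim$fragment_length_mean,
      fragment_length_sd = sim$fragment_length_sd,
      reads_per_nucleosome = sim$reads_per_nucleosome,
      brdu_reads_per_bp = sim$brdu_reads_per_bp,
      cells_per_sample = sim$cells_per_sample,
      strand_recovery_w = sim$strand_recovery_w,
      seed = cfg$seed)
    genotypes <- resolve_genotypes(sim$genotypes)
    res <- withCallingHandlers(
      simulate_experiment(scfg, genotypes, marks = sim$marks,
                          analysis_radius = an$radius),
      warning = function(w) {
        say("warning [simulate]: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    samples <- res$samples
    utils::write.table(res$manifest, file.path(outdir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (nm in names(samples)) {
      write_fragments_bed(samples[[nm]], file.path(outdir, paste0(nm, ".bed")))
      say("simulated ", nm, ": ", nrow(samples[[nm]]), " fragments")
    }
  } else {
    genome <- read_chrom_sizes(cfg$genome)
    origins <- read_origins(cfg$origins, genome)
    samples <- list()
    for (s in cfg$samples) {
      nm <- paste(s$genotype, s$mark, sep = ".")
      samples[[nm]] <- read_fragments(s$path, genome, sample_id = nm,
                                      genotype_label = s$genotype, mark = s$mark)
      say("loaded ", nm, ": ", nrow(samples[[nm]]), " fragments")
    }
  }
  write_chrom_sizes(genome, file.path(outdir, "genome.sizes"))
  write_origins_bed(origins, file.path(outdir, "origins.bed"))

  ## --- stage: coverage ---------------------------------------------------
  covs <- list()
  for (nm in names(samples)) {
    covs[[nm]] <- tryCatch(coverage_from_fragments(samples[[nm]], genome),
                           error = function(e) stop("stage coverage, sample ", nm,
                                                    ": ", conditionMessage(e)))
    if (cfg$write_bedgraphs) {
      write_bedgraph(covs[[nm]],
                     file.path(outdir, paste0(nm, ".watson.bedgraph")),
                     file.path(outdir, paste0(nm, ".crick.bedgraph")))
    }
  }
  samples <- NULL  # fragments no longer needed; free the memory

  ## --- stage: origin filter ---------------------------------------------
  is_brdu <- vapply(covs, function(x) x$mark == "BrdU", logical(1))
  ref_brdu <- covs[is_brdu & vapply(covs, function(x)
    identical(x$genotype_label, cfg$reference), logical(1))]
  if (!length(ref_brdu)) {
    stop("stage filter-origins: no BrdU sample for reference genotype '",
         cfg$reference, "'")
  }
  report <- origin_usage_report(origins, ref_brdu,
                                halfwidth = an$filter_halfwidth,
                                threshold = an$filter_threshold)
  origins_used <- withCallingHandlers(
    select_origins(origins, report),
    message = function(m) {
      say("filter-origins: ", trimws(conditionMessage(m)))
      invokeRestart("muffleMessage")
    })
  write_origins_bed(origins_used, file.path(outdir, "origins.filtered.bed"))

  ## --- stage: bias --------------------------------------------------------
  genotype_of <- vapply(covs, function(x) x$genotype_label, character(1))
  for (nm in names(covs)[!is_brdu]) {
    g <- genotype_of[[nm]]
    brdu_nm <- names(covs)[is_brdu & genotype_of == g]
    if (length(brdu_nm) != 1L) {
      stop("stage bias, sample ", nm, ": expected exactly one BrdU sample for genotype ",
           g, ", found ", length(brdu_nm))
    }
    prof <- tryCatch(
      bias_profile(covs[[nm]], covs[[brdu_nm]], origins_used,
                   radius = an$radius, window = an$window, step = an$step,
                   exclude = an$exclude,
                   replicated_halfwidth = if (!is.null(cfg$simulation))
                     cfg$simulation$replicated_halfwidth),
      error = function(e) stop("stage bias, sample ", nm, ": ", conditionMessage(e)))
    bias_heatmap_matrix(prof, path = file.path(outdir, paste0(nm, ".bias.tsv")))
    utils::write.table(prof$aggregate, file.path(outdir, paste0(nm, ".aggregate.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(prof$folded, file.path(outdir, paste0(nm, ".folded.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    say("bias ", nm, ": mean folded ", signif(mean(prof$folded$folded), 4),
        " over ", nrow(prof$folded), " origins")
  }

  ## --- stage: density -----------------------------------------------------
  marks_here <- unique(vapply(covs[!is_brdu], function(x) x$mark, character(1)))
  for (mk in marks_here) {
    entries <- list()
    for (nm in names(covs)[!is_brdu]) {
      if (covs[[nm]]$mark != mk) next
      g <- genotype_of[[nm]]
      brdu_nm <- names(covs)[is_brdu & genotype_of == g]
      entries[[length(entries) + 1L]] <-
        list(genotype = g, espan = covs[[nm]], brdu = covs[[brdu_nm]])
    }
    if (!length(entries)) next
    tab <- tryCatch(
      density_table(entries, origins_used,
                    halfwidth = an$density_halfwidth, bin = an$density_bin,
                    exclude = an$exclude, normalization = an$normalization),
      error = function(e) stop("stage density, mark ", mk, ": ", conditionMessage(e)))
    if (cfg$reference %in% tab$genotype) {
      tab <- fold_change(tab, cfg$reference)
      if (length(unique(tab$genotype)) > 1L) {
        tests <- density_tests(tab, cfg$reference)
        utils::write.table(tests, file.path(outdir, paste0(mk, ".tests.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    density_violin_export(tab, file.path(outdir, paste0(mk, ".density.tsv")))
    say("density ", mk, ": ", nrow(tab), " measurements across ",
        length(unique(tab$genotype)), " genotype(s)")
  }

  ## --- wrap up -------------------------------------------------------------
  cfg_out <- unclass(cfg)
  yaml::write_yaml(cfg_out, file.path(outdir, "config_used.yaml"))
  writeLines(log_lines, file.path(outdir, "run.log"))
  say("pipeline done: ", outdir)
  invisible(outdir)
}
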