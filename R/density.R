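## Bin grid for the density fit: `bin`-bp bins tiling [-halfwidth,
## +halfwidth], keeping only bins entirely outside the origin-proximal
## exclusion zone. Returns offsets of bin starts plus the side of each.
density_bins <- function(halfwidth, bin, exclude) {
  starts <- seq(-halfwidth, halfwidth - bin, by = bin)
  ends <- starts + bin
  keep <- ends <= -exclude | starts >= exclude
  data.frame(start = starts[keep], end = ends[keep],
             side = ifelse(starts[keep] >= 0, "right", "left"))
}

## Strand carrying the requested strand class in each bin, via the fork
## geometry of nascent_strand_of(): leading = right-side Watson bins
## plus left-side Crick bins; lagging is the complement.
class_strand <- function(side, strand_class) {
  daughter <- match.arg(strand_class, c("leading", "lagging"))
  nascent_strand_of(rep(daughter, length(side)), side)
}

#' Fit the per-origin BrdU coefficient for one strand class
#'
#' Expresses a histone-mark eSPAN signal in units of the matched
#' BrdU-input signal: over `bin`-bp bins within `[-halfwidth,
#' +halfwidth]` of the origin (excluding the origin-proximal
#' `exclude`-bp zone), on the strand carrying the requested strand
#' class, the coefficient `c` minimizes `sum((e_k - c * b_k)^2)`, i.e.
#' `c = sum(e * b) / sum(b^2)` (no intercept), clamped at 0. Bins with
#' zero BrdU signal are dropped.
#'
#' @param espan_cov,brdu_cov `strand_coverage` objects on a common
#'   scale.
#' @param chrom,pos Origin location.
#' @param strand_class `"leading"` or `"lagging"`.
#' @param halfwidth Fit half-width, bp (default 2500).
#' @param bin Bin width, bp (default 100).
#' @param exclude Origin-proximal exclusion radius, bp (default 300).
#' @return The coefficient, with attribute `n_bins` (bins used); `NA`
#'   with a warning when every BrdU bin is zero (origin unreplicated in
#'   the window).
#' @export
fit_brdu_coefficient <- function(espan_cov, brdu_cov, chrom, pos,
                                 strand_class = c("leading", "lagging"),
                                 halfwidth = 2500, bin = 100, exclude = 300) {
  strand_class <- match.arg(strand_class)
  bins <- density_bins(halfwidth, bin, exclude)
  strand <- class_strand(bins$side, strand_class)
  len <- chrom_length(espan_cov$genome, chrom)
  starts <- pos + bins$start
  ends <- pos + bins$end
  ok <- starts >= 0 & ends <= len
  e <- b <- rep(NA_real_, nrow(bins))
  for (s in c("W", "C")) {
    sel <- ok & strand == s
    if (!any(sel)) next
    e[sel] <- window_sums_rle(if (s == "W") espan_cov$w[[chrom]] else espan_cov$c[[chrom]],
                              starts[sel], ends[sel])
    b[sel] <- window_sums_rle(if (s == "W") brdu_cov$w[[chrom]] else brdu_cov$c[[chrom]],
                              starts[sel], ends[sel])
  }
  use <- !is.na(b) & b > 0
  if (!any(use)) {
    warning("origin at ", chrom, ":", pos, " (", strand_class,
            "): all BrdU bins zero (unreplicated in window); coefficient NA")
    return(structure(NA_real_, n_bins = 0L))
  }
  cc <- max(0, sum(e[use] * b[use]) / sum(b[use]^2))
  structure(cc, n_bins = sum(use))
}

#' Strand-resolved histone density table across genotypes
#'
#' For every genotype, fits one BrdU coefficient per origin and strand
#' class ([fit_brdu_coefficient()]), giving a dimensionless
#' BrdU-relative density.
#'
#' `normalization` controls the common scale the samples are put on
#' before fitting. `"none"` (default) fits raw fragment coverage, which
#' keeps densities proportional to absolute per-strand histone
#' occupancy whenever library yield tracks chromatin abundance (true of
#' the simulator, or of spike-in calibrated libraries). `"cpm"` rescales
#' each sample to counts per million of its own total first, the
#' conventional treatment when sequencing depths are arbitrary; note
#' that per-sample totals then absorb any genome-wide change in histone
#' recycling, so genotype fold changes report redistribution between
#' strands rather than absolute retention.
#'
#' @param samples A list; each element a list with fields `genotype`,
#'   `espan` (a [fragment_set()] or `strand_coverage`) and `brdu`
#'   (likewise, mark `"BrdU"`). Each genotype must have its own BrdU
#'   sample; two genotypes sharing one BrdU sample id is an error.
#' @param origins An [origin_set()].
#' @param genome A [genome_spec()] (needed when fragment sets are
#'   passed).
#' @param halfwidth,bin,exclude See [fit_brdu_coefficient()].
#' @param normalization `"none"` or `"cpm"` (see above).
#' @return A data.frame of class `density_table` with columns
#'   `origin_id`, `strand_class`, `genotype`, `density`, `n_bins`, and
#'   a `fold_change` column filled by [fold_change()].
#' @export
density_table <- function(samples, origins, genome = NULL,
                          halfwidth = 2500, bin = 100, exclude = 300,
                          normalization = c("none", "cpm")) {
  normalization <- match.arg(normalization)
  if (!length(samples)) stop("no samples given")
  as_cov <- function(x) {
    if (inherits(x, "strand_coverage")) return(x)
    if (inherits(x, "fragment_set")) {
      if (is.null(genome)) stop("genome required when passing fragment sets")
      return(coverage_from_fragments(x, genome))
    }
    stop("samples must hold fragment_set or strand_coverage objects")
  }
  genotypes <- vapply(samples, function(s) s$genotype, character(1))
  if (anyDuplicated(genotypes)) stop("duplicated genotype in samples")
  brdu_ids <- vapply(samples, function(s) {
    id <- if (inherits(s$brdu, "strand_coverage")) s$brdu$sample_id else attr(s$brdu, "sample_id")
    if (is.null(id)) NA_character_ else id
  }, character(1))
  dup <- duplicated(brdu_ids) & !is.na(brdu_ids)
  if (any(dup)) {
    stop("genotypes ", paste(genotypes[brdu_ids %in% brdu_ids[dup]], collapse = ", "),
         " share a BrdU sample ('", brdu_ids[dup][1L],
         "'); each genotype needs its own matched BrdU input")
  }
  rows <- list()
  for (s in samples) {
    if (is.null(s$brdu)) stop("genotype ", s$genotype, " is missing a BrdU sample")
    ecov <- as_cov(s$espan)
    bcov <- as_cov(s$brdu)
    if (bcov$mark != "BrdU") stop("genotype ", s$genotype, ": brdu sample has mark ", bcov$mark)
    if (normalization == "cpm") {
      if (!ecov$scaled) ecov <- cpm_scale(ecov)
      if (!bcov$scaled) bcov <- cpm_scale(bcov)
    }
    for (cl in c("leading", "lagging")) {
      dens <- nb <- numeric(nrow(origins))
      for (i in seq_len(nrow(origins))) {
        co <- fit_brdu_coefficient(ecov, bcov, origins$chrom[i], origins$pos[i],
                                   cl, halfwidth, bin, exclude)
        dens[i] <- as.numeric(co)
        nb[i] <- attr(co, "n_bins")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        origin_id = origins$origin_id, strand_class = cl,
        genotype = s$genotype, density = dens, n_bins = nb,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$fold_change <- NA_real_
  dropped <- sum(is.na(out$density))
  if (dropped > 0) message(dropped, " origin/strand combinations dropped (no BrdU signal)")
  attr(out, "params") <- list(halfwidth = halfwidth, bin = bin,
                              exclude = exclude, normalization = normalization)
  class(out) <- c("density_table", "data.frame")
  out
}

#' Fill genotype-vs-reference fold changes
#'
#' Per origin and strand class, each genotype's density divided by the
#' reference genotype's density at the same origin and strand class;
#' `NaN` (with a warning) where the reference density is zero.
#'
#' @param table A [density_table()].
#' @param reference_genotype Reference genotype label (present in the
#'   table).
#' @return The table with `fold_change` filled and the reference
#'   recorded in `attr(, "reference_genotype")`.
#' @export
fold_change <- function(table, reference_genotype) {
  if (!reference_genotype %in% table$genotype) {
    stop("reference genotype '", reference_genotype, "' not in table")
  }
  ref <- table[table$genotype == reference_genotype, ]
  key <- function(d) paste(d$origin_id, d$strand_class)
  ref_density <- ref$density[match(key(table), key(ref))]
  zero_ref <- !is.na(ref_density) & ref_density == 0
  if (any(zero_ref)) {
    warning(sum(zero_ref), " measurement(s) with zero reference density; fold change NaN")
  }
  table$fold_change <- ifelse(zero_ref, NaN, table$density / ref_density)
  attr(table, "reference_genotype") <- reference_genotype
  table
}

#' Mean per-origin fold change per genotype and strand class
#'
#' @param table A [fold_change()]-filled [density_table()].
#' @return A data.frame with columns `genotype`, `strand_class`,
#'   `mean_fold_change`, `n_origins`.
#' @export
fold_change_summary <- function(table) {
  fin <- is.finite(table$fold_change)
  agg <- stats::aggregate(fold_change ~ genotype + strand_class,
                          data = table[fin, , drop = FALSE], FUN = mean)
  n <- stats::aggregate(fold_change ~ genotype + strand_class,
                        data = table[fin, , drop = FALSE], FUN = length)
  data.frame(genotype = agg$genotype, strand_class = agg$strand_class,
             mean_fold_change = agg$fold_change, n_origins = n$fold_change,
             stringsAsFactors = FALSE)
}

#' Welch two-sample t-test of per-origin densities
#'
#' Compares the per-origin density values of two genotypes for one
#' strand class with an unequal-variance (Welch) two-sided t-test.
#'
#' @param table A [density_table()].
#' @param genotype_a,genotype_b Genotype labels.
#' @param strand_class `"leading"` or `"lagging"`.
#' @return A list with `t`, `p`, `n_a`, `n_b`, `mean_a`, `mean_b`.
#' @export
compare_density <- function(table, genotype_a, genotype_b,
                            strand_class = c("leading", "lagging")) {
  strand_class <- match.arg(strand_class)
  pick <- function(g) {
    v <- table$density[table$genotype == g & table$strand_class == strand_class]
    v[is.finite(v)]
  }
  a <- pick(genotype_a); b <- pick(genotype_b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("need >= 2 origins per group (got ", length(a), " and ", length(b), ")")
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value,
       n_a = length(a), n_b = length(b),
       mean_a = mean(a), mean_b = mean(b))
}

#' All-genotypes-vs-reference density tests
#'
#' Runs [compare_density()] for every non-reference genotype and strand
#' class; raw p-values are reported alongside a Bonferroni column for
#' transparency (no correction is applied to the primary column).
#'
#' @param table A [density_table()].
#' @param reference_genotype Reference genotype label.
#' @return A data.frame with one row per genotype/strand class.
#' @export
density_tests <- function(table, reference_genotype) {
  gts <- setdiff(unique(table$genotype), reference_genotype)
  rows <- list()
  for (g in gts) {
    for (cl in c("leading", "lagging")) {
      r <- compare_density(table, g, reference_genotype, cl)
      rows[[length(rows) + 1L]] <- data.frame(
        genotype = g, strand_class = cl, t = r$t, p = r$p,
        n = r$n_a, n_ref = r$n_b, mean = r$mean_a, mean_ref = r$mean_b,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out
}

#' Export the density table in long format
#'
#' One row per measurement with columns `origin_id`, `genotype`,
#' `strand_class`, `density`, `fold_change` — the layout violin plots
#' are drawn from.
#'
#' @param table A [density_table()].
#' @param path Optional TSV output path.
#' @return The long-format data.frame, invisibly when `path` is given.
#' @export
density_violin_export <- function(table, path = NULL) {
  out <- data.frame(origin_id = table$origin_id, genotype = table$genotype,
                    strand_class = table$strand_class, density = table$density,
                    fold_change = table$fold_change, stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
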