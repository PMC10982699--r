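#' Per-base Watson/Crick coverage from a fragment set
#'
#' Coverage is full-fragment overlap counting at 1-bp resolution, held
#' as one run-length-encoded vector per chromosome per strand. The
#' base-mass identity `sum(w + c) == sum(fragment lengths)` holds
#' exactly.
#'
#' @param frags A [fragment_set()].
#' @param genome The [genome_spec()] the fragments were validated
#'   against; vectors are allocated at each declared chromosome length.
#' @return An object of class `strand_coverage` with fields `w` and `c`
#'   (named lists of integer [S4Vectors::Rle], one per chromosome),
#'   `genome`, `total_fragments` and sample metadata.
#' @export
coverage_from_fragments <- function(frags, genome) {
  if (!inherits(frags, "fragment_set")) stop("frags must be a fragment_set")
  if (nrow(frags) > 0L) {
    check_intervals(genome, frags$chrom, frags$start, frags$end, what = "fragment")
  }
  one_strand <- function(s) {
    sel <- frags$strand == s
    out <- vector("list", length(genome$chrom_names))
    names(out) <- genome$chrom_names
    for (chrom in genome$chrom_names) {
      len <- unname(genome$chrom_lengths[chrom])
      i <- sel & frags$chrom == chrom
      if (!any(i)) {
        out[[chrom]] <- S4Vectors::Rle(0L, len)
      } else {
        ir <- IRanges::IRanges(start = frags$start[i] + 1L, end = frags$end[i])
        out[[chrom]] <- IRanges::coverage(ir, width = len)
      }
    }
    out
  }
  structure(list(w = one_strand("W"), c = one_strand("C"),
                 genome = genome,
                 total_fragments = nrow(frags),
                 sample_id = attr(frags, "sample_id"),
                 genotype_label = attr(frags, "genotype_label"),
                 mark = attr(frags, "mark"),
                 scaled = FALSE, scale_factor = 1),
            class = "strand_coverage")
}

#' @export
print.strand_coverage <- function(x, ...) {
  cat("strand_coverage '", x$sample_id, "': ", x$total_fragments,
      " fragments (", x$mark, ", genotype ", x$genotype_label, ")",
      if (x$scaled) " [CPM-scaled]", "\n", sep = "")
  invisible(x)
}

#' Scale coverage to counts per million fragments
#'
#' Multiplies both strand vectors by `1e6 / total_fragments`. Scaling an
#' already scaled object is an error (the `scaled` flag guards against
#' double normalization).
#'
#' @param cov A [coverage_from_fragments()] result.
#' @return The scaled `strand_coverage` (real-valued vectors).
#' @export
cpm_scale <- function(cov) {
  if (!inherits(cov, "strand_coverage")) stop("cov must be a strand_coverage")
  if (cov$scaled) stop("coverage is already CPM-scaled")
  if (cov$total_fragments == 0) stop("empty sample cannot be normalized")
  f <- 1e6 / cov$total_fragments
  cov$w <- lapply(cov$w, function(r) r * f)
  cov$c <- lapply(cov$c, function(r) r * f)
  cov$scaled <- TRUE
  cov$scale_factor <- f
  cov
}

## Multiply all coverage vectors by a constant (used in tests for scale
## invariance and internally for custom normalizations).
scale_coverage <- function(cov, k) {
  cov$w <- lapply(cov$w, function(r) r * k)
  cov$c <- lapply(cov$c, function(r) r * k)
  cov$scale_factor <- cov$scale_factor * k
  cov
}

#' Total coverage of one strand over an interval
#'
#' @param cov A `strand_coverage`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval bounds.
#' @param strand `"W"` or `"C"`.
#' @return The exact sum of the strand vector over `[start, end)`.
#' @export
window_sum <- function(cov, chrom, start, end, strand = c("W", "C")) {
  strand <- match.arg(strand)
  len <- chrom_length(cov$genome, chrom)
  if (length(start) != 1L || length(end) != 1L ||
      start < 0 || end > len || start >= end) {
    stop("window [", start, ", ", end, ") out of range on ", chrom,
         " (length ", len, ")")
  }
  r <- if (strand == "W") cov$w[[chrom]] else cov$c[[chrom]]
  sum(as.numeric(S4Vectors::window(r, start + 1L, end)))
}

## Vectorized window sums over one chromosome strand vector (0-based
## half-open starts/ends); windows must already be range-checked.
window_sums_rle <- function(rle, starts, ends) {
  v <- IRanges::Views(rle, start = starts + 1L, end = ends)
  as.numeric(IRanges::viewSums(v))
}

## Sum of w + c over the whole genome (used by enrichment and audits).
total_mass <- function(cov) {
  sum(vapply(cov$w, function(r) sum(as.numeric(S4Vectors::runValue(r)) *
                                      as.numeric(S4Vectors::runLength(r))), numeric(1))) +
    sum(vapply(cov$c, function(r) sum(as.numeric(S4Vectors::runValue(r)) *
                                        as.numeric(S4Vectors::runLength(r))), numeric(1)))
}
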