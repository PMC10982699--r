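#' Per-origin sliding-window strand-partition bias
#'
#' For each origin and each window center `t` on the step grid spanning
#' `[-radius, +radius]`, sums Watson and Crick coverage over the 100-bp
#' (by default) window `[t - window/2, t + window/2)` and computes
#' `bias = (W - C) / (W + C)`. Windows with `W + C = 0` and windows
#' extending past a chromosome end are `NaN`.
#'
#' @param cov A [coverage_from_fragments()] result.
#' @param origins An [origin_set()].
#' @param radius Profile half-width around each origin, bp.
#' @param window Sliding-window width, bp.
#' @param step Step of the window-center grid, bp.
#' @return Numeric matrix (origins x bins) with origin ids as rownames
#'   and window-center offsets as colnames; finite entries lie in
#'   `[-1, 1]`.
#' @export
windowed_bias <- function(cov, origins, radius = 10000, window = 100, step = 10) {
  if (window < 1 || step < 1 || radius < 1) {
    stop("radius, window and step must be >= 1")
  }
  centers <- seq(-radius, radius, by = step)
  lo <- floor(window / 2)          # window = [t - lo, t + hi)
  hi <- ceiling(window / 2)
  mat <- matrix(NaN, nrow = nrow(origins), ncol = length(centers),
                dimnames = list(origins$origin_id, centers))
  for (i in seq_len(nrow(origins))) {
    chrom <- origins$chrom[i]
    len <- chrom_length(cov$genome, chrom)
    starts <- origins$pos[i] + centers - lo
    ends <- origins$pos[i] + centers + hi
    ok <- starts >= 0 & ends <= len
    if (!any(ok)) {
      warning("origin ", origins$origin_id[i],
              ": profile window entirely off-chromosome; row is NaN")
      next
    }
    w <- window_sums_rle(cov$w[[chrom]], starts[ok], ends[ok])
    c_ <- window_sums_rle(cov$c[[chrom]], starts[ok], ends[ok])
    tot <- w + c_
    b <- ifelse(tot > 0, (w - c_) / tot, NaN)
    mat[i, ok] <- b
  }
  attr(mat, "bin_centers") <- centers
  mat
}

#' Subtract the matched BrdU bias matrix from an eSPAN bias matrix
#'
#' Cancels technical Watson/Crick asymmetries (e.g. strand-specific
#' recovery in library preparation) shared between the eSPAN and the
#' BrdU-input sample of the same genotype. `NaN` propagates from either
#' operand.
#'
#' @param espan_bias,brdu_bias Congruent matrices from
#'   [windowed_bias()] (same origins, same bins).
#' @return The elementwise difference; finite entries lie in `[-2, 2]`.
#' @export
subtract_brdu <- function(espan_bias, brdu_bias) {
  if (!identical(dim(espan_bias), dim(brdu_bias)) ||
      !identical(dimnames(espan_bias), dimnames(brdu_bias))) {
    stop("bias matrices are not congruent (origins/bins differ): ",
         nrow(espan_bias), "x", ncol(espan_bias), " eSPAN vs ",
         nrow(brdu_bias), "x", ncol(brdu_bias), " BrdU")
  }
  out <- espan_bias - brdu_bias
  attr(out, "bin_centers") <- attr(espan_bias, "bin_centers")
  out
}

#' Aggregate a bias matrix across origins
#'
#' Per-bin arithmetic mean over origins with finite values, with a
#' ribbon half-width of twice the standard error; bins with fewer than
#' two finite values are reported `NaN`.
#'
#' @param mat Bias matrix from [windowed_bias()] or [subtract_brdu()].
#' @return A data.frame with columns `bin_center`, `mean`, `halfwidth`
#'   (2 x SE) and `n` (finite origins per bin).
#' @export
aggregate_bias <- function(mat) {
  fin <- is.finite(mat)
  n <- colSums(fin)
  m <- ifelse(n >= 2, colMeans(mat, na.rm = TRUE), NaN)
  sd_ <- apply(mat, 2L, function(col) stats::sd(col[is.finite(col)]))
  hw <- ifelse(n >= 2, 2 * sd_ / sqrt(n), NaN)
  centers <- attr(mat, "bin_centers")
  if (is.null(centers)) centers <- as.numeric(colnames(mat))
  data.frame(bin_center = centers, mean = m, halfwidth = hw, n = n,
             row.names = NULL)
}

#' Per-origin side means and folded leading-strand bias
#'
#' Averages each origin's finite bias bins on the left and right of the
#' origin (excluding bins within `exclude` bp, where leading/lagging
#' identity is undefined at the initiation point) and folds them using
#' the fork-geometry convention of [nascent_strand_of()] (right side:
#' Watson = leading), so positive folded values mean leading-strand
#' preference: `folded = (right - left) / 2`.
#'
#' @param mat Bias matrix (typically BrdU-subtracted).
#' @param exclude Origin-proximal exclusion radius, bp (default 300).
#' @return A data.frame with columns `origin_id`, `left`, `right`,
#'   `folded`; origins with one side entirely `NaN` are dropped with a
#'   warning.
#' @export
side_resolved_bias <- function(mat, exclude = 300) {
  centers <- attr(mat, "bin_centers")
  if (is.null(centers)) centers <- as.numeric(colnames(mat))
  left <- centers < -exclude
  right <- centers > exclude
  if (!any(left) || !any(right)) stop("no bins outside the exclusion zone")
  row_mean <- function(row, sel) {
    v <- row[sel]
    v <- v[is.finite(v)]
    if (!length(v)) NaN else mean(v)
  }
  lm <- apply(mat, 1L, row_mean, sel = left)
  rm_ <- apply(mat, 1L, row_mean, sel = right)
  keep <- is.finite(lm) & is.finite(rm_)
  if (any(!keep)) {
    warning(sum(!keep), " origin(s) dropped from side-resolved bias (one side entirely NaN)")
  }
  data.frame(origin_id = rownames(mat)[keep], left = lm[keep],
             right = rm_[keep], folded = (rm_[keep] - lm[keep]) / 2,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Full per-origin bias profile with BrdU normalization
#'
#' Convenience wrapper running [windowed_bias()] on an eSPAN and its
#' matched BrdU-input coverage, subtracting the BrdU bias, and
#' aggregating across origins.
#'
#' @param espan_cov,brdu_cov `strand_coverage` objects for the eSPAN
#'   sample and the BrdU input of the same genotype; a genotype mismatch
#'   is an error unless `allow_mismatch = TRUE`.
#' @param origins An [origin_set()].
#' @param radius,window,step See [windowed_bias()].
#' @param exclude Origin-proximal exclusion for the folded summary, bp.
#' @param replicated_halfwidth Optional distance the forks travel (bp;
#'   known for simulated data, recorded in the simulation manifest).
#'   When given and smaller than `radius`, bins whose window is not
#'   entirely inside the replicated interval are masked `NaN`: beyond
#'   the fork only fragment spill-over remains and its near-empty
#'   windows produce unstable bias values.
#' @param allow_mismatch Set `TRUE` to pair samples across genotypes.
#' @return An object of class `bias_profile` with elements `raw`,
#'   `brdu`, `normalized` (matrices), `aggregate` (of the normalized
#'   matrix), `aggregate_raw`, `folded` (from [side_resolved_bias()]),
#'   and the parameters used.
#' @export
bias_profile <- function(espan_cov, brdu_cov, origins, radius = 10000,
                         window = 100, step = 10, exclude = 300,
                         replicated_halfwidth = NULL, allow_mismatch = FALSE) {
  if (!allow_mismatch &&
      !identical(espan_cov$genotype_label, brdu_cov$genotype_label)) {
    stop("genotype mismatch between eSPAN ('", espan_cov$genotype_label,
         "') and BrdU ('", brdu_cov$genotype_label,
         "') samples; use allow_mismatch = TRUE to override")
  }
  if (brdu_cov$mark != "BrdU") stop("brdu_cov must be a BrdU sample")
  raw <- windowed_bias(espan_cov, origins, radius, window, step)
  brdu <- windowed_bias(brdu_cov, origins, radius, window, step)
  if (!is.null(replicated_halfwidth)) {
    centers <- attr(raw, "bin_centers")
    outside <- abs(centers) > replicated_halfwidth - window / 2
    raw[, outside] <- NaN
    brdu[, outside] <- NaN
  }
  normalized <- subtract_brdu(raw, brdu)
  structure(list(raw = raw, brdu = brdu, normalized = normalized,
                 aggregate = aggregate_bias(normalized),
                 aggregate_raw = aggregate_bias(raw),
                 folded = side_resolved_bias(normalized, exclude = exclude),
                 sample_id = espan_cov$sample_id, mark = espan_cov$mark,
                 genotype_label = espan_cov$genotype_label,
                 params = list(radius = radius, window = window, step = step,
                               exclude = exclude)),
            class = "bias_profile")
}

#' @export
print.bias_profile <- function(x, ...) {
  cat("bias_profile '", x$sample_id, "' (", x$mark, ", genotype ",
      x$genotype_label, "): ", nrow(x$raw), " origins x ", ncol(x$raw),
      " bins; mean folded bias ",
      signif(mean(x$folded$folded), 3), "\n", sep = "")
  invisible(x)
}

#' Origin-sorted heatmap matrix of normalized bias
#'
#' Rows ordered by the sort key (default: descending folded bias, ties
#' broken by origin id); values are unchanged. Optionally written as
#' TSV via [write_matrix_tsv()].
#'
#' @param profile A [bias_profile()].
#' @param sort_by `"folded"` (descending folded bias) or `"origin"`
#'   (origin id order).
#' @param path Optional TSV output path.
#' @return The reordered normalized matrix (origins with no folded
#'   summary sort last).
#' @export
bias_heatmap_matrix <- function(profile, sort_by = c("folded", "origin"),
                                path = NULL) {
  sort_by <- match.arg(sort_by)
  mat <- profile$normalized
  ids <- rownames(mat)
  if (sort_by == "folded") {
    folded <- profile$folded$folded[match(ids, profile$folded$origin_id)]
    ord <- order(-folded, ids, na.last = TRUE)
  } else {
    ord <- order(ids)
  }
  out <- mat[ord, , drop = FALSE]
  attr(out, "bin_centers") <- attr(mat, "bin_centers")
  if (!is.null(path)) write_matrix_tsv(out, path)
  out
}
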