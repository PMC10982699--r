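#' BrdU enrichment of an origin
#'
#' Mean total (W + C) BrdU coverage within `halfwidth` bp of the origin
#' divided by the genome-wide mean coverage. Values near 1 indicate no
#' local replication signal; fired origins in a partially replicated
#' genome score well above 1.
#'
#' @param brdu_cov A `strand_coverage` of a BrdU sample.
#' @param chrom,pos Origin location.
#' @param halfwidth Window half-width, bp (default 1000).
#' @return The enrichment ratio (>= 0).
#' @export
brdu_enrichment <- function(brdu_cov, chrom, pos, halfwidth = 1000) {
  genome_bp <- sum(brdu_cov$genome$chrom_lengths)
  gw_mean <- total_mass(brdu_cov) / genome_bp
  if (gw_mean == 0) stop("zero genome-wide coverage; cannot compute enrichment")
  len <- chrom_length(brdu_cov$genome, chrom)
  start <- max(0, pos - halfwidth)
  end <- min(len, pos + halfwidth)
  local <- (window_sum(brdu_cov, chrom, start, end, "W") +
            window_sum(brdu_cov, chrom, start, end, "C")) / (end - start)
  local / gw_mean
}

#' Per-origin, per-sample BrdU usage report
#'
#' Computes [brdu_enrichment()] for every origin in every
#' reference-genotype BrdU sample and flags origins passing the
#' threshold in each sample, plus a `consistent` flag (pass in all
#' samples).
#'
#' @param origins An [origin_set()].
#' @param brdu_covs Named list of BrdU `strand_coverage` objects
#'   (reference replicates).
#' @param halfwidth Window half-width, bp.
#' @param threshold Enrichment required to pass (default 2).
#' @return A data.frame of class `origin_usage_report` with one row per
#'   origin: enrichment and pass columns per sample, and `consistent`.
#' @export
origin_usage_report <- function(origins, brdu_covs, halfwidth = 1000,
                                threshold = 2) {
  if (!length(brdu_covs)) stop("at least one BrdU sample is required")
  if (is.null(names(brdu_covs))) {
    names(brdu_covs) <- paste0("sample_", seq_along(brdu_covs))
  }
  out <- data.frame(origin_id = origins$origin_id, stringsAsFactors = FALSE)
  pass_all <- rep(TRUE, nrow(origins))
  for (nm in names(brdu_covs)) {
    enr <- vapply(seq_len(nrow(origins)), function(i) {
      brdu_enrichment(brdu_covs[[nm]], origins$chrom[i], origins$pos[i], halfwidth)
    }, numeric(1))
    out[[paste0("enrichment.", nm)]] <- enr
    out[[paste0("pass.", nm)]] <- enr >= threshold
    pass_all <- pass_all & (enr >= threshold)
  }
  out$consistent <- pass_all
  attr(out, "threshold") <- threshold
  attr(out, "halfwidth") <- halfwidth
  class(out) <- c("origin_usage_report", "data.frame")
  out
}

#' Select origins with consistent BrdU signal
#'
#' Keeps origins whose enrichment is at or above `threshold` in every
#' reference sample of the report. Raising the threshold never enlarges
#' the retained set, and filtering an already filtered set with the
#' same report is the identity.
#'
#' @param origins An [origin_set()].
#' @param report An [origin_usage_report()] covering all `origins`.
#' @param threshold Enrichment threshold (default: the report's).
#' @return The filtered [origin_set()].
#' @export
select_origins <- function(origins, report, threshold = NULL) {
  idx <- match(origins$origin_id, report$origin_id)
  if (any(is.na(idx))) {
    stop("report does not cover origin(s): ",
         paste(origins$origin_id[is.na(idx)][1:min(3, sum(is.na(idx)))], collapse = ", "))
  }
  enr_cols <- grep("^enrichment\\.", names(report), value = TRUE)
  if (is.null(threshold)) threshold <- attr(report, "threshold")
  keep <- rep(TRUE, nrow(origins))
  for (cc in enr_cols) keep <- keep & report[[cc]][idx] >= threshold
  message(sum(keep), " of ", nrow(origins), " origins retained at enrichment >= ",
          threshold)
  out <- origins[keep, , drop = FALSE]
  attr(out, "provenance") <- paste0(attr(origins, "provenance"),
                                    " | filtered at enrichment >= ", threshold)
  class(out) <- c("origin_set", "data.frame")
  out
}
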