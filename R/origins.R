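#' Construct a set of replication origins
#'
#' Origins are points (0-based base-pair positions) around which bias
#' profiles and density fits are computed. The set is kept sorted by
#' (chromosome order as declared in the genome, position).
#'
#' @param chrom Character vector of chromosome names.
#' @param pos Numeric vector of 0-based positions, strictly inside the
#'   chromosome.
#' @param origin_id Character vector of unique identifiers; generated as
#'   `origin_<k>` when `NULL`.
#' @param genome A [genome_spec()] used for validation and chromosome
#'   ordering.
#' @param provenance Free-text label recording where the list came from.
#' @return A data.frame of class `origin_set` with columns `chrom`,
#'   `pos`, `origin_id`.
#' @export
origin_set <- function(chrom, pos, origin_id = NULL, genome, provenance = "unspecified") {
  chrom <- as.character(chrom)
  pos <- as.numeric(pos)
  if (length(chrom) == 1L) chrom <- rep(chrom, length(pos))
  if (length(chrom) != length(pos)) stop("chrom and pos lengths differ")
  if (is.null(origin_id)) {
    origin_id <- paste0("origin_", seq_along(pos))
  }
  origin_id <- as.character(origin_id)
  if (anyDuplicated(origin_id)) {
    stop("origin ids must be unique; duplicated: ",
         paste(unique(origin_id[duplicated(origin_id)]), collapse = ", "))
  }
  len <- genome$chrom_lengths[chrom]
  if (any(is.na(len))) {
    bad <- which(is.na(len))[1L]
    stop("origin ", origin_id[bad], ": chromosome not declared: ", chrom[bad])
  }
  bad <- which(pos < 0 | pos >= len)
  if (length(bad)) {
    b <- bad[1L]
    stop("origin ", origin_id[b], ": position ", pos[b],
         " outside [0, ", len[b], ") on ", chrom[b])
  }
  ord <- order(match(chrom, genome$chrom_names), pos)
  out <- data.frame(chrom = chrom[ord], pos = pos[ord],
                    origin_id = origin_id[ord], stringsAsFactors = FALSE)
  attr(out, "provenance") <- provenance
  class(out) <- c("origin_set", "data.frame")
  out
}

#' Read replication origins from a BED file
#'
#' Each BED3+ interval is converted to a point at the integer midpoint
#' `floor((start + end) / 2)`. Identifiers come from the BED name column
#' when present, otherwise `origin_<k>` in file order.
#'
#' @param path BED file path.
#' @param genome A [genome_spec()]; intervals off a declared chromosome
#'   are an error.
#' @param provenance Free-text provenance label (default: the file path).
#' @return An [origin_set()].
#' @export
read_origins <- function(path, genome, provenance = path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) stop("no BED records in ", path)
  chrom <- character(length(idx)); start <- numeric(length(idx))
  end <- numeric(length(idx)); name <- character(length(idx))
  for (i in seq_along(idx)) {
    ln <- idx[i]
    f <- strsplit(trimws(lines[ln]), "[ \t]+")[[1L]]
    if (length(f) < 3L) {
      stop("parse error at line ", ln, " of ", path, ": fewer than 3 fields")
    }
    s <- suppressWarnings(as.numeric(f[2L])); e <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(s) || is.na(e)) {
      stop("parse error at line ", ln, " of ", path, ": non-numeric coordinates")
    }
    if (s >= e) {
      stop("parse error at line ", ln, " of ", path,
           ": empty or inverted interval [", s, ", ", e, ")")
    }
    chrom[i] <- f[1L]; start[i] <- s; end[i] <- e
    name[i] <- if (length(f) >= 4L && nzchar(f[4L]) && f[4L] != ".") f[4L] else paste0("origin_", i)
  }
  check_intervals(genome, chrom, start, end, what = "origin record")
  origin_set(chrom, floor((start + end) / 2), name, genome, provenance = provenance)
}

#' Write origins as BED intervals of width 1
#'
#' @param origins An [origin_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_origins_bed <- function(origins, path) {
  utils::write.table(
    data.frame(origins$chrom,
               format(origins$pos, scientific = FALSE, trim = TRUE),
               format(origins$pos + 1, scientific = FALSE, trim = TRUE),
               origins$origin_id),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
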