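#' Declare a genome as an ordered set of chromosome lengths
#'
#' All coordinates in the package are 0-based, half-open (BED convention).
#' Every interval handed to a reader or to the simulator is validated
#' against the declared genome; records falling outside a declared
#' chromosome are rejected, never clamped.
#'
#' @param chrom_names Character vector of unique chromosome names.
#' @param chrom_lengths Integer vector of chromosome lengths in base
#'   pairs, parallel to `chrom_names`; every length must be >= 1.
#' @return An object of class `genome_spec`.
#' @examples
#' genome_spec(c("chrI", "chrII"), c(1e5, 2e5))
#' @export
genome_spec <- function(chrom_names, chrom_lengths) {
  chrom_names <- as.character(chrom_names)
  chrom_lengths <- as.numeric(chrom_lengths)
  if (length(chrom_names) != length(chrom_lengths)) {
    stop("chrom_names and chrom_lengths must have the same length")
  }
  if (length(chrom_names) == 0L) stop("a genome needs at least one chromosome")
  if (anyDuplicated(chrom_names)) {
    stop("duplicate chromosome name: ",
         paste(unique(chrom_names[duplicated(chrom_names)]), collapse = ", "))
  }
  if (any(is.na(chrom_lengths)) || any(chrom_lengths < 1) ||
      any(chrom_lengths != floor(chrom_lengths))) {
    stop("chromosome lengths must be positive integers")
  }
  structure(
    list(chrom_names = chrom_names,
         chrom_lengths = stats::setNames(chrom_lengths, chrom_names)),
    class = "genome_spec"
  )
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("genome_spec:", length(x$chrom_names), "chromosome(s),",
      format(sum(x$chrom_lengths), big.mark = ","), "bp total\n")
  invisible(x)
}

chrom_length <- function(genome, chrom) {
  len <- genome$chrom_lengths[chrom]
  if (any(is.na(len))) {
    stop("chromosome not declared in genome: ",
         paste(unique(chrom[is.na(len)]), collapse = ", "))
  }
  unname(len)
}

## Strict interval check against the genome; `what` names the records in
## the error message so callers can point at the offending line/record.
check_intervals <- function(genome, chrom, start, end, what = "record") {
  len <- genome$chrom_lengths[as.character(chrom)]
  if (any(is.na(len))) {
    bad <- which(is.na(len))[1L]
    stop(what, " ", bad, ": chromosome not declared in genome: ", chrom[bad])
  }
  bad <- which(start < 0 | end > len | start >= end)
  if (length(bad)) {
    b <- bad[1L]
    stop(what, " ", b, ": interval [", start[b], ", ", end[b],
         ") is invalid on ", chrom[b], " (length ", len[b], ")")
  }
  invisible(TRUE)
}

#' Read a two-column chrom.sizes table
#'
#' @param path Path to a whitespace-delimited file with columns
#'   chromosome name and length.
#' @return A [genome_spec()].
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  genome_spec(tab$chrom, tab$length)
}

#' Write a chrom.sizes table
#'
#' @param genome A [genome_spec()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(genome, path) {
  utils::write.table(
    data.frame(chrom = genome$chrom_names,
               length = format(unname(genome$chrom_lengths), scientific = FALSE, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
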