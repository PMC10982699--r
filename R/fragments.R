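## Recognized sample marks and the histone class each one reports.
ESPAN_MARKS <- c("BrdU", "H3K4me3", "H3K9me3", "H3K56ac")

#' Histone class reported by a chromatin mark
#'
#' `H3K4me3` and `H3K9me3` travel with recycled parental H3-H4 tetramers;
#' `H3K56ac` marks newly synthesized H3; `BrdU` labels replicated DNA
#' irrespective of chromatin.
#'
#' @param mark One of `"BrdU"`, `"H3K4me3"`, `"H3K9me3"`, `"H3K56ac"`.
#' @return `"replication"`, `"parental"`, or `"new"`.
#' @export
mark_class <- function(mark) {
  switch(match.arg(mark, ESPAN_MARKS),
         BrdU = "replication",
         H3K4me3 = "parental",
         H3K9me3 = "parental",
         H3K56ac = "new")
}

#' Construct a stranded nascent-DNA fragment set
#'
#' Fragments are 0-based half-open intervals with a strand label:
#' `W` (Watson, the BED `+` strand) or `C` (Crick, `-`). The set is
#' treated as already deduplicated; upstream alignment and duplicate
#' filtering are out of scope.
#'
#' @param chrom,start,end,strand Parallel vectors describing the
#'   fragments; `strand` must be exactly `"W"` or `"C"`.
#' @param genome A [genome_spec()] for validation.
#' @param sample_id Sample identifier.
#' @param genotype_label Genotype the sample was derived from.
#' @param mark One of `"BrdU"`, `"H3K4me3"`, `"H3K9me3"`, `"H3K56ac"`.
#' @return A data.frame of class `fragment_set` with columns `chrom`,
#'   `start`, `end`, `strand` and metadata attributes.
#' @export
fragment_set <- function(chrom, start, end, strand, genome,
                         sample_id, genotype_label, mark) {
  mark <- match.arg(mark, ESPAN_MARKS)
  chrom <- as.character(chrom)
  start <- as.numeric(start); end <- as.numeric(end)
  strand <- as.character(strand)
  n <- length(chrom)
  if (length(start) != n || length(end) != n || length(strand) != n) {
    stop("fragment columns must have equal length")
  }
  if (n > 0L) {
    bad <- which(!strand %in% c("W", "C"))
    if (length(bad)) {
      stop("fragment ", bad[1L], ": strand must be 'W' or 'C', got '",
           strand[bad[1L]], "'")
    }
    check_intervals(genome, chrom, start, end, what = "fragment")
  }
  out <- data.frame(chrom = chrom, start = start, end = end,
                    strand = strand, stringsAsFactors = FALSE)
  attr(out, "sample_id") <- sample_id
  attr(out, "genotype_label") <- genotype_label
  attr(out, "mark") <- mark
  class(out) <- c("fragment_set", "data.frame")
  out
}

#' @export
print.fragment_set <- function(x, ...) {
  cat("fragment_set '", attr(x, "sample_id"), "': ", nrow(x),
      " fragments (", attr(x, "mark"), ", genotype ",
      attr(x, "genotype_label"), ")\n", sep = "")
  invisible(x)
}

#' Read stranded fragments from a BED6 file
#'
#' Column 6 must be `+` (mapped to Watson, `W`) or `-` (Crick, `C`);
#' a `.` strand is rejected with the offending record index. All
#' intervals are validated against the genome.
#'
#' @param path BED6 file path.
#' @param genome A [genome_spec()].
#' @param sample_id,genotype_label,mark Sample metadata (see
#'   [fragment_set()]).
#' @return A [fragment_set()]. An empty file yields an empty set with a
#'   warning.
#' @export
read_fragments <- function(path, genome, sample_id, genotype_label, mark) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) {
    warning("no fragment records in ", path, "; returning an empty set")
    return(fragment_set(character(), numeric(), numeric(), character(),
                        genome, sample_id, genotype_label, mark))
  }
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 6L) stop("BED6 required (6 columns) in ", path)
  strand_in <- as.character(tab[[6L]])
  bad <- which(!strand_in %in% c("+", "-"))
  if (length(bad)) {
    stop("record ", bad[1L], " of ", path, ": strand must be '+' or '-', got '",
         strand_in[bad[1L]], "'")
  }
  fr <- fragment_set(tab[[1L]], tab[[2L]], tab[[3L]],
                     ifelse(strand_in == "+", "W", "C"),
                     genome, sample_id, genotype_label, mark)
  message("read ", nrow(fr), " fragments from ", path)
  fr
}

#' Write a fragment set as BED6
#'
#' Inverse of [read_fragments()]: Watson fragments get strand `+`,
#' Crick `-`; the name column carries the sample id and the score is 0.
#'
#' @param frags A [fragment_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(frags, path) {
  if (nrow(frags) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  utils::write.table(
    data.frame(frags$chrom,
               format(frags$start, scientific = FALSE, trim = TRUE),
               format(frags$end, scientific = FALSE, trim = TRUE),
               paste0(attr(frags, "sample_id"), "_", seq_len(nrow(frags))),
               0L,
               ifelse(frags$strand == "W", "+", "-")),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
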