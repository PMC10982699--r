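#' Write strand coverage as a pair of BedGraph files
#'
#' One file per strand, run-length encoded; zero runs are omitted so a
#' round-trip through [read_bedgraph()] reproduces the coverage vectors
#' exactly.
#'
#' @param cov A [strand_coverage()] object.
#' @param path_w,path_c Output paths for Watson and Crick coverage.
#' @return `c(path_w, path_c)`, invisibly.
#' @export
write_bedgraph <- function(cov, path_w, path_c) {
  write_one <- function(rlelist, path) {
    con <- file(path, open = "wt")
    on.exit(close(con))
    for (chrom in names(rlelist)) {
      r <- rlelist[[chrom]]
      rl <- S4Vectors::runLength(r)
      rv <- S4Vectors::runValue(r)
      ends <- cumsum(as.numeric(rl))
      starts <- ends - as.numeric(rl)        # 0-based half-open
      keep <- rv != 0
      if (!any(keep)) next
      writeLines(paste(chrom,
                       format(starts[keep], scientific = FALSE, trim = TRUE),
                       format(ends[keep], scientific = FALSE, trim = TRUE),
                       format(rv[keep], scientific = FALSE, trim = TRUE),
                       sep = "\t"), con)
    }
  }
  write_one(cov$w, path_w)
  write_one(cov$c, path_c)
  invisible(c(path_w, path_c))
}

#' Read a BedGraph file into per-chromosome Rle vectors
#'
#' @param path BedGraph path.
#' @param genome A [genome_spec()]; intervals are validated against it.
#' @return A named list of [S4Vectors::Rle] vectors, one per declared
#'   chromosome (all-zero where the file has no data).
#' @export
read_bedgraph <- function(path, genome) {
  if (!file.exists(path)) stop("file not found: ", path)
  out <- lapply(genome$chrom_lengths, function(len) S4Vectors::Rle(0, len))
  info <- file.info(path)
  if (is.na(info$size) || info$size == 0) return(out)
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "value"))
  check_intervals(genome, tab$chrom, tab$start, tab$end, what = "bedgraph record")
  for (chrom in unique(tab$chrom)) {
    sel <- tab$chrom == chrom
    vec <- as.numeric(out[[chrom]])
    for (i in which(sel)) {
      vec[(tab$start[i] + 1):tab$end[i]] <- tab$value[i]
    }
    out[[chrom]] <- S4Vectors::Rle(vec)
  }
  out
}

#' Write an origins-by-bins matrix as TSV
#'
#' The header row holds the bin centers (bp relative to the origin), the
#' first column the origin ids; `NaN`/`NA` cells are serialized as
#' `"nan"`.
#'
#' @param mat Numeric matrix with rownames (origin ids) and numeric
#'   colnames (bin centers).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path) {
  if (!is.matrix(mat)) stop("mat must be a matrix")
  cells <- format(mat, scientific = FALSE, trim = TRUE, digits = 15)
  cells[!is.finite(mat)] <- "nan"
  rows <- apply(cells, 1L, paste, collapse = "\t")
  header <- paste(c("origin_id", colnames(mat)), collapse = "\t")
  writeLines(c(header, paste(rownames(mat), rows, sep = "\t")), path)
  invisible(path)
}

#' Read a matrix TSV written by [write_matrix_tsv()]
#'
#' @param path Input path.
#' @return Numeric matrix with origin ids as rownames and bin centers as
#'   colnames; `"nan"` cells become `NaN`.
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  ncols <- length(header) - 1L
  if (any(lengths(body) != ncols + 1L)) stop("ragged rows in ", path)
  ids <- vapply(body, `[[`, character(1L), 1L)
  vals <- vapply(body, function(f) {
    v <- suppressWarnings(as.numeric(f[-1L]))
    v[f[-1L] == "nan"] <- NaN
    v
  }, numeric(ncols))
  mat <- t(matrix(vals, nrow = ncols))
  dimnames(mat) <- list(ids, header[-1L])
  mat
}
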