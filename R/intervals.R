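#' Construct a table of genomic intervals
#'
#' Intervals follow the BED convention throughout the package: 0-based
#' start, exclusive end (half-open). Any 1-based display is formatting only.
#'
#' @param chrom character vector of chromosome names (non-empty strings).
#' @param start integer vector, 0-based inclusive start.
#' @param end integer vector, exclusive end; must satisfy `start < end`.
#' @param name optional identifiers; generated (`ivl_1`, ...) when missing.
#' @return A `data.frame` with columns `name`, `chrom`, `start`, `end`.
#' @examples
#' genomic_intervals("chr1", 100, 300, "cgi_1")
#' @export
genomic_intervals <- function(chrom, start, end, name = NULL) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- length(chrom)
  if (length(start) != n || length(end) != n)
    stop("chrom, start and end must have equal length")
  if (is.null(name)) {
    name <- if (n > 0) paste0("ivl_", seq_len(n)) else character(0)
  }
  ivl <- data.frame(name = as.character(name), chrom = chrom,
                    start = start, end = end, stringsAsFactors = FALSE)
  validate_intervals(ivl)
  ivl
}

validate_intervals <- function(ivl) {
  stopifnot(is.data.frame(ivl),
            all(c("name", "chrom", "start", "end") %in% names(ivl)))
  if (any(is.na(ivl$chrom)) || any(!nzchar(ivl$chrom)))
    stop("chrom names must be non-empty")
  bad <- which(is.na(ivl$start) | is.na(ivl$end) |
                 ivl$start < 0 | ivl$start >= ivl$end)
  if (length(bad))
    stop(sprintf("invalid interval at row %d: need 0 <= start < end", bad[1]))
  invisible(ivl)
}

#' Read a BED3/BED4 file of intervals
#'
#' Coordinates are kept in the file's native BED convention (0-based,
#' half-open). A 4th column, when present, supplies the interval name;
#' otherwise ids `ivl_<line>` are generated. Track/browser/comment lines are
#' skipped.
#'
#' @param path path to a tab-separated BED file.
#' @param normalize_chrom if `TRUE`, prefix bare chromosome names with
#'   `"chr"` (`"1"` becomes `"chr1"`). Comparison elsewhere is string-exact.
#' @return interval `data.frame` as from [genomic_intervals()], in file order.
#' @export
read_bed <- function(path, normalize_chrom = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0)
    return(genomic_intervals(character(0), numeric(0), numeric(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop(sprintf("line %d: expected >= 3 tab-separated fields",
                 lineno[which(nf < 3)[1]]))
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop(sprintf("line %d: non-integer coordinates", lineno[bad[1]]))
  bad <- which(start < 0 | start >= end)
  if (length(bad))
    stop(sprintf("line %d: invalid interval (start >= end or negative)",
                 lineno[bad[1]]))
  name <- ifelse(nf >= 4, vapply(fields, function(f) f[min(4L, length(f))], ""),
                 paste0("ivl_", lineno))
  if (normalize_chrom)
    chrom <- ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
  genomic_intervals(chrom, start, end, name)
}

#' Write intervals to a BED4 file
#'
#' @param ivl interval table as from [genomic_intervals()].
#' @param path output path.
#' @return `path`, invisibly. `read_bed(write_bed(x))` reproduces `x`.
#' @export
write_bed <- function(ivl, path) {
  validate_intervals(ivl)
  out <- data.frame(ivl$chrom, format_coord(ivl$start), format_coord(ivl$end),
                    ivl$name)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

# GRanges view of an interval table (internal). BED half-open -> IRanges
# 1-based closed: start+1 .. end.
intervals_as_granges <- function(ivl) {
  validate_intervals(ivl)
  GenomicRanges::GRanges(
    seqnames = ivl$chrom,
    ranges = IRanges::IRanges(start = ivl$start + 1, end = ivl$end),
    name = ivl$name)
}

#' Midpoint of an interval
#'
#' @param start,end half-open interval bounds.
#' @return floor of the arithmetic midpoint, a 0-based coordinate.
#' @keywords internal
interval_midpoint <- function(start, end) floor((start + end) / 2)

is_autosome <- function(chrom) {
  !grepl("^(chr)?[XYxy]$", chrom) & !grepl("^(chr)?M(T)?$", chrom)
}
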