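#' Construct a methylome track
#'
#' A methylome track holds per-sample CpG site methylation calls (beta
#' values in [0, 1]) with read depth, plus sample metadata. Sites with depth
#' below the track's minimum-depth threshold carry a missing (`NA`) level;
#' this mirrors the standard read-depth inclusion rule for BS-Seq calls.
#'
#' @param sample_id sample identifier.
#' @param sites `data.frame` with columns `chrom`, `pos` (0-based), `level`
#'   (fraction in [0,1] or `NA`), `depth` (non-negative reads).
#' @param tissue tissue label.
#' @param compartment one of `"somatic"`, `"oocyte"`, `"sperm"`,
#'   `"blastocyst"`, `"placenta"`, `"cancer"`, `"stem_derived"`.
#' @param conversion_rate bisulfite conversion rate in [0,1].
#' @param min_depth minimum read depth for a site-level call (default 10);
#'   sites below it get `NA` level.
#' @return an object of class `methylome_track`.
#' @export
methylome_track <- function(sample_id, sites, tissue = "unknown",
                            compartment = "somatic", conversion_rate = 1,
                            min_depth = 10) {
  compartment <- match.arg(compartment, track_compartments())
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "level", "depth") %in% names(sites)))
  if (!is.numeric(conversion_rate) || conversion_rate < 0 || conversion_rate > 1)
    stop("conversion_rate must be in [0, 1]")
  sites <- sites[, c("chrom", "pos", "level", "depth")]
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.numeric(sites$pos)
  sites$level <- as.numeric(sites$level)
  sites$depth <- as.numeric(sites$depth)
  ok <- is.na(sites$level) | (sites$level >= 0 & sites$level <= 1)
  if (!all(ok))
    stop("methylation level outside [0, 1] at row ", which(!ok)[1])
  if (any(sites$depth < 0, na.rm = TRUE)) stop("negative read depth")
  key <- paste(sites$chrom, sites$pos)
  if (anyDuplicated(key))
    stop("duplicate (chrom, pos) site: ", key[which(duplicated(key))[1]])
  sites$level[!is.na(sites$depth) & sites$depth < min_depth] <- NA_real_
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  rownames(sites) <- NULL
  structure(list(sample_id = sample_id, tissue = tissue,
                 compartment = compartment,
                 conversion_rate = conversion_rate,
                 min_depth = min_depth, sites = sites),
            class = "methylome_track")
}

track_compartments <- function() {
  c("somatic", "oocyte", "sperm", "blastocyst", "placenta", "cancer",
    "stem_derived")
}

#' @export
print.methylome_track <- function(x, ...) {
  cat(sprintf(
    "methylome_track '%s' (%s, %s): %d sites, %d with level, conversion %.3f\n",
    x$sample_id, x$tissue, x$compartment, nrow(x$sites),
    sum(!is.na(x$sites$level)), x$conversion_rate))
  invisible(x)
}

#' Read a methylation track from a 4-column TSV
#'
#' The dialect is `chrom  pos  level  depth` with a header line; sample
#' metadata travel in `#key: value` comment lines above the header
#' (`sample_id`, `tissue`, `compartment`, `conversion_rate`) or as arguments,
#' which take precedence. Missing levels are encoded as `NA`. Tracks whose
#' bisulfite conversion rate falls below `min_conversion` are rejected, the
#' standard methylome inclusion rule; pass `allow_low_conversion = TRUE` to
#' override.
#'
#' @param path path to the TSV track file.
#' @param min_depth sites with `depth < min_depth` get a missing level
#'   (default 10).
#' @param min_conversion minimum acceptable bisulfite conversion rate
#'   (default 0.95).
#' @param allow_low_conversion keep tracks failing the conversion gate.
#' @param sample_id,tissue,compartment,conversion_rate metadata overrides.
#' @return a [methylome_track()].
#' @export
read_methylation_track <- function(path, min_depth = 10,
                                   min_conversion = 0.95,
                                   allow_low_conversion = FALSE,
                                   sample_id = NULL, tissue = NULL,
                                   compartment = NULL,
                                   conversion_rate = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", h))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) stop("track file has no header line: ", path)
  tab <- utils::read.table(text = body, sep = "\t", header = TRUE,
                           na.strings = c("NA", ""), stringsAsFactors = FALSE,
                           colClasses = c("character", "numeric", "numeric",
                                          "numeric"))
  if (!all(c("chrom", "pos", "level", "depth") %in% names(tab)))
    stop("expected columns chrom, pos, level, depth in ", path)
  sid <- sample_id %||% meta$sample_id %||%
    sub("\\.tsv$", "", basename(path))
  conv <- as.numeric(conversion_rate %||% meta$conversion_rate %||% 1)
  trk <- methylome_track(
    sample_id = sid, sites = tab,
    tissue = tissue %||% meta$tissue %||% "unknown",
    compartment = compartment %||% meta$compartment %||% "somatic",
    conversion_rate = conv, min_depth = min_depth)
  if (!allow_low_conversion && trk$conversion_rate < min_conversion)
    stop(sprintf(
      "track '%s' rejected: conversion rate %.3f < %.2f (set allow_low_conversion = TRUE to keep)",
      sid, trk$conversion_rate, min_conversion))
  trk
}

#' Write a methylation track to the 4-column TSV dialect
#'
#' Metadata are written as `#key: value` comment lines so that
#' [read_methylation_track()] round-trips the track, including missingness.
#'
#' @param track a [methylome_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_methylation_track <- function(track, path) {
  stopifnot(inherits(track, "methylome_track"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("#sample_id: ", track$sample_id),
    paste0("#tissue: ", track$tissue),
    paste0("#compartment: ", track$compartment),
    paste0("#conversion_rate: ",
           format(track$conversion_rate, digits = 15)),
    paste(c("chrom", "pos", "level", "depth"), collapse = "\t")), con)
  s <- track$sites
  if (nrow(s))
    writeLines(paste(s$chrom, format_coord(s$pos),
                     ifelse(is.na(s$level), "NA",
                            format(s$level, digits = 15)),
                     format_coord(s$depth), sep = "\t"), con)
  invisible(path)
}

#' Import a bedGraph-style methylation file
#'
#' Maps `chrom  start  end  level` (optionally with a 5th depth column) to
#' the package's 4-column site dialect using `start` as the CpG position.
#'
#' @param path bedGraph path.
#' @param depth assumed read depth when the file has no 5th column.
#' @param ... passed to [methylome_track()].
#' @return a [methylome_track()].
#' @export
read_bedgraph_track <- function(path, depth = 10, ...) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(tab) < 4) stop("bedGraph needs >= 4 columns")
  sites <- data.frame(chrom = as.character(tab[[1]]),
                      pos = as.numeric(tab[[2]]),
                      level = as.numeric(tab[[4]]),
                      depth = if (ncol(tab) >= 5) as.numeric(tab[[5]])
                              else depth)
  methylome_track(sites = sites, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
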