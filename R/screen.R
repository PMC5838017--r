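#' Parameters for the candidate-iDMR screen
#'
#' @param min_records minimum number of overlapping AMR records for a CGI to
#'   be retained (default 16, the minimal count observed across most known
#'   gametic and secondary iDMRs).
#' @param intermediate_low,intermediate_high the intermediate
#'   (hemimethylated) band, inclusive at both bounds (defaults 0.35, 0.65).
#' @param reference_methylome sample id of the somatic reference track used
#'   for the intermediate filter.
#' @param min_covered_sites minimum non-missing reference sites a CGI needs
#'   to be evaluable (default 1).
#' @param require_reference_amr additionally require each CGI to have at
#'   least one AMR record from the reference methylome (off by default).
#' @param count_unique_methylomes count at most one AMR record per source
#'   methylome instead of raw records (off by default).
#' @param autosomes_only drop X/Y (and mitochondrial) CGIs before screening
#'   (default `TRUE`).
#' @return a list of class `screen_params`.
#' @export
screen_params <- function(min_records = 16L, intermediate_low = 0.35,
                          intermediate_high = 0.65,
                          reference_methylome = NULL,
                          min_covered_sites = 1L,
                          require_reference_amr = FALSE,
                          count_unique_methylomes = FALSE,
                          autosomes_only = TRUE) {
  stopifnot(min_records >= 1,
            intermediate_low >= 0, intermediate_high <= 1,
            intermediate_low < intermediate_high,
            min_covered_sites >= 1)
  structure(list(min_records = as.integer(min_records),
                 intermediate_low = intermediate_low,
                 intermediate_high = intermediate_high,
                 reference_methylome = reference_methylome,
                 min_covered_sites = as.integer(min_covered_sites),
                 require_reference_amr = require_reference_amr,
                 count_unique_methylomes = count_unique_methylomes,
                 autosomes_only = autosomes_only),
            class = "screen_params")
}

#' Count AMR records overlapping each CpG island
#'
#' An AMR record counts for a CGI iff the two intervals share at least one
#' base pair under half-open semantics (abutting intervals do not overlap).
#' Alongside the raw record count, the number of distinct source methylomes
#' contributing at least one overlapping record is reported for diagnostics.
#'
#' @param cgis interval table of CGIs ([genomic_intervals()]; `name` is the
#'   CGI id).
#' @param amrs `data.frame` of AMR records: `chrom`, `start`, `end`,
#'   `source_methylome`.
#' @return `data.frame` with `cgi_id`, `record_count`, `methylome_count`;
#'   every input CGI appears, zero-overlap CGIs with (0, 0).
#' @export
count_overlapping_amrs <- function(cgis, amrs) {
  validate_intervals(cgis)
  stopifnot(is.data.frame(amrs),
            all(c("chrom", "start", "end", "source_methylome") %in%
                  names(amrs)))
  out <- data.frame(cgi_id = cgis$name,
                    record_count = 0L, methylome_count = 0L,
                    stringsAsFactors = FALSE)
  if (nrow(cgis) == 0 || nrow(amrs) == 0) return(out)
  gr_c <- intervals_as_granges(cgis)
  gr_a <- GenomicRanges::GRanges(
    seqnames = amrs$chrom,
    ranges = IRanges::IRanges(start = amrs$start + 1, end = amrs$end))
  # disjoint seqlevels (e.g. "1" vs "chr1") are a legitimate zero-overlap
  # case under string-exact chromosome comparison, not a user error
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gr_c, gr_a, minoverlap = 1L))
  if (length(hits)) {
    q <- S4Vectors::queryHits(hits)
    src <- amrs$source_methylome[S4Vectors::subjectHits(hits)]
    rc <- tapply(src, q, length)
    mc <- tapply(src, q, function(s) length(unique(s)))
    idx <- as.integer(names(rc))
    out$record_count[idx] <- as.integer(rc)
    out$methylome_count[idx] <- as.integer(mc)
  }
  out
}

#' Record-count filter
#'
#' @param counts output of [count_overlapping_amrs()].
#' @param params a [screen_params()].
#' @return character vector of retained `cgi_id`s (`record_count >=
#'   min_records`; distinct methylomes instead when
#'   `count_unique_methylomes`).
#' @export
filter_by_record_count <- function(counts, params = screen_params()) {
  n <- if (isTRUE(params$count_unique_methylomes)) counts$methylome_count
       else counts$record_count
  counts$cgi_id[n >= params$min_records]
}

#' Intermediate-methylation filter against the reference methylome
#'
#' A CGI passes iff it has at least `min_covered_sites` non-missing CpG
#' sites in the reference track and every covered site's level lies within
#' the intermediate band, bounds inclusive — the per-site consistency
#' demanded of constitutively hemimethylated regions, stricter than a mean
#' criterion.
#'
#' @param cgi one-row interval (list or data.frame row) with `chrom`,
#'   `start`, `end`.
#' @param reference_track the reference somatic [methylome_track()].
#' @param params a [screen_params()].
#' @return logical scalar; attribute `"evaluable"` is `FALSE` when the CGI
#'   has too few covered sites to judge.
#' @export
intermediate_filter <- function(cgi, reference_track,
                                params = screen_params()) {
  s <- reference_track$sites
  inside <- s$chrom == cgi$chrom & s$pos >= cgi$start & s$pos < cgi$end
  lv <- s$level[inside]
  lv <- lv[!is.na(lv)]
  if (length(lv) < params$min_covered_sites)
    return(structure(FALSE, evaluable = FALSE))
  pass <- all(lv >= params$intermediate_low &
                lv <= params$intermediate_high)
  structure(pass, evaluable = TRUE)
}

#' Classify a candidate iDMR from gamete methylomes
#'
#' Gametic iDMRs carry asymmetric methylation already in the gametes:
#' hypermethylated in oocytes and hypomethylated in sperm for a maternal
#' imprint, the mirror image for a paternal one. Any other combination —
#' both gametes hypomethylated (the secondary-iDMR signature), both
#' intermediate, or an unevaluable gamete — yields a secondary candidate,
#' since secondary iDMRs are defined by absence of gametic asymmetry.
#' Status comes from the region mean in each gamete via [call_status()]
#' (hypo < low, hyper > high, strict).
#'
#' @param cgi one-row interval with `chrom`, `start`, `end` (and `name`).
#' @param oocyte_track,sperm_track gamete [methylome_track()]s.
#' @param params a [screen_params()].
#' @return list: `klass` (`"gametic_maternal"`, `"gametic_paternal"` or
#'   `"secondary_candidate"`), `oocyte_mean`, `sperm_mean`, `oocyte_status`,
#'   `sperm_status`, `annotation` (`"unevaluable gamete"` when either gamete
#'   could not be scored, else `NA`).
#' @export
classify_candidate <- function(cgi, oocyte_track, sperm_track,
                               params = screen_params()) {
  if (is.null(oocyte_track) || is.null(sperm_track))
    stop("both oocyte and sperm tracks are required for classification")
  oo <- region_mean(oocyte_track, cgi, params$intermediate_low,
                    params$intermediate_high)
  sp <- region_mean(sperm_track, cgi, params$intermediate_low,
                    params$intermediate_high)
  klass <-
    if (oo$status == "hypermethylated" && sp$status == "hypomethylated")
      "gametic_maternal"
    else if (oo$status == "hypomethylated" && sp$status == "hypermethylated")
      "gametic_paternal"
    else "secondary_candidate"
  unev <- oo$status == "unevaluable" || sp$status == "unevaluable"
  list(klass = klass, oocyte_mean = oo$mean, sperm_mean = sp$mean,
       oocyte_status = oo$status, sperm_status = sp$status,
       annotation = if (unev) "unevaluable gamete" else NA_character_)
}

#' Flag candidates matching known iDMRs
#'
#' @param candidates candidate table with `cgi_id` (and coordinates when
#'   interval matching is used).
#' @param known_idmrs character vector of known CGI ids, or an interval
#'   table ([genomic_intervals()]) when `match = "interval"`.
#' @param match `"id"` (default) or `"interval"` (any 1-bp overlap).
#' @return `candidates` with `klass` set to `"known"` and `novel = FALSE`
#'   for matches; all others keep their class with `novel = TRUE`.
#' @export
annotate_known <- function(candidates, known_idmrs, match = c("id", "interval")) {
  match <- match.arg(match)
  if (match == "id") {
    hit <- candidates$cgi_id %in% known_idmrs
  } else {
    validate_intervals(known_idmrs)
    if (nrow(known_idmrs) == 0 || nrow(candidates) == 0) {
      hit <- rep(FALSE, nrow(candidates))
    } else {
      gr_c <- GenomicRanges::GRanges(
        seqnames = candidates$chrom,
        ranges = IRanges::IRanges(start = candidates$start + 1,
                                  end = candidates$end))
      hit <- GenomicRanges::countOverlaps(
        gr_c, intervals_as_granges(known_idmrs), minoverlap = 1L) > 0
    }
  }
  candidates$klass[hit] <- "known"
  candidates$novel <- !hit
  candidates
}

candidate_classes <- function() {
  c("gametic_maternal", "gametic_paternal", "secondary_candidate",
    "known", "rejected")
}

#' Run the full candidate-iDMR screen
#'
#' Applies the discovery stages in order: AMR record counting, the
#' record-count filter, the intermediate-methylation filter against the
#' reference somatic methylome, gametic/secondary classification from
#' oocyte and sperm methylomes, and known-iDMR annotation. Every input CGI
#' appears exactly once in the output; rejected CGIs retain the stage that
#' rejected them in `reject_reason`.
#'
#' @param cgis CGI interval table ([genomic_intervals()]).
#' @param amrs AMR record table (`chrom`, `start`, `end`,
#'   `source_methylome`).
#' @param reference_track somatic reference [methylome_track()]; when
#'   `params$reference_methylome` is set its `sample_id` must match.
#' @param oocyte_track,sperm_track gamete [methylome_track()]s.
#' @param params a [screen_params()].
#' @param known_idmrs known-iDMR ids (or interval table) for
#'   [annotate_known()]; optional.
#' @param known_match matching mode for `known_idmrs`.
#' @return candidate table (one row per CGI): `cgi_id`, coordinates,
#'   `record_count`, `methylome_count`, `oocyte_mean`, `sperm_mean`, gamete
#'   statuses, `klass`, `novel`, `reject_reason`.
#' @export
run_screen <- function(cgis, amrs, reference_track, oocyte_track,
                       sperm_track, params = screen_params(),
                       known_idmrs = NULL, known_match = "id") {
  validate_intervals(cgis)
  if (!is.null(params$reference_methylome) &&
      !identical(reference_track$sample_id, params$reference_methylome))
    stop("reference track '", reference_track$sample_id,
         "' does not match configured reference methylome '",
         params$reference_methylome, "'")
  if (anyDuplicated(cgis$name))
    stop("CGI ids must be unique")

  res <- data.frame(cgi_id = cgis$name, chrom = cgis$chrom,
                    start = cgis$start, end = cgis$end,
                    record_count = 0L, methylome_count = 0L,
                    oocyte_mean = NA_real_, sperm_mean = NA_real_,
                    oocyte_status = NA_character_,
                    sperm_status = NA_character_,
                    klass = "rejected", novel = FALSE,
                    reject_reason = NA_character_,
                    stringsAsFactors = FALSE)
  if (nrow(res) == 0) return(res)

  live <- rep(TRUE, nrow(res))
  if (isTRUE(params$autosomes_only)) {
    sex <- !is_autosome(res$chrom)
    res$reject_reason[sex] <- "non_autosomal"
    live <- live & !sex
  }

  counts <- count_overlapping_amrs(cgis, amrs)
  stopifnot(identical(counts$cgi_id, res$cgi_id))
  res$record_count <- counts$record_count
  res$methylome_count <- counts$methylome_count

  keep <- res$cgi_id %in%
    filter_by_record_count(counts, params)
  res$reject_reason[live & !keep] <- "below_record_count"
  live <- live & keep

  if (isTRUE(params$require_reference_amr)) {
    ref_amrs <- amrs[amrs$source_methylome == reference_track$sample_id, ,
                     drop = FALSE]
    ref_counts <- count_overlapping_amrs(cgis, ref_amrs)
    has_ref <- ref_counts$record_count >= 1
    res$reject_reason[live & !has_ref] <- "no_reference_amr"
    live <- live & has_ref
  }

  for (i in which(live)) {
    cgi <- res[i, c("chrom", "start", "end")]
    cgi$name <- res$cgi_id[i]
    ok <- intermediate_filter(cgi, reference_track, params)
    if (!ok) {
      res$reject_reason[i] <- if (isFALSE(attr(ok, "evaluable")))
        "not_evaluable_in_reference" else "not_intermediate"
      live[i] <- FALSE
      next
    }
    cl <- classify_candidate(cgi, oocyte_track, sperm_track, params)
    res$klass[i] <- cl$klass
    res$oocyte_mean[i] <- cl$oocyte_mean
    res$sperm_mean[i] <- cl$sperm_mean
    res$oocyte_status[i] <- cl$oocyte_status
    res$sperm_status[i] <- cl$sperm_status
    res$reject_reason[i] <- cl$annotation
  }

  res$novel <- live
  if (!is.null(known_idmrs)) {
    cand <- res[live, , drop = FALSE]
    cand <- annotate_known(cand, known_idmrs, match = known_match)
    res[live, ] <- cand
  }
  res
}
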