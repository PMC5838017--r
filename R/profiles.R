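#' Methylation status bounds
#'
#' The intermediate (hemimethylated) band [0.35, 0.65] is the signature of
#' one methylated and one unmethylated allele: region means below 0.35 are
#' hypomethylated, above 0.65 hypermethylated (strict), and means inside the
#' band, bounds included, are intermediate.
#'
#' @param mean region mean methylation in [0,1], or `NA`.
#' @param low,high band bounds (defaults 0.35 and 0.65).
#' @return one of `"hypomethylated"`, `"intermediate"`, `"hypermethylated"`,
#'   `"unevaluable"` (for `NA` means). Vectorised over `mean`.
#' @examples
#' call_status(c(0.2, 0.35, 0.65, 0.66, NA))
#' @export
call_status <- function(mean, low = 0.35, high = 0.65) {
  stopifnot(low < high)
  out <- rep("unevaluable", length(mean))
  out[!is.na(mean) & mean < low] <- "hypomethylated"
  out[!is.na(mean) & mean >= low & mean <= high] <- "intermediate"
  out[!is.na(mean) & mean > high] <- "hypermethylated"
  out
}

methylation_statuses <- function() {
  c("hypomethylated", "intermediate", "hypermethylated", "unevaluable")
}

#' Region-level methylation summary
#'
#' Mean and standard deviation of site methylation levels across a genomic
#' interval, excluding sites with no data (missing level), the standard
#' normalisation for sparse BS-Seq calls. The sd uses the n-1 denominator
#' and is `NA` when fewer than two sites are usable.
#'
#' @param track a [methylome_track()].
#' @param interval one-row interval table (or list) with `chrom`, `start`,
#'   `end` (half-open), optionally `name`.
#' @param low,high status band bounds passed to [call_status()].
#' @return one-row `data.frame`: `sample_id`, `name`, `chrom`, `start`,
#'   `end`, `mean`, `sd`, `n_used`, `n_missing`, `status`. Zero usable sites
#'   give an `NA` mean and status `"unevaluable"`.
#' @export
region_mean <- function(track, interval, low = 0.35, high = 0.65) {
  stopifnot(inherits(track, "methylome_track"))
  s <- track$sites
  inside <- s$chrom == interval$chrom &
    s$pos >= interval$start & s$pos < interval$end
  lv <- s$level[inside]
  used <- lv[!is.na(lv)]
  m <- if (length(used)) mean(used) else NA_real_
  data.frame(
    sample_id = track$sample_id,
    name = as.character(interval$name %||% NA_character_),
    chrom = interval$chrom, start = interval$start, end = interval$end,
    mean = m,
    sd = if (length(used) >= 2) stats::sd(used) else NA_real_,
    n_used = length(used), n_missing = sum(is.na(lv)),
    status = call_status(m, low, high),
    stringsAsFactors = FALSE)
}

#' Expected methylation level under an allele-dosage model
#'
#' For a region methylated on a known number of allele copies, the expected
#' bulk methylation level is the fraction of methylated copies. A maternal
#' iDMR in a disomic cell (1 of 2) gives 0.5; in a trisomic cell the
#' supernumerary chromosome's origin shifts it to 1/3 (paternal extra copy)
#' or 2/3 (maternal extra copy).
#'
#' @param methylated_copies number of methylated allele copies.
#' @param total_copies total allele copies (>= 1).
#' @return `methylated_copies / total_copies`.
#' @export
expected_dosage_level <- function(methylated_copies, total_copies) {
  if (any(total_copies < 1)) stop("total_copies must be >= 1")
  if (any(methylated_copies < 0 | methylated_copies > total_copies))
    stop("need 0 <= methylated_copies <= total_copies")
  methylated_copies / total_copies
}

#' Parent-of-origin call for a supernumerary chromosome from methylation
#'
#' For a maternal iDMR on a trisomic chromosome, skewed hypomethylation
#' (observed mean at or below `lower`, default 0.33, the rounded 1/3
#' dosage expectation) indicates a paternal supernumerary copy; skewed
#' hypermethylation (at or above `upper`, default 0.66, the 2/3
#' expectation) indicates a maternal one. Means are rounded to two decimals
#' before comparison so the theoretical 1/3 and 2/3 satisfy their bounds.
#'
#' @param observed_mean region mean methylation in [0,1]; vectorised.
#' @param lower,upper decision thresholds (defaults 0.33 and 0.66).
#' @return `"paternal_supernumerary"`, `"maternal_supernumerary"` or
#'   `"indeterminate"` per element.
#' @examples
#' call_trisomy_origin(c(0.26, 0.5, 0.70))
#' @export
call_trisomy_origin <- function(observed_mean, lower = 0.33, upper = 0.66) {
  stopifnot(all(observed_mean >= 0 & observed_mean <= 1, na.rm = TRUE))
  m <- round(observed_mean, 2)
  out <- rep("indeterminate", length(m))
  out[!is.na(m) & m <= lower] <- "paternal_supernumerary"
  out[!is.na(m) & m >= upper] <- "maternal_supernumerary"
  out
}

#' Proportion of digestion-resistant methylated sites from an MSRE-PCR triplex
#'
#' Each methylation-sensitive restriction enzyme PCR triplex amplifies the
#' target region, an enzyme-site-free reference amplimer used to normalise
#' signal between the digested and undigested lanes, and a constitutively
#' unmethylated digestion control whose signal must vanish after digestion.
#' The resistant proportion is the reference-normalised ratio of ratios
#'
#'   (target_dig / ref_dig) / (target_undig / ref_undig)
#'
#' clamped to [0, 1]: 1 when the target is fully methylated (resistant), 0
#' when fully unmethylated. The result is invariant to rescaling all signals
#' of one lane, as lane-wise normalisation requires.
#'
#' @param target_dig,target_undig target signal in the digested and
#'   undigested reactions.
#' @param ref_dig,ref_undig reference-amplimer signals; must be positive.
#' @param control_dig digestion-control signal in the digested reaction.
#' @param control_threshold maximum tolerated `control_dig / ref_dig` ratio
#'   for digestion to count as complete (default 0.05).
#' @return resistant proportion in [0, 1].
#' @export
msre_proportion <- function(target_dig, target_undig, ref_dig, ref_undig,
                            control_dig = 0, control_threshold = 0.05) {
  if (any(ref_dig <= 0) || any(ref_undig <= 0))
    stop("reference amplimer signals must be positive")
  if (any(target_dig < 0) || any(target_undig < 0) || any(control_dig < 0))
    stop("signal intensities must be non-negative")
  if (any(control_dig / ref_dig > control_threshold))
    stop("incomplete digestion: control amplimer persists in digested lane")
  if (any(target_undig == 0))
    stop("zero undigested target signal: target did not amplify")
  p <- (target_dig / ref_dig) / (target_undig / ref_undig)
  pmin(pmax(p, 0), 1)
}

#' Cohort methylation-status profile and epipolymorphism flags
#'
#' Labels each sample's region summary with its methylation status and flags
#' samples outside the intermediate band as dysregulated (hypo- or
#' hypermethylated), e.g. cancer methylomes departing from the hemimethylated
#' status of healthy tissue, or trisomic placentas skewed by the dosage
#' model. A cohort with zero flags shows absence of epipolymorphism.
#'
#' @param summaries `data.frame` of region summaries as returned by
#'   [region_mean()] (rows = samples for one region).
#' @param low,high intermediate band bounds.
#' @return list with `profile` (per-sample `data.frame`: `sample_id`,
#'   `name`, `mean`, `status`, `dysregulated`), `n_dysregulated`,
#'   `fraction_intermediate` (among evaluable samples).
#' @export
cohort_status_profile <- function(summaries, low = 0.35, high = 0.65) {
  stopifnot(is.data.frame(summaries), nrow(summaries) >= 1)
  status <- call_status(summaries$mean, low, high)
  dys <- status %in% c("hypomethylated", "hypermethylated")
  profile <- data.frame(
    sample_id = summaries$sample_id,
    name = if ("name" %in% names(summaries)) summaries$name else NA_character_,
    mean = summaries$mean, status = status, dysregulated = dys,
    stringsAsFactors = FALSE)
  evaluable <- status != "unevaluable"
  list(profile = profile,
       n_dysregulated = sum(dys),
       fraction_intermediate =
         if (any(evaluable)) mean(status[evaluable] == "intermediate")
         else NA_real_)
}
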