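#' Parameters for the allele-specific-expression pipeline
#'
#' Defaults follow the standard GTEx-style calling thresholds: per-donor
#' site depth >= 8 reads, per-SNP depth >= 12 reads for gene-level calls, at
#' least 3 non-discordant informative SNPs per gene and tissue, monoallelic
#' consistency threshold 0.33 on the ASE statistic, sample-unicity ASE
#' threshold 0.42, MAF >= 0.1, and a 2.3 Mb cis window on each side of the
#' anchor (a 4.6 Mb span).
#'
#' @param donor_min_depth minimum per-donor read depth at a site (reads).
#' @param gene_snp_min_depth minimum per-SNP depth for gene calls (reads).
#' @param min_snps minimum non-discordant informative SNPs per gene call.
#' @param mono_threshold ASE bound separating consistent-monoallelic from
#'   consistent-biallelic evidence.
#' @param strict_value the ASE value of complete monoallelic expression.
#' @param maf_min minimum global minor allele frequency.
#' @param unicity_threshold minimum ASE for the unicity criterion (i).
#' @param window_bp half-width of the cis scan window in bp.
#' @param epsilon equality tolerance for the "strictly" category rules.
#' @param quantile_type quantile estimator passed to [stats::quantile()]
#'   (default 7, linear interpolation between order statistics).
#' @param snp_depth_rule `"min"` (conservative: the SNP's minimum qualifying
#'   per-donor depth must reach `gene_snp_min_depth`) or `"mean"`.
#' @return a list of class `ase_params`.
#' @export
ase_params <- function(donor_min_depth = 8L, gene_snp_min_depth = 12L,
                       min_snps = 3L, mono_threshold = 0.33,
                       strict_value = 0.5, maf_min = 0.1,
                       unicity_threshold = 0.42, window_bp = 2300000,
                       epsilon = 1e-9, quantile_type = 7L,
                       snp_depth_rule = c("min", "mean")) {
  stopifnot(mono_threshold > 0, mono_threshold < strict_value,
            strict_value <= 0.5, donor_min_depth >= 1, min_snps >= 1)
  structure(list(donor_min_depth = as.integer(donor_min_depth),
                 gene_snp_min_depth = as.integer(gene_snp_min_depth),
                 min_snps = as.integer(min_snps),
                 mono_threshold = mono_threshold,
                 strict_value = strict_value, maf_min = maf_min,
                 unicity_threshold = unicity_threshold,
                 window_bp = window_bp, epsilon = epsilon,
                 quantile_type = as.integer(quantile_type),
                 snp_depth_rule = match.arg(snp_depth_rule)),
            class = "ase_params")
}

#' The ASE statistic from allelic read counts
#'
#' ASE is the magnitude of the deviation of the reference-allele read
#' fraction from one half, |0.5 - ref / (ref + alt)|: 0 for perfectly
#' balanced (biallelic) counts, 0.5 when only one allele is observed
#' (monoallelic). Symmetric under swapping ref and alt. Set
#' `signed = TRUE` for the raw signed deviation 0.5 - ref/(ref+alt)
#' (positive when the alternate allele dominates), used internally for
#' allele-flip detection.
#'
#' @param ref_count,alt_count non-negative read counts; at least one read
#'   in total. Vectorised.
#' @param signed return the signed deviation instead of the magnitude.
#' @return ASE values in [0, 0.5] (or [-0.5, 0.5] when signed).
#' @examples
#' ase_magnitude(10, 10)  # 0
#' ase_magnitude(0, 20)   # 0.5
#' ase_magnitude(30, 10)  # 0.25
#' @export
ase_magnitude <- function(ref_count, alt_count, signed = FALSE) {
  if (any(ref_count < 0) || any(alt_count < 0))
    stop("read counts must be non-negative")
  tot <- ref_count + alt_count
  if (any(tot == 0)) stop("ref_count + alt_count must be >= 1")
  v <- 0.5 - ref_count / tot
  if (signed) v else abs(v)
}

#' Aggregate per-donor ASE values at one SNP
#'
#' Donors whose total read depth at the site falls below
#' `params$donor_min_depth` are excluded; the five-number summary (min, Q1,
#' median, Q3, max) of the remaining per-donor ASE magnitudes is computed
#' with the configured quantile estimator.
#'
#' @param observations `data.frame` with columns `snp_id`, `gene`, `tissue`,
#'   `donor`, `ref_count`, `alt_count` (one SNP x tissue; mixed snp ids are
#'   an error).
#' @param params an [ase_params()].
#' @return one-row `data.frame` (`snp_id`, `gene`, `tissue`, `n_donors`,
#'   `min`, `q1`, `median`, `q3`, `max`, `min_depth_observed`), or `NULL`
#'   when no donor qualifies.
#' @export
summarize_site <- function(observations, params = ase_params()) {
  stopifnot(is.data.frame(observations), nrow(observations) >= 1)
  if (length(unique(observations$snp_id)) != 1)
    stop("summarize_site expects observations for a single SNP")
  depth <- observations$ref_count + observations$alt_count
  keep <- depth >= params$donor_min_depth
  if (!any(keep)) return(NULL)
  obs <- observations[keep, , drop = FALSE]
  a <- ase_magnitude(obs$ref_count, obs$alt_count)
  qs <- stats::quantile(a, probs = c(0, 0.25, 0.5, 0.75, 1),
                        names = FALSE, type = params$quantile_type)
  data.frame(snp_id = obs$snp_id[1], gene = obs$gene[1],
             tissue = obs$tissue[1], n_donors = nrow(obs),
             min = qs[1], q1 = qs[2], median = qs[3], q3 = qs[4],
             max = qs[5], min_depth_observed = min(depth[keep]),
             stringsAsFactors = FALSE)
}

#' Classify one SNP's aggregated ASE evidence
#'
#' Applies the four mutually exclusive categorical rules on the (min, Q1,
#' max) aggregates of the per-donor ASE magnitudes:
#' \describe{
#'   \item{strictly_monoallelic}{min = Q1 = max = 0.5}
#'   \item{consistent_monoallelic}{min < 0.5, Q1 >= 0.33 and max >= 0.33}
#'   \item{strictly_biallelic}{min = Q1 = max = 0}
#'   \item{consistent_biallelic}{min < 0.5, Q1 < 0.33 and max > 0}
#' }
#' Equalities are tested with tolerance `params$epsilon`; ASE values are
#' exact small-integer rationals so this is safe. A summary matching none
#' of the rules is `unclassified`.
#'
#' @param summary one-row `data.frame` from [summarize_site()], or any list
#'   with `min`, `q1`, `max` in [0, 0.5].
#' @param params an [ase_params()].
#' @return one of `"strictly_monoallelic"`, `"consistent_monoallelic"`,
#'   `"strictly_biallelic"`, `"consistent_biallelic"`, `"unclassified"`.
#' @export
classify_site <- function(summary, params = ase_params()) {
  mn <- summary$min; q1 <- summary$q1; mx <- summary$max
  stopifnot(mn >= 0, mx <= 0.5 + params$epsilon, mn <= q1 + params$epsilon,
            q1 <= mx + params$epsilon)
  eps <- params$epsilon
  s <- params$strict_value
  t <- params$mono_threshold
  eq <- function(a, b) abs(a - b) <= eps
  if (eq(mn, s) && eq(q1, s) && eq(mx, s)) return("strictly_monoallelic")
  if (eq(mn, 0) && eq(q1, 0) && eq(mx, 0)) return("strictly_biallelic")
  if (mn < s - eps && q1 >= t - eps && mx >= t - eps)
    return("consistent_monoallelic")
  if (mn < s - eps && q1 < t - eps && mx > eps)
    return("consistent_biallelic")
  "unclassified"
}

ase_categories <- function() {
  c("strictly_monoallelic", "consistent_monoallelic", "strictly_biallelic",
    "consistent_biallelic", "unclassified")
}

ase_direction <- function(category) {
  c(strictly_monoallelic = "monoallelic",
    consistent_monoallelic = "monoallelic",
    strictly_biallelic = "biallelic",
    consistent_biallelic = "biallelic",
    unclassified = NA_character_)[category]
}

#' Gene x tissue expression-profile call
#'
#' A gene is called in a tissue only on unambiguous evidence: after dropping
#' SNPs below the per-SNP depth threshold or without a category, at least
#' `min_snps` informative SNPs must remain and all must agree in direction
#' (strict and consistent variants collapse to monoallelic or biallelic).
#' A single opposing SNP voids the call (`discordant`); too few SNPs give
#' `too_few_snps`.
#'
#' @param site_categories `data.frame` with `snp_id`, `category` (from
#'   [classify_site()]) and `depth` (the per-SNP depth under the configured
#'   rule, e.g. `min_depth_observed`).
#' @param gene,tissue labels for the output row.
#' @param params an [ase_params()].
#' @return one-row `data.frame`: `gene`, `tissue`, `profile`
#'   (`"monoallelic"`, `"biallelic"` or `"not_callable"`),
#'   `n_informative_snps`, `reason` (`NA` when callable).
#' @export
call_gene_tissue <- function(site_categories, gene = NA_character_,
                             tissue = NA_character_, params = ase_params()) {
  stopifnot(is.data.frame(site_categories),
            all(c("snp_id", "category", "depth") %in%
                  names(site_categories)))
  dir <- ase_direction(site_categories$category)
  keep <- !is.na(dir) & site_categories$depth >= params$gene_snp_min_depth
  dir <- dir[keep]
  n <- length(dir)
  if (n < params$min_snps) {
    profile <- "not_callable"; reason <- "too_few_snps"
  } else if (length(unique(dir)) > 1) {
    profile <- "not_callable"; reason <- "discordant"
    n <- 0L
  } else {
    profile <- dir[1]; reason <- NA_character_
  }
  data.frame(gene = gene, tissue = tissue, profile = profile,
             n_informative_snps = if (profile == "not_callable") 0L
                                  else as.integer(n),
             reason = reason, stringsAsFactors = FALSE)
}

#' Filter ASE observations by minor allele frequency
#'
#' @param observations `data.frame` with a `maf` column (global minor allele
#'   frequency in [0, 0.5]).
#' @param params an [ase_params()].
#' @return observations with `maf >= maf_min`; rows with missing MAF are
#'   removed with a warning.
#' @export
maf_filter <- function(observations, params = ase_params()) {
  if (any(is.na(observations$maf))) {
    warning("removing ", sum(is.na(observations$maf)),
            " observation(s) with missing MAF")
  }
  observations[!is.na(observations$maf) &
                 observations$maf >= params$maf_min, , drop = FALSE]
}

#' Genes within the cis window around an anchor region
#'
#' Returns the genes whose transcription start site lies within
#' `window_bp` of the anchor interval's midpoint in either direction
#' (bounds inclusive), i.e. inside the `2 * window_bp` span centred on the
#' anchor — the scan used to look for parent-of-origin expression effects
#' of an iDMR on its neighbourhood.
#'
#' @param anchor one-row interval with `chrom`, `start`, `end` (half-open).
#' @param gene_annotations `data.frame` with `gene`, `chrom`, `tss`.
#' @param params an [ase_params()].
#' @return character vector of gene names in the window.
#' @export
cis_window_genes <- function(anchor, gene_annotations,
                             params = ase_params()) {
  stopifnot(all(c("gene", "chrom", "tss") %in% names(gene_annotations)))
  mid <- interval_midpoint(anchor$start, anchor$end)
  hit <- gene_annotations$chrom == anchor$chrom &
    abs(gene_annotations$tss - mid) <= params$window_bp
  gene_annotations$gene[hit]
}

#' Sample-unicity check on an imprinted-gene control panel
#'
#' Establishes that an expression-experiment collection behaves like pure,
#' healthy single-donor tissue by interrogating SNPs in genes known to be
#' expressed monoallelically. Three criteria, all required:
#' (i) every qualifying control SNP has ASE >= the unicity threshold,
#' judged on the SNP's donor-median ASE magnitude (the aggregate the
#' source expression tracks report), consistent with monoallelic
#' expression; (ii) allele flip —
#' within experiments of individual tissues, each control locus shows both
#' alleles as the expressed (dominant) allele in at least one experiment
#' each; (iii) no control SNP aggregates to a strictly biallelic pattern.
#'
#' @param observations control-panel observations: `snp_id`, `tissue`,
#'   `donor` (experiment id), `ref_count`, `alt_count`. Column `gene` is
#'   accepted and ignored for the check.
#' @param experiment_id label for the collection under test.
#' @param params an [ase_params()].
#' @return one-row `data.frame`: `experiment_id`, `criterion_ase_pass`,
#'   `criterion_flip_pass`, `criterion_no_strict_biallelic_pass`, `overall`.
#' @export
unicity_check <- function(observations, experiment_id = "collection",
                          params = ase_params()) {
  stopifnot(is.data.frame(observations))
  if (nrow(observations) == 0) stop("empty control panel")
  depth <- observations$ref_count + observations$alt_count
  obs <- observations[depth >= params$donor_min_depth, , drop = FALSE]
  if (nrow(obs) == 0) stop("no control-panel observation meets the depth bound")
  a <- ase_magnitude(obs$ref_count, obs$alt_count)
  med_by_snp <- vapply(split(a, paste(obs$snp_id, obs$tissue)),
                       stats::median, numeric(1))
  crit_ase <- all(med_by_snp >= params$unicity_threshold - params$epsilon)

  # allele flip: per locus within a tissue, the dominant (expressed) allele
  # must be ref in some experiment and alt in another
  signed <- ase_magnitude(obs$ref_count, obs$alt_count, signed = TRUE)
  flip_by_locus <- vapply(
    split(signed, paste(obs$snp_id, obs$tissue)),
    function(s) any(s < 0) && any(s > 0), logical(1))
  crit_flip <- length(flip_by_locus) > 0 && all(flip_by_locus)

  # strictly biallelic pattern at any control SNP voids unicity
  strict_bi <- vapply(
    split(seq_len(nrow(obs)), paste(obs$snp_id, obs$tissue)),
    function(ix) {
      sm <- summarize_site(obs[ix, , drop = FALSE], params)
      !is.null(sm) && classify_site(sm, params) == "strictly_biallelic"
    }, logical(1))
  crit_nobi <- !any(strict_bi)

  data.frame(experiment_id = experiment_id,
             criterion_ase_pass = crit_ase,
             criterion_flip_pass = crit_flip,
             criterion_no_strict_biallelic_pass = crit_nobi,
             overall = crit_ase && crit_flip && crit_nobi,
             stringsAsFactors = FALSE)
}

#' Run the ASE classification over an observation table
#'
#' Convenience wrapper: MAF filter, per-SNP aggregation, categorical
#' classification, and gene x tissue calls.
#'
#' @param observations ASE observation table (`snp_id`, `gene`, `tissue`,
#'   `donor`, `ref_count`, `alt_count`, `maf`).
#' @param params an [ase_params()].
#' @return list with `site_summaries`, `site_categories` and `gene_calls`
#'   data frames.
#' @export
run_ase <- function(observations, params = ase_params()) {
  obs <- maf_filter(observations, params)
  groups <- split(obs, list(obs$snp_id, obs$gene, obs$tissue), drop = TRUE)
  summaries <- do.call(rbind, lapply(groups, summarize_site, params = params))
  if (is.null(summaries))
    summaries <- utils::read.table(text = "", col.names = names(
      table_schemas()$ase_site_summaries))
  rownames(summaries) <- NULL
  categories <- data.frame(
    snp_id = summaries$snp_id, gene = summaries$gene,
    tissue = summaries$tissue,
    category = vapply(seq_len(nrow(summaries)), function(i)
      classify_site(summaries[i, ], params), character(1)),
    stringsAsFactors = FALSE)
  gt <- unique(summaries[, c("gene", "tissue"), drop = FALSE])
  gene_calls <- do.call(rbind, lapply(seq_len(nrow(gt)), function(i) {
    sel <- summaries$gene == gt$gene[i] & summaries$tissue == gt$tissue[i]
    call_gene_tissue(
      data.frame(snp_id = summaries$snp_id[sel],
                 category = categories$category[sel],
                 depth = summaries$min_depth_observed[sel],
                 stringsAsFactors = FALSE),
      gene = gt$gene[i], tissue = gt$tissue[i], params = params)
  }))
  if (is.null(gene_calls))
    gene_calls <- utils::read.table(text = "", col.names = names(
      table_schemas()$gene_calls))
  rownames(gene_calls) <- NULL
  list(site_summaries = summaries, site_categories = categories,
       gene_calls = gene_calls)
}
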