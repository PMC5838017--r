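# Genotypes are unordered allele pairs written "A/G" (alleles are arbitrary
# strings, e.g. "I"/"D" for an indel). parse_genotype() returns the two
# alleles as a character vector.
parse_genotype <- function(gt) {
  if (length(gt) == 1 && is.character(gt) && grepl("/", gt))
    gt <- strsplit(gt, "/", fixed = TRUE)[[1]]
  gt <- as.character(gt)
  if (length(gt) != 2 || any(!nzchar(gt)))
    stop("a genotype must hold exactly two alleles, e.g. \"A/G\"")
  gt
}

#' Deduce which parent transmitted each child allele
#'
#' Standard single-SNP Mendelian phasing: for a heterozygous child, each of
#' the two ways of assigning the child alleles to the parents is tested for
#' consistency with the parental genotypes. Exactly one consistent
#' assignment identifies the maternally and paternally transmitted alleles;
#' when both assignments are consistent (e.g. all three members share the
#' same heterozygous genotype) the trio is uninformative. A homozygous
#' child is always uninformative for origin phasing. A trio in which the
#' child's alleles cannot have come one from each parent is a Mendelian
#' inconsistency and an error.
#'
#' @param mother,father,child genotypes as `"A/G"` strings or length-2
#'   character vectors; unordered.
#' @param family_id optional label used in error messages.
#' @return list with `informative` (logical), and when informative
#'   `maternal_allele` and `paternal_allele`.
#' @examples
#' transmitted_alleles("I/I", "D/D", "I/D")  # maternal I, paternal D
#' @export
transmitted_alleles <- function(mother, father, child, family_id = NULL) {
  m <- parse_genotype(mother); f <- parse_genotype(father)
  c_ <- parse_genotype(child)
  assignments <- unique(list(c(c_[1], c_[2]), c(c_[2], c_[1])))
  consistent <- Filter(function(a) a[1] %in% m && a[2] %in% f, assignments)
  if (length(consistent) == 0)
    stop("Mendelian inconsistency",
         if (!is.null(family_id)) paste0(" in trio '", family_id, "'") else "",
         ": child ", paste(c_, collapse = "/"), " from mother ",
         paste(m, collapse = "/"), " and father ", paste(f, collapse = "/"))
  if (c_[1] == c_[2] || length(consistent) > 1)
    return(list(informative = FALSE,
                maternal_allele = NA_character_,
                paternal_allele = NA_character_))
  list(informative = TRUE,
       maternal_allele = consistent[[1]][1],
       paternal_allele = consistent[[1]][2])
}

#' Parental origin of the methylated allele from digestion-resistant calls
#'
#' After methylation-sensitive digestion only methylated (resistant)
#' templates amplify, so genotyping the surviving alleles reveals which
#' parental allele carries the methylation imprint. With the transmission
#' phased by [transmitted_alleles()]: a resistant set equal to the maternal
#' allele gives a maternal imprint, equal to the paternal allele a paternal
#' imprint, both alleles resistant means biparental (parent-of-origin-
#' independent) methylation, and an empty set an unmethylated locus.
#'
#' @param transmission result of [transmitted_alleles()].
#' @param resistant_alleles character vector of alleles detected after
#'   digestion (possibly empty); must be a subset of the child's alleles.
#' @return one of `"maternal"`, `"paternal"`, `"biparental_methylation"`,
#'   `"unmethylated"`, `"uninformative"`.
#' @export
infer_imprint_origin <- function(transmission, resistant_alleles) {
  if (!isTRUE(transmission$informative)) return("uninformative")
  child_alleles <- c(transmission$maternal_allele,
                     transmission$paternal_allele)
  res <- unique(as.character(resistant_alleles))
  res <- res[nzchar(res)]
  if (!all(res %in% child_alleles))
    stop("resistant allele(s) not carried by the child: ",
         paste(setdiff(res, child_alleles), collapse = ", "))
  if (length(res) == 0) return("unmethylated")
  if (setequal(res, child_alleles)) return("biparental_methylation")
  if (identical(res, transmission$maternal_allele)) return("maternal")
  "paternal"
}

#' Per-family imprint-origin calls for a trio table
#'
#' @param trios `data.frame` with columns `family_id`, `snp_id`,
#'   `mother_gt`, `father_gt`, `child_gt`, `resistant_alleles`
#'   (comma-separated, empty string for none).
#' @return `data.frame` with `family_id`, `snp_id`, `maternal_allele`,
#'   `paternal_allele`, `origin`.
#' @export
call_trio_origins <- function(trios) {
  stopifnot(is.data.frame(trios),
            all(c("family_id", "snp_id", "mother_gt", "father_gt",
                  "child_gt", "resistant_alleles") %in% names(trios)))
  out <- lapply(seq_len(nrow(trios)), function(i) {
    tr <- transmitted_alleles(trios$mother_gt[i], trios$father_gt[i],
                              trios$child_gt[i],
                              family_id = trios$family_id[i])
    res <- trios$resistant_alleles[i]
    res <- if (is.na(res) || !nzchar(res)) character(0)
           else strsplit(res, ",", fixed = TRUE)[[1]]
    data.frame(family_id = trios$family_id[i], snp_id = trios$snp_id[i],
               maternal_allele = tr$maternal_allele,
               paternal_allele = tr$paternal_allele,
               origin = infer_imprint_origin(tr, res),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Consensus imprint origin across families
#'
#' Uninformative families are excluded; a consensus is emitted only when
#' every informative family agrees (the default, matching fully concordant
#' family panels). `majority` mode instead returns the strict-majority
#' origin when one exists.
#'
#' @param calls `data.frame` from [call_trio_origins()], or a character
#'   vector of origin calls.
#' @param mode `"unanimous"` (default) or `"majority"`.
#' @return list with `consensus` (an origin, or `"conflict"`),
#'   `n_informative`, and `calls` (the informative per-family calls).
#' @export
cohort_consensus <- function(calls, mode = c("unanimous", "majority")) {
  mode <- match.arg(mode)
  if (is.data.frame(calls)) origins <- calls$origin else origins <- calls
  informative <- origins != "uninformative"
  inf <- origins[informative]
  if (length(inf) == 0) stop("no informative family")
  tab <- table(inf)
  consensus <- if (mode == "unanimous") {
    if (length(tab) == 1) names(tab) else "conflict"
  } else {
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1 && max(tab) > length(inf) / 2) top else "conflict"
  }
  list(consensus = consensus, n_informative = length(inf),
       calls = if (is.data.frame(calls))
         calls[informative, , drop = FALSE] else inf)
}
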