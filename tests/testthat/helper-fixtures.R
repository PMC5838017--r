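# Shared fixture builders. All fixtures are built in code; no data files.

# A methylome track from bare site levels on one chromosome.
make_track <- function(levels, pos = NULL, chrom = "chr1", depth = 30,
                       sample_id = "s1", compartment = "somatic",
                       tissue = "soma", min_depth = 10) {
  n <- length(levels)
  if (is.null(pos)) pos <- seq(100, by = 10, length.out = n)
  methylome_track(
    sample_id,
    data.frame(chrom = chrom, pos = pos, level = levels,
               depth = rep_len(depth, n), stringsAsFactors = FALSE),
    tissue = tissue, compartment = compartment, min_depth = min_depth)
}

# All-pairs brute-force overlap counting: the independent oracle for
# interval overlap under half-open semantics.
brute_force_amr_counts <- function(cgis, amrs) {
  rc <- integer(nrow(cgis)); mc <- integer(nrow(cgis))
  for (i in seq_len(nrow(cgis))) {
    hit <- logical(nrow(amrs))
    for (j in seq_len(nrow(amrs))) {
      hit[j] <- cgis$chrom[i] == amrs$chrom[j] &&
        cgis$start[i] < amrs$end[j] && amrs$start[j] < cgis$end[i]
    }
    rc[i] <- sum(hit)
    mc[i] <- length(unique(amrs$source_methylome[hit]))
  }
  data.frame(cgi_id = cgis$name, record_count = rc, methylome_count = mc,
             stringsAsFactors = FALSE)
}

# Independent rule table for the four categorical ASE rules, written
# directly from their definitions (no tolerance machinery).
ase_rule_oracle <- function(mn, q1, mx, t = 0.33, s = 0.5) {
  rules <- c(
    strictly_monoallelic = (mn == s && q1 == s && mx == s),
    consistent_monoallelic = (mn < s && q1 >= t && mx >= t),
    strictly_biallelic = (mn == 0 && q1 == 0 && mx == 0),
    consistent_biallelic = (mn < s && q1 < t && mx > 0))
  names(rules)[rules]
}

# Probability that a random trio is informative for origin phasing, by
# exhaustive enumeration of parental allele draws and transmissions at
# allele frequency p (biallelic SNP). Informative: heterozygous child with
# a unique parental assignment, i.e. NOT (paternal allele also carried by
# the mother AND maternal allele also carried by the father).
informative_fraction_oracle <- function(p) {
  alleles <- c("A", "B")
  pr <- c(A = p, B = 1 - p)
  total <- 0
  for (m1 in alleles) for (m2 in alleles)
    for (f1 in alleles) for (f2 in alleles)
      for (tm in 1:2) for (tf in 1:2) {
        prob <- pr[m1] * pr[m2] * pr[f1] * pr[f2] * 0.25
        cm <- c(m1, m2)[tm]; cf <- c(f1, f2)[tf]
        if (cm != cf && !(cf %in% c(m1, m2) && cm %in% c(f1, f2)))
          total <- total + prob
      }
  unname(total)
}

# Map from simulator truth classes to screen classes.
truth_to_screen_class <- c(gametic_maternal = "gametic_maternal",
                           gametic_paternal = "gametic_paternal",
                           secondary = "secondary_candidate")
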