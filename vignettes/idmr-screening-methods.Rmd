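---
title: "Screening for imprinted differentially methylated regions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for imprinted differentially methylated regions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idmrscreen)
```

## The problem

Genomic imprinting marks a small set of human loci with
parent-of-origin-dependent DNA methylation: at an imprinted differentially
methylated region (iDMR), one parental allele of a CpG island (CGI) is
methylated and the other is not. In bulk bisulfite sequencing this
hemimethylation shows up as a stable *intermediate* methylation level —
roughly half the reads methylated at every CpG site — in essentially every
somatic tissue. Gametic (primary) iDMRs acquire the mark in one gamete
(hypermethylated in oocytes for maternal imprints, in sperm for paternal
ones) and keep it after fertilisation; secondary iDMRs acquire
parent-specific methylation somatically, and the gametes show no
asymmetry.

`idmrscreen` implements, as a tested and reusable pipeline, a
discovery-and-validation workflow for candidate iDMRs:

1. **Screen** — count allelically methylated region (AMR) records
   overlapping each CGI across a panel of methylome repositories, keep
   CGIs with many independent records whose CpG sites are consistently
   intermediate in a reference somatic methylome, and classify candidates
   as gametic maternal, gametic paternal or secondary from oocyte and
   sperm methylomes.
2. **Profile** — summarise region-level methylation across sample cohorts
   (placenta, cancer), flag dysregulation, and interpret trisomic
   placentas through an allele-dosage model.
3. **ASE** — classify allele-specific expression evidence at SNPs around
   candidate iDMRs into four categorical profiles and call gene × tissue
   expression modes, with a sample-unicity check.
4. **Trios** — establish the parental origin of the methylated allele
   from Mendelian transmission plus methylation-sensitive
   restriction-digest (MSRE) resistant-allele genotyping.

Because the original inputs (dozens of public BS-Seq methylomes, GTEx
expression tracks, SRA experiment atlases) are not redistributable at desk
scale, the package ships a first-class synthetic-data generator that
emulates their statistical structure with known ground truth; every stage
is exercised end-to-end against that truth.

## The screen

For CGI $c$ and AMR record set $\mathcal{A}$, the record count is

$$ n(c) = \#\{a \in \mathcal{A} : a \text{ shares} \ge 1\,\text{bp with } c\} $$

under half-open (BED) interval semantics: abutting intervals do not
overlap. Records are counted individually, not collapsed per source
methylome — two AMR calls from the same repository count twice — because
repeated detection is the screening signal; the distinct-methylome count
is reported alongside and a `count_unique_methylomes` switch makes the
stricter semantics available. CGIs on the sex chromosomes are excluded by
default (imprinting evidence there is confounded by X inactivation);
`autosomes_only = FALSE` overrides.

Retention requires `min_records` (default 16) overlapping records — the
minimal count observed for most *known* gametic and secondary iDMRs, so
the threshold is anchored on positive controls rather than a null model.

The **intermediate filter** then demands that in the reference somatic
methylome *every* covered CpG site in the CGI lies inside the
hemimethylation band $[0.35, 0.65]$, bounds inclusive. The per-site (not
mean) criterion is deliberate: a region mean of 0.5 can arise from a
sharply bimodal (half-methylated/half-unmethylated) site profile, which is
a boundary artefact, not allelic hemimethylation. A CGI with zero covered
sites is "not evaluable" and rejected with that annotation rather than
silently dropped.

**Gamete classification** uses the region mean in each gamete track via
`call_status()`: hypomethylated below 0.35, hypermethylated strictly above
0.65. Oocyte-hyper with sperm-hypo is gametic maternal; the mirror is
gametic paternal; *every* other combination — both hypo (the canonical
secondary signature), both intermediate, or an unevaluable gamete — falls
through to secondary candidate, because secondary iDMRs are defined by the
absence of gametic asymmetry. Region means (rather than per-site
consistency) are used here because gamete methylomes are sparse and
site-level coverage is unreliable.

Two ambiguities in the screen's published description were resolved as
explicit options, both off by default:

* whether AMR records from different repositories were deduplicated
  before counting — the loader preserves records verbatim;
* whether each CGI additionally required an AMR record in the reference
  methylome itself — available as `require_reference_amr`.

## Methylation profiles and the trisomy dosage model

Region summaries average site levels across an interval **excluding
no-data sites** (sites below the 10-read depth floor carry a missing
level); the standard deviation uses the $n-1$ denominator and is absent
for a single usable site. Status calls reuse the same band: dysregulation
in cancer cohorts is defined against the fixed intermediate band observed
in healthy tissue, not against matched-normal deltas, and a cohort whose
samples all sit inside the band exhibits absence of epipolymorphism.

The **dosage model** predicts the bulk methylation level of a region
methylated on $m$ of $k$ allele copies as $m/k$. At a maternal iDMR in a
trisomic placenta, a paternal supernumerary chromosome gives $1/3$
(skewed hypomethylation) and a maternal one $2/3$ (skewed
hypermethylation); the decision thresholds are $\le 0.33$ and
$\ge 0.66$. Observed means are rounded to two decimals before comparison
so the theoretical $1/3$ and $2/3$ satisfy their own bounds — without the
rounding, $1/3 > 0.33$ in exact arithmetic and the model's own prediction
would be indeterminate. The thresholds are applied to per-sample region
means (the per-probe alternative is not supported).

The **MSRE-PCR proportion** of digestion-resistant methylated sites is
computed from a triplex assay — target amplimer, an enzyme-site-free
reference amplimer for lane normalisation, and a constitutively
unmethylated digestion control — as the reference-normalised ratio of
ratios

$$ p = \frac{T_\mathrm{dig}/R_\mathrm{dig}}{T_\mathrm{undig}/R_\mathrm{undig}}, $$

clamped to $[0,1]$. The published assay cites its equation from earlier
work rather than printing it; the ratio-of-ratios form implemented here
follows directly from the stated role of the reference amplimer
("normalisation of the ratio of resistant sites") and is isolated behind
`msre_proportion()` so an alternative can be swapped in. It is invariant
to rescaling either lane's signals, which is exactly what lane
normalisation must guarantee, and refuses to report when the digestion
control still amplifies (incomplete digestion) or the undigested target
failed.

## ASE classification

The ASE statistic at a heterozygous SNP is
$|0.5 - \mathrm{ref}/(\mathrm{ref}+\mathrm{alt})|$: 0 when balanced, 0.5
when monoallelic. The published formula is signed; the categorical rules
only use $[0, 0.5]$, so the magnitude is taken (the source-track
convention), and the signed value is retained internally to detect which
allele is expressed for allele-flip analysis.

Per SNP, donors with fewer than 8 reads are excluded and the five-number
summary of per-donor ASE magnitudes is computed with linear interpolation
between order statistics (`stats::quantile` type 7; the estimator is
configurable because the upstream tracks do not document theirs). The four
categories are applied to (min, Q1, max) exactly as published —

* strictly monoallelic: min = Q1 = max = 0.5;
* consistent with monoallelic: min < 0.5, Q1 ≥ 0.33, max ≥ 0.33;
* strictly biallelic: min = Q1 = max = 0;
* consistent with biallelic: min < 0.5, Q1 < 0.33, max > 0 —

with equality tolerance $10^{-9}$ (ASE values are exact rationals of
small integers, so the tolerance can be tiny without risk). The test
suite verifies constructively, over an exhaustive grid of valid
(min, Q1, max) triples, that the four rules are pairwise disjoint — the
published "mutually exclusive" claim — and that the classifier agrees
with an independent rule table everywhere; on exact aggregates the four
rules also turn out to be jointly exhaustive, so the `unclassified`
category acts as a guard for malformed summaries rather than a fifth
profile.

A gene × tissue profile is called only from at least 3 non-discordant
informative SNPs with ≥ 12 reads each; "non-discordant" is read as *all*
informative SNPs sharing one direction after collapsing strict/consistent
pairs, so a single opposing SNP voids the call, and "≥ 12 reads per SNP"
is applied to the SNP's minimum qualifying per-donor depth (the
conservative reading; a mean-depth mode is available). Cis-window scans
anchor at the iDMR interval midpoint and include genes whose TSS lies
within 2.3 Mb on either side, bounds inclusive — the published spans name
the window width but not the anchor points, and midpoint-to-TSS is the
symmetric choice.

The **unicity check** screens an experiment collection against a small
panel of control loci known to be expressed monoallelically. Three
criteria must all hold: (i) every control SNP is consistent with
monoallelic expression, judged on its donor-median ASE ≥ 0.42 — the
median is used because that is the aggregate the source expression tracks
report, and a per-read-set reading would fail honest monoallelic data
whenever a single donor's counts wobble; (ii) allele flip: within a
tissue, each control locus shows each of the two alleles as the dominant
one in at least one experiment — the signature of sampling different
individuals' random parental alleles; (iii) no control SNP aggregates to
a strictly biallelic pattern. The pipeline's synthetic panel uses three
random-allelic loci, mirroring the size of real imprinted-gene control
panels; with 10 donors a single locus fails to flip with probability
$2 \cdot 0.5^{10} \approx 0.002$, so small panels keep the all-loci flip
requirement statistically meaningful.

## Trio inference

For each informative family, single-SNP Mendelian phasing assigns the
heterozygous child's alleles to parents when exactly one assignment is
consistent with the parental genotypes; trios where both assignments are
consistent, or with a homozygous child, are uninformative (a homozygous
child's resistant allele cannot be attributed to a parent even when
detected). The digestion-resistant allele set then maps directly to the
origin call: the maternal allele resistant → maternal imprint; paternal →
paternal; both → biparental (parent-of-origin-independent) methylation —
the signature separating a truly imprinted locus from a constitutively
hemimethylated, randomly allelically methylated one; empty → unmethylated.
Resistant calls are treated as presence/absence of a genotyping peak, not
quantitatively. The cohort consensus requires unanimity among informative
families (published panels are fully concordant); a majority-vote mode
exists behind a flag.

## The synthetic-data generator

Defaults are the study conditions used throughout the tests: 300 CGIs of
1 kb with 10 CpG sites each on 4 synthetic autosomes, 39 somatic
methylomes contributing AMR records at sensitivity 0.7 with a false-call
rate of 0.02 per CGI per methylome, site noise sd 0.03; 50 genes × 4
tissues × 4 SNPs × 10 donors at mean RNA-Seq depth 30 with monoallelic
expressed-allele fraction 0.98; 1,000 trios at allele frequency 0.5 with
error-free resistant calls.

Truth classes and their compartment means:

| class | somatic | oocyte | sperm | blastocyst |
|---|---|---|---|---|
| gametic_maternal | 0.50 | 0.95 | 0.05 | 0.50 |
| gametic_paternal | 0.50 | 0.05 | 0.95 | 0.50 |
| secondary | 0.50 | 0.05 | 0.05 | 0.05 |
| random_hemimethylated | 0.50 | 0.95 | 0.05 | 0.50 |
| unmethylated | 0.05 | 0.05 | 0.05 | 0.05 |
| hypermethylated | 0.95 | 0.95 | 0.95 | 0.95 |

The somatic intermediate mean is the idealised 0.5 of perfect allelic
hemimethylation rather than any particular tissue's observed value, so
class separation is controlled by configuration, not hard-coded to one
dataset. The class mix defaults to a minority of true iDMRs
(10% gametic maternal, 8% gametic paternal, 22% secondary — roughly the
published 18:11:96 ratio among candidates — plus 5% random-hemimethylated)
against a background of unmethylated and hypermethylated CGIs. Site noise
is Beta-distributed, reparameterised by mean and sd and clamped to keep
both shape parameters positive: methylation fractions are bounded, and
Beta is the natural bounded-noise model; sd 0 degenerates exactly to the
class mean.

The `random_hemimethylated` class is the deliberate trap: it is
AMR-positive, somatically intermediate and gamete-asymmetric, so the
*screen* classifies it as a gametic candidate — only the *trio* stage,
where both parental alleles resist digestion, unmasks it as
parent-of-origin-independent. This mirrors how such loci are actually
discovered and is why end-to-end screen accuracy is measured against the
three true-iDMR classes only.

Trisomic placenta tracks draw hemimethylated CGIs at the dosage
expectation (1/3 or 2/3 per the configured supernumerary origin); cancer
tracks perturb them to 0.1 or 0.9. AMR boundaries are jittered within
half a CGI length while always retaining overlap. RNA-Seq depths are
shifted Poisson (1 + Pois(mean − 1)); methylome depths are floored at the
10-read threshold so simulated sites are never masked by the depth rule
(coverage-driven missingness is tested separately through the readers).
Under random-allelic expression the expressed allele is drawn per donor
*per gene* and shared by the gene's SNPs, since the allelic choice is
clonal in a donor and every SNP on the transcript reports the same
allele.

Every generator derives an independent deterministic stream from the
single seed, so stages can be regenerated in isolation and full runs are
byte-reproducible.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: read-level bisulfite chemistry and conversion
failure, correlated noise along a CGI, cell-composition heterogeneity,
array probe effects, mapping bias in allelic read counts, linkage between
SNPs, population structure in trios, and tissue-specific or polymorphic
imprinting. Recovery rates measured here are properties of the idealised
generative model at its configured noise, not sensitivity estimates for
any real cohort.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open throughout; 1-based appears only in
  formatted output. Chromosome names compare string-exactly, with an
  opt-in "chr" prefix normaliser.
* Band bounds are inclusive ($0.35 \le x \le 0.65$ is intermediate);
  hypermethylation is strict ($> 0.65$).
* Zero usable sites → status "unevaluable", never 0 or NA-as-0; a single
  usable site has an absent sd.
* Tracks below bisulfite conversion 0.95 are rejected at load unless
  explicitly allowed; duplicate (chrom, pos) sites and out-of-range
  levels are hard errors.
* The MSRE proportion is clamped to $[0,1]$ (signal noise can push the
  raw ratio slightly above 1) and errors on incomplete digestion.
* Consensus ties and conflicts are reported as `"conflict"`, never
  silently resolved.

## Problem sizes

The shipped tests run the screen recovery at the full default design
(300 CGIs × 39 methylomes), ASE recovery at 50 genes × 4 tissues × 10
donors, the trio stage at 1,000 families, overlap-counting equivalence
against a brute-force oracle on 200 random instances, and the end-to-end
reproducibility check on a reduced genome (80 CGIs); the complete suite
finishes in well under a minute on one core.

## Known limitations

* The screen's record-count threshold is a fixed cutoff, not a
  significance test; no attempt is made to model repository-specific AMR
  calling error.
* ASE calling is purely categorical — no binomial tests, no mapping-bias
  correction, no phasing; genes without ≥ 3 informative SNPs are
  `not_callable`, which on sparse data is the common outcome.
* Trio phasing is single-SNP; multi-SNP haplotypes are out of scope.
* The MSRE equation is the declared ratio-of-ratios stand-in described
  above, pending the exact published form.
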