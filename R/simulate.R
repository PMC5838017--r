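#' Configuration for the synthetic-data generator
#'
#' The generator emulates the statistical structure of the pipeline's real
#' inputs: a panel of BS-Seq methylomes with intermediate (~0.5) somatic
#' methylation at imprinted CGIs, hyper/hypo asymmetry in gametes, AMR
#' detection with imperfect sensitivity and a small false-call rate,
#' binomial allelic RNA-Seq read counts with biallelic and monoallelic
#' expression modes, and Mendelian trios with digestion-resistant maternal
#' alleles. All generators are deterministic for a fixed `seed`.
#'
#' @param seed integer seed; each generator derives its own stream from it.
#' @param n_cgis number of CpG islands to place.
#' @param n_chroms number of synthetic autosomes.
#' @param chrom_length chromosome length in bp.
#' @param cgi_length CGI length in bp.
#' @param sites_per_cgi CpG sites simulated per CGI.
#' @param class_proportions named proportions over the CGI truth classes
#'   `gametic_maternal`, `gametic_paternal`, `secondary`,
#'   `random_hemimethylated`, `unmethylated`, `hypermethylated`; must sum
#'   to 1.
#' @param n_methylomes number of somatic methylome repositories contributing
#'   AMR records (default 39).
#' @param amr_sensitivity probability that a methylome reports an AMR at a
#'   hemimethylated (AMR-positive) CGI.
#' @param amr_false_rate per-methylome probability of a spurious AMR at any
#'   other CGI.
#' @param site_noise_sd standard deviation of the bounded (Beta) site-level
#'   noise around each class mean.
#' @param methylome_depth_mean mean simulated read depth per CpG site.
#' @param n_trisomy_placentas,trisomy_origin trisomic placenta tracks and
#'   the supernumerary chromosome's parental origin (`"paternal"` or
#'   `"maternal"`) driving the 1/3 vs 2/3 dosage expectation at maternal
#'   iDMRs.
#' @param n_cancer_tracks cancer methylomes with dysregulated (hypo- or
#'   hypermethylated) iDMR levels.
#' @param n_genes,n_tissues,snps_per_gene,n_donors shape of the ASE table.
#' @param gene_mode_proportions named proportions over gene x tissue
#'   expression modes `biallelic`, `monoallelic_imprinted`,
#'   `monoallelic_random`.
#' @param read_depth_mean mean RNA-Seq depth per SNP per donor (shifted
#'   Poisson).
#' @param mono_expression_p expressed-allele read fraction under
#'   monoallelic expression (default 0.98).
#' @param n_trios simulated nuclear families.
#' @param trio_truth_origin true imprint origin at the interrogated locus
#'   (`"maternal"`, `"paternal"`, `"biparental"` or `"unmethylated"`).
#' @param allele_freq allele frequency of the trio SNP's first allele.
#' @param genotyping_error per-call probability of flipping a
#'   digestion-resistant allele call.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_cgis = 300L,
                       n_chroms = 4L,
                       chrom_length = 6e7,
                       cgi_length = 1000L,
                       sites_per_cgi = 10L,
                       class_proportions = c(gametic_maternal = 0.10,
                                             gametic_paternal = 0.08,
                                             secondary = 0.22,
                                             random_hemimethylated = 0.05,
                                             unmethylated = 0.40,
                                             hypermethylated = 0.15),
                       n_methylomes = 39L,
                       amr_sensitivity = 0.7,
                       amr_false_rate = 0.02,
                       site_noise_sd = 0.03,
                       methylome_depth_mean = 30,
                       n_trisomy_placentas = 4L,
                       trisomy_origin = c("paternal", "maternal"),
                       n_cancer_tracks = 4L,
                       n_genes = 50L,
                       n_tissues = 4L,
                       snps_per_gene = 4L,
                       n_donors = 10L,
                       gene_mode_proportions = c(biallelic = 0.6,
                                                 monoallelic_imprinted = 0.2,
                                                 monoallelic_random = 0.2),
                       read_depth_mean = 30,
                       mono_expression_p = 0.98,
                       n_trios = 1000L,
                       trio_truth_origin = "maternal",
                       allele_freq = 0.5,
                       genotyping_error = 0) {
  trisomy_origin <- match.arg(trisomy_origin)
  cls <- c("gametic_maternal", "gametic_paternal", "secondary",
           "random_hemimethylated", "unmethylated", "hypermethylated")
  stopifnot(setequal(names(class_proportions), cls),
            abs(sum(class_proportions) - 1) < 1e-8,
            all(class_proportions >= 0),
            abs(sum(gene_mode_proportions) - 1) < 1e-8,
            amr_sensitivity >= 0, amr_sensitivity <= 1,
            amr_false_rate >= 0, amr_false_rate <= 1,
            site_noise_sd >= 0, mono_expression_p >= 0.5,
            mono_expression_p <= 1,
            allele_freq > 0, allele_freq < 1,
            genotyping_error >= 0, genotyping_error <= 1)
  cfg <- as.list(environment())
  cfg$cls <- NULL
  cfg$class_proportions <- class_proportions[cls]
  structure(cfg, class = "sim_config")
}

# Derived deterministic seed streams, kept below 2^31.
sim_seed <- function(config, stage) {
  offset <- c(genome = 101L, methylomes = 202L, amr = 303L, ase = 404L,
              trios = 505L)[[stage]]
  (as.integer(config$seed) * 1009L + offset) %% .Machine$integer.max
}

# Beta noise reparameterised by mean and sd; sd = 0 degenerates to the mean.
# The sd is shrunk where necessary to keep both shape parameters positive
# (near the [0,1] boundary the requested sd may be infeasible).
rbeta_mean_sd <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  max_var <- mean * (1 - mean)
  v <- min(sd^2, 0.95 * max_var)
  nu <- max_var / v - 1
  stats::rbeta(n, mean * nu, (1 - mean) * nu)
}

# True-class mean methylation by compartment. Maternal-iDMR-like classes are
# hypermethylated in oocytes; the mirror for paternal. Secondary iDMRs are
# hypomethylated in both gametes and in blastocysts; primary iDMRs stay
# intermediate in blastocysts.
class_mean <- function(true_class, compartment,
                       trisomy_origin = "paternal") {
  idmr_like <- c("gametic_maternal", "gametic_paternal", "secondary",
                 "random_hemimethylated")
  base <- switch(true_class,
                 unmethylated = 0.05, hypermethylated = 0.95, 0.5)
  switch(compartment,
    somatic = base,
    placenta = base,
    oocyte = switch(true_class,
                    gametic_maternal = 0.95, random_hemimethylated = 0.95,
                    gametic_paternal = 0.05, secondary = 0.05,
                    unmethylated = 0.05, hypermethylated = 0.95),
    sperm = switch(true_class,
                   gametic_maternal = 0.05, random_hemimethylated = 0.05,
                   gametic_paternal = 0.95, secondary = 0.05,
                   unmethylated = 0.05, hypermethylated = 0.95),
    blastocyst = switch(true_class,
                        gametic_maternal = 0.5, gametic_paternal = 0.5,
                        random_hemimethylated = 0.5,
                        secondary = 0.05, unmethylated = 0.05,
                        hypermethylated = 0.95),
    trisomy_placenta = if (true_class %in% idmr_like) {
      if (trisomy_origin == "paternal") 1 / 3 else 2 / 3
    } else base,
    stop("unknown compartment ", compartment))
}

amr_positive_classes <- function() {
  c("gametic_maternal", "gametic_paternal", "secondary",
    "random_hemimethylated")
}

true_idmr_classes <- function() {
  c("gametic_maternal", "gametic_paternal", "secondary")
}

#' Simulate a genome: CGIs, CpG site positions, genes, and the truth table
#'
#' Places non-overlapping CGIs evenly (with jitter) along synthetic
#' autosomes, draws each CGI's truth class from the configured proportions,
#' lays `sites_per_cgi` CpG positions within each CGI (shared by all
#' simulated methylomes), and places genes with transcription start sites
#' both inside and beyond the cis scan window around their anchor CGIs,
#' with a known expression mode per gene and tissue.
#'
#' @param config a [sim_config()].
#' @return list: `cgis` (interval table), `cpg_sites` (`chrom`, `pos`,
#'   `cgi_id`), `genes` (`gene`, `chrom`, `tss`, `anchor_cgi`,
#'   `in_window`), `truth` (list with `cgis` and `genes` truth tables).
#' @export
simulate_genome <- function(config = sim_config()) {
  set.seed(sim_seed(config, "genome"))
  n <- config$n_cgis
  per_chrom <- ceiling(n / config$n_chroms)
  slot_width <- floor(config$chrom_length / per_chrom)
  if (slot_width < 2 * config$cgi_length)
    stop("infeasible placement: too many CGIs for chrom_length")
  chrom <- paste0("chr", rep(seq_len(config$n_chroms), each = per_chrom))[seq_len(n)]
  slot <- rep(seq_len(per_chrom) - 1L, times = config$n_chroms)[seq_len(n)]
  jitter_max <- slot_width - config$cgi_length - 1
  start <- slot * slot_width +
    if (n > 0) floor(stats::runif(n, 0, jitter_max)) else numeric(0)
  cgis <- genomic_intervals(chrom, start, start + config$cgi_length,
                            if (n > 0) sprintf("cgi_%04d", seq_len(n))
                            else character(0))
  classes <- names(config$class_proportions)
  true_class <- if (n > 0)
    sample(classes, n, replace = TRUE, prob = config$class_proportions)
  else character(0)

  cpg <- if (n > 0) {
    offs <- floor(seq(1, config$cgi_length - 1,
                      length.out = config$sites_per_cgi))
    data.frame(chrom = rep(cgis$chrom, each = config$sites_per_cgi),
               pos = rep(cgis$start, each = config$sites_per_cgi) +
                 rep(offs, times = n),
               cgi_id = rep(cgis$name, each = config$sites_per_cgi),
               stringsAsFactors = FALSE)
  } else data.frame(chrom = character(0), pos = numeric(0),
                    cgi_id = character(0))

  ng <- config$n_genes
  genes <- if (ng > 0) {
    anchor_idx <- rep(seq_len(max(n, 1)), length.out = ng)
    if (n == 0) stop("cannot place genes without CGIs")
    in_window <- stats::runif(ng) < 0.8
    w <- 2300000
    mid <- interval_midpoint(cgis$start, cgis$end)[anchor_idx]
    off <- ifelse(in_window,
                  round(stats::runif(ng, -w, w)),
                  sample(c(-1, 1), ng, TRUE) *
                    round(stats::runif(ng, w + 1e5, w + 1e6)))
    tss <- pmax(0, pmin(mid + off, config$chrom_length - 1))
    data.frame(gene = sprintf("gene_%03d", seq_len(ng)),
               chrom = cgis$chrom[anchor_idx], tss = tss,
               anchor_cgi = cgis$name[anchor_idx],
               in_window = in_window, stringsAsFactors = FALSE)
  } else data.frame(gene = character(0), chrom = character(0),
                    tss = numeric(0), anchor_cgi = character(0),
                    in_window = logical(0))

  tissues <- paste0("tissue_", seq_len(config$n_tissues))
  gene_truth <- if (ng > 0) {
    gt <- expand.grid(gene = genes$gene, tissue = tissues,
                      stringsAsFactors = FALSE)
    gt$true_mode <- sample(names(config$gene_mode_proportions),
                           nrow(gt), replace = TRUE,
                           prob = config$gene_mode_proportions)
    gt
  } else data.frame(gene = character(0), tissue = character(0),
                    true_mode = character(0))

  list(cgis = cgis, cpg_sites = cpg, genes = genes,
       truth = list(
         cgis = data.frame(cgi_id = cgis$name, true_class = true_class,
                           stringsAsFactors = FALSE),
         genes = gene_truth))
}

#' Simulate the methylome track panel
#'
#' Generates per-sample CpG methylation tracks at the genome's site
#' positions: `n_methylomes` somatic tissues (the first, "esophagus", is
#' the screen's reference), oocyte and sperm gamete tracks, a blastocyst
#' track, normal and trisomic placenta tracks following the allele-dosage
#' expectation (1/3 or 2/3 at hemimethylated CGIs depending on the
#' supernumerary origin), and cancer tracks whose hemimethylated CGIs are
#' perturbed to hypo- or hypermethylated levels. Site levels are the class
#' mean plus bounded Beta noise with sd `site_noise_sd`; at sd 0 levels
#' equal the class means exactly.
#'
#' @param genome output of [simulate_genome()].
#' @param config a [sim_config()].
#' @return named list of [methylome_track()] objects; somatic tracks are
#'   `somatic_01` ... and the reference is `somatic_01`.
#' @export
simulate_methylomes <- function(genome, config = sim_config()) {
  set.seed(sim_seed(config, "methylomes"))
  truth <- genome$truth$cgis
  cpg <- genome$cpg_sites
  cls_of_site <- truth$true_class[match(cpg$cgi_id, truth$cgi_id)]

  draw_track <- function(sample_id, tissue, compartment, mean_by_class) {
    m <- unname(mean_by_class[cls_of_site])
    lv <- numeric(nrow(cpg))
    for (cl in unique(cls_of_site)) {
      ix <- cls_of_site == cl
      lv[ix] <- rbeta_mean_sd(sum(ix), mean_by_class[[cl]],
                              config$site_noise_sd)
    }
    depth <- config$methylome_depth_mean
    dp <- 10 + stats::rpois(nrow(cpg), max(depth - 10, 0))
    methylome_track(sample_id,
                    data.frame(chrom = cpg$chrom, pos = cpg$pos,
                               level = lv, depth = dp,
                               stringsAsFactors = FALSE),
                    tissue = tissue, compartment = compartment,
                    conversion_rate = 0.99, min_depth = 10)
  }

  means_for <- function(compartment) {
    cls <- names(config$class_proportions)
    stats::setNames(vapply(cls, class_mean, numeric(1),
                           compartment = compartment,
                           trisomy_origin = config$trisomy_origin), cls)
  }

  tracks <- list()
  som_means <- means_for("somatic")
  for (i in seq_len(config$n_methylomes)) {
    id <- sprintf("somatic_%02d", i)
    tracks[[id]] <- draw_track(id, if (i == 1) "esophagus"
                                   else paste0("tissue_", i),
                               "somatic", som_means)
  }
  tracks$oocyte <- draw_track("oocyte", "oocyte", "oocyte",
                              means_for("oocyte"))
  tracks$sperm <- draw_track("sperm", "spermatozoa", "sperm",
                             means_for("sperm"))
  tracks$blastocyst <- draw_track("blastocyst", "blastocyst", "blastocyst",
                                  means_for("blastocyst"))
  tracks$placenta_normal <- draw_track("placenta_normal", "placenta",
                                       "placenta", means_for("placenta"))
  tri_means <- means_for("trisomy_placenta")
  for (i in seq_len(config$n_trisomy_placentas)) {
    id <- sprintf("placenta_trisomy_%02d", i)
    tracks[[id]] <- draw_track(id, "placenta_trisomy", "placenta",
                               tri_means)
  }
  for (i in seq_len(config$n_cancer_tracks)) {
    id <- sprintf("cancer_%02d", i)
    perturbed <- som_means
    idmr <- names(perturbed) %in% amr_positive_classes()
    perturbed[idmr] <- if (i %% 2 == 1) 0.1 else 0.9
    tracks[[id]] <- draw_track(id, "hematopoietic_cancer", "cancer",
                               perturbed)
  }
  tracks
}

#' Simulate AMR record collections per methylome
#'
#' Each hemimethylated (AMR-positive) CGI yields an overlapping AMR record
#' in each of the `n_methylomes` repositories with probability
#' `amr_sensitivity`; record boundaries are jittered within half a CGI
#' length while always retaining at least 1 bp of overlap. Every other CGI
#' attracts a spurious overlapping record per methylome with probability
#' `amr_false_rate`.
#'
#' @param genome output of [simulate_genome()].
#' @param config a [sim_config()].
#' @return `data.frame` of AMR records: `chrom`, `start`, `end`,
#'   `source_methylome`.
#' @export
simulate_amr_calls <- function(genome, config = sim_config()) {
  set.seed(sim_seed(config, "amr"))
  truth <- genome$truth$cgis
  cgis <- genome$cgis
  positive <- truth$true_class %in% amr_positive_classes()
  L <- config$cgi_length
  out <- vector("list", config$n_methylomes)
  for (m in seq_len(config$n_methylomes)) {
    p <- ifelse(positive, config$amr_sensitivity, config$amr_false_rate)
    hit <- stats::runif(nrow(cgis)) < p
    if (!any(hit)) next
    s0 <- cgis$start[hit]; e0 <- cgis$end[hit]
    # jitter keeps start' < end' and >= 1 bp overlap with the CGI
    s1 <- s0 + round(stats::runif(sum(hit), -0.5 * L, 0.4 * L))
    e1 <- e0 + round(stats::runif(sum(hit), -0.4 * L, 0.5 * L))
    s1 <- pmax(s1, 0)
    out[[m]] <- data.frame(chrom = cgis$chrom[hit], start = s1, end = e1,
                           source_methylome = sprintf("somatic_%02d", m),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), source_methylome = character(0))
  rownames(res) <- NULL
  res
}

#' Simulate allele-specific-expression observations
#'
#' For each gene x tissue x SNP x donor, read depth is a shifted Poisson
#' with mean `read_depth_mean` and the reference-allele count is Binomial
#' with p = 0.5 (biallelic mode) or p in {p0, 1 - p0} with
#' p0 = `mono_expression_p` (monoallelic modes). Under imprinted
#' monoallelic expression the expressed allele is fixed per gene x tissue
#' (one parental allele); under random-allelic expression it is drawn per
#' donor and shared by all SNPs of the gene (the allelic choice is made
#' once per donor per gene, and every SNP on the transcript reports the
#' same allele), which produces allele flips across donors.
#'
#' @param genome output of [simulate_genome()].
#' @param config a [sim_config()].
#' @return ASE observation table: `snp_id`, `gene`, `tissue`, `donor`,
#'   `ref_count`, `alt_count`, `maf`.
#' @export
simulate_ase <- function(genome, config = sim_config()) {
  set.seed(sim_seed(config, "ase"))
  gt <- genome$truth$genes
  if (nrow(gt) == 0)
    return(data.frame(snp_id = character(0), gene = character(0),
                      tissue = character(0), donor = character(0),
                      ref_count = numeric(0), alt_count = numeric(0),
                      maf = numeric(0)))
  genes <- unique(gt$gene)
  snp_maf <- stats::runif(length(genes) * config$snps_per_gene, 0.1, 0.5)
  snp_tab <- data.frame(
    gene = rep(genes, each = config$snps_per_gene),
    snp_id = sprintf("rs%05d", seq_len(length(genes) * config$snps_per_gene)),
    maf = round(snp_maf, 3), stringsAsFactors = FALSE)

  rows <- vector("list", nrow(gt))
  for (i in seq_len(nrow(gt))) {
    snps <- snp_tab[snp_tab$gene == gt$gene[i], , drop = FALSE]
    mode <- gt$true_mode[i]
    imprint_ref <- stats::runif(1) < 0.5  # which parental allele is expressed
    nd <- config$n_donors
    # random-allelic choice is per donor per gene, shared across its SNPs
    donor_ref <- stats::runif(nd) < 0.5
    block <- vector("list", nrow(snps))
    for (s in seq_len(nrow(snps))) {
      depth <- 1 + stats::rpois(nd, max(config$read_depth_mean - 1, 0))
      p <- switch(mode,
        biallelic = rep(0.5, nd),
        monoallelic_imprinted =
          rep(if (imprint_ref) config$mono_expression_p
              else 1 - config$mono_expression_p, nd),
        monoallelic_random =
          ifelse(donor_ref, config$mono_expression_p,
                 1 - config$mono_expression_p),
        stop("unknown expression mode ", mode))
      ref <- stats::rbinom(nd, depth, p)
      block[[s]] <- data.frame(
        snp_id = snps$snp_id[s], gene = gt$gene[i], tissue = gt$tissue[i],
        donor = sprintf("donor_%02d", seq_len(nd)),
        ref_count = ref, alt_count = depth - ref, maf = snps$maf[s],
        stringsAsFactors = FALSE)
    }
    rows[[i]] <- do.call(rbind, block)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Simulate nuclear trios with digestion-resistant allele calls
#'
#' Parental genotypes are drawn at the configured allele frequency for a
#' biallelic SNP (alleles `A`/`B`); the child receives one allele from each
#' parent. The digestion-resistant allele set reflects the configured true
#' imprint origin: the maternally transmitted allele for a maternal
#' imprint, the paternal one for a paternal imprint, both child alleles for
#' biparental methylation, and none for an unmethylated locus. With
#' probability `genotyping_error`, a single-allele resistant call is
#' flipped to the other child allele.
#'
#' @param config a [sim_config()].
#' @param snp_id SNP label written to the table.
#' @return list with `trios` (schema `trios`: `family_id`, `snp_id`,
#'   `mother_gt`, `father_gt`, `child_gt`, `resistant_alleles`) and `truth`
#'   (`family_id`, `snp_id`, `true_origin`).
#' @export
simulate_trios <- function(config = sim_config(), snp_id = "rs_locus") {
  set.seed(sim_seed(config, "trios"))
  n <- config$n_trios
  p <- config$allele_freq
  draw_allele <- function(k) ifelse(stats::runif(k) < p, "A", "B")
  m1 <- draw_allele(n); m2 <- draw_allele(n)
  f1 <- draw_allele(n); f2 <- draw_allele(n)
  from_m <- ifelse(stats::runif(n) < 0.5, m1, m2)
  from_f <- ifelse(stats::runif(n) < 0.5, f1, f2)
  origin <- config$trio_truth_origin
  resistant <- switch(origin,
    maternal = from_m,
    paternal = from_f,
    biparental = NA_character_,  # handled below
    unmethylated = "",
    stop("unknown trio_truth_origin ", origin))
  if (origin == "biparental") {
    resistant <- ifelse(from_m == from_f, from_m,
                        paste(pmin(from_m, from_f), pmax(from_m, from_f),
                              sep = ","))
  } else if (origin %in% c("maternal", "paternal") &&
             config$genotyping_error > 0) {
    flip <- stats::runif(n) < config$genotyping_error
    other <- ifelse(resistant == from_m & origin == "maternal", from_f, from_m)
    resistant[flip] <- other[flip]
  }
  gt <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "/")
  trios <- data.frame(
    family_id = sprintf("fam_%04d", seq_len(n)), snp_id = snp_id,
    mother_gt = gt(m1, m2), father_gt = gt(f1, f2),
    child_gt = gt(from_m, from_f),
    resistant_alleles = resistant, stringsAsFactors = FALSE)
  list(trios = trios,
       truth = data.frame(family_id = trios$family_id, snp_id = snp_id,
                          true_origin = origin, stringsAsFactors = FALSE))
}
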