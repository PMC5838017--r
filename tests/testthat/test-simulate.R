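small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_cgis = 40, n_genes = 8, n_tissues = 2, n_trios = 50),
    list(...))
  do.call(sim_config, args)
}

test_that("all generators are deterministic under a fixed seed", {
  cfg <- small_cfg(seed = 3)
  g1 <- simulate_genome(cfg); g2 <- simulate_genome(cfg)
  expect_identical(g1, g2)
  expect_identical(simulate_methylomes(g1, cfg),
                   simulate_methylomes(g2, cfg))
  expect_identical(simulate_amr_calls(g1, cfg), simulate_amr_calls(g2, cfg))
  expect_identical(simulate_ase(g1, cfg), simulate_ase(g2, cfg))
  expect_identical(simulate_trios(cfg), simulate_trios(cfg))
  # a different seed changes the draw
  expect_false(identical(g1, simulate_genome(small_cfg(seed = 4))))
})

test_that("genome generation honours proportions, placement and edge cases", {
  all_sec <- small_cfg(seed = 5, class_proportions = c(
    gametic_maternal = 0, gametic_paternal = 0, secondary = 1,
    random_hemimethylated = 0, unmethylated = 0, hypermethylated = 0))
  g <- simulate_genome(all_sec)
  expect_true(all(g$truth$cgis$true_class == "secondary"))

  empty <- simulate_genome(small_cfg(seed = 5, n_cgis = 0, n_genes = 0))
  expect_equal(nrow(empty$cgis), 0)
  expect_equal(nrow(empty$truth$cgis), 0)

  expect_error(simulate_genome(sim_config(n_cgis = 1e6, chrom_length = 1e6)),
               "infeasible placement")

  # CGIs are valid, non-overlapping intervals with unique site positions
  g2 <- simulate_genome(small_cfg(seed = 6))
  expect_silent(idmrscreen:::validate_intervals(g2$cgis))
  byc <- split(g2$cgis, g2$cgis$chrom)
  for (b in byc) {
    b <- b[order(b$start), ]
    if (nrow(b) > 1) expect_true(all(b$start[-1] >= b$end[-nrow(b)]))
  }
  expect_false(any(duplicated(
    paste(g2$cpg_sites$chrom, g2$cpg_sites$pos))))
})

test_that("zero-noise methylomes sit exactly at their class means", {
  cfg <- small_cfg(seed = 7, site_noise_sd = 0)
  g <- simulate_genome(cfg)
  tracks <- simulate_methylomes(g, cfg)
  truth <- g$truth$cgis
  som <- tracks$somatic_01$sites
  cls <- truth$true_class[match(g$cpg_sites$cgi_id, truth$cgi_id)]
  expected <- ifelse(cls == "unmethylated", 0.05,
                     ifelse(cls == "hypermethylated", 0.95, 0.5))
  expect_equal(som$level, expected)

  # secondary-class CGIs are hypomethylated in both gametes
  sec <- truth$cgi_id[truth$true_class == "secondary"]
  if (length(sec)) {
    cgi <- g$cgis[g$cgis$name == sec[1], ]
    oo <- region_mean(tracks$oocyte, cgi)
    sp <- region_mean(tracks$sperm, cgi)
    expect_lt(oo$mean, 0.35); expect_lt(sp$mean, 0.35)
  }
  # gametic maternal: oocyte hyper, sperm hypo
  mat <- truth$cgi_id[truth$true_class == "gametic_maternal"]
  if (length(mat)) {
    cgi <- g$cgis[g$cgis$name == mat[1], ]
    expect_equal(region_mean(tracks$oocyte, cgi)$mean, 0.95)
    expect_equal(region_mean(tracks$sperm, cgi)$mean, 0.05)
  }
})

test_that("trisomic placentas follow the dosage expectation at iDMR CGIs", {
  cfg <- small_cfg(seed = 8, site_noise_sd = 0, trisomy_origin = "paternal")
  g <- simulate_genome(cfg)
  tracks <- simulate_methylomes(g, cfg)
  mat <- g$truth$cgis$cgi_id[g$truth$cgis$true_class == "gametic_maternal"]
  cgi <- g$cgis[g$cgis$name == mat[1], ]
  expect_equal(region_mean(tracks$placenta_trisomy_01, cgi)$mean, 1 / 3)

  cfg2 <- small_cfg(seed = 8, site_noise_sd = 0, trisomy_origin = "maternal")
  tracks2 <- simulate_methylomes(g, cfg2)
  expect_equal(region_mean(tracks2$placenta_trisomy_01, cgi)$mean, 2 / 3)
})

test_that("AMR simulation matches its sensitivity model", {
  # sensitivity 1, false rate 0: every hemimethylated CGI has exactly one
  # overlapping record per methylome
  cfg <- small_cfg(seed = 9, amr_sensitivity = 1, amr_false_rate = 0)
  g <- simulate_genome(cfg)
  amrs <- simulate_amr_calls(g, cfg)
  counts <- count_overlapping_amrs(g$cgis, amrs)
  pos <- g$truth$cgis$true_class %in%
    c("gametic_maternal", "gametic_paternal", "secondary",
      "random_hemimethylated")
  expect_true(all(counts$record_count[pos] == cfg$n_methylomes))
  expect_true(all(counts$record_count[!pos] == 0))

  # sensitivity 0 and false rate 0: nothing is called, the screen retains nothing
  cfg0 <- small_cfg(seed = 9, amr_sensitivity = 0, amr_false_rate = 0)
  expect_equal(nrow(simulate_amr_calls(g, cfg0)), 0)

  # sensitivity 0.7 over 200 hemimethylated CGIs: mean record count within
  # 3 standard errors of the binomial expectation 39 * 0.7
  cfgb <- sim_config(seed = 10, n_cgis = 200, n_genes = 4, n_trios = 5,
                     amr_sensitivity = 0.7, amr_false_rate = 0,
                     class_proportions = c(
                       gametic_maternal = 0.4, gametic_paternal = 0.3,
                       secondary = 0.3, random_hemimethylated = 0,
                       unmethylated = 0, hypermethylated = 0))
  gb <- simulate_genome(cfgb)
  cb <- count_overlapping_amrs(gb$cgis, simulate_amr_calls(gb, cfgb))
  expected <- 39 * 0.7
  se <- sqrt(39 * 0.7 * 0.3 / nrow(cb))
  expect_lt(abs(mean(cb$record_count) - expected), 3 * se)
})

test_that("ASE simulation produces the configured expression modes", {
  # complete monoallelic expression: every donor at ASE 0.5
  cfg <- small_cfg(seed = 12, mono_expression_p = 1,
                   gene_mode_proportions = c(biallelic = 0,
                                             monoallelic_imprinted = 1,
                                             monoallelic_random = 0))
  g <- simulate_genome(cfg)
  obs <- simulate_ase(g, cfg)
  expect_true(all(ase_magnitude(obs$ref_count, obs$alt_count) == 0.5))

  # biallelic at great depth concentrates near 0
  cfgb <- small_cfg(seed = 13, read_depth_mean = 1000,
                    gene_mode_proportions = c(biallelic = 1,
                                              monoallelic_imprinted = 0,
                                              monoallelic_random = 0))
  gb <- simulate_genome(cfgb)
  ob <- simulate_ase(gb, cfgb)
  expect_true(all(ase_magnitude(ob$ref_count, ob$alt_count) < 0.1))

  # random-allelic mode shows both alleles expressed (allele flips)
  cfgr <- small_cfg(seed = 14, mono_expression_p = 1,
                    gene_mode_proportions = c(biallelic = 0,
                                              monoallelic_imprinted = 0,
                                              monoallelic_random = 1))
  gr <- simulate_genome(cfgr)
  orr <- simulate_ase(gr, cfgr)
  signed <- ase_magnitude(orr$ref_count, orr$alt_count, signed = TRUE)
  expect_true(any(signed > 0) && any(signed < 0))
  # MAF always passes the 0.1 filter by construction
  expect_true(all(orr$maf >= 0.1))
})

test_that("trio simulation writes resistant alleles per the true origin", {
  cfg <- small_cfg(seed = 15, n_trios = 300, genotyping_error = 0)
  sim <- simulate_trios(cfg)
  calls <- call_trio_origins(sim$trios)
  inf <- calls[calls$origin != "uninformative", ]
  expect_gt(nrow(inf), 0)
  expect_true(all(inf$origin == "maternal"))

  cfgb <- small_cfg(seed = 15, trio_truth_origin = "biparental")
  simb <- simulate_trios(cfgb)
  callsb <- call_trio_origins(simb$trios)
  infb <- callsb[callsb$origin != "uninformative", ]
  expect_true(all(infb$origin == "biparental_methylation"))
  # heterozygous-child biparental rows carry both alleles
  het <- vapply(strsplit(simb$trios$child_gt, "/"), function(a)
    a[1] != a[2], logical(1))
  expect_true(all(grepl(",", simb$trios$resistant_alleles[het])))

  cfgu <- small_cfg(seed = 15, trio_truth_origin = "unmethylated")
  callsu <- call_trio_origins(simulate_trios(cfgu)$trios)
  infu <- callsu[callsu$origin != "uninformative", ]
  expect_true(all(infu$origin == "unmethylated"))
})

test_that("generated tracks and intervals pass the readers' validation", {
  cfg <- small_cfg(seed = 16)
  g <- simulate_genome(cfg)
  tracks <- simulate_methylomes(g, cfg)
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "cgis.bed")
  write_bed(g$cgis, bed)
  expect_equal(read_bed(bed), g$cgis)
  tsv <- file.path(dir, "oocyte.tsv")
  write_methylation_track(tracks$oocyte, tsv)
  expect_silent(back <- read_methylation_track(tsv))
  expect_equal(back$sites, tracks$oocyte$sites)
})
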