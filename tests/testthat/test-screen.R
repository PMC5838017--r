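amr_df <- function(chrom, start, end, src) {
  data.frame(chrom = chrom, start = start, end = end,
             source_methylome = src, stringsAsFactors = FALSE)
}

test_that("AMR record counting uses half-open overlap and counts records and methylomes", {
  cgis <- genomic_intervals("chr1", 100, 300, "cgi_1")
  amrs <- amr_df("chr1", c(250, 0), c(400, 150), c("m1", "m2"))
  expect_equal(count_overlapping_amrs(cgis, amrs),
               data.frame(cgi_id = "cgi_1", record_count = 2L,
                          methylome_count = 2L, stringsAsFactors = FALSE))

  # abutting is not overlap; zero-overlap CGIs still appear
  expect_equal(count_overlapping_amrs(
    cgis, amr_df("chr1", 300, 400, "m1"))$record_count, 0L)
  expect_equal(count_overlapping_amrs(
    cgis, amr_df("chr1", 0, 100, "m1"))$record_count, 0L)
  # 1 bp of shared sequence counts; same methylome twice -> 2 records, 1 methylome
  cnt <- count_overlapping_amrs(
    cgis, amr_df("chr1", c(299, 10), c(400, 101), c("m1", "m1")))
  expect_equal(cnt$record_count, 2L)
  expect_equal(cnt$methylome_count, 1L)
  # chromosome comparison is string-exact
  expect_equal(count_overlapping_amrs(
    cgis, amr_df("1", 150, 250, "m1"))$record_count, 0L)
})

test_that("overlap counting equals the all-pairs brute-force oracle on random instances", {
  set.seed(42)
  for (rep in 1:10) {
    nc <- sample(5:50, 1); na <- sample(20:200, 1)
    cs <- sample(0:5000, nc)
    cgis <- genomic_intervals(sample(c("chr1", "chr2"), nc, TRUE),
                              cs, cs + sample(50:500, nc, TRUE),
                              paste0("c", seq_len(nc)))
    as_ <- sample(0:5000, na, TRUE)
    amrs <- amr_df(sample(c("chr1", "chr2"), na, TRUE), as_,
                   as_ + sample(30:600, na, TRUE),
                   paste0("m", sample(1:8, na, TRUE)))
    expect_equal(count_overlapping_amrs(cgis, amrs),
                 brute_force_amr_counts(cgis, amrs))
  }
})

test_that("the record-count filter retains CGIs at exactly the threshold", {
  counts <- data.frame(cgi_id = c("a", "b", "c"),
                       record_count = c(16L, 15L, 40L),
                       methylome_count = c(10L, 15L, 20L))
  p <- screen_params(min_records = 16)
  expect_equal(filter_by_record_count(counts, p), c("a", "c"))
  counts$record_count <- c(0L, 0L, 0L)
  expect_equal(filter_by_record_count(counts, p), character(0))
  # distinct-methylome counting mode
  p2 <- screen_params(min_records = 16, count_unique_methylomes = TRUE)
  counts$record_count <- c(40L, 40L, 40L)
  expect_equal(filter_by_record_count(counts, p2), c("c"))
})

test_that("the intermediate filter demands every covered site in band, bounds inclusive", {
  cgi <- list(chrom = "chr1", start = 0, end = 1000, name = "c")
  p <- screen_params()
  expect_true(intermediate_filter(cgi, make_track(c(0.40, 0.50, 0.60)), p))
  expect_false(intermediate_filter(cgi, make_track(c(0.40, 0.70)), p))
  expect_true(intermediate_filter(cgi, make_track(c(0.35, 0.65)), p))
  # zero covered sites -> not evaluable
  r <- intermediate_filter(cgi, make_track(c(0.5), pos = 5000), p)
  expect_false(r)
  expect_false(attr(r, "evaluable"))
  # missing-level sites do not count as covered
  r2 <- intermediate_filter(cgi, make_track(c(0.5, NA), depth = c(30, 5)), p)
  expect_true(r2)
})

test_that("gamete asymmetry classification covers all combinations", {
  cgi <- list(chrom = "chr1", start = 0, end = 1000, name = "c")
  trk <- function(m, who) make_track(rep(m, 5), sample_id = who,
                                     compartment = who)
  expect_equal(classify_candidate(cgi, trk(0.90, "oocyte"),
                                  trk(0.05, "sperm"))$klass,
               "gametic_maternal")
  expect_equal(classify_candidate(cgi, trk(0.05, "oocyte"),
                                  trk(0.90, "sperm"))$klass,
               "gametic_paternal")
  expect_equal(classify_candidate(cgi, trk(0.05, "oocyte"),
                                  trk(0.05, "sperm"))$klass,
               "secondary_candidate")
  expect_equal(classify_candidate(cgi, trk(0.50, "oocyte"),
                                  trk(0.50, "sperm"))$klass,
               "secondary_candidate")
  # unevaluable gamete -> secondary with annotation, not rejection
  far <- make_track(0.9, pos = 99999, sample_id = "oocyte",
                    compartment = "oocyte")
  cl <- classify_candidate(cgi, far, trk(0.05, "sperm"))
  expect_equal(cl$klass, "secondary_candidate")
  expect_equal(cl$annotation, "unevaluable gamete")
  expect_error(classify_candidate(cgi, NULL, trk(0.05, "sperm")),
               "required")
})

test_that("known-iDMR annotation supports id and interval matching", {
  cand <- data.frame(cgi_id = c("a", "b"), chrom = "chr1",
                     start = c(0, 5000), end = c(1000, 6000),
                     klass = c("gametic_maternal", "secondary_candidate"),
                     novel = TRUE, stringsAsFactors = FALSE)
  out <- annotate_known(cand, "a")
  expect_equal(out$klass, c("known", "secondary_candidate"))
  expect_equal(out$novel, c(FALSE, TRUE))

  out2 <- annotate_known(cand, character(0))
  expect_true(all(out2$novel))

  known_ivl <- genomic_intervals("chr1", 5500, 7000, "k1")
  out3 <- annotate_known(cand, known_ivl, match = "interval")
  expect_equal(out3$klass, c("gametic_maternal", "known"))
  expect_equal(out3$novel, c(TRUE, FALSE))
})

test_that("run_screen applies the stages in order and partitions the CGIs", {
  cfg <- sim_config(seed = 11, n_cgis = 80, n_genes = 4, n_trios = 5,
                    site_noise_sd = 0, amr_sensitivity = 1,
                    amr_false_rate = 0)
  g <- simulate_genome(cfg)
  tr <- simulate_methylomes(g, cfg)
  amrs <- simulate_amr_calls(g, cfg)
  res <- run_screen(g$cgis, amrs, tr$somatic_01, tr$oocyte, tr$sperm)

  expect_equal(nrow(res), nrow(g$cgis))
  expect_true(all(!duplicated(res$cgi_id)))
  # partition identity: novel = candidate classes; rejected carry a reason
  expect_equal(sum(res$novel),
               sum(res$klass %in% c("gametic_maternal", "gametic_paternal",
                                    "secondary_candidate")))
  expect_true(all(!is.na(res$reject_reason[res$klass == "rejected"])))

  # zero AMR records -> nothing survives the record filter
  none <- run_screen(g$cgis, amrs[0, ], tr$somatic_01, tr$oocyte, tr$sperm)
  expect_true(all(none$klass == "rejected"))
  expect_true(all(none$reject_reason == "below_record_count"))

  # known annotation folds in as klass = known, novel = FALSE
  truth <- g$truth$cgis
  some_true <- res$cgi_id[res$klass == "gametic_maternal"][1]
  withk <- run_screen(g$cgis, amrs, tr$somatic_01, tr$oocyte, tr$sperm,
                      known_idmrs = some_true)
  expect_equal(withk$klass[withk$cgi_id == some_true], "known")
  expect_false(withk$novel[withk$cgi_id == some_true])
})

test_that("sex-chromosome CGIs are excluded by default and kept on request", {
  cgis <- genomic_intervals(c("chr1", "chrX"), c(0, 0), c(1000, 1000),
                            c("auto", "x"))
  amrs <- amr_df(rep(c("chr1", "chrX"), each = 20), 100, 900,
                 paste0("m", 1:20))
  ref <- make_track(rep(0.5, 3), chrom = "chr1", sample_id = "ref")
  oo <- make_track(rep(0.9, 3), chrom = "chr1", sample_id = "oocyte",
                   compartment = "oocyte")
  sp <- make_track(rep(0.05, 3), chrom = "chr1", sample_id = "sperm",
                   compartment = "sperm")
  res <- run_screen(cgis, amrs, ref, oo, sp)
  expect_equal(res$reject_reason[res$cgi_id == "x"], "non_autosomal")
  res2 <- run_screen(cgis, amrs, ref, oo, sp,
                     params = screen_params(autosomes_only = FALSE))
  expect_true(is.na(res2$reject_reason[res2$cgi_id == "x"]) ||
                res2$reject_reason[res2$cgi_id == "x"] != "non_autosomal")
})

test_that("screen retention is monotone in min_records and the intermediate band", {
  cfg <- sim_config(seed = 23, n_cgis = 60, n_genes = 4, n_trios = 5)
  g <- simulate_genome(cfg)
  tr <- simulate_methylomes(g, cfg)
  amrs <- simulate_amr_calls(g, cfg)
  retained <- function(p) {
    r <- run_screen(g$cgis, amrs, tr$somatic_01, tr$oocyte, tr$sperm, p)
    r$cgi_id[r$novel]
  }
  r16 <- retained(screen_params(min_records = 16))
  r20 <- retained(screen_params(min_records = 20))
  expect_true(all(r20 %in% r16))
  rwide <- retained(screen_params(intermediate_low = 0.25,
                                  intermediate_high = 0.75))
  expect_true(all(r16 %in% rwide))
})
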