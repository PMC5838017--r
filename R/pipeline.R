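#' Run the full synthetic end-to-end analysis
#'
#' Executes every stage on generated data with known ground truth:
#' synthetic genome and methylomes, AMR simulation, the candidate-iDMR
#' screen, region methylation summaries and cohort status profiles
#' (placenta and cancer panels at hemimethylated candidate CGIs, with
#' trisomy parent-of-origin calls), the ASE classification with the
#' unicity check on a random-allelic control panel, and trio imprint-origin
#' inference with its cohort consensus. All stage outputs are written as
#' TSVs under `out_dir` together with a run manifest recording the seed and
#' a hash of the configuration; reruns with the same configuration are
#' byte-identical.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory; created if missing. `NULL` keeps
#'   everything in memory.
#' @param screen a [screen_params()]; its reference methylome defaults to
#'   the generator's reference (`somatic_01`).
#' @param ase an [ase_params()].
#' @return (invisibly) list with `candidates`, `region_summaries`,
#'   `cohort_profile`, `trisomy_calls`, `ase`, `unicity`, `trio_calls`,
#'   `trio_consensus`, `truth`, `summary`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         screen = screen_params(reference_methylome = "somatic_01"),
                         ase = ase_params()) {
  genome <- simulate_genome(config)
  tracks <- simulate_methylomes(genome, config)
  amrs <- simulate_amr_calls(genome, config)

  reference <- screen$reference_methylome %||% "somatic_01"
  candidates <- run_screen(genome$cgis, amrs,
                           reference_track = tracks[[reference]],
                           oocyte_track = tracks$oocyte,
                           sperm_track = tracks$sperm, params = screen)

  # placenta + cancer cohort at retained hemimethylated candidates
  cand <- candidates[candidates$klass %in%
                       c("gametic_maternal", "gametic_paternal",
                         "secondary_candidate", "known"), , drop = FALSE]
  cohort_ids <- grep("^(placenta|cancer)", names(tracks), value = TRUE)
  region_summaries <- do.call(rbind, lapply(cohort_ids, function(id) {
    do.call(rbind, lapply(seq_len(nrow(cand)), function(i) {
      region_mean(tracks[[id]],
                  list(chrom = cand$chrom[i], start = cand$start[i],
                       end = cand$end[i], name = cand$cgi_id[i]))
    }))
  }))
  if (is.null(region_summaries))
    region_summaries <- utils::read.table(text = "", col.names = names(
      table_schemas()$region_summaries))
  cohort <- if (nrow(region_summaries))
    cohort_status_profile(region_summaries)
  else list(profile = utils::read.table(text = "", col.names = names(
    table_schemas()$cohort_profile)), n_dysregulated = 0L,
    fraction_intermediate = NA_real_)

  # trisomy parent-of-origin calls at maternal candidates in trisomic placentas
  tri <- region_summaries[
    grepl("^placenta_trisomy", region_summaries$sample_id) &
      region_summaries$name %in%
        cand$cgi_id[cand$klass == "gametic_maternal"], , drop = FALSE]
  trisomy_calls <- if (nrow(tri)) data.frame(
    sample_id = tri$sample_id, cgi_id = tri$name, mean = tri$mean,
    origin = call_trisomy_origin(tri$mean), stringsAsFactors = FALSE)
  else data.frame(sample_id = character(0), cgi_id = character(0),
                  mean = numeric(0), origin = character(0))

  observations <- simulate_ase(genome, config)
  ase_res <- run_ase(observations, ase)

  # unicity control panel: a small panel (up to 3 loci, mirroring the
  # usual three-imprinted-gene panels) of gene x tissue pairs with random
  # allelic expression, which show monoallelic skew with allele flips
  gt_truth <- genome$truth$genes
  panel_key <- utils::head(paste(gt_truth$gene, gt_truth$tissue)[
    gt_truth$true_mode == "monoallelic_random"], 3)
  unicity <- if (length(panel_key)) {
    panel <- observations[paste(observations$gene, observations$tissue) %in%
                            panel_key, , drop = FALSE]
    unicity_check(panel, experiment_id = "synthetic_collection", ase)
  } else NULL

  trio_sim <- simulate_trios(config)
  trio_calls <- call_trio_origins(trio_sim$trios)
  trio_consensus <- cohort_consensus(trio_calls)

  summary_tab <- data.frame(
    metric = c("n_cgis", "n_amr_records",
               "n_gametic_maternal", "n_gametic_paternal",
               "n_secondary_candidate", "n_known", "n_rejected",
               "cohort_fraction_intermediate",
               "n_gene_calls_monoallelic", "n_gene_calls_biallelic",
               "trio_consensus", "trio_n_informative"),
    value = c(nrow(genome$cgis), nrow(amrs),
              sum(candidates$klass == "gametic_maternal"),
              sum(candidates$klass == "gametic_paternal"),
              sum(candidates$klass == "secondary_candidate"),
              sum(candidates$klass == "known"),
              sum(candidates$klass == "rejected"),
              format(cohort$fraction_intermediate, digits = 6),
              sum(ase_res$gene_calls$profile == "monoallelic"),
              sum(ase_res$gene_calls$profile == "biallelic"),
              trio_consensus$consensus, trio_consensus$n_informative),
    stringsAsFactors = FALSE)

  result <- list(candidates = candidates,
                 region_summaries = region_summaries,
                 cohort_profile = cohort$profile,
                 trisomy_calls = trisomy_calls,
                 ase = ase_res, unicity = unicity,
                 trio_calls = trio_calls, trio_consensus = trio_consensus,
                 truth = list(cgis = genome$truth$cgis,
                              genes = genome$truth$genes,
                              trios = trio_sim$truth),
                 summary = summary_tab)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(x, f) write_table(x, file.path(out_dir, f))
    write_bed(genome$cgis, file.path(out_dir, "cgis.bed"))
    w(candidates, "candidates.tsv")
    w(region_summaries, "region_summaries.tsv")
    w(cohort$profile, "cohort_profile.tsv")
    utils::write.table(trisomy_calls, file.path(out_dir, "trisomy_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    w(ase_res$site_summaries, "ase_site_summaries.tsv")
    w(ase_res$site_categories, "ase_site_categories.tsv")
    w(ase_res$gene_calls, "ase_gene_calls.tsv")
    if (!is.null(unicity))
      utils::write.table(unicity, file.path(out_dir, "unicity.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    w(trio_sim$trios, "trios.tsv")
    w(trio_calls, "trio_calls.tsv")
    w(genome$truth$cgis, "truth_cgis.tsv")
    w(genome$truth$genes, "truth_genes.tsv")
    w(trio_sim$truth, "truth_trios.tsv")
    utils::write.table(summary_tab, file.path(out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(c(paste0("seed: ", config$seed),
                 paste0("config_hash: ", config_hash(config)),
                 paste0("reference_methylome: ", reference)),
               file.path(out_dir, "manifest.txt"))
  }
  invisible(result)
}

# Stable md5 of the configuration (via a canonical deparse written to a
# temporary file; no extra dependency).
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(names(config),
                   vapply(config, function(v)
                     paste(format(v, digits = 15), collapse = ","),
                     character(1)), sep = "="), tmp)
  unname(tools::md5sum(tmp))
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields map one-to-one onto [sim_config()] arguments;
#' `class_proportions` and `gene_mode_proportions` are given as named
#' mappings.
#'
#' @param path YAML file path.
#' @return a [sim_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configurations")
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  for (f in c("class_proportions", "gene_mode_proportions"))
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  do.call(sim_config, raw)
}
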