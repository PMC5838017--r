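# Declared output schemas: column names and reader classes. write_table()
# refuses records that match no declared schema or mix columns from several,
# and read_table() restores column types so write/read round-trips.
table_schemas <- function() {
  list(
    candidates = c(cgi_id = "character", chrom = "character",
                   start = "numeric", end = "numeric",
                   record_count = "integer", methylome_count = "integer",
                   oocyte_mean = "numeric", sperm_mean = "numeric",
                   oocyte_status = "character", sperm_status = "character",
                   klass = "character", novel = "logical",
                   reject_reason = "character"),
    region_summaries = c(sample_id = "character", name = "character",
                         chrom = "character", start = "numeric",
                         end = "numeric", mean = "numeric", sd = "numeric",
                         n_used = "integer", n_missing = "integer",
                         status = "character"),
    cohort_profile = c(sample_id = "character", name = "character",
                       mean = "numeric", status = "character",
                       dysregulated = "logical"),
    ase_observations = c(snp_id = "character", gene = "character",
                         tissue = "character", donor = "character",
                         ref_count = "numeric", alt_count = "numeric",
                         maf = "numeric"),
    ase_site_summaries = c(snp_id = "character", gene = "character",
                           tissue = "character", n_donors = "integer",
                           min = "numeric", q1 = "numeric",
                           median = "numeric", q3 = "numeric",
                           max = "numeric", min_depth_observed = "numeric"),
    ase_site_categories = c(snp_id = "character", gene = "character",
                            tissue = "character", category = "character"),
    gene_calls = c(gene = "character", tissue = "character",
                   profile = "character", n_informative_snps = "integer",
                   reason = "character"),
    gene_annotations = c(gene = "character", chrom = "character",
                         tss = "numeric"),
    trios = c(family_id = "character", snp_id = "character",
              mother_gt = "character", father_gt = "character",
              child_gt = "character", resistant_alleles = "character"),
    trio_calls = c(family_id = "character", snp_id = "character",
                   maternal_allele = "character",
                   paternal_allele = "character", origin = "character"),
    msre_measurements = c(sample_id = "character", target_dig = "numeric",
                          target_undig = "numeric", ref_dig = "numeric",
                          ref_undig = "numeric", control_dig = "numeric"),
    truth_cgis = c(cgi_id = "character", true_class = "character"),
    truth_genes = c(gene = "character", tissue = "character",
                    true_mode = "character"),
    truth_trios = c(family_id = "character", snp_id = "character",
                    true_origin = "character"))
}

match_schema <- function(records) {
  schemas <- table_schemas()
  cols <- names(records)
  for (nm in names(schemas)) {
    if (identical(sort(cols), sort(names(schemas[[nm]])))) return(nm)
  }
  NULL
}

#' Write a table of records of one declared output schema
#'
#' @param records a `data.frame` whose columns exactly match one of the
#'   package's declared output schemas (candidates, region summaries, ASE
#'   tables, trio tables, ...). Mixed or unknown column sets are rejected.
#' @param path output path; a tab-separated file with a header is written.
#' @return `path`, invisibly. Writing then [read_table()]-ing reproduces the
#'   records, including `NA`s.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  schema <- match_schema(records)
  if (is.null(schema))
    stop("records match no declared output schema; columns: ",
         paste(names(records), collapse = ", "))
  spec <- table_schemas()[[schema]]
  records <- records[, names(spec), drop = FALSE]
  out <- records
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]))
      out[[j]] <- ifelse(is.na(out[[j]]), NA,
                         format(out[[j]], digits = 15, scientific = FALSE,
                                trim = TRUE))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a table written by [write_table()]
#'
#' @param path path to the TSV.
#' @param schema optional schema name; inferred from the header otherwise.
#' @return a `data.frame` with the schema's column types restored.
#' @export
read_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  schemas <- table_schemas()
  if (is.null(schema)) {
    for (nm in names(schemas)) {
      if (identical(sort(header), sort(names(schemas[[nm]])))) schema <- nm
    }
  }
  if (is.null(schema) || is.null(schemas[[schema]]))
    stop("cannot infer a declared schema from header of ", path)
  spec <- schemas[[schema]]
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           na.strings = "NA",
                           colClasses = unname(spec[header]),
                           quote = "", comment.char = "")
  tab[, names(spec), drop = FALSE]
}
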