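# End-to-end orchestration: taxonomic profiling -> subsystem selection ->
# database reduction -> translated search -> best-hit profiling, with a
# machine-readable run report.

#' Run the full profiling pipeline
#'
#' Steps: (1) estimate genus abundances from the reads' k-mer signature,
#' (2) select the subsystems carried by the reported genera and reduce the
#' database to them, (3) align the reads against the surviving
#' representatives (or take external m8 hits), (4) keep threshold-passing
#' lowest-E-value hits, (5) aggregate into level-1/2/3 profiles. With
#' `reduce = FALSE`, steps 1-2 are skipped and the full database is searched
#' (the "plain fast aligner" baseline).
#'
#' @param reads named character vector of DNA reads, or a FASTA/FASTQ path.
#' @param db a `subsys_db` (or a `db_<cutoff>` directory).
#' @param presence presence matrix (or its TSV path); required when
#'   `reduce = TRUE`.
#' @param tax_ref reference signature matrix (or its TSV path); required
#'   when `reduce = TRUE`.
#' @param out_prefix optional output prefix; when given, writes
#'   `<prefix>.level{1,2,3}.tsv`, `<prefix>.taxonomy.tsv` (if reducing),
#'   `<prefix>.hits.m8` and `<prefix>.report.json`.
#' @param thresholds a [filter_thresholds()] list.
#' @param mode aligner mode, see [search_hits()].
#' @param method `"seeded"` or `"exhaustive"`.
#' @param reduce reduce the database to the predicted genera's subsystems.
#' @param min_reported genus abundance floor, see [fit_genus_abundances()].
#' @param hits optional external m8 hits (data.frame or path); bypasses the
#'   built-in aligner.
#' @param levels hierarchy levels to profile.
#' @return list with `profiles` (per level), `taxonomy`, `subsystems_kept`,
#'   `assignments`, `hits`, and `report` (the run report, also written as
#'   JSON when `out_prefix` is given).
#' @export
run_pipeline <- function(reads, db, presence = NULL, tax_ref = NULL,
                         out_prefix = NULL,
                         thresholds = filter_thresholds(),
                         mode = "default", method = "seeded", reduce = TRUE,
                         min_reported = 0.01, hits = NULL, levels = 1:3) {
  t0 <- proc.time()[["elapsed"]]
  done <- FALSE
  if (!is.null(out_prefix)) on.exit({
    # never leave partial outputs behind on failure
    if (!done) unlink(paste0(out_prefix,
                             c(paste0(".level", 1:3, ".tsv"),
                               ".taxonomy.tsv", ".hits.m8", ".report.json")))
  }, add = TRUE)
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_sequences(reads, "dna")
  if (is.character(db)) db <- read_database(db)
  if (is.character(presence)) presence <- read_presence_matrix(presence)
  if (is.character(tax_ref)) tax_ref <- read_reference_matrix(tax_ref)

  taxonomy <- NULL
  keep <- db_subsystems(db)
  search_db <- db
  if (reduce) {
    if (is.null(presence) || is.null(tax_ref))
      stop("reduce = TRUE needs a presence matrix and a taxonomic reference",
           call. = FALSE)
    sig <- kmer_signature(reads, attr(tax_ref, "k"))
    taxonomy <- fit_genus_abundances(sig, tax_ref, min_reported)
    keep <- select_subsystems(taxonomy, presence)
    search_db <- reduce_database(db, keep)
  }

  if (is.null(hits)) {
    hits <- search_hits(reads, search_db, mode = mode, method = method)
  } else if (is.character(hits)) {
    hits <- read_tabular_hits(hits)
  }
  best <- filter_hits(hits, thresholds)
  assignments <- assign_reads(best, search_db)
  profiles <- lapply(levels, function(l)
    aggregate_profile(assignments, l, n_total = length(reads)))
  names(profiles) <- paste0("level", levels)

  elapsed <- proc.time()[["elapsed"]] - t0
  thr <- measure_throughput(max(length(reads), 1L), max(elapsed, 1e-9))
  report <- list(
    n_reads = length(reads), db_cutoff = db$cutoff, reduced = reduce,
    n_subsystems_total = length(db_subsystems(db)),
    n_subsystems_kept = length(keep),
    fraction_subsystems_kept = length(keep) / length(db_subsystems(db)),
    n_assigned = length(unique(assignments$read_id)),
    n_unassigned = length(reads) - length(unique(assignments$read_id)),
    mode = mode, method = method, thresholds = thresholds,
    min_reported = min_reported, elapsed_seconds = elapsed,
    sequences_per_minute = thr$sequences_per_minute)
  message(sprintf(
    "pipeline: %d/%d subsystems retained, %d/%d reads assigned (%.1f seq/min)",
    report$n_subsystems_kept, report$n_subsystems_total, report$n_assigned,
    report$n_reads, report$sequences_per_minute))

  if (!is.null(out_prefix)) {
    for (l in names(profiles))
      write_profile(profiles[[l]], paste0(out_prefix, ".", l, ".tsv"))
    if (!is.null(taxonomy))
      write_taxonomic_profile(taxonomy, paste0(out_prefix, ".taxonomy.tsv"))
    write_tabular_hits(hits, paste0(out_prefix, ".hits.m8"))
    jsonlite::write_json(report, paste0(out_prefix, ".report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  done <- TRUE
  invisible(list(profiles = profiles, taxonomy = taxonomy,
                 subsystems_kept = keep, assignments = assignments,
                 hits = hits, report = report))
}
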