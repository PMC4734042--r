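# Subsystem-annotated protein reference and its identity-clustered
# (reduced-redundancy) form. Each reference protein carries one subsystem
# path (level1, level2, level3, function); proteins are clustered greedily
# within each level-3 subsystem, CD-HIT style, and only cluster
# representatives are searched.

path_cols <- c("level1", "level2", "level3", "fn")

validate_protein_table <- function(proteins) {
  need <- c("protein_id", "seq", path_cols)
  miss <- setdiff(need, names(proteins))
  if (length(miss))
    stop("protein table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(proteins$protein_id))
    stop("duplicate protein_id(s)", call. = FALSE)
  bad <- is.na(proteins$level1) | !nzchar(proteins$level1) |
    is.na(proteins$level3) | !nzchar(proteins$level3) | is.na(proteins$fn)
  if (any(bad))
    stop("protein(s) without a subsystem path: ",
         paste(head(proteins$protein_id[bad], 3), collapse = ", "),
         call. = FALSE)
  invisible(proteins)
}

#' Pairwise protein identity (clustering criterion)
#'
#' Identity between two proteins is the number of identical residues in the
#' alignment maximising identical residues -- a global alignment of the
#' shorter sequence with free gaps, so a full-length substring of the longer
#' sequence scores 100% -- divided by the length of the shorter sequence.
#' This is the matches/shorter-length convention of CD-HIT; it is symmetric
#' and lies in \[0, 100\].
#'
#' @param a,b non-empty protein sequences (single strings).
#' @return identity as a percentage in \[0, 100\].
#' @export
pairwise_identity <- function(a, b) {
  assert_scalar_string(a, "a"); assert_scalar_string(b, "b")
  cpp_pairwise_identity(toupper(a), toupper(b))
}

#' Remove duplicate reference proteins
#'
#' Records with byte-identical sequences *and* identical subsystem paths are
#' collapsed to the first occurrence (input order). Identical sequences
#' annotated into different subsystems are all kept: they are distinct
#' reference records.
#'
#' @param proteins data.frame with columns `protein_id`, `seq`, `level1`,
#'   `level2`, `level3`, `fn`.
#' @return the deduplicated data.frame.
#' @export
deduplicate_proteins <- function(proteins) {
  if (nrow(proteins) == 0L) return(proteins)
  key <- paste(proteins$seq, proteins$level1, proteins$level2,
               proteins$level3, proteins$fn, sep = "\r")
  proteins[!duplicated(key), , drop = FALSE]
}

#' Greedy identity clustering of one subsystem's proteins
#'
#' Sequences are taken longest first (ties broken by `protein_id` ascending,
#' which makes the run deterministic); each sequence joins the first existing
#' cluster whose representative is at least `cutoff` percent identical, else
#' founds a new cluster with itself as representative.
#'
#' @param proteins data.frame of proteins sharing one level-3 subsystem.
#' @param cutoff identity cut-off in (0, 100].
#' @param prefilter use the shared-4-mer prefilter (speed only; results are
#'   identical for family-structured inputs and equivalence is asserted in
#'   the test suite).
#' @return `proteins` with a `representative_id` column added.
#' @export
cluster_subsystem <- function(proteins, cutoff, prefilter = TRUE) {
  stopifnot(cutoff > 0, cutoff <= 100)
  if (length(unique(proteins$level3)) > 1L)
    stop("cluster_subsystem expects proteins of a single level-3 subsystem",
         call. = FALSE)
  ord <- order(-nchar(proteins$seq), proteins$protein_id, method = "radix")
  p <- proteins[ord, , drop = FALSE]
  rep_idx <- cpp_cluster_greedy(p$seq, cutoff, prefilter)
  p$representative_id <- p$protein_id[rep_idx]
  p[order(match(p$protein_id, proteins$protein_id)), , drop = FALSE]
}

#' Build an identity-clustered subsystem database
#'
#' Deduplicates the reference, groups proteins by level-3 subsystem, and
#' clusters each subsystem separately at the given identity cut-off. Cluster
#' representatives form the searchable sequence set; the member-to-
#' representative map is retained so that hits to a representative are
#' attributed to its subsystem. Presets mirror the published databases:
#' cut-offs 100, 98 (the default database), 95 and 90.
#'
#' @param proteins data.frame with columns `protein_id`, `seq`, `level1`,
#'   `level2`, `level3`, `fn`.
#' @param cutoff identity cut-off in (0, 100].
#' @param prefilter see [cluster_subsystem()].
#' @return an object of class `subsys_db`: list with `cutoff`, `proteins`
#'   (the deduplicated table plus `representative_id`), and `rep_seqs`
#'   (named character vector of representative sequences).
#' @export
build_clustered_database <- function(proteins, cutoff = 98, prefilter = TRUE) {
  validate_protein_table(proteins)
  p <- deduplicate_proteins(proteins)
  parts <- split(p, p$level3)
  clustered <- lapply(parts, cluster_subsystem, cutoff = cutoff,
                      prefilter = prefilter)
  p <- do.call(rbind, clustered)
  p <- p[order(match(p$protein_id, proteins$protein_id)), , drop = FALSE]
  rownames(p) <- NULL
  reps <- p$protein_id == p$representative_id
  rep_seqs <- stats::setNames(p$seq[reps], p$protein_id[reps])
  structure(list(cutoff = cutoff, proteins = p, rep_seqs = rep_seqs),
            class = "subsys_db")
}

#' @export
print.subsys_db <- function(x, ...) {
  cat("subsystem database (identity cut-off ", x$cutoff, "%)\n",
      "  proteins:        ", nrow(x$proteins), "\n",
      "  representatives: ", length(x$rep_seqs), "\n",
      "  level-3 subsystems: ", length(db_subsystems(x)), "\n", sep = "")
  invisible(x)
}

#' Level-3 subsystem labels of a database
#' @param db a `subsys_db`.
#' @return sorted character vector.
#' @export
db_subsystems <- function(db) sort(unique(db$proteins$level3))

#' Clusters of a database, per level-3 subsystem
#'
#' @param db a `subsys_db`.
#' @return nested list: subsystem -> representative id -> character vector of
#'   member protein ids (the representative is always a member).
#' @export
db_clusters <- function(db) {
  lapply(split(db$proteins, db$proteins$level3), function(p)
    split(p$protein_id, p$representative_id))
}

# Subsystem path rows for representative ids; errors on unknown ids.
rep_paths <- function(db, subject_ids) {
  i <- match(subject_ids, db$proteins$protein_id)
  if (anyNA(i)) {
    stop("subject id(s) not in database: ",
         paste(head(unique(subject_ids[is.na(i)]), 3), collapse = ", "),
         " (hits/database mismatch?)", call. = FALSE)
  }
  db$proteins[i, c("protein_id", path_cols), drop = FALSE]
}

#' Restrict a database to a set of level-3 subsystems
#'
#' Returns a lightweight view: exactly the clusters of the retained
#' subsystems, byte-identical to their originals, same identity cut-off.
#'
#' @param db a `subsys_db`.
#' @param keep character vector of level-3 subsystem labels; labels unknown
#'   to `db` are ignored with a warning.
#' @return a `subsys_db` view.
#' @export
reduce_database <- function(db, keep) {
  unknown <- setdiff(keep, db$proteins$level3)
  if (length(unknown))
    warning("ignoring ", length(unknown),
            " subsystem label(s) not in the database", call. = FALSE)
  sel <- db$proteins$level3 %in% keep
  if (!any(sel))
    stop("reduction removed every subsystem; refusing to build an empty ",
         "database", call. = FALSE)
  p <- db$proteins[sel, , drop = FALSE]
  reps <- p$protein_id == p$representative_id
  structure(list(cutoff = db$cutoff, proteins = p,
                 rep_seqs = stats::setNames(p$seq[reps], p$protein_id[reps])),
            class = "subsys_db")
}

#' Serialize a clustered database
#'
#' Writes `sequences.faa` (representatives, FASTA) and `annotations.tsv`
#' (columns `protein_id`, `representative_id`, `level1`, `level2`, `level3`,
#' `function`, one row per deduplicated protein) under
#' `dir/db_<cutoff>/`.
#'
#' @param db a `subsys_db`.
#' @param dir output directory.
#' @return the database subdirectory, invisibly.
#' @export
write_database <- function(db, dir) {
  sub <- file.path(dir, paste0("db_", db$cutoff))
  dir.create(sub, recursive = TRUE, showWarnings = FALSE)
  write_sequences(db$rep_seqs, file.path(sub, "sequences.faa"))
  ann <- db$proteins[, c("protein_id", "representative_id", path_cols)]
  names(ann)[names(ann) == "fn"] <- "function"
  utils::write.table(ann, file.path(sub, "annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(sub)
}

#' Load a clustered database written by [write_database()]
#' @param dir the `db_<cutoff>` directory.
#' @return a `subsys_db`.
#' @export
read_database <- function(dir) {
  ann_path <- file.path(dir, "annotations.tsv")
  faa_path <- file.path(dir, "sequences.faa")
  if (!file.exists(ann_path) || !file.exists(faa_path))
    stop("not a database directory (need annotations.tsv + sequences.faa): ",
         dir, call. = FALSE)
  ann <- utils::read.table(ann_path, sep = "\t", header = TRUE, quote = "",
                           check.names = FALSE, colClasses = "character",
                           na.strings = NULL)
  names(ann)[names(ann) == "function"] <- "fn"
  reps <- read_sequences(faa_path, "protein")
  cutoff <- as.numeric(sub("^db_", "", basename(dir)))
  i <- match(ann$protein_id, names(reps))
  proteins <- data.frame(protein_id = ann$protein_id,
                         seq = ifelse(is.na(i), NA_character_, reps[i]),
                         ann[, c("representative_id", path_cols)],
                         stringsAsFactors = FALSE)
  # member sequences are not stored on disk; only representatives carry seqs
  structure(list(cutoff = cutoff, proteins = proteins,
                 rep_seqs = reps), class = "subsys_db")
}
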