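# Genus x subsystem presence/absence from annotated complete genomes. Each
# genome's proteins are aligned against the clustered reference; only
# lowest-E-value hits passing the thresholds vote, and a genus carries a
# subsystem iff at least one of its species does (union aggregation).

#' Annotate one genome with level-3 subsystems
#'
#' Every protein of the genome is searched (protein-protein) against the
#' database representatives; hits failing the thresholds are dropped; among
#' the survivors only the lowest-E-value hit(s) -- all ties -- contribute
#' their subsystems. The genome's annotation is the union over its proteins.
#'
#' @param genome list with elements `species`, `genus` (optional; defaults
#'   to the first whitespace token of `species`), and `proteins` (named
#'   character vector of protein sequences).
#' @param db a `subsys_db`.
#' @param thresholds a [filter_thresholds()] list (defaults 1e-5 / 60% /
#'   15 aa).
#' @param method search method, see [search_hits()].
#' @return sorted character vector of level-3 subsystem labels (empty, with
#'   a warning, if nothing passes).
#' @export
annotate_genome <- function(genome, db, thresholds = filter_thresholds(),
                            method = "seeded") {
  stopifnot(length(genome$proteins) >= 1L)
  hits <- search_hits(genome$proteins, db, method = method,
                      query_is_protein = TRUE)
  best <- filter_hits(hits, thresholds)
  if (nrow(best) == 0L) {
    warning("genome ", genome$species %||% "?",
            ": no hit passed the thresholds", call. = FALSE)
    return(character(0))
  }
  sort(unique(rep_paths(db, best$subject_id)$level3))
}

genome_genus <- function(genome) {
  g <- genome$genus %||% strsplit(trimws(genome$species), "\\s+")[[1]][1]
  if (is.null(g) || !nzchar(g)) stop("genome without genus", call. = FALSE)
  g
}

#' Build the genus x subsystem presence/absence matrix
#'
#' Rows are genera, columns the database's level-3 subsystems; a cell is
#' TRUE iff at least one species of the genus was annotated with that
#' subsystem. Genera with zero subsystems are dropped with a warning.
#'
#' @param genomes list of genomes (see [annotate_genome()]).
#' @param db a `subsys_db`.
#' @param thresholds a [filter_thresholds()] list.
#' @param method search method, see [search_hits()].
#' @return logical matrix with genus rownames and subsystem colnames.
#' @export
build_presence_matrix <- function(genomes, db,
                                  thresholds = filter_thresholds(),
                                  method = "seeded") {
  stopifnot(length(genomes) >= 1L)
  subsystems <- db_subsystems(db)
  genera <- sort(unique(vapply(genomes, genome_genus, character(1))))
  mat <- matrix(FALSE, nrow = length(genera), ncol = length(subsystems),
                dimnames = list(genera, subsystems))
  for (g in genomes) {
    ann <- annotate_genome(g, db, thresholds, method)
    mat[genome_genus(g), ann] <- TRUE
  }
  empty <- rowSums(mat) == 0L
  if (any(empty)) {
    warning("dropping genus with zero subsystems: ",
            paste(genera[empty], collapse = ", "), call. = FALSE)
    mat <- mat[!empty, , drop = FALSE]
  }
  mat
}

#' Write a presence matrix as TSV (cells 0/1)
#' @param mat logical matrix from [build_presence_matrix()].
#' @param path output file.
#' @export
write_presence_matrix <- function(mat, path) {
  df <- data.frame(genus = rownames(mat), (mat * 1L), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a presence matrix written by [write_presence_matrix()]
#' @param path TSV file.
#' @return logical matrix.
#' @export
read_presence_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE]) == 1
  rownames(mat) <- df$genus
  mat
}

#' Select the subsystems carried by the predicted genera
#'
#' The union of presence-matrix rows for every genus reported by the
#' taxonomic profile. Genera absent from the matrix are skipped with a
#' warning; if the selection comes out empty the full subsystem set is
#' returned with a prominent warning -- annotating against nothing is never
#' the right answer.
#'
#' @param profile a `taxonomic_profile` (genera with abundance > 0 count as
#'   reported).
#' @param matrix presence matrix from [build_presence_matrix()].
#' @return character vector of level-3 subsystem labels.
#' @export
select_subsystems <- function(profile, matrix) {
  reported <- names(profile)[as.numeric(profile) > 0]
  known <- intersect(reported, rownames(matrix))
  missing <- setdiff(reported, rownames(matrix))
  if (length(missing))
    warning("genus(era) not in presence matrix, skipped: ",
            paste(missing, collapse = ", "), call. = FALSE)
  keep <- if (length(known))
    colnames(matrix)[colSums(matrix[known, , drop = FALSE]) > 0]
  else character(0)
  if (length(keep) == 0L) {
    warning("database reduction selected ZERO subsystems; falling back to ",
            "the FULL subsystem set", call. = FALSE)
    keep <- colnames(matrix)
  }
  sort(keep)
}
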