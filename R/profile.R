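# Steps 4-5: filter hits, resolve best hits (keeping all E-value ties), and
# aggregate read assignments into level-1/2/3 (or function-level) profiles.

#' Hit filtering thresholds
#'
#' Defaults are the pipeline's published ones: maximum E-value 1e-5, minimum
#' 60% identity, minimum alignment length 15 amino acids. All comparisons
#' are inclusive at the boundary.
#'
#' @param max_evalue maximum E-value.
#' @param min_identity minimum percent identity.
#' @param min_aln_len minimum alignment length (amino acids).
#' @export
filter_thresholds <- function(max_evalue = 1e-5, min_identity = 60,
                              min_aln_len = 15) {
  stopifnot(is.finite(max_evalue), is.finite(min_identity),
            is.finite(min_aln_len))
  list(max_evalue = max_evalue, min_identity = min_identity,
       min_aln_len = min_aln_len)
}

#' Filter hits and keep the best hit(s) per read
#'
#' Drops hits failing any threshold, then keeps, per read, only the hits
#' whose E-value equals the minimum among the survivors -- all ties are
#' kept. E-values are compared exactly as parsed; aligners that round their
#' printed E-values can therefore produce different tie sets.
#'
#' @param hits tabular hit data.frame ([read_tabular_hits()] or
#'   [search_hits()]).
#' @param thresholds a [filter_thresholds()] list.
#' @return the surviving rows (reads with no survivor are unassigned).
#' @export
filter_hits <- function(hits, thresholds = filter_thresholds()) {
  keep <- hits$evalue <= thresholds$max_evalue &
    hits$pct_identity >= thresholds$min_identity &
    hits$aln_length >= thresholds$min_aln_len
  h <- hits[keep, , drop = FALSE]
  if (nrow(h) == 0L) return(h)
  best <- stats::ave(h$evalue, h$query_id, FUN = min)
  h <- h[h$evalue == best, , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Resolve best hits to subsystem path assignments
#'
#' Each read's tied best hits contribute the subsystem paths of their
#' subjects; duplicate paths from multiple tied hits count once, and the
#' read's unit weight is split equally over its distinct paths, so every
#' assigned read contributes exactly 1 to the profile.
#'
#' @param best_hits output of [filter_hits()].
#' @param db the `subsys_db` the hits were searched against (subject ids
#'   must resolve to representatives; a mismatch is an error).
#' @return data.frame with columns `read_id`, `level1`, `level2`, `level3`,
#'   `fn`, `weight`; zero rows if nothing was assigned.
#' @export
assign_reads <- function(best_hits, db) {
  if (nrow(best_hits) == 0L) {
    return(data.frame(read_id = character(0), level1 = character(0),
                      level2 = character(0), level3 = character(0),
                      fn = character(0), weight = numeric(0),
                      stringsAsFactors = FALSE))
  }
  paths <- rep_paths(db, best_hits$subject_id)
  a <- data.frame(read_id = best_hits$query_id,
                  paths[, path_cols, drop = FALSE],
                  stringsAsFactors = FALSE)
  a <- a[!duplicated(a), , drop = FALSE]
  n_paths <- table(a$read_id)
  a$weight <- 1 / as.numeric(n_paths[a$read_id])
  rownames(a) <- NULL
  a
}

#' Aggregate read assignments into a functional profile
#'
#' Each assigned read contributes total weight 1, split over its tied paths,
#' summed by the requested hierarchy level's label; abundances are weighted
#' counts divided by the number of assigned reads.
#'
#' @param assignments output of [assign_reads()].
#' @param level 1, 2, 3 or `"function"`. Function-level output is most
#'   meaningful on a 100% database: below that, a cluster representative may
#'   stand in for members with different functional roles.
#' @param n_total optional total number of reads searched, used to report
#'   `n_unassigned`.
#' @return a `functional_profile`: data.frame (`label`, `read_count`,
#'   `abundance`) with attributes `level`, `n_assigned`, `n_unassigned`.
#' @export
aggregate_profile <- function(assignments, level = 3, n_total = NULL) {
  col <- level_column(level)
  n_assigned <- length(unique(assignments$read_id))
  if (n_assigned == 0L) {
    warning("no assigned reads; empty profile", call. = FALSE)
    df <- data.frame(label = character(0), read_count = numeric(0),
                     abundance = numeric(0), stringsAsFactors = FALSE)
  } else {
    counts <- tapply(assignments$weight, assignments[[col]], sum)
    df <- data.frame(label = names(counts), read_count = as.numeric(counts),
                     abundance = as.numeric(counts) / n_assigned,
                     stringsAsFactors = FALSE)
    df <- df[order(-df$abundance, df$label, method = "radix"), , drop = FALSE]
    rownames(df) <- NULL
  }
  structure(df, level = level, n_assigned = n_assigned,
            n_unassigned = if (is.null(n_total)) NA_integer_
                           else n_total - n_assigned,
            class = c("functional_profile", "data.frame"))
}

level_column <- function(level) {
  if (identical(level, "function") || identical(level, "fn")) return("fn")
  if (!level %in% c(1, 2, 3, "1", "2", "3"))
    stop("level must be 1, 2, 3 or \"function\"", call. = FALSE)
  paste0("level", level)
}

#' @export
print.functional_profile <- function(x, n = 10, ...) {
  cat("functional profile, level ", attr(x, "level"), ": ",
      nrow(x), " label(s), ", attr(x, "n_assigned"), " assigned read(s)",
      if (!is.na(attr(x, "n_unassigned")))
        paste0(", ", attr(x, "n_unassigned"), " unassigned"),
      "\n", sep = "")
  print.data.frame(head(as.data.frame(x), n))
  invisible(x)
}

#' Throughput of a profiling run
#'
#' Reported as sequences per minute and seconds per sequence; logged, never
#' asserted (wall-clock speed is hardware-bound).
#'
#' @param n_sequences sequences processed (>= 1).
#' @param elapsed_seconds wall-clock seconds (> 0).
#' @return list with `sequences_per_minute` and `seconds_per_sequence`.
#' @export
measure_throughput <- function(n_sequences, elapsed_seconds) {
  if (n_sequences < 1) stop("n_sequences must be >= 1", call. = FALSE)
  if (elapsed_seconds <= 0) stop("elapsed_seconds must be > 0", call. = FALSE)
  list(sequences_per_minute = n_sequences / elapsed_seconds * 60,
       seconds_per_sequence = elapsed_seconds / n_sequences)
}
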