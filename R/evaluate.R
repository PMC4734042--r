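# Benchmarking against a truth annotation: the truth for a read is the
# lowest-E-value hit(s) of an exhaustive translated search against the full
# (100% cut-off) database; sensitivity is correct / truth-annotated reads,
# precision is correct / classified reads. Plus confusion matrices and
# hierarchical clustering of sample profiles.

#' Build the truth annotation for a read set
#'
#' Runs the exhaustive Smith-Waterman search (not the seeded heuristic)
#' against the full database, applies the default filter/best-hit rule, and
#' records the paths of all tied best hits per read. Reads with no
#' surviving hit are absent from the truth.
#'
#' @param reads named character vector of DNA reads.
#' @param db the full `subsys_db`; a clustered cut-off below 100 triggers a
#'   warning, since truth is defined against the unreduced reference.
#' @param thresholds a [filter_thresholds()] list.
#' @return data.frame (`read_id`, `level1`, `level2`, `level3`, `fn`,
#'   `weight`) -- the same shape as [assign_reads()].
#' @export
make_truth <- function(reads, db, thresholds = filter_thresholds()) {
  if (db$cutoff < 100)
    warning("truth should be built on a 100% database; got ", db$cutoff,
            call. = FALSE)
  hits <- search_hits(reads, db, method = "exhaustive")
  assign_reads(filter_hits(hits, thresholds), db)
}

#' Write / read a truth annotation
#'
#' TSV with columns `read_id`, `level1`, `level2`, `level3`, `function`;
#' one row per tied path.
#' @param truth assignment data.frame.
#' @param path file.
#' @export
write_truth <- function(truth, path) {
  out <- truth[, c("read_id", path_cols)]
  names(out)[names(out) == "fn"] <- "function"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          check.names = FALSE, colClasses = "character",
                          na.strings = NULL)
  names(df)[names(df) == "function"] <- "fn"
  n_paths <- table(df$read_id)
  df$weight <- 1 / as.numeric(n_paths[df$read_id])
  df
}

#' Sensitivity and precision against a truth annotation
#'
#' A read counts as correct if its predicted label set at the given level
#' intersects its truth label set at that level (the weakest rule consistent
#' with "correct assignment" when ties are recorded on both sides).
#' Sensitivity = correct / reads annotated by truth x 100; precision =
#' correct / reads classified by the tool x 100.
#'
#' @param predicted,truth assignment data.frames ([assign_reads()] /
#'   [make_truth()]).
#' @param level 1, 2 or 3.
#' @param mask optional character vector of read ids; when given, both sides
#'   are restricted to those reads before computing the report (e.g. to
#'   exclude reads of non-target clades).
#' @return an `eval_report` list: `level`, `sensitivity`, `precision` (both
#'   percentages, NA when the denominator is zero), `n_truth`,
#'   `n_classified`, `n_correct`.
#' @export
evaluate_annotations <- function(predicted, truth, level = 1, mask = NULL) {
  col <- level_column(level)
  if (!is.null(mask)) {
    predicted <- predicted[predicted$read_id %in% mask, , drop = FALSE]
    truth <- truth[truth$read_id %in% mask, , drop = FALSE]
  }
  p_labels <- split(predicted[[col]], predicted$read_id)
  t_labels <- split(truth[[col]], truth$read_id)
  n_truth <- length(t_labels)
  n_classified <- length(p_labels)
  common <- intersect(names(p_labels), names(t_labels))
  n_correct <- sum(vapply(common, function(r)
    length(intersect(p_labels[[r]], t_labels[[r]])) > 0, logical(1)))
  structure(list(
    level = level,
    sensitivity = if (n_truth == 0) NA_real_ else 100 * n_correct / n_truth,
    precision = if (n_classified == 0) NA_real_
                else 100 * n_correct / n_classified,
    n_truth = n_truth, n_classified = n_classified, n_correct = n_correct),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "level %s: sensitivity %.2f%%, precision %.2f%% (%d correct / %d truth / %d classified)\n",
    x$level, x$sensitivity, x$precision, x$n_correct, x$n_truth,
    x$n_classified))
  invisible(x)
}

#' Row-normalized confusion matrix
#'
#' Rows are truth labels at the given level; columns are the union of
#' predicted labels plus `"unclassified"`. Cell (i, j) is the percentage of
#' truth-i reads predicted as j; reads with tied labels contribute
#' fractionally (1 / |truth set| x 1 / |predicted set|). Every row sums to
#' 100.
#'
#' @param predicted,truth assignment data.frames.
#' @param level hierarchy level (default 1).
#' @return numeric matrix, rows summing to 100.
#' @export
confusion_matrix <- function(predicted, truth, level = 1) {
  col <- level_column(level)
  t_labels <- lapply(split(truth[[col]], truth$read_id), unique)
  p_labels <- lapply(split(predicted[[col]], predicted$read_id), unique)
  row_names <- sort(unique(unlist(t_labels)))
  col_names <- c(sort(unique(unlist(p_labels))), "unclassified")
  mat <- matrix(0, length(row_names), length(col_names),
                dimnames = list(row_names, col_names))
  for (r in names(t_labels)) {
    tl <- t_labels[[r]]
    pl <- p_labels[[r]]
    if (is.null(pl) || length(pl) == 0L) pl <- "unclassified"
    w <- 1 / (length(tl) * length(pl))
    for (ti in tl) for (pj in pl) mat[ti, pj] <- mat[ti, pj] + w
  }
  rs <- rowSums(mat)
  rs[rs == 0] <- 1
  100 * mat / rs
}

#' Hierarchical clustering of sample profiles
#'
#' Aligns the samples' abundance vectors on the union label set (absent
#' labels are 0), computes pairwise Euclidean distances and clusters
#' agglomeratively. Useful for asking whether replicate samples (e.g. from
#' one site) group together.
#'
#' @param profiles named list: sample -> named numeric abundance vector.
#' @param linkage `"average"` (default), `"single"`, `"complete"` or
#'   `"ward"` (Ward.D2).
#' @param newick optional path; when given the dendrogram is also written as
#'   a Newick tree.
#' @return the `hclust` object, with the distance matrix attached as
#'   attribute `dist`.
#' @export
cluster_profiles <- function(profiles, linkage = c("average", "single",
                                                   "complete", "ward"),
                             newick = NULL) {
  linkage <- match.arg(linkage)
  if (length(profiles) < 2L)
    stop("need at least two samples to cluster", call. = FALSE)
  labels <- sort(unique(unlist(lapply(profiles, names))))
  mat <- t(vapply(profiles, function(p) {
    v <- stats::setNames(numeric(length(labels)), labels)
    v[names(p)] <- as.numeric(p)
    v
  }, numeric(length(labels))))
  d <- stats::dist(mat, method = "euclidean")
  hc <- stats::hclust(d, method = switch(linkage, ward = "ward.D2", linkage))
  if (!is.null(newick))
    ape::write.tree(ape::as.phylo(hc), file = newick)
  attr(hc, "dist") <- d
  hc
}
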