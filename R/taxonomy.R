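# Genus-level taxonomic profiling from k-mer composition. A sample's k-mer
# frequency vector is modelled as a non-negative mixture of per-genus genome
# signatures and deconvolved by non-negative least squares; genera above an
# abundance floor seed the database reduction.

#' k-mer signature of a set of DNA sequences
#'
#' Counts every overlapping k-mer of each sequence and of its reverse
#' complement (sequencing is strand-agnostic) and normalizes to sum 1.
#' k-mers containing non-ACGT symbols are skipped.
#'
#' @param seqs character vector of DNA sequences (or a `DNAStringSet`).
#' @param k k-mer length, default 7.
#' @return named numeric vector over all 4^k k-mers summing to 1, with
#'   attribute `k`.
#' @export
kmer_signature <- function(seqs, k = 7) {
  stopifnot(k >= 1)
  x <- Biostrings::DNAStringSet(seqs)
  counts <- colSums(Biostrings::oligonucleotideFrequency(x, width = k)) +
    colSums(Biostrings::oligonucleotideFrequency(
      Biostrings::reverseComplement(x), width = k))
  total <- sum(counts)
  if (total == 0) stop("input too short for k = ", k, call. = FALSE)
  sig <- counts / total
  attr(sig, "k") <- k
  sig
}

#' Reference genus signature matrix
#'
#' One column per genus: the equal-weight average of that genus's per-species
#' genome signatures, renormalized to sum 1.
#'
#' @param genomes named list mapping genus to either a character vector of
#'   DNA sequences (a single species' genome) or a list of such vectors (one
#'   per species).
#' @param k k-mer length.
#' @return 4^k x n_genera column-stochastic matrix with attribute `k`.
#' @export
build_reference_matrix <- function(genomes, k = 7) {
  if (length(genomes) < 1L) stop("need at least one genus", call. = FALSE)
  if (is.null(names(genomes)) || anyDuplicated(names(genomes)))
    stop("genomes must be a named list with unique genus names", call. = FALSE)
  kmer_names <- NULL
  cols <- lapply(names(genomes), function(g) {
    species <- genomes[[g]]
    if (!is.list(species)) species <- list(species)
    if (length(species) == 0L || any(lengths(species) == 0L))
      stop("genus without sequence: ", g, call. = FALSE)
    sigs <- vapply(species, function(s) {
      sig <- kmer_signature(s, k)
      if (is.null(kmer_names)) kmer_names <<- names(sig)
      as.numeric(sig)
    }, numeric(4^k))
    m <- rowMeans(matrix(sigs, ncol = length(species)))
    m / sum(m)
  })
  mat <- do.call(cbind, cols)
  dimnames(mat) <- list(kmer_names, names(genomes))
  attr(mat, "k") <- k
  mat
}

# Lawson-Hanson active-set non-negative least squares: min ||Ax - b|| s.t.
# x >= 0. Problem sizes here are tiny in columns (one per genus).
nnls_fit <- function(A, b, tol = 1e-10) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  w <- as.numeric(crossprod(A, b - A %*% x))
  outer_iter <- 0L
  while (any(!passive & w > tol)) {
    cand <- which(!passive)
    j <- cand[which.max(w[cand])]
    passive[j] <- TRUE
    repeat {
      z <- numeric(n)
      P <- which(passive)
      zb <- qr.coef(qr(A[, P, drop = FALSE]), b)
      zb[is.na(zb)] <- 0
      z[P] <- zb
      if (all(z[P] > tol)) { x <- z; break }
      neg <- P[z[P] <= tol]
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[x <= tol] <- FALSE
      x[!passive] <- 0
    }
    w <- as.numeric(crossprod(A, b - A %*% x))
    outer_iter <- outer_iter + 1L
    if (outer_iter > 10L * n) break
  }
  x
}

#' Estimate genus abundances by non-negative least squares
#'
#' Solves min || M x - s || subject to x >= 0 over the reference k-mer
#' vocabulary, normalizes x to sum 1, zeroes genera below the reporting
#' floor and renormalizes. Sample k-mer mass falling entirely outside the
#' reference vocabulary triggers a coverage warning.
#'
#' @param sample a [kmer_signature()].
#' @param ref a [build_reference_matrix()]; must share `k` with `sample`.
#' @param min_reported abundance floor for calling a genus present
#'   (default 0.01: a genus must reach 1% to contribute subsystems to the
#'   database reduction).
#' @return named numeric vector of abundances summing to 1 with attribute
#'   `min_reported`; class `taxonomic_profile`.
#' @export
fit_genus_abundances <- function(sample, ref, min_reported = 0.01) {
  if (!identical(attr(sample, "k"), attr(ref, "k")))
    stop("sample and reference use different k", call. = FALSE)
  s <- as.numeric(sample)[match(rownames(ref), names(sample))]
  s[is.na(s)] <- 0
  uncovered <- sum(sample) - sum(s)
  if (uncovered > 0.05)
    warning(sprintf("%.1f%% of sample k-mer mass outside reference vocabulary",
                    100 * uncovered), call. = FALSE)
  x <- nnls_fit(unclass(ref), s)
  if (sum(x) <= 0) stop("no genus explains the sample", call. = FALSE)
  x <- x / sum(x)
  x[x < min_reported] <- 0
  if (sum(x) <= 0) stop("no genus explains the sample", call. = FALSE)
  x <- x / sum(x)
  structure(stats::setNames(x, colnames(ref)), min_reported = min_reported,
            class = "taxonomic_profile")
}

#' @export
print.taxonomic_profile <- function(x, ...) {
  cat("taxonomic profile (", sum(x > 0), " genera reported, floor ",
      attr(x, "min_reported"), ")\n", sep = "")
  v <- sort(unclass(x)[x > 0], decreasing = TRUE)
  for (g in names(v)) cat(sprintf("  %-24s %.4f\n", g, v[[g]]))
  invisible(x)
}

#' Write a taxonomic profile to TSV
#' @param profile a `taxonomic_profile`.
#' @param path output file.
#' @export
write_taxonomic_profile <- function(profile, path) {
  v <- unclass(profile)[profile > 0]
  ord <- order(-v, names(v), method = "radix")
  writeLines(c("genus\trelative_abundance",
               sprintf("%s\t%.6f", names(v)[ord], v[ord])), path)
  invisible(path)
}

#' Serialize a reference signature matrix (rows k-mers, columns genera)
#' @param ref a [build_reference_matrix()].
#' @param path output TSV.
#' @export
write_reference_matrix <- function(ref, path) {
  df <- data.frame(kmer = rownames(ref), unclass(ref), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a reference signature matrix written by [write_reference_matrix()]
#' @param path TSV file.
#' @return matrix with attribute `k`.
#' @export
read_reference_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$kmer
  attr(mat, "k") <- nchar(df$kmer[1])
  mat
}
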