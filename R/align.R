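# Built-in desk-scale translated homology search. Reads are translated in
# all six frames; exact amino-acid seeds shared with a representative are
# extended by banded gapped Smith-Waterman (BLOSUM62, gap open 11 / extend
# 1); the best local alignment per (read, subject) is reported as one
# BLAST-tabular row. An exhaustive (unseeded, unbanded) mode serves as the
# oracle search for truth construction. External aligners are supported by
# feeding their m8 output straight to the profiler.

#' Alignment parameters for the built-in search
#'
#' Bit scores use the published gapped-BLOSUM62 Karlin-Altschul constants
#' (lambda = 0.267, K = 0.041): `bit = (lambda * S - ln K) / ln 2` and
#' `E = m * n * 2^-bit`, with m the query length in residues and n the total
#' database residues. Exact E-value calibration is not a goal; downstream
#' logic depends only on E-value ordering and the 1e-5 ceiling.
#'
#' @param seed_len exact-match seed length in amino acids; the `sensitive`
#'   mode uses 3, `fast` uses 5, default 4.
#' @param gap_open,gap_ext affine gap penalties (a gap of length L costs
#'   `gap_open + L * gap_ext`).
#' @param band_width half-width added around the seed diagonals for the
#'   banded extension.
#' @param min_bit reporting floor in bits.
#' @param lambda,K Karlin-Altschul constants.
#' @return list of parameters.
#' @export
align_params <- function(seed_len = 4, gap_open = 11, gap_ext = 1,
                         band_width = 16, min_bit = 30,
                         lambda = 0.267, K = 0.041) {
  list(seed_len = as.integer(seed_len), gap_open = as.integer(gap_open),
       gap_ext = as.integer(gap_ext), band_width = as.integer(band_width),
       min_bit = min_bit, lambda = lambda, K = K)
}

#' Six-frame translation of a DNA read
#'
#' Standard genetic code; frames -1..-3 translate the reverse complement;
#' trailing partial codons are dropped; codons containing `N` translate to
#' `X`; stop codons to `*`.
#'
#' @param read a DNA sequence (single string).
#' @return named character vector of the six peptides (`+1`..`-3`); reads
#'   shorter than 3 nt give zero frames with a warning.
#' @export
six_frame_translate <- function(read) {
  assert_scalar_string(read, "read")
  read <- toupper(read)
  if (nchar(read) < 3L) {
    warning("read shorter than 3 nt; no frames", call. = FALSE)
    return(stats::setNames(character(0), character(0)))
  }
  unlist(cpp_six_frames(read, codon_table_string()))
}

#' E-value from a bit score
#'
#' `E = m * n * 2^-bit`: the expected number of chance alignments scoring at
#' least as well in a search of an m-residue query against n database
#' residues. Strictly decreasing in the bit score, linear in m and n.
#'
#' @param bit bit score.
#' @param m query length (residues).
#' @param n total database residues.
#' @export
evalue_from_bitscore <- function(bit, m, n) {
  stopifnot(m >= 1, n >= 1)
  m * n * 2^(-bit)
}

#' Translated homology search against database representatives
#'
#' @param reads named character vector of DNA reads (or, with
#'   `query_is_protein = TRUE`, of protein queries as used when annotating
#'   genomes for the presence matrix).
#' @param db a `subsys_db`; only cluster representatives are searched.
#' @param mode `"default"` (seed length 4), `"sensitive"` (3) or `"fast"`
#'   (5); ignored when `method = "exhaustive"`.
#' @param method `"seeded"` runs the banded seeded heuristic; `"exhaustive"`
#'   runs the full Smith-Waterman dynamic program on every read-subject pair
#'   (the oracle search, used e.g. by [make_truth()]).
#' @param params an [align_params()] list.
#' @param query_is_protein skip translation and search queries as proteins.
#' @return data.frame of tabular hits (the 12 m8 columns plus `frame`),
#'   sorted by read (input order), then E-value, then subject id, so results
#'   are invariant to database iteration order.
#' @export
search_hits <- function(reads, db,
                        mode = c("default", "sensitive", "fast"),
                        method = c("seeded", "exhaustive"),
                        params = align_params(), query_is_protein = FALSE) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  if (length(db$rep_seqs) == 0L) stop("empty database", call. = FALSE)
  if (length(reads) == 0L)
    return(empty_hits())
  if (is.null(names(reads)) || anyDuplicated(names(reads)))
    stop("reads must have unique names", call. = FALSE)
  seed_len <- switch(mode, default = params$seed_len, sensitive = 3L,
                     fast = 5L)
  bl <- blosum62()
  n_residues <- sum(nchar(db$rep_seqs))
  hits <- cpp_search(names(reads), toupper(unname(reads)),
                     names(db$rep_seqs), unname(db$rep_seqs),
                     bl, paste(rownames(bl), collapse = ""),
                     codon_table_string(), query_is_protein,
                     params$gap_open, params$gap_ext, seed_len,
                     method == "exhaustive", params$band_width,
                     params$lambda, log(params$K), params$min_bit,
                     n_residues)
  ord <- order(match(hits$query_id, names(reads)), hits$evalue,
               hits$subject_id, method = "radix")
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

empty_hits <- function() {
  df <- as.data.frame(stats::setNames(
    c(rep(list(character(0)), 2), rep(list(numeric(0)), 10),
      list(integer(0))), c(m8_columns, "frame")))
  df
}
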