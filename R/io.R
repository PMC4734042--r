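# Readers and writers for the on-disk formats the pipeline touches:
# FASTA/FASTQ sequences, BLAST tabular ("m8") hits, and TSV profile output.

#' Read sequences from FASTA or FASTQ
#'
#' Auto-detects the format from the first non-empty character (`>` FASTA,
#' `@` FASTQ); `.gz` inputs are decompressed transparently. FASTQ qualities
#' are discarded: the pipeline is quality-agnostic. Sequences are returned
#' uppercase and validated against the declared alphabet.
#'
#' @param path input file.
#' @param alphabet `"dna"` (A,C,G,T,N) or `"protein"` (20 residues plus X).
#' @return named character vector of sequences (names are record ids) with
#'   attribute `alphabet`.
#' @export
read_sequences <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "r")  # file() handles gz transparently
  first <- ""
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) break
    if (nzchar(trimws(ln))) { first <- substr(trimws(ln), 1L, 1L); break }
  }
  close(con)
  if (first == "") {
    warning("empty sequence file: ", path, call. = FALSE)
    out <- character(0)
    attr(out, "alphabet") <- alphabet
    return(out)
  }
  fmt <- if (first == ">") "fasta" else if (first == "@") "fastq" else
    stop("cannot detect format of ", path, ": first character ", sQuote(first),
         " (line 1)", call. = FALSE)
  set <- withCallingHandlers(
    tryCatch({
      if (alphabet == "dna") Biostrings::readDNAStringSet(path, format = fmt)
      else Biostrings::readAAStringSet(path, format = fmt)
    }, error = function(e) {
      stop("malformed ", fmt, " in ", path, ": ", conditionMessage(e),
           call. = FALSE)
    }),
    warning = function(w) {
      # Biostrings silently drops letters outside its alphabet; that would
      # mask corrupt input, so treat it as a parse error instead
      if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
        stop("sequence(s) with characters outside the ", alphabet,
             " alphabet in ", path, call. = FALSE)
      invokeRestart("muffleWarning")
    })
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  bad_alpha <- if (alphabet == "dna") grepl("[^ACGTN]", seqs) else
    grepl(paste0("[^", paste(AA20, collapse = ""), "X]"), seqs)
  if (any(bad_alpha)) {
    stop("sequence(s) outside ", alphabet, " alphabet: ",
         paste(head(ids[bad_alpha], 3), collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(seqs))) {
    stop("empty sequence record(s): ",
         paste(head(ids[!nzchar(seqs)], 3), collapse = ", "), call. = FALSE)
  }
  attr(seqs, "alphabet") <- alphabet
  seqs
}

#' Write sequences to FASTA or FASTQ
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param format `"fasta"` or `"fastq"` (constant `I` qualities).
#' @export
write_sequences <- function(seqs, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "fasta") {
    writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  } else {
    quals <- vapply(nchar(seqs), function(n) strrep("I", n), character(1))
    writeLines(paste0("@", names(seqs), "\n", unname(seqs), "\n+\n", quals),
               path)
  }
  invisible(path)
}

m8_columns <- c("query_id", "subject_id", "pct_identity", "aln_length",
                "mismatches", "gap_openings", "q_start", "q_end",
                "s_start", "s_end", "evalue", "bit_score")

#' Read BLAST tabular (m8) hits
#'
#' Twelve tab-separated columns, no header, in the BLAST `-outfmt 6` order;
#' lines starting with `#` are skipped. Any aligner producing this format can
#' feed the profiler.
#'
#' @param path tabular hit file.
#' @return data.frame with columns `query_id`, `subject_id`, `pct_identity`,
#'   `aln_length`, `mismatches`, `gap_openings`, `q_start`, `q_end`,
#'   `s_start`, `s_end`, `evalue`, `bit_score`, in file order.
#' @export
read_tabular_hits <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = "\t", comment.char = "#",
                            quote = "")
  keep <- !is.na(nf)  # NA: blank/comment-only lines
  if (any(nf[keep] != 12L)) {
    bad <- which(keep & nf != 12L)[1L]
    stop("expected 12 tab-separated columns, got ", nf[bad], " (line ", bad,
         " of ", path, ")", call. = FALSE)
  }
  if (!any(keep)) {
    hits <- as.data.frame(stats::setNames(
      rep(list(character(0)), 12L), m8_columns))
    num <- c(3:12)
    hits[num] <- lapply(hits[num], as.numeric)
    return(hits)
  }
  hits <- utils::read.table(path, sep = "\t", comment.char = "#",
                            quote = "", col.names = m8_columns,
                            colClasses = c("character", "character",
                                           rep("numeric", 10)),
                            stringsAsFactors = FALSE)
  bad <- hits$pct_identity < 0 | hits$pct_identity > 100 |
    hits$aln_length < 1 | hits$evalue < 0
  if (any(bad)) {
    stop("invalid hit values (identity/length/evalue) at data row ",
         which(bad)[1L], " of ", path, call. = FALSE)
  }
  hits
}

#' Write hits as BLAST tabular (m8)
#'
#' Numeric columns are printed with full (17 significant digit) precision so
#' a write/read round trip is lossless -- unlike most aligners, which round
#' their printed E-values (and can thereby change downstream tie sets).
#'
#' @param hits data.frame as returned by [read_tabular_hits()] or
#'   [search_hits()] (extra columns such as `frame` are dropped).
#' @param path output file.
#' @export
write_tabular_hits <- function(hits, path) {
  out <- hits[, m8_columns, drop = FALSE]
  out$pct_identity <- sprintf("%.17g", out$pct_identity)
  out$evalue <- sprintf("%.17g", out$evalue)
  out$bit_score <- sprintf("%.17g", out$bit_score)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a functional profile to TSV
#'
#' Columns `label`, `relative_abundance`, `read_count`; rows sorted by
#' abundance descending with lexicographic tie-break on the label;
#' abundances printed with 6 decimals.
#'
#' @param profile a `functional_profile` (see [aggregate_profile()]).
#' @param path output file.
#' @export
write_profile <- function(profile, path) {
  df <- as.data.frame(profile)
  if (nrow(df) == 0L) warning("writing empty profile to ", path, call. = FALSE)
  ord <- order(-df$abundance, df$label, method = "radix")
  df <- df[ord, , drop = FALSE]
  lines <- c("label\trelative_abundance\tread_count",
             sprintf("%s\t%.6f\t%.6f", df$label, df$abundance, df$read_count))
  writeLines(lines, path)
  invisible(path)
}

#' Read a functional profile written by [write_profile()]
#' @param path profile TSV.
#' @return data.frame with columns `label`, `abundance`, `read_count`.
#' @export
read_profile <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          colClasses = c("character", "numeric", "numeric"),
                          stringsAsFactors = FALSE)
  names(df) <- c("label", "abundance", "read_count")
  df
}
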