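# Internal helpers shared across modules.

.sf_env <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

# BLOSUM62 from Biostrings, fetched once per session.
blosum62 <- function() {
  if (is.null(.sf_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .sf_env$blosum62 <- e$BLOSUM62
  }
  .sf_env$blosum62
}

# Standard genetic code (translation table 1) as a 64-character string in
# ACGT-major codon order, derived from Biostrings::GENETIC_CODE so the C++
# search and the R-level translation share one source.
codon_table_string <- function() {
  if (is.null(.sf_env$codon_table)) {
    b <- c("A", "C", "G", "T")
    codons <- vapply(0:63, function(i) {
      paste0(b[i %/% 16 + 1], b[(i %/% 4) %% 4 + 1], b[i %% 4 + 1])
    }, character(1))
    .sf_env$codon_table <- paste(Biostrings::GENETIC_CODE[codons], collapse = "")
  }
  .sf_env$codon_table
}

# Run expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")

assert_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
    stop(what, " must be a non-empty string", call. = FALSE)
}
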