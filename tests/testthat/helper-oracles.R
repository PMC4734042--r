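# Independent oracles and shared fixtures for the test suite. Oracles are
# deliberately written against different code paths than the implementation
# they check (plain-R dynamic programming, Biostrings alignments, brute-force
# enumeration).

# Plain-R maximum-matches dynamic program (the clustering identity oracle).
r_max_matches <- function(a, b) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  prev <- integer(length(b) + 1L)
  for (i in seq_along(a)) {
    cur <- integer(length(b) + 1L)
    for (j in seq_along(b)) {
      cur[j + 1L] <- if (a[i] == b[j]) prev[j] + 1L
                     else max(prev[j + 1L], cur[j])
    }
    prev <- cur
  }
  prev[length(b) + 1L]
}

r_identity_oracle <- function(a, b) {
  100 * r_max_matches(a, b) / min(nchar(a), nchar(b))
}

# Biostrings-based identity oracle (match = 1, everything else free): the
# optimal score is the maximum number of identical aligned residues.
bio_identity_oracle <- function(a, b) {
  alpha <- c(subsysfocus:::AA20, "X", "*")
  m <- outer(alpha, alpha, function(x, y) ifelse(x == y, 1L, 0L))
  dimnames(m) <- list(alpha, alpha)
  sc <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = m, gapOpening = 0, gapExtension = 0,
    scoreOnly = TRUE)
  100 * sc / min(nchar(a), nchar(b))
}

# Plain-R affine-gap Smith-Waterman, score only (the search oracle).
r_sw_score <- function(q, s, gap_open = 11, gap_ext = 1) {
  bl <- subsysfocus:::blosum62()
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  qc[!qc %in% rownames(bl)] <- "X"
  sc[!sc %in% rownames(bl)] <- "X"
  m <- length(qc); n <- length(sc)
  NEG <- -1e9
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F_ <- matrix(NEG, m + 1, n + 1)
  go <- gap_open + gap_ext
  best <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      E[i + 1, j + 1] <- max(H[i + 1, j] - go, E[i + 1, j] - gap_ext)
      F_[i + 1, j + 1] <- max(H[i, j + 1] - go, F_[i, j + 1] - gap_ext)
      sub <- if (qc[i] == "*" || sc[j] == "*") NEG else bl[qc[i], sc[j]]
      H[i + 1, j + 1] <- max(0, H[i, j] + sub, E[i + 1, j + 1],
                             F_[i + 1, j + 1])
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

# Best subject(s) for a DNA read by exhaustive plain-R translated SW.
r_best_subjects <- function(read, rep_seqs) {
  frames <- six_frame_translate(read)
  scores <- vapply(rep_seqs, function(s)
    max(vapply(frames, r_sw_score, numeric(1), s = s)), numeric(1))
  list(best = names(rep_seqs)[scores == max(scores)], score = max(scores))
}

# Brute-force best-hit enumeration: per query, scan every row.
brute_best_hits <- function(hits, t) {
  keep <- list()
  for (q in unique(hits$query_id)) {
    rows <- hits[hits$query_id == q, , drop = FALSE]
    ok <- rows[rows$evalue <= t$max_evalue &
                 rows$pct_identity >= t$min_identity &
                 rows$aln_length >= t$min_aln_len, , drop = FALSE]
    if (nrow(ok) == 0L) next
    keep[[q]] <- ok[ok$evalue == min(ok$evalue), , drop = FALSE]
  }
  if (length(keep) == 0L) return(hits[0, , drop = FALSE])
  out <- do.call(rbind, keep)
  rownames(out) <- NULL
  out
}

with_seed_local <- function(seed, expr) subsysfocus:::with_seed(seed, expr)

random_aa <- function(n) paste(sample(subsysfocus:::AA20, n, TRUE),
                               collapse = "")

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# Mutate a DNA sequence at the given per-base substitution rate.
mutate_dna <- function(seq, rate) {
  chars <- strsplit(seq, "")[[1]]
  pos <- which(runif(length(chars)) < rate)
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  paste(chars, collapse = "")
}

# Small standard fixture: database + community + error-free reads.
small_world <- function(seed = 42, n_reads = 120, cutoff = 98,
                        within_identity = 93) {
  proteins <- generate_subsystem_db(
    n_level1 = 3, n_level3_per_level1 = 3, families_per_subsystem = 2,
    seqs_per_family = 3, within_family_identity = within_identity,
    seed = seed)
  db <- build_clustered_database(proteins, cutoff)
  community <- generate_community(proteins, n_genera = 3,
                                  species_per_genus = 2,
                                  subsystems_per_genus = 3, seed = seed + 1)
  ab <- stats::setNames(c(0.5, 0.3, 0.2), rownames(community$truth_presence))
  sim <- generate_reads(community, ab, n_reads = n_reads, read_length = 150,
                        db_proteins = proteins, seed = seed + 2)
  list(proteins = proteins, db = db, community = community, ab = ab,
       reads = sim$reads, read_truth = sim$truth)
}
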