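# Six-frame translation, E-value arithmetic, and the built-in translated
# search against Smith-Waterman oracles.

test_that("six_frame_translate follows the standard code", {
  fr <- six_frame_translate("ATGGCC")
  expect_identical(fr[["+1"]], "MA")
  expect_identical(fr[["-1"]], "GH")  # revcomp GGCCAT -> GGC CAT -> G H
  expect_identical(six_frame_translate("ATGNCC")[["+1"]], "MX")
  expect_identical(six_frame_translate("TAATAG")[["+1"]], "**")
  expect_warning(fr0 <- six_frame_translate("AT"), "shorter")
  expect_length(fr0, 0)
})

test_that("six-frame translation agrees with Biostrings", {
  set.seed(6)
  for (i in 1:10) {
    dna <- random_dna(sample(30:80, 1))
    fr <- six_frame_translate(dna)
    d <- Biostrings::DNAString(dna)
    rc <- Biostrings::reverseComplement(d)
    for (off in 0:2) {
      fwd_len <- 3 * ((nchar(dna) - off) %/% 3)
      expect_identical(fr[[paste0("+", off + 1)]], as.character(
        Biostrings::translate(Biostrings::subseq(d, off + 1, off + fwd_len),
                              no.init.codon = TRUE)))
      expect_identical(fr[[paste0("-", off + 1)]], as.character(
        Biostrings::translate(Biostrings::subseq(rc, off + 1, off + fwd_len),
                              no.init.codon = TRUE)))
    }
  }
})

test_that("evalue_from_bitscore arithmetic and monotonicity", {
  expect_equal(evalue_from_bitscore(30, 100, 1e6), 100 * 1e6 * 2^-30)
  expect_equal(evalue_from_bitscore(30, 100, 1e6), 0.0931, tolerance = 1e-3)
  expect_equal(evalue_from_bitscore(1000, 100, 1e6), 0, tolerance = 1e-200)
  expect_equal(evalue_from_bitscore(30, 100, 2e6),
               2 * evalue_from_bitscore(30, 100, 1e6))
  b <- seq(10, 60, 5)
  expect_true(all(diff(evalue_from_bitscore(b, 50, 1e5)) < 0))
})

test_that("an exact coding read is a perfect self-hit", {
  w <- small_world(seed = 13, n_reads = 5)
  rep_id <- names(w$db$rep_seqs)[1]
  aa30 <- substr(w$db$rep_seqs[[rep_id]], 1, 30)
  read <- reverse_translate(aa30)
  hits <- search_hits(stats::setNames(read, "q"), w$db)
  top <- hits[which.max(hits$bit_score), ]
  expect_identical(top$subject_id, rep_id)
  expect_equal(top$pct_identity, 100)
  expect_equal(top$aln_length, 30)
  expect_equal(top$frame, 1)
})

test_that("exhaustive search agrees with the plain-R SW oracle", {
  set.seed(17)
  subjects <- stats::setNames(replicate(5, random_aa(sample(30:50, 1))),
                              paste0("p", 1:5))
  db <- structure(list(cutoff = 100, rep_seqs = subjects,
                       proteins = data.frame(
                         protein_id = names(subjects), seq = subjects,
                         representative_id = names(subjects),
                         level1 = "L", level2 = "", level3 = "S", fn = "f",
                         stringsAsFactors = FALSE)), class = "subsys_db")
  # reads derived from subjects with mutations, so real homology exists
  reads <- stats::setNames(vapply(1:20, function(i) {
    src <- subjects[[sample(5, 1)]]
    aa <- substr(src, 1, 25)
    mutate_dna(reverse_translate(aa), 0.05)
  }, character(1)), paste0("r", 1:20))
  params <- align_params(min_bit = 5)
  hits <- search_hits(reads, db, method = "exhaustive", params = params)
  for (r in names(reads)) {
    h <- hits[hits$query_id == r, ]
    oracle <- r_best_subjects(reads[[r]], subjects)
    if (nrow(h) == 0) next
    builtin_best <- h$subject_id[which.max(h$bit_score)]
    expect_true(builtin_best %in% oracle$best, info = r)
    # and the reported score equals the oracle optimum
    s_max <- (max(h$bit_score) * log(2) + log(0.041)) / 0.267
    expect_equal(s_max, oracle$score, tolerance = 1e-6, info = r)
  }
})

test_that("seeded heuristic is near-oracle when a seed exists", {
  w <- small_world(seed = 19, n_reads = 60)
  ex <- search_hits(w$reads, w$db, method = "exhaustive")
  se <- search_hits(w$reads, w$db, method = "seeded")
  best_ex <- tapply(ex$bit_score, ex$query_id, max)
  best_se <- tapply(se$bit_score, se$query_id, max)
  common <- intersect(names(best_ex), names(best_se))
  ratio <- best_se[common] / best_ex[common]
  expect_gte(mean(ratio >= 0.95), 0.95)
})

test_that("search is invariant to database iteration order", {
  w <- small_world(seed = 23, n_reads = 20)
  db2 <- w$db
  perm <- rev(seq_along(db2$rep_seqs))
  db2$rep_seqs <- db2$rep_seqs[perm]
  h1 <- search_hits(w$reads, w$db)
  h2 <- search_hits(w$reads, db2)
  expect_equal(h1, h2)
})

test_that("reported identity/length are self-consistent on gapless hits", {
  w <- small_world(seed = 29, n_reads = 40)
  hits <- search_hits(w$reads, w$db)
  gapless <- hits[hits$gap_openings == 0, ]
  expect_gt(nrow(gapless), 0)
  expect_equal(gapless$pct_identity,
               100 * (gapless$aln_length - gapless$mismatches) /
                 gapless$aln_length)
  expect_equal(abs(gapless$q_end - gapless$q_start) + 1,
               3 * gapless$aln_length)
  expect_equal(gapless$s_end - gapless$s_start + 1, gapless$aln_length)
  gapped <- hits[hits$gap_openings > 0, ]
  if (nrow(gapped) > 0) {
    matches <- gapped$pct_identity * gapped$aln_length / 100
    expect_equal(matches, round(matches), tolerance = 1e-9)
    # gap columns account for the rest of the alignment length
    expect_true(all(matches + gapped$mismatches < gapped$aln_length))
  }
})

test_that("degenerate searches behave", {
  w <- small_world(seed = 31, n_reads = 3)
  empty_db <- w$db
  empty_db$rep_seqs <- empty_db$rep_seqs[0]
  expect_error(search_hits(w$reads, empty_db), "empty database")
  # a read sharing no seed with any subject yields no hits
  h <- search_hits(stats::setNames(strrep("A", 60), "polyA"), w$db)
  expect_equal(nrow(h), 0)
})
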