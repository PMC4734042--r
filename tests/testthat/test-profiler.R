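# Best-hit filtering, tied-path assignment, profile aggregation.

mk_hits <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) data.frame(
    query_id = r[[1]], subject_id = r[[2]], pct_identity = r[[3]],
    aln_length = r[[4]], mismatches = 0, gap_openings = 0, q_start = 1,
    q_end = 1, s_start = 1, s_end = 1, evalue = r[[5]], bit_score = r[[6]],
    stringsAsFactors = FALSE)))
  df
}

mk_db <- function(map) {
  # map: subject_id -> c(level1, level2, level3, fn)
  p <- do.call(rbind, lapply(names(map), function(id) data.frame(
    protein_id = id, seq = "MKL", representative_id = id,
    level1 = map[[id]][1], level2 = map[[id]][2], level3 = map[[id]][3],
    fn = map[[id]][4], stringsAsFactors = FALSE)))
  structure(list(cutoff = 100, proteins = p,
                 rep_seqs = stats::setNames(p$seq, p$protein_id)),
            class = "subsys_db")
}

test_that("filter_hits keeps exactly the tied lowest-E survivors", {
  h <- mk_hits(list("r1", "a", 90, 30, 1e-10, 50),
               list("r1", "b", 90, 30, 1e-8, 45))
  expect_identical(filter_hits(h)$subject_id, "a")
  tie <- mk_hits(list("r1", "a", 90, 30, 1e-10, 50),
                 list("r1", "b", 90, 30, 1e-10, 50))
  expect_identical(filter_hits(tie)$subject_id, c("a", "b"))
  # inclusive boundaries on all three thresholds
  edge <- mk_hits(list("r1", "a", 100, 14, 1e-30, 80),
                  list("r2", "b", 100, 15, 1e-30, 80),
                  list("r3", "c", 60, 15, 1e-5, 80),
                  list("r4", "d", 59.9, 15, 1e-30, 80))
  out <- filter_hits(edge)
  expect_setequal(out$query_id, c("r2", "r3"))
})

test_that("assign_reads dedups paths and splits weight over ties", {
  db <- mk_db(list(a = c("A", "x", "S1", "f1"), b = c("A", "x", "S1", "f1"),
                   c = c("B", "y", "S3", "f3")))
  one <- assign_reads(mk_hits(list("r1", "a", 100, 30, 1e-10, 50)), db)
  expect_equal(nrow(one), 1)
  expect_equal(one$weight, 1)
  same <- assign_reads(mk_hits(list("r1", "a", 100, 30, 1e-10, 50),
                               list("r1", "b", 100, 30, 1e-10, 50)), db)
  expect_equal(nrow(same), 1)  # identical paths collapse
  expect_equal(same$weight, 1)
  split2 <- assign_reads(mk_hits(list("r1", "a", 100, 30, 1e-10, 50),
                                 list("r1", "c", 100, 30, 1e-10, 50)), db)
  expect_equal(nrow(split2), 2)
  expect_equal(split2$weight, c(0.5, 0.5))
  expect_error(
    assign_reads(mk_hits(list("r1", "zz", 100, 30, 1e-10, 50)), db), "zz")
})

test_that("aggregate_profile matches hand-computed sums and rolls up", {
  db <- mk_db(list(a = c("A", "x", "S1", "f1"), b = c("A", "x", "S2", "f2")))
  h <- mk_hits(list("r1", "a", 100, 30, 1e-10, 50),
               list("r2", "a", 100, 30, 1e-10, 50),
               list("r2", "b", 100, 30, 1e-10, 50))
  asg <- assign_reads(filter_hits(h), db)
  p3 <- aggregate_profile(asg, 3, n_total = 4)
  expect_equal(stats::setNames(p3$read_count, p3$label),
               c(S1 = 1.5, S2 = 0.5))
  expect_equal(stats::setNames(p3$abundance, p3$label),
               c(S1 = 0.75, S2 = 0.25))
  expect_equal(attr(p3, "n_unassigned"), 2)
  # the two level-3 labels share level1: weights add to a single label
  p1 <- aggregate_profile(asg, 1)
  expect_equal(p1$label, "A")
  expect_equal(p1$abundance, 1)
  expect_warning(p0 <- aggregate_profile(asg[0, ], 1), "no assigned")
  expect_equal(nrow(p0), 0)
})

test_that("profiler invariants hold on random hit tables", {
  set.seed(55)
  labels <- list(a = c("A", "x", "S1", "f1"), b = c("A", "y", "S2", "f2"),
                 c = c("B", "z", "S3", "f3"), d = c("C", "w", "S4", "f4"))
  db <- mk_db(labels)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    hits <- data.frame(
      query_id = paste0("r", sample(1:8, n, TRUE)),
      subject_id = sample(names(labels), n, TRUE),
      pct_identity = sample(c(50, 61, 80, 100), n, TRUE),
      aln_length = sample(c(10, 15, 40), n, TRUE), mismatches = 0,
      gap_openings = 0, q_start = 1, q_end = 1, s_start = 1, s_end = 1,
      evalue = sample(c(1e-20, 1e-10, 1e-10, 1e-3), n, TRUE),
      bit_score = 50, stringsAsFactors = FALSE)
    t <- filter_thresholds()
    mine <- filter_hits(hits, t)
    brute <- brute_best_hits(hits, t)
    ord <- function(d) d[order(d$query_id, d$subject_id, d$evalue), ,
                         drop = FALSE]
    expect_equal(ord(mine), ord(brute), ignore_attr = TRUE)
    # conservation at every level
    asg <- assign_reads(mine, db)
    for (lev in c(1, 2, 3, "function")) {
      p <- aggregate_profile(asg, lev)
      if (nrow(p) > 0)
        expect_equal(sum(p$read_count), length(unique(asg$read_id)))
    }
    # level-1 profile equals level-3 pushed through the hierarchy map
    p3 <- aggregate_profile(asg, 3)
    p1 <- aggregate_profile(asg, 1)
    l3_to_l1 <- vapply(labels, `[`, character(1), 1)
    names(l3_to_l1) <- vapply(labels, `[`, character(1), 3)
    if (nrow(p3) > 0) {
      rolled <- tapply(p3$abundance, l3_to_l1[p3$label], sum)
      expect_equal(sort(rolled),
                   sort(stats::setNames(p1$abundance, p1$label)),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
    # relaxing any threshold never decreases the number of assigned reads
    relaxed <- filter_hits(hits, filter_thresholds(1e-3, 50, 5))
    expect_gte(length(unique(relaxed$query_id)),
               length(unique(mine$query_id)))
  }
})

test_that("measure_throughput arithmetic", {
  expect_equal(measure_throughput(600, 60)$sequences_per_minute, 600)
  expect_equal(measure_throughput(600, 60)$seconds_per_sequence, 0.1)
  expect_equal(measure_throughput(1, 1)$sequences_per_minute, 60)
  expect_error(measure_throughput(0, 1), ">= 1")
})
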