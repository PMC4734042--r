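# Reference modelling: pairwise identity, deduplication, greedy clustering.

test_that("pairwise_identity matches stated cases and is symmetric", {
  expect_equal(pairwise_identity("MKLV", "MKLV"), 100)
  expect_equal(pairwise_identity("AAAAAAAAAA", "AAAAAAAAAC"), 90)
  # full-length substrings of the longer sequence are 100% identical
  expect_equal(pairwise_identity("KLVD", "AMKLVDRR"), 100)
  expect_error(pairwise_identity("", "MK"), "non-empty")
  set.seed(11)
  for (i in 1:20) {
    a <- random_aa(sample(5:30, 1)); b <- random_aa(sample(5:30, 1))
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
})

test_that("pairwise_identity equals the exhaustive DP oracle on random pairs", {
  set.seed(101)
  for (i in 1:50) {
    a <- random_aa(sample(3:30, 1))
    b <- random_aa(sample(3:30, 1))
    expect_equal(pairwise_identity(a, b), r_identity_oracle(a, b),
                 info = paste(a, b))
  }
})

test_that("deduplicate_proteins keeps first of identical (seq, path) pairs", {
  p <- data.frame(protein_id = c("p1", "p2", "p3"),
                  seq = c("MKLV", "MKLV", "MKLV"),
                  level1 = c("A", "A", "B"), level2 = "", level3 = "s",
                  fn = "f", stringsAsFactors = FALSE)
  d <- deduplicate_proteins(p)
  expect_identical(d$protein_id, c("p1", "p3"))  # p2 is a true duplicate
  expect_identical(deduplicate_proteins(p[0, ]), p[0, ])
})

test_that("cluster_subsystem follows the greedy rule", {
  s1 <- random_aa(100)
  set.seed(3)
  s2 <- paste(ifelse(runif(100) < 0.95, strsplit(s1, "")[[1]],
                     sample(subsysfocus:::AA20, 100, TRUE)), collapse = "")
  s3 <- random_aa(100)
  p <- data.frame(protein_id = c("a", "b", "c"), seq = c(s1, s2, s3),
                  level1 = "L", level2 = "", level3 = "S", fn = "f",
                  stringsAsFactors = FALSE)
  cl <- cluster_subsystem(p, 90)
  expect_equal(length(unique(cl$representative_id)), 2)
  expect_identical(cl$representative_id[cl$protein_id == "a"],
                   cl$representative_id[cl$protein_id == "b"])
  # n identical sequences -> one cluster at any cut-off
  pid <- data.frame(protein_id = paste0("p", 1:5), seq = s1, level1 = "L",
                    level2 = "", level3 = "S", fn = paste0("f", 1:5),
                    stringsAsFactors = FALSE)
  expect_equal(length(unique(cluster_subsystem(pid, 100)$representative_id)),
               1)
  expect_error(cluster_subsystem(rbind(p, within(p, {
    level3 <- "T"; protein_id <- paste0(protein_id, "x")})), 90), "single")
})

test_that("random families satisfy the clustering contract (oracle check)", {
  set.seed(77)
  for (rep in 1:5) {
    proteins <- generate_subsystem_db(
      n_level1 = 1, n_level3_per_level1 = 1, families_per_subsystem = 3,
      seqs_per_family = sample(3:6, 1), within_family_identity = 93,
      seed = 1000 + rep)
    for (cutoff in c(90, 95)) {
      for (pf in c(TRUE, FALSE)) {
        cl <- cluster_subsystem(proteins, cutoff, prefilter = pf)
        # exhaustive, disjoint partition
        expect_setequal(cl$protein_id, proteins$protein_id)
        expect_false(anyDuplicated(cl$protein_id) > 0)
        # representative is a member of its own cluster
        expect_true(all(cl$representative_id %in% cl$protein_id))
        # member-representative identity >= cutoff, by independent oracle
        seqs <- stats::setNames(cl$seq, cl$protein_id)
        for (i in seq_len(nrow(cl))) {
          expect_gte(bio_identity_oracle(seqs[[cl$protein_id[i]]],
                                         seqs[[cl$representative_id[i]]]),
                     cutoff)
        }
      }
      # prefilter must not change the clustering
      expect_identical(cluster_subsystem(proteins, cutoff, prefilter = TRUE),
                       cluster_subsystem(proteins, cutoff, prefilter = FALSE))
    }
  }
})

test_that("build_clustered_database: presets, partition, determinism", {
  proteins <- generate_subsystem_db(
    n_level1 = 2, n_level3_per_level1 = 2, families_per_subsystem = 2,
    seqs_per_family = 3, within_family_identity = 93, seed = 5)
  counts <- vapply(c(100, 98, 95, 90), function(co)
    length(build_clustered_database(proteins, co)$rep_seqs), numeric(1))
  # representative count non-increasing as the cut-off loosens
  expect_true(all(diff(counts) <= 0))
  db100 <- build_clustered_database(proteins, 100)
  # 93%-identity variants are all distinct at cut-off 100
  expect_equal(length(db100$rep_seqs), nrow(deduplicate_proteins(proteins)))
  db90 <- build_clustered_database(proteins, 90)
  # one cluster per 93%-identity family at cut-off 90
  expect_equal(length(db90$rep_seqs),
               length(unique(proteins$fn)))
  # partition property: cluster sizes sum to deduplicated input size
  cl <- db_clusters(db90)
  expect_equal(sum(lengths(unlist(cl, recursive = FALSE))),
               nrow(deduplicate_proteins(proteins)))
  # deterministic given identical input
  expect_identical(db90$proteins,
                   build_clustered_database(proteins, 90)$proteins)
  # missing path is an error
  broken <- proteins
  broken$level3[1] <- ""
  expect_error(build_clustered_database(broken, 90), "path")
})

test_that("100% cut-off absorbs exact substrings of the representative", {
  long <- random_aa(120)
  p <- data.frame(protein_id = c("long", "sub"),
                  seq = c(long, substr(long, 10, 60)),
                  level1 = "L", level2 = "", level3 = "S", fn = "f",
                  stringsAsFactors = FALSE)
  db <- build_clustered_database(p, 100)
  expect_equal(length(db$rep_seqs), 1)
  expect_identical(names(db$rep_seqs), "long")  # longest-first greedy order
})

test_that("database serialization round-trips", {
  proteins <- generate_subsystem_db(n_level1 = 2, n_level3_per_level1 = 2,
                                    families_per_subsystem = 1,
                                    seqs_per_family = 2, seed = 9)
  db <- build_clustered_database(proteins, 98)
  dir <- withr::local_tempdir()
  sub <- write_database(db, dir)
  expect_identical(basename(sub), "db_98")
  back <- read_database(sub)
  expect_equal(back$cutoff, 98)
  expect_identical(back$rep_seqs[order(names(back$rep_seqs))],
                   db$rep_seqs[order(names(db$rep_seqs))])
  expect_identical(
    back$proteins[order(back$proteins$protein_id),
                  c("protein_id", "representative_id", "level3")],
    db$proteins[order(db$proteins$protein_id),
                c("protein_id", "representative_id", "level3")],
    ignore_attr = TRUE)
})
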