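# Synthetic fixtures with known truth: a subsystem-annotated protein
# reference with controllable within-family identity, communities of
# annotated genomes carrying known subsystem subsets, and metagenomic reads
# sampled from their coding regions. Everything is deterministic under a
# seed, so each pipeline stage can be tested against generator truth with no
# external database.

random_protein <- function(len) paste(sample(AA20, len, replace = TRUE),
                                      collapse = "")

mutate_protein <- function(seq, target_identity) {
  chars <- strsplit(seq, "")[[1]]
  n_sub <- round(length(chars) * (100 - target_identity) / 100)
  if (n_sub > 0) {
    pos <- sample(length(chars), n_sub)
    for (p in pos) chars[p] <- sample(setdiff(AA20, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic subsystem-annotated protein reference
#'
#' Families are independent random proteins (ancestor length uniform in
#' 80-300 aa); family members are point-substitution variants hitting the
#' target within-family identity (the substitution count is rounded, so the
#' realized member-ancestor identity is within ~2% of the target). Labels
#' follow the scheme `L1_*` / `L2_*` / `L3_*` / `fn_*`, with two level-3
#' subsystems per level-2 class.
#'
#' @param n_level1 number of level-1 classes.
#' @param n_level3_per_level1 level-3 subsystems per level-1 class.
#' @param families_per_subsystem protein families per level-3 subsystem
#'   (each family is one functional role).
#' @param seqs_per_family members per family (the ancestor included).
#' @param within_family_identity target member-ancestor identity in
#'   (50, 100].
#' @param seed RNG seed.
#' @return protein data.frame (`protein_id`, `seq`, `level1`, `level2`,
#'   `level3`, `fn`) accepted by [build_clustered_database()].
#' @export
generate_subsystem_db <- function(n_level1 = 3, n_level3_per_level1 = 4,
                                  families_per_subsystem = 2,
                                  seqs_per_family = 4,
                                  within_family_identity = 95, seed = 1) {
  stopifnot(within_family_identity > 50, within_family_identity <= 100)
  with_seed(seed, {
    rows <- list()
    fam_counter <- 0L
    l3_counter <- 0L
    for (i in seq_len(n_level1)) {
      l1 <- sprintf("L1_%02d", i)
      for (k in seq_len(n_level3_per_level1)) {
        l3_counter <- l3_counter + 1L
        l3 <- sprintf("L3_%03d", l3_counter)
        l2 <- sprintf("L2_%03d", (l3_counter + 1L) %/% 2L)
        for (f in seq_len(families_per_subsystem)) {
          fam_counter <- fam_counter + 1L
          fn <- sprintf("fn_%03d", fam_counter)
          ancestor <- random_protein(sample(80:300, 1))
          for (s in seq_len(seqs_per_family)) {
            seq <- if (s == 1) ancestor
                   else mutate_protein(ancestor, within_family_identity)
            rows[[length(rows) + 1L]] <- data.frame(
              protein_id = sprintf("%s_f%02d_s%02d", l3, f, s), seq = seq,
              level1 = l1, level2 = l2, level3 = l3, fn = fn,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

# AA -> synonymous codons (stops excluded), from the standard code.
synonymous_codons <- function() {
  if (is.null(.sf_env$syn_codons)) {
    gc <- Biostrings::GENETIC_CODE
    .sf_env$syn_codons <- split(names(gc), unname(gc))
  }
  .sf_env$syn_codons
}

#' Reverse-translate a protein with random synonymous codons
#' @param aa protein sequence (single string).
#' @return DNA coding sequence (no stop codon appended).
#' @export
reverse_translate <- function(aa) {
  syn <- synonymous_codons()
  chars <- strsplit(aa, "")[[1]]
  paste(vapply(chars, function(a) {
    cods <- syn[[a]]
    if (is.null(cods)) stop("cannot reverse-translate residue ", a,
                            call. = FALSE)
    cods[sample.int(length(cods), 1)]
  }, character(1)), collapse = "")
}

#' Generate a synthetic community of annotated genomes
#'
#' Each genus draws a random subset of the database's level-3 subsystems;
#' each of its species carries reverse-translated coding DNA for a sample of
#' proteins from *every* subsystem of its genus (so the genus-level truth
#' table is exactly recoverable from its species).
#'
#' @param db_proteins protein data.frame from [generate_subsystem_db()] (or
#'   the `proteins` table of a `subsys_db`).
#' @param n_genera,species_per_genus community shape.
#' @param subsystems_per_genus subsystems drawn per genus.
#' @param proteins_per_subsystem proteins sampled per subsystem per species.
#' @param seed RNG seed.
#' @return list with `genomes` (each: `species`, `genus`, `proteins` named
#'   AA vector, `cds` named DNA vector parallel to `proteins`) and
#'   `truth_presence` (logical genus x subsystem matrix over all database
#'   subsystems).
#' @export
generate_community <- function(db_proteins, n_genera = 5,
                               species_per_genus = 2,
                               subsystems_per_genus = 4,
                               proteins_per_subsystem = 2, seed = 1) {
  subsystems <- sort(unique(db_proteins$level3))
  stopifnot(subsystems_per_genus <= length(subsystems))
  with_seed(seed, {
    genera <- sprintf("Genus_%02d", seq_len(n_genera))
    truth <- matrix(FALSE, n_genera, length(subsystems),
                    dimnames = list(genera, subsystems))
    genomes <- list()
    for (g in genera) {
      drawn <- sort(sample(subsystems, subsystems_per_genus))
      truth[g, drawn] <- TRUE
      for (sp in seq_len(species_per_genus)) {
        prot_ids <- unlist(lapply(drawn, function(s3) {
          pool <- db_proteins$protein_id[db_proteins$level3 == s3]
          sample(pool, min(proteins_per_subsystem, length(pool)))
        }))
        aa <- stats::setNames(
          db_proteins$seq[match(prot_ids, db_proteins$protein_id)], prot_ids)
        cds <- vapply(aa, reverse_translate, character(1))
        genomes[[length(genomes) + 1L]] <- list(
          species = paste0(g, " species", sp), genus = g,
          proteins = aa, cds = cds)
      }
    }
    list(genomes = genomes, truth_presence = truth)
  })
}

#' Sample metagenomic reads from a community's coding regions
#'
#' Reads are drawn genus-proportional to `abundances`, then uniformly over a
#' random species of the genus and over positions of its coding sequences
#' (sequences shorter than the read length are excluded), on a random
#' strand. Substitution errors are applied at `error_rate` per base. An
#' optional fraction of random-DNA reads serves as a negative control; those
#' reads have no truth row.
#'
#' @param community output of [generate_community()].
#' @param abundances named numeric vector over the community's genera,
#'   summing to 1.
#' @param n_reads number of reads.
#' @param read_length read length in nt (default 150).
#' @param error_rate per-base substitution rate in \[0, 0.05\].
#' @param intergenic_fraction fraction of reads drawn as uniform random DNA.
#' @param db_proteins protein table used to build the community, for the
#'   per-read subsystem truth.
#' @param seed RNG seed.
#' @return list with `reads` (named DNA vector) and `truth` (data.frame
#'   `read_id`, `genus`, `species`, `protein_id`, `level1`, `level2`,
#'   `level3`, `fn`; coding reads only).
#' @export
generate_reads <- function(community, abundances, n_reads = 2000,
                           read_length = 150, error_rate = 0,
                           intergenic_fraction = 0, db_proteins = NULL,
                           seed = 1) {
  stopifnot(abs(sum(abundances) - 1) < 1e-6, error_rate >= 0,
            error_rate <= 0.05)
  genomes <- community$genomes
  by_genus <- split(seq_along(genomes),
                    vapply(genomes, `[[`, character(1), "genus"))
  stopifnot(all(names(abundances) %in% names(by_genus)))
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    ids <- sprintf("read_%06d", seq_len(n_reads))
    reads <- character(n_reads)
    truth_rows <- vector("list", n_reads)
    genus_draw <- sample(names(abundances), n_reads, replace = TRUE,
                         prob = abundances)
    intergenic <- runif(n_reads) < intergenic_fraction
    for (i in seq_len(n_reads)) {
      if (intergenic[i]) {
        reads[i] <- paste(sample(bases, read_length, TRUE), collapse = "")
        next
      }
      g <- genus_draw[i]
      gi <- by_genus[[g]][sample.int(length(by_genus[[g]]), 1)]
      genome <- genomes[[gi]]
      lens <- nchar(genome$cds)
      ok <- which(lens >= read_length)
      if (length(ok) == 0L) stop("no coding sequence >= read length",
                                 call. = FALSE)
      ci <- ok[sample.int(length(ok), 1)]
      start <- sample.int(lens[ci] - read_length + 1L, 1)
      frag <- substr(genome$cds[ci], start, start + read_length - 1L)
      if (runif(1) < 0.5)
        frag <- paste(rev(strsplit(chartr("ACGT", "TGCA", frag), "")[[1]]),
                      collapse = "")
      if (error_rate > 0) {
        chars <- strsplit(frag, "")[[1]]
        err <- which(runif(read_length) < error_rate)
        for (p in err) chars[p] <- sample(setdiff(bases, chars[p]), 1)
        frag <- paste(chars, collapse = "")
      }
      reads[i] <- frag
      pid <- names(genome$cds)[ci]
      truth_rows[[i]] <- data.frame(
        read_id = ids[i], genus = g, species = genome$species,
        protein_id = pid, stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, truth_rows[!vapply(truth_rows, is.null,
                                               logical(1))])
    if (!is.null(db_proteins) && !is.null(truth)) {
      j <- match(truth$protein_id, db_proteins$protein_id)
      truth <- cbind(truth, db_proteins[j, path_cols, drop = FALSE])
      rownames(truth) <- NULL
    }
    list(reads = stats::setNames(reads, ids), truth = truth)
  })
}
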