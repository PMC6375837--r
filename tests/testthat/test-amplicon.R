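phred <- function(q, n = 1) strrep(intToUtf8(q + 33), n)

test_that("quality trimming clips terminal low-quality bases only", {
  rd <- tibble::tibble(
    sequence = c(strrep("A", 100), "ACGTCA", strrep("C", 36)),
    quality = c(phred(35, 100),
                paste0(phred(10, 2), phred(35, 3), phred(10, 1)),
                phred(30, 36)))
  out <- quality_trim(rd, q_threshold = 30, min_len = 36)
  # read 1 untouched; read 2 trimmed to 3 bases then discarded; read 3 kept
  # exactly at the boundary
  expect_equal(nrow(out), 2)
  expect_equal(attr(out, "n_discarded"), 1)
  expect_equal(out$sequence[1], strrep("A", 100))
  expect_equal(out$sequence[2], strrep("C", 36))
  # interior low-quality bases survive
  rd2 <- tibble::tibble(sequence = strrep("A", 40),
                        quality = paste0(phred(35, 20), phred(5, 2), phred(35, 18)))
  expect_equal(nchar(quality_trim(rd2)$sequence), 40)
  expect_error(quality_trim(tibble::tibble(sequence = "ACGT", quality = "II")),
               "length mismatch")
})

test_that("pair merging reconstructs a constructed fragment", {
  set.seed(31)
  amp <- paste(sample(c("A", "C", "G", "T"), 475, replace = TRUE), collapse = "")
  pr <- perfect_pair(amp, read_len = 300)
  m <- merge_pairs(pr)
  expect_equal(m$sequence, amp)
  expect_equal(m$overlap, 2 * 300 - 475)
})

test_that("pair merging enforces the overlap floor and consensus rule", {
  set.seed(32)
  left <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE), collapse = "")
  right <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE), collapse = "")
  ov <- paste(sample(c("A", "C", "G", "T"), 19, replace = TRUE), collapse = "")
  r1 <- paste0(left, ov)
  r2rc <- paste0(ov, right)
  r2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r2rc)))
  pr <- tibble::tibble(sample = "s", id = "x",
                       seq1 = r1, qual1 = phred(38, nchar(r1)),
                       seq2 = r2, qual2 = phred(38, nchar(r2)))
  # 19 nt true overlap at min_overlap 20: discarded
  expect_equal(nrow(merge_pairs(pr, min_overlap = 20)), 0)
  expect_equal(nrow(merge_pairs(pr, min_overlap = 19)), 1)
  # consensus: the higher-quality base wins and takes quality max
  ov25 <- strrep("ACGTA", 5)
  r1b <- paste0(left, ov25)
  ov_mm <- paste0("T", substr(ov25, 2, 25))  # one mismatch at overlap pos 1
  r2b <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(paste0(ov_mm, right))))
  prb <- tibble::tibble(
    sample = "s", id = "y",
    seq1 = paste0(left, ov25), qual1 = phred(40, nchar(r1b)),
    seq2 = r2b, qual2 = phred(20, nchar(r2b)))
  mb <- merge_pairs(prb, min_overlap = 20)
  expect_equal(substr(mb$sequence, 51, 51), "A")  # q40 base wins over q20 "T"
  expect_equal(substr(mb$quality, 51, 51), phred(40))
})

test_that("translation picks the longest stop-free run in six frames", {
  set.seed(33)
  aa <- random_protein_str(143)
  nt <- markerprobe:::back_translate(aa)  # 429 nt ORF -> 143 aa, kept
  expect_equal(translate_filter(nt), aa)
  expect_equal(nchar(translate_filter(markerprobe:::back_translate(
    random_protein_str(140)))), 140)
  expect_true(is.na(translate_filter(markerprobe:::back_translate(
    random_protein_str(139)))))
  # reverse-complemented ORF is still found
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
  expect_equal(translate_filter(rc), aa)
  # internal stops in every frame: discarded
  chopped <- paste(rep(c("TAA", "TAG"), 60), collapse = "")
  expect_true(is.na(translate_filter(chopped)))
})

test_that("dereplication preserves per-sample counts and sort order", {
  pr <- tibble::tibble(
    sample = c("s1", "s2", "s1", "s1", "s2"),
    sequence = c("PEPTIDE", "PEPTIDE", "MARKER", "MARKER", "MARKER"))
  u <- dereplicate(pr)
  expect_equal(u$sequence, c("MARKER", "PEPTIDE"))
  expect_equal(u$total, c(3L, 2L))
  cm <- attr(u, "counts")
  expect_equal(unname(cm[1, c("s1", "s2")]), c(2L, 1L))
  expect_equal(sum(cm), 5L)
})

test_that("greedy OTU clustering joins by abundance and drops singletons", {
  set.seed(34)
  a <- random_protein_str(150)
  b <- mutate_protein(a, 3)   # ~0.98 to a
  cc <- mutate_protein(a, 15) # ~0.90 to a
  lone <- random_protein_str(150)
  pr <- tibble::tibble(
    sample = "s1",
    sequence = c(rep(a, 100), b, rep(cc, 50), lone))
  otus <- greedy_otu_cluster(dereplicate(pr), identity = 0.97)
  # b joins a's OTU (0.98 >= 0.97), cc splits, singleton removed
  expect_equal(nrow(otus), 2)
  expect_equal(otus$size, c(101L, 50L))
  expect_equal(attr(otus, "n_singletons_removed"), 1)
  # at a 0.99 threshold the 0.98 pair splits (b then dies as a singleton)
  otus99 <- greedy_otu_cluster(dereplicate(pr), identity = 0.99)
  expect_equal(otus99$size, c(100L, 50L))
})

test_that("a genotype pair at exactly 0.98 identity collapses at 0.97 and splits at 0.99", {
  set.seed(35)
  a <- random_protein_str(100)
  b <- mutate_protein(a, 2)
  stopifnot(pairwise_identity(a, b) == 0.98)
  pr <- tibble::tibble(sample = "s1", sequence = c(rep(a, 10), rep(b, 5)))
  expect_equal(nrow(greedy_otu_cluster(dereplicate(pr), 0.97)), 1)
  expect_equal(nrow(greedy_otu_cluster(dereplicate(pr), 0.99)), 2)
})

test_that("constructed bimeras are flagged; near-copies and top OTUs are not", {
  set.seed(36)
  p1 <- random_protein_str(160)
  p2 <- mutate_protein(p1, 32)  # ~0.8 identity to p1
  bim <- paste0(substr(p1, 1, 80), substr(p2, 81, 160))
  near <- mutate_protein(p1, 1)
  pr <- tibble::tibble(sample = "s1",
                       sequence = c(rep(p1, 200), rep(p2, 180), rep(bim, 20),
                                    rep(near, 30)))
  otus <- greedy_otu_cluster(dereplicate(pr), identity = 0.97)
  flagged <- chimera_flag(otus)
  is_bim <- flagged$centroid == bim
  expect_true(any(is_bim))
  expect_true(flagged$chimera_flag[is_bim])
  # near-copy of a single parent: not flagged; most abundant OTU: never flagged
  expect_false(any(flagged$chimera_flag[!is_bim]))
})

test_that("OTU filtering applies the size boundary and reference screen", {
  set.seed(37)
  ref <- random_protein_str(158)
  junk <- random_protein_str(158)
  pr <- tibble::tibble(sample = "s1",
                       sequence = c(rep(ref, 500), rep(mutate_protein(ref, 8), 499),
                                    rep(junk, 600)))
  otus <- greedy_otu_cluster(dereplicate(pr), identity = 0.97)
  kept <- filter_otus(otus, refs = c(r1 = ref), min_size = 500)
  # size-499 OTU removed at the boundary; random-residue OTU fails the screen
  expect_equal(nrow(kept), 1)
  expect_equal(kept$centroid, ref)
  expect_true(kept$screen_pass)
  expect_error(filter_otus(otus, refs = character(0)), "non-empty")
})

test_that("clade assignment uses nearest reference, ties and novelty floor", {
  set.seed(38)
  rA <- random_protein_str(150)
  rB <- mutate_protein(rA, 40)
  far <- random_protein_str(150)
  clades <- tibble::tibble(reference = c("refA", "refB"), clade = c("I", "II"))
  pr <- tibble::tibble(sample = "s1", sequence = c(rep(rA, 10), rep(far, 10)))
  otus <- greedy_otu_cluster(dereplicate(pr), 0.97)
  got <- assign_clades(otus, c(refA = rA, refB = rB), clades,
                       novelty_floor = 0.75)
  expect_equal(got$clade[got$centroid == rA], "I")
  expect_equal(got$clade[got$centroid == far], "novel")
  # exact tie: two references in different clades at the same identity
  tie_refs <- c(zb = rA, za = rA)
  clades2 <- tibble::tibble(reference = c("zb", "za"), clade = c("II", "I"))
  otusA <- otus[otus$centroid == rA, ]
  attr(otusA, "counts") <- attr(otus, "counts")[otus$centroid == rA, , drop = FALSE]
  expect_warning(gotA <- assign_clades(otusA, tie_refs, clades2), "tie")
  expect_equal(gotA$clade, "I")  # lexicographically first label wins: "za"
  expect_error(assign_clades(otus, c(refA = rA, refX = rB), clades), "refX")
})

test_that("the OTU table conserves counts and handles absent OTUs", {
  set.seed(39)
  a <- random_protein_str(150); b <- mutate_protein(a, 20)
  pr <- tibble::tibble(sample = c(rep("s1", 6), rep("s2", 4)),
                       sequence = c(rep(a, 4), rep(b, 2), rep(a, 4)))
  otus <- greedy_otu_cluster(dereplicate(pr), 0.97)
  tbl <- build_otu_table(otus)
  m <- as.matrix(tbl[, -1]); rownames(m) <- tbl$sample
  expect_equal(unname(colSums(m)[otus$otu_id]), as.numeric(otus$size))
  expect_equal(unname(m["s2", otus$otu_id[otus$centroid == b]]), 0)
  expect_error(build_otu_table(otus, samples = c("s1", "s1")), "duplicate")
})

test_that("the read ledger balances and recovery works end to end (small)", {
  panel <- simulate_genotype_panel(5, seed = 41)
  comm <- simulate_community(names(panel$amplicons_aa), 4, seed = 42)
  reads <- simulate_reads(panel$amplicons_nt, comm$abundances,
                          reads_per_sample = NULL, reads_per_genotype = 300,
                          seed = 43)
  res <- run_amplicon_pipeline(reads, refs = panel$amplicons_aa, min_size = 100)
  sc <- setNames(res$stage_counts$n, res$stage_counts$stage)
  expect_equal(sc[["input_pairs"]],
               sum(sc[c("discarded_at_trim", "discarded_at_merge",
                        "discarded_at_translate", "member_of_unique")]))
  expect_equal(nrow(res$otus), 5)
  expect_setequal(res$otus$best_reference, names(panel$amplicons_aa))
  # error-free clade recovery: every OTU maps to its own genotype's clade
  expect_equal(res$otus$clade, res$otus$best_reference)
})
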