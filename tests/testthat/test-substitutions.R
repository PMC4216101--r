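test_that("radical/conservative classification follows the category tables", {
  expect_equal(classify_substitution("K", "R")$classification,
               "conservative")
  ke <- classify_substitution("K", "E")
  expect_equal(ke$classification, "radical")
  expect_true("charge" %in% ke$categories_changed)
  expect_error(classify_substitution("A", "A"), "not a substitution")
  expect_error(classify_substitution("A", "Z"), "nonstandard")
})

test_that("classification is symmetric and radical iff a category changes", {
  set.seed(4)
  aa20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  tabs <- physchem_tables()
  for (i in 1:40) {
    pair <- sample(aa20, 2)
    f <- classify_substitution(pair[1], pair[2], tabs)
    r <- classify_substitution(pair[2], pair[1], tabs)
    expect_equal(f$classification, r$classification)
    expect_setequal(f$categories_changed, r$categories_changed)
    expect_equal(f$classification == "radical",
                 length(f$categories_changed) > 0)
  }
})

test_that("substitution calling merges carriers and separates deletions", {
  aln <- coding_alignment(c(ref = "AAAAAAGGG",
                            t1 = "GAAAAAGGG",   # K1E
                            t2 = "GAAAAAGGG",   # K1E again
                            t3 = "AAA---GGG")) # deletion at 2
  res <- call_aa_substitutions(aln)
  expect_equal(nrow(res$substitutions), 1L)
  expect_equal(res$substitutions$position, 1L)
  expect_equal(res$substitutions$ref_aa, "K")
  expect_equal(res$substitutions$alt_aa, "E")
  expect_equal(res$substitutions$n_carriers, 2L)
  expect_equal(res$substitutions$carriers, "t1,t2")
  expect_equal(res$deletions$position, 2L)
  expect_equal(res$deletions$carriers, "t3")
})

test_that("identical subset yields no substitution records", {
  aln <- coding_alignment(c(ref = "ATGAAA", t1 = "ATGAAA"))
  res <- call_aa_substitutions(aln)
  expect_equal(nrow(res$substitutions), 0L)
  expect_equal(nrow(res$deletions), 0L)
  expect_equal(nrow(call_nt_substitutions(aln)), 0L)
})

test_that("substitution records match a direct per-column oracle", {
  set.seed(9)
  for (rep in 1:20) {
    seqs <- random_alignment(4, 10)
    names(seqs)[1] <- "ref"
    aln <- coding_alignment(seqs, reference = "ref")
    res <- call_aa_substitutions(aln)
    got <- sort(paste0(res$substitutions$position, ":",
                       res$substitutions$alt_aa))
    expect_identical(got, oracle_aa_records(as.list(seqs), "ref"))
  }
})

test_that("nt substitutions carry single-base-in-reference-context synonymy", {
  aln <- coding_alignment(c(ref = "AAAAAA", t1 = "AAGGAA"))
  nt <- call_nt_substitutions(aln)
  expect_equal(nrow(nt), 2L)
  # AAA->AAG both Lys: synonymous at nt 3; AAA->GAA K->E: nonsynonymous at 4
  expect_equal(nt$synonymy[nt$nt_position == 3], "synonymous")
  expect_equal(nt$synonymy[nt$nt_position == 4], "nonsynonymous")
  expect_equal(nt$codon_index, c(1L, 2L))
})

test_that("every nonsynonymous nt record has an AA record at its codon", {
  set.seed(21)
  for (rep in 1:10) {
    seqs <- random_alignment(4, 12)
    names(seqs)[1] <- "ref"
    aln <- coding_alignment(seqs, reference = "ref")
    nt <- call_nt_substitutions(aln)
    aa <- call_aa_substitutions(aln)$substitutions
    nonsyn_codons <- unique(nt$codon_index[nt$synonymy == "nonsynonymous"])
    ## multi-hit codons can in principle revert the AA; rare on random data,
    ## so require containment of AA-substituted codons instead both ways:
    expect_true(all(aa$position %in% nt$codon_index))
  }
})

test_that("per-region summaries count positions once and records per class", {
  topo <- topology_map(data.frame(
    region = c("Nterm", "rest"),
    class = c("extracellular", "intracellular"),
    start = c(1, 53), end = c(52, 100)))
  empty <- summarize_by_region(
    call_aa_substitutions(coding_alignment(
      c(ref = "ATGAAA", t1 = "ATGAAA")))$substitutions, topo)
  expect_true(all(empty$fraction == 0))

  recs <- data.frame(position = c(10L, 10L, 60L), ref_aa = c("K", "K", "A"),
                     alt_aa = c("E", "R", "P"), carriers = "t1",
                     n_carriers = 1L,
                     classification = c("radical", "conservative",
                                        "conservative"),
                     categories_changed = c("charge", "", ""))
  sm <- summarize_by_region(recs, topo)
  expect_equal(sm$n_substituted_positions, c(1L, 1L))
  expect_equal(sm$fraction[1], 1 / 52)
  expect_equal(sm$n_radical, c(1L, 0L))
  expect_equal(sm$n_conservative, c(1L, 1L))
  ## distinct positions sum across regions equals overall distinct positions
  expect_equal(sum(sm$n_substituted_positions),
               length(unique(recs$position)))
})

test_that("homology percentage uses the reference length denominator", {
  aln <- coding_alignment(c(ref = "AAAAAAGGGTTT", t1 = "AAAAAAGGGTTT",
                            t2 = "GAAAAAGGGTTT", t3 = "AAA---GGGTTT"))
  expect_equal(homology_percent(aln, "ref"), 100)
  expect_equal(homology_percent(aln, "t2"), 100 * 3 / 4)
  ## deletions count as mismatches
  expect_equal(homology_percent(aln, "t3"), 100 * 3 / 4)
  hp <- vapply(aln$taxa, function(tx) homology_percent(aln, tx), 0)
  expect_true(all(hp >= 0 & hp <= 100))
})

test_that("frequency classes assign conserved/genus-specific/high-frequency", {
  meta <- taxon_metadata(data.frame(
    taxon = c("ref", paste0("t", 1:6)),
    genus = c("Gref", "G1", "G1", "G2", "G3", "G4", "G5"),
    family = "F",
    group = c("out", rep("NWM", 6)),
    monogamy = FALSE))
  recs <- data.frame(
    position = c(1L, 2L, 3L),
    ref_aa = "K", alt_aa = c("E", "R", "Q"),
    carriers = c("t1,t2,t3,t4,t5,t6",  # all group taxa
                 "t1,t2",              # one genus (G1)
                 "t1,t3,t4,t5"),       # 4 of 5 genera
    n_carriers = c(6L, 2L, 4L),
    classification = "radical", categories_changed = "charge")
  fc <- frequency_classes(recs, meta, "NWM", threshold = 0.75)
  expect_equal(fc$freq_class, c("conserved", "genus-specific",
                                "high-frequency"))
  expect_equal(fc$genus_frequency, c(1, 1 / 5, 4 / 5))
  expect_error(frequency_classes(recs, meta, "NWM", threshold = 0),
               "threshold")
})

test_that("clade-diagnostic substitutions need all in-group, no out-group", {
  recs <- data.frame(
    position = c(5L, 6L, 7L),
    ref_aa = "A", alt_aa = c("P", "P", "P"),
    carriers = c("t1,t2", "t1,t2,t3", "t1"),
    n_carriers = c(2L, 3L, 1L),
    classification = "conservative", categories_changed = "")
  got <- group_specific_substitutions(recs, c("t1", "t2"), c("t3", "t4"))
  expect_equal(got$position, 5L)
  ## in-group = all carriers of record 2 -> taxon-conserved records only
  all_in <- group_specific_substitutions(recs, c("t1", "t2", "t3"),
                                         character(0))
  expect_equal(all_in$position, 6L)
  expect_error(group_specific_substitutions(recs, character(0), "t3"),
               "non-empty")
})
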