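test_that("codon site counts match the mutant-enumeration oracle", {
  cs <- codon_sites("TTT")
  expect_equal(cs$s_sites, 1 / 3)
  expect_equal(cs$n_sites, 8 / 3)
  ## Trp: all non-stop mutants are nonsynonymous under stop exclusion
  cs <- codon_sites("TGG")
  expect_equal(cs$s_sites, 0)
  expect_equal(cs$n_sites, 3)
  expect_error(codon_sites("TAA"), "stop")
  expect_error(codon_sites("T-A"), "gapped")
  gc_ <- genetic_code()
  for (cd in gc_$codons) {
    cs <- codon_sites(cd)
    orc <- oracle_sites(cd)
    expect_equal(cs$s_sites + cs$n_sites, 3)
    expect_equal(cs$s_sites, unname(orc["s"]))
  }
})

test_that("pathway differences average over minimal stop-free pathways", {
  expect_equal(count_pathway_differences("AAA", "AAA"), list(Nd = 0, Sd = 0))
  expect_equal(count_pathway_differences("AAA", "AAG"), list(Nd = 0, Sd = 1))
  pd <- count_pathway_differences("TTT", "GTA")
  expect_equal(pd$Nd, 1.5)
  expect_equal(pd$Sd, 0.5)
})

test_that("pathway counts equal exhaustive enumeration on random pairs", {
  set.seed(7)
  for (i in 1:60) {
    pr <- random_codons(2)
    got <- count_pathway_differences(pr[1], pr[2])
    orc <- suppressWarnings(oracle_pathways(pr[1], pr[2]))
    if (is.null(orc)) next
    expect_equal(got$Nd, unname(orc["Nd"]), tolerance = 1e-12)
    expect_equal(got$Sd, unname(orc["Sd"]), tolerance = 1e-12)
    expect_equal(got$Nd + got$Sd,
                 sum(strsplit(pr[1], "")[[1]] != strsplit(pr[2], "")[[1]]))
  }
})

test_that("pairwise dN/dS matches an independent NG86 reimplementation", {
  set.seed(13)
  a <- paste(random_codons(100), collapse = "")
  bv <- random_codons(100)
  av <- substring(a, seq(1, 298, 3), seq(3, 300, 3))
  keep <- runif(100) < 0.7   # 30% differing codons
  bv[keep] <- av[keep]
  b <- paste(bv, collapse = "")
  got <- pairwise_dnds(a, b)
  orc <- oracle_pairwise_dnds(a, b)
  expect_equal(got$N, orc$N, tolerance = 1e-10)
  expect_equal(got$S, orc$S, tolerance = 1e-10)
  expect_equal(got$Nd, orc$Nd, tolerance = 1e-10)
  expect_equal(got$Sd, orc$Sd, tolerance = 1e-10)
  expect_equal(got$dN, orc$dN, tolerance = 1e-10)
  expect_equal(got$dS, orc$dS, tolerance = 1e-10)
  ## symmetry
  rev <- pairwise_dnds(b, a)
  expect_equal(rev$dN, got$dN)
  expect_equal(rev$dS, got$dS)
})

test_that("identical sequences give zero divergence, undefined ratio", {
  s <- paste(rep("ATGAAA", 10), collapse = "")
  got <- pairwise_dnds(s, s)
  expect_equal(got$dN, 0)
  expect_equal(got$dS, 0)
  expect_true(is.na(got$ratio))
})

test_that("pS = 0 with pN > 0 flags the ratio undefined", {
  ## single nonsynonymous difference only
  a <- "AAAGGGTTT"
  b <- "GAAGGGTTT"
  got <- pairwise_dnds(a, b)
  expect_equal(got$dS, 0)
  expect_gt(got$dN, 0)
  expect_true(is.na(got$ratio))
})

test_that("Jukes-Cantor correction is monotone and saturates at 3/4", {
  p <- seq(0, 0.7, by = 0.05)
  d <- vapply(p, codonevo:::.jc_correct, 0)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= p - 1e-12))
  expect_error(codonevo:::.jc_correct(0.75), "saturation")
})

test_that("pooled estimate reduces to pairwise and is consistent", {
  set.seed(15)
  seqs <- random_alignment(2, 60)
  aln <- coding_alignment(seqs)
  pooled <- mean_dnds(aln)
  pw <- pairwise_dnds(seqs[[1]], seqs[[2]])
  expect_equal(pooled$dN, pw$dN)
  expect_equal(pooled$dS, pw$dS)
  ## pooling k copies of the same pair leaves the estimate unchanged
  seqs4 <- c(seqs, stats::setNames(seqs, c("t3", "t4")))
  aln4 <- coding_alignment(seqs4)
  pooled_dup <- mean_dnds(aln4, against = "t1",
                          taxa_subset = c("t2", "t4"))
  expect_equal(pooled_dup$dN, pw$dN, tolerance = 1e-12)
  expect_equal(pooled_dup$dS, pw$dS, tolerance = 1e-12)
})

test_that("pooled NG86 recovers the simulated omega under M0", {
  tree <- ape::read.tree(text = paste0(
    "(((a:0.08,b:0.08):0.05,(c:0.08,d:0.08):0.05):0.04,",
    "((e:0.08,f:0.08):0.05,(g:0.08,h:0.08):0.05):0.04);"))
  spec <- simulation_spec(tree = tree, n_codons = 400, kappa = 2, seed = 31,
                          site_omega_map = data.frame(start = 1, end = 400,
                                                      omega = 0.1))
  sim <- simulate_alignment(spec)
  est <- mean_dnds(sim$alignment)
  expect_equal(est$ratio, 0.1, tolerance = 0.5)   # within +-0.05 absolute
  expect_lt(abs(est$ratio - 0.1), 0.05)
})

test_that("sliding windows have the pinned count and localize planted omega", {
  ## window count: floor((L - w)/s) + 1
  set.seed(17)
  seqs <- random_alignment(3, 419, mut_rate = 0.1)
  aln <- coding_alignment(seqs)
  prof <- sliding_window_dnds(aln, window_len = 50, step = 10)
  expect_equal(nrow(prof$windows), 37L)
  expect_true(all(diff(prof$windows$midpoint) > 0))

  ## identical sequences: all zero, ratio undefined
  same <- coding_alignment(c(r = paste(rep("ATGAAA", 30), collapse = ""),
                             t = paste(rep("ATGAAA", 30), collapse = "")))
  p0 <- sliding_window_dnds(same, window_len = 10, step = 5)
  expect_true(all(p0$windows$dN == 0))
  expect_true(all(is.na(p0$windows$ratio)))

  ## planted high-omega region detected at the window peak
  tree <- ape::read.tree(text = "((a:0.15,b:0.15):0.1,(c:0.15,d:0.15):0.1);")
  som <- data.frame(start = c(1, 51), end = c(50, 300),
                    omega = c(3, 0.05))
  spec <- simulation_spec(tree = tree, n_codons = 300, kappa = 2, seed = 41,
                          site_omega_map = som)
  sim <- simulate_alignment(spec)
  prof <- sliding_window_dnds(sim$alignment, against = "a",
                              window_len = 50, step = 10)
  w <- prof$windows
  peak <- w$midpoint[which.max(ifelse(is.na(w$ratio), -Inf, w$ratio))]
  expect_lte(peak, 50)

  expect_error(sliding_window_dnds(aln, window_len = 1000), "exceeds")
})
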