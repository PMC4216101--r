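## helper: random nucleotide pair with controlled divergence
.rand_pair <- function(n, sub_rate, seed) {
  set.seed(seed)
  a <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  b <- a
  idx <- which(runif(n) < sub_rate)
  b[idx] <- vapply(b[idx], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}

test_that("T3P distance matches its closed form and reduces to K2P", {
  s <- paste(rep("ACGT", 100), collapse = "")
  expect_equal(t3p_distance(s, s), 0)

  ## direct closed-form check: construct a pair with known P, Q, theta
  ## 200 sites, GC content 0.4, 20 transitions, 10 transversions
  a <- c(rep("A", 60), rep("T", 60), rep("G", 40), rep("C", 40))
  b <- a
  b[1:20] <- "G"     # A->G transitions
  b[61:70] <- "G"    # T->G transversions
  P <- 20 / 200; Q <- 10 / 200
  theta <- (sum(a %in% c("G", "C")) + sum(b %in% c("G", "C"))) / 400
  h <- 2 * theta * (1 - theta)
  d_expected <- -h * log(1 - P / h - Q) - 0.5 * (1 - h) * log(1 - 2 * Q)
  expect_equal(t3p_distance(paste(a, collapse = ""),
                            paste(b, collapse = "")), d_expected,
               tolerance = 1e-12)

  ## gamma variant equals its closed form
  ashape <- 0.8
  dg_expected <- h * ashape * ((1 - P / h - Q)^(-1 / ashape) - 1) +
    0.5 * (1 - h) * ashape * ((1 - 2 * Q)^(-1 / ashape) - 1)
  expect_equal(t3p_distance(paste(a, collapse = ""),
                            paste(b, collapse = ""), gamma_shape = ashape),
               dg_expected, tolerance = 1e-12)

  ## theta = 0.5 reduces to Kimura 2-parameter (substitutions chosen to
  ## keep the pair's mean GC content exactly 0.5)
  a2 <- c(rep("A", 50), rep("T", 50), rep("G", 50), rep("C", 50))
  b2 <- a2
  b2[1:6] <- "G"        # A->G transitions (+6 GC)
  b2[101:106] <- "A"    # G->A transitions (-6 GC)
  b2[51:53] <- "A"      # T->A transversions (GC neutral)
  b2[7:10] <- "T"       # A->T transversions (GC neutral)
  P2 <- 12 / 200; Q2 <- 7 / 200
  k2p <- -0.5 * log(1 - 2 * P2 - Q2) - 0.25 * log(1 - 2 * Q2)
  expect_equal(t3p_distance(paste(a2, collapse = ""),
                            paste(b2, collapse = "")), k2p,
               tolerance = 1e-10)
})

test_that("T3P agrees with ape's T92 implementation", {
  pr <- .rand_pair(600, 0.12, seed = 23)
  m <- rbind(strsplit(pr$a, "")[[1]], strsplit(pr$b, "")[[1]])
  rownames(m) <- c("x", "y")
  expect_equal(t3p_distance(pr$a, pr$b),
               as.numeric(ape::dist.dna(ape::as.DNAbin(m), model = "T92")),
               tolerance = 1e-10)
  expect_equal(t3p_distance(pr$a, pr$b), t3p_distance(pr$b, pr$a))
})

test_that("three-taxon NJ solves the exact star equations", {
  dm <- matrix(c(0, 0.3, 0.4,
                 0.3, 0, 0.5,
                 0.4, 0.5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_build(dm)
  d <- ape::cophenetic.phylo(tr)[c("a", "b", "c"), c("a", "b", "c")]
  expect_equal(unname(d), unname(dm), tolerance = 1e-10)
})

test_that("NJ recovers the generating topology from additive matrices", {
  for (seed in 1:50) {
    set.seed(seed)
    n <- sample(4:8, 1)
    tr <- ape::rtree(n)
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.5)
    dm <- ape::cophenetic.phylo(tr)
    est <- nj_build(dm)
    expect_equal(ape::dist.topo(ape::unroot(tr), est), 0,
                 ignore_attr = TRUE)
    ## cross-check against ape's NJ
    expect_equal(ape::dist.topo(ape::nj(stats::as.dist(dm)), est), 0,
                 ignore_attr = TRUE)
    ## additive matrices are reproduced exactly
    rec <- ape::cophenetic.phylo(est)[rownames(dm), colnames(dm)]
    expect_lt(max(abs(rec - dm)), 1e-8)
  }
})

test_that("NJ is deterministic under ties and input order", {
  dm <- matrix(0.4, 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  diag(dm) <- 0
  t1 <- nj_build(dm)
  t2 <- nj_build(dm)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  perm <- c("c", "a", "d", "b")
  t3 <- nj_build(dm[perm, perm])
  expect_equal(ape::dist.topo(t1, t3), 0, ignore_attr = TRUE)
  expect_error(nj_build(dm[1:2, 1:2]), ">= 3 taxa")
})

test_that("bootstrap supports are seeded, reproducible and find real splits", {
  ## two clearly separated clades: long internal branch
  tree <- ape::read.tree(
    text = "((a:0.05,b:0.05):0.4,(c:0.05,d:0.05):0.4);")
  spec <- simulation_spec(tree = tree, n_codons = 200, kappa = 2,
                          seed = 51,
                          site_omega_map = data.frame(start = 1, end = 200,
                                                      omega = 0.5))
  sim <- simulate_alignment(spec)
  bs1 <- bootstrap_support(sim$alignment, n_reps = 100, seed = 7)
  bs2 <- bootstrap_support(sim$alignment, n_reps = 100, seed = 7)
  expect_identical(bs1$node.label, bs2$node.label)
  sup <- suppressWarnings(as.numeric(bs1$node.label))
  expect_true(all(sup[!is.na(sup)] >= 95))

  ## supports invariant under taxon-order permutation of the alignment
  perm <- c("c", "a", "d", "b")
  aln_p <- coding_alignment(sim$alignment$sequences[perm],
                            reference = "c")
  bs3 <- bootstrap_support(aln_p, n_reps = 100, seed = 7)
  s1 <- sort(suppressWarnings(as.numeric(bs1$node.label)))
  s3 <- sort(suppressWarnings(as.numeric(bs3$node.label)))
  expect_identical(s1, s3)
})

test_that("outgroup rooting bisects the outgroup pendant edge", {
  tree <- ape::read.tree(text = "((a:0.1,b:0.2):0.05,c:0.3,out:0.6);")
  rooted <- root_with_outgroup(tree, "out")
  expect_true(ape::is.rooted(rooted))
  root_node <- ape::Ntip(rooted) + 1L
  kids <- rooted$edge[rooted$edge[, 1] == root_node, 2]
  expect_equal(length(kids), 2L)
  tip <- which(rooted$tip.label == "out")
  e <- which(rooted$edge[, 2] == tip & rooted$edge[, 1] == root_node)
  expect_equal(rooted$edge.length[e], 0.3)
  ## rooting again with the same outgroup keeps the topology
  again <- root_with_outgroup(rooted, "out")
  expect_equal(ape::dist.topo(ape::unroot(again), ape::unroot(rooted)), 0,
               ignore_attr = TRUE)
  expect_error(root_with_outgroup(tree, "zz"), "unknown")
})
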