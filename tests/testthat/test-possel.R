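gc61 <- genetic_code()
pi_u <- rep(1 / 61, 61)

test_that("the GY94 generator has the pinned structural properties", {
  set.seed(5)
  pi_r <- as.numeric(stats::rgamma(61, 2)); pi_r <- pi_r / sum(pi_r)
  Q <- gy94_rate_matrix(kappa = 2.5, omega = 0.4, pi = pi_r)
  expect_lt(max(abs(rowSums(Q))), 1e-12)
  ## mean rate scaled to one
  expect_equal(-sum(pi_r * diag(Q)), 1, tolerance = 1e-12)
  ## detailed balance (time reversibility): diag(pi) Q is symmetric
  M <- pi_r * Q
  expect_lt(max(abs(M - t(M))), 1e-14)
  ## no multi-position changes
  st <- codonevo:::.gy94_structure(gc61)
  expect_true(all(Q[!st$single & !diag(61)] == 0))
  ## omega = 0 removes all nonsynonymous flow
  Q0 <- gy94_rate_matrix(2.5, 0, pi_r, scale = FALSE)
  expect_true(all(Q0[st$single & !st$synonymous] == 0))
})

test_that("transition probabilities are stochastic and stationary", {
  Q <- gy94_rate_matrix(2, 0.3, pi_u)
  P0 <- transition_probabilities(Q, 0, pi_u)
  expect_equal(unname(P0), diag(61), tolerance = 1e-10)
  for (t_ in c(0.05, 0.7, 3)) {
    P <- transition_probabilities(Q, t_, pi_u)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
    expect_true(all(P >= 0))
    expect_lt(max(abs(as.numeric(pi_u %*% P) - pi_u)), 1e-10)
  }
})

test_that("pruning equals the two-taxon brute-force sum", {
  tree <- ape::read.tree(text = "(A:0.3,B:0.2);")
  spec <- simulation_spec(tree = tree, n_codons = 25, kappa = 2, seed = 5,
                          site_omega_map = data.frame(start = 1, end = 25,
                                                      omega = 0.2))
  sim <- simulate_alignment(spec)
  ll <- alignment_loglik(sim$alignment, tree, 2,
                         data.frame(omega = 0.2, prob = 1), pi_u)
  Q <- gy94_rate_matrix(2, 0.2, pi_u)
  P1 <- transition_probabilities(Q, 0.3, pi_u)
  P2 <- transition_probabilities(Q, 0.2, pi_u)
  cods <- function(tx) match(
    substring(sim$alignment$sequences[[tx]], seq(1, 73, 3), seq(3, 75, 3)),
    gc61$codons)
  sA <- cods("A"); sB <- cods("B")
  bf <- sum(log(vapply(seq_along(sA), function(s)
    sum(pi_u * P1[, sA[s]] * P2[, sB[s]]), 0)))
  expect_equal(ll, bf, tolerance = 1e-8)

  ## identical codons at t = 0 give site likelihood pi_c
  tiny <- coding_alignment(c(A = "ATG", B = "ATG"))
  t0 <- ape::read.tree(text = "(A:0,B:0);")
  ll0 <- alignment_loglik(tiny, t0, 2, data.frame(omega = 1, prob = 1),
                          pi_u)
  expect_equal(ll0, log(pi_u[match("ATG", gc61$codons)]),
               tolerance = 1e-10)
})

test_that("likelihood is invariant under re-rooting (reversibility)", {
  tree <- ape::read.tree(
    text = "((a:0.1,b:0.15):0.05,(c:0.2,d:0.1):0.08);")
  spec <- simulation_spec(tree = tree, n_codons = 40, kappa = 2, seed = 9,
                          site_omega_map = data.frame(start = 1, end = 40,
                                                      omega = 0.5))
  sim <- simulate_alignment(spec)
  cl <- data.frame(omega = c(0.1, 1.5), prob = c(0.7, 0.3))
  ll1 <- alignment_loglik(sim$alignment, tree, 2, cl, pi_u)
  rer <- ape::root(ape::unroot(tree), outgroup = "c", resolve.root = TRUE)
  ll2 <- alignment_loglik(sim$alignment, rer, 2, cl, pi_u)
  expect_equal(ll1, ll2, tolerance = 1e-8)
})

test_that("M8-family class discretization is an equal-probability grid", {
  cl <- m8_classes(0.85, 0.6, 1.8, 2.5, n_classes = 10)
  expect_equal(nrow(cl), 11L)
  expect_equal(sum(cl$prob), 1)
  expect_equal(cl$omega[11], 2.5)
  expect_equal(cl$prob[11], 0.15)
  expect_true(all(diff(cl$omega[1:10]) > 0))
  expect_true(all(cl$omega[1:10] >= 0 & cl$omega[1:10] <= 1))
  ## medians of equal-probability deciles
  expect_equal(cl$omega[1], stats::qbeta(0.05, 0.6, 1.8))
})

test_that("the LRT uses the boundary-mixture null", {
  f8 <- structure(list(model = "M8", lnL = -100), class = "site_model_fit")
  f8a <- structure(list(model = "M8a", lnL = -101.355),
                   class = "site_model_fit")
  lrt <- lrt_m8_m8a(f8, f8a)
  expect_equal(lrt$statistic, 2.71, tolerance = 1e-6)
  expect_equal(lrt$p_value, 0.05, tolerance = 0.01)
  same <- lrt_m8_m8a(structure(list(model = "M8", lnL = -100),
                               class = "site_model_fit"),
                     structure(list(model = "M8a", lnL = -100),
                               class = "site_model_fit"))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 0.5)
  expect_warning(
    lrt_m8_m8a(structure(list(model = "M8", lnL = -100.5),
                         class = "site_model_fit"),
               structure(list(model = "M8a", lnL = -100),
                         class = "site_model_fit")), "clamped")
})

test_that("M0 fitting recovers simulated kappa and omega", {
  tree <- ape::read.tree(text = paste0(
    "(((a:0.1,b:0.1):0.06,(c:0.1,d:0.1):0.06):0.04,",
    "((e:0.1,f:0.1):0.06,(g:0.1,h:0.1):0.06):0.04);"))
  spec <- simulation_spec(tree = tree, n_codons = 300, kappa = 2, seed = 61,
                          site_omega_map = data.frame(start = 1, end = 300,
                                                      omega = 0.3))
  sim <- simulate_alignment(spec)
  nj <- nj_build(t3p_distance_matrix(sim$alignment))
  m0 <- fit_m0(sim$alignment, nj, seed = 1, restarts = 1,
               branch_passes = 0)
  expect_gte(m0$omega, 0.2)
  expect_lte(m0$omega, 0.4)
  expect_lt(abs(m0$kappa - 2) / 2, 0.3)
})

test_that("NEB class posteriors are proper and site-order equivariant", {
  tree <- ape::read.tree(text = "((a:0.2,b:0.2):0.1,(c:0.2,d:0.2):0.1);")
  spec <- simulation_spec(tree = tree, n_codons = 60, kappa = 2, seed = 71,
                          site_omega_map = data.frame(start = 1, end = 60,
                                                      omega = 0.5))
  sim <- simulate_alignment(spec)
  cl <- m8_classes(0.8, 0.5, 1.5, 3, n_classes = 4)
  res <- alignment_loglik(sim$alignment, tree, 2, cl, pi_u, by_site = TRUE)
  expect_lt(max(abs(colSums(res$class_posterior) - 1)), 1e-10)

  ## permuting codon columns permutes posteriors identically
  perm <- sample(60)
  aln_p <- resample_codons(sim$alignment, perm)
  res_p <- alignment_loglik(aln_p, tree, 2, cl, pi_u, by_site = TRUE)
  expect_equal(res_p$class_posterior[nrow(cl), ],
               res$class_posterior[nrow(cl), perm], tolerance = 1e-10)
})
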