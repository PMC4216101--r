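## Maximum-likelihood fitting of GY94 site models (M0, M8, M8a), the
## M8-vs-M8a likelihood-ratio test for positive selection, and naive
## empirical Bayes site identification.
##
## Optimization is derivative-free (Nelder-Mead) on log/logit-transformed
## parameters with seeded multi-start. Branch lengths are optimized under M0
## (a global scale followed by per-branch coordinate passes) and held fixed
## for the site-heterogeneous models, as is conventional for nested
## site-model comparisons on a shared tree.

.logit <- function(p) log(p / (1 - p))
.inv_logit <- function(x) 1 / (1 + exp(-x))

#' Discretize an M8-family omega distribution
#'
#' The M8 family places probability `p0` on a Beta(p, q) distribution over
#' `[0, 1]`, discretized into `n_classes` equal-probability classes at their
#' medians, plus probability `1 - p0` on a point mass at `omega_s` (`>= 1`
#' for M8, `== 1` for M8a).
#'
#' @param p0 Weight of the beta component, in `[0, 1]`.
#' @param p,q Beta shape parameters (> 0).
#' @param omega_s Omega of the extra class.
#' @param n_classes Number of beta discretization classes.
#' @return Data frame with columns `omega`, `prob`; the last row is the
#'   `omega_s` class.
#' @export
m8_classes <- function(p0, p, q, omega_s, n_classes = 10L) {
  stopifnot(p0 >= 0, p0 <= 1, p > 0, q > 0, omega_s >= 0)
  k <- seq_len(n_classes)
  ## floor: a class at omega exactly 0 zeroes the likelihood of any site
  ## with an observed nonsynonymous difference
  om <- pmax(stats::qbeta((k - 0.5) / n_classes, p, q), 1e-8)
  data.frame(omega = c(om, omega_s),
             prob = c(rep(p0 / n_classes, n_classes), 1 - p0))
}

## Shared multi-start Nelder-Mead driver on transformed parameters.
## `starts` may hold several deterministic start vectors; additional random
## restarts jitter the first start.
.ml_optimize <- function(objective, starts, restarts, seed, maxit,
                         jitter_sd = 0.5) {
  if (!is.list(starts)) starts <- list(starts)
  set.seed(seed)
  n_extra <- max(restarts - length(starts), 0L)
  starts <- c(starts, lapply(seq_len(n_extra), function(i)
    starts[[1]] + stats::rnorm(length(starts[[1]]), sd = jitter_sd)))
  starts <- starts[seq_len(max(restarts, 1L))]
  best <- NULL
  for (s0 in starts) {
    fit <- tryCatch(
      stats::optim(s0, objective, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = 1e-9)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("optimizer failed in all ", length(starts), " starts")
  best
}

#' Fit the one-ratio M0 codon model
#'
#' Maximizes the GY94 likelihood over kappa, a single omega, and the branch
#' lengths (global tree scale jointly with kappa/omega, then per-branch
#' coordinate passes).
#'
#' @param aln A [coding_alignment()].
#' @param tree `ape::phylo` with initial branch lengths; nucleotide-scale
#'   distances (e.g. from [nj_build()] on [t3p_distance_matrix()]) are
#'   converted to per-codon lengths internally when `codon_scale = 3`.
#' @param pi Equilibrium frequencies; default F3x4 from the alignment.
#' @param code A [genetic_code()].
#' @param seed Integer seed for the multi-start optimizer.
#' @param restarts Number of optimizer starts.
#' @param branch_passes Per-branch coordinate optimization passes after the
#'   joint fit (0 to disable).
#' @param maxit Nelder-Mead iteration cap per start.
#' @param codon_scale Multiplier applied to the input branch lengths to
#'   convert them to expected substitutions per codon.
#' @return Object of class `site_model_fit`: `model`, `lnL`, `kappa`,
#'   `omega`, `classes`, `pi`, `tree` (branch lengths as fitted), plus
#'   optimizer metadata.
#' @export
fit_m0 <- function(aln, tree, pi = NULL, code = genetic_code(), seed = 1L,
                   restarts = 2L, branch_passes = 1L, maxit = 300L,
                   codon_scale = 3) {
  if (is.null(pi)) pi <- codon_frequencies(aln, code)
  tree <- stats::reorder(tree, "postorder")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  tree$edge.length <- pmax(tree$edge.length * codon_scale, 1e-6)
  obj <- function(par) {
    if (any(!is.finite(par)) || any(abs(par) > 30)) return(1e10)
    kappa <- exp(par[1]); omega <- exp(par[2]); scale <- exp(par[3])
    tr <- tree; tr$edge.length <- tree$edge.length * scale
    tryCatch(-alignment_loglik(aln, tr, kappa,
                               data.frame(omega = omega, prob = 1),
                               pi, code),
             error = function(e) 1e10)
  }
  best <- .ml_optimize(obj, c(log(2), log(0.3), 0), restarts, seed, maxit)
  kappa <- exp(best$par[1]); omega <- exp(best$par[2])
  tree$edge.length <- tree$edge.length * exp(best$par[3])
  lnL <- -best$value
  ## per-branch coordinate passes
  for (pass in seq_len(branch_passes)) {
    for (e in seq_along(tree$edge.length)) {
      f <- function(t_) {
        tr <- tree; tr$edge.length[e] <- t_
        -alignment_loglik(aln, tr, kappa,
                          data.frame(omega = omega, prob = 1), pi, code)
      }
      op <- stats::optimize(f, c(1e-8, max(5, 3 * tree$edge.length[e])),
                            tol = 1e-4)
      if (-op$objective >= lnL) {
        tree$edge.length[e] <- op$minimum
        lnL <- -op$objective
      }
    }
    ## refresh kappa/omega at the new branch lengths
    obj2 <- function(par) {
      -alignment_loglik(aln, tree, exp(par[1]),
                        data.frame(omega = exp(par[2]), prob = 1), pi, code)
    }
    b2 <- stats::optim(c(log(kappa), log(omega)), obj2,
                       method = "Nelder-Mead",
                       control = list(maxit = maxit, reltol = 1e-10))
    if (-b2$value >= lnL) {
      kappa <- exp(b2$par[1]); omega <- exp(b2$par[2]); lnL <- -b2$value
    }
  }
  structure(list(model = "M0", lnL = lnL, kappa = kappa, omega = omega,
                 classes = data.frame(omega = omega, prob = 1),
                 pi = pi, tree = tree, seed = seed),
            class = "site_model_fit")
}

.fit_m8_family <- function(aln, tree, omega_s_free, pi, code, seed,
                           restarts, n_classes, maxit) {
  if (is.null(pi)) pi <- codon_frequencies(aln, code)
  tree <- stats::reorder(tree, "postorder")
  mk_classes <- function(par) {
    p0 <- .inv_logit(par[2]); p <- exp(par[3]); q <- exp(par[4])
    ws <- if (omega_s_free) 1 + exp(par[5]) else 1
    m8_classes(p0, p, q, ws, n_classes)
  }
  obj <- function(par) {
    if (any(!is.finite(par)) || any(abs(par) > 30)) return(1e10)
    cl <- mk_classes(par)
    tryCatch(-alignment_loglik(aln, tree, exp(par[1]), cl, pi, code),
             error = function(e) 1e10)
  }
  base <- c(log(2), .logit(0.9), log(0.5), log(1.5))
  starts <- if (omega_s_free) {
    ## spread omega_s starts (1.5, 3, 6): the selection-class weight is
    ## prone to a local optimum at the omega_s = 1 boundary
    lapply(log(c(2, 0.5, 5)), function(w5) c(base, w5))
  } else {
    list(base)
  }
  best <- .ml_optimize(obj, starts, restarts, seed, maxit)
  par <- best$par
  kappa <- exp(par[1]); p0 <- .inv_logit(par[2])
  p <- exp(par[3]); q <- exp(par[4])
  omega_s <- if (omega_s_free) 1 + exp(par[5]) else 1
  classes <- m8_classes(p0, p, q, omega_s, n_classes)
  structure(list(model = if (omega_s_free) "M8" else "M8a",
                 lnL = -best$value, kappa = kappa, p0 = p0, p = p, q = q,
                 omega_s = omega_s, classes = classes, pi = pi,
                 tree = tree, n_classes = n_classes, seed = seed),
            class = "site_model_fit")
}

#' Fit the M8 site model (beta plus a free omega >= 1 class)
#'
#' Branch lengths of `tree` are taken as-is (fit them under M0 first, e.g.
#' `fit_m8(aln, fit_m0(aln, nj_tree)$tree, codon_scale = 1)` — the usual
#' workflow passes the M0-fitted tree, already on the per-codon scale).
#'
#' @inheritParams fit_m0
#' @param n_classes Beta discretization classes (default 10).
#' @return A `site_model_fit` with elements `p0`, `p`, `q`, `omega_s`.
#' @export
fit_m8 <- function(aln, tree, pi = NULL, code = genetic_code(), seed = 1L,
                   restarts = 3L, n_classes = 10L, maxit = 500L) {
  .fit_m8_family(aln, tree, TRUE, pi, code, seed, restarts, n_classes,
                 maxit)
}

#' Fit the M8a null model (beta plus a fixed omega = 1 class)
#'
#' @inheritParams fit_m8
#' @return A `site_model_fit` with `omega_s = 1`.
#' @export
fit_m8a <- function(aln, tree, pi = NULL, code = genetic_code(), seed = 1L,
                    restarts = 3L, n_classes = 10L, maxit = 500L) {
  .fit_m8_family(aln, tree, FALSE, pi, code, seed, restarts, n_classes,
                 maxit)
}

#' @export
print.site_model_fit <- function(x, ...) {
  cat("GY94 ", x$model, " fit: lnL = ", sprintf("%.4f", x$lnL),
      ", kappa = ", sprintf("%.3f", x$kappa), sep = "")
  if (x$model == "M0") cat(", omega =", sprintf("%.4f", x$omega))
  else cat(sprintf(", p0 = %.3f, beta(%.3f, %.3f), omega_s = %.3f",
                   x$p0, x$p, x$q, x$omega_s))
  cat("\n")
  invisible(x)
}

#' Likelihood-ratio test of M8 against M8a
#'
#' The statistic is `2 (lnL_M8 - lnL_M8a)`, clamped to zero with a warning
#' if negative (an optimizer artifact under nesting). Because omega_s = 1
#' lies on the boundary of the M8 parameter space, the null distribution is
#' the 50:50 mixture of a point mass at zero and chi-square(1); the reported
#' p-value is `0.5 * P(chisq_1 >= statistic)` (so p = 0.5 at statistic 0).
#' `mixture = FALSE` gives the plain chi-square(1) p-value for comparison
#' with tools that use it.
#'
#' @param fit8 A `site_model_fit` from [fit_m8()].
#' @param fit8a A `site_model_fit` from [fit_m8a()].
#' @param mixture Use the boundary-null mixture (default TRUE).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
lrt_m8_m8a <- function(fit8, fit8a, mixture = TRUE) {
  if (!identical(fit8$model, "M8") || !identical(fit8a$model, "M8a"))
    stop("expected an M8 fit and an M8a fit")
  stat <- 2 * (fit8$lnL - fit8a$lnL)
  if (stat < 0) {
    warning("negative LRT statistic (", signif(stat, 4), ") clamped to 0")
    stat <- 0
  }
  p <- if (mixture) 0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE)
       else stats::pchisq(stat, df = 1, lower.tail = FALSE)
  list(statistic = stat, df = 1L, p_value = p)
}

#' Naive empirical Bayes positively selected sites
#'
#' Evaluates, at the maximum-likelihood estimates of an M8-family fit, the
#' per-site posterior probability of the selection class (the omega_s
#' component) and returns the sites exceeding `threshold`, in reference
#' amino-acid coordinates.
#'
#' @param fit A `site_model_fit` from [fit_m8()] (or [fit_m8a()]).
#' @param aln The [coding_alignment()] the model was fitted to.
#' @param threshold Posterior cutoff (default 0.95).
#' @param code A [genetic_code()].
#' @return Data frame `site` (reference AA position), `posterior`,
#'   `omega_class` for sites above threshold; attribute `"posterior_all"`
#'   holds the full per-site posterior vector.
#' @export
neb_sites <- function(fit, aln, threshold = 0.95, code = genetic_code()) {
  if (!fit$model %in% c("M8", "M8a"))
    stop("NEB site identification needs an M8-family fit")
  res <- alignment_loglik(aln, fit$tree, fit$kappa, fit$classes, fit$pi,
                          code, by_site = TRUE)
  post_sel <- res$class_posterior[nrow(fit$classes), ]
  coords <- .reference_coordinates(aln)
  ref_pos <- coords$ref_pos
  sel <- which(post_sel > threshold & !is.na(ref_pos))
  out <- data.frame(site = ref_pos[sel], posterior = post_sel[sel],
                    omega_class = rep(fit$classes$omega[nrow(fit$classes)],
                                      length(sel)))
  out <- out[order(out$site), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "posterior_all") <- post_sel
  out
}
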