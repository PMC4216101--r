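## Felsenstein pruning likelihood for GY94 site-mixture models.
##
## Site-class mixtures (M0 is the one-class special case) share the tree
## and kappa; each class has its own omega and prior weight. Per-site class
## log-likelihoods are combined by log-sum-exp, and per-node scaling keeps
## partials in range on large trees.

## Integer codon states per taxon x site; NA = gap/missing.
.codon_states <- function(aln, code) {
  S <- n_codons(aln)
  st <- matrix(NA_integer_, nrow = length(aln$taxa), ncol = S,
               dimnames = list(aln$taxa, NULL))
  for (tx in aln$taxa)
    st[tx, ] <- codon_index(split_codons(aln$sequences[[tx]]), code)
  st
}

## Per-class site log-likelihood vectors by pruning.
## tree must be an ape phylo with edge.length set; leaves = rownames(states).
.prune_class <- function(states, tree, P_edges, pi) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  S <- ncol(states)
  edge <- tree$edge
  tip_state <- states[tree$tip.label, , drop = FALSE]
  partial <- vector("list", nnode)
  lsc <- vector("list", nnode)
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1L]; ch <- edge[e, 2L]
    P <- P_edges[[e]]
    if (ch <= ntip) {
      stv <- tip_state[ch, ]
      msg <- matrix(1, nrow(P), S)
      ok <- !is.na(stv)
      msg[, ok] <- P[, stv[ok]]
      msg_lsc <- numeric(S)
    } else {
      p <- partial[[ch]]
      mx <- apply(p, 2L, max)
      if (any(mx <= 0))
        stop("zero partial likelihood at site ", which(mx <= 0)[1])
      p <- sweep(p, 2L, mx, "/")
      msg <- P %*% p
      msg_lsc <- lsc[[ch]] + log(mx)
    }
    if (is.null(partial[[par]])) {
      partial[[par]] <- msg
      lsc[[par]] <- msg_lsc
    } else {
      partial[[par]] <- partial[[par]] * msg
      lsc[[par]] <- lsc[[par]] + msg_lsc
    }
  }
  root <- edge[nrow(edge), 1L]
  sl <- as.numeric(pi %*% partial[[root]])
  if (any(sl <= 0))
    stop("zero site likelihood at site ", which(sl <= 0)[1])
  log(sl) + lsc[[root]]
}

#' Log-likelihood of an alignment under a GY94 site-mixture model
#'
#' Computes the Felsenstein-pruning log-likelihood of a codon alignment on a
#' tree under a mixture of GY94 classes sharing kappa and pi. Gap codons are
#' missing data (all-ones partials). `classes` is a data frame with columns
#' `omega` and `prob` (summing to 1); a single row gives the one-ratio M0
#' model.
#'
#' @param aln A [coding_alignment()].
#' @param tree `ape::phylo` with branch lengths in expected substitutions
#'   per codon; tip labels must equal the alignment taxa.
#' @param kappa Transition/transversion ratio.
#' @param classes Data frame of mixture classes (`omega`, `prob`).
#' @param pi Equilibrium codon frequencies.
#' @param code A [genetic_code()].
#' @param by_site If `TRUE`, also return the per-site log-likelihoods and
#'   per-site class posterior probabilities.
#' @return The total log-likelihood (numeric); with `by_site = TRUE`, a list
#'   `lnL`, `site_loglik`, `class_posterior` (classes x sites).
#' @export
alignment_loglik <- function(aln, tree, kappa, classes, pi,
                             code = genetic_code(), by_site = FALSE) {
  if (!setequal(tree$tip.label, aln$taxa))
    stop("tree tips and alignment taxa differ")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (abs(sum(classes$prob) - 1) > 1e-8)
    stop("class probabilities must sum to 1")
  tree <- stats::reorder(tree, "postorder")
  states <- .codon_states(aln, code)
  K <- nrow(classes)
  S <- n_codons(aln)
  class_ll <- matrix(NA_real_, K, S)
  eigs <- .mixture_eigens(kappa, classes, pi, code)
  for (k in seq_len(K)) {
    P_edges <- lapply(tree$edge.length, function(t_)
      .p_from_eigen(eigs[[k]], max(t_, 0)))
    class_ll[k, ] <- .prune_class(states, tree, P_edges, pi)
  }
  lw <- log(classes$prob)
  m <- apply(class_ll + lw, 2L, max)
  site_ll <- m + log(colSums(exp(sweep(class_ll + lw, 2L, m, "-"))))
  if (!by_site) return(sum(site_ll))
  post <- exp(sweep(class_ll + lw, 2L, site_ll, "-"))
  list(lnL = sum(site_ll), site_loglik = site_ll, class_posterior = post)
}

## Class generators under joint scaling: the unscaled GY94 matrices are
## divided by the mixture-average rate, so branch lengths are expected
## substitutions per codon averaged over classes while high-omega classes
## keep their faster absolute rate (the convention of codeml site models).
.mixture_eigens <- function(kappa, classes, pi, code) {
  Qs <- lapply(classes$omega, function(w)
    gy94_rate_matrix(kappa, w, pi, code, scale = FALSE))
  mu <- vapply(Qs, function(Q) -sum(pi * diag(Q)), 0)
  rho <- sum(classes$prob * mu)
  if (rho <= 0) rho <- 1
  lapply(Qs, function(Q) .gy94_eigen(Q / rho, pi))
}

.p_from_eigen <- function(eg, t_) {
  P <- eg$left %*% (exp(eg$values * t_) * eg$right)
  P[P < 0] <- 0
  P / rowSums(P)
}
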