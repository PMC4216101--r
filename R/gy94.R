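## Goldman-Yang (1994) codon substitution model: equilibrium frequencies,
## rate matrix construction and transition probabilities.
##
## All 61-state objects are ordered as genetic_code()$codons. The generator
## is scaled so the mean substitution rate at stationarity is one, making
## branch lengths expected substitutions per codon.

## Precompute, for the 61 sense codons, which pairs differ at exactly one
## position and whether the change is a transition and/or synonymous.
.gy94_structure <- function(code) {
  cache <- .codonevo_cache
  if (!is.null(cache$gy94) && identical(cache$gy94_codons, code$codons))
    return(cache$gy94)
  n <- length(code$codons)
  mat <- matrix(strsplit(paste(code$codons, collapse = ""), "")[[1]],
                nrow = n, byrow = TRUE)
  single <- matrix(FALSE, n, n)
  transition <- matrix(FALSE, n, n)
  synonymous <- matrix(FALSE, n, n)
  is_ts <- function(a, b) (a %in% c("A", "G")) == (b %in% c("A", "G"))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- which(mat[i, ] != mat[j, ])
    if (length(d) != 1L) next
    single[i, j] <- single[j, i] <- TRUE
    ts <- is_ts(mat[i, d], mat[j, d])
    transition[i, j] <- transition[j, i] <- ts
    syn <- code$aa[i] == code$aa[j]
    synonymous[i, j] <- synonymous[j, i] <- syn
  }
  cache$gy94 <- list(single = single, transition = transition,
                     synonymous = synonymous)
  cache$gy94_codons <- code$codons
  cache$gy94
}

#' F3x4 equilibrium codon frequencies from an alignment
#'
#' Estimates position-specific nucleotide frequencies over the three codon
#' positions, forms products for each sense codon, and renormalizes over the
#' 61 sense codons.
#'
#' @param aln A [coding_alignment()].
#' @param code A [genetic_code()].
#' @param method `"f3x4"` (default), `"f61"` (observed codon frequencies,
#'   with a pseudocount) or `"uniform"`.
#' @return Numeric vector of length 61 summing to 1, named by codon.
#' @export
codon_frequencies <- function(aln, code = genetic_code(),
                              method = c("f3x4", "f61", "uniform")) {
  method <- match.arg(method)
  n61 <- length(code$codons)
  if (method == "uniform")
    return(stats::setNames(rep(1 / n61, n61), code$codons))
  all_cods <- unlist(lapply(aln$taxa, function(tx)
    split_codons(aln$sequences[[tx]])))
  all_cods <- all_cods[all_cods != "---"]
  if (method == "f61") {
    counts <- table(factor(all_cods, levels = code$codons)) + 0.5
    pi_ <- as.numeric(counts) / sum(counts)
    return(stats::setNames(pi_, code$codons))
  }
  pos_freq <- lapply(1:3, function(k) {
    b <- substring(all_cods, k, k)
    tab <- table(factor(b, levels = .NUC)) + 0.5
    as.numeric(tab) / sum(tab)
  })
  nuc_idx <- function(x) match(x, .NUC)
  pi_ <- vapply(code$codons, function(cd) {
    prod(vapply(1:3, function(k)
      pos_freq[[k]][nuc_idx(substring(cd, k, k))], 0))
  }, 0)
  pi_ <- pi_ / sum(pi_)
  stats::setNames(pi_, code$codons)
}

#' GY94 instantaneous rate matrix
#'
#' Builds the 61x61 generator with entries `pi_j * kappa^[transition] *
#' omega^[nonsynonymous]` for single-base changes (0 otherwise), diagonal
#' set so rows sum to zero, scaled so the mean rate at stationarity is one
#' substitution per codon.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio (>= 0).
#' @param pi Equilibrium codon frequencies (length 61, sums to 1).
#' @param code A [genetic_code()].
#' @param scale Logical: scale mean rate to one (default TRUE).
#' @return 61x61 matrix with codon dimnames.
#' @export
gy94_rate_matrix <- function(kappa, omega, pi, code = genetic_code(),
                             scale = TRUE) {
  stopifnot(kappa > 0, omega >= 0, length(pi) == length(code$codons))
  st <- .gy94_structure(code)
  Q <- matrix(0, length(pi), length(pi),
              dimnames = list(code$codons, code$codons))
  rate <- st$single * 1
  rate[st$single & st$transition] <- kappa
  rate[st$single & !st$synonymous] <-
    rate[st$single & !st$synonymous] * omega
  Q <- rate * matrix(pi, nrow = length(pi), ncol = length(pi),
                     byrow = TRUE)
  diag(Q) <- -rowSums(Q)
  if (scale) {
    mean_rate <- -sum(pi * diag(Q))
    if (mean_rate > 0) Q <- Q / mean_rate
  }
  Q
}

## Eigendecomposition of Q in the pi-symmetrized basis; returns a closure
## P(t). Reversibility makes diag(sqrt(pi)) Q diag(1/sqrt(pi)) symmetric.
.gy94_eigen <- function(Q, pi) {
  sp <- sqrt(pi)
  S <- (Q * outer(sp, 1 / sp)) # diag(sp) %*% Q %*% diag(1/sp)
  S <- (S + t(S)) / 2          # symmetrize residual asymmetry
  eg <- eigen(S, symmetric = TRUE)
  left <- eg$vectors * (1 / sp)   # diag(1/sp) %*% V
  right <- t(eg$vectors * sp)     # t(V) %*% diag(sp)
  list(values = eg$values, left = left, right = right)
}

#' Transition probability matrix of a GY94 generator
#'
#' `P(t) = exp(Qt)`, computed by eigendecomposition in the pi-symmetrized
#' basis (the model is time-reversible). Tiny negative entries from
#' round-off are clamped to zero and rows renormalized.
#'
#' @param Q Rate matrix from [gy94_rate_matrix()].
#' @param t Branch length (>= 0), expected substitutions per codon.
#' @param pi Equilibrium frequencies used to build `Q`.
#' @return Row-stochastic 61x61 matrix.
#' @export
transition_probabilities <- function(Q, t, pi) {
  stopifnot(t >= 0)
  eg <- .gy94_eigen(Q, pi)
  P <- eg$left %*% (exp(eg$values * t) * eg$right)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(Q)
  P
}
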