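## Distance-based phylogeny: Tamura 3-parameter (+Gamma) distances,
## neighbor-joining with pinned tie-breaking, codon-block bootstrap support
## and outgroup rooting. Trees are ape "phylo" objects throughout.

#' Tamura 3-parameter distance between two aligned sequences
#'
#' Computes the T3P (Tamura 1992) distance, which corrects for
#' transition/transversion bias and G+C content:
#' `d = -h log(1 - P/h - Q) - (1/2) (1 - h) log(1 - 2Q)` with
#' `h = 2 theta (1 - theta)`, `theta` the mean G+C content of the pair,
#' `P`/`Q` the transition/transversion proportions. With `gamma_shape = a`,
#' each `-log(x)` term is replaced by the gamma rate-heterogeneity
#' correction `a (x^(-1/a) - 1)`. Columns where either sequence is gapped
#' are dropped.
#'
#' @param seq_a,seq_b Equal-length nucleotide strings over `A,C,G,T,-`.
#' @param gamma_shape Optional gamma shape parameter `a > 0`; `NULL` for the
#'   uncorrected model.
#' @return Distance in substitutions per site.
#' @export
t3p_distance <- function(seq_a, seq_b, gamma_shape = NULL) {
  a_ <- strsplit(toupper(seq_a), "")[[1]]
  b_ <- strsplit(toupper(seq_b), "")[[1]]
  if (length(a_) != length(b_)) stop("sequences differ in length")
  keep <- a_ %in% .NUC & b_ %in% .NUC
  a_ <- a_[keep]; b_ <- b_[keep]
  n <- length(a_)
  if (n == 0L) stop("no pairwise-complete sites")
  purine <- function(x) x %in% c("A", "G")
  diff <- a_ != b_
  transitions <- diff & (purine(a_) == purine(b_))
  P <- sum(transitions) / n
  Q <- sum(diff & !transitions) / n
  theta <- (sum(a_ %in% c("G", "C")) + sum(b_ %in% c("G", "C"))) / (2 * n)
  h <- 2 * theta * (1 - theta)
  x1 <- 1 - P / h - Q
  x2 <- 1 - 2 * Q
  if (x1 <= 0 || x2 <= 0)
    stop("T3P distance saturated (log argument <= 0) for this pair")
  if (is.null(gamma_shape)) {
    -h * log(x1) - 0.5 * (1 - h) * log(x2)
  } else {
    a <- gamma_shape
    if (a <= 0) stop("gamma shape must be positive")
    h * a * (x1^(-1 / a) - 1) + 0.5 * (1 - h) * a * (x2^(-1 / a) - 1)
  }
}

#' Pairwise T3P distance matrix of an alignment
#'
#' @param aln A [coding_alignment()].
#' @param gamma_shape Optional gamma shape (see [t3p_distance()]).
#' @param taxa Taxa to include (default all).
#' @return Symmetric matrix with zero diagonal, dimnames = taxa.
#' @export
t3p_distance_matrix <- function(aln, gamma_shape = NULL, taxa = NULL) {
  if (is.null(taxa)) taxa <- aln$taxa
  n <- length(taxa)
  dm <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- tryCatch(
      t3p_distance(aln$sequences[[taxa[i]]], aln$sequences[[taxa[j]]],
                   gamma_shape),
      error = function(e)
        stop("distance failed for pair (", taxa[i], ", ", taxa[j], "): ",
             conditionMessage(e)))
    dm[i, j] <- dm[j, i] <- d
  }
  dm
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining with two behaviors pinned for
#' reproducibility: ties in the Q criterion are broken by the
#' lexicographically smallest pair of cluster representative labels (the
#' smallest leaf label in each cluster), and negative branch lengths are
#' clamped to zero with the deficit moved to the sibling edge.
#'
#' @param dm Symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_build <- function(dm) {
  taxa <- rownames(dm)
  n <- length(taxa)
  if (is.null(taxa) || n < 3L) stop("need a labelled matrix of >= 3 taxa")
  if (!isTRUE(all.equal(dm, t(dm))) || any(diag(dm) != 0))
    stop("distance matrix must be symmetric with zero diagonal")
  ## active clusters: newick fragment + representative label
  frag <- as.list(stats::setNames(taxa, taxa))
  rep_ <- as.list(stats::setNames(taxa, taxa))
  D <- dm
  while (nrow(D) > 2L) {
    m <- nrow(D)
    r <- rowSums(D)
    Qm <- (m - 2) * D - outer(r, r, "+")
    diag(Qm) <- Inf
    qmin <- min(Qm)
    cand <- which(Qm <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    ## tie-break: lexicographically smallest sorted representative pair
    keys <- apply(cand, 1L, function(ij) {
      pr <- sort(c(rep_[[rownames(D)[ij[1]]]], rep_[[rownames(D)[ij[2]]]]))
      paste(pr, collapse = "\r")
    })
    pick <- cand[order(keys)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    d_ij <- D[i, j]
    li <- 0.5 * d_ij + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d_ij - li
    ## clamp negatives, move deficit to sibling
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    if (li < 0) li <- 0
    if (lj < 0) lj <- 0
    ni <- rownames(D)[i]; nj_ <- rownames(D)[j]
    new_lab <- paste0("(", frag[[ni]], ":", format(li, digits = 12),
                      ",", frag[[nj_]], ":", format(lj, digits = 12), ")")
    new_rep <- min(rep_[[ni]], rep_[[nj_]])
    others <- setdiff(rownames(D), c(ni, nj_))
    newd <- vapply(others, function(k)
      0.5 * (D[ni, k] + D[nj_, k] - d_ij), 0)
    D <- D[others, others, drop = FALSE]
    D <- rbind(cbind(D, newd), c(newd, 0))
    rownames(D)[m - 1L] <- colnames(D)[m - 1L] <- new_lab_id <-
      paste0("node", m)
    frag[[new_lab_id]] <- new_lab
    rep_[[new_lab_id]] <- new_rep
    frag[[ni]] <- frag[[nj_]] <- NULL
  }
  a <- rownames(D)[1L]; b <- rownames(D)[2L]
  final <- max(D[1L, 2L], 0)
  nwk <- paste0("(", frag[[a]], ":", format(final / 2, digits = 12), ",",
                frag[[b]], ":", format(final / 2, digits = 12), ");")
  tr <- ape::read.tree(text = nwk)
  ape::unroot(tr)
}

#' Bootstrap support for a distance tree by codon-block resampling
#'
#' Resamples codon columns (3-nt blocks, keeping frame) with replacement,
#' rebuilds the tree per replicate with `builder`, and scores each internal
#' bipartition of the point-estimate tree by the percentage of replicate
#' trees containing it. Replicates whose distance computation saturates are
#' dropped and counted; more than `max_drop_frac` dropped is an error.
#'
#' @param aln A [coding_alignment()].
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed (mandatory; supports are stochastic).
#' @param builder Function `alignment -> phylo`; the default is NJ on T3P
#'   distances with `gamma_shape`.
#' @param gamma_shape Passed to the default builder.
#' @param max_drop_frac Maximum tolerated fraction of dropped replicates.
#' @return The point-estimate `phylo` tree with `node.label` holding
#'   bootstrap percentages (root label empty).
#' @export
bootstrap_support <- function(aln, n_reps = 1000L, seed, builder = NULL,
                              gamma_shape = NULL, max_drop_frac = 0.1) {
  stopifnot(n_reps >= 1L)
  if (missing(seed)) stop("seed is required")
  if (is.null(builder))
    builder <- function(a) nj_build(t3p_distance_matrix(a, gamma_shape))
  point <- builder(aln)
  L <- n_codons(aln)
  set.seed(seed)
  reps <- vector("list", n_reps)
  dropped <- 0L
  for (b in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    res <- resample_codons(aln, cols)
    tr <- tryCatch(builder(res), error = function(e) NULL)
    if (is.null(tr)) dropped <- dropped + 1L else reps[[b]] <- tr
  }
  reps <- Filter(Negate(is.null), reps)
  if (dropped > max_drop_frac * n_reps)
    stop(dropped, " of ", n_reps, " bootstrap replicates dropped ",
         "(saturated distances)")
  if (length(reps)) {
    counts <- ape::prop.clades(point, reps, rooted = FALSE)
    counts[is.na(counts)] <- 0L
    point$node.label <- as.character(round(100 * counts / length(reps), 1))
  } else {
    point$node.label <- rep("0", point$Nnode)
  }
  ## the basal "root" node of an unrooted tree is not a bipartition
  point$node.label[1L] <- ""
  attr(point, "n_dropped") <- dropped
  point
}

#' Extract codon columns from an alignment (bootstrap resampling helper)
#'
#' @param aln A [coding_alignment()].
#' @param cols Integer vector of codon column indices (with repeats allowed).
#' @return A new `coding_alignment` built from those codon columns.
#' @export
resample_codons <- function(aln, cols) {
  seqs <- vapply(aln$taxa, function(tx) {
    cds <- split_codons(aln$sequences[[tx]])
    paste(cds[cols], collapse = "")
  }, character(1))
  ## bypass full validation (resampling preserves it); keep structure
  structure(list(taxa = aln$taxa,
                 sequences = stats::setNames(seqs, aln$taxa),
                 reference = aln$reference,
                 length_nt = 3L * length(cols)),
            class = "coding_alignment")
}

#' Root a tree on an outgroup taxon
#'
#' Places the root at the midpoint of the outgroup's pendant edge.
#'
#' @param tree An `ape::phylo` tree.
#' @param outgroup_taxon Leaf label to root on.
#' @return A rooted `phylo` tree.
#' @export
root_with_outgroup <- function(tree, outgroup_taxon) {
  if (!outgroup_taxon %in% tree$tip.label)
    stop("unknown outgroup taxon: ", outgroup_taxon)
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  rooted <- ape::root(tree, outgroup = outgroup_taxon, resolve.root = TRUE)
  ## split the outgroup pendant edge evenly across the root
  tip <- which(rooted$tip.label == outgroup_taxon)
  root_node <- ape::Ntip(rooted) + 1L
  e_out <- which(rooted$edge[, 2] == tip & rooted$edge[, 1] == root_node)
  if (length(e_out) == 1L) {
    e_in <- which(rooted$edge[, 1] == root_node & rooted$edge[, 2] != tip)
    total <- rooted$edge.length[e_out] +
      sum(rooted$edge.length[e_in])
    rooted$edge.length[e_out] <- total / 2
    rooted$edge.length[e_in[1]] <- total / 2
    if (length(e_in) > 1L) rooted$edge.length[e_in[-1]] <- 0
  }
  rooted
}
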