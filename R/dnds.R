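## Nei-Gojobori (1986) synonymous/nonsynonymous analysis: fractional site
## counting, minimal-pathway difference counting, Jukes-Cantor correction,
## pooled alignment-wide dN/dS and sliding-window selection scans.
##
## Conventions pinned for reproducibility: single-base mutations to stop
## codons are excluded both from site denominators (each codon position is
## renormalized so it contributes exactly one site, hence n + s = 3 per
## codon) and from mutational pathways; minimal pathways between two codons
## are weighted equally; proportions are corrected by the Jukes-Cantor
## formula d = -(3/4) log(1 - (4/3) p).

#' Synonymous/nonsynonymous site counts of a codon
#'
#' For each codon position, the synonymous fraction is the number of
#' synonymous single-base mutants divided by the number of non-stop
#' single-base mutants at that position; positions are scaled to contribute
#' one site each, so `n_sites + s_sites = 3`.
#'
#' @param codon Sense codon string.
#' @param code A [genetic_code()].
#' @return List with `s_sites` and `n_sites`.
#' @export
#' @examples
#' codon_sites("TTT")  # s = 1/3, n = 8/3
codon_sites <- function(codon, code = genetic_code()) {
  codon <- toupper(codon)
  full <- .standard_code_lookup(code)
  if (grepl("-", codon, fixed = TRUE)) stop("gapped codon: ", codon)
  aa <- full[[codon]]
  if (is.null(aa) || is.na(aa)) stop("unknown codon: ", codon)
  if (aa == "*") stop("stop codon: ", codon)
  s <- 0
  for (k in 1:3) {
    base <- substring(codon, k, k)
    syn <- 0L; valid <- 0L
    for (b in setdiff(.NUC, base)) {
      mut <- codon
      substring(mut, k, k) <- b
      maa <- full[[mut]]
      if (maa == "*") next
      valid <- valid + 1L
      if (maa == aa) syn <- syn + 1L
    }
    if (valid > 0L) s <- s + syn / valid
  }
  list(s_sites = s, n_sites = 3 - s)
}

## Cached per-codon site counts over the 61 sense codons.
.site_count_table <- function(code) {
  key <- paste(code$codons, collapse = "")
  cache <- .codonevo_cache
  id <- paste0("sites_", substr(key, 1, 30), nchar(key))
  if (!is.null(cache[[id]])) return(cache[[id]])
  tab <- t(vapply(code$codons, function(cd) {
    cs <- codon_sites(cd, code)
    c(s = cs$s_sites, n = cs$n_sites)
  }, c(s = 0, n = 0)))
  cache[[id]] <- tab
  tab
}

.codonevo_cache <- new.env(parent = emptyenv())

#' Pathway-averaged synonymous/nonsynonymous differences between two codons
#'
#' Averages the synonymous and nonsynonymous step labels over all minimal
#' mutational pathways between the codons, each pathway weighted equally.
#' Pathways passing through a stop codon are excluded; if every pathway is
#' excluded, all pathways are included unweighted with a warning.
#'
#' @param codon_a,codon_b Sense codon strings.
#' @param code A [genetic_code()].
#' @return List with `Nd` and `Sd` (sum equals the number of differing
#'   positions).
#' @export
#' @examples
#' count_pathway_differences("TTT", "GTA")  # Nd = 1.5, Sd = 0.5
count_pathway_differences <- function(codon_a, codon_b,
                                      code = genetic_code()) {
  codon_a <- toupper(codon_a); codon_b <- toupper(codon_b)
  full <- .standard_code_lookup(code)
  for (cd in c(codon_a, codon_b)) {
    if (is.na(full[cd]) || full[[cd]] == "*")
      stop("not a sense codon: ", cd)
  }
  diff_pos <- which(strsplit(codon_a, "")[[1]] != strsplit(codon_b, "")[[1]])
  d <- length(diff_pos)
  if (d == 0L) return(list(Nd = 0, Sd = 0))
  perms <- .permutations(diff_pos)
  path_n <- numeric(0); path_s <- numeric(0)
  for (r in seq_len(nrow(perms))) {
    cur <- codon_a
    ns <- 0; ss <- 0; valid <- TRUE
    for (k in perms[r, ]) {
      nxt <- cur
      substring(nxt, k, k) <- substring(codon_b, k, k)
      if (full[[nxt]] == "*") { valid <- FALSE; break }
      if (full[[nxt]] == full[[cur]]) ss <- ss + 1 else ns <- ns + 1
      cur <- nxt
    }
    if (valid) { path_n <- c(path_n, ns); path_s <- c(path_s, ss) }
  }
  if (!length(path_n)) {
    warning("all minimal pathways between ", codon_a, " and ", codon_b,
            " pass through stop codons; including them unweighted")
    for (r in seq_len(nrow(perms))) {
      cur <- codon_a; ns <- 0; ss <- 0
      for (k in perms[r, ]) {
        nxt <- cur
        substring(nxt, k, k) <- substring(codon_b, k, k)
        aa_cur <- full[[cur]]; aa_nxt <- full[[nxt]]
        if (identical(aa_nxt, aa_cur)) ss <- ss + 1 else ns <- ns + 1
        cur <- nxt
      }
      path_n <- c(path_n, ns); path_s <- c(path_s, ss)
    }
  }
  list(Nd = mean(path_n), Sd = mean(path_s))
}

.permutations <- function(x) {
  n <- length(x)
  if (n == 1L) return(matrix(x, 1L))
  out <- NULL
  for (i in seq_len(n))
    out <- rbind(out, cbind(x[i], .permutations(x[-i])))
  out
}

## Cached pairwise (Nd, Sd) lookup over sense-codon index pairs.
.pathway_table <- function(code) {
  id <- "pathways_standard"
  cache <- .codonevo_cache
  if (!is.null(cache[[id]]) && identical(cache$pathway_codons, code$codons))
    return(cache[[id]])
  n <- length(code$codons)
  Nd <- matrix(0, n, n); Sd <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    pd <- suppressWarnings(
      count_pathway_differences(code$codons[i], code$codons[j], code))
    Nd[i, j] <- Nd[j, i] <- pd$Nd
    Sd[i, j] <- Sd[j, i] <- pd$Sd
  }
  cache[[id]] <- list(Nd = Nd, Sd = Sd)
  cache$pathway_codons <- code$codons
  cache[[id]]
}

## Raw pooled counts over the codon columns of a sequence pair.
.pair_counts <- function(cod_a, cod_b, code, columns = NULL) {
  if (is.null(columns)) columns <- seq_along(cod_a)
  st <- .site_count_table(code)
  pt <- .pathway_table(code)
  ia <- codon_index(cod_a[columns], code)
  ib <- codon_index(cod_b[columns], code)
  ok <- !is.na(ia) & !is.na(ib)
  ia <- ia[ok]; ib <- ib[ok]
  S <- (sum(st[ia, "s"]) + sum(st[ib, "s"])) / 2
  N <- (sum(st[ia, "n"]) + sum(st[ib, "n"])) / 2
  Sd <- sum(pt$Sd[cbind(ia, ib)])
  Nd <- sum(pt$Nd[cbind(ia, ib)])
  list(N = N, S = S, Nd = Nd, Sd = Sd, n_codons = length(ia))
}

.jc_correct <- function(p) {
  if (p >= 0.75)
    stop("proportion ", signif(p, 4),
         " >= 3/4: Jukes-Cantor correction undefined (saturation)")
  -0.75 * log(1 - (4 / 3) * p)
}

#' Nei-Gojobori dN/dS between two sequences
#'
#' Sums fractional site counts and pathway-averaged differences over codons,
#' converts to proportions pN = Nd/N and pS = Sd/S, applies the Jukes-Cantor
#' correction to each, and forms the ratio dN/dS. Codon columns where either
#' sequence is gapped are skipped.
#'
#' @param seq_a,seq_b Equal-length in-frame nucleotide strings.
#' @param code A [genetic_code()].
#' @return List of class `pairwise_dnds`: `N`, `S`, `Nd`, `Sd`, `pN`, `pS`,
#'   `dN`, `dS`, `ratio` (`NA` when `dS == 0`).
#' @export
pairwise_dnds <- function(seq_a, seq_b, code = genetic_code()) {
  ca <- split_codons(toupper(seq_a)); cb <- split_codons(toupper(seq_b))
  if (length(ca) != length(cb)) stop("sequences differ in codon length")
  pc <- .pair_counts(ca, cb, code)
  .finish_dnds(pc)
}

.finish_dnds <- function(pc) {
  if (pc$S <= 0) stop("no synonymous sites (S = 0)")
  pN <- pc$Nd / pc$N
  pS <- pc$Sd / pc$S
  dN <- .jc_correct(pN)
  dS <- .jc_correct(pS)
  ratio <- if (dS == 0) NA_real_ else dN / dS
  structure(list(N = pc$N, S = pc$S, Nd = pc$Nd, Sd = pc$Sd,
                 pN = pN, pS = pS, dN = dN, dS = dS, ratio = ratio),
            class = "pairwise_dnds")
}

#' @export
print.pairwise_dnds <- function(x, ...) {
  cat(sprintf("NG86: N=%.2f S=%.2f Nd=%.2f Sd=%.2f dN=%.4f dS=%.4f dN/dS=%s\n",
              x$N, x$S, x$Nd, x$Sd, x$dN, x$dS,
              ifelse(is.na(x$ratio), "undefined", sprintf("%.4f", x$ratio))))
  invisible(x)
}

## Codon-split alignment subset as a list of codon vectors.
.codon_list <- function(aln, taxa = NULL) {
  if (is.null(taxa)) taxa <- aln$taxa
  lapply(stats::setNames(taxa, taxa),
         function(tx) split_codons(aln$sequences[[tx]]))
}

## Default pair set: every listed taxon against `against`; if `against` is
## NULL, all unordered pairs.
.pair_set <- function(taxa, against = NULL) {
  if (!is.null(against)) {
    others <- setdiff(taxa, against)
    return(lapply(others, function(tx) c(against, tx)))
  }
  pairs <- utils::combn(taxa, 2L)
  lapply(seq_len(ncol(pairs)), function(i) pairs[, i])
}

#' Pooled Nei-Gojobori dN/dS over an alignment
#'
#' Pools raw counts (Nd, Sd, N, S) over all unordered pairs of the subset
#' (or over each taxon vs `against`), then corrects and takes the ratio —
#' a pooled estimate, not a mean of per-pair ratios.
#'
#' @param aln A [coding_alignment()].
#' @param taxa_subset Taxa to include (default: all).
#' @param against Optional taxon: restrict the pair set to `x` vs `against`.
#' @param code A [genetic_code()].
#' @return A `pairwise_dnds` object with the pooled estimates.
#' @export
mean_dnds <- function(aln, taxa_subset = NULL, against = NULL,
                      code = genetic_code()) {
  if (is.null(taxa_subset)) taxa_subset <- aln$taxa
  if (length(unique(c(taxa_subset, against))) < 2L)
    stop("need at least two taxa")
  cl <- .codon_list(aln, unique(c(taxa_subset, against)))
  pairs <- .pair_set(taxa_subset, against)
  tot <- list(N = 0, S = 0, Nd = 0, Sd = 0)
  for (pr in pairs) {
    pc <- .pair_counts(cl[[pr[1]]], cl[[pr[2]]], code)
    tot$N <- tot$N + pc$N; tot$S <- tot$S + pc$S
    tot$Nd <- tot$Nd + pc$Nd; tot$Sd <- tot$Sd + pc$Sd
  }
  .finish_dnds(tot)
}

#' Sliding-window dN/dS scan along the coding region
#'
#' Slides a window of `window_len` codons in steps of `step` codons along the
#' alignment. Within each window, raw NG86 counts are pooled over the pair
#' set (by default every non-reference taxon against `against`, the
#' alignment reference if unset) and corrected. The dN track is always
#' emitted; the ratio is `NA` where the window dS is 0 (or the correction is
#' saturated), so scans over conserved regions remain well defined.
#'
#' @param aln A [coding_alignment()].
#' @param against Reference taxon for the pair set; defaults to
#'   `aln$reference`. Set to `NA` to pool over all unordered pairs.
#' @param window_len,step Window length and step in codons.
#' @param taxa_subset Non-reference taxa to include (default: all others).
#' @param code A [genetic_code()].
#' @return Object of class `sliding_window_profile`: data frame `windows`
#'   (start, end, midpoint, N, S, Nd, Sd, dN, dS, ratio) plus `window_len`,
#'   `step`.
#' @export
sliding_window_dnds <- function(aln, against = NULL, window_len = 50L,
                                step = 10L, taxa_subset = NULL,
                                code = genetic_code()) {
  L <- n_codons(aln)
  if (window_len > L) stop("window length ", window_len,
                           " exceeds alignment codon length ", L)
  all_pairs <- FALSE
  if (is.null(against)) against <- aln$reference
  if (length(against) == 1L && is.na(against)) { all_pairs <- TRUE }
  if (is.null(taxa_subset))
    taxa_subset <- if (all_pairs) aln$taxa else setdiff(aln$taxa, against)
  cl <- .codon_list(aln, unique(c(taxa_subset,
                                  if (!all_pairs) against)))
  pairs <- if (all_pairs) .pair_set(taxa_subset)
           else .pair_set(taxa_subset, against)
  starts <- seq(1L, L - window_len + 1L, by = step)
  rows <- lapply(starts, function(s0) {
    cols <- s0:(s0 + window_len - 1L)
    tot <- list(N = 0, S = 0, Nd = 0, Sd = 0)
    for (pr in pairs) {
      pc <- .pair_counts(cl[[pr[1]]], cl[[pr[2]]], code, columns = cols)
      tot$N <- tot$N + pc$N; tot$S <- tot$S + pc$S
      tot$Nd <- tot$Nd + pc$Nd; tot$Sd <- tot$Sd + pc$Sd
    }
    dN <- dS <- ratio <- NA_real_
    if (tot$N > 0 && tot$S > 0) {
      pN <- tot$Nd / tot$N; pS <- tot$Sd / tot$S
      if (pN < 0.75) dN <- .jc_correct(pN)
      if (pS < 0.75) dS <- .jc_correct(pS)
      if (!is.na(dN) && !is.na(dS) && dS > 0) ratio <- dN / dS
    }
    data.frame(start = s0, end = s0 + window_len - 1L,
               midpoint = s0 + (window_len - 1) / 2,
               N = tot$N, S = tot$S, Nd = tot$Nd, Sd = tot$Sd,
               dN = dN, dS = dS, ratio = ratio)
  })
  structure(list(windows = do.call(rbind, rows),
                 window_len = window_len, step = step),
            class = "sliding_window_profile")
}

#' @export
print.sliding_window_profile <- function(x, ...) {
  cat("Sliding-window dN/dS profile:", nrow(x$windows), "windows (len",
      x$window_len, ", step", x$step, "codons)\n")
  invisible(x)
}
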