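## Test helpers: independent brute-force oracles and small fixture builders.
## The oracles deliberately re-derive quantities by direct enumeration so
## they stay independent of the package's implementation paths.

.nuc <- c("T", "C", "A", "G")
.code_tab <- local({
  gc_ <- genetic_code()
  full <- c(gc_$table, stats::setNames(rep("*", 3), gc_$stops))
  full
})

## random sense codon(s)
random_codons <- function(n) {
  sense <- names(.code_tab)[.code_tab != "*"]
  sample(sense, n, replace = TRUE)
}

## random gap-free coding alignment as named character vector
random_alignment <- function(n_taxa, n_cod, mut_rate = 0.15) {
  base <- random_codons(n_cod)
  sense <- names(.code_tab)[.code_tab != "*"]
  seqs <- vapply(seq_len(n_taxa), function(i) {
    cods <- base
    mut <- runif(n_cod) < mut_rate
    cods[mut] <- sample(sense, sum(mut), replace = TRUE)
    paste(cods, collapse = "")
  }, character(1))
  names(seqs) <- paste0("t", seq_len(n_taxa))
  seqs
}

## --- NG86 oracles (independent of R/dnds.R) ------------------------------

## synonymous site count by direct mutant enumeration
oracle_sites <- function(codon) {
  aa <- .code_tab[[codon]]
  s <- 0
  for (k in 1:3) {
    syn <- 0; valid <- 0
    for (b in setdiff(.nuc, substring(codon, k, k))) {
      mut <- codon; substring(mut, k, k) <- b
      if (.code_tab[[mut]] == "*") next
      valid <- valid + 1
      if (.code_tab[[mut]] == aa) syn <- syn + 1
    }
    if (valid > 0) s <- s + syn / valid
  }
  c(s = s, n = 3 - s)
}

## exhaustive pathway enumeration via recursive descent
oracle_pathways <- function(a, b) {
  diffs <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (!length(diffs)) return(c(Nd = 0, Sd = 0))
  walk <- function(cur, remaining) {
    if (!length(remaining)) return(list(c(n = 0, s = 0)))
    out <- list()
    for (k in remaining) {
      nxt <- cur; substring(nxt, k, k) <- substring(b, k, k)
      if (.code_tab[[nxt]] == "*") next
      step <- if (.code_tab[[nxt]] == .code_tab[[cur]]) c(n = 0, s = 1)
              else c(n = 1, s = 0)
      for (tail in walk(nxt, setdiff(remaining, k)))
        out[[length(out) + 1L]] <- step + tail
    }
    out
  }
  paths <- walk(a, diffs)
  if (!length(paths)) return(NULL)  # all pathways blocked by stops
  m <- do.call(rbind, paths)
  c(Nd = mean(m[, "n"]), Sd = mean(m[, "s"]))
}

## full NG86 pairwise estimate from the oracles
oracle_pairwise_dnds <- function(seq_a, seq_b) {
  ca <- substring(seq_a, seq(1, nchar(seq_a), 3), seq(3, nchar(seq_a), 3))
  cb <- substring(seq_b, seq(1, nchar(seq_b), 3), seq(3, nchar(seq_b), 3))
  N <- S <- Nd <- Sd <- 0
  for (i in seq_along(ca)) {
    sa <- oracle_sites(ca[i]); sb <- oracle_sites(cb[i])
    S <- S + (sa["s"] + sb["s"]) / 2
    N <- N + (sa["n"] + sb["n"]) / 2
    pw <- oracle_pathways(ca[i], cb[i])
    if (is.null(pw)) next
    Nd <- Nd + pw["Nd"]; Sd <- Sd + pw["Sd"]
  }
  pN <- unname(Nd / N); pS <- unname(Sd / S)
  list(N = unname(N), S = unname(S), Nd = unname(Nd), Sd = unname(Sd),
       dN = -0.75 * log(1 - 4 * pN / 3), dS = -0.75 * log(1 - 4 * pS / 3))
}

## --- misc ----------------------------------------------------------------

## per-column substitution caller oracle (direct comparison)
oracle_aa_records <- function(seqs, reference) {
  ref_aa <- sapply(substring(seqs[[reference]],
                             seq(1, nchar(seqs[[reference]]), 3),
                             seq(3, nchar(seqs[[reference]]), 3)),
                   function(cd) .code_tab[[cd]])
  recs <- character(0)
  for (tx in setdiff(names(seqs), reference)) {
    aa <- sapply(substring(seqs[[tx]], seq(1, nchar(seqs[[tx]]), 3),
                           seq(3, nchar(seqs[[tx]]), 3)),
                 function(cd) .code_tab[[cd]])
    d <- which(aa != ref_aa)
    if (length(d)) recs <- union(recs, paste0(d, ":", aa[d]))
  }
  sort(recs)
}

## small valid topology for an L-residue protein
toy_topology <- function(L) {
  b <- floor(L / 3)
  topology_map(data.frame(
    region = c("A", "B", "C"),
    class = c("extracellular", "transmembrane", "intracellular"),
    start = c(1, b + 1, 2 * b + 1),
    end = c(b, 2 * b, L)))
}
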