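## Genetic code and codon bookkeeping.
##
## The standard code is stored as a named character vector codon -> one-letter
## amino acid, with "*" marking stops. Sense codons are kept in a fixed order
## (alphabetical over the 61 non-stop codons); every 61-state object in the
## package (rate matrices, partial likelihoods, equilibrium frequencies) uses
## this ordering.

.NUC <- c("T", "C", "A", "G")

.standard_code_table <- function() {
  ## TCAG expansion order, the classical codon-table layout.
  codons <- as.vector(t(outer(
    as.vector(t(outer(.NUC, .NUC, paste0))), .NUC, paste0)))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(aa, codons)
}

#' Genetic code object
#'
#' Builds a `genetic_code` object: a codon-to-amino-acid map over all 64
#' codons, with the stop codons held separately. Only the standard nuclear
#' code ships with the package; a custom table may be supplied as a named
#' character vector (names = codons, values = one-letter amino acids, `"*"`
#' for stop).
#'
#' @param table Named character vector of length 64 mapping codons to
#'   one-letter amino-acid codes (`"*"` for stop). Defaults to the standard
#'   code.
#' @return An object of class `genetic_code` with elements `table` (the 61
#'   sense codons), `stops` (stop codons), `codons` (ordered sense codons)
#'   and `aa` (amino acid per sense codon, same order).
#' @export
#' @examples
#' gc <- genetic_code()
#' gc$table[["ATG"]]  # "M"
genetic_code <- function(table = NULL) {
  if (is.null(table)) table <- .standard_code_table()
  if (length(table) != 64L || is.null(names(table)))
    stop("genetic code table must cover exactly 64 named codons")
  nm <- toupper(names(table))
  if (anyDuplicated(nm) || !all(nchar(nm) == 3L) ||
      !all(strsplit(paste(nm, collapse = ""), "")[[1]] %in% .NUC))
    stop("genetic code table names must be the 64 distinct DNA codons")
  names(table) <- nm
  stops <- sort(nm[table == "*"])
  sense <- sort(nm[table != "*"])
  structure(list(
    table  = table[sense],
    stops  = stops,
    codons = sense,
    aa     = unname(table[sense])
  ), class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code:", length(x$codons), "sense codons, stops:",
      paste(x$stops, collapse = " "), "\n")
  invisible(x)
}

## Split an in-frame nucleotide string into codons.
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length ", n, " is not a multiple of 3")
  substring(seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

codon_index <- function(codons, code) {
  match(codons, code$codons)
}

#' Translate an in-frame nucleotide sequence
#'
#' Translates codon-aligned DNA to one-letter amino acids. Gap codons
#' (`"---"`) translate to `"-"`. A terminal stop codon is dropped rather than
#' emitted; an internal stop is an error (it violates the coding-frame
#' contract of the package).
#'
#' @param seq Nucleotide string over `A,C,G,T,-`; length a multiple of 3,
#'   gaps codon-aligned.
#' @param code A [genetic_code()] object.
#' @param on_ambiguous `"error"` (default) to fail on non-ACGT bases, or
#'   `"X"` to emit `"X"` for any codon containing one.
#' @return Amino-acid string, one letter per codon (terminal stop removed).
#' @export
#' @examples
#' translate_cds("ATGAAA")   # "MK"
#' translate_cds("---ATG")   # "-M"
translate_cds <- function(seq, code = genetic_code(),
                          on_ambiguous = c("error", "X")) {
  on_ambiguous <- match.arg(on_ambiguous)
  seq <- toupper(seq)
  codons <- split_codons(seq)
  full <- .standard_code_lookup(code)
  aa <- character(length(codons))
  for (i in seq_along(codons)) {
    cd <- codons[i]
    if (cd == "---") { aa[i] <- "-"; next }
    if (grepl("-", cd, fixed = TRUE))
      stop("codon ", i, " ('", cd, "') mixes bases and gaps; frame broken")
    if (!all(strsplit(cd, "")[[1]] %in% .NUC)) {
      if (on_ambiguous == "error")
        stop("ambiguous base in codon ", i, " ('", cd, "')")
      aa[i] <- "X"; next
    }
    aa[i] <- full[[cd]]
  }
  n <- length(aa)
  if (n > 0L && aa[n] == "*") aa <- aa[-n]
  if (any(aa == "*"))
    stop("internal stop codon at codon index ", which(aa == "*")[1])
  paste(aa, collapse = "")
}

## Full 64-codon lookup (sense table plus stops as "*").
.standard_code_lookup <- function(code) {
  full <- c(code$table, stats::setNames(rep("*", length(code$stops)),
                                        code$stops))
  full[order(names(full))]
}
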