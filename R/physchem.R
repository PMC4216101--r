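## Physicochemical classification of amino-acid substitutions.
##
## A replacement is "radical" when it changes the category membership of the
## residue in at least one of three property tables (charge, polarity,
## volume), and "conservative" when all three memberships are preserved.

.default_physchem <- function() {
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  charge <- stats::setNames(rep("neutral", 20L), aa)
  charge[c("R", "K", "H")] <- "positive"
  charge[c("D", "E")] <- "negative"
  polarity <- stats::setNames(rep("nonpolar", 20L), aa)
  polarity[c("R", "N", "D", "C", "Q", "E", "G", "H", "K", "S", "T", "Y")] <-
    "polar"
  volume <- stats::setNames(rep(NA_character_, 20L), aa)
  volume[c("G", "A", "S", "C", "P", "N", "D", "T")] <- "small"
  volume[c("Q", "E", "H", "V", "M")] <- "medium"
  volume[c("R", "K", "I", "L", "F", "Y", "W")] <- "large"
  list(charge = charge, polarity = polarity, volume = volume)
}

#' Physicochemical property tables
#'
#' Category memberships of the 20 standard amino acids under three
#' properties: charge (positive/negative/neutral), polarity
#' (polar/nonpolar) and side-chain volume (small/medium/large). The shipped
#' defaults are documented in the package vignette; users may supply their
#' own tables as a TSV with columns `aa`, `charge`, `polarity`, `volume`.
#'
#' @param path Optional TSV path with custom tables.
#' @return An object of class `physchem_tables`: list of three named
#'   character vectors (`charge`, `polarity`, `volume`), each covering all
#'   20 amino acids.
#' @export
physchem_tables <- function(path = NULL) {
  if (is.null(path)) {
    tabs <- .default_physchem()
  } else {
    tb <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("aa", "charge", "polarity", "volume")
    if (!all(need %in% names(tb)))
      stop("physicochemical table must have columns: ",
           paste(need, collapse = ", "))
    tabs <- list(charge = stats::setNames(tb$charge, tb$aa),
                 polarity = stats::setNames(tb$polarity, tb$aa),
                 volume = stats::setNames(tb$volume, tb$aa))
  }
  aa20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  for (nm in names(tabs)) {
    if (!setequal(names(tabs[[nm]]), aa20) || anyNA(tabs[[nm]]))
      stop("table '", nm, "' must cover all 20 amino acids exactly once")
  }
  structure(tabs, class = "physchem_tables")
}

#' Classify an amino-acid substitution as radical or conservative
#'
#' @param ref_aa,alt_aa Single one-letter amino acids, unequal.
#' @param tables A [physchem_tables()] object.
#' @return List with `classification` (`"radical"` or `"conservative"`) and
#'   `categories_changed` (character vector, subset of
#'   `c("charge", "polarity", "volume")`).
#' @export
#' @examples
#' classify_substitution("K", "R")  # conservative
#' classify_substitution("K", "E")  # radical: charge (and volume) change
classify_substitution <- function(ref_aa, alt_aa,
                                  tables = physchem_tables()) {
  aa20 <- names(tables$charge)
  if (!ref_aa %in% aa20 || !alt_aa %in% aa20)
    stop("nonstandard amino acid: ", ref_aa, "/", alt_aa)
  if (ref_aa == alt_aa)
    stop("ref and alt amino acids are identical ('", ref_aa,
         "'): not a substitution")
  changed <- c("charge", "polarity", "volume")[c(
    tables$charge[[ref_aa]] != tables$charge[[alt_aa]],
    tables$polarity[[ref_aa]] != tables$polarity[[alt_aa]],
    tables$volume[[ref_aa]] != tables$volume[[alt_aa]])]
  list(classification = if (length(changed)) "radical" else "conservative",
       categories_changed = changed)
}
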