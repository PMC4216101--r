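## Input/output and validation for coding alignments, receptor topology
## tables and taxon metadata.

#' Coding alignment object
#'
#' Container for an in-frame codon alignment: equal-length aligned nucleotide
#' strings over `A,C,G,T,-`, one per taxon, with a designated reference taxon
#' whose (ungapped) amino-acid numbering anchors all reported coordinates.
#'
#' Validation enforces the coding-frame contract: equal sequence lengths
#' divisible by 3, gaps only in codon-sized codon-aligned runs, and no
#' internal stop codon in any sequence. A terminal stop codon shared by the
#' alignment (a full `TAA`/`TAG`/`TGA` column block) is stripped on input.
#'
#' @param sequences Named character vector of aligned nucleotide strings.
#' @param reference Taxon label used as the coordinate reference; defaults to
#'   the first taxon.
#' @param code A [genetic_code()] object used for stop-codon checks.
#' @return An object of class `coding_alignment` with elements `taxa`,
#'   `sequences` (named, uppercase), `reference`, `length_nt`.
#' @export
coding_alignment <- function(sequences, reference = NULL,
                             code = genetic_code()) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("sequences must be a named character vector")
  if (anyDuplicated(names(sequences)))
    stop("duplicated taxon labels: ",
         paste(unique(names(sequences)[duplicated(names(sequences))]),
               collapse = ", "))
  sequences <- toupper(sequences)
  taxa <- names(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L)
    stop("sequence length mismatch: ", taxa[which.max(lens)], " has ",
         max(lens), " nt but ", taxa[which.min(lens)], " has ", min(lens))
  L <- lens[[1]]
  if (L %% 3L != 0L)
    stop("alignment length ", L, " is not a multiple of 3 (frame violation)")
  bad <- grepl("[^ACGT-]", sequences)
  if (any(bad))
    stop("non-ACGT characters in taxon ", taxa[bad][1])
  ## gaps must come in codon-aligned triplets
  for (tx in taxa) {
    cods <- split_codons(sequences[[tx]])
    mixed <- grepl("-", cods, fixed = TRUE) & cods != "---"
    if (any(mixed))
      stop("taxon ", tx, ": gap not codon-aligned at codon ",
           which(mixed)[1])
  }
  ## strip a terminal stop codon if every ungapped sequence ends in one
  stops <- code$stops
  last <- substring(sequences, L - 2L, L)
  if (L >= 3L && all(last %in% c(stops, "---"))) {
    sequences <- substring(sequences, 1L, L - 3L)
    L <- L - 3L
  }
  ## internal stop check (per ungapped reading)
  full <- .standard_code_lookup(code)
  for (tx in taxa) {
    cods <- split_codons(sequences[[tx]])
    cods <- cods[cods != "---"]
    aa <- full[cods]
    if (any(aa == "*"))
      stop("taxon ", tx, ": internal stop codon ",
           cods[which(aa == "*")[1]], " at ungapped codon index ",
           which(aa == "*")[1])
  }
  if (is.null(reference)) reference <- taxa[[1]]
  if (!reference %in% taxa)
    stop("reference taxon '", reference, "' not present in alignment")
  structure(list(taxa = taxa, sequences = sequences,
                 reference = reference, length_nt = unname(L)),
            class = "coding_alignment")
}

#' @export
print.coding_alignment <- function(x, ...) {
  cat("Coding alignment:", length(x$taxa), "taxa x", x$length_nt,
      "nt (", x$length_nt / 3L, "codons ), reference:", x$reference, "\n")
  invisible(x)
}

#' Number of codon columns in an alignment
#' @param aln A [coding_alignment()].
#' @return Integer codon count.
#' @export
n_codons <- function(aln) aln$length_nt %/% 3L

#' Read an in-frame FASTA alignment
#'
#' Parses a FASTA file (via \pkg{ape}) into a validated
#' [coding_alignment()]. The taxon label is the header up to the first
#' whitespace; bases are stored uppercase.
#'
#' @param path FASTA file path.
#' @param reference Reference taxon label; defaults to the first record.
#' @param code A [genetic_code()] object.
#' @return A [coding_alignment()].
#' @export
read_fasta <- function(path, reference = NULL, code = genetic_code()) {
  if (!file.exists(path)) stop("file not found: ", path)
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0L) stop("no FASTA records in ", path)
  seqs <- vapply(as.character(dna), function(x)
    paste(toupper(x), collapse = ""), character(1))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  coding_alignment(seqs, reference = reference, code = code)
}

#' Write a coding alignment to FASTA
#'
#' @param aln A [coding_alignment()].
#' @param path Output file path.
#' @param width Line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (tx in aln$taxa) {
    writeLines(paste0(">", tx), con)
    s <- aln$sequences[[tx]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a receptor topology table
#'
#' Reads a TSV with columns `region`, `class`, `start`, `end` describing the
#' domain layout of the reference protein in 1-based inclusive amino-acid
#' coordinates (e.g. the N-terminus, seven transmembrane helices, loops and
#' C-terminus of a GPCR). Regions must tile `1..reference_length`
#' contiguously without overlap.
#'
#' @param path TSV file path.
#' @param reference_length Expected protein length; coverage is checked
#'   against it when supplied.
#' @return An object of class `topology_map`: data frame `regions`
#'   (region, class, start, end) plus `reference_length`.
#' @export
read_topology <- function(path, reference_length = NULL) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  topology_map(tb, reference_length)
}

#' Build a topology map from a data frame
#'
#' @param regions Data frame with columns `region`, `class`, `start`, `end`.
#' @param reference_length Optional expected protein length.
#' @return A `topology_map` object.
#' @export
topology_map <- function(regions, reference_length = NULL) {
  need <- c("region", "class", "start", "end")
  if (!all(need %in% names(regions)))
    stop("topology table must have columns: ", paste(need, collapse = ", "))
  regions <- regions[order(regions$start), need]
  ok_class <- c("extracellular", "transmembrane", "intracellular")
  bad <- !regions$class %in% ok_class
  if (any(bad))
    stop("unknown topology class '", regions$class[bad][1],
         "' (expected one of: ", paste(ok_class, collapse = ", "), ")")
  if (any(regions$end < regions$start))
    stop("region '", regions$region[regions$end < regions$start][1],
         "' has end < start")
  if (regions$start[1] != 1L)
    stop("topology must start at position 1")
  if (nrow(regions) > 1L) {
    gap <- regions$start[-1] != regions$end[-nrow(regions)] + 1L
    if (any(gap))
      stop("topology regions overlap or leave a gap between '",
           regions$region[which(gap)[1]], "' and '",
           regions$region[which(gap)[1] + 1L], "'")
  }
  if (!is.null(reference_length) &&
      regions$end[nrow(regions)] != reference_length)
    stop("topology covers 1..", regions$end[nrow(regions)],
         " but reference protein length is ", reference_length)
  structure(list(regions = regions,
                 reference_length = regions$end[nrow(regions)]),
            class = "topology_map")
}

#' Map reference amino-acid positions to topology regions
#'
#' @param topo A `topology_map`.
#' @param positions Integer vector of 1-based reference AA positions.
#' @return Data frame with columns `position`, `region`, `class`.
#' @export
topology_lookup <- function(topo, positions) {
  idx <- findInterval(positions, topo$regions$start)
  out_of_range <- positions < 1L | positions > topo$reference_length
  if (any(out_of_range))
    stop("position ", positions[out_of_range][1],
         " outside topology coverage 1..", topo$reference_length)
  data.frame(position = positions,
             region = topo$regions$region[idx],
             class = topo$regions$class[idx],
             stringsAsFactors = FALSE)
}

#' Read a taxon metadata table
#'
#' Reads a TSV with columns `taxon`, `genus`, `family`, `group`, `monogamy`
#' (logical or TRUE/FALSE strings). Social-monogamy annotation is a
#' genus-level attribute and must be identical within a genus.
#'
#' @param path TSV file path.
#' @param taxa Optional character vector of alignment taxa; when given, every
#'   taxon must have a metadata row.
#' @return A data frame of class `taxon_metadata`.
#' @export
read_metadata <- function(path, taxa = NULL) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  taxon_metadata(tb, taxa)
}

#' Validate a taxon metadata data frame
#'
#' @param meta Data frame with columns `taxon`, `genus`, `family`, `group`,
#'   `monogamy`.
#' @param taxa Optional alignment taxa to check coverage against.
#' @return The validated data frame, class `taxon_metadata`.
#' @export
taxon_metadata <- function(meta, taxa = NULL) {
  need <- c("taxon", "genus", "family", "group", "monogamy")
  if (!all(need %in% names(meta)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  meta$monogamy <- as.logical(meta$monogamy)
  if (anyNA(meta$monogamy))
    stop("monogamy column must be logical (TRUE/FALSE)")
  if (anyDuplicated(meta$taxon))
    stop("duplicated taxon in metadata: ",
         meta$taxon[duplicated(meta$taxon)][1])
  per_genus <- tapply(meta$monogamy, meta$genus, function(x)
    length(unique(x)))
  if (any(per_genus > 1L))
    stop("monogamy must be constant within genus; violated by genus '",
         names(per_genus)[per_genus > 1L][1], "'")
  if (!is.null(taxa)) {
    missing <- setdiff(taxa, meta$taxon)
    if (length(missing))
      stop("metadata missing for taxon: ", paste(missing, collapse = ", "))
  }
  class(meta) <- c("taxon_metadata", "data.frame")
  meta
}
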