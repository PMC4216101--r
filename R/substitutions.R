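## Substitution census relative to a reference taxon: amino-acid and
## nucleotide substitution calling, physicochemical classification, domain
## mapping, homology percentages, genus-frequency classes and clade-specific
## substitution detection.

## Alignment helper: per-taxon amino-acid matrix (rows = taxa, columns =
## alignment codon columns), plus the reference-coordinate map.
.aa_matrix <- function(aln, code) {
  t(vapply(aln$taxa, function(tx)
    strsplit(.translate_keep_terminal(aln$sequences[[tx]], code), "")[[1]],
    character(n_codons(aln))))
}

## Like translate_cds but never drops a column (alignment-column indexed);
## terminal stops cannot occur because coding_alignment strips them.
.translate_keep_terminal <- function(seq, code) {
  full <- .standard_code_lookup(code)
  cods <- split_codons(seq)
  aa <- ifelse(cods == "---", "-", full[cods])
  paste(aa, collapse = "")
}

## Map alignment codon columns to reference AA coordinates. Columns where the
## reference has a gap (insertions relative to the reference) get ref_pos NA
## and an insertion label "<pos>+<k>".
.reference_coordinates <- function(aln) {
  ref_cods <- split_codons(aln$sequences[[aln$reference]])
  is_ins <- ref_cods == "---"
  ref_pos <- cumsum(!is_ins)
  ref_pos[is_ins] <- NA_integer_
  ins_label <- rep(NA_character_, length(ref_cods))
  if (any(is_ins)) {
    prev <- cumsum(!is_ins)
    idx <- stats::ave(seq_along(ref_cods), cumsum(!is_ins),
                      FUN = seq_along) - 1L
    ins_label[is_ins] <- paste0(prev[is_ins], "+", idx[is_ins])
  }
  list(ref_pos = ref_pos, insertion = is_ins, ins_label = ins_label,
       ref_length = sum(!is_ins))
}

#' Call amino-acid substitutions against the reference taxon
#'
#' Compares the translated alignment to the reference protein and returns one
#' record per distinct (reference position, alternative amino acid) pair seen
#' in at least one taxon of `taxa_subset`. Records are classified as radical
#' or conservative and mapped onto the receptor topology. Gaps in
#' non-reference sequences are reported separately as deletion events, never
#' as substitutions; alignment columns where the reference is gapped
#' (insertions) are excluded from records.
#'
#' @param aln A [coding_alignment()].
#' @param code A [genetic_code()].
#' @param topo Optional [topology_map()]; when given, records carry `domain`
#'   and `domain_class`, and positions must fall inside its coverage.
#' @param taxa_subset Taxa to scan; default all non-reference taxa.
#' @param tables A [physchem_tables()].
#' @return List with `substitutions` (data frame: position, ref_aa, alt_aa,
#'   carriers, n_carriers, domain, domain_class, classification,
#'   categories_changed) and `deletions` (data frame: position, carriers).
#' @export
call_aa_substitutions <- function(aln, code = genetic_code(), topo = NULL,
                                  taxa_subset = NULL,
                                  tables = physchem_tables()) {
  if (is.null(taxa_subset))
    taxa_subset <- setdiff(aln$taxa, aln$reference)
  stopifnot(all(taxa_subset %in% aln$taxa))
  aam <- .aa_matrix(aln, code)
  coords <- .reference_coordinates(aln)
  ref_aa <- aam[aln$reference, ]
  recs <- list(); dels <- list()
  for (col in which(!coords$insertion)) {
    pos <- coords$ref_pos[col]
    ra <- ref_aa[col]
    for (tx in taxa_subset) {
      a <- aam[tx, col]
      if (a == ra) next
      key <- if (a == "-") paste0("del:", pos) else paste0(pos, ":", a)
      if (a == "-") {
        dels[[key]] <- c(dels[[key]], tx)
      } else {
        recs[[key]] <- c(recs[[key]], tx)
      }
    }
  }
  sub_df <- if (length(recs)) {
    keys <- strsplit(names(recs), ":", fixed = TRUE)
    pos <- as.integer(vapply(keys, `[[`, "", 1L))
    alt <- vapply(keys, `[[`, "", 2L)
    df <- data.frame(
      position = pos,
      ref_aa = ref_aa[match(pos, coords$ref_pos)],
      alt_aa = alt,
      carriers = vapply(recs, function(x) paste(sort(x), collapse = ","), ""),
      n_carriers = vapply(recs, length, 0L),
      stringsAsFactors = FALSE, row.names = NULL)
    cls <- Map(classify_substitution, df$ref_aa, df$alt_aa,
               MoreArgs = list(tables = tables))
    df$classification <- vapply(cls, `[[`, "", "classification")
    df$categories_changed <- vapply(cls, function(x)
      paste(x$categories_changed, collapse = ","), "")
    df[order(df$position, df$alt_aa), , drop = FALSE]
  } else {
    data.frame(position = integer(), ref_aa = character(),
               alt_aa = character(), carriers = character(),
               n_carriers = integer(), classification = character(),
               categories_changed = character(), stringsAsFactors = FALSE)
  }
  if (!is.null(topo) && nrow(sub_df)) {
    look <- topology_lookup(topo, sub_df$position)
    sub_df$domain <- look$region
    sub_df$domain_class <- look$class
  } else {
    sub_df$domain <- rep(NA_character_, nrow(sub_df))
    sub_df$domain_class <- rep(NA_character_, nrow(sub_df))
  }
  del_df <- if (length(dels)) {
    data.frame(
      position = as.integer(sub("^del:", "", names(dels))),
      carriers = vapply(dels, function(x) paste(sort(x), collapse = ","), ""),
      n_carriers = vapply(dels, length, 0L),
      stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(position = integer(), carriers = character(),
               n_carriers = integer(), stringsAsFactors = FALSE)
  }
  rownames(sub_df) <- NULL
  list(substitutions = sub_df, deletions = del_df[order(del_df$position), ,
                                                  drop = FALSE])
}

#' Call nucleotide substitutions against the reference taxon
#'
#' Returns one record per distinct (CDS nucleotide position, alternative
#' base) pair observed in `taxa_subset`, in reference coordinates. Synonymy
#' is judged by substituting the single base into the reference codon with
#' the other two positions held at the reference state; codons where a taxon
#' is gapped are suppressed for that taxon.
#'
#' @inheritParams call_aa_substitutions
#' @return Data frame: nt_position, codon_index, ref_nt, alt_nt, carriers,
#'   n_carriers, synonymy.
#' @export
call_nt_substitutions <- function(aln, code = genetic_code(),
                                  taxa_subset = NULL) {
  if (is.null(taxa_subset))
    taxa_subset <- setdiff(aln$taxa, aln$reference)
  stopifnot(all(taxa_subset %in% aln$taxa))
  coords <- .reference_coordinates(aln)
  full <- .standard_code_lookup(code)
  ref_seq <- aln$sequences[[aln$reference]]
  recs <- list()
  for (col in which(!coords$insertion)) {
    cpos <- coords$ref_pos[col]
    ref_cod <- substring(ref_seq, 3L * col - 2L, 3L * col)
    for (tx in taxa_subset) {
      cod <- substring(aln$sequences[[tx]], 3L * col - 2L, 3L * col)
      if (cod == "---" || cod == ref_cod) next
      for (k in 1:3) {
        rb <- substring(ref_cod, k, k)
        ab <- substring(cod, k, k)
        if (ab == rb) next
        nt_pos <- 3L * (cpos - 1L) + k
        key <- paste0(nt_pos, ":", ab)
        recs[[key]] <- c(recs[[key]], tx)
      }
    }
  }
  if (!length(recs))
    return(data.frame(nt_position = integer(), codon_index = integer(),
                      ref_nt = character(), alt_nt = character(),
                      carriers = character(), n_carriers = integer(),
                      synonymy = character(), stringsAsFactors = FALSE))
  keys <- strsplit(names(recs), ":", fixed = TRUE)
  nt_pos <- as.integer(vapply(keys, `[[`, "", 1L))
  alt <- vapply(keys, `[[`, "", 2L)
  cpos <- (nt_pos - 1L) %/% 3L + 1L
  within <- (nt_pos - 1L) %% 3L + 1L
  col <- match(cpos, coords$ref_pos)
  ref_cod <- substring(ref_seq, 3L * col - 2L, 3L * col)
  ref_nt <- substring(ref_cod, within, within)
  mut_cod <- ref_cod
  substring(mut_cod, within, within) <- alt
  synonymy <- ifelse(full[mut_cod] == full[ref_cod],
                     "synonymous", "nonsynonymous")
  df <- data.frame(nt_position = nt_pos, codon_index = cpos,
                   ref_nt = ref_nt, alt_nt = alt,
                   carriers = vapply(recs, function(x)
                     paste(sort(x), collapse = ","), ""),
                   n_carriers = vapply(recs, length, 0L),
                   synonymy = synonymy,
                   stringsAsFactors = FALSE, row.names = NULL)
  df[order(df$nt_position, df$alt_nt), , drop = FALSE]
}

#' Summarize substitutions per topology region
#'
#' @param records Substitution data frame from [call_aa_substitutions()].
#' @param topo A [topology_map()].
#' @return Data frame: region, class, region_length,
#'   n_substituted_positions, fraction, n_radical, n_conservative. Fractions
#'   are distinct substituted positions over region length; radical and
#'   conservative counts are per record, so a position with two alternative
#'   states contributes two records.
#' @export
summarize_by_region <- function(records, topo) {
  rg <- topo$regions
  out <- data.frame(region = rg$region, class = rg$class,
                    region_length = rg$end - rg$start + 1L,
                    n_substituted_positions = 0L, fraction = 0,
                    n_radical = 0L, n_conservative = 0L,
                    stringsAsFactors = FALSE)
  if (nrow(records)) {
    look <- topology_lookup(topo, records$position)
    for (i in seq_len(nrow(rg))) {
      sel <- look$region == rg$region[i]
      out$n_substituted_positions[i] <-
        length(unique(records$position[sel]))
      out$n_radical[i] <- sum(records$classification[sel] == "radical")
      out$n_conservative[i] <-
        sum(records$classification[sel] == "conservative")
    }
    out$fraction <- out$n_substituted_positions / out$region_length
  }
  out
}

#' Amino-acid homology of a taxon to the reference
#'
#' Percentage of reference protein positions at which the taxon carries the
#' reference amino acid. The denominator is the reference protein length;
#' deletion (gap) positions in the taxon count as mismatches.
#'
#' @param aln A [coding_alignment()].
#' @param taxon Taxon to compare.
#' @param code A [genetic_code()].
#' @return Percentage in `[0, 100]`.
#' @export
homology_percent <- function(aln, taxon, code = genetic_code()) {
  stopifnot(taxon %in% aln$taxa)
  aam <- .aa_matrix(aln, code)
  coords <- .reference_coordinates(aln)
  cols <- !coords$insertion
  ref <- aam[aln$reference, cols]
  tgt <- aam[taxon, cols]
  100 * sum(tgt == ref) / coords$ref_length
}

#' Genus-level frequency classes of substitutions
#'
#' For every substitution record, computes the fraction of target-group
#' genera carrying it and assigns a class: `conserved` (carried by every
#' target-group taxon), `high-frequency` (genus frequency above `threshold`),
#' `genus-specific` (exactly one carrier genus) or `intermediate`.
#'
#' @param records Substitution data frame from [call_aa_substitutions()].
#' @param metadata A [taxon_metadata()] data frame covering all carriers.
#' @param target_group Value of the metadata `group` column defining the
#'   in-focus taxa (e.g. `"NWM"`).
#' @param threshold High-frequency cutoff on genus frequency, in `(0, 1]`.
#' @return `records` with added columns `n_genera`, `genus_frequency`,
#'   `freq_class`.
#' @export
frequency_classes <- function(records, metadata, target_group,
                              threshold = 0.94) {
  if (threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  meta <- metadata[metadata$group == target_group, , drop = FALSE]
  if (!nrow(meta)) stop("no metadata rows for group '", target_group, "'")
  group_taxa <- meta$taxon
  group_genera <- unique(meta$genus)
  out <- records
  out$n_genera <- 0L
  out$genus_frequency <- 0
  out$freq_class <- NA_character_
  for (i in seq_len(nrow(out))) {
    carriers <- strsplit(out$carriers[i], ",", fixed = TRUE)[[1]]
    gc_ <- intersect(carriers, group_taxa)
    genera <- unique(meta$genus[match(gc_, meta$taxon)])
    out$n_genera[i] <- length(genera)
    out$genus_frequency[i] <- length(genera) / length(group_genera)
    out$freq_class[i] <-
      if (setequal(gc_, group_taxa)) "conserved"
      else if (out$genus_frequency[i] > threshold) "high-frequency"
      else if (length(genera) == 1L) "genus-specific"
      else "intermediate"
  }
  out
}

#' Substitutions carried by exactly one clade
#'
#' Returns the substitution records carried by every in-group taxon and by
#' no out-group taxon — the signature used to ask whether a clade (e.g. the
#' socially monogamous marmosets and tamarins) is differentiated from the
#' rest of the sample.
#'
#' @param records Substitution data frame from [call_aa_substitutions()].
#' @param in_group Character vector of in-group taxa (non-empty).
#' @param out_group Character vector of out-group taxa.
#' @return The subset of `records` that are in-group-diagnostic.
#' @export
group_specific_substitutions <- function(records, in_group, out_group) {
  if (!length(in_group)) stop("in-group must be non-empty")
  keep <- vapply(seq_len(nrow(records)), function(i) {
    carriers <- strsplit(records$carriers[i], ",", fixed = TRUE)[[1]]
    all(in_group %in% carriers) && !any(out_group %in% carriers)
  }, logical(1))
  records[keep, , drop = FALSE]
}
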