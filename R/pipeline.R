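## End-to-end orchestration: substitution census -> dN/dS -> phylogeny ->
## site-model selection tests, with TSV/JSON/report outputs. All stochastic
## stages derive their seeds from the single run seed, so a config+seed pair
## reproduces byte-identical outputs.

#' Subset a coding alignment to a set of taxa
#'
#' @param aln A [coding_alignment()].
#' @param taxa Taxa to keep (reference added if absent and `keep_reference`).
#' @param reference Reference for the subset (default: current, if kept).
#' @param keep_reference Keep the current reference in the subset.
#' @return A `coding_alignment`.
#' @export
subset_taxa <- function(aln, taxa, reference = NULL,
                        keep_reference = TRUE) {
  if (keep_reference) taxa <- union(taxa, aln$reference)
  stopifnot(all(taxa %in% aln$taxa))
  taxa <- aln$taxa[aln$taxa %in% taxa]  # preserve order
  if (is.null(reference))
    reference <- if (aln$reference %in% taxa) aln$reference else taxa[[1]]
  coding_alignment(aln$sequences[taxa], reference = reference)
}

#' Assemble a pipeline run configuration
#'
#' Either supply loaded objects (`alignment`, `topology`, `metadata`) or
#' file paths (`alignment_path` FASTA, `topology_path`/`metadata_path` TSV).
#' A YAML file with the same fields can be read with
#' [read_run_config()].
#'
#' @param alignment A [coding_alignment()] or `NULL`.
#' @param topology A [topology_map()] or `NULL`.
#' @param metadata A [taxon_metadata()] data frame or `NULL`.
#' @param alignment_path,topology_path,metadata_path File-path alternatives.
#' @param reference Reference taxon (defaults to the alignment's).
#' @param outgroup Outgroup taxon label for rooting (optional).
#' @param target_group Metadata `group` value defining the focal taxa.
#' @param clade_taxa In-group for clade-diagnostic substitution detection;
#'   default: the monogamous taxa of `target_group`.
#' @param window_len,step Sliding-window settings in codons.
#' @param gamma_shape Gamma shape for T3P distances (`NULL` = none).
#' @param bootstrap_reps Bootstrap replicates for the tree (0 disables).
#' @param possel List of site-model settings: `enabled`, `n_classes`,
#'   `restarts`, `maxit`, `branch_passes`.
#' @param freq_threshold High-frequency cutoff for genus frequency classes.
#' @param seed Run seed (mandatory).
#' @param out_dir Output directory.
#' @return A `run_config` list (validated lazily by [run_pipeline()]).
#' @export
run_config <- function(alignment = NULL, topology = NULL, metadata = NULL,
                       alignment_path = NULL, topology_path = NULL,
                       metadata_path = NULL, reference = NULL,
                       outgroup = NULL, target_group = "NWM",
                       clade_taxa = NULL, window_len = 50L, step = 10L,
                       gamma_shape = NULL, bootstrap_reps = 100L,
                       possel = list(enabled = TRUE, n_classes = 10L,
                                     restarts = 2L, maxit = 400L,
                                     branch_passes = 1L),
                       freq_threshold = 0.94, seed, out_dir) {
  if (missing(seed)) stop("seed is mandatory")
  if (missing(out_dir)) stop("out_dir is required")
  for (p in c(alignment_path, topology_path, metadata_path))
    if (!is.null(p) && !file.exists(p)) stop("file not found: ", p)
  structure(mget(names(formals(run_config)), environment()),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with fields matching [run_config()] arguments
#'   (paths rather than objects).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(run_config)))]
  do.call(run_config, args)
}

.write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.6g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full comparative-evolution pipeline
#'
#' Stages: input validation; substitution census (amino-acid and nucleotide
#' substitutions, per-region summary, homology percentages, genus-frequency
#' classes, clade-diagnostic substitutions); pooled and sliding-window
#' Nei-Gojobori dN/dS; neighbor-joining tree with bootstrap support and
#' outgroup rooting; GY94 site models (M0 fit, M8-vs-M8a likelihood-ratio
#' test, naive empirical Bayes sites). Writes `substitutions.tsv`,
#' `deletions.tsv`, `nt_substitutions.tsv`, `regions.tsv`, `homology.tsv`,
#' `frequency_classes.tsv`, `clade_specific.tsv`, `windows.tsv`,
#' `tree.nwk`, `fit.json`, `sites.tsv`, `report.md` and a `MANIFEST` of
#' completed stages to `out_dir`.
#'
#' @param config A [run_config()].
#' @return Invisible list with all stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  done <- character(0)
  manifest <- function() writeLines(c("completed stages:", done),
                                    file.path(out, "MANIFEST"))
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      manifest()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    done <<- c(done, name)
    res
  }
  results <- list()
  code <- genetic_code()

  results$inputs <- stage("validate", {
    aln <- config$alignment
    if (is.null(aln)) aln <- read_fasta(config$alignment_path,
                                        reference = config$reference)
    if (!is.null(config$reference) && aln$reference != config$reference)
      aln <- coding_alignment(aln$sequences, reference = config$reference)
    topo <- config$topology
    if (is.null(topo) && !is.null(config$topology_path))
      topo <- read_topology(config$topology_path)
    meta <- config$metadata
    if (is.null(meta) && !is.null(config$metadata_path))
      meta <- read_metadata(config$metadata_path)
    if (is.null(aln) || is.null(topo) || is.null(meta))
      stop("alignment, topology and metadata are all required")
    meta <- taxon_metadata(as.data.frame(meta), aln$taxa)
    list(aln = aln, topo = topo, meta = meta)
  })
  aln <- results$inputs$aln; topo <- results$inputs$topo
  meta <- results$inputs$meta
  group_taxa <- meta$taxon[meta$group == config$target_group]
  if (!length(group_taxa))
    stop("no taxa in target group '", config$target_group, "'")

  results$census <- stage("substitutions", {
    calls <- call_aa_substitutions(aln, code, topo,
                                   taxa_subset = group_taxa)
    nt <- call_nt_substitutions(aln, code, taxa_subset = group_taxa)
    regions <- summarize_by_region(calls$substitutions, topo)
    homology <- data.frame(
      taxon = group_taxa,
      homology_pct = vapply(group_taxa, function(tx)
        homology_percent(aln, tx, code), 0))
    freq <- frequency_classes(calls$substitutions, meta,
                              config$target_group,
                              threshold = config$freq_threshold)
    clade <- config$clade_taxa
    if (is.null(clade))
      clade <- meta$taxon[meta$monogamy & meta$group == config$target_group]
    clade_spec <- if (length(clade))
      group_specific_substitutions(calls$substitutions, clade,
                                   setdiff(group_taxa, clade))
    else calls$substitutions[0, ]
    .write_tsv(calls$substitutions, file.path(out, "substitutions.tsv"))
    .write_tsv(calls$deletions, file.path(out, "deletions.tsv"))
    .write_tsv(nt, file.path(out, "nt_substitutions.tsv"))
    .write_tsv(regions, file.path(out, "regions.tsv"))
    .write_tsv(homology, file.path(out, "homology.tsv"))
    .write_tsv(freq, file.path(out, "frequency_classes.tsv"))
    .write_tsv(clade_spec, file.path(out, "clade_specific.tsv"))
    list(substitutions = calls$substitutions, deletions = calls$deletions,
         nt = nt, regions = regions, homology = homology, freq = freq,
         clade_specific = clade_spec, clade_taxa = clade)
  })

  results$dnds <- stage("dnds", {
    overall <- mean_dnds(aln, taxa_subset = group_taxa, code = code)
    win <- sliding_window_dnds(aln, against = aln$reference,
                               window_len = config$window_len,
                               step = config$step,
                               taxa_subset = group_taxa, code = code)
    .write_tsv(win$windows, file.path(out, "windows.tsv"))
    list(overall = overall, windows = win)
  })

  results$phylo <- stage("phylo", {
    tr <- if (config$bootstrap_reps > 0L)
      bootstrap_support(aln, n_reps = config$bootstrap_reps,
                        seed = config$seed + 1L,
                        gamma_shape = config$gamma_shape)
    else nj_build(t3p_distance_matrix(aln, config$gamma_shape))
    if (!is.null(config$outgroup))
      tr <- root_with_outgroup(tr, config$outgroup)
    ape::write.tree(tr, file.path(out, "tree.nwk"))
    tr
  })

  possel_cfg <- utils::modifyList(
    list(enabled = TRUE, n_classes = 10L, restarts = 2L, maxit = 400L,
         branch_passes = 1L), as.list(config$possel))
  results$possel <- stage("possel", if (!isTRUE(possel_cfg$enabled)) {
    NULL
  } else {
    sub <- subset_taxa(aln, group_taxa, keep_reference = FALSE)
    dm <- t3p_distance_matrix(sub, config$gamma_shape)
    nj <- nj_build(dm)
    m0 <- fit_m0(sub, nj, code = code, seed = config$seed + 2L,
                 restarts = possel_cfg$restarts,
                 branch_passes = possel_cfg$branch_passes)
    m8 <- fit_m8(sub, m0$tree, code = code, seed = config$seed + 3L,
                 restarts = possel_cfg$restarts,
                 n_classes = possel_cfg$n_classes,
                 maxit = possel_cfg$maxit)
    m8a <- fit_m8a(sub, m0$tree, code = code, seed = config$seed + 4L,
                   restarts = possel_cfg$restarts,
                   n_classes = possel_cfg$n_classes,
                   maxit = possel_cfg$maxit)
    lrt <- lrt_m8_m8a(m8, m8a)
    sites <- neb_sites(m8, sub, code = code)
    jsonlite::write_json(list(
      m0 = list(lnL = m0$lnL, kappa = m0$kappa, omega = m0$omega),
      m8 = list(lnL = m8$lnL, kappa = m8$kappa, p0 = m8$p0, p = m8$p,
                q = m8$q, omega_s = m8$omega_s),
      m8a = list(lnL = m8a$lnL, kappa = m8a$kappa, p0 = m8a$p0,
                 p = m8a$p, q = m8a$q),
      lrt = lrt), file.path(out, "fit.json"),
      auto_unbox = TRUE, digits = 10)
    .write_tsv(sites, file.path(out, "sites.tsv"))
    list(m0 = m0, m8 = m8, m8a = m8a, lrt = lrt, sites = sites)
  })

  results$report <- stage("report", {
    .write_report(results, config, file.path(out, "report.md"))
  })
  manifest()
  invisible(results)
}

.write_report <- function(results, config, path) {
  cz <- results$census
  subs <- cz$substitutions
  n_rad <- sum(subs$classification == "radical")
  n_con <- sum(subs$classification == "conservative")
  ## internal consistency: report counts must equal stage-table sums
  stopifnot(n_rad + n_con == nrow(subs),
            sum(cz$regions$n_radical) == n_rad,
            sum(cz$regions$n_conservative) == n_con)
  lines <- c(
    "# Comparative coding-sequence evolution report", "",
    paste0("Target group: ", config$target_group, " (",
           length(cz$homology$taxon), " taxa); reference: ",
           results$inputs$aln$reference), "",
    "## Substitution census", "",
    paste0("- ", nrow(cz$nt), " distinct nucleotide substitutions (",
           sum(cz$nt$synonymy == "synonymous"), " synonymous, ",
           sum(cz$nt$synonymy == "nonsynonymous"), " nonsynonymous)"),
    paste0("- ", nrow(subs), " distinct amino-acid substitutions, of ",
           "which ", n_rad, " radical / ", n_con, " conservative"),
    paste0("- ", nrow(cz$clade_specific), " clade-diagnostic ",
           "substitutions for clade {",
           paste(cz$clade_taxa, collapse = ", "), "}"),
    paste0("- homology with reference: ",
           sprintf("%.1f%%", min(cz$homology$homology_pct)), " to ",
           sprintf("%.1f%%", max(cz$homology$homology_pct))), "",
    "## Per-region substitution density", "")
  for (i in seq_len(nrow(cz$regions))) {
    r <- cz$regions[i, ]
    lines <- c(lines, sprintf("- %s (%s): %d/%d (%.1f%%), %d radical / %d conservative",
                              r$region, r$class, r$n_substituted_positions,
                              r$region_length, 100 * r$fraction,
                              r$n_radical, r$n_conservative))
  }
  ov <- results$dnds$overall
  lines <- c(lines, "", "## Selection", "",
             sprintf("- pooled NG86 dN/dS = %s (dN = %.4f, dS = %.4f)",
                     ifelse(is.na(ov$ratio), "undefined",
                            sprintf("%.4f", ov$ratio)), ov$dN, ov$dS))
  if (!is.null(results$possel)) {
    ps <- results$possel
    lines <- c(lines,
               sprintf("- GY94 M0: omega = %.4f (kappa = %.2f, lnL = %.2f)",
                       ps$m0$omega, ps$m0$kappa, ps$m0$lnL),
               sprintf("- M8 vs M8a LRT: 2dlnL = %.3f, p = %.4g",
                       ps$lrt$statistic, ps$lrt$p_value),
               sprintf("- %d NEB positively selected sites (posterior > 0.95)%s",
                       nrow(ps$sites),
                       if (nrow(ps$sites))
                         paste0(": ", paste(ps$sites$site, collapse = ", "))
                       else ""))
  }
  win <- results$dnds$windows$windows
  peak <- win[which.max(ifelse(is.na(win$ratio), -Inf, win$ratio)), ]
  if (nrow(peak) && is.finite(peak$ratio))
    lines <- c(lines,
               sprintf("- peak sliding-window dN/dS = %.3f at codon midpoint %.1f",
                       peak$ratio, peak$midpoint))
  writeLines(lines, path)
  path
}
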