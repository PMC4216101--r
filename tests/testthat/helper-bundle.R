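## small end-to-end bundle: simulated 10-taxon, 120-codon gene with a toy
## 3-region topology, plus a matching compact pipeline configuration
make_small_bundle <- function(seed = 77) {
  tr <- paste0("(out:0.5,ref:0.2,((a1:0.03,a2:0.03):0.06,",
               "(a3:0.04,(b1:0.02,b2:0.02):0.04):0.06,",
               "((c1:0.03,c2:0.03):0.03,c3:0.05):0.04):0.1);")
  som <- data.frame(start = c(1, 41), end = c(40, 120),
                    omega = c(1.5, 0.1))
  sim <- simulate_alignment(simulation_spec(
    tree = tr, n_codons = 120, kappa = 2, seed = seed,
    reference_taxon = "ref",
    site_omega_map = som))
  taxa <- sim$alignment$taxa
  meta <- taxon_metadata(data.frame(
    taxon = taxa,
    genus = paste0("G", taxa),
    family = ifelse(grepl("^a", taxa), "A",
                    ifelse(grepl("^b", taxa), "B",
                           ifelse(grepl("^c", taxa), "C", "X"))),
    group = ifelse(taxa %in% c("ref", "out"),
                   ifelse(taxa == "ref", "hominoid", "prosimian"), "NWM"),
    monogamy = grepl("^b", taxa)), taxa)
  list(aln = sim$alignment, topo = toy_topology(120), meta = meta)
}

small_config <- function(bundle, out_dir, seed = 5) {
  run_config(alignment = bundle$aln, topology = bundle$topo,
             metadata = bundle$meta, reference = "ref", outgroup = "out",
             target_group = "NWM", window_len = 30L, step = 10L,
             bootstrap_reps = 10L,
             possel = list(enabled = TRUE, n_classes = 3L, restarts = 1L,
                           maxit = 120L, branch_passes = 0L),
             seed = seed, out_dir = out_dir)
}
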