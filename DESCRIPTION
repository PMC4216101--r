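Package: codonevo
Title: Comparative Molecular Evolution of Coding Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative molecular-evolution analysis of in-frame
    coding-sequence alignments, motivated by ligand/receptor gene pairs such
    as the vasopressin nonapeptide (AVP) and its G-protein-coupled receptor
    (AVPR1a) in primates. Calls nucleotide and amino-acid substitutions
    against a reference taxon and classifies them as radical or conservative
    by charge, polarity and volume; maps substitutions onto receptor
    transmembrane topology; estimates synonymous and nonsynonymous
    divergence by Nei-Gojobori (1986) counting with Jukes-Cantor correction,
    including sliding-window selection scans; builds neighbor-joining trees
    from Tamura 3-parameter (+Gamma) distances with codon-block bootstrap
    support; fits Goldman-Yang (1994) codon site models (M0, M8, M8a) by
    maximum likelihood with a likelihood-ratio test and naive empirical
    Bayes identification of positively selected sites; and simulates codon
    alignments with region-structured selective pressure so that every stage
    can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
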