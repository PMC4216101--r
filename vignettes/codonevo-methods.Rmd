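---
title: "Models and conventions in codonevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and conventions in codonevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`codonevo` analyzes in-frame coding-sequence alignments of a single gene
across related taxa. Its motivating use case is the contrast between a
strongly conserved peptide ligand (such as the nonapeptide arginine
vasopressin) and its much more variable G-protein-coupled receptor
(AVPR1a-like genes): the package censuses substitutions against a reference
taxon, maps them onto receptor topology, quantifies selection with both
counting-based (Nei–Gojobori) and likelihood-based (Goldman–Yang site
model) machinery, reconstructs distance phylogenies, and simulates codon
alignments so that every stage can be validated against known truth. This
vignette records the models, the conventions that had to be pinned for
reproducibility, and the reasoning behind the genuinely open design
choices.

## Coordinates and the coding-frame contract

All positions are reported in 1-based reference amino-acid coordinates
(the numbering of the designated reference taxon's ungapped protein, e.g.
the 418-residue human receptor). Alignment columns where the reference is
gapped are insertions relative to the reference; they are labelled
`pos+k` internally, excluded from per-domain counts, and never become
substitution records. Gaps in non-reference sequences are deletion events,
reported separately from substitutions — a deletion is not an amino-acid
replacement. A terminal stop codon shared by the alignment is stripped on
input so protein-length bookkeeping (e.g. 418 residues) is exact; an
internal stop anywhere is a hard validation error naming the taxon and
codon.

## Physicochemical classification

A replacement is *radical* if it changes the residue's category in at
least one of three property tables — charge (positive `R,K,H`, negative
`D,E`, neutral otherwise), polarity (polar
`R,N,D,C,Q,E,G,H,K,S,T,Y`, nonpolar otherwise) and volume (small
`G,A,S,C,P,N,D,T`, medium `Q,E,H,V,M`, large `R,K,I,L,F,Y,W`) — and
*conservative* if all three are preserved. Category-change classification
schemes differ slightly between authors; the tables above are the package
default and are user-replaceable via a TSV (`physchem_tables(path)`), so
analyses can be re-run under any published scheme. Classification is
symmetric in its arguments and deterministic given the tables.

Counting convention: one record per distinct (position, alternative
amino acid) pair. A position with two alternative states contributes two
records, so radical + conservative counts may exceed the number of
distinct substituted positions; per-region *fractions* use distinct
positions over region length.

Homology percentages use the reference protein length as denominator and
count deletion positions as mismatches. The alternative (excluding
deletions from the denominator) is defensible; we pin the first because it
keeps `100 − homology` proportional to the count of differing positions.

## Nei–Gojobori dN/dS

Synonymous/nonsynonymous divergence uses NG86 counting with three pinned
conventions:

* **Sites.** At each codon position, the synonymous fraction is
  synonymous single-base mutants over *non-stop* single-base mutants,
  renormalized so each position contributes exactly one site; hence
  `n + s = 3` per codon (e.g. `TTT`: s = 1/3; `TGG`: s = 0, n = 3).
* **Differences.** Between two codons, synonymous/nonsynonymous step
  labels are averaged over all minimal mutational pathways, equally
  weighted, excluding pathways through stop codons (e.g. `TTT→GTA`:
  Nd = 1.5, Sd = 0.5). If every pathway is blocked by a stop — not
  possible for 1-step pairs and rare otherwise — all pathways are included
  unweighted with a warning.
* **Correction.** Proportions `pN = Nd/N`, `pS = Sd/S` are Jukes–Cantor
  corrected, `d = −(3/4)·ln(1 − (4/3)p)`, undefined at `p ≥ 3/4`
  (saturation is an error naming the pair, never silently clamped).

Alignment-wide estimates pool raw counts (Nd, Sd, N, S) over pairs and
correct once — a pooled ratio, not a mean of ratios, which keeps
short-window and low-divergence estimates stable. The ratio is reported as
undefined (`NA`) when dS = 0, never as infinity: downstream scans rely on
the always-defined dN track instead.

The sliding-window scan uses windows of 50 codons advanced in steps of 10
codons by default. Codon units keep dN/dS well defined within every
window; the window count for L codons is `floor((L − w)/s) + 1`. The
default pair set is every non-reference taxon against the reference,
pooled, matching the design of scans that compare a clade of interest
against a single outgroup or human sequence.

## Distance phylogeny

Trees are neighbor-joining on Tamura 3-parameter distances,

d = −h·ln(1 − P/h − Q) − ½(1−h)·ln(1 − 2Q),  h = 2θ(1−θ),

with P and Q the transition and transversion proportions and θ the mean
G+C content of the pair; with gamma rate heterogeneity of shape *a*, each
`−ln(x)` becomes `a(x^{−1/a} − 1)`. At θ = 0.5 the distance reduces to
Kimura's two-parameter formula, which the tests verify numerically. Full
maximum-likelihood tree search is deliberately out of scope: NJ over the
same model distances reproduces the clade-level structure the downstream
stages need, is fully deterministic, and an externally estimated ML tree
can be supplied wherever a tree is accepted. Two NJ behaviors are pinned
so results are bit-reproducible: Q-criterion ties break toward the
lexicographically smallest pair of cluster representative labels, and
negative branch lengths are clamped to zero with the deficit moved to the
sibling edge.

Bootstrap support resamples *codon columns* (3-nt blocks), keeping frame —
the resampling unit matches the analysis unit everywhere else in the
package. Support is the percentage of replicate trees containing each
internal bipartition of the point tree; replicates with saturated
distances are dropped (more than 10% dropped is an error). Rooting places
the root at the midpoint of the outgroup's pendant edge. All support
values are reported; display thresholds (e.g. hiding values below 60) are
left to the user.

## GY94 site models

The likelihood engine implements the Goldman–Yang codon model on the 61
sense codons: single-base changes have rate `π_j · κ^[transition] ·
ω^[nonsynonymous]`, multi-base changes rate 0, diagonal set so rows sum to
zero. Equilibrium frequencies default to F3x4 (position-specific
nucleotide frequencies renormalized over sense codons), with F61 and
uniform options. Transition probabilities come from eigendecomposition in
the π-symmetrized basis (the model is reversible), and site likelihoods
from Felsenstein pruning with per-node scaling; gap codons are missing
data.

**Class scaling.** In site-mixture models the class generators are scaled
*jointly*: each unscaled Q(ω_k) is divided by the single mixture-average
rate, so branch lengths are expected substitutions per codon averaged over
classes while high-ω classes keep their faster absolute rate. Scaling each
class to unit rate separately — superficially plausible — removes the
rate differential between selected and purifying sites and with it most of
the test's power; the package's simulator uses the identical joint-scaling
convention, so simulation truth and inference model agree exactly.

Site models: M0 (single ω); M8 (probability p0 on a Beta(p, q) over
[0, 1], discretized into K = 10 equal-probability classes at their
medians, plus 1 − p0 at ω_s ≥ 1); M8a (ω_s = 1). Discretized class ω
values are floored at 10⁻⁸ because a class at exactly ω = 0 annihilates
the likelihood of any site with an observed nonsynonymous difference.
Branch lengths are optimized under M0 (global scale jointly with κ and ω,
then per-branch coordinate passes) and held fixed for M8/M8a — the usual
protocol for nested site-model comparisons on a shared tree, pinned here
for determinism. Optimization is Nelder–Mead on log/logit-transformed
parameters with seeded multi-starts; M8 starts ω_s from a spread grid
(1.5, 3, 6) because the ω_s → 1 boundary is a genuine local optimum on
null-like data.

The M8-vs-M8a statistic is `2ΔlnL` (clamped at 0 with a warning).
Because ω_s = 1 sits on the boundary of the alternative's parameter
space, the null distribution is the 50:50 mixture of χ²₀ and χ²₁; the
reported p-value is `0.5·P(χ²₁ ≥ Λ)`, giving p = 0.5 at Λ = 0 and
p = 0.05 at Λ = 2.71. A pure-χ²₁ option supports comparison with tools
using that convention. Positively selected sites are identified by naive
empirical Bayes: the posterior probability of the ω_s class evaluated at
the MLEs, thresholded at 0.95, reported in reference coordinates. Bayes
empirical Bayes (integrating parameter uncertainty) is out of scope.

## The simulator and what passing tests mean

`simulate_alignment()` draws root codons from π and evolves each site
along each branch by direct sampling from the class transition matrix —
no intermediate-event simulation — so the generating law *is* the
likelihood model; parameter-recovery tests are therefore tests of the
estimator, not of a simulator approximation. Reproducibility is by a
single seeded stream with a pinned traversal order (preorder over
branches, ω classes in map order, parent states in increasing order),
which makes output bit-identical for a given seed and platform RNG; we
chose this over a per-(taxon, site) keyed stream because base R lacks a
splittable generator and the pinned order achieves the same reproducibility
goal.

`make_receptor_fixture()` bundles the study design the package targets: 22
taxa (20 ingroup in three families, a human-like reference, a divergent
outgroup), a 418-codon receptor with a 15-region GPCR topology, ω = 1.5
in the N-terminus/third-intracellular-loop/C-terminus against an ω = 0.08
background, κ = 3, and four clade-diagnostic substitutions (three radical,
one conservative, at positions 241/319/399/409) planted in a six-genus
socially monogamous clade. The tree depth puts ingroup-to-reference
homology near 90–93%, the divergence scale of confamilial primate
comparisons. The monogamous clade's stem is kept at 0.001
substitutions/codon so that, by construction, the planted records are the
clade-diagnostic set rather than an accident of the seed. Planting forces
the alternative codon in the clade and the reference codon elsewhere at
those four positions.

What the fixture does *not* emulate: indels (the simulator is gap-free, so
deletion handling is tested on hand-built alignments), rate variation
beyond the region-ω map, codon-usage bias beyond π, sequencing error, and
alignment uncertainty (inputs are assumed aligned in frame). Passing on
synthetic data therefore validates the estimators under their own model
assumptions; it does not certify robustness to misalignment or to
selection on synonymous sites.

## Problem sizes and numerical choices

Test and acceptance runs use deliberately compact problem sizes chosen to
exercise each claim at useful power: M0 recovery at 8 taxa × 300 and 2000
codons (tolerance tightening from ±30% to ±10%), LRT power at 10% of 300
codons with ω = 4, LRT size over 20 null replicates at 6 taxa × 90 codons
with 3 discretization classes, NJ consistency over 50 seeded additive
matrices of 4–8 taxa, bootstrap at 100 replicates. Degenerate inputs are
handled by rule, not accident: dS = 0 windows report an undefined ratio;
saturated distances and Jukes–Cantor proportions ≥ 3/4 are errors naming
the offending pair; zero site likelihoods name the site; identical codons
contribute zero differences.

## Known limitations

Branch lengths are not re-optimized under M8/M8a; NG86 site counting does
not model transition/transversion bias (the likelihood engine does);
frequency classes treat genera as exchangeable units; and the
published-data reproduction requires the user to supply the original
GenBank-derived alignments, which the package cannot redistribute.
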