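---
title: "Methods: ortholog groups and selection footprints in the LRR-RLK family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ortholog groups and selection footprints in the LRR-RLK family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrrcore)
```

## Scope and model

`lrrcore` implements the desk-reproducible core of a phylogenomic analysis
of the plant leucine-rich-repeat receptor-like kinase (LRR-RLK) family:

1. a **gene-family simulator** producing gene trees with known
   duplication/loss history along a tagged 33-taxon species tree, plus
   receptor sequences with known extracellular-domain (ECD) architecture
   and branch-site test records with known ground truth;
2. **domain-architecture annotation** (LRR motifs, island domains,
   Cys-pairs, GDPC cleavage sites, hydrophobic SP/TM segments, kinase
   hallmarks);
3. **reconciliation**: LCA mapping of gene trees onto the species tree,
   duplication/loss counting, and rooting by minimising D + L;
4. **monocot/dicot ortholog group (MD OG) extraction** under support and
   species-count thresholds, simple/complex classification,
   presence/absence matrices and clade-loss detection;
5. **selection post-processing**: likelihood-ratio tests from paired
   branch-site log-likelihoods, Bonferroni significance coding, Bayes
   empirical Bayes (BEB) site filtering, and site-to-domain accounting.

The package deliberately does *not* run hmmsearch, MAFFT, PhyML, RAP-Green
or codeml; it consumes (or simulates) the kinds of records those tools
produce. The discovery-scale numbers that require the 33 real proteomes
(family size per genome, the identity of the 101 OGs) are represented by
packaged census tables; everything computable from those inputs is
recomputed by code.

## The simulator and what it emulates

`simulate_gene_family()` runs a birth--death copy process: one gene enters
the species-tree root, each extant copy duplicates or dies with exponential
waiting times on every edge (rates per unit branch length; packaged tree
edges default to length 1), and every surviving copy bifurcates at each
speciation node. `root_duplications` forces ancestral duplications at the
root, the mechanism that creates the paired ortholog groups analysed in the
selection module. True event labels, per-edge losses, and the true MD OG
roots (speciation nodes mapping to the angiosperm crown) are recorded.

No duplication/loss rates are available for the real family, so the
defaults (0.05 duplications and 0.02 losses per copy per unit length) are
illustrative: they produce families of roughly 40--250 genes on a 33-taxon
tree, the order of magnitude of single subgroups of the real family. The
simulator emulates topology and annotation structure only -- it does not
model sequence evolution, alignment error, or support estimation; supports
are attached separately by `assign_supports()` (all 1.0 by default, with a
noise model and exact per-node overrides to exercise the 0.85 filter).
Consequently, passing recovery tests demonstrate correctness of the
extraction logic under clean conditions, not robustness to phylogenetic
error in real trees.

`simulate_protein()` assembles receptors from an `architecture_spec()`:
SP–(MLD)–Cys-pair–(GDPC)–LRR×n with islands–Cys-pair–TM–kinase domain.
Each LRR unit instantiates the 24-position template
`LxxLxxLxLxxNxLSGxIPxxLxx` (11 canonical positions fixed, 13 free positions
drawn at random). Linker and island residues are drawn from a hydrophilic
alphabet that excludes Cys and the six canonical consensus residues, and
free LRR positions exclude strongly hydrophobic residues; these exclusions
make the scanner round-trip exact by construction rather than by tuning.
Real sequences are messier in every respect, which is why the scanner
thresholds below are configurable.

`simulate_branch_test()` samples the likelihood-ratio statistic directly --
central chi-square (df = 1) under the null, noncentral under selection --
rather than simulating codon evolution: the tests target the
post-processing, not the optimizer. BEB posteriors are drawn above 0.95 at
true sites and below 0.90 elsewhere.

Every `simulate_*` function is a pure function of its inputs and a seed,
scoped with `withr::with_seed()` so no global RNG state leaks.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| LRR template | `LxxLxxLxLxxNxLSGxIPxxLxx` | residues | plant extracellular LRR consensus, 24 positions, 11 canonical |
| LRR acceptance | ≥ 9 of 11 canonical matches | matches | transparent deterministic surrogate for a profile-HMM search; the original cutoffs are not recoverable |
| island floor `min_gap` | 48 | residues | two LRR units, so the smallest biologically described islands (two LRR-equivalents) are detected |
| Cys-pair window | 8 | residues | covers the CxC…CxxxxxxC spacings described in characterised receptors |
| hydropathy window / threshold | 19 / 1.6 | residues / Kyte–Doolittle mean | standard sliding-window surrogate for TM prediction |
| SP cutoff | 40 | residues | a hydrophobic segment starting later is a TM candidate |
| OG support threshold | 0.85, strict `>` | aLRT/SH-like support | the extraction rule is literally "support > 0.85" |
| OG species minima | 3 monocots, 4 dicots | species | guards against misannotated sequences forming spurious OGs |
| complexity threshold | ≥ 2 ancestral duplications | events | operationalises "duplications occurred disorderly"; species-terminal duplications are ignored because paralog content after the monocot/dicot divergence does not enter the classification |
| Bonferroni scheme | 0.05/24 and 0.01/24 | p | 24 tested branches; the two-tier coding is the unique simple scheme consistent with all 24 printed significance codes |
| BEB filter | posterior strictly > 0.95 | probability | "strictly above 95%" |

## Numerical and design choices

* **Null distribution of the LRT** is a plain chi-square with one degree of
  freedom, not the 50:50 point-mass mixture sometimes used for branch-site
  tests: recomputing all 24 packaged lnL pairs with the plain chi-square
  reproduces every printed p-value, so it is what the original analysis
  used. Negative `2(lnL1 − lnL0)` (optimizer noise) clamps to 0, p = 1.
* **Rounding** of reported means/percentages is half-up to one decimal,
  matching the printed precision. Two printed quantities do not match exact
  recomputation (a mean of 49.2 where the quotient gives 49.13, and 13.8%
  where the ratio gives 13.9%); the summarizer reports computed values and
  does not force-match. Similarly, the per-branch ECD site counts in the
  packaged branch table sum to 76 over the five strong pairs while the
  narrative total is 78; the summarizer reports the computed sums.
* **Reconciliation** is plain parsimony LCA mapping with equal weighting of
  duplications and losses; support-aware rearrangement heuristics are not
  reproduced (the two rooting approaches were reported to give very close
  root locations). Multifurcations are rejected rather than silently
  resolved, because simulated inputs are binary and silent resolution hides
  upstream errors. `root_by_dl()` evaluates every edge exhaustively; ties
  break by smaller D, then the lexicographically smallest sorted leaf list
  of the candidate child clade, so rooting is deterministic.
* **OG extraction**: outgroup (moss/spikemoss) genes just outside an OG
  root do not disqualify it, but outgroup leaves inside either child clade
  do -- "monocot/dicot bifurcation" is kept literal. Complex candidates are
  reported maximally: the highest supported, census-satisfying node with
  intermingled monocot/dicot leaves that neither contains nor is contained
  in another reported OG. A missing support on the root node is treated as
  full support; missing supports elsewhere are an error.
* **MLD detection is annotation-driven**, not sequence-based: the original
  analysis used custom profile HMMs that are out of scope here, so the
  malectin flag enters `domain_architecture()` as an argument.
* **Coordinates** are 0-based half-open everywhere internally; 1-based
  conversion happens only at I/O boundaries.
* The distribution of LRR counts per protein is described in the source
  with modes around 5, 20--21 in one place and 5, 10, 21 in another;
  the package takes no side -- `lrr_count_histogram()` simply reports exact
  counts and modes.

## Test design and problem sizes

The suite builds every fixture in code. Oracles are independent of the
paths they check: reconciliation and rooting are cross-checked against a
separately coded reconciliation (species sets with `ape::getMRCA`, path
lengths with `ape::nodepath`) over exhaustive re-rootings of 200 random
trees of up to 12 leaves; OG recovery uses the simulator's ground truth
over 100 seeded loss-free families; the architecture round-trip covers 100
seeded specifications; null calibration uses 5,000 replicates
(Kolmogorov--Smirnov uniformity, binomial 99% interval around the 5%
type-I rate, and the 11/24 canonical-position fraction). These sizes keep
the whole suite under a minute while leaving Monte-Carlo intervals tight
enough to detect real miscalibration.

## Known limitations

* The simulator's clean constructions cannot probe robustness to alignment
  error, fragmented gene models, or support miscalibration in real trees.
* The hydropathy SP/TM detector is a surrogate; its boundaries are fuzzy by
  ±~10 residues, which is why the generator leaves spacers around the
  Cys-pairs.
* Complexity classification depends on the reconciliation being computed on
  the same rooted tree as the extraction; feeding a different rooting is
  not detected.
* The packaged census tables transcribe printed inputs; quantities that
  would require the original 33 proteomes are not recomputed from sequence.
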