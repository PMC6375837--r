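---
title: "Marker-gene proxies for viral gene content: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-gene proxies for viral gene content: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markerprobe)
```

## The scientific problem

Cyanomyoviruses — T4-like phages infecting *Synechococcus* and
*Prochlorococcus* — exchange and lose accessory genes (including host-derived
auxiliary metabolic genes) so rapidly that no single gene records the whole
genome's history. Yet ecological interpretation of amplicon surveys hinges on
exactly that: when we amplify a fragment of the DNA polymerase gene *gp43*
from seawater, we want each sequence cluster to stand for a coherent genotype
with a predictable gene repertoire.

`markerprobe` implements the validation chain that justifies this use of a
marker gene, and the downstream community analysis:

1. **Gene-content phylogenetics.** Proteins from reference genomes are
   clustered into families at 50% amino-acid identity; for genomes $i$ and
   $j$ with $N_i$ and $N_j$ families of which $S_{ij}$ are shared, the
   distance is
   $$D_{ij} = -\ln\!\left(\frac{S_{ij}}{\sqrt{N_i N_j}}\right),$$
   zero for identical repertoires and growing as sharing decays. A
   neighbor-joining tree summarises the result.
2. **Marker congruence.** Full-length marker proteins give an alignment
   p-distance (optionally Poisson-corrected, $-\ln(1-p)$). A Mantel
   permutation test measures whether marker distance predicts gene-content
   distance.
3. **Threshold calibration.** Clustering amplicon fragments at a grid of
   identity levels, we ask at which level the *full-length* distances inside
   clusters stop varying — the level at which an amplicon OTU is a faithful
   proxy for a full-length genotype.
4. **Amplicon pipeline.** Paired 2 × 300 reads of the ~475 bp amplicon are
   quality-trimmed (Q30, minimum 36 nt), merged, translated (minimum 140 aa),
   dereplicated, clustered at 97% amino-acid identity, screened for chimeras
   and for similarity to a cyanophage reference panel (minimum size 500,
   singletons removed), and placed by nearest reference into clades.
5. **Community statistics**, all implemented from first principles in this
   package: rarefaction, Shannon alpha diversity and the additive beta
   partition, Bray–Curtis/Jaccard/Euclidean dissimilarities, PCoA, ANOSIM,
   CCA with permutation tests and forward selection, environmental
   classification, and Dufrêne–Legendre indicator values.

## The identity definition

Amino-acid identity is computed from a global alignment (BLOSUM62, affine
gaps: open 10, extend 1) as identical residue pairs divided by alignment
columns, *excluding terminal-gap columns*. The exclusion makes the measure
usable when a trimmed fragment is compared with a full-length sequence; the
alignment itself comes from `Biostrings::pairwiseAlignment()`.

Greedy centroid clustering visits candidates in a deterministic order
(length-descending with lexicographic ties for gene families;
abundance-descending for OTUs) and joins each sequence to the *first*
centroid at or above the threshold, as abundance-greedy tools do. For speed
the package first evaluates a bounded-shift ungapped identity (the shorter
sequence slid along the longer without overhangs, identity = matches /
shorter length) in compiled code; only comparisons falling within 0.05 of the
threshold are re-examined with the exact alignment, and cluster founders
whose nearest centroid fell in that band are re-checked and merged when the
exact identity reaches the threshold. For gap-free homologs — which is what
high-identity amplicon data are — the two measures coincide; the test suite
verifies the member-to-centroid invariant with the exact definition.

## Neighbor joining

Saitou–Nei agglomeration with two determinism rules: Q-matrix ties are broken
on the lexicographically lowest label pair, and negative intermediate branch
lengths are clamped to zero with the deficit moved to the sister branch so
the Newick output is always valid. On additive matrices the generating tree
is recovered to machine precision; the suite confirms this against an
exhaustive least-squares search over all unrooted topologies for up to six
leaves, and against `ape::nj()` on perturbed input.

## Permutation tests

All permutation p-values use the +1 correction,
$p = (\#\{T_{\pi} \ge T_{\mathrm{obs}}\} + 1)/(B + 1)$, one-tailed upper,
with a mandatory seed. Defaults are 999 permutations (199 inside repeated
simulation studies). The Mantel test permutes rows and columns of the second
matrix jointly; ANOSIM permutes group labels over mid-ranked
dissimilarities; the IndVal test permutes class labels against each OTU's
maximum indicator value; the CCA global test permutes sample rows of the
environment table against a pseudo-F on constrained inertia. Forward
selection tests each candidate's added inertia by permuting that candidate's
values — exact for the first step and a documented approximation for later
conditional steps.

## CCA from first principles

The community table is converted to chi-square standardized residuals
$\bar Q = (P - r c^\top)/\sqrt{r c^\top}$ with $P$ the relative table and
$r, c$ its margins. Constraints are weighted-standardized, row-weighted by
$\sqrt{r}$, and $\bar Q$ is projected onto their span; singular values of the
projection give the constrained eigenvalues. Axis importance is reported both
as percent of total inertia ("community variation") and as percent of
constrained inertia ("accumulated variation"). Eigenvalues agree with
`vegan::cca()` to 1e-8 in the test suite; collinear constraints (condition
number above 1e8) are refused with the offending variables named.

## Other statistical choices

- **Community dissimilarity** for ordination defaults to Bray–Curtis on
  relative abundances after rarefaction; Jaccard and Euclidean are options.
  The choice is exposed because the upstream literature rarely states it.
- **Beta diversity** is the additive Shannon partition
  $H_\gamma - \overline{H_\alpha}$ (0 for identical samples, at most
  $\ln$ #samples); a multiplicative variant is available behind a flag.
- **Environmental classes** come from k-means on z-scored variables (25
  restarts, seeded), classes renumbered by descending mean nitrate so class 1
  is the nutrient-richest — a declared convention, since the source analyses
  rarely say how classes were drawn. `k = n` returns singleton classes
  without invoking k-means.
- **Rarefaction** subsamples without replacement per sample and drops OTUs
  that become empty; it is a seeded, reproducible operation.
- **Saturated distances.** $S_{ij}=0$ in the gene-content formula and $p=1$
  under the Poisson correction are mapped to a configurable cap (default 10)
  rather than infinity, recorded in the result's attributes, so NJ and Mantel
  stay defined on degenerate inputs.

## The amplicon pipeline's substitutions

Three steps that published pipelines delegate to external tools are
implemented here as declared simplifications:

- **ORF selection** replaces a gene-calling model: six-frame translation,
  keep the longest stop-free run, discard below 140 aa. For single-gene
  amplicons frame selection is the entire problem, so this is adequate; a
  stop-free frame-1 read short-circuits the search since no other frame can
  exceed its run length.
- **Chimera flagging** is a two-parent (bimera) test: a candidate is flagged
  when some left/right split matches two distinct centroids of at least twice
  its abundance at ≥ 0.99 per-segment identity while no single parent reaches
  0.95. Split scanning uses equal-length parents.
- **The reference screen** replaces a BLAST search against a public database:
  an OTU passes if its best global-alignment identity to a supplied reference
  panel reaches 0.5 over at least 100 aligned columns. **Clade placement**
  replaces an evolutionary placement algorithm with nearest-reference
  assignment under a 0.75 novelty floor; amplicons from clades without a
  reference therefore report `"novel"` rather than founding new clades, a
  documented narrowing.

## What the synthetic generator emulates — and what it does not

`simulate_tree()` draws coalescent genealogies; `simulate_gene_content()`
evolves accessory families by Poisson gain/loss along branches over a core
that is never lost (defaults: 25 core families, pool of 120, gain and loss 8
events per unit branch length — chosen so 16 simulated genomes span roughly
the repertoire overlap range seen among sequenced cyanomyoviruses).
Families are realised as mutually unrelated random proteins so that 50%
clustering recovers them exactly, isolating clustering correctness from
simulation noise. `simulate_marker()` applies Poisson amino-acid
substitutions (default 0.3 per site per unit branch length) and slices a
158 aa (474 nt) amplicon on codon boundaries. `simulate_community()` places
genotypes on Gaussian niches along salinity and nitrate gradients
(temperature is carried as a pure noise covariate; defaults: salinity
28 ± 4 PSU, temperature 12 ± 4 °C, nitrate 10 ± 6 µM, niche width one
gradient standard deviation, lognormal noise sd 0.3 — a strong but realistic
coastal gradient). `simulate_reads()` draws 2 × 300 paired reads with
per-base substitution errors (default 0.3%) and a two-level quality model
whose low-quality 3' tails are exactly what Q30 trimming removes.

Deliberately absent: indels and frameshifts, PCR amplification bias and PCR
chimeras, position-dependent error profiles of real sequencers, and
within-family marker variation below the genotype level. Passing tests
therefore demonstrate algorithmic correctness and end-to-end recovery under
substitution noise, not robustness to every artefact of real libraries.

## Problem sizes and determinism

Every generator and every test is a pure function of a seed. The simulation
studies shipped in the test suite and the acceptance script use: 100 random
additive matrices (n ≤ 8) for NJ; 500 null replicates at 199 permutations
for Mantel and ANOSIM calibration; 20 sixteen-taxon histories for marker
congruence; ten 48,000-read pipelines (20 genotypes × 2,400 pairs at 0.3%
error) for recovery; and 20 twenty-sample communities for driver selection —
sizes at which the binomial bands and recovery rates quoted in the tests are
statistically meaningful.

## Known limitations

Greedy clustering is order-dependent by design and not formally nested
across thresholds; the calibration routine warns if cluster counts ever
decrease along the grid. The ungapped fast path can in principle misjudge a
borderline pair whose optimal alignment is gapped; the band fallback makes
this measurable only within 0.05 of a threshold. Forward selection's
conditional p-values are approximate beyond the first step. Nearest-reference
clade assignment cannot discover clades absent from the reference panel. The
gene-content distance treats paralogs as presence only.
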