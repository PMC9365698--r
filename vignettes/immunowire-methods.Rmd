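---
title: "Methods: from arrayed binding screens to predicted cell connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from arrayed binding screens to predicted cell connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunowire)
```

## Scope and model overview

`immunowire` re-implements the computational core of a quantitative immune
receptor interactome analysis: scoring of arrayed extracellular-interaction
screens, assembly of an affinity-annotated cell–cell interactome from
expression data, a mass-action kinetic model of cell–cell connectivity with
in silico protein knockouts, spatial receptor–ligand colocalization testing,
and interaction scoring of high-content-imaging cell tables. Every stage can
be exercised end to end on synthetic data with planted ground truth; nothing
in the package depends on downloads.

## Screen scoring

Arrayed avidity-based screens measure each protein pair twice, once in each
bait–prey orientation, as absorbance values on plates that carry additive
row/column batch structure. The normalization is Tukey's two-way median
polish: `signal = overall + row + col + residual`, iterated row-first to a
tolerance of `1e-8` a.u. with a 100-sweep cap. Row-first order matters only
at tie degeneracies, so it is fixed and documented rather than configurable.
Phases (primary and secondary screens) are polished separately so per-phase
batch effects never mix.

Pair scores sum the two polished orientations; homophilic pairs are doubled.
When one orientation is missing the available value is used un-doubled and
the pair flagged — the published rule sums orientations but does not state a
missing-data convention, so the package takes the conservative reading.
Selection uses the published threshold (combined signal of at least 1.0),
combination weighs the lower-throughput secondary screen three-fold, and the
promiscuity rule excludes proteins appearing more than 20 times in the top
1,000 ranked pairs, with ties broken by lexicographic pair id so the cut is
deterministic. On a desk-scale synthetic screen (tens of proteins) the
top-1,000 window exceeds the number of distinct pairs, which makes the
recurrence rule degenerate; the bundled pipeline therefore applies it to the
ranked selected-hit list, while the operation itself implements the rule
verbatim for full-scale inputs.

Benchmarking treats every distinct score as a classification threshold and
reports ROC and precision–recall curves with trapezoid AUC; random negative
reference sets are sampled without replacement from scored non-positive
pairs, ten per positive by default, under a caller-supplied seed. The test
suite checks the AUC against the Mann–Whitney pairwise-comparison identity
computed by brute force.

## Interactome assembly

Expression is binarized before integration: single-cell data by detection
fraction at least 10% (the boundary is read inclusively and the threshold is
a parameter), bulk data by non-zero expression in strictly more than half of
the replicates. The interaction key enumerates all ordered cell-type pairs
(including self-pairs, since homotypic interactions are biologically real)
against all network edges in both protein orderings; unmapped identifiers
are reported, never dropped silently, and edges present for every cell pair
are flagged ubiquitous for display filtering.

Affinity analyses work on `log10 K_D` throughout because affinities span
orders of magnitude; geometric means are reported alongside arithmetic ones.
The activation affinity-switch test classifies proteins by a fold change
greater than 2 on mean counts with a pseudocount of 1 (the published
analysis found the negative-binomial route and the fold-change rule gave
similar results; only the latter is in scope), pools one `K_D` per
interaction a classified protein participates in, and compares up- versus
down-regulated pools with a two-sided Welch t-test, Holm-corrected across
cell types.

Eigenvector centrality of the weighted cell-type graph (edge weight = count
of detected molecular interactions) is computed by power iteration to
`1e-10`. A small diagonal shift (`0.1 * max` row sum) is added during
iteration: it leaves eigenvectors unchanged but breaks the plus/minus
eigenvalue symmetry of bipartite graphs, where undamped power iteration
oscillates forever. Isolated nodes get centrality 0 with a warning.

## The connectivity model

Protein copies per cell become surface densities on an ideal sphere,
`rho = copies / (4 pi r^2)`. A 3D dissociation constant converts to the 2D
contact geometry as `K_2D = K_D N_A h` with confinement length `h = 0.01 um`
by default (about 6 molecules/um^2 per uM); `h` is exposed in
`model_config()` and only relative comparisons are claimed, since the exact
parameterization is not fixed by the published description. Per interaction,
bound density follows saturation (Michaelis–Menten) occupancy; because the
network is undirected the receptor/ligand role assignment is symmetrized by
averaging both directions (`symmetrize = FALSE` recovers the directional
kernel and its textbook half-saturation identity). Cell-pair affinity sums
bound densities over all shared edges; edges without a measured `K_D`
default to 1 uM — the centre of the observed low-micromolar affinity
distribution — and are flagged so sensitivity can be tested.

Connectivity itself is a law-of-mass-action doublet system: free cells of
types i and j collide at constant rate `k_c` and the doublet dissociates at
`kappa / max(A_ij, epsilon)`, inversely proportional to the relative
affinity. Only doublets are modelled; homotypic dimerization carries the
standard 1/2 formation factor and returns two free cells. Free-cell
frequencies are eliminated by exact per-type conservation, so conservation
holds to machine precision by construction. The integrator is an adaptive
exponential-Euler scheme — exact per step for frozen free frequencies, hence
stable against the stiff `kappa/epsilon` off-rates of non-interacting pairs
— followed, once the transient has decayed, by a damped Newton solve of the
fixed point `F_i (1 + (C F)_i) = init_i` (the standard run-to-steady-state
strategy). Equilibrium requires the detailed-balance residual below `1e-6`
of the flux scale.

Equilibrium states are converted to interaction scores with the same
equation used for the imaging data (below), so model predictions and
measured microscopy scores live on one scale. Knockouts zero one protein's
expression everywhere and re-run the chain; the comparison to measured
perturbations takes each protein's predicted top third of cell pairs by
|change|, requires the prediction maximum to reach one fifth of the median
prediction maximum (eligibility), and tests measured |changes| top-third
versus rest with a one-sided Welch t-test, Benjamini–Hochberg adjusted
across proteins.

Two fine points, decided here and tested accordingly. First, equilibrium
results depend on `k_c` and `kappa` only through their ratio — this is a
tested invariant. Second, interaction scores are *not* exactly invariant
under a uniform rescaling of all initial frequencies once binding depletes
the free pools appreciably (the fixed point is not scale-invariant); the
invariance holds in the dilute limit and is tested there with a `1e-3`
tolerance.

## Interaction-score convention

For a well, `score(A, B) = specific / (f_A f_B total)` where `specific` is
the count of type-B cells within 40 px of type-A cells (`N_AB` for distinct
types, `2 N_AA` for homotypic pairs, because each member of a homotypic
contact counts around the other), `total` is the total directed contact
count (twice the number of contact pairs), and fractions are of all cells in
the well. Under random mixing the expected score is 1 for every pair,
homotypic pairs included, and the off-diagonal matrix is symmetric because
`N_AB` already is. Summing the two directed counts off-diagonal instead —
a plausible alternative reading — doubles the expected off-diagonal score
under random mixing to 2 and breaks the calibration, which is why this
package uses the A-centric count; the model-state scoring uses the
identical convention (`D_AB` off-diagonal, `2 D_AA` homotypic, total
`2 sum(D)`). Contacts never span image sites. Normalization against control
wells is `(obs - ctrl) / max(obs, ctrl)`, bounded in `[-1, 1]` with the
`0/0` case defined as 0 and flagged; Welch t-tests run on raw replicate
values with Benjamini–Hochberg control at a 10% FDR, and rare populations
can be excluded by a minimum-cell-count filter.

## Spatial colocalization

Spot QC follows the published bounds literally: totals in `[4000, 36000]`,
mitochondrial fraction strictly below 20%, at least 2,000 genes per spot,
genes in at least 5 spots. The neighbour graph connects spots within 150
coordinate units (ties at the radius included, for determinism) and is
self-inclusive, since spots contain several cells and same-spot
co-expression is interaction-capable. The score for a gene pair is the
fraction of neighbour pairings, among those whose two members each express
at least one of the two genes, where one member expresses the first gene
and the other the second. Whether the published denominator is this
expression-positive set or all pairings tissue-wide is ambiguous; the
expression-positive reading is the default and `denominator = "all"` is the
documented alternative. The null keeps the same proteins and randomly
permutes which are paired (rejecting any permutation that preserves an
edge's partner); group comparisons use one-way ANOVA followed by Tukey's
HSD, with zero-variance degeneracy reported as a status rather than an
error.

## The synthetic world

The generators state a world once and the tests live in it:

* **Screen** — signal = overall + plate-row + plate-column effect + pair
  effect + Gaussian noise (sd 0.1 a.u. by default); true pairs get +2.0 a.u.
  in both orientations; ~5% of proteins are promiscuous baits adding
  +1.5 a.u. against a random 30% of partners (the recurrence-filter target
  phenotype); planted `K_D` values are log-uniform over `10^-7`–`10^-4` M,
  centring the distribution in the low micromolar range. Gaussian additive
  noise is an assumption matching what median polish targets, not a claim
  about the assay.
* **Expression** — lognormal baselines (300–30,000 counts/cell) over a 60%
  on/off cell-type structure, 4 replicates with 20% CV, a planted 20% of
  proteins regulated 2–8-fold up or down on activation, and a subtype table
  with a 0.9/0.1 split emulating dim/bright populations.
* **Spots** — square lattice at pitch 100 (so the 150-unit radius yields an
  8-neighbourhood plus self; the real array is hexagonal but only the
  neighbour contract matters), zonated gene pairs in bordering 2x3 spot
  blocks and distant control pairs in blocks separated far beyond the
  radius, plus ~2,400 ubiquitous background genes and mitochondrial genes so
  the fixed QC bounds are exercisable, with two planted QC-failing spots.
  Localized adjacent patches (rather than half-planes) are used because
  permuted partners of half-plane zones overlap spatially and would make the
  null score as large as the true one.
* **Cell tables** — cells placed uniformly per well; association propensity
  1 means random mixing, and for propensity above 1 partner cells are
  co-placed within the contact radius with probability proportional to
  `(preference - 1)`. This makes the random-mixing calibration (expected
  score 1) exact by construction and co-occurrence monotone in preference.

A green test on this world establishes that the implementations compute the
stated quantities correctly and recover planted structure under the stated
noise; it does not establish robustness to real-data pathologies (plate
spatial gradients beyond additivity, segmentation errors, spot deconvolution
effects, batch structure across donors), none of which the generators
emulate.

## Numerical choices

Median polish: tolerance `1e-8`, 100 sweeps, row-first. Power iteration:
`1e-10`, diagonal shift as above. ODE equilibrium: tolerance `1e-6` of the
flux scale, affinity floor `epsilon = 1e-12` purely as a division guard.
Ranking ties: lexicographic pair id everywhere a cut is taken. Seeds: every
generator and sampler takes an explicit seed and restores the caller's RNG
state; pipeline stages derive independent sub-seeds from the run seed.

## Known limitations

The package does not fit `k_c`, `kappa` or `h` to data, does not model
membrane mechanics or synapse organization, starts from segmented cell
tables (no image processing), and replaces the negative-binomial
differential-expression route with the published fold-change rule. The
comparison of baseline association predictions against external in vitro
measurements requires the external dataset and is out of scope.
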