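---
title: "Divergent but interacting paralog pairs: models and methods"
author: "dirpscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divergent but interacting paralog pairs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dirpscan)
```

# The question and the model

Recently duplicated genes inherit their protein-interaction context and lose
it gradually as their sequences diverge.  Against that background, some
paralog pairs are striking: their sequences have diverged far past the point
where homology-based interface conservation would be expected, yet they
remain close neighbours in the protein-protein interaction (PPI) network.
`dirpscan` implements a pipeline for finding such *divergent but
interacting* pairs (DIRPs) in a paralogous family (the motivating case is
the human Ras GTPase family), for identifying the amino-acid positions that
are specifically conserved within those pairs, and for asking whether those
positions sit in the binding interfaces the family uses to engage its
partners.

The pipeline has three statistical components:

1. **Network closeness by graph kernels.**  On a hub-filtered PPI graph we
   compute two node-similarity kernels on the largest connected component:
   the Laplacian exponential diffusion kernel $K = e^{-\beta L}$ (with
   $L = D - A$) and the commute-time kernel $K = L^{+}$, the Moore-Penrose
   pseudo-inverse of the Laplacian.  Kernel similarities are normalized to
   association probabilities by the cosine rule
   $p_{ij} = K_{ij}/\sqrt{K_{ii}K_{jj}}$ and transformed to distances
   $d_{ij} = -\ln p_{ij}$.
2. **Divergence by alignment identity and tree distance.**  Pairwise
   identity over mutually ungapped alignment columns, and patristic
   distances from a Newick tree rescaled by $d' = e^{\lambda d} - 1$ so
   that tree distances live on a scale comparable with $-\ln p$.
3. **Differential position conservation.**  For a pair set $S$ and every
   alignment column $c$ where the reference (template) row is ungapped,
   the mean BLOSUM45 score of the pairs in $S$ at $c$, minus the mean over
   all pairs in the alignment; significance from random pair sets of the
   same size.

## Selection thresholds

A pair enters the DIRP set when (i) its sequence identity is at most 45%
— the divergence regime BLOSUM45 was designed for, and the value that
corresponds to a normalized tree distance of about 1.7 under the default
$\lambda$ — and (ii) its kernel similarity is at or above the
$(1-\alpha)$ quantile ($\alpha = 0.05$, type-7 linear interpolation) of a
null distribution obtained by recomputing the kernel on 100
degree-preserving rewirings of the network.  The closeness test is applied
on the similarity scale, not on $-\ln p$; identity is the operative
divergence filter, with the 1.7 tree-distance gate available as an option
(`usePhyloGate`).  Selection is performed independently per kernel.

Hub removal precedes everything: nodes with degree $\ge$ 300 are removed
in a single pass, because nonspecific hubs create shortcuts that flatten
kernel distances.  Pairs that fall outside the largest connected component
after filtering are flagged unreachable and excluded from both the
numerator and denominator of selection rates.

## Null models and p-values

Degree-preserving rewiring uses double-edge swaps with rejection of moves
that would create self-loops or duplicate edges, attempting $10\,|E|$ swaps
per replicate; the degree multiset is preserved exactly.  Empirical
p-values use the permutation-standard add-one estimator
$p = (r+1)/(n+1)$, with ties counting as extreme.  With 100 replicates the
smallest attainable p is $1/101 \approx 0.0099$; a conservation threshold
of $p < 0.01$ is therefore met only by observations more extreme than
every replicate, which is the intended behaviour but also the resolution
limit — `significantPositions()` warns when asked for an `alpha` below it.

## The conservation statistic

For pair set $S$: $C_S(c) = \operatorname{mean}\{B[x_a(c), x_b(c)]:
(a,b) \in S\}$ over the pairs whose members are both ungapped at $c$
(gapped pairs are excluded rather than penalized; columns with under 50%
scorable pairs are flagged unscored).  The background $C_{bg}(c)$ is the
same mean over *all* pairs in the alignment, and
$\Delta(c) = C_S(c) - C_{bg}(c)$.  The null distribution of $\Delta(c)$
comes from 100 random pair sets of size $|S|$ drawn from the alignment's
pair universe; the test is two-sided because both directions are
meaningful (specifically conserved and specifically variable positions).
Scores are raw BLOSUM45 integers; $\Delta$ is invariant to any constant
shift of the matrix, so no diagonal normalization is applied.  Per-position
p-values are reported without multiple-testing correction, mirroring
per-position thresholds; a Benjamini-Hochberg option exists
(`significantPositions(..., adjust = "BH")`).  The per-position null is
the default; a pooled null across positions is available
(`pooledNull = TRUE`).

Positions are reported in reference numbering: column $c$ maps to the
$k$-th ungapped residue of the designated template row (label `"Y32"` for
tyrosine at template position 32).

## Interfaces from solvent accessibility

Binding interfaces are defined by accessibility loss: residue $r$ of the
designated chain is an interface residue when
$\mathrm{SASA}_{\text{alone}}(r) - \mathrm{SASA}_{\text{complex}}(r) >
1\,\mathring{A}^2$ (strict inequality; the threshold is exposed as
`deltaSASAThreshold`).  SASA is computed in-package with the Shrake-Rupley
quadrature: 960 near-uniform points per atom sphere (golden-spiral
layout), probe radius 1.4 Å, Bondi-type van der Waals radii
(C 1.70, N 1.55, O 1.52, S 1.80, H 1.20 Å, default 1.70).  At 960 points
the quadrature error against analytic sphere and two-sphere-overlap areas
is below 1%, which the test suite checks; the unbound state is the chain's
conformation extracted from the complex, not a separate apo structure.

Structures are grouped before tabulation: sequence-identical chains are
merged, then representatives are clustered by single linkage on pairwise
C$\alpha$ RMSD after Kabsch superposition, cut at 1.0 Å.  The Kabsch step
is implemented directly (SVD with a proper-rotation sign correction) so
that degenerate, collinear coordinate sets — which occur in idealized test
geometries — superpose cleanly.

## Overlap tabulation conventions

`matchPositions()` produces the two standard views: per complex, how many
query positions lie in its interface, with the ratio to interface size
reported as a percentage **truncated** to one decimal; per position, the
number of complexes whose interface contains it, ordered by descending
count.  Truncation (rather than round-half) is the package's reporting
convention for these ratios; both conventions appear in published
tabulations of this kind, and the choice only affects the last printed
digit.

`flankingParticipation()` classifies a position as *direct* when it lies
in at least one interface, *flanked* when it does not but both sequence
neighbours $i-1$ and $i+1$ are interface residues — by default in the
union of interfaces across complexes, since consecutive contact residues
are frequently split across different partner structures; a stricter
same-complex rule is available via `withinComplex = TRUE`.

`rasRegionMap()` carries the canonical Ras functional regions: Switch I
(30–38), Switch II (60–76), the C-terminal hyper-variable region
(166–189) and the nucleotide-binding site ({10–17, 28, 35, 57–60,
116–120, 145–147}).  Switch II is taken from residue 60 because residue 59
belongs functionally with the phosphate-binding DxxG motif of the
nucleotide site, which is also how the canonical region tabulations assign
it; multi-membership (e.g. T35 in both Switch I and the nucleotide site)
is intended.  Positions in no region are reported as "Inert".

# The synthetic universe

Because full interactomes, a 35-paralog alignment and dozens of complexes
cannot be bundled or downloaded at test time, every stage is exercised
against a generator with known ground truth (`syntheticSpec()`,
`synthFamily()`, `synthNetwork()`, `synthComplex()`):

* **Interactome** — a 300-node undirected preferential-attachment
  background (power 1, 2 edges per node), giving the heavy-tailed degrees
  the hub filter and kernels must cope with.  Each of 16 family members
  receives 3 private background partners; 5 disjoint planted pairs receive
  3 dedicated shared partners each.  Private and shared partner sets are
  sliced from one permutation, so decoy pairs share nothing by accident
  and the shared-partner count of a planted pair is exactly its
  specification.
* **Family alignment and tree** — a random tree (`ape::rtree`) whose tip
  sequences evolve by a per-site uniform substitution process with
  substitution probability $1 - e^{-\rho\,\ell}$ per branch of length
  $\ell$, at rate $\rho = 0.5$.  This produces the identity-versus-tree-
  distance gradient the selection relies on (rank correlation strongly
  negative; sibling pairs ~60–90% identity, distant pairs ~10–25%).  The
  planted pairs are chosen as the disjoint leaf pairs with the largest
  patristic distances, so they are genuinely divergent.  Planted
  conserved columns give each planted pair its own residue (drawn from the
  high self-score half of BLOSUM45, so the planted effect is several
  score units); planted variable columns hold one background residue
  family-wide and give one member of each planted pair a strongly
  mismatching residue.
* **Toy complexes** — two C$\alpha$-only poly-alanine chains, chain A
  extended at 3.8 Å spacing, chain B placed over the designated contact
  residues at 5.5 Å.  At that separation the vertical neighbour occludes
  ~7 Å² of the contact residue's surface while the diagonal neighbours
  clear the occlusion radius, so the true interface is exactly the
  designed set — a geometric ground truth for the SASA/interface stack.

What the generator deliberately does **not** emulate: correlated
substitution processes or indels (the alignment is gapless; gap handling
is tested on hand-built fixtures), interactome modularity beyond
preferential attachment, weighted or directed interactions, side-chain
packing, and any relationship between the synthetic alignment columns and
the toy-complex geometry.  Passing the synthetic suite therefore
demonstrates that the statistics recover planted signal of realistic
magnitude under honest nulls — not that real interactomes meet the
model's assumptions.

# Numerical and design choices

* $\beta = 1$ for the diffusion kernel (the value is not critical for
  ranking: at small $\beta$ the kernel approaches $I - \beta L$ and at
  large $\beta$ it flattens to the component average; both kernels are
  always computed, and selection is per kernel).
* Both kernels are computed by dense symmetric eigendecomposition, which
  keeps $K$ exactly symmetric and PSD at the few-hundred-node scales this
  package targets; node order is fixed lexicographically before any
  linear algebra so outputs are bit-stable.
* Non-positive kernel entries (possible for $L^{+}$) are floored at
  $p = 10^{-12}$ before the logarithm: such pairs are effectively
  infinitely distant.  $p$ is also clipped at 1 to absorb roundoff above
  the Cauchy-Schwarz bound.
* Quantile convention for thresholds: type 7 (R's default linear
  interpolation), documented so cutoffs are reproducible to the bit.
* All stochastic steps take explicit seeds; replicate $k$ derives its
  seed as `seed + k`.  Identical configuration and seed give identical
  outputs end to end.
* Degenerate inputs: empty networks error in the kernels; graphs without
  edges error in the commute-time kernel ("kernel undefined"); pairs with
  no mutually ungapped columns error in identity; an empty DIRP set is a
  valid selection result; a chain with no partner yields an empty
  interface.

## Problem sizes in the test and acceptance suites

The shipped suites run the full pipeline on the default synthetic
universe (316 nodes, 120 candidate pairs, 100 rewired replicates per
kernel, 100 random pair sets), calibrate the conservation test on 200
null profiles of a 12-member, 40-column family, validate commute times
against a Monte-Carlo walk simulator (1500 walks per pair) on graphs of
up to 8 nodes, and check the SASA engine against analytic sphere
geometry.  These sizes were chosen so the whole suite completes in well
under a minute while every statistical check retains enough replication
to be meaningful (three-standard-error bands for Monte-Carlo
comparisons, binomial-CI bands for calibration).

# Limitations

* The package consumes trees and alignments; it does not build them
  (no alignment or tree inference, no bootstrap).
* Unweighted, undirected graphs only; no edge-confidence weighting.
* The anti-conserved (specifically variable) direction of the
  conservation test has intrinsically lower power than the conserved
  direction: mismatch scores are bounded below, so a variable position
  can fall at most a few score units under the background mean, while a
  conserved position can rise by ten or more.  The suite asserts
  direction and effect for planted variable columns but does not demand
  their significance at $p < 0.01$ through the full pipeline.
* With 100 null replicates, $p < 0.01$ sits at the estimator's
  resolution limit; users wanting finer thresholds should raise
  `nRandomSets`/`nullReplicates`.
* HRas-equivalent numbering of non-reference chains is taken from author
  numbering; an alignment-based renumbering can be layered on via
  `mapToReference()` when chains are not already in template numbering.
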