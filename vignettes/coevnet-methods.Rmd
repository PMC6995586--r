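---
title: "Methods: coevolutionary couplings and structure networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coevolutionary couplings and structure networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevnet)
```

# Scope

`coevnet` implements a two-track analysis of protein families. The
sequence track asks which alignment columns co-vary, and whether that
covariation is direct (a pairwise statistical coupling) or transitively
induced; the structure track asks how the dynamic community architecture
of a 3D model changes across mutational variants. The package was built
around Cu/Zn superoxide dismutase (SOD1), whose metal-binding loops IV and
VII switch between intrinsic disorder (apo state) and order (metallated
state), but every function is generic.

# Sequence-space model

## Reweighting and frequencies

Protein family alignments are phylogenetically redundant, so raw counts
over-represent densely sampled clades. Each row $a$ receives weight
$1/m^a$, where $m^a$ is the number of rows (including $a$) with fractional
identity $\ge x$ to $a$; $M_\mathrm{eff} = \sum_a 1/m^a$ is the effective
sequence number. Identity counts matching symbols over all columns,
gap–gap matches included. The default threshold $x = 0.8$ is the
established convention for mean-field direct coupling analysis; it is a
free parameter of `compute_weights()`.

Frequencies are estimated with a uniform pseudocount $\lambda$ spread over
the $q$-state alphabet:

$$P_i(A) = \frac{1}{\lambda + M_\mathrm{eff}}\Big(\frac{\lambda}{q} +
\sum_a \frac{1}{m^a}\,\delta_{A, A_i^a}\Big), \qquad
P_{ij}(A,B) = \frac{1}{\lambda + M_\mathrm{eff}}\Big(\frac{\lambda}{q^2} +
\sum_a \frac{1}{m^a}\,\delta_{A, A_i^a}\,\delta_{B, A_j^a}\Big).$$

Site-diagonal blocks are set exactly to $P_{ii}(A,B) = \delta_{AB} P_i(A)$
so marginal consistency holds everywhere. The default
$\lambda = M_\mathrm{eff}$ follows the mean-field DCA convention; the
parameter is exposed because published analyses rarely state it, and
because the inference is only defined for $\lambda > 0$ (the correlation
matrix is otherwise singular). Gaps are a genuine 21st state of the model,
not missing data.

One design point deserves emphasis: with a large pseudocount, a mixture of
a uniform and an empirical distribution is not a product distribution even
when the empirical part factorises, so independent columns acquire small
pseudocount-induced couplings. This is inherent to the estimator, shrinks
with $\lambda/M_\mathrm{eff}$, and is one reason each `alignment` carries
its own alphabet: synthetic benchmarks over $q < 21$ states are analysed
in the $q$-state model that generated them, rather than embedding them in
a 21-state model where the 17 never-observed states dominate the
pseudocount mass.

## Mutual and direct information

Mutual information, $\mathrm{MI}_{ij} = \sum_{AB} P_{ij}(A,B)\,
\ln\frac{P_{ij}(A,B)}{P_i(A)P_j(B)}$, measures total dependence between
columns, direct or transitive. All scores use the natural logarithm
(nats). Direct coupling analysis fits a global Potts model by the
mean-field (naive inversion) approximation: the connected correlation
matrix $C_{ij}(A,B) = P_{ij}(A,B) - P_i(A)P_j(B)$ is built over $q-1$
states per site — the last alphabet state (the gap, for proteins) is
removed as the gauge reference — and couplings are read off as
$e = -C^{-1}$. Per pair, a two-site direct distribution
$P^{(dir)}_{ij}(A,B) \propto \exp(e_{ij}(A,B) + \tilde h_i(A) +
\tilde h_j(B))$ is constrained to reproduce the single-site marginals; the
auxiliary fields are solved by alternating marginal-matching updates
(tolerance $10^{-6}$ on the maximum marginal error, at most 500
iterations, with a hard error naming the pair if the residual remains
above bound). The direct information is the Kullback–Leibler divergence of
$P^{(dir)}$ from the product of marginals, and is symmetric, non-negative
and zero exactly when the pair coupling vanishes.

Rankings of pairs are deterministic: ties break lexicographically on
$(i, j)$. The minimum sequence separation for pair selection defaults to
5 positions, excluding the trivially coupled near-diagonal; contact
flagging uses Cβ–Cβ distances at 8 Å (Cα for glycine), the common
evaluation convention for coupling analysis — the analysis this package
reimplements does not define "imposing contacts", so both the atom rule
and cutoff are configuration knobs.

## Graphs, communities, cliques

Selected pairs become weighted undirected residue graphs (one per score
type). Every edge carries two attributes: `weight`, the coupling strength
used for modularity, and `length`, the distance used for shortest-path
quantities ($1/\mathrm{score}$ for coupling graphs, $-\ln|c_{ij}|$ for
correlation networks). This dual bookkeeping resolves a genuine ambiguity
— betweenness wants strong couplings to be short paths, modularity wants
them to be heavy edges — with one consistent convention everywhere.

Girvan–Newman community detection is implemented directly on these
primitives: iteratively delete the edge of globally maximal edge
betweenness (computed with `length`), score the component partition on the
*original* graph by weighted modularity, and return the partition of
maximal $Q$. Among equal-betweenness edges the lexicographically smallest
$(i,j)$ is removed, so the decomposition is deterministic. The stock
`igraph` decomposition could not be used as the implementation because it
applies one weight vector to both roles; it would also not expose the
deterministic tie-break. Maximal cliques use the Bron–Kerbosch enumeration
provided by `igraph`, reported in a deterministic order.

On the published SOD coupled-pair tables shipped with the package, the 18
top direct-information pairs span **35** distinct residues: residue 28
occurs in two pairs (15–28 and 28–99). The analysis we reimplement states
36; the package reports the count it computes.

# Structure-space model

## Elastic network and cross-correlations

`enm()` builds the anisotropic Cα elastic network: every residue pair
within the cutoff is joined by a harmonic spring, and the $3n \times 3n$
Hessian of the pair potential is diagonalised. Defaults — 10 Å cutoff,
uniform spring constant 1 — are standard Cα-network values (the source
analysis states neither); the spring constant only sets the energy scale
and cancels from correlations. A connected, non-collinear structure has
exactly six zero eigenvalues (rigid translations and rotations); these are
excluded from all downstream statistics. Disconnected structures are a
hard error suggesting a larger cutoff. Note that exactly collinear or
planar bead geometries are degenerate for a pair-distance Hessian
(perpendicular displacements cost no energy to second order); the toy
generators therefore only produce non-planar geometries for dynamics
fixtures.

Cross-correlations use the pseudo-inverse over internal modes with
equal-temperature $1/\lambda_k$ weighting:
$c_{ij} = \langle \Delta r_i \cdot \Delta r_j \rangle /
\sqrt{\langle \Delta r_i^2\rangle\langle \Delta r_j^2\rangle}$, a matrix
with unit diagonal, symmetric, invariant under rigid motion of the input.
The correlation network joins residues that are simultaneously in contact
and correlated ($|c_{ij}| \ge 0.35$ by default, a common choice for
dynamic networks; exposed in the configuration). Betweenness profiles are
normalised by $(n-1)(n-2)/2$.

## Variants and metal mimicry

Variants are specified as lists of `H63F`-style substitutions and applied
with wild-type validation. Because the Cα network sees only geometry,
substituting side-chain identities on fixed coordinates does not change
the model; variant analyses therefore use user-supplied per-variant
coordinates, and the test fixtures emulate the physics of metal binding
directly: `add_crosslink_node()` appends a pseudo-atom at the centroid of
the coordinating residues, tethering the loop as a bound ion would. This
is a deliberate, documented simplification — no homology modelling, no
all-atom detail.

The SOD1 variant definitions are reported inconsistently in their source:
the variant table assigns Cu-SOD1 = H120F and Zn-SOD1 = H71F, while the
narrative swaps the two. `sod1_variants()` defaults to the table and
offers `source = "text"` for the alternative; nothing downstream depends
on the naming.

# Synthetic data: what it emulates, and what it does not

`sample_potts_msa()` Gibbs-samples sequences from a Potts model with
planted matching-state couplings. Each sequence is an independent chain
burnt in for 50 full sweeps (no chain reuse, so samples carry no
autocorrelation; defensible for $L \le 100$), all chains advanced in
lockstep so the generator is vectorised and seed-deterministic.
Near-duplicate rows — a parent with 5% of positions re-randomised, i.e.
comfortably above the 0.8 identity threshold — exercise reweighting.
Planted pairs must respect the 5-position separation filter by
construction. The standard benchmark used in the acceptance checks is
$L = 50$, $q = 8$, $M = 4000$, ten disjoint planted pairs of strength
1.5 — sizes chosen so a full run takes seconds while leaving the
recovery far from trivial (1215 candidate pairs).

What the generator does *not* emulate: phylogenetic correlation between
sequences (rows are exchangeable), alignment gaps and insert states,
column-wise conservation gradients, and the long-tailed coupling spectra
of real families. Passing the recovery benchmark therefore demonstrates
the correctness of the estimator chain, not its real-data performance;
published per-pair scores for the SOD family are additionally not exactly
reproducible because the alignment release, $\lambda$, identity threshold
and contact definition behind them are unstated — which is why the
worked-example checks are computed *from the printed tables themselves*.

Toy chains (`make_toy_chain()`) provide an extended chain (3.8 Å
spacing), an ideal α-helix (2.3 Å radius, 1.5 Å rise, 100°/residue), and
an exchange-symmetric dimer of two mirror-image helical protomers.
Disorder fixtures plant high-scoring ranges (mean 0.7 inside, 0.15
outside, predictor-level offset sd 0.04, residue jitter sd 0.05) across a
six-predictor panel, mirroring the consensus panels used for real
disorder profiling.

# Disorder consensus

Per-residue predictor scores are averaged into a mean predicted disorder
score (PDS) with the standard deviation across predictors as the spread.
Classification is threshold-exact: disordered strictly above 0.5,
flexible in the closed interval $[0.2, 0.5]$, ordered below 0.2 — both
boundaries deliberately fall to *flexible*, following the "above 0.5"
wording of the convention this implements. Residues missing from every
predictor are dropped with a warning; pairs with an uncovered member are
annotated unknown and excluded from summary counts.

# Numerical choices and degenerate inputs

- All randomness is funnelled through explicit seeds; generators restore
  the caller's RNG state.
- The DI fixed point guards denominators at $10^{-300}$ and clips
  couplings at $e^{500}$ before exponentiation; genuine non-convergence
  (residual above 100× tolerance) is an error, not a silent result.
- Matrix symmetry is asserted within $10^{-8}$; DI values in
  $(-10^{-12}, 0)$ are floored to zero.
- Betweenness edge lengths are floored at $10^{-12}$ so perfectly
  correlated contacts (distance $-\ln 1 = 0$) remain valid shortest-path
  inputs.
- Edgeless graphs yield singleton communities with $Q = 0$; graphs with
  $n < 3$ get an all-zero centrality profile; alignments with fewer than
  two effective sequences are rejected with a clear error.
- Duplicate pairs in a graph specification collapse to the maximum weight
  with a warning; overlapping disorder ranges merge with a warning.

# Problem sizes

The shipped validation suite runs alignments up to $M = 5000$ rows and
$L = 50$ columns, elastic networks up to ~30 beads, and exhaustive
oracles (all set partitions of 8 nodes, all $2^{10}$ vertex subsets,
explicit path counting on 12-node graphs, finite-difference Hessians on
10-bead chains). These sizes keep every independent oracle exact while
exercising the same code paths a full-family analysis (e.g. $M \approx
4000$, $L \approx 150$ for a real Pfam domain) would use.

# Known limitations

- Mean-field inversion is a first-order approximation; couplings are
  biased at strong coupling or small $M_\mathrm{eff}$, and
  pseudolikelihood variants are deliberately out of scope.
- No average-product correction is applied to MI, matching the analysis
  this package reimplements.
- The Cα elastic network cannot see side-chain chemistry, so sequence
  variants only differ dynamically through the supplied coordinates or
  explicit cross-link nodes.
- Stockholm parsing covers the single- and multi-block core of the format
  (annotations are skipped), which is sufficient for Pfam-style files.
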