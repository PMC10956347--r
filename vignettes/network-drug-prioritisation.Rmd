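---
title: "Cell-type-resolved network drug prioritisation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-type-resolved network drug prioritisation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(celldrugnet)
```

`celldrugnet` screens a drug library against cell-type-specific disease
signatures derived from single-cell RNA-seq and aggregates the results into
one ranked list. This vignette explains the model behind each stage, the
parameters that matter, the numerical conventions the implementation fixes,
and what the synthetic benchmark does and does not demonstrate.

## Inputs and assumptions

The pipeline consumes five inputs on a shared integer gene-ID space: an
undirected protein–protein interaction network (PPIN) edge list, a
drug–target table with per-target pharmacological actions
(activate/inhibit/unknown), per-cell-type tables of differentially
expressed genes (DEGs) with signed log fold changes and adjusted p-values,
a denoised log10-scale expression matrix with cell-type labels, and a
ligand-to-target regulatory-potential prior. Everything upstream —
normalisation, denoising, clustering, cell typing, differential-expression
testing, and any ortholog mapping — is assumed done; the package starts
where those tables end. Only the largest connected component of the PPIN is
used, because shortest-path distances across components are undefined, and
self-loops are removed since they carry no information for either distances
or centralities.

## Stage 1: network proximity

For drug targets $T$ and a cell type's in-network DEGs $S$, the mean
closest distance is

$$d_c = \frac{1}{|T|}\sum_{t \in T} \min_{s \in S} d(t, s),$$

with $d(\cdot,\cdot)$ the unweighted shortest-path distance. Raw closeness
is confounded by degree — hubs are close to everything — so significance is
assessed against a degree-preserving permutation null: genes are sorted by
degree and packed into bins of at least `min_bin` (default 100) genes,
accumulating whole degree values until the bin is full and merging a
trailing undersized bin into its predecessor; each iteration redraws *both*
$T$ and $S$ by sampling uniformly within each gene's own bin, without
replacement inside each sampled set (observed sets are sets, so their nulls
are too). With null mean $\mu$ and standard deviation $\sigma$,
$z_c = (d_c - \mu)/\sigma$. A drug becomes a proximity candidate for a cell
type iff $z_c < -1.64$ (one-sided $P < 0.05$) and $d_c < 1$; both
inequalities are strict, matching the printed cut-offs.

Numerical conventions fixed here:

* $\sigma$ is the **population** standard deviation over the `n_iter`
  iterations (divide by $n$): the iterations are the whole null being
  summarised, and the choice keeps golden test values stable.
* If $\sigma = 0$ (e.g. a complete graph where every permuted distance is
  identical), $z_c$ is an undefined sentinel (`NA`) and the pair can never
  pass selection — preferable to fabricating $\pm\infty$ significance on a
  degenerate graph.
* Every (cell type, drug) pair draws from its own RNG substream, derived
  from the global seed and a hash of the pair's labels (mod $2^{31}-1$).
  Results are therefore byte-identical across reruns *and* independent of
  the order in which pairs are evaluated.
* DEGs outside the interactome are silently excluded from distance
  computations; a cell type with no in-network DEG is dropped with a
  warning rather than given undefined distances.

## Stage 2: pharmacological action

A drug counteracts a targeted DEG when it inhibits an upregulated gene or
activates a downregulated one; a target with unknown action is assumed
not to counteract. A candidate survives iff at least one of its targets is
a DEG of that cell type whose fold change it counteracts. Only targets that
are DEGs of the cell type are consulted — the filter asks whether the drug
opposes the observed signature, not what it does elsewhere — and drugs with
a mix of counteracting and aggravating targets survive, since the criterion
is "at least one". This stage is what removes, e.g., an agonist of an
upregulated cytokine that pure network proximity would rank highly.

## Stage 3: intracellular centrality

Each cell type's disease module is the largest connected component (LCC)
induced by its DEGs in the PPIN; equal-sized components tie-break towards
the one containing the smallest gene ID (an explicit convention — any
deterministic rule would do). Eigenvector centrality is computed on the LCC
subgraph alone and max-normalised to 1; on a connected graph the
Perron–Frobenius theorem guarantees strictly positive values, which the
implementation asserts to guard against sign-flipped eigenvectors. A drug's
intracellular centrality in a cell type is the geometric mean of the
centralities of its targets *inside the module* (targets that are DEGs but
fell outside the LCC do not count), and zero when that intersection is
empty. The combined intracellular centrality of a drug is the sum over cell
types.

## Stage 4: the multicellular disease model

Cell-type crosstalk is modelled from ligand activities. For a receiver cell
type, background genes are those with mean aggregate expression

$$Ea(i) = \log_2\!\Big(\sum_{j=1}^{k} 10^{D_{ij}} / k\Big) \ge 0.2$$

over its $k$ cells (inclusive cut-off; $D$ is the denoised log10
expression matrix). For every ordered (sender, receiver) pair of
DEG-bearing cell types — self-pairs included — the candidate ligands are
the sender's DEGs that appear in the prior; each ligand's activity is the
Pearson correlation between its regulatory-potential row and the binary
indicator of receiver-DEG membership, over the union of the receiver's
background genes and its DEG set, restricted to prior genes. Including the
gene set in the evaluation universe is a deliberate choice the activity
definition leaves open: the indicator must be able to take the value 1, and
requiring DEGs to also pass the background cut-off would silently shrink
the positive class. Zero variance in either vector yields activity 0 with
a warning. Only strictly positive correlations enter the model (negative
ones reflect association with background, not signal), and the directed
edge weight between two cell types is the sum of its kept ligands'
coefficients.

Cell-type importance is eigenvector centrality on this weighted directed
graph under the receiver-importance convention: a cell type's score is
proportional to the weighted sum of the scores of cell types signalling
*to* it (the principal eigenvector of the transposed adjacency). Directed
graphs can be reducible, in which case the principal eigenvector is
supported on a strict subset and says nothing about the rest; the
implementation detects this (vanishing Perron root, complex or mixed-sign
dominant directions, or near-zero mass on connected nodes) and falls back
to the symmetrised graph with a message. Self-loops are kept throughout.
The dense eigendecomposition is exact at MCDM scale (tens of nodes); the
symmetric fallback uses power iteration with a diagonal shift, which leaves
eigenvectors unchanged while making the leading eigenvalue strictly
dominant so bipartite and cyclic structures cannot oscillate.

## Stage 5: ranking and evaluation

A drug's intercellular centrality is the sum of MCDM centralities of the
cell types that selected it after both filters. The compound score is

$$\text{compound} = \text{intercellular} + 0.1 \times \text{combined
intracellular},$$

so cell-type importance dominates and intracellular centrality acts as a
tie-breaker. Ranking uses average positions for ties, so ranks always sum
to $N(N+1)/2$. Drugs with identical target sets and identical per-target
actions (biosimilars, salt forms) are forced into one tie group *before*
ranking and carry the group's best score and candidacy — grouping should
never penalise a drug. Drugs selected by no cell type are still ranked:
they follow all candidates, ordered by the intracellular term and then
alphabetically, so statements about any drug's position in the full library
are well defined. Precision and recall are the usual set-overlap ratios,
and "precision among the top $k$" means all drugs with rank $\le k$ — a tie
group straddling $k$ is included or excluded as a whole by its averaged
rank.

## The synthetic benchmark

`fixture_spec()` defaults define the package's benchmark conditions: a
400-gene preferential-attachment interactome (attachment parameter 2 —
connected by construction and degree-heterogeneous enough to exercise the
binning), 5 cell types with 25-gene connected planted modules, 60 cells per
type, an 80-drug library split between "good" drugs (2–4 in-module targets
with counteracting actions) and decoys (degree-matched random targets, or
in-module targets with aggravating actions — the agonist case), a 30-ligand
prior in which planted sender-DEG ligands mirror a receiver module, and an
expression matrix in which module genes clear the $Ea \ge 0.2$ cut-off in
their own cell type. `frac_counteracting` scales the probability that any
DEG-hitting target receives a counteracting action; at 0 the pharmacology
filter provably empties the candidate set. The minimal bin size for the
benchmark is 20, scaled down from the screening default of 100 in
proportion to the toy graph; both are exposed as `min_bin` everywhere.

The generator emulates the *interfaces and planted structure* the pipeline
needs, not real single-cell data: there is no dropout, no library-size
variation, no correlated module expression, and fold changes are drawn
independently of network position. Passing the benchmark therefore shows
that the pipeline recovers signal it is designed to see and rejects the
decoys it is designed to reject; it does not certify performance on real
tissue atlases, where DEG quality and interactome coverage dominate.

## Problem sizes and runtime choices

The test suite and the acceptance script run the permutation screen at
`n_iter = 200` on the default benchmark and the oracle comparisons on 200
random graphs of up to 30 nodes — sizes chosen so the whole suite completes
in a few minutes on one CPU while still estimating permutation nulls with
two significant digits. Production screens should keep the default
`n_iter = 1000`. Distance computations cache the all-pairs matrix when the
graph has at most 3000 nodes and fall back to per-query shortest paths
above that, so the same code path scales to a 17k-node interactome at the
cost of slower permutations.

## Known limitations

* Binary activate/inhibit actions cannot express dose-dependent or
  biphasic pharmacology; unknown actions are conservatively treated as
  non-counteracting.
* Ligand activities reduce cell–cell communication to a single Pearson
  correlation per ligand against a static prior; receptor expression in
  the receiver is not checked.
* The screened library is only as good as the drug–target table: targets
  missing from the interactome silently shrink a drug's target set, and
  drugs with no in-network target are excluded outright (their count is
  reported at load).
* Eigenvector centrality on small, nearly symmetric MCDMs separates cell
  types weakly; rankings then lean on the intracellular term, which is by
  design a tie-breaker only.
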