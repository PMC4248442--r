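---
title: "Inferring feasible metabolic pathways from transcriptome and phenotype microarray data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring feasible metabolic pathways from transcriptome and phenotype microarray data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feaspath)
```

## The problem

Fast-growing environmental mycobacteria such as *Mycobacterium
smegmatis* grow on a remarkable range of carbon and nitrogen sources.
Which metabolic routes the cell can actually run in a given medium is
not visible from the genome alone: a pathway drawn from sequence
annotation is only *feasible* if every one of its reaction steps has at
least one encoding gene expressed in detectable quantity. feaspath
implements a desk-scale version of the genome → transcriptome → phenome
integration that answers this question: it normalizes a two-replicate
expression array, flags genes as expressed, scores each pathway's step
coverage, resolves which member of a duplicate-gene (paralog) set is the
active one, discretizes Biolog phenotype-microarray (PM) respiration
kinetics into growth classes, and rationalizes the observed growth
calls with a transporter-plus-enzyme utilization rule.

No raw data for this kind of study are typically deposited, so the
package carries a first-class synthetic-data module. Its generators are
not test scaffolding: they encode the study conditions themselves
(array size, replicate noise, pathway composition, plate layout, growth
class mixture), carry ground-truth labels for every generated entity,
and are what both the test suite and the acceptance script run on.

## Expression normalization and flags

Raw per-gene intensities (strictly positive fluorescence units) are
log2-transformed and centered at a chosen percentile of each array:

$$x_i = \log_2 r_i - Q_p(\log_2 r)$$

with $p \in \{25, 50, 75\}$ and $Q_p$ the linear-interpolation
percentile (0-based order-statistic index $p(n-1)/100$; R's `quantile`
type 7). The transform is monotone, invariant to rescaling the raw
intensities, and idempotent on location. Log base 2 is the array
convention; any fixed base would do since the centering removes the
scale. Replicates are combined by the arithmetic mean of the normalized
values.

Two flags drive everything downstream, both computed from the averaged
vector with strict inequalities (ties fall below every cut, so a
constant array has nothing expressed):

* **expressed** — averaged value strictly above the 25th percentile of
  averaged values. The choice of the 25th cut as the feasibility gate
  is a genuinely open design point: the 25/50/75/90 summaries are all
  standard readouts, and no principled argument fixes one of them as
  "detectable". We default to the most permissive cut and expose it
  (`expressed_percentile`), so the sensitivity of a feasibility call to
  this choice can be checked directly.
* **above_median** — strictly above the median; this is the cut used to
  name the *active* member of a duplicate-gene set.

The linear-interpolation percentile has a useful distribution-free
property: for any $n$ distinct values, the number strictly above
$Q_p$ depends only on $n$ and $p$ (e.g. exactly 676 of 6,761 distinct
values exceed their 90th percentile), which the tests exploit as an
analytic oracle.

## Pathway feasibility and paralog resolution

A pathway definition is an ordered list of reaction steps, each with
one or more alternative gene loci (isoenzymes or paralogs). A step is
covered when *any* of its alternatives is expressed; coverage is the
fraction of covered steps; and the status is a deterministic function
of coverage:

| status | coverage |
|---|---|
| inactive | 0 (no member gene expressed at all) |
| partially_expressed | (0, 0.75) |
| mostly_expressed | [0.75, 1) |
| feasible | 1 |

The 1.0 / 0.75 cutoffs are package defaults: four verbal categories
("all", "most", "few", "none" of the genes expressed) need numeric
boundaries, and 0.75 is the smallest cut at which a 4-step pathway can
miss one step and still count as mostly expressed. Both are arguments,
not constants. Genes absent from the expression table count as *not
expressed* rather than being excluded from the denominator, so missing
evidence penalizes coverage — a conservative definition of feasibility.

Per step, the paralog resolver returns all above-median loci; when none
is above the median but some are expressed it returns the single
highest-expressed locus (lexicographic order breaks exact ties), and
when nothing is expressed the step is unresolved. This mirrors the
common observation that of a duplicated enzyme pair only one copy is
transcribed in a given condition, with the duplicates usually far apart
on the chromosome and under separate regulation.

## Annotation transfer and gene redundancy

Cross-proteome annotation transfer uses bidirectional best hits (BBH):
a query and a reference locus pair up when each is the other's unique
top-identity hit and the identity clears a threshold (default 30%).
Identity comes from a Needleman–Wunsch global alignment with match +1,
mismatch −1 and a linear gap penalty of −2, defined as matched columns
over the full alignment length (gap columns included). Database search
heuristics would not be reproducible at this scale, so the package
aligns exhaustively; the DP itself is delegated to
`Biostrings::pairwiseAlignment`, and the test suite keeps an
independent hand-written DP oracle that both rescoring and identity are
checked against. Two numerical details matter for determinism: exact
ties for the top hit (after rounding identities to 4 decimals)
disqualify a locus from having a unique best hit, and because a DP can
have several co-optimal tracebacks with different identities, the
argument order is canonicalized so identity is exactly symmetric.
"Identity" rather than similarity under a substitution matrix is a
deliberate reading: it is the stricter and more reproducible of the
two.

Duplicate genes within one proteome are the connected components (of
size ≥ 2) of the graph joining loci at ≥ 50% identity; the all-vs-all
identity matrix is exportable for dot-plot rendering, and chromosomal
separations are reported when coordinates are available.

## PM kinetics: metrics, discretization, clustering

Each PM well yields a respiration trace in OmniLog units (OU), read
every 15 min for 96 h. Per curve the package computes the maximum, the
trapezoidal area under the curve (AUC), the interpolated 48-h value,
and a lag time (first crossing of 10% of the maximum). Replicates are
averaged pointwise before classification.

Discretization is anchored rather than absolute, since OU are
arbitrary: a condition is **none** when its maximum exceeds the
plate's negative-control maximum by less than Δ\_none = 50 OU;
otherwise it is **high** when its AUC reaches ρ\_high = 0.6 of the
positive anchor's AUC (the glucose well of the carbon-source plate,
the natural reference nutrient), else **moderate**. The two thresholds
are package defaults exposed as arguments; the synthetic fixture's
class parameters are chosen so the classification is robust to ±50%
perturbation of either. The rule is monotone: pointwise-increasing a
curve can never demote its class.

Conditions are clustered agglomeratively with distance
$1 - r_{\text{Pearson}}$ between time-sampled curves and average
linkage, the conventional profile-clustering combination; dendrograms
export as Newick. One limitation is worth stating plainly: a
correlation distance sees only curve *shape*. Two logistic curves that
differ mainly in plateau height are nearly perfectly correlated, and a
no-growth well is a flat trace whose profile is undefined up to noise
(the constant-row case is dropped explicitly). So correlation
clustering separates growth classes only insofar as their kinetic
*shapes* differ; under this package's default kinetic parameters and
noise level the high and moderate archetypes correlate at ≈ 0.93,
which is why the anchored threshold classifier — not the dendrogram —
is the discretization of record, and the clustering fixture test runs
at zero noise where the metric's assumptions hold.

## Compound mapping and utilization prediction

Each PM condition optionally maps to one or more entry metabolites of
the metabolic network, plus transporter and utilizing-enzyme locus
lists. The utilization rule is the two observable requirements for a
nutrient to feed metabolism: the compound is predicted **supported**
iff a transporter is annotated for its uptake and at least one
utilizing enzyme is expressed in the reference condition *or* the
system is flagged substrate-inducible. The inducible flag exists
because several sugar uptake systems (fructose-type PTS clusters,
mannitol transporters) are silent on glucose yet induced by their own
substrate; gating them on reference-condition expression would wrongly
veto them. Predictions are compared with observed growth calls in a
2×2 concordance table over the mapped conditions.

Cross-species comparison consumes a utilization matrix of
growth/no-growth/NA calls per nutrient; rows with any NA are excluded
from every count (this is required for the common/unique tallies to be
well defined), and a row where both species fail to grow contributes
to neither. A transcribed 46-row carbon/nitrogen comparison matrix for
*M. smegmatis* vs *M. tuberculosis* ships in `inst/extdata/`.

## What the synthetic generators emulate — and what they do not

* **Expression arrays** (default 6,761 genes, two replicates): a shared
  standard-normal log2 signal plus independent Gaussian replicate noise
  with noise fraction 0.01 of total variance, so the expected replicate
  correlation is 0.99; exponentiation around a positive baseline gives
  strictly positive raw intensities. Duplicate-gene sets (default 24)
  are embedded by *selection* of already-drawn genes (active member
  above the 60th percentile, silent member below the 20th), which
  leaves the noise calibration untouched while guaranteeing exactly one
  above-median member per set. Not emulated: dye bias, spatial
  artifacts, probe-level effects, ties.
* **Pathways** (default 338: 257 feasible, 14 inactive, 57 partially
  and 10 mostly expressed; 3–15 steps; 1–3 alternative genes per step):
  member genes are drawn from the expressed/silent pools so the
  intended status holds exactly under the default flags. The
  composition is configuration, not inference.
* **PM plates**: three 96-well plates (95 + 95 + 94 test wells, 4
  negative controls, 284 test conditions) on a 15-min grid over 0–96 h.
  Curves follow $y(t) = A/(1+e^{-k(t-t_0)})$ with class parameters
  high (A = 250 OU, k = 0.15 h⁻¹, t₀ = 18 h), moderate (120, 0.10,
  30) and none (flat baseline at 5 OU), plus additive Gaussian noise
  clipped at 0. The noise sd is calibrated analytically so the
  expected cross-replicate correlation of 48-h values across the
  167/96/21 class mixture equals 1 − `pm_noise_ratio` (0.93 by
  default), mirroring the expression-module convention. Not emulated:
  dye chemistry, well-edge effects, plate-to-plate batch effects.
* **Proteomes**: a 48-protein reference with functional categories and
  EC numbers; a query containing point-mutated orthologs (identity
  targets 60–95%), 24 within-proteome paralog pairs at ≈ 92% identity
  placed > 1 Mb apart, and a few unmatchable sequences. Substitution-only
  mutation keeps the realized identity within rounding of its target.

Passing tests on these fixtures demonstrate that the machinery recovers
known structure under the stated statistical model; they do not
demonstrate robustness to the artifacts the generators deliberately
omit, and real-data feasibility calls inherit all the caveats of using
transcript abundance as a proxy for enzyme presence.

All generator randomness flows through one seed per component (derived
deterministically from the configuration seed), outputs are
byte-identical across repeated calls, and the global RNG state of the
caller is never touched.

## Problem sizes and numerical choices

The default fixtures are sized to the study they emulate (6,761 genes,
338 pathways, 284 PM wells at 385 time points × 2 replicates); the
proteome fixtures are desk-scale (dozens of sequences) because
exhaustive global alignment is quadratic. Percentiles are always
quantile type 7; all flag comparisons are strict; best-hit ties
disqualify; lexicographic order breaks the remaining ties; trapezoidal
integration is used on the native time grid with no curve fitting.
Degenerate inputs are rejected loudly (empty pathways, non-positive
intensities naming the offending locus, zero-variance correlation
inputs, unsorted time grids) rather than silently repaired.

## Known limitations

* Feasibility is expression-coverage only: no stoichiometry, no flux
  balance, no gap-filling, and no claim that a feasible pathway carries
  flux.
* The correlation-distance clustering is amplitude-blind, as discussed
  above.
* BBH with global-alignment identity is a deliberate simplification of
  database-scale homology search; it is exact and reproducible but not
  scalable to full proteomes, and identity thresholds are not
  interchangeable with similarity-matrix thresholds.
* The utilization rule is binary evidence logic; it does not model
  expression levels quantitatively, regulation, or transport kinetics.
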