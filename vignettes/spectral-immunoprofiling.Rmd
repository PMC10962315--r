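---
title: "Methods: spectral unmixing, gating and batch-effect assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral unmixing, gating and batch-effect assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specflow)
```

This vignette documents the models, conventions and numerical choices
behind `specflow`, in the spirit of a methods section: what each stage
computes, which parameters matter, and what the built-in simulator does and
does not establish about real data.

## The unmixing model

A spectral cytometer records, for every cell, a vector $y \in
\mathbb{R}^{D}$ over $D$ detectors ($D = 48$ on a four-laser instrument).
Each fluorophore $f$ has a *spectral signature* $m_f \in \mathbb{R}^{D}$:
its relative emission across detectors, stored normalized to unit Euclidean
norm so that signatures encode spectral shape only. Collecting signatures
as columns of $M$, the measurement model is linear,

$$ y = M a + \varepsilon, $$

and `unmix()` estimates the per-cell abundance vector $a$ by unconstrained
ordinary least squares through a QR decomposition. Negative abundances are
retained rather than clipped: they are unbiased noise around zero for
unexpressed markers, and clipping would bias downstream statistics.
Cellular autofluorescence is handled by appending an extra endmember to
$M$ — `extract_autofluorescence()` estimates it as the per-detector
*median* of an unstained control (median rather than mean, because debris
and aggregates contaminate unstained tubes). A rank-deficient $M$ (two
effectively identical signatures) aborts with the colliding pair named.

Panel compatibility is screened with the *similarity index*, the cosine of
two unit-norm signatures. The index is 0 for disjoint detector support and
1 for identical spectra; `validate_panel()` reports pairs above a ceiling
of 0.98, the conventional limit for dyes usable in one panel. The cosine
is the natural reading of a normalized spectral-overlap score with these
endpoints; whether vendor implementations restrict the detector subset is
not observable from outside, so the full-spectrum cosine is used.

Residual spillover that survives unmixing is corrected by a square
percent-coefficient matrix with diagonal 100 (`apply_compensation()`),
interpreted as vendor compensation tools do: with $S =$ coefficients/100,
observed $=$ true $\cdot S$, so the correction right-multiplies by
$S^{-1}$. A coefficient of $-2.79$ from channel A into channel B therefore
*adds back* 2.79 % of A to B. The coefficient is read as percent of the
source unmixed channel; a percent-of-peak-channel convention would differ
only by a channel-specific rescaling of the coefficient.

## Panel quality control

The stain index of a positive/negative peak pair is
$(\mathrm{median}_{pos} - \mathrm{median}_{neg}) / (2\,\mathrm{SD}_{neg})$,
with the plain SD, as the formula is conventionally printed. Everywhere
else the QC module uses a robust SD ($1.4826 \times$ MAD) because
cytometry noise is heavy-tailed.

The NxN screen replaces visual review of all marker-pair density plots
with a statistic. Spillover from marker $i$ into marker $j$ displaces
$j$'s *negative* cluster upward among $i$-positive cells — exactly the
population misalignment a reviewer looks for. The score for the ordered
pair $(i, j)$ is the shift of $j$'s negative cluster between $i^{+}$ and
$i^{-}$ events in robust-SD units, with positives and negatives split at a
data-driven density-valley threshold (`split_threshold()`). Conditioning
on $j$'s negative side is deliberate: the overall median of a strongly
bimodal marker is unstable (it jumps between modes with sampling noise),
so an unconditional median difference flags independent channels. The
default flag threshold is 1.0 robust SDs; the screen is a surrogate for a
visual procedure, so the cutoff is a package convention, not a literature
value. Pairs lacking enough events on either side are reported as not
evaluable rather than silently scored.

## Gating

Gating trees are declarative data: named nodes with a parent, an
expression, and a canonical-population flag. Threshold expressions use the
field's compact notation (`"CD25+/CD127-"`, terms ANDed, `!` for the NOT
gates used to exclude aggregate artifacts); two-channel rectangle gates
cover scatter. Membership of a node is always intersected with its
parent's membership, so containment holds by construction, and sibling
quadrants over the same two markers partition their parent exactly.

Gating operates on arcsinh-transformed intensities, $\mathrm{asinh}(x /
6000)$. The cofactor 6000 matches the simulator's raw intensity scale
(negative populations around 50, positives around 5000); for other data
the cofactor is a panel-config setting. Cutoffs sit at the geometric
midpoints between the expression-class centers — negative/positive at
$\sqrt{50 \cdot 5000} \approx 500$ (raw scale), positive/high at
$\sqrt{5000 \cdot 20000} = 10^4$, and an intermediate band between the
neg/int and int/pos midpoints — all expressed in transformed units and
overridable per marker. Ties break positive: intervals are half-open,
$[\mathrm{cutoff}, \infty)$, so an event exactly on a cutoff is assigned
to the positive side and partitions stay exact.

The standard pregates run in the published order: singlets (FSC-A/FSC-H
ratio within ±15 % of the modal ratio), non-RBC/debris (a low-FSC-A
exclusion at 28,000 — the panels contain no erythrocyte marker, so red
cells can only be removed on scatter; this is a package convention, not a
claim about how any instrument vendor does it), viability-dye-negative,
then CD45-positive. The basophil gate needs CD45-*intermediate* cells,
which the CD45+ pregate retains because the intermediate class straddles
the negative/positive cutoff from above.

`detect_rare_populations()` reports CD4/CD8 double-positive T cells
(CD4hi/CD8lo and CD4lo/CD8hi within CD3+), basophils
(CD45int/CD123hi/HLA-DR−, with the intermediate band running from the
CD45 cutoff to the 10th percentile of the CD45+ events — no numeric
definition of "intermediate" exists in the literature for this purpose, so
a data-driven one is used), and innate lymphoid cells by their
nine-marker exclusion phenotype.

Three panels ship as YAML data files. The bone-marrow hierarchy needed two
disambiguations where the tabulated definitions are not strictly nestable:
plasmablasts (CD20−/CD38+) sit beside CD20+ B cells under a CD19+
intermediate node rather than inside the CD20+ gate, and the NK node is
CD14−/HLA-DR−/CD127− within the CD19−/CD20− parent so that monocytes, DCs
and ILCs are excluded, following the narrative gating order. Checkpoint,
activation and NK functional markers are *overlay gates*
(`overlay_frequencies()`) attachable to any population rather than tree
nodes, since they quantify expression on populations defined elsewhere.

## The simulator

`simulate_sample()` draws each cell from a population template mapping
every marker to an expression class, log-normal on the raw scale:

| class | meanlog | sdlog |
|-------|---------|-------|
| neg   | ln 50   | 0.5   |
| int   | ln 800  | 0.5   |
| pos   | ln 5000 | 0.4   |
| hi    | ln 20000| 0.4   |

These defaults give stain indices near 10, typical of a well-titrated
panel. Markers a population's gating path does not constrain default to a
background class drawn positive at rate 0.002 — spurious positivity is
rare in clean populations, and a much higher rate would let background
draws leak measurable mass into downstream gates. Templates are derived
mechanically from the gating trees (`templates_from_gating()`), with two
supplements: a panel-wide baseline (CD45 positive — the hierarchies start
below the CD45+ pregate, so no gate constrains it) and per-panel
biological overrides for markers biology fixes but the tree never
references (B cells are HLA-DR+, monocytes CD11b+/CD33+, ...). Without
the overrides, negatively-defined gates — the T/B panel's NK gate is
CD3−/TCRγδ−/TCRαβ−/HLA-DR− — would swallow populations that are in
reality positive for the excluded marker, and the two PBMC panels would
disagree on the NK:CD45 ratio they are supposed to agree on.

Detector-space samples are mixed as $y = Ma + b\,\mathrm{af} +
\varepsilon$ with a per-cell log-normal autofluorescence intensity $b$
(meanlog ln 300, sdlog 0.3) and heteroscedastic Gaussian noise of SD $5 +
0.02\,|y|$. Artifacts mirror what the pregates remove: doublets are sums
of two random singlets (FSC-H takes the larger of the pair, so the
FSC-A/FSC-H ratio roughly doubles), dead cells carry a high viability
signal, red-cell-like and debris events are unstained with low scatter.
Default artifact rates are 2 % doublets, 3 % dead, 3 % RBC-like, 2 %
debris. All randomness flows from one seed and the global RNG state is
restored afterwards.

The synthetic signature libraries shipped with the panels are generated by
`make_signature_set()` with fixed seeds: Gaussian main peaks (SD 0.5–0.8
detectors) evenly spaced with jitter, plus a small red-shifted shoulder,
repaired iteratively until every pairwise similarity is at or below 0.98.
The narrow peaks keep the mixing matrix well conditioned so that OLS
unmixing does not amplify detector noise past the expression-class
separation; real dye spectra are broader and real panel design instead
avoids assigning spectrally adjacent dyes to markers that must be resolved
on the same cell. This is the main respect in which passing tests do not
certify behavior on real data: true spectral overlap (and the spillover
spreading it causes), marker–marker biology beyond the template logic, and
instrument drift within a run are all outside the simulator. What the
tests do establish is internal consistency: the unmixer inverts the
simulator's own mixing exactly, the gating engine recovers ground-truth
labels (≥ 99 % at 2×10⁵ events per panel), and the integration stage's
decision rule responds to injected batch structure as designed.

## Batch-effect assessment and correction

The integration stage follows the standard single-cell recipe. Marker
channels (viability and autofluorescence excluded) are arcsinh-transformed
and each channel is min-max scaled to $[-1, 1]$ — an affine map putting
every channel's extremes at ±1 and its center of range at 0, equalizing
the wildly different numeric ranges of fluorescence channels. (Min-max of
a median-centered vector is the same affine map, so the two common
phrasings of this scaling coincide.) PCA retains 20 components by default;
components are sign-fixed so the largest-magnitude loading is positive,
making scores reproducible. UMAP (via `uwot`, single-threaded, seeded)
gives the 2-D embedding; coordinates can be written back into FCS files
via `append_parameters()` + `write_fcs()`.

Mixing is scored by the local inverse Simpson index. For cell $i$, a
Gaussian kernel over its neighborhood — the cell itself plus its $k$
nearest neighbors, $k = 3 \times \mathrm{perplexity} = 90$ — is tuned by
binary search until the kernel entropy equals $\log(\mathrm{perplexity})$,
batch probabilities $p_b$ are the normalized kernel mass per batch, and

$$ \mathrm{LISI}_i = 1 \Big/ \sum_b p_b^2 , $$

the effective number of batches around the cell, ranging from 1 to the
number of batches $B$. Including the cell in its own neighborhood is a
deliberate convention: it makes the limiting cases exact (a cell among
perfectly interleaved co-located triplets has kernel mass exactly uniform
over three batches, hence LISI exactly 3) at the cost of a slight pull
toward the cell's own batch in intermediate regimes. LISI is computed in
2-D UMAP space by default — the space in which mixing is visually judged —
with PC space available; the two differ and the choice is reported with
the result.

The decision rule: cells with LISI above 2 (three batches) or 1.667 (two
batches) count as *high-LISI* (well integrated). If the high-LISI fraction
on the pre-correction embedding is below 20 %, the data cluster by batch
and correction is recommended. No threshold is invented for other batch
counts; `recommend_correction()` demands an explicit one.

`batch_correct()` is a pluggable stage. The external contract is a
function mapping (coordinates, batches, config) to corrected coordinates,
so an established integrator can be registered; the built-in reference
corrector iterates soft k-means moves in PC space: soft cluster
assignments, per-cluster per-batch centroid offsets, and subtraction of
each cell's assignment-weighted offset. The first pass is the $k = 1$
special case — global per-batch centering — which removes a constant batch
displacement even when batches are completely separated (a regime where
cluster-local offsets vanish because every cluster is single-batch);
subsequent passes refine with $k = 20$ soft clusters whose kernel
bandwidth is the mean squared point-to-center distance. Iteration stops at
10 rounds or when the mean-LISI gain drops below 0.01, and any move that
would *lower* mean LISI is rolled back, so the corrected embedding never
mixes worse than its input. This corrector is contract-tested (LISI
non-decreasing; shift-only batch centroids collapse to under 10 % of their
pre-correction distance; event count and truth labels untouched), not
output-matched against any published integrator.

## Numerical conventions and degenerate inputs

* FCS output is fixed to version 3.1, float32, list mode, little-endian;
  `$PnN` carries the channel token, `$PnS` the marker token. Reading
  supports FCS 3.0/3.1 with datatypes F/D/I; malformed headers, unsupported
  datatypes and truncated data segments raise distinct condition classes.
* CSV export is comma-separated, UTF-8, '.' decimal, full precision, one
  header row — and exports raw linear values by default; whether exports
  should be pre-transformed is a config decision left to the caller.
* Constant channels scale to all-zero with a warning; a single-population
  marker matrix min-max-scales to 1 by definition; percentages of an empty
  parent gate are 0; hierarchical clustering of the population-marker
  matrix (average linkage, Euclidean) breaks ties by lexicographic
  population name so orderings are deterministic.
* All simulation, k-means, and UMAP randomness is seeded; fixed seeds give
  bit-identical PC scores and LISI values, and UMAP coordinates identical
  per `uwot`'s single-threaded determinism contract.

## Problem sizes

The test suite exercises gating recovery at 2×10⁵ events per panel
(ground-truth assignment ≥ 99 %), the unmixing identity on 100 random
full-rank signature sets × 1000 events, and the integration scenarios at
3 × 2000 cells — sizes at which the binomial error on every tested
frequency is well below the tolerances asserted, while a full run of the
suite stays comfortably interactive. The simulator itself scales linearly
and has been run at 2×10⁶ events; the frequency-recovery bounds asserted
in the tests are the same ones that apply at that scale.

## Limitations

* The simulator's spectra are synthetic; no claim is made that shipped
  signature CSVs resemble any real dye, and vendor metrics that depend on
  proprietary definitions (panel "complexity" scores) are not reproduced —
  `panel_condition_number()` is a descriptive conditioning diagnostic
  only, not comparable to vendor values.
* Unmixing is plain OLS; weighted or Poisson variants appropriate for
  photon-counting statistics are out of scope.
* The reference batch corrector is a simplified contract-tested stand-in
  for full diversity-penalized clustering integrators; over-correction of
  genuine biology (e.g. a donor-unique malignant clone) is possible with
  any corrector, which is why the recommendation step, not the corrector,
  is the default entry point.
* Gating cutoffs are per-panel constants calibrated to the simulator's
  intensity scale; real data need per-sample inspection or the
  density-valley estimator.
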