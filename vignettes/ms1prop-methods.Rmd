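---
title: "Methods: MS1-centric peptide identity propagation in ms1prop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MS1-centric peptide identity propagation in ms1prop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ms1prop)
```

# The model

`ms1prop` transfers peptide identifications between runs using MS1
evidence only. The measurement model is linear: an MS1 frame (one TIMS
ramp, a nonnegative matrix over m/z bins and 1/K0) is treated as a
nonnegative combination of candidate precursor isotope envelopes plus
residual signal. For each scan at time $T_i$, only candidates whose
retention-time window contains $T_i$ enter the scan-specific dictionary
$D$; for every ion-mobility column $s$ of the frame we solve

$$ a = \arg\min_{a \ge 0} \lVert s - D a \rVert_2 , $$

with no sparsity penalty. Nonnegativity is the physically meaningful
constraint — activation is a share of observed ion current — and is what
makes the per-column problems well posed even with overlapping isobars,
provided the envelopes are linearly independent on their shared support.
Stacking the per-scan solutions along retention time and slicing per
candidate yields the precursor *activation image*, the object every
downstream step consumes. Image pixels are expressed on the
deposited-signal scale (the NNLS coefficient times the candidate's
envelope abundance sum), so summing a masked image estimates the
precursor's ion current directly.

Key assumptions, and where they matter:

* **Binned m/z adequacy.** Envelope peaks and frame points are aggregated
  into fixed-width bins (`mz_bin_width`, default 0.01 Th). Two species
  whose peaks fall in the same bins are indistinguishable to the solver;
  this is intentional — disambiguation is deferred to the ion-mobility
  dimension, the search windows, and the downstream models.
* **Window correctness.** A candidate eluting outside its RT window is
  unrecoverable by construction. Windows are therefore calibrated
  percentiles of measured prediction error, not fixed constants.
* **Separability per column.** Columns are solved independently; no
  elution-shape coupling across scans is imposed. This keeps the solver
  exact and trivially parallel at the cost of ignoring temporal
  smoothness, which the segmentation model recovers at the image level.

# Dictionary construction

Evidence tables are merged on (modified sequence, charge), keeping the
highest observed intensity per key; ties resolve to experiment-sourced
records to keep the merge deterministic and idempotent. Isotope
envelopes are computed by exact per-element convolution aggregated by
neutron count: the zero-neutron peak carries the exact monoisotopic
mass, heavier peaks abundance-weighted mean masses, which is ample
accuracy at 0.01 Th binning. Peaks at or below `isotope_min_abundance`
(default 0.01, i.e. 1%) of the total distribution are dropped *without*
renormalising the survivors, so activation coefficients stay comparable
across candidates.

Retention-time prediction is a pluggable interface with two built-ins:
an external prediction table (modified_sequence, charge, rt_pred[,
im_pred]) or LOWESS alignment of the reference run onto the experiment
run through their shared precursors (at least 20 required). Alignment
output is forced monotone (cumulative maximum of the fitted curve) so
the mapping is single-valued even under nonmonotone noise. A deep
retention-time transfer model would slot into the same interface; the
package deliberately does not bundle one.

Calibration statistics are computed on a seeded holdout
(`rt_holdout_fraction`, default 10%) of the experiment library:
$\Delta RT_{95\%}$ and $\Delta IM_{95\%}$ are 95th percentiles of
absolute prediction error, and $L_{1/K0}$ is the
`im_length_percentile` (default 99.9) percentile of experimental 1/K0
lengths. All percentiles use linear interpolation between order
statistics (R type 7), applied identically everywhere. The RT window is
$RT_{pred} \pm \Delta RT_{95\%}$; elution length is not added because
the calibration error dominates it. The 1/K0 window is
$center \pm (\Delta IM + L_{1/K0}/2)$: mobility is reproducible enough
that the peak's own width is comparable to the calibration error, so
both terms appear. In experimental mode $\Delta IM$ is the
cross-library deviation (95th percentile of |experiment − reference|
1/K0 on shared precursors, falling back to `im_delta_experimental`,
default 0.025); in predicted mode it is the holdout prediction error.
For the exact-dictionary use case (search results from the same run)
`window_mode = "evidence"` takes the RT range and 1/K0 center ± half
length straight from the evidence instead.

Decoys use the fixed-mapping two-round mutation rule: residues 2 and
n−1 are substituted; when the decoy's neutral monoisotopic mass stays
within `mz_bin_width × charge` of the target's — meaning the two
envelopes land in the same m/z bins and the decoy would be
indistinguishable to an MS1 search — residue n−2 is mutated as well.
The closeness tolerance is configurable (`decoy_closeness_tol`).
Decoys whose sequence collides with any target are removed; sequences
shorter than four residues get no decoy (the mutation positions would
collide) and are excluded from target–decoy competition. The mutation
map is configuration data (two-column TSV); a standard fixed mapping
ships as the default, and the test suite exercises the rule with an
explicit toy map so correctness never rests on the default's content.

# Peak selection and confidence scoring

The segmentation and scoring models are deliberately compact, CPU-scale
learners built for the activation-image domain rather than a generic
deep vision stack:

* **Segmentation** is a pixelwise multilayer perceptron (hidden sizes
  16/8) over multiscale contextual features computed from the model
  input: the scaled activation and log-activation channels, box-averaged
  context at radii of 1/32 and 1/8 of the image side, positive- and
  negative-hint window indicators at radii 1/16 and 1/4, and the signed
  and absolute pixel offsets from the positive hint. These features give
  the classifier exactly the cues the task defines — "bright, near my
  predicted coordinates, not nearer to a competitor's" — while keeping
  training deterministic and fast on one CPU core.
* **Scoring** summarises the four channels (the segmentation output is
  channel 4) into image-level features — hint-local activation at two
  scales, activation/segmentation agreement, apex-to-hint distance,
  competitor-local activation — feeding an 8-unit hidden layer and a
  single logit; the sigmoid is the confidence score in [0, 1].

Everything around the learners follows the standard training contract:
seeded 8:1:1 train/validation/test split shared by both models, Adam
with a one-cycle learning-rate schedule (peak `max_lr` 0.03, chosen so
the segmentation model can fit a small separable pool within the epoch
budget; 30% linear warm-up, anneal to 1% of peak), minibatch 32, at most
100 epochs with early stopping at patience 10 on validation loss.
Segmentation minimises the combo loss
$1 \cdot \mathrm{BCE} + 4 \cdot \mathrm{dice} + 1 \cdot \mathrm{focal}$
(focal $\gamma = 2$, $\alpha = 0.5$; dice smoothing 1 — the literature
names the components but not these constants, so they are package
choices, exposed in `ms1prop_config`). The scorer minimises
BCE-with-logits. Training pools are restricted to experiment-library
candidates (whose label rectangles are known) and their decoys;
reference-only targets are excluded because absent targets are
indistinguishable from decoys and would poison the labels.

Geometry is handled by explicit linear operators. Bilinear resize to
`image_size` (default 258) is an interpolation-matrix product; hints and
label rectangles are placed directly on the resized grid through the
crop's coordinate transform (pixel-center membership), never resampled,
so ±1 hints cannot leak across pixels. Predicted masks are binarised at
`mask_threshold` 0.5 and mapped back to native resolution by majority
area — a native pixel is on iff more than half of its area maps to
on-pixels — which preserves axis-aligned rectangles under round trips.
Min–max scaling is per image; a constant image scales to all zeros.
`log_eps = 1` is added before log10 so empty pixels stay finite.

The quality metric is the intensity-weighted intersection-over-union,
$\sum_{pred \wedge true} I / \sum_{pred \vee true} I$, defined as 0 on a
zero-intensity union. It is symmetric, bounded, reduces to plain IoU
under uniform intensity, and connects directly to quantification error:
with nested masks and all signal in the union, a weighted IoU of $w$
bounds the log2 intensity deviation by $|\log_2 w|$ — the quantity
`scripts/acceptance.R` recomputes.

# FDR control

Targets and decoys are searched separately (no competition inside the
solver). The post-processing chain is fixed: intensity filter (strictly
below `intensity_threshold` 100 removed), target–decoy competition
(higher confidence survives; exact ties remove the *target*, the
conservative choice), signal competition, then the confidence-threshold
sweep. Signal competition addresses a failure mode specific to separate
searches: two candidates in the same monoisotopic m/z bin, within
$2\Delta RT_{95\%}$ and $2\Delta IM_{95\%}$ of each other, whose log10
inferred intensities differ by less than 0.01 are treated as claims on
the same MS1 feature, and the lower-confidence claim is dropped.
Competing edges are processed in descending order of their larger
confidence and removed candidates cannot eliminate others — a
deterministic resolution of multi-way chains that the pairwise rule
alone leaves open. `FDR = N_{decoy}/N_{target}` is tabulated at every
distinct confidence value; the chosen threshold is the smallest with
FDR at or below `max_fdr` (default 0.20 — an honest operating point for
MS1-only evidence, far from MS2-grade 1%), which may be 0 when the
unfiltered set already qualifies. The table reports raw FDR; a
q-value-style cumulative-minimum column (`fdr_monotone`) is provided as
a clearly-labelled extension. Decoys surviving the sweep are reported
and flagged rather than silently dropped.

# The synthetic-data generator

The generator is the package's test bed and defines its study
conditions. Libraries draw tryptic-like sequences (length 7–30,
C-terminal K/R, interior residues at natural frequencies), charges 2–4
(0.6/0.3/0.1), retention times uniform over the gradient, elution
lengths log-normal with median 0.16 min, 1/K0 centers correlated with
m/z and charge, 1/K0 lengths log-normal with median 0.072 and 75th
percentile 0.096, and log10 intensities normal (mean 5.5, sd 0.6) —
scales matching a 30-minute LC gradient on a TIMS instrument. Frames
deposit each precursor as a separable Gaussian elution × mobility
profile of its isotope envelope, truncated at ±4σ with the *discrete*
profile renormalised, so the noiseless deposit equals the ledger total
times the envelope abundance sum exactly; conservation checks in the
suite are therefore exact, not asymptotic. Optional noise adds
uniform-m/z points with exponential intensities and never alters the
ledger. The mixture design assigns species labels at fractions
human/yeast/E. coli = 0.65/0.30/0.05 (condition A) and 0.65/0.15/0.20
(condition B), giving expected between-condition ratios of 1, 2 and
0.25.

What the generator does *not* emulate — and hence what green tests do
not establish about real data: chromatographic tailing and peak-shape
irregularities, charge-state envelopes spanning multiple states,
calibration drift within a run, detector saturation, and realistic
isobaric interference density (the `interference` preset plants
composition-preserving sequence permutations, a harder case than most
real interference, but at toy density). Real-data performance claims
require real raw data and are outside this package's test scope.

# Numerical choices

* NNLS: Lawson–Hanson active set, dual tolerance `nnls_tol` 1e-10,
  at most 3·(number of candidates) outer iterations; rank-deficient
  passive sets drop the entering column rather than failing.
  Independent per-column solves over connected components of the
  bin–candidate graph are exact, not approximate (the objective
  separates), and the suite checks block/monolithic agreement to 1e-9.
* Off-grid 1/K0 points snap to the nearest grid value within half a
  local grid step, else are dropped and counted.
* Scan admission is inclusive on both window boundaries.
* Degenerate cases: all-zero frame columns short-circuit to zero
  activation; a candidate whose windows intersect no data yields a
  flagged 1×1 zero image; constant images scale to zero channels.
* All randomness flows from one master seed fanned out to named
  per-stage sub-seeds (`stage_seed`), making every stage independently
  re-runnable and the whole pipeline bit-reproducible at the level of
  written TSVs.

# Problem sizes

The bundled presets and tests are sized for a single CPU core: the
`tiny` preset uses 40 precursors and 60 frames (1.2 min simulated
gradient, 0.02 min frame spacing) and runs the full pipeline in seconds;
model-quality checks train on pools of ~120 images at `image_size`
48–64; the FDR calibration simulation uses 2000 target candidates. The
default `image_size` of 258 remains the production setting; the smaller
test sizes exercise identical code paths through the same configuration
surface.

# Known limitations

MS1-only evidence cannot read sequence; discrimination rests entirely on
envelope, RT and mobility agreement, so close isobars within one search
window remain the dominant error source, mitigated but not eliminated by
the hint channel and signal competition. The segmentation features are
local; no cross-image context is shared. The per-column solver ignores
elution smoothness. Protein-level inference, MS2 rescoring and vendor
raw-file access are out of scope by design.
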