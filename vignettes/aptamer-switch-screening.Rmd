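---
title: "Methods: analysis of massively parallel aptamer-switch screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysis of massively parallel aptamer-switch screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adscreen)
```

## The screen

An anchored displacement strand (ADS) screen converts a known aptamer into a
fluorescent molecular switch. The aptamer strand (quencher-labeled) is
hybridized to a library of switching strands (fluorophore-labeled) through a
shared anchor duplex; each switching strand carries a randomized 10-nt
switching domain (SD) that interacts with the aptamer. Target binding changes
the aptamer's conformation, and with it the fluorophore-quencher distance, so
a responsive SD shows a fluorescence change between buffer and target images.

The constructs are assembled on a sequencing flow cell, which supplies both
halves of the measurement: sequencing yields each cluster's SD (genotype),
and imaging the flow cell in alternating buffer/target cycles yields each
cluster's fluorescence trajectory (phenotype). This package implements the
dry half of the screen: linking the two, filtering and ranking candidates,
characterizing top SDs against the aptamer sequence, and fitting binding
models to follow-up plate-reader titrations.

## Linking genotype to phenotype

Three file families describe one run:

* **FASTQ** — read names carry `tile:x:y` with integer coordinates;
* **locs** — per-tile float32 cluster positions, in cluster-index order;
* **intensity files** — per-tile, per-cycle four-channel int16 RFU values,
  sharing the locs cluster index.

The intensity dialect used here is a simplified, fully specified CIF-like
layout (13-byte header, channel-major int16 payload, one cycle per file). It
reproduces the *roles* of the instrument's files; it does not claim
bit-compatibility with any particular instrument software version, whose
byte layouts vary. All binary I/O is little-endian, and every reader is the
exact inverse of its writer, which is property-tested on random payloads.

A locs coordinate `c` maps to FASTQ space as `round(10 * c + 1000)`. The
instrument's rounding mode at `.5` boundaries is not recoverable from data,
so `locs_to_fastq_coord()` fixes half-up rounding and `link_tile()` matches
against the candidate set `{floor, ceiling}` of `10 c + 1000` in both axes.
This absorbs any rounding-mode difference and locs-space drift up to
±0.049 units (±0.49 FASTQ units). Matching is one-to-one: reads or clusters
involved in multiple cross-matches are counted ambiguous and dropped rather
than resolved by distance — there is no principled resolution rule at this
resolution, and dropping is conservative for hit calling. The SD's position
in the read is a configurable layout (default: offset 0, length 10).

## Screen statistics

For each linked cluster, `summarize_conditions()` computes per-condition
means and replicate RSDs (sample standard deviation over a condition's
replicate cycles divided by the mean; the *n−1* denominator is used because
replicate counts are small, 4–5 cycles), and the ratio of each target
condition's mean to the buffer mean. `apply_filters()` then removes:

* clusters with buffer mean below **100 RFU** — dim clusters are dominated
  by background noise;
* clusters with buffer mean above **1000 RFU** — typically image-processing
  artifacts or debris;
* clusters whose replicate RSD in buffer *or any target condition* exceeds
  **30%**.

The RFU window is applied to the buffer-condition mean: "initial
fluorescence" is the buffer image, and applying the window to target cycles
would bias against strong signal-on switches whose target intensity
legitimately exceeds the window. Removal reasons are recorded in a fixed
check order (`low_rfu`, `high_rfu`, `buffer_rsd`, `target_rsd`), but the
retained/removed membership is the union of the four conditions and is
independent of that order.

Ranking sorts retained clusters by ratio — descending for signal-on,
ascending for signal-off — with a total tie-break (higher buffer mean, then
lexicographic SD) so output is byte-deterministic. Because responsive SDs
recur across clusters, `aggregate_unique_sd()` collapses clusters sharing an
SD into one entry whose aggregate ratio is the **median** of cluster ratios
(robust to stray clusters); cluster means over replicate cycles and the
median across clusters are the package's documented estimator choices, and
both cluster-level and SD-level rankings are exposed because screens can
reasonably operate on either. For multi-concentration screens (e.g. buffer /
10 mM / 100 mM), ranking defaults to the lowest target concentration —
responsiveness in the low range is the property of interest — and the higher
concentration remains available as a consistency column.

The imaging channel carrying the switch fluorophore is selected when the
cluster table is built (`build_cluster_table(channel = )`, default channel
0) and recorded in `filter_config()`; the cluster table itself stores one
intensity column per cycle.

## Sequence analysis of top switching domains

Two complementary views characterize how top SDs engage the aptamer:

* `longest_complementary_run()` finds the longest contiguous perfect
  antiparallel Watson-Crick duplex — the longest common substring of the
  SD's reverse complement and the aptamer. Runs under 3 nt are discarded as
  chemically meaningless; equal-length ties resolve to the 5'-most aptamer
  position so the per-position histogram (`position_histogram()`) is
  deterministic. G·T wobble and other non-canonical pairs are *not*
  counted; the analysis is strict Watson-Crick.
* `sw_to_aptamer()` scores a Smith-Waterman local alignment of the SD's
  reverse complement against the aptamer. The default scores (match +1,
  mismatch −1, gap open −1, gap extend −1; a length-k gap costs
  `gap_open + k * gap_extend`) make the score read as "number of SD bases
  predicted to hybridize", bounded by the SD length. All four scores are
  configurable; the defaults are an interpretive choice, not a claim about
  any particular aligner's presets.

The DP implementation (Gotoh affine-gap recurrences with an empty-alignment
floor at zero) is validated exactly against an independently written
memoized recursion and against `Biostrings::pairwiseAlignment()` at
identical parameters.

Chemically modified bases (e.g. boronic-acid-modified uracils in
base-modified aptamers) are carried as annotation on `aptamer_spec()` only:
the sequenced switching strands are canonical DNA, so complementarity and
alignment treat modified positions as their canonical letter.

## Binding models

Plate-reader titrations of candidate switches are fit with two isotherms.
For an aptamer with two independent target sites,

$$f_r = \frac{K_1 c + K_1 K_2 c^2}{1 + K_1 c + K_1 K_2 c^2},
\qquad y = y_0 + (B_{\max} - y_0)\, f_r,$$

and for a single site,

$$f_r = \frac{c}{c + K_D^{\mathrm{eff}}},
\qquad y = y_0 + (B_{\max} - y_0)\, f_r.$$

In the two-site form, $K_1$ and $K_2$ act multiplicatively and therefore
*must* be association constants (units 1/concentration); the dissociation
constants reported to users are their reciprocals $K_{D,1} = 1/K_1$,
$K_{D,2} = 1/K_2$. `fit_binding()` reports both, which reconciles the
multiplicative functional form with the field's habit of quoting $K_D$
values. $B_{\max} < y_0$ describes signal-off switches; the normalized curve
$(y - y_0)/(B_{\max} - y_0)$ maps the fitted endpoints to exactly 0 and 1.

Fitting is deterministic given the data: a logarithmic grid over
`[min positive conc / 10, max conc × 10]` (15 points per axis) scans the
binding parameters with $y_0$ and $B_{\max} - y_0$ profiled out linearly at
each grid point; the best grid point seeds a Levenberg-Marquardt refinement
with the binding parameters on the log scale (guaranteeing positivity),
followed by one reweighting pass with inverse-squared fitted values —
fluorescence errors scale with the signal, so constant-variance least
squares would over-weight the bright end of the curve. Replicate means are
fit by default (all points optionally). Standard errors come from the
Jacobian, delta-transformed from the log scale. A flat titration returns a
`degenerate` flag rather than a singular fit, and a fitted $K_D$ more than
100× outside the tested concentration range raises a warning flag.

`summarize_kinetics()` fits a mono-exponential relaxation to post-spike
time-course samples and reports $k_{\mathrm{obs}}$ and
$t_{95} = \ln(20)/k_{\mathrm{obs}}$, the time to cover 95% of the signal
step. The mono-exponential form is a deliberate artifact-level
simplification — it summarizes time-to-equilibrium and makes no mechanistic
claim; series without a resolvable step (under 4× the sample-to-sample
noise) are flagged degenerate.

## The synthetic-data generator

`generate_screen()` writes a complete, linkable file set with planted ground
truth. Its statistical structure mirrors the screen:

* cluster baselines are log-normal (`meanlog = log(300)`, `sdlog = 0.35`),
  placing most clusters inside the 100–1000 RFU working window as on a
  well-loaded flow cell;
* configurable fractions of clusters are planted as dim (uniform 20–80 RFU)
  or bright (uniform 1500–20000 RFU) outliers, exercising both window
  filters, with defaults 5% and 1%;
* cycle intensities are `baseline × planted ratio × noise`, with
  multiplicative log-normal noise of configurable RSD (default 10%) —
  intensities are positive and the screen's own filter is a relative
  criterion, so multiplicative noise is the natural model; values are
  rounded to integer RFU and clipped to the int16 range (which is why a
  noiseless planted ratio is reproduced only up to integer quantization);
* planted SDs are carried by 4 clusters each by default — responsive SDs
  recur across clusters in practice, which is precisely why the analysis
  aggregates to unique SDs — and null SDs are drawn uniformly over N10 with
  planted sequences excluded, keeping the truth set separable;
* cluster positions sit on a jittered grid with at least 1.2 locs units of
  separation (clusters must be optically resolvable), are stored as
  float32, and FASTQ coordinates are the exact forward transform of the
  stored float32 values; an optional `coord_jitter` perturbs only the
  written locs to emulate rounding drift between the instrument's outputs;
* the default cycle schedule alternates buffer and `ATP@500uM` five times
  each; a three-condition schedule (4× each of buffer, `glucose@10mM`,
  `glucose@100mM`) models the two-concentration signal-off design.

What the generator does **not** emulate: sequencing errors, optical
point-spread overlap between neighboring clusters, phasing/prephasing,
cross-channel bleed-through, or the quencher/fluorophore photophysics behind
the intensity change (ratios are planted directly — the screen statistics
operate on ratios regardless of mechanism). Passing tests on synthetic data
therefore validate the *analysis* — linking arithmetic, filter logic,
ranking determinism, estimator accuracy — not the instrument model.

`simulate_titration()` and `simulate_time_course()` provide the analogous
closed loops for the binding models.

## Validation scale and numerical choices

The test suite validates the pipeline at realistic-but-economical sizes,
chosen as representative working points: a 10-tile, 50,000-cluster screen
for linking (100% recovery with and without ±0.049 jitter); ten independent
10,000-cluster screens with 50 planted signal-on SDs at ratios 3–8 and 10%
replicate RSD (top-50 unique-SD precision ≥ 0.96, in practice 1.0); 500
random sequence pairs against the brute-force alignment oracle; 100 seeded
titrations per binding model (median $K_D^{\mathrm{eff}}$ error under 5% at
2% noise for the one-site 0.3 mM regime; median $K_{D,1}$ within 15% of
20 µM for the two-site regime); and ten seeded fast time courses (all
$t_{95} < 10$ s).

Numerical details worth knowing: the coordinate transform rounds
`10 c + 1000` after clearing float residue at the sixth decimal, so
decimal-looking inputs behave as written; all ranking ties are totally
ordered; filters are pure partitions; and the acceptance script
(`scripts/acceptance.R`) recomputes every quantity above from scratch at
run time from a user-supplied seed.

## Limitations

Screen counts from a real run depend on instrument-specific intensity
calibration that the synthetic generator does not model; the package's
quantitative guarantees are about the analysis operating on its stated
inputs. Ambiguous coordinate matches are dropped, so extremely dense tiles
lose a fraction of clusters rather than risking mislinks. The two-site
model's $K_2$ is weakly identified when the tested concentrations do not
reach the second binding event; the fit reports standard errors and the
out-of-range flag so such cases are visible.
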