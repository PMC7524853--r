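---
title: "Quantifying biphasic Mig1 nucleocytoplasmic shuttling from synthetic time-lapse movies"
author: "migshuttle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying biphasic Mig1 nucleocytoplasmic shuttling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement problem

When budding yeast growing on a non-fermentable carbon source is switched to
a preferred hexose (glucose, fructose or mannose), the transcriptional
repressor Mig1 relocates from the cytoplasm into the nucleus and represses
genes for alternative carbon utilization, such as *SUC2* and *HXK1*. In
single cells this response is biphasic: a strong initial nuclear
accumulation peaking within about half an hour of the shift and decaying
over the following hours, followed by an adapted phase in which Mig1
shuttles between nucleus and cytoplasm in minute-scale pulses. Which sugar
kinases (Hxk1, Hxk2, Glk1) the cell carries determines each phase
separately: any phosphorylating activity suffices for the initial response,
while sustained shuttling requires Hxk2 in glucose and mannose and either
hexokinase in fructose.

migshuttle implements the complete quantification chain for such
experiments — from raw two-plane brightfield plus fluorescence movies to
per-cell metrics and group statistics — together with a seeded synthetic
movie generator that encodes those dynamics. Because the generator knows
the ground truth behind every pixel, every stage of the pipeline is
testable with known answers; no external data are required.

## The localization index

For each segmented cell with an identified nuclear submask, the Mig1
localization index is

$$\mathrm{index} \;=\; \frac{\mathrm{median}\,f_{\mathrm{nuc}}}{\mathrm{median}\,f_{\mathrm{total}}} \;-\; 1,$$

the median GFP intensity over the nuclear pixels divided by the median
over the whole cell mask, minus one. The index is 0 for uniformly
distributed Mig1-GFP, positive for nuclear enrichment, and bounded below
by −1 for nonnegative intensities. Medians make the statistic robust to
bright inclusions and, as a ratio of intensities from the same cell at the
same exposure, it cancels global intensity scaling. Reporter and
expression-marker channels use means over the cell mask instead, chosen
for linearity with expression level.

## Acquisition model

The default schedule mirrors a microfluidic media-shift protocol: frames
every 30 min from −240 to 0 min (9 frames) and every 5 min from 0 to
720 min (145 frames), with the shift at t = 0 counted once (153 unique
times). The expression-level marker channel (an mAmetrine-type constitutive
fluorophore) is acquired only on every 4th post-shift frame (37 frames) to
limit photodamage; all other channels are imaged at every time point.

## The synthetic generator

`simulate_traces()` draws, per cell,

* an **initial response** $A_i\,k(t)$ with the gamma-shaped kernel
  $k(t) = (t/t_\mathrm{peak})^{t_\mathrm{peak}/\tau} e^{(t_\mathrm{peak}-t)/\tau}$,
  normalized to 1 at its mode $t_\mathrm{peak}$ (default 30 min) and
  decaying with $\tau$ (default 80 min; 40 min for the short-lived
  Glk1-only response). A smooth two-parameter shape that rises to an early
  maximum and declines over hours is the minimal model consistent with the
  observed traces.
* an **adapted-phase plateau** $(L-b)(1-e^{-t/120})$ ramping to the
  sustained level $L$ (index units) over ~2 h.
* **shuttling pulses**: Gaussian bumps of FWHM 10 min whose arrival times
  form a renewal process with a 15-min refractory gap and inter-arrival
  `refractory + Exp(mean 1/λ − refractory)`, so the long-run pulse rate
  equals the configured λ (pulses/h) exactly. The refractory gap equals
  the pulse detector's default minimum separation: at the 5-min sampling
  interval, bumps closer than that merge into a single local maximum and
  are unresolvable in principle, so generating them would make
  ground-truth recovery ill-posed rather than hard. Bump amplitudes are
  Gaussian (mean 0.4, SD 0.12 index units, floored at 0.02).
* **cell-to-cell variability**: mean-preserving log-normal factors
  (CV 0.3) on the initial amplitude, pulse rate, mean pulse height and
  reporter production — the traces vary widely between cells while group
  means stay at the configured values.
* **measurement noise**: additive Gaussian (SD 0.03 index units) on every
  sampled index value.

Recorded ground-truth pulse heights are the *noise-free trace value at the
pulse apex minus the basal level* — exactly the quantity the metrics module
measures (height above the pre-shift basal reference line) — so parameter
recovery compares like with like; the drawn bump amplitudes are stored
alongside.

The **reporter** (a destabilized fluorescent protein under a
catabolite-repressed promoter) follows the delayed-production model
$dF/dt = r(t - m) - \delta F$ with production $r$ stepping from the
repressed to the derepressed rate at the derepression onset, maturation
delay $m$ (default 30 min, a Citrine-like chromophore), and first-order
turnover $\delta$ (default 0.025/min, giving a 40-min response time so the
signal tracks ongoing promoter activity). The piecewise-constant rate makes
the solution closed-form, with the repressed steady state $r_0/\delta$ as
the pre-shift initial condition; fluorescence is exactly zero change before
onset + maturation.

**Presets** (`preset(strain, hexose)`) encode the qualitative
strain-by-hexose matrix: where the initial response is present and how
strong, where shuttling occurs, reporter derepression with fold changes of
about 7.5× (glucose), 1.5× (fructose) and 2–4× (mannose) in the
derepressed mutants, dose-responsive rescue of shuttling by hexokinase
(but not Glk1) overexpression via a Hill coupling to the per-cell
expression-marker level, and the toxicity of hexokinase overexpression in
mannose (cells above an expression threshold arrest at t = 60 min and
freeze). Absolute index magnitudes are deliberately arbitrary design
choices — only orderings and presence/absence encode reported biology —
and they are excluded from quantitative acceptance for that reason.

## Rendering

`render_movie()` draws six channels per frame. Out-of-focus brightfield is
modelled as the minimal pattern the division trick enhances: a bright
diffraction ring at each cell boundary above focus and a dark ring below,
on a common background times the illumination field, blurred by a Gaussian
PSF. The GFP channel fixes each cell's total fluorescence and splits it
analytically between nucleus and cytoplasm so that
`median(nuclear)/median(cell) − 1` equals the ground-truth index *exactly*
at zero noise — rendering is invertible by construction, which turns
round-trip measurement into a strict test. Fluorescence channels are
rendered without PSF blur for that reason; Poisson shot noise plus Gaussian
read noise and 16-bit quantization are applied on top by default. Cells sit
in traps: drift is a bounded random walk around a home position, with
placement clearance chosen so cells can never overlap. Dead cells stop
drifting and their intensities freeze.

What the generator does **not** emulate: growth, budding and lineage;
photobleaching; focus drift; flow artifacts; segmentation-adversarial
morphologies (crowded colonies, irregular shapes). Passing tests therefore
demonstrate correctness of the quantification chain, not robustness to
every pathology of real microscopy data.

## Image analysis choices

* **Brightfield division**: above/(below + ε), ε = 10⁻⁶ × median(below),
  removing multiplicative illumination and enhancing the ring pattern.
* **Segmentation** (a documented equivalent of membrane-pattern
  segmenters such as CellX, which is not reimplemented bit-for-bit):
  absolute deviation of the divided image from its unit background →
  Gaussian smoothing (σ 1.5 px) → fixed threshold 0.35 → morphological
  closing (7-px disc) → hole filling → erosion (5-px disc) back to the
  cell boundary → watershed on the distance transform → area filter
  (150–5000 px).
* **Nucleus identification**: Otsu threshold of the nuclear-marker channel
  within each cell mask, largest connected component; if the marker is
  flat or absent, fallback to the brightest contiguous 12% of the cell's
  GFP pixels (grown greedily from the brightest pixel, exact pixel count).
  The original analysis does not state its nuclear-compartment mechanism,
  so the strategy is exposed as an option.
* **Tracking**: optimal bipartite assignment on centroid distances
  (Hungarian contract via `clue::solve_LSAP`), 10-px gate, gaps up to
  1 frame bridged with a proportionally relaxed gate. Daughter cells
  appear as new tracks; no lineage. The per-cell analysis can require
  tracks to span the shift (pre-shift to ≥240 min) so each cell
  contributes both short- and long-term metrics.

## Trace metrics

Per cell: basal = mean pre-shift index; short-term max/mean and peak time
on [0, 60] min (first occurrence wins ties; ≥3 points required);
adapted-phase mean on [240, 480] min (≥50% frame coverage, missing points
skipped); pulses on [60, 480] min by topographic prominence. A pulse is a
local maximum (plateau runs count once, at their centre) whose prominence —
height above the higher of the two side bases, each the minimum en route to
the nearest strictly higher sample or the window end — reaches
`min_prominence`, with peaks enforced ≥15 min apart (kept in order of
decreasing prominence, earlier peak winning ties). The default
`min_prominence` is max(0.1, 3× the per-trace noise SD), the noise
estimated by the median absolute successive difference of the *pre-shift*
samples: within the analysis window successive differences are dominated by
pulse flanks, so estimating there would inflate the threshold. Pulse height
is measured above the basal reference line (the figure convention); a
local-trough alternative (prominence itself) is exposed as an option.
Gaps of one frame are linearly interpolated; longer gaps split the window.
Pulses before 60 min are excluded because the two phases are analysed
separately. Reporter onset is the first time the signal exceeds the
pre-shift mean + 3 SD for ≥3 consecutive frames; given maturation, detected
onsets lag true derepression by roughly the maturation delay.

## Group statistics

Per condition and metric: mean, SD (n−1), and t-based 95% CI treating
cells as independent units (as the per-cell scatter plots imply).
Comparisons against the wild-type condition in the same hexose use
Welch's unequal-variance two-sample t test: the figure legends cite a
*paired* t test against wild type, but cells in different strains cannot
be paired, so pairing is not reproducible from the text; a permutation
test on the difference of means is available as an option. No
multiple-testing correction is applied by default (none is applied in the
source analysis); Benjamini–Hochberg is available via `p.adjust` if
wanted. Fold changes are ratios of group means of the 240–480 min
time-averaged reporter signal. The dose–response analysis bins cells by
expression-marker level (quantile bins, ≥10 cells each) and reports
Spearman's ρ between expression level and adapted-phase localization.

The **qualitative-matrix check** re-derives every condition's three calls
from measured metrics only: short-term response present if the group mean
short-window maximum exceeds the mean basal by 0.1; shuttling present if
the mean detected pulse rate exceeds 0.5/h (detected false-pulse rates in
no-shuttle conditions are an order of magnitude below this); reporter
derepressed if the adapted-window reporter signal is significantly above
the reference (one-sided Welch, p < 0.05) *and* the group-mean fold change
is ≥1.2 — the significance test is the figure-star convention, and the
effect floor guards the twelve repressed matrix cells against
multiple-testing false positives while sitting well below the weakest
designed derepression (1.5×). In toxicity conditions, dead (frozen) cells
are excluded first and the viability threshold is estimated as the
midpoint between the mean expression-marker levels of dead and surviving
cells.

## Numerical and degenerate-input conventions

Pixel coordinates are (row, column); masks are linear pixel index sets;
intensities are linear AU. A blank frame segments to zero regions (not an
error); a non-positive whole-cell median flags the measurement invalid and
excludes it downstream; per-frame failures in a stack are logged and
skipped; a condition failing inside a run is skipped and the run fails
only if all do. All randomness flows from explicit seeds: a simulation
config seeds the generator, the trace-only observation noise uses an
offset stream from the same seed, and rendering seeds placement and drift
from geometry seed + config seed, so identical configs give bit-identical
artifacts.

## Verification scale

The packaged checks run at these problem sizes, chosen to keep the full
suite in the minutes range while leaving Monte-Carlo margins comfortably
wider than the tested tolerances: index exactness on 1000 random masks;
pulse-detector/oracle identity on 500 random traces of length ≤200;
parameter recovery at 200 cells per condition on the full 153-frame
schedule; segmentation/tracking on a rendered 20-cell, 153-frame,
256×256-px movie; Welch/CI calibration on 1000 null replicates of two
40-cell groups (truth taken from a 5000-cell draw); and the full
7-strain × 3-hexose grid at 50 cells per condition. The same computations
are reproduced by `scripts/acceptance.R`.

## Known limitations

The segmenter is tuned to the renderer's ring contrast; real movies will
need threshold and area parameters adjusted per dataset. Nuclei are drawn
concentric with cells, which makes the marker-based and GFP-fallback
nucleus strategies agree more than they would on real nuclei at the cell
periphery. The pulse detector reports resolvable events: at 5-min sampling
it undercounts generator pulse trains by roughly 10% (near-refractory
pairs), which is why the recovery tolerance on the rate is wider than on
the height. The expected qualitative matrix for the overexpression strains'
reporter behaviour is a generator design choice (those strains carry no
reporter in the source experiments). Chamber or position effects
(mixed-effects structure) are out of scope.
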