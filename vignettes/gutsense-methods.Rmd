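---
title: "Methods: quantifying gut-brain sensory transduction assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying gut-brain sensory transduction assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutsense)
```

`gutsense` implements the quantification stack used in studies of gut
epithelial sensory cells ("neuropod" cells) and their vagal readout: vagal
whole-nerve electrophysiology, per-cell calcium response classification,
single-cell RT-qPCR expression analysis, two-bottle behavioral preference,
and fiber-optic attenuation. This vignette documents the models, the
parameters that matter, the numerical choices, and what the seeded
synthetic-data generators do and do not emulate.

## Vagal electrophysiology

**Model.** A whole-nerve recording is multiunit: no spike sorting is
attempted, and every threshold crossing is pooled. The stack is

1. `detect_spikes()` — the threshold is `k` times the root-mean-square of
   the trace (`k = 4` by default, common extracellular practice; the RMS is
   computed over the whole trace by default, or an initial window via
   `rms_window_s`). A spike is the time of the absolute-amplitude extremum
   of each supra-threshold excursion; events closer than the refractory
   period (1 ms default) merge, keeping the larger extremum.
2. `estimate_firing_rate()` — `rate(t)` is a sum of Gaussian kernels, one
   per spike, evaluated at the centers of 200-ms bins. Each kernel
   integrates to one spike, so the summed `rate x bin_width` mass equals
   the spike count for spikes at least ~3 kernel widths from the window
   edges; no padding is applied, and the mass-conservation guarantee is
   only claimed in that interior. The kernel width defaults to the bin
   width (200 ms) and is freely configurable; the midpoint-rule error of
   the binned evaluation is below 1e-8 per spike once the kernel is at
   least as wide as the bin.
3. `normalize_to_baseline()` — each trial is its own control: the rate is
   divided by its mean over the first 2 min (fold-of-baseline). Ratio
   normalization was chosen because response figures in this field display
   fold-like traces; a subtractive mode sits behind `mode = "subtract"`,
   and a zero baseline is an error instructing the caller to use raw
   rates.
4. `quantify_response()` — peak fold-of-baseline in the analysis window,
   time from infusion onset to that peak, and the *signed* trapezoidal
   integral of `(rate - 1)` as the AUC. Whether the AUC should be signed
   or positive-part is genuinely open; signed is the default and
   `positive_part = TRUE` is available. The analysis window defaults to
   onset + 360 s, matching infusions separated by at least 6 min.

**What the generator emulates.** `gen_vagal_recording()` draws spike times
from an inhomogeneous Poisson process with piecewise-constant rate
(baseline times the epoch multiplier) and writes a biphasic 1-ms template
(a standard extracellular shape; real unit waveforms vary) onto Gaussian
noise. It does not model bursting, electrode drift, movement artifacts, or
the real noise spectrum, so passing tests show correctness of the
detection/estimation chain, not robustness to every in vivo nuisance. At
high rates, template collisions within the refractory period merge, which
biases detected counts down by a few percent; recovery tests therefore use
margin-safe designs (20 Hz baseline, 3x multiplier, 4-s kernel for the
peak-recovery check, 10 seeds of 330-s recordings at 10 kHz).

## Calcium response classification

**Ratiometric (in vitro).** The per-frame ratio is Fluo-4 / Fura Red
(`compute_ratio()`; a non-positive Fura Red frame is an error naming the
frame). A positive response is a ratio increase *strictly* greater than
10% above baseline anywhere in the stimulus window. The baseline for every
window is the mean of the five frames immediately preceding it; the
rebaseline-after-a-response rule generalizes naturally to "rebaseline
before every window", which is what `classify_population()` does (the
initial-baseline alternative stays available via `rebaseline = FALSE`).
Cells whose terminal high-potassium (KCl) window fails the same 10% rule
are non-viable and carry no stimulus calls; stimulus peaks can be
normalized to the KCl peak (`normalize_to_kcl()`). At exactly the
threshold the comparison is strict, though floating-point representation
makes that boundary unobservable in practice.

**Single-channel (in vivo).** `compute_dff()` uses the whole-run
definition `dF/F = (F - mean(F)) / mean(F)`, which is exactly mean-zero.
Because that definition leaves "baseline" unspecified, the 20% call is
applied to the excess of the in-window maximum over the mean dF/F of the
30 s preceding the window (configurable via `baseline_s`).

**Overlap summaries.** `venn_summary()` partitions viable units into
a-only / b-only / both / neither and reports percentages over two
denominators — responders (for dissociated-cell style reporting) and all
viable units (for in vivo style reporting) — because published breakdowns
use both. Assays whose responses are recorded outside this package (e.g.
excitatory currents in coculture patch clamp) enter through
`response_calls_from_logical()`.

**Generator.** `gen_calcium_population()` builds 210-s traces (1.5-s
frames) with two 15-s stimulus windows and a terminal KCl window;
transients are half-sine bumps with designed peaks (0.25 for responders,
0.05 for non-responders, 0.15 for KCl in viable cells). Any designed peak
within one percentage point of the 10% threshold is rejected so fixtures
are decision-theoretically unambiguous. `gen_dff_population()` does the
same for 480-s in vivo runs (0.683-s frames, 60-s windows, 0.5 responder
amplitude against the 0.20 threshold, 2% rejection margin). Neither
generator models photobleaching, motion, or indicator saturation.

## Single-cell RT-qPCR

`quality_filter()` censors wells below the 0.65 quality score to
undetected, then drops cells with no detected transcript for either
housekeeping gene (`Gapdh`, `Actb1`); it is idempotent. `cq_to_rq()`
implements `RQ = 2^(34 - Cq)` with the undetected substitution `RQ = 0.5`,
so `log2(RQ) = 34 - Cq` holds exactly for detected wells.
`normalize_per_gene()` z-scores log2 RQ per gene using the sample (n-1)
standard deviation (the `scale()` convention; a two-cell gene maps to
±1/√2); zero-variance genes become zero columns with a warning. Control
wells (0/10/100-cell calibration wells in real exports) are assumed
excluded before analysis.

`differential_expression()` runs per-gene two-tailed two-sample t-tests on
log2 RQ — Welch by default, pooled behind `var_equal = TRUE` — with
Benjamini–Hochberg adjustment across the panel (the standard open
equivalent of commercial q-values) and a 0.05 q cutoff. The fold change is
the ratio of group means of *linear* RQ by default, with
`fc_basis = "log2"` for `2^(Δ mean log2)`; the two differ under skew, and
the basis used is always recorded in the result. A known limitation: the
0.5 substitution places undetected wells at log2 = -1, far below typically
detected values, so dropout inflates Welch variance and can mask real
effects — the planted-effect demonstrations therefore run at zero dropout,
and analyses of dropout-heavy panels should treat t-tests on substituted
values with care.

`classify_receptors()` calls a gene "expressed" in a cell iff it was
detected after QC (i.e. not the 0.5 substitution — matching the
substitution semantics, not an RQ magnitude threshold), partitions cells
into neither / a-only / b-only / both, computes percentages within each
mouse, and reports the across-mice mean ± s.e.m. (absent with one mouse).

`gen_cq_matrix()` draws detected Cq values from a Normal distribution
truncated below the cutoff (mean 26, s.d. 0.8 cycles by default — chosen
once as a realistic composite of instrument and residual biological
variability; the underlying instruments report no canonical value) and
plants group effects as cycle shifts. It models dropout as
missing-completely-at-random, which real single-cell expression is not
(dropout correlates with expression level); conclusions about dropout
robustness do not transfer.

## Behavior

`clean_intake()` applies the cage-firmware rule literally: scanning left
to right, any reading lower than its corrected predecessor is replaced by
that predecessor. The result is monotone, never below the raw reading,
and the operation is idempotent. `compute_preference()` takes cleaned
cumulative intakes over the 60-min session (referenced to the
session-start reading, so pre-session bottle contents never count) and
reports `100 x sucrose / (sucrose + sucralose)`, flagging zero-intake
sessions as undefined. `stable_preference()` is the advancement rule: two
consecutive tests both above 66% differing by at most 15 — read as 15
percentage points, the natural reading for a difference of percentages.

`periodic_schedule()` produces the 1-min-on / 2-min-off cycle (40 Hz, 20%
duty — a 5-ms pulse — 5 V, session starting laser-on) as an explicit
interval list. `intake_triggered_schedule()` emits a 5-s bout per 0.01 g
consumed; bouts that would overlap merge into one extended interval (the
hardware cannot double-fire), while the trigger count still reflects every
quantum.

`gen_intake_session()` quantizes to the 0.01-g grid, splits the designed
total by the designed preference exactly, spreads consumption uniformly
over the hour, and injects transient single-tick negative dips. Real
intake is bout-structured rather than uniform; the uniform placement is
deliberate — it exercises cleaning, binning and preference arithmetic, not
meal-pattern analysis.

## Fiber optics and closed-form assays

`fit_loss()` converts each cut-back power to attenuation relative to the
shortest length, `-10 log10(P/P_min)` dB, and fits attenuation against
length by ordinary least squares in the dB domain (the conventional
cut-back analysis; fitting percent transmission directly would weight
points differently but estimates the same slope for exact data). Only
power ratios enter, so the fit is invariant to power rescaling.
`gen_cutback()` uses multiplicative lognormal noise of mean 1 at the
stated coefficient of variation. `power_density()` references the core
cross-section (230 µm default), the stated assumption behind the tip
intensity figure. The remaining utilities are the field's standard closed
forms: ellipsoid gallbladder volume `l·w·d·π/6` with percent-change
emptying, gastric percent-remaining `100·post/pre`, membrane capacitance
`C_m = τ·I_0/ΔE` (ms·pA/mV = pF) with capacitance-normalized currents,
and plate-reader glutamate quantification by control subtraction and a
least-squares *linear* standard curve (kit-style; no four-parameter
logistic), flagging extrapolation beyond the standard range.

## Determinism and problem sizes

Every generator takes an explicit seed, restores the caller's RNG state,
and reproduces byte-identical output for identical (parameters, seed).
The test suite sizes were chosen to make the statistical checks sharp but
quick: 10-seed ephys recovery on 330-s recordings, 100-seed cut-back
Monte-Carlo, 200 simulated choice sessions, 200-replicate null for the
false-discovery check, and 20-seed planted-effect replication; the whole
suite runs in well under a minute of compute per module.

## Worked example

```{r example}
pop <- gen_calcium_population(n_neither = 21, n_a_only = 14, n_b_only = 4,
                              n_both = 8, n_nonviable = 0, seed = 7)
venn_summary(classify_population(pop$traces), "glucose", "sucralose")
```

The `analysis/` directory holds numbered driver scripts (one per
modality) that run these stages end to end on seeded synthetic data and
write their tables under `results/`.
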