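---
title: "Models and methods in nucleodyn"
author: "nucleodyn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in nucleodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`nucleodyn` packages the quantitative core of a single-cell study of
nuclear protein dynamics across the cell cycle: fluorescence correlation
spectroscopy (FCS) of protein–chromatin exchange, image metrics of
nuclear foci, and rule-based staging of S phase from PCNA replication
patterns. This vignette explains the models, the conventions behind
every tunable parameter, what the synthetic-data generators do and do
not emulate, and the numerical choices made where the design was open.

## The FCS model

A single-point FCS measurement parks the confocal volume at one spot in
the nucleus and records photon counts at 25–50 kHz for minutes. The
normalized autocorrelation of the fluctuations,
$G(\tau) = \langle \delta F(t)\,\delta F(t+\tau)\rangle / \langle F
\rangle^2$, encodes the timescales on which molecules enter and leave
the observation volume. The package models a protein that either
diffuses freely or resides on one of two kinetically distinct classes of
immobile chromatin sites:

$$G(\tau) = \frac{f_D}{2^{3/2} N}\,
  \Bigl(1+\frac{\tau}{\tau_D}\Bigr)^{-1}
  \Bigl(1+\frac{\tau}{\omega^2\tau_D}\Bigr)^{-1/2}
  + f_{short}\,e^{-\tau/\tau_{short}}
  + f_{long}\,e^{-\tau/\tau_{long}}$$

* $N$ — mean number of fluorescent molecules in the effective confocal
  volume $V_{\mathrm{eff}} = \pi^{3/2} w_{xy}^2 w_z$ (dimensionless,
  > 0);
* $\tau_D = w_{xy}^2/(4D)$ — characteristic diffusion time (s);
* $\omega = w_z/w_{xy}$ — axial-to-radial waist ratio (dimensionless,
  > 1). Instruments rarely report it; the default is 5, typical of
  confocal volumes, and it is **held fixed during fitting** by default
  because $\omega$ and $\tau_D$ are poorly separable on noisy curves
  (pass `fixed = character(0)` to free it);
* $\tau_{short}, \tau_{long}$ — residence times on the two site classes
  (s), with $\tau_{short} < \tau_{long}$ enforced by relabeling (the
  two exponentials are exchangeable, so ordering removes the label-swap
  degeneracy); the dissociation rates are their reciprocals,
  $k_{off} = 1/\tau$;
* $f_D, f_{short}, f_{long}$ — amplitude fractions, stored under the
  sum-to-one convention $f_D + f_{short} + f_{long} = 1$.

### The amplitude convention

As written, the $1/(2^{3/2}N)$ prefactor multiplies only the diffusive
term, while the exponential terms carry their fractions directly. The
package implements this equation literally. One consequence is worth
spelling out: for a physical mixture in which every state contributes
intensity, the true correlation amplitudes of the exponential terms are
the state occupancies divided by the molecule number (in the
$G(0) = 1/N$ normalization of $V_{\mathrm{eff}}$). The literal
parameterization therefore coincides with state occupancies exactly
when $N \approx 1$ — which is why the simulator's default configuration
places about one molecule in the effective volume. At other
concentrations the fitted $f_{short}, f_{long}$ are amplitudes, not
occupancies, and the fitted $N$ compensates through the diffusive term.
Single-molecule-regime FCS of transcription factors operates near
$N \sim 1$, so this is also the physically relevant regime.

## Correlation estimation

`directACF` is the reference estimator: at every lag $k$ it uses only
the overlapping samples and the *symmetric normalization*

$$\hat G(k) = \frac{\overline{F_t F_{t+k}}}
 {\overline{F_t}\;\overline{F_{t+k}}} - 1,$$

with separate means of the leading and lagged segments, which
suppresses drift bias relative to dividing by the global squared mean.
Lag 0 is never reported (shot noise dominates it), and the number of
overlapping pairs is the denominator of every average.

`multitauACF` is the production path: lags are linear in sampling bins
within the first octave (`pointsPerOctave` of them) and the signal is
rebinned by factor 2 between octaves, covering microseconds-to-minutes
lags at geometrically shrinking cost. On the shared first octave it
equals `directACF` to machine precision — this equivalence, not any
external correlator, is the package's correctness anchor.

`segmentACF` adds per-lag standard errors from equal-length contiguous
segments. Two conventions are available. `value = "segment-mean"`
averages per-segment curves, which is self-contained but depresses the
curve by a nearly lag-independent offset of order
$2\int G\,d\tau / T_{seg}$ — any mean-normalized estimator on a record
of length $T$ sits below the truth by about $2\int G / T$, and segments
are short. The default `value = "full"` therefore reports the
full-record estimate (whose offset is `nSegments`-fold smaller) and
uses the segments only for the error bars. On top of either convention
the remaining record-length offset is removed by default
(`biasCorrect = TRUE`): the curve is raised by $2\int \hat G / T$,
iterated to self-consistency — a deterministic correction computed from
the curve itself. This matters exactly when residence times reach a few
percent of the record length, the regime of second-scale chromatin
binding in minutes-long acquisitions.

### Fitting

`fitACF` minimizes weighted squared residuals with the
Levenberg–Marquardt algorithm (`minpack.lm::nls.lm`) under box bounds,
with positive parameters optimized on the log scale. Weights are
$1/\mathrm{sem}^2$ when the curve carries positive per-lag errors,
uniform otherwise. Lags below three sampling intervals are dropped by
default (detector afterpulsing and shot noise dominate there in real
data). With `init = "auto"` the optimizer restarts from five points: a
data-driven guess ($N$ matched to the observed amplitude, $\tau_D$ at
the half-decay lag, residence times at the canonical 0.01 s / 1 s), the
same guess with $\tau_D$ a decade down (the half-decay heuristic
overshoots $\tau_D$ whenever binding terms carry most of the
amplitude), and three jittered by up to ±50%; the lowest-residual
optimum wins. Convergence failure is reported in the `converged` flag,
not as an error.

Two optional refinements address the regime where the slowest
residence time is within two orders of magnitude of the record length.
`fitOffset = TRUE` co-fits an additive baseline (bounded by
`offsetBound`); it is a more agnostic alternative to the estimator-side
bias correction above, but on noisy curves the baseline trades against
the amplitude and timescale of the slowest binding term and pulls both
down, so the deterministic correction in `segmentACF` is preferred and
the baseline stays off by default. `orderedTimes = TRUE` reparametrizes
the three timescales as $\tau_D$ plus two log ratios bounded below one,
enforcing $\tau_D < \tau_{short} < \tau_{long}$ structurally; this
removes a swapped local optimum in which the short exponential models
the diffusive decay (the model is only interpretable as
diffusion-plus-binding when residence exceeds transit), and is the
recommended setting — used by the package pipeline — when fitting
estimated, as opposed to noiseless, curves.

## The Brownian-dynamics simulator

`simulateTrace` generates ground-truth data for the whole FCS stack:
point emitters diffuse in a periodic cube, exchange with two classes of
immobile, non-depleting binding sites under pseudo-first-order kinetics
(free ↔ short, free ↔ long, no direct short–long exchange — the
minimal scheme whose correlation function has the additive two-
exponential form), and emit Poisson photon counts through a 3D Gaussian
observation profile centred in the box. Bound molecules stay
fluorescent at their fixed site; that bound-state intensity correlation
is what produces the exponential terms. The mapping from configuration
to model parameters is exact and closed-form
(`expectedParamsFromConfig`): $\tau_D = w_{xy}^2/4D$, residence times
are reciprocal unbinding rates, fractions are the equilibrium state
probabilities of the three-state chain, and
$N = n_{particles} V_{\mathrm{eff}} / V_{box}$.

Defaults describe the canonical test fixture, chosen to sit inside the
acquisition window of the emulated experiments (a 162 s trace resolves
a 2 s process) rather than to estimate any particular biology: 50 kHz
sampling for 162 s (2.7 min), $w_{xy} = 0.25\,\mu m$,
$w_z = 1.25\,\mu m$ ($\omega = 5$), $D = 15.625\,\mu m^2/s$ giving
$\tau_D = 1$ ms, residence times 0.1 s and 2 s, occupancies
0.5/0.3/0.2, brightness $10^5$ counts/s per molecule at beam centre
(≈ 0.7 counts per 20 µs bin in total). The box edge is 3.125 µm
(12.5 radial waists): at the geometric minimum of 10 radial waists the
axial Gaussian is clipped by the periodic boundary strongly enough to
inflate normalized amplitudes by ~10%, while at 2.5 axial waists the
truncation is ~2.5%. Seventy particles then give $N \approx 1.0$ (the
occupancy-matching regime above).

The time step is the sampling interval, sub-stepped automatically
whenever the fastest rate or the diffusion step would under-resolve the
dynamics (`max rate × dt < 0.1`, step < $w_{xy}/4$), and refused beyond
64 sub-steps. All randomness comes from an internal PCG32 counter
generator seeded by the configuration, so traces are bit-reproducible
across platforms and independent of R's RNG state.

What the simulator does **not** emulate: photobleaching, detector
afterpulsing and dead time, cellular geometry and compartment
boundaries, anomalous or multi-component diffusion, site depletion and
rebinding correlations. Passing recovery tests on these traces
therefore demonstrates correctness of the estimator-fitter pipeline
under the model's own assumptions, not robustness to every artifact of
live-cell data.

### What recovery to expect

A single 2.7-minute trace determines the millisecond diffusion time
tightly but leaves second-scale binding parameters noisy: with about
one molecule in the observation volume, only on the order of fifteen
long-site binding events contribute tail signal per record, so
per-trace $\tau_{long}$ estimates scatter by tens of percent with a
right-skewed distribution. The package's end-to-end tests therefore
assert *median* recovery over batches of seeded acquisitions — medians
of $\tau_{long}$ within 25% and of the bound fractions within ±0.10 —
mirroring how such experiments pool tens of cells per condition. Even
so, the median over a batch of 20 retains appreciable sampling
variability: across 40 independent acquisitions at the default
conditions the median $\tau_{long}$ recovers within about 10% (and the
fit of the 40-trace average curve recovers every parameter within a few
percent), while disjoint 20-trace batches can land on either side of
the 25% band. Bound-fraction and diffusion-time medians are stable in
batches of 20.

## Synthetic nucleus scenes

`makeNucleus` draws one elliptical nucleus (semi-axes ~4.6–5.4 ×
3.4–4.2 µm at 0.1 µm/px in a 160-px frame) with 1–3 darker elliptical
nucleoli, a flat nucleoplasmic background and optional Poisson-scaled
noise of configurable SNR. `addFoci` plants isotropic Gaussian foci
whose "radius" is the full width at half maximum; placement rules
(uniform, interior, peripheral shell, perinucleolar ring) and the
non-overlap constraint (minimum centre distance = sum of radii, scaled
by `minSepFactor`) are the fixture conventions of the generator, not
claims about biology.

The radial coordinate shared by the generator and the classifier is the
*area rank* of the distance to the nucleus boundary: the square root of
the fraction of nucleus pixels strictly more interior. On a disk it
equals $r/R$ exactly, and it adapts to arbitrary mask shapes without
fitting ellipses. The peripheral shell is rank > 0.75; the
perinucleolar ring is the nucleoli mask dilated by 3 px. Both are
configurable; the defaults are conventions.

`renderPCNA` produces the canonical replication patterns: G cells
(G1/G2 pooled; DNA content, not PCNA texture, separates them) have no
foci; early-S cells 30–60 small foci (FWHM 2.5–3.5 px) dispersed
through the interior; mid-S cells 25–45 foci placed 75/25 at the
periphery and around nucleoli (overflowing to the periphery when a
small ring fills up); late-S cells 3–8 foci at twice the early-S FWHM.
Dense patterns use `minSepFactor = 0.6` because strict non-overlap is
geometrically infeasible at early-S densities — random sequential
placement jams well below the required count — and real replication
foci do partially overlap. Two transition mixtures exercise the
tie-break rules: `ES_MS` (interior/peripheral mixture with a
configurable fraction) and `MS_LS` (mid-S geometry at inflated size).
Counts and sizes per phase are generator conventions: the pattern
vocabulary in the literature is qualitative ("multiple small",
"fewer and bigger"), so the package picks values that make the
patterns unambiguous at the default thresholds and records them here.

`makeColonyTable` draws integrated DAPI intensities from DNA-content
means (G1 = 1, G2 = 2, S stages interpolated: 1.25/1.5/1.75 for
early/mid/late), multiplied by a lognormal per-colony gain emulating
illumination and staining variation across a coverslip, plus optional
per-cell noise (default 0).

## Image metrics

All threshold statistics share one analysis region: nucleus minus
nucleoli. The coefficient of variation is the population SD over the
mean of that region (population, not sample, SD throughout — one less
decision surface). `detectFoci` binarizes at mean + 2 SD *of the same
region* (the exclusion is applied consistently even though
thresholding is often described on whole nuclei), labels 8-connected
components, and keeps those with area ≥ that of a circle whose diameter
is the lateral optical resolution (default 0.25 µm, i.e. 2.5 px at
0.1 µm/px ⇒ ≈ 4.9 px²). Foci touching the nucleus border are retained.
The relative foci intensity $I_{r,foci}$ is the mean over all retained
foci pixels divided by the region mean. A strictly-greater comparison
against the threshold makes a perfectly uniform region yield zero foci
(with ≥, zero SD would select every pixel).

`normalizeDapi` divides each cell's integrated DAPI intensity by its
colony mean — exact per-colony mean of 1, invariant to any positive
per-colony gain. `compareGroups` is a deliberately transparent
substitute for model-based group testing: a two-sided permutation test
on the difference of means for each adjacent-phase contrast
(ES vs G, MS vs ES, LS vs MS), seed-deterministic, labeled as a
permutation test in its output.

## The PCNA phase classifier

`classifyPhase` is a three-step decision tree over detected-focus
geometry:

1. fewer than `minFoci` (default 3) foci → **G**;
2. at most `fewMax` (default 10) foci with mean area ≥ `bigAreaFactor`
   (default 2) × the reference area → **LS**, even when the foci sit at
   the periphery — the mid-to-late transition rule;
3. otherwise the majority location decides **ES** (interior) versus
   **MS** (boundary = peripheral ∪ perinucleolar, since both signal
   mid-S), and the cell is **discarded** when
   $|interior - boundary|/n_{foci}$ < `similarityTol` (default 0.2) —
   the early-to-mid transition rule.

"Similar", "bigger than average" and "few" are not quantified in the
qualitative staging vocabulary; the defaults above are declared
conventions. The reference area (default 9 px²) is the median detected
focus area over early-S-like calibration renders at the default scene
settings — recompute it with `calibrateReferenceArea` after changing
scene or detection parameters. Classification is deterministic and
invariant to intensity scaling of the image, because the detection
threshold scales with the image and all features are geometric.

The supplementary machine-learning route some studies describe is
deliberately not implemented: reported performance does not exceed the
manual rules, and the rule set has the advantage of being auditable.

## Orchestration and determinism

`runWorkflow` executes synth → quantify → classify → fcs stages from a
single validated configuration, writes every output under one
directory, and emits a manifest with an MD5 hash per file. Per-task
seeds derive from the global seed as an FNV-1a hash of
`"<seed>/<stage>/<index>"` folded into 31 bits, so batches are
reproducible and insensitive to execution order; re-running an
identical configuration reproduces identical hashes. No stage reads
entropy from anywhere else.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: 1000 random parameter
sets for closed-form checks; 50 (tests) or 10 (script) white-noise
traces of $10^5$ bins for correlator equivalence at $10^{-12}$; 20
(tests) or 10 (script) noiseless fit round trips at $10^{-4}$ relative;
20 (tests) or 12 (script) full 50 kHz × 162 s simulated acquisitions
for end-to-end recovery; 100 scenes each for foci exactness, noise
robustness (SNR 5) and the size-filter rule; 200 scenes (50 per phase)
for the classifier round trip; and 1000 cells across 100 colonies for
DAPI normalization and stage ordering. These sizes were chosen so the
statistical assertions (medians, rates) are stable across seeds while a
full run stays in the minutes range on one core.

Numerical conventions collected in one place: population SD everywhere;
8-connected components; strictly-greater thresholding; fractions kept
on the simplex by construction ($f_D = 1 - f_{short} - f_{long}$,
renormalized after clipping); timescale ordering restored by post-fit
relabeling; log-scale optimization for positive parameters; lag window
from 3 sampling intervals; ties in the radial area rank broken toward
the interior.

## Known limitations

* The model fits the literal two-binding-population equation; triplet
  photophysics, anomalous diffusion, two-component diffusion and
  cross-correlation are out of scope.
* Fitted binding amplitudes equal occupancies only near $N \approx 1$
  (see the amplitude convention above).
* Nucleus and nucleoli masks are inputs (or synthetic); the package
  does not segment raw images.
* The PCNA rules assume single-section 2D geometry and the fixture's
  radial conventions; applying them to real microscopy requires
  recalibrating the reference area and possibly the shell threshold.
* Statistical comparison between phases is by permutation tests on
  means; hierarchical (per-replicate) structure, as a linear mixed
  model would capture, is not modeled.
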