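---
title: "Models and methods behind lretlipid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lretlipid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lretlipid)
```

This vignette explains the models the package implements, the assumptions
behind them, the tunable parameters and their defaults, and the numerical
and design choices made where more than one reasonable option existed.

## The two-state LRET model

A GPCR in a nanodisc exchanges between an inactive conformation and an
active/active-like one. With a long-lived lanthanide donor on the
cytoplasmic end of TM6 and an acceptor on TM1, each conformation has its own
donor–acceptor distance and therefore its own donor-in-presence-of-acceptor
lifetime. Because the acceptor sensitized emission is excited only through
transfer, donor-only and acceptor-only species contribute nothing, and the
sensitized-emission decay is a sum of exponentials,

$$I(t) = b + \sum_i \alpha_i e^{-t/\tau_i},$$

with one component per conformational species. Two assumptions matter:

* **Slow exchange.** Conformational interconversion must be slow on the
  lifetime scale (hundreds of µs); otherwise the components mix and the
  amplitudes lose their population meaning. The package takes the
  multi-exponential description at face value, as the assay design intends.
* **Equal brightness.** Amplitude ratios equal population ratios only if the
  species share donor quantum yield and labeling efficiency. Under this
  assumption the molecular fractions are
  $A_i = 100\,\alpha_i/\sum_j \alpha_j$ (the `"amplitude"` convention,
  default). The `"lifetime"` convention
  ($A_i \propto \alpha_i \tau_i$) instead apportions time-integrated
  emission; it is kept as an option because published amplitude-to-fraction
  corrections differ, and the two conventions bracket them. The amplitude
  convention is the default because fractions combined that way reproduce
  the free-energy arithmetic of the reference dataset in
  `ghsr_lifetimes()`.

### Fitting

The least-squares objective of a biexponential is multimodal, so
`fit_decay()` multi-starts: lifetime combinations are drawn from a
log-spaced grid (50–3000 µs by default, covering the full range of the
reference conditions), amplitudes at each start come from a linear solve at
fixed lifetimes, and every start is refined with bounded
Levenberg–Marquardt (`minpack.lm::nlsLM`; $\tau > 0$, $\alpha \ge 0$,
baseline $\ge 0$). The best converged start wins. The baseline term is off
by default because traces are typically reported as peak-normalized
intensity with negligible offset; it can be enabled when scattered light is
suspected.

Goodness of fit is judged the way decay analysis traditionally does it: by
residual randomness. `fit_decay()` reports a Wald–Wolfowitz runs test on
residual signs (`residual_runs_p`; implemented in the package with the
normal approximation, as no pre-installed package provides it) along with
the reduced chi-square. Numerically exact fits (residuals at rounding-error
scale) are treated as passing, since sign patterns of $10^{-12}$-scale
residuals reflect the optimizer, not the model.

Two lifetimes closer than 5% of each other are not resolvable from this
kind of data; such fits are flagged *degenerate* and the caller is told to
refit with one component fewer. `select_model()` builds on this: candidate
component counts are tried in increasing order, a candidate is accepted when
its residuals pass the runs test (p > 0.05) and AICc prefers it over the
previous count, and a degenerate candidate stops the search at the previous
count. On a synthetic pair of 500 and 505 µs components this correctly
collapses to a single-component description.

Parameter uncertainties come from the fit covariance; replicate-to-replicate
spread should be computed across traces, not taken from a single fit.
Weighted least squares with Poisson-like weights ($\sigma \propto \sqrt I$)
is available but off by default, since normalized analog-detected traces do
not carry counting statistics.

## Efficiencies, distances, free energies

The Förster relations $E = 1 - \tau_{ad}/\tau_d$ and
$R = R_0 (1/E - 1)^{1/6}$ convert lifetimes to distances. $R_0$ and the
donor-only lifetime $\tau_d$ are properties of the probe pair and the
photophysical setup; **they are required inputs with no defaults** —
silently assuming them would manufacture distances. The test suite carries a
pair ($\tau_d \approx 1508.4$ µs, $R_0 \approx 38.25$ Å) derived by a root
find from two published (lifetime, distance) anchors of the GHSR TM1–TM6
pair; it reproduces those anchors and is used only as test configuration.
Lifetimes exceeding $\tau_d$ produce negative efficiencies; these are
returned flagged rather than clipped, because silently clipping would hide
calibration problems.

Free-energy shifts use
$\Delta\Delta G = -RT \ln(K_\mathrm{test}/K_\mathrm{ref})$ with
$K = A_\mathrm{active}/A_\mathrm{inactive}$, so stabilization of the active
state is negative. The assay temperature is rarely reported with the decay
data; the default is 298.15 K and the function accepts 273–320 K. Between
288 and 298 K the reference shifts change by under 0.02 kcal/mol — less
than their rounding — which the test suite asserts explicitly. The gas
constant is fixed at 1.98720425×10⁻³ kcal mol⁻¹ K⁻¹.

## Steady-state assays

**Tr-FRET ratio.** The ratio is acceptor-over-donor (520/490 nm) so that it
increases with transfer. Only the orientation convention is a choice; the
ratio itself is scale invariant.

**Saturation binding.** The titration of a labeled lipid against a receptor
shows fast specific binding that saturates, plus a slow linear rise shared
with control lipids. `fit_saturation()` uses the minimal model with that
shape: offset + hyperbola ($B_{max}, K_{1/2}$, Hill coefficient fixed at 1 —
no cooperativity is claimed) + linear term. The reported saturation point is
where the specific term reaches 95% of its plateau, $19\,K_{1/2}$. A series
is classified *nonspecific-only* when the plateau is indistinguishable from
zero: $B_{max}$ below 5% of the observed dynamic range, or below twice its
standard error, or $K_{1/2}$ beyond the sampled range (in which case the
hyperbola has degenerated into a second straight line). On a pure-linear
control the four-parameter model is unidentifiable and the optimizer may
fail outright; that failure is itself diagnostic and triggers the linear
refit. Affinity is deliberately *not* reported as a Kd: converting
$K_{1/2}$ (a molar ratio) into a concentration-scale affinity involves
assay-specific assumptions, so the package exposes the raw half-saturation
load and leaves the sub-µM-affinity reading to the analyst.

**Peak wavelength.** `emission_lambda_max()` smooths the spectrum with a
quadratic loess fit and refines the maximum by parabolic interpolation
through the three bracketing points. A short running mean was considered and
rejected: on a band of 25 nm width with 1% peak noise, a 5-point running
mean leaves the estimate with ≈1.2 nm standard deviation, while loess at the
default span of 0.25 achieves ≈0.22 nm with ≈0.07 nm bias on noiseless
off-grid bands (both measured over 200 seeded simulations). The span is the
one tunable: larger values suppress noise but would bias strongly asymmetric
bands; 0.25 suits single-band spectra spanning ~4–8 band widths.

**Calibration.** The labeled-lipid calibration is linear and assumes equal
fluorophore quantum yield in calibration micelles and in the bilayer — the
assumption the assay itself makes. Intensities below the intercept map to
ratio 0 with a warning; inversions outside the standards' range are flagged
as extrapolation rather than refused.

## Occupancy analysis

The occupancy module consumes exported per-frame lipid–residue minimal
distances (or precomputed contacts), not raw trajectories, keeping the core
format-agnostic. Three parameters matter:

* **cutoff = 0.6 nm** — headgroup-bead-to-residue-bead contact distance,
  common coarse-grained practice; inclusive boundary; echoed in every
  profile object.
* **min_residues = 2** — a lipid is bound to a site only when it contacts at
  least two of the site's residues simultaneously, suppressing grazing
  contacts.
* **gap = 0** — dwell smoothing (closing short unbound gaps inside a bound
  run) is off by default; it changes event statistics, not mean occupancy,
  and should be a deliberate choice.

Histograms of bound-lipid counts are exact partitions (they sum to 100%).
The site definitions in `ghsr_pip2_sites()` are fixtures with
Ballesteros–Weinstein labels preserved; the module does not discover sites.

## The synthetic-data generator

The generator exists so every analyzer has a verified round trip: noiseless
outputs equal their closed-form curves to machine precision, and noisy
outputs are deterministic per seed (seeding is local — the caller's RNG
stream is untouched).

* **Decays** use the lifetime/fraction regimes of the reference table
  (lifetimes ~267–1075 µs, fractions 2.7–97.3%), a 0–4000 µs grid at 2 µs
  steps (at least four times the slowest lifetime, so the slow tail is well
  constrained), peak normalization, and Gaussian noise of 1% of peak by
  default; Poisson counting noise is available.
* **Titrations** default to a curve saturating at a lipid-to-receptor ratio
  of about 4.6 ($K_{1/2} = 0.24$, i.e. 95% of plateau inside the 4–5
  window characteristic of the reference assay) over a 0–7 load range.
* **Contact series** evolve an independent two-state Markov chain per
  lipid × site with per-frame on/off probabilities, giving a closed-form
  stationary bound probability $p = \mathrm{on}/(\mathrm{on}+\mathrm{off})$
  against which estimators are checked; emitted distances sit at
  cutoff ± 0.1 nm so contact calls are unambiguous.

What the generator does **not** emulate: instrument response functions and
detector afterpulsing, correlated (1/f) noise, bleaching drifts, partial
labeling, multi-lipid cooperativity within one site, or the spatial detail
of real coarse-grained trajectories (distances are binary around the
cutoff). Passing tests therefore demonstrate correctness of the estimators
under the stated generative models — unbiasedness, convergence rates,
classification behavior — not robustness to every instrumental artifact of
real data.

## Problem sizes and statistical checks

The test suite works at desk scale: decay fits use 1000–2000 samples;
noisy-recovery checks use 60 seeded replicates at 2% noise for the bias
property (mean recovered fraction within one simulation standard error of
truth) and a fixed-seed 1% noise trace for tolerance checks (lifetimes
within 5%, fractions within 2 percentage points — tolerances frozen from a
200-replicate calibration). Binding classification is checked over 100
seeded titrations at 2% of dynamic range. Markov occupancy estimates are
compared with their closed-form stationary values within three standard
errors, using the chain's integrated autocorrelation time to compute an
effective sample size, at 10³ and 10⁵ frames.

## Known limitations

* At most three exponential components; no global fitting across traces and
  no instrument-response deconvolution.
* The amplitude→fraction step assumes equal species brightness (see above);
  if quantum yields differ between conformations, fractions are biased by
  that ratio and the two conventions only bracket the truth.
* $\Delta\Delta G$ assumes a strict two-state equilibrium; a third,
  unresolved state folds into whichever component it is closest to.
* The occupancy module treats sites as fixed residue lists and lipids as
  independent; competitive exclusion within a site must be encoded in the
  input rates, not inferred.
* The saturation model fixes the Hill coefficient at 1 and reports the
  half-saturation load in the units of the titration axis, not a Kd.
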