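---
title: "Methods: burst-mode smFRET distances and exterior-loop geometry"
author: "fretends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: burst-mode smFRET distances and exterior-loop geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement and its model

A confocal spot samples freely diffusing, doubly end-labelled molecules at
~90 pM, so that at most one molecule is present at a time. Photon counts in
the donor and acceptor channels are stored in 1 ms bins; a molecule
transiting the spot produces a *burst*, a bin whose total count stands above
the background. For each burst bin the transfer efficiency is estimated as

$$E_i = \frac{I_A^i}{I_A^i + I_D^i},$$

with $I_A$, $I_D$ the background-subtracted channel counts, and the
collection of $E_i$ is histogrammed and fitted with a Gaussian
(`fit_histogram()`), yielding a mean efficiency and a FWHM. Efficiency and
distance are linked by the effective Förster relation

$$E^{-1} = 1 + (R/R_\mathrm{eff})^6,$$

where $R_\mathrm{eff} = R_0\,\gamma^{1/6}$ folds the instrument's quantum
yields and detection efficiencies into a single radius. $R_0$ and $\gamma$
are not separately identifiable from (distance, efficiency) data, so the
calibration (`fit_calibration()`) estimates $R_\mathrm{eff}$ alone;
anything stored about $R_0$ or $\gamma$ is metadata.

Key assumptions, inherited by everything downstream: (i) a burst occupies a
single bin and comes from a single molecule; (ii) background is Poisson
with known mean rates per channel; (iii) photon partitioning at fixed
distance is binomial, which sets the shot-noise width floor
$\sigma_E = \sqrt{E(1-E)/N}$ for $N$ detected photons; (iv) orientational
averaging of the dyes is fast ($\kappa^2$ fixed), which is subsumed in
$R_\mathrm{eff}$.

## What the synthetic-data generator emulates

`simulate_trace()` draws, per bin, Poisson background in each channel;
burst bins occur independently with probability `burst_rate/1000` and
receive $N \sim \mathrm{Poisson}(\texttt{burst\_brightness})$ extra photons
split binomially by $E(r)$, with $r$ drawn per burst from one of three
distance models: fixed; fixed plus isotropic 3-D Gaussian linker jitter of
per-axis sd $\sigma_\mathrm{link}$ (the realised distance is the modulus of
the displaced separation vector, i.e. jitter adds in quadrature); or a
worm-like chain of contour length $L$ and persistence length $l_p$ with
optional jitter on top.

The generator's defaults are the study conditions: ten dsDNA rulers of 10,
13, 16, 19, 20, 21, 22, 25, 28 and 45 bp at 0.34 nm/bp; eleven RNA lengths
of 574–5345 nt; separation trends $a = 6.8$ nm, $b = 7.2\times10^{-4}$
nm/nt (TM, 5 mM MgCl₂) and $a = 7.2$ nm, $b = 7.6\times10^{-4}$ nm/nt
(TE), with 1.2 nm molecular scatter about the line; an effective radius of
8.5 nm. Burst brightness (100 photons/bin), background (1 count/bin per
channel) and burst rate (5 per 1000 bins) are not dictated by the
measurement conditions themselves; they were chosen once as typical for
diode-pumped confocal smFRET at ~90 pM and kept, because they place the
shot-noise FWHM near 0.12 while leaving simulated histograms (with the
default 0.5 nm linker jitter) roughly 1.5–2× wider — bracketing the width
regime the analysis is meant to resolve.

Deliberately **not** emulated: photon-by-photon timestamps and diffusion
through a 3-D Gaussian detection volume (bursts are single whole bins),
spectral crosstalk and direct acceptor excitation (absorbed by the
calibration in a real instrument), triplet blinking and photobleaching,
and multi-molecule coincidence. Passing tests therefore demonstrate the
correctness of the analysis chain under its own statistical model, not
robustness to these instrumental artefacts.

Efficiency noise in `simulate_calibration_dataset()` is truncated to
$(0,1)$ by resampling, which for rulers far from the half-transfer point
(where $E$ nears 0 or 1) slightly biases individual points; because the
calibration fit's sensitivity to those flat-curve points is small, the
recovered $R_\mathrm{eff}$ stays unbiased within Monte-Carlo resolution
(this is verified by a 500-seed test).

## Tunable parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `rise_per_bp` | 0.34 | nm/bp | B-form dsDNA helical rise |
| `linker_total` | 1.5 | nm | two opposed dye linkers, total effective length |
| `linker_rel_uncertainty` | 0.10 | — | relative linker-length uncertainty, folded into the calibration as abscissa error |
| `rise_per_nt` | 0.59 | nm/nt | ssRNA contour per nucleotide |
| `lp` | 2.1 | nm | ssRNA persistence length at 5 mM MgCl₂ |
| burst threshold | $\mu_{bg} + 5\sqrt{\mu_{bg}}$ | counts/bin | Poisson false-positive rate ~3×10⁻⁴ at the default background |
| histogram bins | 40 over $[-0.1, 1.1]$ | — | E left unclamped so background leakage stays visible |
| `scatter_sd` | 1.2 | nm | between-molecule scatter about the length trend |
| `sigma_link` | 0.5 | nm | per-axis linker jitter in RNA simulations |

## Numerical choices

**Calibration.** One-parameter weighted least squares minimised with
Brent's method (`optimize`, tolerance 10⁻¹⁰) on a bracket spanning the
ruler separations. Abscissa (linker) uncertainty is folded in by the
effective-variance method, $\sigma^2_\mathrm{eff} = \sigma_E^2 +
(\partial E/\partial R)^2 \sigma_R^2$ with $\sigma_R =$
`linker_rel_uncertainty * linker_total`; this was preferred to orthogonal
distance regression for transparency and is isolated behind
`fit_calibration()` so it can be swapped. The 1σ error comes from the
curvature of the objective at the minimum (central differences, step
10⁻⁴·$R_\mathrm{eff}$); for unweighted fits it is rescaled by the residual
variance, and a noise-free fit reports exactly zero. Whether the 1.5 nm
linker belongs in the calibration abscissa is a convention the data cannot
settle; the default is to exclude it (`include_linker_in_abscissa =
FALSE`), and the switch exists precisely so both conventions can be run and
compared — including it shifts every abscissa by a constant and raises the
fitted radius accordingly.

**Histogram fits.** Gaussian fits are to binned counts
(Levenberg–Marquardt via `minpack.lm`, moments as starting values), as
smFRET histograms are conventionally fitted — not maximum likelihood on
samples; the sample mean and sd are carried alongside for comparison.
Degenerate inputs (all samples identical, fewer than 50 samples) fail
explicitly rather than silently.

**Trend fits.** Weighted least squares with weights $1/\sigma_i^2$ when
per-point uncertainties are supplied, in which case parameter errors are on
the known-σ scale $(X^TWX)^{-1}$; ordinary least squares with
residual-based errors otherwise. The 1σ band reported by `predict()` is
the confidence band of the fitted mean (switchable to a prediction band).
Inside `run_pipeline()` the trend stage deliberately drops the per-point
inversion σ and uses ordinary least squares: the 1.2 nm between-molecule
scatter dominates the per-point measurement error, so residual-based
parameter errors are the honest ones, and per-point uncertainties are
calibration-dominated and hence correlated across points, which $1/\sigma^2$
weighting would mishandle.

**Worm-like chain.** The radial density is the standard mean-field
interpolation form (normalised numerically; a Gaussian-chain variant is
exposed through `chain_model`), chosen because it reproduces both the rigid
and the coil limit relevant to the argument. Normalisation uses adaptive
quadrature with a trapezoid fallback on a composite grid that is
log-refined near $r = L$, so the near-rigid spike ($l_p \gg L$) is
resolved. Contour inversion brackets from $L = d$ (the statistic is always
below $L$) and doubles upward, then bisects to 10⁻¹⁰ relative. The rms
statistic uses the closed form
$\langle R^2\rangle = 2 l_p L - 2 l_p^2 (1 - e^{-L/l_p})$; mean and mode
use quadrature/optimisation of the density. `match_statistic` defaults to
rms; matching the mean or mode instead yields systematically longer
contour lengths for the same measured distance (both statistics sit below
the rms for this density), which is why the choice is exposed rather than
hard-coded — published loop-length ranges depend on it. Nucleotide counts
round by ceiling by default (every started nucleotide counts, and the
ceiling convention is the one consistent with converting a 5–9 nm range to
9–16 nt); floor and nearest are available because no single convention
reproduces all endpoint pairs quoted in the literature.

**Width analysis and rigidity.** The per-burst efficiency variance
decomposes exactly as $\mathrm{Var}(E_{obs}) = \mathrm{E}[E(r)(1-E(r))]/N
+ \mathrm{Var}(E(r))$; `predict_width()` computes both terms by quadrature.
The predicted width is *not* globally monotone in $l_p$: a sufficiently
floppy chain collapses into the high-efficiency plateau of the Förster
curve and its histogram narrows again. Monotone decrease across
$l_p \in \{1, 2.1, 5, 20\}$ nm holds once the contour length is large
enough that even the floppiest coil spans the responsive distance range
(roughly $L \gtrsim 4.5\,R_\mathrm{eff}$; tests use $L = 45$ nm at
$R_\mathrm{eff} = 8.5$ nm). `infer_persistence_length()` therefore solves
only on the rigid-side branch, from the width maximum toward the
shot-noise limit, and matches the *same* statistic the observation uses — a
Gaussian fit to a binned Monte-Carlo histogram with common random numbers
across $l_p$, so the objective is smooth. An observed width at the
shot-noise floor returns the upper bracket flagged as a lower bound on
rigidity; a width below the floor is rejected as inconsistent.

**Seeds.** Every stochastic function takes a `seed` and restores the
caller's RNG state, so fixed seeds give bit-identical outputs without
perturbing surrounding code. `run_pipeline()` derives per-stage sub-seeds
from its master seed and records them in the report.

## Problem sizes

The shipped tests and the reproduction script use traces of 2×10⁴–2×10⁵
bins (≈100–1000 bursts per sample), 500-seed Monte-Carlo loops for
estimator bias and coverage, 2–4×10⁴ draws for Monte-Carlo histograms and
2000–4000 chains for the discretised-chain oracle. These sizes put
Monte-Carlo error well below the tolerances being asserted while keeping a
full run in seconds.

## Known limitations

- Single-population analysis only: no two-Gaussian deconvolution, no
  dynamic (within-burst) FRET, no ALEX sorting.
- Bursts are single bins; real multi-bin bursts would raise the effective
  photon count per molecule and narrow histograms relative to this model.
- The mean-field density is an interpolation, not the exact semiflexible
  propagator; its rms differs from the closed-form chain rms at
  intermediate $l_p/L$ by up to a few percent, which is why the rms match
  uses the closed form.
- Background subtraction uses known mean rates; estimating rates from
  burst-free stretches is left to the caller.
- Efficiencies are deliberately unclamped, so strongly background-dominated
  bins can yield $E$ outside $[0,1]$; they appear in the histogram tails
  rather than being folded inward.
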