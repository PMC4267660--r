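# fretends

Single-molecule FRET analysis of the 5′–3′ end-to-end separation of long
single-stranded RNA molecules.

Theory predicts that the exterior loop of an RNA secondary structure — the
loop carrying the unpaired 5′ and 3′ ends — stays short regardless of how
long the molecule is, so that mRNAs are "effectively circularized". Testing
this requires measuring nanometre-scale distances on freely diffusing,
end-labelled RNA one molecule at a time. `fretends` implements the complete
analysis chain for burst-mode smFRET distance measurements of this kind,
together with a seeded synthetic-data generator that reproduces the
statistical structure the analysis assumes, so every stage is testable
against known ground truth.

## The model

A donor/acceptor dye pair at distance *R* transfers energy with efficiency

```
E = 1 / (1 + (R / R_eff)^6)
```

where the effective Förster radius `R_eff = R0 * gamma^(1/6)` absorbs the
detection factor γ. Per 1-ms bin *i* of a two-channel photon trace, the
efficiency is estimated as `E_i = I_A / (I_A + I_D)` from
background-subtracted acceptor and donor counts, burst bins being those with
total counts above a background threshold. Histogramming the `E_i` and
fitting a Gaussian gives a mean efficiency and a full width at half maximum;
the width can never fall below the binomial shot-noise limit
`sigma_E = sqrt(E (1 - E) / N)` for *N* photons per burst.

`R_eff` is calibrated with double-stranded DNA rulers (10–45 bp at
0.34 nm/bp); mean efficiencies of end-labelled RNAs are then inverted
through the calibration to inter-dye distances, corrected for the 1.5 nm of
opposed dye linkers, and regressed against RNA length per buffer condition.
End-to-end distances are converted to exterior-loop contour lengths ℒ under
a rigid rod (0.59 nm/nt) and under the worm-like chain, whose radial
end-to-end density

```
P(r) ∝ r^2 (1 - (r/L)^2)^(-9/2) exp(-3L / (4 lp (1 - (r/L)^2)))
```

is inverted for *L* at persistence length `lp` (2.1 nm for ssRNA in 5 mM
MgCl₂). Comparing observed histogram widths with the shot-noise floor and
with chain-fluctuation predictions bounds the effective rigidity of the
exterior loop (`infer_persistence_length()`).

## Worked example

```r
library(fretends)
report <- run_pipeline(pipeline_config(seed = 42L))
print(report)
```

```
smFRET end-to-end distance analysis report
  seed: 42
  calibration: R_eff = 8.48 +/- 0.06 nm (10 rulers)
  samples analysed: 22 (TE: 11, TM: 11)
  trend [TM]: a = 6.27 +/- 0.7 nm, b = 0.00109 +/- 0.00027 nm/nt; residual sd 1.18 nm
  trend [TE]: a = 6.34 +/- 0.77 nm, b = 0.00119 +/- 0.0003 nm/nt; residual sd 1.29 nm
  fractional separation change over 574-5345 nt: TM 75.3%, TE 81.0%
  separations 5.35-13.2 nm -> end-to-end 3.85-11.7 nm after linker correction
  exterior loop: rigid 7-20 nt; WLC (lp = 2.1 nm) 10-59 nt
  mean histogram width excess over shot noise: 1.84
```

The run simulates photon traces for the ten DNA rulers, recovers the
generative `R_eff` of 8.5 nm from their burst histograms, simulates eleven
RNA samples (574–5345 nt) under each of two buffers from a linear
separation-versus-length trend with 1.2 nm molecular scatter, re-measures
each one through the full burst/histogram/inversion chain, and reports the
per-buffer trend fits (intercept *a* in nm, slope *b* in nm/nt, both with
1σ errors), the residual scatter, the linker-corrected end-to-end range,
the exterior-loop contour lengths implied by the rigid and worm-like-chain
models, and the mean histogram-width excess over the shot-noise limit
(1.84, i.e. the simulated linker jitter broadens histograms well beyond
photon statistics, as observed histograms are).

Individual stages are plain functions with classed results:

```r
cal <- fit_calibration(simulate_calibration_dataset(8.5, noise_sd_E = 0.03, seed = 1L))
print(cal)
#> Effective Forster radius calibration (E^-1 = 1 + (R/R_eff)^6)
#>   R_eff = 8.58 +/- 0.11 nm  (10 ruler points, weighted fit)
#>   chi-square = 3.607 on 9 df

invert_contour_length(9, lp = 2.1)
#> Exterior-loop contour estimate [wlc (lp = 2.1 nm, matched rms)]:
#>   L = 21.39 nm  ->  37 nt (ceil, 0.59 nm/nt)
```

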