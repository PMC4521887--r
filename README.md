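# stcadapt

Multi-filter spike-triggered analysis of contrast adaptation in retinal
ganglion cells.

When visual contrast changes, retinal ganglion cells adjust both their
sensitivity and their temporal filtering: at high contrast the
spike-triggered average (STA) becomes faster and more biphasic. `stcadapt`
analyses this adaptation with *multiple* parallel filters instead of a
single one. From responses to a contrast-alternating Gaussian white-noise
flicker (20 s at 32% contrast, 100 s at 12%, updated at 30 Hz) it
estimates, per contrast condition, the STA and the spike-triggered
covariance (STC) spectrum

&nbsp;&nbsp;&nbsp;&nbsp;ΔC = ⟨(sₙ − s̄)(sₙ − s̄)ᵀ⟩ₙ − I,

whose significantly non-zero eigenvalues mark the stimulus features a cell
is sensitive to (negative: reduced spike-triggered variance along a
selective or suppressive axis; positive: increased variance, the signature
of On/Off convergence or spike-timing dynamics). Significance comes from a
nested shuffle test: spikes are randomly re-timed within their contrast
episode, the extreme eigenvalues are compared against the 95% band of the
shuffled extremes, significant eigenvectors are projected out, and the test
recurses. Features are ranked by the information they carry about single
spikes (bits/spike, bias-corrected by extrapolation to infinite sample
size), cells are typed from the information in the spectrum-end
eigenvectors (Type I/II/III), STAs from both contrasts are reconstructed as
weighted sums of a single two-feature basis, On- and Off-pathway spikes are
separated by k-means in feature space, and activation-dependent
spike-latency shifts are quantified as the slope of spike-time shift versus
filter-output peak size.

The package ships the generative models that reproduce the three
phenotypes — a spike-feedback threshold model and a linear-nonlinear-kinetic
(LNK) model for gain-control adaptation (Type I), a two-pathway On/Off
mixture (Type II), and a latency-shift LN-Poisson model (Type III), plus a
plain LN-Poisson control — so the entire pipeline can be exercised and
validated on synthetic recordings with known ground truth. See the methods
vignette (`vignettes/stcadapt-methods.Rmd`) for the model equations,
parameter choices and design decisions.

## Worked example

Simulate a latency-shift cell on the standard stimulus and run the full
analysis (reduced shuffle count for a quick run):

```r
library(stcadapt)
cfg <- run_config(stimulus = stim_config(n_episode_pairs = 40, seed = 21),
                  model = "latency", n_repeats = 300,
                  model_seed = 4, analysis_seed = 9)
res <- run_pipeline(cfg)
res
#> Pipeline run: model 'latency', 2853 spikes
#>   high contrast: 1 sig. positive / 1 sig. negative eigenvalues
#>   low contrast: 1 sig. positive / 1 sig. negative eigenvalues
#>   classification: TypeIII
#>   STA-fit R^2: high basis 0.906/0.837, low basis 0.705/0.967 (high/low STA)
```

The positive significant eigenvalue at both contrasts together with an
uninformative `v1` below the 0.8 bits/spike Type II threshold yields the
Type III label, exactly the phenotype the latency mechanism produces: in
this cell the spectrum-end feature `v20` carries ~0.92 bits/spike and `v1`
~0.31 bits/spike (`res$conditions$high$info`). The four R² values show that
each contrast's own basis reconstructs its STA well and that the bases
partially generalise across contrast. Timing analysis of the same run gives
a strongly negative latency slope (stronger activation, earlier spikes):

```r
res$conditions$high$timing
#> Spike-timing profile (high contrast): 10/40 activation bins kept
#>   shift vs activation: slope -37.59 ms/unit (SE 6.37), intercept 64.1 ms
```

`run_pipeline(cfg, out_dir = "reports")` writes all spectra, information
tables, fits, timing profiles, stimulus/spike/filter CSVs and a manifest
that fully regenerates the run.

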