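---
title: "Multi-filter analysis of retinal contrast adaptation: methods and design"
author: "stcadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-filter analysis of retinal contrast adaptation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

When the contrast of a visual stimulus changes, retinal ganglion cells
adapt: their sensitivity drops at high contrast and their temporal filter —
classically measured as the spike-triggered average (STA) under white-noise
flicker — becomes faster and more biphasic. `stcadapt` implements a
multi-filter account of this phenomenon. Instead of tracking a single
contrast-dependent filter, it extracts a *set* of parallel temporal filters
with spike-triggered covariance (STC) analysis at each contrast level and
asks whether a contrast-invariant feature basis with contrast-dependent
weights captures the filter changes.

The package covers the full analysis chain — stimulus construction, STA/STC
estimation with shuffle-based significance, information-theoretic feature
ranking and cell typing, STA reconstruction from feature bases, On/Off
pathway separation, and activation-dependent spike-latency quantification —
together with generative spike-train models that reproduce the three
qualitative phenotypes the analysis distinguishes. The models double as the
synthetic-data source: every stage of the pipeline is validated on simulated
recordings whose ground truth is known.

## Stimulus model

The stimulus is a spatially uniform Gaussian flicker: intensity values are
drawn independently at 30 Hz (bin width $\Delta t = 33.3$ ms) around a mean
$M$ (default 39.5, photopic range), with contrast $C = \sigma/M$ alternating
between 20-s episodes at 32% and 100-s episodes at 12%. The longer
low-contrast episodes compensate for the lower firing rates there, so both
conditions yield comparable spike counts. Samples are stored as contrast
values (deviation over mean), so the per-bin SD equals the episode contrast.

For spike-triggered analysis each contrast condition is normalized to unit
empirical SD (`normalize_per_contrast()`). Because the stimulus is white,
the prior covariance of 20-bin stimulus windows is then the identity, and
the covariance difference $\Delta C = C - I$ has baseline zero. Windows
reaching across a contrast switch use the true (normalized) stimulus
history; only spikes in the first 19 bins of the whole recording are
dropped. A single seeded random stream generates the entire stimulus;
per-episode streams are not needed for simulation.

One subtlety of the alternating protocol deserves note: for a spike just
after a contrast switch, the bins of its window that fall before the switch
are normalized by the *other* condition's SD, so the effective filter of
those boundary windows is a rescaled version of the cell's filter. The
spike-triggered ensemble of a condition is then a mixture, and with enough
spikes (several thousand) the significance cascade correctly reports the
mixture as additional structure beyond the cell's own features. Analyses
whose purpose is a single-contrast model signature (e.g. the
one-negative-eigenvalue control of the plain LN model) therefore use
constant-contrast stimulus sequences — the protocol the generative models
were originally characterised with — while all cross-contrast comparisons
keep the alternating stimulus.

## Spike-triggered estimation

For spike times $t_n$ (bins with $k$ spikes enter $k$ times) the windows
$s_n(\tau) = s(t_n - \tau)$, $\tau = 0\ldots19$, give the STA
$\bar s(\tau) = \langle s_n(\tau)\rangle_n$ and the covariance
$C = \langle (s_n - \bar s)(s_n - \bar s)^\top \rangle_n$. Eigenvalues of
$\Delta C = C - I$ below zero mark directions of reduced spike-triggered
variance (stimulus selectivity or suppression), values above zero mark
increased variance (e.g. On/Off convergence or spike-timing dynamics).
Eigenvector signs are arbitrary; the package fixes them so the
largest-magnitude tap is negative (Off-dominant convention), which makes
fits and reports reproducible.

### Shuffle significance

The null distribution for eigenvalue significance is built by randomly
time-shifting spikes within their own contrast episode and recomputing the
spectrum (1000 shuffles by default). The default shuffle applies one
circular shift per episode, which decouples spikes from the stimulus while
preserving the temporal clustering of the train. That preservation
matters: clustered spikes have overlapping stimulus windows, which
inflates the sampling variance of the eigenvalue extremes; a null that
re-assigns every spike independently (available as
`shuffle_mode = "independent"`) destroys the clustering, underestimates
that variance, and on simulated LN-family trains flags a marginal spurious
eigenvalue in roughly a quarter of runs at several thousand spikes. Each
round records the null distribution of the maximal and minimal
eigenvalue. The observed
maximum is significant when it exceeds the 97.5% quantile of the null
maxima; the observed minimum when it falls below the 2.5% quantile of the
null minima — together the 95% confidence band of the spectrum's ends. A
significant eigenvector is projected out of every window (true and
shuffled), the analysis recurses in the reduced space, and testing stops
when neither extreme is significant.

Two readings of "the extreme lies outside its 95% interval" exist: the band
reading above, and a symmetric two-sided test per extreme that would also
flag a *maximum* lying unusually low. The symmetric variant roughly doubles
the per-round type-I rate and flags events with no scientific
interpretation (there is nothing to project out when the maximum is small),
so the band reading is the default; `tail = "both"` switches to the
symmetric rule for comparison. With the default rule, pre-shuffled spike
trains yield zero significant eigenvalues in about 95% of runs, matching
the nominal confidence level.

Both shuffle variants are standard in the literature; the circular default
was chosen for the calibration reason above, and the independent variant is
retained for comparison.

### Nonlinearities and spike-count matching

Nonlinearities are estimated by equal-occupancy binning of the generator
signal (40 bins; occupancies differ by at most one), reporting mean
generator value against mean rate. When eigenvalue *counts* are compared
across contrasts, total spike numbers are first matched by discarding
surplus spikes uniformly at random (`match_spike_counts()`), because the
number of significant eigenvalues grows with sample size.

## Information-based feature ranking and cell typing

The relevance of a feature $k$ is the single-spike information
$I = \int ds\, P(s\,|\,\text{spike}) \log_2 \frac{P(s|\text{spike})}{P(s)}$
of its projection distributions, discretized with bins of 0.1 stimulus SD
anchored at zero; spike-conditional samples outside the prior's occupied
range are clipped into the terminal bins so the divergence stays finite,
and empty prior bins are excluded. The two-feature variant uses the
two-dimensional projection histograms.

Plug-in information estimates are biased upward, asymptotically in
proportion to $1/N$. Estimates are therefore computed on data fractions
0.8–1.0 (uniform spike subsamples, 10 draws per fraction averaged; a
single-draw mode is available) and regressed on the inverse sample size;
the intercept is the bias-corrected value, floored at zero. Regressing on
1/fraction is equivalent to regressing on $1/N$ for the intercept.

Cells are classified from the information of the 20 high-contrast
eigenvectors $v_1$ (most positive eigenvalue) to $v_{20}$ (most negative):
cells whose best feature carries less than 0.8 bits/spike, or whose two
most informative eigenvectors do not sit at the spectrum ends, are
discarded; the pair $\{v_{19}, v_{20}\}$ (either order) defines Type I with
$(k_1, k_2) = (v_{20}, v_{19})$; an informative $v_1$ ($\ge$ 0.8
bits/spike) defines Type II with $(v_1, v_{20})$; an intermediate $v_1$
defines Type III with $(v_{20}, v_1)$. The 0.8 bits/spike constant is a
configuration parameter.

## STA reconstruction and pathway separation

To avoid reusing spikes, episodes are split per contrast into 80% training
(feature estimation) and 20% test (STA estimation). The test STA is fitted
as $\hat s(\tau) = \alpha_1 k_1(\tau) + \alpha_2 k_2(\tau)$ by general
least squares — valid also for the non-orthogonal pathway filters, whose
squared weights are then not bounded by one — with
$R^2 = 1 - \sum_\tau (\bar s - \hat s)^2 / \sum_\tau (\bar s - \langle \bar
s\rangle)^2$. How much of the contrast-induced STA *change* a basis
captures is measured by the same statistic applied to the difference of the
two STAs and the difference of their fits; negative values are possible and
meaningful (the basis misses the direction of change).

On/Off separation projects all spike-triggered windows onto $(k_1, k_2)$
and splits them with k-means (k = 2, squared-Euclidean, 20 seeded restarts
with random data-point initialization; raw projections, no whitening). The
count-weighted mean window of each cluster is the pathway STA; the cluster
with a positive extreme tap is labelled ON. By construction the full STA is
the count-weighted mean of the cluster STAs. Negative On-filter weights in
cross-contrast fits are reported, not clipped — they diagnose fit failure.
The Off-cluster spikes can be re-analysed with the full STA/STC/fit chain
(`off_pathway_reanalysis()`), which on two-pathway simulations reproduces a
pure Off-cell signature (negative-only eigenvalues, well-fitted STA).

## Spike-timing dynamics

The activation level is estimated by filtering the stimulus with the cell's
unit-norm STA. Local maxima of this signal (strict on the left, ties broken
to the leftmost bin) are binned by peak value into 40 equal-count bins, and
spike trains are collected in a 367 ms window (±5 bins) around each
maximum. Only the top 10 (high contrast) or 4 (low contrast) bins are kept;
lower bins contain too few spikes for stable histograms. Each averaged
histogram is normalized to peak one, and its characteristic spike-time
shift is the vertex abscissa of the parabola through the largest point and
its two neighbours; histograms peaking at the window edge are flagged and
excluded from further fitting. The slope of an unweighted least-squares
line through shift versus mean peak activation (ms per activation unit)
summarises the latency dependence; group comparisons use two-sample t-tests
on absolute slopes, Bonferroni-corrected beyond two groups. Negative shifts
do not imply acausality — the activation estimate absorbs the mean
stimulus-to-spike delay, and shifts are corrections to it. Spikes may be
counted in the windows of several nearby maxima; no exclusivity rule is
applied.

## Generative models

All models filter the raw contrast-valued stimulus with a common canonical
temporal filter: a unit-norm difference-of-gammas with a dominant negative
lobe peaking at 100 ms and a weaker positive rebound — a surrogate for a
measured salamander ganglion-cell STA, whose slow kinetics it matches.

**Plain LN-Poisson control.** Threshold-linear rate $r = a[x - \theta]_+$
with $a = 20$ Hz, $\theta = 0.08$; inhomogeneous Poisson spiking. Its
spike-triggered signature is a single significant negative eigenvalue, and
its STA recovers the generating filter.

**Latency-shift model.** The LN-Poisson model followed by
activation-dependent delays: rates 0–15 Hz are divided into four levels and
a spike generated at level $L$ is delayed by $(4 - L)\,\Delta t$ — weak
activation, late spikes. A `shift_scale` multiplier scales the rule;
non-integer expected delays are realised by stochastic rounding so the mean
delay scales exactly (halving the schedule roughly halves the measured
shift-vs-activation slope; the ratio stays below two because the
histogram-vertex estimator partially saturates at the discrete delay steps,
for both variants). The delays create a significant positive STC eigenvalue
with an elongated, single-cluster projection cloud, and a slower STA at low
contrast — the Type III phenotype. Unbounded spike counts per bin are
allowed.

**Spike-feedback model.** Filter output minus an adaptive feedback signal
is compared with a hard threshold (0.2); each spike (at most one per bin)
increments the feedback by 3.0, which decays with $\tau = 250$ ms. The
decay is applied at each bin before the threshold comparison and the
increment after the spike decision. The model is deterministic given the
stimulus and shows negative-only significant eigenvalues with faster, more
biphasic high-contrast STAs — the Type I phenotype.

**LNK model.** The filter output, scaled by an input gain (default 6),
passes through the sigmoid $u = 1/(1 + e^{-a(x-\theta)})$ with $a = 2.5$,
$\theta = 2$, and drives a four-state kinetic block (resting R, active A,
inactive I1, I2) in which $u$ modulates R→A and I1→I2; I2 recovers slowly.
The input gain sets the operating point: without it the sigmoid works
entirely in its exponential toe, where temporal integration of an
exponential acts like a soft maximum over lags — a latency-type
nonlinearity that produces spurious *positive* eigenvalues and no
compressive (negative) ones. With the default gain, strong high-contrast
excursions reach the saturating range, giving the synaptic-depression-like
compression that generates negative eigenvalues and contrast adaptation.
The kinetic equations are integrated by forward Euler with 10 substeps per
stimulus bin ($u$ held constant within a bin); occupancies are verified to
remain in $[0, 1]$ and sum to one. The transition rates are surrogate
defaults in the slow-recovery regime (the source values are not published
in usable form) and are all exposed in `lnk_params()`.

The active-state occupancy stands in for the membrane potential, and
spikes are generated at its upward crossings of a threshold (default 0.09)
— the same deterministic readout as the spike-feedback model. A Poisson
readout on the supra-threshold occupancy is available
(`spike_mode = "poisson"`) but not the default: spreading spikes across
suprathreshold epochs acts like spike-time jitter on the filter time scale
and imprints a latency-type positive eigenvalue on the spectrum,
contradicting the gain-control phenotype the model is meant to produce.
With the default readout the model shows negative-only significant
eigenvalues, faster/narrower high-contrast STAs, and the characteristic
cross-contrast fit asymmetry (the high-contrast basis fits the low-contrast
STA at least as well as its own STA; the low-contrast basis does not
generalise as well).

**Two-pathway mixture.** Two threshold-linear pathways — an Off filter and
a delayed, sign-flipped On filter — drive independent Poisson processes
whose spikes are summed, with the Off gain dominating. The true source of
every spike is recorded, giving ground truth for the k-means separation
(agreement is typically above 95%, and the recovered pathway filters
correlate above 0.9 with the generating ones). This generator is plumbing
for validating the Type II analysis; no claim is made that it models real
On-Off cells.

## What the simulations do and do not show

The generators reproduce the qualitative spike-triggered signatures of the
three phenotypes and provide exact ground truth for filters, pathway
labels and latency rules. They do not emulate several properties of real
recordings: spike-sorting artefacts, refractoriness, adaptation of the
*sensitivity* (firing-rate transients after contrast switches are present
only in the LNK/feedback models), spatial structure, and — notably — the
contrast dependence of spike-time jitter. In recorded cells spike-timing
histograms broaden at low contrast; for the Poisson LN-family generators
the measured histogram width is dominated by relative background rate and
does not reproduce that broadening. Passing tests therefore validate the
estimators and the pipeline, not the biological completeness of the
generators.

## Numerical choices and problem sizes

Defaults follow the experimental protocol: 20 lags at 30 Hz, 1000
shuffles, 95% confidence, 40 occupancy bins, 0.1 SD histogram bins,
80/20 episode splits, 0.8 bits/spike threshold. Episode counts in tests
and in `scripts/acceptance.R` are chosen per analysis as the smallest
recording that gives the relevant estimator a comfortable margin: 150
pairs (5 h) where a criterion needs ≥ 5000 high-contrast spikes from
~1.8 Hz firing; 120 pairs for latency-slope estimation (the
vertex-localization estimator needs well-filled histograms); 30–50 pairs
for eigenvalue-count comparisons at matched spike numbers (10³–10⁴ spikes,
the regime of the original recordings); 20–30 pairs for calibration runs.
Equal-count binning assigns group $g = \lceil i \cdot k / n \rceil$ to the
$i$-th sorted value, which keeps occupancies within one of each other for
any $n$. Degenerate inputs (all-zero filters, empty conditions, too few
episodes or maxima, rank-deficient spike sets, collinear bases) raise
errors rather than propagate silently.

## Interfaces

Everything is driven from R: `run_config()` + `run_pipeline()` execute the
whole chain (simulate → analyze → classify → fit → timing) and can write
all reports (JSON spectra, information tables, fits, timing profiles, CSV
stimulus/spike/filter dumps and a manifest that regenerates the run) to a
directory. `scripts/acceptance.R` is a command-line entry point that
recomputes the headline numbers from scratch. Individual stages are exposed
as plain functions so any step can be replaced or inspected.

## Known limitations

* The significance cascade tests only the spectrum extremes per round, as
  in the original procedure; interior eigenvalues reach significance only
  after outer ones are deflated.
* Two-dimensional information estimates at 0.1 SD bins carry a large
  finite-sample bias below ~10⁴ spikes; the linear $1/N$ extrapolation is
  then only approximate. Coarser bins are advisable for joint information
  at small spike counts.
* The latency-shift slope is a vertex estimate on discrete 33 ms bins;
  slopes are comparable across models and conditions but are not unbiased
  estimates of the underlying delay rule.
* LNK transition rates are surrogates; conclusions should rest on the
  model's qualitative regime, not the specific constants.
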