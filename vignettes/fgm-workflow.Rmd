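---
title: "Quantifying and monitoring fecal glucocorticoid metabolites: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and monitoring fecal glucocorticoid metabolites: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgmassay)
```

# The problem

Glucocorticoids (cortisol and corticosterone) are released by the adrenal
cortex when an animal perceives a stressor. Their degraded byproducts are
excreted in feces as fecal glucocorticoid metabolites (FGMs), which can be
collected without handling the animal — the only practical option for
long-term stress monitoring of wildlife in managed care, such as sea
otters in aquaria. `fgmassay` implements the complete desk side of such a
monitoring program: quantification of competitive enzyme immunoassay
(EIA) plates, analytical validation of the assays on a new sample matrix,
and longitudinal per-individual analysis of the resulting concentration
series, including matching detected stress events against husbandry
notes. Because both commercial kits cross-react with related metabolites,
the workflow measures *both* FGMs and only calls an adrenal stress
response when both peak together.

# Plate model and quantification

A competitive EIA plate carries, all in duplicate wells: non-specific
binding (NSB) wells, total activity (TA) wells, maximum binding (B0)
wells, a zero-standard blank, a standard series, and samples. Signal
*decreases* with analyte concentration. The response used throughout is
percent antibody bound,

$$\%B = 100\,\frac{\mathrm{OD} - \overline{\mathrm{NSB}}}
                 {\overline{B_0} - \overline{\mathrm{NSB}}},$$

anchored at 0 on the NSB mean and 100 on the B0 mean. The blank and TA
wells are validated for presence (they are kit controls) but enter no
computation; using the blank as an extra anchor would be an alternative
convention, not adopted here.

Duplicate agreement is scored as a CV, $100\,\mathrm{SD}/\mathrm{mean}$
with the sample SD ($n-1$), on ODs — the re-run decision happens at the
plate stage, before any back-calculation. The cascade: a duplicate CV of
10% or more flags the sample for a re-run; any failing standard pair, or
more than 50% of sample duplicates failing, forces the whole plate to be
re-run. The intra-assay CV is summarised as the mean sample-duplicate CV
within a plate (threshold 10%); the inter-assay CV is the CV of a pooled
control across plates (threshold 16%). The thresholds are conventional;
the summary formulas are this package's operationalisation, since
thresholds are usually quoted without formulas.

Standard curves follow the four-parameter logistic (4PL) model

$$y(x) = d + \frac{a - d}{1 + (x/c)^b},$$

with $a$ the zero-dose response, $d$ the infinite-dose response, $c$ the
inflection (EC50, pg/mL) and $b$ the slope factor. `fit_4pl()` uses
unweighted Levenberg–Marquardt least squares on the duplicate-mean %B of
the standards, started from $a=\max y$, $d=\min y$, $c=$ geometric mean
of the doses, $b=1$, with a fixed fallback restart grid — fitting is
fully deterministic. Back-calculation is the closed form
$x = c\,((a-d)/(y-d) - 1)^{1/b}$; the tests verify it against a
bisection oracle to $10^{-9}$ relative.

**A caution on small curves.** With only 7 (cortisol) or 5
(corticosterone) standards, the zero-dose asymptote $a$ is an
extrapolation (the lowest cortisol standard still reads near 80 %B), and
under realistic response noise $a$ and $c$ trade off along a ridge of the
least-squares surface. At 5% multiplicative response noise the median
relative error of $\hat c$ on the 7-point curve is roughly 25% — a
property of the design, not of the optimizer (a derivative-free
optimizer started at the truth finds the same, lower-SSE, minimum).
Back-calculated *sample concentrations* are far better behaved than the
individual parameters, because errors along the ridge largely cancel in
the fitted curve itself: mid-curve samples are recovered with a median
error well under 10% at that noise level.

Concentrations convert to dry-feces units by

$$C_{\mathrm{fecal}}\ [\mathrm{ng/g}] =
  C_{\mathrm{extract}}\ [\mathrm{ng/mL}] \times D \times
  \frac{V\ [\mathrm{mL}]}{m\ [\mathrm{g}]},$$

with working dilution $D$ (1:10 cortisol, 1:30 corticosterone by
default), solvent volume $V = 2$ mL and dry mass $m$ targeted at
$0.20 \pm 0.02$ g. Samples under 0.18 g are discarded
(`MASS_DISCARD`). Samples whose response falls under the curve are
imputed at half the lowest standard converted through the extraction
ratio: $0.5 \times 0.156 \times 2/0.2 = 0.78$ ng/g (cortisol) and
$0.5 \times 0.032 \times 10 = 0.16$ ng/g (corticosterone). Note these
conventional constants do *not* include the working dilution — a
1:10-corrected cortisol value would be 7.8 ng/g — and
`fgm_config(bld_include_dilution = TRUE)` switches to that reading.
Samples above the curve are flagged `ABOVE_CURVE` for re-dilution and
carry no concentration; the latest passing re-run supersedes earlier
flagged measurements, with the audit trail retained.

# Analytical validation

*Parallelism* checks that a serially diluted pool of extracts (neat,
1:2, …, 1:64) is immunologically similar to the standard: %B is
regressed on $\log_{10}$ dose separately per series (the pool's dose
proxy is $1/\text{dilution}$; only relative dose matters for a slope),
and equality of slopes is tested with the extra-sum-of-squares ANCOVA F
test for the dose-by-series interaction in the two-line model
($\alpha = 0.05$, denominator df $= n - 4$). Points outside the
quasi-linear 20–80 %B window are excluded (logistic tails bend the
line); the window is a tunable argument, and for the corticosterone
curve — whose five 1:5-spaced standards leave only one point in that
window — the analysis scripts widen it to 10–90. The 50%-binding
dilution is interpolated linearly in $(\log_{10}\text{dose}, \%B)$
between the two bracketing pool points; the working dilution is that
value subject to a 1:10 floor against methanol matrix interference.

*Accuracy* spikes the standard series with a fixed pool and regresses
observed on expected concentration after subtracting the known
addition; acceptance requires $r^2 > 0.95$ and slope in $[0.8, 1.2]$.

# Longitudinal analysis

All statistics are per animal and per metabolite, on daily values
(multiple samples in one calendar day are averaged first; raw values are
kept). Two statistics with distinct roles:

* **Baseline**: a one-pass trimmed mean — remove values strictly above
  $\mu + 1\sigma$ of the untrimmed daily series, recompute the mean.
  Trimming only removes high values, so the baseline never exceeds the
  mean. An iterate-to-convergence variant was considered and not made
  the default: the single pass matches the stated procedure of one
  removal and one recalculation.
* **Peak threshold**: $\mu + 2\sigma$ of the *untrimmed* series, strict
  inequality (a value exactly at the threshold is not a peak). The
  sample SD is used everywhere. A useful consequence of the sample-SD
  bound $\max z \le (n-1)/\sqrt n$: series of five or fewer samples can
  never contain a peak.

A stress event requires *both* metabolites to peak on the same sampled
date. Dual-peak dates that are adjacent in the animal's sampled-date
sequence (no intervening non-peak sample) and at most 7 calendar days
apart are grouped into one event: single-date events are *acute*,
multi-date events *chronic*. The 7-day gap bound operationalises
"multiple days or weeks" for opportunistic sampling and is configurable.
Husbandry notes match an event when logged on a peak day or the
preceding calendar day (a 48-h window at day resolution — fecal
timestamps are collection, not excretion, times).

The acute definition is deliberately the 2-SD criterion alone; an
"above baseline" reading of acute peaks would flag far more dates and
is not what the dual-peak counting uses.

# Synthetic data: what it emulates and what it does not

`simulate_series()` generates the study that the analysis scripts and
tests run on: four animals (one male, three females) with opportunistic
sample counts 233/122/72/60 over staggered spans within 1997–2016,
lognormal baselines (FGMs are positive and right-skewed) with medians in
the tens of ng/g, three acute and one three-day chronic injected event
per animal, notes for 39% of injected events plus decoy notes, and
censoring of values under the detection floor to the imputation
constants. A spiked day is set to the animal's natural-scale mean plus
`spike_sd` (default 5) natural-scale SDs — the acute response overwhelms
baseline variation — so detection-theory expectations are analytic: the
spike inflates the estimated SD by a factor of roughly
$\sqrt{1 + k\,s^2/n}$ for $k$ spikes of $s$ SDs in $n$ samples, leaving
a comfortable margin below a 5-SD spike, which is why the sensitivity
checks sit near 100% on noise-free series. `simulate_plate()` adds the
plate layer: a competitive 4PL OD response between NSB and B0 anchor
levels with multiplicative lognormal well noise (default CV 4%) and
jittered extraction masses (SD 0.01 g, so roughly 2% of samples fall
under the 0.18 g discard floor).

The generator does **not** emulate: circadian or seasonal structure
(real sampling was daytime-only), gut-transit lag between stressor and
excretion, assay cross-reactivity between the two metabolites (baseline
noise is independent across metabolites; spikes are shared with
probability `rho`, default 1), drift between plates, or peaks of the
extreme magnitudes seen in real data (tens of thousands of ng/g).
Passing tests therefore demonstrate the correctness of the pipeline's
logic and its statistical behaviour under the stated model, not
performance on real sea-otter data.

Every injected event is recorded in a ledger, and sensitivity /
specificity are always scored against the ledger, never against
re-detected events. All randomness flows from a single integer seed;
fixed seed gives byte-identical output, and the downstream pipeline
draws no random numbers at all.

# Numerical and design choices

* Tie-breaks: duplicate CV passes at strictly `< 10%`; peaks at strictly
  `> mean + 2 SD`; a value exactly at the trim bound is kept.
* Degenerate inputs: a single-value series has SD `NA`, baseline equal
  to the value, and no peaks; a constant series has SD 0 and no peaks
  (strict inequality); exactly parallel series yield an interaction term
  with zero extra sum of squares, which `anova()` reports as `NA` and
  `parallelism_test()` maps to $F = 0$, $p = 1$.
* The imputation constants are computed with a single final division so
  that 0.78 and 0.16 are exact in floating point.
* Problem sizes: the bundled analysis uses the full 487-sample roster
  (27 plates); the statistical tests use 200 curve refits, 500–1000
  parallelism replicates and 10,000 baseline series, sizes at which the
  Monte Carlo error is well below every asserted margin.

# Known limitations

Only the listed CSV dialects are read (no instrument-native exports);
curves are fitted per plate with no pooling or 5PL option; no
physiological (ACTH-challenge) validation is modelled — analytical
validation shows the assays measure the pool proportionately, not that
the metabolites track adrenal activation; and per-animal baselines from
real studies cannot be reproduced here because raw longitudinal data are
not published.
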