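---
title: "Methods: stimulus and choice signals in slant discrimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stimulus and choice signals in slant discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slantchoice)
```

## The task and the data model

A session pairs one neuron's spike counts with behavior in two tasks. In the
*fixation* task a planar surface is shown at 25 slant–tilt combinations
(slants 0–60° in 20° steps × tilts 0–315° in 45° steps, with slant 0
collapsing all tilts into one frontoparallel condition) while the subject
only fixates; this measures 3D orientation tuning uncontaminated by choice.
In the *discrimination* task the surface is slanted about the 90°/270° tilt
axis and the subject reports the slant sign. We use the signed-slant
convention: tilt 90° (top of the plane nearer) is negative, tilt 270° (top
further) is positive, so "top-far" is the correct report for positive
slants. Counts are taken over the half-open 1000-ms stimulus window
`[0, stim_dur)`; the half-open convention avoids double-counting boundary
spikes, and the same convention applies to every sliding analysis window.

Trial tables are plain TSV with a JSON metadata sidecar — diff-able,
language-neutral, and small enough that no binary container is warranted.
Sessions enter the discrimination analyses only with ≥10 repetitions of
every ladder slant, and choice analyses require the slant-preference sign
measured *during fixation*: conditioning the sign on discrimination
responses would let choice-related activity contaminate its own reference.

## Tuning quantification

Tuning strength is the surface orientation discrimination index
$$\mathrm{SODI} = \frac{R_{max}-R_{min}}{R_{max}-R_{min}+2\sqrt{SSE/(N-M)}},$$
with $R_{max},R_{min}$ the extreme condition means, $SSE$ the pooled squared
error around condition means, $N$ trials and $M=25$ conditions. It is 1 for
perfectly repeatable modulated responses ($SSE=0$) and 0 for flat ones; when
the numerator and the noise term are both zero (constant responses) we
define it as 0.

Classification is two-step: a one-way ANOVA over the 25 conditions
(p < 0.05) followed by a Bingham-function fit,
$R(\mathbf n) = A\exp(\lambda_1(\mathbf v_1\!\cdot\!\mathbf n)^2 +
\lambda_2(\mathbf v_2\!\cdot\!\mathbf n)^2) + B$
on unit surface normals, with the Pearson correlation between fitted and
observed means gating at r ≥ 0.8. The second gate rejects multi-peaked
profiles that pass an ANOVA without a unique preference. The exact original
parameterization lives in prior work; since only the correlation gate
matters downstream, we adopt this standard form and fit it by multi-start
Levenberg–Marquardt least squares (`minpack.lm::nls.lm`, 8 starts seeded at
the highest observed condition means; the exponent is parameterized as an
unconstrained symmetric quadratic form with one diagonal entry pinned, since
adding a multiple of the identity is absorbed by the amplitude). A fit that
never converges is assigned r = −∞ and the neuron is untuned. Note the
family is antipodally symmetric, so a pair of bumps at opposite tilts can be
legitimately captured by a near-equatorial peak or a girdle; the multipeak
gate therefore rejects *asymmetric* multi-peaked profiles, which is its
actual purpose.

Preferred directions map to the plane by the Lambert azimuthal equal-area
projection about the frontoparallel pole, $\rho = 2\sin(s/2)$ at azimuth
= tilt. The projection is named only generically in the source literature;
Lambert is the standard closed-form, invertible choice, and its unit
Jacobian is verified numerically in the tests. Uniformity of preferences is
tested by a χ² goodness-of-fit over equal-area cells (tilt sectors × slant
rings at equal-area radii), pooled until each cell expects ≥5 counts —
equal-area cells make the uniform expectation exactly flat, so the test is
calibrated by construction. The binning is not specified in the source
literature; sectors-by-rings is the simplest scheme that respects the
hemisphere geometry.

## Psychometrics and neurometrics

The psychometric function is a cumulative Gaussian with lapses,
$P(\text{top-far}\mid s) = \gamma + (1-\gamma-\lambda)\,\Phi((s-\mu)/\sigma)$,
fitted by binomial maximum likelihood (`optim` L-BFGS-B, four starts). The
P.S.E. is μ and the threshold is σ — the SD of the fit, not an 84%-correct
point. Lapse parameters are fitted but bounded in [0, 0.1], common
psychophysics practice (whether the original fits constrained lapses is not
stated; unbounded lapses destabilize σ). Data with no slant modulation are
flagged non-converged with σ = ∞ rather than a spurious finite threshold.

Neurometric functions use ROC analysis: for each nonzero slant with ≥10
screen-depth repetitions, the area under the ROC comparing the 0° response
distribution with that slant's distribution (rank-sum formulation, ties ½ —
identical to the trapezoidal threshold sweep, as the tests verify to 1e-12).
Each area is oriented as "probability the ideal observer reports positive
slant" using the fixation preference sign, flipping for negative-preferring
neurons, so the neurometric is directly comparable to the behavioral
proportion of top-far choices. Only screen-depth (0 cm) trials enter the
neurometric. The fitted σ is the neuronal threshold; it is doubled before
comparison with behavior because the behavioral task is one-interval while
the ROC compares two response distributions, and the neuronal-to-behavioral
threshold ratio flags values < 1 for review.

The depth-control analysis fits psychometric functions per (session, depth)
and runs one-way ANOVAs of P.S.E. and threshold across the three depths
(−2.25, 0, +2.25 cm). An observer using local absolute disparity rather
than slant would show P.S.E. biases of at least the screen-crossing slant,
$\arctan(|d| / (D \tan(\theta/2)))$ ≈ 14° for the 31° stimulus at
±2.25 cm and D = 32.5 cm — reported alongside as the diagnostic bound.

## Choice probability

CP is the ROC area separating responses on preferred- versus
nonpreferred-sign choices. At the ambiguous 0° slant it needs no
normalization. The *grand CP* pools across slants for statistical power:
within each slant with at least three choices in each direction, responses
are normalized by the *balanced z-score* — center = mean of the two
choice-conditional means, scale = SD of the equal-weight mixture of the two
choice distributions, $s^2 = (v_1+v_2)/2 + (m_1-m_2)^2/4$ with
population-denominator variances — so a slant's choice imbalance cannot
shift the pooled composites. The cited normalization's exact constants are
not reprinted in the source; this choice reduces exactly to the ordinary
population z-score under balanced choices and makes the grand CP invariant
to per-slant positive affine transforms (both asserted in tests).
Significance uses a permutation null: choice labels are shuffled within each
slant (preserving per-slant choice counts and hence the inclusion set), and
the two-sided p is the smoothed fraction of permutations with
$|CP-0.5|$ at least the observed value, floor $1/(n_{perm}+1)$.

Two small-sample facts are worth knowing. First, an undefined CP (an empty
choice group) is reported as missing, never as 0.5. Second, with unbalanced
choice groups at the flanking slants the pooled grand CP carries a slight
finite-sample bias below 0.5 under the null (the label-dependent scale
couples weakly to the cross-slant comparisons); at 40 trials per slant it is
under a percentage point, sits well within the calibration tolerance, and
the within-slant permutation null shares it, so inference is unaffected.

At the population level, the grand CP is regressed on the comparison
threshold per area (Pearson r, slope with 95% CI), and an ANCOVA with
threshold as covariate and area as factor tests the threshold × area
interaction — whether the sensitivity–choice link differs between areas.

## Partial correlations

With F = count, S = signed slant, C = choice (±1; any monotone two-level
coding gives identical correlations),
$$r_{FS.C}=\frac{r_{FS}-r_{FC}r_{SC}}{\sqrt{(1-r_{FC}^2)(1-r_{SC}^2)}},\qquad
r_{FC.S}=\frac{r_{FC}-r_{FS}r_{SC}}{\sqrt{(1-r_{FS}^2)(1-r_{SC}^2)}},$$
computed over all trials with counts from the full stimulus window.
Significance uses the t-transform with n − 3 degrees of freedom (the
original transform is unstated; this is the textbook choice). Slant enters
linearly by default; the source reports robustness to nonlinear recodings,
so a `slant_transform` argument offers them as a sensitivity sweep rather
than a default. A perfect pairwise correlation collapses a partial's
denominator; the implementation returns the analytic limit (0 when the
numerator vanishes) instead of NaN, and perfect slant–choice collinearity is
an error naming the problem. The (r_FS.C, r_FC.S) sign pattern assigns
quadrants; I/III are congruent stimulus/choice effects. Choice-conditioned
tuning curves include a slant only with ≥3 choices in the relevant
direction. Group-level structure is summarized by 95% bivariate-normal
coverage ellipses (χ²₂ scaling — the original estimator is unstated) fit
separately to neurons with grand CP above and below 0.5, with percentile
bootstrap CIs on the major-axis angle; bootstrap angles are aligned to the
estimate modulo 180° before taking percentiles because an axis is
orientation-, not direction-valued.

## Time courses

All per-neuron statistics can be recomputed in sliding windows: width
200 ms, step 50 ms, centers 100→1150 ms. "Starting at 100 ms" is read as
the first *center* (window [0, 200)): only that convention yields the 22
bins that the downstream bin-count arithmetic requires, whereas a first
*edge* at 100 ms would give 20. The last window, [1050, 1250), extends
150 ms past stimulus offset — just short of the median choice time (271 ms
after offset, 1271 ms after onset) — and windows are not clipped at offset.
Population summaries are per-bin means ± SEM; the across-bin test is a
one-way ANOVA with Tukey-corrected comparisons against the first bin, and
the first significant bin locates response or choice-signal latency. The
spike density function uses the same binning (rate in Hz averaged over
trials then neurons) so its time course can be correlated with the squared
slant partial correlation.

## Eye-movement controls

For each covariate (trial-mean vertical eye position, vertical velocity,
vergence), an ANCOVA of count on choice plus the covariate supplies the
per-neuron significance, corrected across neurons by Bonferroni–Holm (the
family is the neuron set within one covariate; the original correction
scope is not further specified). Detrending then removes the *marginal*
linear trend of count on the covariate, so corrected responses have exactly
zero linear trend on it and detrending is idempotent; grand CP and neuronal
threshold are recomputed on corrected responses with paired before/after
comparisons. The ANCOVA could optionally include slant as a factor; the
default matches the stated choice + covariate model.

## The synthetic-session generator

The generator is the package's stand-in for recordings and defines the
study conditions. Tuning is a Bingham profile with baseline 5–15 Hz and
gain 20–60 Hz (typical parietal rates), concentrations λ ∈ [−6, −1.5],
preferences uniform on the hemisphere by default (`slant_bias` concentrates
them at small slants, emulating training effects). Counts are Poisson by
default, or rounded zero-clipped Gaussian with a selectable Fano factor —
the recorded neurons' noise family is uncharacterized in the source, so
both are available. The observer forms
$d = (s-\text{bias})/\sigma_b + \rho\eta + \sqrt{1-\rho^2}\,\nu$ and
reports top-far when d > 0 (lapses flip the report), giving an exactly
cumulative-Gaussian psychometric function with P.S.E. = bias and threshold
= σ_b; the default σ_b = 3.6° and the ±{20, 10, 5, 2.5, 1.25, 0}° ladder
(monkey-P ladder available as a preset) put behavioral performance in the
realistic fine-discrimination regime. Depths are drawn 15/70/15 over
{−2.25, 0, +2.25} cm; correct signs are rewarded and 0° trials are rewarded
with probability ½.

Choice coupling is a *shared standard-normal component* η between the
decision noise and the neuron's standardized count fluctuation, weighted so
the trial-level correlation of the stimulus-window count noise with η is
exactly ρ. This is the minimal generative mechanism that produces CP
without committing to a bottom-up or top-down origin — a question the
analyses cannot resolve and the generator deliberately leaves open. The
shared component enters the count with the neuron's preference sign
(congruent coupling), so ρ > 0 always drives CP above 0.5 regardless of
whether the neuron prefers positive or negative slants; anti-congruent
populations can be made with ρ < 0. Spikes are generated in 50-ms bins over
[0, 1250) ms (flat rate by default; a `rate_profile` function shapes
transients), with η entering only bins at or after `coupling_onset_ms` —
this is what lets the time-course analyses recover a constructed
choice-signal latency. Because η is common across bins while the per-bin
noise is independent, the per-bin weight is solved analytically so the
*trial-level* coupling equals ρ (it caps at 1 for extreme ρ with late
onsets). For Poisson counts the latent normal enters through a Gaussian
copula (`qpois(pnorm(z), μ)`), which preserves the coupling to a very good
approximation at these rates.

What the generator does *not* emulate: cross-neuron noise correlations
(each synthetic neuron is conditionally independent given the stimulus and
its own coupling), saccade-related bursts, adaptation within sessions,
non-stationary excitability, and real eye-movement dynamics (covariates are
Gaussian trial means with optional choice shifts and linear injection into
counts). Passing tests therefore certify the *estimators* — calibration,
invariances, and recovery of generative parameters — not any claim about
cortical data.

## Problem sizes and numerical choices

Test and calibration runs use sizes chosen to make Monte-Carlo bands tight
relative to the assertions: 200 neurons × 40 trials/slant for the null CP
calibration (±0.01), 100 neurons per coupling level for monotonicity,
~10,000 trials for psychometric recovery (5%), 500 random instances for the
exact-equivalence oracles (1e-12), 150–1000 permutations and bootstrap
resamples depending on context. Statistical tolerances in tests are set
from binomial or KS sampling bands at roughly 3σ, not tuned to outcomes.
Degenerate inputs have defined behavior throughout: empty choice groups
report missing CPs, zero balanced scales exclude the slant with a warning,
flat psychometric data yield σ = ∞ sentinels, non-converged Bingham fits
yield r = −∞ and an untuned call, and constant covariates skip the control
with a log entry. All simulators take explicit integer seeds and set the
RNG themselves, so every pipeline output is reproducible from its recorded
seed.

## Known limitations

The Bingham parameterization and equal-area projection match the standard
forms, not necessarily the originals (both live in uncited-here prior
work); only the r-gate and the map's area property matter downstream. The
grand CP's small negative finite-sample bias under imbalance is documented
above. The confidence-ellipse angle CI assumes enough points for the 2×2
covariance to be stable (≥5 enforced, more recommended). The pipeline's
population ANCOVA needs ≥5 neurons per area with finite thresholds and will
log, rather than fabricate, anything below that.
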