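---
title: "Detecting transcriptional rhythms from time of death: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting transcriptional rhythms from time of death: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(todrhythm)
```

## The problem

Postmortem brain cohorts offer a single timepoint per subject — the time
of death (TOD) — yet across a cohort those timepoints scatter over the
whole day, so the cohort as a whole samples the circadian cycle. If a
transcript's expression follows a ~24 h rhythm, expression plotted
against each subject's TOD traces out a sinusoid. `todrhythm` implements
this cross-sectional rhythmometry for a two-group design (a reference,
"unaffected" group and a comparison group), including permutation-based
inference, differential rhythmicity, rhythmic-set comparison, and the
standard report artifacts (phase-ordered heatmaps, fitted scatterplots).

## Zeitgeber time

Clock time of death is a poor circadian coordinate because sunrise moves
with season and location. Each subject's TOD is therefore converted to
Zeitgeber time (ZT) using sunrise on their date of death: ZT0 = sunrise,
negative values are hours immediately before sunrise, and values are
represented on the half-open interval [-6, 18) so that a full day is
covered with the pre-dawn hours shown as negative. `to_zeitgeber()`
implements the conversion as a pure sunrise-anchored offset,
`(tod_clock - sunrise)` wrapped into [-6, 18).

Sunset enters validation (a degenerate photoperiod with sunrise equal to
sunset is rejected) but, under the default convention, not the mapping.
How exactly sunset should modulate the conversion is genuinely open: one
defensible alternative rescales daylight to a fixed 12 h day and night
to a 12 h night so that ZT12 always means sunset. We ship that as
`photoperiod_scale = TRUE` and default to the minimal sunrise-anchor
reading, documenting both rather than asserting either as canonical.

## The cosinor model

For a transcript with expression values $y_i$ at Zeitgeber times $t_i$,
the fixed-period cosinor model is

$$y_i = M + A \cos\!\left(\frac{2\pi (t_i - \phi)}{T}\right) + \varepsilon_i,
\qquad T = 24\ \mathrm{h},$$

with mesor $M$ (rhythm-adjusted mean, the "base"), amplitude $A \ge 0$
(half the peak-to-trough range) and acrophase $\phi \in [0, 24)$ (peak
hour). Although the model looks nonlinear, for fixed $T$ it is exactly
linear after the reparameterization
$\beta_1 = A\cos(2\pi\phi/T)$, $\beta_2 = A\sin(2\pi\phi/T)$, so
`fit_cosinor()` solves the harmonic regression
$y = M + \beta_1\cos(2\pi t/T) + \beta_2\sin(2\pi t/T)$ in closed form
and recovers $A = \sqrt{\beta_1^2+\beta_2^2}$,
$\phi = (T/2\pi)\,\mathrm{atan2}(\beta_2,\beta_1) \bmod T$. This is the
global least-squares optimum — identical to what a converged iterative
nonlinear solver would return — and removes any dependence on starting
values or convergence tolerances. The test suite cross-checks it against
an independent iterative grid-search-plus-refinement oracle to 1e-6.

Goodness of fit is the coefficient of determination
$R^2 = 1 - SSE/SST$, the rhythmicity statistic used throughout.
Degenerate zero-variance transcripts return $R^2 = 0$ and amplitude 0
with a `degenerate` flag instead of erroring, so matrix-scale runs never
abort. The period is fixed at 24 h for all analyses; ultradian (12 h)
components can be *generated* by the simulator to mimic apparent
anti-phasic patterns, but are never fitted.

## Permutation inference

Parametric F-tests for the cosinor are unreliable here: TOD sampling is
irregular and expression is not Gaussian after normalization. Instead,
significance is empirical. For each of `n_perm` (default 1000)
iterations the ZT labels are shuffled across subjects — one shuffle per
iteration applied to *all* transcripts, i.e. a TOD-randomized dataset
that preserves cross-transcript correlation — and all transcripts are
refit. The empirical p-value is

$$p = \frac{1 + \#\{b : R^2_{null}(b) \ge R^2_{obs}\}}{B + 1},$$

the standard add-one correction that makes $p \ge 1/(B+1) > 0$. The
default null is per-transcript (each transcript compared to its own null
distribution, exact per-gene calibration); a pooled null across
transcripts is available via `null_mode = "pooled"`. With
`exhaustive = TRUE` all $n!$ shuffles are enumerated and the p-value is
exact; the suite verifies the sampled and exhaustive paths against an
independent enumerator at $n = 5$ (120 shuffles).

Rhythm calls use nominal $p < \alpha$ (default 0.05) as the primary
analysis; Benjamini–Hochberg correction is available (`mtc = "BH"`) for
building a corrected-p foreground set.

## Differential rhythmicity

Between-group change in rhythmicity is measured by
$\Delta R^2 = R^2_{g1} - R^2_{g2}$ (loss direction; the gain direction is
its negation). The null distribution shuffles each group's ZT vector
independently at every iteration, refits both groups and recomputes the
difference. A transcript is classified **less rhythmic in group 2** iff
(1) it is significantly rhythmic in the reference group and (2) its loss
is significant by the permutation test; **more rhythmic in group 2**
mirrors this with the group-2 rhythmicity call and the gain p-value. In
the edge case where both rules fire simultaneously — possible only at
near-equal $R^2$ — the call resolves to `unchanged`, since the two
definitions are mutually exclusive in intent. On null data the two
criteria are positively correlated (both are driven by the same observed
$R^2$), so the category false-positive rate stays near, never above, the
nominal level; the acceptance suite checks it against the exact binomial
99% band around $\alpha$.

For transcripts rhythmic in *both* groups, `compare_phase_amp_base()`
contrasts the fitted parameters directly: the phase difference is the
minimal circular difference of peak hours signed into (-12, 12], and
amplitude/mesor differences are plain subtractions. No standard test is
established for these contrasts in the single-timepoint design; we use a
group-label permutation (subjects reassigned to pseudo-groups of the
original sizes, both groups refit, observed absolute difference compared
to the null) as one reasonable instantiation, and document it as such.

## Comparing rhythmic sets

Two complementary comparisons of the groups' rhythmic transcript sets
are provided. `fisher_overlap()` tests the 2x2 membership table within
the expressed-transcript universe; sidedness defaults to two-sided (the
conventional choice when none is stated), and the reported odds ratio is
the sample cross-product ratio with Haldane's 0.5 correction applied
only when a cell is zero — and only to the odds ratio, never to the
p-value. `rrho()` is the threshold-free rank–rank hypergeometric
overlap: both lists are ranked by rhythmicity p-value (ties broken by
transcript id for determinism), and every pair of top-list prefixes on a
rank grid is scored by a hypergeometric tail, stored as signed
$-\log_{10} p$ (positive = over-enrichment). The default grid stride is
$\lceil n/100 \rceil$; no correction is applied across grid cells — the
map is exploratory. The suite verifies `rrho(a,b)` equals the transpose
of `rrho(b,a)` and checks a hand-enumerated 6-transcript grid.

## Peak-hour structure and report artifacts

`peak_hour_distribution()` histograms fitted peak hours and reports the
circular mean and mean resultant length. `detect_peak_clusters()` runs
circular k-means (distance = minimal circular difference, centers =
circular means, seeded restarts) to delineate peak clumps such as the
bimodal, ~12 h-apart pattern typical of these cohorts; $k$ is
user-supplied because published analyses identify one or two modes by
inspection, and automatic model selection would add an unverifiable
degree of freedom.

`phase_ordered_heatmap()` selects the top `top_n` (default 200)
transcripts by ascending empirical p (ties: descending $R^2$, then id —
"top rhythmic" alone does not fix an order, so the rule is explicit),
Z-transforms each row, orders rows by peak hour and columns by subject
ZT at their actual (unequally spaced) positions. Cross-group panels —
transcripts selected in one group, expression rendered from the other —
use the same function with mixed inputs. Constant rows are excluded from
Z-scoring and flagged rather than emitted as NaN. `rhythm_scatter()`
returns plot-ready tables (observed points plus the fitted curve sampled
every 0.1 h over [-6, 18)); rendering is left to the caller so tests
assert on tables, not images.

## The synthetic cohort generator

Because the motivating postmortem expression matrix is not publicly
released, every stage is exercised on synthetic cohorts with known
ground truth. `simulate_cohort()` emulates the study design: two groups
of 20 subjects, TOD drawn uniformly over the day (an optional weighted
per-4 h-bin sampler mimics clustered death times; uniform is the default
because it maximizes phase identifiability), fixed sunrise 06:00 /
sunset 18:00, and log-scale expression
$mesor + A\cos(2\pi(ZT-\phi)/24) + N(0, \sigma^2)$, with an optional
12 h component. Defaults: 2000 transcripts; rhythmic fractions 5%
(reference) and 2.5% (comparison) with 2.6% of the larger set shared —
matching the observed regime of roughly 700 and 340 rhythmic transcripts
out of ~15,000 expressed, with largely distinct sets; amplitudes
$N(1.5, 0.5)$ truncated at 0.1 and mesors $N(5, 2)$ on the log scale;
peak hours von Mises around modes {4, 16} h with concentration 2,
echoing the bimodal peak structure; noise sd 0.5. Shared rhythmic
transcripts keep identical phase across groups unless
`phase_shift_hours` is set, isolating gain/loss scenarios from
phase-shift scenarios.

What the generator does *not* emulate: count-level noise (it produces
Gaussian residuals on the log scale, matching the least-squares
assumptions so recovery tests have a clean oracle), covariate structure
(age, pH, postmortem interval), library-size artifacts, and transcript–
transcript correlation beyond the shared TOD design. Passing tests
therefore demonstrate correctness of the statistical machinery under the
model's assumptions, not robustness to every feature of real RNA-seq.

## Numerical and reproducibility choices

* All randomness flows from explicit integer seeds; per-operation
  streams are derived by fixed offsets so stages reproduce independently
  of execution order. Two runs with equal manifests are byte-identical,
  which `run_pipeline()`'s JSON manifest makes checkable.
* TSV is the canonical dialect (UTF-8, `.` decimal); doubles are written
  as `%.17g` so files round-trip to full precision. Missing values fail
  fast by default — no imputation procedure is invented.
* Test and acceptance problem sizes are desk-scale by design: 500–2000
  transcripts, 20+20 subjects, 200–500 permutations. These sizes already
  give exact-binomial calibration bands of a few percent and run the
  whole suite in well under a minute; the machinery is vectorized (one
  3-column design solve per shuffle, all transcripts refit as a single
  matrix product), so full-scale runs (~15,000 transcripts, 1000
  permutations) remain minutes, not hours.

## Known limitations

Single-harmonic fits only; no per-subject covariate adjustment inside
the fit; no repeated-measures designs; cross-sectional TOD sampling
cannot distinguish a phase-shifted rhythm from a remodeled one at low
amplitude; and the phase/amplitude/base permutation test is one of
several defensible schemes for a question the single-timepoint design
answers only weakly.
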