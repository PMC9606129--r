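---
title: "Integrated information analysis of body-brain time series with phistar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated information analysis of body-brain time series with phistar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question and the measure

During the rubber hand illusion (RHI), synchronous visuo-tactile stroking of
a dummy hand induces an illusory, and phenomenologically ambiguous, sense of
ownership.  `phistar` analyses a small body-brain system of seven
simultaneously recorded physiological channels — respiration (RES),
heartbeat (ECG), electrodermal activity (EDA) and four midline EEG leads
(Fz, Cz, Pz, Oz) — and asks how much of the system's temporal information is
*integrated*: carried by the system as a whole over and above its parts.

The measure is the mismatched-decoding form of integrated information for
Gaussian variables.  Let $X(t)$ be the 7-dimensional state and $\tau$ a lag
in frames.  The total predictive information is the mutual information
$I(X(t-\tau); X(t))$.  For a bipartition $\pi$ of the channels into blocks
$B_1, B_2$, consider a decoder that models the present from the past
*within blocks only*,
$q(x(t) \mid x(t-\tau)) = \prod_k p(x_{B_k}(t) \mid x_{B_k}(t-\tau))$.
The information transmissible with this mis-specified model is

$$
\tilde I(\beta) \;=\;
\mathbb{E}_{p}\!\left[\,\log
\frac{q(y\mid x)^{\beta}}{\mathbb{E}_{p(x')}\!\left[q(y\mid x')^{\beta}\right]}
\right],
\qquad I^{*} = \max_{\beta > 0} \tilde I(\beta),
$$

and the integrated information across $\pi$ is
$\Phi^{*}(\pi) = I(X(t-\tau); X(t)) - I^{*}$.  $\Phi^{*}$ is non-negative,
never exceeds the mutual information, and vanishes exactly when the joint
covariance is block-diagonal with respect to $\pi$.  All quantities are
reported in nats.

For jointly Gaussian data every expectation above is a Gaussian integral
and $\tilde I(\beta)$ has a closed form.  Writing $\Sigma_X$, $\Sigma_Y$,
$\Sigma_{XY}$ for the past, present and cross covariance, $H$ and $D$ for
the block-restricted regression matrix and residual covariance
($Q = D^{-1}$), and $R$ for the full residual covariance of $y - Hx$,

$$
\tilde I(\beta) =
-\tfrac{\beta}{2}\,\mathrm{tr}(QR)
+\tfrac{\beta}{2}\,\mathrm{tr}(Q\Sigma_Y)
+\tfrac12 \log\left|I + \beta \Sigma_X H'QH\right|
-\tfrac{\beta^2}{2}\,
 \mathrm{tr}\!\big[(\Sigma_X^{-1}+\beta H'QH)^{-1} H'Q\Sigma_Y QH\big].
$$

`mismatched_information()` implements this expression directly in R; the
compiled search code evaluates the same expression through an
eigendecomposition of $C = R_0 H'QH R_0'$ (with $\Sigma_X = R_0'R_0$), which
turns each $\beta$-evaluation into an $O(n)$ sum and makes the exhaustive
searches cheap.  The two routes are cross-checked against each other in the
test suite, and both are checked against a Monte-Carlo/Gauss-Hermite oracle
that evaluates the defining expectation by brute force on two-node systems.

## MIP, complexes, main complexes

* The **minimum information partition** (MIP) is the bipartition minimising
  $\Phi^{*}$ — the system's weakest link.  `mip_search()` enumerates all
  $2^{n-1}-1$ unordered bipartitions (63 for $n=7$).  Ties are broken
  towards the earliest partition in a fixed enumeration order (ascending
  binary mask of the block not containing channel 1), so results are
  deterministic.
* A **complex** is a subset $T$ (size $\ge 2$) with
  $\Phi_{\mathrm{MIP}}^{T} > 0$ that is more integrated than every strict
  superset.  The whole system qualifies whenever its $\Phi_{\mathrm{MIP}}$
  is positive.  Positivity is tested against `eps_pos = 1e-10`; strict
  positivity would be numerically meaningless.
* A **main complex** is a complex that beats every one of its subsystems;
  among complexes this is equivalent to containing no other complex, which
  is the criterion `find_main_complexes()` uses (the direct definition is
  available as `method = "direct"` and the equivalence is property-tested).
* The per-window summary reports $\sum_M \Phi_{\mathrm{MIP}}^{M}$ over main
  complexes — the measure of subsystem integrity — and the strongest main
  complex.

**Two caveats on main complexes.**  First, it is often stated that two
main complexes must be disjoint.  That does not follow from the
definitions above, and it is false for $\Phi^{*}$ on generic Gaussian
systems: a three-node system with
$\Phi^{\{1,2\}} = 0.039 > \Phi^{S} = 0.027$ and $\Phi^{\{1,3\}} = 0.78$ has
two main complexes sharing node 1, with wide numerical margins.
`phistar` therefore treats overlapping main complexes as legitimate
output; the sum over main complexes simply sums them.  Second, the
contains-no-other-complex shortcut and the beats-every-subset direct
definition are not equivalent in general either: a complex can contain a
non-complex subset of higher $\Phi$ (that subset failing complexhood only
because of a superset *outside* the complex).  One direction is a theorem
— a complex that beats all its subsets cannot contain another complex —
so the direct main complexes are always a subset of the shortcut ones,
and the property suite tests exactly that.  Both phenomena stem from
$\Phi^{*}$ not being monotone over the subset lattice, the assumption
under which the quoted hierarchy results are proven.  On the
seven-channel pipelines exercised here the two criteria almost always
agree, and the shortcut is the operational rule used.

Singleton subsets are excluded throughout ($\Phi$ is undefined for fewer
than two channels).

## The sliding-window pipeline

A full recording is 225,000 frames at 250 Hz (900 s): 0-300 s pre-stimulus
rest, 300-600 s stimulation, 600-900 s post-stimulus rest.  `run_subject()`
computes, for each of 900 steps, a lagged Gaussian model of the window
ending at frame $t \times 250$ and runs the MIP search and the complex
analysis on it.

* **Windows** default to 250 frames (1 s), shifted by 250 frames; 500- and
  750-frame windows are supported.  Windows are right-aligned to step
  boundaries and frames before the recording start are zero-filled, so at
  most the first two steps of a 750-frame window carry padding.
* **Lag.** The default `tau = 50` frames (0.2 s) reflects typical
  physiological response latencies; `tau_scan()` selects the lag maximising
  the mean whole-system $\Phi_{\mathrm{MIP}}$ over a candidate range.
  `tau = 0` is rejected: past and present states then coincide and the
  information quantities degenerate, so the default scan range is 1-250.
* **Covariances** are maximum-likelihood (divide by the pair count),
  per-window mean-subtracted, with a ridge of `1e-8` times the mean channel
  variance added to the marginal diagonals.  Windows containing a constant
  channel are flagged missing, reported once per recording, and excluded
  from phase statistics rather than imputed.
* **Detrending.**  Before phase statistics the per-window series is
  detrended by the least-squares line over the whole 900-step block — the
  simplest reading of "detrended"; detrended $\Phi$ values can be negative.
* **Moving averages** (default 150 steps, trailing) are display-only and
  never enter statistics.
* The `stride` option computes every $k$-th window only; it subsamples the
  timeline uniformly and is the knob used to keep demonstration and test
  runs short.

## Statistics

* `phase_contrast()` pools (detrended) window values across subjects per
  phase and applies Welch's two-sample $t$-test to pre-vs-stim,
  stim-vs-post and pre-vs-post.  Window-level pooling gives the large
  degrees of freedom typical of this design; per-subject means are
  available via `pooled = FALSE`.  Raw $p$-values are reported with **no
  multiple-testing correction** — mirror the convention of reporting
  starred raw $p$-values — so treat marginal significances accordingly.
* `mip_cut_frequency_diff()` / `main_complex_frequency_diff()` compute, per
  subject, the frequency of each MIP cut (or strongest-main-complex subset)
  among stimulus windows minus pre-stimulus windows, then average across
  subjects (per-subject weighting avoids dominance by any one subject).
  Within a condition the differences sum to zero.
* `s_statistic()` is the per-subject condition-difference score: within
  each condition the $\sum_M \Phi_{\mathrm{MIP}}^{M}$ series is
  baseline-subtracted by the subject's mean pre-stimulus value, and the
  SYNC-minus-ASYNC difference is summed over the stimulus steps
  (301-600; the boundary step 300 belongs to the pre phase, 600 to stim).
  The score is invariant to per-condition additive offsets and
  antisymmetric under swapping conditions.  `peak_end_summary()` replaces
  the stimulus sum by the mean of the peak and the final stimulus value.
* `rhi_index()` is the mean of questionnaire items Q1-Q3 per condition on
  the 0-100 visual-analogue scale; `rating_differences()` adds per-item
  SYNC-ASYNC differences and the extended mean over
  {dQ1, dQ2, dQ3, dQ7, dQ8}.  Item semantics are opaque labels to the code.
* `correlate_scores()` is a Pearson correlation with its two-sided test.

## The synthetic cohort

Because the study recordings are not public, `phistar` ships a generator
whose output has the statistical structure the analysis assumes, so that
every stage is testable end-to-end.

The dynamics are a stationary VAR(1),
$x(t) = A_{\mathrm{phase}}\,x(t-1) + \varepsilon(t)$, over the seven
canonical channels with unit innovation covariance and a 1,000-frame
burn-in.  The base coupling has self-coupling 0.5, weak global coupling
0.03, stronger within-body and within-brain coupling (+0.09), and all Oz
couplings halved — the occipital channel is the most loosely coupled node
already at rest, making the {Oz} cut the system's habitual weakest link, as
observed in body-brain recordings.  During the stimulus phase the coupling
is modified at strength $\kappa = \kappa_{\mathrm{cond}}\,\eta_i$, where
$\kappa_{\mathrm{SYNC}} = 1 > \kappa_{\mathrm{ASYNC}} = 0.5$ and $\eta_i$
is log-normal per-subject heterogeneity (mean 1, log-sd 0.2, keeping
$\kappa$ positive):

* Oz off-diagonal couplings are scaled by $1 - 0.8\,\kappa$ (visual
  decoupling),
* body-brain cross couplings are scaled by $1 - 0.15\,\kappa$ (loss of
  whole-system integration),
* the EDA-RES coupling gains $0.15\,\kappa$ (strengthened bodily
  subsystem).

These strengths were chosen once, on population (noise-free) covariances,
so that across the realistic $\kappa$ range the whole-system
$\Phi_{\mathrm{MIP}}$ falls monotonically, the summed main-complex $\Phi$
rises already at the ASYNC strength, the {Oz} cut becomes the MIP for any
$\kappa \ge 0.35$ but not at rest, and {RES,EDA} becomes the strongest main
complex.  Configurations whose modified coupling would be unstable at a
$3\sigma$ subject effect are rejected at construction.

Questionnaire differences follow the imposed effect linearly:
$\mathrm{dQ}_{1..3} = 5 + 60\,(\kappa_{\mathrm{SYNC}} -
\kappa_{\mathrm{ASYNC}})\,\eta_i + \mathcal{N}(0, 5)$, clipped to the 0-100
scale, with a small positive SYNC shift (+8) on the control items Q7/Q8.

**What the generator does not emulate:** realistic EEG spectra, heartbeat
morphology, skin-conductance response shapes, non-stationarity within
phases, or measurement artefacts.  The $\Phi^{*}$ estimator consumes only
second-order structure, so Gaussian surrogates exercise the entire analysis
path; but passing recovery tests demonstrates correctness of the machinery
under the model's assumptions, not validity of those assumptions for real
physiology.  One consequence: the VAR(1) surrogate interacts at a one-frame
delay, so cohort analyses here run at `tau = 1` (and the lag scan, given a
surrogate with a 50-frame interaction delay, duly selects 50); on real
recordings the scan motivates the 50-frame default.

## Problem sizes used in the shipped runs

The recovery analyses in the test suite and the acceptance script use the
full study geometry (22 subjects, two conditions, 225,000-frame
recordings) with every 5th window computed for the effect cohort and every
10th for the null cohort; the resulting 4-8 thousand analysed windows give
the phase contrasts thousands of pooled values per phase while keeping a
cohort pass to a few minutes.  Property suites use populations of small
(2-6 node) random stable VAR models, where exhaustive enumeration doubles
as its own oracle.

## Numerical choices

* $\beta$ is maximised by golden-section search on $(10^{-6}, 32]$ with
  absolute tolerance $10^{-8}$; $\tilde I(\beta)$ is smooth and unimodal in
  practice, and the upper bracket edge is checked explicitly.
* Degenerate inputs: constant channels are an error at model estimation
  (or a flagged-missing window inside the pipeline); non-positive-definite
  covariances raise errors that advise increasing the ridge; near-perfect
  channel correlation triggers a warning, not an error.
* All randomness in the simulator flows from one master seed; each
  recording's seed derives deterministically from (seed, subject,
  condition), so any part of a cohort can be regenerated independently.

## Known limitations

* Exhaustive subset/partition enumeration is intended for $n \le 12$;
  pruned searches for larger systems are out of scope.
* Main complexes may overlap (see above); downstream sums treat them
  as-is.
* The Welch contrasts on pooled windows inherit the independence
  assumption across windows; windows are non-overlapping by default but
  residual autocorrelation of the underlying physiology is not modelled.
* No multiple-testing correction is applied anywhere.
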