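# phistar

Integrated-information (IIT 2.0) analysis of small body–brain systems:
seven channels of simultaneously recorded physiology — respiration (RES),
heartbeat (ECG), electrodermal activity (EDA) and four midline EEG leads
(Fz, Cz, Pz, Oz) — analysed as one multivariate Gaussian system during
rubber-hand-illusion (RHI) experiments.

The package is for researchers who want to quantify, window by window, how
much of a multichannel recording's temporal structure is *integrated*
(carried by the whole system beyond its parts), where the system's weakest
link lies, and which subsystems act as its information cores — and to relate
per-subject changes in these quantities to questionnaire reports of illusory
body ownership.

## The measure

For a lagged Gaussian model of a window, with past state `X(t-τ)` and
present state `X(t)`, the integrated information across a bipartition π is

    Φ*(π) = I(X(t-τ); X(t)) − max_β Ĩ(β)

where `Ĩ(β)` is the information transmissible by a *mismatched decoder*
that predicts each block of the present from the same block of the past
only — evaluated in closed form for Gaussians and maximised over the scalar
β.  `0 ≤ Φ*(π) ≤ I`, with equality to zero exactly when the blocks are
independent.  The **minimum information partition** (MIP) is the bipartition
minimising Φ*; Φ_MIP is the information lost at the system's weakest link.
Subsets whose Φ_MIP exceeds that of every superset are **complexes**;
complexes containing no other complex are **main complexes**, and the sum
of Φ_MIP over main complexes measures subsystem integrity.  All information
is in nats.

The pipeline slides a 250-frame (1 s) window in 250-frame steps over
900-second recordings sampled at 250 Hz, labels the 900 steps as
pre-stimulus rest / stimulation / post-stimulus rest (300 each), detrends
the per-window series, contrasts phases with Welch's t-test, tallies
stimulus-induced changes in MIP-cut and main-complex frequencies, and
computes a per-subject score: the baseline-subtracted SYNC-minus-ASYNC
difference of summed main-complex Φ over the stimulus phase, which is
correlated with the RHI questionnaire index (mean of items Q1–Q3).

Because the underlying human recordings are not public, the package ships a
synthetic cohort generator (stable VAR(1) dynamics with stimulus-phase
coupling changes: occipital decoupling, body–brain decoupling, strengthened
EDA–RES coupling, per-subject effect heterogeneity, and effect-linked
ratings) so the entire analysis is testable end to end.

## Worked example

```r
library(phistar)

cfg    <- sim_config(n_subjects = 4, frames = 45000, seed = 1)
rec    <- simulate_recording(cfg, subject = 1, condition = "SYNC")
series <- run_subject(rec, window_config(tau = 1))
head(series[, c("step", "phase", "phi_mip", "mip_cut", "sum_main_phi")], 4)
#>   step phase    phi_mip                 mip_cut sum_main_phi
#> 1    1   pre 0.03811135 RES,ECG,EDA,Fz,Cz,Pz|Oz   0.04746184
#> 2    2   pre 0.03643998 RES|ECG,EDA,Fz,Cz,Pz,Oz   0.03643998
#> 3    3   pre 0.03733457 RES,EDA,Fz,Cz,Pz,Oz|ECG   0.03752542
#> 4    4   pre 0.03726854 RES|ECG,EDA,Fz,Cz,Pz,Oz   0.05309485
```

Each row is one 1-second window: `phi_mip` is the integrated information of
the whole seven-channel system at its weakest link, `mip_cut` names that
weakest bipartition (`...|Oz` means the occipital lead is the most separable
part), and `sum_main_phi` sums Φ_MIP over the window's main complexes.

```r
cohort <- analyze_cohort(cfg, window_config(tau = 1))
phase_contrast(cohort, "phi_mip", condition = "SYNC")
#>   phase_a phase_b   mean_a   mean_b       t  df        p
#> 1     pre    stim  0.00196 -0.00399  6.8735 477 1.97e-11
#> 2    stim    post -0.00399  0.00203 -7.3462 476 8.93e-13
#> 3     pre    post  0.00196  0.00203 -0.0902 472 9.28e-01
```

Whole-system integration drops during stimulation (pre > stim, p ≈ 2e-11)
and recovers afterwards, with no pre/post difference — the signature the
analysis is designed to detect.

```r
head(mip_cut_frequency_diff(cohort, "SYNC"), 3)
#>                       key        diff
#> 1 RES,ECG,EDA,Fz,Cz,Pz|Oz 0.333333333
#> 2 RES,ECG,EDA,Fz,Oz|Cz,Pz 0.004166667
#> 3 RES,ECG,EDA,Oz|Fz,Cz,Pz 0.004166667

scores <- subject_scores(cohort, simulate_ratings(cfg))
correlate_scores(scores)
#> $r [1] 0.9756866   $n [1] 4   $p [1] 0.02431344
```

The {Oz} cut gains the most MIP frequency under stimulation, and the
per-subject condition-difference score `s_phi` tracks the questionnaire
difference `d_rhi` across subjects.

Single windows can be inspected directly:

```r
m <- estimate_lagged_model(rec$data[1:250, ], tau = 1)
mip_search(m, per_partition = FALSE)
#> <phi_result> Phi_MIP = 0.0381113 nats at cut RES,ECG,EDA,Fz,Cz,Pz|Oz (I = 1.48392, beta* = 0.969)
summarize_complexes(m)
#> <complex_report> 3 complexes, 1 main complexes, sum Phi = 0.0474618
#>   strongest main complex: {Cz,Pz} with Phi_MIP = 0.0474618
```

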