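# figseg

Figure–ground segregation — telling an object apart from its background —
unfolds in stages: figure *borders* are detected early, and enclosed
regions later fill in as distinct *surfaces*. A classic way to dissect
these stages combines motion-defined random-dot stimuli, concurrent EEG,
and double-pulse transcranial magnetic stimulation (TMS) over early visual
cortex at controlled latencies. `figseg` is an R package that implements
the complete computational workflow of such a study, end to end, with a
synthetic-data layer that provides known ground truth:

* **Stimuli** — full-screen random-dot displays partitioned into three
  nested regions (background, figure frame, inner figure). Over two screen
  refreshes each region's dots translate one pixel per refresh along one of
  four diagonal directions; dots never cross region borders, vacated border
  pixels are refilled with fair coin flips. Three stimulus kinds differ
  only in the direction assignment: *homogenous* (all regions move
  together), *frame* (the frame moves orthogonally to background and inner
  region), *stack* (all three regions move in pairwise different
  directions). Audit functions verify the balance claims this design rests
  on: equal motion energy per direction, identical border geometry, and
  equal (dis)appearing-dot flicker across kinds.
* **Synthetic TMS–EEG cohorts** — 64-channel recordings at 1048 Hz with
  1/f + white + 50 Hz line noise, blinks with a known EOG projection,
  mV-scale TMS double-pulse artifacts (pulse pairs at 96/119, 156/179 or
  236/259 ms after stimulus onset), and two injected ERP components with
  condition-dependent gains: a figural negativity (137–211 ms, stack and
  frame) and a surface-segregation positivity (227–313 ms, stack only).
  Behavioral tables are drawn from per-condition confusion matrices and
  log-normal reaction times.
* **Preprocessing** — TMS artifact excision (−2…65 ms around each pulse
  pair) with spline interpolation over 250 ms of context on each side;
  zero-phase *mirror filtering* (0.5 Hz high-pass, 30 Hz low-pass, 50 Hz
  notch) that suppresses ringing at excision boundaries; downsampling to
  256 Hz; Cz re-referencing; regression ocular correction; ±75 µV and
  50 µV/step artifact rejection; spherical-spline surface Laplacian;
  epoching; −100…0 ms baseline; averaging and peri-occipital pooling
  (O1, O2, Oz, POz, PO3–PO8).
* **Statistics** — difference waves (figure − homogenous isolates border
  detection; stack − frame isolates surface segregation), sample-wise
  paired t-tests with Benjamini–Hochberg FDR control over a priori time
  windows (80–230 and 200–350 ms, interpolated samples excluded),
  the cumulative 227–313 ms stack−frame statistic with paired-t condition
  comparisons (all-trials and correct-only), 3 × 4 within-subject
  repeated-measures ANOVAs computed from scratch, reaction-time and
  accuracy filters (100–1500 ms, >67% correct), and error-type analyses.

The package is aimed at EEG methodologists who want a tested, reusable
reference implementation of this analysis chain, and at anyone who needs
a TMS-EEG pipeline they can validate against simulated ground truth
before touching real data.

## Worked example

Simulate an 11-subject cohort of pooled condition ERPs, test where the
stack−frame difference is significant, and quantify how early TMS
attenuates the surface-segregation signal:

```r
library(figseg)

co  <- simulate_erp_cohort(n_subjects = 11, seed = 42)
dw  <- difference_waves(co, "stack-frame", "none")
res <- samplewise_fdr_ttest(dw, window = c(200, 350), q = 0.05)
res$intervals
#>   start_ms   end_ms n_samples single_sample
#> 1 249.2188 296.0938        13         FALSE

ct <- cumulative_diff_test(co)
round(colMeans(ct$cumulative), 2)
#>         none        early intermediate
#>        12.44         3.31        11.85
subset(ct$comparisons, a == "none" & b == "early")
#>      a     b        t df            p
#> 1 none early 10.94942 10 6.880887e-07
```

The detected interval (249–296 ms) falls inside the injected 227–313 ms
surface-segregation window; the cumulative statistic drops from 12.4
(no TMS) to 3.3 (early TMS) while intermediate-window TMS leaves it
intact (11.9) — the signature of an early critical period feeding the
later surface signal.

Behavioral statistics from a full 200-trials-per-condition schedule:

```r
sch <- build_schedule(n_blocks = 25, trials_per_block = 96, seed = 42)
beh <- do.call(rbind, lapply(1:11, function(s)
  sample_behavior(sch, behavior_model(), subject = s,
                  seed = derive_seed(42, s))))
st <- behavior_stats(filter_behavior(beh))
st$anova_accuracy[, c("effect", "df1", "df2", "F", "p")]
#>         effect df1 df2     F        p
#> 1     stimulus   2  20 342.3 3.39e-16
#> 2          tms   3  30  68.8 1.49e-13
#> 3 stimulus:tms   6  60  37.8 1.31e-18
```

The interaction is tested on (6, 60) degrees of freedom, as expected for
11 subjects in a 3 × 4 within-subject design.

For a full simulate → preprocess → stats run on continuous recordings use
`run_experiment(experiment_config("desk", seed = 1))`; the methods
vignette (`vignettes/figseg-methods.Rmd`) documents every stage and every
default.

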