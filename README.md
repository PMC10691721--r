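# eggpipe

Quantifying the effect of vagus nerve stimulation (VNS) on gastric
myoelectric activity from electrogastrography (EGG) recordings.

`eggpipe` is for electrophysiologists and biomedical-signal analysts who
record gastric slow waves — invasively or otherwise — while applying
electrical stimulation, and who want a tested, fully seeded answer to two
questions: *can stimulation windows be distinguished from baseline at all*,
and *through which signal properties*. The package implements the complete
chain:

1. **Synthetic study generator** — seeded EGG-like recordings (slow wave at
   ~10 cpm with Ornstein–Uhlenbeck frequency jitter, pink noise,
   implausible spikes, motion artifacts, biphasic stimulation pulse trains)
   with condition effects: amplitude scaling under 10 Hz VNS,
   dominant-frequency shift and extra irregularity under 30 Hz VNS.
2. **Pre-processing** — excision of samples with |x| > 1e8 µV; zero-phase
   band-pass via the index-blocked DCT filtering method (zero every DCT
   coefficient whose index frequency k·fs/2N lies outside 0.01–0.5 Hz, then
   invert); substitution of samples |x| > 2000 µV by the signal mean;
   decimation; 60 s windows with 20 s overlap; windows losing ≥ 30% of
   their raw samples ("removed-pct") are dropped.
3. **Feature battery** — 27 features per window: moments, RMS, line length,
   approximate/sample/permutation/SVD entropy, Lempel–Ziv complexity,
   Hjorth mobility and complexity, Petrosian fractal dimension
   PFD = log₁₀N / (log₁₀N + log₁₀(N/(N + 0.4·N_δ))), Hurst exponent, and
   Welch-PSD descriptors on a 0.1 cpm grid (dominant frequency DF and power
   DP, PMMP, spectral entropy, bradygastric/normogastric/tachygastric band
   powers, crest factor, median and mean power frequency).
4. **Voting feature selection** — nine base selectors (ANOVA F, mutual
   information, L1/L2 linear classifiers, RFE and permutation importance on
   random forests, forward/backward sequential selection, variance
   threshold) each produce weights summing to 1 under 5-fold CV; weights
   are averaged, ranked, and the smallest prefix with cumulative weight
   ≥ 0.9 is selected.
5. **Evaluation** — stratified 80/20 split, unshuffled stratified 5-fold
   cross-validation of a random forest (plus SVM/NB/logistic baselines);
   AUC/accuracy/F1/F2; significance via a permutation test: the 5 observed
   fold AUCs are compared against the pooled fold AUCs of 1000
   label-shuffled re-runs with a two-sample Kolmogorov–Smirnov test.

## Worked example

```r
library(eggpipe)

# simulate a small study: 3 subjects, 10 Hz stimulation, 10-minute segments
design <- study_design(n_subjects = 3, stim_freqs_hz = 10,
                       segment_duration_s = 600, fs_hz = 200, seed = 42)
recordings <- generate_study(design)
recordings[[1]]
#> <egg_recording> subj01/s01_f10 baseline (stim 0 Hz): 120000 samples @ 200 Hz (600.0 s)

windows <- unlist(lapply(recordings, preprocess_recording),
                  recursive = FALSE)
length(windows)   # 84 raw windows minus one dropped by the 30% rule
#> [1] 83

features <- feature_table(windows)
round(features[1:3, c("rms", "smen", "df", "bp2", "removed_pct")], 3)
#>       rms  smen  df   bp2 removed_pct
#> 1 606.835 0.326 1.0 0.222        0.00
#> 2 944.035 0.253 1.8 0.041       16.55
#> 3 690.776 0.325 1.0 0.212        0.00
```

These first windows happen to contain a clamped motion artifact (window 2
lost 16.6% of its samples and its spectrum is pulled low) — exactly the
kind of contamination the removed-pct bookkeeping and the broad feature
battery are there to absorb.

```r
y <- factor(features$label, levels = c("baseline", "vns"))
voting <- select_features(features[, feature_names()], y, seed = 1)
voting
#> <egg_voting_result> 22/27 features at cutoff 0.90:
#>      ll      dp variance     rms      lz    spen  ...
#>  0.2436  0.0670   0.0533  0.0408  0.0376  0.0333  ...
```

The top-ranked features (line length, dominant power, variance, RMS) are
all amplitude/energy features — the correct signature of the simulated
10 Hz effect, which scales the slow-wave amplitude.

```r
cv <- cross_validate("random_forest", features[, voting$selected], y, seed = 1)
round(cv$fold_auc, 3)
#> [1] 1.000 1.000 0.773 1.000 1.000

pt <- permutation_ks_test("random_forest", features[, voting$selected], y,
                          n_perm = 200, seed = 1)
pt
#> <egg_permutation_test> observed mean AUC 0.955 vs null mean 0.468; KS = 0.967, p = 1.11e-07
```

The observed fold AUCs sit far outside the permutation null, so the
stimulation effect is detectable at this study size (KS = 0.967,
p ≈ 1e-07). `run_pipeline(run_config(), out_dir)` runs the same chain for
both classification scenarios (baseline vs 10 Hz, baseline vs 30 Hz) and
writes feature tables (TSV), selection/evaluation reports (JSON) and a
seeded run manifest.

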