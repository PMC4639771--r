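# zcia — zero-crossing interval analysis of scalp EEG

`zcia` quantifies the *background rhythm* of interictal scalp EEG — the
part of the signal clinical reading usually ignores in its search for
epileptiform discharges — and turns it into candidate diagnostic
markers. It is aimed at clinical neurophysiology researchers who want a
reproducible, fully automated pipeline from raw multichannel EEG to
statistically screened, cross-validated rhythm markers.

## The method in brief

A band-passed EEG channel is reduced to its zero crossings (rising-edge
convention, sub-sample placement by linear interpolation). The intervals
between subsequent crossings are histogrammed in 4-ms bins over
0–4000 ms and normalized into the **interval spectrum** *P*, a discrete
probability distribution: a regular 10 Hz alpha rhythm piles mass near
100 ms; the 8–13 Hz alpha band corresponds to the 77–125 ms interval
range. Markers derived from *P*:

* fixed-length interval counts *p<sub>i</sub>* (one bin's probability),
* descriptive statistics (mean, median, mode, SD, IQR),
* Shannon entropy `Hs = -Σ p_i log2 p_i` and min-entropy
  `Hmin = -log2 max_i p_i` — rhythm-irregularity measures.

Markers are screened with Kruskal–Wallis ANOVA (diagnosis and
antiepileptic drug load as separate 4-level factors, Bonferroni
corrected, Tukey–Kramer rank post-hocs, bins tested only when every
subject has >100 raw counts). Classifier performance is the
pair-counting AUC, estimated out-of-sample by **leave-pair-out
cross-validation** (AUC\*): each case–control pair is held out, the
passband / interval-bin (optionally channel-group × segment) parameters
are refitted on the rest, and the held-out pair is scored. Four
objectives are built in: an alpha score and two entropy scores for
epilepsy vs control, and a theta score for drug polytherapy vs
monotherapy. A 19-channel synthetic EEG cohort generator with planted
group effects makes the whole pipeline testable without patient data.

## Worked example

```r
library(zcia)

# a synthetic cohort: 25 epilepsy-like cases, 25 controls, full
# 19-channel montage, three 60-s protocol segments (runs in ~30 s)
design <- cohort_design(
  n_per_group = c(TLE = 13, FLE = 12, PNES = 13, headache = 12),
  segment_durations = c("pre-Fs" = 60, "Hv" = 60, "post-Hv" = 60),
  seed = 401)
cohort <- simulate_cohort(design)

# whole-recording interval spectrum of a drug-free control subject,
# theta-alpha band
S <- whole_recording_spectrum(cohort$recordings[[45]], bandpass(4, 13))
print(S)
#> <interval_spectrum> 20208 intervals in 47/1000 occupied bins (4 ms)
#>   peak p = 0.1898 at [96, 100) ms; overflow 0
#>   provenance: band=[4-13 Hz], channel_groups=all, segments=all, ...
round(spectrum_markers(S), 3)
#>   mean median   mode     sd    iqr     Hs   Hmin
#> 97.843 98.000 98.000 13.370 12.000  3.391  2.397

# cross-validated alpha-score discrimination over a small band grid
cs <- cohort_spectra(cohort$recordings, band_grid(lo = c(3, 5, 7),
                                                  hi = c(13, 15)))
cv <- lpo_cv(cs, "alpha_score")
print(cv)
#> <zc_lpocv> alpha_score: AUC* = 0.7920 over 625 folds (25 x 25)
#>   most common fit: band [3-15 Hz], interval 100 ms
```

The spectrum peak in the [96, 100) ms bin is the interval-domain image
of this subject's ~10 Hz posterior rhythm; the fitted classifier inverts
the relative count at an alpha-range bin (cases have *less* regular
alpha, hence lower counts), and AUC\* = 0.79 is the fraction of held-out
case–control pairs it ranks correctly. `screen_markers()`, `auc_curve()`, `auc_ratio_map()` (two-step
fits), `subsegment_experiment()` and `averaged_roc()` cover the rest of
the analysis surface; `run_pipeline()` ties them together and writes a
TSV/JSON report bundle, with a thin command-line wrapper in
`inst/scripts/zcia-pipeline.R`.

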