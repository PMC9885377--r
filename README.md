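# mlpitfalls

Paired synthetic experiments that quantify three methodological pitfalls in
machine-learning model development for medical imaging:

1. **Independence-assumption violations (data leakage)** — oversampling,
   data augmentation, or feature selection applied *before* splitting data
   into training/validation/test sets, and row-level splitting of datasets
   where each patient contributes many samples.
2. **Misleading performance indicators and baselines** — accuracy under
   class imbalance, and Dice/IoU scores of a trivial segmenter that merely
   thresholds air inside the body (HU < −400, border-connected air removed)
   as a lung-segmentation "model".
3. **Batch effects** — class labels perfectly confounded with acquisition
   source, so a model can classify the source signature instead of the
   disease, acing internal evaluation and collapsing on external data.

Every experiment pairs a *pitfall* pipeline with a *correct* pipeline that
differ only in the ordering of one step (or the split kind). For each of
`R` repetitions both arms consume the same generated dataset; the test-set
F1 vectors are compared with a two-sided Wilcoxon rank-sum test

    z = (W − n₁(N+1)/2 ± ½) / σ_tie-corrected,

and overlap scores use Dice = 2|X∩Y|/(|X|+|Y|), IoU = |X∩Y|/|X∪Y|, with
the identity Dice = 2·IoU/(1+IoU) (so Dice ≥ IoU always). The leakage
experiments run on **null-signal** data — the features carry no class
information — so the correct arm's F1 sits provably at chance and *any*
pitfall-arm advantage is pure leakage.

Synthetic generators replace the clinical datasets of the motivating
applications: imbalanced radiomics-like tables, per-patient patch
collections with patient signatures, 3-D Hounsfield-unit phantoms with
ground-truth lung and internal-air masks, source-confounded two-site
datasets with a confound-breaking external set, and slide-like RGB images
for the patch-extraction pipeline. Tables round-trip via CSV, volumes via
NIfTI, slides/patches via PNG; experiment results serialize to CSV + JSON.

## Worked example

```r
library(mlpitfalls)

res <- run_paired_experiment(experiment_config("oversampling", seed = 1))
glance(res)
#> # A tibble: 1 × 7
#>   kind         repetitions pitfall_mean_f1 correct_mean_f1 mean_f1_delta wilcoxon_z  p_value
#> 1 oversampling         100           0.927          0.0778         0.849       12.4 2.00e-35
```

Oversampling to class balance *before* the 60/20/20 split copies minority
rows into both training and test sets; a 1-nearest-neighbor classifier
then "recognizes" its own training duplicates, reporting F1 ≈ 0.93 on
pure noise. The identical pipeline with oversampling *after* the split
scores F1 ≈ 0.08 — chance level for the 10% prevalence — and the
difference is overwhelming (z = 12.4). `summarize_experiment(res)` gives
the per-arm min/mean/max/SD rows, `autoplot(res)` the per-arm F1 boxplot,
and `tidy(res)` the per-repetition metrics with leakage-audit counts.

The batch-effect experiment tells the complementary story:

```r
bat <- run_batch_effect(experiment_config("batch_effect", seed = 1))
glance(bat)
#> # A tibble: 1 × 6
#>   kind         internal_accuracy internal_precision internal_recall internal_f1 external_fraction
#> 1 batch_effect                 1                  1               1           1                 0
```

Internally flawless; on external class-0 samples carrying the other
source's signature, **0%** are classified correctly.

The segmentation baseline: on a 10-phantom cohort,
`evaluate_baseline()` scores the internal-air proxy at mean Dice ≈ 0.92
against the lung ground truth even though every predicted mask visibly
includes trachea and bowel gas — a high Dice is not evidence of an
acceptable segmentation, and a proposed model must at least beat this.

Command-style wrappers (`cmd_run()`, `cmd_segment_baseline()`,
`cmd_extract_patches()`, YAML configs via `show_config()`) write
per-repetition CSVs, summary JSONs and a run manifest; a thin CLI lives
at `inst/cli/mlpitfalls.R`.

## See also

The methods vignette (`vignettes/pitfall-experiments.Rmd`) documents the
experiment design, what each generator does and does not emulate, the
metric conventions (both-empty-mask Dice, undefined-metric handling, the
exact small-sample Wilcoxon route), and the package's numerical choices.
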