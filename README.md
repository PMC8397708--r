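# chromosig

Copy-number (CN) and structural-variant (SV) signature analysis for
chromothripsis prediction in multiple myeloma (MM).

Chromothripsis — catastrophic chromosomal shattering with random rejoining —
is detectable in roughly a quarter of newly diagnosed MM patients and is an
independent adverse prognostic factor, but calling it normally requires
whole-genome SV + CN data and manual curation. chromosig implements the
signature route: summarize each genome by six CN feature distributions, learn
CN signatures de novo across the cohort, and predict chromothripsis from each
sample's signature exposures alone, so that the call also works where only CN
data (e.g. exomes, low-coverage genomes) are available.

## The method in brief

Per sample, six CN features are measured from the filtered segmentation
(CN changes < 50 kb removed; IGH/IGK/IGL and chromosome X masked):

1. breakpoints per 10 Mb window,
2. absolute segment copy number — five fixed states
   (0, 1, 2, 3, ≥4: bi-allelic deletion … two-or-more gains),
3. CN difference between adjacent segments,
4. breakpoints per chromosome arm,
5. lengths of oscillating CN chains,
6. segment sizes.

Cohort-wide mixture fits (Poisson for counts, Gaussian for jumps and log
sizes; BIC-selected component counts) define the CN categories; hard
assignment yields a samples × categories count matrix **M**. De novo
extraction factorizes **M ≈ E·S** with signature rows **S** and exposure rows
**E** on the simplex, via a hierarchical Dirichlet process Gibbs sampler
(`extract_hdp()`) or seeded KL-NMF (`extract_nmf()`). SVs are annotated
clustered/non-clustered (piecewise-constant fit of inter-breakend distances)
and tallied into the standard 32 categories. Complex events are classified
from the breakpoint-interconnection graph: chromothripsis (> 10
interconnected pairs + oscillating CN), chromoplexy (> 2 chromosomes + CN
loss), templated insertions (translocations + focal gain), complex-NOS (≥ 3
pairs). Chromothripsis prediction is a ridge logistic model on all exposures
under stratified 10-fold cross-validation; the mean per-fold ROC AUC is the
headline metric and probabilities ≥ 0.6 define a high **CN_pred** score.
A bootstrap procedure (`compare_auc_bootstrap()`) tests AUC differences
between feature sets.

A seed-reproducible cohort simulator (`simulate_cohort()`) generates MM-like
genomes — hyperdiploid trisomies, arm/focal CNAs, planted chromothripsis at
24% prevalence with pair counts around a median of 24, chromoplexy,
templated insertions, complex-NOS, passenger SVs — so the whole pipeline is
testable without controlled-access patient data.

## Worked example

```r
library(chromosig)

cohort <- simulate_cohort(scenario_presets("mm_like", n_samples = 120, seed = 42))
res <- run_end_to_end(cohort$segments, cohort$svs,
  labels = cohort$truth, out_dir = "run", seed = 7
)

res$scheme
#> <cn_category_scheme> 26 categories
#>  bkpt_10mb: 4 (poisson)
#>  seg_cn: 5 (fixed_state)
#>  cn_jump: 1 (gaussian)
#>  bkpt_arm: 3 (poisson)
#>  osc_len: 3 (poisson)
#>  seg_size: 10 (gaussian_log10)

res$prediction
#> <chromothripsis_prediction> 120 samples, 10-fold CV, mean AUC 1.000 (pooled 1.000)

call_cn_pred(res$prediction)[c("sensitivity", "specificity")]
#> $sensitivity
#> [1] 0.6206897
#> $specificity
#> [1] 1
```

The scheme print shows the BIC-chosen category count per feature (26 in
total on this simulated cohort; the count is data-dependent). The prediction
line is the mean of the ten per-fold ROC AUCs — 1.0 here because simulated
chromothripsis is cleanly separated — and `call_cn_pred()` reports the
confusion summary at the 0.6 CN_pred cutoff: every sample called "high"
truly carries chromothripsis (specificity 1), while 62% of true events clear
the conservative 0.6 probability bar on this small cohort; the sweep table
in `call_cn_pred()` shows the full sensitivity/specificity trade-off. `autoplot(res$prediction)` draws the per-fold
(blue) and pooled (red) ROC curves; `autoplot(res$cn_fit)` the signature
profiles.

Per-sample files (`cn_matrix.tsv`, `cn_exposures.tsv`, `complex_calls.tsv`,
`predictions.tsv`, `run_metadata.json`, …) are written under `out_dir`.
A thin command-line wrapper lives at `inst/cli/chromosig.R`
(`simulate` and `run-all` subcommands).

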