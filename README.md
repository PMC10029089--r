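# tp53allele

Resolving the allelic configuration of *TP53* mutations in myeloid neoplasia
from bulk variant allele frequencies.

## The problem

*TP53* is a recessive tumor suppressor: prognosis in myeloid neoplasms (MDS,
AML and overlap entities) is driven by **biallelic** inactivation — both gene
copies lost in the same cell — rather than by the mere presence of a
mutation. Bulk NGS reports only a variant allele frequency (VAF) per
mutation, and cytogenetics/SNP-arrays miss del(17p) or copy-neutral LOH
clones below roughly 20% of cells. Two monoallelic clones in a mosaic can
mimic one biallelic clone, and a small ("cryptic") biallelic subclone can
hide inside a case that looks monoallelic. The traditional single-hit /
double-hit lesion count does not resolve this.

`tp53allele` implements, for analysts working with patient-level myeloid
cohorts:

* **VAF-arithmetic configuration calls.** With per-mutation VAFs
  `v_1..v_k` (fractions) and del(17p) clonality `c`, a case is *obligatory
  biallelic* when any `v_i > 0.5`, or `sum(v_i) > 0.5`, or
  `sum(v_i) + c > 0.5`. Remaining mutated cases are split at a VAF cutoff
  `t`: *probable biallelic* when `sum(v_i) > t`, otherwise *probable
  monoallelic*. The traditional single/double-hit scheme is provided for
  comparison, along with the cross-classification between the two.
* **A survival-guided estimate of the cutoff `t`** (`fit_vaf_cutoff()`):
  log-rank split-point search over candidate cutoffs with a minimum node
  size, bootstrap subsampling of the split choice, and repeated 80/20
  train/test cross-validation scored by Harrell's C-index on an ordinal
  risk score (WT 0 < probable monoallelic 1 < probable biallelic 2 <
  obligatory biallelic 3). Defaults: minimum node 15, 30 runs, 20% test.
* **Self-contained survival utilities**: Kaplan-Meier curves, k-sample
  log-rank test, Harrell's concordance, univariate Cox regression (Breslow
  ties), 2×2 odds ratios.
* **A ground-truthed synthetic cohort generator**: clonal architectures
  (heterozygous, hemizygous, UPD-homozygous, compound heterozygous,
  cryptic subclones), binomial read sampling at configurable depth,
  del(17p) calls with a 20% detection floor, exponential survival with
  per-stratum medians (42/29/14 months), and single-cell genotype matrices
  with allelic dropout — so every statistical claim in the package is
  testable without patient data.

## Worked example

```r
library(tp53allele)

sim <- simulate_cohort(sim_params(n_patients = 800, seed = 7))
run_full_pipeline(sim$cohort, run_config(seed = 7))
```

```
TP53 allelic-configuration report (n = 800, cutoff 23.0%)

Traditional classification:
        WT single_hit double_hit
       317        106        377

Allelic-configuration classification:
                  WT obligatory_biallelic   probable_biallelic
                 317                  246                  130
probable_monoallelic          del17p_only
                  97                   10
...
Survival by group
  obligatory_biallelic   n =  246, events =  209, median OS: 14 [5-22]
  probable_biallelic     n =  130, events =   99, median OS: 21 [6-33]
  probable_monoallelic   n =   97, events =   69, median OS: 32 [12-43]
  WT                     n =  317, events =  251, median OS: 40 [16-64]
Cox hazard ratios vs WT
  obligatory_biallelic   HR 3.34 [2.71-4.11], p = 9.33e-30
  probable_biallelic     HR 1.78 [1.41-2.26], p = 1.68e-06
  probable_monoallelic   HR 1.37 [1.04-1.79], p = 0.0237
```

Note the pattern the three-class scheme is built around: 48 of 106
traditional "single hit" cases move to probable biallelic and carry
intermediate risk, while probable monoallelic cases sit close to wild type
(median OS 32 vs 40 months). The cutoff fit on a cohort with a planted
hazard change-point:

```r
cp  <- simulate_changepoint_cohort(n = 1000, seed = 7)   # change at VAF 23%
fit <- fit_vaf_cutoff(cp$cohort, run_config(cv_runs = 30, subsamples = 200,
                                            seed = 7))
fit
#> Survival-optimized TP53 VAF cutoff
#>   cohort: 1000 patients (495 in the probable classes)
#>   461 candidate cutoffs in [3.4%, 48.5%]
#>   selected cutoff: 19.8% (mean test C = 0.606 over 30 runs)
#>   modal bootstrap split: 19.8% (39 of 200 resamples)
coef(fit)    # the selected cutoff, as a fraction
plot(fit)    # concordance profile over candidates
```

And the cryptic-biallelic arithmetic that motivates the whole approach — a
6% UPD-homozygous subclone beside a 4% heterozygous clone produces a bulk
VAF of only 8%, which every bulk classifier must call monoallelic:

```r
arch <- clonal_architecture(fractions = c(0.06, 0.04, 0.90),
                            total_copies = c(2, 2, 2),
                            mutant_copies = c(2, 1, 0))
expected_vaf(arch)              # 0.08
arch$truth_biallelic_fraction   # 0.06
```

## Package layout

* `R/cohort.R` — the `tp53_cohort` container and TSV readers/writers
  (percent on disk, fractions in memory)
* `R/classify.R` — traditional and three-class allelic classification
* `R/survstats.R` — KM / log-rank / Harrell's C / Cox / odds ratio
* `R/cutoff.R` — candidate grids, split search, subsampling,
  cross-validation, `fit_vaf_cutoff()`
* `R/simulate.R` — clonal architectures and cohort simulators
* `R/pipeline.R` — `run_full_pipeline()` and survival reports
* `vignettes/allelic-configuration-methods.Rmd` — model, assumptions,
  parameter choices and limitations
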