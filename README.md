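# mriscreen

A decision-analytic Markov cohort model of annual prostate-cancer
screening for 65-year-old men with an elevated serum PSA, comparing two
strategies over a 10-year horizon from a federal-payer perspective:

* **standard** — an annual PSA test plus TRUS-guided (standard) biopsy;
* **mri** — an annual PSA test plus prostate MRI, with an MRI-guided
  biopsy only when the MRI is positive.

The package is aimed at health-economic modellers: it provides a
validated parameter registry (beta/gamma distributions fitted from
published means and 95% intervals), a 13-state annual-cycle cohort
engine, discounted cost/QALY aggregation, ICER and net-monetary-benefit
statistics, Monte Carlo probabilistic sensitivity analysis with
cost-effectiveness acceptability curves (CEACs), one-way sweeps and
tornado diagrams, and an individual-level microsimulation that serves as
an independent validation oracle for the cohort engine.

## Model in brief

Men in four PSA strata (<2.5, 2.5–4.0, 4.1–10.0, >10.0 ng/mL) enter with
stratum-specific cancer prevalence, spread over grade (low/intermediate/
high) and comorbidity status. Each annual cycle applies background
mortality, then the strategy's screening round, then grade progression.
Detected high-grade disease is treated; detected low/intermediate-grade
disease is treated unless comorbidities defer it. Treatment costs the
equal-thirds average of prostatectomy, radiotherapy and brachytherapy;
post-treatment disease can recur at a stratum-specific annual rate. Costs
and utilities accrue per state per cycle and are discounted at 3%/year.
Strategies are compared by

ICER = (C_mri − C_std) / (Q_mri − Q_std)

against a $100,000/QALY willingness-to-pay threshold, and by net monetary
benefit NMB(λ) = λ·Q − C across probabilistic draws (CEACs).

All structural conventions that published tables leave open (false-positive
handling, adverse-event disutility timing, half-cycle correction, serial
test composition, salvage costing, screening interval) are explicit
switches in `pca_options()`; the methods vignette
(`vignettes/model-methods.Rmd`) motivates each default and documents which
published magnitudes the reconstruction can and cannot reproduce.

## Worked example

```r
library(mriscreen)

fit <- pca_cea()        # base case, all four strata
print(fit)
```

```
Cost-effectiveness of annual MRI + potential MRI-guided biopsy versus annual standard biopsy
(10-year Markov cohort, entry age 65, 3% discount rate)

PSA stratum lt2.5 (ng/mL)
  standard  cost $    4366   QALYs  8.018
  mri       cost $    5743   QALYs  8.027
  increment cost $    1377   QALYs  0.009   ICER $157400/QALY

PSA stratum 2.5-4.0 (ng/mL)
  standard  cost $    7633   QALYs  7.895
  mri       cost $    8906   QALYs  7.903
  increment cost $    1273   QALYs  0.008   ICER $155427/QALY

PSA stratum 4.1-10.0 (ng/mL)
  standard  cost $   10083   QALYs  7.791
  mri       cost $   11279   QALYs  7.799
  increment cost $    1196   QALYs  0.008   ICER $146570/QALY

PSA stratum gt10 (ng/mL)
  standard  cost $   17637   QALYs  7.407
  mri       cost $   18593   QALYs  7.417
  increment cost $     956   QALYs  0.010   ICER $96719/QALY
```

Reading the output: in every stratum the MRI strategy costs more (the MRI
is dearer than the biopsy it replaces) but yields more QALYs (fewer
biopsies and their adverse effects, and less early treatment of indolent
disease). Its incremental cost falls and its QALY gain rises with PSA, so
the ICER decreases strictly across strata; only the >10 ng/mL stratum
falls under the $100,000/QALY threshold, and the <2.5 ng/mL stratum is
clearly not cost-effective.

Downstream analyses:

```r
psa <- simulate(fit, nsim = 2000, seed = 1)   # probabilistic analysis
cc  <- ceac(psa)                              # acceptability curves
plot(cc)

sw  <- one_way_sweep(load_parameter_table(), "spec_mri", strata = "2.5-4.0")
tor <- tornado(load_parameter_table(), stratum = "gt10",
               outcome = "incremental_qaly")

val <- validate_engine(load_parameter_table(), n = 50000)  # microsim oracle
```

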