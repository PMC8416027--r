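# pppflux

Pentose-phosphate-pathway (PPP) branch-flux analysis from 1,2-¹³C₂
glucose stable-isotope tracing.

## The problem

The PPP makes ribulose 5-phosphate (Ru5P) two ways: the irreversible
**oxidative branch** (G6P → 6PG → Ru5P + CO₂, via G6PD/6PGD, producing
NADPH) and the reversible **non-oxidative branch**
(transketolase/transaldolase chemistry on F6P/GAP). With a 1,2-¹³C₂
glucose tracer the two branches write different signatures into Ru5P:
the oxidative branch loses the labelled C1 as CO₂ and delivers **singly
labelled (m1)** Ru5P, while the non-oxidative route assembles Ru5P from
F6P- and GAP-derived fragments that retain both labels and delivers
**doubly labelled (m2)** Ru5P. Fitting the post-spike accumulation of
each isotopologue with the continuous stirred-tank reactor (CSTR)
relaxation

    m(t) = m_max · (1 − e^(−D·t)) + m_initial

yields a dilution (turnover) rate *D* (1/s) per branch reporter, and a
least-squares Monte Carlo (parametric bootstrap, n = 1000 draws) turns a
treatment-vs-control rate difference into an empirical one-sided p-value

    p = (r + 1) / (n + 1),   H₀: D_treatment − D_control ≥ 0,

where *r* counts paired draws consistent with the null.

The package is aimed at metabolomics analysts running rapid spike-in
tracing time courses (here: 1:1 tracer:natural glucose; samples at 0,
10, 60, 120, 240, 480, 900 s in triplicate). It provides:

- MID handling: normalisation, natural-¹³C-abundance correction
  (nonnegative least squares), mean enrichment (`normalize_to_mid`,
  `natural_abundance_matrix`, `correct_mid`, `mean_enrichment`);
- a forward labelling simulator through glycolysis and both PPP branches,
  used as the synthetic-data generator (`simulate_labeling`,
  `steady_state_mids`, `generate_experiment`, `default_scenarios`);
- CSTR fitting and Monte Carlo inference (`fit_cstr`, `monte_carlo_fit`,
  `dilution_rate_pvalue`, `compare_all`);
- steady-state enrichment QC and an orchestration pipeline with YAML
  configs, manifests and a CLI (`qc_steady_state`, `run_pipeline`,
  `inst/cli/pppflux.R`).

## Worked example

Simulate the four-condition knockdown design (control; oxidative-branch
knockdown ×0.4; both branches ×0.4 twice) and compare dilution rates:

```r
library(pppflux)
scen <- default_scenarios()            # siCon, si6PGD, siAR, siSREBP1
tab <- generate_experiment(scen, tracer_spec(0.5, 1), default_times(),
                           replicates = 3, noise = noise_model(0.01, seed = 7))
qc_steady_state(tab)
cmp <- compare_all(tab, n_draws = 1000, seed = 7)
cmp$report
```

The QC confirms every condition reached the same G6P steady-state
enrichment (≈ 1/6 with a 1:1 m2 spike; no condition flagged), so rate
differences are attributable to flux, not labelling bias:

```
  condition enrichment      sd diff_vs_control flagged
1     siCon      0.175 0.00430         0.00000   FALSE
2    si6PGD      0.172 0.00289         0.00327   FALSE
3      siAR      0.180 0.01100         0.00531   FALSE
4  siSREBP1     0.165 0.00786         0.00965   FALSE
```

The comparison report gives one row per condition × reporter with the
fitted rate, 95% draw interval and empirical p:

```
  condition metabolite isotopologue    D_hat D_ci_low D_ci_high  r    n p_empirical
1     siCon       Ru5P           m1 0.004620 0.004209   0.00509 NA   NA          NA
2    si6PGD       Ru5P           m1 0.002486 0.001983   0.00284  0 1000    0.000999
3      siAR       Ru5P           m1 0.001426 0.001183   0.00157  0 1000    0.000999
4  siSREBP1       Ru5P           m1 0.001681 0.001244   0.00205  0 1000    0.000999
5     siCon       Ru5P           m2 0.001539 0.001150   0.00199 NA   NA          NA
6    si6PGD       Ru5P           m2 0.001062 0.000853   0.00134 19 1000    0.019980
7      siAR       Ru5P           m2 0.000666 0.000369   0.00103  0 1000    0.000999
8  siSREBP1       Ru5P           m2 0.000408 0.000186   0.00104  1 1000    0.001998
```

Read: the oxidative reporter (m1) collapses to the p-value floor
(1/1001 ≈ 0.001) in every knockdown; the non-oxidative reporter (m2)
responds strongly only when both branches are knocked down, and only
weakly (p ≈ 0.02) when the oxidative branch alone is cut — the
branch-specific pattern this tracer design exists to resolve.

The same analysis runs end to end from a config:

```sh
Rscript inst/cli/pppflux.R run --seed 7 --n-draws 1000 --out run_out
```

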