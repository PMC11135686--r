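# liebigsmad

Kinetic models of TGF-beta/SMAD signaling built around the **minimum
principle**: the pathway needs one type I (TGFBR1) and one type II (TGFBR2)
receptor to form each signaling complex, so whichever receptor type is less
abundant caps the output — Liebig's law of the minimum applied to signal
transduction.  The package is for systems biologists who want to simulate,
test and fit this behavior: it predicts which receptor a given cell type is
sensitive to, how single-cell heterogeneity in receptor expression shapes
response heterogeneity, and how knockdown dose-response curves shift with
receptor imbalance.

## What is inside

* **Minimal model** — two reactions with an analytic steady state.  The
  ligand-receptor complex solves `LRC = K1*L*(R1tot-LRC)*(R2tot-LRC)`
  (smaller quadratic root, `0 <= LRC <= min(R1tot, R2tot)`); signaling
  activity is `Sa = Stot * K2*LRC/(1 + K2*LRC)`.  High affinity gives
  `LRC -> min(R1tot, R2tot)`; low affinity gives `LRC ~ K1*L*R1tot*R2tot`.
  Receptor-space landscape scans and log-elasticities quantify both regimes.
* **Extended pathway model** — 11-state mass-action ODE system: medium
  ligand with depletion, receptor synthesis/trafficking/degradation,
  one-step complex formation, ligand-induced complex degradation (negative
  feedback, `k_NFR`), SMAD2 phosphorylation, nucleocytoplasmic shuttling and
  nuclear dephosphorylation.  Compiled adaptive Runge-Kutta 5(4) integrator.
* **Observables** — relative P-SMAD2 (phosphorylated fraction) and the
  imaging-style nuclear-to-cytoplasmic (N2C) SMAD2 fold change.
* **Scans / single cells** — log-uniform expression-space landscapes;
  log-normal cell populations (CV 0.1) with Pearson correlation reports.
* **Dose response** — mechanistic siRNA-knockdown curves and Hill/EC50
  fitting (`y = A x^n/(K^n + x^n)`, EC50 = fold change at half the control
  response).
* **Inference** — multistart Levenberg-Marquardt least squares in log
  space and profile-likelihood identifiability classification.
* **Synthetic data** — generators for 102-point multi-dose time courses,
  siRNA dose series and single-cell imaging tables, each carrying its
  ground truth for closed-loop recovery tests.

## Worked example

```r
library(liebigsmad)

## population model: 100 pM TGF-beta on a balanced (HaCaT-like) cell
p  <- pathway_params("hacat_like")
tc <- simulate_pathway(p, dose_nM = 0.1, t_grid = seq(0, 480, by = 1))
ps <- total_psmad2(tc)
ps$t[which.max(ps$value)]                 # 60   <- P-SMAD2 peaks at 1 h
relative_psmad2(tc)$value[61]             # 0.383 phosphorylated fraction at 1 h
n2c_fold_change(tc)$value[61]             # 2.00  nuclear accumulation at 1 h

## minimum principle, analytically: scarce R1 (100) vs abundant R2 (10000)
imb <- minimal_params(L = 0.1, K1 = 1000, K2 = 10,
                      R1tot = 1e2, R2tot = 1e4)
log_elasticity(imb, "R1")                 # 9.99e-04  output tracks the
log_elasticity(imb, "R2")                 # 1.02e-09  scarce receptor only

## knockdown sensitivity of an R1-rich (RH-30-like) cell
pr1 <- pathway_params("r1_rich")
fit_hill(predict_knockdown_response(pr1, "R1"))$ec50   # 0.057
fit_hill(predict_knockdown_response(pr1, "R2"))$ec50   # 0.216
```

The EC50s say: in a cell with 10x more TGFBR1 than TGFBR2, the P-SMAD2
response falls to half control when TGFBR2 is reduced to only 22% of normal,
but TGFBR1 must be knocked down to 6% before the same loss occurs — the
scarce receptor is the sensitive one.

Single-cell heterogeneity, 5-fold TGFBR1 excess (300 cells, CV 0.1):

```r
pop <- draw_population(p, cv = 0.1, n_cells = 300,
                       mean_multipliers = c(pR1 = 5), seed = 7)
correlate(simulate_population(pop, response_times = 60), 60)
#   covariate pearson_r  p_value n_cells
# 1        R1    0.3108 3.86e-08     300
# 2        R2    0.8142 2.40e-72     300
# 3     SMAD2   -0.0315 5.86e-01     300
# 4     k_NFR   -0.6217 1.79e-33     300
```

The N2C fold-change response of each simulated cell tracks the scarce
receptor (TGFBR2, r = 0.81) far more than the abundant one (r = 0.31).

## Command line

```sh
Rscript -e 'liebigsmad::cli_main()' -- simulate --dose-pM 100 --out out/
Rscript -e 'liebigsmad::cli_main()' -- scan --n 2000 --seed 1 --out out/
Rscript -e 'liebigsmad::cli_main()' -- single-cell --n-cells 300 --cv 0.1 \
    --mult-r1 5 --out out/
Rscript -e 'liebigsmad::cli_main()' -- dose-response --receptor R2 \
    --fit-hill --out out/
```

Each command writes CSV tables plus a JSON manifest (config hash, seed,
package version) so outputs are regenerable.

## Further reading

The methods vignette (`vignettes/receptor-minimum-methods.Rmd`) documents
the model equations and assumptions, the preset calibration, numerical
choices, the identifiability analysis and known limitations.
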