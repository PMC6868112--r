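# gctmod — glucagon challenge test modeling and receptor-change inference

`gctmod` is an R package for the pharmacodynamic analysis of the **glucagon
challenge test**: a 6 h clinical protocol in which, after a 3 h baseline
phase, somatostatin shuts down endogenous pancreatic secretion while insulin
is clamped at its baseline and glucagon is infused to 2–3× physiological
levels, isolating glucagon's effect on hepatic glucose production. It is
aimed at modelers and pharmacometricians who want to simulate the test,
estimate per-subject receptor kinetics from challenge-test records, and
test whether a drug changed the number of glucagon receptors.

## The model

Blood glucose `G` (g/L), insulin `I` (mU/L) and glucagon `E` (pmol/L)
follow turnover equations; during the clamp the hormones are exactly
solvable, `E(t) = Q_E/(V_E k_degE) + (Ē − Q_E/(V_E k_degE)) e^{−k_degE (t−t_s)}`.
Glucagon drives glucose production through the receptor cycle on the
hepatocyte membrane (free → bound → internalized → recycled, fractions
`r`, `r_e`, `r_i` with `r + r_e + r_i = 1`):

    dr/dt   = −k_on V_h E r + k_off r_e + k_rec (1 − r − r_e)
    dr_e/dt =  k_on V_h E r − (k_off + k_in) r_e

and hepatic glucose production is a Hill function (coefficient 2) of the
*bound* fraction:

    F_hgp = b_G + V_1 r_e² / (K₁′² + r_e²)

`K₁′` — the apparent dissociation constant on the bound-fraction scale —
is inversely proportional to the total receptor number, so a treatment
that removes receptors raises `K₁′`. The pipeline estimates `K₁′` before
and after treatment per subject, compares the paired estimates with an
exact Wilcoxon signed-rank test under Benjamini–Hochberg FDR correction,
and converts the change into a relative receptor change
`Δ = K₁′_before/K₁′_after − 1` (negative = receptor loss).

Parameter estimation is by generalized profiling: latent states are
penalized cubic B-splines, an inner Levenberg–Marquardt problem fits the
splines given parameters (data misfit + λ × integrated squared ODE
residual), an outer search over log-parameters minimizes the data misfit
of the inner solution through an increasing λ schedule, ending in the
exact-ODE limit. Baseline steady-state constraints are enforced exactly by
eliminating `b_G` and `V_ii` in closed form. See the methods vignette
(`vignettes/glucagon-challenge-model.Rmd`) for the full account.

## Worked example

```r
library(gctmod)

# simulate one average subject through the test
p <- cohort_average_params()
ss <- receptor_steady_state(14.3, p)         # baseline receptor state
ss$re_bar
#> [1] 0.003697694
tr <- simulate_subject(p, E_bar = 14.3)
max(tr$E) / 14.3                             # glucagon rise at the clamp
#> [1] 2.574526

# a seeded paired cohort (8 subjects x before/after), fitted and compared
cfg <- smoothing_config(receptor_mode = "ode", prior = "population",
                        outer_maxit = 40, outer_ptol = 1e-6,
                        retry_factor = Inf)
coh <- generate_paired_cohort(cohort_spec(seed = 3),
                              noise = noise_model(0.05, 0.05, 0.05, 0.05, 0.05))
fits_b <- lapply(coh, function(s) profile_fit(s$before, cfg))
fits_a <- lapply(coh, function(s) profile_fit(s$after, cfg))
names(fits_b) <- names(fits_a) <- sapply(coh, function(s) s$before$subject_id)
summ <- summarize_cohort(
  parameter_table(fits_b, lapply(coh, `[[`, "before")),
  parameter_table(fits_a, lapply(coh, `[[`, "after")))
summ$comparison[summ$comparison$parameter == "K1_prime", c("p", "fdr")]
#>           p        fdr
#> 8 0.0078125 0.02864583
summ$delta$delta_of_means
#> [1] -0.4981432
```

The `K₁′` row attains the exact extremal p-value `2/2⁸ = 0.0078125`
(all 8 subjects' estimates moved the same way) and survives FDR
correction; the cohort-mean receptor change of about −0.5 recovers the
generating treatment (a `K₁′` multiplier of ≈2.18, i.e. roughly a halving
of the receptor count).

File-based pipeline: `run_simulate()`, `run_fit()`, `run_compare()` (or
`run_all()`) read/write per-subject CSV records
(`time_min,glucose_g_per_L,insulin_mU_per_L,glucagon_pmol_per_L,fhgp_g_per_h_per_L,rd_g_per_h_per_L`),
parameter tables, a comparison table and a manifest, all seeded and
bitwise reproducible.

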