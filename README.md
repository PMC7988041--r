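# csfbc

Comparison of inlet/outlet boundary conditions for cerebrospinal fluid
(CSF) dynamics in hydrocephalus, as a reduced-order, fully testable R
package.

CSF simulations of the ventricular system are highly sensitive to the
choice of boundary conditions (BCs). `csfbc` implements the three
classical schemes on one lumped intracranial network — sinusoidal inlet
pressure (**A**), pulsatile inlet flow with a constant-pressure outlet
(**B**), and pulsatile flow prescribed at both inlet and outlets
(**C**) — with either a rigid ventricle (CFD mode) or a
poro-viscoelastic ventricular wall (FSI mode, three-branch Prony
relaxation).  It ships the per-subject cohort tables of 8 healthy
subjects and 11 non-communicating hydrocephalus patients verbatim, a
statistics layer that recomputes every published summary cell and
in-text claim from them, and a seeded synthetic-cohort generator so the
whole pipeline can be exercised without any external data.

## Worked example

Reproduce the published cohort statistics from the bundled tables:

```r
library(csfbc)

rep <- reproduce_claims()
rep
#> Cohort-table reproduction: all checks pass
#>   summary cells recomputed: 112 (all match: TRUE)
#>   claims: 20 total, 14 hard (14 pass), 5 discordant with the printed tables
```

The five "discordant" claims are the published Pearson correlations
(and the reductions derived from them): they cannot be recomputed from
the published per-subject rows — see `vignettes/methods.Rmd` — and the
package reports that honestly instead of matching them.

Simulate one patient under scheme C with a compliant wall:

```r
sub <- subject_record("patient_1", "patient")
bc  <- build_bc("C", "patient", shape = generate_waveform(seed = 1),
                amplitude = 1.5e-8)
sim <- simulate_csf(sub, bc, mode = "FSI")
glance(sim)
#> # A tibble: 1 × 10
#>   scheme mode  group      dt n_cycles peak_P_sas peak_P_ventricle
#>   <chr>  <chr> <chr>   <dbl>    <dbl>      <dbl>            <dbl>
#> 1 C      FSI   patient  0.01        5      2701.            2700.
#>   peak_Q_aqueduct cycle_periodicity max_mass_residual
#>             <dbl>             <dbl>             <dbl>
#> 1    0.0000000260       0.000000498          1.11e-13
```

`tidy(sim)` gives the long time series, `autoplot(sim)` the
pressure/flow panels, and `hydro_metrics(sim)` the one-row hydrodynamic
summary (both stroke-volume conventions, peak Reynolds number and
laminarity, peak/trough pressures with phases).

Run the full seeded pipeline on a synthetic cohort:

```r
pl <- run_pipeline(cohort_spec(n_healthy = 2, n_patients = 2, seed = 1),
                   schemes = "C", modes = "FSI")
dplyr::select(pl$metrics, subject_id, group,
              stroke_volume_oscillatory_ml, reynolds_max, peak_pressure_pa)
#> # A tibble: 4 × 5
#>   subject_id group   stroke_volume_oscillatory_ml reynolds_max peak_pressure_pa
#>   <chr>      <chr>                          <dbl>        <dbl>            <dbl>
#> 1 H_01       healthy                       0.0400         292.             509.
#> 2 H_02       healthy                       0.0400         280.             509.
#> 3 P_01       patient                       0.316         1467.            2737.
#> 4 P_02       patient                       0.316         1697.            2752.
```

Each subject's pulsatile amplitude is calibrated so the oscillatory
aqueductal stroke volume hits its group target (0.04 ml healthy,
0.316 ml patient, ratio ≈ 7.9), and every run stays laminar
(Re < 2000).

## Package layout

| Area | Entry points |
| --- | --- |
| Fixtures & I/O | `load_cohort_fixture()`, `load_printed_summary()`, `read_waveform()`, `load_config()` |
| Constitutive models | `material_model()`, `relaxation_modulus()`, `cavity_transmural_pressure()`, `fluid_properties()` |
| Boundary conditions | `build_bc()`, `bc_a_inlet_pressure()`, `superpose_flow()` |
| Solver | `subject_record()`, `simulate_csf()`, `run_mode_pair()`, `last_cycle()` |
| Analytic oracle | `womersley_velocity()`, `womersley_flow_amplitude()`, `peak_aqueduct_velocity()` |
| Metrics | `hydro_metrics()`, `stroke_volume()`, `reynolds()`, `peak_phase()`, `compare_runs()` |
| Statistics | `describe_values()`, `cohort_descriptives()`, `pearson_correlation()`, `anova_tukey()`, `t_test_pooled()`, `shapiro_wilk()` |
| Claims | `table_regression()`, `claims_report()`, `reproduce_claims()` |
| Synthetic cohort | `cohort_spec()`, `generate_waveform()`, `generate_cohort()`, `cohort_to_tables()` |
| Pipeline | `run_pipeline()`, `run_manifest()` |

All result objects are tibbles (or carry tibble series) with
`tidy()`/`glance()`/`autoplot()` methods.  See `vignettes/methods.Rmd`
for the model equations, parameter provenance, numerical choices and
the documented discrepancies in the source tables.
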