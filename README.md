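# rcindex

Analysis pipeline for biogeographic competition experiments: do introduced
plant provenances out-compete their native conspecifics when grown in live
soil microbiota from each range?

The package targets the design of a glasshouse test of the EICA
("evolution of increased competitive ability") hypothesis in *Trifolium*:
three species, an introduced provenance (NZ) and two native provenances
(SP, UK), grown singly and in introduced-vs-native pairs, in pots inoculated
with rhizosphere soil from five collection sites per country, two replicates
each. It is aimed at invasion ecologists and plant-soil-feedback researchers
who want the full statistical chain — and a matching synthetic-data
generator, since raw data for such studies are often not deposited.

## What it computes

1. **Design**: the factorial pot layout (`build_design()`,
   `comparison_cells()`), under two readings of the paired-pot scheme.
2. **Synthetic data** (`generate_dataset()`, `apply_mortality()`):
   plant-level growth rates from a log-normal mixed model with soil-site
   random intercepts, a nodulation covariate, early random mortality, and
   competition injected through the RCI identity `GR_A(B) = GR_A * (1 - RCI)`.
3. **Growth model** (`fit_growth_model()`): REML cell-means mixed model of
   log growth rates, no intercept, `log y = mu_cell + beta*nod + b_site + e`;
   `test_provenance_effect()` tests provenance differences (calibrated
   Wald F by default, ML likelihood-ratio test alongside).
4. **RCI inference** (`simulate_fixed_effects()`, `rci_from_draws()`,
   `summarize_rci()`, `rci_difference()`): the relative competition
   intensity `RCI_A(B) = (GR_A - GR_A(B)) / GR_A` with uncertainty
   propagated by 100,000 multivariate-normal draws of the fixed effects,
   summarised by means and 50%/95% quantile intervals; introduced-vs-native
   contrasts on common draws, significant when the 95% interval excludes 0.
5. **Comparison** (`build_comparison_table()`, `pearson_correlation()`):
   do growth-rate differences predict competitive-ability differences
   across the 12 species x soil x partner cells?

`run_pipeline()` chains all stages reproducibly from one master seed and
writes tidy CSVs plus a JSON manifest; `inst/cli/rcindex-cli.R` exposes
`design` / `simulate` / `run-all` subcommands.

## Worked example

```r
library(rcindex)

design <- build_design(design_config())            # 330 pots across 3 soils
params <- default_true_params(design, seed = 42L)  # stated generative world
res <- run_pipeline(run_config(params = params, S = 10000, seed = 42L))

sub <- res$records[res$records$species == "arvense" &
                   res$records$soil_country == "SP", ]
fit <- fit_growth_model(sub)
fit
#> Cell-means growth model (reml_mixed): arvense in SP soil, n = 39
#>              estimate         se
#> NZ         -3.8414181 0.18184292
#> NZ(SP)     -4.0940908 0.15695477
#> SP         -3.5668205 0.13848744
#> SP(NZ)     -3.9353856 0.15001275
#> nodulation  0.2369228 0.06429118
#> sigma_site = 0.0000, sigma_resid = 0.4066

test_provenance_effect(sub)
#> Provenance effect (arvense, SP soil): F(1,17) = 2.151, p = 0.1607

dr     <- simulate_fixed_effects(fit, S = 10000, seed = 99L)
rci_nz <- rci_from_draws(dr, fit, "NZ", "NZ(SP)")  # felt by introduced
rci_sp <- rci_from_draws(dr, fit, "SP", "SP(NZ)")  # felt by native
summarize_rci(rci_nz)
#> RCI NZ(SP) [arvense, SP soil]: mean 0.211, 50% CI (0.122, 0.315), 95% CI (-0.122, 0.461)
summarize_rci(rci_sp)
#> RCI SP(NZ) [arvense, SP soil]: mean 0.295, 50% CI (0.215, 0.390), 95% CI (-0.001, 0.521)

rci_difference(rci_nz, rci_sp)
#> RCI difference (arvense, SP soil, vs SP): -0.084, 95% CI (-0.483, 0.305)

res$correlation
#> Pearson's correlation = 0.04; P = 0.898; N = 12
```

Reading the numbers: the cell means are log growth rates (log g/day) at
nodulation score 0, so the introduced provenance grown alone averages
`exp(-3.84) = 0.021` g/day in Spanish soil. Competition with the native
provenance reduced its growth by an estimated 21% (`RCI_NZ(SP) = 0.211`);
the native provenance lost 30% against the introduced one. The difference
(-0.084, a slight edge to the introduced provenance) has a 95% interval
spanning zero: no significant difference in competitive ability. In this
simulated world all cells share the same true RCI (0.35) and the final
growth-vs-competitiveness correlation is, correctly, near zero.

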