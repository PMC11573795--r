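# mitostereo

Design-based stereology and localization analysis of mitochondrial
distribution in alveolar epithelial type 1 (AE1) cells.

AE1 cells form most of the air-blood barrier of the lung. Every organelle
in their thin cytoplasmic extensions thickens the barrier and impedes gas
exchange, so where a cell keeps its mitochondria — over the capillaries,
or over the connective tissue pillars between them — is a question of
structural design. `mitostereo` provides the quantitative toolkit for
answering it from thin microscopy sections:

* **Point-count stereology.** Nested coarse/fine test grids
  (`point_grid()`), systematic uniform random sampling of fields
  (`surs_fields()`), and the volume-fraction ratio estimators, e.g.
  V_V(sept/par) = P_sept / (P_sept + 6 · P_air) for a 6:1 nested grid and
  V_V(Mito/AE1) = P_mito / (16 · P_AE1) for a 16:1 grid. `cascade()`
  chains fractions down the reference volumes to absolute compartment
  volumes, V(X) = V_V(X/ref) · V(ref).
* **Index of relative localization (IRL).** Under random localization the
  expected profile count in compartment *c* is N_E,c = N_tot · P_c /
  P_tot; the IRL is N_0/N_E (≈1 random, >1 preferential, <1
  non-preferential), tested by the chi-squared statistic
  Σ (N_0 − N_E)²/N_E with k−1 degrees of freedom (`chi_squared()`).
* **Fluorescence colocalization.** Pearson coefficient with Costes
  automatic thresholding (orthogonal regression + threshold scan), the Van
  Steensel cross-correlation function over lateral shifts, the three-case
  classification (no / partial / colocalization) and Evans strength
  classes (`coloc_analysis()`).
* **Synthetic ground truth.** `generate_section()` builds labeled septum
  rasters with known area fractions and a configurable true IRL;
  `generate_two_channel_image()` builds channel pairs with known overlap
  or shift. Every estimator in the package is validated against these
  generators.

Results are tibbles; fitted objects support `tidy()`, `glance()` and
`autoplot()`.

## Worked example

The package bundles the pooled compartment counts from a stereological
study of three infant and three adult human lungs
(`ae1_profile_counts()`): test points P from a 25-point grid and observed
mitochondrial profile counts N_0 for the two AE1 compartments.

```r
library(mitostereo)
fit <- chi_squared(ae1_profile_counts("adult"))
fit
#> Index of relative localization / chi-squared test
#>  age_group  compartment    p n_0    n_e  irl     localization  chi2
#>      adult on_capillary 1306 859 924.39 0.93 non-preferential  4.63
#>      adult above_pillar  347 311 245.61 1.27     preferential 17.41
#> X-squared = 22.04, df = 1, p-value <0.001
```

Reading: 859 of 1170 adult mitochondrial profiles (73%) lie on top of
capillaries, but that compartment is also much larger (1306 of 1653 test
points). Relative to compartment size, adult mitochondria are *depleted*
over capillaries (IRL 0.93) and *enriched* above the pillars (IRL 1.27),
and the chi-squared test rejects random localization (22.04 at 1 df,
p < 0.001). The same analysis on the infant counts gives the opposite
pattern (IRL 1.27 / 0.60, statistic 191.52). `autoplot(fit)` draws the
observed-versus-expected bars.

A fully synthetic study — sections, SURS sampling, all three counting
passes, volume cascade and IRL test — runs from one config:

```r
subjects <- tibble::tibble(subject = c("S1", "S2"),
                           age_group = c("infant", "adult"),
                           v_par = c(115, 3285))
bundle <- run_study(study_config(subjects, seed = 1))
bundle$volumes      # per-subject V_V and absolute volumes
write_tables(bundle, "out/")
```

## Documentation

The methods vignette (`vignettes/mitostereo-methods.Rmd`) describes the
estimators, their assumptions, the synthetic-section generator and the
package's numerical choices in detail.
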