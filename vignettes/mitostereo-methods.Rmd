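---
title: "Methods: stereology and localization analysis of AE1 cell mitochondria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stereology and localization analysis of AE1 cell mitochondria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitostereo)
```

## The scientific problem

Alveolar epithelial type 1 (AE1) cells cover most of the gas-exchange
surface of the lung with extremely thin cytoplasmic sheets. Mitochondria
inside those sheets thicken the air-blood barrier, so their placement —
on top of capillaries, where diffusion happens, or above the connective
tissue pillars between capillary segments, where it matters less — is a
question about the structural design of the lung. On a single thin
section one sees only 2D *profiles* of mitochondria and cannot judge
placement by eye, because the two cytoplasmic compartments differ in
size. The package implements the quantitative chain that resolves this:
design-based stereology for compartment sizes and volumes, and a
compartment-size-corrected localization statistic for the profile counts.

## Point-count stereology

The primitive observation is a *test point* falling on a structure. For a
structure X inside a reference space ref, the volume fraction is
estimated by the point-count ratio

$$\hat V_V(X/\mathrm{ref}) = P_X / P_\mathrm{ref}.$$

When X is much sparser than ref, counting both on the same grid wastes
effort, so a *nested* grid is used: a fine lattice for the sparse phase
and a coarse sub-lattice (every a-th point in x, b-th in y) for the
abundant one, the coarse count scaled by the ratio a·b. The two designs
implemented by `vv_sept_par()` and `vv_mito_ae1()` are the 6:1 grid
(septa on 24 fine points, air on 4 coarse points per field, so
$P_{sept}/(P_{sept} + 6P_{air})$) and the 16:1 grid (mitochondria on 144
fine points, AE1 cells on 9 coarse points, so $P_{mito}/(16\,P_{AE1})$).
The nesting geometries `c(3, 2)` and `c(4, 4)` are the near-square
factorizations of those ratios. `total_volume()` and `cascade()` chain
the fractions down the reference volumes — parenchyma → septa → AE1
cells → mitochondria / sub-compartments — so each absolute volume is
`fraction × reference`. Counts are pooled over all fields of a subject
*before* ratio formation (ratio of sums), the standard stereological
estimator; per-field ratios would be noisy and biased.

Fields of view are placed by systematic uniform random sampling
(`surs_fields()`): a step lattice with one uniformly random start per
axis. The lattice conceptually extends over the whole plane and fields
protruding past the section edges are clipped, which is what gives every
location exactly the same inclusion probability `prod(fov/step)`. A field
spanning a full axis is pinned to it, since the offset is then
irrelevant. Pixels and coordinates use a lower-left origin with half-open
pixels `[i·s, (i+1)·s)`, making boundary classification unambiguous; a
test point on a pixel edge belongs to the upper pixel.

Profiles are counted exhaustively (no test system) under the Gundersen
forbidden-line rule: a profile centroid counts if it lies inside the
field and not on the left or bottom edge. Abutting fields therefore
count each profile exactly once, which the test suite verifies by tiling
a section.

## The index of relative localization

Two AE1 compartments are analysed: cytoplasm on top of capillaries and
cytoplasm above connective tissue pillars. Compartment size is estimated
with a 25-point grid per field (an independent 5×5 lattice; the package
accepts any `point_grid`). With pooled test points $P_c$ and observed
profile counts $N_{0,c}$, the expected count under random localization is

$$N_{E,c} = N_\mathrm{tot} \cdot P_c / P_\mathrm{tot},$$

and the index of relative localization is $\mathrm{IRL}_c =
N_{0,c}/N_{E,c}$: ≈1 random, >1 preferential, <1 non-preferential.
`classify_irl()` applies a descriptive band of half-width `tol = 0.05`
around 1 (configurable); significance comes from the chi-squared test,
not the band. The null hypothesis "observed and expected distributions
are equal" is tested with $\sum_c (N_{0,c}-N_{E,c})^2/N_{E,c}$ on $k-1$
degrees of freedom (`chi_squared()`, upper-tail p from `pchisq`). A
flag is raised when any $N_{E,c} < 5$, where the chi-squared
approximation is doubtful; compartments with $P_c = 0$ are an error, not
a silent zero.

Two conventions follow the compartment definitions of the analysis:
nucleus-hitting test points are excluded from the size estimator (the
above-pillar compartment is defined excluding the nucleus), while
profiles over the nucleus are pooled with the above-pillar count, because
a single thin section cannot distinguish a perinuclear mitochondrion from
one above a pillar. Consequently a section with a nucleus compartment is
*not* a null configuration even when all placement intensities are equal
— the pooled compartment receives profiles its size estimator does not
see. Calibration simulations therefore use nucleus-free configurations.
The publication-shaped table writer (`format_irl_table()`) reproduces the
convention of summing every column in the totals row; the summed IRL it
prints is a display artifact of that convention, not a statistic.

Statistical assumptions worth stating: the test treats the expected
counts as known, but $P_c$ is itself a point-count estimate. Its
sampling noise inflates the statistic by roughly a factor
$1 + N_\mathrm{tot}\,\mathrm{Var}(\hat p)/(p(1-p))$. The study design
keeps $P_\mathrm{tot}$ of the same order as $N_\mathrm{tot}$ or larger;
the package's type-I-error calibration uses a grid dense enough
($P_\mathrm{tot} \approx 100 \times$ the estimator noise floor) that this
term is negligible, and this is a validity condition any user of
`irl_pipeline()` should respect.

## The synthetic-section generator

`generate_section()` emulates the geometry the estimators need and
nothing more: a horizontal interalveolar-septum band with air above and
below, thin AE1 rims on both band surfaces, and an alternating
capillary/pillar stripe pattern (default period 10 µm, the scale of an
alveolar capillary segment) that divides the rim into the on-capillary,
above-pillar and nucleus compartments in the configured proportions. The
geometry is deterministic given the configuration, so empirical area
fractions match the configured ones to within pixel rounding (< 0.01
absolute at 1024² rasters, verified by test).

Mitochondrial profiles are placed per AE1 compartment as a Poisson draw
with mean `irl_c × mito_density_um2 × area_c`, uniformly over the
compartment's pixels, as discs of default radius 0.15 µm (profiles on
thin sections measure roughly 0.2–0.5 µm across; the size distribution is
not modelled — a single configurable radius is used). The configured
per-compartment IRL is therefore the exact ground truth of the
localization analysis, and the configuration validator requires the
area-weighted mean IRL over AE1 compartments to equal 1 so that the
overall density is preserved. `balance_irl()` solves the complementary
value. The default density 0.85 µm⁻² corresponds to a mitochondrial
volume fraction near 6 % of AE1 cytoplasm carried by 0.15 µm discs —
the regime reported for human lungs. Default area fractions (air 0.45,
septum 0.45, AE1 0.10 split 0.061/0.028/0.011) mirror a septum-rich
field with the AE1 sub-compartment proportions of the bundled study
table.

What the generator does **not** emulate: 3D geometry and anisotropy,
realistic capillary network topology, TEM texture and staining noise,
profile size variation, section compression. Passing tests show the
estimators are correct on sections whose ground truth is known; they do
not validate biological imaging artifacts.

One root seed drives everything; per-section and per-purpose streams are
derived by fixed offsets, so studies are reproducible bit for bit
(`run_study()` records the seed in its summary).

`generate_two_channel_image()` plays the same role for colocalization:
Gaussian spot fields with channel 2 either identical plus noise, shifted
along x (zero-padded crop — wrap-around would manufacture spurious
correlation), independent, or sharing half its spots.

## Colocalization statistics

`coloc_pearson()` is the sample correlation of pixel intensities (affine
invariant, mask-aware). `costes_threshold()` fits channel 2 against
channel 1 by orthogonal (total least squares) regression — the major
principal axis of the intensity covariance — then scans candidate
thresholds downward through the observed channel-1 intensities with
`t2 = a·t1 + b`, returning the largest `t1` whose below-both-thresholds
pixels correlate non-positively. Degenerate sub-populations (fewer than
two pixels, zero variance) are skipped during the scan; if the criterion
is never met the channel minima are returned and every pixel counts as
signal. The post-threshold coefficient is computed over pixels above
both thresholds. `van_steensel_ccf()` correlates channel 1 with channel
2 translated along x by each shift in `[-max_shift, max_shift]` over the
valid overlap (no wrap); `ccf(0)` equals the global Pearson coefficient
exactly. The three-case rule (`classify_coloc()`) resolves "(almost)
zero" peak shift as `|peak| ≤ eps_shift` with default 1 px, and the
Evans strength bands default to the conventional edges 0.2 / 0.4 / 0.6 /
0.8 with non-positive correlations labelled "no"; both are configuration,
surfaced as such, since no sharper convention exists for them.

## Numerical and testing choices

* Published-table comparisons use unrounded intermediate fractions;
  when recomputing printed totals from printed 3-dp fractions the
  admissible discrepancy is 0.5 % plus what rounding of the printed
  operands alone can produce (half an ulp of the fraction times the
  reference plus half an ulp of the printed total). Report writers round
  fractions to 3 decimals, volumes to 1 (mitochondrial volumes to 3),
  expected counts, IRL and chi-squared contributions to 2 — the print
  format of the study tables.
* The chi-squared implementation is cross-checked against
  `stats::chisq.test(x, p)` as an independent multinomial
  goodness-of-fit oracle on 2–5 compartment cases.
* Type-I calibration runs 1000 simulated nucleus-free sections of
  30 × 30 µm (0.2 µm pixels) with true IRL ≡ 1, ≈ 73 profiles and
  ≈ 7800 test points each, and checks the rejection rate at α = 0.05 and
  0.01 against binomial 95 % bounds. Parameter recovery runs 100
  sections of 60 × 60 µm in the adult-study regime (true IRL 0.93 /
  1.27, ≈ 1170 profiles) and requires the median estimated IRL within
  0.05 of truth. These problem sizes were chosen so each property is
  measured well inside its sampling noise.
* Unbiasedness of point counting is exact for point *fractions* against
  a fixed grid total; the nested-grid *ratio* estimators additionally
  carry an O(1/P) ratio bias, far below the sampling noise at study
  scale. The tests check the first at 2 SEM over 100 offsets and bound
  the second at 0.01 absolute, using a window that holds whole nesting
  cells (45 × 45 µm at 2.5 µm spacing) so the 6:1 correction factor is
  exact for every offset.
* Degenerate inputs error rather than return silent values: zero
  denominators in any ratio, compartments with no test points, constant
  channels in any correlation, empty subject rosters, malformed or
  unknown-compartment count tables.

## Limitations

The package analyses 2D sections; it does not reconstruct 3D cells,
estimate particle numbers (no disector/Euler methods), or model surface
areas and barrier thickness. The colocalization module computes Pearson,
Costes and Van Steensel statistics only — no Manders coefficients or Li
ICQ — and its synthetic images use additive Gaussian noise, not a
microscope PSF. Group comparisons are descriptive (pooled counts and
unweighted subject means); no random-effects modelling across subjects
is attempted.
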