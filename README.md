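# codaclan

Vocal clan delineation and movement-scale analysis for sperm whale
populations, from codas and photo-identification records.

Female sperm whales organise into stable social units nested inside
cultural groupings called **vocal clans**, which are recognisable by their
repertoires of **codas** — short stereotyped click trains. `codaclan`
implements the full analysis chain for studying this structure and the
spatial scale at which it operates:

* **Coda typing** — inter-click-interval (ICI) vectors, the 3–11-click and
  25-coda repertoire filters, and classification of codas into types with
  per-click-count mixtures of multivariate Gaussian components plus a
  shared broad contamination component, fitted by EM with BIC model
  selection (`classify_codas()`, `fit_type_model()`, `label_type()`).
* **Clan delineation** — per-(group, day) usage repertoires, Bhattacharyya
  acoustic similarity, average-linkage clustering, detection of *identity
  codas* (types used consistently by one set of repertoires, proportion ≥
  `u_min` in ≥ `prevalence_min` of a clan's repertoires and mean usage ≤
  `out_max` outside it), an exhaustive dendrogram-cut search accepting the
  deepest cut in which every cluster owns an exclusive identity type and
  that is reproduced by identity-weighted re-clustering, and a robustness
  parameter sweep (`build_repertoires()`, `delineate_clans()`,
  `sweep_parameters()`).
* **Catalogue handling** — photo quality filtering (Q ≥ 3), 2-hour
  association pairs, group delineation by graph components, and social
  units from associations in at least two distinct years
  (`filter_photo_quality()`, `associations()`, `delineate_groups()`,
  `delineate_units()`).
* **Movement scale** — windowed (1/3/6 h) vessel-track displacements; an
  effort-corrected maximum-likelihood estimator of RMS displacement across
  resighting time lags,
  `log L = Σ_pairs [ log E(cell(y)) + log φ₂(y − x; s²I) −
  log Σ_z E(z) φ₂(z_c − x; s²I) ]`, maximised over the per-axis sd `s`
  with RMS = `s√2`, plus individual-jackknife standard errors; per-clan
  kernel-density habitat grids; same-island resighting fractions; and
  order-of-magnitude scale comparisons against packaged Eastern Tropical
  Pacific reference constants (`window_displacement()`, `rms_ml()`,
  `jackknife_se()`, `kernel_density()`, `same_island_fraction()`,
  `compare_scales()`).
* **Synthetic data** — generators for clan-structured codas,
  island-resident diffusive movement and effort-biased photo-identification
  surveys, all with ground-truth manifests (`gen_codas()`, `gen_tracks()`,
  `gen_survey()`, `gen_all()`).

## Worked example

Generate a three-clan synthetic dataset, type its codas, and delineate the
clans:

```r
library(codaclan)

world <- gen_codas(n_groups_per_clan = c(6, 5, 4), days_per_group = 3,
                   coda_day_mean = 80, seed = 31)
cls  <- classify_codas(world$codas, k_max = 5, seed = 4)
reps <- build_repertoires(cls$assignments, world$codas)
clans <- delineate_clans(reps)
clans
#> Vocal clan assignment: 43 repertoires in 3 clan(s); 10 identity coda type(s)
#>
#> C1 C2 C3
#> 17 15 11
#> identity-weighted re-clustering agreement (ARI): 1.000
head(clans$identity_types[, c("clan_id", "type_id", "inside_usage", "outside_usage")], 4)
#>   clan_id type_id inside_usage outside_usage
#> 1      C1     4-2   0.07713789   0.012555835
#> 2      C1     5-3   0.56962589   0.006181361
#> 3      C1     7-1   0.07800106   0.006889363
#> 4      C2     5-1   0.27619997   0.007609742
```

The 43 repertoires (one per group-day with at least 25 codas) fall into
three clans; `C1` is dominated by one coda type at 57% of its usage (type
`5-3`, labelled `1+1+3`), and each clan owns its planted identity types
with near-zero usage outside — exactly the structure the generator
planted.

Movement scale from resighting histories of 40 diffusing individuals
(per-axis sd 10 km/day^0.5) under uniform effort:

```r
tr <- gen_tracks(n_individuals_per_clan = 40, n_days = 120, sigma_d = 10,
                 attraction = 0, switch_prob = 0,
                 clan_islands = list(ec1 = "Dominica"), seed = 8)
set.seed(9)
seen <- tr[runif(nrow(tr)) < 0.4, ]
sightings <- data.frame(individual_id = seen$individual_id, date = seen$date,
                        lat = seen$lat, lon = seen$lon)
eff <- uniform_effort(range(sightings$lat) + c(-0.5, 0.5),
                      range(sightings$lon) + c(-0.5, 0.5), 0.1)
jackknife_se(sightings, eff, lag_bins = c(1, 2, 5, 10, 30),
             max_pairs_per_bin = 300)
#> Effort-corrected RMS displacement by time lag:
#>  lag_lo lag_hi lag_mean_days n_pairs n_individuals rms_km jackknife_se_km
#>       1      2         2.000     300            40  20.89          0.5775
#>       2      5         3.997     300            40  29.35          1.0601
#>       5     10         8.013     300            40  40.55          1.4633
#>      10     30        19.927     300            40  61.15          2.0306
```

RMS displacement grows as the square root of the lag (the Brownian truth
here is `10·√(2τ)`: 20.0, 28.3, 40.0, 63.1 km at the four mean lags), and
the jackknife errors are a few percent of the estimates.

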