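# chinooklipid

Stock-specific lipid and energy-density analysis for Fraser River Chinook
salmon (*Oncorhynchus tshawytscha*), built around the calibration of a
handheld microwave fat meter to whole-body lipid content.

Chinook are the preferred prey of the endangered southern resident killer
whales (SRKWs), and their value as prey is set by their energy density, which
is driven almost entirely by lipid. Fraser River Chinook management units
(MUs) differ widely in migration difficulty and hence in the lipid they
accumulate at sea, so a fishery-side tool that reads lipid non-lethally —
the microwave fat meter — makes MU-resolved prey-quality monitoring
feasible. This package provides, for ecologists and fisheries scientists:

* the **fat-meter calibration**: continuous piecewise (segmented) regression
  with an estimated breakpoint, and model II (major-axis and standardized
  major-axis) regression, fitted across all meter-position combinations and
  ranked by adjusted R²;
* the **survey analysis**: applying a calibration to river-entry test-fishery
  records, MU summaries with run timing, ANOVA + Tukey HSD letter groupings,
  within-season lipid trends and their ANCOVA comparisons, hatchery–wild
  contrasts, and weekly CPUE aggregation;
* **migration-difficulty correlations** between MU mean lipid and elevation,
  distance, work and slope indices;
* **bioenergetics**: gonadal-investment energy, whole-body energy, and SRKW
  prey-requirement scenarios;
* a seeded **synthetic-data generator** emulating the 63-fish homogenization
  cohort and the ~1800-fish 2020 Albion test-fishery survey, so the entire
  pipeline runs reproducibly without field data.

## The model

The calibration maps a position-1 fat-meter reading \(x\) to whole-body lipid
content \(L\) (% wet weight) as a continuous two-segment line in hinge form,

```
L(x) = β₀ + β₁·x + δ·(x − ψ)₊
```

with published coefficients β₀ = −1.973, β₁ = 6.758, δ = −6.202 and
breakpoint ψ = 1.059 meter units; readings are floored at 0.6, the lowest
value the meter records in practice (≈ 2% lipid, near the lowest lipid level
a salmon can sustain). The slope above the breakpoint is β₁ + δ = 0.556.
Energy density is affine in lipid, `ED = a + b·L` (kcal/kg), with `(a, b)`
fitted by least squares to the five MU mean (lipid, ED) pairs; energies are
converted at 4.184 kJ/kcal. Gonadosomatic index (GSI) is gonad mass over
somatic mass, so a fish of total mass `m` carries gonad mass
`m·GSI/(1 + GSI)`.

## Worked example

```r
library(chinooklipid)

cal <- published_calibration()
predict_whole_body_lipid(c(0.6, 1.059, 10, 16.8), cal)
#> [1]  2.081800  5.183722 10.154918 13.935718
```

A reading at the 0.6 floor corresponds to ≈ 2.1% lipid; at the breakpoint the
two segments agree (5.18%); the flat upper segment carries the maximum
observed reading 16.8 to ≈ 13.9% lipid.

The full pipeline on the packaged synthetic defaults (calibration cohort +
survey simulated under one seed, published calibration applied, MU-table
energy conversion):

```r
res <- run_pipeline(pipeline_config(seed = 1))
res$mu_summary[, c("mu", "n", "lipid_mean", "ed_mean", "run_50pct")]
#>          mu   n lipid_mean ed_mean  run_50pct
#> 1 Spring5_2 289     12.828    1901 2020-07-01
#> 2 Spring4_2   9     12.168    1846 2020-05-23
#> 3 Summer5_2  72     12.899    1907 2020-07-30
#> 4 Summer4_1 966     10.880    1737 2020-08-22
#> 5   Fall4_1 473      7.364    1441 2020-09-22

res$anova$letters
#> Summer5_2 Spring5_2 Summer4_1   Fall4_1
#>       "A"       "A"       "B"       "C"
```

The letter display recovers the field result: the two early, far-migrating
MUs are indistinguishable and lipid-rich, Summer 4_1 intermediate, Fall 4_1
lowest. MU mean lipid correlates with migration difficulty (packaged
MU-level indices):

```r
res$correlations
#>       index pearson_r p_value n
#> 1 elevation     0.969 0.00651 5
#> 2  distance     0.826 0.08508 5
#> 3      work     0.802 0.10248 5
#> 4     slope     0.207 0.73859 5
```

and the prey-requirement scenarios (population energy anchored at 245,000
fish/year on the Spring 5_2 diet, 8 kg prey) show the fall diet costs about
a third more fish:

```r
res$scenarios
#>       label ed_kcal_kg prey_count
#> 1 Spring5_2       1901     245000
#> 2 Spring4_2       1846     252387
#> 3 Summer5_2       1907     244232
#> 4 Summer4_1       1737     268160
#> 5   Fall4_1       1441     323317
```

Bioenergetics worked values:

```r
gonad_energy_change(8, 0.1, 0.2)        # 4721 kJ of gonadal investment
conv <- table3_energy_conversion()
whole_body_energy(8, 8.4, conv) -
  whole_body_energy(8, 5.4, conv)       # ~8464 kJ seasonal energy drop
0.82 * conv$slope * conv$kj_per_kcal    # ~289 kJ/kg hatchery-wild ED gap
```

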