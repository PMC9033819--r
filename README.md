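# maeeq

Eco-environmental quality evaluation for coal-mining regions.

Intensive underground coal mining degrades arid-region ecosystems through
surface subsidence, water-table drawdown and vegetation loss. Planners and
mine designers need a defensible, quantitative map of eco-environmental
quality (EEQ), its spatial structure, and its drivers. `maeeq` implements
that workflow end to end for a stack of co-registered indicator rasters —
the 13-indicator system spanning geomorphology, climate, hydrology,
land/vegetation and human activity that has become standard for mining-area
assessments — and ships a synthetic scene generator with planted ground
truth so every stage is testable without proprietary data.

## The model

1. **Standardization.** Quantitative indicators are min-max standardized
   with a per-indicator polarity (X<sub>i</sub> = (x − min)/(max − min),
   reversed for indicators that degrade quality). Qualitative indicators
   get expert grades 1–5 which are then range-normalized.
2. **Weights by genetic projection pursuit.** The unit direction *c*
   (Σc² = 1) maximizing Q(c) = S(c)·D(c) — projection spread times
   within-window density, window radius R = 0.1·S(c) — is found by a
   real-coded, elitist genetic algorithm; the indicator weights are
   u<sub>j</sub> = c<sub>j</sub>², summing to 1.
3. **Index and grading.** MAEEQI = Σ u<sub>i</sub>·X<sub>i</sub> per cell,
   classified into five grades (worse → better) with exact Jenks natural
   breaks; per-region area/proportion reports follow.
4. **Spatial structure.** The index is aggregated to 500 m analysis units;
   global Moran's I (permutation-tested) measures overall clustering and
   local Moran's I with conditional permutation yields LISA clusters
   (H-H, L-L, H-L, L-H).
5. **Drivers.** The geographic detector quantifies each indicator's
   explanatory power q = 1 − SSW/SST over Jenks or categorical strata,
   classifies pairwise interactions (five types), and runs Welch t risk
   detection between strata.
6. **Zoning.** Significant L-L clusters → management area, H-H → close
   attention area, H-L/L-H → protective area.

## Worked example

```r
library(maeeq)

scene <- make_scene(scene_config(seed = 42))   # 100 x 200 cells, 100 m
res <- run_pipeline(scene$stack, scene$specs,
                    ga = ga_params(population_size = 60, elite_count = 15,
                                   max_generations = 40, stall_generations = 10),
                    regions = scene$regions, n_perm = 999, seed = 42)

res$pp
#> <pp_result> m = 13 indicators, best Q = 4.26603e+06 (S = 0.5027, D = 8.486e+06)
#>   weights: X1=0.000 X2=0.000 X3=0.000 X4=0.994 X5=0.002 X6=0.001 X7=0.000
#>   X8=0.000 X9=0.000 X10=0.000 X11=0.000 X12=0.002 X13=0.001
```

The projection pursuit concentrates weight on X4, the two-band landform
layer: a balanced binary indicator maximizes both the spread and the
density term of Q(c) on min-max standardized data (see the methods
vignette — supply `weights =` or a constant `R` if that is undesirable for
your stack). The rest of the pipeline:

```r
res$moran
#> <moran_result> I = 0.5094 (E[I] = -0.0013), z = 28.83, pseudo p = 0.001 (999 perms)
```

Quality clusters strongly in space (I = 0.51 against a null expectation of
−0.001, pseudo p = 0.001 with 999 permutations).

```r
dplyr::arrange(res$factors, dplyr::desc(q))
#> # A tibble: 13 × 4
#>   indicator     q p_value     L
#>   <chr>     <dbl>   <dbl> <int>
#> 1 X1        0.948   0.001     9
#> 2 X5        0.845   0.001     9
#> 3 X4        0.806   0.001     2
#> 4 X10       0.664   0.001     9
#> 5 X6        0.613   0.001     9
#> # i 8 more rows
```

Factor detection: elevation strata explain 94.8% of the index variance on
this scene (the synthetic layers are elevation-coupled), precipitation
84.5%, and so on; every q is significant at the 999-permutation test.

```r
res$zone_summary
#> # A tibble: 4 × 3
#>   zone            n_units area_km2
#>   <chr>             <int>    <dbl>
#> 1 management          147    36.8
#> 2 close_attention     155    38.8
#> 3 protective            7     1.75
#> 4 none                491   123.
```

147 of 800 analysis units (36.8 km²) fall in significant L-L clusters and
are zoned for intensive management; 155 H-H units get close attention;
7 spatial outliers are protective.

```r
grade_share(res$grade_report, 1:2, "mined area")
#> # A tibble: 1 × 4
#>   region     grades area_km2 proportion_pct
#>   <chr>      <chr>     <dbl>          <dbl>
#> 1 mined area 1+2        11.6           29.0
```

29% of the mined block sits in the two lowest quality grades under this
run's Jenks thresholds (`round(res$breaks, 3)` = 0.003, 0.004, 0.996,
0.998 — the X4-dominated index is nearly binary, another view of the
weight concentration above).

`autoplot(res$index)`, `autoplot(res$lisa)`, `plot_moran_scatter(res$lisa)`
and `plot_factor_q(res$factors)` draw the corresponding maps and charts.

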