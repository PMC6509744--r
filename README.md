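# vineyield

Unsupervised grape cluster detection and pre-harvest yield estimation from
high-resolution RGB images of the vine fruiting zone.

Manual pre-harvest yield estimation — walking the rows, counting and
weighing clusters on sample vines — is slow, destructive and
observer-dependent. `vineyield` implements an image-analysis alternative
aimed at oblique fruiting-zone photographs (≈ 2 mm/px ground sample
distance, as produced by a low-altitude camera platform): it detects ripe
clusters without any training data, measures their projected area, and
converts area to grams with a season-calibrated linear regression.

The detection chain:

1. **sRGB → CIELAB**, keeping the b\* (blue–yellow opponent) channel:
   green-yellow foliage has strongly positive b\*, brown soil mildly
   positive b\*, dark blue-purple berries low/negative b\*.
2. **Gaussian smoothing** (σ = 2 px) of b\*.
3. **Two sequential Otsu thresholds**: the first removes the
   above-threshold vegetation class; the histogram is rebuilt on the
   remaining pixels and a second threshold isolates the low-b\* cluster
   class. Otsu's split maximises the between-class variance
   σ²_B(t) = w₀w₁(μ₀ − μ₁)².
4. **Particle analysis**: 8-connected components, calibrated
   area/perimeter/circularity (4πA/P²), an inclusive 200 px area floor and
   a closed 0.25–1.00 circularity window.
5. **Double-cluster adjustment**: a particle larger than 1.5 × the median
   particle area is counted as two touching clusters.
6. **Yield regression**: OLS of measured yield (g) on total cluster area
   per vine (cm²), fitted in a calibration season and applied to a later
   one; validated with TPR, ripe-only TPR and percent accuracy.

The package also includes a ground-vs-UAV survey **cost calculator** and a
seeded **synthetic scene generator** with exact per-pixel ground truth, so
the full pipeline is testable without field imagery. See the methods
vignette (`vignettes/cluster-detection.Rmd`) for the model, parameter and
design details.

## Worked example

```r
library(vineyield)

## a synthetic best-condition scene (8 clusters, known ground truth)
sc  <- generate_scene(best_condition_preset(seed = 42))
sc
#> <vine_scene 280 x 420> 8 cluster(s), 4.5% cluster pixels

cfg <- pipeline_config(pixels_per_cm = 5)
det <- detect_clusters(sc, cfg)
det
#> <cluster_detection 'image'> 8 particle(s), adjusted 8, status ok

head(det$particles$particles[, c("id", "area_px", "area_cm2",
                                 "circularity", "counts_as")], 3)
#>   id area_px area_cm2 circularity counts_as
#> 1  1     399    15.96   1.0000000         1
#> 2  2     710    28.40   0.7112662         1
#> 3  3     668    26.72   1.0000000         1

## per-vine aggregation
aggregate_vine(det$particles, vine_id = "HV_01", zone = "HV",
               condition = "B")[, c("vine_id", "total_cluster_area_cm2",
                                    "detected_count", "adjusted_count")]
#>   vine_id total_cluster_area_cm2 detected_count adjusted_count
#> 1   HV_01                 170.76              8              8

## season transfer: fit on one season's vines, predict the next
train <- generate_vine_records(n_per_zone = 5, seed = 1)
apply <- generate_vine_records(n_per_zone = 8, seed = 2)
run_yield(train, apply, fit_meta = "season-1 pooled B")
#> <area_weight_model> yield[g] = 4.035 * area[cm^2] +12.96  (R^2 = 0.979, n = 10, season-1 pooled B)
#> Zone-mean accuracy:
#>   vigor_zone measured_yield_g estimated_yield_g accuracy_pct
#> 1         HV         702.0683          704.5496     99.64658
#> 2         LV         394.5658          414.2026     95.02319
```

The detection found all 8 clusters (adjusted count 8, status `ok`); the
vine carries ≈ 171 cm² of projected cluster area. The regression recovered
a slope near the generating 4 g/cm² and predicts the held-out season's
zone-mean yields with 95–99 % accuracy.

Evaluation metrics and the cost calculator are plain functions:

```r
tpr_ripe(5.2, 6.0, 0.8)       # detected vs ripe observed clusters -> 100
accuracy_pct(803.7, 682.7)    # measured vs estimated g/vine      -> 84.9
compare_modes(5)
#> Survey cost comparison at 5 ha
#> <ground, 5 ha> survey 2.1 h ($33.6) + elaboration 0.2 h ($3.2) = $36.8 (excl. equipment $36.8)
#> <uav, 5 ha> survey 0.2 h ($4.8) + elaboration 0.8 h ($16.0) + equipment $206.7 = $227.5 (excl. equipment $20.8)
#> UAV saves $16.0 (43.5%) excluding equipment; +1.3 h of work
```

A thin command-line front-end with `detect`, `yield`, `cost` and
`simulate` subcommands is installed at `inst/cli/vineyield.R`:

```sh
Rscript inst/cli/vineyield.R simulate --out scenes --n 3 --condition B
Rscript inst/cli/vineyield.R detect --out results --pixels-per-cm 5 scenes/*.png
Rscript inst/cli/vineyield.R cost --areas 5,10,50
```

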