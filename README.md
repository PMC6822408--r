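# paniclecount

Counting rice grains per panicle from images, for plant phenotyping and
breeding work where grain number per panicle (GN) is scored on hundreds of
panicles. A detached panicle is imaged on a dark background (flatbed
scanner or camera, branches spread or detached); grains touch and overlap,
so counting connected regions of the segmented image undercounts badly.
Instead of separating grains, `paniclecount` predicts the count from global
pixel-fraction features of the segmented branch mask with a linear model.

The pipeline:

1. **Preprocess** — Otsu segmentation of the grayscale image, removal of
   small noise components, and stem removal by morphological opening with a
   5 × 5 disk (structures thinner than the erosion depth — the 5–10 px stem
   — are erased while 30–50 px grains survive).
2. **Features** — three pixel fractions of the stem-free mask, each
   normalized by image area S\_im = H × W:
   coverage degree *CD* = N\_cd / S\_im, skeleton *Sk* = N\_sk / S\_im
   (Zhang–Suen thinning), contour *Co* = N\_co / S\_im (inner boundary),
   summed over primary branches, then min–max normalized with training-set
   extremes (*CD′*, *Sk′*, *Co′*).
3. **Model** — ordinary least squares
   GN = β₀ + β₁ · *CD′* (+ β₂ · *Sk′* + β₃ · *Co′*), predictions rounded
   half-away-from-zero. The univariate *CD′* model is the recommended
   default. `printed_models()` ships the eight published multivariate
   models (subspecies × device × shape), e.g. Indica, Scanner + Shape B:
   GN = 364.93 *CD′* + 0.70 *Sk′* − 3.90 *Co′* + 2.801.

A synthetic panicle generator (`render_panicle()`, `generate_dataset()`)
draws annotated images — elliptical grains on thin rachides over a
near-black background, with ground-truth masks and counts — so every stage
is testable without real image data. Naive baselines
(`count_components()`, `erosion_split_count()`) reproduce the
touching-grain failure the method avoids. See the vignette
`vignettes/grain-counting-methods.Rmd` for the full method description and
design rationale.

## Worked example

Fit and validate a counting model entirely on synthetic panicles:

```r
library(paniclecount)

ds <- generate_dataset(24, seed = 101, count_range = c(60, 220),
                       shape = "C", subspecies = "indica",
                       image_size = c(620, 877))
out <- run_pipeline(ds$panicles, ds$metadata$true_count, terms = "cd", seed = 2)
out$model
#> count_model: GN = 127.2 x CD' +64.86
#>   in-sample R2 = 0.9881, RMSE = 3.6696
out$report
#> eval_report (n=6): R2=0.9956 RMSE=3.0000 accuracy=98.24%
head(out$predictions, 4)
#>   image_id   gn_raw gn_count true_count
#> 1   img006 122.4427      122        118
#> 2   img008 188.5663      189        187
#> 3   img015 215.3740      215        218
#> 4   img017 154.3179      154        154
```

The fitted model maps normalized coverage to grain number (here a slope of
127.2 grains over the observed coverage range with intercept 64.9); on the
held-out images the rounded predictions land within a few grains of the
truth (RMSE 3.0), a mean per-image counting accuracy of 98.2%.

To count new images with the fitted model:

```r
preds <- count_images(new_images, out$model)   # paths, arrays or panicles
```

A command-line front end over the same functions is installed at
`inst/cli/paniclecount.R` with subcommands `simulate`, `preprocess`,
`extract`, `fit`, `predict`, `evaluate` and `baseline`, e.g.

```sh
Rscript inst/cli/paniclecount.R simulate --n 20 --shape C --seed 42 --out demo
Rscript inst/cli/paniclecount.R extract --images demo --out features.csv
Rscript inst/cli/paniclecount.R fit --features features.csv --counts demo/truth.csv --terms cd
```

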