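# camlink

Linking CNN saliency maps to breast lesion characteristics in ultrasound
images.

## The problem

Convolutional networks classify breast-ultrasound lesions as benign or
malignant with high accuracy, but a class label alone does not tell a
clinician *why*. Radiologists reason in terms of standardized lesion
descriptors — calcification flecks, echogenicity pattern, shape and margin.
camlink quantifies how much each of those domain-known cancer signs
contributed to a classifier's decision, by scoring class-activation heatmaps
over the image regions where the signs live, and it evaluates whether the
heatmaps are faithful to the model at all. The package is aimed at
researchers building explainable lesion classifiers: every stage runs on a
seeded synthetic lesion generator and a small trainable CNN, so the whole
framework is exercisable (and testable) without clinical data or pretrained
weights; any real classifier can be plugged in by implementing a four-method
backend contract.

## The methods

**EGrad-CAM** (entropy-gated Grad-CAM). For a class *c* with pre-softmax
score *S<sub>c</sub>* and designated-layer feature maps *f<sub>k</sub>(x,y)*,
each map gets a gradient weight

&nbsp;&nbsp;&nbsp;&nbsp;α<sub>k</sub><sup>c</sup> = Σ<sub>x,y</sub> ∂S<sub>c</sub>/∂f<sub>k</sub>(x,y)

and a Shannon entropy H<sub>k</sub> = −Σ<sub>n=0..255</sub> p<sub>n</sub> log₂ p<sub>n</sub>
computed after min–max quantization of the map to 256 levels. The heatmap is
the rectified weighted sum over the *entropy-kept* maps only,
M = ReLU(Σ<sub>k∈kept</sub> α<sub>k</sub><sup>c</sup> f<sub>k</sub>);
gating modes are `all` (classical Grad-CAM), `positive` (H > 0) and
`top_mass` (smallest entropy-descending prefix holding 95% of the total
entropy). The fraction of maps kept is reported as *feature-map usage*.

**Ablation-CAM.** Map *k*'s importance is the relative score drop when the
map is zeroed and the downstream network re-run:
β<sub>k</sub><sup>c</sup> = (S<sub>c</sub> − S<sub>c</sub><sup>k</sup>)/S<sub>c</sub>,
with heatmap M = ReLU(Σ<sub>k</sub> β<sub>k</sub><sup>c</sup> F<sub>k</sub>).

**Contribution statistics.** Heatmaps are bilinearly upsampled to input
resolution and min–max normalized to [0, 1]. For each characteristic region
R (calcification: 3×3 windows around annotated points; echogenicity: lesion
interior; shape/margin: a boundary ribbon 2% of the mean bounding-box side
on each side of the lesion contour), the significant ratio is
Rs = |{p ∈ R : Hs(p) ≥ 0.5}| / |R|. Ratios are averaged per prediction
outcome (TN/TP/FP/FN, malignant = positive) into AvRs and graded:
0 → No, (0, 0.2] → Very Low, (0.2, 0.35] → Low, (0.35, 0.5) → Medium,
≥ 0.5 → High.

**Faithfulness.** An explanation map keeps the top 80% of heatmap-ranked
pixels (weighted by their scores) and multiplies them into the image.
Comparing model confidence Y on the original with confidence O on the
explanation map gives Average Drop % = mean(max(0, (Y−O)/Y))·100, Percent
Increase = %{Y < O}, and a head-to-head win% between two methods over
positive drops.

## Worked example

```r
library(camlink)
library(dplyr)

# 120 synthetic lesions, cropped to the lesion RoI (+8% margin) at 32x32
train <- prepare_dataset(generate_dataset(120, seed = 2), size = 32)
fit   <- train_backend(build_tiny_cnn(seed = 2), train, epochs = 30, seed = 2)
glance(fit)
#> # A tibble: 1 × 4
#>       n accuracy   tnr   tpr
#>   <int>    <dbl> <dbl> <dbl>
#> 1   120    0.908 0.933 0.883

analysis <- prepare_dataset(generate_dataset(60, seed = 3), size = 32)
report <- run_contribution_analysis(analysis, fit$backend,
                                    method = "egrad_cam", gate = "top_mass")
tidy(report) |> filter(outcome == "TP")
#> # A tibble: 7 × 7
#>   characteristic level       outcome n_cases avg_ratio category featuremap_usage
#>   <chr>          <chr>       <chr>     <int>     <dbl> <ord>               <dbl>
#> 1 calcification  present     TP           20   0.00556 Very Low            0.762
#> 2 echogenicity   non_uniform TP           22   0.190   Very Low            0.75
#> 3 echogenicity   uniform     TP            3   0.215   Low                 0.833
#> 4 margin         circumscri… TP            7   0.393   Medium              0.786
#> 5 margin         not_circum… TP           18   0.390   Medium              0.75
#> 6 shape          irregular   TP           20   0.377   Medium              0.762
#> 7 shape          regular     TP            5   0.443   Medium              0.75

faith <- evaluate_faithfulness(analysis[1:20, ], fit$backend)
tidy(faith)
#> # A tibble: 2 × 5
#>   method           n average_drop percent_increase win_percent
#>   <chr>        <int>        <dbl>            <dbl>       <dbl>
#> 1 egrad_cam       20         50.0               50          35
#> 2 ablation_cam    20         50.0               50          15
```

Reading the report: for correctly classified malignant lesions (TP) this
tiny CNN leans on the boundary ribbon (shape/margin graded Medium,
AvRs ≈ 0.38–0.44) far more than on the calcification flecks (AvRs ≈ 0.006,
Very Low), and under top-95% entropy gating about 75–83% of its feature maps
carry the decision. `autoplot(report)` draws the category grid,
`plot_overlay(image, heatmap, annotation)` a heatmap overlay with the lesion
boundary and calcification marks.

## A command-line interface

A thin Rscript front end covers the shell workflow:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/camlink.R", package = "camlink"))')
Rscript $CLI simulate --n 200 --out data/ --size 128 --seed 7
Rscript $CLI train    --data data/ --out model.rds --input 32 --epochs 30
Rscript $CLI contrib  --data data/ --model model.rds --out report.csv
Rscript $CLI evaluate --data data/ --model model.rds --out metrics.csv
```
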