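# hepaquant

Automatic quantification of hepatocyte nuclei in RGB images of
BrdU-stained rat liver sections, for studies of liver regeneration after
partial hepatectomy. Given a region of interest cropped from a digitized
section, the package counts all hepatocyte nuclei (dark in the red
channel), counts the proliferating ones (dark in the blue channel), and
reports the BrdU labeling index

    BrdU-LI = n_proliferating / n_total ,

the standard proliferation readout. It is written for the people who
would otherwise count those nuclei by hand: experimental hepatology
groups processing whole batches of section images unattended.

## The method

Each channel runs through the pipeline

1. **Bilateral smoothing** — edge-preserving denoising; a direct
   three-pass chain and a fast bilateral-grid approximation
   (σ_s = 16, σ_r = 0.15 for red; σ_s = 50, σ_r = 0.10 for blue, where
   the strong smoothing suppresses non-proliferating nuclei).
2. **EM histogram thresholding** — pixel intensities are modelled as a
   2- or 3-class univariate Gaussian mixture *p(y) = Σ_c π_c
   N(y; μ_c, σ_c)* fitted by expectation-maximization on the 256-bin
   histogram (accuracy 10⁻⁴ on the log-likelihood); class boundaries
   are the intersections of the weighted densities. Three classes
   (nucleus / background / vein) are used when the filename carries a
   `PT`/`CV` token, the convention marking images from the vascular
   liver zones. Otsu and three-class Otsu are included as baselines.
3. **Connected-component shape filtering** — erode, fill holes,
   8-connected labeling, then keep components with area A ∈ [700, 8000]
   px, equivalent diameter d_eq = √(4A/π) ∈ [35, 200] px, dilate, and
   require form factor F = 4πA/P² ≥ 0.2.
4. **Vein exclusion** — the brightest threshold class becomes an
   exclusion mask: hole-filled when it is one connected component,
   smoothed back together first when blood has fragmented it. The mask
   is subtracted from the red-channel candidates and excluded from the
   blue-channel histogram.
5. **Circle Hough transform** — overlapping nuclei are counted as
   circles with radii r ∈ [14, 50] px: compact normal-directed voting,
   accumulator smoothing (σ = 10), relevance-threshold stopping
   (0.5 of the first maximum), and a closeness post-filter
   (dist(c₁,c₂) < F_cl·(r₁+r₂), F_cl = 0.5 / 0.75 per channel).

A validation toolkit scores detections against expert point ground
truth (sensitivity TP/(TP+FN), false positive fraction FP/Detected,
ROC-like parameter sweeps, inter-observer relative standard deviation),
and a seeded synthetic generator produces ground-truthed images for
every pipeline branch, so the whole system is testable without slide
data.

## Worked example

```r
library(hepaquant)

# a synthetic stained section: 60 nuclei, 12 of them proliferating
s <- synth_generate(synth_params(seed = 7))
r <- process_image(s$roi, default_config())
r
#> <image_result> synth-s7 [ok]: total = 60, proliferating = 12, BrdU-LI = 0.200

# score against the generator's ground truth
gt <- s$ground_truth
m <- match_points(r$circles_total, gt[gt$class == "total", ])
detection_metrics(m, r$n_total)$sensitivity
#> [1] 1
```

`n_total = 60` and `n_proliferating = 12` are the planted counts; the
labeling index 12/60 = 0.200 is exactly the planted proliferation
fraction, and every detected circle covers exactly one planted nucleus
(sensitivity 1, no false positives on this clean field). On real
sections the published working point of this method family is ~93%
sensitivity for total and ~91% for proliferating nuclei at a mean false
positive fraction below 15%.

Batch processing and the command-line front end:

```sh
Rscript inst/cli/hepaquant.R run --config cfg.yaml --out results.csv IMG1.tif IMG2.tif
Rscript inst/cli/hepaquant.R synth --preset vein_fragmented --seed 7 --out demo/
Rscript inst/cli/hepaquant.R validate --gt demo/synth-s7-CV1-gt.csv --pred circles.csv
```

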