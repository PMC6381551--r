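# nodtex

CT radiomic features are not portable across scan protocols: the same
lung nodule imaged with a different slice thickness, tube current (mAs)
or reconstruction kernel yields different histogram and texture values.
`nodtex` quantifies that effect on a fully simulated phantom study. It
is written for image-analysis researchers who need a reproducible,
download-free testbed for scan-parameter sensitivity of radiomic
pipelines.

The package simulates spherical nodule phantoms — 10 and 12 mm
diameters at +100 HU (solid) and −630 HU (ground-glass) — in a
lung-like background, renders them under every cell of a 3 × 2 × 2
factorial design (slice thickness 1.25/2.5/5.0 mm × 30/120 mAs ×
lung/standard kernel, ten repeat scans per cell with nodule
relocation), segments each nodule by seeded region growing, extracts
twenty 3D features, and fits dummy-coded regressions with effect-size
summaries.

## The features and the model

Voxels are quantized from the 4096-level HU window to G = 256 gray
levels, g = ⌊(HU + 1024)/16⌋. Per nodule:

* **Histogram (7):** mean, SD, variance, skewness, excess kurtosis of
  the quantized voxel values; energy Σᵢ pᵢ² and Shannon entropy
  −Σᵢ pᵢ log₂ pᵢ of the 256-bin histogram.
* **GLCM (8):** from the gray-level co-occurrence matrix P(i, j) at
  distance 1 — contrast ΣΣ P(i−j)², dissimilarity ΣΣ P|i−j|,
  homogeneity ΣΣ P/(1+(i−j)²), ASM ΣΣ P², energy √ASM, max
  probability, entropy −ΣΣ P log₂ P, correlation
  ΣΣ P(i−μᵢ)(j−μⱼ)/(σᵢσⱼ).
* **GLRLM (5):** from the gray-level run-length matrix — long-run
  emphasis ΣΣ j²P, gray-level and run-length nonuniformity, low/high
  gray-level run emphasis (1-based gray weighting).

Matrix features are computed in each of the 13 unique 3D directions of
the 26-neighbourhood and averaged. Scan-parameter effects are estimated
per feature by ordinary least squares on min–max-scaled values,

y = β₀ + β₁·[T=2.5] + β₂·[T=1.25] + β₃·[mAs=120] + β₄·[kernel=standard] + ε,

with reference levels 5.0 mm / 30 mAs / lung kernel; pairwise contrasts
(e.g. 2.5 vs 1.25 mm = β₂ − β₁), |RC| max/median/min summaries, and
Cohen's d = |m_A − m_B| / s_pooled classified small/medium/large at
0.20/0.50/0.80.

## Worked example

```r
library(nodtex)

## the canonical toy-grid counts
roi <- asQuantizedROI(workedExampleGrid())
computeGLCM(roi, c(1, 0, 0))[2, 2]    # 2  (gray pair (1,1) at 0 degrees)
computeGLRLM(roi, c(1, 0, 0))[3, 2]   # 1  (one run of gray 2, length 2)

## |RC| summaries of the bundled reference coefficient columns
rcSummary(publishedCoefficients("100")$thickness_2.5)
#>    max median    min
#>  0.541  0.388  0.011
rcSummary(publishedCoefficients("100")$thickness_1.25)
#>    max median    min
#>  0.672  0.574  0.135

## a one-repetition smoke study (48 nodule observations)
res <- runStudy(tempfile("study"), repetitions = 1, masterSeed = 7)
res$analysis[["100"]]
#> Parameter-effect analysis (one density stratum)
#>   50 of 100 (feature, contrast) sets significant at p <= 0.05
#>                 contrast   max_abs median_abs    min_abs
#>     thickness_5.0_vs_2.5 0.4431970  0.1616726 0.01310463
#>    thickness_5.0_vs_1.25 0.5110643  0.1405924 0.01306730
#>    thickness_2.5_vs_1.25 0.2123378  0.1016638 0.03387094
#>            mas_30_vs_120 0.3504798  0.1786244 0.05895283
#>  kernel_lung_vs_standard 0.4207433  0.2682878 0.01492867
```

The |RC| columns say how strongly each scan-parameter change moves a
normalized feature; the tally counts how many of the 100 (feature,
contrast) comparisons per density stratum reach p ≤ 0.05. With the full
ten repetitions the tallies rise to ~85–90 of 100.

A thin CLI wrapping the same functions lives at `inst/cli/nodtex.R`
(`run-all`, `simulate`, `segment`, `extract`, `analyze`,
`make-fixtures`).

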