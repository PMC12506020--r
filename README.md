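# rodmap

Quantitative image analysis of subcellular organization in rod-shaped
bacteria.

In cyanobacteria and other rods, carboxysomes (Rubisco-filled CO2-fixing
microcompartments) are held evenly spaced along the cell by a two-protein
system: a ParA-family ATPase (McdA) that oscillates over the nucleoid and a
partner (McdB) on the carboxysome surface. How well that positioning works
depends on the state of the nucleoid itself. `rodmap` implements the
measurement chain needed to study this quantitatively from multi-channel
fluorescence time lapses, together with a synthetic-scene generator that
provides ground truth for every stage, so the whole pipeline is testable
without any proprietary data.

## What it computes

For cells segmented from phase contrast (any segmentation backend; the
package post-processes masks and computes a pole-to-pole midline):

| Quantity | Definition |
|---|---|
| Focus detections | unsharp mask -> blur -> Laplacian of Gaussian at sigma = d/(2 sqrt 2), local maxima above a quality threshold; intensity = sum of raw pixels within radius 2r of the detection |
| Confinement radius | mean distance of a track's first ten localizations from their centroid (tracks from gated linear-assignment linking with gap closing: gates 7.5 / 4.5 px, max frame gap 2) |
| Nucleoid compaction | s_comp = 1 - A_nuc / A_cell, with the nucleoid delimited by Yen's threshold after subtracting the rim-fitted cytoplasmic background and blurring (sigma 66 nm) |
| Oscillation score | fraction of per-cell min-max-normalized pixels with I_n < 0.5; high for polarized or pole-to-pole oscillating distributions, ~0.5 for diffuse |
| Kymographs | band-averaged intensity along the midline (11 px width), each time column min-max normalized |
| Density maps | localizations mapped to (r_rel, l_rel, phi) cell-frame coordinates, binned with per-cell bin areas, fourfold symmetrized, reported as probability density in um^-2 with sum(density x area) = n_cells |
| Colocalization | per-cell (masked) or per-field Pearson correlation of two channels |

Registration (integer cross-correlation to frame 0, phase-channel shifts
applied to all channels), ROUT outlier removal, and per-replicate
median/IQR summaries round out the pipeline.

## Worked example

```r
library(rodmap)

scene <- simulateScene(nCells = 4, nFrames = 10, fociPerCell = 2,
                       areaFraction = 0.5, mcdaMode = "polar_gradient",
                       confinementRadiusUm = 0.15, seed = 42)
res <- runExperiment(scene = scene)
res$cellMetrics[, c("cell_id", "focus_count", "s_comp",
                    "oscillation_score", "confinement_um")]
#>   cell_id focus_count s_comp oscillation_score confinement_um
#> 1       1           2  0.495             0.883         0.0576
#> 2       2           2  0.499             0.886         0.0551
#> 3       3           2  0.491             0.883         0.0633
#> 4       4           2  0.479             0.870         0.0761
```

Both planted foci are found in every cell. The compaction score recovers
the simulated nucleoid area fraction (0.5 -> s_comp ~ 0.49). The polar
oscillating protein pattern scores ~0.88 (a diffuse pattern scores ~0.5),
and the per-cell median confinement radius (~0.06 um here) sits below the
simulated 0.15 um confinement boundary, as a first-ten-localizations
centroid statistic should for a confined walk.

```r
summarizeReplicates(res$cellMetrics, metrics = c("s_comp", "oscillation_score"))
#>   condition replicate            metric n n_removed median   q25   q75  mean      sd
#> 1      cond         1            s_comp 4         0  0.493 0.488 0.496 0.491 0.00852
#> 2      cond         1 oscillation_score 4         0  0.883 0.880 0.884 0.881 0.00733
```

Each stage is also exported on its own (`segmentCells()`,
`cellMorphology()`, `detectFoci()`, `linkTracks()`, `confinementRadius()`,
`nucleoidMorphology()`, `oscillationScore()`, `kymograph()`,
`binLocalizations()`, `densityMap()`, `pearsonPerCell()`,
`registerStack()`, `readStack()`/`writeStack()`), so partial pipelines
and real data are first-class. See the methods vignette
(`vignettes/rodmap-methods.Rmd`) for the models, parameter meanings, and
known limitations.

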