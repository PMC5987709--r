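# perihalo

Quantitation toolkit for experiments on **perilymphatic exosome halos
and directed immune-cell migration**. Inflamed lymphatic endothelium
releases exosome-rich vesicle fractions that accumulate around lymphatic
vessels and change how dendritic cells navigate: more dynamic
protrusions, lower speed, more frequent turning, better directionality
along chemotactic gradients. Testing such claims takes a battery of
quantitative readouts, and perihalo implements all of them as one
coherent, scriptable R package:

* **Cell-track statistics** — track length, displacement, chemotactic
  displacement (upgradient displacement / track length), chemotactic
  index (cos Θ to the gradient), speed, migratory angle change; rose
  plots, displacement filters (24.1 µm collagen-assay convention) and
  Welch group comparisons.
* **Morphometry** — circularity `4πA/P²` of contour polygons.
* **Halo quantitation** — per-channel fluorescence band width σ from
  cross-sectional line profiles and the marker/vessel diameter ratio
  (e.g. σ_CD9 / σ_podoplanin).
* **TMT proteomics** — 6-plex reporter normalization (median
  equalization + concentration scaling), Top3 interprotein abundance,
  ratio/significance calls (Welch + peptide-level one-sample test with
  BH adjustment), ratio-density and heat-map matrices, GMT cluster
  enrichment.
* **Assay statistics** — point-to-vessel minimum distances with a
  CSR-normalized density statistic, the 3-s microfluidic adhesion rule,
  transwell standard-curve calibration and kinetics, NTA replicate
  histogram averaging, membrane pore coverage.
* **Synthetic generators** for every input class (biased persistent
  random walks with a protrusion parameter, spiked peptide tables,
  Gaussian-band profiles, vessel fields, size histograms, star contours,
  transwell kinetics) — seeded, with retrievable ground truth, so the
  whole pipeline is testable without any external data.

See `vignettes/perihalo-methods.Rmd` for the models, parameter choices
and limitations.

## Worked example

```r
library(perihalo)

# 300 cells, 40 one-minute steps, gradient along +x, protrusive phenotype
tk <- simulate_tracks(n_cells = 300, n_steps = 40, bias = 1.5,
                      protrusion = 1, seed = 7)
m <- track_metrics(tk, gradient_frame(1, 0))
round(colMeans(m[, .(chemotactic_index, chemotactic_displacement,
                     speed, mean_angle_change)], na.rm = TRUE), 3)
#>        chemotactic_index chemotactic_displacement
#>                    0.953                    0.376
#>                    speed        mean_angle_change
#>                    2.000                   77.007
```

The simulated cells move straight up the gradient on net (chemotactic
index near 1) while converting only ~38% of their path into upgradient
progress — protrusion = 1 halves the speed (base 4 → 2.000 µm/min) and
drives the large 77° mean turn angle, the speed-for-navigation trade the
generator encodes.

```r
# perivascular halo: marker band twice as wide as the vessel band
p <- simulate_profile(c(CD9 = 18, podoplanin = 9))
r <- diameter_ratio(p, "CD9", "podoplanin")
r$sigma_per_channel; r$ratio
#>        CD9 podoplanin
#>       19.6       10.0
#> [1] 1.96
```

```r
# spiked 6-plex proteomics: 25 of 500 proteins up 2^1.5-fold
fc <- rep(0, 500); fc[1:25] <- 1.5
sim  <- simulate_peptide_table(500, log2_fold_changes = fc,
                               peptide_cv = 0.15, seed = 11)
norm <- normalize_channels(sim$table, sim$meta)
q <- ratios_and_significance(top3(norm), norm, sim$meta,
                             treated = "TNFa", reference = "ss")
sum(q$significant)
#> [1] 18
mean(log2(q$ratio[match(sprintf("P%05d", 1:25), q$protein_id)]))
#> [1] 1.42   # vs spiked truth 1.5

pore_coverage(3, 8e5)   # 3-µm pores, 8e5 pores/cm^2
#> [1] 5.654867          # the printed "5.7%"
```

Only spiked proteins reach significance (18 of the 25 designed, none of
the 475 nulls at this noise level), and their mean estimated log2 fold
change recovers the spike within the noise.

## Command line

```sh
inst/exec/perihalo simulate --design design.json --out sim/
inst/exec/perihalo tracks --path sim/tracks.csv --out res/ \
    --gradient-dx 1 --gradient-dy 0 --min-displacement 24.1
inst/exec/perihalo run --config pipeline.json --out res/
inst/exec/perihalo pore-coverage --diameter-um 3 --density-per-cm2 8e5
```

`run` executes any subset of stages from one JSON config and writes a
`report.json` recording every parameter and every implicitly applied
default.

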