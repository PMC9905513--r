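# artefactscan

Image-based condition-survey tools for paintings, written for conservators
and conservation scientists who need **minimally invasive** answers to two
questions:

1. *Where should we swab?* Large ultraviolet-fluorescence (UVF) photographs
   of a painting show fluorescing patterns where fungi and bacteria colonize
   the paint. Given a small reference crop of such a pattern (a *template*),
   `artefactscan` locates every similar-looking window of the full
   photograph, groups the hits into candidate sampling areas, maps them onto
   the survey grid used to label physical sampling spots (e.g. `63C3`:
   cell 63, subcolumn C, subrow 3), and scores how efficient the guidance
   was once microbiology results come back.
2. *How are the pigment crystals arranged?* Cross-sections of paint are
   photographed under the microscope as overlapping tile mosaics.
   `artefactscan` segments pigment crystals by colour (ultramarine blue,
   chrome yellow, vermilion red by default), removes crystals re-observed in
   overlapping tiles, and reports same-/cross-colour inter-crystal distance
   statistics and densities — the microscopic arrangement behind the
   painting's apparent colour.

Light companions summarize environmental-station logs (diurnal extrema by
clock hour) and convert volumetric spore counts to spores/m³. Seeded
generators produce every input with machine-readable ground truth, so the
whole toolkit is testable without museum photographs.

## The statistic at the core

Template matching uses the normalized correlation coefficient. For a
grayscale template $R$ ($m \times n$, mean $\bar R$) slid over every
same-size window of the scene $I$ ($M \times N$), the score map
$C$ ($(M-m+1) \times (N-n+1)$) is

$$C(r,s) = \frac{\sum_{i,j}\bigl(I(i+r,j+s) - \bar I_{rs}\bigr)\bigl(R(i,j) - \bar R\bigr)}
                {\sqrt{\sum_{i,j}\bigl(I(i+r,j+s)-\bar I_{rs}\bigr)^2\;\sum_{i,j}\bigl(R(i,j)-\bar R\bigr)^2}}$$

with $\bar I_{rs}$ the mean of the window at $(r,s)$. Scores lie in
$[-1, +1]$; $+1$ is an exact (affine-intensity-equivalent) match, which
makes the method robust to the uneven lighting of large-format UVF
panoramas. Pixels above a threshold are grouped into 8-connected detected
areas; the working threshold is chosen where lowering it makes the count
jump drastically (about six-fold in the motivating survey, just below the
0.65–0.70 range).

Crystal arrangement is summarized by nearest-neighbour distances between
crystal centroids (µm), restricted to each crystal's own tile plus the four
edge-adjacent tiles; for a Poisson field of intensity $\lambda$ the mean
nearest-neighbour distance approaches $1/(2\sqrt\lambda)$, a useful sanity
scale.

## Worked example

```r
library(artefactscan)

## --- biodeterioration mapping on a synthetic UVF scene -------------------
t1 <- make_template(101, c(123, 156))     # survey template resolutions
t2 <- make_template(102, c(83, 95))
sc <- make_scene(103, size = c(1024, 1024),
                 templates = list(bacillus_like = t1, penicillium_like = t2),
                 k_plants = c(9, 9), noise_sd = 8, contrast_jitter = c(0.9, 1.1))
ds <- run_detection(sc$scene, list(bacillus_like = t1, penicillium_like = t2),
                    threshold = 0.675)    # midpoint of the useful 0.65-0.70 range
nrow(ds)
#> [1] 18
head(as.data.frame(ds), 2)
#>     template_id anchor_row anchor_col height width     score grid_label
#> 1 bacillus_like         88        332    123   156 0.9766516       15A2
#> 2 bacillus_like        112         55    123   156 0.9788354       12B3
efficiency(18, 2)   # 18 detected areas, 2 sampled positive
#> Sampling efficiency: 11% (11.11% unrounded; 2 positive / 18 detected)
```

All 18 planted deterioration patterns are recovered despite pixel noise and
±10 % contrast jitter; each row names the sampling-grid spot to swab.

```r
## --- pigment arrangement on a synthetic crystal mosaic -------------------
mo  <- make_mosaic(105, layout = c(2, 2), tile_px = c(400, 400), scale = 2,
                   densities = c(blue = 0.01), min_sep_um = 4)
res <- mosaic_crystals(mo$mosaic)         # classify + segment + dedup
res$common_area_index
#> [1] 0.15
pair_distances(res$crystals, "blue")
#> <distance_pair_stats blue-blue (nearest): n = 1369, mean 6.2 um, sd 1.7 um>
crystal_density(res$crystals, "blue", 136900)
#> <density_report blue: 1369 crystals / 136900 um^2 = 0.01 per um^2>
```

The planted density 0.01 crystals/µm² (≈ 20 crystals per 2000 µm², the
ultramarine packing of the motivating sample) is recovered exactly after
overlap deduplication.

```r
## --- environment summaries -----------------------------------------------
summarize_log(make_station_log(106, days = 14, step_min = 5)$log)
#> <station_summary: 4032 records over 335.9 h>
#>   temperature_c mean    23.50  diurnal max 15:00, min 3:00
#>   rh_pct        mean    72.70  diurnal max 3:00, min 15:00
#>   co2_ppm       mean   569.96  diurnal max 15:00, min 3:00
#>   light         mean   120.00  diurnal max 12:00, min 0:00
spore_concentration(150, flow_lpm = 10, duration_min = 15)
#> [1] 1000
```

## Command line

```sh
exec/artefactscan detect --scene scene.png --template t1.png --template t2.png \
    --threshold 0.675 --grid 10x10 --out report.csv --overlay overlay.png
exec/artefactscan sweep --scene scene.png --template t1.png --lo 0.40 --hi 0.95 --step 0.01
exec/artefactscan crystals --mosaic-dir tiles/ --pair blue,blue --out stats.json --hist hist.csv
exec/artefactscan synth scene --seed 1 --out fixtures/
```

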