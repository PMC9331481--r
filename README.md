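# retinaflim

Phasor-based metabolic FLIM analysis of retina cross-sections, with a
built-in synthetic retina so the whole pipeline is testable end to end.

## The problem

Multiphoton fluorescence lifetime imaging (FLIM) of retina sections
distinguishes free NAD(P)H (short lifetime, τ ≈ 0.4 ns — glycolysis)
from protein-bound NAD(P)H (long lifetime — oxidative phosphorylation)
in the 425–475 nm emission band, plus FAD (502–577 nm, free τ ≈ 2.6 ns),
melanin and hemoglobin (600–650 nm) and collagen second harmonic
generation (SHG, effectively instantaneous). `retinaflim` is for
researchers who want to turn per-pixel photon-arrival histograms (TCSPC
decay cubes) into per-region bound-NAD(P)H percentages and
phasor-position structural masks, reproducibly and outside any vendor
GUI.

## The method

Each pixel's decay is summarised by its first-harmonic phasor

    g = Σ I(t) cos(ωt) / Σ I(t),   s = Σ I(t) sin(ωt) / Σ I(t),
    ω = 2π / T,

so that a mono-exponential lifetime τ sits on the universal circle at
g = 1/(1+(ωτ)²), s = ωτ/(1+(ωτ)²), and mixtures combine linearly by
fractional intensity. After calibration against a reference of known
lifetime, a *metabolic trajectory* is drawn from the free-NAD(P)H anchor
(τ = 0.4 ns) through a region of interest's photon-weighted phasor
centre of mass to its second intersection with the circle (100 % bound);
the ROI's bound percentage is its position along that chord. Sections
are zoned by eccentricity (far/mid periphery; peripapillary, central,
paracentral at 200/400/600 µm from the optic disc) and split into outer
vs inner retina, with fixed 150 µm-wide ROIs; per-image region means are
compared with paired two-tailed t-tests. Melanin, hemoglobin and SHG are
segmented purely by phasor position.

Because raw study data are not deposited, the package ships a seeded
retina-section phantom (layered geometry, three vascular plexuses, RPE
hemoglobin bands, optic disc) and a TCSPC forward model (IRF-convolved
exponential decays, Poisson noise) that generate decay cubes with the
statistical structure the analysis assumes.

## Worked example

```r
library(retinaflim)

cfg <- default_config(seed = 42, n_images = 2, photons_per_pixel = 1000)
cfg$phantom$width_um <- 1700      # a compact section: 4 zones per side
run <- suppressWarnings(run_pipeline(cfg))
run
#> <retinaflim_run> 2 image(s), 32 ROI result(s)
#> comparisons:
#> # A tibble: 3 x 5
#>   name                                      n_pairs mean_a mean_b p_two_tailed
#>   <chr>                                       <int>  <dbl>  <dbl>        <dbl>
#> 1 outer vs inner retina                           2   58.9   60.9      0.00628
#> 2 far periphery vs central (overall retina)       2   59.9   59.9      0.553
#> 3 far periphery vs central (outer retina)         2   58.9   58.9      0.774
```

The phantom was generated with ground-truth bound-NAD(P)H percentages of
58.9 (outer retina) and 60.9 (inner retina): the pipeline recovers both
region means to well under a percentage point even at a modest 1000
photons/pixel, and the paired comparison already separates the two
regions (p ≈ 0.006 with only two images, because pairing is
within-image). The far-periphery-vs-central comparisons are null by
construction here — both zones carry the same ground truth — and come
out non-significant.

Individual stages are plain functions on data frames and lightweight
image objects:

```r
map  <- make_phantom(seed = 7)                       # labeled phantom
gt   <- layer_metabolic_profile(map, 58.9, 60.9)     # ground truth (%)
cube <- simulate_decay_cube(map, gt, photons_per_pixel = 1e5, seed = 1)
fld  <- calibrate_phasor(phasor_transform(cube),
                         simulate_reference_cube(1.0), 1.0)
rois <- make_rois(build_zones(map))                  # 20 x 150 um ROIs
analyze_rois(fld, rois, free_tau = 0.4)              # tibble of bound %
autoplot(fld)                                        # phasor plot
```

A thin CLI over the same functions lives at `inst/cli/retinaflim.R`
(subcommands `simulate`, `phasor`, `zones`, `analyze`, `channels`,
`stats`, `run`).

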