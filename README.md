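# livefret

Quantitative analysis for live-cell mRNA imaging by FRET.

## The problem

A transcript can be detected in a *living* cell by hybridizing a
fluorescently labeled 20-mer antisense RNA probe to it and letting a
fluorescently labeled double-stranded-RNA-binding protein (the dsRNA-binding
domain of human protein kinase R, which needs ≥ 18–20 bp of dsRNA) bind the
resulting RNA–RNA duplex.  Donor (protein) and acceptor (probe) fluorophores
are then close enough for Förster resonance energy transfer, so
FRET intensity reports the presence — and, per cell, the relative
abundance — of the target mRNA.  Turning the raw microscope channels into
per-cell numbers requires a chain of corrections that this package
implements and tests end to end:

* **Sensitized-emission (three-cube) FRET.**  The raw FRET channel (donor
  excitation, acceptor emission) contains donor bleed-through and directly
  excited acceptor signal.  With constants measured on single-label
  controls,

  `cFRET = FRET_raw − a·I_donor − b·I_acceptor`

  where `a` and `b` are the relative spectral bleed-through constants of
  donor and acceptor.
* **Spectral (lambda-stack) FRET** for multiplexing several probes: per-pixel
  nonnegative linear unmixing `min ‖F·w − s‖², w ≥ 0` against fingerprints
  from single-label controls, followed by computational removal of the
  acceptor bleed-through that unmixing cannot separate
  (`FRET_corr = FRET − b·acceptor`).
* **Per-cell quantification**: FRET/cell, cFRET/area, nuclear-to-cytoplasmic
  ratio, Manders' overlap coefficient, smFISH spot counting, and cross-assay
  correlation.
* **Equilibrium binding**: gel-shift (EMSA) quantification and nonlinear
  least-squares fits of the Hill model
  `θ = ε·[MF]ⁿ / ([MF]ⁿ + Kdⁿ)`
  with bootstrap uncertainty, Kd fold changes between protein preparations,
  and degree-of-labeling arithmetic.
* **Probe design**: antisense 20-mers against target coordinates, label-site
  counting (1–2 labels optimal; more quench), duplex-length validation
  against the 18-bp floor, and T7 transcription-template construction.  The
  validated probe set (β-actin, MHCα, MLC2a, three NKX2-5 probes, a
  no-target control) ships with the package.

Because the corresponding wet-lab data are microscope images that cannot be
regenerated from a script, the package includes a first-class synthetic
generator: ground-truth scenes (elliptical cells with nuclei, log-normal
per-cell mRNA abundance, configurable nuclear retention and FRET
efficiency) rendered into three-cube sets and lambda stacks under a
Poisson–Gaussian detector model with saturation, plus simulated binding
series and diffraction-limited spot images.  Every correction step is
validated by recovering what the generator put in.

## Worked example

```r
library(livefret)

cfg   <- scene_config(n_cells = 6, image_shape = c(128, 128), seed = 42)
scene <- simulate_scene(cfg)                 # ground truth: cells + abundances
sample_cube <- render_three_cube(scene)      # noisy three-cube acquisition

donor_ctl <- render_three_cube(
  simulate_scene(scene_config(n_cells = 14, image_shape = c(192, 192), seed = 201)),
  mode = "donor_only")
acceptor_ctl <- render_three_cube(
  simulate_scene(scene_config(n_cells = 14, image_shape = c(192, 192), seed = 202)),
  mode = "acceptor_only")

fit <- cfret_pipeline(sample_cube, donor_ctl, acceptor_ctl)
fit$a
#> donor bleed-through a = 0.1993 (4673 px, rms residual 13.34 counts)
fit$b
#> acceptor bleed-through b = 0.1000 (4548 px, rms residual 7.26 counts)
```

The constants estimated from the controls recover the generative values
(a = 0.2, b = 0.1) to a fraction of a percent.  Per-cell quantification of
the corrected image:

```r
cells <- per_cell_fret(fit$cfret, scene$label_map)
cells[, c("cell_id", "area", "fret_sum", "cfret_per_area", "normalized_fret")]
#>   cell_id area fret_sum cfret_per_area normalized_fret
#> 1       1  440    55456          126.0           0.335
#> 2       2  439   116532          265.4           0.704
#> 3       3  441   165507          375.3           1.000
#> 4       4  443    47869          108.1           0.289
#> 5       5  440    53098          120.7           0.321
#> 6       6  442    21875           49.5           0.132

correlate_cells(scene$cells$abundance, cells$fret_sum)$r
#> [1] 0.999994
```

`fret_sum` is the summed corrected FRET per cell (counts), `cfret_per_area`
divides by the cell's valid pixel area, and `normalized_fret` rescales by
the population maximum; the Pearson correlation against the scene's true
per-cell abundances shows the pipeline preserves relative expression.

Designing a probe against a target region:

```r
target <- your_mrna_sequence           # character, RNAString or DNAString
antisense_probe(target, 488, 507, name = "ACTB-488")
#> probe ACTB-488: 5'-GGATAGCACAGCCTGGATAG-3' (20 nt, 3 label sites) target sites 507-488
```

See the methods vignette (`vignettes/livefret-methods.Rmd`) for the models,
parameter choices and limitations.

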