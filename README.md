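# epistrat

A 3D multiscale simulator of epidermal stratification: how a single
layer of committed basal keratinocytes develops into basal, spinous and
granular layers with distinct boundaries, and which mechanisms make
those boundaries sharp.

The package is aimed at modellers of developing epithelia. It couples
three scales:

* **Cell lineage.** A four-stage population model — basal stem cells
  `c0`, proliferative spinous `c1`, mature spinous `c2`, granular `c3` —

  ```
  dc0/dt = (2 p0 − 1) v0 c0
  dc1/dt = 2 (1 − p0) v0 c0 + (2 p1 − 1) v1 c1
  dc2/dt = 2 (1 − p1) v1 c1 − d2 c2
  dc3/dt = d2 c2 − d3 c3
  ```

  with the Ovol1/Ovol2 transcription-factor levels (α, β) modulating the
  rates: `v0 = vmin + vT/(1 + ωα + χβ)`, `p0 = pmin + pT/(1 + λα + μβ)`,
  `d2 = dDKO + ςα + ξβ`. Genotype presets (WT, Ovol1⁻/⁻, Ovol2 SSKO,
  Ovol2 BT, Ovol DKO) reproduce the experimentally observed directions
  of layer-size change.

* **Cell mechanics.** Each cell is a cluster of subcellular elements:
  intracellular all-pair springs `μ(r − r0)²/2`, selective intercellular
  Lennard-Jones forces `F{a,b} ε[(σ/r)¹² − (σ/r)⁶]` (strength `Fa`
  within a layer class, `Fb` across classes, truncated at two cell
  diameters), a polarized basement-membrane pull `ε_ext|z|` on the
  adherent elements of basal cells, and overdamped Langevin dynamics.
  Cells grow by element addition, divide with oriented planes
  (perpendicular to the membrane for symmetric divisions, parallel for
  asymmetric ones), mature in stages, and granular cells shrink away.

* **Morphogen field.** Calcium obeys
  `∂s/∂t = ∇·(D∇s) + δs1 c2 + δs2 c3 − ds s` on a regular grid with
  crowding-reduced diffusivity; in the signal variant the local level
  feeds back on the effective Ovol levels (raising `d2` in spinous
  cells, lowering `v0`, `p0` in basal cells).

Four nested model variants isolate the mechanisms: `base` (lineage
only), `asym_division` (+ asymmetric basal division),
`selective_adhesion` (+ differential adhesion, `Fa = 4 Fb`), `signal`
(+ calcium feedback). Stratification is quantified per slice by the
**Sharpness Index** (one minus the mean squared central differences of a
10×10 label image; 1 = perfectly polarized), the **Isolation Ratio**
(fraction of a type's cells outside its main cluster; 0 = perfect
aggregation), per-slice **Ripley's K**, and per-type counts.

## Worked example

```r
library(epistrat)

# non-spatial lineage: mutant phenotype directions vs wild type
genotype_phenotype()
#> # A tibble: 15 × 6
#>    genotype  layer    WT_value mutant_value relative_change direction
#>    <chr>     <chr>       <dbl>        <dbl>           <dbl> <chr>
#>  1 WT        basal        123.         123.          0      same
#>  2 WT        spinous      488.         488.          0      same
#>  3 WT        granular     319.         319.          0      same
#>  4 Ovol1KO   basal        123.         135.          0.0970 same
#>  5 Ovol1KO   spinous      488.        1072.          1.20   up
#>  ...
#> 13 OvolDKO   basal        123.         196.          0.592  up
#> 14 OvolDKO   spinous      488.        2589.          4.30   up
#> 15 OvolDKO   granular     319.          72.5        -0.773  down

# spatial run: asymmetric-division variant, 2 simulated days
cfg <- simulation_config("asym_division", duration = 48, nx = 6, ny = 6)
run <- run_simulation(cfg, seed = 1)
glance(run)
#>         variant genotype seed t_end early_stop C0 C1 C2 C3 C1_C2 total
#> 1 asym_division       WT    1    48      FALSE 38 34  6  0    40    78
#>   median_si    max_ir
#> 1     0.967    0.0526

autoplot(run)                  # per-type counts over time
plot_tissue(run$tissue)        # side view coloured by layer
metrics_report(run$tissue)     # per-slice SI, isolation, counts
```

Reading the `glance()` row: after 48 h the 36-cell monolayer has grown
to 78 cells; basal cells (C0) still form the bottom layer while the
first differentiated cells appear above them. At this early stage the
slices are still nearly pure, so the median per-slice Sharpness Index is
high (0.97; a value of 1 means perfectly uniform slices) and the worst
per-layer Isolation Ratio is low (0.05: almost every cell sits in its
layer's main cluster). Over a full 5-day run the differentiating
compartments interleave at the moving spinous/granular front and the
median SI settles near 0.65 for this variant, against roughly 0.4 for
the base variant without oriented divisions.

A YAML-driven command line mirrors the R interface
(`inst/cli/epistrat`): `epistrat run --config cfg.yaml --seed 1 --out
out/`, plus `sweep`, `metrics`, `lineage` and `validate-config`
subcommands.

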