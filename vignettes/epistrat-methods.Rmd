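---
title: "Modeling epidermal stratification with epistrat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling epidermal stratification with epistrat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

epistrat simulates how a single layer of committed basal keratinocytes
develops into a stratified epidermis — basal, spinous and granular layers
with distinct boundaries — and quantifies how well the layers form. This
vignette is the package's own account of the model, its assumptions, the
parameters that matter, and the choices we made where the design was
genuinely open.

## The lineage model

The population backbone is a four-stage cell lineage: basal stem cells
$c_0$, proliferative spinous cells $c_1$, mature spinous cells $c_2$ and
granular cells $c_3$,

$$
\begin{aligned}
\dot c_0 &= (2p_0 - 1)\,v_0 c_0, &
\dot c_1 &= 2(1 - p_0)\,v_0 c_0 + (2p_1 - 1)\,v_1 c_1,\\
\dot c_2 &= 2(1 - p_1)\,v_1 c_1 - d_2 c_2, &
\dot c_3 &= d_2 c_2 - d_3 c_3,
\end{aligned}
$$

where $p_0$, $p_1$ are self-renewal probabilities at division, $v_0$,
$v_1$ are proliferation rates of the form $\ln 2/(\text{cycle length})$,
$d_2$ is the spinous-to-granular maturation rate and $d_3$ the granular
removal rate. The basal compartment is maintained exactly when
$p_0 > 1/2$ (`critical_self_renewal()`); above that threshold the
populations grow without bound, which is why phenotype comparisons are
made at a fixed horizon rather than at a steady state.

The transcription factors Ovol1 (level $\alpha$) and Ovol2 ($\beta$)
repress basal proliferation and self-renewal and stimulate terminal
differentiation:

$$
v_0 = v_{\min} + \frac{v_T}{1 + \omega\alpha + \chi\beta},\qquad
p_0 = p_{\min} + \frac{p_T}{1 + \lambda\alpha + \mu\beta},\qquad
d_2 = d_{\mathrm{DKO}} + \varsigma\alpha + \xi\beta .
$$

Because Ovol1 and Ovol2 also repress each other, each genotype is
represented by a fixed pair of effective levels rather than by a dynamic
cross-repression circuit: WT $(\alpha,\beta) = (1,1)$, the Ovol1 knockout
$(0, 1.25)$, the Ovol2 skin knockout $(1.6, 0)$, Ovol2 overexpression
$(0.5, 10)$, and the double knockout $(0,0)$. The de-repression
inequalities (knockout of one factor raises the other) are enforced by
these presets.

### Calibrated rate defaults

The regulation weights and rate scales are not published alongside the
model's main equations, so the package ships a calibrated default set
(all exposed as arguments of `ovol_regulation()` and `lineage_params()`,
never hard-wired):

| parameter | default | units | why |
|---|---|---|---|
| $v_{\min}, v_T$ | 0.01, 0.03 | 1/h | WT $v_0 \approx \ln 2/24$ (24 h cycle) |
| $\omega, \chi$ | 0.3, 0.3 | — | mild inhibition; DKO cycles faster |
| $p_{\min}, p_T$ | 0.495, 0.04 | — | WT $p_0 = 0.515 > 1/2$; floor just below 1/2 so a saturating calcium feedback can halt basal growth |
| $\lambda, \mu$ | 0.5, 0.5 | — | symmetric inhibition of $p_0$ |
| $d_{\mathrm{DKO}}, \varsigma, \xi$ | 0.001, 0.02, 0.006 | 1/h | WT $d_2 = 0.027$; DKO differentiates ~27x slower |
| $p_1$ | 0.2 | — | reported spinous renewal probability |
| $v_1$ | $\ln 2/24$ | 1/h | 24 h spinous cycle |
| $d_3$ | $\ln 2/30$ | 1/h | ~30 h granular residence |

The set was chosen once so that (i) the wild type maintains its basal
layer, and (ii) at the 10-day evaluation horizon every mutant layer-size
direction (up / down / unchanged versus wild type, 20% relative-change
threshold) matches the experimental table encoded in
`genotype_phenotype()`. Only those directions are treated as the model's
validation surface; absolute layer sizes depend on unpublished parameter
tables and are out of scope.

The direction-call threshold of 20% and the 240 h horizon are
conventions: the arrows being reproduced are qualitative, and a fixed
horizon is forced by the unbounded growth noted above.

## The spatial model

Each cell is a cluster of point elements (default 10 per mature cell).
Elements of one cell are tied by all-pair harmonic springs
$V_{\mathrm{intra}} = \mu (r - r_0)^2/2$; elements of different cells
interact through a truncated Lennard-Jones potential
$V_{\mathrm{inter}} = F_{a,b}\,\varepsilon\left[(\sigma/r)^{12} -
(\sigma/r)^{6}\right]$ whose strength is $F_a$ between cells of the same
layer class (basal / spinous / granular) and $F_b$ across classes, cut
off at two (relaxed-cluster) cell diameters. Basal cells adhere to the basement membrane
(the plane $z = 0$) through a constant-magnitude pull
$V_{\mathrm{ext}} = \varepsilon_{\mathrm{ext}}\,|z|$ acting, within half
a cell diameter, only on their membrane-adherent elements — the subset
below the cell centroid. This polarized membrane adhesion is the minimal
reading of "at least two element types with type-dependent external
forces"; the alternative (all basal elements adherent) would let basal
cells adhere through their apical side, which contradicts the polarity
the mechanism is meant to represent.

Positions follow overdamped Langevin dynamics
$\mathrm{d}Y = M F\,\mathrm{d}t + \eta\sqrt{\mathrm{d}t}\,\xi$ with unit
mobility. Setting `noise_amp = 0` recovers the deterministic gradient
flow, under which the total potential energy is non-increasing (tested).

### Mechanical defaults and numerical choices

Units are micrometres and hours. The energy and length scales are
calibrated package choices (the source tables are unpublished):

* `r0 = 3`, `mu_spring = 5`: a relaxed 10-element cluster is roughly
  spherical with diameter ~3 µm (`cluster_diameter = 3`, measured once
  from the defaults); together with the intercellular equilibrium gap
  this packs cells at ~4 µm centroid spacing, the package's operational
  "cell diameter" (`cell_diameter = 4`). The adhesion reach follows the
  cluster scale — intercellular forces are cut at two cluster diameters
  (6 µm) and the membrane pull at half of one (1.5 µm) — while packing-
  based quantities (initial grid spacing, slice thickness, cluster
  adjacency) follow the packing diameter.
* `sigma = 2`, `eps = 1`: intercellular contact scale; `Fa = Fb = 1` in
  the isotropic variants and `Fa = 2, Fb = 0.5` (the reported 4:1 ratio)
  when selective adhesion is on.
* `f_clamp = 15` bounds the magnitude of a single intercellular pair
  force. Freshly divided daughters inherit interleaved, deeply
  overlapping elements; the unbounded LJ core would produce astronomical
  forces there. The clamp resolves overlaps at bounded speed and is
  inactive at ordinary separations (beyond ~0.9 σ).
* `dt_mech = 0.02` h. The crowded tissue sustains net per-element forces
  of a few tens of force units, so larger steps constantly trip the
  displacement bound below; 0.02 h keeps typical displacements well
  under σ/2 while a 5-day tissue takes 6000 mechanics steps.
* Displacement bound: any step that would move an element farther than
  σ/2 is retried at half the time step (forces held fixed) until it
  fits, and the remainder of the step is consumed in further bounded
  chunks. This acts as a safety net after division events rather than as
  the routine integrator.
* `noise_amp = 0.1` µm h^-1/2 (element diffusivity
  $\eta^2/2 = 0.005$ µm²/h). The dynamics are described as stochastic
  but no amplitude is given; the default is chosen small enough that
  thermal shuffling does not erase the layering the deterministic
  mechanisms build over a 5-day run (vertical RMS displacement ~1.1 µm,
  about a quarter of a cell diameter), yet large enough to unjam packing
  defects.
* Coincident elements (exactly overlapping) contribute no force in that
  evaluation and are counted; new elements are always placed with a
  random offset so this is a guard, not a code path that shapes results.
* The basement membrane and the domain top are reflecting; the lateral
  boundaries are periodic by default (minimum-image distances), which
  avoids edge artifacts in a small desk-scale domain.

## The lifecycle

Cells divide when their cycle clock reaches the mean inter-division
time implied by the lineage rate, $1/v$, *and* they have regrown to the
target element count; growth
adds one element near the centroid on a schedule that restores full size
within one cycle. Cycle clocks of the initial monolayer are staggered
uniformly so divisions are asynchronous. Division planes are jittered
within 15° of their target orientation: perpendicular to the membrane
for symmetric divisions (daughters side by side), parallel for
asymmetric divisions (basal daughter below, differentiated daughter
above). Elements are partitioned by signed distance to the plane with
rank tie-breaking, so both daughters receive at least half the elements.

In the variants with asymmetric division, a basal division is asymmetric
with probability $2(1 - p_0)$ and symmetric self-renewal otherwise. This
mapping preserves the expected offspring composition of the lineage
model — $2p_0$ basal daughters per division either way — and requires
$p_0 \ge 1/2$; it is validated at configuration time and clamped at run
time when the calcium feedback pushes the effective $p_0$ below 1/2
(every division then being asymmetric, the basal pool shrinks, which is
the homeostatic point of the feedback).

A deterministic inter-division time of $1/v$ makes the agent-level
per-capita division-event rate equal the lineage coefficient $v$
exactly, which is the correspondence the consistency tests check. The
price is that the labelled "24 h cycle" of the rate convention
$v = \ln 2/24$ unfolds as a ~34.6 h deterministic interval: for
deterministic cycles one can match either the event rate or the
population doubling time, not both, and the package matches the event
rate (the doubling-time reading would inflate every lineage flux by
$1/\ln 2 \approx 1.44$).

### Staged maturation

Mature spinous cells convert to granular cells at rate $d_2$ in the
population model. An agent-level memoryless per-step hazard reproduces
that rate but gives the conversion *age* a coefficient of variation of
one: conversions then happen at essentially every height of the column,
and the spinous/granular interface smears across most of the suprabasal
tissue — visibly sharper layering is reported for the corresponding
models than a memoryless rule can produce at this tissue size. The
package therefore implements maturation as `maturation_stages` internal
stages (default 8), each left at rate $k\,d_2$: mean residence is
exactly $1/d_2$ for any $k$ (so the lineage-model flux $d_2 c_2$ is
preserved at steady state), while the conversion-age spread narrows as
$1/\sqrt{k}$. Setting `maturation_stages = 1` recovers the memoryless
hazard, and the unit tests pin both limits. Granular cells then live a
deterministic $\ln 2 / d_3$ hours and shrink away element by element
over `removal_interval = 6` h. The default granular residence is 30 h
($d_3 = \ln 2/30$), long enough for granular cells to consolidate at
the top of the column before shrinking instead of dying at the
conversion front.

## The calcium field

The extracellular morphogen obeys
$\partial_t s = \nabla\!\cdot\!(D \nabla s) + \delta_{s1} c_2 +
\delta_{s2} c_3 - d_s s$ on a regular grid superimposed on the tissue.
Every element of a mature spinous cell deposits $\delta_{s1}/n$ per hour
into its voxel ($n$ elements per cell), granular elements
$\delta_{s2}/n$ with $\delta_{s2} = 2\delta_{s1}$, so per-cell totals
match the production term exactly. Crowding slows diffusion: a voxel's
diffusivity is the baseline divided by its element count (floor of one
for empty voxels, keeping the field finite and bounded by the baseline),
averaged with its six face neighbors. The discretization is a
conservative flux form with face-averaged diffusivities — it reduces to
the plain Laplacian when $D$ is uniform and conserves mass to rounding
under zero-flux boundaries (tested) — advanced by forward Euler substeps
capped at 90% of the stability bound $h^2/(6D)$ and checked again at run
time against the realized maximum diffusivity.

Defaults: spacing `h = 2.5` µm (the grid resolves the cell scale
without dominating the run time at desk scale), `Ds_base = 360` µm²/h
(0.1 µm²/s) and `ds_decay = 9`/h. The decay length
$\sqrt{D/d_s} \approx 6$ µm is deliberately shorter than the tissue
height so the field actually rises from low basal levels to a peak in
the granular zone (about two-fold under the default geometry) instead
of sitting flat — the long-range mechanism needs that spatial contrast
to act selectively on misplaced cells. `delta_s1 = 1` per cell per hour
in arbitrary concentration units; the field's units are not given, so
it is treated as dimensionless and the feedback gains
(`k_alpha = 4`, `k_beta = 40`) and half-saturation
(`s_half = 0.03`, about the mid-column level at desk scale) are
calibrated against the realized field.

In the signal variant the local field (the mean of $s$ over the voxels
containing a cell's elements, sampled at decision time) feeds back on
the lineage through bounded Hill-type multipliers on the effective Ovol
levels: calcium stimulates Ovol1 in mature spinous cells (raising
$d_2$) and is permissive to Ovol2 in basal cells (lowering $v_0$ and
$p_0$). Gains and the half-saturation level live in
`signal_feedback()`; at $s = 0$ the feedback vanishes identically.

## Variants and metrics

The four model variants are nested, each adding one mechanism: `base`
(lineage dynamics only, isotropic adhesion, symmetric divisions),
`asym_division` (+ oriented asymmetric basal divisions),
`selective_adhesion` (+ $F_a > F_b$), `signal` (+ calcium feedback).
Configuration enforces the nesting (the first two variants force
$F_a = F_b$).

Stratification is quantified per horizontal slice of one cell diameter:
cell centroids are rasterized into a 10×10 label image (0 basal,
1 spinous — C1 and C2 share the label, 2 granular; modal label per
pixel, ties to the lowest; empty pixels filled from the nearest occupied
pixel but excluded, via a mask, from the statistic). The Sharpness Index
of a slice is one minus the mean squared central differences over the
interior pixels; 1 is a perfectly uniform (extremely polarized) slice
and the label range bounds it below by −3. The Isolation Ratio of a
layer is the fraction of its cells outside the largest connected cluster
(single-linkage at 1.2 cell diameters; ties broken by proximity to the
layer's mean height). Ripley's K per slice uses the plain
$\frac{A}{n(n-1)}\sum_{i\ne j} 1[d_{ij}\le r]$ estimator — on periodic
domains the minimum-image metric makes edge correction unnecessary,
which is why no correction is applied by default.

Parameter sweeps classify outcomes by explicit rules (the visual classes
need automating): *stratified* requires dominant-label purity ≥ 0.7 in
≥ 70% of occupied slices, an Isolation Ratio ≤ 0.1 for every layer and
no internal cavity (coarse occupancy check below each column top);
otherwise *cavity*, *salt-pepper* (median slice SI < 0.3), *compact*
(height under 60% of the expected stacked height) or *mixed*. All
thresholds are exposed as arguments.

## What the generator emulates — and what it does not

`init_tissue()` builds the study condition: an `nx × ny` basal monolayer
(default 10×10) of relaxed cells on the membrane with staggered cycle
clocks, and `run_simulation()` grows it for a configured duration
(5 simulated days in the shipped examples and the reproduction
script's runs; tissues
reach roughly 800–1000 cells at that horizon). This emulates embryonic
stratification from a committed precursor sheet. It does not emulate:
the periderm or cornified layer, a deformable basement membrane, hair
follicles or dermis, damage response, or realistic cell shapes — so
passing tests support the mechanisms' qualitative behavior (boundary
sharpening by asymmetric division, sorting by selective adhesion,
homeostasis by long-range feedback) at desk scale, not quantitative
agreement with any particular tissue.

Problem sizes were chosen to keep the full test suite and the
reproduction script desk-sized: the reproduction script runs the 10×10
monolayer for 120 h with 10 elements per cell, five seeds per variant;
the test suite uses 8×8 monolayers for the base/asymmetric comparison
and the adhesion sweep, 5×5 monolayers with 8 elements per cell for the
ten-seed mechanism ordering and growth checks, and a 288 h 8×8 run for
the homeostasis check. These sizes are sufficient for the qualitative
orderings the tests assert; per-type cell counts at this scale carry a
few percent of counting noise, which is why the mechanism ordering is
tested statistically.

## Known limitations

* Slice images at the default scale hold ~1 cell per pixel, so the
  Sharpness Index of a mixed slice sits near the label-mixture limit
  rather than being smoothed by within-pixel majorities; SI values are
  comparative, not absolute (the metric is explicitly relative).
* The lineage calibration reproduces phenotype directions, not
  magnitudes; no attempt is made to match reported absolute layer sizes.
* The intercellular force is discontinuous at the cutoff (a hard
  truncation, as specified); the discontinuity is ~10⁻⁴ of the contact
  force scale and is accepted.
* Event-rate versus growth-rate correspondence for deterministic cycles
  differs by a factor $\ln 2$, as discussed above.
* With the calcium feedback off, populations grow without bound and runs
  end at the configured cell cap with partial outputs.
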