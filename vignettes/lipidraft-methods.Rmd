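---
title: "Methods: membrane trajectory and isotherm analysis in lipidraft"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: membrane trajectory and isotherm analysis in lipidraft}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidraft)
```

`lipidraft` implements the analysis pipeline used to characterise ligand
binding to liquid-ordered (Lo) and liquid-disordered (Ld) model membranes,
together with a synthetic-data generator that provides known ground truth
for every estimator. This vignette documents the models, the conventions
chosen where the field leaves them open, the defaults and their units, and
what the synthetic tests do and do not demonstrate about real data.

## Data model

A **trajectory** stores coordinates as an `n_atoms × 3 × n_frames` array in
nm with a rectangular per-frame box and times in ns. Triclinic boxes are
rejected: planar bilayer simulations are run with semi-isotropic coupling
and rectangular cells, and restricting to that case keeps every
minimum-image computation exact and cheap. GRO (fixed-width, nm, box line
per frame) is the canonical text format; XYZ (Å on disk, converted to nm)
is supported for convenience. Binary formats are out of scope.

The sidecar **topology** table carries, per atom: species, subregion tag
(`choline`, `phosphate`, `glycerol`, `tails`, `sterol`, `ligand`,
`other`), element, mass (amu), van der Waals radius (nm), hydrogen-bond
roles (`is_donor`, `is_hydrogen`, `is_acceptor`) and, for each hydrogen,
the `donor_of` link to its bonded heavy atom. Every lipid must expose one
headgroup reference atom — `P` for phospholipids, `O3` for sterols — used
for leaflet assignment, thickness and midplane location.

## Membrane structure

**Leaflets** are assigned by the sign of the reference atom's z relative
to the mean reference z; an atom exactly at the midplane goes to the
upper leaflet with a warning (a fixed tie-break so repeated runs agree).

**Area per lipid** is the projected box area divided by the lipids per
leaflet, averaged over leaflets and frames. For homogeneous single- or
two-component leaflets this box estimator equals tessellation-based
(Voronoi) APL in the mean; per-lipid areas are not needed by any
downstream statistic here, so the heavy geometric machinery is omitted.

**Thickness** is the distance between the mean reference-atom z of the
two leaflets (phosphate-plane convention). Other conventions (e.g.
density-crossing thickness) differ by a roughly constant offset on planar
bilayers.

**Area compressibility** uses the equilibrium fluctuation estimator
`K_A = k_B T ⟨A⟩ / var(A)` with A the box area; inputs in nm², output in
N/m (conversion factor 1e18 from nm⁻²). At least 100 frames are required
— variance estimates below that are too unstable to report.

**Mass-density profiles** histogram selection masses along z, re-centred
per frame on the instantaneous midplane and wrapped into
(−L_z/2, L_z/2], converted to kg/m³ via the bin volume. The integral of
the all-atom profile times bin volume returns the selected mass exactly
(up to float rounding), which the tests assert.

**Five-region scheme.** Depth regions are numbered 1 (bulk water) to 5
(bilayer centre). The literature defines them from density landmarks
without printing universal z-ranges, so the package derives the four
symmetric boundaries from the lipid profiles: 4|5 at the half-rise of the
tail density from its central trough; 3|4 at the headgroup/tail density
crossover; 2|3 at the outer headgroup half-maximum; 1|2 where the
headgroup density decays to 5 % of its maximum (or crosses the water
profile when one is available). Any published z-ranges can be supplied
verbatim through the `boundaries` argument, which bypasses the recipe.
Ligand localisation reports the mass fraction per region and the region
containing the profile peak.

## Lateral dynamics

Tracks are unwrapped by nearest-image accumulation of frame-to-frame
displacements; a displacement of half a box edge or more between stored
frames is ambiguous and raises an error (store frames more densely).
Centre-of-mass drift removal per leaflet is on by default. Two caveats
follow from it: it is the right correction for real trajectories, where
thermostats and pressure coupling inject collective drift, and it is
harmless but slightly biasing on drift-free synthetic data — subtracting
the mean of n independent walkers shrinks each walker's MSD by a factor
of about (1 − 1/n), and in mixed-species leaflets it transfers a small
amount of apparent mobility from fast to slow species. It is switchable
(`remove_com_drift = FALSE`) and the recovery tests pass with it on.

MSD uses time origins every `origin_stride` frames and an explicit lag
grid, so 20,000-frame trajectories stay cheap; `msd(0) = 0` and the
origin-pair count per lag is recorded. Diffusion coefficients come from
OLS of MSD on τ over a window, `D = slope/4`, converted from nm²/ns to
cm²/s by 1e−5. The default window is 10–200 ns, matching common practice
of fitting past the sub-ns ballistic/cage regime and before the
origin-starved tail; it must be adapted to shorter runs. The fit warns
when r² < 0.98 (MSD not linear in the window). Per-molecule fits use the
same window; negative per-molecule slopes are retained so the species
distribution keeps its honest tails.

## Interactions

**Hydrogen bonds** are geometric: donor–acceptor distance ≤ 3.0 Å *and*
donor–hydrogen–acceptor angle ≥ 150°, under minimum image. Both bounds
are inclusive; boundary cases are vanishing-measure in real data but the
convention is fixed and documented. Aggregation reports time-averaged
counts per donor–acceptor species pair and per donor atom name (the
per-hydroxyl accounting used for polyphenols, whose OH groups are named
by their oxygen index). Whether multiple hydrogens of one donor–acceptor
pair should count once or separately is not standardised; both modes are
available (`dedupe_hydrogens`).

**Contacts** count atom pairs strictly closer than the cutoff ("within
4.5 Å" and "less than 0.16 nm" are both read as strict `<`; "exceeds 800"
as strict `>`). The cell-list implementation bins wrapped coordinates
into cells at least one cutoff wide and deduplicates neighbour cells, so
it is exact — the suite asserts equality with the all-pairs counter on
random frames rather than treating the grid as an approximation. Cutoffs
above half the smallest box edge are refused (minimum-image validity).

**Strong binding time** is `dt × #{frames: count > threshold}` with the
as-published defaults of a 0.16 nm pair cutoff and an 800-count
threshold. Note that 0.16 nm is bond-length scale and therefore extremely
tight for heavy-atom pairs; the parameters are exposed, and a more
conventional profile (0.45 nm cutoff, heavy atoms) is available through
the same functions. The two-state generator provides the exact bound time
alongside its trace, making recovery testable: with zero count noise the
statistic is exact, and with noise well inside the bound/unbound gap the
error stays within a couple of frames per transition.

**SASA** is Shrake–Rupley with a deterministic golden-spiral point set
(n = 960 by default, probe 0.14 nm). A surface point is exposed iff it
lies inside no other inflated sphere. Attribution of exposed area to
"headgroup contact" (choline/phosphate/glycerol/sterol atoms) versus
"tail contact" assigns each exposed point to the nearest non-ligand
inflated surface within one probe diameter, else to solvent — a concrete
rendering of "surface area covering" that standard tools leave implicit.
Partition components sum to the total exactly because each point lands in
exactly one bucket.

## Langmuir isotherms

Curves are (area Å²/molecule, π mN/m) compression sweeps. The collapse
point is not standardised in the literature; here the condensed-branch
slope is estimated by OLS over the points whose smoothed pressure lies in
25–85 % of the maximum, and collapse is the first point past that band
where the smoothed running slope falls below 10 % of the branch slope.
A curve with no such plateau returns the pressure maximum flagged
`no-collapse-plateau`. All smoothing is centred local averaging/OLS, so
noise-free piecewise-linear curves are handled exactly.

The limiting area extrapolates the condensed branch to π = 0, fitting raw
pressures over a band (default 60–95 % of the collapse pressure) whose
membership is judged on the smoothed curve — selecting on raw noisy
pressures would bias the fit near the band edges. `C_s⁻¹ = −A dπ/dA`
uses the same local-OLS derivative and is exact (`m·A`) on a linear
branch. Mixing slopes interpolate A(π) on each curve's smoothed rising
branch, exclude curves already collapsed at the target π with a warning,
and regress area on mole fraction (≥ 3 fractions including the pure
film); the sign is reported as condensing (< 0) or expanding (> 0). An
ideal-mixing excess-area analysis was considered and left out: the slope
indicator is what the monolayer comparison needs, and the excess-area
construction requires pure-component isotherms of both components.

## Statistics

Replicate aggregation uses the unbiased (n−1) sd and flags singleton
groups instead of fabricating an sd. The omnibus test is the classical
equal-variance one-way F (via `stats::oneway.test`); vs-control
comparisons are two-sided Welch t tests, uncorrected by default — the
common practice when a small fixed set of treatments is compared to one
control — with Dunnett-style Bonferroni correction behind a flag, and the
output labels which was used. Fold-change tables divide replicate means
(not per-replicate ratios), matching how such ratios are quoted from
summary tables; values are reported both at full precision and rounded to
one decimal.

## Synthetic generator: what it emulates, and what it does not

The generator exists to give every estimator a known truth at desk scale:

* **Configurations** are coarse pseudo-lipids (4–7 beads: headgroup
  reference, one bead per subregion, 2–3 tail beads; sterols carry an O3
  hydroxyl) on jittered lattices, two identical leaflets, box area
  `N_leaflet × APL_target`, reference planes separated by the target
  thickness. Default compositions mirror the study systems: 40 POPC per
  leaflet (Ld) and 40 PSM + 80 CHOL per leaflet (Lo, a 1:2 molar ratio).
  Hydrogen-bond chemistry follows the real species: POPC-like lipids are
  acceptor-only, sphingomyelin-like lipids carry an amide donor, the
  sterol hydroxyl is donor and acceptor.
* **Dynamics** are free 2-D Brownian walks (per-axis step variance
  `2 D dt`, D given in cm²/s) with optional stationary Gaussian box-area
  fluctuations; a target K_A and temperature can be given instead of an
  area variance. z stays at the leaflet plane plus Gaussian jitter
  (default sd 0.02 nm; the density-region tests use 0.25 nm, the realistic
  headgroup broadening scale, to obtain smooth profiles from the discrete
  bead planes).
* **Binding traces** are two-state Markov chains with per-frame switch
  probabilities `1 − exp(−k dt)` and rounded Gaussian count noise.
* **Isotherms** are piecewise curves — zero-pressure gas phase, linear
  condensed branch `π = s (A₀ − A)`, flat plateau at the collapse
  pressure — with the area axis shifted by `mixing_slope × mole_fraction`
  and additive pressure noise (0.5 mN/m in the noisy tests, a realistic
  film-balance scale).

Everything is seeded explicitly; the same spec gives byte-identical
output, and generators never touch global random state beyond their own
`set.seed`.

What passing these tests shows: the estimators are unbiased and correctly
scaled on data that satisfy their assumptions, the unit conversions are
right, and the detectors agree exactly with construction-level oracles.
What they cannot show: real lipids interact (subdiffusion at short times,
collective flows), real H-bond geometries are thermally correlated, real
contact counts are not conditionally Gaussian, and real isotherms have
curvature in the condensed phase. Absolute agreement with 500-ns atomistic
values is therefore out of reach by design; the published tables are
shipped as plain-text reference data and the package reproduces the
arithmetic built on them (fold changes, stiffness ratios) exactly.

## Problem sizes and numerical choices

Diffusion-recovery runs use 40 lipids per leaflet, 20,000 frames at
0.1 ns (2 µs of synthetic time), a 40-point lag grid and origins every 20
frames — enough for median recovery errors of a few percent while a full
20-seed sweep stays within a couple of minutes on one CPU. K_A recovery
uses 10,000 frames (the variance of a variance estimate shrinks only as
2/n). The ANOVA calibration uses 10,000 null replicates of 3 groups × 3.
Degenerate inputs fail loudly rather than silently: empty selections,
zero-variance area series, one-leaflet systems, windows outside the
available lags, cutoffs beyond minimum-image validity, and hydrogens
without donor parents are all explicit errors.
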