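# lipidraft

Analysis toolkit for studying how small amphiphilic ligands — in the
motivating application, monomeric and dimeric polyphenols — interact with
liquid-ordered (Lo, sphingomyelin/cholesterol-rich, raft-like) and
liquid-disordered (Ld, unsaturated phosphatidylcholine) model membranes.
It is aimed at membrane biophysicists who have bilayer trajectories
(or want statistically controlled synthetic stand-ins) and Langmuir
monolayer isotherms, and who need the standard battery of
structure / dynamics / interaction metrics with honest statistics.

## What it computes

**Membrane structure.** Leaflet assignment from headgroup reference
atoms; area per lipid `APL = A_box / N_leaflet`; bilayer thickness as the
phosphate-plane separation; the area compressibility modulus from
equilibrium box-area fluctuations,

```
K_A = k_B T ⟨A⟩ / var(A)
```

and mass-density profiles along the membrane normal with a five-region
depth classification (1 bulk water → 5 bilayer centre) used to localise a
ligand within the membrane.

**Lateral dynamics.** Periodic-boundary unwrapping, mean-square lateral
displacement with strided time origins, and diffusion coefficients from
the 2-D Einstein relation `MSD(τ) = 4 D τ`, fitted by OLS over a
configurable lag window (default 10–200 ns), per molecule and per
species.

**Interactions.** Geometric hydrogen-bond detection (donor–acceptor
distance ≤ 3.0 Å and donor–hydrogen–acceptor angle ≥ 150° by default)
with per-species-pair and per-hydroxyl accounting; heavy-atom contact
series per lipid subregion (choline, phosphate, glycerol, tails) from an
exact cell-list counter; minimum-distance traces; the *strong lipid
binding time* — the cumulative time during which the number of tight
(< 0.16 nm) ligand–lipid atom contacts exceeds 800 — and Shrake–Rupley
SASA partitioned between lipid headgroups, tails and solvent.

**Langmuir isotherms.** Limiting molecular area by zero-pressure
extrapolation of the condensed branch, collapse-point detection,
compressibility modulus `C_s⁻¹(π) = −A dπ/dA`, and the slope of mean
molecular area versus additive mole fraction at fixed π
(negative = condensing, positive = expanding).

**Statistics.** Replicate aggregation (mean ± unbiased sd), classical
one-way ANOVA with vs-control Welch contrasts, Pearson correlation, and
fold-change tables.

**Synthetic data.** Every estimator ships with a matching generator with
known ground truth: coarse pseudo-lipid bilayers on jittered lattices,
free 2-D Brownian lateral dynamics with box-area fluctuations, two-state
Markov binding traces, planted hydrogen-bond geometries, and parametric
π–A isotherms.

## Worked example

```r
library(lipidraft)

# a liquid-disordered bilayer: 40 POPC per leaflet at 0.651 nm^2 per lipid
cfg <- build_bilayer_config(bilayer_spec(c(POPC = 40), apl_target = 0.651,
                                         thickness_target = 3.90, seed = 1))
area_per_lipid(cfg$trajectory, cfg$topology)$apl
#> [1] 0.651
bilayer_thickness(cfg$trajectory, cfg$topology)$thickness
#> [1] 3.9

# Brownian dynamics at D = 1.2e-7 cm^2/s, then recover D from the MSD fit
ds  <- dynamics_spec(c(POPC = 1.2e-7), n_frames = 5000, dt = 0.1, seed = 3)
tr  <- simulate_lateral_diffusion(cfg, ds, atoms = "reference")
tk  <- unwrap_lateral(tr, attr(tr, "topology"))
fit <- fit_diffusion(msd(tk, lags = round(seq(10, 500, length.out = 40)),
                         origin_stride = 5), window = c(1, 50))
fit$d_xy
#> [1] 1.126245e-07

# fold changes of published strong-binding times against the EC control
rt <- ratio_table(reference_binding_times(), control = "EC")
subset(rt, membrane == "Lo" & lipid == "PSM")
#>   membrane lipid   compound fold_change fold_change_1dp
#> 4       Lo   PSM         EC     1.00000             1.0
#> 5       Lo   PSM  ECG_dimer    14.42969            14.4
#> 6       Lo   PSM EGCG_dimer    10.14844            10.1
```

The APL and thickness are exact by construction of the synthetic bilayer;
the diffusion fit recovers the input coefficient within sampling error
(here −6% at 5,000 frames); the fold changes say that in the ordered
membrane the two dimeric polyphenols stay strongly bound to sphingomyelin
14.4× and 10.1× longer than the monomeric control.

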