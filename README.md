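# crowdsearch

Coarse-grained simulation and analysis of a DNA-binding protein searching
for its target site on double-stranded DNA amid macromolecular crowders.

Proteins locate specific DNA sites by facilitated diffusion — 3D excursions
through the bulk alternating with 1D scanning (groove-tracking *sliding*
and short-range *hopping*) along the DNA. In vivo this happens in a medium
packed with inert macromolecules. `crowdsearch` builds the standard
coarse-grained model of that situation and asks how the crowder volume
fraction

```
Phi = 4 N_c pi R^3 / (3 Lx Ly Lz)
```

reshapes the search:

* **Model building** — ideal B-DNA with three beads per nucleotide
  (phosphate/sugar/base, phosphates −1 e), a one-bead-per-residue (Cα)
  protein with a structure-based (Gō-type) 12-10 contact potential
  (`load_protein()` for PDB input, or the packaged `toy_protein()`
  three-helix bundle), repulsive spherical crowders (radius 10 Å), and
  Debye–Hückel electrostatics between protein charges and DNA phosphates.
* **Dynamics** — BAOAB Langevin integration (γ = 0.05, 300 K, 140 mM salt)
  under periodic boundaries, driven by compiled kernels with Verlet
  neighbour lists; bitwise-reproducible from a seed.
* **Search analysis** — per-frame sliding/hopping/3D classification, mode
  propensities and event tables, positions probed, the 1D diffusion
  coefficient `D1` from segment-wise MSD fits, the crowder–DNA
  depletion-layer width `l_d`, and the z–θ correlation `R` of
  rotation-coupled sliding (−1 for perfect groove tracking).
* **Binding kinetics** — specific-contact time series `N_s(t)`, time to a
  contact fraction (`t_0.8`), association/orientation rates `k_A`/`k_O`,
  per-bp DNA deformation `D_s` against the ideal geometry, and
  binding-landscape ruggedness `σ^E_sp`.
* **Synthetic generators** — seed-deterministic fixtures with exact ground
  truth (mode-labelled trajectories, helical walks, kinetic contact ramps)
  that validate every analysis.

## Worked example

Equilibrate a 40-bp duplex among crowders at Φ = 0.1 and measure the
depletion layer, then dock the toy protein and watch it re-form its
specific contacts:

```r
library(crowdsearch)

box <- simulation_box(c(120, 120, 180))
asm <- toy_system(n_bp = 40, phi = 0.1, box = box, seed = 1,
                  protein = FALSE)
pr  <- sim_protocol(n_steps = 30000, record_stride = 300,
                    equil_steps = 10000, seed = 42)
tr  <- run_simulation(asm, pr)
depletion_width(tr)      # mean bp-to-nearest-crowder surface distance, A
#> [1] 12.06785
#> attr(,"per_bp")
#>  [1]  8.938432  9.802246 10.615724 11.762684 12.850323 13.411610 ...
#> attr(,"n_frames")
#> [1] 101

kin <- toy_system(n_bp = 40, phi = 0.2, box = box, seed = 1,
                  placement = "kinetic", kinetic_offset_bp = 0,
                  kinetic_radial_out = 6, kinetic_theta_off = 60)
kt  <- run_simulation(kin, sim_protocol(n_steps = 30000,
                                        record_stride = 300, seed = 5001),
                      stop_at_contacts = 15)
cs  <- contact_series(kt)
time_to_fraction(list(cs), 0.8)$t_f   # MD steps to 80% of 18 contacts
#> [1] 9300
```

This seed re-forms 15 of its 18 specific contacts after 9300 MD steps;
roughly half of desk-scale seeds stay censored at this step cap, which is
why the kinetics analyses carry explicit censoring bookkeeping. Averaged
over seeds, the depletion width at Φ = 0.1 is ≈ 12.4 Å and shrinks towards
≈ 6.4 Å at Φ = 0.4 — the crowder-free shell around the DNA narrows as the
medium gets denser, while the protein's 1D scanning statistics stay nearly
unchanged. `analyze_search()` bundles the full nonspecific-search summary
(propensities, `D1`, positions probed, `l_d`, protein–crowder excluded
volume, `R`) for any trajectory.

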