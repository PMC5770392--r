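---
title: "Coarse-grained target search on DNA in crowded media: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained target search on DNA in crowded media: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdsearch)
```

## The question the package addresses

A DNA-binding protein finds its specific site by facilitated diffusion: 3D
excursions through the bulk alternate with 1D scanning along the DNA, the
latter split into *sliding* (the recognition helix tracks the major groove,
so axial and rotational motion are coupled) and *hopping* (short
dissociation-reassociation jumps near the DNA surface). Inside a cell this
search happens amid macromolecular crowders. `crowdsearch` implements a
coarse-grained simulation of that situation — a Calpha protein with a
structure-based potential, a three-beads-per-nucleotide B-DNA duplex,
purely repulsive spherical crowders, Langevin dynamics in a periodic box —
together with every analysis needed to ask how the crowder volume fraction
$\Phi = 4 N_c \pi R^3 / (3 L_x L_y L_z)$ reshapes the search: search-mode
propensities, 1D diffusion, the crowder-DNA depletion layer, rotation-
coupled sliding, DNA deformation, binding-landscape ruggedness, and the
kinetics of specific-complex formation.

## Models

**Units.** Energies are in units of $k_BT$ at 300 K, lengths in Angstrom,
bead masses are 1; the reduced time unit follows from these, and all
kinetic quantities are reported in MD steps.

**DNA.** `build_ideal_bdna()` places phosphate (P), sugar (S) and base (B)
beads on an ideal B-form double helix (rise 3.4 Å, twist 34.3°, ~10.5
bp/turn; radial shells P 8.9 Å, S 6.9 Å, B 3.0 Å; the sugars flank the
minor groove at ±60° so the major-groove bisector of bp $i$ points opposite
the bp reference azimuth). Each 5′-terminal nucleotide lacks its phosphate,
so an $N$-bp duplex has $6N-2$ beads; phosphates carry $-1\,e$. Internal
energetics is a harmonic elastic network fit to the as-built geometry
(every intra-DNA pair closer than 12 Å gets a spring with $k = 5\,k_BT/$Å²
at its build distance), plus WCA repulsion between non-networked pairs.
This "harmonic terms fit to the ideal geometry" treatment keeps the duplex
shape and its thermal breathing without the full sequence-dependent
base-stacking machinery of three-site-per-nucleotide force fields, whose
melting/hybridization physics is outside this package's scope. Because the
network already encodes the duplex geometry, DNA-internal electrostatics
is omitted; charges matter only for the protein-DNA interaction. The
as-built geometry is simultaneously the reference for all deformation
measurements, which is why the deformation profile of a freshly built DNA
is exactly zero.

**Protein.** One bead per residue at the Calpha position; Arg/Lys $+1\,e$,
Glu/Asp $-1\,e$. The fold is maintained by harmonic bonds and angles fit to
the build pose and a structure-based (Gō-type) 12-10 contact potential,
$U = \varepsilon\,[5 (r_0/r)^{12} - 6 (r_0/r)^{10}]$, over all residue
pairs with $|i-j| \ge 4$ within 8 Å in the reference structure. No
dihedrals: for the compact bundles used here, bonds + angles + contacts
hold the fold, which is the minimal standard Gō variant. The default
$\varepsilon_{\mathrm{native}} = 2\,k_BT$ keeps the 60-residue toy bundle
folded at 300 K (Calpha RMSD ≈ 4 Å; at $1\,k_BT$ it melts). Any
single-chain PDB file can be loaded instead via `load_protein()`.

**Crowders.** Uncharged spheres of radius 10 Å interacting with everything
through excluded volume only. `count_crowders()` inverts the volume-
fraction formula with round-half-away-from-zero and reports the realized
$\Phi$ alongside the request.

**Interactions.** Electrostatics is a Debye–Hückel potential between
charged protein residues and between protein charges and DNA phosphates,
$U = l_B q_i q_j e^{-\kappa r}/r$ with $l_B$ and $\kappa$ derived from the
dielectric (78), temperature and ionic strength (default 140 mM, Debye
length ≈ 8.1 Å), force-shifted at $4\kappa^{-1}$ so energy and force are
continuous at the cutoff (that C1 continuity is what lets the
finite-difference force checks hold everywhere). Excluded volume is WCA
(truncated-shifted LJ, $\varepsilon_{ev} = 1\,k_BT$). Contact diameters:
additive bead radii (P 2, S/B 3, Calpha 2.5, crowder 10 Å) for every pair
involving a crowder and within the DNA — these set the depletion-layer
physics — but fixed slim diameters for protein-protein nonbonded pairs
(4.0 Å) and protein-DNA cross pairs (3.5 Å). The slim cross-sterics are a
deliberate model choice: with additive radii the recognition helix cannot
enter the major groove (the crystal-like bound pose carries thousands of
$k_BT$ of steric strain), whereas 3.5 Å leaves the default bound pose
strain-free. Specific protein-DNA contacts at the 9-bp target window use
the same 12-10 form with $\varepsilon_{\mathrm{sp}} = 2\,k_BT$ — twice the
excluded-volume scale — so the specifically bound protein does not fully
dissociate at 300 K.

**Docking and specific contacts.** `dock_protein()` lays the recognition
helix along the major-groove track at the window centre and scans the
insertion depth until the contact count (recognition residues within 7 Å of
window DNA beads) reaches 18, rejecting sterically clashing depths. With
18 contacts, "roughly half engaged" corresponds to $N_s \approx 8$–$10$,
the regime where specific-complex formation is slowest.

## Dynamics

`run_simulation()` propagates the system with the BAOAB splitting of the
Langevin equation ($\gamma = 0.05$, $T = 300$ K, $dt = 0.01$ by default;
$\gamma = 0$ reduces exactly to velocity Verlet). Forces come from compiled
kernels with a displacement-triggered Verlet neighbour list; all noise is
drawn from R's RNG, so a protocol seed fixes the trajectory bitwise.
Coordinates are stored unwrapped — interactions use the minimum-image
convention — so diffusive observables need no unwrapping step. Two weak
restraints keep the helical frame usable for analysis: a harmonic restraint
on the DNA centre of mass ($k = 1\,k_BT/$Å², drift well under 5 Å) and
$0.2\,k_BT/$Å² xy-restraints on the terminal two base pairs' sugar beads;
without the latter, rod rotational diffusion tilts the helix axis off $z$
over desk-scale runs and the cylindrical coordinates lose meaning. Dense
crowder fields ($\Phi \gtrsim 0.35$, beyond the jamming density of random
sequential placement) start from a seeded shuffled cubic lattice that the
equilibration phase melts; sparser fields start from uniform rejection
sampling.

## Analyses

**Search modes.** A frame is 3D diffusion (`D`) when every protein bead is
more than 30 Å from every DNA bead. Otherwise it is sliding (`S`) when the
recognition-helix centre of mass is within 13 Å of the DNA axis *and*
within 60° of the nearest bp's major-groove bisector, else hopping (`H`) —
so S and H are complementary within the 1D regime. The paper-level notion
"mostly inside the major groove" had to be quantified; 13 Å / 60° are
configurable arguments and are reported with every summary. Raw labels feed
the propensities; a 3-frame majority filter removes stride-level flicker
before event segmentation so single-frame blips do not fragment events.

**Helical coordinates and coupling.** $z$ is the axial position of the
recognition-helix COM, $\theta$ its azimuth about the DNA axis, unwrapped
by accumulated signed increments and *signed so that following the major
groove towards $+z$ decreases $\theta$*: an ideal groove-tracking path has
$dz/d\theta = -\mathrm{pitch}/360$ and a $z$–$\theta$ Pearson correlation
of exactly $-1$. The correlation pools sliding segments after centring each
segment, so offsets between separate sliding events do not masquerade as
coupling; for the synthetic mixture generator this makes the expected
correlation equal $-\rho$, the groove-coupled segment fraction.

**1D diffusion.** $D_1$ is half the least-squares slope of the MSD of $z$
over lag times pooled within contiguous S/H segments. Lags span 10–50% of
the shortest qualifying segment, capped at 5–25 frames: at lags comparable
to the segment length only a handful of independent displacement intervals
exist and the slope estimate degrades badly (20–40% errors were measured
with lags of hundreds of frames on $10^4$-frame walks). A fit with
$R^2 < 0.98$ is flagged, which catches ballistic (scripted) motion.

**Depletion layer.** $l_d$ averages, over base pairs and frames, the
distance from the bp centre (midpoint of the paired base beads — the same
local coordinate used for deformation) to the nearest crowder surface,
minus the base-bead radius: a surface-to-surface convention. The
crowder-crowder gap is each crowder's nearest-neighbour centre distance
minus one diameter, averaged the same way.

**Deformation and ruggedness.** For each frame the full DNA is rigidly
superposed (Kabsch) onto the ideal reference, removing rigid-body motion;
per-bp deformation is the mean displacement of the bp centre, and $D_s$ is
that profile normalised by its maximum (use `ds_normalize()` to share one
scale across ensembles at different $\Phi$). Landscape ruggedness
$\sigma^E_{sp}$ assigns every 1D frame to the protein's nearest bp and
takes the per-bp *population* standard deviation of the specific energy
(inside the target window) or the protein-DNA excluded-volume energy
(elsewhere), reported 3′→5′ by default.

**Kinetics.** A specific contact counts as formed when its distance is
below $1.2\,r_0$ (configurable). $t_{0.8}$ is the first time
$N_s \ge \lceil 0.8 \cdot 18 \rceil = 15$; runs that never reach it are
right-censored, excluded from means with the censoring fraction reported.
$\tau_1$ (association) is the mean first time the nearest bp lies in the
target window during a 1D frame, $k_A = 1/\tau_1$; $\tau_2$ (orientation)
is the mean extra time to the contact threshold, $k_O = 1/\tau_2$.

## Synthetic generators and what they do (not) show

`toy_protein()` builds a three-helix bundle from ideal helix geometry with
a positively charged DNA-facing recognition face (6 Arg/Lys, 4 Glu/Asp,
net $+2\,e$); `synthetic_mode_trajectory()` screw-transforms its bound pose
along the helix to realise prescribed S/H/D segment plans mid-band of the
classifier criteria; `helical_walk_trajectory()` emits Gaussian $z$-walks
with segment-wise groove coupling; `kinetic_ramp_ensemble()` emits contact
ramps with known arrival/completion laws. Every generator is
seed-deterministic and carries its parameters, so ground truth is exact.
Passing these tests shows the *analyses* are correct; it does not show the
physical model reproduces any particular protein's energetics — the toy
bundle is a structural stand-in, not Sap-1.

## Desk-scale study conditions

The published observables behind this model come from $10^8$-step
simulations of a 100-bp system with hundreds of replicas. The package's
own validation runs on a reduced system chosen once: 40-bp DNA in a
120 × 120 × 180 Å box (same crowder radius, salt, temperature and
friction), $10^4$-step equilibration and (2–6) × 10⁴-step production per
seed, 4–10 seeds per condition for equilibrium quantities and 100 seeds
per $\Phi$ for kinetics. Two consequences of that reduction are handled
explicitly rather than hidden:

* **Nonspecific propensities** are computed from the first DNA encounter
  onward. The 1D/3D time-share of a short bulk-start run is dominated by
  the initial approach time, which grows with $\Phi$; the search-phase
  analysis properly concerns the dynamics after nonspecific association.

* **Kinetic ensembles** start from the bound pose displaced 6 Å radially
  and rotated 60° out of the groove, isolating the orientation/re-insertion
  phase $\tau_2$. A full first passage from ≥ 10 bp away needs
  $10^5$–$10^6$ steps per run at this scale — consistent with the
  full-scale $t_{0.8} \approx 3\times10^5$ steps — which is out of reach
  for a 300-run desk ensemble. The start geometry was fixed from
  completion-rate pilots at $\Phi = 0$ only. Because 30–60% of capped runs
  remain right-censored, ordering comparisons between $\Phi$ values use
  censoring-aware one-sided Cox/log-rank statistics rather than means of
  completers.

## Numerical choices and degenerate inputs

Zero-step protocols return exactly the initial frame. `minimum_image()`
maps components into $(-L/2, L/2]$. Zero ionic strength is rejected
(screening length undefined); use the $\kappa \to 0$ limit explicitly.
`depletion_width()` with no crowders and `d1_coefficient()` with no
qualifying segment return flagged `NA`s rather than numbers. Angle forces
clamp $\cos\theta$ away from ±1. Ties in the majority filter keep the raw
label. The dense-placement lattice fallback jitters sites only within the
free spacing, so the ≥ 2R pair rule holds at build time by construction.

## Known limitations

Sequence-dependent DNA mechanics, base-pair melting, hydrodynamic
interactions and absolute time calibration (MD step → seconds) are out of
scope. The crowder-crowder nearest-neighbour gap of an equilibrated WCA
fluid at $\Phi = 0.4$ is sub-Angstrom (confirmed against an independent
hard-sphere Monte Carlo), so published gap values of several Angstrom for
nominally similar systems must rest on a different distance convention;
the package reports its own convention's value. Desk-scale nonspecific
runs rarely establish true groove-registered sliding from a cold bulk
start — orientational engagement takes $\sim 10^5$ steps — so sliding
propensities at this scale are small, and statements about their
$\Phi$-dependence are statements about flatness, not magnitude.
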