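---
title: "Models and methods behind ecdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ecdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecdyn)
```

ecdyn analyses trajectories of co-aggregating peptide mixtures — amyloid-beta
chains (Aβ40/Aβ42) with small cyclic neuropeptides (SST14, AVP) — through
five coupled lenses: aggregation state, hydrogen bonding, secondary
structure, solvent exposure, and the Essential Collective Dynamics (ECD)
descriptors of correlated motion. This vignette records the models, the
parameters that matter, what the synthetic generator does and does not
emulate, and the numerical choices a maintainer would want to know about.

## The data model

An `md_system` is a topology (chains, residues, atoms) plus one coordinate
set; an `md_trajectory` binds a `T × 3N` frame matrix to it with a frame
spacing `dt` in ps. All internal lengths are nanometres; Angstrom appears
only inside the PDB reader/writer. Atom and frame indices are 1-based
(idiomatic R); residue numbers are 1-based within each chain. Chain species
are recognised by exact sequence match against the four built-in sequences;
anything else is `OTHER`, is excluded from species-classified censuses, and
triggers a one-time warning. If a periodic box is present, chains are made
whole by per-chain minimum-image shifting before any distance computation —
a chain split across a boundary would corrupt every census downstream.

## Hydrogen bonds

The census uses the geometric convention of the GROMACS analysis ecosystem:
a bond exists when the donor–acceptor heavy-atom distance is ≤ `d_max`
(default 0.35 nm) and the hydrogen–donor–acceptor angle is ≤ `angle_max`
(default 30°). Neither cutoff has a single printed standard, so both are
arguments and are logged in the pipeline's run metadata. Amide hydrogens
missing from the structure are constructed 0.1 nm from N, anti-parallel to
the preceding carbonyl — the standard placement; explicit hydrogens are used
as-is. Donor/acceptor pairs fewer than two residues apart along a chain are
excluded (they share the peptide-bond frame and cannot hydrogen-bond).
Counts are classified by the species pair of the two chains (Aβ–Aβ, Aβ–SCP,
SCP–SCP) and split intra-/inter-chain; the `total` column is the exact sum
of the three classes, while `all_bonds` additionally counts bonds on
`OTHER` chains so nothing is silently lost.

`find_extrema()` smooths a census series with a centred moving average and
reports local extrema for snapshot selection. An extremum must dominate its
entire smoothing-scale neighbourhood, not just its two neighbours: the
residual ripple that survives a moving average otherwise spawns alternating
spurious extrema beside every true one. Plateau ties break to the earliest
frame.

## Secondary structure

Assignment follows the Kabsch–Sander rules computed from the backbone
electrostatic hydrogen-bond energy,
`E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)` kcal/mol with a bond
when `E < −0.5`. Two consecutive n-turns give a helix (G/H/I for n = 3/4/5);
parallel and antiparallel bridge patterns give strands, with isolated
bridges reported as B and ladder members as E; turns and bends (CA-trace
direction change > 70°) fill in; the remainder is coil. Priority is
H > E > B > G > I > T > S. The four-colour reporting categories merge bend
into coil. "Stable β-sheet content" is implemented as the window mean of the
per-frame percentage of residues assigned E, over Aβ residues by default —
the only definition needing no extra parameter; a persistence variant
(residue E in ≥ 50% of window frames) is available behind
`definition = "persistence"`. Residues missing a backbone atom are forced to
coil with a warning rather than failing the frame.

## Solvent-accessible surface area

Shrake–Rupley with a deterministic golden-spiral lattice (default 960
points/atom), Bondi radii (C 0.170, N 0.155, O 0.152, S 0.180 nm) and a
0.14 nm probe; all overridable since none of them is uniquely standard. The
hydrophobic/hydrophilic split defaults to the element policy (C/S
hydrophobic, N/O hydrophilic); a residue policy with a configurable
hydrophobic set is provided because published hydrophobicity colourings
rarely state their classification. Deterministic lattices converge in total
area well below 1% at 960 points, but the *relative* area of a nearly
buried atom is dominated by point-count shot noise at any practical lattice
size — convergence should therefore be judged against the atom's free-sphere
area, which is how the test suite asserts it. Window summaries report
first/last means, SDs, and the integer percent decrease
`round(100·(first − last)/first)` with half-up rounding.

## Aggregates

Two chains are in contact when their minimum heavy-atom distance is ≤
0.45 nm; the timeline keeps an edge only if it is present in at least half
of a reporting window's frames, which makes the status robust to transient
detachment–adsorption of single chains. Both numbers are conventions, not
published values, so they are arguments and logged. Composition strings are
canonical (Aβ species first, species counts sorted, e.g. `"3Aβ42+2SST14"`),
and raising the cutoff can only coarsen the partition. Terminus exposure is
the terminal residue's SASA relative to a reference computed *in the same
reduced representation* (the middle residue of an extended Gly-X-Gly built
by the package), rather than an all-atom literature table whose scale would
not match; the default surface threshold is 0.25. π-stacking contacts use
ring-centroid distance only (≤ 0.55 nm) because the ring stubs carry no
reliable plane orientation — a documented simplification.

## ECD descriptors

Within each 0.2 ns segment the positional covariance
`C = (1/T) Σ_t Δr Δrᵀ` is formed from deviations about the segment mean,
after (by default) superposing frames onto the segment mean, iterated once.
The top `d = 10` eigenpairs define the essential subspace; a warning is
logged when they capture less than 95% of the trace. Each atom is mapped to
an image `χᵢ = (√λ₁ e⁽¹⁾ᵢ, …, √λ_d e⁽ᵈ⁾ᵢ)/√Σ_k λ_k` in `R^{3d}` — the
√λ-weighting and normalisation make images dimensionless and comparable
across segments; the mapping is a documented strategy (`weighting = "none"`
gives the unweighted variant). Descriptors are segment averages: the pair
correlation `ρᵢⱼ` is the mean image distance between Cα atoms (small =
strongly coupled motion), flexibility `fᵢ` is the mean distance of a
residue's Cα image from the centroid of all main-chain images, and domains
of correlated motion are single-linkage clusters of the mean image-distance
matrix cut at a threshold, with clusters under 20 atoms off-domain and the
rest ranked by size. Internally the eigenpairs come from an SVD of the
centred `T × 3N` segment block — bit-equivalent to diagonalising `C` (the
test suite checks this against both `eigen()` and an independent Jacobi
solver) without ever forming the `3N × 3N` matrix.

Numerical details worth knowing: a segment with no variance at all maps
every atom to the image origin (otherwise the normalisation would amplify
numerical noise into arbitrary directions); eigenvalues are clamped at zero;
and the published clustering threshold of 0.008 for domain detection is
exposed but its scale depends on the image normalisation, so thresholds
should be calibrated from the empirical within/between distance gap of the
system at hand — the recovery experiments below do exactly that, never the
constant.

**Alignment policy.** Rigid-body superposition before covariance is ON by
default: on real trajectories diffusion would otherwise dominate the
leading eigenvalues. It is exposed (`align = FALSE`, the lab-frame variant)
because the right choice depends on the data: in the synthetic recovery
experiments the generator holds groups in place, and superposing the union
of two independently translating groups aliases their collective modes into
apparent within-group motion, destroying the very separation being
measured. Those experiments therefore run in the lab frame, and the
rotation-invariance guarantees are tested with alignment on.

## The synthetic generator

The generator emulates the *study design*, not the physics: 8 + 8 chains of
the four real sequences, built with ideal backbone geometry (NeRF extension;
N–CA 1.458, CA–C 1.525, C–N 1.329, C=O 1.231 Å; helix (−57°, −47°), strand
(−139°, 135°), coil drawn uniformly from φ ∈ [−150°, −60°], ψ ∈ [−60°, 150°],
and a turn motif frozen at (75°, −15°), chosen once by a geometric search so
a strand–turn–strand spec folds back on itself), packed sparsely with
surface gaps > 0.4 nm at ~4 mM (a 7.5 nm default box — the concentration
fixes the box only approximately). Cyclic peptides are linear chains bent by
a single hinge rotation that minimises the distance between the
disulfide-forming cysteines; the restraint shapes the built geometry only.
Resolution is backbone-level (N, CA, C, O, CB, plus CG/CZ ring stubs for
F/Y/W/H): sufficient for every analysis here — DSSP needs N/CA/C/O, the
census constructs its own amide H, SASA is atom-sphere based — and fast
enough for property-based testing.

Dynamics are latent-mode kinematics: each mode is a unit displacement shape
over a participating atom set whose amplitude follows a stationary
Ornstein–Uhlenbeck process (exact update
`a(t+Δ) = a e^{−Δ/τ} + N(0, σ²(1 − e^{−2Δ/τ}))`), on top of per-atom
isotropic Gaussian noise, inside per-group rigid random walks. Scheduled
events make two groups drift together at a set closing speed; contacts are
sticky — *any* two groups coming within the contact distance merge, whether
scheduled or chance encounters — so the recorded ground-truth partition is
always the trajectory's actual contact state. One master seed drives three
derived streams (amplitudes, noise, rigid motion), making trajectories
bit-reproducible.

What passing the recovery tests shows, and what it does not: the generator
has no force field, no solvent, no realistic conformational ensembles, and
its "correlated motion" is literally low-rank by construction. Recovery of
ground truth therefore validates the *machinery* — that the descriptors
detect exactly the correlation structure present — not that real Aβ/SST14
aggregates behave like the synthetic ones.

**Study conditions for the recovery experiments** (chosen once; the relevant
control is per-mode variance against the total noise trace `3N·σ_noise²`,
not merely the amplitude ratio): mode σ = 0.1 nm with τ = 10 ps; noise
σ = 0.002 nm for domain recovery (amplitude ratio 50); noise drawn uniformly
from 0.002–0.01 nm (a 5× range) for flexibility-rank recovery; noise
0.001 nm for the 8-internal-mode variance-capture check. Problem sizes: four
42-residue chains (~740 atoms) × 10⁴ frames at dt = 2 ps for domains, one
40-residue chain × 10⁴ frames for flexibility, 500-frame schedules for
aggregation status — sizes at which every experiment completes in seconds to
a couple of minutes on one CPU while leaving the statistics overwhelming
(Rand index 1.0, Spearman ≥ 0.99 across seeds).

## Replicate tables and windows

Footer arithmetic uses the sample (n−1) standard deviation and half-up
rounding at the printed precision — the combination that reproduces
published footer values from their per-trajectory entries (note that a mean
recomputed from *rounded* entries can legitimately differ from a footer
computed on unrounded data by one unit in the last digit). Reporting
windows are specified as `"first:Xns"` / `"last:Xns"` and are half-open, so
a 20 ns window at 0.2 ns spacing holds exactly 100 frames and yields
exactly 100 non-overlapping 0.2 ns segments; trailing partial segments are
dropped.

## Known limitations

* The reduced atom representation cannot express side-chain hydrogen bonds
  or ring-plane geometry; censuses on real all-atom structures will count
  more bonds than on the synthetic stand-ins.
* XTC reading is an adapter over Python's `mdtraj`; without it, use
  multi-model PDB or DCD.
* The ECD image mapping and the domain threshold scale are package
  conventions (documented above); absolute flexibility values are not
  comparable across different normalisations, only profiles and rankings.
* Single-linkage domain clustering chains through any bridge atom closer
  than the threshold; calibrate the threshold from the empirical distance
  gap, or raise `min_size`, when the gap is narrow.
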