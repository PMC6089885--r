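---
title: "Quantifying water transport through channel proteins from MD trajectories"
author: "chanflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying water transport through channel proteins from MD trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

# Scope

Aquaporins and related membrane channels conduct water in single file
through a narrow pore. Molecular dynamics (MD) simulation of such channels
produces trajectories from which several complementary observables
quantify transport: the number of complete permeation events, the osmotic
permeability of each monomer channel, the free-energy profile experienced
by water along the pore axis, the time-resolved pore geometry, the
residue contacts formed across monomer-monomer interfaces of the
tetramer, and the dominant collective motions of each monomer. `chanflux`
implements this analysis pipeline for plant plasma-membrane intrinsic
proteins (PIPs) and comparable channels, together with seeded synthetic
generators that produce trajectories with *known* ground truth, so every
stage can be validated quantitatively without running MD.

```{r setup}
library(chanflux)
```

# The channel coordinate system

All stages share one geometric convention. The axial origin (`z = 0`)
sits at the NPA motif region of the channel (the centroid of
user-selected anchor atoms, averaged over frames), and `z` increases
toward the extracellular side, which puts the ar/R selectivity filter of
a plant aquaporin near `z = +10` Å. The axis is the membrane normal
(`fixed_z`, the default, appropriate for a bilayer built in the xy
plane) or the leading principal axis of the anchor atoms
(`principal_axis`, for tilted synthetic channels). A water oxygen is
*inside* the channel at a frame when `z_lower <= z <= z_upper` (closed
planes) and its distance from the axis is at most `lateral_cutoff`.

The boundary planes, lateral cutoff, and axis definition are not
observable quantities; they are analysis parameters. The defaults —
`z_lower = -15` Å, `z_upper = +15` Å, `lateral_cutoff = 6` Å — span the
NPA (0 Å) through the ar/R constriction (≈ +10 Å) with vestibule margin
on both sides, and every stage accepts overrides. Boundary ties are
resolved by closed intervals on both planes; with floating-point
coordinates ties are practically measure-zero, but the convention is
fixed for reproducibility.

# Permeation events

A *complete permeation* is a passage from one bulk side, through the
channel interior, to the other bulk side. Each water is run through a
finite-state machine over the per-frame region states `below`, `inside`,
`above` and `outside_lateral`:

* an **up** event is recorded on the history below → inside (≥ 1 frame) →
  above, with no intervening return to the entry side; **down** is
  symmetric;
* a water that enters the channel and retreats to its entry side records
  nothing;
* a water in the axial slab but beyond the lateral cutoff is bypassing
  the pore (e.g. moving through lipid or another monomer); it resets the
  state machine to the side given by the sign of its `z`, so bypasses
  can never complete an event;
* one water may record many events; the reported total sums both
  directions, and the direction split is retained.

The state machine is path-based, so refining the frame sampling of a
fixed continuous path does not change the count (as long as no boundary
crossing is skipped between frames). Water positions are taken at every
available frame; 1 ps spacing is the intended resolution for event
counting, while 10 ps snapshots are sufficient for the occupancy and
radius stages.

```{r permeation}
g <- gen_planted_crossings(n_up = 5, n_down = 3, n_retreat = 4,
                           n_frames = 400, seed = 2)
traces <- extract_axial_traces(g$traj, g$geom)
count_permeation_events(traces)[c("total_events", "up_events", "down_events")]
```

# Osmotic permeability by collective diffusion

For a single-file channel at equilibrium, the osmotic permeability is
obtained from the dimensionless collective coordinate $n(t)$, which
accumulates the axial displacements of all inside waters divided by the
pore length $L$:

$$\mathrm{d}n = \sum_{i \in \text{inside}} \frac{\mathrm{d}z_i}{L},
\qquad p_f = v_w D_n,$$

where $D_n$ is the diffusion constant of $n(t)$ from the Einstein
relation and $v_w = 2.99 \times 10^{-23}\ \mathrm{cm}^3$ is the volume
of one water molecule (18.015 g/mol at 0.997 g/cm³). A net advance of
$n$ by 1 corresponds to one single-file crossing. A water contributes to
a step only when it is inside at both step endpoints; this excludes
bulk motion and re-entry jumps.

$D_n$ is estimated by splitting $n(t)$ into contiguous 200 ps windows,
computing the mean-squared displacement within each window, averaging
over windows, and fitting a least-squares line *through the origin* over
lags from one frame to half the window. The short-lag regime is the
diffusive one; longer lags within a window are noisy and are excluded.
Window-averaging, the through-origin fit, and the half-window lag cap
are this package's declared choices. A negative fitted slope (possible
in undersampled windows) clamps $D_n$ to 0 with a warning flag rather
than reporting a negative permeability.

```{r pf}
gb <- gen_single_file_channel(D_n_true = 1.0, n_waters = 100,
                              n_frames = 20000, dt_ps = 10, seed = 42)
tr <- extract_axial_traces(gb$traj, gb$geom)
osmotic_permeability(collective_coordinate(tr), bin_width_ps = 200)
```

The synthetic single-file generator behind this check draws independent
1D Brownian displacements whose per-step variance is calibrated so that
$n(t)$ diffuses at the requested $D_n$, with waters recycled
periodically at the domain boundaries so crossings continue at a
sustained rate (re-injection was chosen over reflecting walls precisely
to keep the crossing rate controllable). Across 20 seeds of a 200
ns-equivalent trajectory (20 000 frames at 10 ps) the mean recovered
$D_n$ sits within 20% of truth; the residual few-percent negative bias
comes from boundary steps excluded by the inside-at-both-endpoints rule.

# PMF from axial occupancy

The free-energy profile of water along the axis follows from Boltzmann
inversion of the mean occupancy $\langle n_i(z)\rangle$ of axial bins:

$$G_i(z) = -k_B T \ln \langle n_i(z) \rangle,$$

with $k_B T = 2.577$ kJ/mol at 310 K. Occupancies are accumulated from
snapshots at a 10 ps stride into 0.5 Å bins by default (the bin width is
an analysis choice; 0.5 Å resolves the NPA/ar-R features without
starving bins). Two conventions matter and are explicit in the API:

* **Zero-occupancy bins** are reported as *undefined* (`NA`), not
  $+\infty$: a bin never visited in a finite sample has an occupancy
  lower bound, not a measured free energy.
* **Offset**: profiles are shifted so the minimum over defined bins is
  zero (`min_zero`) for display; the `raw` convention retains absolute
  $-k_BT\ln\langle n\rangle$ values for algebraic checks. Barrier
  *differences* are offset-free and are the quantity to compare between
  systems.

Profiles of several monomers of the same type are combined by pooling
the frame-weighted occupancies first and inverting once
(merge-then-invert) — merging the trajectories, not averaging the PMFs;
the two differ whenever occupancies differ, since $\ln$ is nonlinear.

```{r pmf}
gauss5 <- function(z) 5 * exp(-z^2 / 18)
gp <- gen_boltzmann_axial(gauss5, n_samples = 1e6, seed = 3)
prof <- pmf_from_occupancy(gp$hist, temperature_K = 310)
pmf_barrier(prof)
```

# Temporal pore radius profiles

The pore radius at an axial position is the radius of the largest
sphere, centred in the plane at that position, that touches no atom's
van der Waals surface:

$$r(z) = \max_{(x,y)} \; \min_i \left( \lVert p - a_i \rVert -
  \mathrm{vdw}_i \right).$$

The maximiser is a seeded multi-start simulated-annealing search
(initial step 1 Å, cooling ×0.9, 16 proposals per stage, convergence at
0.01 Å, 3 restarts) followed by a deterministic pattern-search polish.
Profiles are built slice by slice from `z_lower` to `z_upper` (0.5 Å
step), each slice starting from the previous slice's centre. In the
default *local* mode, restarts and proposals are confined to a 2.5 Å
trust region around that starting centre: a pore-following profiler must
track the channel basin and must not tunnel through the wall into open
space, where clearances are trivially larger. A *global* mode (restarts
over the whole allowed disk, bounded by twice the lateral cutoff) exists
for globally multimodal slices and for validation against a dense
grid-search oracle. Radii can be ≤ 0 where the slice is occluded.

Van der Waals radii default to a Bondi-style table (C 1.70, N 1.55, O
1.52, S 1.80, H 1.20 Å) and are configurable; only protein (wall
selection) atoms are walls. Per-snapshot profiles taken every 10 ps are
averaged within 2 ns time bins and across the requested monomers into a
2D time × axial-position map.

On pseudo-atom fixtures the correct reference is the analytic *inscribed*
radius, not the generating surface: where the wall narrows steeply the
sphere touches neighbouring sections first, so the inscribed radius dips
below the nominal profile. The generator's truth record carries both.

```{r pore}
gcyl <- gen_pore_geometry(function(z) 4, vdw = 1.5, seed = 5)
prof1 <- radius_profile_frame(gcyl$traj, gcyl$geom, z_step = 1, rng_seed = 7)
max(abs(prof1$radius - gcyl$truth$inscribed(prof1$z)))
```

# Interface contact maps

Two heavy atoms of different monomers are in contact when within 4.0 Å;
an atom pair is *persistent* when the contact holds in at least 70% of
frames. The 70% criterion is applied per atom pair; persistent atom
pairs are then counted per residue pair, and counts are normalised by
the map maximum to give frequencies in [0, 1] (the normalisation scheme
is recorded in the result). Distances are computed exactly — no
neighbour-list approximation — and periodic images are ignored, which is
appropriate for intra-tetramer interfaces and is a documented
limitation. Difference maps subtract frequencies cellwise on the union
of residue pairs, with an optional label mapping (e.g. from the sequence
alignment below) that places two paralogs in one residue coordinate
system.

# Essential dynamics

Each frame is least-squares superposed onto a reference (frame 1, then
the mean structure in a second pass), and the covariance matrix of the
Cartesian coordinates (population normalisation, Cα selection by
default, no mass weighting) is diagonalised. Eigenvalues in descending
order give the variance along each collective mode; the cumulative
fraction of the first *k* modes summarises how concentrated the motion
is; extreme structures along a mode visualise it. The synthetic
harmonic generator plants orthonormal modes with set variances —
constructed orthogonal to the six rigid-body directions, since
superposition necessarily removes any rigid component of a mode — and
can wrap frames in random rigid motions to exercise the fitting stage.
Note that the fitted trajectory lives in the orientation of its own
mean structure, so planted and recovered mode *directions* are compared
after rotating one frame onto the other.

# Group comparison

Per-monomer metrics (events, $p_f$) are compared between groups with the
Mann–Whitney U test: $U = \min(U_1, U_2)$ with ties counting ½, exact
two-sided p by full enumeration of pooled-rank assignments (used
automatically for tie-free samples with $n_1, n_2 \le 12$; the
enumeration itself remains valid under ties), otherwise a normal
approximation with tie-corrected variance and continuity correction.
Two-sided tests are assumed throughout, and group summaries report mean
± SD with the $n-1$ denominator.

# Sequence comparison of paralogs

Channel paralogs are compared by global Needleman–Wunsch alignment under
EMBOSS-needle conventions: BLOSUM62, affine gaps (open 10, extend 0.5),
end gaps penalised, and identity/similarity percentages computed over
the full alignment length including gap columns. Similarity counts
identical columns plus columns with a positive substitution score.
Aligned-column bookkeeping maps residue numbers between the two
sequences (1-based), which supplies the residue correspondence used by
contact difference maps across paralogs. A small *synthetic* PIP-like
sequence pair ships in `inst/extdata/synthetic_pip_pair.fasta` for
examples; it is an invented demonstration input, not database data.

# What the synthetic generators do and do not show

Each generator reproduces the *statistics* one stage consumes — known
collective diffusion constant, Boltzmann occupancy under a known
profile, analytic wall geometry, planted contact fractions, planted
covariance — with bitwise-reproducible output for a fixed seed, and a
truth record sufficient to score the stage. They are not physical
models: waters are independent rather than hydrogen-bonded in file,
walls are rigid pseudo-atoms, contact toys have single-atom residues,
and harmonic modes are Gaussian. Passing these checks demonstrates that
the estimators are correct and calibrated, not that any particular MD
force field or sampling protocol is adequate; applied to real
trajectories the usual MD caveats (equilibration, sampling, force-field
accuracy) remain.

Problem sizes used in the shipped checks — 100 waters × 20 000 frames ×
20 seeds for permeability, 10⁶ Boltzmann samples for the PMF, 10⁴
frames for the mode recovery, 0.02 Å grid oracles for the pore slices —
were chosen so each stage's statistical error sits comfortably inside
its assertion band on a single CPU.

# Pipeline orchestration

`run_pipeline()` drives the stages per monomer from one YAML
configuration (validated against a schema; unknown keys are rejected),
writes `report.csv`/`report.json` plus a log, stamps outputs with the
MD5 hash of the configuration, and aggregates per-monomer values by
unweighted mean. Reruns with the same configuration and seed are
byte-identical. The package's functions are the primary interface; a
thin `Rscript` wrapper ships in `inst/scripts/run_pipeline.R`.

# Known limitations

* Coordinate input is PDB topology plus DCD or multi-model PDB; XTC/TRR
  must be converted upstream.
* Pore slices are plane-constrained along a fixed axis; a curved 3D
  centreline (as in HOLE's propagation) is out of scope, as are
  conductance predictions. Numerical parity with HOLE's own radius table
  and search schedule is not claimed; correctness is asserted against
  analytic and grid-search oracles.
* Permeability is equilibrium (collective diffusion); pressure-driven
  non-equilibrium protocols are not implemented.
* Contact maps ignore periodic images; hydrogen-bond geometric criteria
  and interaction energies are out of scope.
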