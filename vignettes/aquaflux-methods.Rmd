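---
title: "aquaflux: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{aquaflux: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## What the package computes

`aquaflux` is the analysis layer for molecular-dynamics studies of water
channels (aquaporins).  Given a structure (PDB), a trajectory (DCD or
multi-model PDB) and a channel geometry, it computes:

1. **Order parameters** — per-frame minimum-image distances and proper
   dihedrals.  For human aquaporin 5 the canonical local constriction
   indicators are D1, the distance between the NE2 nitrogen of the
   selectivity-filter histidine (His173) and the backbone oxygen of
   Ser183, and D2, the distance between the CB carbon of the
   cytoplasmic-gate histidine (His67) and the delta carbon of Ile165,
   together with the His173 ring dihedral (CA–CG–CD2–NE2) and the His67
   sidechain dihedral (CG–CB–CA–C).
2. **Gating states** — D2 is banded *closed* / *intermediate* / *open*
   with the intermediate band at 6.5–7.5 Å; D1 is banded *narrow* /
   *wide* around a single cutoff.  Joint two-letter codes (WO, NO, NI,
   WC, …) condition all transport estimates.
3. **Permeation counting** — complete water transits through the channel
   region, the one-directional rate $q_0$, and the diffusive
   permeability $p_d = v_w q_0$, with $v_w$ the specific volume of a
   water molecule ($V_m/N_A$, default $V_m = 18.0\ \mathrm{cm^3/mol}$).
4. **Collective transport** — the dimensionless collective coordinate
   $n(t) = \sum_i \Delta z_i / L$ over waters inside the channel, its
   diffusion coefficient $D_n$ from windowed mean-square-displacement
   regression, and the osmotic permeability $p_f = v_w D_n$.
5. **The single-file check** — for ideal single-file transport the
   continuous-time random-walk (CTRW) model predicts
   $p_f/p_d = N + 1$, with $N$ the mean channel occupancy; the package
   reports the ratio, the prediction and their deviation.
6. **Pore radius profiles** — per-slice maximal-sphere radii along z,
   with gating-state calls from the radius thresholds (selectivity
   filter *wide* above 1.1 Å; cytoplasmic end *closed* below 1.0 Å,
   *open* above 1.4 Å).

Everything is exercised end-to-end on synthetic trajectories with known
ground truth; no MD engine and no download is required.

## Channel geometry and region tracking

The channel is a z-aligned cylinder `[z_lo, z_hi]` with a radial cutoff
(default 6 Å) around an axis anchored either at a fixed (x, y) point or
at the per-frame centroid of a selection (e.g. the NPA-motif backbone).
The z boundaries of the counting region are **mandatory configuration**:
they cannot be inferred from a structure, and silently defaulting them
would make permeation rates irreproducible.  Every report echoes them.

Each water oxygen is labeled per frame *below*, *inside*, *above* or
*outside* (buffer zone or radially excluded).  A transit is counted only
when a water goes from one bulk (beyond a buffer, default 2 Å, past the
mouth) through the interior to the opposite bulk; mouth recrossings
count zero.  Labels are computed from coordinates minimum-imaged about
the channel center each frame.  This is a deliberate, stateless
alternative to cumulative per-water unwrapping: a periodic wrap far from
the channel appears as a direct below↔above jump that never passes
through the interior, and the event automaton ignores exactly those.
Step displacements are minimum-imaged per step, which is the local
equivalent of unwrapping and cannot fake a transit.

## The collective coordinate and its conventions

Per step, each water contributes the signed change of its channel-local
z **clamped to `[z_lo, z_hi]`** — i.e. exactly the displacement accrued
while inside the channel span — gated on radial membership at either end
of the step.  Two consequences matter:

* one complete single-water transit advances $n$ by exactly 1, which is
  what ties the $p_f$ and $p_d$ scales together; and
* waters teleported by re-injection or periodic wrapping contribute
  nothing while in bulk, because the clamp saturates on both ends.

$D_n$ is estimated on non-overlapping windows (default 2 ns), using all
time origins within a window for lags up to half the window, and an
ordinary least-squares fit with free intercept ($D_n$ = slope/2).  The
free intercept absorbs fast librational offsets; whether the original
analysis used overlapping windows is unstated, so the simpler
non-overlapping choice is made and exposed as `window_ns`.  A quadratic
diagnostic flags super-diffusive curvature (drift makes MSD $\sim t^2$).
Uncertainty is the standard error across windows, propagated linearly
into $p_f$; occupancies carry a blocked standard error with block length
equal to the window.

Permeabilities are reported in $10^{-14}\ \mathrm{cm^3/s}$, the
conventional single-channel unit, with the report rounding
(permeabilities 2 decimals, occupancy 1 decimal) matching the precision
of published per-state tables.  Undefined ratios ($p_d = 0$) are
rendered "–", never infinity.

## State classification choices

* D2 cutoffs default to 6.5/7.5 Å — the printed intermediate band;
  *closed* below, *open* above.
* The D1 *narrow*/*wide* boundary is only ever shown graphically in the
  literature, so the classifier default (6.0 Å) is a package choice; the
  pipeline refuses to classify D1 without an explicitly configured
  cutoff, and every report states the cutoffs used.
* Smoothing is a running median (default 5 frames) and hysteresis
  (default 0.2 Å) requires the value to cross `cutoff ± h` before a
  label change.  Implementation detail: a frame within `h` of a cutoff
  keeps the last decided label (leading undecided frames fall back to
  plain banding).  This is equivalent to classical hysteresis for
  band-crossing sequences and is vectorizable.  Both are off-able;
  with `hysteresis = 0, smoothing_window = 1` classification is a pure
  band lookup (property-tested).
* Segments shorter than `min_dwell_ns` (default 1 ns) merge into the
  longer flanking segment.  The default reflects that per-state
  transport estimates are meaningful only over long homogeneous
  "representative sections".

## The synthetic world

The generators state the world the tests live in; their defaults are not
tuned to outcomes.

**Hopping (CTRW) mode.**  `n_waters` (default 7) waters sit on sites
spaced $a = L/n_\mathrm{waters}$ in a channel of length $L$ (default
20 Å), with twice the channel occupancy of reservoir waters in bulk
slabs beyond each mouth.  The file hops rigidly by one site as a Poisson
process of rate $k$ per direction; the end water is pushed into the
destination bulk and a reservoir water enters the opposite mouth
(completed ground-truth transits are logged; re-injection across the
periodic box is handled so the analysis can never mistake it for a
transit).  By construction one hop advances $n$ by exactly 1, so
$D_n = k$; an entrant completes a transit with probability
$1/(N+1)$ (gambler's ruin on the $N$ sites), so $q_0 = k/(N+1)$ and the
ideal single-file relation $p_f/p_d = N+1$ holds exactly.  A noted
deviation: a hop length of $L/(N+1)$ (one reading of the sketchy textual
description of such generators) would give a ratio of
$N^2 (N+1)/ (N+1)^2 \ne N+1$; the $L/N$ spacing is the one consistent
with the CTRW model the check is built on, so it is used.

**Brownian mode.**  The column is a rigid periodic ring of waters with
Gaussian collective steps calibrated to
$\mathrm{Var}(\Delta n) = 2 D_n^\mathrm{true} \Delta t$.  This mode
validates the windowed-MSD estimator against a known $D_n$.

**What the generators do not emulate:** single-water exchange inside the
file, lateral water motion, protein flexibility, mouth dehydration
barriers, or any force-field physics.  A green estimator-recovery test
establishes that the estimator recovers the stated stochastic model —
not that the model describes any particular channel.

**Telegraph order parameters** are continuous-time Markov chains with
Gaussian emissions (labels returned as ground truth), used for
classifier-recovery and dwell-statistics tests.  **Toy pores** place
pseudo-atoms on rings with an analytic radius envelope; the pore-profile
tests compare against that envelope and against a 0.01 Å exhaustive
grid oracle.  **The gating fixture** builds His67/Ile165/His173/Ser183
with requested D1, D2 and dihedrals realized exactly (torsion placement
via the standard internal-coordinate construction).

## Pore radius profiling

The per-slice radius maximizes
$\min_i(\lVert(x,y,z)-a_i\rVert - r^\mathrm{vdw}_i)$ over (x, y) at
fixed z.  Instead of simulated annealing (the choice of the classic
HOLE program), `aquaflux` uses a deterministic compass search ascending
from a seed point, with steps from 0.5 Å halved down to $10^{-3}$ Å,
confined to a search cylinder (default 10 Å).  Determinism was chosen
over fidelity to HOLE internals because the original analysis used HOLE
as a black box and reproducibility of the artifact matters more.  The
search is local *by construction*: the unconstrained maximum escapes
through the pore mouth (clearance grows without bound outside), so the
profiler tracks the interior basin, seeded slice-to-slice
(continuation).  On non-convex slices this finds the pocket connected
to the seed axis — the quantity of interest for a channel profile.
Van der Waals radii default to a Bondi-like table (H 1.20, C 1.70,
N 1.55, O 1.52, S 1.80, P 1.80 Å; unknown elements 1.70 Å with a
warning); the radii actually in force travel with the topology and are
overridable.

## Numerical and degenerate-input policy

* Dihedrals are signed IUPAC torsions in $(-180°, 180°]$; collinear or
  coincident defining atoms raise an error rather than returning NaN.
* Only orthorhombic cells are supported; triclinic PDB/DCD cells are
  rejected so minimum-image arithmetic stays exact.
* PDB and DCD carry no time unit; frame times are synthesized from a
  configurable stride (default 0.1 ns per frame) because the snapshot
  frequency of a producing simulation is generally not recoverable from
  the files.
* Segments too short for two MSD windows report $p_f$ as unavailable
  rather than fitting a slope to noise; $q_0 = 0$ yields exactly
  $p_d = 0.00$ in reports.
* All generators take one integer seed and restore the caller's RNG
  state; the same seed gives bitwise-identical output.

## Known limitations

* The event automaton sees only saved frames: a transit completed
  entirely between two snapshots is invisible (tests therefore compare
  the pipeline against a path-scan oracle on the *same* snapshots, and
  against the generator's event log only statistically).
* The channel axis is a vertical line per frame; strongly tilted or
  curved pores are out of scope, as are XTC/TRR formats, PSF topologies
  and ion permeation.
* `p_f/p_d` on real single-file data is expected to undershoot $N+1$ in
  conducting states; the package reports the deviation and does not
  model its cause.
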