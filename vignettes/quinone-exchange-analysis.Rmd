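---
title: "Quantifying quinone exchange pathways from membrane-protein trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying quinone exchange pathways from membrane-protein trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quinex)
```

## The problem

Photosystem II (PSII) oxidizes water and hands its electrons to the mobile
carrier plastoquinone (PLQ), which is reduced at the exchangeable Q_B site
to plastoquinol (PLQol) and must then leave the complex, to be replaced by
a fresh PLQ from the thylakoid membrane. The traffic runs through a
lipid-filled *exchange cavity* inside the complex, connected to the bulk
membrane by narrow channels between transmembrane helices. Quantifying
this traffic from coarse-grained molecular-dynamics trajectories means
answering bookkeeping questions reliably: which compartment is each
ligand in at each time, when has it *really* crossed a channel, how often
does it reorient (flip-flop) between leaflets, and when has it left the
Q_B site for good rather than rattled in place?

`quinex` implements that bookkeeping as a tested pipeline:

1. **trajio** — read tagged beads, unwrap periodic images per ligand,
   superpose frames onto a protein-fixed reference (Kabsch least squares),
   discard equilibration.
2. **geometry** — a region model (membrane slab, per-monomer cavity,
   channels with planar gates, binding-site sphere) with deterministic
   point-location and channel-size measurement.
3. **events** — hysteresis-filtered state traces; passage, flip-flop and
   unbinding detectors.
4. **stats** — per-channel flux tables with s.e.m. over monomer
   replicates, cavity occupancy, timescale estimates, conservation audit.
5. **density** — 3D occupancy grids with OpenDX export.
6. **synthetic data** — a compartmental CTMC generator with exact ground
   truth, rendered into explicit coordinates, plus an adaptive-respawn
   harness.

## The region model

All analysis happens in a protein-fixed frame in nm, with the membrane
normal along +z and the stromal side positive. Regions come in three
shapes — z-slabs, convex prisms and sphere unions — which are enough to
express a membrane slab, box-like cavities and channels, and binding
sites, while keeping point-location exact and fast. Channels are prisms
with two oriented planar *gates*: the inner gate on the cavity boundary,
the outer gate towards the bulk. Planar gates make "crossing" a
well-defined, orderable event; meshed protein surfaces would not.

`locate()` resolves overlaps with a fixed priority: **channel > cavity >
binding site > protein footprint > bulk slab > off-membrane**. Channel
dwell must dominate at gate boundaries or passage counting would
fragment; and because the Q_B sphere sits inside the cavity, a bound
ligand still counts as cavity content, which is exactly what the
conservation bookkeeping needs (the only ways in and out of the cavity
compartment are the channels).

Two deterministic tie-breaks are fixed and tested rather than left to
floating-point chance: a head exactly on a compartment midplane is
assigned to the *lumenal* leaflet, and boundary points (depth 0) count as
inside a region.

Channel size is measured from two opposing groups of channel-lining
beads: width is the minimum inter-group bead distance, height the z
extent of the pooled opening clipped to the slab. The field reports
channel openings as width × height rectangles; minimum wall-to-wall
distance is one defensible reconstruction of that measurement and the one
implemented here.

## State traces with hysteresis

The raw label of a ligand is `locate()` applied to its *headgroup
centroid* — for an amphiphile the headgroup position is the physically
meaningful marker of which compartment (and which leaflet) the molecule
occupies. Raw labels flicker whenever a ligand diffuses along a boundary,
so `label_trace()` applies a two-threshold rule: a new label is accepted
only once the point has penetrated at least `hysteresis_delta_nm` beyond
the boundary of the new region (for the open labels — bulk, footprint,
off-membrane — once it is at least that far outside the previously held
region). The default of 0.3 nm is about one coarse-grained bead radius:
sub-bead-sized excursions are noise by construction. With the delta at 0
the trace reduces exactly to the raw labels, which is how the
implementation is cross-checked.

## Passage events and the conservation identity

`detect_passages()` scans each trace for maximal excursions into channel
interiors and classifies them **by their endpoints**: an excursion from
bulk that ends in the cavity is a *full entry* (and vice versa for
exits); one that retreats to its originating side is *partial*; one still
inside a channel when the trace starts or ends is *trapped*. Diffusive
recrossings inside one excursion do not fragment it.

Two design points deserve emphasis:

* **`min_dwell_ns` filters partial excursions only** (default 1 ns, two
  frames at the 0.5 ns analysis stride). A side-crossing excursion is a
  real compartment change no matter how fast it was; dropping it would
  break the exact balance below. What the dwell filter is actually for —
  suppressing boundary flicker — only ever produces same-side pokes, and
  those are what it removes. Raising `min_dwell_ns` therefore never
  increases any event count, and never changes full counts.
* **Trapped attribution.** For the balance, a ligand inside a channel at
  a trace boundary is attributed to the membrane side it came from (at
  the trace start: the side it first reaches). With these conventions the
  identity
  *Δ(cavity count) = full entries − full exits*
  holds **exactly** on every trace set, every seed — it is asserted by
  `conservation_audit()` and by the test suite across 50 random runs.

Orientation (`classify_orientation()`) asks whether the head or the tail
led through the decisive gate: the outer gate for entries, the inner gate
for exits. Operationally the crossing time is the first frame at which
the head (respectively tail-bead) centroid is inside the channel
interior within the event window; an excursion enters the interior
through its originating gate, so this is the gate-crossing time, and it
is robust to the approach direction in bulk. Same-frame crossings and
missing tails give `undetermined`.

## Flip-flops and unbinding

`detect_flipflops()` applies a dead band of `delta_z_nm` (default 0.3 nm)
around the compartment midplane to the head z coordinate: an event is the
head moving from beyond the band on one side to beyond it on the other
without leaving the compartment; leaving resets the detector. The
detector is validated against an exact telegraph process: over a time T
at switching rate k per leg the detected count must fall in the central
95% Poisson band of kT.

`detect_unbinding()` tracks the head-to-site distance with two
thresholds, `r_bound_nm = 0.6` and `r_unbound_nm = 1.2` (configurable
conventions, roughly bead contact and clearly-detached at coarse-grained
resolution): an excursion beyond the outer threshold that returns below
the inner one within `t_rebind_ns = 50` is *transient* (rapid rebinding),
otherwise *full*; a *partial* event is the tail centroid leaving the
channel interiors while the head stays put — the head-bound,
tail-released behaviour seen for quinols leaving the Q_B pocket.

## Statistics

Fluxes are reported as molecules ms⁻¹ per monomer. The unit of
replication is the **monomer**, not the event: each monomer's full-event
count divided by its monitored time gives one flux estimate, and the
table reports their mean ± s.e.m. over monomers (the typical design being
ten replicates: five simulations × two monomers). Cavity occupancy is
counted per frame from the traces, and the end-of-run statistic averages
a trailing window (default 5% of the trace) per monomer before averaging
over monomers.

`estimate_timescale()` encodes the estimator behind reorientation
timescales: n events observed over a total residence time R give R/n;
zero events give a *lower bound* equal to R (the convention that at most
one event was just missed — the emulated study's own convention for the
quinol case is unstated, so this explicit one is used). Fourteen events
over 1400 µs of cavity residence give the familiar 100 µs; zero events
over 200 µs give a 200 µs lower bound.

## Density maps

`accumulate_density()` bins selected bead positions (headgroups by
default) of an aligned trajectory into an axis-aligned voxel grid,
default 0.1 nm voxels. Counts are stored as raw integers so grids from
replicate runs merge exactly; normalization to occupancy happens only at
OpenDX export. Out-of-bounds observations are counted, making
*in-bounds + out-of-bounds = frames × beads* an exact invariant.
`threshold_and_project()` gives maximum-intensity projections and counts
26-connected components of the supra-threshold set — the practical way to
ask at which display threshold each channel's density path remains
connected to the cavity (no canonical threshold is asserted; at low
statistics a real pathway can drop below any fixed level).

## The synthetic generator

Validation needs data where the truth is known exactly. Instead of
Brownian dynamics with barriers (whose event statistics would themselves
need estimating), the generator is a **continuous-time Markov chain**
over eight compartments per monomer — stromal/lumenal bulk, channels
I–III, stromal/lumenal cavity, and the Q_B site (adjacent to the stromal
cavity, where the site physically sits) — simulated exactly (exponential
dwells, categorical jumps). Every statistic the pipeline reports has a
closed-form or directly countable ground truth.

The default preset mirrors the emulated study's conditions: 14 bulk PLQ
per monomer (~5 mol% of a monomer's membrane patch), one cavity PLQ, one
PLQol starting bound at Q_B; target full-passage fluxes 10/1/8 in and
4/1/6 out molecules ms⁻¹ monomer⁻¹; cavity flip-flop rate 0.01 µs⁻¹ (the
100 µs scale) against 1 µs⁻¹ in bulk; Q_B unbinding on the 10 µs scale.
Channel escape is symmetric (0.5 µs⁻¹ to each side, mean channel dwell
1 µs), so half of all attempts complete and attempt rates are set to
twice the target flux divided by the attempting population. Entry fluxes
are therefore realized essentially exactly (bulk depletion is ~2%); exit
fluxes ride on the cavity occupancy, which grows over a 95 µs run from 1
toward its stationary value — entries outnumber exits, as in the system
being emulated — giving realized exit fluxes ~25% above target on
average. This drift is well inside the 3σ sampling band at these counts
and is left in deliberately: it is a property of the study conditions,
not a calibration error.

`render_trajectory()` turns state paths into coordinates: the head bead
does a reflected Gaussian random walk (step σ 0.25 nm per 0.5 ns frame)
confined to a sampling volume inset 0.35 nm inside its current region —
safely beyond the 0.3 nm hysteresis delta, so labels are unambiguous —
and is routed through the shared gate at transitions (one frame just
beyond the gate face, then inward), which makes gate-crossing times well
defined. Five tail beads trail the head's recent path; ligands scripted
as tail-first lead with the tail instead, giving ground-truth
orientations. What this generator deliberately does **not** emulate:
excluded volume and ligand–ligand interactions, force-field energetics,
protein conformational gating of the channels (sizes that breathe by up
to 100% in the real trajectories), and the actual PSII architecture.
Passing the validation suite therefore certifies the *bookkeeping* —
labelling, event logic, statistics — not any physical realism of the toy
scene; on real trajectories the geometry configuration carries the
system-specific knowledge.

Seeding: one global seed feeds deterministic per-ligand substreams, so
enlarging the ligand set never reshuffles existing paths, and every
result in the package is bit-reproducible from its seed.

## Adaptive respawning

The adaptive harness mirrors the iterative protocol used to coax rare
binding events out of short simulations: run short runs, store visited
configurations at regular checkpoints (sampling uniformly in time, so a
null selector reduces to respawning from the visited distribution), rank
them with a pluggable progress coordinate, and restart the next batch
from the top of the ranking. The selection criterion in the emulated
study is qualitative, so the selector is an interface, not a guess. On a
three-state toy system (stable A, short-lived intermediate B, absorbing
target T) ranking by graph distance to T enriches hits over an
equal-budget plain-restart baseline roughly three-fold; a constant
selector is statistically indistinguishable from the baseline. The
protocol sizes used in the tests (6 rounds × 12 runs × 4 µs, 20 seeds)
were chosen for statistical power of those two comparisons.

## Validation problem sizes

The test suite exercises the pipeline at the following scales, chosen to
give each statistical check adequate power while keeping a full run in a
couple of minutes on one CPU: flux recovery at the full study conditions
(10 monomer replicates × 95 µs at the 0.5 ns stride, via state traces);
rendered-coordinate event fidelity over 20 replicates of 15 µs at a
ten-fold busier traffic (channel dwell and geometry — what detection
actually depends on — unchanged); conservation over 50 random runs;
10⁴-point location oracles; 10³ random label sequences against the
excursion-scanning oracle; 10⁵-sample density uniformity. Rendering all
ten 95 µs replicates at the 0.5 ns stride would produce ~10⁸ coordinates
and is intentionally not part of the default suite; the rendered route
is validated at the smaller scale, and the trace route at the full one.

## Known limitations

* Orthorhombic boxes only; non-orthorhombic unwrapping is out of scope.
* GRO/XTC input is not supported (no reader available in the R
  ecosystem used here); PDB+DCD is supported via bio3d, and the tabular
  TSV format is the lingua franca for tests and synthetic data.
* The hysteresis rule needs regions separated by more than the delta;
  two regions closer than 2×delta to each other could latch labels.
* Flip-flop detection uses the head bead only; a criterion based on the
  whole molecule's tilt would need tail geometry that the coarse
  trajectories do not reliably provide.
* The CTMC generator has no spatial correlation within a compartment, so
  it cannot be used to validate diffusion-coefficient estimators, only
  event and occupancy statistics.
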