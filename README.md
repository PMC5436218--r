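# quinex — quinone exchange pathway analysis

`quinex` quantifies how plastoquinone (PLQ) and plastoquinol (PLQol) are
exchanged between the thylakoid membrane and the photosystem II (PSII)
complex in molecular-dynamics trajectories. PSII reduces PLQ to PLQol at
the exchangeable Q_B site; the traffic of fresh and spent carriers runs
through a lipid-filled exchange cavity connected to the bulk membrane by
narrow channels (I, II, III). Turning raw bead coordinates into
statements like *"the flux through channel I is 10 ± 2 molecules ms⁻¹
per monomer"* requires careful event bookkeeping, and that bookkeeping is
what this package implements and validates.

## What it computes

Given a structure/trajectory (tabular TSV, or PDB+DCD via bio3d), a role
map (which beads are ligand heads, tails, protein reference) and a
geometry configuration (membrane slab, cavities, channels with gates,
binding sites), the pipeline produces:

* **State traces** — per-ligand compartment labels over time, from
  `locate()` on the headgroup centroid with two-threshold hysteresis
  (label changes accepted only beyond a penetration depth δ, default
  0.3 nm), plus leaflet annotation (stromal/lumenal).
* **Passage events** — channel excursions classified by endpoints as
  full entries (bulk → channel k → cavity), full exits, partials and
  trapped; per-channel flux tables in molecules ms⁻¹ monomer⁻¹ with
  s.e.m. over monomer replicates: mean ± sd/√n over the per-monomer
  estimates N_m/T_m. The exact identity Δ(cavity count) = entries −
  exits is audited on every run.
* **Orientation** — head-first vs tail-first gate crossings.
* **Flip-flop events** — leaflet reorientations of the head within the
  cavity or bulk, via a ±δ_z dead band around the midplane; timescale
  estimates τ = residence/n (n ≥ 1) or a lower bound τ ≥ residence
  (n = 0), e.g. 14 events over 1400 µs of residence → 100 µs.
* **Unbinding events** — full / transient (rapid rebinding) / partial
  (tail-only release) departures from a binding site, via two-threshold
  distance hysteresis.
* **Occupancy density maps** — 3D voxel grids of headgroup positions in
  the protein-fixed frame, exported as OpenDX; thresholded
  maximum-intensity projections with connected-component counts.
* **Synthetic ground truth** — a compartmental CTMC generator (exact
  Gillespie simulation, per-ligand seed substreams) rendered into
  explicit coordinates in a toy PSII scene, so every detector and every
  statistic can be checked against a known answer; plus an
  adaptive-respawn harness for rare-event enrichment experiments.

## Worked example

Recover configured channel fluxes from a synthetic exchange study — ten
monomer replicates of 95 µs with target fluxes 10/1/8 in and 4/1/6 out
(molecules ms⁻¹ monomer⁻¹):

```r
library(quinex)
model <- toy_psii_geometry(1L)
cm <- psii_ctmc()          # entry fluxes 10/1/8, exit 4/1/6 per ms per monomer
ev <- do.call(rbind, lapply(1:10, function(m) {
  paths <- simulate_ctmc(cm, 95, seed = 7000 + m)
  tr <- sample_state_trace(paths, stride_ns = 0.5, model = model)
  e <- detect_passages(tr)
  e$monomer <- m
  e
}))
flux <- compute_flux_table(ev, setNames(rep(95e3, 10), 1:10),
                           channels = c("I", "II", "III"), species = "PLQ")
print(flux)
#> Flux (molecules per ms per monomer), mean +/- s.e.m. over 10 monomer replicates
#>          Channel I    Channel II  Channel III
#> Flux in  11.58 ± 3.99 0 ± 0       6.32 ± 2.33
#> Flux out 4.21 ± 1.72  1.05 ± 1.05 8.42 ± 2.63

full <- ev[ev$completeness == "full" & ev$species == "PLQ", ]
mean_interevent_time(nrow(full), 10 * 95)
#> [1] 31.66667        # us between exchange events, 30 full passages
```

The recovered means sit within sampling error of the configured rates —
at ~1 expected event per cell per run (channel II), a zero is the most
likely single-seed outcome, which is why the statistics are reported
with their standard errors.

The same machinery runs on files. The package bundles a scripted
three-passage fixture:

```r
res <- run_pipeline(list(
  input = list(
    trajectory = system.file("extdata", "toy_three_passages.tsv", package = "quinex"),
    role_map   = system.file("extdata", "toy_role_map.json", package = "quinex"),
    geometry   = system.file("extdata", "toy_psii_geometry.yaml", package = "quinex")),
  out_dir = "toy_out"))
res$events[, c("channel", "direction", "completeness")]
#>      channel direction completeness
#> Q1.1       I        in         full
#> Q1.2     III       out         full
#> Q1.3      II        in         full
res$audit
#> Conservation audit: balanced for 1 monomer(s)
```

`run_pipeline()` writes the flux table, event TSVs, occupancy series,
timescales, conservation audit and a JSON manifest (seed, parameters,
input checksums) into `out_dir`; `simulate_dataset()` writes a complete
synthetic dataset (trajectory, role map, geometry, ground-truth log) for
external tools.

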