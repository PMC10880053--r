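# polylobe

Self-assembly simulations and structural analysis of **polydisperse lobed
patchy colloids** — rigid particles made of a repulsive seed sphere with
2–4 attractive lobe spheres whose diameters vary from particle to
particle.  Lobed colloids self-assemble into porous networks, elongated
clusters and crystals with tissue-engineering-scaffold applications, and
real syntheses produce lobes of *non-uniform* size; `polylobe` lets you
ask, on a desk machine, how that lobe-size polydispersity reshapes the
assembled structures.

It is aimed at soft-matter / coarse-grained simulation practitioners who
want a self-contained, scripted R workflow: model construction, dynamics
and analysis in one package with no external simulation or porosity
software.

## The model in brief

* **Particles.** A seed of diameter σ_S = 2 with N_L lobes (dumbbell DB,
  trigonal planar TP, tetrahedral TH) anchored rigidly on its surface.
  Lobe diameters are drawn from a Gaussian N(μ_G, σ_G²) truncated to
  [μ_G − σ_G, μ_G + σ_G], μ_G = 1 (the length unit), σ_G ∈ [0, 0.5].
* **Interactions.** Seed–seed and seed–lobe pairs repel through a
  surface-shifted, WCA-truncated Lennard-Jones potential
  U = 4ε[(σ_ij/(r−Δ))¹² − (σ_ij/(r−Δ))⁶] + ε with Δ = σ_ij − 1,
  ε_SL = 1; lobe–lobe pairs attract through a Lennard-Jones potential
  truncated and shifted at 3σ_ij with ε_LL = 3.  σ_ij is always the
  arithmetic mean of the two site diameters.
* **Dynamics.** Rigid-body Langevin dynamics (NVT) with a quaternion
  BAOAB integrator, dt = 0.005, cubic periodic box sized by the volume
  fraction rule N(V_S + N_L V_L)/φ at φ = 0.1 (box edges 75/78/80 for
  N = 1000 DB/TP/TH).
* **Metrics.** Radial distribution function g(r) of particle centres;
  relative neighbor orientation P(θ_jik); bonds per lobe (lobe pairs
  within 3σ_ij) with lobe-size/bond joint distributions; bond-network
  clusters; and a voxel-based pore-size distribution (largest included
  sphere, probe radius ½μ_G).

## Worked example

Assemble 64 dumbbells at T\* = 0.2 with σ_G = 0.3, then measure the bond
network:

```r
library(polylobe)

spec <- system_spec(64, "DB", phi = 0.1, T_star = 0.2,
                    poly = poly_spec(sigma_G = 0.3), rng_seed = 42)
spec
#> 64 DB particles, phi = 0.1, T* = 0.2, sigma_G = 0.3, box 30

traj <- run_simulation(spec, integrator_params(T_star = 0.2, rng_seed = 7),
                       n_equil = 1e5, n_prod = 1e5,
                       write_every = 2e4, log_every = 2e4)
traj
#> trajectory: 5 production frames, 10 scalar rows, 64 particles

final <- traj$frames[[length(traj$frames)]]
bonds_per_lobe(final)
#> bond stats: 128 lobes, 96 bonds, mean bonds per lobe = 1.500
cluster_labels(final)
#> 19 clusters; largest holds 25.0% of particles
rdf(traj$frames)
#> g(r): 300 bins (dr = 0.05) over 5 frame(s); max g = 30.4 at r = 3.18
```

Reading the numbers: at this low temperature the attraction
(ε_LL/T\* = 15) drives bonding — on average each lobe holds 1.5 partners,
the signature of branched rings and chains; a quarter of all particles
already sit in one cluster after this short desk-scale run; and the g(r)
peak at r ≈ 3.2 is the centre–centre distance of two particles joined by
a lobe–lobe bond.  At T\* = 1.0 the same system stays a gas (mean bonds
per lobe ≈ 0.15, no large cluster).

The state-diagram pipeline runs the full grid in one call and writes a
summary CSV for labeling:

```r
plan <- sweep_plan(shapes = "DB", T_star = c(0.2, 1.0), sigma_G = c(0, 0.3),
                   n_particles = 64, n_equil = 1e5, n_prod = 1e5,
                   output_root = "runs")
man <- run_sweep(plan)
man$summary
```

Porosity of any configuration (or of the analytic phantoms used for
validation):

```r
cav <- make_fixture("cavity_box", cavity_diameter = 4)
reg <- extract_dense_subbox(cav, min_density = 0.2)
pore_size_distribution(reg, cav, probe_radius = 0.5)
#> pore size distribution over 14390 voxels; modal diameter 3.8 (probe radius 0.5)
```

(The mode sits within two grid bins of the true 4 μ_G cavity diameter;
with the analysis grid centred on the cavity, as in the test suite, it is
exactly 4.0.)

## Package layout

| Area | Functions |
| --- | --- |
| Model building | `poly_spec`, `sample_lobe_diameter`, `build_blueprint`, `compute_box_edge`, `system_spec`, `initialize_configuration`, `actual_volume_fraction` |
| Force field | `pair_params`, `sslj_energy`, `lj_energy`, `pair_force`, `build_interaction_table`, `resolve_pair` |
| Dynamics | `integrator_params`, `body_inertia`, `compute_forces_torques`, `step_system`, `run_simulation` |
| Structure analysis | `rdf`, `bonded_lobe_pairs`, `bonds_per_lobe`, `neighbor_sets`, `relative_neighbor_orientation`, `cluster_labels` |
| Porosity | `extract_dense_subbox`, `distance_field`, `pore_size_distribution` |
| Pipeline & I/O | `sweep_plan`, `run_sweep`, `make_fixture`, `write_xyz`/`read_xyz`, `write_blueprints`, `write_metric_csv` |

The methods vignette (`vignettes/methods.Rmd`) documents the model
conventions, integrator, analysis definitions and their limitations in
full.
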