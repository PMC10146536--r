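# micellar

Structural analysis of single surfactant micelles from molecular-simulation
coordinate trajectories, built around the nonionic Triton X (TX-n) family:
a tert-octylphenol tail linked to a poly(ethylene oxide) chain of *n*
oxyethylene units ending in a hydroxyl (TX-5, TX-114, TX-100 with
*n* = 5, 7, 9).

Given multi-frame GRO/PDB coordinates of one pre-formed micelle plus water
in a periodic box — or a synthetic configuration from the built-in
generator — the package computes the standard micelle structure readouts:

- **Size and shape.** Radius of gyration
  *R*g² = Σᵢ mᵢ |rᵢ − r꜀ₒₘ|² / Σᵢ mᵢ, average micelle radius
  *R*s = √(5/3)·*R*g (the uniform-sphere relation), moments of inertia
  about the COM-centred x/y/z axes, their ratio *I*max/*I*min (1 for a
  perfect sphere), and eccentricity *e* = 1 − *I*min/*I*avg (0 for a
  perfect sphere).
- **Solvent-accessible surface area.** Waters removed, a 1.4 Å spherical
  probe rolled over the atomic van der Waals spheres (deterministic
  sphere-point sampling with cell-grid neighbour culling), decomposed
  exactly into hydrophilic (ether/hydroxyl O, hydroxyl H) and hydrophobic
  (CHₙ carbons) contributions.
- **Solvation structure.** Radial probability profiles of labelled atom
  positions about the per-frame micelle COM, radial distribution functions
  g(r), and hydration numbers as the count of water oxygens within 0.35 nm
  (equivalently the RDF integral n(r꜀) = 4πρ∫₀^{r꜀} g(r) r² dr).
- **Hydrogen-bond statistics and dynamics.** Geometric criterion —
  donor–acceptor distance within 3.5 Å and D–H···A angle ≥ 120° (a
  GROMACS-style H–D–A convention is available) — per-oxygen-position bond
  counts, and the intermittent time correlation function
  C_HB(t) = ⟨h(t)h(0)⟩/⟨h⟩ with curves ranked by decay speed.
- **Synthetic study systems.** A deterministic generator that places
  template-conformant TX-n surfactants on jittered radial spokes
  (controllable aggregation number, chain length, exterior-tail fraction)
  in a water bath, plus analytic fixtures (uniform spheres, spherical
  caps, ideal-gas baths) and two-state Markov hydrogen-bond kinetics with
  closed-form C_HB(t) — so every estimator is testable without running
  molecular dynamics.

Every window-averaged quantity carries a block-averaging standard error
(5 contiguous blocks by default), the convention for correlated
molecular-dynamics series.

## Worked example

Build a desk-scale TX-100 analog (20 surfactants, 2000 waters, 30 stored
frames) and run the full pipeline:

```r
library(micellar)
rec <- micelle_recipe(n_agg = 20, n_eo = 9, n_waters = 2000,
                      n_frames = 30, seed = 42)
cfg <- analysis_config(recipe = rec, window_last = 0.29, seed = 42)
rep <- run_pipeline(cfg)
print(rep)
```

```
micelle structure report (config 3bbd250c )
  rg                   2.1707 +/- 0.0005
  rs                   2.8024 +/- 0.0007
  ratio                1.2062 +/- 0.0016
  e                    0.0878 +/- 0.0008
  sasa_total         131.0110 +/- 0.1097
  sasa_hydrophilic    24.2432 +/- 0.1366
  sasa_hydrophobic   106.7678 +/- 0.2145
  hydration: C1=0.01 C2=0.01 C3=0.01 C4=0.01 CR=0.00 O1=0.03 O2=0.03
             O3=0.04 O4=0.04 O5=0.03 O6=0.04 O7=0.03 O8=0.03 O9=0.02
             OH=0.08 HO=0.12
  C_HB decay (fastest first): HO > OH > O1
```

Reading the report: the micelle is mildly ellipsoidal
(*I*max/*I*min ≈ 1.21, *e* ≈ 0.09), with *R*s ≈ 2.8 nm; the hydrophobic
area dominates the surface (CHₙ groups outnumber the polar oxygens even in
the head chain); hydration rises from the buried tail carbons and inner
ether oxygens to the terminal hydroxyl O and H, which also exchange their
hydrogen-bonded waters fastest (HO decays first). These are the
characteristic TX-micelle trends; absolute desk-scale values depend on the
generator's packing rules, not on force-field physics.

Individual stages are available as plain functions
(`shape_series`, `compute_sasa`, `radial_profile`, `hydration_number`,
`hbond_counts_per_position`, `chb_correlation`, ...), and
`inst/scripts/micellar.R` exposes them as shell subcommands
(`generate`, `run`, `shape`, `sasa`, `profile`, `hydration`, `hbonds`,
`trace`, `export`).

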