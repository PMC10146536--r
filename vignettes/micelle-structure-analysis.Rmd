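---
title: "Micelle structure analysis: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Micelle structure analysis: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
quantities, the estimators behind each exported function, the parameters
that matter, what the synthetic generator does and does not emulate, and
the numerical decisions taken where more than one defensible convention
exists.

## The system and its data model

The package analyses one pre-formed micelle of nonionic alkylphenol
ethoxylate surfactants (the Triton X family, `TX-n`) in water, stored as a
time-ordered list of frames over a fixed atom table. Lengths are nm, times
ps, masses amu. Boxes are orthorhombic only; triclinic input is rejected
rather than silently mis-wrapped.

A `tx_template` declares one molecule: a united-atom tert-octyl tail whose
terminal quaternary carbon (`C2` in the position labelling) marks the tail
end, a benzene ring, the poly(ethylene oxide) chain, and the terminal
hydroxyl. Ether oxygens are labelled `O1` (the phenol-linking oxygen,
innermost) through `On`; the terminal oxygen is the hydroxyl `OH` with
hydrogen `HO`. The linking oxygen is deliberately counted as the first
ether position so per-position analyses read inner to outer without a
special case; chemically the molecule is Ph–O–(CH2CH2O)n–H, so a template
carries exactly `n_eo` ether oxygens plus one hydroxyl. Aliphatic
hydrogens are implicit (united-atom convention, matching GROMOS-family
force fields); the hydroxyl hydrogen and water hydrogens are explicit
because hydrogen-bond geometry needs them.

Polarity classes are fixed by role: every carbon is hydrophobic (each
oxyethylene unit contributes a hydrophobic C2H4 and a hydrophilic O), the
ether/hydroxyl oxygens and hydroxyl hydrogen are hydrophilic, water is
solvent. Masses and Bondi van der Waals radii (united-atom CHn radii
inflated to 0.20 nm) ship as a versioned constant table
(`atom_properties()`, version `micellar-atom-properties-1`), so areas and
masses are reproducible bit-for-bit against a stated table version.

Atom indices are 1-based throughout, matching both R convention and the
1-based numbering of the GRO/PDB formats. PDB I/O delegates to bio3d with
an Angstrom-to-nm conversion at the boundary; GRO is parsed by fixed
columns with errors that name the offending line, because GRO is
position-defined, not whitespace-defined.

## Periodic geometry

`minimum_image` wraps displacement components into `[-L/2, L/2)`; the
half-open convention makes boundary behaviour deterministic.
`unwrap_micelle` first makes every molecule whole by walking its bond
graph (each bonded neighbour is placed at its minimum-image position),
then gathers whole molecules about the toroidal (circular-mean) centre of
the molecule centroids. The toroidal centre matters: a TX micelle is
routinely *larger than half the box* (the reference systems put a ~6 nm
micelle in a 10 nm box), so gathering relative to any single molecule
would mis-wrap distant molecules, while the circular mean is valid
whenever the micelle *radius* stays below half the box edge — which is
also the error condition the function enforces. Unwrapping is idempotent
and never touches water positions.

The analysis window defaults to the trailing 30 ns of the trajectory (the
equilibrated tail of a production run); trajectories shorter than the
requested window fall back to their last 15 percent of frames — never
fewer than 5, so block averaging stays defined — with a warning.

## Shape and size estimators

`radius_of_gyration` is mass-weighted by default (a flag switches to
geometric weighting). `inertia_moments` returns, by default, the moments
about the COM-centred coordinate axes — `I_x = Σ m(dy² + dz²)` etc. —
because the shape ratio `Imax/Imin` and eccentricity `e = 1 − Imin/Iavg`
are defined against fixed axes in the source convention this package
follows; a `principal` mode returns the rotation-invariant eigenvalues
instead, and the test suite documents explicitly that the coordinate-mode
ratio is *not* rotation invariant. `average_radius` applies
`Rs = sqrt(5/3) Rg`, exact for a uniform-density sphere; the Monte-Carlo
sphere fixture closes the loop by recovering `R` from sampled points.

Window uncertainties are block standard errors: the series is cut into 5
contiguous blocks (configurable) and the error is the standard deviation
of block means over `sqrt(n_blocks)`. Frame-level standard deviations
would understate nothing but correlate everything; block averaging is the
standard compromise for correlated series, and reports state the block
count.

## Solvent-accessible surface area

The accessible surface is defined by a 1.4 Å (0.14 nm) probe rolled over
the van der Waals spheres of the micelle atoms with all waters removed.
The implementation samples a deterministic Fibonacci point set (default
960 points) on each probe-augmented sphere and culls buried points against
neighbours found on a uniform cell grid, which keeps the neighbour search
linear in atom count at fixed density. This is a point-sampled realisation
of the same accessible-surface definition as lattice-based codes; it is
chosen because it is directly testable against closed forms — the isolated
sphere `4π(r+rp)²` and the two-sphere spherical-cap formula — and against
an independent brute-force implementation with a different point set.
Because hydrophilic and hydrophobic areas are sums of per-atom areas over
disjoint classes, the partition `total = hydrophilic + hydrophobic` is
exact, not approximate. At 960 points, doubling the point count moves
totals by under half a percent; that sampling tolerance is separate from,
and much smaller than, frame-to-frame time variance.

Periodic images are ignored during SASA: the micelle is analysed unwrapped
and must be smaller than the box, which the unwrapping stage enforces.

## Solvation structure

`radial_profile` pools COM distances of a labelled group over window
frames and members and normalises each histogram to unit integral
(`Σ P Δr = 1`); with this convention profiles of different groups are
directly comparable regardless of group size. The default bin width of
0.02 nm resolves micelle-scale layering without noise domination; the
multimodality check used by the tests (`count_modes`) smooths with a
short moving average and counts maxima above a tenth of the peak, a
deliberately blunt instrument that detects layer structure without
fitting.

`rdf` uses the standard pair normalisation — shell counts over
`n_centers × n_frames`, divided by the ideal-gas expectation
`ρ · V_shell` with exact shell volumes `4π/3 (r₂³ − r₁³)` — under
minimum-image distances, with `r_max` capped at half the smallest box
edge. `hydration_number` counts water *oxygens* within a half-open
`[0, 0.35)` nm cutoff of the labelled atom (water COM would be an
alternative convention; the oxygen is the standard proxy and the cutoff
convention is deterministic about ties). Using exact shell volumes makes
the direct count and the discretised RDF integral
`n(rc) = ρ Σ g_k V_k` algebraically identical on matched bins, which the
suite verifies to within 1 percent — the residual being binning of the
uneven centre environment, not estimator disagreement.

## Hydrogen bonds

The geometric criterion is donor–acceptor distance within 3.5 Å plus an
angular gate at 120 degrees. The angular wording of such criteria is
ambiguous in parts of the literature, so the convention is explicit and
switchable: the default `dha_min` reads "120°" as a *minimum* D–H···A
angle at the hydrogen (straighter, stronger bonds pass; 180° is ideal),
while `hda_max` implements the GROMACS-style maximum H–D–A angle (30° by
convention there). Ether oxygens are acceptor-only — chemically forced —
and the terminal hydroxyl both donates through its hydrogen and accepts
at its oxygen. Water–water bonds are never counted: the package analyses
micelle–water interaction only.

Per-position tables report, for each oxygen position, the mean bonds per
molecule per frame; the `HO` row is the hydrogen's-eye view of the bonds
its hydroxyl donates, so the oxygen rows alone partition the total
surfactant–water bond count (an invariant the suite checks exactly).

`chb_correlation` implements the intermittent correlation
`C_HB(t) = ⟨h(t₀+t) h(t₀)⟩ / ⟨h⟩` over all time origins (stride
configurable) and over the pair population defined as every (donor, H,
acceptor) triple bonded in at least one window frame. With that
population and binary indicators, `C_HB(0) = 1` is an identity
(`⟨h²⟩ = ⟨h⟩`), which pins the normalisation; an alternative would
restrict origins to bonded instants, changing long-time plateaus but not
the decay ordering. Bonds may break and reform within the lag — that is
what "intermittent" means — so for reversible exchange kinetics the curve
relaxes toward the equilibrium occupancy rather than zero.
`decay_ordering` ranks curves by trapezoidal area under `C(t)` (smaller
area = faster decay) with ties broken by input order, a deterministic
summary that needs no kinetic model. The two-state Markov generator
provides the exact reference
`C(t) = (k_on + k_off e^{−(k_on+k_off)t})/(k_on+k_off)`, sampled at the
exact discrete-time transition probabilities so the analytic curve is the
true expectation of the simulated one at every stored lag.

## The synthetic generator: what it emulates, and what it does not

`build_micelle` is a *structural emulator with controllable ground
truth*, not a thermodynamic model. It reproduces the structural features
the estimators consume: an aggregation number, a hydrophobic core with
tail-end carbons inside (`1 − f_out` of molecules) or in the head shell
(`f_out`, defaulting to 0.3 to represent the exterior-tail population
such micelles exhibit), ethoxylate chains extending outward with
per-atom perpendicular offsets at random phases (so no chain position is
systematically more exposed than another — an earlier alternating-offset
design biased even-numbered oxygens outward and was rejected), a water
bath uniform outside a per-atom contact envelope (surface clearance 0.11
nm from every vdW sphere, so water approaches polar oxygens closer than
aliphatic carbons), and frame-to-frame dynamics from a random walk on the
conformation phases plus diffusive water steps with a few percent of
waters exchanged per frame. Everything is deterministic given the recipe
seed.

Consequences for interpretation: hydration and hydrogen-bond *orderings*
(inner versus outer positions, across-system trends with chain length)
are meaningful because they follow from geometry the generator controls;
*absolute* hydration numbers and C_HB time constants are not calibrated
to any force field or temperature, and passing tests on synthetic data
demonstrates estimator correctness, not agreement of absolute values
with simulation or experiment. Reference-scale systems (aggregation
number 100, ~30,000 waters, 10 nm box) are expressible in a
`micelle_recipe`; the analysis sizes used by the test suite and the
acceptance script are desk-scale — aggregation number 30, 3000 waters, a
9 nm box, and 40–60 stored frames at 10 ps — chosen so the full suite
exercises every estimator with comfortable statistics on one CPU.

## Numerical choices and degenerate inputs

- Minimum image uses `d − L·floor(d/L + 0.5)`, giving the half-open
  interval exactly and avoiding banker's-rounding edge cases.
- Inertia-based shape descriptors reject non-positive moments (collinear
  degeneracies) instead of returning infinities.
- Histogram bins are half-open `[a, b)`; tests place fixtures mid-bin
  because a distance exactly at a bin edge is not a well-posed test of
  binning.
- The overlap-relaxation step in the generator pushes clashing
  inter-molecular pairs apart along their axis (with a small random
  component) until no non-bonded pair sits below 0.15 nm; it errors after
  a bounded number of sweeps rather than looping forever.
- `C_HB` errors when `⟨h⟩ = 0` (no bonds in the window) instead of
  returning 0/0.
- The pipeline embeds a provenance block (config hash, seed, package
  version) in every report so outputs are attributable to exact inputs.

## Known limitations

- Orthorhombic boxes only; no triclinic minimum image.
- SASA is point-sampled (no analytic Connolly surfaces) and reports no
  volumes or curvatures.
- No continuous (uninterrupted) hydrogen-bond correlation `S_HB(t)` and
  no kinetic model fitting beyond the closed-form test oracle.
- The generator makes no claim of thermodynamic realism; it cannot
  reproduce force-field-specific absolute values, only structural
  orderings.
- Equilibration detection is left to the user: `equilibration_trace`
  provides per-frame Rg/SASA series for inspection, but the package does
  not decide stationarity.
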