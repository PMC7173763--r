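---
title: "Gating order parameters and ensemble pKa estimation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gating order parameters and ensemble pKa estimation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poregate)
```

# The scientific setting

Voltage-gated potassium channels of the Kv1.2 family conduct through a
tetrameric pore domain (helices S5–P–S6). The conduction pathway contains a
water-filled cavity on the intracellular side of the selectivity filter;
the pore is open when that cavity is hydrated and the S6 inner helices are
bent at their PVP hinge, and closed when the cavity dewets and S6
straightens. Protonation of acidic residues and histidines near the
inter-subunit interface (E327, H418, E420 in Kv1.2 numbering) can drive
this transition, which is why channel gating is pH-sensitive.

`poregate` post-processes conformational ensembles of such a pore domain.
It does not run molecular dynamics and it does not solve
Poisson–Boltzmann electrostatics: trajectories arrive as multi-model PDB
files and per-microstate energies arrive as a CSV table from whatever
electrostatics/force-field machinery produced them. What the package owns
is (i) the geometric gating observables, (ii) their ensemble statistics,
and (iii) the statistical-mechanics reconstruction of titration behaviour
from the energy table.

# Gating order parameters

Three scalars are computed per trajectory frame.

**Cavity water count.** The literature rarely defines "in the cavity"
geometrically, so the package makes the region explicit and configurable:
a finite cylinder whose axis point is the Cα centroid of an axis residue
over the four chains, whose axial bounds are the projections of a
filter-base residue centroid (top) and a gate residue centroid (bottom),
and whose radius defaults to 5 Å. Water oxygens (residue names HOH, TIP3,
SOL, WAT) are counted with inclusive boundaries. The axis direction is by
default derived from the frame itself (the unit vector from the lower to
the upper bound centroid) rather than taken as a fixed laboratory +z;
this keeps the count — like the other two observables — exactly invariant
under rigid rotation of the whole system, which the test suite checks
against brute-force membership oracles and random rigid transforms. A
fixed axis vector can still be forced through the config for aligned
trajectories.

**S6 kink dihedral.** The torsion of the four Cα positions of L393, L400,
V408, Y415 (configurable), computed from plane normals with the sign taken
from the central-bond projection, and mapped to [0°, 360°). The
non-standard range matters: the straight-helix population sits near 245°,
which the conventional (−180°, 180°] range would split across the wrap.
Collinear bond vectors (cross-product norm below 1e-9) raise a
degenerate-geometry error rather than returning an arbitrary angle.

**Inter-subunit distance.** The minimum over all atom pairs between R326
of chain *i* and H418 of the next chain in the ring order A→B→C→D→A (all
four ordered pairs are computed; both the residue pair and the ring order
are configurable, since domain-swapped contacts make the chain mapping
convention-dependent). The default atom subset is heavy atoms: nearest-atom
distances involving hydrogens would change with the very protonation
states under study.

# Ensemble statistics

Trajectories are pooled per variant over the final
`window_fraction` of each run (default 0.25 — the equilibrated final
quarter, e.g. the last 500 ns of a 2 µs production run), keeping
`ceil(window_fraction × n_frames)` frames per trajectory.

Hydration is classified wet/dewet by a threshold count, inclusive at the
boundary. When the config leaves the threshold at `"auto"`, it is placed
at the midpoint of the two dominant modes of the pooled water-count
distribution, but only when the distribution is genuinely bimodal: the two
most prominent modes must be more than 5 waters apart and separated by a
population valley (smoothed mass below half the smaller peak). Otherwise a
fixed fallback of 10 waters is used, so a fully wet ensemble is never
split on sampling noise around its single peak. Gating figures customarily
draw the wet/dewet line without printing its value; the default scheme
makes that line reproducible.

Distributions use fixed-width bins (defaults: 2° for dihedrals, 0.25 Å for
distances, 1 for water counts); dihedral histograms are circular over
[0°, 360°). Modes are local maxima of a moving-average-smoothed histogram
(default window 5 bins, i.e. roughly the 10° within-state spread of the
kink dihedral) with prominence at least 10 % of the global maximum;
circular observables are smoothed and compared with wrap-around.

Population heat maps bin paired observables into a counts matrix whose
total always equals the number of pooled records; the log10 population
scale of the rendered maps is applied only at plotting time,
with empty bins masked. The correlation attached to each map is Pearson's
r computed on the raw unbinned pairs (Spearman available via config) —
binning first would bias r. Correlations pair chain *i*'s dihedral with
the (*i* → next) distance and replicate the per-frame water count across
the four chains; they are computed on the pooled ensemble by default,
with per-trajectory averaging available as a flag since reports rarely
state which convention was used. Note the sign
convention: because the cavity dewets as the dihedral grows, the
water–dihedral correlation of a gating ensemble is *negative*; reports
that quote a positive magnitude are quoting |r|.

# Ensemble titration

The titratable system is a set of sites, each with a reference-compound
(model) pKa, and a table of energies E(x, m) over protonation microstates
x (binary vectors) and ensemble structures m, in kcal/mol. The model
reduces the table row-wise to ⟨E⟩(x) and σ(x) and assigns each microstate
the pH-dependent free energy

$$G(x;\mathrm{pH}) = \langle E\rangle(x) + \ln(10)\,RT\sum_i x_i(\mathrm{pH} - \mathrm{p}K_a^{\mathrm{model},i})$$

with RT = 0.0019872 × T kcal/mol (T defaults to 310 K and is never
hard-coded). This is the standard proton-binding convention of constant-pH
statistical mechanics; acids and bases differ only through their model pKa
and whatever the supplied energies encode. Protonation fractions are
Boltzmann averages over microstates, evaluated in the log domain
(log-sum-exp), so adding any constant to all energies — or shifting them
by ±500 kcal/mol, as a property test does — changes nothing.

Working with every microstate is usually unnecessary: the estimator first
selects the states whose normalised Boltzmann weight reaches
`weight_threshold` (default 1e-6) anywhere on the pH grid, always keeping
the top-weight state per grid point. This mirrors the practice of
pre-selecting the predominant titration states of a pH range before the
expensive energy evaluations. At a threshold of 1e-12 the subset
reproduces full 2⁸ enumeration to better than 1e-10 in θ; exact
enumeration is capped at 20 sites, beyond which Monte-Carlo titration
sampling would be needed (out of scope).

The pKa is the smallest pH where θ crosses ½, located by linear
interpolation between bracketing grid points (the default grid is pH 3–8
in steps of 0.01). Curves that never cross report NA; curves crossing more
than once report the smallest crossing and set a `multi_crossing` flag.
Because θ has an inflection at ½ for a near-independent site, linear
interpolation is extremely accurate there.

**Uncertainty.** Structural fluctuation enters through σ(x): for each
k = 0.1 … 1.0 the pKa is recomputed with every microstate's energy set to
⟨E⟩ + kσ(x) and to ⟨E⟩ − kσ(x), and the band is the (min, max) of the two
results. The shift is applied to all microstates simultaneously with a
common sign because the granularity of the published ±kσ sweep
(per-microstate, global, or per structure subset) is not documented; the
global choice is recorded in the fit object's `uncertainty_scheme` field.
Bands are nested in k by construction, and for a single site whose
protonated state has energy sd σ₀ the k = 1 half-width is exactly
σ₀/(RT ln 10) ≈ 0.705 pH units per kcal/mol at 310 K — a closed form the
tests verify to 1e-4. A single-structure table yields σ = 0 and collapsed
bands, with a warning.

When the sites table omits model pKa values they default to Glu 4.25,
Asp 3.71, His 6.54, Lys 10.40, Arg 12.10, C-terminus 3.80, N-terminus
8.00 — the reference values electrostatics packages conventionally
inherit; published workflows rarely print them.

# The synthetic generator

Real trajectories and energy tables for this system are not publicly
deposited, so the package's validation rests on a generator whose ground
truth is known exactly.

**Toy channel.** A global latent state (open/closed) follows a two-state
Markov chain — all four chains switch together, the simplest mechanism
that produces the observed cross-correlations; per-chain switching can be
emulated by running chains separately. Conditional on the state, each
frame draws: per-chain kink torsions from a wrapped normal (means 130°
open / 245° closed, sd 10°), per-pair separations from a normal (means
6.0 / 14.7 Å, sd 1.0 Å) realised exactly by placing single-atom
R326/H418 proxies on a chord, and a Poisson water count (rates 25 / 3)
placed uniformly in the cavity cylinder (radius 5 Å, height 16 Å, encoded
by marker residues 401/402/417). The state-conditional means and the
Poisson rates reflect reported Kv1.2 gating observations; the
within-state spreads, the 0.05 default switch probability (dwell times of
~20 frames, so a 2000-frame trajectory mixes well) and the cavity
dimensions are the package's own choices, made once, of what a
practitioner would call realistic at this scale. A small isotropic jitter
(sd 0.02 Å) decorrelates coordinates from the exact construction without
measurably moving any observable. All draws are deterministic under the
spec's seed, and the generator restores the caller's RNG state.

Because the observables are conditionally independent given the latent
state, their Pearson correlations have the closed mixture form
`r = u·ΔX·ΔY / sqrt((u·ΔX² + vX)(u·ΔY² + vY))` with `u = p(1−p)` at the
stationary open fraction p; `toy_expected_correlations()` evaluates it,
and the end-to-end tests require the measured pooled correlations to land
within ±0.05 of it (with the analytically predicted signs — positive for
distance–dihedral, negative for waters–dihedral).

What the toy does **not** emulate: realistic helix geometry, lipids and
ions, per-chain asymmetric gating ("2-fold symmetric" intermediates),
slow single-transition trajectories, water exclusion volume, or any
coupling between conformation and titration. Passing the end-to-end tests
therefore demonstrates that the estimators recover known two-state
structure from correctly formatted data — not that any particular real
channel behaves this way.

**Energy tables.** E(x, m) = Σᵢ xᵢ·shiftᵢ + Σᵢ<ⱼ Wᵢⱼxᵢxⱼ + ε with
ε ~ N(0, noise_sd²), seeded; energies are rounded to 1e-6 kcal/mol so CSV
round-trips are byte-exact. Ground-truth curves come from full
enumeration on the noiseless means through a deliberately separate
direct-sum code path, giving the closed-form check that a shift of
ln(10)·RT lowers the true pKa by exactly one unit, and an independent
oracle for the fitting routine (agreement to 1e-10 on noiseless tables).

# Numerical choices and problem sizes

- Boltzmann sums: log-sum-exp with per-column max subtraction; no
  temperature-dependent constants are cached.
- Dihedral degeneracy: cross-product norms below 1e-9 error out.
- Histogram binning: half-open bins with the top edge closed; values
  exactly on a cavity boundary or at the wet threshold are counted in.
- Pooling uses `ceil`, so a 7-frame trajectory at fraction 0.5 keeps 4.
- PDB coordinates are written at the format's 0.001 Å fixed-column
  precision, and the generator rounds to the same precision so write→read
  is the identity. Insertion codes and altlocs are rejected, not dropped.
- Test and validation sizes: 8 sites (256 microstates) for enumeration
  checks, 50 structures for noisy recovery, 5 × 2000 frames for the
  end-to-end gating suite, 1000 random inputs per geometry oracle. These
  sizes make every distributional claim testable in well under a minute
  each while keeping Monte-Carlo error far from the asserted tolerances.

# Known limitations

- Titration and conformation are decoupled: the energy table is taken as
  given per structure, with no reweighting of structures by protonation
  state.
- The ±kσ band is a sensitivity sweep, not a credible interval; it has no
  coverage guarantee.
- The cavity is a cylinder; strongly tilted or deformed pores would need
  the per-frame axis (default) and possibly a smaller radius.
- `estimate_pka` reports the first ½-crossing; strongly coupled sites with
  non-monotone θ should be inspected via the full curve and the
  `multi_crossing` flag.
- Exact enumeration caps at 20 sites; larger systems need sampling
  methods the package intentionally does not provide.
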