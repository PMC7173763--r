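# poregate

Post-processing tools for molecular-dynamics ensembles of tetrameric
potassium-channel pore domains (Kv1.2-style S5–P–S6 constructs), built
around two questions:

1. **Is the pore open or closed, and how do we see it in the trajectory?**
   Three per-frame gating order parameters distinguish the conformations:
   the number of water molecules in the intracellular cavity (wet = open,
   dewet = closed), the S6 kink dihedral spanned by the Cα atoms of four
   residues along the inner helix (bent ≈ 130°, straight ≈ 245°), and the
   inter-subunit nearest-atom distance between an arginine and the
   histidine of the adjacent subunit (≈ 6 Å open, ≈ 15 Å closed).
   Windowed ensembles are pooled into distributions with mode detection,
   2D log-population heat maps and order-parameter correlations.

2. **Which protonation events drive closure?** Given a table of energies
   E(x, m) for protonation microstates x evaluated on ensemble structures
   m (from any continuum-electrostatics/force-field workflow), the package
   reconstructs the pH-dependent partition function

   G(x; pH) = ⟨E⟩(x) + ln(10)·RT·Σᵢ xᵢ·(pH − pKaᵐᵒᵈᵉˡᵢ)

   θᵢ(pH) = Σₓ xᵢ e^(−G(x;pH)/RT) / Σₓ e^(−G(x;pH)/RT)

   and reports per-site protonation fractions θᵢ(pH), the pKa (the pH
   where θ crosses ½) and a structural-fluctuation uncertainty band
   obtained by re-estimating with all microstate energies shifted to
   ⟨E⟩ ± kσ(x) for k = 0.1 … 1.0.

Because published gating studies rarely deposit trajectories or energy
tables, the package ships a synthetic generator: a toy tetramer whose
three observables co-vary through a shared latent open/closed Markov
state, and microstate energy tables with analytically known titration
curves. Both serve as ground truth for every statistical claim the
package makes.

## Worked example: titration

A two-site energy table in which glutamate E327 carries a conformational
penalty of exactly ln(10)·RT ≈ 1.4185 kcal/mol per bound proton (so its
true pKa is the model value minus 1) and H418 is unperturbed, with 0.2
kcal/mol structure noise over 10 structures:

```r
library(poregate)
rt_ln10 <- 0.0019872 * 310 * log(10)
esp <- toy_energy_spec(
  sites = data.frame(site_id = c("E327.A", "H418.A"),
                     model_pka = c(4.25, 6.54),
                     shift = c(round(rt_ln10, 4), 0)),
  n_structures = 10, noise_sd = 0.2, seed = 11)
te  <- generate_energy_table(esp)
fit <- titration_fit(te$table, te$sites)   # pH 3-8, step 0.01, 310 K
summary(fit)
#> Ensemble titration summary (10 structures, 310 K)
#> uncertainty: global common-sign +/- k sigma shift
#>
#>  site_id   pka multi_crossing band_low band_high band_k
#>   E327.A 3.207          FALSE    3.190     3.224      1
#>   H418.A 6.602          FALSE    6.597     6.607      1
```

The point estimates sit within the noise-induced scatter of the true
values (3.25 and 6.54); the `band_low`/`band_high` columns are the
⟨E⟩ ± 1σ band. `coef(fit)` returns the pKa vector, `predict(fit, ph)`
evaluates θ at new pH values, `confint(fit, k = 0.5)` returns any fitted
band, and `plot(fit)` draws the curves.

## Worked example: gating statistics

Two synthetic variants — a wild-type-like ensemble that stays open and a
doubly-protonated-like ensemble that transitions — analysed with the
default last-25 % pooling window:

```r
suite <- make_variant_suite(c("WildUnP", "Ep327_Hp418"), n_trajectories = 2,
                            base_spec = toy_channel_spec(n_frames = 600),
                            master_seed = 8)
sers <- unlist(lapply(names(suite), function(v)
  lapply(suite[[v]], function(tr)
    extract_series(tr$frames, variant_label = v))), recursive = FALSE)
variant_report(sers)
#>       variant n_records r_dist_dihedral r_waters_dihedral wet_threshold
#> 1     WildUnP       300         -0.0299            0.0168            10
#> 2 Ep327_Hp418       300          0.9594           -0.9362            15
#>   frac_wet distance_modes dihedral_modes
#> 1    1.000          6.125            131
#> 2    0.493   6.125;14.625        131;247
```

The mixed variant shows the signature of gating: bimodal distance
(≈ 6 / 14.7 Å) and dihedral (≈ 130° / 245°) distributions, a strong
positive distance–dihedral correlation, a strong negative water–dihedral
correlation (the cavity dewets as S6 straightens), and ~50 % cavity
occupancy. The always-open ensemble has single modes and near-zero
correlations.

## Command line

A thin dispatcher over the same functions is installed at
`inst/scripts/poregate`:

```sh
Rscript inst/scripts/poregate all --out runs/demo --seed 3
```

runs synth → orderparams → gating → pka on one shared config and writes
series CSVs, per-variant summaries, heat-map matrices, titration curves,
a pKa summary with ten band columns, and JSON run manifests.

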