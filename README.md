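# multibind

Statistical-mechanical analysis of small-ligand binding to **multiple
independent, saturable sites** on a membrane protein.

Many small drugs and anesthetics do not bind membrane receptors one-to-one:
they occupy several transmembrane pockets at once, some of which hold one
*or two* copies of the ligand, in a concentration-dependent way. Given
per-site restrained free-energy-perturbation (FEP) estimates — a harmonic
restraint constant `k` (kcal/mol/Å²) and a cumulative reversible work `W*_n`
(kcal/mol) per site and occupancy level, plus the ligand's reservoir excess
chemical potential `μ̄` — this package computes everything downstream of
those numbers:

- **per-site equilibrium constants** and standard binding free energies

  `K_n = (1/n!) ∏ᵢ (2π/βkᵢ)^(3/2) exp(−β(W*_n − n μ̄))`,
  `ΔG° = −β⁻¹ ln(K_n (C°)ⁿ)` with `C° = 1 M ≡ (1660 Å³)⁻¹`;

- **occupancy-state distributions** `ρ(n₁,…,n_s) ∝ cⁿ ∏ⱼ K_{n_j}` at any
  reservoir concentration, by full enumeration (log-sum-exp, up to 10⁶
  states) or factorized marginals at any size, plus macrostates, ensemble
  averages and titration curves;

- **symmetry-class averages** for f-fold oligomers (mean ± population sd on
  the K scale, state-constant reconstruction from class constants);

- **binding-site resolution** from docking-pose centroids (deterministic
  single-linkage clustering into spherical site volumes, double-occupancy
  assignment of re-docking poses);

- **spatial ligand densities**: kernel conditional densities
  `ρ(R | n_j)` normalized to `n_j`, occupancy-weighted site densities
  integrating to `⟨n_j⟩`, transmembrane z-profiles
  `ρ(z) = ρ̄·A(z) + Σⱼ ρⱼ(z)`, and OpenDX export;

- **seeded synthetic generators** (affinity tables, harmonic pose clouds, a
  Metropolis occupancy sampler) that double as independent oracles in the
  test suite.

It ships the worked reference system — twelve sevoflurane sites on the open
Kv1.2 potassium channel (S4S5 linker, S6P-helix interface, extracellular
face; `μ̄ = −0.1 kcal/mol`) — as a plain-text fixture.

Intended users: computational structural biologists and molecular modellers
who already produce docking poses and FEP work values and need the
thermodynamics, state statistics and density maps that follow from them.

## Worked example

```r
library(multibind)

tbl <- kv12_affinity_table()                 # shipped FEP inputs, 12 sites
res <- ligand_reservoir(excess_mu = -0.1)    # sevoflurane in water
cst <- binding_constants(tbl, res)           # K (mM^-n) and dG0 (kcal/mol)

subset(cst, site_id %in% c("S01", "S05", "S10"),
       c(site_id, region, level, K, dG0))
#>    site_id      region level        K    dG0
#> 1      S01   S6P-helix     1 5.96e-01  -3.79
#> 2      S01   S6P-helix     2 5.46e-03  -5.10
#> 9      S05    ext-face     1 7.53e-07   4.26
#> 15     S10 S4S5-linker     1 2.54e+01  -6.01
#> 16     S10 S4S5-linker     2 1.19e+03 -12.38
```

Reading: site S10 at the S4S5 linker binds one sevoflurane with
`K₁ ≈ 25 mM⁻¹` (`ΔG° = −6.0 kcal/mol`) and a second one even more
favourably (`ΔG°₂ = −12.4 kcal/mol` for the pair) — a saturable,
high-affinity spot. The extracellular-face site S05 is effectively a
docking false positive (`ΔG° > 0`).

Averaging over the four symmetry-related copies of each region of the
tetramer, and titrating:

```r
class_constants(cst, kv12_symmetry_classes())
#>      class_id level fold   K_mean     K_sd    dG0
#> 1   S6P-helix     1    4 4.52e-01 2.02e-01  -3.62
#> 2   S6P-helix     2    4 1.23e-02 1.16e-02  -5.58
#> 3    ext-face     1    4 5.76e-03 9.89e-03  -1.04
#> 4 S4S5-linker     1    4 2.06e+01 1.46e+01  -5.89
#> 5 S4S5-linker     2    4 1.63e+04 2.69e+04 -13.93

titration_curve(cst, c(1, 10, 100))[, 1:2]
#>   concentration n_mean
#> 1             1   9.08
#> 2            10  12.13
#> 3           100  15.18
```

The mean occupancy at 1 mM already reflects the strong S4S5 constants; see
the vignette (`vignettes/multisite-binding.Rmd`) for a documented
inconsistency between the constants and the headline occupancies quoted in
the source of this fixture, and for every modelling choice (temperature,
mixed-k convention for doubles, population-sd class errors, clustering and
kernel parameters).

A thin command-line front end wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/multibind.R", package = "multibind"))')
Rscript $CLI affinities --table inst/extdata/kv12_sevoflurane_affinity.tsv --mu -0.1 --out constants.tsv
Rscript $CLI synthesize --seed 1 --dir synthetic/
```

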