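---
title: "Multi-site ligand binding from restrained-FEP inputs: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-site ligand binding from restrained-FEP inputs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multibind)
```

## The problem

A membrane protein in a dilute ligand reservoir (the combined aqueous and
lipid phases, treated as homogeneous at density $\bar\rho$ and excess
chemical potential $\bar\mu$) exposes $s$ binding sites, each a discrete
volume $\delta V_j$ that can hold $0 \le n_j \le n_j^{max}$ ligands. The
receptor's occupancy state $O(n_1,\dots,n_s)$ is then a microstate of a
grand-canonical-like problem, and everything of interest — which states
dominate at a given bath concentration, how the mean number of bound
ligands titrates, where ligand density accumulates in space — follows from
the equilibrium constants $K(n_1,\dots,n_s)$ of the binding reactions
$O(0,\dots,0) + nL \rightleftharpoons O(n_1,\dots,n_s)$.

multibind computes these quantities from *restrained free-energy
perturbation* inputs: for each site and occupancy level, a cumulative
reversible work $W^*_n$ of transferring $n$ ligands from gas phase into the
site while held by isotropic harmonic restraints of force constants
$k_1,\dots,k_n$, plus a statistical error. Generating $W^*_n$ (by FEP, or
any other estimator) is out of scope; this package starts where those
numbers end.

## Per-site constants

With $\beta = 1/(k_B T)$, a harmonically restrained ligand samples an
effective configurational volume

$$V_{\mathrm{eff}}(k) = \left(\frac{2\pi}{\beta k}\right)^{3/2},$$

and the binding constant of $n$ ligands at one site is

$$K_n = \frac{1}{n!}\left[\prod_{i=1}^{n} \left(\frac{2\pi}{\beta k_i}\right)^{3/2}\right]
  e^{-\beta\,(W^*_n - n\bar\mu)},$$

in units of volume$^n$ (converted to mM$^{-n}$ at the interface). The
$1/n!$ corrects for indistinguishable ligands within one site volume. The
standard binding free energy is
$\Delta G^\circ_n = -\beta^{-1}\ln\!\left[K_n (C^\circ)^n\right]$ with
$C^\circ = 1\,\mathrm{M} \equiv (1660\,\text{Å}^3)^{-1}$, and
`free_energy_decomposition()` splits it exactly into the work term
$W^*_n - n\bar\mu$, the expansion term
$-\beta^{-1}\ln\prod_i C^\circ V_{\mathrm{eff}}(k_i)$, and the
indistinguishability term $+\beta^{-1}\ln n!$.

Numerical choices:

* **All constants are computed in log space** and exponentiated last, so
  large $\beta|W^*|$ (state constants of heavily occupied receptors easily
  exceed $e^{300}$) cannot overflow.
* **One reference density.** The standard state $C^\circ = (1660\,Å^3)^{-1}$
  is the single source of truth; the mM ↔ Å$^{-3}$ conversion (1 mM =
  $6.02\times10^{-7}$ Å$^{-3}$) is derived from it. This makes unit
  round-trips, the $\Delta G^\circ$ unit invariance and the decomposition
  identity exact to machine precision rather than approximate.
* **Temperature** is a configuration option, default 298.15 K. The shipped
  reference inputs do not state a temperature; 298.15 K reproduces the
  reference constants from the printed $(k, W^*, \bar\mu)$ inputs to
  within the rounding of the work values (≤ 2%), whereas 300 K drifts to
  ~5%. $k_B = 1.987204\times10^{-3}$ kcal/mol/K.

### Double occupancy and the mixed-k convention

Two-ligand work values are composed sequentially,
$W^*_2 = W^*_1 + W^*_{2|1}$ (`compose_two_step_work()`). Per-step errors
add linearly by default, matching how the shipped reference table quotes
its composed errors; quadrature is available for genuinely independent
step estimates.

Reference tables typically report one force constant per occupancy column.
For the effective-volume product of a doubly occupied site we take ligand 1
under the singly-occupied column's constant and ligand 2 under the
doubly-occupied column's constant (`k_convention = "mixed"`): that is the
restraint schedule actually applied in a sequential coupling, and it is the
convention under which the shipped table's doubly-occupied free energies
are reproduced within 0.14 kcal/mol. A `"per_level"` alternative (the
level-$n$ constant for all $n$ ligands) is provided but is a different
model.

### A documented inconsistency in the shipped reference table

The doubly-occupied constants printed in the source of the shipped fixture
are $10^3\times$ larger than the values consistent with the same table's
$\Delta G^\circ$ column under mM$^{-2}$ units (e.g. site S10: computed
$1.19\times10^3$ mM$^{-2}$, printed $1.18\times10^6$). The free-energy
column is internally consistent with the singly-occupied data and is taken
as authoritative; the package does **not** rescale anything to match the
printed $K_2$ values. A related consequence: the headline mean occupancies
quoted alongside that source (e.g. 0.08 bound ligands at 1 mM) are not
reproducible under *any* single unit convention consistent with the
table's free energies — the S4S5-linker constants imply those sites are
substantially occupied already at 1 mM ($\langle n\rangle \approx 9$).
`mean_occupancy()` reports what the constants imply; nothing is tuned
toward the quoted values.

## Occupancy-state thermodynamics

Under the independent-site approximation the state constant factorizes,
$K(n_1,\dots,n_s) = \prod_j K_{n_j}$, and the state probability at
concentration $c$ is $\rho(n_1,\dots,n_s) \propto c^{\,n} K(n_1,\dots,n_s)$.
Two equivalent code paths exist:

* **Enumerated** (`state_probabilities()`): every state, normalized by
  log-sum-exp. Capped at $10^6$ states by default; a 12-site receptor with
  $n^{max}_j = 2$ everywhere ($3^{12} = 531441$ states) enumerates in a
  few seconds.
* **Factorized** (`factorized_distribution()`): per-site marginals
  $\rho(n_j) \propto c^{n_j} K_{n_j}$, valid at any size. Macrostate
  probabilities $\rho(n)$ over the total bound count come from exact
  polynomial convolution of the per-site level weights — no enumeration.

The test suite holds the two paths to each other at $10^{-10}$ on systems
up to $10^4$ states, and holds both against a Metropolis sampler over
occupancy vectors (`mc_occupancy_sampler()`, an independent stochastic
oracle) within sampling error.

Limits worth knowing: $\langle n\rangle$ is non-decreasing in $c$ with
dilute slope $d\langle n\rangle/dc \to \sum_j K_{1j}$ and saturation at
$\sum_j n_j^{max}$; concentrations at or above 1 M are accepted with a
warning, because the homogeneous dilute-reservoir assumptions behind the
whole construction are stretched there. Correlated-site corrections (the
breakdown of the additive work approximation when nearby sites fill
simultaneously) are deliberately out of scope: the factorized constant is
a zeroth-order model.

## Oligomeric symmetry

For an $f$-fold symmetric oligomer the $s$ sites reduce to $s' \le s$
distinguishable classes. Class estimates are arithmetic means over the $f$
member sites (`class_average()`), with the **population** standard
deviation (divisor $f$): the members are the complete set of symmetry
copies, not a sample, and this is also the convention under which the
shipped class table's spreads are reproduced (a sample sd gives 1.68e1
rather than 1.46e1 for the S4S5 singles). Averaging happens on the $K$
scale, not on $\Delta G^\circ$; by linearity this preserves the dilute
titration slope $\sum_j K_{1j}$ exactly, which is the precise sense in
which symmetrization "redistributes probability without changing average
properties" — at finite concentration the redistribution does perturb
higher moments, and no claim is made otherwise.

State constants are reconstructed from class constants as
$K(n_1,\dots,n_s) = \prod_k \bar K^{\,\chi}$, where each class contributes
one factor per member site at that site's occupancy level (the multiset
reading of the symmetry numbers $\chi(n_k)$, which sum to $s$ over any
state). The notation in the source derivation is ambiguous about whether
member sites of one class may carry *different* occupancies within one
state; the multiset reading is the one that keeps the reconstruction
identical to `state_constant()` on the symmetrized per-site table, which
we verify to $10^{-12}$.

## Site resolution from docking poses

Sites are resolved from round-1 pose centroids by **single-linkage
agglomeration at a distance cutoff** (default 6 Å), chosen because it is
deterministic, has no cluster-count prior, and is permutation-invariant;
the source procedure names no algorithm. Each cluster becomes a spherical
$\delta V_j$ (center = mean member centroid; radius = max member distance,
floored at 4 Å — the sphere is our choice, no shape is prescribed
upstream). A warning fires if two centers fall within 15 Å, the empirical
non-overlap scale for well-separated transmembrane pockets. Pose energies
are not used as weights — positions only. Round-2 poses (re-docking with
one ligand pre-bound) flag a site as double-occupancy-capable when their
centroid falls inside the sphere of their recorded partner site; poses
with foreign or missing partner labels fall back to containment, and
poses outside every sphere are reported, never silently dropped.

## Spatial densities

The conditional density $\rho(\mathbf R \mid n_j)$ — ligand density at
site $j$ given exactly $n_j$ bound — is a Gaussian kernel density over
the pose centroids at that level, normalized so its integral is exactly
$n_j$. Whether the upstream estimates were histograms or smoothed is
unstated; we choose a kernel estimate with a Scott-style bandwidth
($\sigma_{\mathrm{pooled}}\, m^{-1/7}$, floored at 0.8 Å) on a 0.5 Å grid
padded by $3\sigma$, all configurable. The site density
$\rho_j(\mathbf R) = \sum_{n_j} \rho(n_j)\, \rho(\mathbf R\mid n_j)$
integrates to $\langle n_j\rangle$, and the transmembrane profile is
$\rho(z) = \bar\rho\, A(z) + \sum_j \rho_j(z)$ with the reservoir term
$\bar\rho A(z)$ added outside the sites. Projections conserve mass
exactly (slab sums); grids export to plain-text OpenDX
(`write_dx()`/`read_dx()`, round-trip verified). For display, an isovalue
of $9\times10^{-4}$ Å$^{-3}$ is a reasonable default for occupied-site
surfaces; this is cosmetic only.

## Synthetic data and what passing tests show

`synthetic_spec()` mirrors the reference topology — 3 classes × 4-fold =
12 sites, two classes saturable at 2 ligands, one at 1 — with class-level
$(k, W^*)$ means chosen near the reference ranges (linker $k_1 = 0.07$,
$W_1 = -6.5$; interface $0.10, -4.5$; face $0.40, -1.0$; second-ligand
steps $-5.5$ and $-3.8$ kcal/mol), per-site scatter of 0.5 kcal/mol on
work and 0.3 log-units on $k$, and rings of radius 25 Å at $z = -17, 0,
17$ Å so that all separations exceed 15 Å. `generate_pose_cloud()` draws
centroids from the Boltzmann distribution of the harmonic restraint
(per-axis variance $1/(\beta k)$); `generate_pose_set()` instead uses an
effective $k = 0.3$ (≈1.4 Å scatter) for its clouds, because site
resolution operates on docking-pose reproducibility, which is tighter
than the thermal motion the loosest FEP restraints describe. All
generators are seeded, restore the caller's RNG state, and emit their
ground truth.

What the synthetic data does *not* emulate: docking false positives,
non-Gaussian or multimodal pose scatter within a site, correlated
occupancy between nearby sites, and inhomogeneous membrane/water
partitioning of the reservoir. Passing the recovery tests therefore
demonstrates the correctness of the machinery under the stated model
assumptions, not the fidelity of docking or FEP inputs on real systems.

Problem sizes used in the shipped tests — $3^{12}$-state enumeration once,
$10^6$ Metropolis steps, $10^5$-point pose clouds, 480-pose clustering —
were chosen as the smallest sizes at which the statistical tolerances
(2% on variance recovery, $3\sigma$ on sampled marginals) are comfortably
resolved.

## Known limitations

* Independent sites only; no correlated-binding corrections.
* The homogeneous-reservoir treatment folds the membrane into the bulk;
  ligands that partition strongly into lipid will have their effective
  concentration misrepresented at a given nominal molarity.
* $\bar\mu$ is consumed, never estimated; activity corrections beyond the
  dilute assumption are not applied.
* Site volumes are spheres; strongly anisotropic pockets are only
  approximated.
* Class spreads shrink to zero only in the limit of complete
  conformational sampling; with $f = 4$ they are crude error estimates.
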