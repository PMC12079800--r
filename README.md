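# pathppa

Post-simulation **predictive power analysis** for transition-(interface-)path-sampling
data, for researchers who run TIS/RETIS-style rare-event simulations and
want to know, quantitatively, *which collective variables (CVs) predict
reaction success*.

Path sampling yields an ensemble of short trajectories between a reactant
state A and product state B defined by boundaries λ_A, λ_B on an order
parameter λ. For any pair of interfaces λ_A ≤ λᶜ ≤ λʳ ≤ λ_B, every path
that crosses λᶜ contributes the CV value Ψ at its *first crossing*,
labelled **reactive** (it later reaches λʳ) or **unreactive**. With path
weights w from WHAM reweighting of the nested ensembles, these samples
define weighted densities r(Ψ), u(Ψ), t = r + u, and the **predictive
capacity**

```
P = (1/p̄) ∫ r(Ψ)² / t(Ψ) dΨ  =  1 − O / p̄ ,    O = ∫ r u / t dΨ ,   p̄ = ∫ r
```

which runs from p̄ (CV uninformative) to 1 (CV fully determines the
outcome). The practical obstacle is estimating r and u: histogram bins fine
enough to resolve structure hold zero or one point of either kind, so the
binned overlap collapses and fake capacity appears. `pathppa` instead
estimates densities as **Savitzky–Golay derivatives of the weighted
integrated distributions** — step CDFs mapped to a 2000-point grid,
extended by 500-point plateaus, filtered with a second-order polynomial
over a window of 1/16 of the CV range (length 125) — which is stable where
binning fails.

The package covers the full stack:

* **Path model** — CSV frame/metadata tables, (extended) XYZ
  configurations, interface sets, Monte-Carlo-chain subsampling.
* **Reweighting** — closed-form WHAM for nested interface ensembles,
  crossing-probability curves, flux and rate assembly
  (k_AB = f_A · P_A(λ_B|λ_A)).
* **Crossing analysis** — first-crossing extraction, reactive/unreactive
  labelling, weighted sample sets.
* **Density estimation** — the integrated-histogram filter pipeline plus a
  binned fallback/oracle.
* **Predictive power** — overlap integral, capacity, and (λᶜ, λʳ) capacity
  maps.
* **Descriptors** — index-invariant distance matrices (`NaO6`, `NaO6H4`,
  ... features), smooth bridging-water counts, largest-cosine shell
  angles, axial density maps; all invariant to atom input order and rigid
  motions, minimum-image aware.
* **Combination search** — simulated-annealing optimisation of linear CV
  combinations under |α| + |β| + |γ| = 1.
* **Synthetic data** — a seeded double-well Langevin generator whose
  chopped trajectory provides exact direct-counting oracles, and
  Gaussian-mixture sample sets with quadrature ground truth.

## Worked example

A coupled double well (V = h(x²−1)² + y²/2 + g·x·y, λ = x) stands in for a
molecular system; the hidden coordinate `y` is coupled to the transition,
the `noise` channel is not:

```r
library(pathppa)

pp   <- doublewell_params(seed = 1)
traj <- langevin_doublewell(pp, 2e6)
ch   <- chop_trajectory(traj, pp$lam_A, pp$lam_B)    # 30,614 segments, 365 A->B

ifc <- ppa_interfaces(c(-0.7, -0.55, -0.35, -0.1, 0.25, 0.7))
wp  <- wham_weights(tis_like_subsets(ch, ifc, seed = 1)$paths, ifc)

curve <- crossing_curve(wp, seq(-0.7, 0.7, length.out = 200), lam_A = -0.7)
ens   <- vapply(ch$paths, `[[`, "", "ensemble")
rate_estimate(flux_estimate(ch$paths[ens == "0-"], ch$paths[ens == "0+"]), curve)
#> <ppa_rate> f_A = 2.99505e+06 ns^-1, P_A(lambda_B|lambda_A) = 0.0126113,
#>            k_AB = 37771.6 ns^-1

s <- build_sample_set(wp, ppa_query(-0.7, 0.7, lam_A = -0.7), c("y", "noise"))
screen_singles(s)
#>      cv   capacity      p_bar    overlap
#> 1     y 0.02870883 0.01260418 0.01224233
#> 2 noise 0.01333980 0.01261135 0.01244311
```

Reading the numbers: the rate assembled from path statistics (37,772 ns⁻¹
in the toy's nominal units) agrees with brute-force counting on the uncut
trajectory (35,708 ns⁻¹) to ~6%. At the full λ_A → λ_B query the average
transition probability is p̄ ≈ 0.0126; the coupled coordinate `y` reaches
capacity 0.0287 — 2.3× the crossing probability, real predictive signal —
while the noise channel sits at its theoretical floor p̄, as it must.
`ppa_scan()` produces the same quantities on a whole (λᶜ, λʳ) grid, and
`anneal_combo()` searches linear combinations of candidate CVs.

A config-driven run (`run_pipeline("run.yaml")`) wires these stages
together and writes crossing curve, densities, capacities and provenance
(seed, config hash, version) to disk; `inst/cli/pathppa.R` exposes the
same stages as shell subcommands.

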