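# raftmill

Quantitative toolkit for the collective dynamics of floating fire ant
(*Solenopsis invicta*) rafts. A raft is a planar structural network of
interlinked ants with a layer of freely walking ants on top; anchored rafts
reach a treadmilling steady state in which the network contracts at strain
rate ε̇ while free ants deposit at the edge at rate γ per unit perimeter and
bulk structural ants exit back into the free layer at δ = 2ρ_r ε̇ — and
asymmetric edge deposition grows tether-like protrusions. `raftmill` is
written for researchers in collective animal behaviour and active matter
who need to run these analyses on tracked trajectories or to simulate the
models behind them.

It provides:

* **Trajectory statistics** for the free layer treated as self-propelled
  particles: finite-difference velocities and mean speed v0, anomalous MSD
  fits ⟨x²⟩ = 4Dτ^ξ, polar order |φ|(L) scans, persistence length from
  exp(−l_c/l_p), pairwise directional correlation c(σ, τ), and the velocity
  metric tensor g^v = ⟨v̂ ⊗ v̂⟩ (unit trace; diag(0.5, 0.5) = isotropic).
* **Treadmilling rate estimators**: exponential area-decay and radial
  strain fits for ε̇, exit rate δ, edge deposition γ and α = γP/A, packing
  fraction, and protrusion growth metrics V and W ≈ A_p/L_c.
* **A confined self-propelled-particle simulator** (wall attachment,
  gliding, detachment) and the strong-confinement steady wall density
  ρ_s = κ/2π.
* **A boundary-growth model** of protrusion instabilities: a half-elliptic
  mesh advanced by forward Euler under γ(s) = [a ρ_s/ρ0 + γ0](n̂ + βφ̂)/|n̂ + βφ̂|,
  with curvature-weighted magnitude and bias-weight β.
* **Synthetic-data generators** (active Brownian walkers, a contracting
  treadmilling raft, biased strip walkers) so every estimator is testable
  without the original image-tracked data, which have no public accession.

Units: lengths in ant body lengths (ℓ), times in seconds at the data level,
rates per minute.

## Worked example

Generate free-ant trajectories at the measured field parameters
(v0 = 0.59 ℓ/s, τ_r = 34 s), recover them, then estimate treadmilling
rates from a simulated contracting raft:

```r
library(raftmill)

tr  <- gen_abp_trajectories(abp_params(v0 = 0.59, tau_r = 34,
                                       n_ants = 200, t_end = 220,
                                       dt = 2, seed = 301))
vel <- compute_velocities(tr)
attr(vel, "mean_speed")
#> [1] 0.59
persistence_length(tr, min_travel = 5, bin_width = 1.5, max_lc = 50,
                   mode = "pooled")
#> <persistence_fit> l_p = 19.8 l (se 0.13), pooled mode, 200 ants, status: ok

sim   <- gen_contracting_raft(raft_sim_params(seed = 1))
decay <- fit_area_decay(sim$areas)
c(eps_dot = decay$eps_dot, r2 = decay$r_squared)
#> eps_dot      r2
#>  0.0175  1.0000
edge_deposition_rate(sim$areas, rho_r = 2.54)$gamma
#> [1] 0.2936147
#> Warning: A_g exceeds 20% of A: update the tracked edge set more often
exit_rate(decay$eps_dot, rho_r = 2.54)
#> <rate_estimates>
#>   delta_area: 0.0889
#>   delta_per_ant: 0.035
```

The recovered speed is exact by construction, the persistence length 19.8 ℓ
matches the ground truth v0·τ_r = 20.1 ℓ, the contraction rate comes back
at the generating 1.75% min⁻¹ with R² = 1, the deposition rate at the
generating γ = 0.29 min⁻¹ ℓ⁻¹ within Poisson scatter, and δ per structural
ant is 2ε̇ = 3.5% min⁻¹.

Run the protrusion growth model and inspect the bias response:

```r
run_growth(growth_params(beta = 1))
#> <growth_run> beta = 1: L_dot = 0.165 l/min, kappa_tip(final) = 0.614 1/l (max 1.52)
```

A command-line entry point wraps the same functions
(`inst/cli/raftmill`): subcommands `simulate-abp`, `simulate-raft`,
`simulate-confined`, `grow-protrusion`, `analyze-traj`,
`analyze-treadmill`.

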