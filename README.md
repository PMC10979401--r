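# methyldyn

Timescale- and motion-resolved analysis of methyl side-chain dynamics
in protein assemblies.

Methyl groups are the main probes of side-chain motion in solid-state
NMR of fibrils and other assemblies: three-site rotation of the methyl
itself, chi1/chi2 rotamer hopping, within-well libration and slow
collective backbone "breathing" all reorient the H–C bond and drive
dipolar relaxation. `methyldyn` is for spectroscopists and simulators
who want to go from raw time series (or relaxation tables) to
interpretable per-motion amplitudes, timescales, populations and
couplings.

The package implements:

* **Rank-2 correlation functions** — `C(t) = <P2(u(τ)·u(t+τ))>`,
  with plateau `S²` and the partition of the decay `1 − S²` over a
  log-timescale distribution `θ(z)`, `z = log10(τ/s)`.
* **Detector analysis** — sensitivities of NMR experiments (R1, NOE
  cross-relaxation, R1ρ under MAS, from Lorentzian spectral densities)
  or of simulation lags (`exp(−t_k/τ)`), recombined into optimised
  non-negative timescale windows `ρ_n(z)` whose responses
  `ρ_n^(θ,S) = (1 − S²)∫θ(z) ρ_n(z) dz` are fitted from data with
  error propagation.
* **Frame-wise decomposition** — the total methyl H–C correlation
  function factorised into methyl / chi2 / chi1 hopping and libration
  plus Cα–Cβ reorientation (7 components for Ile/Leu, 5 for Val, 3 for
  Ala), with a product-reconstruction residual as the validity check.
* **Methyl parametrisation** — the linear `log10(τ_met)` vs
  `σ_libr⁻²` law, extraction of `⟨τ_met⟩` and `σ_libr` from total
  detector responses, and factoring the methyl contribution out of
  experimental responses.
* **Rotamer analysis** — hysteresis-based state assignment, the
  tetrahedral order parameter `S² = 1 − (8/3)(p1p2 + p1p3 + p2p3)` and
  its closed-form inversion to populations from DIPSHIFT |S| values,
  binned hop rates regressed on state occupancies
  (`⟨R_hop⟩_bin = Σ_i R_hop^i p_bin^i`), and Markov models whose
  implied correlation functions diagnose hidden-variable dynamics.
* **Coupling** — plug-in rotameric entropies (`ΔS = −RΣp ln p`),
  leave-one-out entropy changes, the pair coefficient
  `2(ΔS_p + ΔS_q − ΔS_pq)/(ΔS_p + ΔS_q)`, and PCA of backbone
  coordinates with mode–hop-rate correlations.
* **A stochastic simulator** — continuous-time Markov hopping, OU
  libration and an OU breathing mode log-modulating hop rates, used as
  ground truth by every test.

Everything is tibble-first: results print as tibbles, have
`tidy()`/`glance()` methods and `autoplot()` figures, and chain with
the pipe.

## Worked example

Simulate an isoleucine with 40 ps methyl hopping, 5 ns chi2 exchange
and 9° libration, then analyse it:

```r
library(methyldyn)

spec <- sidechain_spec("Ile", tau_met = 40e-12,
                       chi2_rates = 1 / (3 * 5e-9),
                       sigma_libr = 0.16, tau_libr = 1e-11)
sim <- simulate_sidechain(spec, duration = 2e-7, dt = 2e-12, seed = 1)
sim
#> <synth_result> Ile, 100000 frames at dt = 2e-12 s

decompose_sidechain(sim$dihedrals, "Ile", dt = 2e-12)
#> <decomposed_corr> Ile: 7 components, product residual 0.00955

glance(rank2_correlation(sim$vectors, dt = 2e-12))
#> # A tibble: 1 × 3
#>   n_lags      S2    dt
#>    <int>   <dbl> <dbl>
#> 1    190 0.00867 2e-12

st <- assign_states(sim$dihedrals$chi2, dt = 2e-12)
fit_state_rates(binned_hop_rates(st, 5e-9))
#> <state_rates> R_hop per state (s^-1): 159200000, 153100000, 214900000; r = 0.106

build_markov(st, lag = 2e-11)
#> <markov_model> 3 states, lag 2e-11 s, pi = 0.351, 0.411, 0.239
```

The seven components split the decay into methyl hopping/libration,
chi2 and chi1 hopping/libration and Cα–Cβ motion; the small product
residual (≈0.01) says the independence assumption holds here. The
plateau `S² ≈ 0.009` reflects methyl hopping (×1/9) stacked on chi2
hopping. The fitted per-state hop rates are statistically equal — as
they must be for symmetric exchange — and the stationary populations
are near 1/3 each.

A thin CLI wraps the same functions
(`inst/cli/methyldyn pipeline --config run.yaml --seed 1`), with
subcommands `simulate`, `pipeline` and `fixtures`.

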