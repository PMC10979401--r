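---
title: "Methods: detector analysis and motional decomposition of methyl dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detector analysis and motional decomposition of methyl dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methyldyn)
```

## The problem

Methyl-bearing side chains (Ala, Val, Leu, Ile) in protein assemblies
reorient through a hierarchy of motions: fast rotation of the methyl
group about its three-fold axis, discrete rotamer jumps of the chi1 and
chi2 dihedrals, small librational fluctuations within each dihedral
well, and slow collective deformation of the backbone. All of these
motions reorient the methyl H--C bond and therefore drive dipolar NMR
relaxation. `methyldyn` implements the analysis chain that takes either
a dihedral/bond-vector time series (from simulation or from a
stochastic generator) or a table of relaxation measurements, and
returns a timescale-resolved, motion-resolved picture of the dynamics.

## Rank-2 correlation functions and detectors

The central object is the rank-2 reorientational correlation function

$$C(t) = \langle P_2(\cos\beta_{\tau,\,t+\tau}) \rangle_\tau, \qquad
P_2(x) = \tfrac{3x^2 - 1}{2},$$

where $\beta$ is the angle between the interaction-tensor (H--C bond)
orientation at two times. $C(0) = 1$ and $C(t) \to S^2$, the squared
order parameter. The decay is modelled as a distribution of
correlation times on a logarithmic axis $z = \log_{10}(\tau/\mathrm s)$:

$$C(t) = S^2 + (1 - S^2)\int \theta(z)\, e^{-t/10^z}\, \mathrm dz,
\qquad \int\theta(z)\,\mathrm dz = 1 .$$

A full reconstruction of $\theta(z)$ from a handful of relaxation rates
is ill-posed. The detector approach instead reports amplitudes inside a
few optimised timescale windows $\rho_n(z)$:

$$\rho_n^{(\theta,S)} = (1 - S^2)\int \theta(z)\,\rho_n(z)\,\mathrm dz .$$

### Sensitivities

For relaxation data the rows of the sensitivity matrix are the standard
dipolar expressions built from Lorentzian spectral densities
$J(\omega,\tau) = \frac{2}{5}\tau/(1+(\omega\tau)^2)$: longitudinal
$R_1$, NOE cross-relaxation $\sigma$, and an on-resonance $R_{1\rho}$
whose slow-motion sensitivity comes from the near-rotary-resonance
terms $J(\omega_1 \pm \omega_r)$ and $J(\omega_1 \pm 2\omega_r)$
(`nmr_sensitivities()`; the exact coefficient set is documented in the
function). Contributions from the ~25 ppm 13C CSA and from the two
deuterons of a CHD2 methyl are included as scalable, toggleable
add-ons; they are an order of magnitude weaker than the 1H--13C dipole
term. The default experiment set (`hets_experiments()`) is R1 and NOE
at 400/600/700 MHz plus R1rho at 5 kHz MAS with 12/14/19 kHz spin
locks. For simulation data each sampled lag $t_k$ of $C(t)$ senses
$\exp(-t_k/\tau)$ (`md_sensitivities()`).

### Window optimisation

`optimize_detectors()` recombines the top-$n$ singular vectors of the
(row-normalised) sensitivity matrix into non-negative windows. The
design was genuinely open — the literature defers the algorithm to its
own references — and we chose a joint bound-constrained least-squares
formulation: all $n$ window shapes are optimised at once on the $z$
grid with (i) a linear objective $\sum_n \int \rho_n(z)(z-z_{0,n})^2
\mathrm dz$ that narrows each window about its anchor, (ii) a
quadratic penalty keeping each shape inside the singular subspace (the
result is projected exactly into the subspace afterwards), and (iii) a
quadratic penalty driving $\sum_n \rho_n(z)$ towards the subspace
projection of the constant 1. The third term makes the completed set
approximately partition unity over the covered grid region, which is
what lets the responses be read as a decomposition of the total
amplitude $1 - S^2$. Anchors are initialised at equal quantiles of the
subspace leverage $\mathrm{diag}(BB^\top)$, kept at least half a
window apart, and refined once towards the realised peaks. Two
normalisations are provided: `max1` (window maxima 1; responses are
amplitudes) and `integral` (unit integral; responses estimate
$(1-S^2)\theta(z_0)$ at the window centre).

Response fitting (`fit_responses()`) is weighted least squares in the
truncated singular subspace; because the map from responses to
measurements is linear and invertible inside the subspace, noise-free
round trips are exact, and uncertainties follow from the covariance.
Negative responses trigger a non-negative refit while the reported
uncertainties stay those of the unconstrained fit (a soft constraint).

## Frame-wise decomposition

`decompose_sidechain()` factorises the total H--C correlation function
into per-motion components, $C(t) \approx \prod_n C_n(t)$: methyl
hopping and libration, chi1/chi2 hopping and libration, and Ca--Cb
reorientation — 7 components for Ile/Leu, 5 for Val, 3 for Ala. Each
component is computed geometrically in the frame of the next-outer
rotation: the H--C bond sits at 110.5 degrees to the methyl axis, and
successive rotation axes are at the ideal tetrahedral angle 109.47
degrees. The factorisation assumes the motions are mutually
uncorrelated and timescale-separated; `product_residual()` (RMS of
product minus directly-computed total) quantifies violations and
grows when axes are deliberately correlated. The hop/libration split
(`split_hop_libration()`) assigns each angle to the nearest staggered
well and references libration to the *state mean* rather than the
ideal centre, so hop + libration reconstructs the input exactly.
Ca--Cb reorientation is represented by a user-supplied axis series or
held fixed; in practice its contribution is negligible.

Because methyl hopping multiplies everything slower by its plateau of
1/9, responses of slower motions are rescaled by 9 (and by
$1/S^2_{\mathrm{lib}}$) when methyl and chi hopping are displayed on a
common scale.

## Methyl parametrisation

Both the methyl hop time and the librational amplitude are governed by
the rotation barrier, which makes $\log_{10}\langle\tau_{\mathrm{met}}
\rangle$ approximately linear in $\sigma_{\mathrm{libr}}^{-2}$.
`fit_methyl_line()` fits that line by ordinary least squares with one
outlier-rejection pass at 2 residual SDs. `extract_methyl_params()`
then performs a one-parameter fit of the model

$$C(t) = S^2_{\mathrm{lib}}(\sigma(\tau))\left(\tfrac19 +
\tfrac89 e^{-t/\tau}\right)$$

to the two fastest detector responses, with $\sigma$ slaved to $\tau$
through the line and the fast librational amplitude
$1 - S^2_{\mathrm{lib}}$ placed at the fastest grid point. The
objective need not be unimodal, so a 121-point grid scan precedes the
golden-section refinement; an optimum at the edge of the 10 fs--10 ns
search range is flagged.

The libration order parameter is defined as
$S^2_{\mathrm{lib}} = E[P_2(u(\phi_1)\cdot u(\phi_2))]$ for
independent Gaussian rotations $\phi_i \sim N(0,\sigma^2)$ of a bond
at 110.5 degrees to the axis. Writing $\delta = \phi_1 - \phi_2$ the
expectation reduces to Gaussian cosine moments
($E\cos\delta = e^{-\sigma^2}$, $E\cos 2\delta = e^{-4\sigma^2}$), so
the package evaluates the exact closed form; the test suite checks it
against Gauss–Hermite quadrature. It decreases monotonically from 1 to
$P_2(\cos 110.5^\circ)^2 \approx 1/9$.

`factor_out_methyl()` subtracts the fixed methyl model from the total
responses; since the detector fit is linear in the measurements this
equals a measurement-space refit with the methyl contribution removed.
The fastest window is ambiguous between fast and slow motion, so its
residual is split half/half across both sides.

## Rotamer analysis

States are assigned to the staggered wells (-60, 60, 180 degrees) with
a 30-degree hysteresis margin: a transition is recorded only when the
angle comes within the margin of a *different* centre. The margin was
a design choice (the counting criterion was open); it prevents
libration of realistic amplitude (sigma up to ~15 degrees) from
inflating hop counts, which the tests verify directly.

Populations follow from the tetrahedral order parameter
$S^2 = 1 - \tfrac83(p_1p_2 + p_1p_3 + p_2p_3)$, inverted in closed
form under the constraint models $\{p_3 = 0\}$ (valid for $S^2 \in
[1/3, 1]$), $\{p_2 = p_3\}$ ($[1/9, 1]$) and $\{p_1 = p_2\}$
($[1/9, 1/3]$); `select_model()` picks among the valid models by
distance to reference (simulation) populations. Measured methyl |S|
values can be rescaled by the methyl-rotation factor
$|P_2(\cos 110.5^\circ)| \approx 1/3$ before inversion; whether a
given |S| convention already includes that factor is data-dependent,
so it is an explicit flag.

Hop-rate variability is analysed on consecutive bins (the reference
configuration is 200 bins of 50 ns): per-bin rates are regressed on
per-bin state occupancies by non-negative least squares, giving
per-state rates and an observed/predicted correlation; a flat
prediction with low correlation is the signature of hidden (state-
external) rate modulation. `build_markov()` estimates a transition
matrix at a chosen lag with symmetrised counts (detailed balance holds
by construction; whether to symmetrise was open and we chose to,
since the equilibrium physics demands it), and `markov_corrfn()`
compares the Markov-implied correlation function with the one computed
directly from the state series — agreement for genuinely Markov
dynamics, disagreement under hidden-rate switching.

## Entropy coupling and breathing

Rotameric entropies use plug-in frequencies, natural logarithms and
R = 8.314 J mol$^{-1}$ K$^{-1}$ (nine equal states give
R ln 9 = 18.27 J mol$^{-1}$ K$^{-1}$). No small-sample bias correction
is applied; the plug-in estimator underestimates entropy when the
joint state space is undersampled, which matters for the total
(all-residue) entropy first — a subsampling convergence check is the
recommended guard. Leave-one-out values marginalise the residue out of
the observed joint table rather than re-estimating on a reduced state
space (the alternative reading; marginalisation is exactly consistent
with the plug-in joint). The pair coefficient
$2(\Delta S_p + \Delta S_q - \Delta S_{pq})/(\Delta S_p + \Delta S_q)$
is 0 for independent residues and 1 for fully dependent ones.

Backbone breathing is extracted by PCA after iterative superposition
(5 Kabsch passes against the evolving mean; the alignment protocol was
unspecified and 5 passes converge to machine precision on the tested
sizes). Mode projections are autocorrelated (`pc_autocorr()`,
normalised to C(0) = 1) and correlated against binned hop rates
(`pc_rate_correlation()`), which is positive when hop rates are
log-modulated by the mode.

## The synthetic generator

`simulate_sidechain()` draws continuous-time Markov jumps per axis
(Gillespie thinning when a breathing mode modulates rates), adds
Ornstein–Uhlenbeck libration within wells, and composes the H--C
vector with the ideal geometry above. Defaults represent the study
conditions: tau_met = 50 ps, sigma_libr = 10 degrees, breathing
timescale 350 ns, rate modulation acting on the log of the rates
(Arrhenius-like barrier modulation). It reproduces exactly the
processes the analysis assumes — Poisson hop statistics, Gaussian
libration, a single log-modulating collective mode — and none of the
features of real force-field dynamics: correlated multi-dihedral
transition paths, anharmonic wells, rotamer-dependent libration
widths, or solvent friction. Passing tests therefore demonstrate
correctness of the estimators under the model, not accuracy of any
force field.

One geometric subtlety: with the H--C bond at 110.5 degrees the
three-site hop plateau is $P_2(\cos 110.5^\circ)^2 \approx 0.0999$,
not exactly 1/9; the exact 1/9 belongs to the ideal tetrahedral tilt
of 109.47 degrees. Tests that check the 1/9 constant therefore use the
state-ideal orientation series (the hop component), where the constant
is exact.

## Numerical choices and problem sizes

* Lag sampling is logarithmic, about 50 lags per decade (linear
  sampling by flag); the reference grid for relaxation work is
  $z \in [-14, -3]$ with 200 points.
* Correlation averaging uses all start times with valid endpoints, no
  truncation correction.
* The plateau estimate is the mean of C over the last decade of lags,
  overridable.
* Simulated test problems use 10^5–10^6 frames (e.g. a 1 micro-s
  methyl trajectory at 1 ps steps for the plateau check, 4 micro-s at
  10 ps for the Markov diagnostic, 200 x 50 ns bins for rate
  recovery); these sizes put Monte-Carlo errors comfortably below the
  tested tolerances while keeping the whole suite a few minutes long.
* Monte-Carlo tolerances are computed from block standard errors of
  the quantity under test, not fixed constants, wherever feasible.

## Limitations

* Methionine (an S–CH3 methyl with different geometry) is not
  covered, nor are user-defined frame hierarchies.
* The R1rho coefficient set targets on-resonance spin lock under
  moderate MAS; off-resonance tilt effects are not modelled.
* Plug-in entropies are biased low for undersampled joint spaces.
* The detector windows in sensitivity "dead zones" (between the
  R1-type and R1rho-type lobes) are intrinsically broad and low; their
  responses should be interpreted as upper-bound amplitudes there.

## A worked chain

```{r example, eval = FALSE}
spec <- sidechain_spec("Ile", tau_met = 40e-12, chi2_rates = 1 / (3 * 20e-9),
                       sigma_libr = 0.16, tau_libr = 1e-11)
sim <- simulate_sidechain(spec, duration = 1e-6, dt = 2e-12, seed = 1)
dec <- decompose_sidechain(sim$dihedrals, "Ile", dt = 2e-12)
st  <- assign_states(sim$dihedrals$chi2, dt = 2e-12)
fit <- fit_state_rates(binned_hop_rates(st, 10e-9))
mk  <- build_markov(st, lag = 2e-11)
```
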