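---
title: "Methods: intrinsic efficiency of T1/T2 relaxometry sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intrinsic efficiency of T1/T2 relaxometry sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmrieff)
```

## The efficiency metric

Quantitative MRI methods estimate tissue parameters — here the relaxation
times $T_1$ and $T_2$ — from a set of measured complex signals. Methods
differ enormously in pulse-sequence structure, so raw precision comparisons
confound the method's intrinsic merit with the experiment's SNR and
duration. The package separates these with the efficiency

$$
\eta(\theta) \;=\; \frac{\theta}{\sigma_\theta}\,
\frac{\sigma_0}{M_0}\,\frac{1}{\sqrt{T_{acq}}},
$$

where $\theta/\sigma_\theta$ is the parameter-to-noise ratio, $M_0/\sigma_0$
is the maximum attainable SNR of a single measurement (the signal a $90^\circ$
pulse from thermal equilibrium would give, against the per-readout receiver
noise), and $T_{acq}$ is the total acquisition time in seconds. $\eta$ has
units $s^{-1/2}$ and is, by construction, invariant to receiver gain, voxel
volume and noise level: it quantifies only how effectively the spin dynamics
encode the parameter per square root of measurement time.

$\sigma_\theta$ is evaluated at the Cramér–Rao lower bound. With complex
Gaussian noise of per-quadrature standard deviation $\sigma_0$ and signal
Jacobian $J = \partial s/\partial p$, the Fisher matrix is
$F = \mathrm{Re}(J^H J)/\sigma_0^2$ and
$\sigma_\theta = \sqrt{[F^{-1}]_{\theta\theta}}$, with every other relevant
parameter treated as jointly estimated. For spoiled sequences the relevant
set is $p = \{T_1, T_2, M_0\}$; a balanced readout adds the measurement
phase $\phi_0$ and off-resonance $\omega_0$. Two conventions are deliberate
and documented at the API:

* $\sigma_0$ is *per quadrature*, and the CRLB treats the data as complex
  (not magnitude): this makes $\eta$ independent of $\sigma_0$ and $M_0$
  exactly, and least-squares fits on complex data attain the bound
  (verified by Monte Carlo in the test suite to within 3%).
* A parameter the signal does not depend on at all (e.g. $T_2$ for a pure
  SPGR set) is dropped from the nuisance set rather than reported as a
  singular Fisher matrix; a parameter that is *jointly unidentifiable*
  (collinear columns) yields $\sigma_\theta = \infty$ and $\eta = 0$, so
  optimizers can traverse degenerate regions.

## Signal models

All models are single-pool Bloch dynamics with instantaneous RF pulses;
angles are degrees at interfaces and radians internally, times in ms.

* **SPGR** — ideally spoiled Ernst steady state
  $s = M_0\sin\alpha\,(1-E_1)/(1-E_1\cos\alpha)\,e^{i\phi_0}$,
  $E_1 = e^{-TR/T_1}$. Decay to the echo time is not modelled: under ideal
  spoiling it is a flip-angle-independent factor that an estimator absorbs
  into the effective $M_0$, and the classical variable-flip-angle T1
  estimators are formulated without it.
* **bSSFP** — the exact fixed point of the per-TR rotation–relaxation
  recursion (a 3×3 linear solve), evaluated at TE (default TR/2) with
  off-resonance precession, T2 decay and $\phi_0$; configurable per-TR RF
  phase increment (180° by default). The signal magnitude is periodic in
  $\omega_0$ with period $1/TR$; the complex value carries the extra TE
  phase.
* **DESS / TESS** — the periodic steady state of a gradient-spoiled
  sequence computed as the fixed point of the per-TR extended-phase-graph
  (EPG) operator; echoes are the post-pulse configuration amplitudes
  $F_0$, $F_{-1}$ (and $F_{+1}$ for TESS) with decays
  $e^{-TE/T_2}$, $e^{-(TR-TE)/T_2}$, $e^{-TE/T_2}$. Echo-pathway timing
  conventions differ between vendors and papers; this one is fixed,
  documented, and verified against a 10,000-isochromat brute-force
  simulation to $10^{-6}$ (in fact machine precision, since equally spaced
  isochromat phases form an exact Fourier quadrature of the configuration
  states).
* **Spoiled fingerprinting** — EPG propagation with one ideal unit crusher
  per TR and no RF spoiling; per pulse: RF rotation, readout of $F_0$ at
  TE, relaxation with recovery, gradient shift. Truncation order grows
  adaptively whenever the top configuration state exceeds
  $10^{-12} M_0$ (capped at 4096 orders; design searches lower the cap to
  256 via `options(qmrieff.epg_order_cap=)` — the discarded amplitudes are
  orders of magnitude below cost-ranking precision, while pathological
  short-delay trains would otherwise dominate run time).
* **Balanced fingerprinting** — single-isochromat Bloch recursion with
  alternating (0/180°) RF phase by default, demodulated by the pulse
  phase. No initial inversion pulse is assumed; one can be emulated by
  prepending a 180° pulse to the train.

**Driven equilibrium.** A cyclic train's initial state is the fixed point
of the affine map of one full pass. For balanced trains this is a 3×3
solve. For spoiled trains the truncated EPG state is large; the package
first iterates the cycle map (geometric convergence at
$\approx e^{-T_{cycle}/T_1}$ per pass), and falls back to an explicit
direct solve of the real-ified affine map (dimension $6(K{+}1) \le 480$)
for slowly contracting short cycles. Either route must satisfy
$\lVert A(m^*) - m^* \rVert \le 10^{-10} M_0$; a singular direct solve
falls back to plain fixed-point iteration.

**Acquisition time.** $T_{acq}$ is the sum of the TRs of all measurements
(for DESS/TESS, the TR periods). Recovery dead time after a train is
excluded unless `include_recovery = TRUE`; sequences starting from thermal
equilibrium are therefore "privileged" by assuming prior full recovery,
which matches how such comparisons are conventionally made and can be
switched off.

## Jacobians

Derivatives are central finite differences with relative step
$h = 10^{-4}$ (absolute floor $10^{-6}$ in native units). Two columns are
analytic: $\partial s/\partial \phi_0 = i\,s$, and
$\partial s/\partial M_0 = s/M_0$ (every model is exactly linear in
$M_0$). Step-halving changes entries by less than $10^{-4}$ relative
(tested); for driven-equilibrium trains the fixed point is re-solved at
each perturbed parameter value, so the derivative includes the dependence
of the periodic state itself. A compiled fast path evaluates the identical
scheme for balanced fingerprint trains in one pass.

## Design optimization

Acquisition settings $u$ are chosen by minimizing

$$
\sum_{p\in P}\ \eta(T_1; p, u)^{-2} + \eta(T_2; p, u)^{-2}
$$

over the tissue set $P$: white matter at 3 T ($T_1 = 781$ ms,
$T_2 = 65$ ms, $M_0 = 1$, $\phi_0 = 0$), with $\omega_0 \in [-100, 100]$ Hz
in 5 Hz steps whenever a balanced readout participates (spoiled-only
methods use $\omega_0 = 0$). Vanishing efficiencies contribute a finite cap
of $10^{12}$ per term so gradients stay finite.

Every constraint set in the method catalogue reduces to box bounds
(flips in $[0, 180]°$, TR in $[TE{+}1, 20]$ ms for transient methods by
default), and the driven-equilibrium equality constraint is satisfied by
construction through the exact fixed-point solve, so the search uses
`stats::optim`'s L-BFGS-B — a gradient-based bound-constrained
quasi-Newton method — rather than a general SQP. Multi-start: up to 400
design variables, 100 random initializations (flips uniform, times
log-uniform in bounds, drawn up front from a seed-derived stream so the
best cost is non-increasing in the number of starts); above 400 variables
a single smooth stock schedule seeds the search, mirroring the practice of
starting from a published flip-angle pattern. Ties between equal-cost
starts resolve to the lowest start index. Solver iterations default to
`maxit = 200`; the worked examples use `maxit = 150` and
`factr = 1e8` (relative-reduction stop around $2\cdot 10^{-8}$), which is
well below the cost differences between competing minima.

The method catalogue encodes the structural constraints: spoiled
fingerprints optimize per-pulse flips and TRs; balanced fingerprints
optimize flips with TR fixed at 5 ms; DESPOT/JSR is a mix of SPGR and
phase-cycled bSSFP measurements with per-measurement flips and TRs (2 SPGR
members by default — at least one SPGR decorrelates $T_1$ from $T_2$
information); PLANET is phase-cycled bSSFP constrained to a single flip
and TR (2 free variables); DESS/TESS share one flip and TR across their 2
or 3 echoes per TR. Fingerprints with fewer than 400 excitations are
flagged `not_spatially_encodable` but remain optimizable.

### The five-pulse worked example

A 5-pulse cyclically repeated spoiled fingerprint (TE 2 ms, measurement
after every pulse, inter-pulse delays free in $[2.3, 3000]$ ms — bounds
chosen to span from just above the echo time to several $T_1$) optimized
for white matter contracts to a spin-echo + inversion-recovery motif. Two
distinct local optima recur across the multi-start search: a 3-pulse
schedule with flips near 60°/180°/90° (two pulses driven to zero
amplitude, long recovery segments), and a slightly cheaper 5-pulse variant
that re-uses the two "spare" pulses as additional ~180° refocusing pulses
with millisecond spacings. Which one a run reports depends on the basins
the seeded starts land in; both are genuine minima of this model (pure
gradient crushing without RF spoiling keeps all refocused pathways
coherent, which favors extra refocusing pulses). With RF spoiling, a
larger minimum delay, or diffusion attenuation of high-order coherences —
none of which are part of this model — the 3-pulse schedule would be
expected to dominate.

### Scaled comparison of transient vs steady-state methods

The cross-method comparison in the test suite uses deliberately reduced
problem sizes so a single CPU completes it in minutes, stated here as the
package's choices: balanced fingerprint of $N = 400$ pulses (TR 5 ms, the
shortest spatially encodable train, single stock initialization, 120
solver iterations), DESPOT/JSR with 8 measurements (12 random starts, 150
iterations), both scored on a coarse 5-point off-resonance grid
$\{-100, -50, 0, 50, 100\}$ Hz. Efficiencies are averaged over the grid
and compared as the geometric mean of the $T_1$ and $T_2$ ratios.
Steady-state efficiencies are invariant to replicating the measurement
set, so the small JSR measurement count does not handicap it.

## Undersampling and the dynamics factor

Undersampling by a factor $R$ shortens $T_{acq}$ but, with a zero-filled
reconstruction that treats aliasing as noise, amplifies the parameter
error by the dynamics factor $d_R$, so $\eta_R = \eta/d_R$. Writing
$\sigma_{image,R}$ for the per-pixel standard deviation of the
undersampled reconstruction and $\sigma_{image}$ for the fully sampled
one,

$$
d_R = \frac{1}{\sqrt{R}}\frac{\sigma_{image,R}}{\sigma_{image}}
\approx \sqrt{\frac{1}{R}\frac{SNR_{image}^2}{SaR_{image}^2} + 1},
$$

where $SaR_{image}$ is the signal-to-aliasing ratio of a noiseless
undersampled reconstruction and $SNR_{image}$ the image-domain SNR
(mean nonzero phantom intensity over the per-quadrature image noise).
The package measures both on the standard 10-ellipse head phantom
(modified intensity table, values in $[0,1]$):

* **Masks.** `random`: exact-count uniform selection at rate $1/R$ with a
  4×4 always-sampled centre block. `spiral`: a Cartesian nearest-grid
  variable-density Archimedean spiral whose local arm spacing grows
  linearly from centre to rim ($s(r) = R\,(0.35 + 1.3\,r/r_{max})$, about
  3× denser at the centre at the same average rate $1/R$), rotated by a
  seed-derived angle per draw. No gridding/NUFFT is performed — the
  trajectory is snapped to the Cartesian grid, a documented fidelity
  caveat.
* **Reconstruction.** Zero filling with per-point density-compensation
  weights $1/p$ (analytic sampling density of the mask design: the centre
  block has weight 1, not $R$). This preserves the signal scale, makes the
  all-ones mask an exact identity, and — crucially — avoids the systematic
  low-frequency bias a global $\times R$ scaling would inject through the
  always-sampled centre, which would otherwise contaminate the aliasing
  measurement several-fold.
* **Monte Carlo.** Per trial, fresh complex Gaussian k-space noise and (by
  default) a freshly drawn mask — time-varying trajectories are what turn
  aliasing into pseudo-noise along a fingerprinting timecourse; a
  fixed-mask mode exists for ablation. The per-pixel standard deviation
  across trials gives the $d_R$ map; its mean over the nonzero phantom
  support is reported. The default 100,000 trials can be reduced to a few
  thousand for desk-scale runs; $d_R$ means over the ~6,800-pixel support
  are then still stable to ~1%. Aliasing Gaussianity is an assumption: a
  Shapiro-Wilk p-value on a probe pixel is reported, never enforced.

The aliasing-to-signal ratio follows $1/SaR \approx k\sqrt{R-1}$; the
package fits $k$ by least squares through the origin and feeds $k^2$ into
the closed-form plateau model
$d_R \approx \sqrt{k^2\,\frac{R-1}{R}\,SNR_{image}^2 + 1}$, which explains
the saturation of $d_R$ in $R$ and its linear growth with image SNR
(high-SNR data is aliasing-dominated). The uniform-density spiral is
*worse* than random sampling on this metric; the centre-dense profile
above is what makes the spiral alias less, consistent with how such
trajectories are designed in practice.

## Repeat-experiment validation

The in-silico validation harness emulates the classical single-parameter
validation: 10 repeats of 6 SPGR acquisitions
($\alpha = \{5, 8, 10, 13, 15, 18\}°$, TR 20 ms) of a two-region digital
phantom (region A $T_1 = 781$ ms standing in for white matter, region B
$T_1 = 1200$ ms for gray matter, unit $M_0$, zero background), with
complex Gaussian noise at $SNR_{max} = 200$. For every combination of at
least 3 flip angles, $T_1$ is fitted per repeat by the DESPOT1
linearization ($S/\sin\alpha$ on $S/\tan\alpha$; slope $e^{-TR/T_1}$) on
magnitude images, and the empirical efficiency uses the sample standard
deviation across repeats in place of the CRLB, pixelwise and then averaged
within each region (that ordering is a documented choice). Empirical is
regressed on theoretical efficiency across all 42 subsets × 2 regions; the
synthetic analogue consistently reaches $R^2 \gtrsim 0.99$, comfortably
above the 0.95 the acceptance suite requires.

What this does and does not show: the generator draws ideal Ernst-model
signals with known, spatially uniform noise — no $B_1^+$ error, incomplete
spoiling, magnetization transfer, motion, registration error or
structured noise. Passing therefore validates the metric's internal
consistency (CRLB ↔ repeat statistics), not robustness to the systematic
effects real acquisitions add; $\sigma_0$ is taken as ground truth rather
than estimated from the image background (an optional estimator exists for
parity). Two numerical notes: the linearized fit carries a small
noise-in-regressor bias at low pixel SNR (a Gauss-Newton refinement flag
removes it; the bias cancels in the efficiency ratio so the $R^2$
comparison is unaffected), and with few repeats the $1/\mathrm{sd}$ in
$\eta_{emp}$ is chi-distributed and biased high by
$\approx 3/(4(n{-}1))$ — the bound-attainment check therefore uses 50
repeats, where the residual 1.5% is dominated by the CRLB inequality
itself.

## Reproducibility

All randomness flows from a single integer seed through named substreams
(`derive_seed`): optimizer starts, Monte-Carlo noise, mask draws and
repeat noise never share a stream, so enlarging one component never
perturbs another. `run()` executes a validated `run_config` and embeds the
full configuration echo and package version in every JSON payload; rerun
with the same seed, the result files are byte-identical. The `exec/qmrieff`
script exposes the same five commands from a shell.

## Known limitations

Instantaneous pulses; no slice profile, $B_1^+$, magnetization transfer,
diffusion, flow, or multi-compartment effects; k-space is modelled only at
image level (Cartesian-snapped trajectories, no multi-coil g-factor);
magnitude-only estimators are out of scope except the DESPOT1 harness;
echo-pathway phase conventions for DESS/TESS may differ from other
implementations (magnitudes agree); and the design search is a multi-start
local method — it reports the best local optimum found, with per-start
costs retained so basin structure stays visible.
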