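# qmrieff

Efficiency analysis and sequence design for quantitative MRI relaxometry.

Methods that map the tissue relaxation times T1 and T2 — variable-flip-angle
SPGR (DESPOT1), balanced SSFP relaxometry (DESPOT2/JSR, PLANET), multi-echo
steady state (DESS, TESS), and transient fingerprinting (MRF) with spoiled or
balanced readouts — differ so much in structure that raw precision numbers
confound the method with the scanner, the voxel size and the scan time.
`qmrieff` compares them on a common footing through the intrinsic efficiency

    eta(theta) = (theta / sigma_theta) * (sigma0 / M0) / sqrt(T_acq)

the parameter-to-noise ratio per unit maximum SNR and square root of
acquisition time (units s^-1/2), with `sigma_theta` evaluated at the
Cramér–Rao lower bound of the sequence's complex signal model. The package
provides:

* forward signal models for all the methods above, backed by compiled
  extended-phase-graph (EPG) and Bloch propagation kernels, including exact
  driven-equilibrium (cyclic-train) fixed points;
* Fisher/CRLB machinery and the efficiency metric itself;
* constrained multi-start optimization of acquisition settings (flip-angle
  trains, repetition times) that maximizes joint T1/T2 efficiency over a
  tissue set;
* a Monte-Carlo model of the efficiency loss caused by k-space
  undersampling with zero-filled reconstruction — the "dynamics factor"
  d_R, with random and variable-density spiral masks on the Shepp–Logan
  phantom, and the closed-form plateau model
  `d_R ~ sqrt(k (R-1)/R * SNR_image^2 + 1)`;
* an in-silico repeat-experiment harness that validates predicted
  efficiencies against empirical ones for DESPOT1-style T1 mapping.

Intended users: MR physicists designing or comparing relaxometry protocols,
and methods researchers who need a reproducible CRLB/efficiency baseline.

## Worked example

Efficiency of the classical 6-flip DESPOT1 protocol (flip angles
5–18 degrees, TR 20 ms) for white matter at 3 T:

```r
library(qmrieff)

wm <- tissue_params(t1 = 781, t2 = 65)     # ms
u  <- seq_settings("SPGR", flips = c(5, 8, 10, 13, 15, 18), trs = 20)
efficiency(wm, u, params_of_interest = "T1", param_set = c("T1", "M0"))
#> efficiency over 0.12 s acquisition:
#>   eta(T1) = 0.11965 s^-1/2  (CRLB sd 18842)
```

Reading: over one 120 ms pass of the six measurements, each unit of
`SNR_max * sqrt(T_acq in s)` buys a T1-to-noise ratio of 0.12 — e.g. at
SNR_max = 200 a single pass yields T1NR ≈ 8.3, and averaging for 12 s
yields T1NR ≈ 83. (The CRLB sd is printed for the internal noise scale
`sigma0 = 1`; it divides out of `eta`.)

Optimizing a design instead — here a tiny cyclic spoiled fingerprint of 5
pulses (TE 2 ms, free flips and inter-pulse delays) for joint T1/T2
efficiency of the same tissue:

```r
problem <- method_catalogue("MRF_spoiled", 5, driven_equilibrium = TRUE,
                            te = 2, tr_bounds = c(2.3, 3000))
res <- solve_design(problem, seed = 1, control = list(maxit = 150, factr = 1e8))
res$cost          # sum over the tissue set of 1/eta(T1)^2 + 1/eta(T2)^2
round(res$u_opt$flips, 1)
```

The search contracts to a spin-echo + inversion-recovery motif with long
recovery delays — it is more efficient to measure fewer signals and let
magnetization recover. Two closely competing minima recur across the 100
starts: a 3-pulse schedule with flips near 60/180/90 degrees (the two
remaining pulses driven to zero amplitude, cost ~52.2) and a best-cost
variant (~50.1) that reuses the spare pulses as additional ~180 degree
refocusing pulses; per-start costs are retained in
`res$per_start_costs` so the basin structure stays visible.

Undersampling analysis on the Shepp–Logan phantom:

```r
ph <- shepp_logan(128)
dr <- monte_carlo_dr(ph, kind = "random", R = 8, snr_image = 50,
                     n_trials = 5000, seed = 1)
dr
#> d_R (random, R=8, SNR=50, 5000 trials): mean 21.71, SaR 0.817
eta_undersampled(0.36, dr$d_r_mean)   # a 0.36 s^-1/2 sequence keeps ~0.0166
```

A dynamics factor of ~22 at image SNR 50 means zero-filled undersampling
erodes this sequence's efficiency far below fully-sampled steady-state
alternatives — the reconstruction, not the spin dynamics, becomes the
bottleneck.

A thin command-line front end wraps the same functionality
(`exec/qmrieff <simulate|efficiency|optimize|undersample|validate> ...`);
sequence definitions travel as flat YAML files and results as CSV/JSON with
the full configuration embedded.

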