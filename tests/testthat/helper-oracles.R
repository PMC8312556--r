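# Brute-force oracles, independent of the package's propagation kernels:
# plain-R isochromat ensembles and stepwise Bloch recursions.

wm <- function(...) tissue_params(781, 65, ...)

# Gradient-crushed isochromat ensemble: each TR every isochromat precesses by
# its own angle psi (uniform over 2 pi), emulating one ideal unit crusher.
# Returns the per-pulse ensemble-average transverse signal at TE.
iso_spoiled_train <- function(p, flips_deg, trs, te, n_iso = 10000) {
  psi <- 2 * pi * (seq_len(n_iso) - 0.5) / n_iso
  c1 <- cos(psi); s1 <- sin(psi)
  Mx <- numeric(n_iso); My <- numeric(n_iso); Mz <- rep(p$m0, n_iso)
  sig <- complex(length(flips_deg))
  for (i in seq_along(flips_deg)) {
    a <- flips_deg[i] * pi / 180
    My2 <- cos(a) * My - sin(a) * Mz
    Mz <- sin(a) * My + cos(a) * Mz
    My <- My2
    sig[i] <- mean(complex(real = Mx, imaginary = My)) * exp(-te / p$t2)
    e1 <- exp(-trs[i] / p$t1); e2 <- exp(-trs[i] / p$t2)
    Mx <- Mx * e2; My <- My * e2; Mz <- Mz * e1 + p$m0 * (1 - e1)
    Mx2 <- c1 * Mx - s1 * My
    My <- s1 * Mx + c1 * My
    Mx <- Mx2
  }
  sig * exp(1i * p$phi0)
}

# Ideally spoiled steady state by brute force: transverse magnetization
# destroyed before every pulse (the SPGR model's assumption).
iso_spgr_steady <- function(p, flip_deg, tr, n_pulses = 5000) {
  a <- flip_deg * pi / 180
  e1 <- exp(-tr / p$t1)
  Mz <- p$m0
  s <- 0
  for (i in seq_len(n_pulses)) {
    s <- Mz * sin(a)
    Mz <- Mz * cos(a) * e1 + p$m0 * (1 - e1)
  }
  s * exp(1i * p$phi0)
}

# Single-isochromat balanced recursion iterated to its steady state, written
# directly from the rotation matrices (independent of the C++ kernel and of
# the closed-form linear solve).
iso_bssfp_steady <- function(p, flip_deg, tr, te, dphi_deg, n_iter = 60000) {
  a <- flip_deg * pi / 180
  rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  psi <- 2 * pi * p$omega0 * tr / 1000 - dphi_deg * pi / 180
  rz <- matrix(c(cos(psi), sin(psi), 0, -sin(psi), cos(psi), 0, 0, 0, 1), 3, 3)
  e1 <- exp(-tr / p$t1); e2 <- exp(-tr / p$t2)
  M <- rz %*% diag(c(e2, e2, e1)) %*% rx
  b <- c(0, 0, p$m0 * (1 - e1))
  m <- c(0, 0, p$m0)
  for (i in seq_len(n_iter)) m <- M %*% m + b
  mp <- rx %*% m
  complex(real = mp[1], imaginary = mp[2]) *
    exp(1i * 2 * pi * p$omega0 * te / 1000) * exp(-te / p$t2) * exp(1i * p$phi0)
}

# Post-RF configuration amplitudes F_k of the crushed steady state by brute
# force (Fourier coefficients of the isochromat distribution).
iso_steady_configs <- function(p, flip_deg, tr, orders, n_iso = 10000,
                               n_tr = 3000) {
  psi <- 2 * pi * (seq_len(n_iso) - 0.5) / n_iso
  c1 <- cos(psi); s1 <- sin(psi)
  a <- flip_deg * pi / 180
  e1 <- exp(-tr / p$t1); e2 <- exp(-tr / p$t2)
  Mx <- numeric(n_iso); My <- numeric(n_iso); Mz <- rep(p$m0, n_iso)
  for (i in seq_len(n_tr)) {
    My2 <- cos(a) * My - sin(a) * Mz
    Mz <- sin(a) * My + cos(a) * Mz
    My <- My2
    Mx <- Mx * e2; My <- My * e2; Mz <- Mz * e1 + p$m0 * (1 - e1)
    Mx2 <- c1 * Mx - s1 * My
    My <- s1 * Mx + c1 * My
    Mx <- Mx2
  }
  My2 <- cos(a) * My - sin(a) * Mz
  Mxy <- complex(real = Mx, imaginary = My2)
  vapply(orders, function(k) mean(Mxy * exp(-1i * k * psi)), 0i)
}

expect_rel_equal <- function(actual, expected, tol, scale = NULL) {
  s <- scale %||% max(Mod(expected))
  expect_lt(max(Mod(actual - expected)) / s, tol)
}
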