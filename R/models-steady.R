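#' Ideally spoiled gradient-echo (SPGR) steady-state signal
#'
#' Ernst steady state of an RF- and gradient-spoiled sequence,
#' \deqn{s = M_0 \sin\alpha \frac{1-E_1}{1-E_1\cos\alpha} e^{i\phi_0},
#'       \quad E_1 = e^{-TR/T_1}.}
#' Transverse magnetization is assumed fully destroyed each TR, so the signal
#' carries no T2 weighting and decay to the echo time is not modelled (it is
#' common to all flip angles and would be absorbed into the effective M0).
#'
#' @param p a [tissue_params()] object.
#' @param flip flip angle(s) in degrees.
#' @param tr repetition time(s) in ms.
#' @param te echo time in ms; accepted for interface symmetry, unused.
#' @return complex signal, one value per flip/TR pair.
#' @examples
#' p <- tissue_params(781, 65)
#' acos(exp(-20 / 781)) * 180 / pi # Ernst angle for TR = 20 ms
#' @export
spgr_signal <- function(p, flip, tr, te = 0) {
  stopifnot(inherits(p, "tissue_params"))
  if (any(tr <= 0)) stopf("tr must be positive")
  if (any(flip < 0 | flip > 180)) stopf("flip must lie in [0, 180] degrees")
  a <- deg2rad(flip)
  e1 <- exp(-tr / p$t1)
  p$m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a)) * exp(1i * p$phi0)
}

# One-TR affine recursion of a balanced sequence in the frame demodulated by
# the RF phase: m_pre(next) = M %*% m_pre + b with
# M = Rz(psi) diag(E2,E2,E1) Rx(alpha), psi = 2 pi omega0 TR - dphi.
bssfp_recursion <- function(p, flip_rad, tr, dphi_rad) {
  e1 <- exp(-tr / p$t1); e2 <- exp(-tr / p$t2)
  psi <- 2 * pi * p$omega0 * tr / 1000 - dphi_rad
  ca <- cos(flip_rad); sa <- sin(flip_rad)
  rx <- matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3) # right-handed about x
  rz <- matrix(c(cos(psi), sin(psi), 0, -sin(psi), cos(psi), 0, 0, 0, 1), 3, 3)
  M <- rz %*% diag(c(e2, e2, e1)) %*% rx
  list(M = M, b = c(0, 0, p$m0 * (1 - e1)), rx = rx)
}

#' Balanced SSFP steady-state signal at the echo time
#'
#' Steady state of a fully balanced sequence with a constant per-TR RF phase
#' increment (180 deg, i.e. alternating phase, by default). The signal is the
#' transverse magnetization at TE, demodulated by the pulse phase, including
#' off-resonance precession `exp(i 2 pi omega0 TE)`, T2 decay to TE and the
#' measurement phase `phi0`. The steady state is obtained exactly as the fixed
#' point of the per-TR affine Bloch recursion (a 3x3 linear solve), so the
#' characteristic banding periodicity in `omega0` with period `1000/tr` Hz is
#' inherited from the recursion itself.
#'
#' @param p a [tissue_params()] object.
#' @param flip flip angle(s), degrees.
#' @param tr repetition time(s), ms.
#' @param te echo time(s), ms; defaults to TR/2.
#' @param rf_phase_increment per-TR RF phase increment(s), degrees.
#' @return complex signal, one value per measurement.
#' @export
bssfp_signal <- function(p, flip, tr, te = tr / 2, rf_phase_increment = 180) {
  stopifnot(inherits(p, "tissue_params"))
  if (any(tr <= 0)) stopf("tr must be positive")
  if (any(te > tr)) stopf("te must not exceed tr")
  n <- max(length(flip), length(tr), length(te), length(rf_phase_increment))
  flip <- rep_len(flip, n); tr <- rep_len(tr, n); te <- rep_len(te, n)
  dphi <- rep_len(rf_phase_increment, n)
  bssfp_signal_cpp(deg2rad(flip), tr, te, deg2rad(dphi),
                   p$t1, p$t2, p$m0, p$phi0, p$omega0)
}

# Apply one RF rotation to an EPG state list (used to read out the post-pulse
# configuration amplitudes of a steady state solved at the pre-pulse point).
epg_rf_r <- function(state, flip_rad, phase_rad = 0) {
  a <- flip_rad; phi <- phase_rad
  ei <- exp(1i * phi); e2i <- exp(2i * phi)
  Tm <- matrix(c(
    cos(a / 2)^2,              e2i * sin(a / 2)^2,      -1i * ei * sin(a),
    Conj(e2i) * sin(a / 2)^2,  cos(a / 2)^2,             1i * Conj(ei) * sin(a),
    -0.5i * Conj(ei) * sin(a), 0.5i * ei * sin(a),       cos(a) + 0i
  ), 3, 3, byrow = TRUE)
  S <- rbind(state$Fp, state$Fm, state$Z)
  S2 <- Tm %*% S
  list(Fp = S2[1, ], Fm = S2[2, ], Z = S2[3, ], max_order = state$max_order)
}

#' Echo pathway amplitudes of the gradient-spoiled steady state (DESS/TESS)
#'
#' Computes the periodic steady state of a gradient-spoiled sequence (one
#' ideal unit crusher per TR) as the fixed point of the per-TR extended phase
#' graph operator, then reads out the first `n_echoes` echo pathway
#' amplitudes from the post-pulse configuration states:
#' the FID-like path \eqn{F_0} (decay `exp(-te/T2)`), the refocusing path
#' \eqn{F_{-1}} which forms its echo at `tr - te` (decay `exp(-(tr-te)/T2)`),
#' and for TESS the \eqn{F_{+1}} path (decay `exp(-te/T2)`). All amplitudes
#' carry the measurement phase `phi0`.
#'
#' @param p a [tissue_params()] object.
#' @param flip shared flip angle, degrees.
#' @param tr shared repetition time, ms.
#' @param te echo time, ms.
#' @param n_echoes 2 (DESS) or 3 (TESS).
#' @param max_order EPG truncation order for the fixed-point solve.
#' @return complex vector of `n_echoes` echo amplitudes.
#' @export
steady_state_echoes <- function(p, flip, tr, te, n_echoes, max_order = 24) {
  stopifnot(inherits(p, "tissue_params"))
  if (!n_echoes %in% 2:3) stopf("n_echoes must be 2 or 3")
  if (tr <= 0 || te < 0 || te > tr) stopf("need 0 <= te <= tr, tr > 0")
  a <- deg2rad(flip)
  K <- as.integer(max_order)
  cm <- epg_cycle_map_cpp(a, 0, tr, te, p$t1, p$t2, p$m0, K)
  x <- tryCatch(solve(diag(nrow(cm$A)) - cm$A, cm$b),
                error = function(e) stopf(
                  "EPG steady state unreachable (singular per-TR operator): %s",
                  conditionMessage(e)))
  pre <- real_to_epg_state(x, K)
  post <- epg_rf_r(pre, a)
  dec <- c(exp(-te / p$t2), exp(-(tr - te) / p$t2), exp(-te / p$t2))
  amps <- c(post$Fp[1], Conj(post$Fm[2]), post$Fp[2]) * dec
  amps[seq_len(n_echoes)] * exp(1i * p$phi0)
}

# Inverse of the real-ified EPG layout used by the C++ cycle-map builder.
real_to_epg_state <- function(x, K) {
  L <- K + 1
  list(Fp = complex(real = x[1:L], imaginary = x[L + 1:L]),
       Fm = complex(real = x[2 * L + 1:L], imaginary = x[3 * L + 1:L]),
       Z = complex(real = x[4 * L + 1:L], imaginary = x[5 * L + 1:L]),
       max_order = K)
}

epg_state_to_real <- function(s) {
  c(Re(s$Fp), Im(s$Fp), Re(s$Fm), Im(s$Fm), Re(s$Z), Im(s$Z))
}
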