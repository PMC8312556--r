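test_that("spoiled EPG transient matches a 10,000-isochromat oracle", {
  p <- tissue_params(781, 65, phi0 = 0.3)
  set.seed(11)
  flips <- runif(80, 0, 120)
  trs <- runif(80, 3, 15)
  u <- seq_settings("MRF_spoiled", flips = flips, trs = trs, te = 2,
                    min_readout_margin = 0)
  # 80 pulses exceed the initial truncation order: growth is announced
  expect_warning(rec <- epg_spoiled_transient(p, u), "truncation")
  oracle <- iso_spoiled_train(p, flips, trs, 2)
  expect_rel_equal(rec$signal, oracle, 1e-6)
  expect_equal(rec$t_acq, sum(trs))
  expect_true(all(Mod(rec$signal) <= p$m0))
})

test_that("spoiled EPG trivial cases behave", {
  p <- wm()
  u0 <- seq_settings("MRF_spoiled", flips = rep(0, 8), trs = 10, te = 2,
                     min_readout_margin = 0)
  expect_equal(max(Mod(epg_spoiled_transient(p, u0)$signal)), 0)
  u90 <- seq_settings("MRF_spoiled", flips = 90, trs = 10, te = 0,
                      min_readout_margin = 0)
  expect_equal(Mod(epg_spoiled_transient(p, u90)$signal[1]), p$m0,
               tolerance = 1e-12)
})

test_that("balanced transient converges to the bSSFP closed form", {
  p <- tissue_params(781, 65, omega0 = 23)
  n <- 4000 # ~ 5 T1 / TR pulses to settle well below 1e-6
  u <- seq_settings("MRF_balanced", flips = rep(35, n), trs = 5, te = 2.5)
  rec <- bloch_balanced_transient(p, u)
  cf <- bssfp_signal(p, 35, 5, 2.5, 180)
  expect_lt(Mod(rec$signal[n] - cf) / Mod(cf), 1e-6)
  # zero train stays zero
  u0 <- seq_settings("MRF_balanced", flips = rep(0, 10), trs = 5, te = 2.5)
  expect_equal(max(Mod(bloch_balanced_transient(p, u0)$signal)), 0)
})

test_that("alternating-phase balanced train nulls at the band edge", {
  n <- 3000
  mag_at <- function(w) {
    p <- tissue_params(781, 65, omega0 = w)
    u <- seq_settings("MRF_balanced", flips = rep(40, n), trs = 5, te = 2.5)
    Mod(bloch_balanced_transient(p, u)$signal[n])
  }
  ws <- seq(-100, 100, by = 10) # band edges at +-1/(2 TR) = +-100 Hz
  mags <- vapply(ws, mag_at, 0)
  expect_equal(sort(which(mags <= min(mags) + 1e-12)), c(1L, length(ws)))
  expect_lt(mags[1] / mag_at(0), 0.15)
})

test_that("driven equilibrium fixed point: solve equals long iteration", {
  p <- wm()
  u <- seq_settings("MRF_spoiled", flips = c(60, 0, 180, 0, 90),
                    trs = c(100, 200, 50, 300, 400), te = 2,
                    driven_equilibrium = TRUE, min_readout_margin = 0)
  st <- driven_equilibrium_state(p, u)
  u_open <- u; u_open$driven_equilibrium <- FALSE
  init <- epg_thermal(p$m0, st$max_order)
  for (i in 1:200) # 200 cycles x 1.05 s covers many T1
    init <- attr(epg_spoiled_transient(p, u_open, initial = init), "final_state")
  expect_lt(max(Mod(c(init$Fp - st$Fp, init$Fm - st$Fm, init$Z - st$Z))), 1e-9)
})

test_that("driven equilibrium residual contract holds, also for long trains", {
  p <- wm()
  set.seed(5)
  u <- seq_settings("MRF_spoiled", flips = runif(300, 0, 80),
                    trs = runif(300, 4, 12), te = 2,
                    driven_equilibrium = TRUE, min_readout_margin = 0)
  st <- driven_equilibrium_state(p, u) # long train: iteration path
  one <- epg_spoiled_transient(p, u, initial = st)
  fin <- attr(one, "final_state")
  K <- min(st$max_order, fin$max_order) + 1L
  resid <- max(Mod(c(fin$Fp[1:K] - st$Fp[1:K], fin$Fm[1:K] - st$Fm[1:K],
                     fin$Z[1:K] - st$Z[1:K])))
  expect_lt(resid, 1e-10 * p$m0)
  # trivial train: fixed point is thermal equilibrium
  u0 <- seq_settings("MRF_spoiled", flips = rep(0, 4), trs = 50, te = 2,
                     driven_equilibrium = TRUE, min_readout_margin = 0)
  st0 <- driven_equilibrium_state(p, u0)
  expect_equal(st0$Z[1], p$m0 + 0i, tolerance = 1e-12)
  expect_lt(max(Mod(c(st0$Fp, st0$Fm, st0$Z[-1]))), 1e-12)
})

test_that("balanced driven equilibrium is a true cycle fixed point", {
  p <- tissue_params(781, 65, omega0 = 31)
  u <- seq_settings("MRF_balanced", flips = rep_len(c(50, 20, 70), 60),
                    trs = 5, te = 2.5, driven_equilibrium = TRUE)
  m <- driven_equilibrium_state(p, u)
  rec <- bloch_balanced_transient(p, u, initial = m)
  expect_lt(max(abs(attr(rec, "final_m") - m)), 1e-10 * p$m0)
})

test_that("transient signals are exactly linear in M0", {
  u <- seq_settings("MRF_spoiled", flips = c(30, 70, 10), trs = 8, te = 2,
                    min_readout_margin = 0)
  s1 <- epg_spoiled_transient(tissue_params(700, 60, m0 = 1), u)$signal
  s3 <- epg_spoiled_transient(tissue_params(700, 60, m0 = 3), u)$signal
  expect_equal(s3, 3 * s1)
  ub <- seq_settings("MRF_balanced", flips = c(30, 70, 10), trs = 5, te = 2.5)
  b1 <- bloch_balanced_transient(tissue_params(700, 60, m0 = 1), ub)$signal
  b3 <- bloch_balanced_transient(tissue_params(700, 60, m0 = 3), ub)$signal
  expect_equal(b3, 3 * b1)
})

test_that("signal records serialize to CSV with the documented columns", {
  rec <- signal_record(c(1 + 2i, 3 - 1i), times = c(2, 12), t_acq = 20)
  f <- withr::local_tempfile(fileext = ".csv")
  write_signal_csv(rec, f)
  tab <- read.csv(f)
  expect_equal(names(tab), c("index", "time_ms", "re", "im"))
  expect_equal(tab$re, c(1, 3))
  expect_equal(tab$im, c(2, -1))
})
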