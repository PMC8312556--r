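test_that("jacobian columns: analytic SPGR T1 derivative and M0 linearity", {
  p <- wm()
  u <- seq_settings("SPGR", flips = c(5, 8, 10, 13, 15, 18), trs = 20)
  fb <- model_jacobian(p, u, params = c("T1", "M0"))
  a <- deg2rad(c(5, 8, 10, 13, 15, 18))
  e1 <- exp(-20 / 781)
  de1 <- e1 * 20 / 781^2
  dsdT1 <- sin(a) * de1 * (cos(a) - 1) / (1 - e1 * cos(a))^2 # symbolic
  expect_rel_equal(fb$jacobian[, "T1"], dsdT1, 1e-6)
  expect_equal(fb$jacobian[, "M0"], fb$signal / p$m0)
})

test_that("finite differences are converged (step halving changes little)", {
  p <- tissue_params(781, 65, omega0 = 40)
  u <- seq_settings("bSSFP", flips = c(20, 45, 70), trs = 8)
  J1 <- model_jacobian(p, u, h_rel = 1e-4)$jacobian
  J2 <- model_jacobian(p, u, h_rel = 5e-5)$jacobian
  expect_rel_equal(J1, J2, 1e-4)
  # phi0 column is analytic
  expect_equal(J1[, "phi0"], 1i * signal_model(p, u)$signal)
})

test_that("crlb_std closed form, noise scaling, and singular policy", {
  p <- tissue_params(1000, 100)
  # N identical measurements with d s / d theta = c: sigma = sigma0/(|c| sqrt N)
  N <- 7; cc <- 0.35
  fb <- structure(list(jacobian = matrix(cc + 0i, N, 1,
                                         dimnames = list(NULL, "T1")),
                       sigma0 = 0.2, param_order = "T1", tissue = p,
                       signal = rep(0i, N), t_acq = 100),
                  class = "fisher_bundle")
  expect_equal(crlb_std(fb, "T1"), 0.2 / (cc * sqrt(N)))
  fb2 <- fb; fb2$sigma0 <- 0.4
  expect_equal(crlb_std(fb2, "T1"), 2 * crlb_std(fb, "T1"))
  # two perfectly collinear parameters are jointly unidentifiable
  fb3 <- structure(list(jacobian = matrix(c(1, 2, 1, 2) + 0i, 2, 2,
                                          dimnames = list(NULL, c("T1", "T2"))),
                        sigma0 = 1, param_order = c("T1", "T2"), tissue = p,
                        signal = rep(0i, 2), t_acq = 100),
                   class = "fisher_bundle")
  expect_warning(v <- crlb_std(fb3, "T1"), class = "qmrieff_singular_fisher")
  expect_identical(v, Inf)
})

test_that("efficiency arithmetic and invariances", {
  p <- tissue_params(1000, 80, m0 = 1)
  fb <- structure(list(jacobian = matrix(2 + 0i, 4, 1,
                                         dimnames = list(NULL, "T1")),
                       sigma0 = 1 / 40, param_order = "T1", tissue = p,
                       signal = rep(0i, 4), t_acq = 4000),
                  class = "fisher_bundle")
  sd1 <- crlb_std(fb, "T1")
  expect_equal((p$t1 / sd1) * (fb$sigma0 / p$m0) / sqrt(4),
               eta_from_fisher(fb, "T1"))
  # sigma0 and M0 cancel exactly in the full pipeline
  u <- seq_settings("SPGR", flips = c(5, 8, 10, 13, 15, 18), trs = 20)
  e1 <- efficiency(wm(), u, "T1", sigma0 = 1, param_set = c("T1", "M0"))
  e2 <- efficiency(wm(), u, "T1", sigma0 = 10, param_set = c("T1", "M0"))
  e3 <- efficiency(tissue_params(781, 65, m0 = 7), u, "T1",
                   param_set = c("T1", "M0"))
  expect_equal(e1$eta[["T1"]], e2$eta[["T1"]], tolerance = 1e-12)
  expect_equal(e1$eta[["T1"]], e3$eta[["T1"]], tolerance = 1e-9)
  expect_equal(e1$tnr[["T1"]], e1$eta[["T1"]] * sqrt(e1$t_acq_s))
})

test_that("eta(theta NR = 100, SNR 200, T_acq 4 s) equals 0.25 per second^-1/2", {
  # build a bundle whose CRLB gives thetaNR exactly 100 at SNR_max 200
  p <- tissue_params(1000, 80, m0 = 1)
  sigma0 <- 1 / 200 # SNR_max = M0/sigma0 = 200
  # one measurement with derivative c gives sigma_theta = sigma0/|c|;
  # choose c so that thetaNR = theta |c| / sigma0 = 100
  cc <- 100 * sigma0 / p$t1
  fb <- structure(list(jacobian = matrix(cc + 0i, 1, 1,
                                         dimnames = list(NULL, "T1")),
                       sigma0 = sigma0, param_order = "T1", tissue = p,
                       signal = 0i, t_acq = 4000),
                  class = "fisher_bundle")
  expect_equal(eta_from_fisher(fb, "T1"), 100 / 200 / sqrt(4))
})

test_that("duplicating a steady-state acquisition leaves eta unchanged", {
  # information doubles and acquisition time doubles: thetaNR grows sqrt(2)
  # while sqrt(T_acq) grows sqrt(2), so eta is invariant under replication
  p <- wm()
  u1 <- seq_settings("SPGR", flips = c(5, 10, 15, 18), trs = 20)
  u2 <- seq_settings("SPGR", flips = rep(c(5, 10, 15, 18), 2), trs = 20)
  e1 <- efficiency(p, u1, "T1", param_set = c("T1", "M0"))$eta[["T1"]]
  e2 <- efficiency(p, u2, "T1", param_set = c("T1", "M0"))$eta[["T1"]]
  expect_equal(e2, e1, tolerance = 1e-10)
})

test_that("adding a measurement at fixed T_acq never decreases eta", {
  p <- wm()
  u <- seq_settings("SPGR", flips = c(5, 10, 15), trs = 20)
  fb <- model_jacobian(p, u, params = c("T1", "M0"))
  base <- eta_from_fisher(fb, "T1", t_acq_s = 0.1)
  for (extra in c(2, 8, 14, 17)) {
    uplus <- seq_settings("SPGR", flips = c(5, 10, 15, extra), trs = 20)
    fbp <- model_jacobian(p, uplus, params = c("T1", "M0"))
    expect_gte(eta_from_fisher(fbp, "T1", t_acq_s = 0.1) - base, -1e-12)
  }
})

test_that("efficiency_grid emits one row per tissue with eta columns", {
  tg <- tissue_grid(t1 = c(700, 800), t2 = c(60, 70), omega0 = c(-50, 0))
  u <- seq_settings("bSSFP", flips = c(15, 35, 55, 80), trs = 10)
  tab <- efficiency_grid(tg, u)
  expect_equal(nrow(tab), 8)
  expect_named(tab, c("method", "T1_ms", "T2_ms", "omega0_Hz",
                      "eta_T1", "eta_T2"))
  expect_true(all(is.finite(tab$eta_T1) & tab$eta_T1 >= 0))
})
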