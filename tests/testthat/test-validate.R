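test_that("simulated repeats honor the noise contract", {
  ph <- despot1_phantom(16)
  exp0 <- repeat_experiment(ph, n_repeats = 4, sigma0 = 0, seed = 1)
  d0 <- simulate_repeats(exp0)
  expect_equal(d0[, , , 1], d0[, , , 4]) # no noise -> identical repeats
  expn <- repeat_experiment(ph, n_repeats = 1000, sigma0 = 0.02, seed = 1)
  dn <- simulate_repeats(expn)
  px <- which(ph$masks$A, arr.ind = TRUE)[1, ]
  draws <- dn[px[1], px[2], 1, ]
  expect_equal(sd(Re(draws)), 0.02, tolerance = 0.1) # per-quadrature sigma0
  expect_equal(sd(Im(draws)), 0.02, tolerance = 0.1)
  # mean image converges to the noiseless forward model (law of large numbers)
  expect_equal(Re(mean(draws)), Re(d0[px[1], px[2], 1, 1]),
               tolerance = 5 * 0.02 / sqrt(1000) / Re(d0[px[1], px[2], 1, 1]))
  expect_error(repeat_experiment(ph, n_repeats = 2), ">= 3")
})

test_that("DESPOT1 linearization inverts the model exactly without noise", {
  ph <- despot1_phantom(16)
  exp0 <- repeat_experiment(ph, n_repeats = 3, sigma0 = 0)
  imgs <- simulate_repeats(exp0)[, , , 1]
  fit <- fit_despot1(imgs, exp0$flips, exp0$tr)
  on_a <- ph$masks$A
  expect_lt(max(abs(fit$t1[on_a] - 781)) / 781, 1e-8)
  expect_lt(max(abs(fit$m0[on_a] - 1)), 1e-8)
  expect_lt(max(abs(fit$t1[ph$masks$B] - 1200)) / 1200, 1e-8)
  # slope identity: regression slope equals exp(-TR/T1) pixelwise
  a <- exp0$flips * pi / 180
  px <- which(on_a, arr.ind = TRUE)[1, ]
  y <- Mod(imgs[px[1], px[2], ]) / sin(a)
  x <- Mod(imgs[px[1], px[2], ]) / tan(a)
  expect_equal(unname(coef(lm(y ~ x))[2]), exp(-20 / 781), tolerance = 1e-8)
  # background pixels are flagged invalid, not fabricated
  expect_true(all(is.na(fit$t1[!(ph$masks$A | ph$masks$B)])))
})

test_that("T1 bias at SNR_max = 200 is below 1% for the refined fit", {
  ph <- despot1_phantom(16)
  expn <- repeat_experiment(ph, n_repeats = 200, sigma0 = 1 / 200, seed = 8)
  dat <- simulate_repeats(expn)
  means <- means_lin <- numeric(200)
  for (r in 1:200) {
    means[r] <- mean(fit_despot1(dat[, , , r], expn$flips, expn$tr,
                                 refine = TRUE)$t1[ph$masks$A], na.rm = TRUE)
    means_lin[r] <- mean(fit_despot1(dat[, , , r], expn$flips,
                                     expn$tr)$t1[ph$masks$A], na.rm = TRUE)
  }
  expect_lt(abs(mean(means) - 781) / 781, 0.01)
  # refinement reduces the linearization's noise-in-regressor bias
  expect_lt(abs(mean(means) - 781), abs(mean(means_lin) - 781))
})

test_that("empirical efficiency reproduces the definition on injected data", {
  n <- 8; reps <- 64
  t_acq_s <- 0.12
  sigma0 <- 0.005
  m0 <- matrix(1, n, n)
  set.seed(2)
  mu <- 800; sdev <- 25
  stack <- array(rnorm(n * n * reps, mu, sdev), c(n, n, reps))
  out <- empirical_efficiency(stack, sigma0, m0, t_acq_s)
  px_mu <- apply(stack, c(1, 2), mean)
  px_sd <- apply(stack, c(1, 2), sd)
  expect_equal(out$eta_map, (px_mu / px_sd) * sigma0 / sqrt(t_acq_s))
  # zero-spread pixels are excluded with a warning
  stack[1, 1, ] <- 500
  expect_warning(out2 <- empirical_efficiency(stack, sigma0, m0, t_acq_s),
                 "zero spread")
  expect_true(is.na(out2$eta_map[1, 1]))
})

test_that("empirical subset ranking follows the theoretical ranking", {
  vs <- run_despot1_validation(n_repeats = 50, seed = 21, phantom_n = 24)
  rho <- cor(vs$table$eta_empirical, vs$table$eta_theoretical,
             method = "spearman")
  expect_gte(rho, 0.9)
})

test_that("empirical efficiency does not exceed the CRLB prediction on average", {
  # eta_emp/eta_th averaged over seed replicates; 50 repeats keeps the
  # 1/sd chi-bias below ~1.5% so the CRLB bound dominates the comparison
  ph <- despot1_phantom(16)
  flips <- c(5, 8, 10, 13, 15, 18)
  u <- seq_settings("SPGR", flips = flips, trs = 20)
  th <- efficiency(tissue_params(781, 65), u, "T1", sigma0 = 1 / 200,
                   param_set = c("T1", "M0"))$eta[["T1"]]
  ratios <- vapply(1:30, function(s) {
    expn <- repeat_experiment(ph, flips = flips, n_repeats = 50,
                              sigma0 = 1 / 200, seed = s)
    dat <- simulate_repeats(expn)
    t1s <- array(NA_real_, c(dim(ph$t1_map), 50))
    for (r in 1:50) t1s[, , r] <- fit_despot1(dat[, , , r], flips, 20)$t1
    emp <- empirical_efficiency(t1s, 1 / 200, ph$m0_map, 6 * 20 / 1000,
                                masks = ph$masks["A"])
    emp$eta_regions[["A"]] / th
  }, 0)
  expect_lte(mean(ratios), 1.05)
})
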