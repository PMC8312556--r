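test_that("Shepp-Logan phantom has the documented structure", {
  img <- shepp_logan(128)
  expect_equal(dim(img), c(128, 128))
  expect_equal(max(img), 1) # skull ring is the brightest structure
  expect_true(all(img >= 0 & img <= 1))
  expect_equal(img[1, 1], 0) # background
  # left-right symmetric away from the off-axis ellipses (the ventricle pair
  # has unequal semi-axes): the strip above them (y >= 0.5) mirrors exactly
  top <- img[, 1:32]
  expect_equal(top, top[128:1, ], tolerance = 1e-12)
  # nonzero support matches an independently written point-in-ellipse
  # rasterization (rotation applied via complex multiplication)
  ell <- qmrieff:::SHEPP_LOGAN_ELLIPSES
  xs <- seq(-1, 1, length.out = 128)
  z <- outer(xs, rev(xs), function(x, y) complex(real = x, imaginary = y))
  ref <- matrix(0, 128, 128)
  for (i in seq_len(nrow(ell))) {
    w <- (z - complex(real = ell$x0[i], imaginary = ell$y0[i])) *
      exp(-1i * ell$phi[i] * pi / 180)
    ref <- ref + ell$A[i] * ((Re(w) / ell$a[i])^2 + (Im(w) / ell$b[i])^2 <= 1)
  }
  expect_equal(sum(img > 0), sum(pmax(ref, 0) > 0))
  expect_lt(max(abs(img - pmin(pmax(ref, 0), 1))), 1e-12)
  expect_error(shepp_logan(16), "at least 32")
})

test_that("masks meet their rate contracts", {
  m1r <- make_mask("random", 64, 1)
  m1s <- make_mask("spiral", 64, 1)
  expect_true(all(m1r$mask) && all(m1s$mask))
  m4 <- make_mask("random", 128, 4, seed = 7)
  expect_gt(mean(m4$mask), 0.24)
  expect_lt(mean(m4$mask), 0.26)
  fr <- vapply(c(2, 4, 8), function(R)
    mean(make_mask("spiral", 128, R, seed = 1)$mask), 0)
  expect_true(all(diff(fr) < 0)) # spiral fraction decreases with R
  expect_error(make_mask("random", 32, 200), "16 sampled")
})

test_that("zero-filled reconstruction: exactness, linearity, Parseval", {
  img <- shepp_logan(64)
  m1 <- make_mask("random", 64, 1)
  expect_lt(max(Mod(zero_filled_recon(img, m1) - img)), 1e-12)
  m3 <- make_mask("random", 64, 3, seed = 2)
  r1 <- zero_filled_recon(img, m3)
  r2 <- zero_filled_recon(2.5 * img, m3)
  expect_equal(r2, 2.5 * r1, tolerance = 1e-12)
  # aliasing energy equals the masked-spectrum identity in k-space
  err_img <- sum(Mod(r1 - img)^2)
  K <- fft(img)
  err_k <- sum(Mod((m3$weights - 1) * K)^2) / length(K)
  expect_equal(err_img, err_k, tolerance = 1e-10)
})

test_that("d_R is 1 for full sampling and >= 1 under undersampling", {
  ph <- shepp_logan(64)
  dr1 <- monte_carlo_dr(ph, "random", R = 1, snr_image = 50, n_trials = 300,
                        seed = 3)
  expect_equal(dr1$d_r_mean, 1, tolerance = 3 / sqrt(2 * 300))
  expect_true(all(abs(dr1$d_r_map[!is.na(dr1$d_r_map)] - 1) < 0.5))
  dr4 <- monte_carlo_dr(ph, "random", R = 4, snr_image = 50, n_trials = 300,
                        seed = 3)
  expect_gt(dr4$d_r_mean, 1)
  expect_error(monte_carlo_dr(ph, "random", 4, 50, n_trials = 10), ">= 100")
})

test_that("aliasing scaling fit recovers exact synthetic data", {
  R <- c(2, 4, 8, 16, 32)
  k0 <- 0.37
  sar <- 1 / (k0 * sqrt(R - 1))
  f <- fit_aliasing_scaling(R, sar)
  expect_equal(f$k_asr, k0, tolerance = 1e-10)
  expect_lt(f$residual_norm, 1e-10)
  expect_error(fit_aliasing_scaling(c(2, 4), c(1, 2)), "distinct")
})

test_that("closed-form d_R model obeys its limits and composition", {
  expect_equal(dr_model(1, 123, 0.2), 1)
  expect_equal(dr_model(7, 0, 0.2), 1)
  expect_equal(dr_model(8, 50, 0.09), sqrt(0.09 * 7 / 8 * 2500 + 1))
  expect_equal(eta_undersampled(0.6, 1), 0.6)
  expect_equal(eta_undersampled(0.6, 5), 0.12) # the reduction-factor-5 case
  expect_equal(eta_undersampled(c(1, 2), dr_model(1, 10, 0.1)), c(1, 2))
  expect_error(eta_undersampled(1, 0), "nonzero")
  expect_warning(eta_undersampled(1, 0.5), "least-squares")
})

test_that("d_R maps export as plain-text PGM with a YAML sidecar", {
  map <- matrix(runif(64, 1, 6), 8, 8)
  map[1, 1] <- NA
  f <- withr::local_tempfile(fileext = ".pgm")
  write_pgm(map, f)
  lines <- readLines(f)
  expect_equal(lines[1], "P2")
  expect_equal(lines[2], "8 8")
  side <- yaml::read_yaml(paste0(f, ".yaml"))
  expect_equal(side$max, max(map, na.rm = TRUE))
})

test_that("Monte-Carlo sigma estimates tighten as trials double", {
  ph <- shepp_logan(64)
  reps <- function(n_trials, seeds) vapply(seeds, function(s)
    monte_carlo_dr(ph, "random", 8, 30, n_trials = n_trials, seed = s)$d_r_mean,
    0)
  a <- reps(120, 1:6)
  b <- reps(480, 1:6)
  # spread should shrink roughly 2x (allow generous slack at 6 replicates)
  expect_lt(sd(b), sd(a))
})
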