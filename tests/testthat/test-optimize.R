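test_that("design cost is the capped sum of inverse-squared efficiencies", {
  p <- wm()
  u <- seq_settings("MRF_spoiled", flips = c(40, 90, 20), trs = c(10, 300, 800),
                    te = 2, driven_equilibrium = TRUE, min_readout_margin = 0)
  ef <- efficiency(p, u)
  expect_equal(design_cost(u, p),
               1 / ef$eta[["T1"]]^2 + 1 / ef$eta[["T2"]]^2, tolerance = 1e-10)
  # inherited invariance to M0 (and hence SNR scaling)
  expect_equal(design_cost(u, tissue_params(781, 65, m0 = 4)),
               design_cost(u, p), tolerance = 1e-9)
  # degenerate sequence contributes the cap, not Inf
  u0 <- seq_settings("MRF_spoiled", flips = rep(0, 3), trs = 10, te = 2,
                     min_readout_margin = 0)
  expect_equal(suppressWarnings(design_cost(u0, p)), 2e12)
})

test_that("white-matter cost over the off-resonance grid matches brute force", {
  grid <- seq(-100, 100, by = 25)
  problem <- method_catalogue("DESPOT_JSR", 6, omega0_grid = grid)
  x <- c(10, 20, 25, 45, 65, 85, rep(12, 6))
  u <- problem$builder(x)
  total <- design_cost(u, problem$tissue_set)
  brute <- sum(vapply(grid, function(w) {
    ef <- efficiency(tissue_params(781, 65, omega0 = w), u)
    1 / ef$eta[["T1"]]^2 + 1 / ef$eta[["T2"]]^2
  }, 0))
  expect_equal(total, brute, tolerance = 1e-8)
})

test_that("catalogue builds the documented per-method structures", {
  pl <- method_catalogue("PLANET", 6)
  expect_length(pl$lower, 2) # one flip + one TR
  u <- pl$builder(c(30, 8))
  expect_s3_class(u, "seq_settings")
  expect_equal(length(unique(u$flips)), 1)
  expect_equal(length(unique(u$rf_phases)), 6) # distinct phase increments

  de <- method_catalogue("DESS", 8)
  ud <- de$builder(c(25, 12))
  expect_equal(ud$n_periods, 4L)
  expect_equal(ud$n_measurements, 8L) # 2 echoes per TR period
  expect_equal(length(signal_model(wm(), ud)$signal), 8)
  expect_error(method_catalogue("DESS", 7), "divisible")

  jm <- method_catalogue("DESPOT_JSR", 8)
  uj <- jm$builder(jm$lower + 1)
  expect_s3_class(uj, "sequence_set")
  expect_equal(vapply(uj, `[[`, "", "method"), c("SPGR", "bSSFP"))

  mb <- method_catalogue("MRF_balanced", 300)
  expect_true(mb$not_spatially_encodable) # fewer than 400 excitations
  expect_length(mb$lower, 300) # TR is fixed for balanced fingerprints
  expect_false(method_catalogue("MRF_balanced", 400)$not_spatially_encodable)
  expect_error(method_catalogue("SSFP_X", 4), "supported")
})

test_that("degenerate bounds return the initialization and its cost", {
  problem <- method_catalogue("DESS", 4)
  problem$lower <- problem$upper <- c(30, 10)
  res <- solve_design(problem, seed = 1, n_starts = 3)
  expect_equal(res$par, c(30, 10))
  expect_equal(res$cost, design_cost(problem$builder(c(30, 10)),
                                     problem$tissue_set), tolerance = 1e-10)
})

test_that("two-flip SPGR T1 design matches an exhaustive grid search", {
  p <- wm()
  mkU <- function(x) seq_settings("SPGR", flips = x, trs = 20)
  problem <- structure(list(
    builder = mkU, lower = c(1, 1), upper = c(90, 90),
    var_types = c("flip", "flip"), tissue_set = list(p), n_starts = 8L),
    class = "design_problem")
  res <- solve_design(problem, seed = 4, params_of_interest = "T1",
                      control = list(maxit = 200, factr = 1e7))
  # brute force on a 1-degree grid (upper triangle by symmetry)
  grid <- expand.grid(a = seq(1, 90), b = seq(1, 90))
  grid <- grid[grid$a <= grid$b, ]
  costs <- vapply(seq_len(nrow(grid)), function(i)
    suppressWarnings(design_cost(mkU(c(grid$a[i], grid$b[i])), p,
                                 params_of_interest = "T1")), 0)
  best <- grid[which.min(costs), ]
  expect_lt(max(abs(sort(res$par) - sort(as.numeric(best)))), 0.5)
})

test_that("multi-start search is reproducible and monotone in starts", {
  problem <- method_catalogue("DESS", 4)
  r1 <- solve_design(problem, seed = 9, n_starts = 2,
                     control = list(maxit = 60))
  r2 <- solve_design(problem, seed = 9, n_starts = 2,
                     control = list(maxit = 60))
  expect_identical(r1$par, r2$par)
  expect_identical(r1$per_start_costs, r2$per_start_costs)
  r4 <- solve_design(problem, seed = 9, n_starts = 4,
                     control = list(maxit = 60))
  expect_equal(r4$per_start_costs[1:2], r1$per_start_costs)
  expect_lte(min(r4$per_start_costs), min(r1$per_start_costs))
  # reported optimum respects the bounds
  expect_true(all(r4$par >= problem$lower - 1e-6 &
                    r4$par <= problem$upper + 1e-6))
})
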