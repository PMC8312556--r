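# Modified Shepp-Logan ellipse table: intensity, semi-axes (a, b), centre
# (x0, y0), rotation phi in degrees, on the [-1, 1]^2 square.
SHEPP_LOGAN_ELLIPSES <- data.frame(
  A   = c(1, -0.8, -0.2, -0.2, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1),
  a   = c(0.69, 0.6624, 0.11, 0.16, 0.21, 0.046, 0.046, 0.046, 0.023, 0.023),
  b   = c(0.92, 0.874, 0.31, 0.41, 0.25, 0.046, 0.046, 0.023, 0.023, 0.046),
  x0  = c(0, 0, 0.22, -0.22, 0, 0, 0, -0.08, 0, 0.06),
  y0  = c(0, -0.0184, 0, 0, 0.35, 0.1, -0.1, -0.605, -0.606, -0.605),
  phi = c(0, 0, -18, 18, 0, 0, 0, 0, 0, 0))

#' Shepp-Logan digital phantom
#'
#' Standard 10-ellipse head phantom (modified intensity table, so the skull
#' ring is the brightest structure) rasterized on an `n x n` grid over
#' `[-1, 1]^2`, clipped to `[0, 1]`.
#'
#' @param n grid size, at least 32.
#' @return an `n x n` matrix with values in `[0, 1]`.
#' @export
shepp_logan <- function(n) {
  n <- as.integer(n)
  if (n < 32L) stopf("n must be at least 32")
  xs <- seq(-1, 1, length.out = n)
  X <- matrix(xs, n, n)             # column index -> x
  Y <- matrix(rev(xs), n, n, byrow = TRUE) # row index -> y (top = +1)
  img <- matrix(0, n, n)
  for (i in seq_len(nrow(SHEPP_LOGAN_ELLIPSES))) {
    e <- SHEPP_LOGAN_ELLIPSES[i, ]
    th <- deg2rad(e$phi)
    xr <- (X - e$x0) * cos(th) + (Y - e$y0) * sin(th)
    yr <- -(X - e$x0) * sin(th) + (Y - e$y0) * cos(th)
    img <- img + e$A * ((xr / e$a)^2 + (yr / e$b)^2 <= 1)
  }
  pmin(pmax(img, 0), 1)
}

#' k-space sampling mask
#'
#' Binary Cartesian mask over an `shape[1] x shape[2]` k-space grid (DC at
#' the centre of the *shifted* grid; masks are stored unshifted, matching
#' [stats::fft()] indexing).
#'
#' * `random`: exactly `round(N/R)` points drawn uniformly without
#'   replacement, plus a fully sampled 4x4 centre block.
#' * `spiral`: grid points nearest an Archimedean spiral whose arm spacing is
#'   `R` grid lines per turn, rotated by a seed-derived angle (no gridding;
#'   the trajectory is snapped to the Cartesian grid).
#'
#' `R = 1` returns the all-ones mask for both kinds. The achieved
#' undersampling factor `r_eff = N / #sampled` is stored alongside the
#' nominal `R`.
#'
#' @param kind `"random"` or `"spiral"`.
#' @param shape integer vector of two grid dimensions.
#' @param R nominal undersampling factor, >= 1.
#' @param seed integer seed controlling the draw / rotation.
#' @return an object of class `sampling_mask`.
#' @export
make_mask <- function(kind = c("random", "spiral"), shape, R, seed = 1L) {
  kind <- match.arg(kind)
  shape <- as.integer(shape)
  if (length(shape) == 1L) shape <- c(shape, shape)
  if (R < 1) stopf("R must be >= 1")
  N <- prod(shape)
  if (N / R < 16) stopf("R = %g leaves fewer than 16 sampled points", R)
  if (R == 1) {
    m <- matrix(TRUE, shape[1], shape[2])
  } else if (kind == "random") {
    set.seed(derive_seed(seed, "mask-random"))
    m <- matrix(FALSE, shape[1], shape[2])
    m[sample.int(N, max(round(N / R), 16L))] <- TRUE
    ctr <- lapply(shape, function(s) s %/% 2 + (-1:2))
    mc <- fftshift2(m)
    mc[ctr[[1]], ctr[[2]]] <- TRUE
    m <- fftshift2(mc, inverse = TRUE)
  } else {
    set.seed(derive_seed(seed, "mask-spiral"))
    rot <- runif(1, 0, 2 * pi)
    traj <- spiral_trajectory(shape, R)
    kx <- traj$r * cos(traj$phi + rot)
    ky <- traj$r * sin(traj$phi + rot)
    ix <- round(kx) + shape[1] %/% 2 + 1L
    iy <- round(ky) + shape[2] %/% 2 + 1L
    keep <- ix >= 1 & ix <= shape[1] & iy >= 1 & iy <= shape[2]
    mc <- matrix(FALSE, shape[1], shape[2])
    mc[cbind(ix[keep], iy[keep])] <- TRUE
    m <- fftshift2(mc, inverse = TRUE)
  }
  pkey <- paste("density", kind, paste(shape, collapse = "x"), R, sep = "|")
  p <- .qmrieff_cache[[pkey]]
  if (is.null(p)) {
    p <- density_profile(kind, shape, R)
    .qmrieff_cache[[pkey]] <- p
  }
  w <- ifelse(m, 1 / p, 0)
  structure(list(kind = kind, shape = shape, R = R, mask = m, seed = seed,
                 weights = w, r_eff = N / sum(m)),
            class = "sampling_mask")
}

# Sampling density p of the mask design (analytic, not estimated, so the
# density-compensation weights 1/p carry no estimation noise). Unbiased low
# frequencies require the always-sampled centre not to be over-weighted.
density_profile <- function(kind, shape, R) {
  if (R == 1) return(matrix(1, shape[1], shape[2]))
  N <- prod(shape)
  if (kind == "random") {
    p <- matrix(max(round(N / R), 16L) / N, shape[1], shape[2])
    ctr <- lapply(shape, function(s) s %/% 2 + (-1:2))
    pc <- fftshift2(p)
    pc[ctr[[1]], ctr[[2]]] <- 1
    p <- fftshift2(pc, inverse = TRUE)
  } else {
    # spiral: ~ sqrt(1 + (2 pi r / s)^2) cells marked per unit annulus per
    # arm pass (local spacing s) against 2 pi r cells in the annulus
    ix <- seq_len(shape[1]) - (shape[1] %/% 2 + 1)
    iy <- seq_len(shape[2]) - (shape[2] %/% 2 + 1)
    r <- sqrt(outer(ix^2, iy^2, `+`))
    rmax <- sqrt(2) * max(shape) / 2
    s <- spiral_spacing(r, R, rmax)
    pc <- ifelse(r < 1, 1, pmin(1, sqrt(1 + (2 * pi * r / s)^2) / (2 * pi * r)))
    p <- fftshift2(pc, inverse = TRUE)
  }
  p
}

# Local arm spacing of the variable-density spiral, in grid lines per turn;
# the area-weighted average sampling rate stays close to 1/R.
spiral_spacing <- function(r, R, rmax) R * (0.35 + 1.3 * r / rmax)

.qmrieff_cache <- new.env(parent = emptyenv())

# Base (unrotated) variable-density Archimedean trajectory: the centre is
# ~3x denser than the rim. Integrated once per (shape, R) with an
# arc-length-adaptive azimuthal step and cached; per-draw rotation is cheap.
spiral_trajectory <- function(shape, R) {
  key <- paste("spiral", paste(shape, collapse = "x"), R, sep = "|")
  hit <- .qmrieff_cache[[key]]
  if (!is.null(hit)) return(hit)
  rmax <- sqrt(2) * max(shape) / 2
  cap <- 500000L
  rs <- phis <- numeric(cap)
  i <- 0L; r <- 0; phi <- 0
  while (r <= rmax && i < cap) {
    i <- i + 1L
    rs[i] <- r; phis[i] <- phi
    dphi <- min(pi / 16, 0.4 / max(r, 1))
    r <- r + spiral_spacing(r, R, rmax) * dphi / (2 * pi)
    phi <- phi + dphi
  }
  out <- list(r = rs[seq_len(i)], phi = phis[seq_len(i)])
  .qmrieff_cache[[key]] <- out
  out
}

# 2D fftshift (and its inverse) used to move DC between corner and centre.
fftshift2 <- function(m, inverse = FALSE) {
  d <- dim(m)
  s <- if (inverse) -(d %/% 2) else d %/% 2
  m[(seq_len(d[1]) - 1 - s[1]) %% d[1] + 1,
    (seq_len(d[2]) - 1 - s[2]) %% d[2] + 1, drop = FALSE]
}

#' Zero-filled reconstruction of undersampled k-space
#'
#' Inverse Fourier transform of the masked forward transform with
#' density-compensation scaling (each sampled point weighted by the inverse
#' of its sampling density), so that the all-ones mask returns the input
#' exactly and the signal amplitude is preserved on average under
#' undersampling (unsampled points are treated as zero, i.e. aliasing is
#' folded into the image and later treated as noise).
#'
#' @param image real or complex matrix.
#' @param mask a [make_mask()] object (shapes must match).
#' @param kspace_noise optional complex matrix added to k-space before
#'   masking (receiver noise).
#' @return complex matrix of the same shape.
#' @export
zero_filled_recon <- function(image, mask, kspace_noise = NULL) {
  stopifnot(inherits(mask, "sampling_mask"))
  if (!all(dim(image) == mask$shape)) stopf("image and mask shapes differ")
  k <- fft(image)
  if (!is.null(kspace_noise)) k <- k + kspace_noise
  fft(mask$weights * k, inverse = TRUE) / length(k)
}

#' Monte-Carlo estimate of the dynamics-factor d_R
#'
#' Repeats a zero-filled reconstruction of the phantom under fresh complex
#' Gaussian k-space noise (and, by default, a freshly drawn mask per trial,
#' which is how time-varying trajectories turn aliasing into pseudo-noise
#' along a fingerprinting timecourse). The per-pixel standard deviation
#' across trials gives
#' \deqn{d_R = \frac{1}{\sqrt{R}}\frac{\sigma_{image,R}}{\sigma_{image}}}
#' and the result also carries the signal-to-aliasing ratio `sar_image`
#' measured from one noiseless undersampled reconstruction.
#'
#' `snr_image` is the mean nonzero-phantom intensity divided by the
#' image-domain per-quadrature noise standard deviation of the fully sampled
#' reconstruction.
#'
#' @param phantom real image matrix (e.g. [shepp_logan()]).
#' @param kind,R mask kind and nominal undersampling factor (see
#'   [make_mask()]).
#' @param snr_image image-domain SNR of the fully sampled data.
#' @param n_trials Monte-Carlo trials, at least 100.
#' @param seed master seed.
#' @param redraw_mask redraw the mask each trial (default) or keep it fixed.
#' @return an object of class `dynamics_factor_result` with fields `R`,
#'   `r_eff`, `snr_image`, `d_r_map`, `d_r_mean`, `sar_image`, `n_trials`,
#'   plus an aliasing-normality diagnostic `alias_shapiro_p` (reported, not
#'   enforced).
#' @export
monte_carlo_dr <- function(phantom, kind = "random", R, snr_image,
                           n_trials = 1e5, seed = 1L, redraw_mask = TRUE) {
  if (n_trials < 100) stopf("n_trials must be >= 100")
  shape <- dim(phantom)
  N <- prod(shape)
  support <- phantom > 0
  sig_mean <- mean(phantom[support])
  sigma_image <- sig_mean / snr_image       # per quadrature, image domain
  sigma_k <- sigma_image * sqrt(N)
  mask0 <- make_mask(kind, shape, R, seed = derive_seed(seed, "mask-base"))
  # signal-to-aliasing ratio from one noiseless undersampled reconstruction
  recon0 <- zero_filled_recon(phantom, mask0)
  alias <- recon0 - phantom
  sigma_alias <- sqrt(mean(Mod(alias[support])^2) / 2)
  sar <- sig_mean / sigma_alias
  set.seed(derive_seed(seed, "mc-noise"))
  acc <- matrix(0i, shape[1], shape[2])
  acc2 <- matrix(0, shape[1], shape[2])
  r_eff_acc <- 0
  alias_probe <- numeric(n_trials) # one support pixel tracked for diagnostics
  probe_idx <- which(support)[which.max(phantom[support])]
  for (t in seq_len(n_trials)) {
    # draw noise from the mc-noise stream, then restore it: make_mask seeds
    # its own stream and must not consume (or reset) this one
    noise <- matrix(complex(real = rnorm(N, sd = sigma_k),
                            imaginary = rnorm(N, sd = sigma_k)), shape[1], shape[2])
    rs <- get(".Random.seed", envir = globalenv())
    mask <- if (redraw_mask)
      make_mask(kind, shape, R, seed = derive_seed(seed, paste0("mask", t)))
    else mask0
    assign(".Random.seed", rs, envir = globalenv())
    rec <- zero_filled_recon(phantom, mask, kspace_noise = noise)
    acc <- acc + rec
    acc2 <- acc2 + Mod(rec)^2
    r_eff_acc <- r_eff_acc + mask$r_eff
    alias_probe[t] <- Re(rec[probe_idx])
  }
  r_eff <- r_eff_acc / n_trials
  varc <- pmax(acc2 / n_trials - Mod(acc / n_trials)^2, 0) * n_trials / (n_trials - 1)
  sigma_image_R <- sqrt(varc / 2)
  d_r_map <- sigma_image_R / (sqrt(r_eff) * sigma_image)
  d_r_map[!support] <- NA_real_
  shapiro_p <- tryCatch(
    stats::shapiro.test(sample(alias_probe, min(n_trials, 4000)))$p.value,
    error = function(e) NA_real_)
  structure(list(R = R, r_eff = r_eff, snr_image = snr_image,
                 d_r_map = d_r_map, d_r_mean = mean(d_r_map[support]),
                 sar_image = sar, n_trials = n_trials, kind = kind,
                 alias_shapiro_p = shapiro_p),
            class = "dynamics_factor_result")
}

#' @export
print.dynamics_factor_result <- function(x, ...) {
  cat(sprintf("d_R (%s, R=%g, SNR=%g, %d trials): mean %.4g, SaR %.4g\n",
              x$kind, x$R, x$snr_image, x$n_trials, x$d_r_mean, x$sar_image))
  invisible(x)
}

#' Fit the aliasing-to-signal scaling constant
#'
#' Least-squares fit (through the origin) of the aliasing-to-signal ratio
#' `1/SaR` against `sqrt(R - 1)`. Returns the scaling constant `k_asr` of
#' `1/SaR = k_asr * sqrt(R-1)` together with the residual and data norms.
#' Note [dr_model()] takes the *squared* constant (`k = k_asr^2`).
#'
#' @param R_values undersampling factors (> 1, at least 3 distinct).
#' @param sar_values matching signal-to-aliasing ratios.
#' @return list with `k_asr`, `residual_norm`, `data_norm`.
#' @export
fit_aliasing_scaling <- function(R_values, sar_values) {
  if (length(R_values) != length(sar_values) ||
      length(unique(R_values)) < 3 || any(R_values <= 1))
    stopf("need >= 3 distinct R values, all > 1")
  y <- 1 / sar_values
  x <- sqrt(R_values - 1)
  k <- sum(x * y) / sum(x^2)
  list(k_asr = k, residual_norm = sqrt(sum((y - k * x)^2)),
       data_norm = sqrt(sum(y^2)))
}

#' Closed-form dynamics-factor model
#'
#' Evaluates \deqn{d_R \approx \sqrt{\frac{k (R-1)}{R} SNR_{image}^2 + 1}}
#' where `k` is the squared aliasing-to-signal scaling constant
#' (`k_asr^2` from [fit_aliasing_scaling()]).
#'
#' @param R undersampling factor(s), >= 1.
#' @param snr_image image-domain SNR, >= 0.
#' @param k squared scaling constant.
#' @return predicted d_R.
#' @export
dr_model <- function(R, snr_image, k) {
  if (any(R < 1)) stopf("R must be >= 1")
  if (any(snr_image < 0)) stopf("snr_image must be >= 0")
  sqrt(k * (R - 1) / R * snr_image^2 + 1)
}

#' Efficiency of an undersampled experiment
#'
#' Elementwise `eta_R = eta / d_R`. Values of `d_R` slightly below 1 (within
#' Monte-Carlo error) trigger a warning; `d_R = 0` is an error.
#'
#' @param eta fully-sampled efficiency value(s).
#' @param d_r dynamics-factor value(s).
#' @return undersampled efficiency.
#' @export
eta_undersampled <- function(eta, d_r) {
  if (any(d_r == 0)) stopf("d_r must be nonzero")
  if (any(d_r < 1)) warning("d_r < 1 is inconsistent with a least-squares estimator",
                            call. = FALSE)
  eta / d_r
}

#' Export a d_R map as a plain-text portable graymap (PGM, P2)
#'
#' Values are linearly rescaled to 0..`maxval`; `NA` maps to 0. A YAML
#' sidecar `<path>.yaml` records the original value range.
#'
#' @param map numeric matrix.
#' @param path output file path.
#' @param maxval PGM maximum gray value.
#' @export
write_pgm <- function(map, path, maxval = 255L) {
  rng <- range(map, na.rm = TRUE)
  scaled <- round((map - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps) * maxval)
  scaled[is.na(scaled)] <- 0L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(map), nrow(map)), as.character(maxval)), con)
  write(t(scaled), con, ncolumns = ncol(map))
  yaml::write_yaml(list(min = rng[1], max = rng[2], maxval = maxval,
                        layout = "row-major from top row"),
                   paste0(path, ".yaml"))
  invisible(path)
}
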