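PARAM_NAMES <- c("T1", "T2", "M0", "phi0", "omega0")

#' Parameters that influence a given acquisition
#'
#' Spoiled-only acquisitions are described by `{T1, T2, M0}`; as soon as a
#' balanced readout participates, the off-resonance frequency and measurement
#' phase become relevant and the set grows to `{T1, T2, M0, phi0, omega0}`.
#'
#' @param u a `seq_settings` or `sequence_set`.
#' @return character vector of parameter names.
#' @export
default_param_set <- function(u) {
  if (has_balanced_readout(u)) PARAM_NAMES else c("T1", "T2", "M0")
}

param_field <- c(T1 = "t1", T2 = "t2", M0 = "m0", phi0 = "phi0", omega0 = "omega0")

perturb_tissue <- function(p, param, delta) {
  f <- param_field[[param]]
  p2 <- unclass(p)
  p2[[f]] <- p2[[f]] + delta
  class(p2) <- "tissue_params"
  p2
}

#' Jacobian of the signal model and its Fisher bundle
#'
#' Differentiates the complex measurement vector with respect to the tissue
#' parameters by central finite differences with relative step `h_rel`
#' (absolute floor `h_abs` in each parameter's native units). The `phi0`
#' column is analytic (`i * signal`), and the `M0` column is exact because
#' every model is linear in M0.
#'
#' The bundle carries everything needed for the Cramer-Rao bound: the
#' Jacobian, the per-quadrature receiver noise standard deviation `sigma0`,
#' the parameter ordering, the signal itself and the acquisition time.
#'
#' @param p a [tissue_params()] object.
#' @param u a `seq_settings` or `sequence_set`.
#' @param params parameters to differentiate; defaults to
#'   [default_param_set()] of `u`.
#' @param sigma0 receiver noise standard deviation per readout per quadrature.
#' @param h_rel relative finite-difference step.
#' @param h_abs absolute step floor, native units.
#' @return an object of class `fisher_bundle`.
#' @export
model_jacobian <- function(p, u, params = NULL, sigma0 = 1, h_rel = 1e-4,
                           h_abs = 1e-6) {
  params <- params %||% default_param_set(u)
  if (!all(params %in% PARAM_NAMES))
    stopf("unknown parameter(s): %s",
          paste(setdiff(params, PARAM_NAMES), collapse = ", "))
  if (inherits(u, "seq_settings") && u$method == "MRF_balanced" &&
      !isTRUE(u$driven_equilibrium) && identical(params, PARAM_NAMES) &&
      p$m0 > 0) {
    # compiled fast path: same central-FD scheme, propagated in one call
    res <- bloch_balanced_jacobian_cpp(
      deg2rad(u$flips), deg2rad(u$rf_phases), u$trs, u$te_eff[1],
      p$t1, p$t2, p$m0, p$phi0, p$omega0, c(0, 0, p$m0), h_rel, h_abs)
    J <- res$jacobian
    dimnames(J) <- list(NULL, params)
    return(structure(list(jacobian = J, sigma0 = sigma0,
                          param_order = params, signal = res$signal,
                          t_acq = t_acq_ms(u), tissue = p, settings = u),
                     class = "fisher_bundle"))
  }
  ev <- fast_signal_eval(u) %||% function(pp) signal_model(pp, u)$signal
  s0 <- ev(p)
  J <- matrix(0i, nrow = length(s0), ncol = length(params),
              dimnames = list(NULL, params))
  for (j in seq_along(params)) {
    pm <- params[j]
    if (pm == "phi0") {
      J[, j] <- 1i * s0
      next
    }
    if (pm == "M0" && p$m0 > 0) { # every model is exactly linear in M0
      J[, j] <- s0 / p$m0
      next
    }
    x <- unclass(p)[[param_field[[pm]]]]
    h <- max(abs(x) * h_rel, h_abs)
    sp <- ev(perturb_tissue(p, pm, +h))
    sm <- ev(perturb_tissue(p, pm, -h))
    col <- (sp - sm) / (2 * h)
    if (any(!is.finite(col)))
      stopf("non-finite model output while differentiating '%s'", pm)
    J[, j] <- col
  }
  structure(list(jacobian = J, sigma0 = sigma0, param_order = params,
                 signal = s0, t_acq = t_acq_ms(u), tissue = p, settings = u),
            class = "fisher_bundle")
}

# Direct evaluators for the simple steady-state methods, bypassing the
# signal_record plumbing inside finite-difference loops. Returns NULL when
# only the full signal_model path applies; results are identical either way.
fast_signal_eval <- function(u) {
  if (inherits(u, "sequence_set")) {
    evs <- lapply(u, fast_signal_eval)
    if (any(vapply(evs, is.null, TRUE))) return(NULL)
    return(function(p) unlist(lapply(evs, function(f) f(p))))
  }
  if (!inherits(u, "seq_settings")) return(NULL)
  switch(u$method,
    SPGR = function(p) spgr_signal(p, u$flips, u$trs),
    bSSFP = function(p) bssfp_signal_cpp(deg2rad(u$flips), u$trs, u$te_eff,
                                         deg2rad(u$rf_phases), p$t1, p$t2,
                                         p$m0, p$phi0, p$omega0),
    NULL)
}

fisher_matrix <- function(fb) {
  Re(Conj(t(fb$jacobian)) %*% fb$jacobian) / fb$sigma0^2
}

#' Cramer-Rao lower bound on a parameter's standard deviation
#'
#' For complex Gaussian noise of per-quadrature standard deviation `sigma0`,
#' the Fisher matrix is `F = Re(J^H J) / sigma0^2` and the bound for
#' parameter theta, with all other parameters in the bundle jointly estimated
#' as nuisance parameters, is `sqrt([F^-1]_theta_theta)`.
#'
#' A singular (or numerically unidentifiable) Fisher matrix yields `Inf` with
#' a structured warning of class `qmrieff_singular_fisher`, so that
#' efficiency becomes 0 rather than an error and optimizers can traverse
#' degenerate regions.
#'
#' @param fb a `fisher_bundle` from [model_jacobian()].
#' @param param parameter name.
#' @return standard deviation in the parameter's units.
#' @export
crlb_std <- function(fb, param) {
  stopifnot(inherits(fb, "fisher_bundle"))
  if (!param %in% fb$param_order)
    stopf("parameter '%s' is not in the bundle (%s)", param,
          paste(fb$param_order, collapse = ", "))
  Finv <- fisher_inverse(fb)
  if (is.null(Finv) || !is.finite(Finv[param, param]) ||
      Finv[param, param] <= 0) {
    warning(structure(
      list(message = sprintf(
        "Fisher matrix singular: parameter '%s' unidentifiable", param),
        call = NULL),
      class = c("qmrieff_singular_fisher", "warning", "condition")))
    return(Inf)
  }
  sqrt(Finv[param, param])
}

# Inverse Fisher matrix, or NULL when numerically singular. Rescaled to a
# correlation-like matrix before inverting: parameter units differ by many
# orders of magnitude and would otherwise trip the solver.
fisher_inverse <- function(fb) {
  Fm <- fisher_matrix(fb)
  d <- sqrt(diag(Fm))
  if (any(!is.finite(d)) || any(d <= 0)) return(NULL)
  sc <- tcrossprod(d)
  Finv <- tryCatch(solve(Fm / sc) / sc, error = function(e) NULL)
  if (!is.null(Finv) && any(!is.finite(Finv))) return(NULL)
  Finv
}

#' Intrinsic efficiency of an acquisition
#'
#' Computes, for each parameter of interest,
#' \deqn{\eta(\theta) = \frac{\theta}{\sigma_\theta^{CRLB}}\,
#'   \frac{\sigma_0}{M_0}\,\frac{1}{\sqrt{T_{acq}}}}
#' with `T_acq` in seconds, so `eta` is in \eqn{s^{-1/2}}. By construction the
#' value is invariant to `sigma0` and `M0` (both cancel). The nuisance set
#' defaults to [default_param_set()] of `u`; `tnr` is the parameter-to-noise
#' ratio per unit maximum SNR, i.e. `eta * sqrt(T_acq)`.
#'
#' @param p a [tissue_params()] object.
#' @param u a `seq_settings` or `sequence_set`.
#' @param params_of_interest parameters whose efficiency to report.
#' @param sigma0 receiver noise standard deviation (cancels; kept for
#'   interface fidelity).
#' @param param_set full jointly-estimated parameter set; defaults to
#'   [default_param_set()] of `u` (always includes `params_of_interest`).
#' @return an object of class `efficiency_result` with fields `eta`, `tnr`
#'   (named vectors), `crlb_std`, `t_acq_s`, `tissue`, `settings`.
#' @examples
#' p <- tissue_params(781, 65)
#' u <- seq_settings("SPGR", flips = c(5, 8, 10, 13, 15, 18), trs = 20)
#' efficiency(p, u, params_of_interest = "T1", param_set = c("T1", "M0"))
#' @export
efficiency <- function(p, u, params_of_interest = c("T1", "T2"), sigma0 = 1,
                       param_set = NULL) {
  param_set <- unique(c(params_of_interest, param_set %||% default_param_set(u)))
  fb <- model_jacobian(p, u, params = param_set, sigma0 = sigma0)
  # a parameter the signal does not depend on at all (identically zero
  # column, e.g. T2 for a pure SPGR set) is not a nuisance parameter; keeping
  # it would make the Fisher matrix singular by construction
  dead <- colSums(Mod(fb$jacobian)) == 0 &
    !fb$param_order %in% params_of_interest
  if (any(dead)) {
    fb$jacobian <- fb$jacobian[, !dead, drop = FALSE]
    fb$param_order <- fb$param_order[!dead]
  }
  t_s <- fb$t_acq / 1000
  if (t_s <= 0) stopf("acquisition time must be positive")
  eta <- tnr <- stds <- stats::setNames(numeric(length(params_of_interest)),
                                        params_of_interest)
  Finv <- fisher_inverse(fb) # invert once, read all requested parameters
  for (pm in params_of_interest) {
    sd_pm <- if (!is.null(Finv) && is.finite(Finv[pm, pm]) && Finv[pm, pm] > 0)
      sqrt(Finv[pm, pm]) else Inf
    stds[pm] <- sd_pm
    theta <- unclass(p)[[param_field[[pm]]]]
    tnr[pm] <- if (is.finite(sd_pm)) (theta / sd_pm) * (sigma0 / p$m0) else 0
    eta[pm] <- tnr[pm] / sqrt(t_s)
  }
  structure(list(eta = eta, tnr = tnr, crlb_std = stds, t_acq_s = t_s,
                 param_set = param_set, tissue = p, settings = u),
            class = "efficiency_result")
}

#' @export
print.efficiency_result <- function(x, ...) {
  cat(sprintf("efficiency over %.4g s acquisition:\n", x$t_acq_s))
  for (pm in names(x$eta))
    cat(sprintf("  eta(%s) = %.5g s^-1/2  (CRLB sd %.5g)\n",
                pm, x$eta[pm], x$crlb_std[pm]))
  invisible(x)
}

#' Efficiency table over a tissue grid
#'
#' Evaluates [efficiency()] for every tissue in a grid and returns a flat
#' data frame (exportable as CSV) with columns `method`, `T1_ms`, `T2_ms`,
#' `omega0_Hz`, `eta_T1`, `eta_T2`.
#'
#' @param tissues list of [tissue_params()] (see [tissue_grid()]).
#' @param u a `seq_settings` or `sequence_set`.
#' @param params_of_interest efficiency parameters, default T1 and T2.
#' @param label method label for the output table.
#' @return a data.frame.
#' @export
efficiency_grid <- function(tissues, u, params_of_interest = c("T1", "T2"),
                            label = NULL) {
  tissues <- as_tissue_list(tissues)
  label <- label %||% (if (inherits(u, "sequence_set"))
    paste(unique(vapply(u, `[[`, "", "method")), collapse = "+") else u$method)
  rows <- lapply(tissues, function(p) {
    ef <- efficiency(p, u, params_of_interest)
    out <- data.frame(method = label, T1_ms = p$t1, T2_ms = p$t2,
                      omega0_Hz = p$omega0)
    for (pm in params_of_interest) out[[paste0("eta_", pm)]] <- ef$eta[[pm]]
    out
  })
  do.call(rbind, rows)
}

#' Efficiency from a precomputed Fisher bundle
#'
#' Lower-level entry used by property tests (e.g. information additivity at
#' fixed acquisition time): computes `eta` for `param` from an explicit
#' bundle and acquisition time.
#'
#' @param fb a `fisher_bundle`.
#' @param param parameter name.
#' @param t_acq_s acquisition time in seconds (defaults to the bundle's).
#' @return efficiency in `s^-1/2`.
#' @export
eta_from_fisher <- function(fb, param, t_acq_s = fb$t_acq / 1000) {
  sd_pm <- crlb_std(fb, param)
  if (!is.finite(sd_pm)) return(0)
  theta <- unclass(fb$tissue)[[param_field[[param]]]]
  (theta / sd_pm) * (fb$sigma0 / fb$tissue$m0) / sqrt(t_acq_s)
}
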