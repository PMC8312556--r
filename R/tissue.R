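#' Tissue parameter vector
#'
#' The per-voxel parameters that drive every signal model: relaxation times
#' `t1`/`t2` (ms), equilibrium magnetization `m0` (arbitrary units),
#' measurement phase `phi0` (rad) and off-resonance frequency `omega0` (Hz).
#' `phi0` and `omega0` only influence sequences with a balanced readout.
#'
#' `t2 > t1` is physically implausible for a single spin pool and triggers a
#' warning, but the models remain evaluable so that optimizers and grid sweeps
#' can traverse such corners.
#'
#' @param t1,t2 relaxation times in ms; must be positive.
#' @param m0 equilibrium magnetization, non-negative.
#' @param phi0 receiver/measurement phase in rad.
#' @param omega0 off-resonance frequency in Hz.
#' @return an object of class `tissue_params`.
#' @examples
#' wm <- tissue_params(t1 = 781, t2 = 65) # white matter at 3 T
#' @export
tissue_params <- function(t1, t2, m0 = 1, phi0 = 0, omega0 = 0) {
  for (nm in c("t1", "t2", "m0", "phi0", "omega0")) {
    v <- get(nm)
    if (!is_scalar_num(v)) stopf("'%s' must be a finite numeric scalar", nm)
  }
  if (t1 <= 0 || t2 <= 0) stopf("t1 and t2 must be positive (got %g, %g)", t1, t2)
  if (m0 < 0) stopf("m0 must be non-negative")
  if (t2 > t1) warning("t2 > t1 is not physical for a single pool", call. = FALSE)
  structure(list(t1 = t1, t2 = t2, m0 = m0, phi0 = phi0, omega0 = omega0),
            class = "tissue_params")
}

#' @export
print.tissue_params <- function(x, ...) {
  cat(sprintf("tissue: T1=%g ms  T2=%g ms  M0=%g  phi0=%g rad  omega0=%g Hz\n",
              x$t1, x$t2, x$m0, x$phi0, x$omega0))
  invisible(x)
}

#' Cartesian grid of tissue parameter vectors
#'
#' Expands the supplied marginal values into a list of [tissue_params()],
#' e.g. the white-matter set with an off-resonance sweep used when balanced
#' readouts participate in a design.
#'
#' @param t1,t2,m0,phi0,omega0 numeric vectors of marginal values.
#' @return list of `tissue_params`.
#' @export
tissue_grid <- function(t1, t2, m0 = 1, phi0 = 0, omega0 = 0) {
  g <- expand.grid(t1 = t1, t2 = t2, m0 = m0, phi0 = phi0, omega0 = omega0,
                   KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(g)), function(i) {
    suppressWarnings(tissue_params(g$t1[i], g$t2[i], g$m0[i], g$phi0[i], g$omega0[i]))
  })
}

as_tissue_list <- function(p) {
  if (inherits(p, "tissue_params")) list(p)
  else if (is.list(p) && all(vapply(p, inherits, TRUE, "tissue_params"))) p
  else stopf("expected a tissue_params object or a list of them")
}
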