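SEQ_METHODS <- c("SPGR", "bSSFP", "DESS", "TESS", "MRF_spoiled", "MRF_balanced")

#' Acquisition settings of a relaxometry sequence
#'
#' Describes one acquisition `u`: the method, its flip-angle train, repetition
#' times, echo time and RF phase schedule. Two families are supported:
#'
#' * steady-state methods (`SPGR`, `bSSFP`, `DESS`, `TESS`): each entry of
#'   `flips`/`trs` is an independently acquired steady-state measurement
#'   (for `DESS`/`TESS` a single flip/TR is shared and each TR period yields
#'   2 or 3 echoes over `n_periods` periods);
#' * transient methods (`MRF_spoiled`, `MRF_balanced`): `flips`/`trs` form an
#'   ordered pulse train with one measurement per pulse, optionally run in
#'   driven equilibrium (the train is cycled until it is periodic).
#'
#' `rf_phases` holds per-pulse RF phases (deg) for transient methods and
#' per-measurement phase-cycling increments for `bSSFP`. For `bSSFP` the echo
#' time defaults to TR/2 (set `te = NA`).
#'
#' Total acquisition time is the sum of TRs; `recovery_delay` (dead time after
#' the train) is only counted when `include_recovery = TRUE`, which is how
#' sequences starting from thermal equilibrium are conventionally privileged.
#'
#' @param method one of `r paste(SEQ_METHODS, collapse = ", ")`.
#' @param flips flip angles in degrees, in `[0, 180]`.
#' @param trs repetition times in ms (scalar is broadcast).
#' @param te echo time in ms; `NA` for the bSSFP TR/2 convention.
#' @param rf_phases RF phases / phase increments in degrees.
#' @param driven_equilibrium logical; cycle the train to its periodic state.
#' @param n_periods number of TR periods (DESS/TESS only).
#' @param recovery_delay dead time appended after the train, ms.
#' @param include_recovery count `recovery_delay` in the acquisition time.
#' @param min_readout_margin smallest allowed TR - TE gap, ms.
#' @return an object of class `seq_settings`.
#' @examples
#' u <- seq_settings("SPGR", flips = c(5, 8, 10, 13, 15, 18), trs = 20)
#' @export
seq_settings <- function(method, flips, trs, te = NA_real_, rf_phases = NULL,
                         driven_equilibrium = FALSE, n_periods = NULL,
                         recovery_delay = 0, include_recovery = FALSE,
                         min_readout_margin = 0.3) {
  method <- match.arg(method, SEQ_METHODS)
  flips <- as.numeric(flips)
  if (any(!is.finite(flips)) || any(flips < 0 | flips > 180))
    stopf("flip angles must lie in [0, 180] degrees")
  if (method %in% c("DESS", "TESS")) {
    if (length(flips) != 1L) stopf("%s uses a single shared flip angle", method)
    if (is.null(n_periods)) n_periods <- 1L
  } else if (!is.null(n_periods)) {
    stopf("n_periods only applies to DESS/TESS")
  }
  trs <- as.numeric(trs)
  if (length(trs) == 1L) trs <- rep(trs, length(flips))
  if (length(trs) != length(flips)) stopf("length(trs) must match length(flips)")
  if (any(trs <= 0)) stopf("repetition times must be positive")
  if (is.na(te)) {
    te_eff <- if (method == "bSSFP") trs / 2 else rep(0, length(trs))
  } else {
    if (te < 0) stopf("te must be non-negative")
    te_eff <- rep(te, length(trs))
  }
  if (any(trs < te_eff + min_readout_margin) && !(method %in% c("SPGR")))
    stopf("all TRs must be >= TE + %g ms readout margin", min_readout_margin)
  if (is.null(rf_phases)) {
    rf_phases <- switch(method,
      MRF_balanced = rep_len(c(0, 180), length(flips)),
      bSSFP = rep(180, length(flips)),
      rep(0, length(flips)))
  }
  rf_phases <- rep_len(as.numeric(rf_phases), length(flips))
  n_meas <- switch(method,
    DESS = 2L * as.integer(n_periods),
    TESS = 3L * as.integer(n_periods),
    length(flips))
  if (driven_equilibrium && !method %in% c("MRF_spoiled", "MRF_balanced"))
    stopf("driven equilibrium applies to transient methods only")
  structure(list(method = method, flips = flips, trs = trs, te = te,
                 te_eff = te_eff, rf_phases = rf_phases,
                 driven_equilibrium = driven_equilibrium,
                 n_periods = if (is.null(n_periods)) NA_integer_ else as.integer(n_periods),
                 n_measurements = as.integer(n_meas),
                 recovery_delay = recovery_delay,
                 include_recovery = include_recovery),
            class = "seq_settings")
}

#' @export
print.seq_settings <- function(x, ...) {
  cat(sprintf("%s sequence: %d measurement(s), TE=%s ms%s\n", x$method,
              x$n_measurements, ifelse(is.na(x$te), "TR/2", format(x$te)),
              if (x$driven_equilibrium) " [driven equilibrium]" else ""))
  cat("  flips (deg):", paste(signif(x$flips, 4), collapse = " "), "\n")
  cat("  TRs (ms):   ", paste(signif(x$trs, 4), collapse = " "), "\n")
  invisible(x)
}

#' Bundle several sequences acquired back-to-back
#'
#' Used for composite methods such as DESPOT/JSR (a mix of SPGR and bSSFP
#' acquisitions). Fisher information accumulates over all members and the
#' total acquisition time is the sum of the members' times.
#'
#' @param ... `seq_settings` objects, or a single list of them.
#' @return an object of class `sequence_set`.
#' @export
sequence_set <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) && !inherits(xs[[1]], "seq_settings"))
    xs <- xs[[1]]
  if (!all(vapply(xs, inherits, TRUE, "seq_settings")))
    stopf("all members must be seq_settings objects")
  structure(xs, class = "sequence_set")
}

t_acq_ms <- function(u) {
  if (inherits(u, "sequence_set")) return(sum(vapply(u, t_acq_ms, 0.0)))
  base <- if (u$method %in% c("DESS", "TESS")) u$n_periods * u$trs[1] else sum(u$trs)
  if (isTRUE(u$include_recovery)) base <- base + u$recovery_delay
  base
}

#' Does a settings object contain a balanced readout?
#'
#' Balanced readouts make the off-resonance frequency and measurement phase
#' relevant nuisance parameters.
#' @param u a `seq_settings` or `sequence_set`.
#' @return logical.
#' @export
has_balanced_readout <- function(u) {
  if (inherits(u, "sequence_set")) return(any(vapply(u, has_balanced_readout, TRUE)))
  u$method %in% c("bSSFP", "MRF_balanced")
}

#' Read / write sequence settings as a flat YAML config
#'
#' The schema is a flat key-value document with units in the key names:
#' `method`, `flips_deg`, `trs_ms`, `te_ms`, `rf_phases_deg`,
#' `driven_equilibrium`, `n_periods`, `n_measurements`, `recovery_delay_ms`,
#' `include_recovery`. A file with a top-level `sequences:` list yields a
#' [sequence_set()].
#'
#' @param path file path.
#' @return `read_sequence_config` returns a `seq_settings` or `sequence_set`.
#' @export
read_sequence_config <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!is.null(doc$sequences))
    return(sequence_set(lapply(doc$sequences, settings_from_list)))
  settings_from_list(doc)
}

settings_from_list <- function(doc) {
  req <- c("method", "flips_deg", "trs_ms")
  miss <- setdiff(req, names(doc))
  if (length(miss)) stopf("sequence config missing key(s): %s",
                          paste(miss, collapse = ", "))
  u <- seq_settings(method = doc$method, flips = doc$flips_deg,
                    trs = doc$trs_ms, te = doc$te_ms %||% NA_real_,
                    rf_phases = doc$rf_phases_deg,
                    driven_equilibrium = isTRUE(doc$driven_equilibrium),
                    n_periods = doc$n_periods,
                    recovery_delay = doc$recovery_delay_ms %||% 0,
                    include_recovery = isTRUE(doc$include_recovery))
  if (!is.null(doc$n_measurements) &&
      as.integer(doc$n_measurements) != u$n_measurements)
    stopf("n_measurements (%s) inconsistent with flip train length (%d)",
          doc$n_measurements, u$n_measurements)
  u
}

settings_to_list <- function(u) {
  list(method = u$method, flips_deg = u$flips, trs_ms = u$trs,
       te_ms = if (is.na(u$te)) NULL else u$te, rf_phases_deg = u$rf_phases,
       driven_equilibrium = u$driven_equilibrium,
       n_periods = if (is.na(u$n_periods)) NULL else u$n_periods,
       n_measurements = u$n_measurements,
       recovery_delay_ms = u$recovery_delay,
       include_recovery = u$include_recovery)
}

#' @rdname read_sequence_config
#' @param u a `seq_settings` or `sequence_set` to serialize.
#' @export
write_sequence_config <- function(u, path) {
  doc <- if (inherits(u, "sequence_set"))
    list(sequences = lapply(u, settings_to_list)) else settings_to_list(u)
  yaml::write_yaml(doc, path)
  invisible(path)
}
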