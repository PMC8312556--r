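#' Evaluate the forward signal model of any supported acquisition
#'
#' Dispatches on the method of `u` and returns the full complex measurement
#' vector together with its timing. For a [sequence_set()] the members'
#' records are concatenated (times restart per member; `t_acq` accumulates).
#'
#' Steady-state methods return one steady-state value per measurement
#' (DESS/TESS: the echo set of one TR period replicated over `n_periods`).
#' Transient methods propagate the train from thermal equilibrium or, in
#' driven-equilibrium mode, from the periodic fixed point.
#'
#' @param p a [tissue_params()] object.
#' @param u a `seq_settings` or `sequence_set`.
#' @return a [signal_record()].
#' @export
signal_model <- function(p, u) {
  if (inherits(u, "sequence_set")) {
    recs <- lapply(u, function(ui) signal_model(p, ui))
    return(signal_record(
      unlist(lapply(recs, `[[`, "signal")),
      unlist(lapply(recs, `[[`, "times")),
      sum(vapply(recs, `[[`, 0.0, "t_acq"))))
  }
  stopifnot(inherits(u, "seq_settings"))
  switch(u$method,
    SPGR = {
      s <- spgr_signal(p, u$flips, u$trs)
      signal_record(s, cumsum(u$trs) - u$trs, t_acq_ms(u))
    },
    bSSFP = {
      s <- bssfp_signal(p, u$flips, u$trs, u$te_eff, u$rf_phases)
      signal_record(s, cumsum(u$trs) - u$trs + u$te_eff, t_acq_ms(u))
    },
    DESS = steady_echo_record(p, u, 2L),
    TESS = steady_echo_record(p, u, 3L),
    MRF_spoiled = {
      init <- if (isTRUE(u$driven_equilibrium))
        driven_equilibrium_state(p, u) else NULL
      epg_spoiled_transient(p, u, initial = init)
    },
    MRF_balanced = {
      init <- if (isTRUE(u$driven_equilibrium))
        driven_equilibrium_state(p, u) else NULL
      bloch_balanced_transient(p, u, initial = init)
    })
}

steady_echo_record <- function(p, u, n_echoes) {
  e <- steady_state_echoes(p, u$flips[1], u$trs[1],
                           if (is.na(u$te)) u$trs[1] / 2 else u$te, n_echoes)
  tr <- u$trs[1]
  te1 <- if (is.na(u$te)) tr / 2 else u$te
  echo_times <- c(te1, tr - te1, te1)[seq_len(n_echoes)]
  np <- u$n_periods
  times <- rep((seq_len(np) - 1L) * tr, each = n_echoes) + echo_times
  signal_record(rep(e, np), times, t_acq_ms(u))
}
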