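#' Periodic inflow waveform
#'
#' Prescribed volumetric flow rate at the coronary ostium, sampled on a
#' uniform grid over one cardiac period. The first and last samples must
#' agree (periodicity). `diastole_onset_fraction` marks aortic valve closure
#' as a fraction of the period and anchors the wave-free window.
#'
#' @param t time samples, s (uniform, from 0 to the period T)
#' @param Q flow samples, cm3/s
#' @param state "resting" or "hyperaemic"
#' @param diastole_onset_fraction valve-closure time / T, in (0, 1)
#' @return object of class `inflow_waveform`
#' @export
inflow_waveform <- function(t, Q, state = c("resting", "hyperaemic"),
                            diastole_onset_fraction) {
  state <- match.arg(state)
  stopifnot(length(t) == length(Q), length(t) >= 3)
  dt <- diff(t)
  if (max(abs(dt - dt[1])) > 1e-9 * dt[1]) stop("time grid must be uniform")
  if (abs(Q[1] - Q[length(Q)]) > 1e-8 * max(abs(Q)))
    stop("waveform must be periodic (first sample == last sample)")
  if (mean(Q) <= 0) stop("mean inflow must be positive")
  if (diastole_onset_fraction <= 0 || diastole_onset_fraction >= 1)
    stop("diastole_onset_fraction must be in (0,1)")
  structure(list(t = t, Q = Q, period = t[length(t)] - t[1], state = state,
                 diastole_onset_fraction = diastole_onset_fraction),
            class = "inflow_waveform")
}

#' Evaluate an inflow waveform at arbitrary times
#'
#' Periodic linear interpolation; exact at grid points.
#'
#' @param wf an `inflow_waveform`
#' @param t times, s (any real values; wrapped into the period)
#' @return flow, cm3/s
#' @export
waveform_at <- function(wf, t) {
  tau <- (t - wf$t[1]) %% wf$period
  stats::approx(wf$t - wf$t[1], wf$Q, xout = tau, rule = 2)$y
}

#' Write / read waveform CSV files
#'
#' Two-column CSV (t_s, Q_mL_per_s) with a comment header carrying the state
#' tag and diastole onset fraction.
#'
#' @param wf an `inflow_waveform`
#' @param path file path
#' @return `read_waveform` returns an `inflow_waveform`
#' @export
write_waveform <- function(wf, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# coroflow-waveform state=%s diastole_onset_fraction=%.12g",
                     wf$state, wf$diastole_onset_fraction), con)
  utils::write.csv(data.frame(t_s = wf$t, Q_mL_per_s = wf$Q), con,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path) {
  hdr <- readLines(path, n = 1)
  m <- regmatches(hdr, regexec(
    "state=(\\w+) diastole_onset_fraction=([0-9.eE+-]+)", hdr))[[1]]
  if (length(m) != 3) stop("malformed waveform header in '", path, "'")
  df <- utils::read.csv(path, comment.char = "#")
  inflow_waveform(df$t_s, df$Q_mL_per_s, state = m[2],
                  diastole_onset_fraction = as.numeric(m[3]))
}

#' Ventricular pressure traces
#'
#' Periodic left and right ventricular pressures supplying the external
#' (intramyocardial) pressure of the terminal beds.
#'
#' @param t uniform time grid over one period, s
#' @param P_LV,P_RV pressures, dyn/cm2
#' @return object of class `ventricular_traces`
#' @export
ventricular_traces <- function(t, P_LV, P_RV) {
  stopifnot(length(t) == length(P_LV), length(t) == length(P_RV))
  if (max(P_LV) <= max(P_RV) || max(P_RV) <= 0)
    stop("expected max(P_LV) > max(P_RV) > 0")
  structure(list(t = t, P_LV = P_LV, P_RV = P_RV,
                 period = t[length(t)] - t[1]),
            class = "ventricular_traces")
}

#' Evaluate a ventricular trace periodically
#' @param vt a `ventricular_traces`
#' @param t times, s
#' @param which "left" or "right"
#' @return pressure, dyn/cm2
#' @export
ventricular_at <- function(vt, t, which = c("left", "right")) {
  which <- match.arg(which)
  tau <- (t - vt$t[1]) %% vt$period
  y <- if (which == "left") vt$P_LV else vt$P_RV
  stats::approx(vt$t - vt$t[1], y, xout = tau, rule = 2)$y
}

#' Total resistance of a coronary branch from state pressures and inflow
#'
#' R = (systolic/3 + 2 diastolic/3) / Q, i.e. the estimated mean arterial
#' pressure over the branch mean inflow; pressures are given in mmHg and the
#' result is returned in CGS (dyn s/cm5).
#'
#' @param systolic,diastolic brachial pressures, mmHg
#' @param Q_branch mean branch inflow, cm3/s
#' @return resistance, dyn s/cm5
#' @export
total_branch_resistance <- function(systolic, diastolic, Q_branch) {
  if (systolic <= 0 || diastolic <= 0) stop("pressures must be > 0")
  if (Q_branch <= 0) stop("branch flow must be > 0")
  mmhg_to_cgs(systolic / 3 + 2 * diastolic / 3) / Q_branch
}

#' Distribute a branch resistance over terminals by Murray's law
#'
#' Terminal k receives \eqn{R_k = R\,S/d_k^p} with \eqn{S = \sum_j d_j^p}
#' (default power 2.27, applied to each terminal segment's proximal reference
#' diameter). Larger vessels get lower resistance and the parallel
#' combination of all terminals returns the branch total exactly.
#'
#' @param R_branch branch total resistance, dyn s/cm5
#' @param terminal_diameters vector of terminal proximal diameters, cm
#' @param power Murray exponent (default 2.27)
#' @return vector of per-terminal resistances
#' @export
distribute_resistance_murray <- function(R_branch, terminal_diameters,
                                         power = 2.27) {
  if (length(terminal_diameters) == 0) stop("no terminal diameters given")
  if (any(terminal_diameters <= 0)) stop("terminal diameters must be > 0")
  w <- terminal_diameters^power
  R_branch * sum(w) / w
}

#' Lumped coronary terminal bed
#'
#' Five-element coronary outlet: arterial resistance Ra into a node with
#' compliance Ca_bed, then Rm into the intramyocardial node with compliance
#' Cim biased by the ventricular external pressure Pim(t), then venous
#' resistance Rv to the venous pressure Pv. The Pim bias produces the
#' characteristic systolic impediment of coronary flow. The resistance split
#' Ra:Rm:Rv defaults to 0.32:0.52:0.16 of the terminal total; compliances
#' default to fixed time constants over the terminal total resistance.
#'
#' @param R_total total terminal resistance, dyn s/cm5
#' @param side "left" (Pim = P_LV) or "right" (Pim = pim_scale * P_RV)
#' @param splits length-3 fractions for Ra, Rm, Rv (sums to 1)
#' @param tau_a,tau_im time constants defining Ca_bed = tau_a/R_total and
#'   Cim = tau_im/R_total, s
#' @param Pv venous pressure, dyn/cm2 (default 5 mmHg)
#' @param pim_scale scaling of the ventricular pressure applied as Pim
#'   (default 1 for left, 0.5 for right)
#' @return object of class `terminal_bed`
#' @export
terminal_bed <- function(R_total, side = c("left", "right"),
                         splits = c(0.32, 0.52, 0.16),
                         tau_a = 0.05, tau_im = 0.15,
                         Pv = mmhg_to_cgs(5),
                         pim_scale = NULL) {
  side <- match.arg(side)
  if (R_total <= 0) stop("terminal resistance must be > 0")
  if (abs(sum(splits) - 1) > 1e-12) stop("resistance splits must sum to 1")
  if (is.null(pim_scale)) pim_scale <- if (side == "left") 1 else 0.5
  structure(list(Ra = splits[1] * R_total, Rm = splits[2] * R_total,
                 Rv = splits[3] * R_total, R_total = R_total,
                 Ca_bed = tau_a / R_total, Cim = tau_im / R_total,
                 Pv = Pv, side = side, pim_scale = pim_scale),
            class = "terminal_bed")
}

#' Advance a terminal bed one time step
#'
#' Crank-Nicolson update of the bed's two compartment pressures given the
#' terminal pressure P_in at both time levels and the external pressure trace
#' Pim at both time levels. Returns the updated state and the inflow drawn
#' through Ra at the new level. Used standalone for bed verification; inside
#' the network solver the same equations are embedded in the global implicit
#' system.
#'
#' @param bed a `terminal_bed`
#' @param state list(P1, P2) compartment pressures, dyn/cm2; NULL initializes
#'   both to P_in_old
#' @param P_in_old,P_in_new terminal pressure at t and t+dt, dyn/cm2
#' @param Pim_old,Pim_new external (ventricular) pressure at t and t+dt
#' @param dt time step, s
#' @return list(state = list(P1, P2), Q_in = inflow at t+dt)
#' @export
bed_update <- function(bed, state, P_in_old, P_in_new, Pim_old, Pim_new, dt) {
  if (dt <= 0) stop("dt must be > 0")
  if (is.null(state)) state <- list(P1 = P_in_old, P2 = P_in_old)
  Pim_old <- bed$pim_scale * Pim_old; Pim_new <- bed$pim_scale * Pim_new
  th <- 0.5
  # unknowns x = (P1, P2)
  # Ca (P1-P1o)/dt = th[(Pin-P1)/Ra - (P1-P2)/Rm] + (1-th)[old fluxes]
  # Cim (P2-P2o)/dt - Cim (Pim_new-Pim_old)/dt =
  #       th[(P1-P2)/Rm - (P2-Pv)/Rv] + (1-th)[old fluxes]
  P1o <- state$P1; P2o <- state$P2
  f1o <- (P_in_old - P1o) / bed$Ra - (P1o - P2o) / bed$Rm
  f2o <- (P1o - P2o) / bed$Rm - (P2o - bed$Pv) / bed$Rv
  A <- matrix(c(bed$Ca_bed / dt + th / bed$Ra + th / bed$Rm, -th / bed$Rm,
                -th / bed$Rm, bed$Cim / dt + th / bed$Rm + th / bed$Rv),
              2, 2, byrow = TRUE)
  rhs <- c(bed$Ca_bed / dt * P1o + th * P_in_new / bed$Ra + (1 - th) * f1o,
           bed$Cim / dt * P2o + bed$Cim * (Pim_new - Pim_old) / dt +
             th * bed$Pv / bed$Rv + (1 - th) * f2o)
  x <- solve(A, rhs)
  if (any(!is.finite(x)))
    stop("terminal bed update unstable (dt = ", dt, " too large?)")
  list(state = list(P1 = x[1], P2 = x[2]),
       Q_in = (P_in_new - x[1]) / bed$Ra)
}

#' Simulate a terminal bed driven by a prescribed terminal pressure
#'
#' Convenience harness integrating [bed_update] over a time grid; used for
#' verification against analytic lumped-circuit responses.
#'
#' @param bed a `terminal_bed`
#' @param t uniform time grid, s
#' @param P_in terminal pressure trace, dyn/cm2
#' @param Pim external pressure trace (unscaled ventricular pressure)
#' @param n_cycles repeat the trace this many times (returns the last pass)
#' @return list(t, Q_in, P1, P2) for the final pass
#' @export
bed_simulate <- function(bed, t, P_in, Pim = 0 * t, n_cycles = 1) {
  dt <- t[2] - t[1]
  state <- NULL
  n <- length(t)
  Q <- P1 <- P2 <- numeric(n)
  for (cyc in seq_len(n_cycles)) {
    for (i in seq_len(n - 1)) {
      if (is.null(state)) state <- list(P1 = P_in[1], P2 = P_in[1])
      res <- bed_update(bed, state, P_in[i], P_in[i + 1], Pim[i], Pim[i + 1], dt)
      state <- res$state
      Q[i + 1] <- res$Q_in; P1[i + 1] <- state$P1; P2[i + 1] <- state$P2
    }
    Q[1] <- Q[n]; P1[1] <- P1[n]; P2[1] <- P2[n]
  }
  list(t = t, Q_in = Q, P1 = P1, P2 = P2)
}
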