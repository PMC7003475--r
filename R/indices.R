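#' Probe pair for pressure-ratio indices
#'
#' @param proximal,distal lists with `segment` (id) and `fraction` (0-1 along
#'   the segment axis); proximal is conventionally the tree inlet (aortic
#'   ostium), distal lies downstream of the stenosis
#' @return object of class `probe_pair`
#' @export
probe_pair <- function(proximal, distal) {
  chk <- function(p, nm) {
    if (!is.list(p) || is.null(p$segment) || is.null(p$fraction))
      stop(nm, " probe needs $segment and $fraction")
    if (p$fraction < 0 || p$fraction > 1)
      stop(nm, " probe fraction must be in [0,1]")
    p
  }
  structure(list(proximal = chk(proximal, "proximal"),
                 distal = chk(distal, "distal")), class = "probe_pair")
}

#' Wave-free diastolic window
#'
#' The window opens one fifth of the way into diastole and closes at the end
#' of the cardiac cycle: t_start = t_d + 0.2 (T - t_d), t_end = T, where t_d
#' is diastole onset (aortic valve closure).
#'
#' @param diastole_onset t_d, s (0 < t_d < T)
#' @param period cycle length T, s
#' @return c(t_start, t_end); errors if t_d lies outside the cycle or the
#'   window degenerates below 5% of the cycle
#' @export
wave_free_window <- function(diastole_onset, period) {
  if (diastole_onset <= 0 || diastole_onset >= period)
    stop("diastole onset must lie strictly inside the cycle")
  t_start <- diastole_onset + 0.2 * (period - diastole_onset)
  if (period - t_start < 0.05 * period)
    stop("degenerate wave-free window (< 5% of the cycle)")
  c(t_start = t_start, t_end = period)
}

# trapezoid mean of y(t) over [a, b] within the result grid
trapz_mean <- function(t, y, a = min(t), b = max(t)) {
  sel <- t >= a - 1e-12 & t <= b + 1e-12
  tt <- t[sel]; yy <- y[sel]
  if (length(tt) < 2) stop("window contains fewer than 2 samples")
  sum(diff(tt) * (yy[-1] + yy[-length(yy)]) / 2) / (tt[length(tt)] - tt[1])
}

#' Computed fractional flow reserve
#'
#' Mean of the instantaneous pressure ratio Pd/Pp over the final cardiac
#' cycle of a converged hyperaemic simulation (mean of the ratio, not ratio
#' of the means).
#'
#' @param result hyperaemic `corosim_result`
#' @param probes a `probe_pair`
#' @return list with `cffr`, `mean_Pd`, `mean_Pp` (mmHg)
#' @export
compute_cffr <- function(result, probes) {
  Pp <- probe_trace(result, probes$proximal$segment, probes$proximal$fraction)
  Pd <- probe_trace(result, probes$distal$segment, probes$distal$fraction)
  if (any(Pp <= 0)) stop("proximal pressure crosses zero")
  list(cffr = trapz_mean(result$t, Pd / Pp),
       mean_Pd = cgs_to_mmhg(trapz_mean(result$t, Pd)),
       mean_Pp = cgs_to_mmhg(trapz_mean(result$t, Pp)))
}

#' Computed instantaneous wave-free ratio
#'
#' Mean of the instantaneous ratio Pd/Pp over the wave-free window of a
#' converged resting simulation.
#'
#' @param result resting `corosim_result`
#' @param probes a `probe_pair`
#' @param diastole_onset aortic valve closure time within the cycle, s
#'   (normally tier-1's exported value; see [detect_diastole_onset] for a
#'   fallback)
#' @return list with `cifr`, `window` (s), `mean_Pd`, `mean_Pp` (mmHg over
#'   the window)
#' @export
compute_cifr <- function(result, probes, diastole_onset) {
  Pp <- probe_trace(result, probes$proximal$segment, probes$proximal$fraction)
  Pd <- probe_trace(result, probes$distal$segment, probes$distal$fraction)
  if (any(Pp <= 0)) stop("proximal pressure crosses zero")
  win <- wave_free_window(diastole_onset, result$period)
  list(cifr = trapz_mean(result$t, Pd / Pp, win[1], win[2]), window = win,
       mean_Pd = cgs_to_mmhg(trapz_mean(result$t, Pd, win[1], win[2])),
       mean_Pp = cgs_to_mmhg(trapz_mean(result$t, Pp, win[1], win[2])))
}

#' Dicrotic-notch fallback detector for diastole onset
#'
#' For externally supplied pressure traces without a valve-closure time:
#' finds the local minimum of dP/dt in the descending limb after the systolic
#' peak (the notch). Prefer the valve-closure time exported by the
#' closed-loop generator when available.
#'
#' @param t time grid, s
#' @param P pressure trace over one cycle
#' @return estimated diastole onset, s
#' @export
detect_diastole_onset <- function(t, P) {
  ipk <- which.max(P)
  n <- length(P)
  if (ipk >= n - 2) stop("pressure peak too close to cycle end")
  dP <- diff(P) / diff(t)
  seg <- (ipk + 1):(n - 1)
  # local minima of P (notch) or of dP/dt in the descending limb
  cand <- seg[which(diff(sign(diff(P[seg]))) > 0) + 1]
  i <- if (length(cand)) cand[1] else seg[which.min(dP[seg])]
  t[i]
}

#' Forward / backward wave separation
#'
#' Linearized characteristic decomposition of pressure increments:
#' dP+- = (dP +- rho c dU)/2 with U = Q/A; the cumulative sums give the
#' forward and backward pressure waveforms and reconstruct P - P(0) exactly
#' (dP_forward + dP_backward = dP by construction).
#'
#' @param P,Q,A traces on a uniform time grid (dyn/cm2, cm3/s, cm2)
#' @param c wave speed trace, cm/s (scalar or vector)
#' @param rho blood density, g/cm3
#' @return list with increments `dP_forward`, `dP_backward` and cumulative
#'   `P_forward`, `P_backward` (same length as P, starting at 0)
#' @export
separate_waves <- function(P, Q, A, c, rho = 1.05) {
  n <- length(P)
  stopifnot(length(Q) == n, length(A) == n)
  if (length(c) == 1) c <- rep(c, n)
  U <- Q / A
  dP <- diff(P); dU <- diff(U)
  zc <- rho * 0.5 * (c[-1] + c[-n])
  dPf <- 0.5 * (dP + zc * dU)
  dPb <- 0.5 * (dP - zc * dU)
  list(dP_forward = dPf, dP_backward = dPb,
       P_forward = c(0, cumsum(dPf)), P_backward = c(0, cumsum(dPb)))
}

#' Place index probes around a stenosis
#'
#' Proximal probe at the tree inlet (root, fraction 0); distal probe 1 cm or
#' three throat diameters (whichever is larger) downstream of the most distal
#' stenosis throat, clamped to the carrying segment.
#'
#' @param network a `coronary_network` (post-stenosis)
#' @param stenoses list of stenosis specs (lists with segment_id,
#'   center_fraction, ...); NULL places the distal probe at the end of the
#'   root segment
#' @return a `probe_pair`
#' @export
place_probes <- function(network, stenoses = NULL) {
  prox <- list(segment = network$root, fraction = 0)
  if (is.null(stenoses) || length(stenoses) == 0)
    return(probe_pair(prox, list(segment = network$root, fraction = 1)))
  last <- stenoses[[which.max(vapply(stenoses, function(s)
    s$center_fraction, numeric(1)))]]
  seg <- network$segments[[last$segment_id]]
  x_throat <- last$center_fraction * seg$length
  d_throat <- stats::approx(seq(0, seg$length, length.out = seg$n_points),
                            segment_diameters(seg), xout = x_throat)$y
  offset <- max(1, 3 * d_throat)
  frac <- min(1, (x_throat + offset) / seg$length)
  probe_pair(prox, list(segment = last$segment_id, fraction = frac))
}

#' Terminal beds from the geometry-based resistance rule
#'
#' Second-tier parameter assignment: the branch total resistance is
#' (systolic/3 + 2 diastolic/3) / Q_branch (mmHg inputs, CGS output) and is
#' distributed over the terminal segments by Murray's law with power 2.27 on
#' each terminal's proximal reference diameter, so the parallel combination
#' recovers the branch total exactly.
#'
#' @param network a `coronary_network`
#' @param state a `physiological_state` (supplies the pressures)
#' @param Q_branch mean branch inflow for this state, cm3/s
#' @param power Murray exponent
#' @param ... passed to [terminal_bed] (splits, time constants, Pv)
#' @return named list of [terminal_bed], one per terminal segment
#' @export
assign_terminal_beds <- function(network, state, Q_branch, power = 2.27, ...) {
  R_branch <- total_branch_resistance(state$systolic, state$diastolic,
                                      Q_branch)
  d <- vapply(network$terminals, function(sid)
    segment_diameters(network$segments[[sid]])[1], numeric(1))
  Rk <- distribute_resistance_murray(R_branch, d, power)
  beds <- lapply(Rk, terminal_bed, side = network$side, ...)
  names(beds) <- network$terminals
  beds
}

#' One patient-equivalent pipeline pass
#'
#' Applies the stenoses to the tree, then for each state (resting,
#' hyperaemic) builds the wall law (P0 = state diastolic pressure), assigns
#' terminal beds from the state's branch inflow, runs the 1D simulation to a
#' periodic state with the shared tier-1 waveforms, and computes ciFR
#' (resting run) and cFFR (hyperaemic run) with identical geometry and
#' probes.
#'
#' @param network a `coronary_network` (without the stenoses)
#' @param stenoses list of stenosis specs: lists with `segment_id`,
#'   `center_fraction`, `stenosed_length`, `area_reduction`, optional `shape`
#' @param boundary_data output of [tier1_boundary_data] (cacheable; see
#'   [cached_boundary_data])
#' @param config a `solver_config`
#' @param case_id identifier carried into the record
#' @param probes optional `probe_pair` (default from [place_probes])
#' @param wall_args named list of overrides passed to [wall_params]
#' @return a `diagnostic_record`: list with case_id, cffr, cifr, window,
#'   probes, per-state convergence metadata
#' @export
run_case <- function(network, stenoses = list(), boundary_data = NULL,
                     config = solver_config(), case_id = "case",
                     probes = NULL, wall_args = list()) {
  if (is.null(boundary_data)) boundary_data <- cached_boundary_data()
  net <- network
  for (s in stenoses)
    net <- apply_stenosis(net, s$segment_id, s$center_fraction,
                          s$stenosed_length, s$area_reduction,
                          shape = s$shape %||% "cosine")
  probes <- probes %||% place_probes(net, stenoses)
  side <- net$side
  run_state <- function(bd) {
    st <- bd$state
    wall <- do.call(wall_params,
                    c(list(P0 = mmhg_to_cgs(st$diastolic)), wall_args))
    Q_branch <- unname(bd$mean_inflow[side])
    beds <- assign_terminal_beds(net, st, Q_branch)
    inflow <- if (side == "left") bd$inflow_left else bd$inflow_right
    bnd <- network_boundaries(inflow, beds = beds,
                              ventricular = bd$ventricular)
    run_to_periodic(net, wall, bnd, config)
  }
  res_rest <- run_state(boundary_data$resting)
  res_hyper <- run_state(boundary_data$hyperaemic)
  t_d <- boundary_data$resting$inflow_left$diastole_onset_fraction *
    res_rest$period
  ci <- compute_cifr(res_rest, probes, t_d)
  cf <- compute_cffr(res_hyper, probes)
  structure(list(case_id = case_id, cffr = cf$cffr, cifr = ci$cifr,
                 window = ci$window, probes = probes,
                 mean_Pp_hyper = cf$mean_Pp, mean_Pd_hyper = cf$mean_Pd,
                 resting_converged = res_rest$converged,
                 hyperaemic_converged = res_hyper$converged,
                 resting_cycles = res_rest$cycles,
                 hyperaemic_cycles = res_hyper$cycles,
                 results = list(resting = res_rest, hyperaemic = res_hyper)),
            class = "diagnostic_record")
}

#' @export
print.diagnostic_record <- function(x, ...) {
  cat(sprintf("<diagnostic_record '%s'> cFFR = %.4f, ciFR = %.4f (window %.3f-%.3f s)\n",
              x$case_id, x$cffr, x$cifr, x$window[1], x$window[2]))
  invisible(x)
}

#' Serialize / deserialize a diagnostic record
#'
#' JSON round-trip of the scalar content of a record (fields, probes,
#' window); the bulky simulation results are not serialized.
#'
#' @param record a `diagnostic_record`
#' @param path file path
#' @return `read_record` returns the scalar record
#' @export
write_record <- function(record, path) {
  keep <- record[c("case_id", "cffr", "cifr", "window", "mean_Pp_hyper",
                   "mean_Pd_hyper", "resting_converged",
                   "hyperaemic_converged", "resting_cycles",
                   "hyperaemic_cycles")]
  keep$window <- as.list(keep$window)
  keep$probes <- list(proximal = record$probes$proximal,
                      distal = record$probes$distal)
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_record
#' @export
read_record <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
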