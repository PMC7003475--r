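#' Solver configuration
#'
#' Controls the space/time discretization of the 1D pressure-flow system.
#' The scheme is a control-volume collocation (staggered) discretization -
#' pressures at cell centres, flows at cell faces - with theta = 0.5
#' (Crank-Nicolson) time integration and Picard iteration of the nonlinear
#' coefficients, giving second order in both dx and dt. It is implicit, so
#' dt is limited by accuracy, not stability; the advective CFL number is
#' recorded in result metadata as a sanity check.
#'
#' @param dx_target target axial cell size, cm (default 0.05)
#' @param dt time step, s (default 1e-4)
#' @param theta implicitness (0.5 = Crank-Nicolson; keep at 0.5 for second
#'   order)
#' @param periodic_tol relative cycle-to-cycle change of pressure below which
#'   the run is declared periodic (default 1e-3)
#' @param max_cycles maximum cardiac cycles (default 10)
#' @param picard_tol nonlinear iteration tolerance (scaled, default 1e-7)
#' @param max_picard maximum Picard sweeps per step (default 10)
#' @param output_dt output sampling interval, s (default 1e-3, i.e. 1 kHz)
#' @return object of class `solver_config`
#' @export
solver_config <- function(dx_target = 0.05, dt = 1e-4, theta = 0.5,
                          periodic_tol = 1e-3, max_cycles = 10,
                          picard_tol = 1e-7, max_picard = 10,
                          output_dt = 1e-3) {
  stopifnot(dx_target > 0, dt > 0, theta >= 0.5, theta <= 1,
            periodic_tol > 0, picard_tol > 0, max_cycles >= 1)
  structure(list(dx_target = dx_target, dt = dt, theta = theta,
                 periodic_tol = periodic_tol, max_cycles = max_cycles,
                 picard_tol = picard_tol, max_picard = max_picard,
                 output_dt = output_dt),
            class = "solver_config")
}

#' Boundary set for a network simulation
#'
#' Packages the root inflow and one outlet closure per terminal segment.
#' Outlets are either coronary terminal beds (the default for physiology;
#' requires `ventricular` traces for the intramyocardial pressure) or plain
#' resistances to a fixed outlet pressure (validation runs, absorbing
#' outlets).
#'
#' @param inflow an [inflow_waveform]
#' @param beds named list of [terminal_bed], one per terminal segment id
#' @param ventricular a [ventricular_traces] (required with beds whose
#'   pim_scale is nonzero)
#' @param resistances named numeric of terminal resistances (alternative to
#'   beds), dyn s/cm5
#' @param P_out outlet reference pressure for resistance terminals, dyn/cm2
#' @return object of class `network_boundaries`
#' @export
network_boundaries <- function(inflow, beds = NULL, ventricular = NULL,
                               resistances = NULL, P_out = 0) {
  stopifnot(inherits(inflow, "inflow_waveform"))
  if (is.null(beds) && is.null(resistances))
    stop("need either terminal beds or terminal resistances")
  if (!is.null(beds) && is.null(ventricular) &&
      any(vapply(beds, function(b) b$pim_scale != 0, logical(1))))
    stop("terminal beds with external pressure require ventricular traces")
  structure(list(inflow = inflow, beds = beds, ventricular = ventricular,
                 resistances = resistances, P_out = P_out),
            class = "network_boundaries")
}

# ---------------------------------------------------------------------------
# mesh + implicit system construction

#' Discretize a network for the 1D solver
#'
#' Internal-facing but exported for inspection: builds the staggered mesh
#' (cells and faces per segment, junction and terminal nodes) and evaluates
#' the per-cell/per-face wall properties (A0, c0, b, Gamma).
#'
#' @param network a `coronary_network`
#' @param wall a `wall_params`
#' @param config a `solver_config`
#' @return a `coroflow_mesh` list
#' @export
build_mesh <- function(network, wall, config) {
  ord <- network_order(network)
  cells <- list(); faces <- list()
  seg_info <- list()
  nc <- 0L; nf <- 0L
  for (sid in ord) {
    seg <- network$segments[[sid]]
    n <- max(2L, as.integer(round(seg$length / config$dx_target)))
    dx <- seg$length / n
    xs <- seq(0, seg$length, length.out = seg$n_points)
    a0_at <- function(x) stats::approx(xs, seg$area_profile, xout = x,
                                       rule = 2)$y
    xc <- (seq_len(n) - 0.5) * dx
    xf <- (0:n) * dx
    A0c <- a0_at(xc); A0f <- a0_at(xf)
    seg_info[[sid]] <- list(n = n, dx = dx, cell0 = nc, face0 = nf,
                            xc = xc, xf = xf, A0c = A0c, A0f = A0f)
    nc <- nc + n; nf <- nf + n + 1L
  }
  NC <- nc; NF <- nf
  cell_seg <- character(NC); cell_dx <- numeric(NC)
  A0c <- numeric(NC); A0f <- numeric(NF)
  face_seg <- character(NF); face_dx <- numeric(NF)
  for (sid in ord) {
    si <- seg_info[[sid]]
    ic <- si$cell0 + seq_len(si$n); iff <- si$face0 + seq_len(si$n + 1)
    cell_seg[ic] <- sid; cell_dx[ic] <- si$dx; A0c[ic] <- si$A0c
    face_seg[iff] <- sid; face_dx[iff] <- si$dx; A0f[iff] <- si$A0f
  }
  D0c <- 2 * sqrt(A0c / pi); D0f <- 2 * sqrt(A0f / pi)
  c0c <- reference_wave_speed(D0c, wall); c0f <- reference_wave_speed(D0f, wall)
  bc <- stiffness_exponent(c0c, wall); bf <- stiffness_exponent(c0f, wall)
  Gc <- wall_viscosity(D0c, wall)

  # nodes: one per junction parent, one per terminal
  junction_parents <- names(network$children)
  node_ids <- c(junction_parents, network$terminals)
  node_type <- c(rep("junction", length(junction_parents)),
                 rep("terminal", length(network$terminals)))
  names(node_type) <- node_ids
  NN <- length(node_ids)
  node_index <- stats::setNames(seq_len(NN), node_ids)

  # face classification
  ftype <- integer(NF)         # 0 root, 1 interior, 2 prox-node, 3 dist-node
  f_lc <- f_rc <- f_node <- rep(NA_integer_, NF)
  f_fm1 <- f_fp1 <- rep(NA_integer_, NF)
  for (sid in ord) {
    si <- seg_info[[sid]]
    f0 <- si$face0; c0i <- si$cell0; n <- si$n
    prox <- f0 + 1L; dist <- f0 + n + 1L
    # interior faces j = 1..n-1 (local), global f0+1+j
    if (n >= 2) {
      fj <- f0 + 1L + seq_len(n - 1L)
      ftype[fj] <- 1L
      f_lc[fj] <- c0i + seq_len(n - 1L)
      f_rc[fj] <- c0i + seq_len(n - 1L) + 1L
      f_fm1[fj] <- fj - 1L; f_fp1[fj] <- fj + 1L
    }
    if (sid == network$root) {
      ftype[prox] <- 0L
      f_rc[prox] <- c0i + 1L
    } else {
      ftype[prox] <- 2L
      f_rc[prox] <- c0i + 1L
      f_node[prox] <- node_index[[network$parent[[sid]]]]
    }
    ftype[dist] <- 3L
    f_lc[dist] <- c0i + n
    f_node[dist] <- node_index[[sid]]   # its own junction node or terminal node
  }
  # node face lists
  node_in_face <- integer(NN); node_out_faces <- vector("list", NN)
  for (k in seq_len(NN)) {
    sid <- node_ids[k]
    si <- seg_info[[sid]]
    node_in_face[k] <- si$face0 + si$n + 1L
    if (node_type[[sid]] == "junction")
      node_out_faces[[k]] <- vapply(network$children[[sid]], function(ch)
        seg_info[[ch]]$face0 + 1L, integer(1))
  }
  cell_lf <- unlist(lapply(ord, function(sid) {
    si <- seg_info[[sid]]; si$face0 + seq_len(si$n)
  }), use.names = FALSE)
  structure(list(network = network, wall = wall, seg_info = seg_info,
                 ord = ord, NC = NC, NF = NF, NN = NN, cell_lf = cell_lf,
                 cell_seg = cell_seg, cell_dx = cell_dx,
                 face_seg = face_seg, face_dx = face_dx,
                 A0c = A0c, A0f = A0f, c0c = c0c, c0f = c0f,
                 bc = bc, bf = bf, Gc = Gc, D0c = D0c,
                 node_ids = node_ids, node_type = node_type,
                 node_index = node_index,
                 ftype = ftype, f_lc = f_lc, f_rc = f_rc, f_node = f_node,
                 f_fm1 = f_fm1, f_fp1 = f_fp1,
                 node_in_face = node_in_face, node_out_faces = node_out_faces),
            class = "coroflow_mesh")
}

#' Assemble the implicit network system
#'
#' Couples mesh, wall law, boundaries and solver configuration into a
#' stepping system. The unknown vector holds cell pressures, face flows,
#' node pressures and two bed pressures per terminal.
#'
#' @param network,wall,boundaries,config as in [run_to_periodic]
#' @return a `coroflow_system`
#' @export
coroflow_system <- function(network, wall, boundaries, config) {
  mesh <- build_mesh(network, wall, config)
  NC <- mesh$NC; NF <- mesh$NF; NN <- mesh$NN
  terminals <- mesh$node_ids[mesh$node_type == "terminal"]
  use_beds <- !is.null(boundaries$beds)
  if (use_beds) {
    missing <- setdiff(terminals, names(boundaries$beds))
    if (length(missing)) stop("no terminal bed for segment(s): ",
                              paste(missing, collapse = ", "))
  } else {
    missing <- setdiff(terminals, names(boundaries$resistances))
    if (length(missing)) stop("no terminal resistance for segment(s): ",
                              paste(missing, collapse = ", "))
  }
  NB <- if (use_beds) length(terminals) else 0L
  NU <- NC + NF + NN + 2L * NB
  iP <- seq_len(NC); iQ <- NC + seq_len(NF); iN <- NC + NF + seq_len(NN)
  ib1 <- ib2 <- integer(0)
  if (use_beds) {
    ib1 <- NC + NF + NN + 2L * seq_len(NB) - 1L
    ib2 <- ib1 + 1L
  }
  term_node_idx <- mesh$node_index[terminals]
  scale <- numeric(NU)
  scale[iP] <- 1e4; scale[iQ] <- 0.05; scale[iN] <- 1e4
  if (NB) { scale[ib1] <- 1e4; scale[ib2] <- 1e4 }
  sys <- structure(list(mesh = mesh, wall = wall, boundaries = boundaries,
                 config = config, NC = NC, NF = NF, NN = NN, NB = NB, NU = NU,
                 iP = iP, iQ = iQ, iN = iN, ib1 = ib1, ib2 = ib2,
                 terminals = terminals, term_node_idx = term_node_idx,
                 use_beds = use_beds, scale = scale),
            class = "coroflow_system")
  sys$pattern <- build_pattern(sys)
  sys
}

# static sparsity pattern and constant coefficient slots of the implicit
# system; only area-dependent values are refilled each Picard sweep
build_pattern <- function(sys) {
  m <- sys$mesh; cf <- sys$config
  th <- cf$theta; dt <- cf$dt
  iP <- sys$iP; iQ <- sys$iQ; iN <- sys$iN
  interior <- which(m$ftype == 1L)
  fprox <- which(m$ftype == 2L)
  fdist <- which(m$ftype == 3L)
  froot <- which(m$ftype == 0L)
  lf <- left_face(m); rf <- lf + 1L
  dx_i <- m$face_dx[interior]
  h_p <- m$face_dx[fprox] / 2; h_d <- m$face_dx[fdist] / 2

  ti <- integer(0); tj <- integer(0); tv <- numeric(0)
  slots <- list(); pos <- 0L
  push <- function(name, i, j, v) {
    n <- max(length(i), length(j), length(v))
    ti <<- c(ti, rep_len(as.integer(i), n))
    tj <<- c(tj, rep_len(as.integer(j), n))
    tv <<- c(tv, rep_len(v, n))
    slots[[name]] <<- pos + seq_len(n)
    pos <<- pos + n
  }
  push("mass_diag", iP, iP, 0)                       # Camid/dt (varies)
  push("mass_qr", iP, iQ[rf], th / m$cell_dx)
  push("mass_ql", iP, iQ[lf], -th / m$cell_dx)
  if (length(interior)) {
    push("int_diag", iQ[interior], iQ[interior], 0)  # varies
    push("int_fp", iQ[interior], iQ[m$f_fp1[interior]], 0)
    push("int_fm", iQ[interior], iQ[m$f_fm1[interior]], 0)
    push("int_pr", iQ[interior], iP[m$f_rc[interior]], th / dx_i)
    push("int_pl", iQ[interior], iP[m$f_lc[interior]], -th / dx_i)
  }
  if (length(fprox)) {
    push("prox_diag", iQ[fprox], iQ[fprox], 0)       # varies
    push("prox_pc", iQ[fprox], iP[m$f_rc[fprox]], th / h_p)
    push("prox_pn", iQ[fprox], iN[m$f_node[fprox]], -th / h_p)
  }
  push("dist_diag", iQ[fdist], iQ[fdist], 0)         # varies
  push("dist_pn", iQ[fdist], iN[m$f_node[fdist]], th / h_d)
  push("dist_pl", iQ[fdist], iP[m$f_lc[fdist]], -th / h_d)
  push("root", iQ[froot], iQ[froot], 1)
  for (k in seq_len(sys$NN)) {
    row <- iN[k]
    if (m$node_type[[m$node_ids[k]]] == "junction") {
      outs <- m$node_out_faces[[k]]
      push(paste0("junc", k), rep(row, 1 + length(outs)),
           c(iQ[m$node_in_face[k]], iQ[outs]), c(1, rep(-1, length(outs))))
    } else {
      tf <- m$node_in_face[k]
      tk <- match(m$node_ids[k], sys$terminals)
      if (sys$use_beds) {
        bed <- sys$boundaries$beds[[sys$terminals[tk]]]
        push(paste0("term", k), rep(row, 3),
             c(iQ[tf], iN[k], sys$ib1[tk]), c(1, -1 / bed$Ra, 1 / bed$Ra))
      } else {
        R <- sys$boundaries$resistances[[sys$terminals[tk]]]
        push(paste0("term", k), rep(row, 2), c(iQ[tf], iN[k]), c(1, -1 / R))
      }
    }
  }
  if (sys$use_beds) {
    for (tk in seq_along(sys$terminals)) {
      bed <- sys$boundaries$beds[[sys$terminals[tk]]]
      nk <- sys$term_node_idx[tk]
      r1 <- sys$ib1[tk]; r2 <- sys$ib2[tk]
      push(paste0("bed1_", tk), rep(r1, 3), c(r1, r2, iN[nk]),
           c(bed$Ca_bed / dt + th / bed$Ra + th / bed$Rm, -th / bed$Rm,
             -th / bed$Ra))
      push(paste0("bed2_", tk), rep(r2, 2), c(r2, r1),
           c(bed$Cim / dt + th / bed$Rm + th / bed$Rv, -th / bed$Rm))
    }
  }
  list(ti = ti, tj = tj, tv = tv, slots = slots,
       interior = interior, fprox = fprox, fdist = fdist, froot = froot,
       lf = lf, rf = rf, dx_i = dx_i, h_p = h_p, h_d = h_d)
}

#' Equilibrium initial state for a system
#'
#' All pressures at the wall reference pressure P0 (plus Pext), all flows
#' zero; with zero inflow this is an exact fixed point of the scheme.
#'
#' @param sys a `coroflow_system`
#' @param P optional uniform starting pressure, dyn/cm2
#' @return numeric state vector
#' @export
initial_state <- function(sys, P = NULL) {
  P <- P %||% (sys$wall$P0 + sys$wall$Pext)
  x <- numeric(sys$NU)
  x[sys$iP] <- P; x[sys$iN] <- P
  if (sys$NB) { x[sys$ib1] <- P; x[sys$ib2] <- P }
  x[sys$iQ] <- 0
  x
}

#' Advance the network state one time step
#'
#' One Crank-Nicolson step of the discretized mass/momentum system with
#' Picard iteration of the area-dependent coefficients. Aborts with a
#' diagnostic naming the offending segment on Picard non-convergence or
#' collapse of the tube law (negative area).
#'
#' @param sys a `coroflow_system`
#' @param x state vector at time t (see [initial_state])
#' @param t current time, s
#' @return state vector at t + dt
#' @export
advance_step <- function(sys, x, t) {
  m <- sys$mesh; cf <- sys$config; w <- sys$wall
  dt <- cf$dt; th <- cf$theta
  NC <- sys$NC; NF <- sys$NF
  iP <- sys$iP; iQ <- sys$iQ; iN <- sys$iN
  rho <- w$rho; fr_coef <- w$visc_coeff * w$mu * pi

  Pn <- x[iP]; Qn <- x[iQ]; PNn <- x[iN]
  An <- area_from_pressure(sys, Pn)

  interior <- which(m$ftype == 1L)
  fprox <- which(m$ftype == 2L)
  fdist <- which(m$ftype == 3L)
  froot <- which(m$ftype == 0L)
  lc_i <- m$f_lc[interior]; rc_i <- m$f_rc[interior]
  dx_i <- m$face_dx[interior]
  fl <- m$f_lc[fdist]; fn_d <- m$f_node[fdist]
  fr_ <- m$f_rc[fprox]; fn_p <- m$f_node[fprox]
  h_d <- m$face_dx[fdist] / 2; h_p <- m$face_dx[fprox] / 2

  Qin_new <- waveform_at(sys$boundaries$inflow, t + dt)

  # advection flux at old level (interior faces only)
  Qc_n <- 0.5 * (Qn[left_face(m)] + Qn[right_face(m)])
  Gn <- Qc_n^2 / An
  adv_old <- (Gn[rc_i] - Gn[lc_i]) / dx_i

  pt <- sys$pattern
  lf <- pt$lf; rf <- pt$rf
  vals <- pt$tv
  sl <- pt$slots

  # rhs parts independent of the Picard iterate
  rhs0 <- numeric(sys$NU)
  rhs0[iP] <- -(1 - th) * (Qn[rf] - Qn[lf]) / m$cell_dx
  if (length(fprox))
    rhs0[iQ[fprox]] <- -(1 - th) * (Pn[fr_] - PNn[fn_p]) / h_p
  rhs0[iQ[fdist]] <- -(1 - th) * (PNn[fn_d] - Pn[fl]) / h_d
  rhs0[iQ[froot]] <- Qin_new
  if (sys$use_beds) {
    for (tk in seq_along(sys$terminals)) {
      bed <- sys$boundaries$beds[[sys$terminals[tk]]]
      nk <- sys$term_node_idx[tk]
      P1n <- x[sys$ib1[tk]]; P2n <- x[sys$ib2[tk]]
      Pim_o <- bed_pim_raw(sys, tk, t); Pim_n <- bed_pim_raw(sys, tk, t + dt)
      f1o <- (PNn[nk] - P1n) / bed$Ra - (P1n - P2n) / bed$Rm
      f2o <- (P1n - P2n) / bed$Rm - (P2n - bed$Pv) / bed$Rv
      rhs0[sys$ib1[tk]] <- bed$Ca_bed / dt * P1n + (1 - th) * f1o
      rhs0[sys$ib2[tk]] <- bed$Cim / dt * P2n +
        bed$Cim * (Pim_n - Pim_o) / dt + th * bed$Pv / bed$Rv + (1 - th) * f2o
    }
  }

  xk <- x
  ok <- FALSE
  for (sweep in seq_len(cf$max_picard)) {
    Pmid <- 0.5 * (Pn + xk[iP])
    Amid <- area_from_pressure(sys, Pmid)
    Camid <- m$A0c * (Amid / m$A0c)^(1 - m$bc / 2) / (rho * m$c0c^2)
    nu_c <- m$Gc / (m$A0c * sqrt(Amid))
    # face areas at midpoint (arithmetic mean of neighbours / node pressure)
    Pf <- face_pressure(sys, Pmid, 0.5 * (PNn + xk[iN]))
    Af <- m$A0f * pmax(1 + m$bf * (Pf - w$P0 - w$Pext) /
                         (2 * rho * m$c0f^2), 1e-12)^(2 / m$bf)
    ia <- rho / (Af * dt)
    frc <- fr_coef / Af^2

    # advection at current iterate (CN average with the old level)
    Ak <- area_from_pressure(sys, xk[iP])
    Qc_k <- 0.5 * (xk[iQ][lf] + xk[iQ][rf])
    Gk <- Qc_k^2 / Ak
    adv_mid <- 0.5 * (adv_old + (Gk[rc_i] - Gk[lc_i]) / dx_i)

    # varying matrix slots
    vals[sl$mass_diag] <- Camid / dt
    nuL <- nu_c[lc_i]; nuR <- nu_c[rc_i]
    if (length(interior)) {
      vals[sl$int_diag] <- ia[interior] + th * frc[interior] +
        th * (nuL + nuR) / dx_i^2
      vals[sl$int_fp] <- -th * nuR / dx_i^2
      vals[sl$int_fm] <- -th * nuL / dx_i^2
    }
    if (length(fprox))
      vals[sl$prox_diag] <- ia[fprox] + th * frc[fprox]
    vals[sl$dist_diag] <- ia[fdist] + th * frc[fdist]

    rhs <- rhs0
    rhs[iP] <- rhs[iP] + Camid / dt * Pn
    viscL_old <- (-nuR * (Qn[m$f_fp1[interior]] - Qn[interior]) +
                    nuL * (Qn[interior] - Qn[m$f_fm1[interior]])) / dx_i^2
    rhs[iQ[interior]] <- ia[interior] * Qn[interior] -
      (1 - th) * (frc[interior] * Qn[interior] +
                    (Pn[rc_i] - Pn[lc_i]) / dx_i + viscL_old) - adv_mid
    if (length(fprox))
      rhs[iQ[fprox]] <- rhs[iQ[fprox]] + ia[fprox] * Qn[fprox] -
        (1 - th) * frc[fprox] * Qn[fprox]
    rhs[iQ[fdist]] <- rhs[iQ[fdist]] + ia[fdist] * Qn[fdist] -
      (1 - th) * frc[fdist] * Qn[fdist]
    if (!sys$use_beds) {
      term_nodes <- which(m$node_type[m$node_ids] == "terminal")
      rhs[iN[term_nodes]] <- -sys$boundaries$P_out /
        unlist(sys$boundaries$resistances[
          m$node_ids[term_nodes]], use.names = FALSE)
    }

    M <- Matrix::sparseMatrix(i = pt$ti, j = pt$tj, x = vals,
                              dims = c(sys$NU, sys$NU))
    xnew <- as.numeric(Matrix::solve(M, rhs))
    err <- max(abs(xnew - xk) / sys$scale)
    xk <- xnew
    if (err < cf$picard_tol) { ok <- TRUE; break }
  }
  if (!ok && err > 100 * cf$picard_tol)
    stop(sprintf(
      "Picard iteration not converged at t = %.5f (err %.2e); segment '%s'",
      t, err, m$cell_seg[which.max(abs(xk[iP] - Pn))]))
  check_area_positive(sys, xk[iP], t)
  xk
}

# helpers -------------------------------------------------------------------

# faces are numbered contiguously per segment: cell i has faces f0+i, f0+i+1
left_face <- function(m) m$cell_lf
right_face <- function(m) m$cell_lf + 1L

area_from_pressure <- function(sys, P) {
  m <- sys$mesh; w <- sys$wall
  arg <- 1 + m$bc * (P - w$P0 - w$Pext) / (2 * w$rho * m$c0c^2)
  if (any(arg <= 0)) {
    bad <- which(arg <= 0)[1]
    stop("negative area (tube-law collapse) in segment '",
         m$cell_seg[bad], "'")
  }
  m$A0c * arg^(2 / m$bc)
}

check_area_positive <- function(sys, P, t) {
  m <- sys$mesh; w <- sys$wall
  arg <- 1 + m$bc * (P - w$P0 - w$Pext) / (2 * w$rho * m$c0c^2)
  if (any(arg <= 0)) {
    bad <- which(arg <= 0)[1]
    stop(sprintf("negative area at t = %.5f in segment '%s'",
                 t, m$cell_seg[bad]))
  }
  invisible(TRUE)
}

# pressure interpolated to faces (cells inside, node pressures at node faces)
face_pressure <- function(sys, Pc, Pnode) {
  m <- sys$mesh
  Pf <- numeric(sys$NF)
  it <- which(m$ftype == 1L)
  Pf[it] <- 0.5 * (Pc[m$f_lc[it]] + Pc[m$f_rc[it]])
  ir <- which(m$ftype == 0L)
  Pf[ir] <- Pc[m$f_rc[ir]]
  ip <- which(m$ftype == 2L)
  Pf[ip] <- 0.5 * (Pc[m$f_rc[ip]] + Pnode[m$f_node[ip]])
  id <- which(m$ftype == 3L)
  Pf[id] <- 0.5 * (Pc[m$f_lc[id]] + Pnode[m$f_node[id]])
  Pf
}

bed_pim_raw <- function(sys, tk, t) {
  bed <- sys$boundaries$beds[[sys$terminals[tk]]]
  if (bed$pim_scale == 0 || is.null(sys$boundaries$ventricular)) return(0)
  bed$pim_scale * ventricular_at(sys$boundaries$ventricular, t,
                                 if (bed$side == "left") "left" else "right")
}

#' Run a simulation to a cycle-periodic state
#'
#' Advances whole cardiac cycles of the inflow waveform until the maximum
#' relative change of pressure (all cells, all output times) between
#' consecutive cycles drops below `config$periodic_tol`, or `max_cycles` is
#' reached (recorded as a warning in the result metadata, not fatal).
#' Returns the final cycle sampled at `config$output_dt`.
#'
#' @param network a `coronary_network`
#' @param wall a `wall_params`
#' @param boundaries a `network_boundaries`
#' @param config a `solver_config`
#' @param x0 optional initial state (default [initial_state])
#' @return object of class `corosim_result`: fields `t` (s, one cycle),
#'   `P` (NC x nt, dyn/cm2), `Q` (NF x nt), `A` (NC x nt), the `mesh`,
#'   the advective CFL number of the final cycle (`cfl`), and convergence
#'   metadata
#' @export
run_to_periodic <- function(network, wall, boundaries, config = solver_config(),
                            x0 = NULL) {
  T <- boundaries$inflow$period
  dt <- config$dt
  n_steps <- max(2L, as.integer(round(T / dt)))
  dt <- T / n_steps
  config$dt <- dt              # snap dt to an integer number of steps
  sys <- coroflow_system(network, wall, boundaries, config)
  rec_every <- max(1L, as.integer(round(config$output_dt / dt)))
  rec_steps <- seq(0L, n_steps, by = rec_every)
  if (rec_steps[length(rec_steps)] != n_steps)
    rec_steps <- c(rec_steps, n_steps)
  nt <- length(rec_steps)
  tgrid <- rec_steps * dt

  x <- x0 %||% initial_state(sys)
  Pmat <- matrix(0, sys$NC, nt); Qmat <- matrix(0, sys$NF, nt)
  Nmat <- matrix(0, sys$NN, nt)
  prevP <- NULL; converged <- FALSE; cycles <- 0; delta <- NA_real_
  while (cycles < config$max_cycles) {
    cycles <- cycles + 1
    t0 <- (cycles - 1) * T
    ri <- 1
    Pmat[, 1] <- x[sys$iP]; Qmat[, 1] <- x[sys$iQ]; Nmat[, 1] <- x[sys$iN]
    for (s in seq_len(n_steps)) {
      x <- advance_step(sys, x, t0 + (s - 1) * dt)
      if (s == rec_steps[ri + 1]) {
        ri <- ri + 1
        Pmat[, ri] <- x[sys$iP]; Qmat[, ri] <- x[sys$iQ]
        Nmat[, ri] <- x[sys$iN]
      }
    }
    if (!is.null(prevP)) {
      delta <- max(abs(Pmat - prevP)) / max(abs(Pmat))
      if (delta < config$periodic_tol) { converged <- TRUE; break }
    }
    prevP <- Pmat
  }
  warn <- NULL
  if (!converged) {
    warn <- sprintf("not periodic after %d cycles (delta %.2e)", cycles, delta)
    warning(warn)
  }
  Amat <- apply(Pmat, 2, function(p) area_from_pressure(sys, p))
  # advective CFL number over the final cycle (sanity metadata; the implicit
  # scheme is stable regardless, large values flag accuracy risk)
  m <- sys$mesh
  lf <- left_face(m); rf <- lf + 1L
  Ucell <- abs(Qmat[lf, , drop = FALSE] + Qmat[rf, , drop = FALSE]) / 2 / Amat
  Ccell <- m$c0c * (Amat / m$A0c)^(m$bc / 4)
  cfl <- max((Ucell + Ccell) * dt / m$cell_dx)
  structure(list(t = tgrid, P = Pmat, Q = Qmat, A = Amat, Pnode = Nmat,
                 cfl = cfl,
                 sys = sys, mesh = sys$mesh, network = network,
                 wall = wall, boundaries = boundaries, config = sys$config,
                 period = T, cycles = cycles, converged = converged,
                 cycle_delta = delta, warning = warn, final_state = x),
            class = "corosim_result")
}

#' @export
print.corosim_result <- function(x, ...) {
  cat(sprintf(
    "<corosim_result> %d cells, %d output samples over T = %.3f s; %d cycles (%s)\n",
    nrow(x$P), length(x$t), x$period, x$cycles,
    if (x$converged) sprintf("periodic, delta %.1e", x$cycle_delta)
    else "NOT periodic"))
  invisible(x)
}

#' Pressure (or flow) probe at a point of the network
#'
#' Linear interpolation of the cell-centred pressure field at a fractional
#' position along a segment; constant extrapolation within the first/last
#' half-cell.
#'
#' @param result a `corosim_result`
#' @param segment_id segment id
#' @param fraction axial position as fraction of segment length in [0, 1]
#' @param what "P" (dyn/cm2), "Q" (cm3/s) or "A" (cm2)
#' @return numeric vector over the result's time grid
#' @export
probe_trace <- function(result, segment_id, fraction, what = c("P", "Q", "A")) {
  what <- match.arg(what)
  si <- result$mesh$seg_info[[segment_id]]
  if (is.null(si)) stop("no segment '", segment_id, "' in result")
  xq <- fraction * (si$n * si$dx)
  if (what == "Q") {
    rows <- si$face0 + seq_len(si$n + 1)
    xs <- si$xf
    M <- result$Q[rows, , drop = FALSE]
  } else {
    rows <- si$cell0 + seq_len(si$n)
    xs <- si$xc
    M <- result[[what]][rows, , drop = FALSE]
  }
  apply(M, 2, function(col) stats::approx(xs, col, xout = xq, rule = 2)$y)
}

#' Write a CSV summary of probe traces from a simulation result
#'
#' One row per output time; columns t_s plus P (mmHg) and Q (cm3/s) at each
#' segment's proximal and distal ends. A `# coroflow-result` comment header
#' records convergence metadata and the solver configuration for provenance.
#'
#' @param result a `corosim_result`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_result_csv <- function(result, path) {
  segs <- result$mesh$ord
  df <- data.frame(t_s = result$t)
  for (sid in segs) {
    df[[paste0("P_", sid, "_prox_mmHg")]] <-
      cgs_to_mmhg(probe_trace(result, sid, 0))
    df[[paste0("P_", sid, "_dist_mmHg")]] <-
      cgs_to_mmhg(probe_trace(result, sid, 1))
    df[[paste0("Q_", sid, "_prox")]] <- probe_trace(result, sid, 0, "Q")
    df[[paste0("Q_", sid, "_dist")]] <- probe_trace(result, sid, 1, "Q")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# coroflow-result cycles=%d converged=%s delta=%.3e dt=%g dx_target=%g",
    result$cycles, result$converged, result$cycle_delta,
    result$config$dt, result$config$dx_target), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Steady-state solve of the network (validation harness)
#'
#' Time-independent solution with a constant inflow: flow splits over the
#' tree according to the series/parallel combination of segment friction
#' resistances (Poiseuille-type, R = integral of 22 mu pi / A^2 dx) and the
#' outlet resistances; areas and resistances are updated from the tube law by
#' Picard iteration. Advective momentum is neglected (it vanishes for
#' uniform segments and is second order in the taper otherwise); this is the
#' analytic steady limit of the momentum balance used to validate the time
#' stepper.
#'
#' @param network a `coronary_network`
#' @param wall a `wall_params`
#' @param inflow_Q constant root inflow, cm3/s
#' @param outlet_resistances named vector, one per terminal, dyn s/cm5
#' @param P_out outlet pressure, dyn/cm2 (default 0)
#' @param config a `solver_config` (mesh resolution)
#' @param rigid if TRUE areas stay at A0 (linear resistive limit)
#' @return list: per-segment flows `Q`, cell pressure field `P`, segment
#'   resistances, inlet pressure
#' @export
steady_solve <- function(network, wall, inflow_Q, outlet_resistances,
                         P_out = 0, config = solver_config(), rigid = FALSE) {
  mesh <- build_mesh(network, wall, config)
  ord <- mesh$ord
  fr_coef <- wall$visc_coeff * wall$mu * pi
  Pcell <- stats::setNames(rep(wall$P0 + wall$Pext, mesh$NC), mesh$cell_seg)
  Qseg <- stats::setNames(rep(0, length(ord)), ord)
  for (iter in seq_len(60)) {
    A <- if (rigid) mesh$A0c else {
      arg <- 1 + mesh$bc * (Pcell - wall$P0 - wall$Pext) /
        (2 * wall$rho * mesh$c0c^2)
      mesh$A0c * pmax(arg, 1e-12)^(2 / mesh$bc)
    }
    Rseg <- vapply(ord, function(sid) {
      si <- mesh$seg_info[[sid]]
      ic <- si$cell0 + seq_len(si$n)
      sum(fr_coef / A[ic]^2 * si$dx)
    }, numeric(1))
    # effective downstream resistance, leaves up
    Reff <- stats::setNames(numeric(length(ord)), ord)
    for (sid in rev(ord)) {
      kids <- network$children[[sid]]
      Reff[sid] <- Rseg[sid] + if (is.null(kids))
        outlet_resistances[[sid]] else 1 / sum(1 / Reff[kids])
    }
    # flows root down
    Qs <- stats::setNames(numeric(length(ord)), ord)
    Qs[network$root] <- inflow_Q
    for (sid in ord) {
      kids <- network$children[[sid]]
      if (!is.null(kids)) {
        g <- 1 / Reff[kids]
        Qs[kids] <- Qs[sid] * g / sum(g)
      }
    }
    # pressures: distal node of terminal = P_out + Q*R_term; integrate up
    Pnew <- Pcell
    Pdist <- stats::setNames(numeric(length(ord)), ord)
    for (sid in rev(ord)) {
      kids <- network$children[[sid]]
      Pdist[sid] <- if (is.null(kids))
        P_out + Qs[sid] * outlet_resistances[[sid]]
      else Pdist[kids[1]] + Qs[kids[1]] * Rseg[kids[1]]
      si <- mesh$seg_info[[sid]]
      ic <- si$cell0 + seq_len(si$n)
      drop_per_cell <- fr_coef / A[ic]^2 * si$dx * Qs[sid]
      # cumulative drop from the distal end to each cell centre
      cum <- rev(cumsum(rev(drop_per_cell)))
      Pnew[ic] <- Pdist[sid] + cum - drop_per_cell / 2
    }
    change <- max(abs(Pnew - Pcell)) / max(abs(Pnew), 1)
    Pcell <- Pnew; Qseg <- Qs
    if (change < 1e-12 && iter > 1) break
  }
  root_si <- mesh$seg_info[[network$root]]
  P_in <- Pcell[root_si$cell0 + 1] +
    fr_coef / (if (rigid) mesh$A0c else A)[root_si$cell0 + 1]^2 *
      root_si$dx / 2 * Qseg[network$root]
  list(Q = Qseg, P = Pcell, A = if (rigid) mesh$A0c else A,
       R_segment = Rseg, P_inlet = unname(P_in), mesh = mesh,
       iterations = iter)
}
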