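#' Parametric inflow waveform
#'
#' Two-parameter periodic stand-in for a measured main-pulmonary-artery flow:
#' `q(t) = Q_max * sin^2(pi t / (systole_fraction * T))` during systole and 0
#' during diastole (`shape = "sine2"`), or a constant flow `Q_max`
#' (`shape = "constant"`, used for steady-state checks).
#'
#' @param Q_max peak flow, ml/s (> 0).
#' @param systole_fraction fraction of the cycle in systole, in (0, 1).
#' @param shape `"sine2"` or `"constant"`.
#' @return An object of class `pw_inflow`.
#' @export
inflow_spec <- function(Q_max = 0.5, systole_fraction = 0.45,
                        shape = c("sine2", "constant")) {
  shape <- match.arg(shape)
  stopifnot(Q_max > 0, systole_fraction > 0, systole_fraction < 1)
  structure(list(Q_max = Q_max, systole_fraction = systole_fraction,
                 shape = shape), class = "pw_inflow")
}

#' Evaluate an inflow waveform
#' @param t times, s (vectorized).
#' @param inflow a [inflow_spec()].
#' @param cycle_T cycle length, s.
#' @return Flow, ml/s.
#' @export
inflow_eval <- function(t, inflow, cycle_T) {
  tc <- t %% cycle_T
  if (inflow$shape == "constant") return(rep(inflow$Q_max, length(t)))
  ts <- inflow$systole_fraction * cycle_T
  ifelse(tc < ts, inflow$Q_max * sin(pi * tc / ts)^2, 0)
}

#' Simulation configuration
#'
#' All numerical and physiological settings of the pulse-wave solver. The
#' murine-scale defaults are: cycle length 0.11 s, 32 output samples per
#' cycle, 24 cells per vessel, CFL number 0.5, periodicity tolerance 0.05
#' mmHg, at most 30 cycles. Windkessel nominals distribute a total arterial
#' resistance `wk_total_R` (mmHg s/ml) and compliance `wk_total_C` (ml/mmHg)
#' over the terminal vessels in proportion to r0^3 (flow-weighted), with a
#' fraction `wk_Rp_frac` of each terminal resistance placed proximally.
#'
#' @param cycle_T cardiac cycle length, s.
#' @param m output samples per cycle (>= 2).
#' @param cells_per_vessel spatial cells per vessel.
#' @param cfl CFL number in (0, 1].
#' @param periodicity_tol cycle-to-cycle convergence tolerance, mmHg.
#' @param n_cycles_max maximum cycles before giving up.
#' @param inflow a [inflow_spec()].
#' @param bc_kind `"WK"` or `"ST"` terminal boundary condition.
#' @param p_ref reference (diastolic) pressure, mmHg.
#' @param law pressure-area relationship: `"sqrt"` (default,
#'   `p = p_ref + s(sqrt(A/A0)-1)`) or `"linear"` (`p = p_ref + s(A/A0-1)`).
#' @param fluid a [fluid_properties()].
#' @param wk_total_R,wk_Rp_frac,wk_total_C Windkessel nominal distribution.
#' @param st_n_harmonics harmonics for the structured-tree impedance.
#' @param st_kernel_m samples per cycle of the time-domain impedance kernel.
#' @return An object of class `pw_config`.
#' @export
simulation_config <- function(cycle_T = 0.11, m = 32, cells_per_vessel = 24,
                              cfl = 0.5, periodicity_tol = 0.05,
                              n_cycles_max = 30, inflow = inflow_spec(),
                              bc_kind = c("WK", "ST"), p_ref = 0,
                              law = c("sqrt", "linear"),
                              fluid = fluid_properties(),
                              wk_total_R = 130, wk_Rp_frac = 0.1,
                              wk_total_C = 1e-3,
                              st_n_harmonics = 16, st_kernel_m = 32) {
  bc_kind <- match.arg(bc_kind)
  law <- match.arg(law)
  stopifnot(m >= 2, cfl > 0, cfl <= 1, periodicity_tol > 0,
            cells_per_vessel >= 4, st_n_harmonics >= floor(st_kernel_m / 2))
  structure(list(cycle_T = cycle_T, m = m, cells_per_vessel = cells_per_vessel,
                 cfl = cfl, periodicity_tol = periodicity_tol,
                 n_cycles_max = n_cycles_max, inflow = inflow,
                 bc_kind = bc_kind, p_ref = p_ref, law = law, fluid = fluid,
                 wk_total_R = wk_total_R, wk_Rp_frac = wk_Rp_frac,
                 wk_total_C = wk_total_C, st_n_harmonics = st_n_harmonics,
                 st_kernel_m = st_kernel_m),
            class = "pw_config")
}

#' Pressure from cross-sectional area (tube law)
#'
#' `p = p_ref + stiffness(r0) * (sqrt(A/A0) - 1)` for the default square-root
#' law, or `p = p_ref + stiffness(r0) * (A/A0 - 1)` for the linear-in-area
#' variant. Strictly increasing in A with `p(A0) = p_ref`.
#'
#' @param A area, cm^2 (> 0, vectorized).
#' @param A0 reference area, cm^2.
#' @param stiff Eh/r0, mmHg (e.g. from [stiffness()]).
#' @param p_ref reference pressure, mmHg.
#' @param law `"sqrt"` or `"linear"`.
#' @return Pressure, mmHg.
#' @export
wall_pressure <- function(A, A0, stiff, p_ref = 0, law = c("sqrt", "linear")) {
  law <- match.arg(law)
  if (any(A <= 0) || any(A0 <= 0)) stop("wall_pressure: nonpositive area")
  if (law == "sqrt") p_ref + stiff * (sqrt(A / A0) - 1)
  else p_ref + stiff * (A / A0 - 1)
}

#' Area from pressure (inverse tube law)
#' @inheritParams wall_pressure
#' @param p pressure, mmHg.
#' @return Area, cm^2.
#' @export
wall_area <- function(p, A0, stiff, p_ref = 0, law = c("sqrt", "linear")) {
  law <- match.arg(law)
  if (law == "sqrt") A0 * ((p - p_ref) / stiff + 1)^2
  else A0 * ((p - p_ref) / stiff + 1)
}

#' One Richtmyer step of a single vessel's interior
#'
#' Exposes the solver's two-step Lax-Wendroff update for verification: given
#' node values of area and flow, advances interior nodes one step and returns
#' the half-step mass fluxes, so that total-mass bookkeeping
#' `sum(dA)*dx = -dt*(flux_out - flux_in)` can be checked exactly.
#'
#' @param A,q node values (length `N+1`), cm^2 and ml/s.
#' @param dt,dx step sizes, s and cm.
#' @param r0 reference radius, cm.
#' @param wall a [wall_model()].
#' @param fluid a [fluid_properties()].
#' @param law tube law, `"sqrt"` or `"linear"`.
#' @return List with updated `A`, `q` (boundary nodes unchanged) and
#'   `mass_flux_half`.
#' @export
step_vessel <- function(A, q, dt, dx, r0, wall = wall_model(),
                        fluid = fluid_properties(),
                        law = c("sqrt", "linear")) {
  law <- match.arg(law)
  nu <- if (fluid$mu_is_kinematic) fluid$mu else fluid$mu / fluid$rho
  .pw_step_vessel(A, q, dt, dx, fluid$rho,
                  (fluid$gamma + 2) / (fluid$gamma + 1),
                  2 * pi * nu * (fluid$gamma + 2),
                  stiffness(r0, wall) * 1333.223874,
                  wall$p_ref * 1333.223874, pi * r0^2,
                  if (law == "sqrt") 0L else 1L)
}

#' Solve a bifurcation junction
#'
#' Solves flow conservation `q_p = q_d1 + q_d2` and pressure continuity
#' `p_p = p_d1 = p_d2` together with the outgoing Riemann-invariant
#' extrapolations of the parent and the two daughters, by damped Newton
#' iteration (scaled residual < 1e-10).
#'
#' @param W_parent outgoing invariant `u + Cw*c` of the parent at its distal
#'   end, cm/s.
#' @param W_d1,W_d2 outgoing invariants `u - Cw*c` of the daughters at their
#'   proximal ends.
#' @param r0 length-3 radii (parent, d1, d2), cm.
#' @param wall a [wall_model()] (shared stiffness law).
#' @param fluid a [fluid_properties()].
#' @param law tube law.
#' @param guess optional length-6 start `(A_p, u_p, A_d1, u_d1, A_d2, u_d2)`.
#' @return List with the six boundary values, the final scaled residual and
#'   the iteration count.
#' @export
couple_junction <- function(W_parent, W_d1, W_d2, r0, wall = wall_model(),
                            fluid = fluid_properties(),
                            law = c("sqrt", "linear"), guess = NULL) {
  law <- match.arg(law)
  A0 <- pi * r0^2
  if (is.null(guess)) guess <- c(A0[1], 0, A0[2], 0, A0[3], 0)
  .pw_couple_junction(W_parent, W_d1, W_d2,
                      stiffness(r0, wall) * 1333.223874, A0,
                      rep(wall$p_ref * 1333.223874, 3), fluid$rho,
                      if (law == "sqrt") 0L else 1L, guess)
}

theta_full_names <- function(bc_kind) {
  if (bc_kind == "WK") c("k1", "k2", "k3", "rp", "rd", "cT")
  else c("k1", "k2", "k3", "k1SA", "k2SA", "k3SA", "alpha", "beta", "lrr",
         "rmin")
}

as_full_theta <- function(theta, config) {
  full <- default_parameter_space(config$bc_kind, reduced = FALSE)
  if (length(theta) == 0)
    return(stats::setNames(full$nominal, full$names))
  nm <- names(theta)
  if (is.null(nm)) {
    if (length(theta) != full$d)
      stop("simulate: unnamed theta must have length ", full$d)
    nm <- full$names
  }
  out <- stats::setNames(full$nominal, full$names)
  unknown <- setdiff(nm, full$names)
  if (length(unknown)) stop("simulate: unknown parameter ", unknown[1])
  out[nm] <- as.numeric(theta)
  out
}

terminal_weights <- function(topo) {
  term <- topo$vessels[topo$vessels$id %in% topo$terminal_ids, ]
  w <- term$r0_cm^3 / sum(term$r0_cm^3)
  stats::setNames(w, term$id)
}

#' Run the pulse-wave simulator
#'
#' Solves the 1D haemodynamics system on the vessel network for the given
#' biophysical parameter vector, cycling until the root pressure waveform is
#' periodic (cycle-to-cycle maximum change below `periodicity_tol`) or
#' `n_cycles_max` is reached, and returns the root (main pulmonary artery)
#' inlet pressure sampled at `m` uniform points of the last cycle. The run is
#' fully deterministic.
#'
#' `theta` is a named vector over (a subset of) the model's full parameter
#' space; unnamed entries default to nominal values. Windkessel parameters:
#' `k1, k2, k3` (large-vessel stiffness) and scale factors `rp, rd, cT`.
#' Structured tree: `k1, k2, k3, k1SA, k2SA, k3SA, alpha, beta, lrr, rmin`.
#'
#' @param theta named numeric parameter vector (see Details).
#' @param topo a `pw_network` (e.g. [fixture_network()]).
#' @param config a [simulation_config()].
#' @param probes optional integer matrix (vessel row index, node index,
#'   0-based) of pressure probes recorded at every solver step.
#' @return An object of class `pw_waveform`: list with `t` (s), `p` (mmHg),
#'   `theta`, `converged`, `cycles_used`, `cycle_delta` and (if requested)
#'   `probe_t`, `probe_p`.
#' @export
simulate_waveform <- function(theta, topo = fixture_network("bifurcation3"),
                              config = simulation_config(), probes = NULL) {
  th <- as_full_theta(theta, config)
  df <- topo$vessels
  V <- nrow(df)
  idx <- stats::setNames(seq_len(V) - 1L, df$id)   # 0-based
  parent <- ifelse(is.na(df$parent), -1L, idx[as.character(df$parent)])
  daughters <- matrix(-1L, V, 2)
  for (v in seq_len(V)) {
    dd <- which(!is.na(df$parent) & df$parent == df$id[v])
    if (length(dd) == 2) daughters[v, ] <- as.integer(dd - 1L)
  }
  is_term <- df$id %in% topo$terminal_ids
  term_idx <- rep(-1L, V)
  term_idx[is_term] <- seq_len(sum(is_term)) - 1L

  wallm <- wall_model(th[["k1"]], th[["k2"]], th[["k3"]], config$p_ref)
  stiff <- stiffness(df$r0_cm, wallm)
  fl <- config$fluid
  nu <- if (fl$mu_is_kinematic) fl$mu else fl$mu / fl$rho
  w <- terminal_weights(topo)

  qbar <- if (config$inflow$shape == "constant") config$inflow$Q_max
          else config$inflow$Q_max * config$inflow$systole_fraction / 2

  if (config$bc_kind == "WK") {
    Rp <- config$wk_Rp_frac * config$wk_total_R / w * th[["rp"]]
    Rd <- (1 - config$wk_Rp_frac) * config$wk_total_R / w * th[["rd"]]
    Cv <- config$wk_total_C * w * th[["cT"]]
    pd0 <- qbar * w * Rd                 # capacitor at its DC operating point
    qbuf0 <- numeric(length(w))
    kern <- matrix(0, 1, 1)
  } else {
    st <- structured_tree_params(alpha = th[["alpha"]], beta = th[["beta"]],
                                 lrr = th[["lrr"]], rmin = th[["rmin"]],
                                 k1SA = th[["k1SA"]], k2SA = th[["k2SA"]],
                                 k3SA = th[["k3SA"]])
    term_r <- df$r0_cm[is_term]
    kern <- vapply(term_r, function(r) {
      Z <- structured_tree_impedance(r, st, fl, config$cycle_T,
                                     config$st_n_harmonics)
      impedance_kernel(Z, config$st_kernel_m)
    }, numeric(config$st_kernel_m))
    Rp <- Rd <- Cv <- pd0 <- numeric(sum(is_term))
    qbuf0 <- qbar * unname(w)            # mean flow split by r0^3
  }

  if (is.null(probes)) probes <- matrix(0L, 0, 2)
  storage.mode(probes) <- "integer"

  res <- .pw_run_simulation(
    df$length_cm, df$r0_cm, as.integer(parent), daughters, term_idx,
    stiff, config$p_ref, if (config$law == "sqrt") 0L else 1L,
    fl$rho, nu, fl$gamma, config$cycle_T, as.integer(config$m),
    as.integer(config$cells_per_vessel), config$cfl, config$periodicity_tol,
    as.integer(config$n_cycles_max),
    if (config$inflow$shape == "constant") 1L else 0L,
    config$inflow$Q_max, config$inflow$systole_fraction,
    if (config$bc_kind == "WK") 0L else 1L,
    unname(Rp), unname(Rd), unname(Cv), kern, unname(pd0), qbuf0, probes)

  structure(list(t = res$t, p = res$p, theta = th,
                 converged = res$converged, cycles_used = res$cycles_used,
                 cycle_delta = res$cycle_delta[!is.na(res$cycle_delta)],
                 probe_t = res$probe_t, probe_p = res$probe_p),
            class = "pw_waveform")
}

#' Simulate a design of parameter vectors
#'
#' Runs [simulate_waveform()] for every row of `Theta` and assembles the
#' m x n waveform matrix `F` (column j is the waveform at row j of `Theta`).
#' Failures are recorded per column rather than dropped.
#'
#' @param Theta n x d matrix with parameter names as column names.
#' @param topo a `pw_network`.
#' @param config a [simulation_config()].
#' @return An object of class `pw_waveset`: list with `F` (m x n), `t`,
#'   `Theta`, `converged` (logical n), `errors` (list, NULL where fine).
#' @export
batch_simulate <- function(Theta, topo = fixture_network("bifurcation3"),
                           config = simulation_config()) {
  Theta <- as.matrix(Theta)
  n <- nrow(Theta)
  F <- matrix(NA_real_, config$m, n)
  conv <- logical(n)
  errors <- vector("list", n)
  tgrid <- NULL
  for (j in seq_len(n)) {
    wf <- tryCatch(simulate_waveform(Theta[j, ], topo, config),
                   error = function(e) e)
    if (inherits(wf, "error")) {
      errors[[j]] <- conditionMessage(wf)
    } else {
      F[, j] <- wf$p
      conv[j] <- wf$converged
      tgrid <- wf$t
    }
  }
  nfail <- sum(!vapply(errors, is.null, logical(1)))
  if (nfail > 0)
    warning("batch_simulate: ", nfail, " of ", n, " simulations failed")
  structure(list(F = F, t = tgrid, Theta = Theta, converged = conv,
                 errors = errors), class = "pw_waveset")
}

#' Write / read a waveform set as CSV (+ JSON sidecar)
#'
#' The CSV has a `time_s` column followed by one pressure column per design
#' point; convergence flags and dimensions go to `<path>.json`.
#'
#' @param ws a `pw_waveset`.
#' @param path output CSV path.
#' @export
write_waveset <- function(ws, path) {
  df <- data.frame(time_s = ws$t)
  for (j in seq_len(ncol(ws$F))) df[[paste0("p_mmHg_", j)]] <- ws$F[, j]
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(n = ncol(ws$F), m = nrow(ws$F),
                            converged = ws$converged),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
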