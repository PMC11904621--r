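# mmHg <-> CGS (dyn/cm^2) conversion used at solver/impedance boundaries only
MMHG <- 1333.223874

# Bessel J0/J1 for complex argument by power series. The Womersley arguments
# arising from murine radii and <= ~20 cycle harmonics have |z| < 15, where
# the alternating series still retains ~9 significant digits.
besselJ01_complex <- function(z) {
  if (Mod(z) > 30)
    stop("besselJ01_complex: |z| too large for series evaluation")
  zz <- -(z / 2)^2
  t0 <- 1 + 0i; t1 <- 1 + 0i
  s0 <- t0; s1 <- t1
  for (k in 1:90) {
    t0 <- t0 * zz / k^2
    t1 <- t1 * zz / (k * (k + 1))
    s0 <- s0 + t0
    s1 <- s1 + t1
    if (Mod(t0) < 1e-18 * Mod(s0) && Mod(t1) < 1e-18 * Mod(s1)) break
  }
  list(J0 = s0, J1 = s1 * z / 2)
}

#' Three-element Windkessel parameters
#'
#' Per-terminal nominal proximal resistance `Rp_nominal`, distal resistance
#' `Rd_nominal` (mmHg s/ml) and compliance `C_nominal` (ml/mmHg), together
#' with dimensionless global scale factors `rp`, `rd`, `cT` that multiply
#' them. Effective values are `Rp_nominal*rp` etc.
#'
#' @param Rp_nominal,Rd_nominal,C_nominal per-terminal nominal values (> 0).
#' @param rp,rd,cT global scale factors (> 0).
#' @return An object of class `pw_wk`.
#' @export
windkessel_params <- function(Rp_nominal, Rd_nominal, C_nominal,
                              rp = 1, rd = 1, cT = 1) {
  stopifnot(Rp_nominal > 0, Rd_nominal > 0, C_nominal > 0,
            rp > 0, rd > 0, cT > 0)
  structure(list(Rp_nominal = Rp_nominal, Rd_nominal = Rd_nominal,
                 C_nominal = C_nominal, rp = rp, rd = rd, cT = cT),
            class = "pw_wk")
}

#' Advance a Windkessel outlet over a flow history
#'
#' Integrates the RCR capacitor state `dp_d/dt = (q - p_d/Rd_eff)/C_eff` over
#' a uniformly sampled terminal flow history and returns the outlet pressure
#' `p = p_d + q*Rp_eff + p_ref` at each sample. The capacitor update is the
#' trapezoidal (Crank-Nicolson) rule, which is unconditionally stable and
#' second-order accurate; `method = "backward_euler"` selects the first-order
#' implicit update instead.
#'
#' @param q_t terminal flow history, ml/s, sampled at spacing `dt`.
#' @param wk a [windkessel_params()].
#' @param dt time step, s.
#' @param p_ref reference pressure added to the outlet, mmHg.
#' @param p_d0 initial capacitor (distal) pressure, mmHg.
#' @param method `"trapezoid"` (default) or `"backward_euler"`.
#' @return Numeric vector of outlet pressures, same length as `q_t`.
#' @export
windkessel_outlet <- function(q_t, wk, dt, p_ref = 0, p_d0 = 0,
                              method = c("trapezoid", "backward_euler")) {
  method <- match.arg(method)
  stopifnot(dt > 0, length(q_t) >= 1)
  Rp <- wk$Rp_nominal * wk$rp
  Rd <- wk$Rd_nominal * wk$rd
  C  <- wk$C_nominal * wk$cT
  if (Rp <= 0 || Rd <= 0 || C <= 0)
    stop("windkessel_outlet: nonpositive effective R or C")
  n <- length(q_t)
  pd <- numeric(n)
  prev <- p_d0
  qprev <- q_t[1]
  for (i in seq_len(n)) {
    if (method == "trapezoid") {
      a <- dt / (2 * C)
      pd[i] <- (prev * (1 - a / Rd) + a * (qprev + q_t[i])) / (1 + a / Rd)
    } else {
      pd[i] <- (prev + dt * q_t[i] / C) / (1 + dt / (Rd * C))
    }
    qprev <- q_t[i]
    prev <- pd[i]
  }
  pd + q_t * Rp + p_ref
}

#' Structured-tree parameters
#'
#' Geometry and wall stiffness of the self-similar asymmetric binary tree
#' closing each terminal vessel: daughter radius scale factors `alpha` (large)
#' and `beta` (small), length-to-radius ratio `lrr`, minimum radius `rmin`
#' (cm) below which no daughter is spawned, and the small-artery stiffness law
#' parameters `k1SA` (mmHg), `k2SA` (1/cm), `k3SA` (mmHg).
#'
#' @param alpha,beta scale factors, `0 < beta <= alpha < 1`.
#' @param lrr length-to-radius ratio (> 0).
#' @param rmin minimum radius, cm (> 0).
#' @param k1SA,k2SA,k3SA stiffness law for the small arteries.
#' @return An object of class `pw_st`.
#' @export
structured_tree_params <- function(alpha = 0.88, beta = 0.62, lrr = 20,
                                   rmin = 0.003,
                                   k1SA = 1e4, k2SA = 30, k3SA = 2e4) {
  if (!(alpha < 1)) stop("structured_tree_params: alpha >= 1 would not terminate")
  stopifnot(beta > 0, beta <= alpha, lrr > 0, rmin > 0, k3SA > 0)
  structure(list(alpha = alpha, beta = beta, lrr = lrr, rmin = rmin,
                 k1SA = k1SA, k2SA = k2SA, k3SA = k3SA),
            class = "pw_st")
}

#' Enumerate a structured tree
#'
#' Builds the self-similar tree rooted at `root_radius`: a vessel of radius r
#' has length `lrr*r` and daughters of radii `alpha*r` and `beta*r`; a
#' daughter is spawned only if its radius is at least `rmin`. Self-similar
#' subtrees are shared: every vessel corresponds to an exponent pair (i, j)
#' with radius `root_radius * alpha^i * beta^j`, so the tree is summarized by
#' the table of reachable exponent pairs and their path multiplicities.
#'
#' @param root_radius cm (> 0).
#' @param st a [structured_tree_params()].
#' @return List with `segments` (data.frame: `i`, `j`, `radius`, `length`,
#'   `count`, `terminal`), `n_vessels` (total, counting multiplicity),
#'   `n_terminal` and `max_generation`.
#' @export
build_structured_tree <- function(root_radius, st) {
  stopifnot(root_radius > 0)
  if (st$alpha >= 1) stop("build_structured_tree: alpha >= 1 would not terminate")
  imax <- if (st$alpha * root_radius < st$rmin) 0L else
    floor(log(st$rmin / root_radius) / log(st$alpha))
  jmax <- if (st$beta * root_radius < st$rmin) 0L else
    floor(log(st$rmin / root_radius) / log(st$beta))
  seg <- expand.grid(i = 0:imax, j = 0:jmax)
  seg$radius <- root_radius * st$alpha^seg$i * st$beta^seg$j
  seg <- seg[seg$radius >= st$rmin | (seg$i == 0 & seg$j == 0), , drop = FALSE]
  # multiplicity of (i, j) = number of distinct root->vessel paths
  seg$count <- choose(seg$i + seg$j, seg$i)
  seg$length <- st$lrr * seg$radius
  seg$terminal <- (seg$radius * st$alpha < st$rmin) &
                  (seg$radius * st$beta < st$rmin)
  # a daughter may exist on one side only; "terminal" means no daughter at all
  seg <- seg[order(seg$i + seg$j, seg$i), , drop = FALSE]
  rownames(seg) <- NULL
  list(segments = seg,
       n_vessels = sum(seg$count),
       n_terminal = sum(seg$count[seg$terminal]),
       max_generation = max(seg$i + seg$j))
}

st_stiffness_cgs <- function(r, st) {
  (st$k1SA * exp(-st$k2SA * r) + st$k3SA) * MMHG
}

#' Root input impedance of a structured tree
#'
#' Frequency-domain input impedance of the structured tree at the harmonics
#' `0..n_harmonics` of the cardiac cycle. Each segment is modelled by the
#' linearized Womersley-profile wave solution; the vessel compliance comes
#' from the small-artery stiffness law evaluated at the segment radius; leaf
#' segments see zero distal impedance; impedances combine by series transfer
#' along segments and parallel admittance addition at bifurcations.
#' Self-similar subtrees are memoized by radius exponent pair.
#'
#' At zero frequency the impedance reduces to the Poiseuille resistance
#' `8*mu*L/(pi*r^4)` composed through the tree, which is evaluated in closed
#' form.
#'
#' @param root_radius cm.
#' @param st a [structured_tree_params()].
#' @param fluid a [fluid_properties()].
#' @param cycle_T cardiac cycle length, s.
#' @param n_harmonics number of positive harmonics (>= 1).
#' @return An object of class `pw_impedance`: list with `frequencies` (Hz,
#'   length `n_harmonics + 1` including 0), `Z` (complex, mmHg s/ml),
#'   `dc_resistance`, `cycle_T`, `n_harmonics`.
#' @export
structured_tree_impedance <- function(root_radius, st, fluid = fluid_properties(),
                                      cycle_T = 0.11, n_harmonics = 16) {
  stopifnot(n_harmonics >= 1, root_radius > 0, cycle_T > 0)
  if (st$alpha >= 1) stop("structured_tree_impedance: alpha >= 1")
  nu <- if (fluid$mu_is_kinematic) fluid$mu else fluid$mu / fluid$rho
  mu_dyn <- nu * fluid$rho
  rho <- fluid$rho
  omega <- 2 * pi * (1:n_harmonics) / cycle_T
  memo <- new.env(parent = emptyenv())

  z_tree <- function(i, j, gen) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    r <- root_radius * st$alpha^i * st$beta^j
    L <- st$lrr * r
    # distal impedance: parallel admittances of whichever daughters exist
    da <- st$alpha * r >= st$rmin
    db <- st$beta * r >= st$rmin
    if (da && db) {
      Z1 <- z_tree(i + 1, j, gen + 1); Z2 <- z_tree(i, j + 1, gen + 1)
      ZL <- 1 / (1 / Z1 + 1 / Z2)
    } else if (da) {
      ZL <- z_tree(i + 1, j, gen + 1)
    } else if (db) {
      ZL <- z_tree(i, j + 1, gen + 1)
    } else {
      ZL <- rep(0 + 0i, n_harmonics + 1)
    }
    A0 <- pi * r^2
    CA <- 1.5 * A0 / st_stiffness_cgs(r, st)    # linearized area compliance
    Z <- complex(n_harmonics + 1)
    Z[1] <- 8 * mu_dyn * L / (pi * r^4) + ZL[1] # Poiseuille DC limit
    for (k in seq_len(n_harmonics)) {
      w0 <- r * sqrt(omega[k] / nu)
      zeta <- complex(modulus = w0, argument = 3 * pi / 4)  # i^{3/2} w0
      B <- besselJ01_complex(zeta)
      FJ <- 2 * B$J1 / (zeta * B$J0)
      cc <- sqrt(A0 * (1 - FJ) / (rho * CA))
      g <- CA * cc
      s <- sin(omega[k] * L / cc); cs <- cos(omega[k] * L / cc)
      Z[k + 1] <- (1i * s / g + ZL[k + 1] * cs) / (cs + 1i * g * ZL[k + 1] * s)
    }
    if (any(!is.finite(Z)))
      stop(sprintf(
        "structured_tree_impedance: overflow at generation %d (radius %.4g cm)",
        gen, r))
    memo[[key]] <- Z
    Z
  }

  Zroot <- z_tree(0L, 0L, 0L) / MMHG   # cgs -> mmHg s/ml
  structure(list(frequencies = (0:n_harmonics) / cycle_T,
                 Z = Zroot, dc_resistance = Re(Zroot[1]),
                 cycle_T = cycle_T, n_harmonics = n_harmonics),
            class = "pw_impedance")
}

#' Periodic impedance outlet: pressure from one cycle of flow
#'
#' Treats `q_cycle` as one full cardiac cycle of terminal flow sampled
#' uniformly, multiplies its Fourier coefficients by the terminal impedance
#' harmonic by harmonic, and transforms back: `p = F^-1(Z(w) Q(w)) + p_ref`.
#' The impedance spectrum is extended to negative frequencies by conjugate
#' symmetry so the result is real.
#'
#' @param q_cycle flow samples over exactly one cycle, ml/s.
#' @param Z a `pw_impedance` with at least `floor(length(q_cycle)/2)`
#'   harmonics.
#' @param p_ref reference pressure, mmHg.
#' @return Pressure trace, mmHg, same length as `q_cycle`.
#' @export
impedance_outlet <- function(q_cycle, Z, p_ref = 0) {
  M <- length(q_cycle)
  if (M < 2) stop("impedance_outlet: flow history shorter than one cycle")
  if (Z$n_harmonics < floor(M / 2))
    stop("impedance_outlet: impedance has too few harmonics for ", M,
         " samples")
  idx <- c(0:floor(M / 2), if (M > 2) -((ceiling(M / 2) - 1):1))
  Zfull <- ifelse(idx >= 0, Z$Z[abs(idx) + 1], Conj(Z$Z[abs(idx) + 1]))
  qhat <- stats::fft(q_cycle) / M
  Re(stats::fft(qhat * Zfull, inverse = TRUE)) + p_ref
}

#' Real time-domain impedance kernel for periodic convolution
#'
#' Converts a harmonic impedance spectrum into the length-`M` real kernel
#' `z_j` such that `p_n = dT * sum_j z_j q_{n-j}` reproduces the
#' frequency-domain relation for cycle-periodic flow (`dT = cycle_T / M`).
#' Used by the pulse-wave solver's structured-tree outlet.
#'
#' @param Z a `pw_impedance`.
#' @param M samples per cycle, requires `Z$n_harmonics >= floor(M/2)`.
#' @return Numeric kernel of length `M` (mmHg/ml).
#' @export
impedance_kernel <- function(Z, M) {
  if (Z$n_harmonics < floor(M / 2))
    stop("impedance_kernel: need at least floor(M/2) harmonics")
  idx <- c(0:floor(M / 2), if (M > 2) -((ceiling(M / 2) - 1):1))
  Zfull <- ifelse(idx >= 0, Z$Z[abs(idx) + 1], Conj(Z$Z[abs(idx) + 1]))
  Re(stats::fft(Zfull, inverse = TRUE)) / Z$cycle_T
}

#' Export an impedance spectrum to CSV
#'
#' Writes columns `harmonic, freq_hz, re_z, im_z` (mmHg s/ml).
#'
#' @param Z a `pw_impedance`.
#' @param path output CSV path.
#' @export
write_impedance <- function(Z, path) {
  utils::write.csv(data.frame(harmonic = 0:Z$n_harmonics,
                              freq_hz = Z$frequencies,
                              re_z = Re(Z$Z), im_z = Im(Z$Z)),
                   path, row.names = FALSE)
  invisible(path)
}
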