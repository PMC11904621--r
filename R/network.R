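#' Blood fluid properties
#'
#' Container for the fluid constants entering the 1D momentum equation:
#' blood density `rho` (g/ml), viscosity `mu` and the power coefficient
#' `gamma` of the assumed axial velocity profile (blunt profile for large
#' `gamma`). The friction term of the momentum balance is
#' `-2*pi*mu*(gamma+2)/rho * q/A`; with `mu_is_kinematic = TRUE` the division
#' by `rho` is dropped and `mu` is taken as the kinematic viscosity directly
#' (see the methods vignette for why both conventions are provided).
#'
#' @param rho blood density, g/ml.
#' @param mu blood viscosity (cm^2/s as printed in murine studies).
#' @param gamma velocity-profile power coefficient (dimensionless).
#' @param mu_is_kinematic logical; if `TRUE` the friction coefficient is
#'   `2*pi*mu*(gamma+2)` with `mu` read as kinematic viscosity.
#' @return An object of class `pw_fluid`.
#' @export
fluid_properties <- function(rho = 1.055, mu = 0.049, gamma = 9,
                             mu_is_kinematic = FALSE) {
  stopifnot(rho > 0, mu > 0, gamma > 0)
  structure(list(rho = rho, mu = mu, gamma = gamma,
                 mu_is_kinematic = isTRUE(mu_is_kinematic)),
            class = "pw_fluid")
}

#' Vessel wall stiffness model
#'
#' Exponential-plus-baseline model of the wall material parameter Eh/r0 as a
#' function of the reference radius, `Eh/r0 = k1*exp(-k2*r0) + k3`: stiffness
#' increases sharply for small vessel radii. All pressures in mmHg.
#'
#' @param k1 mmHg, amplitude of the exponential term (>= 0).
#' @param k2 1/cm, radial decay rate.
#' @param k3 mmHg, baseline stiffness (> 0).
#' @param p_ref reference (diastolic) transmural pressure, mmHg.
#' @return An object of class `pw_wall`.
#' @export
wall_model <- function(k1 = 1e4, k2 = 30, k3 = 2e4, p_ref = 0) {
  stopifnot(k1 >= 0, k3 > 0)
  structure(list(k1 = k1, k2 = k2, k3 = k3, p_ref = p_ref),
            class = "pw_wall")
}

#' Evaluate the wall stiffness law
#'
#' @param r0 reference radius, cm (> 0); vectorized.
#' @param wall a [wall_model()].
#' @return Eh/r0 in mmHg.
#' @export
stiffness <- function(r0, wall) {
  if (any(r0 <= 0)) stop("stiffness: reference radius must be positive")
  wall$k1 * exp(-wall$k2 * r0) + wall$k3
}

new_network <- function(df) {
  df <- df[order(df$id), , drop = FALSE]
  rownames(df) <- NULL
  root <- df$id[is.na(df$parent)]
  kids <- split(df$id[!is.na(df$parent)], factor(df$parent[!is.na(df$parent)],
                                                 levels = df$id))
  terminal <- vapply(as.character(df$id),
                     function(i) length(kids[[i]]) == 0L, logical(1))
  structure(list(vessels = df, root_id = root,
                 terminal_ids = df$id[terminal]),
            class = "pw_network")
}

validate_network <- function(net) {
  df <- net$vessels
  if (anyDuplicated(df$id))
    stop("network: duplicated vessel id ", df$id[duplicated(df$id)][1])
  if (any(df$length_cm <= 0) || any(df$r0_cm <= 0))
    stop("network: nonpositive length or radius for vessel id ",
         df$id[df$length_cm <= 0 | df$r0_cm <= 0][1])
  root <- df$id[is.na(df$parent)]
  if (length(root) != 1L)
    stop("network: expected exactly one root, found ", length(root))
  known <- df$parent[!is.na(df$parent)]
  bad <- setdiff(known, df$id)
  if (length(bad))
    stop("network: parent id ", bad[1], " does not exist")
  ndaught <- table(factor(known, levels = df$id))
  if (any(!ndaught %in% c(0L, 2L)))
    stop("network: vessel id ", names(ndaught)[!ndaught %in% c(0L, 2L)][1],
         " has ", ndaught[!ndaught %in% c(0L, 2L)][1],
         " daughters (0 or 2 required)")
  # reachability from the root implies acyclicity given unique parents
  reach <- root
  repeat {
    nxt <- df$id[!is.na(df$parent) & df$parent %in% reach & !df$id %in% reach]
    if (!length(nxt)) break
    reach <- c(reach, nxt)
  }
  orphan <- setdiff(df$id, reach)
  if (length(orphan))
    stop("network: vessel id ", orphan[1],
         " is not reachable from the root (cycle or disconnection)")
  net
}

#' Read a vessel network from a topology CSV
#'
#' The file has header `id,parent,length_cm,r0_cm`; `parent` is empty for the
#' root. Daughters are inferred from the parent column. The resulting tree is
#' validated: single root, 0 or 2 daughters per vessel, no cycles, positive
#' geometry; violations raise an error naming the offending vessel id.
#'
#' @param path CSV file path.
#' @return A `pw_network`: list with `vessels` (data.frame), `root_id`,
#'   `terminal_ids`.
#' @export
load_topology <- function(path) {
  df <- utils::read.csv(path, colClasses = c(id = "integer",
                                             parent = "integer",
                                             length_cm = "numeric",
                                             r0_cm = "numeric"))
  validate_network(new_network(df))
}

#' Write a vessel network to a topology CSV
#'
#' Inverse of [load_topology()]; a write/read round trip reproduces the
#' network exactly.
#'
#' @param net a `pw_network`.
#' @param path output CSV path.
#' @export
write_topology <- function(net, path) {
  utils::write.csv(net$vessels, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Built-in murine-scale fixture networks
#'
#' Deterministic toy geometries used throughout the package in place of a
#' full image-based pulmonary tree: a single vessel, a 3-vessel bifurcation
#' (root L = 0.5 cm, r0 = 0.05 cm; daughters L = 0.35 cm, r0 = 0.035 cm) and
#' a 7-vessel symmetric tree of depth 3.
#'
#' @param kind one of `"single"`, `"bifurcation3"`, `"tree7"`.
#' @return A `pw_network`.
#' @export
fixture_network <- function(kind = c("bifurcation3", "single", "tree7")) {
  kind <- match.arg(kind)
  df <- switch(kind,
    single = data.frame(id = 1L, parent = NA_integer_,
                        length_cm = 0.5, r0_cm = 0.05),
    bifurcation3 = data.frame(
      id = 1:3, parent = c(NA_integer_, 1L, 1L),
      length_cm = c(0.5, 0.35, 0.35), r0_cm = c(0.05, 0.035, 0.035)),
    tree7 = data.frame(
      id = 1:7, parent = c(NA_integer_, 1L, 1L, 2L, 2L, 3L, 3L),
      length_cm = c(0.5, 0.35, 0.35, 0.25, 0.25, 0.25, 0.25),
      r0_cm = c(0.05, 0.035, 0.035, 0.025, 0.025, 0.025, 0.025)))
  validate_network(new_network(df))
}

#' Biophysical parameter space
#'
#' Ordered, bounded, named parameter hyper-rectangle over which designs are
#' drawn and emulators are trained. Bounds and nominal values are in physical
#' units (mmHg, 1/cm, cm, or dimensionless scale factors).
#'
#' @param names character vector of parameter labels.
#' @param lower,upper numeric bounds, elementwise `lower < upper`.
#' @param nominal baseline values within the bounds.
#' @return An object of class `pw_space` with element `d = length(names)`.
#' @export
parameter_space <- function(names, lower, upper, nominal) {
  stopifnot(length(names) == length(lower), length(lower) == length(upper),
            length(nominal) == length(names))
  if (any(lower >= upper)) stop("parameter_space: need lower < upper")
  if (any(nominal < lower | nominal > upper))
    stop("parameter_space: nominal outside bounds")
  structure(list(names = as.character(names),
                 lower = as.numeric(lower), upper = as.numeric(upper),
                 nominal = as.numeric(nominal), d = length(names)),
            class = "pw_space")
}

#' Default parameter spaces for the two outflow models
#'
#' Windkessel (`"WK"`): stiffness parameters k1, k2, k3 at +/- 50% of their
#' nominal values (1e4 mmHg, 30 /cm, 2e4 mmHg) plus global proximal/distal
#' resistance and compliance scale factors rp, rd, cT in \[0.5, 2\].
#' Structured tree (`"ST"`): the three large-vessel stiffness parameters plus
#' small-artery stiffness k1SA, k2SA, k3SA (+/- 50% of the same nominals),
#' daughter radius scale factors alpha in \[0.80, 0.92\], beta in
#' \[0.55, 0.70\], length-to-radius ratio lrr in \[10, 50\] and minimum radius
#' rmin in \[0.001, 0.01\] cm. `reduced = TRUE` restricts to the influential
#' subsets used for emulation: \{k1, k2, rp, rd, cT\} (WK, d = 5) and
#' \{k1, k2, alpha, lrr\} (ST, d = 4), the remaining parameters being fixed at
#' their nominal values at simulation time.
#'
#' @param model `"WK"` or `"ST"`.
#' @param reduced logical; return the reduced (screened) subset.
#' @return A `pw_space`.
#' @export
default_parameter_space <- function(model = c("WK", "ST"), reduced = FALSE) {
  model <- match.arg(model)
  stiff <- list(names = c("k1", "k2", "k3"),
                lower = c(0.5e4, 15, 1.0e4),
                upper = c(1.5e4, 45, 3.0e4),
                nominal = c(1e4, 30, 2e4))
  if (model == "WK") {
    sp <- parameter_space(
      c(stiff$names, "rp", "rd", "cT"),
      c(stiff$lower, 0.5, 0.5, 0.5),
      c(stiff$upper, 2.0, 2.0, 2.0),
      c(stiff$nominal, 1, 1, 1))
    keep <- c("k1", "k2", "rp", "rd", "cT")
  } else {
    sp <- parameter_space(
      c(stiff$names, "k1SA", "k2SA", "k3SA", "alpha", "beta", "lrr", "rmin"),
      c(stiff$lower, stiff$lower, 0.80, 0.55, 10, 0.001),
      c(stiff$upper, stiff$upper, 0.92, 0.70, 50, 0.01),
      c(stiff$nominal, stiff$nominal, 0.88, 0.62, 20, 0.003))
    keep <- c("k1", "k2", "alpha", "lrr")
  }
  if (reduced) subset_space(sp, keep) else sp
}

#' Read / write a parameter space as JSON
#'
#' The file records names, bounds, nominal values and (optionally) units, so
#' a design or study can be reproduced from its sidecar alone.
#'
#' @param space a `pw_space`.
#' @param path JSON file path.
#' @param units optional character vector of unit labels.
#' @export
write_space <- function(space, path, units = NULL) {
  jsonlite::write_json(list(names = space$names, lower = space$lower,
                            upper = space$upper, nominal = space$nominal,
                            units = units),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_space
#' @export
read_space <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  parameter_space(x$names, x$lower, x$upper, x$nominal)
}

#' Restrict a parameter space to a subset of its parameters
#'
#' @param space a `pw_space`.
#' @param names parameters to keep, in the order given.
#' @return A `pw_space` over the subset.
#' @export
subset_space <- function(space, names) {
  idx <- match(names, space$names)
  if (anyNA(idx)) stop("subset_space: unknown parameter ",
                       names[is.na(idx)][1])
  parameter_space(space$names[idx], space$lower[idx], space$upper[idx],
                  space$nominal[idx])
}

#' Expand a (possibly reduced) parameter vector to the full space
#'
#' Missing parameters are filled with the full space's nominal values.
#'
#' @param theta named numeric vector, or unnamed vector ordered as `space`.
#' @param space the `pw_space` that `theta` lives in.
#' @param full_space the full `pw_space` expected by the simulator.
#' @return Named numeric vector over `full_space$names`.
#' @export
expand_theta <- function(theta, space, full_space) {
  th <- stats::setNames(as.numeric(theta), space$names)
  out <- stats::setNames(full_space$nominal, full_space$names)
  out[names(th)] <- th
  out
}
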