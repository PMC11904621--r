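# Model archives. All numeric payload goes through JSON at full precision
# (17 significant digits), which round-trips IEEE doubles exactly, so a
# loaded model reproduces predictions bitwise on the same platform. A CSV of
# the main factor matrices is written alongside for human inspection.

space_to_list <- function(space) {
  list(names = space$names, lower = space$lower, upper = space$upper,
       nominal = space$nominal)
}

space_from_list <- function(x) {
  parameter_space(x$names, x$lower, x$upper, x$nominal)
}

spec_to_list <- function(spec) {
  list(family = spec$family, ard = spec$ard, jitter = spec$jitter,
       period = spec$period)
}

spec_from_list <- function(x, hyp = NULL) {
  kernel_spec(x$family, ard = x$ard, jitter = x$jitter, period = x$period,
              hyp = hyp)
}

#' Archive a trained GP model
#'
#' Serializes a `pw_gp_scores` or `pw_gp_time` model (kernel family,
#' hyperparameters, jitter, standardization constants, training inputs and
#' solve factors) to `<path>.json`, with the factor matrices additionally
#' dumped to `<path>.csv`. [read_gp()] restores a model whose predictions
#' are bitwise identical on the same platform.
#'
#' @param model a `pw_gp_scores` or `pw_gp_time`.
#' @param path base path (without extension).
#' @return `path`, invisibly.
#' @export
write_gp <- function(model, path) {
  if (inherits(model, "pw_gp_time")) {
    payload <- list(
      kind = "gp_time",
      spec_theta = spec_to_list(model$spec_theta),
      spec_time = spec_to_list(model$spec_time),
      hyp_theta = model$hyp_theta, hyp_time = model$hyp_time,
      X = model$X, Tm = as.vector(model$Tm), Alpha = model$Alpha,
      mu = model$mu, sd = model$sd, space = space_to_list(model$space),
      cycle_T = model$cycle_T, tgrid = model$tgrid, nll = model$nll)
    utils::write.csv(model$Alpha, paste0(path, ".csv"), row.names = FALSE)
  } else {
    payload <- list(
      kind = "gp_scores",
      spec = spec_to_list(model$spec),
      X = model$X, space = space_to_list(model$space),
      components = lapply(model$components, function(cj)
        if (cj$constant) list(constant = TRUE, mu = cj$mu, sd = cj$sd)
        else list(constant = FALSE, mu = cj$mu, sd = cj$sd, hyp = cj$hyp,
                  alpha = cj$alpha, nll = cj$nll)))
    al <- vapply(model$components,
                 function(cj) if (cj$constant) rep(NA_real_, nrow(model$X))
                              else cj$alpha, numeric(nrow(model$X)))
    utils::write.csv(al, paste0(path, ".csv"), row.names = FALSE)
  }
  jsonlite::write_json(payload, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' @rdname write_gp
#' @export
read_gp <- function(path) {
  x <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  if (x$kind == "gp_time") {
    structure(list(
      spec_theta = spec_from_list(x$spec_theta),
      spec_time = spec_from_list(x$spec_time),
      hyp_theta = as.list(x$hyp_theta), hyp_time = as.list(x$hyp_time),
      X = as.matrix(x$X), Tm = matrix(x$Tm, ncol = 1),
      Alpha = as.matrix(x$Alpha), mu = x$mu, sd = x$sd,
      space = space_from_list(x$space), cycle_T = x$cycle_T,
      tgrid = x$tgrid, nll = x$nll), class = "pw_gp_time")
  } else {
    comps <- lapply(x$components, function(cj)
      if (isTRUE(cj$constant)) list(constant = TRUE, mu = cj$mu, sd = cj$sd)
      else list(constant = FALSE, mu = cj$mu, sd = cj$sd,
                hyp = as.list(cj$hyp), alpha = cj$alpha, nll = cj$nll))
    structure(list(components = comps, spec = spec_from_list(x$spec),
                   space = space_from_list(x$space), X = as.matrix(x$X)),
              class = "pw_gp_scores")
  }
}

#' Archive a polynomial-chaos model
#'
#' Coefficient matrix as CSV, multi-index set / bounds / mode as JSON.
#'
#' @param model a `pw_pce`.
#' @param path base path (without extension).
#' @return `path`, invisibly.
#' @export
write_pce <- function(model, path) {
  utils::write.csv(model$Z, paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(Z = model$Z, indices = model$basis$indices,
                            d = model$basis$d, K = model$basis$K,
                            mode = model$mode, rank = model$rank,
                            space = space_to_list(model$space)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_pce
#' @export
read_pce <- function(path) {
  x <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  basis <- build_basis(x$d, x$K)
  stopifnot(identical(unname(basis$indices), unname(as.matrix(x$indices))))
  structure(list(Z = as.matrix(x$Z), basis = basis,
                 space = space_from_list(x$space), mode = x$mode,
                 rank = x$rank), class = "pw_pce")
}

#' Write Sobol indices to CSV
#'
#' Columns: parameter, first-order S, total-order ST, generalized flag.
#'
#' @param sobol a `pw_sobol`.
#' @param path CSV path.
#' @export
write_sobol <- function(sobol, path) {
  utils::write.csv(data.frame(parameter = names(sobol$first_order),
                              S = unname(sobol$first_order),
                              ST = unname(sobol$total_order),
                              generalized = sobol$generalized),
                   path, row.names = FALSE)
  invisible(path)
}
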