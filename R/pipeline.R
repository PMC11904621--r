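#' Waveform mean squared error
#'
#' `MSE = mean((f - g)^2)` over the m output samples.
#'
#' @param f,g equal-length waveforms.
#' @return Scalar MSE.
#' @export
mse_waveform <- function(f, g) {
  if (length(f) != length(g)) stop("mse_waveform: length mismatch")
  mean((f - g)^2)
}

#' Relative square error of a parameter estimate
#'
#' `RSE = sum_l ((theta_true_l - theta_hat_l) / theta_true_l)^2`.
#'
#' @param theta_true,theta_hat equal-length parameter vectors; all entries of
#'   `theta_true` must be nonzero.
#' @return Scalar RSE.
#' @export
rse_params <- function(theta_true, theta_hat) {
  if (length(theta_true) != length(theta_hat))
    stop("rse_params: length mismatch")
  if (any(theta_true == 0))
    stop("rse_params: zero true parameter; relative error undefined")
  sum(((theta_true - theta_hat) / theta_true)^2)
}

#' Per-parameter absolute relative errors
#'
#' `ARE_l = |theta_true_l - theta_hat_l| / |theta_true_l|`.
#'
#' @inheritParams rse_params
#' @return Vector of d AREs.
#' @export
are_params <- function(theta_true, theta_hat) {
  if (length(theta_true) != length(theta_hat))
    stop("are_params: length mismatch")
  if (any(theta_true == 0))
    stop("are_params: zero true parameter; relative error undefined")
  abs((theta_true - theta_hat) / theta_true)
}

#' Candidate hyperparameter grids for the four emulator variants
#'
#' For GP.PCA: parameter-kernel families crossed with jitter values. For
#' GP.time: (parameter kernel, time kernel) pairs crossed with jitters. For
#' the PCE variants: polynomial orders. Defaults give the full printed grids;
#' pass shorter vectors for desk-scale runs.
#'
#' @param gp_kernels parameter-kernel families.
#' @param gp_time_kernels time-kernel families.
#' @param jitters jitter values, subset of 1e-4 ... 1e-9.
#' @param pce_orders polynomial orders K.
#' @param ard automatic relevance determination for parameter kernels.
#' @return List of per-variant candidate lists.
#' @export
candidate_grid <- function(gp_kernels = c("SE", "Matern32", "Matern52", "NN"),
                           gp_time_kernels = c("Periodic", "Matern32",
                                               "Matern52"),
                           jitters = 10^-(4:9), pce_orders = 1:6,
                           ard = FALSE) {
  gp_pca <- list()
  for (k in gp_kernels) for (j in jitters)
    gp_pca[[length(gp_pca) + 1]] <- list(id = sprintf("%s.j%g", k, j),
                                         kernel = k, jitter = j, ard = ard)
  gp_time <- list()
  for (k in gp_kernels) for (kt in gp_time_kernels) for (j in jitters)
    gp_time[[length(gp_time) + 1]] <-
      list(id = sprintf("(%s,%s).j%g", k, kt, j), kernel = k,
           time_kernel = kt, jitter = j, ard = ard)
  pce <- lapply(pce_orders, function(K) list(id = sprintf("K%d", K), K = K))
  list(GP.PCA = gp_pca, GP.time = gp_time, PCE.PCA = pce, PCE.time = pce)
}

#' Train one emulator variant
#'
#' Dispatches to the GP or PCE fitting routines. `variant` is one of
#' `"GP.time"`, `"GP.PCA"`, `"PCE.time"`, `"PCE.PCA"`; `candidate` is one
#' element of the corresponding [candidate_grid()] list. PCA variants require
#' a fitted `pw_pca` basis.
#'
#' @param variant emulator variant name.
#' @param Theta n x d training design (physical units).
#' @param F m x n training waveform matrix.
#' @param candidate hyperparameter candidate (see [candidate_grid()]).
#' @param space the `pw_space`.
#' @param basis a `pw_pca` (PCA variants).
#' @param cycle_T cardiac cycle length, s.
#' @param n_restarts GP multistart count.
#' @return An object of class `pw_emulator`.
#' @export
train_emulator <- function(variant, Theta, F, candidate, space, basis = NULL,
                           cycle_T = 0.11, n_restarts = 5) {
  variant <- match.arg(variant, c("GP.time", "GP.PCA", "PCE.time", "PCE.PCA"))
  F <- as.matrix(F)
  model <- switch(variant,
    GP.PCA = {
      if (is.null(basis)) stop("train_emulator: PCA variant needs a basis")
      spec <- kernel_spec(candidate$kernel, ard = isTRUE(candidate$ard),
                          jitter = candidate$jitter)
      fit_gp_scores(Theta, basis$scores, spec, space,
                    n_restarts = n_restarts)
    },
    GP.time = {
      spec_th <- kernel_spec(candidate$kernel, ard = isTRUE(candidate$ard),
                             jitter = candidate$jitter)
      spec_t <- kernel_spec(candidate$time_kernel, jitter = candidate$jitter,
                            period = 1)
      fit_gp_time(Theta, F, spec_th, spec_t, space, cycle_T = cycle_T,
                  n_restarts = n_restarts)
    },
    PCE.time = {
      bs <- build_basis(space$d, candidate$K)
      fit_pce(Theta, t(F), bs, space, mode = "time")
    },
    PCE.PCA = {
      if (is.null(basis)) stop("train_emulator: PCA variant needs a basis")
      bs <- build_basis(space$d, candidate$K)
      fit_pce(Theta, t(basis$scores), bs, space, mode = "pca")
    })
  structure(list(variant = variant, model = model, basis = basis,
                 candidate = candidate, space = space, cycle_T = cycle_T),
            class = "pw_emulator")
}

#' Predict waveforms from a trained emulator
#'
#' Always returns full time-domain waveforms: PCA-variant score predictions
#' are reconstructed through the stored basis.
#'
#' @param emulator a `pw_emulator`.
#' @param theta_new parameter vector or matrix of rows.
#' @return m x n_new waveform matrix.
#' @export
predict_emulator <- function(emulator, theta_new) {
  switch(emulator$variant,
    GP.PCA = predict_gp(emulator$model, theta_new, emulator$basis),
    GP.time = predict_gp(emulator$model, theta_new),
    PCE.time = predict_pce(emulator$model, theta_new),
    PCE.PCA = predict_pce(emulator$model, theta_new, emulator$basis))
}

#' Select the winning candidate from validation errors
#'
#' Argmin of the median validation MSE; ties (to within `tie_tol` relative)
#' are broken by the smaller interquartile range, then by candidate order.
#'
#' @param mse_by_candidate named list (or list) of per-validation-point MSE
#'   vectors, one entry per candidate.
#' @param tie_tol relative tolerance for declaring medians tied.
#' @return List with `index`, `id` (names if present), `median`, `iqr`.
#' @export
select_hyperparameters <- function(mse_by_candidate, tie_tol = 1e-12) {
  if (!length(mse_by_candidate))
    stop("select_hyperparameters: empty report")
  med <- vapply(mse_by_candidate, stats::median, numeric(1))
  iqr <- vapply(mse_by_candidate, stats::IQR, numeric(1))
  best_med <- min(med)
  tied <- which(med <= best_med * (1 + tie_tol) + tie_tol)
  win <- tied[order(iqr[tied])][1]
  list(index = unname(win), id = names(mse_by_candidate)[win],
       median = unname(med[win]), iqr = unname(iqr[win]),
       medians = med, iqrs = iqr)
}

#' Forward-emulation error report
#'
#' Per-test-point MSE between simulator waveforms and emulator predictions
#' (PCA-variant predictions are reconstructed to the time domain first).
#'
#' @param emulator a `pw_emulator`.
#' @param Theta_test rows of test parameters.
#' @param F_test m x n_test simulator waveforms.
#' @return List with `mse` (vector), `median`, `iqr`.
#' @export
run_forward_evaluation <- function(emulator, Theta_test, F_test) {
  F_test <- as.matrix(F_test)
  pred <- predict_emulator(emulator, Theta_test)
  if (nrow(pred) != nrow(F_test))
    stop("run_forward_evaluation: emulator/test dimension mismatch")
  mse <- vapply(seq_len(ncol(F_test)),
                function(j) mse_waveform(F_test[, j], pred[, j]), numeric(1))
  list(mse = mse, median = stats::median(mse), iqr = stats::IQR(mse))
}

#' Emulator-based inverse problem with multistart optimization
#'
#' Minimizes the MSE between the emulator prediction and a target waveform
#' over the parameter bounds with a gradient-based bound-constrained
#' optimizer (L-BFGS-B) from `n_starts` starting points drawn by a seeded
#' maximin Latin-hypercube rule. Deterministic for a fixed seed.
#'
#' @param emulator a `pw_emulator`.
#' @param target_waveform m-vector.
#' @param space the `pw_space` (finite bounds).
#' @param n_starts number of starts.
#' @param seed integer seed for the start draw.
#' @return An object of class `pw_inverse`: `theta_hat`, `objective`,
#'   `starts` (data.frame with per-start audit trail), `chosen_start`.
#' @export
invert_waveform <- function(emulator, target_waveform, space, n_starts = 20,
                            seed = 1) {
  d <- space$d
  obj <- function(th) {
    mse_waveform(drop(predict_emulator(emulator, th)), target_waveform)
  }
  U <- withr::with_seed(seed, lhs::maximinLHS(n_starts, d))
  starts <- sweep(sweep(U, 2, space$upper - space$lower, `*`), 2,
                  space$lower, `+`)
  recs <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    fit <- tryCatch(
      stats::optim(starts[s, ], obj, method = "L-BFGS-B",
                   lower = space$lower, upper = space$upper,
                   control = list(maxit = 200, factr = 1e4)),
      error = function(e) NULL)
    recs[[s]] <- if (is.null(fit))
      list(ok = FALSE, value = Inf, par = rep(NA_real_, d))
    else list(ok = TRUE, value = fit$value, par = fit$par)
  }
  vals <- vapply(recs, function(r) r$value, numeric(1))
  if (all(!vapply(recs, function(r) r$ok, logical(1))))
    stop("invert_waveform: all ", n_starts, " starts failed")
  best <- which.min(vals)
  audit <- data.frame(start = seq_len(n_starts),
                      converged = vapply(recs, function(r) r$ok, logical(1)),
                      objective = vals)
  for (l in seq_len(d)) {
    audit[[paste0("start_", space$names[l])]] <- starts[, l]
    audit[[paste0("hat_", space$names[l])]] <-
      vapply(recs, function(r) r$par[l], numeric(1))
  }
  structure(list(theta_hat = stats::setNames(recs[[best]]$par, space$names),
                 objective = vals[best], starts = audit,
                 chosen_start = best),
            class = "pw_inverse")
}

#' Retain parameters with large generalized total-order Sobol index
#'
#' @param sobol a `pw_sobol`.
#' @param threshold retention threshold on the generalized total-order index.
#' @return Character vector of retained parameter names.
#' @export
screen_parameters <- function(sobol, threshold = 0.05) {
  names(sobol$total_order)[sobol$total_order >= threshold]
}

#' Run the full emulator-comparison study
#'
#' End-to-end pipeline: Sobol design, batch simulation, PCA reduction,
#' training of the requested emulator variants over their candidate grids,
#' hyperparameter selection on the validation block (lowest median MSE),
#' forward evaluation on the test block, and inverse parameter estimation on
#' (a subset of) the test waveforms with a final simulator re-run at each
#' estimate for simulator-based error metrics. Deterministic for a fixed
#' seed.
#'
#' @param space a `pw_space` (typically a reduced subset, see
#'   [default_parameter_space()]).
#' @param topo a `pw_network`.
#' @param sim_config a [simulation_config()].
#' @param n_train,n_valid,n_test design block sizes.
#' @param variants emulator variants to compare.
#' @param candidates a [candidate_grid()] (defaults to a desk-scale grid).
#' @param q number of principal components.
#' @param n_invert number of test waveforms to invert (first `n_invert`).
#' @param n_starts multistart count for inversion.
#' @param seed integer seed (inversion starts; all other stages are
#'   deterministic by construction).
#' @param n_restarts GP hyperparameter multistarts.
#' @return An object of class `pw_study`: design, waveforms, basis, and per
#'   variant the validation selection, forward error report and inverse
#'   results.
#' @export
run_study <- function(space = default_parameter_space("WK", reduced = TRUE),
                      topo = fixture_network("bifurcation3"),
                      sim_config = simulation_config(),
                      n_train = 20, n_valid = 20, n_test = 20,
                      variants = c("GP.time", "GP.PCA", "PCE.time",
                                   "PCE.PCA"),
                      candidates = candidate_grid(gp_kernels = "SE",
                                                  gp_time_kernels = "Periodic",
                                                  jitters = 1e-6,
                                                  pce_orders = 1:3),
                      q = 5, n_invert = n_test, n_starts = 20, seed = 1,
                      n_restarts = 5) {
  variants <- match.arg(variants, several.ok = TRUE)
  design <- make_design(space, n_train, n_valid, n_test)
  ws <- batch_simulate(design$Theta, topo, sim_config)
  if (anyNA(ws$F))
    stop("run_study: simulation stage failed for ",
         sum(colSums(is.na(ws$F)) > 0), " design points")
  seg <- design$segment
  F_tr <- ws$F[, seg == "train", drop = FALSE]
  F_va <- ws$F[, seg == "valid", drop = FALSE]
  F_te <- ws$F[, seg == "test", drop = FALSE]
  Th_tr <- design_block(design, "train")
  Th_va <- design_block(design, "valid")
  Th_te <- design_block(design, "test")
  basis <- fit_pca(F_tr, q = q)
  cycle_T <- sim_config$cycle_T

  full_space <- default_parameter_space(sim_config$bc_kind, reduced = FALSE)
  out <- list(design = design, waves = ws, basis = basis, variants = list(),
              space = space, sim_config = sim_config)
  for (v in variants) {
    cands <- candidates[[v]]
    if (is.null(cands) || !length(cands))
      stop("run_study: no candidates for variant ", v)
    val_mse <- list()
    fits <- list()
    for (ci in seq_along(cands)) {
      em <- withCallingHandlers(
        train_emulator(v, Th_tr, F_tr, cands[[ci]], space, basis, cycle_T,
                       n_restarts = n_restarts),
        warning = function(w) invokeRestart("muffleWarning"))
      fits[[ci]] <- em
      val_mse[[cands[[ci]]$id]] <-
        run_forward_evaluation(em, Th_va, F_va)$mse
    }
    sel <- select_hyperparameters(val_mse)
    winner <- fits[[sel$index]]
    fwd <- run_forward_evaluation(winner, Th_te, F_te)

    inv <- list()
    ninv <- min(n_invert, ncol(F_te))
    for (j in seq_len(ninv)) {
      ir <- invert_waveform(winner, F_te[, j], space, n_starts = n_starts,
                            seed = seed + j)
      th_full <- expand_theta(ir$theta_hat, space, full_space)
      sim_hat <- simulate_waveform(th_full, topo, sim_config)
      inv[[j]] <- list(
        test_index = j,
        theta_hat = ir$theta_hat,
        emulator_mse = ir$objective,
        simulator_mse = mse_waveform(F_te[, j], sim_hat$p),
        rse = rse_params(Th_te[j, ], ir$theta_hat),
        are = are_params(Th_te[j, ], ir$theta_hat),
        chosen_start = ir$chosen_start)
    }
    out$variants[[v]] <- list(
      validation = val_mse, selection = sel, winner = winner,
      forward = fwd,
      inverse = inv,
      inverse_simulator_mse = vapply(inv, `[[`, numeric(1), "simulator_mse"),
      inverse_rse = vapply(inv, `[[`, numeric(1), "rse"))
  }
  structure(out, class = "pw_study")
}
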