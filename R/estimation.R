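#' Experimental time-course datasets
#'
#' A dataset is a tibble with a `time_h` column and one column per measured
#' species (canonical names, mM); empty cells are `NA` and are skipped, never
#' imputed. At least two non-missing values per species are required.
#'
#' @param tbl Data frame with `time_h` plus measured species columns.
#' @param label Provenance label.
#' @return A `tbl_df` of class `abe_dataset`.
#' @export
abe_dataset <- function(tbl, label = "unlabelled") {
  tbl <- as_tibble(tbl)
  if (!"time_h" %in% names(tbl)) abort("Dataset needs a `time_h` column.")
  meas <- setdiff(names(tbl), "time_h")
  bad <- setdiff(meas, abe_species())
  if (length(bad)) {
    abort(paste0("Unknown species column(s): ", paste(bad, collapse = ", ")))
  }
  if (length(meas) == 0L) abort("Dataset has no measured species.")
  if (any(!is.finite(tbl$time_h)) || any(tbl$time_h < 0)) {
    abort("Sample times must be finite and non-negative.")
  }
  if (is.unsorted(tbl$time_h, strictly = TRUE)) {
    abort("Sample times must be strictly increasing.")
  }
  for (sp in meas) {
    if (sum(!is.na(tbl[[sp]])) < 2L) {
      abort(paste0("Species ", sp, " needs at least 2 measured time points."))
    }
  }
  structure(tbl, label = label, class = c("abe_dataset", class(tbl)))
}

measured_species <- function(dataset) setdiff(names(dataset), "time_h")

#' Per-species scaling weights
#'
#' Diagonal weights for the least-squares objective, chosen so that species
#' measured on different concentration scales contribute discrepancies of
#' comparable magnitude: `w_i = 1 / max_t |C_i^meas(t)|^2`. A species whose
#' measurements are all zero gets weight 0, with a warning.
#'
#' @param dataset An [abe_dataset].
#' @return Named numeric weights, one per measured species.
#' @export
#' @examples
#' d <- abe_dataset(tibble::tibble(time_h = c(0, 10), G = c(10, 10)))
#' scaling_weights(d)   # 1/10^2
scaling_weights <- function(dataset) {
  meas <- measured_species(dataset)
  w <- vapply(meas, function(sp) {
    m <- max(abs(dataset[[sp]]), na.rm = TRUE)
    if (m == 0) {
      warn(paste0("Species ", sp, " is measured as all-zero; weight set to 0."))
      0
    } else 1 / m^2
  }, numeric(1))
  w
}

# weighted residual vector sqrt(w_i) * (pred - meas), missing cells skipped;
# on solver failure returns a large flat penalty so optimizers can continue
weighted_residuals <- function(params, dataset, weights,
                               rtol = 1e-8, atol = 1e-10) {
  meas <- measured_species(dataset)
  tmax <- max(dataset$time_h)
  pred <- tryCatch(
    {
      traj <- simulate_batch(attr(dataset, "initial") %||% abe_initial("shinto"),
                             params, t_end = max(tmax, 1e-6),
                             times = sort(unique(c(0, dataset$time_h))),
                             rtol = rtol, atol = atol)
      states_at(traj, dataset$time_h)
    },
    abekin_solver_error = function(e) NULL,
    error = function(e) NULL
  )
  n <- sum(vapply(meas, function(sp) sum(!is.na(dataset[[sp]])), integer(1)))
  if (is.null(pred)) {
    return(structure(rep(1e6, n), failed = TRUE))
  }
  res <- unlist(lapply(meas, function(sp) {
    ok <- !is.na(dataset[[sp]])
    sqrt(weights[[sp]]) * (pred[[sp]][ok] - dataset[[sp]][ok])
  }))
  structure(res, failed = FALSE)
}

#' Weighted least-squares objective
#'
#' The scalar `1/2 * sum_t e(t)' W e(t)` with `e_i(t)` the difference
#' between predicted and measured concentration of species i at sample time
#' t, and W the diagonal [scaling_weights()]. Missing cells contribute
#' nothing. If the simulation fails at the supplied parameters the objective
#' returns a large penalty (flagged in the `"failed"` attribute) rather than
#' erroring, which keeps optimizers alive.
#'
#' @param params An [abe_parameters] set.
#' @param dataset An [abe_dataset]; its `initial` attribute (a state vector)
#'   gives the simulation's initial condition.
#' @param weights Named per-species weights; default [scaling_weights()].
#' @return Non-negative scalar with attribute `failed`.
#' @export
fit_objective <- function(params, dataset, weights = scaling_weights(dataset)) {
  r <- weighted_residuals(params, dataset, weights)
  structure(0.5 * sum(r^2), failed = attr(r, "failed"))
}

#' Fit kinetic parameters to a time course
#'
#' Bounded nonlinear least squares on the weighted objective, using
#' Levenberg-Marquardt with box constraints (`minpack.lm::nls.lm`). Only the
#' parameters named in `free` are estimated; all others stay at their values
#' in `start`. Optional seeded multi-start draws additional starting points
#' log-uniformly within the bounds and keeps the best solution.
#'
#' Default bounds are `[start/100, start*100]` around the starting values.
#'
#' @param dataset An [abe_dataset] with an `initial` attribute (state vector
#'   used to simulate); [generate_synthetic_dataset()] sets it
#'   automatically.
#' @param start An [abe_parameters] set of starting (and fixed) values.
#' @param free Character vector of flat parameter names to estimate,
#'   e.g. `c("V1", "V10", "V14")`; see [param_vector()].
#' @param lower,upper Named bounds on the free parameters (defaults
#'   start/100 and start*100).
#' @param n_starts Number of starts (1 = start point only).
#' @param seed Seed for the multi-start draws.
#' @param control Passed to [minpack.lm::nls.lm.control()].
#' @return An object of class `abe_fit`: list with elements `params` (fitted
#'   set), `objective`, `pearson` (per-species correlation tibble),
#'   `residuals`, `at_bounds` (logical per free parameter), `diagnostics`.
#' @export
fit_parameters <- function(dataset, start, free,
                           lower = NULL, upper = NULL,
                           n_starts = 1L, seed = 1L,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 100, epsfcn = 1e-6)) {
  stopifnot(inherits(dataset, "abe_dataset"))
  theta0 <- param_vector(start)[free]
  if (any(is.na(theta0))) {
    abort(paste0("Unknown free parameter(s): ",
                 paste(free[is.na(theta0)], collapse = ", ")))
  }
  if (is.null(lower)) lower <- theta0 / 100
  if (is.null(upper)) upper <- theta0 * 100
  lower <- rep_len(lower, length(free)); upper <- rep_len(upper, length(free))
  if (any(lower <= 0) || any(lower > upper)) {
    abort("Bounds must satisfy 0 < lower <= upper.")
  }
  if (any(theta0 < lower) || any(theta0 > upper)) {
    abort("Starting values must lie within the bounds.")
  }
  weights <- scaling_weights(dataset)
  f0 <- fit_objective(start, dataset, weights)
  if (isTRUE(attr(f0, "failed"))) {
    abort("Simulation fails at the starting parameters; nothing to fit.")
  }

  resid_fn <- function(theta) {
    th <- setNames(pmin(pmax(theta, lower), upper), free)
    weighted_residuals(set_params(start, th), dataset, weights)
  }

  starts <- list(theta0)
  if (n_starts > 1L) {
    set.seed(seed)
    for (k in seq_len(n_starts - 1L)) {
      starts[[k + 1L]] <- exp(runif(length(free), log(lower), log(upper)))
    }
  }

  best <- NULL
  for (th in starts) {
    res <- if (all(lower == upper)) {
      list(par = lower, deviance = sum(resid_fn(lower)^2),
           niter = 0L, info = 0L, message = "degenerate bounds")
    } else {
      minpack.lm::nls.lm(par = th, lower = lower, upper = upper,
                         fn = resid_fn, control = control)
    }
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }

  theta_hat <- setNames(as.numeric(best$par), free)
  fitted <- set_params(start, theta_hat)
  traj <- simulate_batch(attr(dataset, "initial") %||% abe_initial("shinto"),
                         fitted, t_end = max(dataset$time_h))
  structure(list(
    params = fitted,
    free = free,
    estimate = theta_hat,
    start = theta0,
    objective = 0.5 * best$deviance,
    pearson = pearson_by_species(traj, dataset),
    residuals = weighted_residuals(fitted, dataset, weights),
    at_bounds = theta_hat <= lower * (1 + 1e-8) | theta_hat >= upper / (1 + 1e-8),
    lower = setNames(lower, free), upper = setNames(upper, free),
    diagnostics = list(niter = best$niter, info = best$info,
                       message = best$message, n_starts = n_starts, seed = seed)
  ), class = "abe_fit")
}

#' Per-species Pearson correlation of prediction and measurement
#'
#' The goodness-of-fit statistic reported for each measured species: the
#' Pearson correlation between the model prediction (interpolated at the
#' sample times) and the measurements. Constant measurements have no defined
#' correlation and are reported as `NA`.
#'
#' @param trajectory An `abe_trajectory` covering all sample times.
#' @param dataset An [abe_dataset].
#' @return Tibble with columns `species`, `r`, `n`.
#' @export
pearson_by_species <- function(trajectory, dataset) {
  meas <- measured_species(dataset)
  pred <- states_at(trajectory, dataset$time_h)
  purrr::map_dfr(meas, function(sp) {
    ok <- !is.na(dataset[[sp]])
    x <- dataset[[sp]][ok]; y <- pred[[sp]][ok]
    r <- if (length(unique(x)) < 2L || length(unique(y)) < 2L) NA_real_
         else cor(x, y)
    tibble(species = sp, r = r, n = sum(ok))
  })
}

#' @export
print.abe_fit <- function(x, ...) {
  cat("<abe_fit> ", length(x$free), " free parameter(s), objective ",
      signif(x$objective, 6), "\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' Tidy a parameter fit
#'
#' @param x An `abe_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per free parameter (`term`, `estimate`,
#'   `start`, `lower`, `upper`, `at_bound`). `glance()`: a one-row summary
#'   (`objective`, `n_free`, `niter`, `converged`).
#' @method tidy abe_fit
#' @export
tidy.abe_fit <- function(x, ...) {
  tibble(term = x$free,
         estimate = unname(x$estimate),
         start = unname(x$start),
         lower = unname(x$lower), upper = unname(x$upper),
         at_bound = unname(x$at_bounds))
}

#' @rdname tidy.abe_fit
#' @method glance abe_fit
#' @export
glance.abe_fit <- function(x, ...) {
  tibble(objective = x$objective,
         n_free = length(x$free),
         niter = x$diagnostics$niter %||% NA_integer_,
         converged = (x$diagnostics$info %||% 0L) %in% 1:4)
}
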