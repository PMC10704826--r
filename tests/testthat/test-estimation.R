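fitA <- abe_fit("A")

test_that("scaling weights equalise species measured on different scales", {
  d <- abe_dataset(tibble::tibble(time_h = c(0, 10), G = c(10, 10)))
  expect_equal(unname(scaling_weights(d)), 0.01)
  d2 <- abe_dataset(tibble::tibble(time_h = c(0, 10),
                                   G = c(1, 0.5), BuOH = c(100, 50)))
  w <- scaling_weights(d2)
  # equal relative discrepancies contribute equally after weighting
  expect_equal(w[["G"]] * (0.1 * 1)^2, w[["BuOH"]] * (0.1 * 100)^2)
  d3 <- abe_dataset(tibble::tibble(time_h = c(0, 10), Lac = c(0, 0)))
  expect_warning(w3 <- scaling_weights(d3), "all-zero")
  expect_equal(unname(w3), 0)
  expect_error(abe_dataset(tibble::tibble(time_h = numeric(0))), "species")
})

test_that("objective is half the weighted sum of squared discrepancies", {
  # exact prediction except a +2 mM error at one sample, weight 0.25
  traj <- simulate_batch(abe_initial("shinto"), fitA, t_end = 10)
  pred <- states_at(traj, c(0, 10))
  meas <- tibble::tibble(time_h = c(0, 10), G = pred$G + c(0, 2))
  d <- abe_dataset(meas)
  attr(d, "initial") <- abe_initial("shinto")
  obj <- fit_objective(fitA, d, weights = c(G = 0.25))
  expect_equal(as.numeric(obj), 0.5 * 0.25 * 4, tolerance = 1e-6)
  # linear in the weights
  obj2 <- fit_objective(fitA, d, weights = c(G = 0.5))
  expect_equal(as.numeric(obj2), 2 * as.numeric(obj), tolerance = 1e-6)
})

test_that("objective is invariant to species and time-point ordering", {
  d <- generate_synthetic_dataset(fitA, cv = 0.05, seed = 5)
  w <- scaling_weights(d)
  o1 <- fit_objective(fitA, d, w)
  shuffled <- d[, c("time_h", rev(setdiff(names(d), "time_h")))]
  d2 <- abe_dataset(shuffled)
  attr(d2, "initial") <- attr(d, "initial")
  expect_equal(as.numeric(fit_objective(fitA, d2, w)), as.numeric(o1))
})

test_that("noise-free self-generated data refits to a near-zero objective", {
  d <- generate_synthetic_dataset(fitA, cv = 0, floor = 0, seed = 1)
  expect_lt(as.numeric(fit_objective(fitA, d)), 1e-10)
})

test_that("per-species Pearson matches the hand formula", {
  traj <- simulate_batch(abe_initial("shinto"), fitA, t_end = 30)
  times <- c(0, 10, 20, 30)
  pred <- states_at(traj, times)
  # perfect agreement
  d <- abe_dataset(tibble::tibble(time_h = times, BuOH = pred$BuOH))
  expect_equal(pearson_by_species(traj, d)$r, 1)
  # perfect anti-correlation
  d2 <- abe_dataset(tibble::tibble(time_h = times, BuOH = -pred$BuOH + 50))
  expect_equal(pearson_by_species(traj, d2)$r, -1)
  # four-point example against the explicit formula
  y <- c(5, 9, 20, 28)
  d3 <- abe_dataset(tibble::tibble(time_h = times, BuOH = y))
  x <- pred$BuOH
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_by_species(traj, d3)$r, r_hand)
  # constant measurements have no defined correlation
  d4 <- abe_dataset(tibble::tibble(time_h = times, BuOH = rep(7, 4)))
  expect_true(is.na(pearson_by_species(traj, d4)$r))
})

test_that("noise-free recovery of the key maximum rates is within 5%", {
  d <- generate_synthetic_dataset(fitA, cv = 0, floor = 0, seed = 1)
  truth <- param_vector(fitA)[c("V1", "V10", "V14")]
  start <- set_params(fitA, truth * 1.5)
  fit <- fit_parameters(d, start, free = c("V1", "V10", "V14"))
  expect_true(all(abs(fit$estimate - truth) / truth < 0.05))
  expect_true(glance(fit)$converged)
})

test_that("degenerate point bounds return the point itself", {
  d <- generate_synthetic_dataset(fitA, cv = 0, seed = 2)
  v0 <- param_vector(fitA)[["V1"]]
  start <- set_params(fitA, c(V1 = v0 * 2))
  fit <- fit_parameters(d, start, free = "V1", lower = v0 * 2, upper = v0 * 2)
  expect_equal(unname(fit$estimate), v0 * 2)
  expect_gt(fit$objective, 0)
  # a start outside the box is a configuration error
  expect_error(fit_parameters(d, fitA, free = "V1",
                              lower = v0 * 2, upper = v0 * 3),
               "within the bounds")
})

test_that("tightening bounds never decreases the optimal objective", {
  d <- generate_synthetic_dataset(fitA, cv = 0.05, seed = 3)
  v0 <- param_vector(fitA)[["V1"]]
  start <- set_params(fitA, c(V1 = v0 * 2))
  wide <- fit_parameters(d, start, free = "V1",
                         lower = v0 / 10, upper = v0 * 10)
  # narrow band that excludes the wide optimum
  narrow <- fit_parameters(d, start, free = "V1",
                           lower = v0 * 1.5, upper = v0 * 3)
  expect_gte(narrow$objective, wide$objective - 1e-10)
  expect_true(narrow$at_bounds[["V1"]])
})
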