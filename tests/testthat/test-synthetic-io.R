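fitA <- abe_fit("A")

test_that("packaged parameter fixtures pin every published table cell", {
  A <- abe_fit("A")
  expect_equal(A$V,  c(9.89, 41.10, 148.27, 14.23, 6.22e-2, 166.00, 5.40e-3,
                       144.91, 2.18, 100.23, 7.63e-1, 6.35, NA, 44.43, 3.55,
                       44.76, 91.59, 4.84, 26.27))
  expect_equal(A$kA, c(11.54, 4.0e-4, 4.91e-2, 154.19, 494.70, 0.31, 111.61,
                       0.85, 85.45, 3.63e-1, 46.31, 0.11, 5.06e-2, 7.42e-1,
                       4.30, 2.43e-1, 2.85, 12.66, 6.0e-1))
  expect_equal(A$kB, c(89.50, NA, NA, NA, NA, NA, NA, 12.77, NA, NA, 26.27,
                       144.58, NA, 2.40, 53.62, NA, 2.36, NA, 28.45))
  expect_equal(A$kC, c(2.56, rep(NA, 14), 2.56, NA, 2.56, 105.51))
  B <- abe_fit("B")
  expect_equal(B$V,  c(7.30, 44.84, 144.84, 24.61, 2.06e-3, 178.808, 1.14e-4,
                       106.84, 5.96, 83.61, 15.95, 16.16, NA, 9.00, 91.37,
                       NA, 15.60, NA, 14.61))
  expect_equal(B$kA, c(42.40, 3.20e-5, 16.93, 172.78, 502.49, 2.53, 92.65,
                       1.51e-2, 65.19, 0.49, 37.62, 1.05, 5.77e-4, 4.51,
                       26.79, 1.09, 23.78, 17.35, 1.82))
  expect_equal(B$kB, c(62.98, NA, NA, NA, NA, NA, NA, 19.88, NA, NA, 46.45,
                       155.71, NA, 1.29, 46.78, NA, 14.96, NA, 32.49))
  expect_equal(B$kC, c(5.11, rep(NA, 17), 81.06))
  # named spot checks through the fixture interface
  r19 <- abe_fixture("fit_A") |> dplyr::filter(reaction == "r19")
  expect_equal(unlist(r19[c("V", "kA", "kB", "kC")], use.names = FALSE),
               c(26.27, 0.6, 28.45, 105.51))
})

test_that("packaged initial conditions pin the published batch conditions", {
  s <- abe_fixture("shinto_initial")
  expect_equal(unname(s[c("G", "X", "Ac", "Buty", "An", "BuOH")]),
               c(70.6, 0.20, 40.12, 2.12, 2.58, 4.46))
  a <- abe_fixture("alshorgani_initial")
  expect_equal(unname(a[["G"]]), 277.78)
  expect_error(abe_fixture("nope"))
})

test_that("noise-free generation reproduces the trajectory samples", {
  times <- seq(0, 30, by = 10)
  d <- generate_synthetic_dataset(fitA, cv = 0, floor = 0, seed = 1,
                                  sample_times = times)
  traj <- simulate_batch(abe_initial("shinto"), fitA, t_end = 30,
                         times = times)
  clean <- states_at(traj, times)
  for (sp in c("G", "X", "BuOH")) {
    expect_equal(d[[sp]], clean[[sp]], tolerance = 1e-8)
  }
})

test_that("generation is seed-reproducible", {
  d1 <- generate_synthetic_dataset(fitA, cv = 0.05, seed = 42)
  d2 <- generate_synthetic_dataset(fitA, cv = 0.05, seed = 42)
  d3 <- generate_synthetic_dataset(fitA, cv = 0.05, seed = 43)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  expect_false(identical(as.data.frame(d1), as.data.frame(d3)))
})

test_that("the multiplicative noise has the configured coefficient of variation", {
  reps <- purrr::map(1:100, function(s) {
    generate_synthetic_dataset(fitA, cv = 0.05, seed = s,
                               sample_times = c(0, 20, 40), measured = "BuOH")
  })
  vals <- vapply(reps, function(d) d$BuOH[d$time_h == 40], numeric(1))
  expect_equal(stats::sd(vals) / mean(vals), 0.05, tolerance = 0.3)
})

test_that("parameter, dataset and trajectory files round-trip", {
  tmp <- withr::local_tempdir()
  pfile <- file.path(tmp, "params.csv")
  write_parameters(fitA, pfile)
  back <- read_parameters(pfile)
  expect_equal(as.data.frame(back), as.data.frame(fitA), ignore_attr = TRUE)

  d <- generate_synthetic_dataset(fitA, cv = 0.05, seed = 1)
  dfile <- file.path(tmp, "data.csv")
  write_dataset(d, dfile)
  dback <- read_dataset(dfile)
  expect_equal(as.data.frame(dback), as.data.frame(d), tolerance = 1e-12,
               ignore_attr = TRUE)

  traj <- simulate_batch(abe_initial("shinto"), fitA, t_end = 10,
                         times = seq(0, 10, by = 2))
  tfile <- file.path(tmp, "traj.csv")
  write_trajectory(traj, tfile)
  tback <- read_trajectory(tfile)
  expect_equal(as.data.frame(tback), as.data.frame(traj)[names(tback)],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("malformed files are rejected with pointed errors", {
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "bad.csv")
  writeLines(c("time_h,Glucose", "0,1", "5,2"), f)
  expect_error(read_dataset(f), "Unknown species")
  # non-dot decimal separators are a parse error, not a silent NA
  writeLines(c("time_h,G", "0,\"1,5\"", "5,2"), f)
  expect_error(read_dataset(f), "not numeric|Parse error")
  writeLines(c("hours,G", "0,1", "5,2"), f)
  expect_error(read_dataset(f), "time_h")
})
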