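test_that("Michaelis-Menten rate reproduces direct substitution", {
  expect_equal(mm_rate(10, 5, 5), 5)        # half saturation
  expect_equal(mm_rate(10, 5, 0), 0)        # no substrate
  # glucose isomerisation constants (fit A, r2) at 0.01 mM substrate
  expect_equal(mm_rate(41.10, 4.0e-4, 0.01), 41.10 * 0.01 / (4.0e-4 + 0.01))
  expect_error(mm_rate(-1, 5, 5), "positive")
  expect_error(mm_rate(10, 5, -1), "non-negative")
  expect_error(mm_rate(10, NaN, 5), "positive")
})

test_that("ping-pong rate has the saturating bi-substrate form", {
  expect_equal(ping_pong_rate(1, 1, 1, 1, 1), 1 / 3)
  expect_equal(ping_pong_rate(5, 2, 3, 7, 0), 0)     # co-substrate depleted
  expect_equal(ping_pong_rate(5, 2, 3, 0, 7), 0)
  expect_equal(ping_pong_rate(5, 2, 3, 0, 0), 0)     # limit convention
  # V approached only at joint saturation
  expect_equal(ping_pong_rate(5, 2, 3, 1e9, 1e9), 5, tolerance = 1e-6)
  # with one substrate saturating, the co-substrate still limits the rate
  expect_lt(ping_pong_rate(5, 2, 3, 1e3, 2), 5 * 2 / (2 + 2))
})

test_that("inhibited ping-pong reduces to ping-pong at zero inhibitor", {
  expect_equal(ping_pong_inhibited_rate(1, 1, 1, 1, 1, 1, 1), 1 / 4)
  set.seed(42)
  for (i in 1:1000) {
    a <- runif(5, 1e-3, 100)
    expect_identical(
      ping_pong_inhibited_rate(a[1], a[2], a[3], Ki = runif(1, 1e-3, 100),
                               S1 = a[4], S2 = a[5], I = 0),
      ping_pong_rate(a[1], a[2], a[3], a[4], a[5])
    )
  }
})

test_that("inhibited ping-pong decreases strictly with inhibitor", {
  # butanol-forming reduction constants (fit A, r19)
  r <- vapply(c(0, 10, 50, 100), function(I) {
    ping_pong_inhibited_rate(26.27, 0.6, 28.45, 105.51, S1 = 2, S2 = 1, I = I)
  }, numeric(1))
  expect_true(all(diff(r) < 0))
  # direct substitution at (BCoA = 2, NADH = 1, BuOH = 10)
  expect_equal(r[2],
               26.27 * 2 * 1 / (0.6 * 2 + 28.45 * 1 + 2 * (1 + 10 / 105.51)))
})

test_that("dual Michaelis-Menten is the product of two saturations", {
  expect_equal(dual_mm_rate(8, 2, 3, 2, 3), 8 / 4)   # both half saturated
  expect_equal(dual_mm_rate(8, 2, 3, 5, 0), 0)
  # acetate re-assimilation constants (fit A, r8) at half saturation
  expect_equal(dual_mm_rate(144.91, 0.85, 12.77, 0.85, 12.77), 144.91 / 4)
})

test_that("every rate law saturates below V and vanishes without substrate", {
  set.seed(7)
  p <- oracle_flat_params()
  Vmax <- c(p$V1, p$V2, p$V3, p$V4, p$V5, p$V6, p$V7, p$V8, p$V9, p$V10,
            p$V11, p$V12, p$k13A, p$V14, p$V15, p$V16, p$V17, p$V18, p$V19)
  for (i in 1:1000) {
    st <- random_state()
    r <- compute_rates(st, abe_fit("A"))
    expect_true(all(r >= 0))
    expect_true(all(r <= Vmax + 1e-12))
  }
  # zero state: everything but the constant death rate vanishes
  r0 <- compute_rates(abe_state(.base = setNames(rep(0, 16), abe_species())),
                      abe_fit("A"))
  expect_equal(unname(r0["r13"]), 5.06e-2)
  expect_equal(unname(r0[names(r0) != "r13"]), rep(0, 18))
})

test_that("glucose uptake is inhibited by butanol and saturates in glucose", {
  r_clean <- glucose_uptake_rate(9.89, 11.54, 89.50, 2.56, G = 70, BuOH = 0)
  r_inhib <- glucose_uptake_rate(9.89, 11.54, 89.50, 2.56, G = 70, BuOH = 100)
  expect_lt(r_inhib, r_clean)
  expect_equal(glucose_uptake_rate(9.89, 11.54, 89.50, 2.56, 0, 0), 0)
  # bounded by the saturating-limit rate V/(1 + kA/kC)
  g <- glucose_uptake_rate(9.89, 11.54, 89.50, 2.56, 10^(0:5), BuOH = 0)
  expect_true(all(g <= 9.89 / (1 + 11.54 / 2.56) + 1e-12))
})
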