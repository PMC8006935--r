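test_that("the all-zero state is absorbing under integration", {
  tc <- integrate_model(cell_state(0, 0, 0, 0), test_p, t_end = 300)
  expect_true(all(as.matrix(tc[, -1]) == 0))
})

test_that("precursor dynamics match the scalar logistic closed form", {
  p0 <- params_with(rho = 0)
  N0 <- 1e3
  r <- p0[["alpha_N"]] - p0[["delta_N"]]
  Keff <- p0[["K"]] * (1 - p0[["delta_N"]] / p0[["alpha_N"]])
  tc <- integrate_model(cell_state(N0, 0, 0, 0), p0, t_end = 200)
  closed <- Keff * N0 * exp(r * tc$time_h) /
    (Keff + N0 * (exp(r * tc$time_h) - 1))
  expect_equal(tc$N, closed, tolerance = 1e-6)
  st <- steady_state(cell_state(N0, 0, 0, 0), p0, t_max = 400)
  expect_equal(st[["N"]], Keff, tolerance = 1e-3)
})

test_that("default parameters reach steady state within 300 h with C_R above C_S", {
  st <- steady_state(test_init, test_p)
  expect_true(attr(st, "converged"))
  expect_lte(attr(st, "time_h"), 300)
  expect_gt(st[["C_R"]], st[["C_S"]])
  # endpoint is stable: doubling the window moves it by < 0.1%
  tc2 <- integrate_model(test_init, test_p, t_end = 600)
  n <- nrow(tc2)
  for (v in c("N", "C", "C_R", "C_S"))
    expect_equal(st[[v]], tc2[[v]][n], tolerance = 1e-3)
})

test_that("trajectories stay non-negative under default and treated dynamics", {
  tc <- integrate_model(test_init, test_p, t_end = 300)
  expect_true(all(as.matrix(tc[, -1]) >= 0))
  expect_lte(attr(tc, "n_clipped"), 0)
  tct <- integrate_model(test_init, test_p, test_cfg$drug_effects$AC26,
                         dose_pair(200, 6), t_end = 300)
  expect_true(all(as.matrix(tct[, -1]) >= 0))
})

test_that("steady state is robust to halving the solver tolerances", {
  st1 <- steady_state(test_init, test_p, rtol = 1e-8, atol = 1e-8)
  st2 <- steady_state(test_init, test_p, rtol = 5e-9, atol = 5e-9)
  for (v in c("N", "C", "C_R", "C_S"))
    expect_equal(st1[[v]], st2[[v]], tolerance = 1e-3)
})

test_that("relative growth is 100% at zero dose or with an inert drug", {
  dp <- test_cfg$drug_effects$AC26
  expect_equal(relative_growth(test_p, dp, dose_pair(0, 0), "C_R", "fixed"),
               100)
  expect_equal(relative_growth(test_p, inert_drug(), dose_pair(150, 5),
                               "C_R", "fixed"), 100)
  expect_equal(relative_growth(test_p, inert_drug(), dose_pair(150, 5),
                               "C_S", "steady"), 100)
})

test_that("relative growth decreases monotonically with TMZ dose", {
  dp <- test_cfg$drug_effects$AC26
  for (d2 in c(0, 0.5)) {
    g <- vapply(c(0, 50, 100, 150, 200), function(d1)
      relative_growth(test_p, dp, dose_pair(d1, d2), "C_R", "fixed",
                      rtol = 1e-6, atol = 1e-6), numeric(1))
    expect_true(all(diff(g) < 1e-8))
    expect_true(all(g > 0 & g <= 100 + 1e-9))
  }
})

test_that("relative growth errors when the untreated baseline is empty", {
  dp <- test_cfg$drug_effects$AC26
  expect_error(
    relative_growth(test_p, dp, dose_pair(10, 1), "C_R", "fixed",
                    initial = cell_state(0, 0, 0, 0)),
    "baseline")
})

test_that("time courses round-trip through CSV at 12 significant digits", {
  tc <- integrate_model(test_init, test_p, t_end = 48, dt = 4)
  f <- tempfile(fileext = ".csv")
  write_time_course(tc, f)
  back <- read_time_course(f)
  for (v in c("time_h", "N", "C", "C_R", "C_S"))
    expect_equal(back[[v]], tc[[v]], tolerance = 1e-12)
})
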