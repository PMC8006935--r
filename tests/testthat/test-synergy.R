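test_that("Bliss expectation has its identity and absorbing elements", {
  for (y in c(0, 0.3, 0.7, 1)) {
    expect_equal(bliss_expected(0, y), y)
    expect_equal(bliss_expected(1, y), 1)
  }
  expect_equal(bliss_expected(0.5, 0.5), 0.75)
  expect_error(bliss_expected(-0.1, 0.5), "\\[0, 1\\]")
  expect_error(bliss_expected(0.5, 1.2), "\\[0, 1\\]")
})

test_that("synergy scores vanish on the monotherapy margins and on a toy grid", {
  # toy 3x3: monotherapy inhibitions 0.2 (rows) and 0.3 (columns);
  # observed combined growth 50% -> Bliss-expected inhibition 44%,
  # deviation 6 percentage points above expectation
  grid <- structure(list(d1_levels = c(0, 1, 2), d2_levels = c(0, 1, 2),
                         spacing = "linear", acridone = "AC26"),
                    class = "dose_grid")
  vals <- matrix(100, 3, 3)
  vals[2:3, 1] <- 80   # d1 alone: 20% inhibition
  vals[1, 2:3] <- 70   # d2 alone: 30% inhibition
  vals[2:3, 2:3] <- 50
  m <- structure(vals, class = c("dose_response_matrix", "matrix"),
                 grid = grid, compartment = "C_R", horizon = "fixed")
  s <- synergy_surface(m)
  expect_identical(s[1, ], setNames(rep(0, 3), colnames(s)))
  expect_identical(s[, 1], setNames(rep(0, 3), rownames(s)))
  expect_equal(unname(s[2, 2]), 50 - 44)
  expect_true(all(abs(s) <= 100))
})

test_that("an inert second drug produces an exactly zero synergy surface", {
  dp <- drug_with(emax_D2r = 0, emax_D2s = 0)
  grid <- dose_grid(n_levels = 5)
  m <- dose_response_matrix(test_p, dp, grid, rtol = 1e-6, atol = 1e-6)
  s <- synergy_surface(m)
  expect_equal(max(abs(s)), 0, tolerance = 1e-9)
})

test_that("dose grids include zero, increase, and respect toxicity limits", {
  g <- dose_grid(acridone = "AC2")
  expect_equal(g$d1_levels[1], 0)
  expect_equal(g$d2_levels[100], 2)
  expect_true(all(diff(g$d1_levels) > 0))
  expect_error(dose_grid(d1_max = 260), "toxicity")
  expect_error(dose_grid(d2_max = 150), "toxicity")
})

test_that("dose-response matrices are 100% everywhere for an inert drug pair", {
  g <- dose_grid(n_levels = 4)
  m <- dose_response_matrix(test_p, inert_drug(), g, rtol = 1e-6, atol = 1e-6)
  expect_equal(unclass(m), matrix(100, 4, 4), ignore_attr = TRUE,
               tolerance = 1e-9)
})

test_that("dose-response matrices anchor at 100 and decrease along both axes", {
  g <- dose_grid(n_levels = 6)
  m <- dose_response_matrix(test_p, test_cfg$drug_effects$AC26, g,
                            rtol = 1e-6, atol = 1e-6)
  expect_identical(unname(m[1, 1]), 100)
  expect_true(all(apply(m, 1, function(r) all(diff(r) < 1e-8))))
  expect_true(all(apply(m, 2, function(cl) all(diff(cl) < 1e-8))))
  expect_true(all(m >= 0 & m <= 100 + 1e-9))
  f <- tempfile(fileext = ".csv")
  write_dose_matrix(m, f)
  back <- read_dose_matrix(f)
  expect_equal(as.vector(back), as.vector(m), tolerance = 1e-12)
})

test_that("IC50 interpolation matches exact Hill curves and flags flat ones", {
  for (ic in c(190, 0.76)) {
    doses <- c(0, 10^seq(log10(ic / 30), log10(ic * 30), length.out = 20))
    g <- 100 * (1 - ifelse(doses == 0, 0, doses / (ic + doses)))
    expect_lt(abs(ic50_from_curve(doses, g) - ic) / ic, 0.005)
  }
  expect_error(ic50_from_curve(c(1, 10, 100), c(100, 100, 100)),
               "does not cross")
})

test_that("selectivity index reproduces the measured CC50/IC50 ratios", {
  expect_equal(selectivity_index(482, 23.33), 20.66)
  expect_equal(selectivity_index(66.08, 0.9), 73.42)
  expect_equal(selectivity_index(7.3, 7.3), 1)
  expect_error(selectivity_index(0, 1), "positive")
})

test_that("fold change reports the combination-induced IC50 shift", {
  fc <- fold_change(190, 102.3)
  expect_equal(round(fc$ratio, 2), 0.54)
  expect_equal(round(fold_change(0.76, 0.67)$percent, 2), 11.84)
  fc2 <- fold_change(3, 3)
  expect_equal(fc2$ratio, 1)
  expect_equal(fc2$percent, 0)
  expect_error(fold_change(-1, 2), "positive")
})

test_that("combination index classifies by the synergy bands", {
  at_ic50 <- combination_index(190, 1.53, 190, 1.53)
  expect_equal(at_ic50$ci, 2)
  expect_equal(at_ic50$interpretation, "antagonism")
  half <- combination_index(95, 0, 190, 1.53)
  expect_equal(half$ci, 0.5)
  expect_equal(half$interpretation, "synergism")
  expect_true(half$single_agent)
  combo <- combination_index(36.3, 1.48, 190, 1.53)
  expect_equal(combo$ci, 36.3 / 190 + 1.48 / 1.53, tolerance = 1e-12)
  expect_equal(combo$interpretation, "additive")
  expect_error(combination_index(0, 0, 190, 1.53), "not both zero")
})

test_that("growth and inhibition are complementary percentages", {
  expect_equal(growth_to_inhibition(100), 0)
  expect_equal(growth_to_inhibition(50), 50)
  expect_equal(growth_to_inhibition(growth_to_inhibition(37.2)), 37.2)
})
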