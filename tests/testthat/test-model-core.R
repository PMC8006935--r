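test_that("Gompertz term matches its closed form and boundary behaviour", {
  expect_identical(gompertz_term(0.1, 0, 1000, 1), 0)
  expect_equal(gompertz_term(0.1, 999, 1000, 1), 0)
  expect_equal(gompertz_term(0.05, 100, 1000, 1), 0.05 * 100 * log(1000 / 101))
  # positive below capacity, negative above
  expect_gt(gompertz_term(0.05, 100, 1000, 1), 0)
  expect_lt(gompertz_term(0.05, 2000, 1000, 1), 0)
  expect_error(gompertz_term(0.1, 10, -5, 1), "positive")
  expect_error(gompertz_term(0.1, 10, 1000, 0), "positive")
})

test_that("Hill kill rate is half-maximal at the IC50 and saturates at emax", {
  expect_identical(hill_kill_term(0.2, 0, 190, 1), 0)
  for (eta in c(0.5, 1, 3, 7))
    expect_equal(hill_kill_term(0.2, 190, 190, eta), 0.1)
  expect_equal(hill_kill_term(0.2, 1e12, 190, 1), 0.2, tolerance = 1e-9)
  doses <- seq(0, 500, by = 25)
  k <- hill_kill_term(0.2, doses, 190, 3)
  expect_true(all(diff(k) >= 0))
  expect_true(all(k >= 0 & k < 0.2))
  expect_error(hill_kill_term(0.2, -1, 190, 1), "non-negative")
})

test_that("parameter constructors enforce domain invariants", {
  expect_error(params_with(gamma_R = 0.7), "gamma_R \\+ omega_S")
  expect_error(params_with(rho = 1.5), "rho")
  expect_error(params_with(K = -1), "K")
  expect_error(params_with(mu = 0), "mu")
  expect_error(cell_state(-1, 0, 0, 0), "non-negative")
  expect_error(drug_with(ic50_D1r = 0), "ic50")
  expect_error(drug_with(eta_D2s = -1), "eta")
  expect_true(attr(dose_pair(260, 0), "toxicity_flag"))
  expect_true(attr(dose_pair(0, 101), "toxicity_flag"))
  expect_false(attr(dose_pair(250, 100), "toxicity_flag"))
  expect_error(dose_pair(-1, 0), "non-negative")
})

test_that("drug-free derivatives respect seeding and absorbing states", {
  p0 <- params_with(rho = 0)
  d <- growth_rhs(cell_state(5e4, 0, 0, 0), p0)
  expect_identical(unname(d[c("C", "C_R", "C_S")]), c(0, 0, 0))
  expect_identical(unname(growth_rhs(cell_state(0, 0, 0, 0), test_p)),
                   rep(0, 4))
  # logistic steady state of the precursor equation at rho = 0
  Nstar <- test_p[["K"]] * (1 - p0[["delta_N"]] / p0[["alpha_N"]])
  d2 <- growth_rhs(cell_state(Nstar, 0, 0, 0), p0)
  expect_lt(abs(d2[["N"]]), 1e-9)
})

test_that("treated derivatives reduce to drug-free at zero dose, exactly", {
  dp <- test_cfg$drug_effects$AC26
  set.seed(11)
  for (i in 1:25) {
    st <- cell_state(runif(1, 0, 1e6), runif(1, 0, 1e6),
                     runif(1, 0, 1e6), runif(1, 0, 1e6))
    expect_identical(treated_rhs(st, test_p, dp, dose_pair(0, 0)),
                     growth_rhs(st, test_p))
  }
})

test_that("kill terms act only on their target compartment", {
  st <- cell_state(1e5, 5e4, 2e4, 1e4)
  dp0 <- drug_with(emax_D1r = 0)
  base <- growth_rhs(st, test_p)
  tr <- treated_rhs(st, test_p, dp0, dose_pair(50, 0))
  expect_identical(tr[["C_R"]], base[["C_R"]])
  expect_lt(tr[["C_S"]], base[["C_S"]])
  expect_identical(tr[["N"]], base[["N"]])
  expect_identical(tr[["C"]], base[["C"]])
  # half-maximal kill at dose = IC50
  dp1 <- drug_with(emax_D1r = 0.2, ic50_D1r = 190, eta_D1r = 4)
  tr1 <- treated_rhs(st, test_p, dp1, dose_pair(190, 0))
  expect_equal(tr1[["C_R"]], base[["C_R"]] - 0.1 * st[["C_R"]])
})

test_that("compiled right-hand side agrees with the R reference", {
  dp <- test_cfg$drug_effects$AC7
  set.seed(21)
  for (i in 1:20) {
    st <- cell_state(runif(1, 0, 1e6), runif(1, 0, 1e6),
                     runif(1, 0, 1e6), runif(1, 0, 1e6))
    doses <- dose_pair(runif(1, 0, 200), runif(1, 0, 6))
    expect_equal(compiled_rhs(st, test_p), growth_rhs(st, test_p),
                 tolerance = 1e-12)
    expect_equal(compiled_rhs(st, test_p, dp, doses),
                 treated_rhs(st, test_p, dp, doses), tolerance = 1e-12)
  }
})

test_that("configuration reader validates its schema", {
  cfg <- read_params_config()
  expect_s3_class(cfg$growth, "growth_params")
  expect_length(cfg$drug_effects, 3)
  bad <- tempfile(fileext = ".yaml")
  raw <- yaml::read_yaml(default_config_path())
  raw$growth$typo_key <- 1
  yaml::write_yaml(raw, bad)
  expect_error(read_params_config(bad), "unknown keys")
})
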