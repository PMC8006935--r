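# Shared fixtures: packaged defaults loaded once per test run.
test_cfg <- read_params_config()
test_p <- test_cfg$growth
test_init <- test_cfg$initial_state

# Growth parameters with selected entries replaced (re-validated).
params_with <- function(...) {
  v <- as.list(unclass(test_p))
  mod <- list(...)
  for (nm in names(mod)) v[[nm]] <- mod[[nm]]
  do.call(growth_params, v)
}

# Drug-effect parameters with selected entries replaced.
drug_with <- function(base = test_cfg$drug_effects$AC26, ...) {
  v <- as.list(unclass(base))
  mod <- list(...)
  for (nm in names(mod)) v[[nm]] <- mod[[nm]]
  do.call(drug_effect_params, c(v, list(acridone = attr(base, "acridone"))))
}

# Inert drug: no kill at any dose.
inert_drug <- function() {
  drug_with(emax_D1r = 0, emax_D2r = 0, emax_D1s = 0, emax_D2s = 0)
}

# Compiled-model derivative at one state (for R/C agreement checks).
compiled_rhs <- function(state, p, dp = NULL, doses = NULL) {
  out <- deSolve::DLLfunc(
    y = unclass(state)[c("N", "C", "C_R", "C_S")], times = 0,
    func = "tumor_deriv", parms = model_parms_vector_(p, dp, doses),
    dllname = "gliomaSynergy", initfunc = "tumor_init")
  setNames(out$dy, c("N", "C", "C_R", "C_S"))
}
model_parms_vector_ <- getFromNamespace("model_parms_vector", "gliomaSynergy")
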