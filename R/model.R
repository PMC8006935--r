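#' Gompertz growth-rate contribution
#'
#' The cancerous compartments grow with Gompertz kinetics
#' `alpha * X * log(K / (X + mu))`, decelerating as `X` approaches the
#' carrying capacity `K`.  The offset `mu > 0` keeps the term finite at
#' `X = 0`.
#'
#' @param alpha birth rate (per hour, >= 0).
#' @param X population abundance (>= 0).
#' @param K carrying capacity (> 0).
#' @param mu regularisation offset (> 0).
#' @return Growth-rate contribution (abundance per hour); positive while
#'   `X + mu < K`, negative beyond the capacity.
#' @export
gompertz_term <- function(alpha, X, K, mu) {
  if (K <= 0 || mu <= 0) stop("gompertz_term: K and mu must be positive")
  if (alpha < 0 || any(X < 0)) stop("gompertz_term: alpha and X must be >= 0")
  alpha * X * log(K / (X + mu))
}

#' Emax/Hill drug-kill rate
#'
#' Saturating pharmacodynamic kill rate
#' `emax * dose^eta / (ic50^eta + dose^eta)`, equal to `emax / 2` at
#' `dose = ic50` for any Hill exponent.
#'
#' @param emax maximal kill rate (per hour, >= 0).
#' @param dose drug concentration (uM, >= 0).
#' @param ic50 half-maximal concentration (uM, > 0).
#' @param eta Hill exponent (> 0).
#' @return Kill rate in `[0, emax)`, monotone non-decreasing in `dose`.
#' @export
hill_kill_term <- function(emax, dose, ic50, eta) {
  if (any(dose < 0)) stop("hill_kill_term: dose must be non-negative")
  if (ic50 <= 0 || eta <= 0) stop("hill_kill_term: ic50 and eta must be positive")
  if (emax < 0) stop("hill_kill_term: emax must be non-negative")
  dn <- dose^eta
  ifelse(dose == 0, 0, emax * dn / (ic50^eta + dn))
}

#' Drug-free model right-hand side
#'
#' Time derivatives of the four populations.  Precursor cells renew
#' logistically with probability `1 - rho` and mutate into cancer cells with
#' probability `rho`; cancer cells grow with Gompertz kinetics and
#' differentiate into resistant (`gamma_R`) and sensitive (`omega_S`)
#' subpopulations, which grow with their own Gompertz terms and interconvert
#' with probabilities `gamma_R_tilde` (sensitive to resistant) and
#' `omega_S_tilde` (resistant to sensitive).
#'
#' @param state a [cell_state()] (or named vector with N, C, C_R, C_S).
#' @param p a [growth_params()] vector.
#' @return Named numeric vector of derivatives (per hour) for N, C, C_R, C_S.
#' @export
growth_rhs <- function(state, p) {
  N <- state[["N"]]; C <- state[["C"]]
  CR <- state[["C_R"]]; CS <- state[["C_S"]]
  K <- p[["K"]]; mu <- p[["mu"]]
  dN <- p[["alpha_N"]] * N * (1 - p[["rho"]]) * (1 - N / K) -
    p[["delta_N"]] * N - p[["alpha_N"]] * N * p[["rho"]]
  dC <- p[["alpha_N"]] * p[["rho"]] * N +
    gompertz_term(p[["alpha_C"]], C, K, mu) -
    p[["gamma_R"]] * p[["alpha_C"]] * C -
    p[["omega_S"]] * p[["alpha_C"]] * C -
    p[["delta_C"]] * C
  dCR <- p[["gamma_R"]] * p[["alpha_C"]] * C +
    p[["gamma_R_tilde"]] * p[["alpha_CS"]] * CS +
    gompertz_term(p[["alpha_CR"]], CR, K, mu) -
    p[["delta_R"]] * CR -
    p[["omega_S_tilde"]] * p[["alpha_CR"]] * CR
  dCS <- p[["omega_S_tilde"]] * p[["alpha_CR"]] * CR +
    p[["omega_S"]] * p[["alpha_C"]] * C +
    gompertz_term(p[["alpha_CS"]], CS, K, mu) -
    p[["delta_S"]] * CS -
    p[["gamma_R_tilde"]] * p[["alpha_CS"]] * CS
  c(N = dN, C = dC, C_R = dCR, C_S = dCS)
}

#' Drug-treated model right-hand side
#'
#' Identical to [growth_rhs()] except that the resistant compartment loses
#' cells at rate `hill_kill(D1; r) + hill_kill(D2; r)` and the sensitive
#' compartment at the analogous sensitive-cell rates.  The precursor and
#' undifferentiated-cancer equations are unchanged; at zero doses the output
#' equals [growth_rhs()] exactly.
#'
#' @inheritParams growth_rhs
#' @param dp a [drug_effect_params()] vector.
#' @param doses a [dose_pair()].
#' @return Named numeric vector of derivatives (per hour).
#' @export
treated_rhs <- function(state, p, dp, doses) {
  base <- growth_rhs(state, p)
  d1 <- doses[["d1"]]; d2 <- doses[["d2"]]
  kill_r <- hill_kill_term(dp[["emax_D1r"]], d1, dp[["ic50_D1r"]], dp[["eta_D1r"]]) +
    hill_kill_term(dp[["emax_D2r"]], d2, dp[["ic50_D2r"]], dp[["eta_D2r"]])
  kill_s <- hill_kill_term(dp[["emax_D1s"]], d1, dp[["ic50_D1s"]], dp[["eta_D1s"]]) +
    hill_kill_term(dp[["emax_D2s"]], d2, dp[["ic50_D2s"]], dp[["eta_D2s"]])
  base[["C_R"]] <- base[["C_R"]] - kill_r * state[["C_R"]]
  base[["C_S"]] <- base[["C_S"]] - kill_s * state[["C_S"]]
  base
}

# Full 29-parameter vector in the order the compiled rhs expects.
# With dp NULL or doses (0, 0) the drug terms vanish exactly.
model_parms_vector <- function(p, dp = NULL, doses = NULL) {
  if (is.null(dp)) {
    drug <- c(emax_D1r = 0, eta_D1r = 1, ic50_D1r = 1,
              emax_D2r = 0, eta_D2r = 1, ic50_D2r = 1,
              emax_D1s = 0, eta_D1s = 1, ic50_D1s = 1,
              emax_D2s = 0, eta_D2s = 1, ic50_D2s = 1)
  } else {
    drug <- unclass(dp)[DRUG_PARAM_NAMES]
  }
  if (is.null(doses)) doses <- c(d1 = 0, d2 = 0)
  c(unclass(p)[GROWTH_PARAM_NAMES],
    drug[c("emax_D1r", "eta_D1r", "ic50_D1r",
           "emax_D2r", "eta_D2r", "ic50_D2r",
           "emax_D1s", "eta_D1s", "ic50_D1s",
           "emax_D2s", "eta_D2s", "ic50_D2s")],
    d1 = doses[["d1"]], d2 = doses[["d2"]])
}
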