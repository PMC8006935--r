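#' @useDynLib gliomaSynergy
#' @importFrom stats cor dnorm lm pnorm pt qnorm quantile residuals rnorm
#'   runif sd setNames var
#' @importFrom utils head read.csv tail write.csv
NULL

GROWTH_PARAM_NAMES <- c(
  "alpha_N", "delta_N", "rho", "K", "mu",
  "alpha_C", "delta_C", "gamma_R", "omega_S",
  "gamma_R_tilde", "omega_S_tilde",
  "alpha_CR", "delta_R", "alpha_CS", "delta_S"
)

DRUG_PARAM_NAMES <- c(
  "emax_D1r", "eta_D1r", "ic50_D1r",
  "emax_D2r", "eta_D2r", "ic50_D2r",
  "emax_D1s", "eta_D1s", "ic50_D1s",
  "emax_D2s", "eta_D2s", "ic50_D2s"
)

ACRIDONE_LABELS <- c("AC2", "AC7", "AC26")

#' Construct a cell-state vector
#'
#' The model tracks four cell populations: non-cancerous precursor cells
#' (`N`), undifferentiated cancer cells (`C`), drug-resistant cancer cells
#' (`C_R`) and drug-sensitive cancer cells (`C_S`).
#'
#' @param N,C,C_R,C_S non-negative, finite abundances.
#' @return Named numeric vector of class `cell_state`.
#' @export
cell_state <- function(N, C, C_R, C_S) {
  x <- c(N = N, C = C, C_R = C_R, C_S = C_S)
  if (any(!is.finite(x))) stop("cell_state: all abundances must be finite")
  if (any(x < 0)) stop("cell_state: all abundances must be non-negative")
  structure(x, class = c("cell_state", "numeric"))
}

#' Construct the drug-free growth parameter set
#'
#' The 15 parameters of the heterogeneous tumor-growth model: logistic
#' growth of the precursor pool, Gompertz growth of the three cancerous
#' compartments sharing one carrying capacity `K`, mutation of precursors
#' into cancer cells with probability `rho`, differentiation of cancer cells
#' into resistant/sensitive subpopulations with probabilities
#' `gamma_R`/`omega_S` (which must sum to 1), and reversible
#' sensitive/resistant switching with forward probability `gamma_R_tilde`
#' larger than the backward `omega_S_tilde`.
#'
#' @param alpha_N,delta_N birth and death rates of precursor cells (per hour).
#' @param rho mutation probability precursor to cancer, in \[0, 1\].
#' @param K shared carrying capacity of the cancerous compartments (cells).
#' @param mu Gompertz regularisation offset (cells, > 0) keeping the growth
#'   term finite at zero abundance.
#' @param alpha_C,alpha_CR,alpha_CS birth rates of C, C_R, C_S (per hour).
#' @param delta_C,delta_R,delta_S death rates of C, C_R, C_S (per hour).
#' @param gamma_R,omega_S differentiation probabilities C to C_R / C_S;
#'   must sum to 1 (tolerance 1e-12).
#' @param gamma_R_tilde,omega_S_tilde switching probabilities C_S to C_R
#'   (forward) and C_R to C_S (backward).
#' @return Named numeric vector of class `growth_params` (length 15).
#' @export
growth_params <- function(alpha_N, delta_N, rho, K, mu,
                          alpha_C, delta_C, gamma_R, omega_S,
                          gamma_R_tilde, omega_S_tilde,
                          alpha_CR, delta_R, alpha_CS, delta_S) {
  p <- c(alpha_N = alpha_N, delta_N = delta_N, rho = rho, K = K, mu = mu,
         alpha_C = alpha_C, delta_C = delta_C,
         gamma_R = gamma_R, omega_S = omega_S,
         gamma_R_tilde = gamma_R_tilde, omega_S_tilde = omega_S_tilde,
         alpha_CR = alpha_CR, delta_R = delta_R,
         alpha_CS = alpha_CS, delta_S = delta_S)
  if (any(!is.finite(p))) stop("growth_params: all parameters must be finite")
  rates <- p[c("alpha_N", "delta_N", "alpha_C", "delta_C",
               "alpha_CR", "delta_R", "alpha_CS", "delta_S")]
  if (any(rates < 0)) stop("growth_params: rates must be non-negative")
  if (p[["K"]] <= 0) stop("growth_params: K must be positive")
  if (p[["mu"]] <= 0) stop("growth_params: mu must be positive")
  if (p[["rho"]] < 0 || p[["rho"]] > 1)
    stop("growth_params: rho must lie in [0, 1]")
  if (abs(p[["gamma_R"]] + p[["omega_S"]] - 1) > 1e-12)
    stop("growth_params: gamma_R + omega_S must equal 1")
  probs <- p[c("gamma_R", "omega_S", "gamma_R_tilde", "omega_S_tilde")]
  if (any(probs < 0) || any(probs > 1))
    stop("growth_params: probabilities must lie in [0, 1]")
  structure(p, class = c("growth_params", "numeric"))
}

#' Construct the drug-effect (Emax/Hill) parameter set
#'
#' Per drug (D1 = temozolomide, D2 = an acridone derivative) and per
#' cancerous subpopulation (r = resistant, s = sensitive), an Emax/Hill
#' triplet: maximal kill rate `emax` (per hour), Hill exponent `eta`
#' (unitless, > 0) and half-maximal concentration `ic50` (micromolar, > 0).
#'
#' @param emax_D1r,eta_D1r,ic50_D1r TMZ effect on resistant cells.
#' @param emax_D2r,eta_D2r,ic50_D2r acridone effect on resistant cells.
#' @param emax_D1s,eta_D1s,ic50_D1s TMZ effect on sensitive cells.
#' @param emax_D2s,eta_D2s,ic50_D2s acridone effect on sensitive cells.
#' @param acridone label of the acridone value set, one of
#'   `"AC2"`, `"AC7"`, `"AC26"`.
#' @return Named numeric vector of class `drug_effect_params` with
#'   attribute `acridone`.
#' @export
drug_effect_params <- function(emax_D1r, eta_D1r, ic50_D1r,
                               emax_D2r, eta_D2r, ic50_D2r,
                               emax_D1s, eta_D1s, ic50_D1s,
                               emax_D2s, eta_D2s, ic50_D2s,
                               acridone = "AC26") {
  acridone <- match.arg(acridone, ACRIDONE_LABELS)
  p <- c(emax_D1r = emax_D1r, eta_D1r = eta_D1r, ic50_D1r = ic50_D1r,
         emax_D2r = emax_D2r, eta_D2r = eta_D2r, ic50_D2r = ic50_D2r,
         emax_D1s = emax_D1s, eta_D1s = eta_D1s, ic50_D1s = ic50_D1s,
         emax_D2s = emax_D2s, eta_D2s = eta_D2s, ic50_D2s = ic50_D2s)
  if (any(!is.finite(p))) stop("drug_effect_params: values must be finite")
  if (any(p[grep("^emax", names(p))] < 0))
    stop("drug_effect_params: emax must be non-negative")
  if (any(p[grep("^eta", names(p))] <= 0))
    stop("drug_effect_params: eta must be positive")
  if (any(p[grep("^ic50", names(p))] <= 0))
    stop("drug_effect_params: ic50 must be positive")
  structure(p, class = c("drug_effect_params", "numeric"),
            acridone = acridone)
}

#' Construct a dose pair
#'
#' Doses held constant over the whole integration window (no
#' pharmacokinetic clearance).  Doses above the literature toxicity limits
#' (250 uM for TMZ, 100 uM for acridones) raise a toxicity flag but are not
#' rejected, so that guard behaviour is testable.
#'
#' @param d1 TMZ concentration (uM, >= 0).
#' @param d2 acridone concentration (uM, >= 0).
#' @return Named numeric vector of class `dose_pair` with logical attribute
#'   `toxicity_flag`.
#' @export
dose_pair <- function(d1, d2) {
  if (!is.finite(d1) || !is.finite(d2) || d1 < 0 || d2 < 0)
    stop("dose_pair: doses must be finite and non-negative")
  structure(c(d1 = d1, d2 = d2), class = c("dose_pair", "numeric"),
            toxicity_flag = (d1 > 250 || d2 > 100))
}

## ---- configuration file ----------------------------------------------------

config_schema <- function() {
  list(
    growth = GROWTH_PARAM_NAMES,
    initial_state = c("N", "C", "C_R", "C_S"),
    drug_effects = c("tmz", ACRIDONE_LABELS),
    horizons = c("dose_response_h", "steady_state_max_h", "steady_state_tol")
  )
}

#' Read a model configuration file
#'
#' Parameter sets are shipped in a version-controlled YAML file rather than
#' hard-coded.  Unknown keys anywhere in the file are rejected.
#'
#' @param path YAML file; defaults to the packaged configuration
#'   `inst/extdata/default_params.yaml`.
#' @return List with elements `growth` (`growth_params`), `initial_state`
#'   (`cell_state`), `drug_effects` (list of per-acridone
#'   `drug_effect_params`), and `horizons`.
#' @export
read_params_config <- function(path = default_config_path()) {
  raw <- yaml::read_yaml(path)
  schema <- config_schema()
  unknown <- setdiff(names(raw), names(schema))
  if (length(unknown))
    stop("config: unknown top-level keys: ", paste(unknown, collapse = ", "))
  missing <- setdiff(names(schema), names(raw))
  if (length(missing))
    stop("config: missing sections: ", paste(missing, collapse = ", "))
  for (sec in names(schema)) {
    bad <- setdiff(names(raw[[sec]]), schema[[sec]])
    if (length(bad))
      stop("config: unknown keys in '", sec, "': ", paste(bad, collapse = ", "))
  }
  growth <- do.call(growth_params, raw$growth)
  init <- do.call(cell_state, raw$initial_state)
  tmz <- raw$drug_effects$tmz
  drugs <- lapply(ACRIDONE_LABELS, function(lab) {
    ac <- raw$drug_effects[[lab]]
    drug_effect_params(
      emax_D1r = tmz$emax_r, eta_D1r = tmz$eta_r, ic50_D1r = tmz$ic50_r,
      emax_D2r = ac$emax_r,  eta_D2r = ac$eta_r,  ic50_D2r = ac$ic50_r,
      emax_D1s = tmz$emax_s, eta_D1s = tmz$eta_s, ic50_D1s = tmz$ic50_s,
      emax_D2s = ac$emax_s,  eta_D2s = ac$eta_s,  ic50_D2s = ac$ic50_s,
      acridone = lab)
  })
  names(drugs) <- ACRIDONE_LABELS
  list(growth = growth, initial_state = init, drug_effects = drugs,
       horizons = raw$horizons)
}

#' @rdname read_params_config
#' @export
default_config_path <- function() {
  system.file("extdata", "default_params.yaml", package = "gliomaSynergy",
              mustWork = TRUE)
}

#' Default drug-free growth parameters
#' @return A `growth_params` vector (packaged defaults).
#' @export
default_growth_params <- function() {
  read_params_config()$growth
}

#' Default drug-effect parameters for one acridone derivative
#' @param acridone one of `"AC2"`, `"AC7"`, `"AC26"`.
#' @return A `drug_effect_params` vector.
#' @export
default_drug_params <- function(acridone = "AC26") {
  acridone <- match.arg(acridone, ACRIDONE_LABELS)
  read_params_config()$drug_effects[[acridone]]
}

#' Default initial cell state
#' @return A `cell_state` vector (packaged defaults).
#' @export
default_initial_state <- function() {
  read_params_config()$initial_state
}
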