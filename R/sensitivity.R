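#' Latin hypercube sample
#'
#' One sample per equal-probability stratum per parameter, uniform within
#' the stratum and independently permuted across parameters (via
#' [lhs::randomLHS()]), rescaled to the requested ranges.  Reproducible
#' given `seed`.
#'
#' @param ranges named list (or 2-column matrix) of `c(lo, hi)` per
#'   parameter, `lo < hi`.
#' @param n number of samples (>= k + 2 for downstream PRCC).
#' @param seed integer seed.
#' @return `n x k` matrix with parameter names as columns.
#' @export
lhs_sample <- function(ranges, n, seed = 1) {
  if (is.matrix(ranges))
    ranges <- setNames(lapply(seq_len(nrow(ranges)),
                              function(i) ranges[i, ]), rownames(ranges))
  k <- length(ranges)
  lo <- vapply(ranges, `[`, numeric(1), 1)
  hi <- vapply(ranges, `[`, numeric(1), 2)
  if (any(hi <= lo)) stop("lhs_sample: degenerate range (lo >= hi)")
  set.seed(seed)
  u <- lhs::randomLHS(n, k)
  x <- sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`)
  colnames(x) <- names(ranges)
  x
}

#' Partial rank correlation coefficients
#'
#' For each parameter column, rank-transforms all columns (average-rank tie
#' convention), regresses the parameter ranks and the output ranks on the
#' remaining parameter ranks, and correlates the two residual vectors.  The
#' p-value comes from the t statistic with `n - 2 - (k - 1)` degrees of
#' freedom.
#'
#' @param samples `n x k` parameter matrix.
#' @param outputs length-`n` output vector.
#' @return Data.frame of class `prcc_result` with columns `parameter`,
#'   `prcc`, `p_value`, and attribute `n_samples`.
#' @export
prcc <- function(samples, outputs) {
  n <- nrow(samples)
  k <- ncol(samples)
  if (n <= k + 2) stop("prcc: insufficient samples (need n > k + 2)")
  if (any(apply(samples, 2, function(x) length(unique(x)) == 1)))
    stop("prcc: constant parameter column")
  rx <- apply(samples, 2, rank)
  ry <- rank(outputs)
  df_resid <- n - 2 - (k - 1)
  res <- lapply(seq_len(k), function(j) {
    others <- rx[, -j, drop = FALSE]
    ex <- if (k == 1) rx[, j] - mean(rx[, j]) else
      residuals(lm.fit(cbind(1, others), rx[, j]))
    ey <- if (k == 1) ry - mean(ry) else
      residuals(lm.fit(cbind(1, others), ry))
    r <- suppressWarnings(cor(ex, ey))
    if (is.na(r)) r <- 0
    r <- max(min(r, 1), -1)
    tstat <- r * sqrt(df_resid / max(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = df_resid)
    data.frame(parameter = colnames(samples)[j] %||% paste0("x", j),
               prcc = r, p_value = p)
  })
  structure(do.call(rbind, res), class = c("prcc_result", "data.frame"),
            n_samples = n)
}

#' Default sensitivity ranges for the 29-parameter treated model
#'
#' The 15 growth parameters and the TMZ Emax/Hill triplets vary +/- 50%
#' around the packaged defaults; acridone (D2) triplets span the three
#' derivatives (0.5x the minimum to 1.5x the maximum over AC2/AC7/AC26);
#' doses cover the simulated grid ranges (TMZ 0-200 uM, acridone 0-6 uM).
#' `gamma_R` and `omega_S` vary independently here and are renormalised to
#' sum to 1 inside the model evaluation.
#'
#' @param config parsed configuration from [read_params_config()].
#' @return Named list of `c(lo, hi)` ranges covering all 29 parameters.
#' @export
default_sensitivity_ranges <- function(config = read_params_config()) {
  p <- unclass(config$growth)
  ranges <- lapply(names(p), function(nm) c(0.5 * p[[nm]], 1.5 * p[[nm]]))
  names(ranges) <- names(p)
  probs <- c("rho", "gamma_R", "omega_S", "gamma_R_tilde", "omega_S_tilde")
  for (nm in probs) ranges[[nm]][2] <- min(ranges[[nm]][2], 1)
  d1 <- unclass(config$drug_effects[["AC26"]])
  for (nm in c("emax_D1r", "eta_D1r", "ic50_D1r",
               "emax_D1s", "eta_D1s", "ic50_D1s"))
    ranges[[nm]] <- c(0.5 * d1[[nm]], 1.5 * d1[[nm]])
  for (nm in c("emax_D2r", "eta_D2r", "ic50_D2r",
               "emax_D2s", "eta_D2s", "ic50_D2s")) {
    vals <- vapply(config$drug_effects, `[[`, numeric(1), nm)
    ranges[[nm]] <- c(0.5 * min(vals), 1.5 * max(vals))
  }
  ranges$d1 <- c(0, 200)
  ranges$d2 <- c(0, 6)
  ranges
}

#' Global LHS-PRCC sensitivity analysis
#'
#' Samples the parameter space by Latin hypercube, simulates each row of
#' the treated model to the horizon (steady state with a 300-h cap by
#' default), and computes the PRCC of every parameter against each
#' compartment abundance.  Rows whose simulation fails are dropped with a
#' logged count; more than 10% dropped is an error.
#'
#' @param ranges named list of `c(lo, hi)` per parameter (default:
#'   [default_sensitivity_ranges()]); a point range (`lo == hi`) holds that
#'   parameter fixed and excludes it from the PRCC.
#' @param n number of LHS samples.
#' @param seed integer seed.
#' @param horizon `"steady"` (default) or `"fixed"`.
#' @param horizon_h evaluation time when `horizon = "fixed"` (hours).
#' @param initial initial [cell_state()].
#' @param outputs compartments to analyse.
#' @return Data.frame with columns `output`, `parameter`, `prcc`,
#'   `p_value`; attributes `n_samples`, `n_dropped`.
#' @export
run_sensitivity <- function(ranges = default_sensitivity_ranges(), n = 500,
                            seed = 1, horizon = c("steady", "fixed"),
                            horizon_h = 72,
                            initial = default_initial_state(),
                            outputs = c("N", "C", "C_R", "C_S")) {
  horizon <- match.arg(horizon)
  lo <- vapply(ranges, `[`, numeric(1), 1)
  hi <- vapply(ranges, `[`, numeric(1), 2)
  fixed <- names(ranges)[lo == hi]
  varying <- setdiff(names(ranges), fixed)
  X <- lhs_sample(ranges[varying], n, seed)
  if (length(fixed)) {
    Xf <- matrix(rep(lo[fixed], each = n), nrow = n,
                 dimnames = list(NULL, fixed))
    X <- cbind(X, Xf)[, names(ranges), drop = FALSE]
  }
  sim_row <- function(row) {
    vals <- as.list(row)
    s <- vals$gamma_R + vals$omega_S
    vals$gamma_R <- vals$gamma_R / s
    vals$omega_S <- vals$omega_S / s
    p <- try(do.call(growth_params, vals[GROWTH_PARAM_NAMES]), silent = TRUE)
    if (inherits(p, "try-error")) return(NULL)
    dp <- try(do.call(drug_effect_params,
                      c(vals[DRUG_PARAM_NAMES], list(acridone = "AC26"))),
              silent = TRUE)
    if (inherits(dp, "try-error")) return(NULL)
    doses <- dose_pair(vals$d1, vals$d2)
    st <- try(
      if (horizon == "steady")
        suppressWarnings(steady_state(initial, p, dp, doses,
                                      rtol = 1e-6, atol = 1e-6))
      else {
        tc <- integrate_model(initial, p, dp, doses,
                              times = c(0, horizon_h),
                              rtol = 1e-6, atol = 1e-6)
        nr <- nrow(tc)
        c(N = tc$N[nr], C = tc$C[nr], C_R = tc$C_R[nr], C_S = tc$C_S[nr])
      }, silent = TRUE)
    if (inherits(st, "try-error")) NULL else unclass(st)[outputs]
  }
  Y <- lapply(seq_len(n), function(i) sim_row(X[i, ]))
  ok <- !vapply(Y, is.null, logical(1))
  n_dropped <- sum(!ok)
  if (n_dropped > 0.1 * n)
    stop("run_sensitivity: more than 10% of simulations failed (",
         n_dropped, " of ", n, ")")
  Ymat <- do.call(rbind, Y[ok])
  Xok <- X[ok, varying, drop = FALSE]  # fixed parameters carry no variation
  res <- lapply(outputs, function(v) {
    pr <- prcc(Xok, Ymat[, v])
    cbind(output = v, as.data.frame(pr))
  })
  structure(do.call(rbind, c(res, list(make.row.names = FALSE))),
            n_samples = sum(ok), n_dropped = n_dropped)
}
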