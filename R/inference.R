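#' Substitute free parameters into a growth-parameter set
#'
#' Overrides the named entries of `p` with the values of `free`.  If
#' `gamma_R` is free, `omega_S` is set to `1 - gamma_R` so the
#' differentiation probabilities stay normalised.  Returns `NULL` (rather
#' than erroring) when the resulting set violates the parameter-domain
#' invariants, which samplers treat as a rejection.
#'
#' @param p a [growth_params()] vector.
#' @param free named numeric vector of replacement values.
#' @return A `growth_params` vector, or `NULL` if invalid.
#' @export
apply_free_params <- function(p, free) {
  vals <- as.list(unclass(p))
  bad <- setdiff(names(free), names(vals))
  if (length(bad))
    stop("apply_free_params: unknown parameters: ", paste(bad, collapse = ", "))
  for (nm in names(free)) vals[[nm]] <- unname(free[[nm]])
  if ("gamma_R" %in% names(free)) vals$omega_S <- 1 - vals$gamma_R
  out <- try(do.call(growth_params, vals), silent = TRUE)
  if (inherits(out, "try-error")) NULL else out
}

#' Gaussian log-likelihood of growth-curve data
#'
#' Simulates the drug-free model at the observation times with the free
#' parameters substituted into the dataset's base parameter set, and sums
#' Gaussian log-densities of the observations around the trajectory.
#' Solver failures and invalid parameter sets return `-Inf` (a rejection
#' signal for the sampler).
#'
#' @param free_params named numeric vector of free-parameter values.
#' @param dataset a `synthetic_growth_data` object (or a list with the same
#'   fields read from CSV).
#' @param noise_sd observation SD per observed compartment; defaults to the
#'   dataset's recorded noise SDs.
#' @return Log density (scalar), `-Inf` on failure.
#' @export
log_likelihood <- function(free_params, dataset, noise_sd = NULL) {
  if (is.null(noise_sd)) noise_sd <- dataset$noise_sd
  noise_sd <- setNames(rep_len(unlist(noise_sd), length(dataset$observed)),
                       dataset$observed)
  if (any(noise_sd <= 0)) stop("log_likelihood: noise_sd must be positive")
  p <- apply_free_params(dataset$true_params, free_params)
  if (is.null(p)) return(-Inf)
  tc <- try(integrate_model(dataset$initial, p, times = dataset$times),
            silent = TRUE)
  if (inherits(tc, "try-error")) return(-Inf)
  ll <- 0
  for (v in dataset$observed) {
    ll <- ll + sum(dnorm(dataset$observations[[v]], tc[[v]],
                         noise_sd[[v]], log = TRUE))
  }
  if (!is.finite(ll)) -Inf else ll
}

#' Prior specification for free parameters
#'
#' Independent normal priors with hard biological-feasibility bounds.
#'
#' @param parameter character vector of free-parameter names.
#' @param mean,sd prior means and SDs (sd > 0).
#' @param lower,upper hard bounds (finite, ordered).
#' @return Data.frame of class `prior_spec`.
#' @export
prior_spec <- function(parameter, mean, sd, lower, upper) {
  if (any(sd <= 0)) stop("prior_spec: sd must be positive")
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower >= upper))
    stop("prior_spec: bounds must be finite and ordered")
  structure(data.frame(parameter = parameter, mean = mean, sd = sd,
                       lower = lower, upper = upper),
            class = c("prior_spec", "data.frame"))
}

#' Default priors centred on the packaged parameter values
#'
#' Normal priors with SD 30% of the default value and bounds at 0.2x / 5x
#' the default (probabilities additionally clamped to \[0, 1\]).
#'
#' @param free character vector of free-parameter names.
#' @param p base [growth_params()] set.
#' @return A [prior_spec()].
#' @export
default_priors <- function(free = c("alpha_N", "delta_N", "alpha_C", "delta_C",
                                    "alpha_CR", "delta_R", "alpha_CS", "delta_S",
                                    "gamma_R_tilde", "omega_S_tilde"),
                           p = default_growth_params()) {
  v <- unclass(p)[free]
  lo <- 0.2 * v
  hi <- 5 * v
  probs <- free %in% c("rho", "gamma_R", "omega_S", "gamma_R_tilde", "omega_S_tilde")
  hi[probs] <- pmin(hi[probs], 1)
  prior_spec(free, mean = unname(v), sd = unname(0.3 * v),
             lower = unname(lo), upper = unname(hi))
}

log_prior <- function(theta, priors) {
  if (any(theta < priors$lower | theta > priors$upper)) return(-Inf)
  sum(dnorm(theta, priors$mean, priors$sd, log = TRUE))
}

#' Delayed-rejection adaptive-Metropolis (DRAM) sampler
#'
#' Random-walk Metropolis with (i) proposal-covariance adaptation from the
#' chain history (scaled empirical covariance `2.38^2/d` plus a small
#' diagonal jitter, updated every `adapt_interval` iterations after
#' `adapt_start`) and (ii) one delayed-rejection stage that, after a
#' first-stage rejection, retries from a `dr_scale`-shrunk proposal with the
#' proper second-stage acceptance ratio.  Reproducible given `seed`.
#'
#' @param log_post function of a parameter vector returning the log
#'   posterior density (finite at `init`).
#' @param init numeric initial parameter vector.
#' @param n_iter number of iterations (>= 1000 for the model-fitting
#'   wrapper; any positive value accepted here).
#' @param seed integer seed.
#' @param proposal_cov initial proposal covariance; default diagonal from
#'   `init` scale.
#' @param adapt_start iteration at which adaptation begins.
#' @param adapt_interval iterations between covariance updates.
#' @param dr_scale shrink factor of the delayed-rejection proposal SD.
#' @param adapt set `FALSE` to disable adaptation (plain Metropolis + DR).
#' @param lower,upper optional hard bounds (proposals outside get density 0).
#' @return List of class `mcmc_chain`: `samples` (n_iter x d matrix),
#'   `log_posterior`, `acceptance_rate`, `seed`, `n_iter`.
#' @export
dram_sample <- function(log_post, init, n_iter, seed = 1,
                        proposal_cov = NULL, adapt_start = 1000,
                        adapt_interval = 100, dr_scale = 0.2,
                        adapt = TRUE, lower = NULL, upper = NULL) {
  d <- length(init)
  if (is.null(lower)) lower <- rep(-Inf, d)
  if (is.null(upper)) upper <- rep(Inf, d)
  sd_scale <- 2.38^2 / d
  jitter <- 1e-10
  if (is.null(proposal_cov))
    proposal_cov <- diag((0.1 * pmax(abs(init), 1e-3))^2, d)
  set.seed(seed)
  L <- chol(proposal_cov)
  samples <- matrix(NA_real_, n_iter, d)
  colnames(samples) <- names(init)
  lp_trace <- numeric(n_iter)
  x <- as.numeric(init)
  lpx <- log_post(x)
  if (!is.finite(lpx)) stop("dram_sample: non-finite log posterior at init")
  eval_lp <- function(z) {
    if (any(z < lower | z > upper)) return(-Inf)
    v <- log_post(z)
    if (is.na(v)) -Inf else v
  }
  # log N(z; m, C) with L = chol(C)
  dmvn_log <- function(z, m, L) {
    u <- backsolve(L, z - m, transpose = TRUE)
    -0.5 * sum(u * u) - sum(log(diag(L)))
  }
  sum_x <- numeric(d)
  sum_xx <- matrix(0, d, d)
  n_accept <- 0L
  for (i in seq_len(n_iter)) {
    y1 <- x + drop(crossprod(L, rnorm(d)))
    lpy1 <- eval_lp(y1)
    a1 <- if (lpy1 > lpx) 1 else exp(lpy1 - lpx)
    if (runif(1) < a1) {
      x <- y1; lpx <- lpy1; n_accept <- n_accept + 1L
    } else {
      # delayed-rejection stage from a shrunk proposal
      y2 <- x + dr_scale * drop(crossprod(L, rnorm(d)))
      lpy2 <- eval_lp(y2)
      if (is.finite(lpy2)) {
        a1_rev <- if (lpy1 > lpy2) 1 else exp(lpy1 - lpy2)  # alpha1(y2 -> y1)
        if (a1_rev < 1 && a1 < 1) {
          log_a2 <- (lpy2 - lpx) +
            (dmvn_log(y1, y2, L) - dmvn_log(y1, x, L)) +
            (log1p(-a1_rev) - log1p(-a1))
          if (log_a2 > 0 || runif(1) < exp(log_a2)) {
            x <- y2; lpx <- lpy2; n_accept <- n_accept + 1L
          }
        }
      }
    }
    samples[i, ] <- x
    lp_trace[i] <- lpx
    sum_x <- sum_x + x
    sum_xx <- sum_xx + tcrossprod(x)
    if (adapt && i >= adapt_start && i %% adapt_interval == 0) {
      m <- sum_x / i
      emp_cov <- (sum_xx - i * tcrossprod(m)) / (i - 1)
      Cnew <- sd_scale * emp_cov + sd_scale * jitter * diag(d)
      Lnew <- try(chol(Cnew), silent = TRUE)
      if (!inherits(Lnew, "try-error")) L <- Lnew
    }
  }
  structure(list(samples = samples, log_posterior = lp_trace,
                 acceptance_rate = n_accept / n_iter,
                 seed = seed, n_iter = n_iter),
            class = "mcmc_chain")
}

# Fast likelihood closure for samplers: precomputes the parameter vector,
# observation matrix and noise SDs, and calls the solver directly without
# the construction/validation overhead of the public path.  Equivalent to
# log_likelihood() for in-bounds parameters (tested); bound enforcement is
# the caller's job.
make_loglik_closure <- function(dataset, free_names, noise_sd = NULL) {
  if (is.null(noise_sd)) noise_sd <- dataset$noise_sd
  noise_sd <- setNames(rep_len(unlist(noise_sd), length(dataset$observed)),
                       dataset$observed)
  parms0 <- model_parms_vector(dataset$true_params)
  idx <- match(free_names, names(parms0))
  if (anyNA(idx)) stop("make_loglik_closure: unknown free parameter")
  gamma_idx <- match("gamma_R", free_names)
  omega_pos <- match("omega_S", names(parms0))
  y0 <- unclass(dataset$initial)[c("N", "C", "C_R", "C_S")]
  times <- dataset$times
  obs <- as.matrix(dataset$observations)
  obs_cols <- match(dataset$observed, c("N", "C", "C_R", "C_S")) + 1L
  sds <- noise_sd[dataset$observed]
  norm_const <- -sum(vapply(dataset$observed, function(v)
    length(times) * log(sqrt(2 * pi) * noise_sd[[v]]), numeric(1)))
  function(theta) {
    parms <- parms0
    parms[idx] <- theta
    if (!is.na(gamma_idx)) parms[omega_pos] <- 1 - theta[gamma_idx]
    sol <- try(deSolve::ode(
      y = y0, times = times, func = "tumor_deriv", parms = parms,
      dllname = "gliomaSynergy", initfunc = "tumor_init",
      method = "ode45", rtol = 1e-8, atol = 1e-8, hini = 0.1), silent = TRUE)
    if (inherits(sol, "try-error") || any(!is.finite(sol))) return(-Inf)
    ll <- norm_const
    for (m in seq_along(obs_cols)) {
      r <- obs[, m] - sol[, obs_cols[m]]
      ll <- ll - 0.5 * sum(r * r) / sds[m]^2
    }
    if (is.finite(ll)) unname(ll) else -Inf
  }
}

#' Fit growth parameters to a dataset by DRAM MCMC
#'
#' Builds the posterior (Gaussian likelihood of the growth-curve
#' observations times the normal priors with hard bounds) and runs
#' [dram_sample()] from the prior means.
#'
#' @param dataset a `synthetic_growth_data` object (or equivalent).
#' @param priors a [prior_spec()]; its `parameter` column defines the free
#'   set.
#' @param n_iter iterations (>= 1000).
#' @param seed integer seed.
#' @param noise_sd observation SD override (default: dataset's).
#' @inheritParams dram_sample
#' @return An `mcmc_chain` with attribute `priors`.
#' @export
run_dram <- function(dataset, priors, n_iter = 20000, seed = 1,
                     adapt_start = 1000, adapt_interval = 100,
                     dr_scale = 0.2, noise_sd = NULL) {
  if (n_iter < 1000) stop("run_dram: n_iter must be at least 1000")
  free_names <- priors$parameter
  loglik <- make_loglik_closure(dataset, free_names, noise_sd)
  log_post <- function(theta) {
    lp <- log_prior(theta, priors)
    if (!is.finite(lp)) return(-Inf)
    lp + loglik(theta)
  }
  init <- setNames(priors$mean, free_names)
  d <- length(init)
  chain <- dram_sample(log_post, init, n_iter, seed = seed,
                       proposal_cov = diag((0.1 * priors$sd)^2, d),
                       adapt_start = adapt_start,
                       adapt_interval = adapt_interval,
                       dr_scale = dr_scale,
                       lower = priors$lower, upper = priors$upper)
  attr(chain, "priors") <- priors
  chain
}

# Effective sample size by Geyer's initial-positive-sequence estimator.
ess_ips <- function(x) {
  n <- length(x)
  if (sd(x) == 0) return(0)
  rho <- drop(stats::acf(x, lag.max = min(n - 1, 2000), plot = FALSE,
                         demean = TRUE)$acf)
  tau <- 0
  m <- 1
  while (m + 1 <= length(rho)) {
    g <- rho[m] + rho[m + 1]
    if (g <= 0) break
    tau <- tau + g
    m <- m + 2
  }
  tau <- max(2 * tau - 1, 1)
  n / tau
}

#' Chain summary diagnostics
#'
#' Per-parameter posterior mean, SD, 2.5/50/97.5 percentiles, effective
#' sample size (Geyer initial positive sequence) and a Geweke-style z score
#' comparing the first 10% against the last 50% of the chain.  A constant
#' (degenerate) parameter is flagged with `ess = 0` and `degenerate = TRUE`.
#'
#' @param chain an `mcmc_chain`.
#' @return Data.frame with one row per parameter.
#' @export
chain_diagnostics <- function(chain) {
  s <- chain$samples
  if (is.null(dim(s))) s <- matrix(s, ncol = 1)
  if (nrow(s) == 0) stop("chain_diagnostics: empty chain")
  out <- lapply(seq_len(ncol(s)), function(j) {
    x <- s[, j]
    n <- length(x)
    degenerate <- sd(x) == 0
    ess <- if (degenerate) 0 else ess_ips(x)
    a <- x[seq_len(max(1, floor(0.1 * n)))]
    b <- x[seq.int(floor(0.5 * n) + 1, n)]
    gz <- if (degenerate) NA_real_ else {
      se2 <- var(a) / max(ess_ips(a), 1) + var(b) / max(ess_ips(b), 1)
      (mean(a) - mean(b)) / sqrt(se2)
    }
    q <- quantile(x, c(0.025, 0.5, 0.975), names = FALSE)
    data.frame(parameter = colnames(s)[j] %||% paste0("par", j),
               mean = mean(x), sd = sd(x),
               q2.5 = q[1], q50 = q[2], q97.5 = q[3],
               ess = ess, geweke_z = gz, degenerate = degenerate)
  })
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Posterior-predictive envelopes
#'
#' Simulates the drug-free trajectory for `n_draws` evenly thinned posterior
#' draws and returns pointwise 2.5%/50%/97.5% envelopes per observed
#' compartment at the dataset's observation times.  With
#' `include_noise = TRUE` (default) each draw adds Gaussian observation
#' noise at the dataset's recorded SD, giving a predictive envelope for new
#' observations; with `FALSE` the envelope reflects parameter uncertainty
#' only.
#'
#' @param chain an `mcmc_chain` from [run_dram()].
#' @param dataset the dataset the chain was fitted to.
#' @param n_draws number of posterior draws (<= chain length).
#' @param include_noise add observation noise to each draw.
#' @param seed integer seed for the noise draws.
#' @return Data.frame with columns `time_h`, `compartment`, `lo`, `med`,
#'   `hi`.
#' @export
posterior_predictive <- function(chain, dataset, n_draws = 200,
                                 include_noise = TRUE, seed = 1) {
  n <- nrow(chain$samples)
  if (n_draws > n) stop("posterior_predictive: n_draws exceeds chain length")
  idx <- unique(round(seq(1, n, length.out = n_draws)))
  free_names <- colnames(chain$samples)
  sims <- lapply(idx, function(i) {
    p <- apply_free_params(dataset$true_params,
                           setNames(chain$samples[i, ], free_names))
    if (is.null(p)) return(NULL)
    tc <- try(integrate_model(dataset$initial, p, times = dataset$times),
              silent = TRUE)
    if (inherits(tc, "try-error")) NULL else tc
  })
  sims <- Filter(Negate(is.null), sims)
  if (!length(sims)) stop("posterior_predictive: all draws failed to simulate")
  set.seed(seed)
  out <- list()
  for (v in dataset$observed) {
    mat <- vapply(sims, function(tc) tc[[v]], numeric(length(dataset$times)))
    mat <- matrix(mat, nrow = length(dataset$times))
    if (include_noise && dataset$noise_sd[[v]] > 0)
      mat[] <- pmax(0, mat + rnorm(length(mat), 0, dataset$noise_sd[[v]]))
    qs <- apply(mat, 1, quantile, probs = c(0.025, 0.5, 0.975), names = FALSE)
    out[[v]] <- data.frame(time_h = dataset$times, compartment = v,
                           lo = qs[1, ], med = qs[2, ], hi = qs[3, ])
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Persist / load an MCMC chain as CSV plus JSON metadata
#'
#' One row per iteration (parameter columns plus `log_posterior`); seed,
#' acceptance rate and priors go to `<path>.meta.json`.
#'
#' @param chain an `mcmc_chain`.
#' @param path CSV path.
#' @export
write_chain <- function(chain, path) {
  df <- as.data.frame(chain$samples)
  df$log_posterior <- chain$log_posterior
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(seed = chain$seed, n_iter = chain$n_iter,
               acceptance_rate = chain$acceptance_rate)
  pr <- attr(chain, "priors")
  if (!is.null(pr)) meta$priors <- as.list(as.data.frame(pr))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
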