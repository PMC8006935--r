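#' Integrate the tumor-growth model
#'
#' Solves the drug-free (no `dp`) or drug-treated system with an adaptive
#' Runge-Kutta solver (Dormand-Prince 4(5), deSolve's `ode45`), sampled on a
#' regular dense grid.  Tiny negative numerical excursions are clipped to
#' zero post hoc and counted in the attribute `n_clipped`.
#'
#' @param initial a [cell_state()].
#' @param p a [growth_params()] vector.
#' @param dp optional [drug_effect_params()]; `NULL` for the drug-free model.
#' @param doses optional [dose_pair()]; defaults to (0, 0).
#' @param t_end end of the integration window (hours, > 0).
#' @param times optional explicit output times (overrides `t_end`/`dt`).
#' @param dt output sampling interval (hours).
#' @param rtol,atol solver tolerances (> 0).
#' @param method deSolve method; `"ode45"` by default, `"lsoda"` available
#'   for stiff parameter sets.
#' @return A `time_course`: data.frame with columns `time_h`, `N`, `C`,
#'   `C_R`, `C_S`; parameters used are kept in attributes.
#' @export
integrate_model <- function(initial, p, dp = NULL, doses = NULL,
                            t_end = 300, times = NULL, dt = 1,
                            rtol = 1e-8, atol = 1e-8, method = "ode45") {
  if (is.null(times)) {
    if (t_end <= 0) stop("integrate_model: t_end must be positive")
    times <- seq(0, t_end, by = dt)
    if (times[length(times)] < t_end) times <- c(times, t_end)
  }
  if (rtol <= 0 || atol <= 0) stop("integrate_model: tolerances must be positive")
  parms <- model_parms_vector(p, dp, doses)
  y0 <- unclass(initial)[c("N", "C", "C_R", "C_S")]
  extra <- if (method %in% c("lsoda", "lsode", "vode", "daspk")) list()
           else list(hini = 0.1)  # rk-family needs a finite initial step
  sol <- try(do.call(deSolve::ode, c(list(
    y = y0, times = times, func = "tumor_deriv", parms = parms,
    dllname = "gliomaSynergy", initfunc = "tumor_init",
    method = method, rtol = rtol, atol = atol), extra)), silent = TRUE)
  if (inherits(sol, "try-error") || any(!is.finite(sol)))
    stop("integrate_model: solver failure for parameters [",
         paste(signif(parms, 4), collapse = ", "), "]")
  m <- as.data.frame(unclass(sol))
  names(m) <- c("time_h", "N", "C", "C_R", "C_S")
  vals <- as.matrix(m[, -1])
  n_clipped <- sum(vals < 0)
  if (n_clipped > 0) {
    if (min(vals) < -1e-6)
      warning("integrate_model: negative excursion below -1e-6 clipped")
    vals[vals < 0] <- 0
    m[, -1] <- vals
  }
  structure(m, class = c("time_course", "data.frame"),
            params = p, drug_params = dp, doses = doses,
            n_clipped = n_clipped)
}

#' Steady state of the model
#'
#' Integrates up to `t_max` hours and returns the state at the first sampled
#' time where the relative derivative `|dX/dt| / (X + mu)` falls below `tol`
#' for every compartment; if never reached, the `t_max` state is returned
#' with a warning and attribute `converged = FALSE`.
#'
#' @inheritParams integrate_model
#' @param t_max integration cap (hours).
#' @param tol steady-state tolerance (per hour, relative).
#' @return A [cell_state()] with attributes `time_h` and `converged`.
#' @export
steady_state <- function(initial, p, dp = NULL, doses = NULL,
                         t_max = 300, tol = 1e-6, dt = 1,
                         rtol = 1e-8, atol = 1e-8) {
  if (tol <= 0) stop("steady_state: tol must be positive")
  tc <- integrate_model(initial, p, dp, doses, t_end = t_max, dt = dt,
                        rtol = rtol, atol = atol)
  mu <- p[["mu"]]
  if (is.null(doses)) doses <- dose_pair(0, 0)
  for (i in seq_len(nrow(tc))) {
    st <- c(N = tc$N[i], C = tc$C[i], C_R = tc$C_R[i], C_S = tc$C_S[i])
    dx <- if (is.null(dp)) growth_rhs(st, p) else treated_rhs(st, p, dp, doses)
    if (max(abs(dx) / (st + mu)) < tol) {
      return(structure(cell_state(st[["N"]], st[["C"]], st[["C_R"]], st[["C_S"]]),
                       time_h = tc$time_h[i], converged = TRUE))
    }
  }
  warning("steady_state: not converged by t_max = ", t_max, " h")
  n <- nrow(tc)
  structure(cell_state(tc$N[n], tc$C[n], tc$C_R[n], tc$C_S[n]),
            time_h = tc$time_h[n], converged = FALSE)
}

#' Relative growth under treatment
#'
#' SRB-style readout: `100 * X_treated / X_untreated` for a chosen
#' compartment, with the untreated run using the identical initial state and
#' parameters at zero doses.  `horizon = "fixed"` evaluates at
#' `horizon_h` hours (default 72 h, matching the SRB exposure);
#' `horizon = "steady"` evaluates both runs at steady state (300 h cap).
#'
#' @inheritParams integrate_model
#' @param compartment one of `"C_R"`, `"C_S"`, `"cancer"` (C + C_R + C_S).
#' @param horizon `"fixed"` or `"steady"`.
#' @param horizon_h evaluation time for the fixed horizon (hours).
#' @param t_max,tol steady-state settings (see [steady_state()]).
#' @return Relative growth in percent (100 at zero dose).
#' @export
relative_growth <- function(p, dp, doses, compartment = c("C_R", "C_S", "cancer"),
                            horizon = c("fixed", "steady"),
                            initial = default_initial_state(),
                            horizon_h = 72, t_max = 300, tol = 1e-6,
                            rtol = 1e-8, atol = 1e-8) {
  compartment <- match.arg(compartment)
  horizon <- match.arg(horizon)
  pick <- function(st) {
    if (compartment == "cancer") st[["C"]] + st[["C_R"]] + st[["C_S"]]
    else st[[compartment]]
  }
  end_state <- function(d) {
    if (horizon == "fixed") {
      tc <- integrate_model(initial, p, dp, d, times = c(0, horizon_h),
                            rtol = rtol, atol = atol)
      n <- nrow(tc)
      c(N = tc$N[n], C = tc$C[n], C_R = tc$C_R[n], C_S = tc$C_S[n])
    } else {
      suppressWarnings(
        steady_state(initial, p, dp, d, t_max = t_max, tol = tol,
                     rtol = rtol, atol = atol))
    }
  }
  base <- pick(end_state(dose_pair(0, 0)))
  if (base <= 0)
    stop("relative_growth: untreated abundance is zero at the horizon; ",
         "baseline undefined")
  100 * pick(end_state(doses)) / base
}

#' Write / read a time course as tidy CSV
#'
#' Columns `time_h`, `N`, `C`, `C_R`, `C_S`; values round-trip at full
#' double precision (15 significant digits).
#'
#' @param tc a `time_course` data.frame.
#' @param path CSV file path.
#' @return `read_time_course` returns the time-course data.frame.
#' @export
write_time_course <- function(tc, path) {
  df <- as.data.frame(tc)
  df[] <- lapply(df, function(x) format(x, digits = 15, scientific = TRUE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_time_course
#' @export
read_time_course <- function(path) {
  df <- read.csv(path)
  need <- c("time_h", "N", "C", "C_R", "C_S")
  if (!all(need %in% names(df)))
    stop("read_time_course: missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  structure(df[need], class = c("time_course", "data.frame"))
}
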