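#' Generate synthetic 96-h growth-curve data
#'
#' Simulates the drug-free model and adds i.i.d. Gaussian observation noise,
#' truncated at zero, to the observed compartments.  Emulates 96-h SRB
#' growth kinetics of the sensitive/resistant glioma cell lines; the true
#' parameters are recorded so recovery can be tested.
#'
#' @param true_params a [growth_params()] vector.
#' @param times observation times (hours), default every 8 h over 0-96 h.
#' @param observed compartments observed, default `c("C", "C_R", "C_S")`.
#' @param noise_sd Gaussian observation SD (abundance units).  `NULL`
#'   (default) uses 5% of each observed compartment's trajectory mean.
#' @param seed integer seed; the dataset is reproducible given the seed.
#' @param initial initial [cell_state()].
#' @return List of class `synthetic_growth_data` with elements
#'   `true_params`, `times`, `observations` (data.frame, one column per
#'   observed compartment), `truth` (noise-free trajectory), `noise_sd`
#'   (named per compartment), `observed`, `initial`, `seed`.
#' @export
generate_growth_data <- function(true_params,
                                 times = seq(0, 96, by = 8),
                                 observed = c("C", "C_R", "C_S"),
                                 noise_sd = NULL,
                                 seed = 1,
                                 initial = default_initial_state()) {
  stopifnot(all(observed %in% c("N", "C", "C_R", "C_S")))
  if (!is.null(noise_sd) && any(noise_sd < 0))
    stop("generate_growth_data: noise_sd must be non-negative")
  tc <- integrate_model(initial, true_params, times = times)
  truth <- as.data.frame(tc)[, observed, drop = FALSE]
  if (is.null(noise_sd)) {
    noise_sd <- vapply(truth, function(x) 0.05 * mean(x), numeric(1))
  } else {
    noise_sd <- setNames(rep_len(noise_sd, length(observed)), observed)
  }
  set.seed(seed)
  obs <- truth
  for (v in observed) {
    obs[[v]] <- pmax(0, truth[[v]] + rnorm(length(times), 0, noise_sd[[v]]))
  }
  structure(list(true_params = true_params, times = times,
                 observations = obs, truth = truth,
                 noise_sd = noise_sd, observed = observed,
                 initial = initial, seed = seed),
            class = "synthetic_growth_data")
}

#' Generate synthetic Hill-shaped dose-response observations
#'
#' Emulates SRB triplicate readouts: relative growth
#' `100 * (1 - dose^eta / (ic50^eta + dose^eta))` plus Gaussian noise in
#' percentage points, clipped to `[0, 100 + 3 * noise_sd_pct]`.
#'
#' @param ic50 half-maximal concentration (uM, > 0).
#' @param eta Hill exponent (> 0).
#' @param doses dose levels (uM, >= 0).
#' @param noise_sd_pct Gaussian noise SD in percentage points.
#' @param seed integer seed.
#' @return Data.frame with columns `dose_uM` and `relative_growth_pct`.
#' @export
generate_dose_response_data <- function(ic50, eta, doses,
                                        noise_sd_pct = 0, seed = 1) {
  if (ic50 <= 0 || eta <= 0)
    stop("generate_dose_response_data: ic50 and eta must be positive")
  if (any(doses < 0))
    stop("generate_dose_response_data: doses must be non-negative")
  frac <- ifelse(doses == 0, 0, doses^eta / (ic50^eta + doses^eta))
  g <- 100 * (1 - frac)
  if (noise_sd_pct > 0) {
    set.seed(seed)
    g <- g + rnorm(length(doses), 0, noise_sd_pct)
    g <- pmin(pmax(g, 0), 100 + 3 * noise_sd_pct)
  }
  data.frame(dose_uM = doses, relative_growth_pct = g)
}

#' Write a synthetic growth dataset as CSV plus a JSON sidecar
#'
#' The CSV matches the reader schema of the simulation module (`time_h` plus
#' one column per observed compartment); the sidecar records the seed, noise
#' SDs and true parameters.
#'
#' @param dataset a `synthetic_growth_data` object.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.meta.json`.
#' @export
write_growth_data <- function(dataset, path) {
  df <- cbind(time_h = dataset$times, dataset$observations)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(seed = dataset$seed,
               noise_sd = as.list(dataset$noise_sd),
               observed = dataset$observed,
               true_params = as.list(unclass(dataset$true_params)),
               initial = as.list(unclass(dataset$initial)))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
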