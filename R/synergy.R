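#' Convert relative growth to growth inhibition
#'
#' `inhibition (%) = 100 - growth (%)`; the dose giving 50% inhibition is
#' the same dose giving 50% relative growth (the IC50).
#'
#' @param growth_pct relative growth in percent.
#' @return Growth inhibition in percent.
#' @export
growth_to_inhibition <- function(growth_pct) 100 - growth_pct

#' Dose grid for combination screening
#'
#' Linearly spaced dose levels including zero for both drugs.  Defaults
#' reproduce the screening ranges: TMZ 0-200 uM; acridone 0-2 uM for AC2
#' and 0-6 uM for AC7/AC26.  Grids exceeding the toxicity limits (TMZ
#' 250 uM, acridone 100 uM) are rejected.
#'
#' @param d1_max,d2_max top dose of TMZ / acridone (uM).
#' @param n_levels number of levels per drug (including zero).
#' @param acridone acridone label; sets `d2_max` when that is `NULL`.
#' @return List of class `dose_grid` with `d1_levels`, `d2_levels`,
#'   `spacing`, `acridone`.
#' @export
dose_grid <- function(d1_max = 200, d2_max = NULL, n_levels = 100,
                      acridone = "AC26") {
  acridone <- match.arg(acridone, ACRIDONE_LABELS)
  if (is.null(d2_max)) d2_max <- if (acridone == "AC2") 2 else 6
  if (d1_max <= 0 || d2_max <= 0) stop("dose_grid: top doses must be positive")
  if (d1_max > 250 || d2_max > 100)
    stop("dose_grid: grid exceeds toxicity limits (TMZ 250 uM, acridone 100 uM)")
  structure(list(d1_levels = seq(0, d1_max, length.out = n_levels),
                 d2_levels = seq(0, d2_max, length.out = n_levels),
                 spacing = "linear", acridone = acridone),
            class = "dose_grid")
}

#' Simulated dose-response matrix over a dose grid
#'
#' Relative growth (%) of one compartment for every (d1, d2) pair of the
#' grid, each against the shared zero-dose baseline run.  The (0, 0) entry
#' is exactly 100.
#'
#' @param p a [growth_params()] vector.
#' @param dp a [drug_effect_params()] vector.
#' @param grid a [dose_grid()].
#' @param compartment `"C_R"`, `"C_S"` or `"cancer"`.
#' @param horizon `"fixed"` (72-h SRB-style readout, default) or
#'   `"steady"` (steady-state readout, 300-h cap).
#' @param initial initial [cell_state()].
#' @param horizon_h fixed-horizon evaluation time (hours).
#' @param rtol,atol solver tolerances.
#' @return Matrix of class `dose_response_matrix` (`d1` rows x `d2`
#'   columns, in percent) with attributes `grid`, `compartment`, `horizon`.
#' @export
dose_response_matrix <- function(p, dp, grid,
                                 compartment = c("C_R", "C_S", "cancer"),
                                 horizon = c("fixed", "steady"),
                                 initial = default_initial_state(),
                                 horizon_h = 72,
                                 rtol = 1e-6, atol = 1e-6) {
  compartment <- match.arg(compartment)
  horizon <- match.arg(horizon)
  pick <- function(st) {
    if (compartment == "cancer") st[["C"]] + st[["C_R"]] + st[["C_S"]]
    else st[[compartment]]
  }
  end_state <- function(d1, d2) {
    doses <- dose_pair(d1, d2)
    if (horizon == "fixed") {
      tc <- integrate_model(initial, p, dp, doses, times = c(0, horizon_h),
                            rtol = rtol, atol = atol)
      nr <- nrow(tc)
      c(N = tc$N[nr], C = tc$C[nr], C_R = tc$C_R[nr], C_S = tc$C_S[nr])
    } else {
      suppressWarnings(steady_state(initial, p, dp, doses,
                                    rtol = rtol, atol = atol))
    }
  }
  base <- pick(end_state(0, 0))
  if (base <= 0)
    stop("dose_response_matrix: zero untreated baseline at the horizon")
  n1 <- length(grid$d1_levels)
  n2 <- length(grid$d2_levels)
  vals <- matrix(NA_real_, n1, n2,
                 dimnames = list(signif(grid$d1_levels, 6),
                                 signif(grid$d2_levels, 6)))
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      if (grid$d1_levels[i] == 0 && grid$d2_levels[j] == 0) {
        vals[i, j] <- 100
        next
      }
      st <- try(end_state(grid$d1_levels[i], grid$d2_levels[j]), silent = TRUE)
      if (inherits(st, "try-error"))
        stop("dose_response_matrix: solver failure at (d1 = ",
             grid$d1_levels[i], ", d2 = ", grid$d2_levels[j], ")")
      vals[i, j] <- 100 * pick(st) / base
    }
  }
  structure(vals, class = c("dose_response_matrix", "matrix"),
            grid = grid, compartment = compartment, horizon = horizon)
}

#' Bliss-independence expected inhibition
#'
#' Expected fractional inhibition of two non-interacting drugs:
#' `yA + yB - yA * yB`.
#'
#' @param yA,yB fractional inhibitions in `[0, 1]`.
#' @return Expected fractional inhibition in `[0, 1]`.
#' @export
bliss_expected <- function(yA, yB) {
  if (any(yA < 0 | yA > 1) || any(yB < 0 | yB > 1))
    stop("bliss_expected: inhibitions must lie in [0, 1]")
  yA + yB - yA * yB
}

#' Bliss synergy surface from a dose-response matrix
#'
#' The monotherapy margins (first row: d1 = 0; first column: d2 = 0)
#' define the single-drug fractional inhibitions; the score per cell is the
#' observed percent inhibition minus the Bliss-expected percent inhibition
#' `100 * bliss_expected(yA, yB)`, in percentage points.  Any zero-dose
#' margin scores exactly 0.
#'
#' Sign convention: this is the deviation of the inhibition response from
#' the Bliss independence reference, and the study's surface plots label
#' negative values as synergy and positive values as antagonism; the same
#' convention is kept here.  Note that a negative deviation on the
#' inhibition scale literally means less combined inhibition than
#' independent action would predict; the tumor model produces it through
#' regrowth compensation (Gompertz growth accelerates as a compartment is
#' depleted) and replenishment of the killed compartments from the
#' undifferentiated cancer pool.  See the methods vignette.
#'
#' @param matrix a [dose_response_matrix()] whose grid includes zero doses.
#' @return Matrix of class `synergy_surface` (same shape, percentage
#'   points) with the source matrix attributes.
#' @export
synergy_surface <- function(matrix) {
  grid <- attr(matrix, "grid")
  if (is.null(grid) || grid$d1_levels[1] != 0 || grid$d2_levels[1] != 0)
    stop("synergy_surface: monotherapy margins (zero doses) are required")
  vals <- unclass(matrix)
  yA <- (100 - vals[, 1]) / 100   # TMZ alone, by d1 level
  yB <- (100 - vals[1, ]) / 100   # acridone alone, by d2 level
  yA <- pmin(pmax(yA, 0), 1)
  yB <- pmin(pmax(yB, 0), 1)
  expected_inhibition <- 100 * outer(yA, yB, bliss_expected)
  score <- (100 - vals) - expected_inhibition
  score[1, ] <- 0
  score[, 1] <- 0
  structure(score, class = c("synergy_surface", "matrix"),
            grid = grid, compartment = attr(matrix, "compartment"),
            horizon = attr(matrix, "horizon"))
}

#' Interpolate the IC50 from a dose-response curve
#'
#' Log-dose linear interpolation between the two observations bracketing
#' 50% relative growth; the zero dose is excluded from the log axis.  If
#' the curve never crosses 50%, an error reports the maximum inhibition
#' reached.
#'
#' @param doses dose levels (uM).
#' @param growth_pct relative growth (%) at each dose.
#' @return Interpolated IC50 (uM).
#' @export
ic50_from_curve <- function(doses, growth_pct) {
  stopifnot(length(doses) == length(growth_pct))
  ord <- order(doses)
  doses <- doses[ord]
  growth_pct <- growth_pct[ord]
  pos <- doses > 0
  doses <- doses[pos]
  growth_pct <- growth_pct[pos]
  below <- growth_pct <= 50
  if (!any(below) || all(below))
    stop("ic50_from_curve: curve does not cross 50% growth ",
         "(max inhibition reached: ",
         signif(max(100 - growth_pct), 4), "%)")
  i <- which(below)[1]
  if (i == 1) return(doses[1])
  g1 <- growth_pct[i - 1]; g2 <- growth_pct[i]
  l1 <- log10(doses[i - 1]); l2 <- log10(doses[i])
  10^(l1 + (50 - g1) * (l2 - l1) / (g2 - g1))
}

#' Selectivity index
#'
#' `SI = CC50 (non-cancerous Vero cells) / IC50 (cancer cells)`; a wider
#' value means the drug kills cancer cells at concentrations further below
#' its host-cell toxicity.
#'
#' @param cc50_vero CC50 on Vero cells (uM, > 0).
#' @param ic50_cancer IC50 on the cancer line (uM, > 0).
#' @return Selectivity index (unitless, 2-decimal rounding applied).
#' @export
selectivity_index <- function(cc50_vero, ic50_cancer) {
  if (cc50_vero <= 0 || ic50_cancer <= 0)
    stop("selectivity_index: inputs must be positive")
  round(cc50_vero / ic50_cancer, 2)
}

#' IC50 fold change under combination
#'
#' Ratio `final / initial` of a drug's IC50 when used in combination versus
#' alone, and the percent change reported as a magnitude
#' `|final - initial| / initial * 100`.
#'
#' @param initial_ic50,final_ic50 IC50s (uM, > 0).
#' @return List with `ratio` and `percent`.
#' @export
fold_change <- function(initial_ic50, final_ic50) {
  if (initial_ic50 <= 0 || final_ic50 <= 0)
    stop("fold_change: IC50s must be positive")
  list(ratio = final_ic50 / initial_ic50,
       percent = abs(final_ic50 - initial_ic50) / initial_ic50 * 100)
}

#' Combination index with interpretation band
#'
#' Chou-Talalay-style index
#' `CI = d1_combo / ic50_d1_alone + d2_combo / ic50_d2_alone`, classified
#' as synergism (< 0.8), additive (0.8-1.2) or antagonism (> 1.2).
#'
#' @param d1_combo,d2_combo doses of the two drugs in the combination
#'   achieving the reference effect (uM; one may be 0 for a degenerate
#'   single-agent check).
#' @param ic50_d1_alone,ic50_d2_alone monotherapy IC50s (uM, > 0).
#' @return List with `ci`, `interpretation`, and `single_agent` (TRUE when
#'   one combination dose is zero).
#' @export
combination_index <- function(d1_combo, d2_combo,
                              ic50_d1_alone, ic50_d2_alone) {
  if (ic50_d1_alone <= 0 || ic50_d2_alone <= 0)
    stop("combination_index: monotherapy IC50s must be positive")
  if (d1_combo < 0 || d2_combo < 0 || (d1_combo == 0 && d2_combo == 0))
    stop("combination_index: combination doses must be non-negative and not both zero")
  ci <- d1_combo / ic50_d1_alone + d2_combo / ic50_d2_alone
  band <- if (ci < 0.8) "synergism" else if (ci <= 1.2) "additive" else "antagonism"
  list(ci = ci, interpretation = band,
       single_agent = (d1_combo == 0 || d2_combo == 0))
}

#' Write / read a dose-indexed matrix as CSV
#'
#' The header row carries the d2 dose levels and the first column the d1
#' levels; values round-trip at full double precision.
#'
#' @param m a `dose_response_matrix` or `synergy_surface`.
#' @param path CSV path.
#' @return `read_dose_matrix` returns a plain matrix with dose-level
#'   dimnames.
#' @export
write_dose_matrix <- function(m, path) {
  df <- data.frame(d1 = rownames(m), unclass(m), check.names = FALSE)
  names(df) <- c("d1_uM\\d2_uM", colnames(m))
  write.csv(format(df, digits = 15), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dose_matrix
#' @export
read_dose_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  m
}
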