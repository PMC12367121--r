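#' Error metrics between two membrane-potential traces
#'
#' Compares a test trace against a reference on a shared time base:
#' mean absolute error, root-mean-square error, RMSE normalized by the
#' reference's range (`nrmse`, reported as a fraction; multiply by 100 for
#' percent), and Pearson correlation.
#'
#' @param reference,test Numeric series of equal length, or
#'   `fhn_trajectory` objects (their `V` columns are compared and the time
#'   bases must agree).
#' @return A one-row tibble of class `fhn_metrics`: `mae`, `rmse`, `nrmse`,
#'   `corr`, `n`, `v_max`, `v_min`.
#' @examples
#' compare_traces(c(0, 1, 2), c(0, 1, 3))  # MAE 1/3, RMSE 1/sqrt(3)
#' @export
compare_traces <- function(reference, test) {
  if (is.data.frame(reference)) {
    if (!is.data.frame(test)) abort("both inputs must be trajectories, or both numeric.")
    if (nrow(reference) != nrow(test) ||
        max(abs(reference$t - test$t)) > 1e-9) {
      abort("trajectories must share one time base (equal length, aligned t).")
    }
    reference <- reference$V
    test <- test$V
  }
  reference <- as.double(reference)
  test <- as.double(test)
  if (length(reference) != length(test)) {
    abort("series lengths differ; align the traces before comparing.")
  }
  n <- length(reference)
  if (n < 2) abort("need at least two samples.")
  d <- test - reference
  v_max <- max(reference)
  v_min <- min(reference)
  if (sd(reference) == 0 || sd(test) == 0) {
    abort("a series has zero variance; correlation is undefined.")
  }
  out <- tibble(
    mae = mean(abs(d)),
    rmse = sqrt(mean(d^2)),
    nrmse = sqrt(mean(d^2)) / (v_max - v_min),
    corr = cor(reference, test),
    n = n,
    v_max = v_max,
    v_min = v_min
  )
  class(out) <- c("fhn_metrics", class(out))
  out
}

#' @export
glance.fhn_metrics <- function(x, ...) as_tibble(x)

#' Normalized RMSE between two Lyapunov-exponent curves
#'
#' RMSE between the exponent curves of the two models on a shared parameter
#' grid, normalized by the range of the reference curve and reported in
#' percent. This is the statistic used to quantify how closely the CORDIC
#' model's chaos map follows the original's.
#'
#' @param mle_ref,mle_test Numeric exponent curves on the same grid, or
#'   tibbles from [mle_sweep()] (their `lambda` columns are used and the
#'   parameter grids must agree).
#' @return Percentage (scalar).
#' @examples
#' nrmse_mle(c(0, 1), c(0, 0))  # 100/sqrt(2)
#' @export
nrmse_mle <- function(mle_ref, mle_test) {
  if (is.data.frame(mle_ref)) {
    if (!is.data.frame(mle_test)) abort("both inputs must be sweeps, or both numeric.")
    if (nrow(mle_ref) != nrow(mle_test) ||
        max(abs(mle_ref$param - mle_test$param)) > 1e-9) {
      abort("sweeps must share one parameter grid.")
    }
    mle_ref <- mle_ref$lambda
    mle_test <- mle_test$lambda
  }
  mle_ref <- as.double(mle_ref)
  mle_test <- as.double(mle_test)
  if (length(mle_ref) != length(mle_test)) abort("curve lengths differ.")
  rng <- max(mle_ref) - min(mle_ref)
  if (rng == 0) abort("reference curve has zero range; nRMSE is undefined.")
  100 * sqrt(mean((mle_test - mle_ref)^2)) / rng
}

#' Hardware cost functions
#'
#' Composite figures of merit for a digital neuron implementation:
#' `CF1 = MAE / f_max` trades approximation error against the achievable
#' clock frequency, and `CF2 = MAE * P / f_max` additionally charges for
#' power consumption. Units follow the implementation tables: frequency in
#' MHz, power in mW (converted to Hz and W internally), so e.g.
#' `MAE = 0.015` at 320 MHz gives `CF1 = 46.88e-12`.
#'
#' @param mae Simulation mean absolute error (dimensionless).
#' @param freq_mhz Maximum clock frequency in MHz.
#' @param power_mw Power consumption in mW, or `NULL` if unreported (then
#'   `cf2` is `NA`).
#' @return A one-row tibble with columns `cf1`, `cf2`.
#' @examples
#' cost_functions(0.00083, 232.156, 182.41)
#' @export
cost_functions <- function(mae, freq_mhz, power_mw = NULL) {
  stopifnot(is.finite(mae), is.finite(freq_mhz))
  if (mae < 0) abort("`mae` must be non-negative.")
  if (freq_mhz <= 0) abort("`freq_mhz` must be positive.")
  freq_hz <- freq_mhz * 1e6
  cf1 <- mae / freq_hz
  cf2 <- if (is.null(power_mw)) {
    NA_real_
  } else {
    if (!is.finite(power_mw) || power_mw <= 0) abort("`power_mw` must be positive.")
    mae * (power_mw / 1000) / freq_hz
  }
  tibble(cf1 = cf1, cf2 = cf2)
}
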