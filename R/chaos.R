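#' 1D bifurcation diagram under sinusoidal drive
#'
#' Integrates the model from rest for each value of the swept drive
#' parameter (amplitude `I_in` at fixed frequency, or frequency at fixed
#' amplitude), discards the transient, and records every strict local
#' maximum of `V(t)`. Peak heights are refined by a three-point parabolic
#' fit so that branch splitting is not masked by the sampling grid. Windows
#' with one or two distinct peak values are simple periodic responses,
#' `2^k`-value windows mark period doubling, and wide unstructured peak sets
#' mark chaos.
#'
#' All sweep points are co-integrated with vectorized forward Euler at the
#' model's `dt`.
#'
#' @param model `"fhn"` or `"cordic"`.
#' @param params An [fhn_params()].
#' @param sweep `"I_in"` or `"f"`: which drive parameter varies.
#' @param sweep_values Values of the swept parameter.
#' @param I_in Fixed amplitude when sweeping frequency.
#' @param f Fixed frequency when sweeping amplitude.
#' @param transient Time discarded before sampling peaks.
#' @param horizon Total integration time per sweep point.
#' @param sched [cordic_schedule()] for the CORDIC model.
#' @return A tibble of class `fhn_bifurcation` with columns `param`, `peak`
#'   (one row per recorded peak), plus sweep metadata attributes.
#' @examples
#' bd <- bifurcation_diagram(sweep_values = c(0.5, 1), f = 0.13,
#'                           transient = 200, horizon = 1000)
#' count_peak_clusters(bd)
#' @export
bifurcation_diagram <- function(model = c("fhn", "cordic"),
                                params = fhn_params(),
                                sweep = c("I_in", "f"),
                                sweep_values,
                                I_in = 1,
                                f = 0.01,
                                transient = 500,
                                horizon = 4500,
                                sched = cordic_schedule()) {
  model <- match.arg(model)
  sweep <- match.arg(sweep)
  if (missing(sweep_values) || length(sweep_values) == 0) {
    abort("`sweep_values` must be a non-empty numeric vector.")
  }
  if (horizon <= transient) abort("`horizon` must exceed `transient`.")
  sweep_values <- sort(as.double(sweep_values))
  amp <- if (sweep == "I_in") sweep_values else rep_len(I_in, length(sweep_values))
  frq <- if (sweep == "f") sweep_values else rep_len(f, length(sweep_values))

  peaks <- euler_sweep_peaks(model, params, amp, frq, transient, horizon, sched)
  out <- tibble(
    param = rep(sweep_values, lengths(peaks)),
    peak = unlist(peaks, use.names = FALSE) %||% numeric()
  )
  class(out) <- c("fhn_bifurcation", class(out))
  attr(out, "model") <- model
  attr(out, "sweep") <- sweep
  attr(out, "fixed") <- if (sweep == "I_in") c(f = f) else c(I_in = I_in)
  attr(out, "transient") <- transient
  attr(out, "horizon") <- horizon
  attr(out, "sweep_values") <- sweep_values
  out
}

# vectorized Euler over (amplitude, frequency) pairs, recording local maxima
# of V with parabolic refinement
euler_sweep_peaks <- function(model, params, amp, frq, transient, horizon,
                              sched) {
  dt <- params$dt
  a <- params$a; b <- params$b; Tc <- params$T
  m <- length(amp)
  cube <- if (model == "fhn") function(v) v^3
          else function(v) cordic_cube_real(v, sched$i_min, sched$i_max)
  V <- W <- numeric(m)
  nt <- round(transient / dt)
  nh <- round((horizon - transient) / dt)
  tt <- 0
  for (n in seq_len(nt)) {
    I <- amp * sin(2 * pi * frq * tt)
    Vn <- V + dt * (V - cube(V) / 3 - W + I)
    W <- W + (dt / Tc) * (a - b * W + V)
    V <- Vn
    tt <- tt + dt
  }
  peaks <- vector("list", m)
  prev <- V
  prev2 <- V
  for (n in seq_len(nh)) {
    I <- amp * sin(2 * pi * frq * tt)
    Vn <- V + dt * (V - cube(V) / 3 - W + I)
    W <- W + (dt / Tc) * (a - b * W + V)
    tt <- tt + dt
    idx <- which(prev > prev2 & prev >= Vn)
    for (j in idx) {
      y1 <- prev2[j]; y2 <- prev[j]; y3 <- Vn[j]
      den <- y1 - 2 * y2 + y3
      pv <- if (abs(den) > 1e-12) y2 - (y3 - y1)^2 / (8 * den) else y2
      peaks[[j]] <- c(peaks[[j]], pv)
    }
    prev2 <- prev
    prev <- Vn
    V <- Vn
  }
  peaks
}

#' Count distinct peak branches per sweep point
#'
#' Sorts the recorded peak heights at each swept parameter value and counts
#' clusters separated by more than `tol`. A period-k response shows k
#' branches (counting the subthreshold maxima of the forced subthreshold
#' oscillation as branches of their own); chaotic windows show counts far
#' above any small period.
#'
#' @param bif An `fhn_bifurcation` from [bifurcation_diagram()].
#' @param tol Cluster separation tolerance on the peak height.
#' @return A tibble with columns `param`, `n_peaks`, `n_clusters`.
#' @export
count_peak_clusters <- function(bif, tol = 1e-3) {
  stopifnot(inherits(bif, "fhn_bifurcation"))
  counted <- bif |>
    as_tibble() |>
    group_by(.data$param) |>
    summarise(
      n_peaks = dplyr::n(),
      n_clusters = {
        p <- sort(.data$peak)
        if (length(p) == 0) 0L else sum(diff(p) > tol) + 1L
      },
      .groups = "drop"
    )
  # sweep points whose response has no local maxima (settled fixed points)
  # are reported with zero peaks rather than dropped
  all_params <- attr(bif, "sweep_values") %||% unique(bif$param)
  missing <- setdiff(all_params, counted$param)
  if (length(missing)) {
    counted <- bind_rows(
      counted,
      tibble(param = missing, n_peaks = 0L, n_clusters = 0L)
    )
  }
  arrange(counted, .data$param)
}

#' Maximum Lyapunov exponent by two-trajectory renormalization
#'
#' Wolf-style estimate of the largest Lyapunov exponent: a reference and a
#' perturbed trajectory (initial separation `d0`) are co-integrated; every
#' `renorm_interval` time units the log separation growth is accumulated and
#' the perturbed state is rescaled back to distance `d0` along the current
#' separation vector. The estimate is `lambda = sum(log(d_n/d0)) / total
#' time`. The two-trajectory form needs no Jacobian, so it applies equally
#' to the CORDIC staircase model. `lambda < 0` marks a stable fixed point,
#' `lambda ~ 0` periodic/bifurcating responses and `lambda > 0` chaos.
#'
#' The default separation is model-dependent: `1e-8` for the smooth model,
#' one staircase step `2^-i_max` for the CORDIC model. A probe below the
#' tread width of the staircase nonlinearity measures the jump between
#' treads rather than the divergence of the flow and reports spuriously
#' positive exponents in every regime; at or above the tread width the two
#' models' exponent curves agree closely.
#'
#' @param model `"fhn"` or `"cordic"`.
#' @param params An [fhn_params()].
#' @param drive A [drive_constant()] or [drive_sinusoid()].
#' @param d0 Initial separation; `NULL` picks the per-model default
#'   (see Details).
#' @param renorm_interval Time between renormalizations.
#' @param transient Settling time before the estimate starts.
#' @param horizon Total time (transient included).
#' @param sched [cordic_schedule()] for the CORDIC model.
#' @return An object of class `fhn_mle`: list with `lambda`, `n_renorm`,
#'   `d0`, `horizon`, `model`, `drive`. `glance()` returns it as a one-row
#'   tibble.
#' @examples
#' m <- max_lyapunov("fhn", drive = drive_constant(2),
#'                   transient = 100, horizon = 600)
#' m$lambda < 0  # stable node
#' @export
max_lyapunov <- function(model = c("fhn", "cordic"),
                         params = fhn_params(),
                         drive = drive_sinusoid(1, 0.13),
                         d0 = NULL,
                         renorm_interval = 1,
                         transient = 500,
                         horizon = 5000,
                         sched = cordic_schedule()) {
  model <- match.arg(model)
  d0 <- d0 %||% default_d0(model, sched)
  stopifnot(inherits(drive, "drive_spec"), d0 > 0, renorm_interval > 0,
            horizon > transient)
  res <- mle_engine(model, params,
                    amp = drive$I_in, frq = drive$f,
                    d0 = d0, renorm_interval = renorm_interval,
                    transient = transient, horizon = horizon, sched = sched)
  structure(
    list(lambda = res$lambda[1], n_renorm = res$n_renorm, d0 = d0,
         renorm_interval = renorm_interval, transient = transient,
         horizon = horizon, model = model, drive = drive),
    class = "fhn_mle"
  )
}

#' @export
format.fhn_mle <- function(x, ...) {
  sprintf("<fhn_mle: model %s, lambda = %.5f (%d renormalizations)>",
          x$model, x$lambda, x$n_renorm)
}

#' @export
print.fhn_mle <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
glance.fhn_mle <- function(x, ...) {
  tibble(model = x$model, lambda = x$lambda, n_renorm = x$n_renorm,
         d0 = x$d0, renorm_interval = x$renorm_interval,
         transient = x$transient, horizon = x$horizon)
}

#' @export
tidy.fhn_mle <- function(x, ...) glance(x)

#' Maximum Lyapunov exponent across a drive-parameter sweep
#'
#' Runs the two-trajectory estimator of [max_lyapunov()] for every value of
#' the swept drive parameter, co-integrating all sweep points with
#' vectorized Euler. This is the curve the bifurcation diagrams are read
#' against, and the input to [nrmse_mle()] when comparing the two models.
#'
#' @inheritParams bifurcation_diagram
#' @inheritParams max_lyapunov
#' @return A tibble with columns `param`, `lambda`.
#' @export
mle_sweep <- function(model = c("fhn", "cordic"),
                      params = fhn_params(),
                      sweep = c("I_in", "f"),
                      sweep_values,
                      I_in = 1,
                      f = 0.13,
                      d0 = NULL,
                      renorm_interval = 1,
                      transient = 500,
                      horizon = 5000,
                      sched = cordic_schedule()) {
  model <- match.arg(model)
  sweep <- match.arg(sweep)
  d0 <- d0 %||% default_d0(model, sched)
  if (missing(sweep_values) || length(sweep_values) == 0) {
    abort("`sweep_values` must be a non-empty numeric vector.")
  }
  sweep_values <- as.double(sweep_values)
  amp <- if (sweep == "I_in") sweep_values else rep_len(I_in, length(sweep_values))
  frq <- if (sweep == "f") sweep_values else rep_len(f, length(sweep_values))
  res <- mle_engine(model, params, amp, frq, d0, renorm_interval,
                    transient, horizon, sched)
  tibble(param = sweep_values, lambda = res$lambda)
}

default_d0 <- function(model, sched) {
  if (model == "fhn") 1e-8 else 2^(-sched$i_max)
}

mle_engine <- function(model, params, amp, frq, d0, renorm_interval,
                       transient, horizon, sched) {
  dt <- params$dt
  a <- params$a; b <- params$b; Tc <- params$T
  m <- length(amp)
  cube <- if (model == "fhn") function(v) v^3
          else function(v) cordic_cube_real(v, sched$i_min, sched$i_max)
  step <- function(V, W, I) {
    Vn <- V + dt * (V - cube(V) / 3 - W + I)
    Wn <- W + (dt / Tc) * (a - b * W + V)
    list(V = Vn, W = Wn)
  }
  V <- W <- numeric(m)
  nt <- round(transient / dt)
  tt <- 0
  for (n in seq_len(nt)) {
    I <- ifelse(frq > 0, amp * sin(2 * pi * frq * tt), amp)
    s <- step(V, W, I)
    V <- s$V; W <- s$W
    tt <- tt + dt
  }
  Vp <- V + d0
  Wp <- W
  spr <- max(1L, round(renorm_interval / dt))
  nseg <- as.integer(round((horizon - transient) / dt) %/% spr)
  if (nseg < 1) abort("`horizon - transient` must cover at least one renormalization interval.")
  S <- numeric(m)
  for (seg in seq_len(nseg)) {
    for (k in seq_len(spr)) {
      I <- ifelse(frq > 0, amp * sin(2 * pi * frq * tt), amp)
      s <- step(V, W, I)
      sp <- step(Vp, Wp, I)
      V <- s$V; W <- s$W
      Vp <- sp$V; Wp <- sp$W
      tt <- tt + dt
    }
    d <- sqrt((Vp - V)^2 + (Wp - W)^2)
    if (seg == 1 && any(!is.finite(d))) {
      abort("separation overflowed before the first renormalization; reduce `renorm_interval` or `d0`.")
    }
    d[d == 0] <- .Machine$double.eps
    S <- S + log(d / d0)
    scl <- d0 / d
    Vp <- V + (Vp - V) * scl
    Wp <- W + (Wp - W) * scl
  }
  list(lambda = S / (nseg * spr * dt), n_renorm = nseg)
}

#' Lyapunov exponent of a one-dimensional map
#'
#' The same two-trajectory renormalization estimator as [max_lyapunov()],
#' applied to an iterated scalar map with renormalization after every
#' iteration. Serves as the estimator's validation harness: for the
#' logistic map with growth parameter 4 the exponent is exactly `log(2)`.
#'
#' @param map A function `x -> f(x)`.
#' @param x0 Initial point.
#' @param n_iter Iterations used for the estimate.
#' @param d0 Perturbation size.
#' @param discard Iterations discarded before estimating.
#' @return Estimated Lyapunov exponent (per iteration).
#' @examples
#' max_lyapunov_map(logistic_map(4), n_iter = 2000)  # ~ log(2)
#' @export
max_lyapunov_map <- function(map, x0 = 0.2, n_iter = 5000, d0 = 1e-8,
                             discard = 100) {
  stopifnot(is.function(map), n_iter > 0, d0 > 0)
  x <- x0
  for (i in seq_len(discard)) x <- map(x)
  y <- x + d0
  S <- 0
  for (i in seq_len(n_iter)) {
    x <- map(x)
    y <- map(y)
    d <- abs(y - x)
    if (d == 0) d <- .Machine$double.eps
    S <- S + log(d / d0)
    y <- x + sign(y - x) * d0
  }
  S / n_iter
}

#' @rdname max_lyapunov_map
#' @param r Logistic growth parameter.
#' @export
logistic_map <- function(r = 4) {
  force(r)
  function(x) r * x * (1 - x)
}

#' Post-transient phase-plane orbit
#'
#' Drops the transient from a trajectory and returns the remaining `(V, W)`
#' points, the raw material of phase-portrait plots and orbit-closure
#' checks.
#'
#' @param traj An `fhn_trajectory`.
#' @param transient Time to discard from the start.
#' @return A tibble with columns `t`, `V`, `W`.
#' @export
phase_orbit <- function(traj, transient = 500) {
  stopifnot(is.data.frame(traj), all(c("t", "V", "W") %in% names(traj)))
  if (max(traj$t) <= transient) {
    abort("trajectory must extend beyond the transient.")
  }
  out <- as_tibble(traj)[traj$t > transient, c("t", "V", "W")]
  class(out) <- c("fhn_orbit", class(out))
  out
}
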