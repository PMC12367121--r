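#' FitzHugh-Nagumo model parameters
#'
#' The two-variable excitable-membrane model
#' \deqn{dV/dt = V - V^3/3 - W + I(t)}
#' \deqn{dW/dt = (a - b W + V) / T}
#' with membrane potential `V`, recovery variable `W`, recovery offset `a`,
#' recovery gain `b` and recovery time constant `T`. Defaults are the
#' classical excitable regime `a = 0.7`, `b = 0.8`, `T = 12.5`; these values
#' also reproduce the reference equilibria and Jacobians exactly (the
#' Jacobian entry `D = -b/T = -0.064` pins `b = 0.8`). The Euler step
#' defaults to `dt = 2^-5`, a power of two so the step multiplication is a
#' 5-bit right shift in the fixed-point backend.
#'
#' @param a Recovery offset (dimensionless).
#' @param b Recovery gain (dimensionless).
#' @param T Recovery time constant (model time units, labelled ms).
#' @param dt Forward-Euler step.
#' @return An object of class `fhn_params`.
#' @examples
#' fhn_params()
#' fhn_params(a = 0.8, b = 0.7)  # alternative published assignment
#' @export
fhn_params <- function(a = 0.7, b = 0.8, T = 12.5, dt = 2^-5) {
  stopifnot(is.finite(a), is.finite(b), is.finite(T), is.finite(dt))
  if (T <= 0) abort("`T` must be positive.")
  if (dt <= 0) abort("`dt` must be positive.")
  structure(list(a = a, b = b, T = T, dt = dt), class = "fhn_params")
}

#' @export
format.fhn_params <- function(x, ...) {
  sprintf("<fhn_params: a=%g b=%g T=%g dt=%g>", x$a, x$b, x$T, x$dt)
}

#' @export
print.fhn_params <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Input current specification
#'
#' Constant drive `I(t) = I_in` or sinusoidal drive
#' `I(t) = I_in * sin(2 pi f t)`. Frequencies follow the model's time axis
#' (cycles per model time unit, labelled Hz with time in ms).
#'
#' @param I_in Amplitude (mA).
#' @param f Frequency for the sinusoid.
#' @return An object of class `drive_spec`.
#' @examples
#' drive_constant(0.5)
#' drive_sinusoid(1, f = 0.13)
#' @export
drive_constant <- function(I_in) {
  stopifnot(is.finite(I_in))
  structure(list(kind = "constant", I_in = I_in, f = 0), class = "drive_spec")
}

#' @rdname drive_constant
#' @export
drive_sinusoid <- function(I_in, f) {
  stopifnot(is.finite(I_in), is.finite(f), f >= 0)
  structure(list(kind = "sinusoid", I_in = I_in, f = f), class = "drive_spec")
}

#' @rdname drive_constant
#' @param drive A `drive_spec`.
#' @param t Time points at which to evaluate the drive.
#' @export
drive_current <- function(drive, t) {
  stopifnot(inherits(drive, "drive_spec"))
  if (drive$kind == "constant") rep_len(drive$I_in, length(t))
  else drive$I_in * sin(2 * pi * drive$f * t)
}

#' @export
format.drive_spec <- function(x, ...) {
  if (x$kind == "constant") sprintf("<drive: constant I=%g mA>", x$I_in)
  else sprintf("<drive: %g*sin(2*pi*%g*t) mA>", x$I_in, x$f)
}

#' @export
print.drive_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Model right-hand sides
#'
#' `fhn_rhs()` evaluates the original model's derivatives; `cordic_fhn_rhs()`
#' replaces the cubic term with the two-stage CORDIC cube (the recovery
#' equation is unchanged).
#'
#' @param V,W State values (vectorized).
#' @param params An [fhn_params()].
#' @param I Input current (recycled against the states).
#' @param sched [cordic_schedule()] for the CORDIC nonlinearity.
#' @return A tibble with columns `dV`, `dW`.
#' @examples
#' fhn_rhs(0, 0, I = 0)  # (0, a/T)
#' @export
fhn_rhs <- function(V, W, params = fhn_params(), I = 0) {
  stopifnot(all(is.finite(V)), all(is.finite(W)), all(is.finite(I)))
  tibble(
    dV = V - V^3 / 3 - W + I,
    dW = (params$a - params$b * W + V) / params$T
  )
}

#' @rdname fhn_rhs
#' @export
cordic_fhn_rhs <- function(V, W, params = fhn_params(), I = 0,
                           sched = cordic_schedule()) {
  stopifnot(all(is.finite(V)), all(is.finite(W)), all(is.finite(I)))
  cube <- as.double(cordic_cube(V, sched))
  tibble(
    dV = V - cube / 3 - W + I,
    dW = (params$a - params$b * W + V) / params$T
  )
}

new_trajectory <- function(t, V, W, model, backend, params, drive,
                           extra = list()) {
  out <- tibble(t = t, V = V, W = W)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  class(out) <- c("fhn_trajectory", class(out))
  attr(out, "model") <- model
  attr(out, "backend") <- backend
  attr(out, "params") <- params
  attr(out, "drive") <- drive
  out
}

#' Continuous-time simulation (adaptive Runge-Kutta)
#'
#' Integrates either model with the Dormand-Prince 4(5) pair (`deSolve`'s
#' `ode45`), returning the solution on a regular output grid. Default error
#' tolerances are `rtol = 1e-8`, `atol = 1e-10` for the smooth model. The
#' CORDIC model's right-hand side is a staircase with jumps of order
#' `2^-i_max / 3`, so its defaults are relaxed to `rtol = 1e-6`,
#' `atol = 1e-8`: tighter control only forces the integrator to resolve each
#' recoding discontinuity without improving the trajectory below the
#' staircase granularity.
#'
#' @param model `"fhn"` (original) or `"cordic"`.
#' @param params An [fhn_params()].
#' @param drive A [drive_constant()] or [drive_sinusoid()].
#' @param t_span Integration interval `c(t0, t1)`; a zero-length span
#'   returns the initial state.
#' @param init Initial `c(V, W)`; both variables start at zero by default.
#' @param sched [cordic_schedule()] for the CORDIC nonlinearity.
#' @param rtol,atol Solver tolerances; `NULL` picks the per-model defaults.
#' @param sample_dt Output grid spacing.
#' @return An `fhn_trajectory` tibble with columns `t`, `V`, `W`.
#' @examples
#' tr <- simulate_continuous("fhn", drive = drive_constant(0.5),
#'                           t_span = c(0, 100))
#' glance(tr)
#' @export
simulate_continuous <- function(model = c("fhn", "cordic"),
                                params = fhn_params(),
                                drive = drive_constant(0.5),
                                t_span = c(0, 1000),
                                init = c(0, 0),
                                sched = cordic_schedule(),
                                rtol = NULL, atol = NULL,
                                sample_dt = 0.1) {
  model <- match.arg(model)
  stopifnot(inherits(params, "fhn_params"), inherits(drive, "drive_spec"),
            length(init) == 2, all(is.finite(init)))
  if (length(t_span) == 1) t_span <- c(0, t_span)
  if (t_span[2] < t_span[1]) abort("`t_span` must be non-decreasing.")
  if (t_span[2] == t_span[1]) {
    return(new_trajectory(t_span[1], init[1], init[2], model, "continuous",
                          params, drive))
  }
  if (is.null(rtol)) rtol <- if (model == "fhn") 1e-8 else 1e-6
  if (is.null(atol)) atol <- if (model == "fhn") 1e-10 else 1e-8
  cube <- if (model == "fhn") {
    function(v) v^3
  } else {
    function(v) cordic_cube_real(v, sched$i_min, sched$i_max)
  }
  rhs <- function(t, y, p) {
    I <- drive_current(drive, t)
    list(c(
      y[1] - cube(y[1]) / 3 - y[2] + I,
      (params$a - params$b * y[2] + y[1]) / params$T
    ))
  }
  times <- seq(t_span[1], t_span[2], by = sample_dt)
  if (times[length(times)] < t_span[2]) times <- c(times, t_span[2])
  sol <- deSolve::ode(y = init, times = times, func = rhs, parms = NULL,
                      method = "ode45", rtol = rtol, atol = atol,
                      maxsteps = 1e6)
  if (attr(sol, "istate")[1] < 0) {
    abort(sprintf("ode45 failed (istate %d); see deSolve diagnostics.",
                  attr(sol, "istate")[1]))
  }
  new_trajectory(sol[, 1], sol[, 2], sol[, 3], model, "continuous",
                 params, drive)
}

#' Discrete-time simulation (forward Euler)
#'
#' Forward-Euler integration of either model:
#' \deqn{V[n+1] = V[n] + dt (V[n] - V[n]^3/3 - W[n] + I_n)}
#' \deqn{W[n+1] = W[n] + (dt/T)(a - b W[n] + V[n])}
#' The `"real"` backend runs in double precision. The `"fixed"` backend is
#' bit-accurate: all signals are Q-format words, the cube goes through the
#' fixed-point CORDIC datapath, multiplications by `1/3`, `b` and `1/T` are
#' shift-add decompositions (tolerance one ulp, see [shift_decompose()]),
#' and the `dt` multiplication is an arithmetic right shift -- hence `dt`
#' must be a power of two there. The integrator state carries
#' `guard_bits` extra fraction bits (default 8): the recovery increment
#' `dt/T * (...)` is below one Q8.8 ulp per step, so an accumulator at
#' output precision would truncate it to zero and freeze `W`; guard bits
#' are the standard fixed-point integrator remedy. The exported trajectory
#' is the Q-format view of the state.
#'
#' @inheritParams simulate_continuous
#' @param duration Simulated time (model units); or give `n_steps`.
#' @param n_steps Number of Euler steps (overrides `duration`).
#' @param backend `"real"` or `"fixed"`.
#' @param guard_bits Extra fraction bits carried by the fixed-backend state.
#' @return An `fhn_trajectory` tibble (`t`, `V`, `W`; plus `V_raw`, `W_raw`
#'   mantissa columns for the fixed backend). The attribute `n_saturated`
#'   counts clamped state updates; `shift_sets` records the constant
#'   decompositions used.
#' @examples
#' tr <- simulate_discrete("fhn", drive = drive_constant(1), n_steps = 1)
#' tr$V[2]  # 0.03125 after one step from rest
#' @export
simulate_discrete <- function(model = c("fhn", "cordic"),
                              params = fhn_params(),
                              drive = drive_constant(0.5),
                              duration = 1000,
                              n_steps = NULL,
                              init = c(0, 0),
                              backend = c("real", "fixed"),
                              sched = cordic_schedule(),
                              guard_bits = 8L) {
  model <- match.arg(model)
  backend <- match.arg(backend)
  stopifnot(inherits(params, "fhn_params"), inherits(drive, "drive_spec"),
            length(init) == 2, all(is.finite(init)))
  dt <- params$dt
  if (is.null(n_steps)) n_steps <- round(duration / dt)
  n_steps <- as.integer(n_steps)
  if (n_steps < 0) abort("`n_steps` must be non-negative.")
  tgrid <- (0:n_steps) * dt
  Ivec <- drive_current(drive, tgrid[-length(tgrid)])

  if (backend == "real") {
    a <- params$a; b <- params$b; Tc <- params$T
    V <- W <- numeric(n_steps + 1)
    V[1] <- init[1]; W[1] <- init[2]
    if (model == "fhn") {
      for (n in seq_len(n_steps)) {
        V[n + 1] <- V[n] + dt * (V[n] - V[n]^3 / 3 - W[n] + Ivec[n])
        W[n + 1] <- W[n] + (dt / Tc) * (a - b * W[n] + V[n])
      }
    } else {
      imin <- sched$i_min; imax <- sched$i_max
      for (n in seq_len(n_steps)) {
        cb <- cordic_cube_real(V[n], imin, imax)
        V[n + 1] <- V[n] + dt * (V[n] - cb / 3 - W[n] + Ivec[n])
        W[n + 1] <- W[n] + (dt / Tc) * (a - b * W[n] + V[n])
      }
    }
    return(new_trajectory(tgrid, V, W, model, "real", params, drive))
  }

  # ---- fixed-point backend ----
  s <- -log2(dt)
  if (abs(s - round(s)) > 1e-12 || s < 0) {
    abort("fixed backend requires `dt` to be a (negative) power of two so the step multiply is a right shift.")
  }
  s <- as.integer(round(s))
  fmt <- sched$fmt
  G <- as.integer(guard_bits)
  if (G < 0) abort("`guard_bits` must be >= 0.")
  FB <- fmt$frac_bits
  wide_min <- fmt$raw_min * 2^G
  wide_max <- fmt$raw_max * 2^G
  dec_third <- shift_decompose(1 / 3, tol = fmt$ulp)
  dec_b <- shift_decompose(params$b, tol = fmt$ulp)
  dec_invT <- shift_decompose(1 / params$T, tol = fmt$ulp)
  cube_raw <- if (model == "cordic") {
    function(r8) cordic_mult_fixed_raw(
      cordic_mult_fixed_raw(r8, r8, sched$i_min, sched$i_max, fmt)$raw,
      r8, sched$i_min, sched$i_max, fmt)$raw
  } else {
    # exact product, truncated to the format like a full-width multiplier
    function(r8) floor(r8^3 / 2^(2 * FB))
  }
  qa_wide <- floor(params$a * 2^(FB + G))
  mI <- floor(Ivec * 2^(FB + G))
  mV <- mW <- numeric(n_steps + 1)
  mV[1] <- floor(init[1] * 2^(FB + G))
  mW[1] <- floor(init[2] * 2^(FB + G))
  n_sat <- 0L
  for (n in seq_len(n_steps)) {
    v8 <- floor(mV[n] / 2^G)                  # Q-format view feeding the datapath
    zc <- cube_raw(v8) * 2^G
    zv <- mV[n] - apply_shifts_raw(zc, dec_third) - mW[n] + mI[n]
    vn <- mV[n] + floor(zv / 2^s)
    zw <- apply_shifts_raw(
      qa_wide - apply_shifts_raw(mW[n], dec_b) + mV[n], dec_invT)
    wn <- mW[n] + floor(zw / 2^s)
    if (vn < wide_min || vn > wide_max) { n_sat <- n_sat + 1L }
    if (wn < wide_min || wn > wide_max) { n_sat <- n_sat + 1L }
    mV[n + 1] <- min(max(vn, wide_min), wide_max)
    mW[n + 1] <- min(max(wn, wide_min), wide_max)
  }
  v8 <- floor(mV / 2^G)
  w8 <- floor(mW / 2^G)
  out <- new_trajectory(tgrid, v8 * fmt$ulp, w8 * fmt$ulp, model, "fixed",
                        params, drive,
                        extra = list(V_raw = v8, W_raw = w8))
  attr(out, "n_saturated") <- n_sat
  attr(out, "guard_bits") <- G
  attr(out, "shift_sets") <- list(third = dec_third, b = dec_b,
                                  invT = dec_invT, dt_shift = s)
  out
}

#' Spike detection by threshold crossing
#'
#' A spike is an upward crossing of `threshold` by the membrane potential,
#' with subsequent crossings ignored for `refractory` time units. The model
#' itself has no discrete spike events, so this detector defines spike times
#' for firing-rate and raster analyses.
#'
#' @param x An `fhn_trajectory`, or a numeric `V` series (then supply `t`).
#' @param t Time base when `x` is a bare numeric vector.
#' @param threshold Crossing level, default `V = 1`.
#' @param refractory Dead time after each detected spike (default 5).
#' @return Numeric vector of spike times.
#' @examples
#' tr <- simulate_discrete("fhn", drive = drive_constant(0.5), duration = 200)
#' detect_spikes(tr)
#' @export
detect_spikes <- function(x, t = NULL, threshold = 1, refractory = 5) {
  if (inherits(x, "fhn_trajectory") || is.data.frame(x)) {
    t <- x$t
    v <- x$V
  } else {
    v <- as.double(x)
    if (is.null(t)) t <- seq_along(v)
  }
  stopifnot(length(t) == length(v))
  if (length(v) < 2) return(numeric())
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1L
  times <- t[up]
  keep <- numeric(0)
  last <- -Inf
  for (tt in times) {
    if (tt - last >= refractory) {
      keep <- c(keep, tt)
      last <- tt
    }
  }
  keep
}

#' @export
glance.fhn_trajectory <- function(x, ...) {
  tibble(
    model = attr(x, "model"),
    backend = attr(x, "backend"),
    n = nrow(x),
    t_end = max(x$t),
    v_min = min(x$V), v_max = max(x$V),
    w_min = min(x$W), w_max = max(x$W),
    n_spikes = length(detect_spikes(x)),
    n_saturated = attr(x, "n_saturated") %||% 0L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
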