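#' CORDIC iteration schedule
#'
#' The linear-mode CORDIC multiplier runs one shift-add step per iteration
#' index `i`, with shift magnitude `2^-i`. The default schedule runs indices
#' -7 through +8 (16 steps), so the coarsest term is `2^7` and the finest is
#' `2^-8` -- one Q8.8 ulp. The backend selects real (double precision)
#' arithmetic or the bit-accurate fixed-point datapath.
#'
#' @param i_min First iteration index (coarsest shift `2^-i_min`).
#' @param i_max Last iteration index (finest shift `2^-i_max`).
#' @param backend `"real"` or `"fixed"`.
#' @param fmt [q_format()] used by the fixed backend.
#' @return An object of class `cordic_schedule`.
#' @examples
#' cordic_schedule()                  # 16 iterations, i = -7..+8
#' cordic_schedule(i_max = 6)         # 14 iterations (finest shift 2^-6)
#' @export
cordic_schedule <- function(i_min = -7L, i_max = 8L,
                            backend = c("real", "fixed"),
                            fmt = q_format()) {
  i_min <- as.integer(i_min)
  i_max <- as.integer(i_max)
  backend <- match.arg(backend)
  if (i_min >= i_max) abort("`i_min` must be smaller than `i_max`.")
  stopifnot(is_q_format(fmt))
  structure(
    list(
      i_min = i_min, i_max = i_max,
      n_iter = i_max - i_min + 1L,
      backend = backend, fmt = fmt,
      # convergence domain of the multiplier residual
      y_bound = sum(2^(-(i_min:i_max)))
    ),
    class = "cordic_schedule"
  )
}

#' @export
format.cordic_schedule <- function(x, ...) {
  sprintf("<cordic_schedule: i = %+d..%+d (%d steps), backend %s>",
          x$i_min, x$i_max, x$n_iter, x$backend)
}

#' @export
print.cordic_schedule <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

check_y_domain <- function(y, sched) {
  bad <- abs(y) > sched$y_bound
  if (any(bad)) {
    abort(sprintf(
      "multiplier out of the CORDIC convergence domain: |y| must be <= %.6g (worst offender %.6g).",
      sched$y_bound, max(abs(y))
    ))
  }
}

# Real-backend multiplier core, vectorized. Direction rule: mu = sign(y),
# with mu = 0 once the residual is exactly zero (the step is skipped, which
# keeps exact products exact). Residual after the last step is bounded by
# 2^-i_max; z + x*y is conserved at every step.
cordic_mult_real <- function(x, y, i_min, i_max) {
  z <- numeric(length(y))
  for (i in i_min:i_max) {
    d <- 2^(-i)
    mu <- sign(y)
    y <- y - mu * d
    z <- z + mu * x * d
  }
  z
}

# Fixed-backend multiplier core on mantissas. The x-shift is truncated toward
# -inf at every step (hardware right shift); internal y/z registers carry
# guard headroom (no intermediate clamp) and only the final product is
# saturated -- the software analog of the extra overflow-guard bits a
# hardware datapath holds around its adder tree.
cordic_mult_fixed_raw <- function(rx, ry, i_min, i_max, fmt) {
  fb <- fmt$frac_bits
  rz <- numeric(length(ry))
  for (i in i_min:i_max) {
    dm <- 2^(fb - i)  # y-path delta in mantissa units
    mu <- sign(ry)
    ry <- ry - mu * dm
    xs <- if (i >= 0) floor(rx / 2^i) else rx * 2^(-i)
    rz <- rz + mu * xs
  }
  sat_raw(rz, fmt)
}

as_input_raw <- function(v, fmt) {
  if (inherits(v, "q_value")) v$raw else quantize(v, fmt)$raw
}

#' Shift-add (CORDIC) multiplication
#'
#' Multiplies `x` by `y` using only shifts, additions and sign tests: the
#' multiplier `y` is recoded into signed powers of two over the schedule's
#' iteration window while the correspondingly shifted multiplicand is
#' accumulated into the product. The result is `x * (y - r)` with residual
#' `|r| <= 2^-i_max`; the fixed backend additionally truncates every shifted
#' multiplicand to the Q-format granularity.
#'
#' @param x Multiplicand: numeric, or `q_value` for the fixed backend.
#' @param y Multiplier, within the schedule's convergence domain
#'   (approximately `|y| <= 2^(-i_min + 1)`).
#' @param sched A [cordic_schedule()].
#' @return Numeric product (real backend) or `q_value` (fixed backend).
#'   `x` and `y` are recycled to a common length.
#' @examples
#' cordic_multiply(1.7, 0)       # exactly 0
#' cordic_multiply(-1.5, 1.25)   # -1.875 (1.25 recodes exactly)
#' @export
cordic_multiply <- function(x, y, sched = cordic_schedule()) {
  stopifnot(inherits(sched, "cordic_schedule"))
  if (sched$backend == "real") {
    x <- as.double(x)
    y <- as.double(y)
    if (any(!is.finite(x)) || any(!is.finite(y))) abort("inputs must be finite.")
    n <- max(length(x), length(y))
    x <- rep_len(x, n)
    y <- rep_len(y, n)
    check_y_domain(y, sched)
    cordic_mult_real(x, y, sched$i_min, sched$i_max)
  } else {
    fmt <- sched$fmt
    # the domain check applies to the requested multiplier, before any
    # saturation could silently fold it back into range
    check_y_domain(as.double(y), sched)
    rx <- as_input_raw(x, fmt)
    ry <- as_input_raw(y, fmt)
    n <- max(length(rx), length(ry))
    rx <- rep_len(rx, n)
    ry <- rep_len(ry, n)
    r <- cordic_mult_fixed_raw(rx, ry, sched$i_min, sched$i_max, fmt)
    new_q_value(r$raw, fmt, r$sat)
  }
}

#' Per-iteration trace of the CORDIC multiplier
#'
#' Runs the real-backend multiplier one scalar pair at a time and records the
#' full state after every iteration. Mainly a diagnostic: the invariant
#' `z + x*y = const` (conservation of the partial product) can be read off
#' directly, as can the shrinking multiplier residual.
#'
#' @inheritParams cordic_multiply
#' @return A tibble with one row per iteration: `i`, `mu`, `y` (residual
#'   after the step), `z` (accumulated product), `invariant` (`z + x*y`).
#' @export
cordic_trace <- function(x, y, sched = cordic_schedule()) {
  stopifnot(length(x) == 1, length(y) == 1, is.finite(x), is.finite(y))
  check_y_domain(y, sched)
  idx <- sched$i_min:sched$i_max
  out <- vector("list", length(idx))
  z <- 0
  for (k in seq_along(idx)) {
    i <- idx[k]
    d <- 2^(-i)
    mu <- sign(y)
    y <- y - mu * d
    z <- z + mu * x * d
    out[[k]] <- tibble(i = i, mu = mu, y = y, z = z, invariant = z + x * y)
  }
  bind_rows(out)
}

#' Two-stage CORDIC cube
#'
#' Approximates `V^3` as `(V x V) x V`: stage one multiplies `V` by itself,
#' stage two multiplies the stage-one result by `V`, both through
#' [cordic_multiply()]. With the default 16-step schedule the two stages
#' total 32 shift-add iterations.
#'
#' @param v Membrane potential values, nominally in `[-2, 2]`.
#' @param sched A [cordic_schedule()] applied to both stages.
#' @return Numeric (real backend) or `q_value` (fixed backend).
#' @examples
#' cordic_cube(0)          # 0
#' cordic_cube(2)          # 8 within the two-stage error bound
#' @export
cordic_cube <- function(v, sched = cordic_schedule()) {
  stopifnot(inherits(sched, "cordic_schedule"))
  if (sched$backend == "real") {
    s1 <- cordic_multiply(v, v, sched)
    cordic_multiply(s1, v, sched)
  } else {
    fmt <- sched$fmt
    rv <- as_input_raw(v, fmt)
    s1 <- cordic_mult_fixed_raw(rv, rv, sched$i_min, sched$i_max, fmt)
    r <- cordic_mult_fixed_raw(s1$raw, rv, sched$i_min, sched$i_max, fmt)
    new_q_value(r$raw, fmt, r$sat | s1$sat)
  }
}

# fast internal: real-backend cube on a numeric vector, default window
cordic_cube_real <- function(v, i_min = -7L, i_max = 8L) {
  cordic_mult_real(cordic_mult_real(v, v, i_min, i_max), v, i_min, i_max)
}

#' Cube approximation error versus iteration count
#'
#' Evaluates the two-stage CORDIC cube against the exact cubic on a uniform
#' grid over `v_range` for a set of per-stage iteration counts, reporting MAE
#' and normalized RMSE per count. Iteration counts other than the default
#' keep the coarsest shift fixed at `2^-i_min` and move the finest shift:
#' dropping coarse terms would break convergence for large products, whereas
#' the finest shift sets the attainable accuracy.
#'
#' @param iterations Per-stage iteration counts (the error table rows).
#' @param grid_step Grid spacing; default one Q8.8 ulp.
#' @param v_range Evaluation interval, default `[-2, 2]`.
#' @param i_min Coarsest iteration index, fixed across counts.
#' @param backend `"real"` or `"fixed"`.
#' @param fmt Fixed-point format for `backend = "fixed"`.
#' @param normalization Range used for nRMSE: `"range"` divides by
#'   `max(V^3) - min(V^3)` (16 on `[-2, 2]`), `"half_range"` by half of it.
#' @return A tibble with columns `n_iter`, `i_max`, `mae`, `nrmse`.
#' @examples
#' cube_error_sweep(iterations = c(12, 14, 16), grid_step = 2^-6)
#' @export
cube_error_sweep <- function(iterations = seq(10L, 20L, by = 2L),
                             grid_step = 2^-8,
                             v_range = c(-2, 2),
                             i_min = -7L,
                             backend = c("real", "fixed"),
                             fmt = q_format(),
                             normalization = c("range", "half_range")) {
  backend <- match.arg(backend)
  normalization <- match.arg(normalization)
  stopifnot(length(v_range) == 2, v_range[1] < v_range[2], grid_step > 0)
  grid <- seq(v_range[1], v_range[2], by = grid_step)
  if (length(grid) < 2) abort("evaluation grid is empty or degenerate.")
  exact <- grid^3
  denom <- diff(range(exact)) / if (normalization == "range") 1 else 2
  purrr::map(as.integer(iterations), function(n) {
    i_max <- i_min + n - 1L
    sched <- cordic_schedule(i_min, i_max, backend = backend, fmt = fmt)
    approx <- cordic_cube(grid, sched)
    err <- as.double(approx) - exact
    tibble(
      n_iter = n, i_max = i_max,
      mae = mean(abs(err)),
      nrmse = sqrt(mean(err^2)) / denom
    )
  }) |> bind_rows()
}
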