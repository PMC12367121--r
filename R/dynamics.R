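#' Stability class from Jacobian entries
#'
#' Classifies a planar fixed point from its Jacobian
#' `J = [A B; C D]` via the trace `tau = A + D`, determinant
#' `Delta = AD - BC` and discriminant `tau^2 - 4 Delta`:
#' saddle (`Delta < 0`), stable/unstable node (`Delta > 0`,
#' `tau` negative/positive, real eigenvalues), stable/unstable spiral
#' (complex eigenvalues), and center/degenerate on the boundaries.
#'
#' @param A,B,C,D Jacobian entries (vectorized).
#' @return Character vector of classifications.
#' @examples
#' classify_equilibrium(-0.7798, -1, 0.08, -0.064)  # stable node
#' @export
classify_equilibrium <- function(A, B, C, D) {
  stopifnot(all(is.finite(A)), all(is.finite(B)),
            all(is.finite(C)), all(is.finite(D)))
  tau <- A + D
  det <- A * D - B * C
  disc <- tau^2 - 4 * det
  out <- character(length(tau))
  out[det < 0] <- "saddle"
  node <- det > 0 & disc >= 0
  spiral <- det > 0 & disc < 0
  out[node & tau < 0] <- "stable node"
  out[node & tau > 0] <- "unstable node"
  out[spiral & tau < 0] <- "stable spiral"
  out[spiral & tau > 0] <- "unstable spiral"
  out[det > 0 & tau == 0] <- "center/degenerate"
  out[det == 0] <- "center/degenerate"
  out
}

#' Jacobian of either model at a state-space point
#'
#' For the original model the entries are analytic:
#' `A = 1 - V^2`, `B = -1`, `C = 1/T`, `D = -b/T`. The CORDIC model's
#' nonlinearity is a staircase without a classical derivative, so `A` is
#' estimated by a central finite difference of the CORDIC V-equation with
#' step `h` (default `2^-6`, two staircase treads, so the quotient averages
#' across jumps).
#'
#' @param model `"fhn"` or `"cordic"`.
#' @param params An [fhn_params()].
#' @param V,W Evaluation point (`W` does not enter either Jacobian but is
#'   accepted for symmetry).
#' @param sched [cordic_schedule()] for the CORDIC model.
#' @param h Finite-difference step for the CORDIC model.
#' @return A one-row tibble with columns `A`, `B`, `C`, `D`.
#' @examples
#' jacobian_at("fhn", V = 0.4089)  # A = 0.8328
#' @export
jacobian_at <- function(model = c("fhn", "cordic"),
                        params = fhn_params(),
                        V, W = NULL,
                        sched = cordic_schedule(),
                        h = 2^-6) {
  model <- match.arg(model)
  stopifnot(is.finite(V))
  A <- if (model == "fhn") {
    1 - V^2
  } else {
    g <- function(v) v - as.double(cordic_cube(v, sched)) / 3
    (g(V + h) - g(V - h)) / (2 * h)
  }
  tibble(A = A, B = -1, C = 1 / params$T, D = -params$b / params$T)
}

original_equilibrium_roots <- function(params, I) {
  # V - V^3/3 - (a + V)/b + I = 0, as a cubic in V
  co <- c(I - params$a / params$b, 1 - 1 / params$b, 0, -1 / 3)
  r <- polyroot(co)
  v <- Re(r[abs(Im(r)) < 1e-8 * pmax(1, Mod(r))])
  sort(unique(round(v, 12)))
}

polish_root <- function(fun, v0, lower, upper) {
  # Newton polish with bisection fallback
  v <- v0
  for (k in 1:50) {
    fv <- fun(v)
    if (abs(fv) < 1e-13) break
    dfd <- (fun(v + 1e-7) - fun(v - 1e-7)) / 2e-7
    if (!is.finite(dfd) || dfd == 0) break
    v <- v - fv / dfd
    if (v < lower || v > upper) {
      v <- uniroot(fun, c(lower, upper), tol = 1e-14)$root
      break
    }
  }
  v
}

#' Find equilibria of either model at constant drive
#'
#' Equilibria are intersections of the two nullclines
#' `W = V - V^3/3 + I` (or its CORDIC staircase counterpart) and
#' `W = (a + V)/b`. For the original model the intersection is a cubic whose
#' real roots come from the companion polynomial and are Newton-polished; for
#' the CORDIC model sign changes of the staircase residual are bracketed on a
#' `2^-8` grid and refined by bisection. Each equilibrium is reported with
#' its Jacobian, trace, determinant and stability class.
#'
#' @param model `"fhn"` or `"cordic"`.
#' @param params An [fhn_params()].
#' @param I Constant input current.
#' @param sched [cordic_schedule()] for the CORDIC model.
#' @param v_range Search interval for the CORDIC staircase bracketing.
#' @return A tibble of class `fhn_equilibria`: one row per equilibrium with
#'   columns `I`, `V_star`, `W_star`, `A`, `B`, `C`, `D`, `trace`, `det`,
#'   `discriminant`, `stability`.
#' @examples
#' find_equilibria("fhn", I = 0.5)  # (-0.8048, -0.1311), unstable spiral
#' @export
find_equilibria <- function(model = c("fhn", "cordic"),
                            params = fhn_params(),
                            I = 0.5,
                            sched = cordic_schedule(),
                            v_range = c(-4, 4)) {
  model <- match.arg(model)
  stopifnot(length(I) == 1, is.finite(I))
  a <- params$a; b <- params$b

  if (model == "fhn") {
    g <- function(v) v - v^3 / 3 - (a + v) / b + I
    vs <- original_equilibrium_roots(params, I)
    vs <- vapply(vs, function(v) polish_root(g, v, v - 1e-3, v + 1e-3),
                 numeric(1))
  } else {
    g <- function(v) v - as.double(cordic_cube(v, sched)) / 3 - (a + v) / b + I
    grid <- seq(v_range[1], v_range[2], by = 2^-8)
    gv <- g(grid)
    flips <- which(gv[-1] * gv[-length(gv)] <= 0 & is.finite(gv[-1]))
    vs <- vapply(flips, function(k) {
      lo <- grid[k]; hi <- grid[k + 1]
      # bisection on the (possibly discontinuous) staircase residual
      for (it in 1:60) {
        mid <- (lo + hi) / 2
        if (g(lo) * g(mid) <= 0) hi <- mid else lo <- mid
      }
      (lo + hi) / 2
    }, numeric(1))
    vs <- vs[!duplicated(round(vs, 6))]
  }
  if (length(vs) == 0) {
    return(structure(tibble(I = numeric(), V_star = numeric(),
                            W_star = numeric(), A = numeric(), B = numeric(),
                            C = numeric(), D = numeric(), trace = numeric(),
                            det = numeric(), discriminant = numeric(),
                            stability = character()),
                     class = c("fhn_equilibria", class(tibble()))))
  }
  rows <- purrr::map(vs, function(v) {
    w <- (a + v) / b
    J <- jacobian_at(model, params, V = v, sched = sched)
    tibble(
      I = I, V_star = v, W_star = w,
      A = J$A, B = J$B, C = J$C, D = J$D,
      trace = J$A + J$D,
      det = J$A * J$D - J$B * J$C,
      discriminant = (J$A + J$D)^2 - 4 * (J$A * J$D - J$B * J$C),
      stability = classify_equilibrium(J$A, J$B, J$C, J$D)
    )
  })
  out <- bind_rows(rows)
  class(out) <- c("fhn_equilibria", class(out))
  attr(out, "model") <- model
  attr(out, "params") <- params
  out
}

#' @export
tidy.fhn_equilibria <- function(x, ...) {
  as_tibble(x)
}

#' Equilibrium-branch scan over the input current (Hopf diagram)
#'
#' Follows the (unique) equilibrium branch of either model as the constant
#' input current varies, recording the stability class and, from a
#' post-transient simulation, the orbit extrema of `V`. Where the branch is
#' unstable a limit cycle surrounds it and the extrema open up; where it is
#' stable they collapse onto the fixed point. The scan flags the parameter
#' intervals where stability changes (the Hopf window, roughly
#' `I` in `[0.5, 1.5]` at default parameters).
#'
#' @inheritParams find_equilibria
#' @param I_range Current interval to scan.
#' @param n_points Number of scan points.
#' @param transient Simulation time discarded before measuring extrema.
#' @param horizon Total simulation time per point.
#' @param cycle_tol Minimum `V` peak-to-peak amplitude that counts as a
#'   limit cycle.
#' @return A tibble of class `fhn_hopf`: `I`, `V_star`, `stability`,
#'   `V_min`, `V_max`, `limit_cycle`; the attribute `instability_window`
#'   holds the bracketing currents of the stability changes.
#' @examples
#' hs <- hopf_scan(n_points = 11, horizon = 400)
#' attr(hs, "instability_window")
#' @export
hopf_scan <- function(model = c("fhn", "cordic"),
                      params = fhn_params(),
                      I_range = c(0, 2),
                      n_points = 41,
                      transient = 300,
                      horizon = 800,
                      sched = cordic_schedule(),
                      cycle_tol = 0.2) {
  model <- match.arg(model)
  stopifnot(length(I_range) == 2, I_range[1] <= I_range[2],
            horizon > transient)
  Is <- seq(I_range[1], I_range[2], length.out = n_points)
  eq <- purrr::map(Is, function(I) {
    e <- find_equilibria(model, params, I = I, sched = sched)
    # the default cubic has a single real root; keep the one nearest rest
    e[which.min(abs(e$V_star)), c("V_star", "stability")]
  }) |> bind_rows()
  # post-transient orbit extrema, vectorized across the scan
  ext <- euler_sweep_extrema(model, params, Is, f = 0, transient = transient,
                             horizon = horizon, sched = sched)
  out <- tibble(
    I = Is,
    V_star = eq$V_star,
    stability = eq$stability,
    V_min = ext$V_min,
    V_max = ext$V_max,
    limit_cycle = (ext$V_max - ext$V_min) > cycle_tol
  )
  unstable <- !grepl("^stable", out$stability)
  flips <- which(diff(unstable) != 0)
  attr(out, "instability_window") <-
    if (length(flips)) cbind(I_lo = Is[flips], I_hi = Is[flips + 1]) else NULL
  class(out) <- c("fhn_hopf", class(out))
  attr(out, "model") <- model
  out
}

# Euler co-integration of one model across a vector of constant or sinusoidal
# drives; returns post-transient V extrema per sweep point.
euler_sweep_extrema <- function(model, params, I_in, f, transient, horizon,
                                sched) {
  dt <- params$dt
  a <- params$a; b <- params$b; Tc <- params$T
  m <- length(I_in)
  cube <- if (model == "fhn") function(v) v^3
          else function(v) cordic_cube_real(v, sched$i_min, sched$i_max)
  V <- W <- numeric(m)
  nt <- round(transient / dt)
  nh <- round((horizon - transient) / dt)
  tt <- 0
  sinusoid <- any(f > 0)
  for (n in seq_len(nt)) {
    I <- if (sinusoid) I_in * sin(2 * pi * f * tt) else I_in
    Vn <- V + dt * (V - cube(V) / 3 - W + I)
    W <- W + (dt / Tc) * (a - b * W + V)
    V <- Vn
    tt <- tt + dt
  }
  vmin <- V
  vmax <- V
  for (n in seq_len(nh)) {
    I <- if (sinusoid) I_in * sin(2 * pi * f * tt) else I_in
    Vn <- V + dt * (V - cube(V) / 3 - W + I)
    W <- W + (dt / Tc) * (a - b * W + V)
    V <- Vn
    tt <- tt + dt
    vmin <- pmin(vmin, V)
    vmax <- pmax(vmax, V)
  }
  list(V_min = vmin, V_max = vmax)
}
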