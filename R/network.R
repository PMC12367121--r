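#' Random spiking-network configuration
#'
#' Configuration of the seeded random network used to compare the two neuron
#' models at population scale: `n_neurons` cells, each receiving exactly
#' `in_degree` presynaptic connections sampled uniformly without replacement
#' (no self-connections), with `frac_excitatory` of the cells labelled
#' excitatory and the rest inhibitory. Each presynaptic spike injects a
#' rectangular current pulse (`w_exc` or `w_inh` by the presynaptic label,
#' duration `pulse_width`) into its targets, on top of the common drive.
#' The analysis window keeps the last `crop` time units of the `duration`.
#'
#' @param n_neurons Number of neurons.
#' @param in_degree Presynaptic connections per neuron.
#' @param frac_excitatory Fraction of excitatory neurons.
#' @param w_exc,w_inh Synaptic current increments (mA) for excitatory and
#'   inhibitory presynaptic spikes.
#' @param pulse_width Synaptic pulse duration (time units).
#' @param seed RNG seed fixing topology and labels.
#' @param duration Total simulated time.
#' @param crop Length of the trailing analysis window.
#' @param drive Common input drive, default constant 0.5 mA.
#' @param threshold,refractory Spike-detector settings shared by all runs.
#' @param connectivity `"fixed_in_degree"` draws exactly `in_degree` inputs
#'   per neuron; `"bernoulli"` instead connects each ordered pair
#'   independently with probability `in_degree / (n_neurons - 1)`.
#' @return An object of class `network_config`.
#' @examples
#' network_config(n_neurons = 20, in_degree = 5, duration = 100, crop = 80)
#' @export
network_config <- function(n_neurons = 1000L,
                           in_degree = 100L,
                           frac_excitatory = 0.8,
                           w_exc = 0.05,
                           w_inh = -0.25,
                           pulse_width = 1,
                           seed = 42L,
                           duration = 1200,
                           crop = 1000,
                           drive = drive_constant(0.5),
                           threshold = 1,
                           refractory = 5,
                           connectivity = c("fixed_in_degree", "bernoulli")) {
  n_neurons <- as.integer(n_neurons)
  in_degree <- as.integer(in_degree)
  connectivity <- match.arg(connectivity)
  if (in_degree <= 0 || in_degree >= n_neurons) {
    abort("`in_degree` must satisfy 0 < in_degree < n_neurons.")
  }
  if (frac_excitatory < 0 || frac_excitatory > 1) {
    abort("`frac_excitatory` must lie in [0, 1].")
  }
  if (duration < crop) abort("`duration` must be at least `crop`.")
  stopifnot(inherits(drive, "drive_spec"), pulse_width > 0)
  structure(
    list(n_neurons = n_neurons, in_degree = in_degree,
         frac_excitatory = frac_excitatory,
         w_exc = w_exc, w_inh = w_inh, pulse_width = pulse_width,
         seed = as.integer(seed), duration = duration, crop = crop,
         drive = drive, threshold = threshold, refractory = refractory,
         connectivity = connectivity),
    class = "network_config"
  )
}

#' Build a seeded random network
#'
#' Draws the topology and excitatory/inhibitory labels from the
#' configuration's seed. The same seed always yields the same network, so
#' the original and CORDIC populations can be run on identical wiring.
#'
#' @param config A [network_config()].
#' @return An object of class `fhn_network`: presynaptic lists, postsynaptic
#'   target lists, the excitatory label vector, per-neuron outgoing weights,
#'   and the config.
#' @examples
#' net <- build_network(network_config(n_neurons = 10, in_degree = 3))
#' lengths(net$presynaptic)  # all 3
#' @export
build_network <- function(config = network_config()) {
  stopifnot(inherits(config, "network_config"))
  n <- config$n_neurons
  withr::with_seed(config$seed, {
    pre <- if (config$connectivity == "fixed_in_degree") {
      lapply(seq_len(n), function(j) sort(sample((1:n)[-j], config$in_degree)))
    } else {
      p <- config$in_degree / (n - 1)
      lapply(seq_len(n), function(j) {
        cand <- (1:n)[-j]
        cand[runif(n - 1) < p]
      })
    }
    exc <- rep(FALSE, n)
    exc[sample(n, round(config$frac_excitatory * n))] <- TRUE
  })
  targets <- vector("list", n)
  for (j in seq_len(n)) {
    for (p in pre[[j]]) targets[[p]] <- c(targets[[p]], j)
  }
  structure(
    list(presynaptic = pre,
         targets = targets,
         excitatory = exc,
         weight = ifelse(exc, config$w_exc, config$w_inh),
         config = config),
    class = "fhn_network"
  )
}

#' @export
format.fhn_network <- function(x, ...) {
  sprintf("<fhn_network: %d neurons, %d excitatory, seed %d>",
          x$config$n_neurons, sum(x$excitatory), x$config$seed)
}

#' @export
print.fhn_network <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
tidy.fhn_network <- function(x, ...) {
  tibble(
    to = rep(seq_along(x$presynaptic), lengths(x$presynaptic)),
    from = unlist(x$presynaptic, use.names = FALSE)
  ) |>
    mutate(excitatory = x$excitatory[.data$from],
           weight = x$weight[.data$from])
}

#' @export
glance.fhn_network <- function(x, ...) {
  tibble(
    n_neurons = x$config$n_neurons,
    n_edges = sum(lengths(x$presynaptic)),
    n_excitatory = sum(x$excitatory),
    in_degree_min = min(lengths(x$presynaptic)),
    in_degree_max = max(lengths(x$presynaptic)),
    seed = x$config$seed
  )
}

#' Simulate a network of either neuron model
#'
#' Co-integrates all neurons with vectorized forward Euler at the model
#' `dt`. Each neuron follows the single-neuron dynamics under the common
#' drive plus its synaptic current; when a neuron's membrane potential
#' crosses the spike threshold (respecting the refractory period), a
#' rectangular current pulse of its weight and the configured width is
#' injected into all its targets. Spikes inside the trailing analysis
#' window are returned as a raster.
#'
#' @param net An [build_network()] result.
#' @param model `"fhn"` or `"cordic"`.
#' @param params An [fhn_params()].
#' @param sched [cordic_schedule()] for the CORDIC model.
#' @return A tibble of class `spike_raster` with columns `neuron`, `time`,
#'   carrying the network and model metadata as attributes.
#' @examples
#' cfg <- network_config(n_neurons = 10, in_degree = 3,
#'                       duration = 150, crop = 100)
#' r <- simulate_network(build_network(cfg), "fhn")
#' @export
simulate_network <- function(net, model = c("fhn", "cordic"),
                             params = fhn_params(),
                             sched = cordic_schedule()) {
  stopifnot(inherits(net, "fhn_network"))
  model <- match.arg(model)
  cfg <- net$config
  dt <- params$dt
  a <- params$a; b <- params$b; Tc <- params$T
  n <- cfg$n_neurons
  cube <- if (model == "fhn") function(v) v^3
          else function(v) cordic_cube_real(v, sched$i_min, sched$i_max)
  n_steps <- round(cfg$duration / dt)
  pw_steps <- max(1L, round(cfg$pulse_width / dt))
  ring <- vector("list", pw_steps + 1L)
  V <- W <- Isyn <- numeric(n)
  last_spike <- rep(-Inf, n)
  spikes <- vector("list", n)
  w <- net$weight
  tgt <- net$targets
  for (s in seq_len(n_steps)) {
    tt <- s * dt
    sl <- (s %% (pw_steps + 1L)) + 1L
    if (!is.null(ring[[sl]])) {
      Isyn <- Isyn - ring[[sl]]
      ring[sl] <- list(NULL)
    }
    I <- drive_current(cfg$drive, tt - dt) + Isyn
    Vn <- V + dt * (V - cube(V) / 3 - W + I)
    W <- W + (dt / Tc) * (a - b * W + V)
    sp <- which(Vn >= cfg$threshold & V < cfg$threshold &
                  (tt - last_spike) >= cfg$refractory)
    if (length(sp)) {
      last_spike[sp] <- tt
      es <- ((s + pw_steps) %% (pw_steps + 1L)) + 1L
      for (j in sp) {
        spikes[[j]] <- c(spikes[[j]], tt)
        tg <- tgt[[j]]
        if (length(tg)) {
          Isyn[tg] <- Isyn[tg] + w[j]
          if (is.null(ring[[es]])) ring[[es]] <- numeric(n)
          ring[[es]][tg] <- ring[[es]][tg] + w[j]
        }
      }
    }
    V <- Vn
  }
  t0 <- cfg$duration - cfg$crop
  out <- tibble(
    neuron = rep(seq_len(n), vapply(spikes, function(x) sum(x > t0), 1L)),
    time = unlist(lapply(spikes, function(x) x[x > t0]), use.names = FALSE)
      %||% numeric()
  )
  class(out) <- c("spike_raster", class(out))
  attr(out, "model") <- model
  attr(out, "config") <- cfg
  attr(out, "n_neurons") <- n
  out
}

#' @export
glance.spike_raster <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble(
    model = attr(x, "model"),
    n_neurons = attr(x, "n_neurons"),
    n_spikes = nrow(x),
    rate_hz = nrow(x) / attr(x, "n_neurons") / cfg$crop * 1000,
    window = cfg$crop
  )
}

#' Spike-timing discrepancy between two rasters
#'
#' Per neuron, greedily matches each spike of raster `a` to the nearest
#' unmatched spike of raster `b` within `match_window`; returns the mean
#' absolute time difference over the matched pairs and the fraction of all
#' spikes that found a match. The intended use is the same network run with
#' the original and the CORDIC neuron on identical wiring.
#'
#' @param raster_a,raster_b `spike_raster` objects over the same neurons.
#' @param match_window Maximum |time difference| for a match (default 20).
#' @return A one-row tibble: `mean_abs_dt`, `matched_fraction`, `n_matched`,
#'   `n_a`, `n_b`. With two empty rasters the discrepancy is undefined and
#'   both statistics are `NA`.
#' @examples
#' r <- tibble::tibble(neuron = c(1, 1, 2), time = c(10, 30, 20))
#' class(r) <- c("spike_raster", class(r)); attr(r, "n_neurons") <- 2L
#' s <- r; s$time <- s$time + 3
#' raster_discrepancy(r, s)  # mean 3, all matched
#' @export
raster_discrepancy <- function(raster_a, raster_b, match_window = 20) {
  stopifnot(is.data.frame(raster_a), is.data.frame(raster_b))
  na_n <- attr(raster_a, "n_neurons") %||% max(raster_a$neuron, 0)
  nb_n <- attr(raster_b, "n_neurons") %||% max(raster_b$neuron, 0)
  if (na_n != nb_n) abort("rasters must cover the same neuron count.")
  n_a <- nrow(raster_a)
  n_b <- nrow(raster_b)
  if (n_a == 0 && n_b == 0) {
    return(tibble(mean_abs_dt = NA_real_, matched_fraction = NA_real_,
                  n_matched = 0L, n_a = 0L, n_b = 0L))
  }
  la <- split(raster_a$time, factor(raster_a$neuron, levels = seq_len(na_n)))
  lb <- split(raster_b$time, factor(raster_b$neuron, levels = seq_len(nb_n)))
  tot <- 0
  m <- 0L
  for (j in seq_len(na_n)) {
    ta <- la[[j]]
    tb <- lb[[j]]
    while (length(ta) && length(tb)) {
      k <- which.min(abs(tb - ta[1]))
      if (abs(tb[k] - ta[1]) <= match_window) {
        tot <- tot + abs(tb[k] - ta[1])
        m <- m + 1L
        tb <- tb[-k]
      }
      ta <- ta[-1]
    }
  }
  tibble(
    mean_abs_dt = if (m > 0) tot / m else NA_real_,
    matched_fraction = 2 * m / (n_a + n_b),
    n_matched = m,
    n_a = n_a,
    n_b = n_b
  )
}
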