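test_that("topology honours the in-degree, labels and seed", {
  cfg <- network_config(seed = 42L)
  net <- build_network(cfg)
  expect_true(all(lengths(net$presynaptic) == 100L))
  expect_identical(sum(net$excitatory), 800L)
  # no self-connections
  expect_false(any(vapply(seq_along(net$presynaptic),
                          function(j) j %in% net$presynaptic[[j]],
                          logical(1))))
  # same seed, same wiring
  net2 <- build_network(cfg)
  expect_identical(net$presynaptic, net2$presynaptic)
  expect_identical(net$excitatory, net2$excitatory)
  # forced complete digraph at n = 5, k = 4
  small <- build_network(network_config(n_neurons = 5, in_degree = 4))
  expect_identical(lapply(small$presynaptic, sort),
                   lapply(1:5, function(j) setdiff(1:5, j)))
  expect_error(network_config(n_neurons = 10, in_degree = 10), "in_degree")
  expect_error(network_config(duration = 100, crop = 200), "at least")
})

test_that("edge list and summaries are consistent", {
  net <- build_network(network_config(n_neurons = 50, in_degree = 7))
  ed <- tidy(net)
  expect_identical(nrow(ed), 350L)
  expect_identical(glance(net)$n_edges, 350L)
  expect_true(all(ed$weight[ed$excitatory] > 0))
  expect_true(all(ed$weight[!ed$excitatory] < 0))
})

test_that("decoupled network reproduces the single-neuron train bitwise", {
  cfg <- network_config(n_neurons = 10, in_degree = 3, w_exc = 0, w_inh = 0,
                        duration = 150, crop = 100, seed = 5)
  raster <- simulate_network(build_network(cfg), "fhn")
  single <- simulate_discrete("fhn", drive = drive_constant(0.5),
                              duration = 150)
  want <- detect_spikes(single)
  want <- want[want > 50]
  for (j in 1:10) {
    expect_identical(raster$time[raster$neuron == j], want)
  }
})

test_that("raster discrepancy measures matching and shifts exactly", {
  r <- tibble::tibble(neuron = c(1L, 1L, 2L), time = c(110, 130, 120))
  class(r) <- c("spike_raster", class(r))
  attr(r, "n_neurons") <- 2L
  expect_identical(raster_discrepancy(r, r)$mean_abs_dt, 0)
  expect_identical(raster_discrepancy(r, r)$matched_fraction, 1)
  s <- r
  s$time <- s$time + 3
  d <- raster_discrepancy(r, s)
  expect_identical(d$mean_abs_dt, 3)
  expect_identical(d$matched_fraction, 1)
  # empty rasters: undefined, reported as NA
  e <- r[0, ]
  class(e) <- c("spike_raster", class(e))
  attr(e, "n_neurons") <- 2L
  expect_true(is.na(raster_discrepancy(e, e)$mean_abs_dt))
})

test_that("timing discrepancy grows as the cube gets coarser", {
  cfg <- network_config(n_neurons = 100, in_degree = 10,
                        duration = 500, crop = 400, seed = 7)
  net <- build_network(cfg)
  ra <- simulate_network(net, "fhn")
  disc <- vapply(c(8L, 6L, 4L, 2L), function(imax) {
    rb <- simulate_network(net, "cordic",
                           sched = cordic_schedule(i_max = imax))
    raster_discrepancy(ra, rb)$mean_abs_dt
  }, numeric(1))
  # strictly increasing from 16 down to 12 iterations; by 10 iterations the
  # trains have decohered and the windowed matching saturates, but the
  # discrepancy stays far above the 16-iteration baseline
  expect_true(all(diff(disc[1:3]) > 0))
  expect_gt(disc[4], 5 * disc[1])
})
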