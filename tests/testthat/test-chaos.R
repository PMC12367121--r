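test_that("map estimator recovers the logistic-map exponent", {
  lam <- max_lyapunov_map(logistic_map(4), n_iter = 5000)
  expect_lt(abs(lam - log(2)) / log(2), 0.01)
  # a contracting map gives a negative exponent
  lam <- max_lyapunov_map(function(x) 0.5 * x, x0 = 1, n_iter = 200)
  expect_equal(lam, log(0.5), tolerance = 1e-6)
})

test_that("constant drive onto the stable node gives a negative exponent", {
  m <- max_lyapunov("fhn", drive = drive_constant(2),
                    transient = 100, horizon = 1100)
  expect_lt(m$lambda, 0)
  expect_identical(m$n_renorm, 1000L)
})

test_that("exponent estimate is robust to the probe settings in chaos", {
  dr <- drive_sinusoid(1, 0.13)
  base <- max_lyapunov("fhn", drive = dr, horizon = 3000)$lambda
  half_d0 <- max_lyapunov("fhn", drive = dr, horizon = 3000,
                          d0 = 5e-9)$lambda
  half_tau <- max_lyapunov("fhn", drive = dr, horizon = 3000,
                           renorm_interval = 0.5)$lambda
  expect_gt(base, 0)
  expect_lt(abs(half_d0 - base) / abs(base), 0.1)
  expect_lt(abs(half_tau - base) / abs(base), 0.1)
})

test_that("bifurcation peaks are post-transient and sorted by parameter", {
  bd <- bifurcation_diagram("fhn", sweep_values = c(1, 0.5), f = 0.01,
                            transient = 300, horizon = 1200)
  expect_identical(sort(unique(bd$param)), c(0.5, 1))
  cl <- count_peak_clusters(bd)
  expect_identical(cl$param, c(0.5, 1))
  expect_true(all(cl$n_peaks > 0))
  # constant-drive stable regime: at most the settling maximum remains
  bd0 <- bifurcation_diagram("fhn", sweep_values = 2, f = 0,
                             transient = 300, horizon = 800)
  expect_lte(count_peak_clusters(bd0)$n_clusters, 1L)
  expect_error(bifurcation_diagram("fhn", sweep_values = numeric()), "non-empty")
  expect_error(
    bifurcation_diagram("fhn", sweep_values = 1, transient = 10, horizon = 5),
    "exceed"
  )
})

test_that("period-doubling and chaotic windows appear in the fast sweeps", {
  # the doubling route sits at f = 0.13: 4-branch windows and wide chaotic
  # peak sets along the amplitude axis
  bd <- bifurcation_diagram("fhn", sweep_values = seq(0.5, 1.1, by = 0.05),
                            f = 0.13, transient = 500, horizon = 3000)
  cl <- count_peak_clusters(bd)
  expect_true(any(cl$n_clusters == 4))
  expect_true(any(cl$n_clusters > 20))
})

test_that("phase orbits collapse onto stable equilibria and close when periodic", {
  tr <- simulate_discrete("fhn", drive = drive_constant(2), duration = 600)
  orb <- phase_orbit(tr, transient = 400)
  expect_lt(max(abs(orb$V - 1.3341)), 0.01)
  expect_lt(max(abs(orb$W - 2.5426)), 0.01)
  # periodically driven orbit returns near its starting point
  tr <- simulate_discrete("fhn", drive = drive_sinusoid(1, 0.01),
                          duration = 800)
  orb <- phase_orbit(tr, transient = 600)  # two full drive periods
  p0 <- c(orb$V[1], orb$W[1])
  later <- sqrt((orb$V[-(1:100)] - p0[1])^2 + (orb$W[-(1:100)] - p0[2])^2)
  expect_lt(min(later), 0.05)
  expect_error(phase_orbit(tr, transient = 1000), "beyond")
})
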