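test_that("multiplier handles exact and recodable inputs exactly", {
  expect_identical(cordic_multiply(1.7, 0), 0)
  expect_identical(cordic_multiply(1, 1), 1)
  # 1.25 = 2^0 + 2^-2 is recodable over i = -7..8 (checked by enumeration
  # over the fine window), so the product is exact
  expect_true(oracle_recodable(1.25, 0, 4))
  expect_identical(cordic_multiply(-1.5, 1.25), -1.875)
  expect_lt(abs(cordic_multiply(-1.5, 1.25) - (-1.875)), 1.5 * 2^-8)
})

test_that("multiplier residual stays within |x| * 2^-i_max", {
  set.seed(11)
  x <- runif(1e4, -8, 8)
  y <- runif(1e4, -2, 2)
  err <- abs(cordic_multiply(x, y) - x * y)
  expect_true(all(err <= abs(x) * 2^-8 + 1e-12))
  # exhaustive over a coarse Q8.8 lattice slice
  xs <- seq(-2, 2, by = 2^-4)
  ys <- seq(-2, 2, by = 2^-4)
  g <- expand.grid(x = xs, y = ys)
  err <- abs(cordic_multiply(g$x, g$y) - g$x * g$y)
  expect_true(all(err <= abs(g$x) * 2^-8 + 1e-12))
})

test_that("z + x*y is conserved along the iteration", {
  for (pair in list(c(1.7, 0.3), c(-1.2, 1.9), c(0.5, -1.99))) {
    tr <- cordic_trace(pair[1], pair[2])
    expect_equal(tr$invariant, rep(pair[1] * pair[2], nrow(tr)),
                 tolerance = 1e-12)
    expect_lte(abs(tr$y[nrow(tr)]), 2^-8)
  }
})

test_that("multiplier rejects inputs outside the convergence domain", {
  expect_error(cordic_multiply(1, 300), "convergence domain")
  expect_error(cordic_multiply(1, 300, cordic_schedule(backend = "fixed")),
               "convergence domain")
})

test_that("two-stage cube is odd and within the two-stage error bound", {
  expect_identical(as.double(cordic_cube(0)), 0)
  expect_lt(abs(as.double(cordic_cube(2)) - 8), 0.032)
  v <- seq(-2, 2, by = 0.01)
  expect_equal(cordic_cube(-v), -cordic_cube(v), tolerance = 1e-12)
  # pointwise bound |e| <= |V| 2^-8 (1 + |V|) + V^2 2^-8
  err <- abs(cordic_cube(v) - v^3)
  bound <- abs(v) * 2^-8 * (1 + abs(v)) + v^2 * 2^-8
  expect_true(all(err <= bound + 1e-12))
})

test_that("fixed-backend multiply stays within residual plus truncation", {
  set.seed(7)
  x <- round(runif(3000, -2, 2) * 256) / 256
  y <- round(runif(3000, -2, 2) * 256) / 256
  sched <- cordic_schedule(backend = "fixed")
  p <- as.double(cordic_multiply(x, y, sched))
  # residual |x| 2^-8 plus one ulp of truncation per iteration
  expect_true(all(abs(p - x * y) <= abs(x) * 2^-8 + 16 * 2^-8 + 1e-12))
  expect_lt(mean(abs(p - x * y)), 0.02)
})

test_that("cube error sweep decreases at least geometrically", {
  sweep <- cube_error_sweep()
  expect_identical(sweep$n_iter, seq(10L, 20L, by = 2L))
  expect_true(all(diff(sweep$mae) <= 0))
  # error at n+2 iterations is at most half the error at n
  for (k in seq_len(nrow(sweep) - 1)) {
    expect_lte(sweep$mae[k + 1], sweep$mae[k] / 2 + 1e-12)
  }
  expect_error(cube_error_sweep(grid_step = 10, v_range = c(0, 1)), "grid")
})

test_that("half-range normalization is available for the cube sweep", {
  a <- cube_error_sweep(iterations = 12L)
  b <- cube_error_sweep(iterations = 12L, normalization = "half_range")
  expect_equal(b$nrmse, 2 * a$nrmse, tolerance = 1e-12)
})
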