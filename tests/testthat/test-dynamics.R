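test_that("original-model equilibria match the reference table to 4 decimals", {
  e <- find_equilibria("fhn", I = 0.5)
  expect_identical(nrow(e), 1L)
  expect_equal(round(e$V_star, 4), -0.8048)
  expect_equal(round(e$W_star, 4), -0.1311)
  expect_equal(round(e$A, 4), 0.3522)

  e <- find_equilibria("fhn", I = 1)
  expect_equal(round(e$V_star, 4), 0.4089)
  expect_equal(round(e$W_star, 4), 1.3861)
  expect_equal(round(e$A, 4), 0.8328)

  e <- find_equilibria("fhn", I = 2)
  expect_equal(round(e$V_star, 4), 1.3341)
  expect_equal(round(e$W_star, 4), 2.5426)
  expect_equal(round(e$A, 4), -0.7798)
})

test_that("Jacobian entries are analytic for the original model", {
  J <- jacobian_at("fhn", V = 0.4089)
  expect_equal(round(J$A, 4), 0.8328)
  expect_identical(J$B, -1)
  expect_identical(J$C, 0.08)
  expect_identical(J$D, -0.064)
  expect_identical(jacobian_at("fhn", V = 0)$A, 1)
})

test_that("stability classes follow the trace/determinant rules", {
  # I = 1: unstable node; I = 2: stable node
  expect_identical(find_equilibria("fhn", I = 1)$stability, "unstable node")
  expect_identical(find_equilibria("fhn", I = 2)$stability, "stable node")
  # I = 0.5: tau = 0.3522 - 0.064 > 0 with complex eigenvalues, hence an
  # unstable spiral (consistent with the observed tonic firing at I = 0.5)
  e <- find_equilibria("fhn", I = 0.5)
  expect_equal(round(e$trace, 4), 0.2882)
  expect_identical(e$stability, "unstable spiral")
})

test_that("classification agrees with direct eigenvalues on random draws", {
  set.seed(42)
  n <- 1000
  A <- runif(n, -2, 2); B <- runif(n, -2, 2)
  C <- runif(n, -2, 2); D <- runif(n, -2, 2)
  got <- classify_equilibrium(A, B, C, D)
  want <- vapply(seq_len(n),
                 function(i) oracle_classify(A[i], B[i], C[i], D[i]),
                 character(1))
  expect_identical(got, want)
})

test_that("CORDIC equilibria stay within the cube-error band of the originals", {
  for (I in c(0.5, 1, 2)) {
    e0 <- find_equilibria("fhn", I = I)
    e1 <- find_equilibria("cordic", I = I)
    expect_gte(nrow(e1), 1L)
    expect_lt(min(abs(e1$V_star - e0$V_star)), 0.02)
  }
})

test_that("equilibrium branch scan flags the instability window", {
  hs <- hopf_scan(n_points = 21, transient = 300, horizon = 800)
  at <- function(I) hs[abs(hs$I - I) < 1e-9, ]
  expect_false(at(0)$limit_cycle)
  expect_true(at(0.5)$limit_cycle)
  expect_true(at(1)$limit_cycle)
  expect_false(at(2)$limit_cycle)
  # orbit extrema collapse onto the fixed point where the branch is stable
  expect_lt(abs(at(2)$V_max - at(2)$V_star), 0.01)
  expect_identical(at(0)$stability, "stable spiral")
  # the stability changes bracket the oscillatory window around [0.5, 1.5]
  w <- attr(hs, "instability_window")
  expect_identical(nrow(w), 2L)
  expect_true(w[1, "I_lo"] >= 0.2 && w[1, "I_hi"] <= 0.6)
  expect_true(w[2, "I_lo"] >= 1.3 && w[2, "I_hi"] <= 1.6)
})
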