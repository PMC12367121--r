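test_that("quantization truncates toward -inf and saturates at the range", {
  q <- quantize(0, q_format())
  expect_identical(q_raw(q), 0)
  expect_identical(as.double(q), 0)

  q <- quantize(0.08)
  expect_identical(q_raw(q), 20)            # floor(0.08 * 256)
  expect_identical(as.double(q), 0.078125)

  q <- quantize(200)
  expect_identical(as.double(q), (2^15 - 1) / 256)  # 127.99609375
  expect_true(q_saturated(q))

  q <- quantize(-1000)
  expect_identical(as.double(q), -128)

  expect_error(quantize(NaN), "finite")
  expect_error(quantize(Inf), "finite")
})

test_that("quantize is the identity on representable values", {
  fmt <- q_format()
  raw <- sample(fmt$raw_min:fmt$raw_max, 2000)
  vals <- raw * fmt$ulp
  expect_identical(q_raw(quantize(vals, fmt)), as.double(raw))
  # truncation error below one ulp inside the range
  x <- runif(2000, -127, 127)
  err <- x - as.double(quantize(x, fmt))
  expect_true(all(err >= 0 & err < fmt$ulp))
})

test_that("fixed-point add/sub are exact with saturating overflow", {
  one <- quantize(1)
  expect_identical(as.double(q_add(one, quantize(-1))), 0)
  expect_identical(as.double(q_add(quantize(127.99609375), one)),
                   127.99609375)
  expect_identical(as.double(q_add(quantize(0.078125), quantize(0.00390625))),
                   0.08203125)  # 20 + 1 = 21 mantissa units
  expect_identical(as.double(q_sub(quantize(-128), one)), -128)
  expect_error(q_add(one, quantize(1, q_format(4, 12))), "mismatch")
})

test_that("arithmetic shift matches division with truncation toward -inf", {
  expect_identical(as.double(q_shift(quantize(1), -5)), 0.03125)
  expect_identical(as.double(q_shift(quantize(-1), -8)), -0.00390625)
  expect_identical(as.double(q_shift(quantize(64), 2)), 127.99609375)
  expect_error(q_shift(quantize(1), 20), "word width")

  # q_shift(a, -k) == quantize(value(a) / 2^k), all Q8.8 mantissas
  fmt <- q_format()
  all_raw <- fmt$raw_min:fmt$raw_max
  q <- quantize(all_raw * fmt$ulp, fmt)
  for (k in c(1, 5, 8)) {
    expect_identical(q_raw(q_shift(q, -k)),
                     q_raw(quantize(all_raw * fmt$ulp / 2^k, fmt)))
  }
})

test_that("shift-add decompositions stay within one ulp of the constant", {
  for (c0 in c(0.8, 0.7, 1 / 3, 0.08, 0.33, -0.6)) {
    dec <- shift_decompose(c0)
    expect_lt(abs(attr(dec, "error")), 2^-8)
    expect_equal(sum(dec$term), attr(dec, "value"))
  }
  # the 1/T multiplier at T = 12.5 is two right shifts
  dec <- shift_decompose(0.08)
  expect_identical(dec$exponent, c(-4L, -6L))
})
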