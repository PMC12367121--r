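#' Signed fixed-point format descriptor
#'
#' Describes a two's-complement fixed-point word with `int_bits` integer bits
#' (including the sign bit) and `frac_bits` fraction bits. The default Q8.8
#' word is the 16-bit format used throughout the bit-accurate simulation
#' backend: 8 integer bits (including sign) and 8 fraction bits, so the unit
#' in the last place (ulp) is `2^-8` and the representable range is
#' `[-128, 128 - 2^-8]`.
#'
#' @param int_bits Integer bits including the sign bit (>= 1).
#' @param frac_bits Fraction bits (>= 0). Total width `int_bits + frac_bits`
#'   must not exceed 64.
#'
#' @return An object of class `q_format` with fields `int_bits`, `frac_bits`,
#'   `ulp`, `min`, `max` and the mantissa bounds `raw_min`, `raw_max`.
#' @examples
#' q_format()          # Q8.8
#' q_format(4, 12)     # Q4.12
#' @export
q_format <- function(int_bits = 8L, frac_bits = 8L) {
  int_bits <- as.integer(int_bits)
  frac_bits <- as.integer(frac_bits)
  if (is.na(int_bits) || int_bits < 1L) abort("`int_bits` must be >= 1.")
  if (is.na(frac_bits) || frac_bits < 0L) abort("`frac_bits` must be >= 0.")
  if (int_bits + frac_bits > 64L) abort("total width must be <= 64 bits.")
  w <- int_bits + frac_bits
  structure(
    list(
      int_bits = int_bits,
      frac_bits = frac_bits,
      width = w,
      ulp = 2^(-frac_bits),
      raw_min = -(2^(w - 1)),
      raw_max = 2^(w - 1) - 1,
      min = -(2^(int_bits - 1)),
      max = 2^(int_bits - 1) - 2^(-frac_bits)
    ),
    class = "q_format"
  )
}

#' @export
format.q_format <- function(x, ...) {
  sprintf("<Q%d.%d fixed point, range [%g, %g], ulp %g>",
          x$int_bits, x$frac_bits, x$min, x$max, x$ulp)
}

#' @export
print.q_format <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

is_q_format <- function(x) inherits(x, "q_format")

new_q_value <- function(raw, fmt, saturated = rep(FALSE, length(raw))) {
  structure(list(raw = raw, fmt = fmt, saturated = saturated),
            class = "q_value")
}

#' Quantize real numbers to a fixed-point format
#'
#' Converts real values to fixed-point by truncation toward negative infinity
#' of `x * 2^frac_bits` (the behaviour of a hardware arithmetic right shift),
#' saturating at the format limits. Quantization is idempotent: quantizing a
#' representable value returns it unchanged.
#'
#' @param x Finite numeric vector.
#' @param fmt A [q_format()].
#' @return A `q_value`: a vector of mantissas tagged with its format. Use
#'   [as.double()] to recover the represented real values, [q_raw()] for the
#'   integer mantissas, and [q_saturated()] to see which elements hit the
#'   range limits.
#' @examples
#' quantize(0.08)               # raw 20, value 0.078125
#' quantize(200)                # saturates at 127.99609375
#' as.double(quantize(-1.5))
#' @export
quantize <- function(x, fmt = q_format()) {
  stopifnot(is_q_format(fmt))
  if (!is.numeric(x) || any(!is.finite(x))) {
    abort("`x` must be finite numeric (non-finite values cannot be quantized).")
  }
  raw <- floor(x * 2^fmt$frac_bits)
  sat <- raw < fmt$raw_min | raw > fmt$raw_max
  raw <- pmin(pmax(raw, fmt$raw_min), fmt$raw_max)
  new_q_value(raw, fmt, sat)
}

#' Access the mantissa, format or saturation flags of a fixed-point value
#'
#' @param q A `q_value` created by [quantize()] or the fixed-point operators.
#' @return `q_raw()` the integer mantissas; `q_fmt()` the [q_format()];
#'   `q_saturated()` a logical vector marking elements that saturated.
#' @export
q_raw <- function(q) {
  stopifnot(inherits(q, "q_value"))
  q$raw
}

#' @rdname q_raw
#' @export
q_fmt <- function(q) {
  stopifnot(inherits(q, "q_value"))
  q$fmt
}

#' @rdname q_raw
#' @export
q_saturated <- function(q) {
  stopifnot(inherits(q, "q_value"))
  q$saturated
}

#' @export
as.double.q_value <- function(x, ...) x$raw * x$fmt$ulp

#' @export
length.q_value <- function(x) length(x$raw)

#' @export
format.q_value <- function(x, ...) {
  sprintf("%g (raw %d)", as.double(x), as.integer(x$raw))
}

#' @export
print.q_value <- function(x, ...) {
  cat(sprintf("<q_value Q%d.%d>\n", x$fmt$int_bits, x$fmt$frac_bits))
  print(utils::head(format(x), 20))
  if (length(x) > 20) cat("...", length(x) - 20, "more\n")
  invisible(x)
}

check_same_fmt <- function(a, b) {
  if (!inherits(a, "q_value") || !inherits(b, "q_value")) {
    abort("both operands must be `q_value` objects.")
  }
  if (a$fmt$int_bits != b$fmt$int_bits || a$fmt$frac_bits != b$fmt$frac_bits) {
    abort("fixed-point format mismatch: operands must share one q_format.")
  }
}

sat_raw <- function(raw, fmt) {
  sat <- raw < fmt$raw_min | raw > fmt$raw_max
  list(raw = pmin(pmax(raw, fmt$raw_min), fmt$raw_max), sat = sat)
}

#' Saturating fixed-point addition, subtraction and arithmetic shift
#'
#' `q_add()` and `q_sub()` perform exact integer mantissa arithmetic and
#' saturate the result at the format range, mirroring a hardware adder with
#' overflow clamping. `q_shift()` is the arithmetic shift: `k > 0` shifts left
#' (multiplies by `2^k`, saturating on overflow), `k < 0` shifts right
#' (divides by `2^|k|`, truncating toward negative infinity, so
#' `q_shift(x, -k)` equals `quantize(value(x) / 2^k)` for every mantissa).
#'
#' @param a,b `q_value` operands in the same format.
#' @param k Signed shift count, `|k|` at most the word width.
#' @return A `q_value` in the shared format.
#' @examples
#' one <- quantize(1)
#' as.double(q_shift(one, -5))                 # 0.03125
#' as.double(q_add(quantize(127.9960938), one)) # saturates at the maximum
#' @export
q_add <- function(a, b) {
  check_same_fmt(a, b)
  r <- sat_raw(a$raw + b$raw, a$fmt)
  new_q_value(r$raw, a$fmt, r$sat)
}

#' @rdname q_add
#' @export
q_sub <- function(a, b) {
  check_same_fmt(a, b)
  r <- sat_raw(a$raw - b$raw, a$fmt)
  new_q_value(r$raw, a$fmt, r$sat)
}

#' @rdname q_add
#' @export
q_shift <- function(a, k) {
  stopifnot(inherits(a, "q_value"))
  k <- as.integer(k)
  if (abs(k) > a$fmt$width) abort("|k| must not exceed the word width.")
  raw <- if (k >= 0) a$raw * 2^k else floor(a$raw / 2^(-k))
  r <- sat_raw(raw, a$fmt)
  new_q_value(r$raw, a$fmt, r$sat)
}

#' Decompose a constant into signed powers of two
#'
#' Greedy signed-digit recoding of a multiplicative constant into a sum of
#' terms `s * 2^k` (`s` in {-1, +1}), stopping when the remainder falls below
#' `tol`. This is how the fixed-point backend realizes multiplications by
#' model constants (`b`, `1/T`, `1/3`) as shift-add networks: each term is one
#' arithmetic shift of the multiplicand. The default tolerance is the Q8.8
#' ulp, so the decomposition error is below one representable step.
#'
#' @param x Constant to decompose (non-zero magnitude below `2^32`).
#' @param tol Stop once `|remainder| < tol`.
#' @return A tibble with columns `sign`, `exponent`, `term`, plus attributes
#'   `value` (the represented sum) and `error`.
#' @examples
#' shift_decompose(0.08)  # 2^-4 + 2^-6: the 1/T multiplier at T = 12.5
#' shift_decompose(1 / 3)
#' @export
shift_decompose <- function(x, tol = 2^-8) {
  stopifnot(is.numeric(x), length(x) == 1, is.finite(x), tol > 0)
  signs <- integer()
  exps <- integer()
  r <- x
  while (abs(r) >= tol) {
    k <- floor(log2(abs(r)))
    # pick the nearer of 2^k and 2^(k+1)
    if (2^(k + 1) - abs(r) < abs(r) - 2^k) k <- k + 1
    signs <- c(signs, as.integer(sign(r)))
    exps <- c(exps, as.integer(k))
    r <- r - sign(r) * 2^k
  }
  out <- tibble(sign = signs, exponent = exps, term = signs * 2^exps)
  attr(out, "value") <- sum(out$term)
  attr(out, "error") <- x - sum(out$term)
  out
}

# Apply a shift-add decomposition to a mantissa vector, truncating each
# right shift toward -inf (one truncation per shift term, as the adder tree
# in hardware would).
apply_shifts_raw <- function(raw, dec) {
  tot <- numeric(length(raw))
  for (j in seq_len(nrow(dec))) {
    k <- dec$exponent[j]
    sh <- if (k >= 0) raw * 2^k else floor(raw / 2^(-k))
    tot <- tot + dec$sign[j] * sh
  }
  tot
}
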