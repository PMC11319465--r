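test_that("polynomial arithmetic is exact and canonical", {
  x <- mvp_var("x"); y <- mvp_var("y")
  sq <- mvp_pow(mvp_add(x, y), 2)
  expanded <- mvp_add(mvp_add(mvp_pow(x, 2), mvp_scale(mvp_mul(x, y), 2)),
                      mvp_pow(y, 2))
  expect_true(mvp_equal(sq, expanded))
  expect_true(mvp_is_zero(mvp_sub(sq, expanded)))
  expect_false(mvp_is_zero(mvp_sub(sq, mvp_pow(x, 2))))
  # cancellation to exact zero
  expect_true(mvp_is_zero(mvp_sub(mvp_mul(x, y), mvp_mul(y, x))))
  expect_identical(format(mvp_const(0)), "0")
})

test_that("evaluation agrees with direct arithmetic on random points", {
  x <- mvp_var("x"); y <- mvp_var("y"); z <- mvp_var("z")
  p <- mvp_add(mvp_scale(mvp_mul(mvp_pow(x, 3), y), 2),
               mvp_sub(mvp_mul(y, mvp_pow(z, 2)), mvp_const(5)))
  set.seed(42)
  for (i in 1:25) {
    v <- list(x = runif(1, -2, 2), y = runif(1, -2, 2), z = runif(1, -2, 2))
    expect_equal(mvp_eval(p, v), 2 * v$x^3 * v$y + v$y * v$z^2 - 5,
                 tolerance = 1e-14)
  }
})

test_that("substitution and square-reduction implement ring identities", {
  x <- mvp_var("x"); a <- mvp_var("a"); b <- mvp_var("b")
  # substitute x -> a + b into x^2: (a+b)^2
  p <- mvp_subst(mvp_pow(x, 2), "x", mvp_add(a, b))
  expect_true(mvp_equal(p, mvp_pow(mvp_add(a, b), 2)))
  # ratio substitution clears denominators: x^2 + x with x -> a/b gives
  # a^2 + a*b (times b^deg = b^2)
  q <- mvp_subst_ratio(mvp_add(mvp_pow(x, 2), x), "x", a, b)
  expect_true(mvp_equal(q, mvp_add(mvp_pow(a, 2), mvp_mul(a, b))))
  # reduce x^2 = a/b: b*x^3 - a*x must vanish
  r <- mvp_sub(mvp_mul(b, mvp_pow(x, 3)), mvp_mul(a, x))
  expect_true(mvp_is_zero(mvp_reduce_square(r, "x", a, b)))
  # and a non-member does not
  r2 <- mvp_sub(mvp_mul(b, mvp_pow(x, 3)), mvp_mul(b, x))
  expect_false(mvp_is_zero(mvp_reduce_square(r2, "x", a, b)))
})

test_that("rendering is deterministic and sorted", {
  p <- mvp_add(mvp_mul(mvp_var("b"), mvp_var("a")), mvp_const(1))
  expect_identical(format(p), format(p))
  expect_match(format(p), "1 \\+ a\\*b")
})
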