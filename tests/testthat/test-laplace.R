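# Laplace quadrature of 1/x: exactness limits, minimality, error bounds.

test_that("degenerate range is reproduced exactly by one point", {
  q <- laplace_quadrature(0.5, 0.5, 1e-2)
  expect_equal(q$n, 1L)
  expect_equal(laplace_eval(q, 0.5), 2, tolerance = 1e-12)
})

test_that("the relative error bound holds across the range", {
  q <- laplace_quadrature(0.4, 8, 1e-4)
  x <- exp(seq(log(0.4), log(8), length.out = 1777))
  expect_lt(max(abs(laplace_eval(q, x) * x - 1)), 1.5e-4)
})

test_that("point counts do not increase as the tolerance loosens", {
  ns <- vapply(c(1e-6, 1e-4, 1e-2), function(tol)
    laplace_quadrature(0.4, 8, tol)$n, 0L)
  expect_true(all(diff(ns) <= 0))
})

test_that("typical valence denominator ranges need only 3-4 points", {
  q <- laplace_quadrature(0.6, 4, 1e-2)
  expect_lte(q$n, 4L)
  expect_gte(q$n, 3L)
})

test_that("non-positive ranges are rejected", {
  expect_error(laplace_quadrature(-0.1, 1, 1e-2), "non-positive")
  expect_error(laplace_quadrature(0, 1, 1e-2), "non-positive")
})
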