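# Gaussian integral engine against closed-form values, and the
# density-fitting machinery against textbook H2 numbers.

mkb <- function(l, atom, centers, exps, coefs)
  list(l = as.integer(l), atom = as.integer(atom), centers = centers,
       exps = exps, coefs = coefs)

test_that("s-function integrals match closed forms", {
  a <- 0.5; b <- 1.3; R <- 1.1
  bas <- mkb(c(0, 0), c(0, 1), rbind(c(0, 0, 0), c(0, 0, R)), list(a, b), list(1, 1))
  S <- cpp_overlap(bas)
  p <- a + b
  Na <- (2 * a / pi)^0.75; Nb <- (2 * b / pi)^0.75
  expect_equal(S[1, 2], (pi / p)^1.5 * exp(-a * b * R^2 / p) * Na * Nb, tolerance = 1e-12)
  expect_equal(diag(S), c(1, 1), tolerance = 1e-12)
  Tm <- cpp_kinetic(bas)
  mu <- a * b / p
  expect_equal(Tm[1, 2], mu * (3 - 2 * mu * R^2) * (pi / p)^1.5 *
                 exp(-mu * R^2) * Na * Nb, tolerance = 1e-12)
  expect_equal(Tm[1, 1], 1.5 * a, tolerance = 1e-12)
  V1 <- cpp_nuclear(mkb(0, 0, rbind(c(0, 0, 0)), list(a), list(1)),
                    1.0, rbind(c(0, 0, 0)))
  expect_equal(V1[1, 1], -2 * sqrt(2 * a / pi), tolerance = 1e-12)
  # 2-center Coulomb at distance: closed form with the Boys function
  alpha <- a * b / p
  F0 <- 0.5 * sqrt(pi / (alpha * R^2)) * pracma::erf(sqrt(alpha * R^2))
  e2 <- cpp_eri2c(bas)
  expect_equal(e2[1, 2], 2 * pi^2.5 / (a * b * sqrt(p)) * F0 * Na * Nb,
               tolerance = 1e-12)
})

test_that("higher angular momentum overlap matches numerical quadrature", {
  a <- 0.7; b <- 0.4; R <- 0.9
  bas <- mkb(c(2, 1), c(0, 1), rbind(c(0, 0, 0), c(0.2, 0.3, R)),
             list(a, b), list(1, 1))
  S <- cpp_overlap(bas)
  g <- pracma::gaussLegendre(60, -6, 6)
  grid <- expand.grid(x = g$x, y = g$x, z = g$x)
  wt <- as.vector(outer(outer(g$w, g$w), g$w))
  f3 <- function(comp, alpha, cen)
    (grid$x - cen[1])^comp[1] * (grid$y - cen[2])^comp[2] *
    (grid$z - cen[3])^comp[3] *
    exp(-alpha * ((grid$x - cen[1])^2 + (grid$y - cen[2])^2 + (grid$z - cen[3])^2))
  comps2 <- list(c(2, 0, 0), c(1, 1, 0), c(0, 0, 2))
  rows <- c(1, 2, 6)
  fb <- f3(c(0, 0, 1), b, c(0.2, 0.3, R))
  nb <- 1 / sqrt(sum(wt * fb * fb))
  for (k in seq_along(comps2)) {
    fa <- f3(comps2[[k]], a, c(0, 0, 0))
    na <- 1 / sqrt(sum(wt * fa * fa))
    expect_equal(S[rows[k], 6 + 3], sum(wt * fa * fb) * na * nb, tolerance = 1e-7)
  }
})

test_that("density-fitted ERIs reproduce the textbook H2/STO-3G values", {
  ref <- ref_h2_sto()
  Bm <- matrix(ref$df$B, 4, ref$df$naux)
  g <- array(tcrossprod(Bm), c(2, 2, 2, 2))
  # Szabo-Ostlund Table 3.2 (exact-integral values; DF reproduces them
  # to the fitting accuracy)
  expect_equal(g[1, 1, 1, 1], 0.7746, tolerance = 2e-3)
  expect_equal(g[1, 1, 2, 2], 0.5697, tolerance = 2e-3)
  expect_equal(g[1, 2, 1, 2], 0.2970, tolerance = 2e-2)
  expect_equal(g[1, 1, 1, 2], 0.4441, tolerance = 2e-3)
  # symmetry of the fitted ERIs
  expect_equal(g, aperm(g, c(3, 4, 1, 2)), tolerance = 1e-12)
})

test_that("basis parsing and the auxiliary generator are sane", {
  bs <- load_basis("sto-3g")
  expect_named(bs, c("H", "C", "N", "O"))
  expect_length(bs$C, 3)           # 1s, 2s, 2p
  expect_error(load_basis("no-such-basis"), "unknown basis")
  aux <- autoaux_basis(bs)
  lH <- vapply(aux$H, `[[`, 0L, "l")
  expect_true(max(lH) >= 1L)       # H auxiliary carries p functions
  lC <- vapply(aux$C, `[[`, 0L, "l")
  expect_true(max(lC) == 2L)       # s/p orbital basis -> d auxiliary
})
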