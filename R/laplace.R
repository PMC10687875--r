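# Laplace quadrature for orbital-energy denominators:
# 1/x ~ sum_q w_q exp(-x t_q) on [x_min, x_max] to relative accuracy T_LT.

#' Build a Laplace quadrature for 1/x on a denominator range
#'
#' Finds the smallest number of quadrature points whose least-squares
#' weights meet the requested sup-norm relative error on a dense
#' logarithmic test grid. Deterministic: fixed grids and candidate
#' exponent spacings.
#'
#' @param x_min,x_max positive denominator range bounds (hartree).
#' @param T_LT relative-error tolerance.
#' @param n_max maximum number of quadrature points tried.
#' @return \code{lnocc_laplace}: points \code{t}, weights \code{w},
#'   \code{n}, achieved \code{err}, range.
#' @export
laplace_quadrature <- function(x_min, x_max, T_LT = 1e-2, n_max = 40) {
  if (!(x_min > 0)) stop("non-positive denominator bound (x_min = ",
                         signif(x_min, 4), "): near-degenerate reference")
  if (x_max < x_min) stop("x_max < x_min")
  if (x_max / x_min < 1 + 1e-12) {
    t1 <- 1 / x_min
    return(structure(list(t = t1, w = exp(x_min * t1) / x_min, n = 1L,
                          err = 0, x_min = x_min, x_max = x_max, T_LT = T_LT),
                     class = "lnocc_laplace"))
  }
  xg <- exp(seq(log(x_min), log(x_max), length.out = 400))
  solve_w <- function(tq) {
    A <- exp(-outer(xg, tq)) * xg
    sv <- svd(A)
    keep <- sv$d > 1e-13 * sv$d[1]
    pinv_apply <- function(rhs)
      sv$v[, keep, drop = FALSE] %*%
        ((crossprod(sv$u[, keep, drop = FALSE], rhs)) / sv$d[keep])
    rhs <- rep(1, length(xg))
    w <- pinv_apply(rhs)
    for (it in 1:3) w <- w + pinv_apply(rhs - A %*% w)
    w <- as.vector(w)
    if (any(!is.finite(w))) return(NULL)
    list(w = w, err = max(abs(A %*% w - 1)))
  }
  best <- NULL
  # start near the theoretical best-exponential-sum point count
  n_start <- max(1, floor(0.7 * log(1 / T_LT) * log(16 * x_max / x_min) / pi^2))
  for (n in n_start:n_max) {
    best_n <- NULL
    for (spread in c(0.5, 0.75, 1, 1.5, 2.5)) {
      # exponential tail at x_min only needs to decay to ~T_LT
      t_hi <- spread * log(20 / T_LT) / x_min
      t_lo <- T_LT^0.25 / (spread * 10 * x_max)
      tq <- if (n == 1) sqrt(t_lo * t_hi) else
        exp(seq(log(t_lo), log(t_hi), length.out = n))
      sol <- solve_w(tq)
      if (is.null(sol)) next
      if (is.null(best_n) || sol$err < best_n$err)
        best_n <- list(t = tq, w = sol$w, err = sol$err)
    }
    # deterministic refinement of the point positions (fixed start,
    # fixed iteration budget) brings the least-squares grid close to the
    # minimax point count
    if (!is.null(best_n) && best_n$err > T_LT && n > 1) {
      obj <- function(lt) {
        s <- solve_w(exp(lt))
        if (is.null(s)) return(1e10)
        s$err
      }
      op <- stats::optim(log(best_n$t), obj, method = "Nelder-Mead",
                         control = list(maxit = 150 * n, reltol = 1e-12))
      s2 <- solve_w(exp(op$par))
      if (!is.null(s2) && s2$err < best_n$err)
        best_n <- list(t = exp(op$par), w = s2$w, err = s2$err)
    }
    if (!is.null(best_n)) {
      if (is.null(best) || best_n$err < best$err) best <- best_n
      if (best_n$err <= T_LT) {
        ord <- order(best_n$t)
        return(structure(list(t = best_n$t[ord], w = best_n$w[ord],
                              n = as.integer(n), err = best_n$err,
                              x_min = x_min, x_max = x_max, T_LT = T_LT),
                         class = "lnocc_laplace"))
      }
    }
  }
  stop("Laplace quadrature did not reach T_LT = ", T_LT,
       " with ", n_max, " points (best ", signif(best$err, 3), ")")
}

#' @export
print.lnocc_laplace <- function(x, ...) {
  cat("<laplace quadrature>", x$n, "points on [",
      signif(x$x_min, 4), ",", signif(x$x_max, 4), "], rel err",
      signif(x$err, 3), "\n")
  invisible(x)
}

# evaluate the quadrature approximation of 1/x
laplace_eval <- function(quad, x) {
  as.vector(exp(-outer(x, quad$t)) %*% quad$w)
}

# memoized quadrature on a slightly padded, rounded range: domains with
# near-identical denominator ranges share one quadrature object
.quad_cache <- new.env(parent = emptyenv())
laplace_quadrature_cached <- function(x_min, x_max, T_LT) {
  lo <- signif(x_min * 0.95, 2)
  hi <- signif(x_max * 1.06, 2)
  key <- paste(lo, hi, T_LT, sep = "|")
  q <- .quad_cache[[key]]
  if (is.null(q)) {
    q <- laplace_quadrature(lo, hi, T_LT)
    .quad_cache[[key]] <- q
  }
  q
}
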