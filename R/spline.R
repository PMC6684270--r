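#' Penalized cubic smoothing splines (csaps convention)
#'
#' Fits a natural cubic smoothing spline minimizing
#' \deqn{p \sum_j w_j (y_j - f(x_j))^2 + (1 - p) \int f''(t)^2 \, dt}
#' over all cubic splines with knots at the unique data sites. The smoothing
#' parameter `p` lies in \[0, 1\]: `p = 1` interpolates the data and `p = 0`
#' gives the weighted least-squares straight line. This is the convention
#' under which the pipeline's printed smoothing parameters (0.10 for activity
#' smoothing, 0.03/0.01 for maturity trajectories, 0.1/0.3 for peri-event
#' session/population splines, 0.0001 for developmental curves) are
#' meaningful; other spline tools parameterize the trade-off differently.
#'
#' Duplicate abscissa values are collapsed to their weighted mean with summed
#' weight, which leaves the objective (and hence the minimizer) unchanged.
#' Non-finite pairs are dropped. Outside the data range the natural spline is
#' extrapolated linearly.
#'
#' @param x,y Numeric vectors of equal length; at least 4 finite pairs.
#' @param p Smoothing parameter in \[0, 1\].
#' @param w Optional nonnegative observation weights (default 1).
#' @return An object of class `csaps_spline` with elements `knots` (unique
#'   sorted sites), `values` (fitted values at the knots), `gamma` (second
#'   derivatives at the knots, zero at the ends), and `p`.
#' @examples
#' set.seed(1)
#' x <- seq(0, 10, length.out = 50)
#' fit <- fit_spline(x, sin(x) + rnorm(50, sd = 0.1), p = 0.6)
#' plot(x, predict(fit, x), type = "l")
#' @export
fit_spline <- function(x, y, p, w = NULL) {
  stopifnot(length(x) == length(y), is.numeric(p), length(p) == 1L)
  if (is.na(p) || p < 0 || p > 1) {
    stop("smoothing parameter `p` must lie in [0, 1], got ", p)
  }
  if (is.null(w)) w <- rep(1, length(x))
  keep <- is.finite(x) & is.finite(y) & is.finite(w) & w > 0
  x <- x[keep]; y <- y[keep]; w <- w[keep]
  if (length(x) < 4L) {
    stop("fit_spline needs at least 4 finite (x, y) pairs, got ", length(x))
  }
  # collapse duplicate sites: weighted mean, summed weight
  o <- order(x)
  x <- x[o]; y <- y[o]; w <- w[o]
  grp <- cumsum(c(TRUE, diff(x) > 0))
  if (max(grp) < length(x)) {
    xs <- as.numeric(tapply(x, grp, `[`, 1L))
    ws <- as.numeric(tapply(w, grp, sum))
    ys <- as.numeric(tapply(w * y, grp, sum)) / ws
  } else {
    xs <- x; ys <- y; ws <- w
  }
  n <- length(xs)
  if (n < 2L) stop("fit_spline needs at least 2 distinct sites")

  if (p == 0 || n < 3L) {
    # least-squares line (the p -> 0 limit; also the n = 2 case)
    fitv <- stats::lm.wfit(cbind(1, xs), ys, ws)$fitted.values
    return(new_csaps_spline(xs, as.numeric(fitv), rep(0, n), p))
  }

  # Reinsch algorithm: with alpha = (1 - p) / p the stationarity conditions
  # reduce to the banded system (R + alpha Q' W^-1 Q) gamma = Q' y,
  # f = y - alpha W^-1 Q gamma, solved in O(n) via sparse Cholesky.
  alpha <- (1 - p) / p
  QR <- csaps_qr_sparse(xs)
  Qt <- Matrix::t(QR$Q)
  M <- QR$R + alpha * (Qt %*% (QR$Q / ws))
  gam_int <- Matrix::solve(M, Qt %*% ys)
  f <- ys - alpha * as.numeric(QR$Q %*% gam_int) / ws
  gam <- c(0, as.numeric(gam_int), 0)
  new_csaps_spline(xs, as.numeric(f), gam, p)
}

new_csaps_spline <- function(knots, values, gamma, p) {
  structure(list(knots = knots, values = values, gamma = gamma, p = p),
            class = "csaps_spline")
}

# sparse Q (n x (n-2)) and R ((n-2) x (n-2)) for the Reinsch system
csaps_qr_sparse <- function(xs) {
  n <- length(xs)
  h <- diff(xs)
  j <- 2:(n - 1L)
  Q <- Matrix::sparseMatrix(
    i = c(j - 1L, j, j + 1L),
    j = rep(j - 1L, 3L),
    x = c(1 / h[j - 1L], -(1 / h[j - 1L] + 1 / h[j]), 1 / h[j]),
    dims = c(n, n - 2L))
  k <- seq_len(n - 2L)
  diag0 <- (h[k] + h[k + 1L]) / 3
  R <- if (n == 3L) {
    Matrix::Matrix(matrix(diag0), sparse = TRUE)
  } else {
    Matrix::bandSparse(n - 2L, k = c(0, 1),
                       diagonals = list(diag0, h[k[-length(k)] + 1L] / 6),
                       symmetric = TRUE)
  }
  list(Q = Q, R = R)
}

# dense Q and R of the natural-spline roughness factorization:
# integral f''^2 = f' Q R^-1 Q' f, with Q'f = R gamma (used by the
# fixed-grid smoother-matrix path).
csaps_qr <- function(xs) {
  n <- length(xs)
  h <- diff(xs)
  Q <- matrix(0, n, n - 2L)
  R <- matrix(0, n - 2L, n - 2L)
  for (j in 2:(n - 1L)) {
    k <- j - 1L
    Q[j - 1L, k] <- 1 / h[j - 1L]
    Q[j, k] <- -(1 / h[j - 1L] + 1 / h[j])
    Q[j + 1L, k] <- 1 / h[j]
    R[k, k] <- (h[j - 1L] + h[j]) / 3
    if (k < n - 2L) {
      R[k, k + 1L] <- h[j] / 6
      R[k + 1L, k] <- h[j] / 6
    }
  }
  list(Q = Q, R = R)
}

#' Evaluate a fitted smoothing spline
#'
#' @param object A `csaps_spline` from [fit_spline()].
#' @param newdata Numeric vector of evaluation points (default: the knots).
#' @param ... Unused.
#' @return Numeric vector of spline values; linear extrapolation outside the
#'   knot range.
#' @export
predict.csaps_spline <- function(object, newdata = object$knots, ...) {
  xs <- object$knots; f <- object$values; gam <- object$gamma
  n <- length(xs)
  t <- as.numeric(newdata)
  out <- rep(NA_real_, length(t))
  h <- diff(xs)
  d1_left <- (f[2] - f[1]) / h[1] - h[1] * gam[2] / 6
  d1_right <- (f[n] - f[n - 1]) / h[n - 1] + h[n - 1] * gam[n - 1] / 6
  lo <- t < xs[1]; hi <- t > xs[n]
  out[lo] <- f[1] + (t[lo] - xs[1]) * d1_left
  out[hi] <- f[n] + (t[hi] - xs[n]) * d1_right
  mid <- which(!lo & !hi & !is.na(t))
  if (length(mid)) {
    i <- findInterval(t[mid], xs, rightmost.closed = TRUE)
    i[i >= n] <- n - 1L
    xl <- xs[i]; xr <- xs[i + 1L]; hi_ <- xr - xl
    a <- (xr - t[mid]) / hi_; b <- (t[mid] - xl) / hi_
    out[mid] <- a * f[i] + b * f[i + 1L] -
      (t[mid] - xl) * (xr - t[mid]) / 6 *
        ((1 + a) * gam[i] + (1 + b) * gam[i + 1L])
  }
  out
}

#' @export
print.csaps_spline <- function(x, ...) {
  cat("<csaps_spline> ", length(x$knots), " knots on [",
      format(min(x$knots)), ", ", format(max(x$knots)),
      "], p = ", format(x$p), "\n", sep = "")
  invisible(x)
}

# Smoother matrix S for a fixed design: fitted values at the sites are S %*% y.
# Used by the resampling loops, where thousands of fits share one grid.
csaps_smoother <- function(xs, p, w = rep(1, length(xs))) {
  n <- length(xs)
  stopifnot(n >= 3L, all(diff(xs) > 0), p > 0, p <= 1)
  QR <- csaps_qr(xs)
  K <- QR$Q %*% solve(QR$R, t(QR$Q))
  A <- (1 - p) * K
  diag(A) <- diag(A) + p * w
  solve(A, p * diag(w, n))
}

#' Tidy a fitted smoothing spline
#'
#' @param x A `csaps_spline`.
#' @param ... Unused.
#' @return A tibble with one row per knot: `knot`, `value`, `second_deriv`.
#' @export
tidy.csaps_spline <- function(x, ...) {
  tibble::tibble(knot = x$knots, value = x$values, second_deriv = x$gamma)
}

#' @export
glance.csaps_spline <- function(x, ...) {
  tibble::tibble(n_knots = length(x$knots), p = x$p,
                 x_min = min(x$knots), x_max = max(x$knots))
}
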