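#' Fit a straight-line quantile regression by exact check-loss minimization
#'
#' Finds `(intercept, slope)` minimizing the asymmetric check loss
#' \deqn{\sum_i \rho_\tau(y_i - a - b x_i), \quad
#'       \rho_\tau(u) = u(\tau - 1[u < 0]),}
#' i.e. the conditional \eqn{\tau}-quantile line of `y` given `x`. The
#' solver works on the linear-programming geometry of the problem: an
#' optimal line passes through at least two data points, and the algorithm
#' alternates exact one-dimensional line searches ("rotations" of the line
#' about one of its active points, each solved as a weighted median over the
#' candidate slopes to the remaining points) until neither active point
#' admits an improving rotation, which certifies a vertex optimum of the
#' piecewise-linear convex objective. Ties among optima are resolved
#' deterministically (stable sort, smallest breakpoint index); the achieved
#' check loss is reported so ties can be audited.
#'
#' @param x,y Numeric vectors (n >= 3); `x` must not be constant.
#' @param tau Quantile level in (0, 1).
#' @return List of class `quantile_fit`: `coefficients` (named
#'   `intercept`, `slope`), `tau`, `loss` (achieved check loss), `n`,
#'   `basis` (indices of the two active observations), `x`, `y`,
#'   `convention` (latitude sign convention; `NA` for raw fits), and `mcmb`
#'   (`NULL` until [mcmb_standard_errors()] is run).
#' @seealso [fit_age_gradient()] for the data-frame interface,
#'   [mcmb_standard_errors()] for uncertainty.
#' @export
#' @examples
#' set.seed(1)
#' x <- runif(50); y <- 1 + 2 * x
#' fit_quantile_regression(x, y, 0.9)$coefficients  # exact line, any tau
fit_quantile_regression <- function(x, y, tau) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("x and y must not contain NA", call. = FALSE)
  if (!(tau > 0 && tau < 1)) stop("tau must be in (0, 1)", call. = FALSE)
  if (diff(range(x)) == 0) {
    stop("all x identical: slope is unidentifiable", call. = FALSE)
  }

  # initial pivot: the tau-order statistic of y for the horizontal line b = 0
  i <- order(y, seq_len(n))[min(n, max(1L, ceiling(tau * n)))]
  a <- b <- NA_real_
  loss <- Inf
  basis <- c(NA_integer_, NA_integer_)
  for (it in seq_len(500L)) {
    rot <- qr_rotate(x, y, tau, i)
    a_new <- y[i] - rot$b * x[i]
    l_new <- qr_check_loss(y - a_new - rot$b * x, tau)
    if (is.finite(loss) && l_new >= loss - 1e-12 * (1 + abs(loss))) break
    loss <- l_new
    a <- a_new
    b <- rot$b
    basis <- c(i, rot$partner)
    i <- rot$partner
  }

  structure(
    list(
      coefficients = c(intercept = a, slope = b),
      tau = tau, loss = loss, n = n, basis = basis,
      x = x, y = y, convention = NA_character_, mcmb = NULL
    ),
    class = "quantile_fit"
  )
}

qr_check_loss <- function(r, tau) sum(r * (tau - (r < 0)))

# Exact minimization over b of sum_k rho_tau(y_k - y_i - b (x_k - x_i)):
# the derivative in b is a step function, negative at -Inf, with a positive
# jump |dx_k| at each candidate slope s_k = dy_k / dx_k; the minimizer is the
# weighted-median breakpoint where the subgradient first covers zero.
qr_rotate <- function(x, y, tau, i) {
  dx <- x - x[i]
  dy <- y - y[i]
  ok <- which(dx != 0)
  s <- dy[ok] / dx[ok]
  o <- order(s, ok)  # stable, deterministic tie-break by index
  s <- s[o]
  idx <- ok[o]
  w <- abs(dx[ok][o])
  g0 <- -tau * sum(dx[dx > 0]) + (1 - tau) * sum(dx[dx < 0])
  cum <- g0 + cumsum(w)
  m <- which(cum >= 0)[1]
  list(b = s[m], partner = idx[m])
}

#' @export
print.quantile_fit <- function(x, ...) {
  cat(sprintf("Quantile regression (tau = %.2f, n = %d)\n", x$tau, x$n))
  cat(sprintf("  intercept %.4g, slope %.4g (check loss %.6g)\n",
              x$coefficients[1], x$coefficients[2], x$loss))
  if (!is.null(x$mcmb)) {
    cat(sprintf("  MCMB (%d resamples): slope s.e. %.4g, t = %.3g, p = %.3g\n",
                x$mcmb$n_resamples, x$mcmb$se["slope"], x$mcmb$t, x$mcmb$p))
  }
  invisible(x)
}

#' @export
coef.quantile_fit <- function(object, ...) object$coefficients

#' Markov chain marginal bootstrap standard errors for a quantile fit
#'
#' Resampling uncertainty for the quantile-regression coefficients using the
#' Markov chain marginal bootstrap (MCMB): a chain of coefficient draws is
#' built by updating one coefficient at a time, each update solving its
#' one-dimensional marginal estimating equation
#' \eqn{\sum_i x_{ij}\,\psi_\tau(y_i - x_i'\beta) = Z_j} with the right-hand
#' side a with-replacement bootstrap draw of the fitted score terms
#' \eqn{x_{ij}\,\psi_\tau(\hat r_i)}. Each marginal solve reduces to a
#' weighted quantile and is exact. The chain runs on centered and scaled `x`
#' (which decorrelates the two updates and improves mixing) and the draws
#' are mapped back to the original scale. The first 10% of the chain is
#' discarded as burn-in; the standard error is the standard deviation of
#' the remaining draws, `t = slope / se`, and the two-sided p-value uses
#' Student's t with `n - 2` degrees of freedom.
#'
#' @param fit A `quantile_fit` from [fit_quantile_regression()].
#' @param n_resamples Chain length (resamples); at least 50.
#' @param seed Integer seed; the whole chain is reproducible from it.
#' @return The fit with an `mcmb` element: `chain` (post-burn-in draws,
#'   columns `intercept`, `slope`), `se`, `t`, `p`, `n_resamples`, `burn_in`,
#'   `seed`.
#' @export
mcmb_standard_errors <- function(fit, n_resamples = 999, seed = 1) {
  stopifnot(inherits(fit, "quantile_fit"))
  if (n_resamples < 50) {
    stop("n_resamples < 50 gives unstable standard errors", call. = FALSE)
  }
  x <- fit$x
  y <- fit$y
  tau <- fit$tau
  n <- fit$n
  mx <- mean(x)
  sx <- stats::sd(x)
  xs <- (x - mx) / sx
  X <- cbind(1, xs)
  # same line in standardized coordinates
  beta <- c(fit$coefficients[1] + fit$coefficients[2] * mx,
            fit$coefficients[2] * sx)
  r_hat <- y - as.vector(X %*% beta)
  psi_hat <- tau - (r_hat < 0)

  chain <- matrix(NA_real_, n_resamples, 2)
  withr::with_seed(as.integer(seed), {
    for (k in seq_len(n_resamples)) {
      for (j in 1:2) {
        idx <- sample.int(n, n, replace = TRUE)
        z <- sum(X[idx, j] * psi_hat[idx])
        u <- y - X[, -j] * beta[-j]
        beta[j] <- mcmb_marginal_solve(X[, j], u, tau, z)
      }
      chain[k, ] <- beta
    }
  })

  slope <- chain[, 2] / sx
  intercept <- chain[, 1] - slope * mx
  draws <- cbind(intercept = intercept, slope = slope)
  burn <- floor(0.1 * n_resamples)
  kept <- draws[(burn + 1):n_resamples, , drop = FALSE]
  se <- apply(kept, 2, stats::sd)
  t_stat <- unname(fit$coefficients["slope"] / se["slope"])
  p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  fit$mcmb <- list(chain = kept, se = se, t = t_stat, p = p,
                   n_resamples = n_resamples, burn_in = burn,
                   seed = as.integer(seed))
  fit
}

# Solve sum_i v_i (tau - 1[u_i - v_i b < 0]) = z for b. The left side is a
# non-increasing step function of b with drops |v_i| at t_i = u_i / v_i;
# return the first breakpoint at which it falls to or below z.
mcmb_marginal_solve <- function(v, u, tau, z) {
  nz <- v != 0
  tt <- u[nz] / v[nz]
  w <- abs(v[nz])
  o <- order(tt)
  tt <- tt[o]
  w <- w[o]
  g0 <- tau * sum(v[v > 0]) + (tau - 1) * sum(v[v < 0])
  cum <- g0 - cumsum(w)
  m <- which(cum <= z)[1]
  if (is.na(m)) m <- length(tt)  # z below the infimum: clamp to last breakpoint
  tt[m]
}
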