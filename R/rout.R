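# Robust straight-line regression with outlier removal (ROUT).
#
# The procedure, following Motulsky & Brown's robust-regression-and-outlier
# removal scheme specialized to a straight line:
#   1. fit the line robustly by minimizing the Lorentzian merit function
#      sum(log(1 + (residual/RSDR)^2)), starting from ordinary least squares
#      and re-estimating the robust residual scale between iterations;
#   2. estimate the robust standard deviation of residuals (RSDR) as the
#      68.27th percentile of |residuals| times N/(N-K), K = 2;
#   3. scan residuals from the largest: the j-th largest is called an
#      outlier while its two-tailed t-probability (df = N-K) stays below
#      j * Q / N (equivalently Q * (N - i + 1) / N for ascending rank i),
#      where Q is the desired maximum false-discovery rate; the scan stops
#      at the first survivor;
#   4. report the ordinary least-squares fit through the surviving points.

.lorentzian_fit <- function(x, y, K, tol = 1e-9, max_iter = 500L) {
  N <- length(y)
  X <- cbind(1, x)
  beta <- stats::.lm.fit(X, y)$coefficients
  merit_old <- Inf
  rsdr <- NA_real_
  for (iter in seq_len(max_iter)) {
    res <- y - X %*% beta
    rsdr <- stats::quantile(abs(res), 0.6827, type = 7, names = FALSE) *
      N / (N - K)
    if (rsdr <= 0) break  # perfect fit: nothing to robustify
    fn <- function(b) sum(log1p(((y - X %*% b) / rsdr)^2))
    gr <- function(b) {
      u <- (y - X %*% b) / rsdr
      w <- 2 * u / (1 + u^2) / rsdr
      -c(sum(w), sum(w * x))
    }
    opt <- stats::optim(beta, fn, gr, method = "BFGS",
                        control = list(maxit = 200))
    beta <- opt$par
    if (is.finite(merit_old) &&
        abs(merit_old - opt$value) <= tol * max(abs(merit_old), 1)) break
    merit_old <- opt$value
  }
  res <- as.numeric(y - X %*% beta)
  rsdr <- stats::quantile(abs(res), 0.6827, type = 7, names = FALSE) *
    N / (N - K)
  list(coefficients = as.numeric(beta), residuals = res, rsdr = rsdr)
}

# FDR-style scan over |residuals|, largest first; returns logical inlier
# mask. `scale` guards the essentially-perfect fit: when the robust residual
# spread is indistinguishable from floating-point rounding of the data there
# are no outliers to call.
.rout_scan <- function(res, rsdr, Q, df, scale = 1) {
  N <- length(res)
  inlier <- rep(TRUE, N)
  if (rsdr <= 1e-12 * scale) return(inlier)
  p <- 2 * stats::pt(-abs(res) / rsdr, df = df)
  ord <- order(abs(res), decreasing = TRUE)
  # step-down from the most extreme residual: the j-th largest is tested at
  # the Benjamini-Hochberg-style threshold j*Q/N and the scan stops at the
  # first survivor
  for (j in seq_len(N)) {
    if (p[ord[j]] < Q * j / N) inlier[ord[j]] <- FALSE else break
  }
  inlier
}

#' Robust straight-line fit with ROUT outlier removal
#'
#' Fits `y = a + b x` robustly (Lorentzian merit function), identifies
#' outliers by the ROUT false-discovery scan with budget `Q`, and reports the
#' ordinary least-squares fit through the surviving points. This is the
#' regression engine behind [fit_ar_regression()] and
#' [fit_minimum_work_regression()].
#'
#' @param formula either a formula `y ~ x` (one predictor) or a numeric
#'   vector of x values.
#' @param data data frame for the formula interface, or the numeric y vector
#'   when `formula` is numeric.
#' @param Q maximum desired false-discovery rate for outlier calls, in
#'   `[0, 1)`; `Q = 0` calls no outliers. Default 0.01 (1%).
#' @param through_origin logical; fit `y = b x` without intercept for the
#'   final reported fit (the robust stage always carries an intercept).
#' @param tol relative convergence tolerance on the robust merit function.
#' @param max_iter maximum robust iterations.
#' @return an object of class `rout_lm` with components `coefficients`
#'   (intercept, slope of the inlier OLS fit), `robust_coefficients`, `se`
#'   (standard errors), `r_squared`, `p_value` (slope = 0 test),
#'   `p_slope_one` (slope = 1 test), `inlier` (logical mask), `n_total`,
#'   `n_outliers`, `rsdr`, `Q`, and the data. Methods: `print`, `summary`,
#'   `coef`, `predict`, `residuals`, `fitted`, `plot`.
#' @examples
#' x <- seq(0, 10, length.out = 50)
#' y <- 2 + 0.5 * x + rnorm(50, sd = 0.1)
#' y[7] <- y[7] + 5          # a gross outlier
#' fit <- rout_lm(x, y, Q = 0.01)
#' coef(fit); which(!fit$inlier)
#' @export
rout_lm <- function(formula, data = NULL, Q = 0.01, through_origin = FALSE,
                    tol = 1e-9, max_iter = 500L) {
  if (inherits(formula, "formula")) {
    mf <- stats::model.frame(formula, data)
    if (ncol(mf) != 2L) stop("rout_lm fits a straight line: y ~ x")
    y <- mf[[1L]]
    x <- mf[[2L]]
  } else {
    x <- as.numeric(formula)
    y <- as.numeric(data)
  }
  if (length(x) != length(y)) stop("x and y lengths differ")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  N <- length(y)
  if (N < 10L) stop("ROUT needs at least 10 points")
  if (stats::var(x) == 0) stop("x is degenerate (zero variance)")
  if (!is.finite(Q) || Q < 0 || Q >= 1) stop("Q must be in [0, 1)")
  K <- 2L
  rob <- .lorentzian_fit(x, y, K = K, tol = tol, max_iter = max_iter)
  inlier <- .rout_scan(rob$residuals, rob$rsdr, Q, df = N - K,
                       scale = max(abs(y), 1e-300))
  fml <- if (through_origin) y ~ x + 0 else y ~ x
  fit <- stats::lm(fml, data = data.frame(x = x, y = y), subset = inlier)
  sm <- suppressWarnings(summary(fit))  # perfect fits warn harmlessly
  cf <- sm$coefficients
  slope_row <- if (through_origin) 1L else 2L
  slope <- cf[slope_row, 1L]
  se_slope <- cf[slope_row, 2L]
  intercept <- if (through_origin) 0 else cf[1L, 1L]
  structure(list(
    coefficients = c(intercept = intercept, slope = slope),
    robust_coefficients = c(intercept = rob$coefficients[1L],
                            slope = rob$coefficients[2L]),
    se = c(intercept = if (through_origin) NA_real_ else cf[1L, 2L],
           slope = se_slope),
    r_squared = sm$r.squared,
    p_value = cf[slope_row, 4L],
    p_slope_one = 2 * stats::pt(-abs(slope - 1) / se_slope,
                                df = fit$df.residual),
    inlier = inlier,
    n_total = N,
    n_outliers = sum(!inlier),
    rsdr = rob$rsdr,
    Q = Q,
    through_origin = through_origin,
    x = x, y = y,
    lm_fit = fit,
    call = match.call()
  ), class = "rout_lm")
}

#' @export
print.rout_lm <- function(x, digits = 4, ...) {
  cat("Robust line fit with ROUT outlier removal (Q = ",
      format(100 * x$Q), "%)\n", sep = "")
  cat("  slope     ", format(x$coefficients["slope"], digits = digits),
      " ± ", format(x$se["slope"], digits = 2), "\n", sep = "")
  if (!x$through_origin)
    cat("  intercept ", format(x$coefficients["intercept"], digits = digits),
        "\n", sep = "")
  cat("  R² = ", format(x$r_squared, digits = digits),
      ", n = ", x$n_total, " (", x$n_outliers, " outlier",
      if (x$n_outliers == 1) "" else "s", " removed)\n", sep = "")
  invisible(x)
}

#' @export
summary.rout_lm <- function(object, ...) {
  out <- object[c("coefficients", "se", "r_squared", "p_value",
                  "p_slope_one", "n_total", "n_outliers", "rsdr", "Q")]
  class(out) <- "summary.rout_lm"
  out
}

#' @export
print.summary.rout_lm <- function(x, digits = 4, ...) {
  cat("slope        ", format(x$coefficients["slope"], digits = digits),
      " (SE ", format(x$se["slope"], digits = 3), ")\n", sep = "")
  cat("intercept    ", format(x$coefficients["intercept"], digits = digits),
      "\n", sep = "")
  cat("R-squared    ", format(x$r_squared, digits = digits), "\n", sep = "")
  cat("P (slope=0)  ", format.pval(x$p_value, digits = 3), "\n", sep = "")
  cat("P (slope=1)  ", format.pval(x$p_slope_one, digits = 3), "\n", sep = "")
  cat("n            ", x$n_total, ", outliers removed ", x$n_outliers,
      " (RSDR ", format(x$rsdr, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' @export
coef.rout_lm <- function(object, ...) object$coefficients

#' @export
fitted.rout_lm <- function(object, ...) {
  object$coefficients["intercept"] + object$coefficients["slope"] * object$x
}

#' @export
residuals.rout_lm <- function(object, ...) object$y - fitted(object)

#' @export
predict.rout_lm <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x
       else if (is.data.frame(newdata)) newdata[[1L]]
       else as.numeric(newdata)
  unname(object$coefficients["intercept"] + object$coefficients["slope"] * x)
}

#' @export
plot.rout_lm <- function(x, xlab = "x", ylab = "y", ...) {
  graphics::plot(x$x, x$y, col = ifelse(x$inlier, "grey30", "red"),
                 pch = ifelse(x$inlier, 1, 4), xlab = xlab, ylab = ylab, ...)
  graphics::abline(x$coefficients["intercept"], x$coefficients["slope"],
                   col = "steelblue", lwd = 2)
  invisible(x)
}

#' Univariate ROUT outlier removal
#'
#' The constant-model (K = 1) specialization of the ROUT scheme, used to
#' clean a single parameter before summarizing it: the robust centre
#' minimizes the Lorentzian merit, the RSDR uses the `N/(N-1)` correction,
#' and the same false-discovery scan flags outliers.
#'
#' @param values numeric vector.
#' @param Q false-discovery budget, as in [rout_lm()].
#' @return logical inlier mask the length of `values` (`NA`s are kept out of
#'   the scan and marked `FALSE`).
#' @export
rout_values <- function(values, Q = 0.01) {
  ok <- is.finite(values)
  y <- values[ok]
  N <- length(y)
  mask <- rep(FALSE, length(values))
  if (N < 5L) {            # too few points to call outliers
    mask[ok] <- TRUE
    return(mask)
  }
  K <- 1L
  centre <- stats::median(y)
  merit_old <- Inf
  rsdr <- NA_real_
  for (iter in 1:500) {
    res <- y - centre
    rsdr <- stats::quantile(abs(res), 0.6827, type = 7, names = FALSE) *
      N / (N - K)
    if (rsdr <= 0) break
    opt <- stats::optimize(function(a) sum(log1p(((y - a) / rsdr)^2)),
                           range(y))
    centre <- opt$minimum
    if (is.finite(merit_old) &&
        abs(merit_old - opt$objective) <= 1e-9 * max(abs(merit_old), 1))
      break
    merit_old <- opt$objective
  }
  res <- y - centre
  rsdr <- stats::quantile(abs(res), 0.6827, type = 7, names = FALSE) *
    N / (N - K)
  mask[ok] <- .rout_scan(res, rsdr, Q, df = N - K,
                         scale = max(abs(y), 1e-300))
  mask
}
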