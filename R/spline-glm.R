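#' Natural cubic spline specification
#'
#' A `df`-dimensional natural cubic spline basis has `df - 1` interior knots
#' plus two boundary knots; interior knots are placed at equally spaced
#' quantiles of the data (the dominant convention in time-series
#' epidemiology), boundaries at the data range.
#'
#' @param x numeric data vector.
#' @param df basis dimension (>= 1, excluding the intercept).
#' @return object of class `spline_spec`: list with `df`, `boundary`,
#'   `interior`.
#' @export
place_knots <- function(x, df) {
  if (df < 1L) stop("df must be >= 1")
  x <- x[is.finite(x)]
  if (length(unique(x)) <= df)
    stop("df (", df, ") must be smaller than the number of distinct values")
  boundary <- range(x)
  interior <- numeric(0)
  if (df > 1L) {
    interior <- unname(stats::quantile(x, probs = seq_len(df - 1L) / df,
                                       type = 7))
    if (any(duplicated(interior)) ||
        any(interior <= boundary[1L]) || any(interior >= boundary[2L]))
      stop("ties in x collapse interior knots; reduce df")
  }
  sp <- list(df = as.integer(df), boundary = boundary, interior = interior)
  class(sp) <- "spline_spec"
  sp
}

#' Evaluate a natural cubic spline basis
#'
#' Basis columns exclude the intercept and are linear beyond the boundary
#' knots. Evaluation is deterministic given the knots in `spec`, so new data
#' can be projected onto a basis placed on training data.
#'
#' @param x evaluation points.
#' @param spec a [place_knots] result (or an integer df, in which case knots
#'   are placed on `x` itself).
#' @return length(x) x df basis matrix.
#' @export
ns_basis <- function(x, spec) {
  if (is.numeric(spec) && length(spec) == 1L) spec <- place_knots(x, spec)
  stopifnot(inherits(spec, "spline_spec"))
  B <- splines::ns(x, knots = spec$interior, Boundary.knots = spec$boundary,
                   intercept = FALSE)
  B <- unname(as.matrix(B))
  stopifnot(ncol(B) == spec$df)
  B
}

#' Fit a quasi-Poisson log-linear model
#'
#' Log-link iteratively reweighted least squares to the Poisson maximum
#' likelihood coefficients (relative change < 1e-10 or 100 iterations), with
#' the quasi-likelihood dispersion estimated from Pearson residuals:
#' `dispersion = sum(pearson^2) / (n - p)`; the coefficient covariance is
#' the dispersion-scaled inverse Fisher information. Coefficients are
#' therefore identical to a plain Poisson fit; only the uncertainty is
#' inflated.
#'
#' @param y nonnegative integer counts.
#' @param X design matrix including the intercept column; must be full
#'   column rank (collinear columns are reported by name).
#' @param dispersion_type `"pearson"` (default) or `"deviance"`.
#' @return object of class `glm_fit`: list with `coefficients`, `cov`
#'   (dispersion-scaled), `dispersion`, `deviance`, `n_obs`, `rank`,
#'   `fitted`.
#' @export
fit_quasipoisson <- function(y, X, dispersion_type = c("pearson",
                                                       "deviance")) {
  dispersion_type <- match.arg(dispersion_type)
  X <- as.matrix(X)
  if (any(y < 0) || any(y != round(y))) stop("y must be nonnegative counts")
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    cn <- colnames(X)
    if (is.null(cn)) cn <- paste0("V", seq_len(ncol(X)))
    dropped <- cn[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  start <- c(log(mean(y) + 0.5), rep(0, ncol(X) - 1L))
  fit <- stats::glm.fit(X, y, family = stats::quasipoisson(link = "log"),
                        start = start,
                        control = stats::glm.control(epsilon = 1e-10,
                                                     maxit = 100L))
  if (!fit$converged)
    stop("IRLS did not converge in 100 iterations (possible separation)")
  if (any(abs(fit$coefficients) > 30))
    stop("diverging coefficients (possible separation)")
  n <- length(y)
  p <- ncol(X)
  mu <- fit$fitted.values
  pearson2 <- sum((y - mu)^2 / mu)
  dispersion <- if (dispersion_type == "pearson") pearson2 / (n - p)
                else fit$deviance / (n - p)
  # unscaled covariance from the final IRLS weights
  W <- fit$weights
  info <- crossprod(X * sqrt(W))
  cov <- dispersion * chol2inv(chol(info))
  cov <- (cov + t(cov)) / 2
  out <- list(coefficients = stats::setNames(fit$coefficients, colnames(X)),
              cov = cov, dispersion = dispersion, deviance = fit$deviance,
              n_obs = n, rank = p, fitted = mu)
  class(out) <- "glm_fit"
  out
}

#' Wald confidence interval for one coefficient
#'
#' `estimate +/- z * SE` with the SE taken from the dispersion-scaled
#' covariance matrix.
#'
#' @param fit a [fit_quasipoisson] result.
#' @param coef_index coefficient position (or name).
#' @param level confidence level (default 0.95).
#' @return numeric `c(lo, hi)`.
#' @export
wald_interval <- function(fit, coef_index, level = 0.95) {
  if (is.character(coef_index))
    coef_index <- match(coef_index, names(fit$coefficients))
  if (is.na(coef_index) || coef_index < 1L ||
      coef_index > length(fit$coefficients))
    stop("coef_index out of range")
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- fit$coefficients[[coef_index]]
  se <- sqrt(fit$cov[coef_index, coef_index])
  c(lo = est - z * se, hi = est + z * se)
}

#' Percent change in relative risk per exposure increment
#'
#' Converts a per-unit log relative-risk coefficient and its standard error
#' into the conventional reporting scale: percent change in RR for a
#' `delta`-unit (default 10 ug/m3) exposure increase,
#' `100 * (exp(delta * beta) - 1)`, with the confidence bounds obtained by
#' transforming the Wald endpoints of `delta * beta` (hence symmetric on the
#' log-RR scale).
#'
#' @param beta per-unit log-RR coefficient.
#' @param se its standard error.
#' @param delta exposure increment (must be positive).
#' @param level confidence level.
#' @return numeric `c(pct, lo, hi)`.
#' @export
percent_change <- function(beta, se, delta = 10, level = 0.95) {
  if (delta <= 0) stop("delta must be positive")
  z <- stats::qnorm(1 - (1 - level) / 2)
  b <- delta * beta
  s <- delta * se
  c(pct = 100 * (exp(b) - 1),
    lo = 100 * (exp(b - z * s) - 1),
    hi = 100 * (exp(b + z * s) - 1))
}
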