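# Robust estimators composing the CNV caller: Sn scale, MAD, Sn-correlation,
# Theil-Sen regression, robust studentized residuals, Hodges-Lehmann location,
# normalised Euclidean distance, and Benjamini-Hochberg adjustment.

# Finite-sample consistency factors for Sn (Rousseeuw & Croux).
.sn_finite_factor <- function(n) {
  if (n <= 9) {
    c(NA, 0.743, 1.851, 0.954, 1.351, 0.993, 1.198, 1.005, 1.131)[n]
  } else if (n %% 2 == 1) {
    n / (n - 0.9)
  } else {
    1
  }
}

#' Sn robust scale estimator
#'
#' Rousseeuw-Croux Sn estimator of standard deviation: the low median over
#' observations of the high median of absolute differences to all other
#' observations, scaled by the normal-consistency constant 1.1926 and a
#' finite-sample correction factor.
#'
#' Sn has a 50\% breakdown point and is the scale estimator used throughout
#' the caller: as the residual scale of the robust regressions, as the
#' per-amplicon dispersion of normalised log coverages, and inside the
#' Sn-correlation coefficient.
#'
#' @param x Numeric vector, length >= 2, finite values.
#' @return Non-negative scalar; 0 iff all values are equal.
#' @examples
#' sn_scale(c(1, 2, 3, 4, 5))
#' sn_scale(rnorm(100))
#' @export
sn_scale <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2) stop("sn_scale() requires at least 2 values")
  if (any(!is.finite(x))) stop("sn_scale() requires finite values")
  n <- length(x)
  raw <- if (n > 200) cpp_sn_raw_fast(x) else cpp_sn_raw(x)
  1.1926 * .sn_finite_factor(n) * raw
}

#' Median absolute deviation
#'
#' MAD about the median with the normal-consistency constant 1.4826.
#'
#' @param x Numeric vector, length >= 1.
#' @return Non-negative scalar.
#' @export
mad_scale <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 1) stop("mad_scale() requires at least 1 value")
  if (any(!is.finite(x))) stop("mad_scale() requires finite values")
  stats::mad(x, constant = 1.4826)
}

#' Sn-correlation coefficient
#'
#' Robust correlation built from the robust principal variables
#' \eqn{u = (x - med(x))/(\sqrt{2} MAD(x)) + (y - med(y))/(\sqrt{2} MAD(y))}
#' and \eqn{v} (their difference):
#' \eqn{r = (Sn^2(u) - Sn^2(v)) / (Sn^2(u) + Sn^2(v))}.
#'
#' Used as the similarity measure for partner/cluster selection because it is
#' insensitive to the CNV-carrying outlier samples that the method is trying
#' to find.
#'
#' @param x,y Numeric vectors of equal length >= 3 with positive MAD.
#' @return Correlation in \[-1, 1\].
#' @export
sn_correlation <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("sn_correlation() requires n >= 3")
  mx <- mad_scale(x); my <- mad_scale(y)
  if (mx == 0 || my == 0) {
    stop("degenerate input: MAD is zero, pair unusable for Sn-correlation")
  }
  xs <- (x - median(x)) / (sqrt(2) * mx)
  ys <- (y - median(y)) / (sqrt(2) * my)
  su2 <- sn_scale(xs + ys)^2
  sv2 <- sn_scale(xs - ys)^2
  if (su2 + sv2 == 0) return(0)
  r <- (su2 - sv2) / (su2 + sv2)
  max(-1, min(1, r))
}

#' Theil-Sen robust linear regression
#'
#' Slope is the median of all pairwise slopes \eqn{(y_j - y_i)/(x_j - x_i)}
#' (pairs with tied x are skipped); intercept is the median of
#' \eqn{y - slope \cdot x}; the residual scale is the Sn estimate of the
#' residuals. Breakdown point \eqn{1 - 1/\sqrt{2} \approx 29.3\%}.
#'
#' @param x,y Numeric vectors of equal length n >= 3; x not all identical.
#' @return Object of class `robust_linear_model`: list with `slope`,
#'   `intercept`, `residual_scale`, `n`, `predictor_mean`, `predictor_ss`.
#' @examples
#' m <- theil_sen(1:10, 2 * (1:10) + 1)
#' m$slope
#' @export
theil_sen <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("theil_sen() requires n >= 3")
  slopes <- cpp_pairwise_slopes(x, y)
  if (length(slopes) == 0) stop("all x values identical: slope undefined")
  slope <- median(slopes)
  intercept <- median(y - slope * x)
  res <- y - slope * x - intercept
  structure(list(
    slope = slope,
    intercept = intercept,
    residual_scale = sn_scale(res),
    n = n,
    predictor_mean = mean(x),
    predictor_ss = sum((x - mean(x))^2)
  ), class = "robust_linear_model")
}

#' @export
print.robust_linear_model <- function(x, ...) {
  cat(sprintf(
    "Theil-Sen fit: slope %.4g, intercept %.4g, Sn residual scale %.4g (n = %d)\n",
    x$slope, x$intercept, x$residual_scale, x$n
  ))
  invisible(x)
}

#' Robust internally studentized residuals
#'
#' Standard internally studentized residuals with the residual standard
#' deviation replaced by the Sn scale of the fit:
#' \eqn{r_i = \hat\varepsilon_i / (S_n \sqrt{1 - h_i})} with leverage
#' \eqn{h_i = 1/n + (x_i - \bar x)^2 / \sum_j (x_j - \bar x)^2}.
#'
#' @param model A `robust_linear_model` fitted on `(x, y)`.
#' @param x,y The data the model was fitted on.
#' @return Numeric vector of studentized residuals.
#' @export
studentized_residuals <- function(model, x, y) {
  stopifnot(inherits(model, "robust_linear_model"))
  if (model$residual_scale <= 0) {
    stop("degenerate model: residual scale is zero (perfect fit)")
  }
  x <- as.numeric(x); y <- as.numeric(y)
  eps <- y - model$slope * x - model$intercept
  h <- 1 / model$n + (x - model$predictor_mean)^2 / model$predictor_ss
  eps / (model$residual_scale * sqrt(pmax(1 - h, .Machine$double.eps)))
}

#' Hodges-Lehmann location (median of Walsh averages)
#'
#' Median of all \eqn{n(n+1)/2} pairwise averages \eqn{(x_i + x_j)/2},
#' \eqn{i \le j} (singletons included). Robust and efficient location
#' estimate used for per-amplicon reference profiles and model locations.
#'
#' @param x Numeric vector, length >= 1.
#' @return Scalar location estimate.
#' @export
hodges_lehmann <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 1) stop("hodges_lehmann() requires at least 1 value")
  if (any(!is.finite(x))) stop("hodges_lehmann() requires finite values")
  median(cpp_walsh_averages(x))
}

#' Normalised Euclidean distance
#'
#' \eqn{d(x, y) = \sqrt{\sum_i (x_i - y_i)^2 / s_i^2}}: Euclidean distance
#' with each coordinate scaled by its own dispersion. With independent
#' normal coordinates, \eqn{d^2} follows a chi-squared distribution with as
#' many degrees of freedom as coordinates.
#'
#' @param x,y Numeric vectors of equal length.
#' @param s Positive per-coordinate scales, same length.
#' @return Non-negative scalar distance.
#' @export
ned <- function(x, y, s) {
  x <- as.numeric(x); y <- as.numeric(y); s <- as.numeric(s)
  if (length(x) != length(y) || length(x) != length(s)) {
    stop("x, y and s must have equal length")
  }
  if (any(s <= 0)) stop("all scales s must be strictly positive")
  sqrt(sum((x - y)^2 / s^2))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; a validated wrapper around [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in \[0, 1\], same length.
#' @export
benjamini_hochberg <- function(p) {
  p <- as.numeric(p)
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Monte-Carlo variance ratio of log-transformed Poisson coverage
#'
#' Estimates \eqn{Var(\log Pois(m\lambda)) / Var(\log Pois(\lambda))} by
#' simulation. By the delta method \eqn{Var(\log X) \approx 1/\lambda}, so
#' the ratio tends to \eqn{1/m}: the factor 2 behind the heterozygous-
#' deletion model scale (m = 0.5) and 2/3 behind the duplication model scale
#' (m = 1.5).
#'
#' @param lambda Wild-type Poisson rate (default 1000).
#' @param multiplier Copy-number multiplier m applied to the rate.
#' @param n_draws Monte-Carlo sample size per rate.
#' @return Scalar variance ratio.
#' @export
poisson_log_variance_ratio <- function(lambda = 1000, multiplier = 0.5,
                                       n_draws = 1e5) {
  stopifnot(lambda > 0, multiplier > 0, n_draws >= 2)
  a <- rpois(n_draws, multiplier * lambda)
  b <- rpois(n_draws, lambda)
  if (any(a == 0) || any(b == 0)) {
    a <- pmax(a, 0.5); b <- pmax(b, 0.5)  # guard for tiny rates
  }
  var(log(a)) / var(log(b))
}
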