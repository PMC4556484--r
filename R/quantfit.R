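#' Check (tilted absolute) loss
#'
#' `rho_tau(r) = r * (tau - 1[r < 0])`, the loss whose minimiser is the
#' conditional `tau`-quantile.
#'
#' @param residuals Numeric residuals.
#' @param tau Quantile level in (0, 1).
#' @return Vector of losses.
#' @export
check_loss <- function(residuals, tau) {
  stopifnot(tau > 0, tau < 1)
  residuals * (tau - (residuals < 0))
}

#' Asymmetric-Laplace log-likelihood of a quantile fit
#'
#' The standard quantile-regression likelihood with the maximum-likelihood
#' plug-in scale (mean check loss):
#' `loglik = n * (log(tau * (1 - tau)) - 1 - log(mean check loss))`.
#' Symmetric in `tau` vs `1 - tau` for mirrored residuals. A zero mean check
#' loss (perfect fit) returns `+Inf` as a sentinel.
#'
#' @inheritParams check_loss
#' @return Scalar log-likelihood.
#' @export
al_loglik <- function(residuals, tau) {
  n <- length(residuals)
  stopifnot(n >= 1)
  m <- mean(check_loss(residuals, tau))
  if (m <= 0) return(Inf)
  n * (log(tau * (1 - tau)) - 1 - log(m))
}

#' Small-sample corrected Akaike Information Criterion
#'
#' `AICc = -2 loglik + 2K + 2K(K + 1) / (n - K - 1)`. The correction term
#' vanishes as `n` grows, recovering the plain AIC.
#'
#' @param loglik Model log-likelihood.
#' @param n Sample size.
#' @param K Number of estimated parameters.
#' @return Scalar AICc.
#' @export
aicc <- function(loglik, n, K) {
  if (n <= K + 1)
    abort(sprintf("AICc undefined: n = %d too small for K = %d", n, K))
  -2 * loglik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Exact linear quantile regression in an arbitrary space
#'
#' Minimises the check loss for a straight line `y = a + b x` by the
#' Barrodale-Roberts exterior-point simplex (an exact linear-programming
#' solution passing through at least two data points), via
#' [quantreg::rq.fit.br()].
#'
#' @param x,y Covariate and response.
#' @param tau Quantile level.
#' @return List with `intercept`, `slope`, `residuals`, `sigma_check` (mean
#'   check loss) and `perfect_fit` flag.
#' @export
fit_quantile_line <- function(x, y, tau) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  f <- quantreg::rq.fit.br(cbind(1, x), y, tau = tau)
  res <- as.numeric(f$residuals)
  m <- mean(check_loss(res, tau))
  list(intercept = unname(f$coefficients[1]), slope = unname(f$coefficients[2]),
       residuals = res, sigma_check = m, perfect_fit = m <= 1e-12)
}

#' Power-law quantile regression of age on cost distance
#'
#' Fits the upper envelope of early dates: a straight line in log-log space,
#' `ln(age) = a + b ln(distance)`, positioned so that a fraction `q_exceed`
#' of the sites lie above it (older than the curve). This corresponds to
#' check-loss level `tau = 1 - q_exceed` on log age in years BP. Back in
#' natural units the fit is the power law `age = A * distance^b` with
#' `A = exp(a)`; for dispersal data `b < 0` (ages decline away from the
#' origin). The asymmetric-Laplace log-likelihood and AICc are attached, with
#' `K = 3` by default (two regression coefficients plus the scale).
#'
#' @param ages Ages in years BP (all positive).
#' @param distances Cost distances in km (all positive; clamp upstream).
#' @param q_exceed Fraction of sites allowed above the curve (default 0.10).
#' @param K Parameter count used in the AICc (raise by one per additional
#'   estimated speed ratio when the distances come from a multi-origin
#'   hypothesis).
#' @param min_n Minimum sample size (default 10).
#' @return A `quantile_fit` object.
#' @export
fit_quantile_loglog <- function(ages, distances, q_exceed = 0.10, K = 3,
                                min_n = 10) {
  keep <- is.finite(ages) & is.finite(distances)
  ages <- ages[keep]
  distances <- distances[keep]
  n <- length(ages)
  if (n < min_n)
    abort(sprintf("too few sites for a quantile fit: %d < %d", n, min_n))
  if (any(ages <= 0) || any(distances <= 0))
    abort("ages and distances must be positive (clamp distances upstream)")
  tau <- 1 - q_exceed
  f <- fit_quantile_line(log(distances), log(ages), tau)
  ll <- if (f$perfect_fit) Inf else al_loglik(f$residuals, tau)
  structure(
    list(intercept_log = f$intercept, slope = f$slope,
         power_A = exp(f$intercept), power_b = f$slope,
         sigma_check = f$sigma_check, n = n, K = K, tau = tau,
         q_exceed = q_exceed, loglik = ll,
         aicc = if (is.finite(ll)) aicc(ll, n, K) else -Inf,
         perfect_fit = f$perfect_fit, residuals = f$residuals),
    class = "quantile_fit")
}

#' @export
print.quantile_fit <- function(x, ...) {
  cat(sprintf(
    "<quantile_fit> age = %.4f * distance^%.6f  (q_exceed = %.2g)\n",
    x$power_A, x$power_b, x$q_exceed))
  cat(sprintf("  n = %d, K = %d, loglik = %.4f, AICc = %.4f%s\n",
              x$n, x$K, x$loglik, x$aicc,
              if (x$perfect_fit) " [perfect fit]" else ""))
  invisible(x)
}

#' @export
tidy.quantile_fit <- function(x, ...) {
  tibble(term = c("intercept_log", "slope"),
         estimate = c(x$intercept_log, x$slope))
}

#' @export
glance.quantile_fit <- function(x, ...) {
  tibble(n = x$n, K = x$K, sigma_check = x$sigma_check, loglik = x$loglik,
         aicc = x$aicc, power_A = x$power_A, power_b = x$power_b,
         perfect_fit = x$perfect_fit)
}

#' Power-law age-distance curve
#'
#' @param A Age scale in years (age at unit distance).
#' @param b Exponent (negative for dispersal data).
#' @return A `power_law_curve`.
#' @export
power_law_curve <- function(A, b) {
  stopifnot(A > 0)
  structure(list(A = A, b = b), class = "power_law_curve")
}

#' @export
print.power_law_curve <- function(x, ...) {
  cat(sprintf("<power_law_curve> age = %.4f * distance^%.6f\n", x$A, x$b))
  invisible(x)
}

#' Predicted age at a cost distance
#'
#' @param curve A [power_law_curve()] (or a `quantile_fit`, whose power-law
#'   form is used).
#' @param distance Cost distance in km (positive).
#' @return Predicted age in years BP.
#' @export
predict_age <- function(curve, distance) {
  if (inherits(curve, "quantile_fit"))
    curve <- power_law_curve(curve$power_A, curve$power_b)
  if (any(distance <= 0)) abort("distance must be positive")
  curve$A * distance^curve$b
}

#' Predicted arrival-age raster
#'
#' Evaluates the fitted power law at the effective distance of every
#' traversable cell (distances clamped below one cell size), giving the map
#' of predicted first-arrival ages. Masked cells are `NA`.
#'
#' @param fit A `quantile_fit` (or `power_law_curve`).
#' @param field An [fast_march()] result on the same domain.
#' @return Matrix of predicted ages (years BP).
#' @export
predict_arrival_raster <- function(fit, field) {
  d <- pmax(field$arrival, field$spec$cell_size)
  out <- matrix(NA_real_, nrow(d), ncol(d))
  fin <- is.finite(d)
  out[fin] <- predict_age(fit, d[fin])
  out
}

#' Flag sites older than the fitted dispersal curve
#'
#' A site is an outlier when its median age is strictly greater than the age
#' the power law predicts at its cost distance; the age excess in years is
#' reported. These are candidate additional origins, mis-dated records, or
#' routes the model does not include.
#'
#' @param sites Data frame with `median_age`.
#' @param distances Cost distances (km) aligned with `sites`.
#' @param curve A [power_law_curve()] or `quantile_fit`.
#' @return The input plus `predicted_age`, `age_excess`, `outlier`.
#' @export
find_outliers <- function(sites, distances, curve) {
  stopifnot(nrow(sites) == length(distances))
  pred <- predict_age(curve, distances)
  out <- as_tibble(sites)
  out$predicted_age <- pred
  out$age_excess <- pmax(out$median_age - pred, 0)
  out$outlier <- out$median_age > pred
  out
}
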