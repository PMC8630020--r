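#' Relative depth within the oxic zone
#'
#' Normalises sediment depth by the oxygen penetration depth so that 0 is the
#' sediment-water interface and 1 the oxic-anoxic boundary. Values above 1
#' are flagged (attribute \code{out_of_oxic_zone}) rather than dropped.
#'
#' @param z Depth (m), >= 0.
#' @param OPD Oxygen penetration depth (m), > 0.
#' @return Numeric vector x = z/OPD with logical attribute
#'   \code{out_of_oxic_zone}.
#' @export
relative_depth <- function(z, OPD) {
  if (any(OPD <= 0)) stop("OPD must be > 0")
  if (any(z < 0)) stop("depths must be >= 0")
  x <- z / OPD
  attr(x, "out_of_oxic_zone") <- x > 1
  x
}

#' Fit an exponential decay of AOA fraction over relative depth
#'
#' Nonlinear least squares of \eqn{y = a e^{b x}} on untransformed fractions
#' (percent of the total community), matching the conventional curve-fitting
#' treatment of such data; an optional log-space fit is available for
#' heteroscedastic data. Start values a = max(y), b = -1; bounds
#' a in (0, 100], b in [-10, 0].
#'
#' @param x Relative depths in [0, 1].
#' @param y AOA fractions (percent), >= 0.
#' @param log_space Fit in log space (lm on log y) instead; default FALSE.
#' @return Object of class \code{aoa_fit}: coefficients \code{a} (surface
#'   intercept, percent) and \code{b} (decay per unit relative depth),
#'   covariance, R2, n, residual variance.
#' @export
fit_exponential_decay <- function(x, y, log_space = FALSE) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need at least 3 observations")
  if (any(x < 0 | x > 1)) stop("relative depths must lie in [0, 1]")
  if (any(y < 0)) stop("fractions must be >= 0")
  if (diff(range(x)) == 0)
    stop("no depth contrast: all relative depths identical; cannot fit decay")

  if (log_space) {
    if (any(y <= 0)) stop("log-space fit requires positive fractions")
    lf <- stats::lm(log(y) ~ x)
    a <- exp(unname(stats::coef(lf)[1])); b <- unname(stats::coef(lf)[2])
    # delta-method covariance on (a, b) from the log-space covariance
    Vl <- stats::vcov(lf)
    Jt <- matrix(c(a, 0, 0, 1), 2, 2)
    V <- Jt %*% Vl %*% t(Jt)
    fitted <- a * exp(b * x)
    res <- y - fitted
    nls_obj <- lf
  } else {
    df <- data.frame(x = x, y = y)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(b * x), data = df,
                        start = list(a = max(y), b = -1),
                        lower = c(a = 1e-9, b = -10),
                        upper = c(a = 100, b = 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) stop("exponential fit failed to converge: ",
                               conditionMessage(e)))
    co <- stats::coef(fit)
    a <- unname(co["a"]); b <- unname(co["b"])
    V <- tryCatch(stats::vcov(fit), error = function(e)
      matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b"))))
    fitted <- a * exp(b * x)
    res <- y - fitted
    nls_obj <- fit
  }
  # heteroscedasticity-robust (HC3 sandwich) parameter covariance; fraction
  # scatter is multiplicative in real data, so the homoscedastic covariance
  # understates the uncertainty near the surface
  Vr <- tryCatch({
    J <- cbind(exp(b * x), a * x * exp(b * x))
    Ainv <- solve(crossprod(J))
    hlev <- pmin(rowSums((J %*% Ainv) * J), 0.99)
    rw <- (y - a * exp(b * x)) / (1 - hlev)
    Ainv %*% crossprod(J * rw, J * rw) %*% Ainv
  }, error = function(e) V)
  sstot <- sum((y - mean(y))^2)
  ssres <- sum(res^2)
  r2 <- if (sstot > 0) 1 - ssres / sstot else 0
  df_res <- length(y) - 2
  structure(list(a = a, b = b, vcov = V, vcov_robust = Vr,
                 R2 = r2, n = length(y),
                 sigma2 = ssres / max(df_res, 1), df = df_res,
                 x = x, y = y, fitted = fitted, log_space = log_space,
                 fit = nls_obj),
            class = "aoa_fit")
}

#' @export
print.aoa_fit <- function(x, ...) {
  cat(sprintf("<aoa_fit> y = %.3g * exp(%.3g x),  R2 = %.3f, n = %d%s\n",
              x$a, x$b, x$R2, x$n,
              if (x$log_space) " (log-space fit)" else ""))
  invisible(x)
}

#' @export
coef.aoa_fit <- function(object, ...) c(a = object$a, b = object$b)

#' @export
summary.aoa_fit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  out <- list(coef = cbind(estimate = c(a = object$a, b = object$b),
                           se = se),
              R2 = object$R2, n = object$n, sigma2 = object$sigma2)
  class(out) <- "summary.aoa_fit"
  out
}

#' @export
print.summary.aoa_fit <- function(x, ...) {
  cat("Exponential decay of AOA fraction over relative oxic-zone depth\n")
  print(signif(x$coef, 4))
  cat(sprintf("R2 = %.3f, n = %d, residual variance %.3g\n",
              x$R2, x$n, x$sigma2))
  invisible(x)
}

#' Predict AOA fraction with confidence interval
#'
#' Point prediction \eqn{a e^{b x}} with a delta-method 95% confidence band;
#' the standard error at each point is the larger of the homoscedastic and
#' the HC3 sandwich estimate, a conservative guard because the fraction
#' scatter is strongly heteroscedastic. Fractions are clipped to [0, 100].
#' Refuses extrapolation past the oxic-anoxic boundary (x > 1), where the
#' decay relationship does not hold.
#'
#' @param object An \code{aoa_fit}.
#' @param x Relative depths in [0, 1].
#' @param level Confidence level (default 0.95).
#' @param ... Unused.
#' @return Data frame: x, fraction, ci_low, ci_high (percent).
#' @export
predict.aoa_fit <- function(object, x, level = 0.95, ...) {
  if (any(x < 0)) stop("relative depths must be >= 0")
  if (any(x > 1))
    stop("refusing to extrapolate beyond the oxic zone (x > 1)")
  a <- object$a; b <- object$b
  f <- a * exp(b * x)
  g <- cbind(exp(b * x), a * x * exp(b * x))
  Vr <- if (is.null(object$vcov_robust)) object$vcov else object$vcov_robust
  se <- pmax(sqrt(pmax(rowSums((g %*% object$vcov) * g), 0)),
             sqrt(pmax(rowSums((g %*% Vr) * g), 0)))
  tq <- stats::qt(1 - (1 - level) / 2, df = max(object$df, 1))
  clip <- function(v) pmin(pmax(v, 0), 100)
  data.frame(x = x, fraction = clip(f),
             ci_low = clip(f - tq * se), ci_high = clip(f + tq * se))
}

#' @export
plot.aoa_fit <- function(x, ...) {
  xx <- seq(0, 1, length.out = 101)
  pr <- predict(x, xx)
  graphics::plot(x$x, x$y, pch = 19, xlab = "relative depth in oxic zone",
                 ylab = "AOA fraction (%)", ...)
  graphics::lines(xx, pr$fraction)
  graphics::lines(xx, pr$ci_low, lty = 2)
  graphics::lines(xx, pr$ci_high, lty = 2)
  invisible(x)
}

#' Predicted fraction at given relative depths
#'
#' Thin functional wrapper over \code{\link{predict.aoa_fit}}.
#' @param fit An \code{aoa_fit}.
#' @param x Relative depths in [0, 1].
#' @param level Confidence level.
#' @return Data frame: x, fraction, ci_low, ci_high.
#' @export
predict_fraction <- function(fit, x, level = 0.95) predict(fit, x, level)

#' Absolute AOA abundance from total cells and fraction
#'
#' Abundance = total cells x fraction/100, with the fraction confidence
#' interval propagated multiplicatively.
#'
#' @param total_cells Total cell abundance (cells cm-3), >= 0.
#' @param fraction AOA fraction (percent, 0-100).
#' @param ci_low,ci_high Optional CI bounds on the fraction (percent).
#' @return Data frame: abundance, ci_low, ci_high (cells cm-3).
#' @export
estimate_aoa_absolute <- function(total_cells, fraction,
                                  ci_low = fraction, ci_high = fraction) {
  if (any(total_cells < 0) || any(fraction < 0))
    stop("inputs must be >= 0")
  if (any(fraction > 100)) stop("fraction exceeds 100%")
  data.frame(abundance = total_cells * fraction / 100,
             ci_low = total_cells * ci_low / 100,
             ci_high = total_cells * ci_high / 100)
}

#' Compare regression-derived AOA abundances with qPCR
#'
#' Per-depth fold difference max(est, qpcr)/min(est, qpcr) with a summary of
#' the median and maximum fold. Zero qPCR values are excluded with a warning.
#'
#' @param estimated Data frame with columns \code{depth} and
#'   \code{abundance}.
#' @param qpcr Data frame with columns \code{depth} and \code{copies}
#'   (amoA copies cm-3).
#' @return List: \code{per_depth} data frame (depth, estimated, qpcr, fold),
#'   \code{median_fold}, \code{max_fold}.
#' @export
compare_with_qpcr <- function(estimated, qpcr) {
  m <- merge(estimated[, c("depth", "abundance")],
             qpcr[, c("depth", "copies")], by = "depth")
  if (!nrow(m)) stop("no overlapping depths between estimate and qPCR")
  drop <- m$copies <= 0 | m$abundance <= 0
  if (any(drop)) {
    warning(sum(drop), " depth(s) with zero abundance/qPCR excluded")
    m <- m[!drop, , drop = FALSE]
  }
  fold <- pmax(m$abundance, m$copies) / pmin(m$abundance, m$copies)
  list(per_depth = data.frame(depth = m$depth, estimated = m$abundance,
                              qpcr = m$copies, fold = fold),
       median_fold = stats::median(fold), max_fold = max(fold))
}
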