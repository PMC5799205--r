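# Poisson limiting-dilution quantification: convert the occupied fraction of
# a microwell array into a mean occupancy and a number density with a
# confidence interval.

#' Probability that a well is occupied at a given number density
#'
#' Under random (Poisson) partitioning of particles into wells, the number of
#' particles per well is Poisson with mean `lambda = density * well_volume`,
#' so the probability that a well holds at least one particle is
#' `p = 1 - exp(-density * well_volume)`.
#'
#' @param density Number density in particles per uL; non-negative
#'   (vectorised).
#' @param well_volume Per-well volume in uL; positive.
#' @return Occupancy probability in `[0, 1)`.
#' @examples
#' g <- array_geometry()
#' occupancy_probability(log(2) / g$well_volume, g$well_volume)  # exactly 0.5
#' @export
occupancy_probability <- function(density, well_volume) {
  wc_check(is.numeric(density) && all(is.finite(density)) && all(density >= 0),
           "wellcount_domain_error", "density must be non-negative")
  wc_check(is.numeric(well_volume) && all(well_volume > 0),
           "wellcount_domain_error", "well_volume must be positive")
  -expm1(-density * well_volume)
}

# Wilson score interval for a binomial proportion. `sides = 2` gives the
# usual two-sided interval; `sides = -1/+1` the one-sided lower/upper bound
# at the same confidence level.
.wilson <- function(k, n, conf_level, sides = 2) {
  z <- if (sides == 2) stats::qnorm(1 - (1 - conf_level) / 2)
       else stats::qnorm(conf_level)
  p <- k / n
  center <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z / (1 + z^2 / n) * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  lo <- max(0, center - half)
  hi <- min(1, center + half)
  if (sides == -1) c(lo, 1) else if (sides == 1) c(0, hi) else c(lo, hi)
}

.clopper_pearson <- function(k, n, conf_level) {
  a <- 1 - conf_level
  lo <- if (k == 0) 0 else stats::qbeta(a / 2, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - a / 2, k + 1, n - k)
  c(lo, hi)
}

#' Estimate number density from occupied-well counts
#'
#' The core estimator of digital (limiting-dilution) counting. From `k`
#' occupied wells out of `n`, the occupied fraction `p_hat = k/n` gives the
#' mean occupancy `lambda_hat = -ln(1 - p_hat)` and the number density
#' `lambda_hat / well_volume` (particles per uL). The confidence interval is
#' an interval on the binomial proportion `p` (Wilson score by default,
#' Clopper-Pearson optionally) mapped through the same monotone transform,
#' which preserves its coverage.
#'
#' With `k = 0` the estimate is 0 with `ci_low = 0`; the upper limit still
#' reflects what densities are compatible with seeing no occupied well. With
#' `k = n` (saturation) the density is not identifiable from occupancy --
#' `-ln(1 - p)` diverges -- and a saturation error is raised carrying the
#' one-sided lower density bound in its `lower_bound` field.
#'
#' `k` may be non-integral (e.g. an expected count `n * p` in analytic
#' design calculations); the Wilson interval is well defined for fractional
#' counts, while `"clopper-pearson"` requires integers.
#'
#' @param k Occupied wells, `0 <= k <= n`.
#' @param n Total wells, `n >= 1`.
#' @param well_volume Per-well volume in uL.
#' @param conf_level Confidence level of the interval (default 0.95).
#' @param ci_method `"wilson"` (default) or `"clopper-pearson"`.
#' @return An object of class `"well_count"`: list with `k`, `n`, `p_hat`,
#'   `lambda_hat`, `density`, `ci_low`, `ci_high` (particles/uL),
#'   `lambda_ci`, `conf_level`, `ci_method`, `well_volume`. Methods:
#'   `print`, `summary`, `coef`, `confint`, `simulate`, `plot`.
#' @examples
#' est <- estimate_density(k = 450, n = 900, well_volume = 1.257e-5)
#' est$lambda_hat        # log(2)
#' coef(est)
#' @export
estimate_density <- function(k, n, well_volume, conf_level = 0.95,
                             ci_method = c("wilson", "clopper-pearson")) {
  ci_method <- match.arg(ci_method)
  wc_check(is.numeric(n) && length(n) == 1L && n >= 1,
           "wellcount_domain_error", "n must be >= 1")
  wc_check(is.numeric(k) && length(k) == 1L && k >= 0 && k <= n,
           "wellcount_domain_error", "k must satisfy 0 <= k <= n")
  wc_check(is.numeric(well_volume) && length(well_volume) == 1L && well_volume > 0,
           "wellcount_domain_error", "well_volume must be positive")
  wc_check(conf_level > 0 && conf_level < 1,
           "wellcount_domain_error", "conf_level must be in (0, 1)")
  if (ci_method == "clopper-pearson")
    wc_check(k == round(k), "wellcount_domain_error",
             "clopper-pearson requires an integer k")
  if (k == n) {
    p_lo <- .wilson(k, n, conf_level, sides = -1)[1]
    lb <- -log1p(-p_lo) / well_volume
    wc_abort("wellcount_saturation_error",
             sprintf(paste0("all %d wells occupied: density is not identifiable ",
                            "from occupancy (one-sided %g%% lower bound: ",
                            "%.4g particles/uL)"),
                     as.integer(n), 100 * conf_level, lb),
             lower_bound = lb, k = k, n = n)
  }
  p_hat <- k / n
  lambda_hat <- -log1p(-p_hat)
  density <- lambda_hat / well_volume
  ci_p <- if (ci_method == "wilson") .wilson(k, n, conf_level)
          else .clopper_pearson(k, n, conf_level)
  ci_p <- pmin(ci_p, 1 - 1e-15)
  lambda_ci <- -log1p(-ci_p)
  structure(list(
    k = k, n = n, p_hat = p_hat, lambda_hat = lambda_hat,
    density = density,
    ci_low = lambda_ci[1] / well_volume, ci_high = lambda_ci[2] / well_volume,
    lambda_ci = lambda_ci, conf_level = conf_level, ci_method = ci_method,
    well_volume = well_volume
  ), class = "well_count")
}

#' Confidence interval width as a percentage of the mean
#'
#' The figure of merit of the design analysis: the CI half-width
#' `(ci_high - ci_low) / 2` expressed as a percentage of the estimated
#' density. Smaller values mean a more precise count; the percentage shrinks
#' roughly as `1 / sqrt(n)` with the number of wells.
#'
#' @param estimate A `"well_count"` object with positive density.
#' @return Percentage, `100 * (ci_high - ci_low) / (2 * density)`.
#' @export
ci_percent_of_mean <- function(estimate) {
  stopifnot(inherits(estimate, "well_count"))
  if (estimate$density <= 0)
    wc_abort("wellcount_domain_error",
             "CI percentage of the mean is undefined at zero density")
  100 * (estimate$ci_high - estimate$ci_low) / (2 * estimate$density)
}

#' @export
print.well_count <- function(x, digits = 4, ...) {
  cat("Microwell occupancy count estimate\n")
  cat(sprintf("  occupied wells: %s of %s (p_hat = %.4f)\n",
              format(x$k), format(x$n), x$p_hat))
  cat(sprintf("  mean occupancy lambda_hat: %.*g particles/well\n",
              digits, x$lambda_hat))
  cat(sprintf("  number density: %.*g particles/uL  [%g%% CI %.*g -- %.*g, %s]\n",
              digits, x$density, 100 * x$conf_level,
              digits, x$ci_low, digits, x$ci_high, x$ci_method))
  invisible(x)
}

#' @export
coef.well_count <- function(object, ...) {
  c(lambda = object$lambda_hat, density = object$density)
}

#' @export
confint.well_count <- function(object, parm = c("density", "lambda"),
                               level = NULL, ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  if (is.null(level)) level <- object$conf_level
  est <- if (level == object$conf_level) object
         else estimate_density(object$k, object$n, object$well_volume,
                               conf_level = level, ci_method = object$ci_method)
  out <- rbind(density = c(est$ci_low, est$ci_high),
               lambda = est$lambda_ci)[parm, , drop = FALSE]
  colnames(out) <- paste0(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2),
                                 trim = TRUE), " %")
  out
}

#' @export
summary.well_count <- function(object, ...) {
  structure(list(estimate = object,
                 ci_pct = if (object$density > 0) ci_percent_of_mean(object) else NA_real_,
                 occupancy = object$occupancy), class = "summary.well_count")
}

#' @export
print.summary.well_count <- function(x, ...) {
  print(x$estimate)
  if (!is.na(x$ci_pct))
    cat(sprintf("  CI half-width: %.2f%% of the mean\n", x$ci_pct))
  if (!is.null(x$occupancy)) {
    occ <- x$occupancy
    cat(sprintf("  classification threshold: %.4f (%s)\n",
                occ$threshold, occ$modality))
  }
  invisible(x)
}

#' Simulate re-counts from a fitted occupancy estimate
#'
#' Draws `nsim` replicate occupied-well counts `k* ~ Binomial(n, p_hat)` and
#' re-estimates the density from each, giving the sampling distribution of
#' the estimator at the fitted occupancy. Saturated draws (`k* = n`) yield
#' `NA` densities.
#'
#' @param object A `"well_count"` object.
#' @param nsim Number of replicates.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param ... Unused.
#' @return Data frame with columns `k` and `density`.
#' @export
simulate.well_count <- function(object, nsim = 1, seed = NULL, ...) {
  draw <- function() stats::rbinom(nsim, object$n, object$p_hat)
  ks <- if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
  dens <- vapply(ks, function(k) {
    if (k >= object$n) return(NA_real_)
    -log1p(-k / object$n) / object$well_volume
  }, numeric(1))
  data.frame(k = ks, density = dens)
}

#' Plot a well-count estimate
#'
#' For estimates fitted from images (see [wellcount()]) draws the per-well
#' mean-intensity histogram with the classification threshold; for bare
#' `(k, n)` estimates draws the density estimate with its confidence
#' interval.
#'
#' @param x A `"well_count"` object.
#' @param ... Passed to [graphics::hist()] / [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.well_count <- function(x, ...) {
  if (!is.null(x$occupancy)) {
    occ <- x$occupancy
    graphics::hist(occ$intensities, breaks = occ$histogram$breaks,
                   main = "Well intensity histogram",
                   xlab = "mean well intensity", ...)
    graphics::abline(v = occ$threshold, col = "red", lty = 2)
  } else {
    graphics::plot(1, x$density, ylim = range(x$ci_low, x$ci_high, x$density),
                   xaxt = "n", xlab = "", ylab = "particles / uL",
                   main = "Density estimate", pch = 19, ...)
    graphics::arrows(1, x$ci_low, 1, x$ci_high, angle = 90, code = 3,
                     length = 0.1)
  }
  invisible(x)
}
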