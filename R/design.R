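# Design-space analysis: how counting precision scales with the number of
# wells, and how the measurable density range scales with well volume.

.design_curve <- function(df, method, fixed, rng_seed = NULL) {
  structure(df, method = method, fixed = fixed, rng_seed = rng_seed,
            class = c("design_curve", "data.frame"))
}

#' @export
print.design_curve <- function(x, ...) {
  cat(sprintf("design_curve (%s), %d points; fixed: %s\n",
              attr(x, "method"), nrow(x),
              paste(names(attr(x, "fixed")), unlist(attr(x, "fixed")),
                    sep = "=", collapse = ", ")))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' @export
plot.design_curve <- function(x, ...) {
  graphics::plot(x[[1]], x[[2]], log = "xy", type = "b",
                 xlab = names(x)[1], ylab = names(x)[2], ...)
  invisible(x)
}

#' Confidence interval width versus number of wells
#'
#' For a fixed particle density, evaluates the relative confidence interval
#' width ([ci_percent_of_mean()]) as a function of the number of wells
#' analysed. The `"analytic"` method plugs the expected occupied count
#' `k = n * p` into the estimator; `"monte_carlo"` draws `k ~ Binomial(n, p)`
#' `reps` times and averages the CI percentage (draws with `k = 0` or
#' `k = n`, where the percentage is undefined, are dropped). Both produce
#' curves decreasing roughly as `1 / sqrt(n)`: more wells, tighter counts.
#'
#' @param density Particle density in particles/uL; positive.
#' @param geometry An [array_geometry()] supplying the well volume.
#' @param well_counts Vector of well numbers `n` to evaluate.
#' @param method `"analytic"` or `"monte_carlo"`.
#' @param reps Monte-Carlo replicates per point.
#' @param rng_seed Seed, required for `"monte_carlo"`.
#' @param conf_level Confidence level.
#' @return A `"design_curve"` data frame with columns `wells` and `ci_pct`
#'   (and, for Monte Carlo, `mc_se`, the standard error of the mean CI
#'   percentage).
#' @export
ci_vs_well_count <- function(density, geometry, well_counts,
                             method = c("analytic", "monte_carlo"),
                             reps = 1000, rng_seed = NULL,
                             conf_level = 0.95) {
  method <- match.arg(method)
  stopifnot(inherits(geometry, "array_geometry"))
  wc_check(is.numeric(density) && length(density) == 1L && density > 0,
           "wellcount_domain_error", "density must be positive")
  wc_check(all(well_counts >= 2), "wellcount_domain_error",
           "well_counts must be >= 2")
  p <- occupancy_probability(density, geometry$well_volume)
  if (p > 1 - 1e-12)
    warning("density saturates the wells (p ~ 1); CI percentages unreliable",
            call. = FALSE)
  if (method == "analytic") {
    y <- vapply(well_counts, function(n)
      ci_percent_of_mean(estimate_density(n * p, n, geometry$well_volume,
                                          conf_level = conf_level)),
      numeric(1))
    return(.design_curve(data.frame(wells = well_counts, ci_pct = y),
                         "analytic",
                         list(density = density,
                              well_volume = geometry$well_volume)))
  }
  wc_check(!is.null(rng_seed), "wellcount_parameter_error",
           "monte_carlo requires rng_seed")
  res <- withr::with_seed(as.integer(rng_seed), {
    lapply(well_counts, function(n) {
      ks <- stats::rbinom(reps, n, p)
      ks <- ks[ks > 0 & ks < n]
      pct <- vapply(ks, function(k)
        ci_percent_of_mean(estimate_density(k, n, geometry$well_volume,
                                            conf_level = conf_level)),
        numeric(1))
      c(mean(pct), stats::sd(pct) / sqrt(length(pct)))
    })
  })
  m <- do.call(rbind, res)
  .design_curve(data.frame(wells = well_counts, ci_pct = m[, 1],
                           mc_se = m[, 2]),
                "monte_carlo",
                list(density = density, well_volume = geometry$well_volume,
                     reps = reps),
                rng_seed = as.integer(rng_seed))
}

#' Measurable number density versus well volume
#'
#' The dynamic-range design curve: for each occupied fraction `f` and well
#' volume `V`, the density that produces that fraction under Poisson
#' loading, `-ln(1 - f) / V`. Each fixed-`f` curve is a straight line of
#' slope -1 in log-log coordinates: femtoliter-scale wells resolve densities
#' beyond 1e6 particles/uL while nanoliter wells count tens per uL.
#'
#' @param occupied_fractions Fractions in `(0, 1)`.
#' @param volumes Well volumes in uL; positive.
#' @return A `"design_curve"` data frame with columns `volume_ul`,
#'   `occupied_fraction`, `density` (exact closed form).
#' @examples
#' density_vs_volume(1 - exp(-1), 1e-6)$density  # 1e6 particles/uL
#' @export
density_vs_volume <- function(occupied_fractions, volumes) {
  wc_check(is.numeric(occupied_fractions) && all(occupied_fractions > 0) &&
             all(occupied_fractions < 1),
           "wellcount_domain_error", "occupied_fractions must be in (0, 1)")
  wc_check(is.numeric(volumes) && all(volumes > 0),
           "wellcount_domain_error", "volumes must be positive")
  grid <- expand.grid(volume_ul = volumes,
                      occupied_fraction = occupied_fractions)
  grid$density <- -log1p(-grid$occupied_fraction) / grid$volume_ul
  .design_curve(grid, "analytic", list())
}

.derive_seed <- function(seed, i) as.integer((seed + 7919 * i) %% 2147483629L)

#' End-to-end recovery of a known density from synthetic images
#'
#' Composition harness for validation: seeds particles at a known density
#' ([seed_particles()]), renders each panel ([render_panel()]), runs the
#' full counting pipeline ([wellcount()]) and returns the estimate alongside
#' the ground truth, so bias and CI coverage can be measured.
#'
#' @param density True particle density, particles/uL.
#' @param geometry An [array_geometry()]; `panels` controls how many panels
#'   are simulated unless overridden.
#' @param noise A [noise_spec()]; its seed is re-derived per panel from
#'   `rng_seed`.
#' @param aggregation Clumping strength passed to [seed_particles()].
#' @param rng_seed Master seed for the run.
#' @param modality Imaging modality to render and analyse.
#' @param panels Number of panels to simulate (default `geometry$panels`).
#' @param ... Passed to [wellcount()].
#' @return A `"well_count"` object with attributes `true_density`,
#'   `true_lambda` and `true_occupied` (ground-truth occupied wells).
#' @export
end_to_end_recovery <- function(density, geometry, noise = noise_spec(),
                                aggregation = 0, rng_seed = 1L,
                                modality = "brightfield",
                                panels = geometry$panels, ...) {
  stopifnot(inherits(geometry, "array_geometry"), inherits(noise, "noise_spec"))
  imgs <- vector("list", panels)
  true_k <- 0L
  for (p in seq_len(panels)) {
    truth <- seed_particles(geometry, density, aggregation,
                            rng_seed = .derive_seed(rng_seed, 2L * p))
    true_k <- true_k + sum(truth$occupied)
    np <- noise
    np$rng_seed <- .derive_seed(rng_seed, 2L * p + 1L)
    imgs[[p]] <- render_panel(geometry, truth, modality, np)
  }
  est <- wellcount(imgs, geometry, modality = modality, ...)
  attr(est, "true_density") <- density
  attr(est, "true_lambda") <- density * geometry$well_volume
  attr(est, "true_occupied") <- true_k
  est
}
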