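# Vague, data-located priors for the hierarchical split-plot model.

#' Moment-match a gamma distribution
#'
#' Converts a requested mean and SD into the (shape, rate) parameterization:
#' shape = mean^2 / sd^2, rate = mean / sd^2. A gamma with these parameters
#' has exactly the requested mean and SD.
#'
#' @param mean,sd Positive reals.
#' @return Named numeric vector `c(shape, rate)`.
#' @examples
#' gamma_from_mean_sd(1, 1)       # shape 1, rate 1: the exponential
#' gamma_from_mean_sd(5.0e-05, 33)  # shape ~ 2e-12, rate ~ 4.6e-8
#' @export
gamma_from_mean_sd <- function(mean, sd) {
  if (!is.numeric(mean) || !is.numeric(sd) || mean <= 0 || sd <= 0) {
    stop("`mean` and `sd` must be positive")
  }
  c(shape = mean^2 / sd^2, rate = mean / sd^2)
}

#' Build vague priors from a median table
#'
#' The priors are located at broad data summaries so that they are
#' noncommittal: a normal prior on the baseline centered at the pooled mean
#' with 1e-6 times the pooled precision; a uniform prior on the shared scale
#' between the pooled SD divided and multiplied by 1000; an exponential prior
#' with mean 29 on the t degrees of freedom nu (balancing nearly-normal and
#' heavy-tailed regimes); and a gamma prior on the common deflection precision
#' moment-matched to the mean of the observed per-cell precisions and an
#' SD inflated by `precision_sd_inflation` (1e+6), which makes it effectively
#' flat.
#'
#' @param medians A `pwi_medians` table (>= 2 participants, >= 2 conditions).
#' @param nu_prior_mean Mean of the exponential prior on nu.
#' @param precision_sd_inflation Multiplier applied to the SD of the observed
#'   cell precisions before moment matching.
#' @return An object of class `pwi_priors`: a list with `baseline_mean`,
#'   `baseline_precision`, `sd_lower`, `sd_upper`, `nu_prior_mean`,
#'   `deflection_shape`, `deflection_rate`.
#' @export
build_priors <- function(medians, nu_prior_mean = 29,
                         precision_sd_inflation = 1e6) {
  conditions <- attr(medians, "conditions")
  if (is.null(conditions)) {
    conditions <- setdiff(names(medians), c("participant_id", "group"))
  }
  long <- medians_long(medians, conditions)
  if (length(unique(long$participant_id)) < 2) stop("need >= 2 participants")
  if (length(unique(long$condition)) < 2) stop("need >= 2 conditions")
  pooled <- long$median_rt
  v <- stats::var(pooled)
  if (!is.finite(v) || v == 0) stop("pooled variance is zero: degenerate data")

  cell_var <- tapply(long$median_rt, interaction(long$group, long$condition),
                     stats::var)
  cell_prec <- 1 / cell_var[is.finite(cell_var) & cell_var > 0]
  if (length(cell_prec) < 2) stop("need >= 2 cells with positive variance")
  gam <- gamma_from_mean_sd(mean(cell_prec),
                            precision_sd_inflation * stats::sd(cell_prec))

  structure(list(baseline_mean = mean(pooled),
                 baseline_precision = 1e-6 / v,
                 sd_lower = sqrt(v) / 1000,
                 sd_upper = sqrt(v) * 1000,
                 nu_prior_mean = nu_prior_mean,
                 deflection_shape = unname(gam["shape"]),
                 deflection_rate = unname(gam["rate"])),
            class = "pwi_priors")
}

#' @export
print.pwi_priors <- function(x, ...) {
  cat("Vague priors for the hierarchical split-plot model\n")
  cat(sprintf("  baseline  ~ Normal(mean = %.6g, precision = %.3g)\n",
              x$baseline_mean, x$baseline_precision))
  cat(sprintf("  sigma     ~ Uniform(%.6g, %.6g)\n", x$sd_lower, x$sd_upper))
  cat(sprintf("  nu        ~ Exponential(mean = %g)\n", x$nu_prior_mean))
  cat(sprintf("  deflection precision ~ Gamma(shape = %.3g, rate = %.3g)\n",
              x$deflection_shape, x$deflection_rate))
  invisible(x)
}
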