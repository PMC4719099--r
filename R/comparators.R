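# Frequentist comparators: split-plot repeated-measures ANOVA, per-group
# one-sample t tests on the distractor effects, Welch between-group
# comparisons, and a logistic error-rate comparison.

#' Split-plot repeated-measures ANOVA on condition medians
#'
#' Two-factor mixed ANOVA with distractor condition as the within-participant
#' factor and group as the between-participant factor: the group effect is
#' tested against the participants-within-group stratum, condition and the
#' group x condition interaction against the participant x condition stratum.
#' P-values are uncorrected for multiple comparisons; a Greenhouse-Geisser
#' sphericity correction of the within-participant tests is available but off
#' by default.
#'
#' @param medians A `pwi_medians` table; participants with any missing cell
#'   are dropped with a warning.
#' @param gg_correction Apply the Greenhouse-Geisser epsilon to the df and
#'   p-values of the within-participant terms.
#' @return An object of class `pwi_anova`: a data.frame with one row per term
#'   (`group`, `condition`, `group:condition`) giving sums of squares, F,
#'   numerator/denominator df and p, with the full stratum table (including
#'   error terms) in attribute `strata` and, if requested, the GG epsilon in
#'   attribute `gg_epsilon`.
#' @export
splitplot_anova <- function(medians, gg_correction = FALSE) {
  conditions <- attr(medians, "conditions")
  if (is.null(conditions)) {
    conditions <- setdiff(names(medians), c("participant_id", "group"))
  }
  complete <- stats::complete.cases(medians[, conditions, drop = FALSE])
  if (any(!complete)) {
    warning(sprintf("dropping %d participant(s) with missing cells",
                    sum(!complete)))
    medians <- medians[complete, , drop = FALSE]
  }
  long <- medians_long(medians, conditions)
  long$participant_id <- factor(long$participant_id)
  long$group <- factor(long$group)
  long$condition <- factor(long$condition, levels = conditions)

  fit <- stats::aov(median_rt ~ group * condition + Error(participant_id),
                    data = long)
  sm <- summary(fit)
  between <- as.data.frame(sm[["Error: participant_id"]][[1]])
  within <- as.data.frame(sm[["Error: Within"]][[1]])
  row_of <- function(tab, term, err_row) {
    i <- match(term, trimws(rownames(tab)))
    data.frame(term = term, ss = tab[i, "Sum Sq"], df1 = tab[i, "Df"],
               df2 = tab[err_row, "Df"], ss_error = tab[err_row, "Sum Sq"],
               F = tab[i, "F value"], p = tab[i, "Pr(>F)"],
               stringsAsFactors = FALSE)
  }
  out <- rbind(row_of(between, "group", nrow(between)),
               row_of(within, "condition", nrow(within)),
               row_of(within, "group:condition", nrow(within)))

  eps <- NA_real_
  if (gg_correction) {
    eps <- gg_epsilon(medians, conditions)
    w <- out$term != "group"
    out$df1[w] <- out$df1[w] * eps
    out$df2[w] <- out$df2[w] * eps
    out$p[w] <- stats::pf(out$F[w], out$df1[w], out$df2[w], lower.tail = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("pwi_anova", "data.frame")
  attr(out, "strata") <- list(between = between, within = within)
  attr(out, "gg_epsilon") <- eps
  out
}

# Greenhouse-Geisser epsilon from the pooled within-group covariance of the
# condition columns.
gg_epsilon <- function(medians, conditions) {
  mats <- lapply(split(medians[, conditions, drop = FALSE], medians$group),
                 function(m) {
                   m <- as.matrix(m)
                   if (nrow(m) < 2) return(NULL)
                   (nrow(m) - 1) * stats::cov(m)
                 })
  mats <- mats[!vapply(mats, is.null, logical(1))]
  n_tot <- nrow(medians); n_g <- length(mats)
  S <- Reduce(`+`, mats) / (n_tot - n_g)
  k <- length(conditions)
  C <- diag(k) - 1 / k  # centering projector
  SC <- C %*% S %*% C
  sum(diag(SC))^2 / ((k - 1) * sum(SC^2))
}

#' t tests on the distractor effects
#'
#' For each effect (lexical, semantic, phonological): a one-sample t test of
#' the effect against zero within each group (df = n - 1), and a Welch
#' unequal-variance t test of the group difference (patient - control) with
#' Welch-Satterthwaite fractional df. Two-sided 95% confidence intervals use
#' the same df as the accompanying t.
#'
#' @param effects Effect table from [compute_effects()].
#' @param conf_level Confidence level for the intervals.
#' @return An object of class `pwi_ttests`: a data.frame with columns
#'   `comparison`, `effect`, `mean`, `t`, `df`, `p`, `ci_low`, `ci_high`.
#'   Zero-variance cells are reported with `NA` statistics.
#' @export
effect_ttests <- function(effects, conf_level = 0.95) {
  rows <- list()
  for (eff in c("lexical", "semantic", "phonological")) {
    col <- paste0(eff, "_ms")
    xs <- split(effects[[col]], effects$group)
    xs <- lapply(xs, function(x) x[!is.na(x)])
    for (g in names(xs)) {
      x <- xs[[g]]
      if (length(x) < 2) next
      if (stats::sd(x) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          comparison = g, effect = eff, mean = mean(x), t = NA_real_,
          df = NA_real_, p = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
          stringsAsFactors = FALSE)
        next
      }
      tt <- stats::t.test(x, mu = 0, conf.level = conf_level)
      rows[[length(rows) + 1]] <- data.frame(
        comparison = g, effect = eff, mean = mean(x),
        t = unname(tt$statistic), df = unname(tt$parameter),
        p = tt$p.value, ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
        stringsAsFactors = FALSE)
    }
    if (all(c("control", "patient") %in% names(xs)) &&
        length(xs$control) >= 2 && length(xs$patient) >= 2 &&
        (stats::sd(xs$control) > 0 || stats::sd(xs$patient) > 0)) {
      wt <- stats::t.test(xs$patient, xs$control, var.equal = FALSE,
                          conf.level = conf_level)
      rows[[length(rows) + 1]] <- data.frame(
        comparison = "patient_vs_control", effect = eff,
        mean = mean(xs$patient) - mean(xs$control),
        t = unname(wt$statistic), df = unname(wt$parameter),
        p = wt$p.value, ci_low = wt$conf.int[1], ci_high = wt$conf.int[2],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pwi_ttests", "data.frame")
  out
}

#' Per-condition group comparison of error proportions
#'
#' For each distractor condition, fits a binomial GLM (logit link) of error
#' vs. correct status on group, among trials with a scoreable response
#' (voice-key failures excluded), and reports the Wald p-value for the group
#' term. A condition with zero errors in both groups is flagged degenerate.
#'
#' @param trials Trial-level data.
#' @return data.frame with one row per condition: error counts and rates per
#'   group, the group log-odds ratio, `p`, and `degenerate`.
#' @export
error_rate_comparison <- function(trials) {
  scoreable <- trials[trials$status != "voicekey_fail", , drop = FALSE]
  conds <- unique(scoreable$condition)
  rows <- lapply(conds, function(cond) {
    d <- scoreable[scoreable$condition == cond, , drop = FALSE]
    err <- d$status == "error"
    n_c <- sum(d$group == "control"); n_p <- sum(d$group == "patient")
    e_c <- sum(err & d$group == "control"); e_p <- sum(err & d$group == "patient")
    degenerate <- (e_c + e_p) == 0 || (e_c == n_c && e_p == n_p)
    lor <- NA_real_; p <- NA_real_
    if (!degenerate) {
      fit <- stats::glm(err ~ group, family = stats::binomial(), data = d)
      co <- summary(fit)$coefficients
      if (nrow(co) == 2) {
        lor <- co[2, "Estimate"]
        p <- co[2, "Pr(>|z|)"]
      }
    }
    data.frame(condition = cond, n_control = n_c, errors_control = e_c,
               rate_control = if (n_c > 0) e_c / n_c else NA_real_,
               n_patient = n_p, errors_patient = e_p,
               rate_patient = if (n_p > 0) e_p / n_p else NA_real_,
               log_odds_ratio = lor, p = p, degenerate = degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
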