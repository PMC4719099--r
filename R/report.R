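# End-to-end pipeline and report assembly.

#' Run the full analysis pipeline and assemble the report
#'
#' From a trial-level table: applies the exclusion rules, computes
#' per-participant condition medians, distractor effects, single-case
#' standardized scores and general-slowing RT ratios, fits the hierarchical
#' Bayesian split-plot model and summarizes the standard contrasts, and runs
#' the frequentist comparators (split-plot ANOVA, effect t tests, error-rate
#' comparison). Sections whose preconditions are unmet (e.g. no inferential
#' tables on an empty dataset) are left `NULL` and listed in `gaps`.
#'
#' @param trials Trial-level data.frame ([simulate_trials()] /
#'   [read_trials()]).
#' @param min_rt_ms Fast-response exclusion threshold (ms).
#' @param mcmc A `pwi_mcmc` configuration for the Bayesian fit.
#' @param priors Optional `pwi_priors`; by default built from the data.
#' @return An object of class `pwi_report`: a list with elements
#'   `exclusions`, `medians`, `group_medians`, `effects`, `scores`, `ratios`,
#'   `contrasts`, `posterior`, `anova`, `ttests`, `error_rates` and `gaps`.
#' @export
build_report <- function(trials, min_rt_ms = 200, mcmc = mcmc_config(),
                         priors = NULL) {
  rep <- list(gaps = character(0))
  ex <- exclude_trials(trials, min_rt_ms)
  rep$exclusions <- ex$report

  if (nrow(ex$retained) == 0) {
    rep$gaps <- c(rep$gaps, "no retained trials: no inferential tables")
    class(rep) <- "pwi_report"
    return(rep)
  }

  conds_present <- unique(ex$retained$condition)
  conds <- if (all(conds_present %in% pwi_conditions())) {
    pwi_conditions()
  } else {
    sort(conds_present)
  }
  med <- condition_medians(ex$retained, conds)
  rep$medians <- med
  rep$group_medians <- stats::aggregate(med[, conds, drop = FALSE],
                                        by = list(group = med$group), mean,
                                        na.rm = TRUE)

  standard <- all(pwi_conditions() %in% names(med))
  if (standard) {
    rep$effects <- compute_effects(med)
    rep$ratios <- rt_ratios(med)
    n_ctrl <- sum(rep$effects$group == "control" &
                    !is.na(rep$effects$lexical_ms))
    if (n_ctrl >= 2) {
      rep$scores <- standardized_scores(rep$effects)
    } else {
      rep$gaps <- c(rep$gaps, "fewer than 2 controls: no standardized scores")
    }
  } else {
    rep$gaps <- c(rep$gaps, "non-standard conditions: no effect tables")
  }

  n_part <- nrow(med)
  if (n_part >= 4 && length(unique(med$group)) == 2) {
    pr <- if (is.null(priors)) build_priors(med) else priors
    rep$posterior <- fit_splitplot(med, priors = pr, mcmc = mcmc)
    if (standard) rep$contrasts <- as.data.frame(standard_contrasts(rep$posterior))
    rep$anova <- splitplot_anova(med)
    if (standard) rep$ttests <- effect_ttests(rep$effects)
  } else {
    rep$gaps <- c(rep$gaps, "too few participants/groups: no group inference")
  }
  rep$error_rates <- error_rate_comparison(trials)
  class(rep) <- "pwi_report"
  rep
}

#' Write a report to disk
#'
#' Writes each table as CSV, a machine-readable JSON bundle, and a plain-text
#' summary. Output is deterministic: two runs on the same data produce
#' byte-identical files.
#'
#' @param report A `pwi_report`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  wr <- function(tab, nm) {
    if (is.null(tab)) return()
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(as.data.frame(tab), p, row.names = FALSE, na = "")
    paths <<- c(paths, p)
  }
  wr(report$exclusions, "exclusions")
  wr(report$medians, "condition_medians")
  wr(report$group_medians, "group_medians")
  wr(report$effects, "effects")
  wr(report$scores, "standardized_scores")
  wr(report$ratios, "rt_ratios")
  wr(report$contrasts, "bayes_contrasts")
  wr(report$anova, "anova")
  wr(report$ttests, "ttests")
  wr(report$error_rates, "error_rates")

  json <- list(gaps = report$gaps)
  for (nm in c("exclusions", "group_medians", "effects", "scores", "ratios",
               "contrasts", "anova", "ttests", "error_rates")) {
    if (!is.null(report[[nm]])) json[[nm]] <- as.data.frame(report[[nm]])
  }
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(json, jp, auto_unbox = TRUE, digits = NA, na = "null")
  paths <- c(paths, jp)

  tp <- file.path(dir, "report.txt")
  con <- file(tp, "w")
  on.exit(close(con))
  sink(con)
  print(report)
  sink()
  paths <- c(paths, tp)
  invisible(paths)
}

#' @export
print.pwi_report <- function(x, ...) {
  cat("Picture-word interference analysis report\n")
  cat("==========================================\n\n")
  cat("Trial exclusions\n")
  print(as.data.frame(x$exclusions), row.names = FALSE, digits = 3)
  if (!is.null(x$group_medians)) {
    cat("\nGroup mean of per-participant condition medians (ms)\n")
    print(x$group_medians, row.names = FALSE, digits = 4)
  }
  if (!is.null(x$contrasts)) {
    cat("\nBayesian posterior contrasts (ms)\n")
    df <- x$contrasts
    df$mean <- round(df$mean, 1)
    df$hdi_low <- round(df$hdi_low, 1); df$hdi_high <- round(df$hdi_high, 1)
    print(df, row.names = FALSE)
  }
  if (!is.null(x$scores)) {
    cat("\nStandardized scores (SD units vs. control sample; flag = beyond 2 SD)\n")
    sc <- x$scores[x$scores$group == "patient",
                   c("participant_id", "z_lexical", "z_semantic",
                     "z_phonological", "beyond_lexical", "beyond_semantic",
                     "beyond_phonological")]
    print(sc, row.names = FALSE, digits = 3)
  }
  if (!is.null(x$anova)) {
    cat("\nSplit-plot repeated-measures ANOVA\n")
    print(as.data.frame(x$anova), row.names = FALSE, digits = 4)
  }
  if (!is.null(x$ttests)) {
    cat("\nEffect t tests\n")
    print(as.data.frame(x$ttests), row.names = FALSE, digits = 3)
  }
  if (!is.null(x$error_rates)) {
    cat("\nError-rate comparison (logistic regression per condition)\n")
    print(x$error_rates, row.names = FALSE, digits = 3)
  }
  if (length(x$gaps) > 0) {
    cat("\nGaps:\n")
    for (g in x$gaps) cat(" -", g, "\n")
  }
  invisible(x)
}
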