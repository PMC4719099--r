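# Shared fixtures: reduced MCMC settings and small generator configurations
# keep the suite fast while leaving the model and pipeline untouched.

quick_mcmc <- function(seed = 1, n_samples = 2000, n_chains = 1,
                       thin = 2, burn_in = 500, n_adapt = 300) {
  mcmc_config(n_samples = n_samples, thin = thin, burn_in = burn_in,
              n_chains = n_chains, n_adapt = n_adapt, seed = seed)
}

# A clean configuration: no artifact trials, no participant offsets, equal
# noise in both groups. Handy for exact-rate and invariance checks.
clean_config <- function(seed = 1,
                         participant_sd = c(control = 0, patient = 0), ...) {
  generator_config(
    participant_sd = participant_sd,
    rt_noise = list(family = "shifted_lognormal", shift_ms = 250,
                    sigma = c(control = 0.2, patient = 0.2)),
    error_rate = c(control = 0, patient = 0),
    voicekey_fail_rate = c(control = 0, patient = 0),
    fast_guess_rate = c(control = 0, patient = 0),
    seed = seed, ...)
}

paper_like_medians <- function(seed = 1) {
  trials <- simulate_trials(paper_like_config(seed = seed))
  condition_medians(exclude_trials(trials)$retained)
}

# Independent sums-of-squares oracle for a balanced two-group split-plot
# design (participants nested in group, crossed with condition). Textbook
# unweighted-means formulas, written without reference to aov().
splitplot_ss_oracle <- function(medians, conditions) {
  y <- as.matrix(medians[, conditions])
  n_subj <- nrow(y); k <- ncol(y)
  groups <- unique(medians$group)
  G <- mean(y)
  subj_means <- rowMeans(y)
  cond_means <- colMeans(y)
  grp_means <- vapply(groups, function(g) mean(y[medians$group == g, ]),
                      numeric(1))
  n_g <- vapply(groups, function(g) sum(medians$group == g), numeric(1))

  ss_total <- sum((y - G)^2)
  ss_between_subj <- k * sum((subj_means - G)^2)
  ss_group <- k * sum(n_g * (grp_means - G)^2)
  ss_subj_within <- ss_between_subj - ss_group
  ss_cond <- n_subj * sum((cond_means - G)^2)
  cell_means <- vapply(groups, function(g) {
    colMeans(y[medians$group == g, , drop = FALSE])
  }, numeric(k))
  ss_cells <- sum(rep(n_g, each = k) * (c(cell_means) - G)^2)
  ss_inter <- ss_cells - ss_group - ss_cond
  ss_resid <- ss_total - ss_between_subj - ss_cond - ss_inter

  df_group <- length(groups) - 1
  df_subj <- n_subj - length(groups)
  df_cond <- k - 1
  df_inter <- df_group * df_cond
  df_resid <- df_cond * df_subj
  list(
    F_group = (ss_group / df_group) / (ss_subj_within / df_subj),
    F_cond = (ss_cond / df_cond) / (ss_resid / df_resid),
    F_inter = (ss_inter / df_inter) / (ss_resid / df_resid),
    df = c(group = df_group, subj = df_subj, cond = df_cond,
           inter = df_inter, resid = df_resid),
    ss = c(total = ss_total, group = ss_group, subj_within = ss_subj_within,
           cond = ss_cond, inter = ss_inter, resid = ss_resid))
}

# Closed-form Welch statistics, independent of t.test().
welch_oracle <- function(x1, x2) {
  m <- mean(x1) - mean(x2)
  v1 <- var(x1) / length(x1); v2 <- var(x2) / length(x2)
  se2 <- v1 + v2
  t <- m / sqrt(se2)
  df <- se2^2 / (v1^2 / (length(x1) - 1) + v2^2 / (length(x2) - 1))
  list(mean = m, t = t, df = df,
       ci = m + c(-1, 1) * qt(0.975, df) * sqrt(se2))
}

# A tiny balanced 4-participant x 4-condition median table with distinct,
# hand-typed values (2 controls, 2 patients).
tiny_medians <- function() {
  out <- data.frame(
    participant_id = c("C01", "C02", "P01", "P02"),
    group = c("control", "control", "patient", "patient"),
    neutral = c(700, 760, 1100, 1180),
    unrelated = c(780, 820, 1400, 1500),
    related = c(810, 880, 1450, 1620),
    phonological = c(750, 800, 1250, 1330),
    stringsAsFactors = FALSE)
  class(out) <- c("pwi_medians", "data.frame")
  attr(out, "conditions") <- pwi_conditions()
  out
}
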