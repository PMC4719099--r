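# Robust hierarchical Bayesian split-plot model over participant-condition
# median RTs, sampled with JAGS.
#
# Likelihood: each median ~ t(nu) with shared scale sigma and location
#   baseline + group deflection + distractor deflection + interaction
#   deflection + participant deflection (participants nested in group).
# All deflection families have zero-mean normal priors whose precisions carry
# the vague gamma hyperprior of build_priors(); sampling uses an unconstrained
# parameterization and every retained draw is swept into the sum-to-zero
# deflection decomposition afterwards (recentering moves no cell mean).

pwi_model_string <- "
model {
  for (i in 1:N) {
    y[i] ~ dt(mu[i], tauLik, nu)
    mu[i] <- a0 + aG[g[i]] + aD[d[i]] + aGD[g[i], d[i]] + aS[s[i]]
  }
  tauLik <- pow(sigma, -2)
  a0 ~ dnorm(a0Mean, a0Prec)
  sigma ~ dunif(sdLo, sdHi)
  nu ~ dexp(nuRate)
  tauA ~ dgamma(defShape, defRate)
  tauS ~ dgamma(defShape, defRate)
  for (j in 1:NG) { aG[j] ~ dnorm(0, tauA) }
  for (k in 1:ND) { aD[k] ~ dnorm(0, tauA) }
  for (j in 1:NG) { for (k in 1:ND) { aGD[j, k] ~ dnorm(0, tauA) } }
  for (p in 1:NS) { aS[p] ~ dnorm(0, tauSubj[p]) }
}
"

#' MCMC configuration
#'
#' Defaults follow the analysis settings this model was designed with:
#' 100,000 retained draws, keeping every 50th step after a 2,000-step burn-in.
#' Reduced draw counts (a few thousand retained, light thinning) are adequate
#' for simulation studies and tests.
#'
#' @param n_samples Total retained draws across chains.
#' @param thin Keep every `thin`-th step.
#' @param burn_in Initial steps discarded per chain.
#' @param n_chains Number of chains (>= 2 enables split-R-hat diagnostics).
#' @param n_adapt JAGS adaptation steps per chain.
#' @param seed Integer seed; per-chain RNG seeds are derived from it, so the
#'   same configuration reproduces identical draws.
#' @return An object of class `pwi_mcmc` (a validated list).
#' @export
mcmc_config <- function(n_samples = 100000, thin = 50, burn_in = 2000,
                        n_chains = 4, n_adapt = 1000, seed = 1L) {
  stopifnot(n_samples >= 1, thin >= 1, burn_in >= 0, n_chains >= 1,
            n_adapt >= 0)
  structure(list(n_samples = as.integer(n_samples), thin = as.integer(thin),
                 burn_in = as.integer(burn_in), n_chains = as.integer(n_chains),
                 n_adapt = as.integer(n_adapt), seed = as.integer(seed)),
            class = "pwi_mcmc")
}

#' Fit the robust hierarchical split-plot model
#'
#' @param medians A `pwi_medians` table (long or wide; see
#'   [condition_medians()]). Missing cells are dropped from the likelihood.
#' @param priors A `pwi_priors` object; by default built from the data with
#'   [build_priors()].
#' @param mcmc A `pwi_mcmc` configuration.
#' @param subject_precision `"separate"` (default) gives the participant
#'   deflections their own precision parameter under the same gamma
#'   hyperprior; `"shared"` ties it to the precision of the group, distractor
#'   and interaction deflections.
#' @param rhat_threshold Convergence flag threshold on the largest split
#'   R-hat (checked when `n_chains >= 2`).
#' @param quiet Suppress JAGS progress output.
#' @return An object of class `pwi_posterior` holding the sum-to-zero swept
#'   draws: `baseline` (vector), `group`, `distractor`, `interaction` and
#'   `subject` (matrices, one column per level / cell / participant), `sigma`,
#'   `nu`, plus level metadata, convergence diagnostics (`diagnostics`,
#'   `converged`) and the priors and configuration used.
#' @export
fit_splitplot <- function(medians, priors = build_priors(medians),
                          mcmc = mcmc_config(),
                          subject_precision = c("separate", "shared"),
                          rhat_threshold = 1.1, quiet = TRUE) {
  subject_precision <- match.arg(subject_precision)
  stopifnot(inherits(priors, "pwi_priors"), inherits(mcmc, "pwi_mcmc"))
  conditions <- attr(medians, "conditions")
  long <- if (all(c("condition", "median_rt") %in% names(medians))) {
    medians
  } else {
    medians_long(medians, conditions)
  }
  if (is.null(conditions)) conditions <- unique(long$condition)
  groups <- sort(unique(long$group))
  subjects <- unique(long[, c("participant_id", "group")])
  subjects <- subjects[order(match(subjects$group, groups),
                             subjects$participant_id), , drop = FALSE]

  g <- match(long$group, groups)
  d <- match(long$condition, conditions)
  s <- match(long$participant_id, subjects$participant_id)
  y <- long$median_rt
  NG <- length(groups); ND <- length(conditions); NS <- nrow(subjects)

  dat <- list(y = y, g = g, d = d, s = s, N = length(y),
              NG = NG, ND = ND, NS = NS,
              a0Mean = priors$baseline_mean, a0Prec = priors$baseline_precision,
              sdLo = priors$sd_lower, sdHi = priors$sd_upper,
              nuRate = 1 / priors$nu_prior_mean,
              defShape = priors$deflection_shape,
              defRate = priors$deflection_rate)
  model_str <- pwi_model_string
  if (subject_precision == "shared") {
    model_str <- sub("tauS ~ dgamma(defShape, defRate)", "tauS <- tauA",
                     model_str, fixed = TRUE)
  }
  model_str <- sub("tauSubj[p]", "tauS", model_str, fixed = TRUE)

  # chains initialized at data summaries, with per-chain RNG seeds
  grand <- mean(y)
  g_mean <- tapply(y, g, mean) - grand
  d_mean <- tapply(y, d, mean) - grand
  s_mean <- tapply(y, s, mean)[as.character(seq_len(NS))] -
    grand - g_mean[as.character(match(subjects$group, groups))]
  chain_seeds <- derive_seeds(mcmc$seed, mcmc$n_chains)
  inits <- lapply(seq_len(mcmc$n_chains), function(i) {
    list(a0 = grand, aG = unname(g_mean), aD = unname(d_mean),
         aGD = matrix(0, NG, ND), aS = unname(s_mean),
         sigma = stats::sd(y), nu = priors$nu_prior_mean,
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = chain_seeds[i])
  })

  per_chain <- ceiling(mcmc$n_samples / mcmc$n_chains)
  jm <- rjags::jags.model(textConnection(model_str), data = dat, inits = inits,
                          n.chains = mcmc$n_chains, n.adapt = mcmc$n_adapt,
                          quiet = quiet)
  if (mcmc$burn_in > 0) {
    update(jm, mcmc$burn_in, progress.bar = if (quiet) "none" else "text")
  }
  monitors <- c("a0", "aG", "aD", "aGD", "aS", "sigma", "nu")
  sm <- rjags::coda.samples(jm, monitors, n.iter = per_chain * mcmc$thin,
                            thin = mcmc$thin,
                            progress.bar = if (quiet) "none" else "text")

  # Sweep each chain into the sum-to-zero decomposition, then diagnose the
  # identified quantities. The unconstrained parameterization has flat ridges
  # (a translation between the baseline and each deflection family leaves the
  # likelihood and, under these vague priors, essentially the posterior
  # unchanged), so raw-parameter autocorrelation is uninformative; all
  # reported inference is about the swept parameters.
  swept <- lapply(seq_len(mcmc$n_chains), function(i) {
    sweep_to_zero(as.matrix(sm[[i]]), groups, conditions, subjects)
  })
  ident <- lapply(seq_len(mcmc$n_chains), function(i) {
    coda::mcmc(cbind(baseline = swept[[i]]$baseline, swept[[i]]$group,
                     swept[[i]]$distractor, swept[[i]]$interaction,
                     sigma = as.matrix(sm[[i]])[, "sigma"],
                     nu = as.matrix(sm[[i]])[, "nu"]))
  })
  diag <- convergence_diagnostics(coda::mcmc.list(ident))
  converged <- is.na(diag$max_rhat) || diag$max_rhat <= rhat_threshold
  if (!converged) {
    warning(sprintf("chains may not have converged: max split R-hat = %.3f",
                    diag$max_rhat))
  }

  m <- as.matrix(sm)
  post <- list(
    baseline = do.call(c, lapply(swept, `[[`, "baseline")),
    group = do.call(rbind, lapply(swept, `[[`, "group")),
    distractor = do.call(rbind, lapply(swept, `[[`, "distractor")),
    interaction = do.call(rbind, lapply(swept, `[[`, "interaction")),
    subject = do.call(rbind, lapply(swept, `[[`, "subject")),
    cells = swept[[1]]$cells,
    cell_draws = do.call(rbind, lapply(swept, `[[`, "cell_draws")))
  post$sigma <- m[, "sigma"]
  post$nu <- m[, "nu"]
  post$groups <- groups
  post$conditions <- conditions
  post$subjects <- subjects
  post$n_draws <- nrow(m)
  post$diagnostics <- diag
  post$converged <- converged
  post$priors <- priors
  post$mcmc <- mcmc
  class(post) <- "pwi_posterior"
  post
}

derive_seeds <- function(seed, n) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

convergence_diagnostics <- function(sm) {
  ess <- coda::effectiveSize(sm)
  rhat <- NA_real_
  if (coda::nchain(sm) >= 2) {
    gd <- try(coda::gelman.diag(sm, autoburnin = FALSE,
                                multivariate = FALSE), silent = TRUE)
    if (!inherits(gd, "try-error")) rhat <- max(gd$psrf[, 1], na.rm = TRUE)
  }
  list(max_rhat = rhat, min_ess = min(ess), ess = ess)
}

# Recenter unconstrained draws into the sum-to-zero decomposition.
# Per draw: participant deflections are centered within group (their group
# means move into the group deflections); the 2 x ND grid of cell means is
# then swept into baseline + row + column + interaction parts. Cell means are
# unchanged by the sweep.
sweep_to_zero <- function(m, groups, conditions, subjects) {
  NG <- length(groups); ND <- length(conditions); NS <- nrow(subjects)
  n <- nrow(m)
  # JAGS drops the bracket index from singleton monitors ("aG" not "aG[1]")
  cols <- function(base, k) {
    nm <- sprintf("%s[%d]", base, seq_len(k))
    if (k == 1 && !nm %in% colnames(m)) nm <- base
    m[, nm, drop = FALSE]
  }
  A0 <- m[, "a0"]
  AG <- cols("aG", NG)
  AD <- cols("aD", ND)
  AS <- cols("aS", NS)
  grp_idx <- match(subjects$group, groups)

  sbar <- vapply(seq_len(NG), function(j) {
    rowMeans(AS[, grp_idx == j, drop = FALSE])
  }, numeric(n))
  AGe <- AG + sbar
  BS <- AS - sbar[, grp_idx, drop = FALSE]

  cells <- expand.grid(group = groups, condition = conditions,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  M <- matrix(0, n, NG * ND)
  gd_name <- function(j, k) {
    nm <- sprintf("aGD[%d,%d]", j, k)
    if (NG * ND == 1 && !nm %in% colnames(m)) nm <- "aGD"
    nm
  }
  for (idx in seq_len(NG * ND)) {
    j <- match(cells$group[idx], groups)
    k <- match(cells$condition[idx], conditions)
    M[, idx] <- A0 + AGe[, j] + AD[, k] + m[, gd_name(j, k)]
  }
  B0 <- rowMeans(M)
  BG <- vapply(seq_len(NG), function(j) {
    rowMeans(M[, cells$group == groups[j], drop = FALSE]) - B0
  }, numeric(n))
  BD <- vapply(seq_len(ND), function(k) {
    rowMeans(M[, cells$condition == conditions[k], drop = FALSE]) - B0
  }, numeric(n))
  BGD <- M - B0 -
    BG[, match(cells$group, groups), drop = FALSE] -
    BD[, match(cells$condition, conditions), drop = FALSE]

  colnames(BG) <- groups
  colnames(BD) <- conditions
  cell_names <- paste(cells$group, cells$condition, sep = ":")
  colnames(BGD) <- cell_names
  colnames(M) <- cell_names
  colnames(BS) <- subjects$participant_id
  list(baseline = B0, group = BG, distractor = BD, interaction = BGD,
       subject = BS, cells = cells, cell_draws = M)
}

#' Posterior draws of the group-by-condition cell means
#'
#' Per draw, cell mean = baseline + group deflection + distractor deflection
#' + interaction deflection (participant deflections average to zero within
#' group and do not enter the cell mean).
#'
#' @param post A `pwi_posterior`.
#' @return Matrix of draws, one column per cell, named `"group:condition"`.
#' @export
cell_means <- function(post) {
  stopifnot(inherits(post, "pwi_posterior"))
  idx_g <- match(post$cells$group, post$groups)
  idx_d <- match(post$cells$condition, post$conditions)
  out <- post$baseline +
    post$group[, idx_g, drop = FALSE] +
    post$distractor[, idx_d, drop = FALSE] +
    post$interaction
  colnames(out) <- colnames(post$interaction)
  out
}

#' @export
print.pwi_posterior <- function(x, ...) {
  cat("Hierarchical Bayesian split-plot posterior\n")
  cat(sprintf("  %d retained draws (%d chain%s), %d participants, %d conditions\n",
              x$n_draws, x$mcmc$n_chains, if (x$mcmc$n_chains > 1) "s" else "",
              nrow(x$subjects), length(x$conditions)))
  cat(sprintf("  sigma: %.1f ms   nu: %.1f%s\n", mean(x$sigma), mean(x$nu),
              if (mean(x$nu) < 10) " (heavy tails)" else ""))
  if (!is.na(x$diagnostics$max_rhat)) {
    cat(sprintf("  max split R-hat: %.3f   min ESS: %.0f%s\n",
                x$diagnostics$max_rhat, x$diagnostics$min_ess,
                if (!x$converged) "  ** convergence warning **" else ""))
  }
  invisible(x)
}
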