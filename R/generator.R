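# Synthetic trial-level data with known ground truth.
#
# Correct-response latencies are drawn from a shifted lognormal located so that
# the *median* of the trial distribution equals the configured cell location:
#   rt = shift + (location - shift) * exp(sigma * Z),   Z ~ N(0, 1)
# Since median(exp(sigma * Z)) = 1, median(rt) = location exactly, which makes
# effect injection additive on the median scale.

#' Configure the synthetic picture-word interference generator
#'
#' All locations are medians of the trial-level RT distribution in ms. Effects
#' are additive shifts relative to the group's neutral-condition location, so
#' the configured effect map is exactly the ground truth that downstream
#' median-based estimates should recover.
#'
#' @param n_controls,n_patients Participants per group (`n_controls >= 2`, so
#'   that standardized scores have a control SD).
#' @param control_baseline_ms Location (median) of the control group's
#'   neutral-condition RT distribution.
#' @param patient_slowing_ms Additive location shift applied to all patient
#'   conditions.
#' @param effect_ms Named list with elements `control` and `patient`, each a
#'   named numeric vector giving, for every condition in the design, the
#'   additive shift relative to that group's neutral location.
#' @param rt_noise List describing the right-skewed latency family:
#'   `family` (only `"shifted_lognormal"` is built in), `shift_ms` (lower
#'   bound of the support), and `sigma`, a named vector of lognormal shape
#'   parameters per group.
#' @param participant_sd Named vector, per group, of the SD (ms) of stable
#'   between-participant offsets added to all of a participant's locations.
#' @param error_rate,voicekey_fail_rate,fast_guess_rate Named per-group rates
#'   in \[0, 1\]: probability a trial is a (disfluent/incorrect) error, a
#'   voice-key trigger failure (no usable RT), or an artifactual fast guess
#'   (RT below 200 ms).
#' @param seed Integer seed; the same configuration and seed reproduce the
#'   dataset bit-for-bit.
#'
#' @return An object of class `pwi_config` (a validated list).
#' @seealso [paper_like_config()] for the calibrated default preset,
#'   [simulate_trials()] to generate data.
#' @export
generator_config <- function(n_controls = 13,
                             n_patients = 6,
                             control_baseline_ms = 750,
                             patient_slowing_ms = 400,
                             effect_ms = list(
                               control = c(neutral = 0, unrelated = 80,
                                           related = 126, phonological = 62),
                               patient = c(neutral = 0, unrelated = 332,
                                           related = 407, phonological = 160)),
                             rt_noise = list(family = "shifted_lognormal",
                                             shift_ms = 250,
                                             sigma = c(control = 0.2,
                                                       patient = 0.45)),
                             participant_sd = c(control = 100, patient = 200),
                             error_rate = c(control = 0.02, patient = 0.03),
                             voicekey_fail_rate = c(control = 0.03,
                                                    patient = 0.053),
                             fast_guess_rate = c(control = 0.001,
                                                 patient = 0.001),
                             seed = 1L) {
  cfg <- list(n_controls = as.integer(n_controls),
              n_patients = as.integer(n_patients),
              control_baseline_ms = control_baseline_ms,
              patient_slowing_ms = patient_slowing_ms,
              effect_ms = effect_ms,
              rt_noise = rt_noise,
              participant_sd = participant_sd,
              error_rate = error_rate,
              voicekey_fail_rate = voicekey_fail_rate,
              fast_guess_rate = fast_guess_rate,
              seed = as.integer(seed))
  class(cfg) <- "pwi_config"
  validate_config(cfg)
  cfg
}

#' Paper-like generator preset
#'
#' The calibrated fixture emulating the published study conditions: 13
#' controls and 6 left-PFC patients, 22 items x 4 conditions, control neutral
#' location 750 ms, patient slowing 400 ms, control distractor effects of
#' (lexical 80, semantic 46, phonological -18) ms and patient effects of
#' (332, 75, -172) ms, right-skewed trial noise, and realistic error,
#' voice-key-failure and fast-guess rates. Used as a realistic test fixture;
#' it makes no claim about the patients' actual data.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed on to [generator_config()].
#' @return A `pwi_config`.
#' @export
paper_like_config <- function(seed = 1L, ...) {
  generator_config(seed = seed, ...)
}

validate_config <- function(cfg) {
  grp <- c("control", "patient")
  rate_of <- function(x, what) {
    x <- unlist(x)
    if (!all(grp %in% names(x))) {
      stop(sprintf("`%s` must be named for groups %s", what,
                   paste(grp, collapse = ", ")))
    }
    if (any(x < 0 | x > 1)) stop(sprintf("`%s` must lie in [0, 1]", what))
    x[grp]
  }
  cfg$error_rate <- rate_of(cfg$error_rate, "error_rate")
  cfg$voicekey_fail_rate <- rate_of(cfg$voicekey_fail_rate, "voicekey_fail_rate")
  cfg$fast_guess_rate <- rate_of(cfg$fast_guess_rate, "fast_guess_rate")
  if (cfg$n_controls < 2) stop("`n_controls` must be >= 2 (control SD needed)")
  if (cfg$n_patients < 1) stop("`n_patients` must be >= 1")
  if (cfg$control_baseline_ms <= 200) stop("RT locations must exceed 200 ms")
  if (cfg$control_baseline_ms + cfg$patient_slowing_ms <= 200) {
    stop("patient baseline location must exceed 200 ms")
  }
  if (!all(grp %in% names(cfg$effect_ms))) {
    stop("`effect_ms` must have elements 'control' and 'patient'")
  }
  if (!identical(cfg$rt_noise$family, "shifted_lognormal")) {
    stop("unsupported rt_noise family: ", cfg$rt_noise$family)
  }
  if (!all(grp %in% names(cfg$rt_noise$sigma))) {
    stop("`rt_noise$sigma` must be named per group")
  }
  if (cfg$rt_noise$shift_ms < 0) stop("`rt_noise$shift_ms` must be >= 0")
  if (!all(grp %in% names(cfg$participant_sd))) {
    stop("`participant_sd` must be named per group")
  }
  invisible(cfg)
}

#' Ground-truth cell locations of a configuration
#'
#' @param cfg A `pwi_config`.
#' @param design A `pwi_design`.
#' @return data.frame with `group`, `condition` and `location_ms`, the true
#'   median RT of each group x condition cell (before participant offsets).
#' @export
true_cell_locations <- function(cfg, design = build_design()) {
  out <- expand.grid(group = c("control", "patient"),
                     condition = design$conditions,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  base <- ifelse(out$group == "control", cfg$control_baseline_ms,
                 cfg$control_baseline_ms + cfg$patient_slowing_ms)
  eff <- mapply(function(g, cond) {
    e <- cfg$effect_ms[[g]]
    if (!cond %in% names(e)) {
      stop(sprintf("effect_ms missing entry for (%s, %s)", g, cond))
    }
    e[[cond]]
  }, out$group, out$condition)
  out$location_ms <- base + eff
  out
}

#' Simulate a trial-level picture-word interference dataset
#'
#' Generates one record per design trial per participant. Correct and error
#' trials carry a latency drawn from the configured shifted-lognormal family
#' located at the group baseline plus the condition effect plus a stable
#' participant offset; voice-key failures carry no RT; fast guesses are
#' correct-status trials with an artifactual RT below 200 ms. Trial order is
#' shuffled per participant (the analysis is order-insensitive).
#'
#' @param cfg A `pwi_config` from [generator_config()].
#' @param design A `pwi_design` from [build_design()].
#' @return data.frame with columns `participant_id`, `group`, `item_id`,
#'   `condition`, `rt_ms` (NA for voice-key failures) and `status`
#'   (`correct`, `error` or `voicekey_fail`), with attributes `truth` (the
#'   [true_cell_locations()] table), `participant_offsets` and `config`.
#' @export
simulate_trials <- function(cfg, design = build_design()) {
  stopifnot(inherits(cfg, "pwi_config"), inherits(design, "pwi_design"))
  validate_config(cfg)
  truth <- true_cell_locations(cfg, design)  # errors if effect_ms incomplete
  loc_of <- function(g, cond) {
    truth$location_ms[truth$group == g & truth$condition == cond]
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(cfg$seed)

  n <- c(control = cfg$n_controls, patient = cfg$n_patients)
  ids <- c(sprintf("C%02d", seq_len(cfg$n_controls)),
           sprintf("P%02d", seq_len(cfg$n_patients)))
  groups <- rep(c("control", "patient"), times = n)
  offsets <- stats::rnorm(length(ids), 0, cfg$participant_sd[groups])
  names(offsets) <- ids

  shift <- cfg$rt_noise$shift_ms
  per_part <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    g <- groups[i]
    tr <- design$trials[sample.int(design$n_trials), , drop = FALSE]
    m <- design$n_trials
    # one categorical draw per trial: error > voicekey > fast > correct
    u <- stats::runif(m)
    p_e <- cfg$error_rate[[g]]
    p_v <- cfg$voicekey_fail_rate[[g]]
    p_f <- cfg$fast_guess_rate[[g]]
    status <- ifelse(u < p_e, "error",
                     ifelse(u < p_e + p_v, "voicekey_fail", "correct"))
    fast <- status == "correct" & u >= p_e + p_v & u < p_e + p_v + p_f
    loc <- vapply(tr$condition, loc_of, numeric(1), g = g) + offsets[i]
    scale <- pmax(loc - shift, 1)
    rt <- shift + scale * exp(cfg$rt_noise$sigma[[g]] * stats::rnorm(m))
    rt[fast] <- stats::runif(sum(fast), 80, 199)
    rt[status == "voicekey_fail"] <- NA_real_
    per_part[[i]] <- data.frame(participant_id = ids[i], group = g,
                                item_id = tr$item_id,
                                condition = tr$condition,
                                rt_ms = round(rt, 1), status = status,
                                stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, per_part)
  rownames(out) <- NULL
  attr(out, "truth") <- truth
  attr(out, "participant_offsets") <- offsets
  attr(out, "config") <- cfg
  out
}

#' Write / read a trial table as tidy CSV
#'
#' Header `participant_id,group,item_id,condition,rt_ms,status`; a missing RT
#' (voice-key failure) is encoded as an empty field. Identical data produce a
#' byte-identical file.
#'
#' @param trials data.frame as returned by [simulate_trials()].
#' @param path File path.
#' @return `write_trials()` returns `path` invisibly; `read_trials()` returns
#'   the trial data.frame.
#' @export
write_trials <- function(trials, path) {
  cols <- c("participant_id", "group", "item_id", "condition", "rt_ms", "status")
  stopifnot(all(cols %in% names(trials)))
  utils::write.csv(trials[, cols], path, row.names = FALSE, na = "",
                   quote = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(participant_id = "character",
                                        group = "character",
                                        item_id = "character",
                                        condition = "character",
                                        rt_ms = "numeric",
                                        status = "character"))
  out
}

#' Read a generator configuration from a YAML file
#'
#' The file may specify any subset of [generator_config()]'s arguments; the
#' remainder take the paper-like defaults.
#'
#' @param path Path to a YAML file.
#' @param seed Optional seed overriding the file's `seed` entry.
#' @return A `pwi_config`.
#' @export
read_generator_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  for (nm in c("effect_ms", "rt_noise")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- rapply(raw[[nm]], unlist, how = "replace")
  }
  for (nm in c("participant_sd", "error_rate", "voicekey_fail_rate",
               "fast_guess_rate")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  if (!is.null(raw$effect_ms)) {
    raw$effect_ms <- lapply(raw$effect_ms, unlist)
  }
  if (!is.null(seed)) raw$seed <- seed
  do.call(generator_config, raw)
}
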