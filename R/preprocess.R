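# Exclusion rules, condition medians, distractor effects, standardized scores
# and the general-slowing ratio correction.

#' Apply trial exclusion rules
#'
#' Removes error trials, voice-key trigger failures, and artifactual fast
#' responses (RT below `min_rt_ms`). Each removed trial is counted once, with
#' precedence error > voice-key failure > fast, so the report partitions the
#' input exactly. Applying the function to its own output changes nothing.
#'
#' @param trials Trial-level data.frame (see [simulate_trials()] /
#'   [read_trials()]).
#' @param min_rt_ms Lower RT bound in ms for a usable trial (default 200).
#' @return A list with `retained` (correct trials with `rt_ms >= min_rt_ms`)
#'   and `report`, an object of class `pwi_exclusions`: a data.frame with one
#'   row per group plus an `overall` row, giving counts and percentages of
#'   each exclusion class.
#' @export
exclude_trials <- function(trials, min_rt_ms = 200) {
  if (min_rt_ms <= 0) stop("`min_rt_ms` must be positive")
  if (nrow(trials) == 0) {
    rep0 <- exclusion_counts(trials["group"], logical(0), logical(0), logical(0))
    return(list(retained = trials, report = rep0))
  }
  is_error <- trials$status == "error"
  is_vk <- !is_error & trials$status == "voicekey_fail"
  is_fast <- !is_error & !is_vk & (is.na(trials$rt_ms) | trials$rt_ms < min_rt_ms)
  retained <- trials[!(is_error | is_vk | is_fast), , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained,
       report = exclusion_counts(trials, is_error, is_vk, is_fast))
}

exclusion_counts <- function(trials, is_error, is_vk, is_fast) {
  tab <- function(idx, label) {
    n_total <- sum(idx)
    n_err <- sum(is_error[idx]); n_vk <- sum(is_vk[idx]); n_fast <- sum(is_fast[idx])
    data.frame(group = label, n_total = n_total, n_errors = n_err,
               n_voicekey = n_vk, n_fast = n_fast,
               n_retained = n_total - n_err - n_vk - n_fast,
               pct_errors = pct(n_err, n_total),
               pct_voicekey = pct(n_vk, n_total),
               pct_fast = pct(n_fast, n_total),
               stringsAsFactors = FALSE)
  }
  groups <- unique(trials$group)
  out <- do.call(rbind, c(lapply(groups, function(g) tab(trials$group == g, g)),
                          list(tab(rep(TRUE, nrow(trials)), "overall"))))
  rownames(out) <- NULL
  class(out) <- c("pwi_exclusions", "data.frame")
  out
}

pct <- function(k, n) if (n > 0) 100 * k / n else 0

#' Per-participant condition medians
#'
#' The unit of all downstream inference: for each participant, the median of
#' the retained RTs in each distractor condition (the median being the robust
#' summary of choice for right-skewed latencies). Even-count cells use the
#' mean of the two central order statistics. An empty cell yields `NA`.
#'
#' @param retained Retained trials from [exclude_trials()].
#' @param conditions Permitted condition labels; rows with labels outside this
#'   set are rejected.
#' @return An object of class `pwi_medians`: a data.frame with
#'   `participant_id`, `group`, and one column of median RTs per condition.
#' @export
condition_medians <- function(retained, conditions = pwi_conditions()) {
  bad <- setdiff(unique(retained$condition), conditions)
  if (length(bad) > 0) {
    stop("unknown condition label(s): ", paste(bad, collapse = ", "))
  }
  parts <- unique(retained[, c("participant_id", "group")])
  parts <- parts[order(parts$group, parts$participant_id), , drop = FALSE]
  med <- function(pid, cond) {
    x <- retained$rt_ms[retained$participant_id == pid &
                          retained$condition == cond]
    x <- x[!is.na(x)]
    if (length(x) == 0) NA_real_ else stats::median(x)
  }
  for (cond in conditions) {
    parts[[cond]] <- vapply(parts$participant_id, med, numeric(1), cond = cond)
  }
  rownames(parts) <- NULL
  class(parts) <- c("pwi_medians", "data.frame")
  attr(parts, "conditions") <- conditions
  parts
}

medians_long <- function(medians, conditions = attr(medians, "conditions")) {
  long <- stats::reshape(as.data.frame(medians),
                         varying = conditions, v.names = "median_rt",
                         timevar = "condition", times = conditions,
                         direction = "long")
  long <- long[!is.na(long$median_rt),
               c("participant_id", "group", "condition", "median_rt")]
  rownames(long) <- NULL
  long
}

#' Distractor-effect scores per participant
#'
#' The three contrasts of interest, signed so that interference is positive
#' and facilitation negative:
#' lexical interference = unrelated - neutral; semantic interference =
#' related - unrelated; phonological facilitation = phonological - unrelated.
#' A missing condition median propagates to `NA` (no imputation).
#'
#' @param medians A `pwi_medians` table containing the four standard
#'   conditions.
#' @return data.frame with `participant_id`, `group`, `lexical_ms`,
#'   `semantic_ms`, `phonological_ms`.
#' @export
compute_effects <- function(medians) {
  need <- pwi_conditions()
  if (!all(need %in% names(medians))) {
    stop("medians table must contain columns: ", paste(need, collapse = ", "))
  }
  data.frame(participant_id = medians$participant_id,
             group = medians$group,
             lexical_ms = medians$unrelated - medians$neutral,
             semantic_ms = medians$related - medians$unrelated,
             phonological_ms = medians$phonological - medians$unrelated,
             stringsAsFactors = FALSE)
}

#' Single-case standardized scores against the control sample
#'
#' Each effect is expressed in SD units relative to the control group's mean
#' and sample SD (n-1 denominator); 2 SDs approximate the 95th percentile, so
#' scores beyond +/- 2 flag individually atypical effects. Controls are
#' standardized against their own group, so their z-scores have sample mean 0
#' and SD 1 by construction.
#'
#' @param effects Effect table from [compute_effects()].
#' @param flag_sd Flag threshold in SD units (default 2).
#' @return The input with added columns `z_lexical`, `z_semantic`,
#'   `z_phonological` and logical flags `beyond_lexical`, `beyond_semantic`,
#'   `beyond_phonological`. If a control SD is zero the corresponding z-scores
#'   are `NA` (undefined).
#' @export
standardized_scores <- function(effects, flag_sd = 2) {
  ctrl <- effects[effects$group == "control", , drop = FALSE]
  if (sum(!is.na(ctrl$lexical_ms)) < 2) {
    stop("need at least 2 controls with non-missing effects")
  }
  out <- effects
  for (eff in c("lexical", "semantic", "phonological")) {
    col <- paste0(eff, "_ms")
    m <- mean(ctrl[[col]], na.rm = TRUE)
    s <- stats::sd(ctrl[[col]], na.rm = TRUE)
    z <- if (is.na(s) || s == 0) rep(NA_real_, nrow(out)) else (out[[col]] - m) / s
    out[[paste0("z_", eff)]] <- z
    out[[paste0("beyond_", eff)]] <- !is.na(z) & abs(z) > flag_sd
  }
  out
}

#' General-slowing RT ratios
#'
#' Divides each distractor effect by the participant's unrelated-condition
#' median, the condition common to all three effects. A purely multiplicative
#' group slowing cancels in these dimensionless ratios, so residual group
#' differences in the ratios cannot be explained by general slowing alone.
#'
#' @param medians A `pwi_medians` table with the four standard conditions.
#' @return data.frame with `participant_id`, `group`, `ratio_lexical`,
#'   `ratio_semantic`, `ratio_phonological`. All ratios are `NA` when the
#'   unrelated median is missing or non-positive.
#' @export
rt_ratios <- function(medians) {
  eff <- compute_effects(medians)
  denom <- medians$unrelated
  denom[!is.na(denom) & denom <= 0] <- NA_real_
  data.frame(participant_id = eff$participant_id,
             group = eff$group,
             ratio_lexical = eff$lexical_ms / denom,
             ratio_semantic = eff$semantic_ms / denom,
             ratio_phonological = eff$phonological_ms / denom,
             stringsAsFactors = FALSE)
}
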