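# Posterior contrasts over the group x condition cell means, with HDI-based
# decisions.

#' Posterior contrast of cell means
#'
#' Forms the posterior distribution of a linear combination of the
#' group-by-condition cell means and summarizes it with its mean, the
#' highest-density interval, the posterior mass on each side of zero, and a
#' decision: `credible_positive` iff the HDI lies entirely above 0,
#' `credible_negative` iff entirely below 0, otherwise
#' `credibly_null_candidate` (the HDI includes 0; whether that constitutes
#' evidence *for* a null effect depends on the HDI being narrow, reported via
#' `narrow_hdi`).
#'
#' @param post A `pwi_posterior` from [fit_splitplot()].
#' @param coef Named numeric vector of coefficients over the cells (names
#'   `"group:condition"` as in [cell_means()]); unnamed cells get 0. Must not
#'   be all zero.
#' @param name Label for the contrast.
#' @param mass HDI mass (default 0.95).
#' @param narrow_ms Half-width (ms) under which an HDI including zero is
#'   annotated as narrow.
#' @return An object of class `pwi_contrast`: a list with `name`, `draws`,
#'   `mean`, `hdi_low`, `hdi_high`, `pct_above_zero`, `pct_below_zero`,
#'   `pct_at_zero`, `decision`, `narrow_hdi` and `degenerate` (all draws
#'   identical, e.g. a cell contrasted with itself).
#' @export
contrast <- function(post, coef, name = "contrast", mass = 0.95,
                     narrow_ms = 25) {
  cm <- cell_means(post)
  bad <- setdiff(names(coef), colnames(cm))
  if (length(bad) > 0) stop("unknown cell(s): ", paste(bad, collapse = ", "))
  if (all(coef == 0)) stop("contrast coefficients are all zero")
  # duplicate names are allowed (a cell contrasted with itself is degenerate)
  draws <- drop(cm[, names(coef), drop = FALSE] %*% coef)
  degenerate <- max(draws) == min(draws)
  h <- if (degenerate) c(low = draws[1], high = draws[1]) else hdi(draws, mass)
  pct_above <- 100 * mean(draws > 0)
  pct_below <- 100 * mean(draws < 0)
  decision <- if (h["low"] > 0) {
    "credible_positive"
  } else if (h["high"] < 0) {
    "credible_negative"
  } else {
    "credibly_null_candidate"
  }
  structure(list(name = name, draws = draws, mean = mean(draws),
                 hdi_low = unname(h["low"]), hdi_high = unname(h["high"]),
                 pct_above_zero = pct_above, pct_below_zero = pct_below,
                 pct_at_zero = 100 - pct_above - pct_below,
                 mass = mass, decision = decision,
                 narrow_hdi = (h["high"] - h["low"]) / 2 < narrow_ms,
                 degenerate = degenerate),
            class = "pwi_contrast")
}

#' @export
print.pwi_contrast <- function(x, ...) {
  cat(sprintf("%s: mean %.1f ms, %.0f%% HDI [%.1f, %.1f], %s%s\n",
              x$name, x$mean, 100 * x$mass, x$hdi_low, x$hdi_high,
              x$decision,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

cells_of <- function(group, condition) paste(group, condition, sep = ":")

#' The standard distractor-effect contrasts
#'
#' The seven contrasts of interest in the patient-control design:
#' \describe{
#'   \item{group_main}{patient - control, averaged over conditions (positive =
#'     patients slower).}
#'   \item{control_lexical / patient_lexical}{unrelated - neutral per group
#'     (positive = lexical interference).}
#'   \item{control_semantic / patient_semantic}{related - unrelated (positive
#'     = semantic interference).}
#'   \item{control_phonological / patient_phonological}{phonological -
#'     unrelated (negative = phonological facilitation).}
#'   \item{diff_lexical / diff_semantic / diff_phonological}{control effect -
#'     patient effect: values below zero mean a larger interference effect
#'     (decreased performance) in patients; values above zero for the
#'     phonological contrast mean larger facilitation in patients.}
#' }
#'
#' @param post A `pwi_posterior` with groups `control` and `patient` and the
#'   four standard conditions.
#' @param mass HDI mass.
#' @return A named list of `pwi_contrast` objects, with class
#'   `pwi_contrast_set`; `as.data.frame()` yields the summary table.
#' @export
standard_contrasts <- function(post, mass = 0.95) {
  stopifnot(all(c("control", "patient") %in% post$groups),
            all(pwi_conditions() %in% post$conditions))
  nd <- length(post$conditions)
  eff_coef <- function(grp, plus, minus) {
    stats::setNames(c(1, -1), cells_of(grp, c(plus, minus)))
  }
  diff_coef <- function(plus, minus) {
    c(eff_coef("control", plus, minus), -eff_coef("patient", plus, minus))
  }
  specs <- list(
    group_main = stats::setNames(
      c(rep(1 / nd, nd), rep(-1 / nd, nd)),
      c(cells_of("patient", post$conditions),
        cells_of("control", post$conditions))),
    control_lexical = eff_coef("control", "unrelated", "neutral"),
    control_semantic = eff_coef("control", "related", "unrelated"),
    control_phonological = eff_coef("control", "phonological", "unrelated"),
    patient_lexical = eff_coef("patient", "unrelated", "neutral"),
    patient_semantic = eff_coef("patient", "related", "unrelated"),
    patient_phonological = eff_coef("patient", "phonological", "unrelated"),
    diff_lexical = diff_coef("unrelated", "neutral"),
    diff_semantic = diff_coef("related", "unrelated"),
    diff_phonological = diff_coef("phonological", "unrelated")
  )
  out <- lapply(names(specs), function(nm) contrast(post, specs[[nm]], nm, mass))
  names(out) <- names(specs)
  class(out) <- "pwi_contrast_set"
  out
}

#' @export
as.data.frame.pwi_contrast_set <- function(x, ...) {
  out <- do.call(rbind, lapply(x, function(cc) {
    data.frame(name = cc$name, mean = cc$mean, hdi_low = cc$hdi_low,
               hdi_high = cc$hdi_high, pct_above_zero = cc$pct_above_zero,
               pct_below_zero = cc$pct_below_zero, decision = cc$decision,
               narrow_hdi = cc$narrow_hdi, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.pwi_contrast_set <- function(x, ...) {
  df <- as.data.frame(x)
  df$mean <- sprintf("%.1f", df$mean)
  df$hdi <- sprintf("[%.1f, %.1f]", df$hdi_low, df$hdi_high)
  df$`%>0` <- sprintf("%.1f", df$pct_above_zero)
  df$`%<0` <- sprintf("%.1f", df$pct_below_zero)
  print(df[, c("name", "mean", "hdi", "%>0", "%<0", "decision")],
        row.names = FALSE)
  invisible(x)
}
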