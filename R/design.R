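#' Standard distractor conditions
#'
#' The four distractor conditions of the picture-word interference task, in
#' canonical order: a neutral string of Xs, an unrelated word, a semantically
#' related word, and a phonologically related word.
#'
#' @export
pwi_conditions <- function() {
  c("neutral", "unrelated", "related", "phonological")
}

#' Build a picture-word interference design
#'
#' Constructs the full factorial trial list for one participant: every picture
#' (item) is presented once with each distractor condition. The default
#' corresponds to the classic design of 22 pictures crossed with 4 distractor
#' conditions, i.e. 88 experimental trials per participant, preceded by a
#' short practice block that is never analyzed.
#'
#' @param n_items Number of distinct pictures (>= 1).
#' @param conditions Character vector of distractor condition labels
#'   (>= 2 distinct labels).
#' @param n_practice Number of practice trials (recorded in the design for
#'   completeness; practice trials are excluded from analysis and are not
#'   generated by [simulate_trials()]).
#' @param presentations_per_item_condition Number of times each item appears
#'   in each condition (fixed at 1 in the classic design).
#'
#' @return An object of class `pwi_design`: a list with elements `n_items`,
#'   `conditions`, `n_practice`, `presentations_per_item_condition`,
#'   `n_trials` (trials per participant) and `trials`, a data.frame with one
#'   row per experimental trial (`item_id`, `condition`).
#' @examples
#' d <- build_design()
#' d$n_trials  # 88
#' @export
build_design <- function(n_items = 22, conditions = pwi_conditions(),
                         n_practice = 7, presentations_per_item_condition = 1) {
  if (!is.numeric(n_items) || length(n_items) != 1 || n_items < 1 ||
      n_items != round(n_items)) {
    stop("`n_items` must be a single integer >= 1")
  }
  conditions <- as.character(conditions)
  if (length(conditions) < 2) stop("need at least 2 distractor conditions")
  if (anyDuplicated(conditions)) {
    stop("duplicate condition labels: ",
         paste(unique(conditions[duplicated(conditions)]), collapse = ", "))
  }
  if (presentations_per_item_condition != 1) {
    stop("`presentations_per_item_condition` is fixed at 1 in this design")
  }
  items <- sprintf("item%02d", seq_len(n_items))
  trials <- expand.grid(item_id = items, condition = conditions,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  structure(
    list(n_items = as.integer(n_items),
         conditions = conditions,
         n_practice = as.integer(n_practice),
         presentations_per_item_condition = 1L,
         n_trials = nrow(trials),
         trials = trials),
    class = "pwi_design"
  )
}

#' @export
print.pwi_design <- function(x, ...) {
  cat("Picture-word interference design\n")
  cat("  items:     ", x$n_items, "\n")
  cat("  conditions:", paste(x$conditions, collapse = ", "), "\n")
  cat("  trials per participant:", x$n_trials,
      sprintf("(+ %d practice, not analyzed)\n", x$n_practice))
  invisible(x)
}
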