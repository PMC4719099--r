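make_trials <- function(rt, status, group = "control",
                        condition = "neutral") {
  n <- length(rt)
  data.frame(participant_id = rep("C01", n), group = rep(group, n),
             item_id = sprintf("item%02d", seq_len(n)),
             condition = rep(condition, length.out = n),
             rt_ms = rt, status = status, stringsAsFactors = FALSE)
}

test_that("exclusion rules remove errors, voice-key failures and fast trials", {
  tr <- make_trials(c(450, 500, NA, 150, 900),
                    c("correct", "error", "voicekey_fail", "correct", "correct"))
  out <- exclude_trials(tr)
  expect_equal(sort(out$retained$rt_ms), c(450, 900))
  ov <- out$report[out$report$group == "overall", ]
  expect_equal(ov$n_errors, 1)
  expect_equal(ov$n_voicekey, 1)
  expect_equal(ov$n_fast, 1)
  expect_equal(ov$n_retained, 2)
  expect_equal(ov$n_total, ov$n_retained + ov$n_errors + ov$n_voicekey + ov$n_fast)
})

test_that("all-correct input passes through unchanged, empty input is not an error", {
  tr <- make_trials(c(300, 400, 500), rep("correct", 3))
  out <- exclude_trials(tr)
  expect_equal(out$retained$rt_ms, tr$rt_ms)
  ov <- out$report[out$report$group == "overall", ]
  expect_equal(ov$n_retained, 3)

  empty <- exclude_trials(tr[0, ])
  expect_equal(nrow(empty$retained), 0)
  expect_equal(empty$report$n_total[empty$report$group == "overall"], 0)
})

test_that("exclusion is idempotent", {
  tr <- simulate_trials(paper_like_config(seed = 21))
  once <- exclude_trials(tr)
  twice <- exclude_trials(once$retained)
  expect_equal(nrow(twice$retained), nrow(once$retained))
  ov <- twice$report[twice$report$group == "overall", ]
  expect_equal(ov$n_errors + ov$n_voicekey + ov$n_fast, 0)
})

test_that("reported exclusion percentages recover the configured rates", {
  cfg <- paper_like_config(
    seed = 31,
    error_rate = c(control = 0.02, patient = 0.02),
    voicekey_fail_rate = c(control = 0.04, patient = 0.04),
    fast_guess_rate = c(control = 0.005, patient = 0.005))
  rep <- exclude_trials(simulate_trials(cfg))$report
  ov <- rep[rep$group == "overall", ]  # n = 88 * 19 trials
  expect_lt(abs(ov$pct_errors - 2), 1.5)
  expect_lt(abs(ov$pct_voicekey - 4), 1.5)
  expect_lt(abs(ov$pct_fast - 0.5), 1.5)
})

test_that("condition medians follow the order-statistic conventions", {
  tr <- make_trials(c(400, 600, 500), rep("correct", 3))
  m <- condition_medians(tr)
  expect_equal(m$neutral, 500)

  tr2 <- make_trials(c(400, 600), rep("correct", 2))
  expect_equal(condition_medians(tr2)$neutral, 500)  # even-count convention

  expect_error(condition_medians(make_trials(500, "correct",
                                             condition = "identity")),
               "unknown condition")
  # empty cell -> explicit NA, median within range of retained RTs
  m3 <- condition_medians(make_trials(c(400, 600, 500), rep("correct", 3)))
  expect_true(is.na(m3$unrelated))
  expect_true(m3$neutral >= 400 && m3$neutral <= 600)
})

test_that("sample medians converge to the analytic median of the RT family", {
  # the shifted lognormal is parameterized so its median equals the configured
  # location: 750 ms for the control neutral condition
  cfg <- clean_config(seed = 41, n_controls = 2, n_patients = 1,
                      effect_ms = list(control = c(neutral = 0, unrelated = 0),
                                       patient = c(neutral = 0, unrelated = 0)))
  des <- build_design(n_items = 500, conditions = c("neutral", "unrelated"))
  tr <- simulate_trials(cfg, des)
  x <- tr$rt_ms[tr$participant_id == "C01"]  # 1,000 draws at location 750
  expect_lt(abs(median(x) - 750) / 750, 0.02)
})

test_that("distractor effects follow the interference/facilitation sign convention", {
  m <- tiny_medians()[1, ]
  m$neutral <- 800; m$unrelated <- 880; m$related <- 920; m$phonological <- 850
  eff <- compute_effects(m)
  expect_equal(eff$lexical_ms, 80)
  expect_equal(eff$semantic_ms, 40)
  expect_equal(eff$phonological_ms, -30)

  m$unrelated <- m$related <- m$phonological <- m$neutral
  expect_equal(unlist(compute_effects(m)[, c("lexical_ms", "semantic_ms",
                                             "phonological_ms")],
                      use.names = FALSE), c(0, 0, 0))

  m$related <- NA
  eff2 <- compute_effects(m)
  expect_true(is.na(eff2$semantic_ms))
  expect_false(is.na(eff2$lexical_ms))  # missing cells do not leak
})

test_that("effects are translation-invariant and ratios scale-invariant", {
  med <- paper_like_medians(seed = 51)
  shifted <- med
  shifted[, pwi_conditions()] <- shifted[, pwi_conditions()] + 123.4
  expect_equal(compute_effects(shifted)[, -(1:2)],
               compute_effects(med)[, -(1:2)])

  scaled <- med
  scaled[, pwi_conditions()] <- scaled[, pwi_conditions()] * 1.7
  expect_equal(rt_ratios(scaled)[, -(1:2)], rt_ratios(med)[, -(1:2)])
})

test_that("standardized scores flag effects beyond 2 control SDs", {
  eff <- data.frame(
    participant_id = c(sprintf("C%02d", 1:3), "P01"),
    group = c(rep("control", 3), "patient"),
    lexical_ms = c(70, 80, 90, 332),   # control mean 80, sd 10
    semantic_ms = c(36, 46, 56, 46),   # patient z = 0
    phonological_ms = c(-28, -18, -8, -172),
    stringsAsFactors = FALSE)
  sc <- standardized_scores(eff)
  p <- sc[sc$group == "patient", ]
  expect_equal(p$z_lexical, 25.2)
  expect_true(p$beyond_lexical)
  expect_equal(p$z_semantic, 0)
  expect_false(p$beyond_semantic)
  expect_true(p$beyond_phonological)

  # controls standardized against their own group: mean 0, sd 1
  cz <- sc$z_lexical[sc$group == "control"]
  expect_equal(mean(cz), 0)
  expect_equal(sd(cz), 1)

  eff$lexical_ms[1:3] <- 80  # zero control SD -> undefined scores
  sc2 <- standardized_scores(eff)
  expect_true(all(is.na(sc2$z_lexical)))
})

test_that("patients far outside the control distribution are reliably flagged", {
  flagged <- vapply(1:10, function(i) {
    med <- paper_like_medians(seed = 60 + i)
    sc <- standardized_scores(compute_effects(med))
    mean(sc$beyond_lexical[sc$group == "patient"])
  }, numeric(1))
  # patient lexical truth (332 ms) is ~ 7 control SDs above the control truth
  expect_gt(mean(flagged), 0.5)
})

test_that("RT ratios divide each effect by the unrelated median", {
  m <- tiny_medians()[1, ]
  m$neutral <- 800; m$unrelated <- 880; m$related <- 920; m$phonological <- 850
  r <- rt_ratios(m)
  expect_equal(r$ratio_lexical, 80 / 880)
  expect_equal(r$ratio_semantic, 40 / 880)
  expect_equal(r$ratio_phonological, -30 / 880)

  m$unrelated <- NA
  expect_true(all(is.na(rt_ratios(m)[, -(1:2)])))
})

test_that("ratios cancel a purely multiplicative group slowing", {
  # patients = 1.5 x controls everywhere: ratio distributions coincide
  base <- c(neutral = 0, unrelated = 80, related = 126, phonological = 62)
  cfg <- clean_config(
    seed = 71, n_controls = 40, n_patients = 40,
    control_baseline_ms = 750, patient_slowing_ms = 375,
    effect_ms = list(control = base, patient = 1.5 * base))
  r <- rt_ratios(condition_medians(exclude_trials(simulate_trials(cfg))$retained))
  by_grp <- aggregate(r[, -(1:2)], by = list(group = r$group), mean)
  gap <- abs(by_grp[1, -1] - by_grp[2, -1])
  expect_true(all(gap < 0.03))
})
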