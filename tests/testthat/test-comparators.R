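test_that("identical groups give a null group effect", {
  med <- tiny_medians()
  med[med$group == "patient", pwi_conditions()] <-
    med[med$group == "control", pwi_conditions()]
  a <- splitplot_anova(med)
  g <- a[a$term == "group", ]
  expect_lt(g$F, 1e-6)
  expect_gt(g$p, 0.999)
})

test_that("split-plot F ratios match the independent sums-of-squares oracle", {
  med <- tiny_medians()
  a <- splitplot_anova(med)
  o <- splitplot_ss_oracle(med, pwi_conditions())
  expect_equal(a$F[a$term == "group"], o$F_group, tolerance = 1e-10)
  expect_equal(a$F[a$term == "condition"], o$F_cond, tolerance = 1e-10)
  expect_equal(a$F[a$term == "group:condition"], o$F_inter, tolerance = 1e-10)
  expect_equal(a$df1, c(1, 3, 3))
  expect_equal(a$df2, unname(c(o$df["subj"], o$df["resid"], o$df["resid"])))
})

test_that("sums of squares partition total variability exactly", {
  for (seed in c(3, 14)) {
    med <- paper_like_medians(seed = seed)
    a <- splitplot_anova(med)
    strata <- attr(a, "strata")
    ss_all <- sum(strata$between[, "Sum Sq"]) + sum(strata$within[, "Sum Sq"])
    y <- as.matrix(med[, pwi_conditions()])
    expect_equal(ss_all, sum((y - mean(y))^2), tolerance = 1e-10)
    # split-plot df decomposition: distractor tested on 3 and 3(N-2) df
    n <- nrow(med)
    expect_equal(a$df2[a$term == "condition"], 3 * (n - 2))
    expect_equal(a$df2[a$term == "group"], n - 2)
  }
})

test_that("participants with missing cells are dropped with a warning", {
  med <- paper_like_medians(seed = 3)
  med$related[1] <- NA
  expect_warning(a <- splitplot_anova(med), "missing cells")
  expect_equal(a$df2[a$term == "group"], nrow(med) - 1 - 2)
})

test_that("Greenhouse-Geisser correction shrinks the within-participant df", {
  med <- paper_like_medians(seed = 3)
  a0 <- splitplot_anova(med)
  a1 <- splitplot_anova(med, gg_correction = TRUE)
  eps <- attr(a1, "gg_epsilon")
  expect_true(eps > 1 / 3 && eps <= 1 + 1e-12)
  w <- a1$term != "group"
  expect_equal(a1$df1[w], a0$df1[w] * eps)
  expect_equal(a1$F, a0$F)  # epsilon rescales df, not F
  expect_true(all(a1$p[w] >= a0$p[w] - 1e-12))
})

test_that("Welch group comparisons match the closed-form oracle", {
  eff <- data.frame(
    participant_id = c("C1", "C2", "C3", "P1", "P2", "P3"),
    group = rep(c("control", "patient"), each = 3),
    lexical_ms = c(70, 80, 90, 300, 340, 360),
    semantic_ms = c(40, 46, 52, 60, 75, 90),
    phonological_ms = c(-20, -18, -16, -160, -172, -184),
    stringsAsFactors = FALSE)
  tt <- effect_ttests(eff)
  o <- welch_oracle(eff$lexical_ms[4:6], eff$lexical_ms[1:3])
  w <- tt[tt$comparison == "patient_vs_control" & tt$effect == "lexical", ]
  expect_equal(w$t, o$t, tolerance = 1e-10)
  expect_equal(w$df, o$df, tolerance = 1e-10)
  expect_equal(w$mean, o$mean, tolerance = 1e-10)
  expect_equal(c(w$ci_low, w$ci_high), o$ci, tolerance = 1e-10)
  # Welch df bound: between min(n1, n2) - 1 and n1 + n2 - 2
  expect_gte(w$df, 2)
  expect_lte(w$df, 4)

  # one-sample t: explicit formula
  x <- eff$lexical_ms[1:3]
  c1 <- tt[tt$comparison == "control" & tt$effect == "lexical", ]
  expect_equal(c1$t, mean(x) / (sd(x) / sqrt(3)), tolerance = 1e-10)
  expect_equal(c1$df, 2)
})

test_that("zero-variance effects are reported as undefined", {
  eff <- data.frame(
    participant_id = c("C1", "C2", "P1", "P2"),
    group = rep(c("control", "patient"), each = 2),
    lexical_ms = c(0, 0, 10, 20),
    semantic_ms = c(1, 2, 3, 4),
    phonological_ms = c(0, 0, 0, 0),
    stringsAsFactors = FALSE)
  tt <- effect_ttests(eff)
  c_lex <- tt[tt$comparison == "control" & tt$effect == "lexical", ]
  expect_true(is.na(c_lex$t))
  expect_equal(c_lex$mean, 0)
  # between-group Welch still defined when one group has variance
  expect_true(any(tt$comparison == "patient_vs_control" & tt$effect == "lexical"))
  # all-zero variance in both groups: no Welch row
  expect_false(any(tt$comparison == "patient_vs_control" &
                     tt$effect == "phonological"))
})

test_that("Welch df stays within its theoretical bounds on simulated data", {
  for (seed in c(5, 23)) {
    eff <- compute_effects(paper_like_medians(seed = seed))
    tt <- effect_ttests(eff)
    w <- tt[tt$comparison == "patient_vs_control", ]
    n1 <- sum(eff$group == "control"); n2 <- sum(eff$group == "patient")
    expect_true(all(w$df >= min(n1, n2) - 1 - 1e-9))
    expect_true(all(w$df <= n1 + n2 - 2 + 1e-9))
  }
})

test_that("error-rate comparison handles equal and degenerate inputs", {
  mk <- function(e_c, e_p, n = 200) {
    data.frame(
      participant_id = rep(c("C1", "P1"), each = n),
      group = rep(c("control", "patient"), each = n),
      item_id = "item01",
      condition = rep("neutral", 2 * n),
      rt_ms = 500,
      status = c(rep("error", e_c), rep("correct", n - e_c),
                 rep("error", e_p), rep("correct", n - e_p)),
      stringsAsFactors = FALSE)
  }
  same <- error_rate_comparison(mk(8, 8))
  expect_gt(same$p, 0.99)
  expect_false(same$degenerate)

  none <- error_rate_comparison(mk(0, 0))
  expect_true(none$degenerate)
  expect_true(is.na(none$p))
})

test_that("the error-rate comparison is underpowered at realistic rates", {
  # 2% vs 4% error rates, 88 trials/participant, 13 + 6 participants: the
  # per-condition logistic contrast should rarely reach significance
  rejections <- unlist(lapply(1:25, function(i) {
    cfg <- paper_like_config(seed = 400 + i,
                             error_rate = c(control = 0.02, patient = 0.04))
    er <- error_rate_comparison(simulate_trials(cfg))
    er$p[!er$degenerate] < 0.05
  }))
  expect_lt(mean(rejections), 0.5)
})
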