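measure_rows <- function(pid, measure, sessions, phases, values,
                         group = "physical_activity") {
  data.frame(participant_id = pid, group = group, measure = measure,
             session_id = sessions, phase = phases, value = values)
}

test_that("chronic and acute difference scores subtract later minus earlier", {
  m <- rbind(
    measure_rows("P01", "sifi_acc_overall",
                 c("baseline", "post_intervention"),
                 c("baseline", "post_intervention"), c(0.70, 0.85)),
    measure_rows("P01", "mean_rt_AV",
                 c("s1_pre", "s1_post"), c("pre", "post"), c(400, 370)))
  d <- difference_scores(m)
  expect_equal(d$value[d$measure == "sifi_acc_overall" &
                         d$contrast == "chronic"], 0.15)
  expect_equal(d$value[d$measure == "mean_rt_AV" &
                         d$contrast == "acute_1"], -30)
})

test_that("a missing side of a contrast emits no score", {
  m <- measure_rows("P02", "auc", "baseline", "baseline", 0.3)
  expect_equal(nrow(difference_scores(m)), 0L)
  expect_equal(nrow(difference_scores(m[0, ])), 0L)
})

test_that("difference scores are antisymmetric under phase swap", {
  m <- measure_rows("P03", "tbw_sj", c("baseline", "post_intervention"),
                    c("baseline", "post_intervention"), c(120, 95))
  swapped <- m; swapped$value <- rev(swapped$value)
  expect_equal(difference_scores(m)$value, -difference_scores(swapped)$value)
})

test_that("Friedman statistic matches the hand-ranked example", {
  x <- matrix(rep(c(1, 2, 3), 4), 4, 3, byrow = TRUE)
  res <- friedman_test(x)
  expect_equal(res$chi2, 8)
  expect_equal(res$df, 2L)
  expect_equal(res$p_value, stats::pchisq(8, 2, lower.tail = FALSE))
})

test_that("fully tied tables are degenerate: chi2 = 0, p = 1", {
  res <- friedman_test(matrix(5, 4, 3))
  expect_equal(res$chi2, 0)
  expect_equal(res$p_value, 1)
})

test_that("Friedman matches stats::friedman.test on random tables", {
  set.seed(90)
  for (rep in 1:100) {
    n <- sample(3:12, 1); k <- sample(2:6, 1)
    x <- matrix(sample(1:5, n * k, replace = TRUE), n, k)  # ties guaranteed
    if (all(apply(x, 1, function(r) length(unique(r))) == 1)) next
    ours <- friedman_test(x)
    ref <- stats::friedman.test(x)
    expect_equal(ours$chi2, unname(ref$statistic))
    expect_equal(ours$df, unname(ref$parameter))
    expect_equal(ours$p_value, unname(ref$p.value))
  }
})

test_that("Friedman is invariant under monotone within-block transforms", {
  set.seed(91)
  x <- matrix(runif(24), 6, 4)
  expect_equal(friedman_test(x)$chi2, friedman_test(exp(3 * x))$chi2)
  expect_error(friedman_test(cbind(x, NA)))
})

test_that("a configured intervention effect surfaces in the group report", {
  eff <- data.frame(group = "physical_activity", phase = "post",
                    rt_shift_ms = -60)
  cfg <- quick_config(seed = 17, session_effects = eff)
  trials <- simulate_rt_dataset(cfg)
  rmi <- suppressWarnings(rmi_analysis(trials, seed = 17))
  s <- rmi$summaries
  m <- data.frame(participant_id = s$participant_id, group = s$group,
                  measure = paste0("mean_rt_", s$modality),
                  session_id = s$session_id, phase = s$phase,
                  value = s$mean_rt)
  rep <- group_report(difference_scores(m))
  acute_av <- rep$summary[rep$summary$measure == "mean_rt_AV" &
                            rep$summary$contrast == "acute_1", ]
  expect_lt(acute_av$mean[acute_av$group == "physical_activity"],
            acute_av$mean[acute_av$group == "reading"])
  expect_true(all(c("n", "mean", "se") %in% names(rep$summary)))
})

test_that("empty input yields an empty report", {
  rep <- group_report(data.frame())
  expect_equal(nrow(rep$summary), 0L)
})
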