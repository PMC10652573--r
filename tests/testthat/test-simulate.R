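test_that("ex-Gaussian sampler: degenerate limit, analytic mean, determinism", {
  expect_equal(sample_exgaussian(5, 400, 0, 0), rep(400, 5))
  x <- sample_exgaussian(1e5, 400, 40, 80, seed = 42)
  se <- sqrt(40^2 + 80^2) / sqrt(1e5)
  expect_lt(abs(mean(x) - 480), 3 * se)
  expect_identical(sample_exgaussian(10, 400, 40, 80, seed = 7),
                   sample_exgaussian(10, 400, 40, 80, seed = 7))
  expect_error(sample_exgaussian(5, 400, -1, 80))
})

test_that("ex-Gaussian CDF matches an empirical oracle and inverts cleanly", {
  set.seed(1)
  x <- sample_exgaussian(2e5, 350, 50, 90)
  qs <- c(300, 400, 500, 700, 1000)
  emp <- vapply(qs, function(q) mean(x <= q), numeric(1))
  expect_equal(pexgauss(qs, 350, 50, 90), emp, tolerance = 0.01)
  p <- c(0.05, 0.25, 0.5, 0.9, 0.99)
  expect_equal(pexgauss(qexgauss(p, 350, 50, 90), 350, 50, 90), p,
               tolerance = 1e-6)
})

test_that("judgment response models evaluate to their closed-form values", {
  expect_equal(sj_probability(0, 1, 0, 100), 1)
  expect_equal(sj_probability(25, 0.9, 25, 120), 0.9)
  expect_equal(sj_probability(145, 0.9, 25, 120), 0.9 * exp(-0.5))
  expect_equal(toj_probability(-15, -15, 90), 0.5)
  expect_equal(toj_probability(230, 0, 50), 1 / (1 + exp(-4.6)))
  expect_equal(toj_probability(-230, 0, 50), 1 - 1 / (1 + exp(-4.6)))
  expect_equal(sifi_illusion_probability(230, 0.8, 150, 0),
               0.8 * exp(-230 / 150))
  expect_equal(sifi_illusion_probability(0, 0.8, 150, 0), 0.8)
})

test_that("simulated RTs respect the acquisition repeat rule and the seed", {
  cfg <- quick_config(seed = 3)
  rt <- simulate_rt_dataset(cfg)
  expect_true(all(rt$rt_ms > 100 & rt$rt_ms < 3000))
  expect_identical(rt, simulate_rt_dataset(quick_config(seed = 3)))
  expect_false(identical(rt$rt_ms,
                         simulate_rt_dataset(quick_config(seed = 4))$rt_ms))
  # per participant x session the design counts carry through
  one <- rt[rt$participant_id == "P01" & rt$session_id == "baseline", ]
  expect_equal(nrow(one), 156L)
  expect_equal(sum(one$condition == "AV" & one$block == "main"), 50L)
})

test_that("coactivation produces redundancy gain; antithetic pairing runs", {
  cfg <- quick_config(seed = 5)
  rt <- simulate_rt_dataset(cfg)
  main <- rt[rt$block == "main", ]
  m <- tapply(main$rt_ms, main$condition, mean)
  expect_lt(m[["AV"]], m[["A"]])
  expect_lt(m[["AV"]], m[["V"]])
  neg <- simulate_rt_dataset(quick_config(seed = 5,
                                          dependence = "neg_dependent"))
  expect_true(all(neg$rt_ms > 100 & neg$rt_ms < 3000))
})

test_that("judgment simulators hit their generative probabilities", {
  cfg <- quick_config(seed = 9)
  sj <- simulate_sj_dataset(cfg)
  expect_setequal(unique(sj$response), c("simultaneous", "not_simultaneous"))
  expect_setequal(unique(sj$phase), c("baseline", "post_intervention"))
  toj <- simulate_toj_dataset(cfg)
  main <- toj[toj$block == "main", ]
  # far vision-lead SOAs are overwhelmingly judged vision-first
  p230 <- mean(main$response[main$soa_ms == 230] == "vision_first")
  expect_gt(p230, 0.8)
  pneg <- mean(main$response[main$soa_ms == -230] == "vision_first")
  expect_lt(pneg, 0.2)
})

test_that("illusion-free SIFI config yields perfect illusory accuracy", {
  cfg <- quick_config(
    seed = 2,
    sifi_truth = c(g0 = 0, tau_decay = 150, lapse = 0, eps_control = 0,
                   p_report3 = 0))
  si <- simulate_sifi_dataset(cfg)
  ill <- si[si$condition == "1f2b" & si$block == "audiovisual", ]
  expect_true(all(ill$response == "1"))
  ctrl <- si[si$block != "practice" & si$condition != "1f2b", ]
  correct <- ifelse(ctrl$block == "unimodal_auditory",
                    ctrl$n_beeps, ctrl$n_flashes)
  expect_true(all(as.integer(ctrl$response) == correct))
})

test_that("session effects shift the targeted group and phase only", {
  eff <- data.frame(group = "physical_activity", phase = "post",
                    rt_shift_ms = -80)
  cfg <- quick_config(seed = 6, session_effects = eff)
  base <- quick_config(seed = 6)
  rt_eff <- simulate_rt_dataset(cfg)
  rt_base <- simulate_rt_dataset(base)
  sel <- rt_eff$block == "main" & rt_eff$phase == "post" &
    rt_eff$group == "physical_activity"
  expect_lt(mean(rt_eff$rt_ms[sel]) - mean(rt_base$rt_ms[sel]), -50)
  other <- rt_eff$block == "main" & rt_eff$group == "reading"
  expect_identical(rt_eff$rt_ms[other], rt_base$rt_ms[other])
})
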