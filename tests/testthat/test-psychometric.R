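make_table <- function(soas, props, n = 10L) {
  out <- data.frame(soa_ms = soas, n_trials = n,
                    n_target = round(props * n), proportion = props)
  class(out) <- c("soa_table", class(out))
  out
}

test_that("response tabulation produces exact per-SOA counts", {
  cfg <- quick_config(seed = 4)
  sj <- simulate_sj_dataset(cfg)
  one <- sj[sj$participant_id == "P01" & sj$session_id == "baseline", ]
  tab <- tabulate_responses(one, "SJ")
  expect_equal(nrow(tab), 7L)
  expect_true(all(tab$n_trials == 10L))
  expect_equal(tab$proportion, tab$n_target / tab$n_trials)
  # hand check one SOA against the raw trials
  n0 <- sum(one$block == "main" & one$soa_ms == 0 &
              one$response == "simultaneous")
  expect_equal(tab$n_target[tab$soa_ms == 0], n0)
  expect_error(tabulate_responses(one[0, ], "SJ"))
})

test_that("noiseless curves are recovered essentially exactly", {
  soas <- DESIGN_SOAS
  sj_tab <- make_table(soas, sj_probability(soas, 0.95, 20, 110))
  f <- fit_sj_gaussian(sj_tab)
  expect_equal(f$a, 0.95, tolerance = 1e-4)
  expect_equal(f$x0, 20, tolerance = 1e-3)
  expect_equal(f$b, 110, tolerance = 1e-3)
  expect_equal(f$r2, 1, tolerance = 1e-8)
  expect_false(f$excluded)
  toj_tab <- make_table(soas, toj_probability(soas, 0, 60))
  g <- fit_toj_logistic(toj_tab)
  expect_equal(g$x0, 0, tolerance = 1e-3)
  expect_equal(g$b, 60, tolerance = 1e-3)
  expect_equal(g$a, 1)
})

test_that("fits are invariant to row order and percent-vs-proportion scale", {
  set.seed(14)
  soas <- DESIGN_SOAS
  tab <- binomial_table(function(x) sj_probability(x, 0.9, 25, 120),
                        soas, 50)
  f1 <- fit_sj_gaussian(tab)
  f2 <- fit_sj_gaussian(tab[sample(nrow(tab)), ])
  expect_equal(f1$x0, f2$x0)
  expect_equal(f1$b, f2$b)
  pct <- tab; pct$proportion <- pct$proportion * 100
  f3 <- fit_sj_gaussian(pct)
  expect_equal(f3$x0, f1$x0, tolerance = 1e-6)
  expect_equal(f3$b, f1$b, tolerance = 1e-6)
  expect_equal(f3$a, f1$a * 100, tolerance = 1e-4)
})

test_that("mirrored order-judgment proportions give a centred PSS", {
  soas <- DESIGN_SOAS
  props <- toj_probability(soas, 0, 80)
  f <- fit_toj_logistic(make_table(soas, props))
  expect_equal(f$x0, 0, tolerance = 1e-3)
})

test_that("flat data yield r2 = 0 and exclusion; thresholds are strict", {
  flat <- make_table(DESIGN_SOAS, rep(0.5, 7))
  f <- fit_sj_gaussian(flat)
  expect_equal(f$r2, 0)
  expect_true(f$excluded)
  expect_equal(r_squared(c(0.2, 0.5, 0.9), c(0.2, 0.5, 0.9)), 1)
  # r2 = 0.2 exactly is retained; 0.19 is excluded
  fit <- structure(list(model = "gaussian", a = 1, x0 = 0, b = 100,
                        r2 = 0.2, converged = TRUE, excluded = NA),
                   class = "psychometric_fit")
  expect_false(apply_exclusion(fit)$excluded)
  fit$r2 <- 0.19
  expect_true(apply_exclusion(fit)$excluded)
})

test_that("random responders drive exclusions while curve-driven fits are kept", {
  set.seed(77)
  soas <- DESIGN_SOAS
  # an exactly flat responder is always excluded (r2 defined as 0)
  flat <- make_table(soas, rep(0.5, 7))
  expect_true(fit_sj_gaussian(flat)$excluded)
  # a cohort with injected binomial random responders: every curve-driven
  # fit is retained and the exclusion count is at least one
  curve_excl <- replicate(10, fit_sj_gaussian(
    binomial_table(function(x) sj_probability(x, 0.9, 10, 110),
                   soas, 10))$excluded)
  rand_excl <- replicate(10, fit_sj_gaussian(
    binomial_table(function(x) rep(0.5, length(x)), soas, 10))$excluded)
  expect_false(any(curve_excl))
  expect_gte(sum(rand_excl), 1)
})

test_that("too few informative SOAs are rejected", {
  tab <- make_table(c(0, 70, 150), c(1, 0.8, 0.4))
  expect_error(fit_sj_gaussian(tab), "at least 4")
})

test_that("cohort-level fitting returns one row per participant-session", {
  cfg <- quick_config(seed = 21)
  fits <- fit_judgment_task(simulate_sj_dataset(cfg), "SJ")
  expect_equal(nrow(fits), 6 * 2)  # 6 participants x 2 judgment sessions
  expect_true(all(fits$model == "gaussian"))
  expect_true(all(fits$b[!fits$excluded] > 0))
})
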