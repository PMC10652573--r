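test_that("trimming to infinity uses strict bounds and keeps denominators", {
  tr <- trim_to_infinity(c(99, 100, 1500, 1501))
  expect_equal(tr$rts, c(Inf, 100, 1500, Inf))
  expect_equal(tr$fraction_finite, 0.5)
  tr2 <- trim_to_infinity(c(300, 400))
  expect_equal(tr2$rts, c(300, 400))
  expect_equal(tr2$fraction_finite, 1)
  expect_error(trim_to_infinity(numeric(0)))
})

test_that("observed CDF counts infinite entries in the denominator", {
  rts <- c(200, 300, Inf, Inf)
  expect_equal(rt_ecdf(rts, 250), 0.25)
  expect_equal(rt_ecdf(rts, 150), 0)
  expect_equal(rt_ecdf(c(200, 300), Inf), 1)
  expect_equal(rt_ecdf(rts, Inf), 0.5)
  # brute-force oracle on random queries
  set.seed(10)
  for (rep in 1:5) {
    x <- c(round(runif(40, 100, 1500)), rep(Inf, sample(0:5, 1)))
    q <- runif(200, 0, 2000)
    oracle <- vapply(q, function(t) sum(x[is.finite(x)] <= t) / length(x),
                     numeric(1))
    expect_equal(rt_ecdf(x, q), oracle)
  }
})

test_that("percentile quantization interpolates linearly over 21 bins", {
  x <- seq(100, 200, by = 5)
  expect_equal(quantize_percentiles(x), x)
  expect_equal(quantize_percentiles(c(1, 2, 3, 4), probs = 0.5), 2.5)
  # oracle: base type-7 quantiles on finite data
  set.seed(20)
  for (rep in 1:100) {
    x <- runif(sample(5:60, 1), 100, 1500)
    expect_equal(quantize_percentiles(x),
                 unname(stats::quantile(x, seq(0, 1, 0.05), type = 7)))
  }
  q <- quantize_percentiles(rnorm(30, 400, 50))
  expect_length(q, 21)
  expect_true(all(diff(q) >= 0))
})

test_that("quantiles beyond the finite fraction return Inf; all-Inf rejected", {
  x <- c(seq(100, 1000, length.out = 18), Inf, Inf)
  q <- quantize_percentiles(x)
  expect_true(all(is.finite(q[1:17])))
  expect_true(all(is.infinite(q[19:21])))
  expect_error(quantize_percentiles(c(Inf, Inf)))
  expect_error(quantize_percentiles(c(300, Inf)))
})

test_that("difference wave follows the Miller-bound construction", {
  # identical samples in all three modalities can never violate the bound
  set.seed(30)
  x <- sort(runif(50, 200, 800))
  w <- race_difference_wave(list(A = x, V = x, AV = x))
  expect_true(all(w$d <= 1e-12))
  expect_equal(w$observed, seq(0, 1, 0.05))
  expect_true(all(w$predicted >= 0 & w$predicted <= 1))
  # brute-force check of predicted at each eval time
  oracle <- pmin(vapply(w$eval_times, function(t) mean(x <= t), 1) * 2, 1)
  expect_equal(w$predicted, oracle)
  # fastest AV faster than every unisensory RT: both CDFs are 0 there
  w2 <- race_difference_wave(list(A = x + 500, V = x + 500, AV = x))
  expect_equal(w2$d[1], 0)
  expect_equal(w2$predicted[1], 0)
})

test_that("predicted CDF caps at 1 and d is bounded below by p - 1", {
  set.seed(31)
  for (rep in 1:20) {
    av <- runif(30, 600, 1200)
    a <- runif(30, 150, 400)   # A and V fully faster: bound saturates
    v <- runif(30, 150, 400)
    w <- race_difference_wave(list(A = a, V = v, AV = av))
    expect_equal(w$predicted[21], 1)
    expect_true(all(w$d >= w$probabilities - 1 - 1e-12))
  }
})

test_that("first-quartile AUC is the pairwise trapezoid sum and is linear", {
  expect_equal(auc_first_quartile(rep(0.1, 21)), 0.5)
  expect_equal(auc_first_quartile(rep(0, 21)), 0)
  expect_equal(auc_first_quartile(c(0, 0.02, 0.04, 0.06, 0.08, 0.10,
                                    rep(0, 15))), 0.25)
  set.seed(40)
  for (rep in 1:100) {
    d <- rnorm(21, 0, 0.1)
    oracle <- sum(vapply(1:5, function(i) (d[i] + d[i + 1]) / 2, 1))
    expect_equal(auc_first_quartile(d), oracle)
    expect_equal(auc_first_quartile(2 * d), 2 * auc_first_quartile(d))
  }
})

test_that("sign-flip permutation test matches exhaustive enumeration oracle", {
  set.seed(50)
  n <- 5
  d <- matrix(rnorm(n * 21, 0.05, 0.1), n, 21)
  res <- gondan_test(d)
  expect_true(res$exhaustive)
  # independent oracle: loop all sign vectors, t statistics via t.test
  tmax_of <- function(m) {
    max(apply(m[, 1:6], 2, function(col) {
      if (stats::sd(col) == 0) 0 else unname(stats::t.test(col)$statistic)
    }))
  }
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  perm <- apply(signs, 1, function(s) tmax_of(d * s))
  expect_equal(res$tmax, tmax_of(d))
  expect_equal(res$p_value, mean(perm >= tmax_of(d) - 1e-9))
  expect_equal(res$tcrit, unname(stats::quantile(perm, 0.95)))
  # exhaustive p values are multiples of 2^-n and never below it
  expect_equal(res$p_value * 2^n, round(res$p_value * 2^n))
  expect_gte(res$p_value, 2^-n)
})

test_that("degenerate all-zero waves give tmax 0 and p 1 with a warning", {
  d <- matrix(0, 4, 21)
  expect_warning(res <- gondan_test(d), "zero variance")
  expect_equal(res$tmax, 0)
  expect_equal(res$p_value, 1)
})

test_that("RT summaries use finite values only", {
  s <- rt_summaries(list(A = c(200, 300, Inf)))
  expect_equal(s$mean_rt, 250)
  expect_equal(s$median_rt, 250)
  s2 <- rt_summaries(list(V = 412))
  expect_equal(s2$mean_rt, 412)
  expect_equal(s2$median_rt, 412)
  expect_warning(s3 <- rt_summaries(list(AV = c(Inf, Inf))))
  expect_true(is.na(s3$mean_rt))
})

test_that("the wave pipeline is invariant to trial order within modality", {
  set.seed(60)
  mods <- list(A = runif(50, 200, 900), V = runif(50, 250, 950),
               AV = runif(50, 180, 800))
  w1 <- race_difference_wave(mods)
  w2 <- race_difference_wave(lapply(mods, sample))
  expect_equal(w1$d, w2$d)
  expect_equal(w1$eval_times, w2$eval_times)
})

test_that("rmi_analysis tests each group separately with exhaustive nulls", {
  cfg <- quick_config(seed = 8)
  trials <- simulate_rt_dataset(cfg)
  res <- suppressWarnings(rmi_analysis(trials, seed = 8))
  expect_setequal(names(res$tests), c("physical_activity", "reading"))
  t1 <- res$tests$physical_activity$baseline
  expect_true(t1$exhaustive)
  expect_equal(t1$n_permutations, 2^3)
  expect_gt(res$fraction_finite, 0.99)
  expect_equal(length(res$waves$baseline), 6L)
})
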