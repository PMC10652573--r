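#' Race-model-inequality analysis of redundant-signals response times
#'
#' The race model holds that the redundant (audiovisual) response is the
#' faster of two unisensory channels, which bounds the audiovisual CDF by
#' the Miller inequality `F_AV(t) <= F_A(t) + F_V(t)`. The pipeline trims
#' implausible responses to infinity (keeping them in CDF denominators),
#' Vincentizes each participant's audiovisual RTs onto a 21-point
#' percentile grid, forms the observed and Miller-bound-predicted CDFs,
#' takes their difference wave, summarises violation magnitude as the
#' trapezoidal AUC over the fastest quartile, and tests the inequality with
#' a max-t sign-flip permutation test across participants.
#'
#' @name rt_analysis
NULL

TRIM_BOUNDS_MS <- c(100, 1500)

#' Percentile grid for Vincentized CDFs
#'
#' @return List with `probabilities` (0, 0.05, ..., 1; 21 values) and
#'   `quartile_mask` (probabilities <= 0.25; 6 values TRUE).
#' @export
percentile_grid <- function() {
  p <- seq(0, 1, by = 0.05)
  list(probabilities = p, quartile_mask = p <= 0.25)
}

#' Trim implausible response times to infinity
#'
#' Responses faster than 100 ms or slower than 1500 ms are set to `Inf`
#' rather than excluded, so they still count in CDF denominators. Bounds
#' are strict: 100 and 1500 ms themselves are retained.
#'
#' @param rts Positive response times in ms.
#' @param bounds Lower/upper retention bounds in ms.
#' @return List with `rts` (trimmed vector) and `fraction_finite`.
#' @export
trim_to_infinity <- function(rts, bounds = TRIM_BOUNDS_MS) {
  if (length(rts) == 0) stop("empty RT vector")
  stopifnot(all(rts > 0))
  out <- ifelse(rts < bounds[1] | rts > bounds[2], Inf, rts)
  list(rts = out, fraction_finite = mean(is.finite(out)))
}

#' Observed cumulative distribution with infinite entries in the denominator
#'
#' `P(RT <= t)` estimated as the count of finite RTs at or below t divided
#' by the total number of trials including infinite (trimmed) ones; a
#' right-continuous step function that never reaches 1 if any trial was
#' trimmed.
#'
#' @param rts RT vector, possibly containing `Inf`.
#' @param t Evaluation times (vectorized).
#' @return Probabilities in \[0, 1\].
#' @export
rt_ecdf <- function(rts, t) {
  stopifnot(length(rts) > 0)
  fin <- sort(rts[is.finite(rts)])
  vapply(t, function(tt) {
    if (is.infinite(tt) && tt > 0) return(length(fin) / length(rts))
    sum(fin <= tt) / length(rts)
  }, numeric(1))
}

#' Vincentize response times into 21 percentile bins
#'
#' Quantiles at 0, 5, ..., 100 percent by linear interpolation between
#' order statistics (0th = minimum, 100th = maximum). Infinite entries
#' occupy the top ranks, so percentiles beyond the finite fraction return
#' `Inf`.
#'
#' @param rts RT vector, possibly containing `Inf`; at least two finite
#'   values required.
#' @param probs Probability grid (defaults to the 21-point grid).
#' @return Non-decreasing vector of quantile times, one per grid point.
#' @export
quantize_percentiles <- function(rts, probs = percentile_grid()$probabilities) {
  fin_n <- sum(is.finite(rts))
  if (fin_n == 0) stop("all response times are infinite")
  if (fin_n < 2) stop("need at least two finite response times")
  x <- sort(rts)  # Inf sorts last
  n <- length(x)
  h <- (n - 1) * probs
  lo <- pmin(floor(h) + 1, n)
  hi <- pmin(ceiling(h) + 1, n)
  g <- h - floor(h)
  q <- numeric(length(probs))
  for (i in seq_along(probs)) {
    a <- x[lo[i]]; b <- x[hi[i]]
    q[i] <- if (g[i] == 0) a
            else if (is.infinite(b)) Inf
            else (1 - g[i]) * a + g[i] * b
  }
  q
}

#' Per-participant race-model difference wave
#'
#' Evaluates the three CDFs at the participant's audiovisual quantile
#' times: observed(p) = p by construction, predicted(p) =
#' `min(F_A(t_p) + F_V(t_p), 1)` (the Miller bound), and
#' d(p) = observed - predicted. Positive d flags a violation bin.
#'
#' @param rts_by_modality Named list with elements `A`, `V`, `AV`, each an
#'   RT vector (possibly containing `Inf`) with at least two finite values.
#' @return List of class `difference_wave` with `probabilities`,
#'   `eval_times`, `observed`, `predicted`, `d`.
#' @export
race_difference_wave <- function(rts_by_modality) {
  stopifnot(all(c("A", "V", "AV") %in% names(rts_by_modality)))
  for (m in c("A", "V", "AV"))
    if (sum(is.finite(rts_by_modality[[m]])) < 2)
      stop("modality ", m, " needs at least two finite response times")
  grid <- percentile_grid()
  t_p <- quantize_percentiles(rts_by_modality$AV)
  predicted <- pmin(rt_ecdf(rts_by_modality$A, t_p) +
                      rt_ecdf(rts_by_modality$V, t_p), 1)
  observed <- grid$probabilities
  structure(
    list(probabilities = grid$probabilities, eval_times = t_p,
         observed = observed, predicted = predicted,
         d = observed - predicted),
    class = "difference_wave"
  )
}

#' First-quartile area under the difference wave
#'
#' Trapezoidal sum over the six grid points p in {0, .05, .10, .15, .20,
#' .25}: adjacent d values are averaged pairwise and the five averages
#' summed (units: probability x bin).
#'
#' @param wave A `difference_wave`, or a numeric d vector whose first six
#'   entries are the quartile bins.
#' @return Scalar AUC; positive values quantify race-model violation.
#' @export
auc_first_quartile <- function(wave) {
  d <- if (inherits(wave, "difference_wave")) wave$d else wave
  stopifnot(length(d) >= 6, !anyNA(d[1:6]))
  dq <- d[1:6]
  sum((dq[-6] + dq[-1]) / 2)
}

#' Max-t sign-flip permutation test of the race-model inequality
#'
#' At each quartile bin a one-sample t statistic of the participants'
#' difference-wave values is computed; the test statistic is the maximum
#' over the six bins. The null distribution flips the sign of each
#' participant's whole difference vector: exhaustively (all 2^N flips) when
#' N <= 14, otherwise by Monte Carlo. `tcrit` is the 95th percentile of the
#' permuted maxima and the p value is the one-sided proportion of permuted
#' maxima at or above the observed one.
#'
#' @param waves List of `difference_wave` objects (one per participant), or
#'   a numeric matrix of d values with participants in rows.
#' @param n_perm Monte Carlo permutation count used when N > 14.
#' @param seed Seed for the Monte Carlo draw (required for
#'   reproducibility).
#' @param alpha Significance level defining `tcrit`.
#' @return List of class `rmi_test`: `tmax`, `tcrit`, `p_value`,
#'   `t_by_bin`, `auc_by_participant`, `group_auc_mean`, `n_permutations`,
#'   `exhaustive`, `seed`.
#' @export
gondan_test <- function(waves, n_perm = 10000L, seed = 1L, alpha = 0.05) {
  if (is.list(waves) && !is.matrix(waves)) {
    d_mat <- do.call(rbind, lapply(waves, function(w) {
      if (inherits(w, "difference_wave")) w$d else as.numeric(w)
    }))
  } else d_mat <- as.matrix(waves)
  n <- nrow(d_mat)
  if (n < 2) stop("need at least two participants")
  dq <- d_mat[, 1:6, drop = FALSE]
  if (anyNA(dq)) stop("difference waves incomplete on quartile bins")

  t_stat <- function(m, ss) {
    # sign flips leave sum of squares invariant; only the mean moves
    v <- (ss - n * m^2) / (n - 1)
    ifelse(v <= .Machine$double.eps, 0, m / sqrt(v / n))
  }
  ss <- colSums(dq^2)
  m_obs <- colMeans(dq)
  if (any((ss - n * m_obs^2) / (n - 1) <= .Machine$double.eps))
    warning("zero variance at a quartile bin; its t statistic is set to 0")
  t_obs <- t_stat(m_obs, ss)
  tmax <- max(t_obs)

  exhaustive <- n <= 14
  if (exhaustive) {
    n_flip <- 2^n
    signs <- matrix(1, n_flip, n)
    for (j in seq_len(n))
      signs[, j] <- ifelse(bitwAnd(seq_len(n_flip) - 1L, bitwShiftL(1L, j - 1L)) > 0, -1, 1)
  } else {
    set.seed(seed)
    n_flip <- n_perm
    signs <- matrix(sample(c(-1, 1), n_flip * n, replace = TRUE), n_flip, n)
  }
  perm_means <- (signs %*% dq) / n
  perm_tmax <- apply(t_stat(perm_means, rep(ss, each = nrow(perm_means))),
                     1, max)
  auc <- apply(d_mat, 1, auc_first_quartile)
  structure(
    list(tmax = tmax, t_by_bin = t_obs,
         tcrit = unname(stats::quantile(perm_tmax, 1 - alpha)),
         # tolerance so the identity sign vector always counts as >= observed
         p_value = mean(perm_tmax >= tmax - 1e-9),
         auc_by_participant = auc, group_auc_mean = mean(auc),
         n_permutations = n_flip, exhaustive = exhaustive,
         seed = as.integer(seed)),
    class = "rmi_test"
  )
}

#' @export
print.rmi_test <- function(x, ...) {
  cat(sprintf(
    "<rmi_test> tmax=%.3f tcrit=%.3f p=%.4g (%s, %d permutations)\n",
    x$tmax, x$tcrit, x$p_value,
    if (x$exhaustive) "exhaustive" else "Monte Carlo", x$n_permutations))
  cat(sprintf("mean first-quartile AUC = %.4f over %d participants\n",
              x$group_auc_mean, length(x$auc_by_participant)))
  invisible(x)
}

#' Mean and median response time per modality
#'
#' Central-tendency summaries over finite RTs only; trimmed (infinite)
#' entries are excluded here, unlike in the CDF denominators.
#'
#' @param rts_by_modality Named list of RT vectors (`A`, `V`, `AV`).
#' @return Data frame with modality, n_finite, mean_rt, median_rt;
#'   modalities with no finite RT get NA and a warning.
#' @export
rt_summaries <- function(rts_by_modality) {
  rows <- lapply(names(rts_by_modality), function(m) {
    fin <- rts_by_modality[[m]][is.finite(rts_by_modality[[m]])]
    if (length(fin) == 0) {
      warning("no finite response times in modality ", m)
      return(data.frame(modality = m, n_finite = 0L,
                        mean_rt = NA_real_, median_rt = NA_real_))
    }
    data.frame(modality = m, n_finite = length(fin),
               mean_rt = mean(fin), median_rt = stats::median(fin))
  })
  do.call(rbind, rows)
}

#' Run the full race-model pipeline on a trial table
#'
#' Groups RT-task trials by participant and session, trims to infinity,
#' builds each participant's difference wave, and runs the permutation
#' test per session.
#'
#' @param trials Trial-record data frame (practice trials are dropped).
#' @param n_perm,seed,alpha Passed to [gondan_test()].
#' @return List with `waves` (nested by session then participant),
#'   `tests` (one `rmi_test` per group x session, nested by group: with
#'   group sizes of 14 or fewer the sign-flip null is exhaustive),
#'   `summaries` (per participant/session mean/median RTs), and
#'   `fraction_finite` (overall post-trim finite fraction).
#' @export
rmi_analysis <- function(trials, n_perm = 10000L, seed = 1L, alpha = 0.05) {
  rt <- trials[trials$task == "RT" & trials$block == "main", , drop = FALSE]
  if (nrow(rt) == 0) stop("no RT main-block trials present")
  sessions <- unique(rt$session_id)
  waves <- list(); tests <- list(); summ <- list()
  n_fin <- 0; n_tot <- 0
  for (sid in sessions) {
    sdat <- rt[rt$session_id == sid, , drop = FALSE]
    pw <- list()
    grp_of <- character()
    for (pid in unique(sdat$participant_id)) {
      pdat <- sdat[sdat$participant_id == pid, , drop = FALSE]
      by_mod <- lapply(c(A = "A", V = "V", AV = "AV"), function(m) {
        tr <- trim_to_infinity(pdat$rt_ms[pdat$condition == m])
        tr$rts
      })
      n_fin <- n_fin + sum(vapply(by_mod, function(v) sum(is.finite(v)), 0))
      n_tot <- n_tot + sum(lengths(by_mod))
      pw[[pid]] <- race_difference_wave(by_mod)
      grp_of[pid] <- pdat$group[1]
      s <- rt_summaries(by_mod)
      s$participant_id <- pid; s$session_id <- sid
      s$group <- pdat$group[1]; s$phase <- pdat$phase[1]
      summ[[paste(sid, pid)]] <- s
    }
    waves[[sid]] <- pw
    # one test per group, as the study reports its two groups separately
    for (grp in unique(grp_of)) {
      tests[[grp]][[sid]] <- gondan_test(
        pw[names(grp_of)[grp_of == grp]], n_perm = n_perm,
        seed = substream_seed(seed, "gondan", grp, sid), alpha = alpha)
    }
  }
  list(waves = waves, tests = tests,
       summaries = do.call(rbind, c(summ, list(make.row.names = FALSE))),
       fraction_finite = n_fin / n_tot)
}
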