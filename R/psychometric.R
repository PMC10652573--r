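#' Psychometric fits for simultaneity and temporal-order judgments
#'
#' Per-SOA response proportions are fitted by unweighted least squares to a
#' Gaussian (simultaneity judgment) or a fixed-amplitude logistic
#' (temporal-order judgment). The fitted centre x0 is the point of
#' subjective simultaneity (PSS); the width b serves as a proxy for the
#' temporal binding window. Fits with r-squared below 0.2 are flagged for
#' exclusion from group statistics.
#'
#' @name psychometric
NULL

R2_EXCLUSION_THRESHOLD <- 0.2

#' Tabulate per-SOA response counts
#'
#' Counts target responses ("simultaneous" for SJ, "vision_first" for TOJ)
#' per SOA for one participant/session; practice trials are excluded.
#'
#' @param trials Trial-record rows for a single participant, session and
#'   task.
#' @param task `"SJ"` or `"TOJ"`; inferred from the trials when missing.
#' @return Data frame of class `soa_table`: soa_ms, n_trials, n_target,
#'   proportion.
#' @export
tabulate_responses <- function(trials, task = NULL) {
  if (nrow(trials) == 0) stop("no trials to tabulate")
  if (is.null(task)) task <- trials$task[1]
  stopifnot(task %in% c("SJ", "TOJ"))
  tr <- trials[trials$task == task & trials$block == "main", , drop = FALSE]
  if (nrow(tr) == 0) stop("no main-block ", task, " trials present")
  if (length(unique(tr$participant_id)) > 1 ||
      length(unique(tr$session_id)) > 1)
    stop("tabulate_responses expects a single participant and session")
  target <- if (task == "SJ") "simultaneous" else "vision_first"
  soas <- sort(unique(tr$soa_ms))
  out <- data.frame(
    soa_ms = soas,
    n_trials = vapply(soas, function(s) sum(tr$soa_ms == s), 0L),
    n_target = vapply(soas, function(s)
      sum(tr$soa_ms == s & tr$response == target), 0L)
  )
  out$proportion <- ifelse(out$n_trials > 0, out$n_target / out$n_trials, NA)
  class(out) <- c("soa_table", class(out))
  attr(out, "task") <- task
  out
}

new_psychometric_fit <- function(model, a, x0, b, r2,
                                 converged = TRUE) {
  structure(
    list(model = model, a = a, x0 = x0, b = b, r2 = r2,
         converged = converged,
         excluded = !converged || r2 < R2_EXCLUSION_THRESHOLD),
    class = "psychometric_fit"
  )
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "<psychometric_fit> %s: a=%.3f, PSS=%.1f ms, b=%.1f ms, r2=%.3f%s\n",
    x$model, x$a, x$x0, x$b, x$r2,
    if (x$excluded) " [excluded]" else ""))
  invisible(x)
}

failed_fit <- function(model) new_psychometric_fit(model, NA, NA, NA, -Inf,
                                                   converged = FALSE)

#' Coefficient of determination over per-SOA proportions
#'
#' `1 - SS_res / SS_tot`. Flat data (SS_tot = 0) yield r2 = 0 so that
#' uninformative participants fall under the exclusion threshold.
#'
#' @param observed,fitted Per-SOA proportions.
#' @return Scalar r-squared (can be negative for a fit worse than the
#'   mean).
#' @export
r_squared <- function(observed, fitted) {
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) return(0)
  1 - sum((observed - fitted)^2) / ss_tot
}

#' Apply the poor-fit exclusion rule
#'
#' Participants whose psychometric fit explains too little variance
#' (r2 < 0.2, strict) are excluded from group statistics; r2 = 0.2 exactly
#' is retained.
#'
#' @param fit A `psychometric_fit`.
#' @param threshold Exclusion threshold on r2.
#' @return The fit with its `excluded` flag set.
#' @export
apply_exclusion <- function(fit, threshold = R2_EXCLUSION_THRESHOLD) {
  fit$excluded <- !isTRUE(fit$converged) || fit$r2 < threshold
  fit
}

fit_table_checks <- function(table) {
  tab <- table[table$n_trials > 0, , drop = FALSE]
  if (nrow(tab) < 4) stop("need at least 4 SOAs with trials to fit")
  tab
}

# Levenberg-Marquardt from a small ladder of start values; a near-linear
# psychometric segment can make the gradient singular at one start, so the
# first convergent fit with the lowest residual sum of squares wins.
try_nls <- function(formula, data, starts, lower, upper) {
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = st,
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12)
        best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) NULL else best$fit
}

#' Fit the Gaussian simultaneity-judgment model
#'
#' Unweighted least squares of `a * exp(-0.5 * ((x - x0) / b)^2)` to the
#' per-SOA proportion of "simultaneous" responses. Start values: a at the
#' maximum proportion, x0 at its SOA, b at half the SOA range; bounds
#' a in (0, 1.2], b in (1, 1000] ms, x0 in \[-500, 500\] ms keep the width
#' away from degenerate solutions. Non-convergence yields an excluded fit
#' with r2 = -Inf.
#'
#' @param table A `soa_table` (or data frame with soa_ms, n_trials,
#'   proportion).
#' @return A `psychometric_fit` with model `"gaussian"`; `x0` is the PSS
#'   and `b` the temporal-binding-window proxy.
#' @export
fit_sj_gaussian <- function(table) {
  tab <- fit_table_checks(table)
  x <- tab$soa_ms; y <- tab$proportion
  # tolerate percentage-scale input: x0 and b are scale-free, a rescales
  scale <- if (max(y) > 1.5) 100 else 1
  y <- y / scale
  a0 <- if (max(y) > 0) max(y) else 0.5
  x00 <- x[which.max(y)]
  b0 <- diff(range(x)) / 2
  starts <- list(list(a = a0, x0 = x00, b = b0),
                 list(a = a0, x0 = x00, b = b0 / 2),
                 list(a = a0, x0 = 0, b = b0 / 4))
  fit <- try_nls(y ~ a * exp(-0.5 * ((x - x0) / b)^2),
                 data.frame(x = x, y = y), starts,
                 lower = c(a = 1e-6, x0 = -500, b = 1 + 1e-9),
                 upper = c(a = 1.2, x0 = 500, b = 1000))
  if (is.null(fit)) return(failed_fit("gaussian"))
  cf <- stats::coef(fit)
  new_psychometric_fit("gaussian", cf[["a"]] * scale, cf[["x0"]],
                       abs(cf[["b"]]), r_squared(y, stats::fitted(fit)))
}

#' Fit the logistic temporal-order-judgment model
#'
#' Unweighted least squares of `1 / (1 + exp(-(x - x0) / b))` to the
#' per-SOA proportion of "vision first" responses, on the proportion
#' scale with amplitude fixed at 1. The fitted x0 is the PSS (the 50%
#' crossing of the curve); b is the width. Start values: x0 at the SOA
#' whose proportion is nearest 0.5, b at half the SOA range; bounds as in
#' [fit_sj_gaussian()].
#'
#' @inheritParams fit_sj_gaussian
#' @return A `psychometric_fit` with model `"logistic"` and `a = 1`.
#' @export
fit_toj_logistic <- function(table) {
  tab <- fit_table_checks(table)
  x <- tab$soa_ms; y <- tab$proportion
  scale <- if (max(y) > 1.5) 100 else 1
  y <- y / scale
  x00 <- x[which.min(abs(y - 0.5))]
  b0 <- diff(range(x)) / 2
  starts <- list(list(x0 = x00, b = b0),
                 list(x0 = x00, b = b0 / 4),
                 list(x0 = 0, b = b0 / 2))
  fit <- try_nls(y ~ 1 / (1 + exp(-(x - x0) / b)),
                 data.frame(x = x, y = y), starts,
                 lower = c(x0 = -500, b = 1 + 1e-9),
                 upper = c(x0 = 500, b = 1000))
  if (is.null(fit)) return(failed_fit("logistic"))
  cf <- stats::coef(fit)
  new_psychometric_fit("logistic", 1, cf[["x0"]], abs(cf[["b"]]),
                       r_squared(y, stats::fitted(fit)))
}

#' Fit every participant/session of a judgment task
#'
#' @param trials Trial-record data frame containing SJ and/or TOJ trials.
#' @param task `"SJ"` or `"TOJ"`.
#' @return Data frame with one row per participant x session: model, a,
#'   x0 (PSS), b (TBW proxy), r2, excluded.
#' @export
fit_judgment_task <- function(trials, task) {
  stopifnot(task %in% c("SJ", "TOJ"))
  tr <- trials[trials$task == task & trials$block == "main", , drop = FALSE]
  if (nrow(tr) == 0) stop("no ", task, " trials present")
  keys <- unique(tr[, c("participant_id", "group", "session_id", "phase")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- tr[tr$participant_id == keys$participant_id[i] &
                tr$session_id == keys$session_id[i], , drop = FALSE]
    tab <- tabulate_responses(sub, task)
    fit <- if (task == "SJ") fit_sj_gaussian(tab) else fit_toj_logistic(tab)
    cbind(keys[i, , drop = FALSE],
          data.frame(task = task, model = fit$model, a = fit$a,
                     pss = fit$x0, b = fit$b, r2 = fit$r2,
                     excluded = fit$excluded))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
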