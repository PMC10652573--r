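#' Synthetic trial-level data with known ground truth
#'
#' The generator emulates a two-group behavioural intervention cohort
#' (physical-activity intervention n = 13, reading control n = 14) measured
#' at a baseline / post-intervention pair plus three acute pre/post session
#' pairs. Response times follow an ex-Gaussian race with an optional
#' coactivation speed-up; simultaneity and temporal-order judgments are
#' Bernoulli draws from the same Gaussian / logistic psychometric models the
#' analysis fits; flash-illusion responses follow an exponential SOA-decay
#' illusion model. All randomness descends from one master seed through
#' deterministic per-participant substreams.
#'
#' @name synthetic_data
NULL

RT_ACQ_BOUNDS_MS <- c(100, 3000)

#' Deterministic substream seed
#'
#' Hashes a master seed plus any number of string/numeric keys into a
#' 31-bit seed, so every participant x session x task stream is reproducible
#' independently of generation order.
#'
#' @param seed Master integer seed.
#' @param ... Keys (coerced to character) identifying the substream.
#' @return An integer in \[0, 2^31 - 2\].
#' @export
substream_seed <- function(seed, ...) {
  key <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(key)) h <- (h * 69069 + ch) %% 2147483647
  as.integer(h)
}

#' Default session schedule
#'
#' Eight administrations for the repeated tasks: baseline, three acute
#' pre/post pairs during the intervention, and post-intervention. The
#' judgment tasks (SJ/TOJ) run only at baseline and post-intervention.
#'
#' @return Data frame with columns session_id and phase.
#' @export
default_sessions <- function() {
  data.frame(
    session_id = c("baseline", "s1_pre", "s1_post", "s2_pre", "s2_post",
                   "s3_pre", "s3_post", "post_intervention"),
    phase = c("baseline", "pre", "post", "pre", "post", "pre", "post",
              "post_intervention"),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Ground-truth parameters of the synthetic cohort. Defaults describe a
#' plausible older-adult cohort: unimodal ex-Gaussian RTs with means near
#' 465-500 ms, a 50 ms coactivation speed-up of the audiovisual race
#' minimum (so the race-model inequality is genuinely violated, as the
#' redundant-signals literature reports for such cohorts), a Gaussian
#' simultaneity profile (a = 0.9, PSS = 25 ms, width 120 ms), a logistic
#' order-judgment profile (PSS = -15 ms, width 90 ms), and a flash-illusion
#' strength of 0.6 at SOA 0 decaying with time constant 150 ms.
#'
#' @param n_intervention,n_control Group sizes (13 / 14).
#' @param sessions Data frame of session_id/phase rows; see
#'   [default_sessions()].
#' @param exgauss_A,exgauss_V Named numeric `c(mu=, sigma=, tau=)` in ms for
#'   the auditory and visual RT channels.
#' @param coactivation_shift_ms Constant speed-up c >= 0 subtracted from the
#'   audiovisual race minimum; c = 0 gives a legal race.
#' @param dependence `"independent"` channel draws, or `"neg_dependent"`
#'   antithetic sampling (one uniform u for A, 1 - u for V), which pushes
#'   the audiovisual CDF toward the Miller bound's equality case.
#' @param sj_truth Named `c(a=, pss=, b=)` for the Gaussian simultaneity
#'   model.
#' @param toj_truth Named `c(pss=, b=)` for the logistic order-judgment
#'   model (amplitude fixed at 1).
#' @param sifi_truth Named `c(g0=, tau_decay=, lapse=, eps_control=,
#'   p_report3=)`: illusion strength at SOA 0, exponential decay constant
#'   (ms), lapse rate on illusory trials, error rate on control/unimodal
#'   trials, and the probability (relative to an illusory "2" report) of
#'   reporting three or more stimuli.
#' @param session_effects Optional data frame with columns group, phase and
#'   any of rt_shift_ms (additive to both channel means), c_shift_ms
#'   (additive to the coactivation shift), pss_shift_ms, b_scale, g0_scale;
#'   unmatched group/phase combinations are neutral.
#' @param between Named numeric of between-participant SDs:
#'   rt_mu_sd (ms, additive to both channel means), pss_sd (ms),
#'   b_lnsd (log-scale SD of the width), g0_logit_sd.
#' @param seed Master seed; every substream derives from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_intervention = 13L,
                       n_control = 14L,
                       sessions = default_sessions(),
                       exgauss_A = c(mu = 375, sigma = 50, tau = 90),
                       exgauss_V = c(mu = 400, sigma = 55, tau = 100),
                       coactivation_shift_ms = 50,
                       dependence = c("independent", "neg_dependent"),
                       sj_truth = c(a = 0.9, pss = 25, b = 120),
                       toj_truth = c(pss = -15, b = 90),
                       sifi_truth = c(g0 = 0.6, tau_decay = 150,
                                      lapse = 0.02, eps_control = 0.03,
                                      p_report3 = 0.02),
                       session_effects = NULL,
                       between = c(rt_mu_sd = 30, pss_sd = 10,
                                   b_lnsd = 0.12, g0_logit_sd = 0.3),
                       seed = 1L) {
  dependence <- match.arg(dependence)
  stopifnot(
    n_intervention >= 1, n_control >= 1,
    all(c("session_id", "phase") %in% names(sessions)),
    exgauss_A[["sigma"]] >= 0, exgauss_A[["tau"]] >= 0,
    exgauss_V[["sigma"]] >= 0, exgauss_V[["tau"]] >= 0,
    coactivation_shift_ms >= 0,
    sj_truth[["a"]] > 0, sj_truth[["a"]] <= 1, sj_truth[["b"]] > 0,
    toj_truth[["b"]] > 0,
    sifi_truth[["g0"]] >= 0, sifi_truth[["g0"]] <= 1,
    sifi_truth[["tau_decay"]] > 0,
    sifi_truth[["lapse"]] >= 0, sifi_truth[["lapse"]] <= 0.1,
    sifi_truth[["eps_control"]] >= 0, sifi_truth[["eps_control"]] <= 0.1,
    sifi_truth[["p_report3"]] >= 0, sifi_truth[["p_report3"]] <= 0.05
  )
  structure(
    list(n_intervention = as.integer(n_intervention),
         n_control = as.integer(n_control),
         sessions = sessions,
         exgauss_A = exgauss_A, exgauss_V = exgauss_V,
         coactivation_shift_ms = coactivation_shift_ms,
         dependence = dependence,
         sj_truth = sj_truth, toj_truth = toj_truth,
         sifi_truth = sifi_truth,
         session_effects = session_effects,
         between = between,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Read a simulation configuration from YAML
#'
#' Scalar fields override [sim_config()] defaults; `sessions` and
#' `session_effects`, if present, must be lists of named rows.
#'
#' @param path YAML file path.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("n_intervention", "n_control", "coactivation_shift_ms",
               "dependence", "seed"))
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  for (nm in c("exgauss_A", "exgauss_V", "sj_truth", "toj_truth",
               "sifi_truth", "between"))
    if (!is.null(raw[[nm]])) args[[nm]] <- unlist(raw[[nm]])
  for (nm in c("sessions", "session_effects"))
    if (!is.null(raw[[nm]]))
      args[[nm]] <- do.call(rbind, lapply(raw[[nm]], as.data.frame))
  do.call(sim_config, args)
}

# Neutral effect row, overridden by any matching session_effects entry.
effects_for <- function(config, group, phase) {
  eff <- list(rt_shift_ms = 0, c_shift_ms = 0, pss_shift_ms = 0,
              b_scale = 1, g0_scale = 1)
  se <- config$session_effects
  if (is.null(se)) return(eff)
  hit <- se$group == group & se$phase == phase
  if (!any(hit)) return(eff)
  row <- se[which(hit)[1], , drop = FALSE]
  for (nm in names(eff))
    if (!is.null(row[[nm]]) && !is.na(row[[nm]])) eff[[nm]] <- row[[nm]]
  eff
}

participant_table <- function(config) {
  ids <- c(sprintf("P%02d", seq_len(config$n_intervention)),
           sprintf("C%02d", seq_len(config$n_control)))
  grp <- rep(c("physical_activity", "reading"),
             c(config$n_intervention, config$n_control))
  set.seed(substream_seed(config$seed, "traits"))
  b <- config$between
  n <- length(ids)
  data.frame(
    participant_id = ids, group = grp,
    rt_mu_offset = stats::rnorm(n, 0, b[["rt_mu_sd"]]),
    sj_pss_offset = stats::rnorm(n, 0, b[["pss_sd"]]),
    toj_pss_offset = stats::rnorm(n, 0, b[["pss_sd"]]),
    b_lnoffset = stats::rnorm(n, 0, b[["b_lnsd"]]),
    g0_logit_offset = stats::rnorm(n, 0, b[["g0_logit_sd"]]),
    stringsAsFactors = FALSE
  )
}

#' Ex-Gaussian response-time samples
#'
#' Draws from Normal(mu, sigma) + Exponential(tau), the standard skewed
#' model for simple response times. `sigma = 0` or `tau = 0` degenerate
#' gracefully to the remaining component.
#'
#' @param n Number of samples.
#' @param mu,sigma,tau Ex-Gaussian parameters in ms; sigma, tau >= 0.
#' @param seed Optional seed set before drawing.
#' @return Numeric vector of length n.
#' @export
sample_exgaussian <- function(n, mu, sigma, tau, seed = NULL) {
  stopifnot(sigma >= 0, tau >= 0, n >= 0)
  if (!is.null(seed)) set.seed(seed)
  g <- if (sigma > 0) stats::rnorm(n, mu, sigma) else rep(mu, n)
  e <- if (tau > 0) stats::rexp(n, rate = 1 / tau) else rep(0, n)
  g + e
}

#' Ex-Gaussian distribution function
#'
#' Closed-form CDF, evaluated on the log scale for numerical stability at
#' small tau.
#'
#' @param q Quantiles.
#' @inheritParams sample_exgaussian
#' @return P(X <= q).
#' @export
pexgauss <- function(q, mu, sigma, tau) {
  stopifnot(sigma >= 0, tau >= 0)
  if (tau == 0) return(stats::pnorm(q, mu, sigma))
  if (sigma == 0) return(stats::pexp(pmax(q - mu, 0), rate = 1 / tau))
  z <- (q - mu) / sigma
  lterm <- sigma^2 / (2 * tau^2) - (q - mu) / tau +
    stats::pnorm(z - sigma / tau, log.p = TRUE)
  pmin(pmax(stats::pnorm(z) - exp(lterm), 0), 1)
}

#' @rdname pexgauss
#' @param p Probabilities in (0, 1).
#' @export
qexgauss <- function(p, mu, sigma, tau) {
  stopifnot(all(p > 0 & p < 1))
  lo <- mu - 10 * max(sigma, 1e-6)
  hi <- mu + 10 * max(sigma, 1e-6) + 50 * max(tau, 1e-6)
  vapply(p, function(pp) {
    stats::uniroot(function(x) pexgauss(x, mu, sigma, tau) - pp,
                   lower = lo, upper = hi, tol = 1e-8)$root
  }, numeric(1))
}

# Channel pair samples for AV trials under the configured dependence.
draw_av_pairs <- function(n, parA, parV, dependence) {
  if (dependence == "independent") {
    a <- sample_exgaussian(n, parA[["mu"]], parA[["sigma"]], parA[["tau"]])
    v <- sample_exgaussian(n, parV[["mu"]], parV[["sigma"]], parV[["tau"]])
  } else {
    u <- stats::runif(n)
    a <- qexgauss(u, parA[["mu"]], parA[["sigma"]], parA[["tau"]])
    v <- qexgauss(1 - u, parV[["mu"]], parV[["sigma"]], parV[["tau"]])
  }
  cbind(a, v)
}

# Redraw-until-in-bounds, mirroring the acquisition rule that trials with
# responses < 100 ms or > 3 s were repeated.
redraw_in_bounds <- function(draw_fun, n) {
  x <- draw_fun(n)
  bad <- which(x <= RT_ACQ_BOUNDS_MS[1] | x >= RT_ACQ_BOUNDS_MS[2])
  guard <- 0L
  while (length(bad) > 0L && guard < 1000L) {
    x[bad] <- draw_fun(length(bad))
    bad <- bad[x[bad] <= RT_ACQ_BOUNDS_MS[1] | x[bad] >= RT_ACQ_BOUNDS_MS[2]]
    guard <- guard + 1L
  }
  x
}

record_frame <- function(pid, group, session_id, phase, design_trials) {
  cbind(
    data.frame(participant_id = pid, group = group,
               session_id = session_id, phase = phase,
               stringsAsFactors = FALSE),
    design_trials
  )
}

sessions_for_task <- function(config, task) {
  s <- config$sessions
  if (task %in% c("SJ", "TOJ"))
    s <- s[s$phase %in% c("baseline", "post_intervention"), , drop = FALSE]
  s
}

#' Simulate the response-time task for the whole cohort
#'
#' Each participant x session receives a fresh randomized design from
#' [build_rt_design()]. Unimodal trials are ex-Gaussian draws; audiovisual
#' trials are the channel-pair minimum minus the coactivation shift. Any
#' draw outside (100, 3000) ms is redrawn, reproducing the acquisition
#' repeat rule, so every simulated RT is strictly inside those bounds.
#'
#' @param config A [sim_config()].
#' @return Trial-record data frame (one row per trial) with columns
#'   participant_id, group, session_id, phase, the design columns, response
#'   (NA for this task) and rt_ms.
#' @export
simulate_rt_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  pts <- participant_table(config)
  sess <- sessions_for_task(config, "RT")
  out <- vector("list", nrow(pts) * nrow(sess))
  k <- 0L
  for (i in seq_len(nrow(pts))) {
    for (j in seq_len(nrow(sess))) {
      pid <- pts$participant_id[i]
      sid <- sess$session_id[j]
      eff <- effects_for(config, pts$group[i], sess$phase[j])
      des <- build_rt_design(substream_seed(config$seed, "rt-design",
                                            pid, sid))
      set.seed(substream_seed(config$seed, "rt-resp", pid, sid))
      parA <- config$exgauss_A
      parV <- config$exgauss_V
      parA[["mu"]] <- parA[["mu"]] + pts$rt_mu_offset[i] + eff$rt_shift_ms
      parV[["mu"]] <- parV[["mu"]] + pts$rt_mu_offset[i] + eff$rt_shift_ms
      cshift <- max(config$coactivation_shift_ms + eff$c_shift_ms, 0)
      tr <- des$trials
      rt <- numeric(nrow(tr))
      for (cond in c("A", "V", "AV")) {
        idx <- which(tr$condition == cond)
        rt[idx] <- switch(
          cond,
          A = redraw_in_bounds(function(m)
            sample_exgaussian(m, parA[["mu"]], parA[["sigma"]],
                              parA[["tau"]]), length(idx)),
          V = redraw_in_bounds(function(m)
            sample_exgaussian(m, parV[["mu"]], parV[["sigma"]],
                              parV[["tau"]]), length(idx)),
          AV = redraw_in_bounds(function(m) {
            pr <- draw_av_pairs(m, parA, parV, config$dependence)
            pmin(pr[, 1], pr[, 2]) - cshift
          }, length(idx))
        )
      }
      rec <- record_frame(pid, pts$group[i], sid, sess$phase[j], tr)
      rec$response <- NA_character_
      rec$rt_ms <- rt
      k <- k + 1L
      out[[k]] <- rec
    }
  }
  do.call(rbind, out)
}

#' Gaussian simultaneity-response probability
#'
#' `a * exp(-0.5 * ((x - x0) / b)^2)`: probability of a "simultaneous"
#' report at SOA x, the same model the analysis stage fits.
#'
#' @param soa_ms SOA in ms (positive = vision leads).
#' @param a Amplitude in (0, 1\].
#' @param pss Centre x0 (point of subjective simultaneity), ms.
#' @param b Width (temporal-binding-window proxy), ms.
#' @export
sj_probability <- function(soa_ms, a, pss, b) {
  a * exp(-0.5 * ((soa_ms - pss) / b)^2)
}

#' Logistic "vision first" probability
#'
#' `1 / (1 + exp(-(x - x0) / b))` on the proportion scale.
#'
#' @inheritParams sj_probability
#' @export
toj_probability <- function(soa_ms, pss, b) {
  1 / (1 + exp(-(soa_ms - pss) / b))
}

simulate_judgment <- function(config, task) {
  stopifnot(inherits(config, "sim_config"))
  pts <- participant_table(config)
  sess <- sessions_for_task(config, task)
  builder <- if (task == "SJ") build_sj_design else build_toj_design
  out <- list()
  for (i in seq_len(nrow(pts))) {
    for (j in seq_len(nrow(sess))) {
      pid <- pts$participant_id[i]
      sid <- sess$session_id[j]
      eff <- effects_for(config, pts$group[i], sess$phase[j])
      des <- builder(substream_seed(config$seed, paste0(task, "-design"),
                                    pid, sid))
      set.seed(substream_seed(config$seed, paste0(task, "-resp"), pid, sid))
      tr <- des$trials
      if (task == "SJ") {
        p <- sj_probability(
          tr$soa_ms, config$sj_truth[["a"]],
          config$sj_truth[["pss"]] + pts$sj_pss_offset[i] + eff$pss_shift_ms,
          config$sj_truth[["b"]] * exp(pts$b_lnoffset[i]) * eff$b_scale)
        resp <- ifelse(stats::runif(nrow(tr)) < p,
                       "simultaneous", "not_simultaneous")
      } else {
        p <- toj_probability(
          tr$soa_ms,
          config$toj_truth[["pss"]] + pts$toj_pss_offset[i] +
            eff$pss_shift_ms,
          config$toj_truth[["b"]] * exp(pts$b_lnoffset[i]) * eff$b_scale)
        resp <- ifelse(stats::runif(nrow(tr)) < p,
                       "vision_first", "auditory_first")
      }
      rec <- record_frame(pid, pts$group[i], sid, sess$phase[j], tr)
      rec$response <- resp
      rec$rt_ms <- NA_real_
      out[[length(out) + 1L]] <- rec
    }
  }
  do.call(rbind, out)
}

#' Simulate the simultaneity-judgment task
#'
#' Per-trial Bernoulli draws from the Gaussian response model
#' [sj_probability()], with participant- and session-level shifts of the
#' centre and width.
#'
#' @inheritParams simulate_rt_dataset
#' @return Trial-record data frame; `response` is `"simultaneous"` /
#'   `"not_simultaneous"`.
#' @export
simulate_sj_dataset <- function(config) simulate_judgment(config, "SJ")

#' Simulate the temporal-order-judgment task
#'
#' Per-trial Bernoulli draws from the logistic model [toj_probability()].
#'
#' @inheritParams simulate_rt_dataset
#' @return Trial-record data frame; `response` is `"vision_first"` /
#'   `"auditory_first"`.
#' @export
simulate_toj_dataset <- function(config) simulate_judgment(config, "TOJ")

#' Flash-illusion "saw two flashes" probability on illusory trials
#'
#' `lapse + (1 - lapse) * g0 * exp(-|SOA| / tau_decay)`: the illusion is
#' strongest at SOA 0 and decays exponentially as the beeps move away from
#' the flash, mirroring the narrow temporal window of the illusion.
#'
#' @param soa_ms Signed SOA, ms.
#' @param g0 Illusion strength at SOA 0.
#' @param tau_decay Decay constant, ms.
#' @param lapse Lapse rate.
#' @export
sifi_illusion_probability <- function(soa_ms, g0, tau_decay, lapse = 0) {
  lapse + (1 - lapse) * g0 * exp(-abs(soa_ms) / tau_decay)
}

#' Simulate the sound-induced flash illusion task
#'
#' Illusory one-flash/two-beep trials report "2" with probability
#' [sifi_illusion_probability()], "3" with probability `p_report3` times
#' that (reports are not capped at the presented count), and the veridical
#' "1" otherwise. Control and unimodal trials are correct with probability
#' `1 - eps_control` and off by one otherwise.
#'
#' @inheritParams simulate_rt_dataset
#' @return Trial-record data frame; `response` is the reported count.
#' @export
simulate_sifi_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  pts <- participant_table(config)
  sess <- sessions_for_task(config, "SIFI")
  st <- config$sifi_truth
  out <- list()
  for (i in seq_len(nrow(pts))) {
    g0_i <- stats::plogis(stats::qlogis(min(max(st[["g0"]], 1e-6), 1 - 1e-6)) +
                            pts$g0_logit_offset[i])
    for (j in seq_len(nrow(sess))) {
      pid <- pts$participant_id[i]
      sid <- sess$session_id[j]
      eff <- effects_for(config, pts$group[i], sess$phase[j])
      des <- build_sifi_design(substream_seed(config$seed, "sifi-design",
                                              pid, sid))
      set.seed(substream_seed(config$seed, "sifi-resp", pid, sid))
      tr <- des$trials
      g0 <- min(g0_i * eff$g0_scale, 1)
      correct <- ifelse(tr$block == "unimodal_auditory",
                        tr$n_beeps, tr$n_flashes)
      resp <- integer(nrow(tr))
      u <- stats::runif(nrow(tr))
      for (r in seq_len(nrow(tr))) {
        if (tr$condition[r] == "1f2b") {
          p2 <- sifi_illusion_probability(tr$soa_ms[r], g0,
                                          st[["tau_decay"]], st[["lapse"]])
          p3 <- st[["p_report3"]] * p2
          resp[r] <- if (u[r] < p2) 2L
                     else if (u[r] < p2 + p3) 3L
                     else 1L
        } else {
          resp[r] <- if (u[r] < 1 - st[["eps_control"]]) correct[r]
                     else max(correct[r] + sample(c(-1L, 1L), 1L), 1L)
        }
      }
      rec <- record_frame(pid, pts$group[i], sid, sess$phase[j], tr)
      rec$response <- as.character(resp)
      rec$rt_ms <- NA_real_
      out[[length(out) + 1L]] <- rec
    }
  }
  do.call(rbind, out)
}

#' Simulate the full cohort across all four tasks
#'
#' @inheritParams simulate_rt_dataset
#' @return One trial-record data frame combining RT, SIFI, SJ and TOJ
#'   tasks.
#' @export
simulate_cohort <- function(config) {
  rbind(simulate_rt_dataset(config),
        simulate_sifi_dataset(config),
        simulate_sj_dataset(config),
        simulate_toj_dataset(config))
}
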