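# Small cohort configuration used where the full 27 x 8-session default
# would be needlessly slow.
quick_config <- function(seed = 1L, ...) {
  sim_config(
    n_intervention = 3L, n_control = 3L,
    sessions = data.frame(
      session_id = c("baseline", "s1_pre", "s1_post", "post_intervention"),
      phase = c("baseline", "pre", "post", "post_intervention")),
    seed = seed, ...)
}

# One-group, one-session RT cohort: the unit at which the race-model
# permutation test operates (13 participants, 50 trials per modality).
rt_cohort_rmi <- function(seed, c_shift, n = 13L, n_perm = 2000L) {
  cfg <- sim_config(
    n_intervention = n, n_control = 1L,
    sessions = data.frame(session_id = "baseline", phase = "baseline"),
    coactivation_shift_ms = c_shift, seed = seed)
  trials <- simulate_rt_dataset(cfg)
  trials <- trials[trials$group == "physical_activity", , drop = FALSE]
  suppressWarnings(rmi_analysis(trials, n_perm = n_perm, seed = seed))
}

# Hand-built SIFI trial rows for scoring tests.
make_sifi_trials <- function(condition, soa_ms, response,
                             block = "audiovisual",
                             pid = "P01", sid = "baseline") {
  n_flashes <- c(`1f1b` = 1L, `2f2b` = 2L, `1f2b` = 1L,
                 `2f` = 2L, `2b` = 0L)[condition]
  n_beeps <- c(`1f1b` = 1L, `2f2b` = 2L, `1f2b` = 2L,
               `2f` = 0L, `2b` = 2L)[condition]
  data.frame(
    participant_id = pid, group = "physical_activity", session_id = sid,
    phase = "baseline", task = "SIFI", block = block,
    condition = condition, soa_ms = as.integer(soa_ms),
    lead = "none", n_flashes = n_flashes, n_beeps = n_beeps,
    response = as.character(response), rt_ms = NA_real_,
    iti_ms = 1500L, stringsAsFactors = FALSE)
}

# Per-SOA binomial response table drawn from a ground-truth curve.
binomial_table <- function(probs_fun, soas, n_per_soa) {
  k <- stats::rbinom(length(soas), n_per_soa, probs_fun(soas))
  out <- data.frame(soa_ms = soas, n_trials = n_per_soa, n_target = k,
                    proportion = k / n_per_soa)
  class(out) <- c("soa_table", class(out))
  out
}

DESIGN_SOAS <- c(-230, -150, -70, 0, 70, 150, 230)
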