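#' Trial-level CSV dialect and the end-to-end pipeline
#'
#' Trials travel as plain CSV with one row per trial and a fixed header;
#' the infinity sentinel is the literal string `"inf"` so trimmed response
#' times survive a round trip. [run_pipeline()] chains simulation through
#' the group report deterministically from one master seed.
#'
#' @name io_pipeline
NULL

TRIAL_COLUMNS <- c("participant_id", "group", "session_id", "phase",
                   "task", "block", "condition", "soa_ms", "lead",
                   "n_flashes", "n_beeps", "response", "rt_ms", "iti_ms")

VALID_TOKENS <- list(
  task = c("RT", "SIFI", "SJ", "TOJ"),
  block = c("practice", "unimodal_visual", "unimodal_auditory",
            "audiovisual", "main"),
  condition = c("A", "V", "AV", "1f1b", "2f2b", "1f2b", "2f", "2b",
                "sj_pair", "toj_pair"),
  lead = c("none", "auditory_lead", "vision_lead"),
  phase = c("baseline", "pre", "post", "post_intervention")
)

#' Write trial records to CSV
#'
#' @param records Trial-record data frame (the columns produced by the
#'   simulators; extra columns are dropped, missing optional ones written
#'   empty).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(records, path) {
  out <- records
  for (col in TRIAL_COLUMNS) if (is.null(out[[col]])) out[[col]] <- NA
  out <- out[, TRIAL_COLUMNS]
  out$rt_ms <- ifelse(is.na(out$rt_ms), "",
                      ifelse(is.infinite(out$rt_ms), "inf",
                             format(out$rt_ms, digits = 15,
                                    scientific = FALSE, trim = TRUE)))
  out$response[is.na(out$response)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read trial records from CSV
#'
#' Validates every categorical token and the RT field; malformed rows
#' raise an error naming the offending row number.
#'
#' @param path Input file path.
#' @return Trial-record data frame; `rt_ms` is numeric with `Inf` for the
#'   `"inf"` sentinel and `NA` where empty.
#' @export
read_trials <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(TRIAL_COLUMNS, names(raw))
  if (length(missing_cols) > 0)
    stop("malformed header: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  for (field in names(VALID_TOKENS)) {
    bad <- which(!(raw[[field]] %in% VALID_TOKENS[[field]]))
    if (length(bad) > 0)
      stop("row ", bad[1], ": invalid ", field, " token '",
           raw[[field]][bad[1]], "'")
  }
  rt_chr <- raw$rt_ms
  rt <- suppressWarnings(as.numeric(rt_chr))
  rt[rt_chr == "inf"] <- Inf
  rt[rt_chr == ""] <- NA_real_
  bad_rt <- which(!is.na(rt_chr) & rt_chr != "" & rt_chr != "inf" &
                    is.na(suppressWarnings(as.numeric(rt_chr))))
  if (length(bad_rt) > 0)
    stop("row ", bad_rt[1], ": malformed rt_ms value '",
         rt_chr[bad_rt[1]], "'")
  raw$rt_ms <- rt
  raw$response[raw$response == ""] <- NA_character_
  for (col in c("soa_ms", "n_flashes", "n_beeps", "iti_ms"))
    raw[[col]] <- as.integer(raw[[col]])
  raw
}

# Long measure table feeding difference_scores(): one row per
# participant x session x measure.
collect_measures <- function(trials, rmi, sj_fits, toj_fits, sifi_tab) {
  rows <- list()
  s <- rmi$summaries
  for (stat in c("mean_rt", "median_rt")) {
    rows[[stat]] <- data.frame(
      participant_id = s$participant_id, group = s$group,
      measure = paste0(sub("_rt", "", stat), "_rt_", s$modality),
      session_id = s$session_id, phase = s$phase, value = s[[stat]])
  }
  phase_of <- unique(trials[, c("session_id", "phase")])
  auc_rows <- list()
  grp_of <- unique(trials[, c("participant_id", "group")])
  for (sid in names(rmi$waves)) {
    pw <- rmi$waves[[sid]]
    auc_rows[[sid]] <- data.frame(
      participant_id = names(pw),
      group = grp_of$group[match(names(pw), grp_of$participant_id)],
      measure = "auc",
      session_id = sid,
      phase = phase_of$phase[match(sid, phase_of$session_id)],
      value = vapply(pw, auc_first_quartile, numeric(1)))
  }
  rows$auc <- do.call(rbind, auc_rows)
  rows$sifi <- data.frame(
    participant_id = sifi_tab$participant_id, group = sifi_tab$group,
    measure = paste0("sifi_acc_", sifi_tab$condition),
    session_id = sifi_tab$session_id, phase = sifi_tab$phase,
    value = sifi_tab$accuracy)
  fit_rows <- function(fits, tag) {
    keep <- fits[!fits$excluded, , drop = FALSE]
    if (nrow(keep) == 0) return(NULL)
    map <- c(tbw = "b", pss = "pss", amplitude = "a")
    do.call(rbind, lapply(names(map), function(nm) {
      data.frame(participant_id = keep$participant_id, group = keep$group,
                 measure = paste0(nm, "_", tag),
                 session_id = keep$session_id, phase = keep$phase,
                 value = keep[[map[[nm]]]])
    }))
  }
  rows$sj <- fit_rows(sj_fits, "sj")
  rows$toj <- fit_rows(toj_fits, "toj")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[!is.na(out$value), , drop = FALSE]
}

#' Run the full analysis pipeline on a configuration
#'
#' Simulates the cohort, trims response times, runs the race-model
#' analysis per session, fits the judgment tasks, scores the flash
#' illusion, computes chronic/acute difference scores and the group
#' report. Two runs with the same configuration produce identical output.
#'
#' @param config A [sim_config()]; its seed drives every stage.
#' @param n_perm Monte Carlo permutation count for [gondan_test()] (used
#'   only above 14 participants per group analysis).
#' @param out_dir Optional directory: writes `trials.csv`,
#'   `difference_scores.csv` and `report.json` there.
#' @return List of class `pipeline_result`: `trials`, `rmi`, `sj_fits`,
#'   `toj_fits`, `sifi`, `measures`, `diff_scores`, `report` (a plain
#'   list ready for JSON).
#' @export
run_pipeline <- function(config = sim_config(), n_perm = 10000L,
                         out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  trials <- simulate_cohort(config)
  rmi <- rmi_analysis(trials, n_perm = n_perm, seed = config$seed)
  sj_fits <- fit_judgment_task(trials, "SJ")
  toj_fits <- fit_judgment_task(trials, "TOJ")
  sifi_tab <- sifi_condition_matrix(trials)
  measures <- collect_measures(trials, rmi, sj_fits, toj_fits, sifi_tab)
  diffs <- difference_scores(measures)
  grp <- group_report(diffs)
  excl <- rbind(sj_fits[sj_fits$excluded, c("participant_id", "session_id",
                                            "task", "r2")],
                toj_fits[toj_fits$excluded, c("participant_id", "session_id",
                                              "task", "r2")])
  report <- list(
    seed = config$seed,
    n_participants = list(
      physical_activity = config$n_intervention,
      reading = config$n_control),
    n_trials = nrow(trials),
    rt_fraction_finite = rmi$fraction_finite,
    rmi_tests = lapply(rmi$tests, function(by_session)
      lapply(by_session, function(t)
        list(tmax = t$tmax, tcrit = t$tcrit, p_value = t$p_value,
             mean_auc = t$group_auc_mean,
             n_permutations = t$n_permutations))),
    psychometric_exclusions = if (nrow(excl) == 0) list() else
      lapply(seq_len(nrow(excl)), function(i)
        list(participant_id = excl$participant_id[i],
             session_id = excl$session_id[i], task = excl$task[i],
             r2 = excl$r2[i], reason = "r2 below exclusion threshold")),
    group_summary = grp$summary,
    delegated = grp$delegated
  )
  res <- structure(
    list(trials = trials, rmi = rmi, sj_fits = sj_fits,
         toj_fits = toj_fits, sifi = sifi_tab, measures = measures,
         diff_scores = diffs, report = report),
    class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trials(trials, file.path(out_dir, "trials.csv"))
    utils::write.csv(diffs, file.path(out_dir, "difference_scores.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}
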