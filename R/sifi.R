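#' Sound-induced flash illusion scoring
#'
#' A trial is correct when the reported count equals the number of flashes
#' presented (audiovisual and visual blocks) or the number of beeps
#' (auditory block); on illusory one-flash/two-beep trials the veridical
#' answer is therefore "1", and lower accuracy there indexes susceptibility
#' to the illusion. Reports of three or more stimuli are always incorrect
#' under this design.
#'
#' @name sifi_scoring
NULL

sifi_correct <- function(trials) {
  expected <- ifelse(trials$block == "unimodal_auditory",
                     trials$n_beeps, trials$n_flashes)
  as.integer(trials$response) == expected
}

acc_of <- function(ok) if (length(ok) == 0) NA_real_ else mean(ok)

#' Score the flash-illusion task for one participant/session
#'
#' @param trials Trial-record rows for a single participant and session;
#'   practice trials are excluded and trials with missing responses are
#'   dropped from both numerator and denominator.
#' @return List of class `sifi_scores`: overall audiovisual accuracy,
#'   per-condition accuracies (1f1b, 2f2b, illusory 1f2b, unimodal visual,
#'   unimodal auditory), a per-|SOA| breakdown for the illusory condition,
#'   and the number of dropped trials.
#' @export
score_sifi <- function(trials) {
  tr <- trials[trials$task == "SIFI" & trials$block != "practice", ,
               drop = FALSE]
  if (nrow(tr) == 0) stop("no scorable SIFI trials present")
  if (length(unique(tr$participant_id)) > 1 ||
      length(unique(tr$session_id)) > 1)
    stop("score_sifi expects a single participant and session")
  missing <- is.na(tr$response) | tr$response == ""
  n_dropped <- sum(missing)
  tr <- tr[!missing, , drop = FALSE]
  ok <- sifi_correct(tr)
  av <- tr$block == "audiovisual"
  ill <- tr$condition == "1f2b"
  per_soa <- vapply(sort(unique(abs(tr$soa_ms[ill]))), function(s)
    acc_of(ok[ill & abs(tr$soa_ms) == s]), numeric(1))
  names(per_soa) <- sort(unique(abs(tr$soa_ms[ill])))
  structure(
    list(participant_id = tr$participant_id[1],
         session_id = tr$session_id[1],
         group = tr$group[1], phase = tr$phase[1],
         acc_overall = acc_of(ok[av]),
         acc_1f1b = acc_of(ok[tr$condition == "1f1b"]),
         acc_2f2b = acc_of(ok[tr$condition == "2f2b"]),
         acc_illusory = acc_of(ok[ill]),
         acc_unimodal_V = acc_of(ok[tr$block == "unimodal_visual"]),
         acc_unimodal_A = acc_of(ok[tr$block == "unimodal_auditory"]),
         acc_illusory_by_soa = per_soa,
         n_dropped = n_dropped),
    class = "sifi_scores"
  )
}

#' @export
print.sifi_scores <- function(x, ...) {
  cat(sprintf(
    "<sifi_scores> %s/%s overall=%.2f 1f1b=%.2f 2f2b=%.2f illusory=%.2f\n",
    x$participant_id, x$session_id, x$acc_overall, x$acc_1f1b,
    x$acc_2f2b, x$acc_illusory))
  invisible(x)
}

#' Long-format session-by-condition accuracy table
#'
#' Scores every participant x session in a trial table and stacks the four
#' audiovisual condition accuracies (overall, 1f1b, 2f2b, illusory) plus
#' the two unimodal accuracies into the long format the group analyses
#' consume. Missing sessions simply have no rows.
#'
#' @param trials Trial-record data frame containing SIFI trials.
#' @return Data frame keyed by (participant_id, group, session_id, phase,
#'   condition) with an `accuracy` column.
#' @export
sifi_condition_matrix <- function(trials) {
  tr <- trials[trials$task == "SIFI", , drop = FALSE]
  if (nrow(tr) == 0) stop("no SIFI trials present")
  keys <- unique(tr[, c("participant_id", "session_id")])
  conds <- c(overall = "acc_overall", `1f1b` = "acc_1f1b",
             `2f2b` = "acc_2f2b", illusory = "acc_illusory",
             unimodal_V = "acc_unimodal_V", unimodal_A = "acc_unimodal_A")
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    s <- score_sifi(tr[tr$participant_id == keys$participant_id[i] &
                         tr$session_id == keys$session_id[i], ,
                       drop = FALSE])
    data.frame(participant_id = s$participant_id, group = s$group,
               session_id = s$session_id, phase = s$phase,
               condition = names(conds),
               accuracy = vapply(conds, function(f) s[[f]], numeric(1)),
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
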