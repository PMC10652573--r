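#' Task designs for the four perceptual tasks
#'
#' Builders for the exact trial schedules of the response-time (RT),
#' sound-induced flash illusion (SIFI), simultaneity judgment (SJ) and
#' temporal-order judgment (TOJ) tasks. Each builder is a pure function of
#' its seed: the same seed always yields the same trial order, and different
#' seeds permute the same multiset of conditions. Simulation and scoring both
#' consume these designs, so trial counts and SOA sets are defined in exactly
#' one place.
#'
#' Sign convention for `soa_ms`: positive = vision leads, negative =
#' audition leads, 0 = simultaneous. Inter-trial intervals are drawn
#' uniformly on integer milliseconds in \[1000, 3000\].
#'
#' @name task_design
NULL

SOA_SET <- c(-230L, -150L, -70L, 0L, 70L, 150L, 230L)
SOA_UNIMODAL <- c(70L, 150L, 230L)
ITI_RANGE_MS <- c(1000L, 3000L)

lead_of <- function(soa_ms, unimodal = FALSE) {
  if (unimodal) return(rep("none", length(soa_ms)))
  ifelse(soa_ms > 0L, "vision_lead", ifelse(soa_ms < 0L, "auditory_lead", "none"))
}

draw_iti <- function(n) {
  sample.int(ITI_RANGE_MS[2] - ITI_RANGE_MS[1] + 1L, n, replace = TRUE) +
    ITI_RANGE_MS[1] - 1L
}

new_task_design <- function(task, trials, n_practice, seed) {
  trials$index <- seq_len(nrow(trials))
  structure(
    list(task = task, trials = trials, n_practice = n_practice,
         rng_seed = seed),
    class = "task_design"
  )
}

#' @export
print.task_design <- function(x, ...) {
  cat(sprintf("<task_design> task=%s, %d trials (%d practice), seed=%d\n",
              x$task, nrow(x$trials), x$n_practice, x$rng_seed))
  print(table(x$trials$block, x$trials$condition))
  invisible(x)
}

trial_frame <- function(task, block, condition, soa_ms, lead,
                        n_flashes, n_beeps) {
  data.frame(
    task = task, block = block, condition = condition,
    soa_ms = as.integer(soa_ms), lead = lead,
    n_flashes = as.integer(n_flashes), n_beeps = as.integer(n_beeps),
    stringsAsFactors = FALSE
  )
}

#' Build the redundant-signals response-time task design
#'
#' 150 main trials (50 each of auditory-only A, visual-only V, and
#' simultaneous audiovisual AV, in seeded random order) preceded by 6
#' practice trials (two per modality).
#'
#' @param seed Integer seed; the design is a pure function of it.
#' @return A `task_design` whose `trials` data frame has one row per trial
#'   with columns task, block, condition, soa_ms, lead, n_flashes, n_beeps,
#'   iti_ms and index.
#' @export
build_rt_design <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  set.seed(seed)
  main <- trial_frame(
    "RT", "main",
    rep(c("A", "V", "AV"), each = 50L),
    0L, "none",
    rep(c(0L, 1L, 1L), each = 50L),
    rep(c(1L, 0L, 1L), each = 50L)
  )
  main <- main[sample.int(nrow(main)), , drop = FALSE]
  practice <- trial_frame(
    "RT", "practice", rep(c("A", "V", "AV"), times = 2L),
    0L, "none", rep(c(0L, 1L, 1L), times = 2L), rep(c(1L, 0L, 1L), times = 2L)
  )
  trials <- rbind(practice, main)
  trials$iti_ms <- draw_iti(nrow(trials))
  rownames(trials) <- NULL
  new_task_design("RT", trials, 6L, as.integer(seed))
}

#' Build the sound-induced flash illusion task design
#'
#' 166 trials in total: 6 practice, a 100-trial audiovisual block (ten cells
#' of ten repetitions: one-flash/one-beep at SOA 0; two-flash/two-beep at
#' SOAs 70/150/230 ms; illusory one-flash/two-beep at +/-70, +/-150,
#' +/-230 ms, where the sign carries auditory- vs vision-lead), and two
#' 30-trial unimodal blocks (two flashes or two beeps at SOAs 70/150/230,
#' ten repetitions each). The unimodal visual trials are interleaved with
#' the audiovisual block; the auditory block is run separately.
#'
#' @inheritParams build_rt_design
#' @return A `task_design`; see [build_rt_design()].
#' @export
build_sifi_design <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  set.seed(seed)
  av_cells <- rbind(
    data.frame(condition = "1f1b", soa_ms = 0L,  n_flashes = 1L, n_beeps = 1L),
    data.frame(condition = "2f2b", soa_ms = SOA_UNIMODAL,
               n_flashes = 2L, n_beeps = 2L),
    data.frame(condition = "1f2b", soa_ms = c(-SOA_UNIMODAL, SOA_UNIMODAL),
               n_flashes = 1L, n_beeps = 2L)
  )
  av <- av_cells[rep(seq_len(nrow(av_cells)), each = 10L), , drop = FALSE]
  av <- trial_frame("SIFI", "audiovisual", av$condition, av$soa_ms,
                    lead_of(av$soa_ms), av$n_flashes, av$n_beeps)
  vis <- trial_frame("SIFI", "unimodal_visual",
                     "2f", rep(SOA_UNIMODAL, each = 10L),
                     "none", 2L, 0L)
  aud <- trial_frame("SIFI", "unimodal_auditory",
                     "2b", rep(SOA_UNIMODAL, each = 10L),
                     "none", 0L, 2L)
  # visual unimodal trials are randomized together with the audiovisual block
  inter <- rbind(av, vis)
  inter <- inter[sample.int(nrow(inter)), , drop = FALSE]
  aud <- aud[sample.int(nrow(aud)), , drop = FALSE]
  practice <- trial_frame(
    "SIFI", "practice",
    c("1f1b", "1f1b", "2f2b", "2f2b", "1f2b", "1f2b"),
    c(0L, 0L, 150L, 150L, -150L, 150L),
    c("none", "none", "vision_lead", "vision_lead",
      "auditory_lead", "vision_lead"),
    c(1L, 1L, 2L, 2L, 1L, 1L), c(1L, 1L, 2L, 2L, 2L, 2L)
  )
  trials <- rbind(practice, inter, aud)
  trials$iti_ms <- draw_iti(nrow(trials))
  rownames(trials) <- NULL
  new_task_design("SIFI", trials, 6L, as.integer(seed))
}

build_judgment_design <- function(task, seed) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  set.seed(seed)
  condition <- if (task == "SJ") "sj_pair" else "toj_pair"
  main <- trial_frame(task, "main", condition,
                      rep(SOA_SET, each = 10L),
                      lead_of(rep(SOA_SET, each = 10L)), 1L, 1L)
  main <- main[sample.int(nrow(main)), , drop = FALSE]
  prac_soa <- c(0L, 70L, -70L, 230L, -230L, 150L)
  practice <- trial_frame(task, "practice", condition, prac_soa,
                          lead_of(prac_soa), 1L, 1L)
  trials <- rbind(practice, main)
  trials$iti_ms <- draw_iti(nrow(trials))
  rownames(trials) <- NULL
  new_task_design(task, trials, 6L, as.integer(seed))
}

#' Build the simultaneity / temporal-order judgment designs
#'
#' Seven SOAs (0, +/-70, +/-150, +/-230 ms) with ten trials each in seeded
#' random order, plus six practice trials: 76 trials. The TOJ design is
#' structurally identical to the SJ design (only the instruction differs),
#' so the same seed yields the same SOA sequence in both.
#'
#' @inheritParams build_rt_design
#' @return A `task_design`; see [build_rt_design()].
#' @export
build_sj_design <- function(seed) build_judgment_design("SJ", seed)

#' @rdname build_sj_design
#' @export
build_toj_design <- function(seed) build_judgment_design("TOJ", seed)
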