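#' Session contrasts and rank statistics
#'
#' Chronic contrasts subtract baseline from post-intervention; acute
#' contrasts subtract each pre-session from its paired post-session
#' (later minus earlier throughout, so a negative RT difference is an
#' improvement). The tie-adjusted Friedman rank test covers the repeated
#' occasions where variance homogeneity fails for accuracy-type outcomes.
#'
#' @name aggregate_stats
NULL

#' Chronic and acute difference scores
#'
#' @param measures Long data frame with columns participant_id, group,
#'   measure, session_id, phase, value (one row per participant x session
#'   x measure).
#' @return Data frame with columns participant_id, group, measure,
#'   contrast (`"chronic"` or `"acute_k"`), value. Contrasts with a
#'   missing side emit no row.
#' @export
difference_scores <- function(measures) {
  req <- c("participant_id", "group", "measure", "session_id", "phase",
           "value")
  stopifnot(all(req %in% names(measures)))
  if (nrow(measures) == 0)
    return(data.frame(participant_id = character(), group = character(),
                      measure = character(), contrast = character(),
                      value = numeric()))
  # acute pairs are identified by a shared "sK" session stem
  stem <- sub("_(pre|post)$", "", measures$session_id)
  rows <- list()
  keys <- unique(measures[, c("participant_id", "group", "measure")])
  for (i in seq_len(nrow(keys))) {
    sub <- measures[measures$participant_id == keys$participant_id[i] &
                      measures$measure == keys$measure[i], , drop = FALSE]
    sstem <- stem[measures$participant_id == keys$participant_id[i] &
                    measures$measure == keys$measure[i]]
    add <- function(contrast, later, earlier) {
      if (length(later) == 1 && length(earlier) == 1 &&
          !is.na(later) && !is.na(earlier))
        rows[[length(rows) + 1L]] <<- cbind(
          keys[i, , drop = FALSE],
          data.frame(contrast = contrast, value = later - earlier))
    }
    add("chronic",
        sub$value[sub$phase == "post_intervention"],
        sub$value[sub$phase == "baseline"])
    acute_stems <- sort(unique(sstem[sub$phase %in% c("pre", "post")]))
    for (k in seq_along(acute_stems)) {
      st <- acute_stems[k]
      add(paste0("acute_", k),
          sub$value[sstem == st & sub$phase == "post"],
          sub$value[sstem == st & sub$phase == "pre"])
    }
  }
  if (length(rows) == 0)
    return(data.frame(participant_id = character(), group = character(),
                      measure = character(), contrast = character(),
                      value = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tie-adjusted Friedman rank test
#'
#' Ranks within each block (row), with average ranks for ties, and forms
#' the tie-adjusted chi-squared statistic on k - 1 degrees of freedom. A
#' table whose blocks are all constant is fully tied: the statistic is 0
#' and p = 1.
#'
#' @param x Numeric matrix: blocks (e.g. participants) in rows, treatments
#'   (e.g. sessions or conditions) in columns; no missing values.
#' @return List of class `friedman_result`: `chi2`, `df`, `p_value`, `n`,
#'   `k`.
#' @export
friedman_test <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("incomplete blocks are not supported; drop or complete them")
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) stop("need at least 2 blocks and 2 treatments")
  r <- t(apply(x, 1, rank))
  rj <- colSums(r)
  tie_term <- sum(apply(r, 1, function(row) {
    tt <- table(row)
    sum(tt^3 - tt)
  }))
  denom <- n * k * (k + 1) - tie_term / (k - 1)
  chi2 <- if (denom <= 0) 0 else
    12 * sum((rj - n * (k + 1) / 2)^2) / denom
  structure(
    list(chi2 = chi2, df = k - 1L,
         p_value = if (denom <= 0) 1 else
           stats::pchisq(chi2, k - 1, lower.tail = FALSE),
         n = n, k = k),
    class = "friedman_result"
  )
}

#' @export
print.friedman_result <- function(x, ...) {
  cat(sprintf("<friedman_result> chi2(%d) = %.3f, p = %.4g (n = %d)\n",
              x$df, x$chi2, x$p_value, x$n))
  invisible(x)
}

#' Group-level summary of difference scores
#'
#' Per-group mean, SE and n for every measure x contrast cell. Heavier
#' machinery (mixed-design ANOVA, covariate adjustment) is deliberately
#' delegated to standard routines by the caller; any such delegation can
#' be recorded in the `delegated` field of the returned report.
#'
#' @param diffs Output of [difference_scores()].
#' @param delegated Optional character vector naming external routines the
#'   caller applied (recorded verbatim, not executed here).
#' @return List of class `group_report` with a `summary` data frame
#'   (group, measure, contrast, n, mean, se) and `delegated`.
#' @export
group_report <- function(diffs, delegated = character()) {
  if (is.null(diffs) || nrow(diffs) == 0)
    return(structure(list(summary = data.frame(), delegated = delegated),
                     class = "group_report"))
  keys <- unique(diffs[, c("group", "measure", "contrast")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    v <- diffs$value[diffs$group == keys$group[i] &
                       diffs$measure == keys$measure[i] &
                       diffs$contrast == keys$contrast[i]]
    data.frame(keys[i, , drop = FALSE], n = length(v), mean = mean(v),
               se = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                    else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(list(summary = out, delegated = delegated),
            class = "group_report")
}
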