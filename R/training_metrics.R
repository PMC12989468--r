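# Strength and adherence metrics derived from machine-recorded session logs
# and the week-0/4/8 fitness tests.

#' Average strength gain across machines
#'
#' The headline strength metric: the mean over exercise machines of the log2
#' fold change in maximum strength between two assessments, reported both in
#' log2 units and as a percent gain `(2^mean - 1) * 100`. The percent is
#' derived from the mean log2 fold change, not from the mean of per-machine
#' percents.
#'
#' @param baseline,followup data.frames with columns `machine` and
#'   `max_strength` (kg), one row per machine, covering the same machine set.
#' @return list with `avg_log2fc` and `percent_gain`.
#' @export
average_strength_gain <- function(baseline, followup) {
  b <- stats::setNames(baseline$max_strength, baseline$machine)
  f <- stats::setNames(followup$max_strength, followup$machine)
  missing <- union(setdiff(names(b), names(f)), setdiff(names(f), names(b)))
  if (length(missing)) {
    stop("machines missing at one timepoint: ", paste(missing, collapse = ", "))
  }
  f <- f[names(b)]
  if (any(b <= 0) || any(f <= 0)) stop("max strength must be positive")
  lfc <- mean(log2(f / b))
  list(avg_log2fc = lfc, percent_gain = (2^lfc - 1) * 100)
}

#' Leg press maximum strength at a timepoint
#'
#' @param assessments data.frame with columns `timepoint`, `machine`,
#'   `max_strength`.
#' @param timepoint one of "W0", "W4", "W8".
#' @param machine machine name (default "Leg press").
#' @return max strength in kg (the maximum, if several records fall in the
#'   test window).
#' @export
legpress_max <- function(assessments, timepoint, machine = "Leg press") {
  rows <- assessments$timepoint == timepoint & assessments$machine == machine
  if (!any(rows)) {
    stop("no ", machine, " record at ", timepoint)
  }
  max(assessments$max_strength[rows])
}

#' Parameters of the surrogate age-strength reference curve
#'
#' The reference is an exponential decline in relative strength
#' (strength / body weight) after a peak age:
#' `R(age) = peak_relative_strength * exp(-decline_rate * (age - peak_age))`.
#' This is a deliberately minimal monotone surrogate for the proprietary
#' age-strength model used by commercial training equipment; its parameters
#' are exposed so they can be refit, and results carry the 21-year floor of
#' the commercial metric.
#'
#' @param peak_age years at which relative strength peaks.
#' @param peak_relative_strength named numeric, sex-specific peak relative
#'   strength (composite over machines, strength / body weight).
#' @param decline_rate proportional decline per year (> 0).
#' @param floor minimum reportable age in years.
#' @return list of class `bioage_params`.
#' @export
bioage_params <- function(peak_age = 25,
                          peak_relative_strength = c(male = 1.2, female = 0.85),
                          decline_rate = 0.01, floor = 21) {
  stopifnot(decline_rate > 0, floor >= 0)
  structure(list(peak_age = peak_age,
                 peak_relative_strength = peak_relative_strength,
                 decline_rate = decline_rate, floor = floor),
            class = "bioage_params")
}

#' Strength-based biological age
#'
#' Each machine's relative strength (strength / body weight) is mapped to the
#' age at which the sex-specific reference curve takes that value (analytic
#' inversion of the exponential surrogate, extrapolated below the peak age
#' for above-reference strength); the per-machine ages are averaged and the
#' average is clamped to `params$floor` (so exceptionally strong individuals
#' bottom out at 21 years). Stronger than average for one's age gives a
#' younger BioAge, weaker an older one.
#'
#' @param relative_strength numeric vector, one value per machine (> 0).
#' @param age chronological age in years (used only by callers that want the
#'   fixed-point check; the mapping itself does not depend on it).
#' @param sex "male" or "female".
#' @param params a [bioage_params()] object.
#' @return BioAge in years.
#' @export
bioage_strength <- function(relative_strength, age, sex = "male",
                            params = bioage_params()) {
  if (!length(relative_strength)) stop("empty machine set")
  if (any(relative_strength <= 0)) stop("relative strength must be positive")
  peak <- params$peak_relative_strength[[sex]]
  ages <- params$peak_age - log(relative_strength / peak) / params$decline_rate
  max(mean(ages), params$floor)
}

#' Reference relative strength at a given age
#'
#' Forward evaluation of the surrogate curve behind [bioage_strength()]
#' (constant before the peak age).
#'
#' @inheritParams bioage_strength
#' @export
bioage_reference <- function(age, sex = "male", params = bioage_params()) {
  peak <- params$peak_relative_strength[[sex]]
  peak * exp(-params$decline_rate * pmax(age - params$peak_age, 0))
}

#' Training compliance
#'
#' Percent of targeted repetitions actually performed across all sessions.
#' Values above 100 (over-performance) are reported as-is, not clamped.
#'
#' @param sessions data.frame with columns `reps_target`, `reps_done`.
#' @return compliance percent.
#' @export
compliance <- function(sessions) {
  tt <- sum(sessions$reps_target)
  if (!nrow(sessions) || tt == 0) stop("undefined compliance: no targeted repetitions")
  100 * sum(sessions$reps_done) / tt
}

#' Number of distinct training days
#'
#' @param sessions data.frame with a `date` column.
#' @return count of distinct calendar dates with at least one session.
#' @export
training_days <- function(sessions) {
  if (!nrow(sessions)) return(0L)
  length(unique(as.character(sessions$date)))
}

#' Per-participant strength metrics table
#'
#' Computes, for every participant in the fitness-test table, the leg press
#' maxima, average log2 strength gains (W0-W4 and W0-W8, with the percent
#' form of the latter), BioAge at each timepoint, compliance and training-day
#' counts. Max strength per timepoint is taken from the fitness test; session
#' logs feed only compliance and training days.
#'
#' @param sessions session log data.frame (`participant`, `date`,
#'   `reps_target`, `reps_done`, ...).
#' @param fitness fitness-test data.frame (`participant`, `timepoint`,
#'   `machine`, `max_strength`).
#' @param participants optional participant data.frame with `participant`,
#'   `sex`, `age`, `body_weight` enabling the BioAge columns.
#' @param params [bioage_params()].
#' @return data.frame, one row per participant with complete W0/W8 tests.
#' @export
strength_metrics_table <- function(sessions, fitness, participants = NULL,
                                   params = bioage_params()) {
  ids <- unique(fitness$participant)
  rows <- lapply(ids, function(id) {
    ft <- fitness[fitness$participant == id, ]
    tp <- split(ft, ft$timepoint)
    if (is.null(tp$W0) || is.null(tp$W8)) return(NULL)
    g08 <- average_strength_gain(tp$W0, tp$W8)
    g04 <- if (!is.null(tp$W4)) average_strength_gain(tp$W0, tp$W4) else
      list(avg_log2fc = NA_real_, percent_gain = NA_real_)
    ss <- sessions[sessions$participant == id, ]
    bio <- c(W0 = NA_real_, W4 = NA_real_, W8 = NA_real_)
    if (!is.null(participants)) {
      pr <- participants[participants$participant == id, ]
      if (nrow(pr) == 1) {
        for (t in names(tp)) {
          bio[t] <- bioage_strength(tp[[t]]$max_strength / pr$body_weight,
                                    pr$age, pr$sex, params)
        }
      }
    }
    data.frame(participant = id,
               legpress_W0 = legpress_max(tp$W0, "W0"),
               legpress_W4 = if (!is.null(tp$W4)) legpress_max(tp$W4, "W4") else NA_real_,
               legpress_W8 = legpress_max(tp$W8, "W8"),
               avg_log2fc_W0W4 = g04$avg_log2fc,
               avg_log2fc_W0W8 = g08$avg_log2fc,
               percent_gain = g08$percent_gain,
               bioage_W0 = bio[["W0"]], bioage_W4 = bio[["W4"]],
               bioage_W8 = bio[["W8"]],
               compliance = if (nrow(ss)) compliance(ss) else NA_real_,
               training_days = training_days(ss),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
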