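# Diary-based endpoint derivation: daily UAS, weekly UAS7 and its
# itch/hive components, changes from baseline, responder classification
# with the nonresponder rule, and time-to-MID series.
#
# Conventions (the published endpoint definitions leave these open):
# * a day with exactly one observed session uses that session's sum;
# * a week is valid with >= 4 observed days; sums are prorated by
#   7/days_observed and rounded half-up to 1 decimal per component;
# * week w covers study days 7(w-1)+1 .. 7w; week 0 (baseline) covers
#   the 7 days immediately before day 1 (days -7 .. -1);
# * UAS7 is defined as itch7 + hive7 after component proration, so the
#   decomposition holds exactly for every patient-week.

MID_UAS7 <- 11          # minimally important difference, UAS7 reduction
WELL_CONTROLLED_MAX <- 6
MIN_DAYS_PER_WEEK <- 4

#' Score the daily UAS for one patient-day
#'
#' Each session score is itch + hive for that session (0-6); the daily
#' UAS is the average of the morning and evening session scores. With a
#' single observed session, that session's sum is used; with none, the
#' day is missing.
#'
#' @param entries data.frame of 0-2 diary rows for one patient-day with
#'   columns \code{session}, \code{itch_score}, \code{hive_score} (and
#'   optionally \code{missing})
#' @return list with \code{uas}, \code{itch}, \code{hive} (each NA when
#'   no session is observed) and \code{sessions_observed}
#' @examples
#' score_daily_uas(data.frame(session = c("AM", "PM"),
#'                            itch_score = c(2, 1), hive_score = c(1, 2)))
#' @export
score_daily_uas <- function(entries) {
  if (nrow(entries) > 2) stop("at most one record per session per day")
  obs <- entries
  if ("missing" %in% names(obs)) obs <- obs[!obs$missing, , drop = FALSE]
  obs <- obs[!is.na(obs$itch_score) & !is.na(obs$hive_score), , drop = FALSE]
  if (nrow(obs) == 0)
    return(list(uas = NA_real_, itch = NA_real_, hive = NA_real_,
                sessions_observed = 0L))
  if (any(!obs$itch_score %in% 0:3) || any(!obs$hive_score %in% 0:3))
    stop("itch and hive scores must lie in {0, 1, 2, 3}")
  list(uas = mean(obs$itch_score + obs$hive_score),
       itch = mean(obs$itch_score),
       hive = mean(obs$hive_score),
       sessions_observed = nrow(obs))
}

#' Daily scores for a full diary
#'
#' Vectorized application of the daily-UAS rule over a long-format diary.
#'
#' @param diary data.frame with columns \code{patient_id},
#'   \code{study_day}, \code{session}, \code{itch_score},
#'   \code{hive_score}, \code{missing}
#' @return data.frame with one row per patient-day: \code{uas_day},
#'   \code{itch_day}, \code{hive_day}, \code{sessions_observed}
#' @export
daily_scores <- function(diary) {
  ok <- !diary$missing & !is.na(diary$itch_score) & !is.na(diary$hive_score)
  obs <- diary[ok, , drop = FALSE]
  if (nrow(obs) > 0 &&
      (any(!obs$itch_score %in% 0:3) || any(!obs$hive_score %in% 0:3)))
    stop("itch and hive scores must lie in {0, 1, 2, 3}")
  key <- interaction(diary$patient_id, diary$study_day, drop = TRUE)
  okey <- interaction(obs$patient_id, obs$study_day,
                      drop = FALSE, lex.order = FALSE)
  okey <- factor(as.character(okey), levels = levels(key))
  agg <- function(x) {
    s <- tapply(x, okey, mean)
    as.numeric(s[levels(key)])
  }
  n_obs <- tapply(rep(1L, nrow(obs)), okey, sum)
  out <- data.frame(
    patient_id = tapply(as.character(diary$patient_id), key, `[`, 1),
    study_day = as.integer(tapply(diary$study_day, key, `[`, 1)),
    itch_day = agg(obs$itch_score),
    hive_day = agg(obs$hive_score),
    sessions_observed = {
      v <- as.integer(n_obs[levels(key)]); v[is.na(v)] <- 0L; v
    },
    stringsAsFactors = FALSE
  )
  out$uas_day <- out$itch_day + out$hive_day
  out <- out[order(out$patient_id, out$study_day), ]
  rownames(out) <- NULL
  out
}

week_of_day <- function(study_day) {
  ifelse(study_day >= 1, (study_day + 6) %/% 7,
         ifelse(study_day >= -7, 0L, -((-study_day - 1) %/% 7)))
}

#' Derive weekly UAS7, itch and hive scores
#'
#' Sums daily scores over 7-day windows (week 0 = the 7 days before
#' day 1). Weeks with 4-6 observed days are prorated by
#' 7/days_observed and rounded half-up to 1 decimal per component;
#' weeks with fewer than 4 observed days are invalid. \code{uas7} is
#' \code{itch7 + hive7} exactly.
#'
#' @param daily data.frame from [daily_scores()]
#' @param weeks integer weeks to derive (default: all present)
#' @return data.frame: \code{patient_id}, \code{week}, \code{uas7},
#'   \code{itch7}, \code{hive7}, \code{days_observed}, \code{valid}
#' @export
derive_weekly_scores <- function(daily, weeks = NULL) {
  daily$week <- week_of_day(daily$study_day)
  if (is.null(weeks)) weeks <- sort(unique(daily$week))
  daily <- daily[daily$week %in% weeks, , drop = FALSE]
  key <- interaction(daily$patient_id, daily$week, drop = TRUE)
  comp_sum <- function(x) {
    s <- tapply(ifelse(is.na(x), 0, x), key, sum)
    as.numeric(s)
  }
  days_obs <- as.integer(tapply(!is.na(daily$uas_day), key, sum))
  out <- data.frame(
    patient_id = as.character(tapply(as.character(daily$patient_id),
                                     key, `[`, 1)),
    week = as.integer(tapply(daily$week, key, `[`, 1)),
    days_observed = days_obs,
    stringsAsFactors = FALSE
  )
  itch <- comp_sum(daily$itch_day)
  hive <- comp_sum(daily$hive_day)
  scale <- ifelse(days_obs >= MIN_DAYS_PER_WEEK, 7 / pmax(days_obs, 1), NA)
  out$itch7 <- round_half_up(itch * scale, 1)
  out$hive7 <- round_half_up(hive * scale, 1)
  out$uas7 <- out$itch7 + out$hive7
  out$valid <- out$days_observed >= MIN_DAYS_PER_WEEK
  out <- out[order(out$patient_id, out$week), ]
  rownames(out) <- NULL
  out
}

#' Changes from baseline for weekly scores
#'
#' Baseline is week 0 (the 7 days before day 1). Patients without a
#' valid baseline week are excluded from change endpoints; their ids and
#' the reason are recorded in the \code{"excluded"} attribute and
#' reported via \code{message()}.
#'
#' @param weekly data.frame from [derive_weekly_scores()]
#' @param baseline_week index of the baseline week (default 0)
#' @return \code{weekly} restricted to post-baseline weeks of patients
#'   with a valid baseline, with \code{uas7_change}, \code{itch7_change},
#'   \code{hive7_change} and \code{*_baseline} columns added
#' @export
change_from_baseline <- function(weekly, baseline_week = 0L) {
  base <- weekly[weekly$week == baseline_week & weekly$valid, , drop = FALSE]
  all_ids <- unique(weekly$patient_id)
  excluded <- setdiff(all_ids, base$patient_id)
  if (length(excluded))
    message(sprintf(
      "excluding %d patient(s) with no valid baseline week: %s",
      length(excluded), paste(excluded, collapse = ", ")))
  out <- weekly[weekly$week > baseline_week &
                  weekly$patient_id %in% base$patient_id, , drop = FALSE]
  m <- match(out$patient_id, base$patient_id)
  out$uas7_baseline <- base$uas7[m]
  out$itch7_baseline <- base$itch7[m]
  out$hive7_baseline <- base$hive7[m]
  out$uas7_change <- ifelse(out$valid, out$uas7 - out$uas7_baseline, NA)
  out$itch7_change <- ifelse(out$valid, out$itch7 - out$itch7_baseline, NA)
  out$hive7_change <- ifelse(out$valid, out$hive7 - out$hive7_baseline, NA)
  attr(out, "excluded") <- data.frame(
    patient_id = excluded,
    reason = rep("no valid baseline week", length(excluded)))
  rownames(out) <- NULL
  out
}

#' Classify responders per week with the nonresponder rule
#'
#' Well-controlled means UAS7 <= 6; complete response means UAS7 = 0;
#' the UAS7 MID responder has a reduction from baseline >= \code{mid}
#' (default 11 points). Patients who discontinued treatment before the
#' reporting week are nonresponders for all three flags regardless of
#' any observed scores, as are weeks with no valid score.
#'
#' @param changes data.frame from [change_from_baseline()]
#' @param dropout data.frame with \code{patient_id}, \code{dropout_day}
#'   (NA for completers); typically the cohort profiles
#' @param mid UAS7 MID threshold (reduction, score points)
#' @param itch_mid weekly-itch MID threshold (reduction, score points);
#'   the published MID for the weekly itch score is not stated, so this
#'   is configurable (default 5)
#' @return data.frame: one row per patient-week with logical
#'   \code{well_controlled}, \code{complete_response}, \code{mid_uas7},
#'   \code{mid_itch7}, \code{discontinued_before_week}
#' @export
classify_responders <- function(changes, dropout, mid = MID_UAS7,
                                itch_mid = 5) {
  dd <- dropout$dropout_day[match(changes$patient_id, dropout$patient_id)]
  disc <- !is.na(dd) & dd < 7 * changes$week
  have <- changes$valid & !is.na(changes$uas7)
  out <- data.frame(
    patient_id = changes$patient_id,
    week = changes$week,
    well_controlled = !disc & have & changes$uas7 <= WELL_CONTROLLED_MAX,
    complete_response = !disc & have & changes$uas7 == 0,
    mid_uas7 = !disc & have & !is.na(changes$uas7_change) &
      (-changes$uas7_change) >= mid,
    mid_itch7 = !disc & have & !is.na(changes$itch7_change) &
      (-changes$itch7_change) >= itch_mid,
    discontinued_before_week = disc,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Time to first MID response
#'
#' First-passage time (weeks) to a UAS7 reduction from baseline
#' >= \code{mid}; patients never reaching it are censored at their last
#' valid on-treatment week (through \code{max_week}).
#'
#' @param changes data.frame from [change_from_baseline()]
#' @param mid MID threshold (default 11)
#' @param max_week end of the treatment period (default 8)
#' @return data.frame: \code{patient_id}, \code{time} (weeks),
#'   \code{event} (1 = MID reached, 0 = censored)
#' @export
time_to_mid_series <- function(changes, mid = MID_UAS7, max_week = 8L) {
  ch <- changes[changes$week >= 1 & changes$week <= max_week &
                  changes$valid & !is.na(changes$uas7_change), , drop = FALSE]
  ids <- unique(changes$patient_id)
  rows <- lapply(ids, function(id) {
    x <- ch[ch$patient_id == id, , drop = FALSE]
    x <- x[order(x$week), , drop = FALSE]
    hit <- which(-x$uas7_change >= mid)
    if (length(hit))
      data.frame(patient_id = id, time = x$week[hit[1]], event = 1L)
    else
      data.frame(patient_id = id,
                 time = if (nrow(x)) max(x$week) else NA_integer_,
                 event = 0L)
  })
  out <- do.call(rbind, rows)
  out <- out[!is.na(out$time), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Proportion of rescue-medication-free days
#'
#' Day-level fraction of observed study days without rescue use, per
#' patient over the given day range.
#'
#' @param diary long-format diary data.frame
#' @param days integer study days to include (default: baseline week)
#' @return data.frame: \code{patient_id}, \code{pct_rescue_free}
#' @export
rescue_free_days <- function(diary, days = -7:-1) {
  d <- diary[diary$study_day %in% days & !diary$missing &
               !is.na(diary$rescue_used), , drop = FALSE]
  used <- tapply(d$rescue_used, list(d$patient_id, d$study_day), any)
  pct <- apply(used, 1, function(r) 100 * mean(!r, na.rm = TRUE))
  data.frame(patient_id = rownames(used), pct_rescue_free = as.numeric(pct),
             stringsAsFactors = FALSE, row.names = NULL)
}
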