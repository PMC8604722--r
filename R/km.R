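# Kaplan-Meier estimation for time-to-MID endpoints. The product-limit
# computation is delegated to survival::survfit; the median rule
# (inclusive survival <= 0.5, midpoint convention on exact-0.5 plateaus)
# is applied to the extracted curve.

#' Kaplan-Meier fit
#'
#' Product-limit estimator for (time, event) records at weekly
#' resolution; simultaneous events precede censorings at the same time.
#'
#' @param time positive event/censoring times (weeks)
#' @param event 1 = event, 0 = censored
#' @return object of class \code{csu_km}: \code{time}, \code{surv},
#'   \code{n_risk}, \code{n_event}, \code{n_censor}, \code{n},
#'   \code{median}
#' @examples
#' km <- km_fit(c(1, 2, 3), c(1, 1, 1))
#' km$surv     # 2/3, 1/3, 0
#' km$median   # 2
#' @export
km_fit <- function(time, event) {
  if (!length(time)) stop("empty input: no time-to-event records")
  stopifnot(length(time) == length(event), all(time > 0))
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- structure(
    list(time = sf$time, surv = sf$surv, n_risk = sf$n.risk,
         n_event = sf$n.event, n_censor = sf$n.censor, n = sf$n),
    class = "csu_km")
  out$median <- km_median(out)
  out
}

#' Median time from a Kaplan-Meier curve
#'
#' Smallest time with survival <= 0.5 (inclusive convention). When the
#' curve sits exactly at 0.5 over a plateau, the midpoint of the plateau
#' endpoints is reported. Undefined (NA) when survival never reaches
#' 0.5.
#'
#' @param curve a \code{csu_km}
#' @return median time in weeks, or NA
#' @export
km_median <- function(curve) {
  s <- curve$surv
  t <- curve$time
  idx <- which(s <= 0.5 + 1e-12)
  if (!length(idx)) return(NA_real_)
  i <- idx[1]
  if (abs(s[i] - 0.5) < 1e-12) {
    later <- which(s < 0.5 - 1e-12)
    if (length(later)) return((t[i] + t[later[1]]) / 2)
  }
  t[i]
}

#' @export
print.csu_km <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d, median = %s weeks\n",
              x$n, sum(x$n_event),
              if (is.na(x$median)) "undefined" else format(x$median)))
  invisible(x)
}

#' Kaplan-Meier curves per arm for time to MID
#'
#' @param tte data.frame from [time_to_mid_series()]
#' @param profiles cohort profiles (for arm labels)
#' @return data.frame of per-arm curves (arm, time, surv, n_risk,
#'   n_event) with per-arm medians in the \code{"medians"} attribute
#' @export
km_by_arm <- function(tte, profiles) {
  arm <- profiles$arm[match(tte$patient_id, profiles$patient_id)]
  res <- lapply(levels(arm), function(a) {
    sub <- tte[arm == a, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    km <- km_fit(sub$time, sub$event)
    data.frame(arm = a, time = km$time, surv = km$surv,
               n_risk = km$n_risk, n_event = km$n_event,
               median = km$median, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "medians") <- unique(out[, c("arm", "median")])
  rownames(out) <- NULL
  out
}
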