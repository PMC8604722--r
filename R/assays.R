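# Bespoke assay quantification.
#
# IgG-anti-FcERI competition ELISA: per well the 630 nm reading is
# subtracted from the 450 nm reading; a four-parameter logistic (4PL)
# standard curve is fitted to the corrected standards; sample
# concentrations come from analytic inverse prediction (duplicates
# averaged after inversion). Relative reactivity (RR) is the
# concentration of the control-protein-spiked aliquot minus the
# antigen-spiked aliquot; the per-batch upper normal range (UNR) is the
# healthy-panel mean + 3 s.d., with positivity strictly above the UNR
# and percent change computed after flooring values below the UNR at
# the UNR.
#
# BHRA: percentage histamine release is HR_sample / HR_total x 100; the
# BHRA value is %HR_sample / %HR_healthy x 10 with %HR_healthy the
# healthy-panel mean + 2 s.d.; values >= 10 are positive.

LOW_IGE_THRESHOLD <- 43   # IU/ml, strict: low IgE means total IgE < 43
BHRA_POSITIVE_MIN <- 10   # inclusive positivity bound for the BHRA value

#' Background-correct absorbance readings
#'
#' Subtracts the 630 nm reference reading from the 450 nm reading per
#' well. Wells missing either wavelength are flagged unusable.
#'
#' @param wells data.frame with \code{absorbance_450},
#'   \code{absorbance_630}
#' @return \code{wells} with \code{corrected} and logical \code{usable}
#'   columns added
#' @export
correct_absorbance <- function(wells) {
  wells$usable <- is.finite(wells$absorbance_450) &
    is.finite(wells$absorbance_630)
  wells$corrected <- ifelse(wells$usable,
                            wells$absorbance_450 - wells$absorbance_630,
                            NA_real_)
  wells
}

fourpl_fun <- function(conc, lower, upper, ec50, slope) {
  lower + (upper - lower) / (1 + (ec50 / conc)^slope)
}

#' Fit a four-parameter-logistic standard curve
#'
#' Fits corrected absorbance against nominal concentration with a 4PL
#' (lower/upper asymptote, inflection concentration, slope) by
#' Levenberg-Marquardt nonlinear least squares. Duplicate standards are
#' averaged per concentration before fitting. Degenerate (flat or
#' non-monotone) standards raise an error naming the plate.
#'
#' @param conc nominal standard concentrations (ng/ml)
#' @param absorbance corrected absorbances (same length)
#' @param plate label used in error messages
#' @return object of class \code{csu_4pl}: \code{par} (named list),
#'   \code{converged}, \code{sigma} (residual s.d.), \code{range}
#'   (calibration range, ng/ml)
#' @export
fit_standard_curve <- function(conc, absorbance, plate = "plate") {
  ok <- is.finite(conc) & is.finite(absorbance) & conc > 0
  conc <- conc[ok]; absorbance <- absorbance[ok]
  mean_abs <- tapply(absorbance, conc, mean)
  concs <- as.numeric(names(mean_abs))
  o <- order(concs); concs <- concs[o]; y <- as.numeric(mean_abs)[o]
  if (length(concs) < 4)
    stop(sprintf("standard curve on %s: need >= 4 usable standard levels",
                 plate))
  if (diff(range(y)) < 1e-6 || stats::cor(concs, y, method = "spearman") < 0.8)
    stop(sprintf("standard curve on %s: degenerate or non-monotone standards",
                 plate))
  start <- list(lower = min(y), upper = max(y),
                ec50 = exp(stats::approx(y, log(concs),
                                         xout = mean(range(y)),
                                         rule = 2, ties = mean)$y),
                slope = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ fourpl_fun(concs, lower, upper, ec50, slope),
      start = start,
      lower = c(lower = -0.5, upper = 0, ec50 = 1e-6, slope = 0.05),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop(sprintf("standard curve on %s failed to converge: %s",
                   plate, conditionMessage(e)), call. = FALSE))
  par <- as.list(stats::coef(fit))
  structure(list(par = par, converged = TRUE,
                 sigma = stats::sigma(fit),
                 range = range(concs), plate = plate),
            class = "csu_4pl")
}

#' @export
print.csu_4pl <- function(x, ...) {
  cat(sprintf(
    "4PL standard curve [%s]: lower %.3f, upper %.3f, ec50 %.4g ng/ml, slope %.3f\n",
    x$plate, x$par$lower, x$par$upper, x$par$ec50, x$par$slope))
  cat(sprintf("  calibration range %.4g - %.4g ng/ml, residual s.d. %.2g\n",
              x$range[1], x$range[2], x$sigma))
  invisible(x)
}

#' Inverse-predict concentrations from a standard curve
#'
#' Analytic inverse of the fitted 4PL. Absorbances at or beyond the
#' asymptotes, and inverted concentrations beyond the calibration range,
#' are clamped to the corresponding range endpoint with a warning
#' (no extrapolation).
#'
#' @param fit a \code{csu_4pl} from [fit_standard_curve()]
#' @param absorbance corrected absorbance values
#' @return concentrations (ng/ml)
#' @export
quantify_concentration <- function(fit, absorbance) {
  stopifnot(inherits(fit, "csu_4pl"), isTRUE(fit$converged))
  p <- fit$par
  eps <- 1e-9
  clamped <- absorbance <= p$lower | absorbance >= p$upper
  a <- pmin(pmax(absorbance, p$lower + eps), p$upper - eps)
  conc <- p$ec50 / ((p$upper - p$lower) / (a - p$lower) - 1)^(1 / p$slope)
  out_of_range <- conc < fit$range[1] | conc > fit$range[2]
  if (any(clamped | out_of_range, na.rm = TRUE))
    warning(sprintf(
      "%d value(s) outside the calibration range clamped to its endpoints",
      sum(clamped | out_of_range, na.rm = TRUE)))
  pmin(pmax(conc, fit$range[1]), fit$range[2])
}

#' Relative IgG-anti-FcERI reactivity
#'
#' RR = concentration of the control-protein-spiked aliquot minus the
#' antigen-spiked aliquot of the same serum. Negative values are allowed
#' (thresholding happens downstream).
#'
#' @param conc_control_spiked,conc_antigen_spiked paired concentrations
#'   (ng/ml) from the same serum sample and visit
#' @return RR (ng/ml)
#' @export
compute_relative_reactivity <- function(conc_control_spiked,
                                        conc_antigen_spiked) {
  if (length(conc_control_spiked) != length(conc_antigen_spiked))
    stop("pairing error: control- and antigen-spiked values differ in length")
  conc_control_spiked - conc_antigen_spiked
}

#' Upper normal range and positivity for relative reactivity
#'
#' UNR = healthy-panel mean + 3 sample s.d. (n-1 denominator); samples
#' strictly above the UNR are IgG-anti-FcERI positive, values <= UNR
#' negative. The UNR is recomputed per assay batch, never pooled.
#'
#' @param healthy_rr healthy-panel RR values (>= 2)
#' @param patient_rr patient RR value(s)
#' @return list: \code{unr}, logical \code{positive} (same length as
#'   \code{patient_rr})
#' @export
compute_unr_and_status <- function(healthy_rr, patient_rr) {
  healthy_rr <- healthy_rr[is.finite(healthy_rr)]
  if (length(healthy_rr) < 2)
    stop("UNR requires at least 2 healthy values")
  unr <- mean(healthy_rr) + 3 * stats::sd(healthy_rr)
  list(unr = unr, positive = patient_rr > unr)
}

#' Floored percent change in relative reactivity
#'
#' Both baseline and follow-up RR are floored at the UNR before the
#' percent change 100 x (RR_followup - RR_baseline) / RR_baseline is
#' computed (defined for patients positive at baseline).
#'
#' @param rr_baseline,rr_followup RR values (ng/ml)
#' @param unr the batch UNR (ng/ml)
#' @return percent change
#' @export
percent_change_reactivity <- function(rr_baseline, rr_followup, unr) {
  b <- pmax(rr_baseline, unr)
  f <- pmax(rr_followup, unr)
  if (any(b == 0))
    stop("floored baseline RR of 0: percent change undefined")
  100 * (f - b) / b
}

#' BHRA value and positivity
#'
#' Percentage histamine release is HR_sample / HR_total x 100. The
#' healthy threshold %HR_healthy is the healthy-panel mean + 2 sample
#' s.d. of percentage release; the BHRA value is
#' %HR_sample / %HR_healthy x 10 and values >= 10 are positive.
#'
#' @param hr_sample histamine released in response to the serum sample
#' @param hr_total total histamine in lysed donor basophils (> 0)
#' @param healthy_pct_release healthy-panel percentage release values
#'   (>= 2)
#' @return data.frame: \code{pct_release_sample},
#'   \code{pct_release_healthy_threshold}, \code{bhra_value},
#'   \code{positive}
#' @export
compute_bhra <- function(hr_sample, hr_total, healthy_pct_release) {
  if (any(hr_total <= 0)) stop("assay error: total lysate release must be > 0")
  healthy_pct_release <- healthy_pct_release[is.finite(healthy_pct_release)]
  if (length(healthy_pct_release) < 2)
    stop("BHRA threshold requires at least 2 healthy panel values")
  pct <- 100 * hr_sample / hr_total
  thr <- mean(healthy_pct_release) + 2 * stats::sd(healthy_pct_release)
  value <- 10 * pct / thr
  data.frame(pct_release_sample = pct,
             pct_release_healthy_threshold = thr,
             bhra_value = value,
             positive = value >= BHRA_POSITIVE_MIN)
}

#' Low total-IgE classification
#'
#' @param total_ige total serum IgE (IU/ml, >= 0)
#' @return logical: TRUE iff total IgE is strictly below 43 IU/ml
#' @export
classify_low_ige <- function(total_ige) {
  stopifnot(all(total_ige >= 0, na.rm = TRUE))
  total_ige < LOW_IGE_THRESHOLD
}

#' Quantify all assays for a cohort
#'
#' Runs the full quantification chain on raw simulated (or imported)
#' assay data: absorbance correction, per-batch 4PL standard-curve fit,
#' inverse prediction with duplicate averaging after inversion, RR,
#' per-batch UNR and positivity, floored percent change from baseline
#' (day 1) to day 57 for baseline-positive patients, BHRA value and
#' positivity, and the low-IgE flag.
#'
#' @param assays list with \code{elisa} and \code{bhra} data.frames as
#'   produced by [simulate_assay_measurements()]
#' @param profiles cohort profiles (for total IgE); optional
#' @return data.frame keyed by patient and visit:
#'   \code{rr}, \code{unr}, \code{igg_fceri_pos}, \code{pct_change_rr}
#'   (day 57 rows only), \code{bhra_value}, \code{bhra_pos},
#'   \code{low_ige}
#' @export
quantify_assays <- function(assays, profiles = NULL) {
  elisa <- correct_absorbance(assays$elisa)
  batches <- unique(elisa$batch)
  res <- list()
  for (b in batches) {
    pb <- elisa[elisa$batch == b & elisa$usable, , drop = FALSE]
    std <- pb[pb$role == "standard", , drop = FALSE]
    fit <- fit_standard_curve(std$nominal_conc, std$corrected, plate = b)
    samp <- pb[pb$role %in% c("sample", "healthy_control"), , drop = FALSE]
    samp$conc <- suppressWarnings(quantify_concentration(fit, samp$corrected))
    # duplicate averaging after inversion, per serum x spike
    agg <- stats::aggregate(conc ~ patient_id + role + spike, data = samp,
                            FUN = mean)
    wide <- merge(
      agg[agg$spike == "control_protein",
          c("patient_id", "role", "conc")],
      agg[agg$spike == "antigen", c("patient_id", "conc")],
      by = "patient_id", suffixes = c("_control", "_antigen"))
    wide$rr <- compute_relative_reactivity(wide$conc_control,
                                           wide$conc_antigen)
    healthy <- wide$rr[wide$role == "healthy_control"]
    pat <- wide[wide$role == "sample", , drop = FALSE]
    st <- compute_unr_and_status(healthy, pat$rr)
    res[[b]] <- data.frame(
      patient_id = pat$patient_id, visit = b,
      conc_control_spiked = pat$conc_control,
      conc_antigen_spiked = pat$conc_antigen,
      rr = pat$rr, unr = st$unr, igg_fceri_pos = st$positive,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)

  # floored percent change day 1 -> day 57 for baseline-positive patients
  out$pct_change_rr <- NA_real_
  b0 <- out[out$visit == "day 1", , drop = FALSE]
  f1 <- out[out$visit == "day 57", , drop = FALSE]
  m <- match(f1$patient_id, b0$patient_id)
  eligible <- !is.na(m) & b0$igg_fceri_pos[m]
  if (any(eligible)) {
    rows <- which(out$visit == "day 57")[eligible]
    out$pct_change_rr[rows] <- percent_change_reactivity(
      b0$rr[m[eligible]], f1$rr[eligible], f1$unr[eligible])
  }

  # BHRA (screening serum)
  bh <- assays$bhra
  healthy_pct <- 100 * bh$hr_released[bh$role == "healthy"] /
    bh$hr_total[bh$role == "healthy"]
  pat <- bh[bh$role == "patient", , drop = FALSE]
  bres <- compute_bhra(pat$hr_released, pat$hr_total, healthy_pct)
  bres$patient_id <- pat$patient_id
  out$bhra_value <- bres$bhra_value[match(out$patient_id, bres$patient_id)]
  out$bhra_pos <- bres$positive[match(out$patient_id, bres$patient_id)]

  if (!is.null(profiles))
    out$low_ige <- classify_low_ige(
      profiles$total_ige[match(out$patient_id, profiles$patient_id)])
  rownames(out) <- NULL
  out
}
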