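# Longitudinal efficacy analysis.
#
# The primary analysis is a mixed model for repeated measures (MMRM):
# a multivariate-normal model of the weekly change from baseline with
# arm-by-visit cell means, country as a fixed covariate, and an
# unstructured within-patient covariance across visits, estimated by
# REML. Missing visits are handled by the likelihood (no imputation;
# valid under missing-at-random dropout). The fit is delegated to
# nlme::gls with corSymm correlation and per-visit variance weights;
# if the unstructured fit fails, a compound-symmetry fit is returned
# with a warning and the covariance structure recorded.
#
# Kenward-Roger denominator degrees of freedom are not available for
# this engine; contrasts use emmeans' approximate Satterthwaite method
# (labelled in the output), with a fast residual-df mode for Monte
# Carlo work where the two are indistinguishable.

#' Assemble the longitudinal analysis dataset
#'
#' One row per patient-visit with the endpoint change from baseline,
#' arm, country and (optionally) baseline BHRA status. Patients with no
#' post-baseline value are excluded from the model rows; their ids are
#' kept in the \code{"excluded"} attribute.
#'
#' @param changes data.frame from [change_from_baseline()]
#' @param profiles cohort profiles (arm, country, dropout)
#' @param biomarkers optional data.frame from [quantify_assays()]
#'   supplying \code{bhra_pos}
#' @param endpoint change column to analyze
#'   (\code{"uas7_change"}, \code{"itch7_change"}, \code{"hive7_change"})
#' @param visits integer weeks to include (default 1:8)
#' @return data.frame with \code{patient_id}, \code{arm},
#'   \code{country}, \code{visit} (factor), \code{change},
#'   \code{baseline}, \code{bhra_status}
#' @export
build_longitudinal_dataset <- function(changes, profiles, biomarkers = NULL,
                                       endpoint = "uas7_change",
                                       visits = 1:8) {
  stopifnot(endpoint %in% names(changes))
  d <- changes[changes$week %in% visits & !is.na(changes[[endpoint]]), ,
               drop = FALSE]
  m <- match(d$patient_id, profiles$patient_id)
  out <- data.frame(
    patient_id = d$patient_id,
    arm = profiles$arm[m],
    country = factor(profiles$country[m]),
    visit = factor(d$week, levels = sort(unique(visits))),
    change = d[[endpoint]],
    baseline = d$uas7_baseline,
    stringsAsFactors = FALSE
  )
  if (!is.null(biomarkers)) {
    bm <- biomarkers[biomarkers$visit == "screening", , drop = FALSE]
    pos <- bm$bhra_pos[match(out$patient_id, bm$patient_id)]
    out$bhra_status <- factor(ifelse(pos, "BHRA+", "BHRA-"),
                              levels = c("BHRA-", "BHRA+"))
  }
  excluded <- setdiff(profiles$patient_id, out$patient_id)
  attr(out, "excluded") <- excluded
  out$visit <- droplevels(out$visit)
  out
}

mmrm_formula <- function(data, interaction_with = NULL) {
  rhs <- character()
  if (nlevels(droplevels(data$country)) > 1) rhs <- c(rhs, "country")
  cell <- if (nlevels(droplevels(data$visit)) > 1) "arm * visit" else "arm"
  if (!is.null(interaction_with))
    cell <- if (nlevels(droplevels(data$visit)) > 1)
      sprintf("arm * visit * %s", interaction_with)
    else sprintf("arm * %s", interaction_with)
  stats::as.formula(paste("change ~", paste(c(rhs, cell), collapse = " + ")))
}

gls_unstructured <- function(form, data) {
  # do.call embeds evaluated arguments in the stored call so the fit
  # can be re-evaluated later (emmeans' Satterthwaite machinery refits)
  many_visits <- nlevels(droplevels(data$visit)) > 1
  if (!many_visits)
    return(list(fit = do.call(nlme::gls, list(model = form, data = data,
                                              method = "REML")),
                structure = "independent", data = data))
  data$visit_num <- as.integer(data$visit)
  fit <- tryCatch(
    do.call(nlme::gls, list(
      model = form, data = data,
      correlation = nlme::corSymm(form = ~visit_num | patient_id),
      weights = nlme::varIdent(form = ~1 | visit),
      method = "REML",
      control = nlme::glsControl(maxIter = 100, msMaxIter = 200))),
    error = function(e) e)
  if (!inherits(fit, "error"))
    return(list(fit = fit, structure = "unstructured", data = data))
  warning("unstructured covariance fit failed (",
          conditionMessage(fit), "); falling back to compound symmetry")
  fit <- do.call(nlme::gls, list(
    model = form, data = data,
    correlation = nlme::corCompSymm(form = ~1 | patient_id),
    method = "REML"))
  list(fit = fit, structure = "compound-symmetry", data = data)
}

#' Fit the MMRM
#'
#' REML fit of the arm-by-visit cell-means model with country effects
#' and unstructured within-patient covariance. A single-country dataset
#' drops the country term with a message; a single post-baseline visit
#' reduces to the corresponding cell-means linear model.
#'
#' @param data data.frame from [build_longitudinal_dataset()]
#' @return object of class \code{csu_mmrm}: \code{fit} (the gls object),
#'   \code{data}, \code{formula}, \code{converged},
#'   \code{cov_structure}, \code{dof_method}
#' @export
fit_mmrm <- function(data) {
  stopifnot(all(c("patient_id", "arm", "country", "visit", "change") %in%
                  names(data)))
  data <- droplevels(data[!is.na(data$change), , drop = FALSE])
  if (nlevels(data$visit) < 1 || nlevels(data$arm) < 2)
    stop("MMRM requires >= 2 arms and >= 1 post-baseline visit")
  if (nlevels(data$country) < 2)
    message("single country: country term dropped from the model")
  form <- mmrm_formula(data)
  res <- gls_unstructured(form, data)
  structure(list(fit = res$fit, data = res$data, formula = form,
                 converged = TRUE, cov_structure = res$structure,
                 dof_method = "appx-satterthwaite"),
            class = "csu_mmrm")
}

#' @export
print.csu_mmrm <- function(x, ...) {
  cat("MMRM (REML,", x$cov_structure, "covariance):",
      deparse(x$formula), "\n")
  cat(sprintf("  %d observations, %d patients, visits: %s\n",
              nrow(x$data), length(unique(x$data$patient_id)),
              paste(levels(x$data$visit), collapse = ", ")))
  invisible(x)
}

#' Estimated within-patient covariance matrix
#'
#' @param fit a \code{csu_mmrm}
#' @return visit-by-visit covariance matrix (marginal residual
#'   covariance of one patient's visits)
#' @export
mmrm_covariance <- function(fit) {
  if (fit$cov_structure == "independent") {
    s2 <- stats::sigma(fit$fit)^2
    return(matrix(s2, 1, 1))
  }
  cnt <- table(fit$data$patient_id)
  full <- names(cnt)[cnt == nlevels(fit$data$visit)][1]
  v <- nlme::getVarCov(fit$fit, individual = full)
  m <- matrix(as.numeric(v), nrow = nrow(v))
  dimnames(m) <- list(levels(fit$data$visit), levels(fit$data$visit))
  m
}

# containment-style denominator df: subjects minus between-subject
# parameters (arm cells + country effects); equals the OLS residual df
# in the single-visit independent case
containment_df <- function(fit, cells = nlevels(fit$data$arm)) {
  n_pat <- length(unique(fit$data$patient_id))
  n_pat - cells - (nlevels(fit$data$country) - 1)
}

# least-squares-mean contrast rows (arm vs reference at one visit),
# averaging the design over country levels
lsmean_rows <- function(fit, visit) {
  d <- fit$data
  grid <- expand.grid(arm = levels(d$arm), country = levels(d$country),
                      visit = factor(visit, levels = levels(d$visit)),
                      KEEP.OUT.ATTRS = FALSE)
  if ("bhra_status" %in% all.vars(fit$formula))
    stop("use subgroup_contrasts for subgroup fits")
  X <- stats::model.matrix(fit$formula[-2], grid)
  t(sapply(levels(d$arm), function(a)
    colMeans(X[grid$arm == a, , drop = FALSE])))
}

#' LS-mean treatment contrasts from an MMRM
#'
#' Least-squares mean difference of each active arm versus the reference
#' (first) arm at the requested visit, with unadjusted 95% confidence
#' intervals from a t distribution. \code{dof = "satterthwaite"} uses
#' emmeans' approximate Satterthwaite method; \code{dof = "residual"}
#' uses the residual degrees of freedom (fast; used for simulation
#' suites).
#'
#' @param fit a \code{csu_mmrm}
#' @param visit visit (week) at which to contrast; default last
#' @param dof degrees-of-freedom method; Satterthwaite falls back to
#'   containment df (recorded) when the numerical approximation fails,
#'   as it can for large unstructured covariances
#' @param level confidence level
#' @return data.frame: \code{comparison}, \code{visit}, \code{estimate},
#'   \code{se}, \code{dof}, \code{lcl}, \code{ucl}, \code{p_value},
#'   \code{dof_method}
#' @export
estimate_contrasts <- function(fit, visit = NULL,
                               dof = c("satterthwaite", "containment"),
                               level = 0.95) {
  dof <- match.arg(dof)
  d <- fit$data
  if (is.null(visit)) visit <- utils::tail(levels(d$visit), 1)
  visit <- as.character(visit)
  if (!visit %in% levels(d$visit)) stop("visit not in the fitted model")
  ref <- levels(d$arm)[1]

  # the numeric Satterthwaite approximation refits per covariance
  # parameter and becomes unstable and slow for large unstructured
  # covariances; use containment df beyond 5 visits (15 parameters)
  many_cov_par <- nlevels(d$visit) > 5 && fit$cov_structure == "unstructured"
  if (dof == "satterthwaite" && fit$cov_structure != "independent" &&
      !many_cov_par) {
    res <- tryCatch({
      em <- suppressMessages(emmeans::emmeans(
        fit$fit, ~ arm | visit, data = d, mode = "appx-satterthwaite",
        at = list(visit = visit)))
      ct <- summary(emmeans::contrast(em, "trt.vs.ctrl", ref = 1),
                    infer = c(TRUE, TRUE), level = level, adjust = "none")
      out <- data.frame(
        comparison = paste(sub(paste0(" - ", ref), "", ct$contrast),
                           "vs", ref),
        visit = visit, estimate = ct$estimate, se = ct$SE, dof = ct$df,
        lcl = ct$lower.CL, ucl = ct$upper.CL, p_value = ct$p.value,
        dof_method = "appx-satterthwaite", stringsAsFactors = FALSE)
      rownames(out) <- NULL
      out
    }, error = function(e) NULL)
    if (!is.null(res)) return(res)
    dof_label <- "containment (satterthwaite unavailable)"
  } else {
    dof_label <- if (dof == "satterthwaite" && many_cov_par)
      "containment (satterthwaite unavailable)" else "containment"
  }

  L <- lsmean_rows(fit, visit)
  b <- stats::coef(fit$fit)
  V <- stats::vcov(fit$fit)
  arms <- levels(d$arm)[-1]
  Ld <- L[arms, , drop = FALSE] -
    matrix(L[1, ], length(arms), ncol(L), byrow = TRUE)
  est <- as.numeric(Ld %*% b)
  se <- sqrt(diag(Ld %*% V %*% t(Ld)))
  df_c <- containment_df(fit)
  tq <- stats::qt(1 - (1 - level) / 2, df_c)
  out <- data.frame(
    comparison = paste(arms, "vs", levels(d$arm)[1]),
    visit = visit, estimate = est, se = se, dof = df_c,
    lcl = est - tq * se, ucl = est + tq * se,
    p_value = 2 * stats::pt(-abs(est / se), df_c),
    dof_method = dof_label, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' ANCOVA sensitivity analysis with LOCF / BOCF imputation
#'
#' Missing week-\code{week} changes are imputed by the last available
#' post-baseline change (LOCF) or the best (most negative, i.e. most
#' favorable) post-baseline change (BOCF); the imputed week-\code{week}
#' change is then modelled by a linear model on arm + country and
#' arm-vs-reference contrasts are reported. Patients with no
#' post-baseline value are excluded with a message.
#'
#' @param changes data.frame from [change_from_baseline()]
#' @param profiles cohort profiles
#' @param method \code{"LOCF"} or \code{"BOCF"}
#' @param week analysis week (default 8)
#' @param endpoint change column (default \code{"uas7_change"})
#' @param level confidence level
#' @return contrast data.frame as in [estimate_contrasts()]
#' @export
ancova_with_imputation <- function(changes, profiles,
                                   method = c("LOCF", "BOCF"),
                                   week = 8L, endpoint = "uas7_change",
                                   level = 0.95) {
  method <- match.arg(method)
  ch <- changes[changes$week >= 1 & changes$week <= week &
                  !is.na(changes[[endpoint]]), , drop = FALSE]
  ids <- unique(profiles$patient_id)
  val <- vapply(ids, function(id) {
    x <- ch[ch$patient_id == id, , drop = FALSE]
    if (!nrow(x)) return(NA_real_)
    at_week <- x[[endpoint]][x$week == week]
    if (length(at_week)) return(at_week[1])
    if (method == "LOCF") x[[endpoint]][which.max(x$week)]
    else min(x[[endpoint]])
  }, numeric(1))
  excl <- ids[is.na(val)]
  if (length(excl))
    message(sprintf("%s ANCOVA: excluding %d patient(s) with no post-baseline data",
                    method, length(excl)))
  d <- data.frame(
    change = val[!is.na(val)],
    arm = profiles$arm[match(ids[!is.na(val)], profiles$patient_id)],
    country = factor(profiles$country[match(ids[!is.na(val)],
                                            profiles$patient_id)]))
  d <- droplevels(d)
  form <- if (nlevels(d$country) > 1) change ~ arm + country else change ~ arm
  lmfit <- stats::lm(form, data = d)
  em <- emmeans::emmeans(lmfit, ~arm)
  ct <- summary(emmeans::contrast(em, "trt.vs.ctrl", ref = 1),
                infer = c(TRUE, TRUE), level = level, adjust = "none")
  ref <- levels(d$arm)[1]
  out <- data.frame(
    comparison = paste(sub(paste0(" - ", ref), "", ct$contrast), "vs", ref),
    visit = as.character(week), estimate = ct$estimate, se = ct$SE,
    dof = ct$df, lcl = ct$lower.CL, ucl = ct$upper.CL,
    p_value = ct$p.value, dof_method = paste0("ancova-", tolower(method)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Subgroup MMRM by baseline BHRA status
#'
#' Extends the primary MMRM with the BHRA subset indicator and the
#' visit-by-arm-by-BHRA interaction, and reports arm-vs-reference
#' contrasts within each BHRA stratum at the requested visit. If the
#' indicator has a single level the primary model is fitted instead
#' with a warning.
#'
#' @param data longitudinal dataset including \code{bhra_status}
#' @param visit visit for the contrasts (default last)
#' @param level confidence level
#' @return list: \code{fit} (\code{csu_mmrm}), \code{contrasts}
#'   (data.frame with a \code{bhra_status} column)
#' @export
fit_subgroup_mmrm <- function(data, visit = NULL, level = 0.95) {
  stopifnot("bhra_status" %in% names(data))
  data <- droplevels(data[!is.na(data$change) & !is.na(data$bhra_status), ,
                          drop = FALSE])
  if (nlevels(data$bhra_status) < 2) {
    warning("BHRA indicator has a single level; fitting the primary MMRM")
    fit <- fit_mmrm(data)
    ct <- estimate_contrasts(fit, visit, level = level)
    ct$bhra_status <- levels(data$bhra_status)[1] %||% NA
    return(list(fit = fit, contrasts = ct))
  }
  form <- mmrm_formula(data, interaction_with = "bhra_status")
  res <- gls_unstructured(form, data)
  data <- res$data
  fit <- structure(list(fit = res$fit, data = data, formula = form,
                        converged = TRUE, cov_structure = res$structure,
                        dof_method = "appx-satterthwaite"),
                   class = "csu_mmrm")
  if (is.null(visit)) visit <- utils::tail(levels(data$visit), 1)
  visit <- as.character(visit)
  ref <- levels(data$arm)[1]
  many_cov_par <- nlevels(data$visit) > 5 && res$structure == "unstructured"
  out <- if (many_cov_par) NULL else tryCatch({
    em <- suppressMessages(emmeans::emmeans(
      res$fit, ~ arm | bhra_status, data = data,
      mode = "appx-satterthwaite", at = list(visit = visit)))
    ct <- summary(emmeans::contrast(em, "trt.vs.ctrl", ref = 1),
                  infer = c(TRUE, TRUE), level = level, adjust = "none")
    o <- data.frame(
      comparison = paste(sub(paste0(" - ", ref), "", ct$contrast), "vs", ref),
      bhra_status = as.character(ct$bhra_status), visit = visit,
      estimate = ct$estimate, se = ct$SE, dof = ct$df,
      lcl = ct$lower.CL, ucl = ct$upper.CL, p_value = ct$p.value,
      dof_method = "appx-satterthwaite", stringsAsFactors = FALSE)
    rownames(o) <- NULL
    o
  }, error = function(e) NULL)
  if (is.null(out)) {   # containment fallback for large covariances
    b <- stats::coef(res$fit)
    V <- stats::vcov(res$fit)
    df_c <- length(unique(data$patient_id)) -
      nlevels(data$arm) * nlevels(data$bhra_status) -
      (nlevels(data$country) - 1)
    tq <- stats::qt(1 - (1 - level) / 2, df_c)
    pieces <- lapply(levels(data$bhra_status), function(s) {
      grid <- expand.grid(arm = levels(data$arm),
                          country = levels(data$country),
                          visit = factor(visit, levels = levels(data$visit)),
                          bhra_status = factor(s,
                            levels = levels(data$bhra_status)),
                          KEEP.OUT.ATTRS = FALSE)
      X <- stats::model.matrix(form[-2], grid)
      L <- t(sapply(levels(data$arm), function(a)
        colMeans(X[grid$arm == a, , drop = FALSE])))
      arms <- levels(data$arm)[-1]
      Ld <- L[arms, , drop = FALSE] -
        matrix(L[1, ], length(arms), ncol(L), byrow = TRUE)
      est <- as.numeric(Ld %*% b)
      se <- sqrt(diag(Ld %*% V %*% t(Ld)))
      data.frame(
        comparison = paste(arms, "vs", ref), bhra_status = s,
        visit = visit, estimate = est, se = se, dof = df_c,
        lcl = est - tq * se, ucl = est + tq * se,
        p_value = 2 * stats::pt(-abs(est / se), df_c),
        dof_method = "containment (satterthwaite unavailable)",
        stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, pieces)
    rownames(out) <- NULL
  }
  list(fit = fit, contrasts = out)
}

#' Spearman correlation of biomarker change with clinical response
#'
#' Rank correlation (average ranks for ties) between the percent change
#' in IgG-anti-FcERI relative reactivity and the change from baseline
#' in UAS7, over paired complete observations.
#'
#' @param pct_change_rr percent changes in RR
#' @param uas7_change paired UAS7 changes
#' @return list: \code{rho}, \code{n} (complete pairs); \code{rho} is NA
#'   with a warning when fewer than 3 pairs are available
#' @export
correlate_biomarker_response <- function(pct_change_rr, uas7_change) {
  ok <- is.finite(pct_change_rr) & is.finite(uas7_change)
  n <- sum(ok)
  if (n < 3) {
    warning("fewer than 3 complete pairs: correlation undefined")
    return(list(rho = NA_real_, n = n))
  }
  list(rho = stats::cor(pct_change_rr[ok], uas7_change[ok],
                        method = "spearman"),
       n = n)
}
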