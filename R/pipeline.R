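# End-to-end orchestration: simulate -> derive endpoints -> quantify
# assays -> longitudinal/sensitivity/subgroup analyses -> Kaplan-Meier
# -> report tables, with a checksummed run manifest. The report layer
# does no analysis of its own: every number it prints is recomputed
# from the intermediate CSVs.

stage_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[csutrial] ", fmt), ...))
}

#' Run the full trial pipeline
#'
#' Executes every stage on a synthetic cohort and writes the complete
#' output set under \code{out_dir}: cohort files, weekly scores,
#' responder records, biomarker quantifications, MMRM and ANCOVA
#' contrasts, subgroup contrasts, Kaplan-Meier curves, the efficacy
#' report table and a JSON run manifest with MD5 checksums of every
#' file. Reruns with the same (config, seed) reproduce identical
#' checksums.
#'
#' @param cfg a [trial_config()] (or path to a YAML config)
#' @param seed master seed (defaults to the config seed)
#' @param out_dir output directory
#' @param verbose log each stage via \code{message()}
#' @return the manifest (list), invisibly
#' @export
run_full_pipeline <- function(cfg = trial_config(), seed = NULL,
                              out_dir, verbose = TRUE) {
  if (is.character(cfg)) cfg <- read_trial_config(cfg)
  validate_trial_config(cfg)
  if (is.null(seed)) seed <- cfg$seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage_log(verbose, "stage 1/6: generating cohort (seed %s)", format(seed))
  cohort <- generate_cohort(cfg, seed = seed)
  files <- as.list(write_cohort(cohort, out_dir))

  stage_log(verbose, "stage 2/6: deriving diary endpoints")
  daily <- daily_scores(cohort$diary)
  weekly <- derive_weekly_scores(daily, weeks = 0:12)
  changes <- suppressMessages(change_from_baseline(weekly))
  responders <- classify_responders(changes, cohort$profiles)
  files$weekly <- file.path(out_dir, "weekly_scores.csv")
  files$responders <- file.path(out_dir, "responders.csv")
  utils::write.csv(weekly, files$weekly, row.names = FALSE)
  utils::write.csv(responders, files$responders, row.names = FALSE)

  stage_log(verbose, "stage 3/6: quantifying biomarker assays")
  biomarkers <- quantify_assays(cohort$assays, cohort$profiles)
  files$biomarkers <- file.path(out_dir, "biomarkers.csv")
  utils::write.csv(biomarkers, files$biomarkers, row.names = FALSE)

  stage_log(verbose, "stage 4/6: longitudinal efficacy models")
  contrasts <- list()
  for (ep in c(uas7 = "uas7_change", itch7 = "itch7_change",
               hive7 = "hive7_change")) {
    ld <- build_longitudinal_dataset(changes, cohort$profiles,
                                     biomarkers, endpoint = ep)
    fit <- fit_mmrm(ld)
    for (wk in intersect(c(4, 8), levels(ld$visit))) {
      ct <- estimate_contrasts(fit, visit = wk)
      ct$endpoint <- ep
      ct$analysis <- "mmrm"
      contrasts[[length(contrasts) + 1L]] <- ct
    }
    if (ep == "uas7_change") {
      for (m in c("LOCF", "BOCF")) {
        ct <- suppressMessages(
          ancova_with_imputation(changes, cohort$profiles, method = m))
        ct$endpoint <- ep
        ct$analysis <- paste0("ancova-", tolower(m))
        contrasts[[length(contrasts) + 1L]] <- ct
      }
      sub <- fit_subgroup_mmrm(ld)
      sc <- sub$contrasts
      sc$endpoint <- ep
      sc$analysis <- "mmrm-bhra-subgroup"
      files$subgroup <- file.path(out_dir, "subgroup_contrasts.csv")
      utils::write.csv(sc, files$subgroup, row.names = FALSE)
    }
  }
  contrasts <- do.call(rbind, lapply(contrasts, function(x) {
    x$bhra_status <- NULL; x
  }))
  files$contrasts <- file.path(out_dir, "contrasts.csv")
  utils::write.csv(contrasts, files$contrasts, row.names = FALSE)

  stage_log(verbose, "stage 5/6: time to MID (Kaplan-Meier)")
  tte <- time_to_mid_series(changes)
  km <- km_by_arm(tte, cohort$profiles)
  files$km <- file.path(out_dir, "km.csv")
  utils::write.csv(km, files$km, row.names = FALSE)

  stage_log(verbose, "stage 6/6: efficacy report table")
  eff <- summarize_efficacy_table(changes, responders, contrasts,
                                  cohort$profiles)
  files$efficacy <- file.path(out_dir, "efficacy_table.csv")
  utils::write.csv(eff, files$efficacy, row.names = FALSE)
  writeLines(format_efficacy_table(eff),
             file.path(out_dir, "efficacy_table.txt"))
  files$efficacy_txt <- file.path(out_dir, "efficacy_table.txt")

  # correlation of biomarker change with clinical response
  bio8 <- biomarkers[biomarkers$visit == "day 57", , drop = FALSE]
  ch8 <- changes[changes$week == 8, , drop = FALSE]
  m <- match(bio8$patient_id, ch8$patient_id)
  rho <- tryCatch(
    correlate_biomarker_response(bio8$pct_change_rr, ch8$uas7_change[m]),
    warning = function(w) list(rho = NA_real_, n = 0L))

  manifest <- list(
    package = "csutrial",
    version = as.character(utils::packageVersion("csutrial")),
    seed = seed,
    config_hash = unname(tools::md5sum(
      write_trial_config(cfg, file.path(out_dir, "trial_config.yaml")))),
    n_patients = nrow(cohort$profiles),
    spearman_rho_rr_uas7 = rho$rho,
    spearman_n = rho$n,
    files = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  stage_log(verbose, "done: %d files under %s", length(files), out_dir)
  invisible(manifest)
}

#' Efficacy summary table
#'
#' One row per endpoint per arm with the within-arm mean change and its
#' 95% CI, the LS-mean difference versus the reference arm, and the
#' responder counts with the nonresponder rule applied, in n (%) style
#' (percentages rounded half-up to integers; means and CIs to one
#' decimal).
#'
#' @param changes data.frame from [change_from_baseline()]
#' @param responders data.frame from [classify_responders()]
#' @param contrasts data.frame of contrasts from the pipeline
#' @param profiles cohort profiles
#' @param week reporting week (default 8)
#' @return data.frame, one row per arm
#' @export
summarize_efficacy_table <- function(changes, responders, contrasts,
                                     profiles, week = 8L) {
  arms <- levels(profiles$arm)
  ch <- changes[changes$week == week, , drop = FALSE]
  arm_of <- function(ids) profiles$arm[match(ids, profiles$patient_id)]
  ch$arm <- arm_of(ch$patient_id)
  resp <- responders[responders$week == week, , drop = FALSE]
  resp$arm <- arm_of(resp$patient_id)

  mmrm8 <- contrasts[contrasts$analysis == "mmrm" &
                       contrasts$endpoint == "uas7_change" &
                       contrasts$visit == as.character(week), , drop = FALSE]
  rows <- lapply(arms, function(a) {
    x <- ch$uas7_change[ch$arm == a & !is.na(ch$uas7_change)]
    n_arm <- sum(profiles$arm == a)
    mci <- if (length(x) > 1) {
      tt <- stats::t.test(x)
      sprintf("%.1f (%.1f to %.1f)", round_half_up(mean(x), 1),
              round_half_up(tt$conf.int[1], 1),
              round_half_up(tt$conf.int[2], 1))
    } else NA_character_
    ctr <- mmrm8[startsWith(mmrm8$comparison, a), , drop = FALSE]
    lsd <- if (nrow(ctr) == 1)
      sprintf("%.1f (%.1f to %.1f)", round_half_up(ctr$estimate, 1),
              round_half_up(ctr$lcl, 1), round_half_up(ctr$ucl, 1))
    else NA_character_   # reference arm: self-comparison suppressed
    fmt_resp <- function(flag) {
      n <- sum(resp[[flag]][resp$arm == a], na.rm = TRUE)
      sprintf("%d (%d)", n, round_half_up(100 * n / n_arm))
    }
    data.frame(
      arm = a, n = n_arm,
      uas7_change_mean_ci = mci,
      uas7_lsmean_diff_ci = lsd,
      well_controlled = fmt_resp("well_controlled"),
      complete_response = fmt_resp("complete_response"),
      mid_uas7 = fmt_resp("mid_uas7"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

format_efficacy_table <- function(eff) {
  widths <- vapply(names(eff), function(cn)
    max(nchar(cn), max(nchar(as.character(eff[[cn]])), na.rm = TRUE)),
    numeric(1))
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  header <- paste(mapply(pad, names(eff), widths), collapse = "  ")
  lines <- apply(eff, 1, function(r)
    paste(mapply(pad, r, widths), collapse = "  "))
  c("Efficacy end points (week 8, nonresponder rule applied)",
    strrep("-", nchar(header)), header, strrep("-", nchar(header)), lines)
}
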