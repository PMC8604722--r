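test_that("single-visit complete-data MMRM equals the cell-means linear model", {
  set.seed(101)
  d <- data.frame(
    patient_id = sprintf("p%03d", 1:60),
    arm = factor(rep(c("placebo", "active"), each = 30),
                 levels = c("placebo", "active")),
    country = factor("X"),
    visit = factor(8),
    change = rnorm(60, rep(c(-11, -20), each = 30), 8),
    baseline = 27.5)
  fit <- suppressMessages(fit_mmrm(d))
  ct <- estimate_contrasts(fit, visit = 8, dof = "containment")
  raw <- mean(d$change[d$arm == "active"]) -
    mean(d$change[d$arm == "placebo"])
  expect_equal(ct$estimate, raw, tolerance = 1e-8)
  lmfit <- lm(change ~ arm, data = d)
  expect_equal(ct$estimate, unname(coef(lmfit)["armactive"]),
               tolerance = 1e-8)
  expect_equal(ct$se, summary(lmfit)$coefficients["armactive", 2],
               tolerance = 1e-6)
})

test_that("MMRM recovers configured contrasts and covariance structure", {
  Sig <- matrix(c(60, 35, 30, 35, 70, 45, 30, 45, 90), 3)
  means <- list(placebo = cbind(-5, -8, -11.2),
                active = cbind(-10, -16, -20.7))
  d <- simulate_longitudinal(120, means, Sig, seed = 7)
  fit <- fit_mmrm(d)
  expect_true(fit$converged)
  expect_equal(fit$cov_structure, "unstructured")
  ct <- estimate_contrasts(fit, visit = 3)
  expect_lt(abs(ct$estimate - (-9.5)), 3 * ct$se)
  expect_lt(ct$lcl, ct$estimate); expect_gt(ct$ucl, ct$estimate)
  # estimated covariance is symmetric positive semi-definite
  V <- mmrm_covariance(fit)
  expect_equal(V, t(V), tolerance = 1e-8)
  expect_true(all(eigen(V, symmetric = TRUE)$values > -1e-8))
  expect_lt(max(abs(V - Sig)) / max(Sig), 0.5)
  # exchangeable arms give a near-zero contrast with covering CI
  d0 <- simulate_longitudinal(250, list(a = cbind(-8, -11), b = cbind(-8, -11)),
                              Sig[1:2, 1:2], seed = 8)
  ct0 <- estimate_contrasts(fit_mmrm(d0), visit = 2)
  expect_lt(ct0$lcl, 0); expect_gt(ct0$ucl, 0)
})

test_that("satterthwaite and containment contrasts agree on the estimate", {
  Sig <- matrix(c(60, 35, 35, 70), 2)
  means <- list(placebo = cbind(-5, -11), active = cbind(-9, -18))
  d <- simulate_longitudinal(60, means, Sig, seed = 12)
  fit <- fit_mmrm(d)
  ct_s <- estimate_contrasts(fit, visit = 2, dof = "satterthwaite")
  ct_c <- estimate_contrasts(fit, visit = 2, dof = "containment")
  expect_equal(ct_s$estimate, ct_c$estimate, tolerance = 1e-6)
  expect_equal(ct_s$se, ct_c$se, tolerance = 1e-6)
  expect_equal(ct_s$dof_method, "appx-satterthwaite")
})

test_that("CI width shrinks as 1/sqrt(n)", {
  Sig <- matrix(c(64, 40, 40, 81), 2)
  means <- list(placebo = cbind(-5, -11), active = cbind(-9, -18))
  widths <- sapply(c(50, 200, 800), function(n) {
    d <- simulate_longitudinal(n, means, Sig, seed = 100 + n)
    ct <- estimate_contrasts(fit_mmrm(d), visit = 2, dof = "containment")
    ct$ucl - ct$lcl
  })
  expect_equal(widths[1] / widths[2], 2, tolerance = 0.35)
  expect_equal(widths[2] / widths[3], 2, tolerance = 0.35)
})

test_that("LOCF and BOCF imputation follow their carry-forward rules", {
  prof <- data.frame(
    patient_id = c("a", "b", "c"),
    arm = factor(c("placebo", "active", "active"),
                 levels = c("placebo", "active")),
    country = "X", dropout_day = c(NA, 20L, 20L))
  mk <- function(id, vals) data.frame(
    patient_id = id, week = seq_along(vals), uas7 = 27 + vals,
    days_observed = 7, valid = TRUE, uas7_change = vals)
  # patient b: changes (-5, -12, missing); patient c: (-12, -5, missing)
  ch <- rbind(mk("a", c(-3, -4, -5)), mk("b", c(-5, -12)),
              mk("c", c(-12, -5)))
  # 3-patient fixture fits exactly; suppress the perfect-fit warning
  locf <- suppressWarnings(suppressMessages(
    ancova_with_imputation(ch, prof, "LOCF", week = 3)))
  bocf <- suppressWarnings(suppressMessages(
    ancova_with_imputation(ch, prof, "BOCF", week = 3)))
  # active arm mean under LOCF: (-12 + -5)/2; under BOCF: (-12 + -12)/2
  expect_equal(locf$estimate, mean(c(-12, -5)) - (-5), tolerance = 1e-8)
  expect_equal(bocf$estimate, mean(c(-12, -12)) - (-5), tolerance = 1e-8)
})

test_that("imputation is a no-op without missing data", {
  set.seed(33)
  prof <- data.frame(
    patient_id = sprintf("p%02d", 1:40),
    arm = factor(rep(c("placebo", "active"), 20),
                 levels = c("placebo", "active")),
    country = "X", dropout_day = NA_integer_)
  ch <- do.call(rbind, lapply(1:40, function(i) data.frame(
    patient_id = prof$patient_id[i], week = 1:8, uas7 = 20,
    days_observed = 7, valid = TRUE,
    uas7_change = rnorm(8, if (i %% 2) -11 else -18, 4))))
  locf <- ancova_with_imputation(ch, prof, "LOCF")
  bocf <- ancova_with_imputation(ch, prof, "BOCF")
  expect_equal(locf$estimate, bocf$estimate, tolerance = 1e-10)
  cc <- lm(change ~ arm, data = data.frame(
    change = ch$uas7_change[ch$week == 8], arm = prof$arm))
  expect_equal(locf$estimate, unname(coef(cc)[2]), tolerance = 1e-8)
})

test_that("MMRM is less biased than complete-case ANCOVA under MAR dropout", {
  # dropout depends on the past observed outcome: patients with poor
  # week-1 response are more likely to miss week 2
  Sig <- matrix(c(60, 45, 45, 70), 2)
  means <- list(placebo = cbind(-6, -11.2), active = cbind(-12, -20.7))
  reps <- 30
  bias_mmrm <- bias_cc <- numeric(reps)
  for (r in seq_len(reps)) {
    d <- simulate_longitudinal(60, means, Sig, seed = 400 + r)
    set.seed(900 + r)
    wide1 <- d$change[d$visit == 1]
    ids1 <- d$patient_id[d$visit == 1]
    p_drop <- plogis((wide1 - mean(wide1)) / 6)   # worse = more dropout
    dropped <- ids1[runif(length(ids1)) < p_drop]
    dd <- d[!(d$patient_id %in% dropped & d$visit == 2), ]
    ct_m <- estimate_contrasts(fit_mmrm(dd), visit = 2, dof = "containment")
    cc <- dd[dd$visit == 2, ]
    ct_c <- mean(cc$change[cc$arm == "active"]) -
      mean(cc$change[cc$arm == "placebo"])
    bias_mmrm[r] <- ct_m$estimate - (-9.5)
    bias_cc[r] <- ct_c - (-9.5)
  }
  expect_lt(abs(mean(bias_mmrm)), abs(mean(bias_cc)))
})

test_that("subgroup model nests the primary model and splits by BHRA", {
  Sig <- matrix(c(60, 35, 35, 70), 2)
  means <- list(placebo = cbind(-5, -11), active = cbind(-9, -18))
  d <- simulate_longitudinal(80, means, Sig, seed = 55)
  # collapsed indicator: estimates equal the primary fit's
  d$bhra_status <- factor("BHRA+", levels = c("BHRA-", "BHRA+"))
  expect_warning(sub1 <- fit_subgroup_mmrm(d, visit = 2), "single level")
  ct_primary <- estimate_contrasts(fit_mmrm(d[, setdiff(names(d), "bhra_status")]),
                                   visit = 2)
  expect_equal(sub1$contrasts$estimate, ct_primary$estimate,
               tolerance = 1e-6)
  # two-level indicator with no interaction: strata agree within error
  set.seed(66)
  d$bhra_status <- factor(sample(c("BHRA-", "BHRA+"), nrow(d), TRUE),
                          levels = c("BHRA-", "BHRA+"))
  # make status patient-constant
  first <- tapply(as.character(d$bhra_status), d$patient_id, `[`, 1)
  d$bhra_status <- factor(first[d$patient_id],
                          levels = c("BHRA-", "BHRA+"))
  sub2 <- fit_subgroup_mmrm(d, visit = 2)
  est <- sub2$contrasts$estimate
  se <- sub2$contrasts$se
  expect_lt(abs(est[1] - est[2]), 3 * sqrt(se[1]^2 + se[2]^2))
})

test_that("Spearman correlation handles monotone, reversed and tied data", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(correlate_biomarker_response(x, x^2)$rho, 1)
  expect_equal(correlate_biomarker_response(x, -x)$rho, -1)
  # 6-pair set with one tie: matches a hand rank computation
  px <- c(10, 20, 20, 30, 40, 50)   # ranks 1, 2.5, 2.5, 4, 5, 6
  py <- c(5, 1, 4, 6, 2, 3)
  rx <- c(1, 2.5, 2.5, 4, 5, 6)
  hand <- sum((rx - mean(rx)) * (py - mean(py))) /
    sqrt(sum((rx - mean(rx))^2) * sum((py - mean(py))^2))
  got <- correlate_biomarker_response(px, py)
  expect_equal(got$rho, hand, tolerance = 1e-12)
  expect_equal(got$n, 6)
  expect_warning(und <- correlate_biomarker_response(c(1, 2), c(3, 4)),
                 "fewer than 3")
  expect_true(is.na(und$rho))
})
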