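# Design-stage computations: dropout-adjusted power for the two-sample
# comparison of normal means, a simulation cross-check, the Bayesian
# posterior-predictive go/no-go rule for the interim analysis, and
# stratified permuted-block randomization.
#
# Benefit direction: these functions code effects as positive-is-better
# magnitudes; UAS7 improvements (negative changes) should be negated on
# entry.

GO_CUTOFF <- 0.60
NOGO_CUTOFF <- 0.25

#' Dropout-adjusted power for a two-arm comparison
#'
#' Evaluable sample size is \code{floor(n_per_arm * (1 - dropout))};
#' power is that of the two-sided two-sample comparison of normal means
#' at the evaluable n, by normal approximation (default) or the exact
#' t-based computation.
#'
#' @param difference true mean difference (score points)
#' @param sd common s.d. (score points)
#' @param alpha two-sided significance level
#' @param n_per_arm randomized patients per arm
#' @param dropout expected dropout fraction by the analysis visit
#' @param method \code{"normal"} or \code{"t"}
#' @return power (fraction in [0, 1])
#' @examples
#' compute_power(difference = 11, sd = 13, alpha = 0.10,
#'               n_per_arm = 30, dropout = 0.10)
#' @export
compute_power <- function(difference, sd, alpha = 0.10, n_per_arm,
                          dropout = 0, method = c("normal", "t")) {
  method <- match.arg(method)
  stopifnot(sd > 0, alpha > 0, alpha < 1, dropout >= 0, dropout < 1)
  n_eval <- floor(n_per_arm * (1 - dropout))
  if (n_eval < 2) stop("fewer than 2 evaluable patients per arm")
  if (method == "t")
    return(stats::power.t.test(n = n_eval, delta = abs(difference), sd = sd,
                               sig.level = alpha)$power)
  se <- sd * sqrt(2 / n_eval)
  z <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(abs(difference) / se - z) +
    stats::pnorm(-abs(difference) / se - z)
}

#' Simulated power (Monte Carlo cross-check)
#'
#' Simulates two-arm normal data at the evaluable n and reports the
#' rejection fraction of the two-sided two-sample t-test.
#'
#' @inheritParams compute_power
#' @param replicates number of simulated trials (>= 1000)
#' @param seed RNG seed
#' @return list: \code{power}, \code{se} (binomial Monte Carlo s.e.),
#'   \code{replicates}
#' @export
simulate_power <- function(difference, sd, alpha = 0.10, n_per_arm,
                           dropout = 0, replicates = 10000, seed = 1) {
  stopifnot(replicates >= 1000)
  n_eval <- floor(n_per_arm * (1 - dropout))
  if (n_eval < 2) stop("fewer than 2 evaluable patients per arm")
  set.seed(seed)
  x <- matrix(stats::rnorm(replicates * n_eval, 0, sd), replicates)
  y <- matrix(stats::rnorm(replicates * n_eval, difference, sd), replicates)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- apply(x, 1, stats::var); vy <- apply(y, 1, stats::var)
  tstat <- (my - mx) / sqrt((vx + vy) / n_eval)
  p <- 2 * stats::pt(-abs(tstat), df = 2 * n_eval - 2)
  pw <- mean(p < alpha)
  list(power = pw, se = sqrt(pw * (1 - pw) / replicates),
       replicates = replicates)
}

#' Posterior-predictive go/no-go decision
#'
#' With a flat prior and known s.d., the posterior for the true effect
#' is normal centred at the interim estimate with variance
#' \eqn{sd^2 (2/n_{interim})}; the predictive distribution of the future
#' phase 3 estimate adds \eqn{sd^2 (2/n_{phase3})}. The reported
#' probability is the upper tail of that distribution at the phase 3
#' effect threshold; decisions follow the >60% (go) / <25% (no-go)
#' cutoffs, with the zone between. \code{rule = "posterior"} instead
#' evaluates the posterior probability that the true effect exceeds the
#' threshold.
#'
#' @param estimate interim effect estimate (positive = benefit)
#' @param n_interim evaluable patients per arm at the interim
#' @param sd known s.d. (default 13, the design s.d.)
#' @param threshold phase 3 effect threshold (same scale as
#'   \code{estimate})
#' @param n_phase3 planned phase 3 patients per arm
#' @param rule \code{"predictive"} (future observed estimate) or
#'   \code{"posterior"} (true effect)
#' @return list of class \code{csu_gonogo}: \code{probability},
#'   \code{decision} ("go", "no-go" or "zone"), inputs echoed
#' @examples
#' posterior_predictive_go_nogo(estimate = 9, n_interim = 20,
#'                              threshold = 11, n_phase3 = 80)
#' @export
posterior_predictive_go_nogo <- function(estimate, n_interim, sd = 13,
                                         threshold, n_phase3,
                                         rule = c("predictive", "posterior")) {
  rule <- match.arg(rule)
  stopifnot(sd > 0, n_interim >= 2, n_phase3 >= 2)
  v_post <- sd^2 * 2 / n_interim
  v <- if (rule == "predictive") v_post + sd^2 * 2 / n_phase3 else v_post
  if (v <= 0) stop("nonpositive predictive variance")
  prob <- stats::pnorm((estimate - threshold) / sqrt(v))
  decision <- if (prob > GO_CUTOFF) "go"
    else if (prob < NOGO_CUTOFF) "no-go" else "zone"
  structure(list(probability = prob, decision = decision,
                 estimate = estimate, threshold = threshold,
                 n_interim = n_interim, n_phase3 = n_phase3,
                 sd = sd, rule = rule),
            class = "csu_gonogo")
}

#' @export
print.csu_gonogo <- function(x, ...) {
  cat(sprintf(
    "Go/no-go (%s rule): P(effect >= %.3g) = %.3f -> %s\n",
    x$rule, x$threshold, x$probability, toupper(x$decision)))
  invisible(x)
}

#' Stratified permuted-block randomization
#'
#' Assigns patients to arms within each stratum (e.g. country) using
#' permuted blocks; complete blocks are exactly balanced at the target
#' ratio. Deterministic for a given seed.
#'
#' @param strata character/factor vector, one entry per patient
#' @param arms arm labels
#' @param ratio integer allocation ratio, one per arm (default 1:1:...)
#' @param block_size block size; must be a multiple of \code{sum(ratio)}
#' @param seed RNG seed
#' @return factor of arm assignments, one per patient
#' @export
randomize_patients <- function(strata, arms, ratio = rep(1L, length(arms)),
                               block_size = sum(ratio), seed = 1) {
  stopifnot(length(ratio) == length(arms), all(ratio >= 1))
  if (block_size %% sum(ratio) != 0)
    stop("block size must be a multiple of the allocation ratio sum")
  set.seed(seed)
  strata <- as.character(strata)
  out <- character(length(strata))
  per_block <- rep(arms, times = ratio * (block_size / sum(ratio)))
  for (s in unique(strata)) {
    idx <- which(strata == s)
    n_blocks <- ceiling(length(idx) / block_size)
    seq_assign <- unlist(lapply(seq_len(n_blocks),
                                function(i) sample(per_block)))
    out[idx] <- seq_assign[seq_along(idx)]
  }
  factor(out, levels = arms)
}
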