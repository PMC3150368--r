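# Case-control association power under genomic inflation.

#' Power simulation scenario
#'
#' Defaults mirror a fully stratified GWAS design question: repeated
#' samples of 500 cases and 500 controls, a genome-wide significance
#' threshold of 5e-8, and 10,000 replicates per scenario.
#'
#' @param n_cases,n_controls group sizes.
#' @param maf_controls control-group minor allele frequency in (0, 1).
#' @param odds_ratio allelic odds ratio (> 0).
#' @param lambda_gc genomic inflation factor (>= 1) applied as a divisor
#'   to every test statistic.
#' @param alpha significance threshold.
#' @param n_replicates Monte-Carlo replicates.
#' @param seed integer seed.
#' @return list of class `power_scenario`.
#' @export
power_scenario <- function(n_cases = 500, n_controls = 500,
                           maf_controls = 0.16, odds_ratio = 2,
                           lambda_gc = 1, alpha = 5e-8,
                           n_replicates = 10000, seed = 1) {
  stopifnot(n_cases >= 1, n_controls >= 1,
            maf_controls > 0, maf_controls < 1,
            odds_ratio > 0, lambda_gc >= 1,
            alpha > 0, alpha < 1, n_replicates >= 1)
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 maf_controls = maf_controls, odds_ratio = odds_ratio,
                 lambda_gc = lambda_gc, alpha = alpha,
                 n_replicates = n_replicates, seed = as.integer(seed)),
            class = "power_scenario")
}

#' Case allele frequency implied by an allelic odds ratio
#'
#' Multiplying the control allelic odds `p/(1-p)` by `OR` gives
#' `p_case = OR * p / (1 - p + OR * p)`.
#'
#' @param p_control control allele frequency.
#' @param odds_ratio allelic odds ratio.
#' @return case allele frequency.
#' @export
case_allele_frequency <- function(p_control, odds_ratio) {
  stopifnot(all(p_control > 0), all(p_control < 1), all(odds_ratio > 0))
  odds_ratio * p_control / (1 - p_control + odds_ratio * p_control)
}

# 1-df allelic chi-square statistic from allele counts (vectorized);
# degenerate tables give NaN, treated as non-rejections downstream.
allelic_chisq_stat <- function(a_case, n_case_alleles, a_ctrl, n_ctrl_alleles) {
  b_case <- n_case_alleles - a_case
  b_ctrl <- n_ctrl_alleles - a_ctrl
  n <- n_case_alleles + n_ctrl_alleles
  n * (a_case * b_ctrl - b_case * a_ctrl)^2 /
    (n_case_alleles * n_ctrl_alleles * (a_case + a_ctrl) * (b_case + b_ctrl))
}

#' Simulate association-test power under genomic inflation
#'
#' Per replicate, the risk-allele count is drawn
#' `Binomial(2 n_cases, p_case)` in cases and
#' `Binomial(2 n_controls, p_control)` in controls, the 1-df allelic
#' chi-square is computed from the 2x2 allele table and divided by
#' `lambda_gc`, and the replicate rejects when the corrected statistic
#' exceeds the chi-square(1) critical value at `alpha`. Degenerate tables
#' (all one allele) count as non-rejections. Power is the rejection
#' fraction with an exact (Clopper-Pearson) binomial confidence interval.
#'
#' @param scenario a [power_scenario()].
#' @return list with `power`, `ci` (95% exact), `rejections`,
#'   `n_replicates` and the scenario.
#' @export
simulate_power <- function(scenario) {
  stopifnot(inherits(scenario, "power_scenario"))
  p0 <- scenario$maf_controls
  p1 <- case_allele_frequency(p0, scenario$odds_ratio)
  crit <- stats::qchisq(scenario$alpha, df = 1, lower.tail = FALSE)
  R <- scenario$n_replicates
  stat <- with_seed(scenario$seed, {
    a_case <- stats::rbinom(R, 2 * scenario$n_cases, p1)
    a_ctrl <- stats::rbinom(R, 2 * scenario$n_controls, p0)
    allelic_chisq_stat(a_case, 2 * scenario$n_cases,
                       a_ctrl, 2 * scenario$n_controls)
  })
  corrected <- stat / scenario$lambda_gc
  reject <- !is.na(corrected) & is.finite(corrected) & corrected > crit
  k <- sum(reject)
  # exact binomial CI
  lo <- if (k == 0) 0 else stats::qbeta(0.025, k, R - k + 1)
  hi <- if (k == R) 1 else stats::qbeta(0.975, k + 1, R - k)
  list(power = k / R, ci = c(lo, hi), rejections = k,
       n_replicates = R, scenario = scenario)
}

#' Closed-form power of the allelic test without inflation
#'
#' Noncentral chi-square approximation with noncentrality
#' `(p1 - p2)^2 / (pbar (1 - pbar) (1/(2 n1) + 1/(2 n2)))`; used as the
#' analytic reference for the simulation at lambda = 1.
#'
#' @param n_cases,n_controls group sizes.
#' @param maf_controls control allele frequency.
#' @param odds_ratio allelic odds ratio.
#' @param alpha significance threshold.
#' @param lambda_gc inflation divisor applied to the statistic, i.e. the
#'   critical value is multiplied by lambda.
#' @return approximate power.
#' @export
power_closed_form <- function(n_cases = 500, n_controls = 500,
                              maf_controls = 0.16, odds_ratio = 2,
                              alpha = 5e-8, lambda_gc = 1) {
  p1 <- case_allele_frequency(maf_controls, odds_ratio)
  p2 <- maf_controls
  pbar <- (n_cases * p1 + n_controls * p2) / (n_cases + n_controls)
  ncp <- (p1 - p2)^2 /
    (pbar * (1 - pbar) * (1 / (2 * n_cases) + 1 / (2 * n_controls)))
  crit <- stats::qchisq(alpha, df = 1, lower.tail = FALSE) * lambda_gc
  stats::pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE)
}

#' Power over a grid of MAF, odds ratio and lambda
#'
#' Runs [simulate_power()] on the Cartesian grid, with a seed derived per
#' cell from the base scenario's seed so cells are independent and the
#' grid is reproducible.
#'
#' @param maf_list,or_list,lambda_list grid axes.
#' @param base_scenario scenario supplying the remaining parameters.
#' @return long-format data.frame: maf, odds_ratio, lambda, power,
#'   ci_low, ci_high, n_replicates.
#' @export
power_grid <- function(maf_list, or_list, lambda_list,
                       base_scenario = power_scenario()) {
  cells <- expand.grid(maf = maf_list, odds_ratio = or_list,
                       lambda = lambda_list, KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    sc <- power_scenario(
      n_cases = base_scenario$n_cases, n_controls = base_scenario$n_controls,
      maf_controls = cells$maf[i], odds_ratio = cells$odds_ratio[i],
      lambda_gc = cells$lambda[i], alpha = base_scenario$alpha,
      n_replicates = base_scenario$n_replicates,
      seed = derive_seed(base_scenario$seed, 1000L + i))
    out <- simulate_power(sc)
    data.frame(maf = cells$maf[i], odds_ratio = cells$odds_ratio[i],
               lambda = cells$lambda[i], power = out$power,
               ci_low = out$ci[1], ci_high = out$ci[2],
               n_replicates = out$n_replicates)
  })
  do.call(rbind, res)
}
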