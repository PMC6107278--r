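#' Strategy names
#'
#' The two diagnostic strategies compared: the biomarker triage pathway
#' (positive triage test referred on to confirmatory cystoscopy, series
#' positivity) and cystoscopy for everyone.
#'
#' @return Character vector `c("dcrshp_triage", "cystoscopy_only")`.
#' @export
strategies <- function() c("dcrshp_triage", "cystoscopy_only")

match_strategy <- function(strategy) {
  rlang::arg_match0(strategy, strategies())
}

#' Split the presenting cohort by true disease and test outcome
#'
#' Applies the decision tree to a cohort presenting with haematuria.
#' Under `cystoscopy_only` everyone receives cystoscopy; under
#' `dcrshp_triage` only triage-positive patients do, and a case counts as
#' detected only if both tests are positive (series rule, tests
#' conditionally independent given disease).
#'
#' @param prevalence Probability of bladder cancer among presenters.
#' @param strategy One of [strategies()].
#' @param params A `bc_params` object supplying the four accuracy values.
#' @return A one-row tibble: `strategy`, `tp`, `fp`, `tn`, `fn`,
#'   `p_dcrshp_positive` (fraction referred to cystoscopy; equals 1 in
#'   the cystoscopy arm), `prevalence`.
#' @export
#' @examples
#' classify_cohort(0.1295, "dcrshp_triage")
classify_cohort <- function(prevalence, strategy, params = bc_parameters()) {
  strategy <- match_strategy(strategy)
  if (!is.numeric(prevalence) || prevalence < 0 || prevalence > 1) {
    rlang::abort("`prevalence` must be a probability in [0, 1].")
  }
  se_c <- params$sens_cysto
  sp_c <- params$spec_cysto
  if (strategy == "cystoscopy_only") {
    tp <- prevalence * se_c
    fn <- prevalence * (1 - se_c)
    tn <- (1 - prevalence) * sp_c
    fp <- (1 - prevalence) * (1 - sp_c)
    referred <- 1
  } else {
    se_d <- params$sens_dcrshp
    sp_d <- params$spec_dcrshp
    tp <- prevalence * se_d * se_c
    fn <- prevalence * (1 - se_d * se_c)
    fp <- (1 - prevalence) * (1 - sp_d) * (1 - sp_c)
    tn <- 1 - tp - fn - fp
    referred <- prevalence * se_d + (1 - prevalence) * (1 - sp_d)
  }
  tibble::tibble(
    strategy = strategy, tp = tp, fp = fp, tn = tn, fn = fn,
    p_dcrshp_positive = referred, prevalence = prevalence
  )
}

#' One-off testing-phase cost per presenting patient
#'
#' Test acquisition plus the initial diagnostic TURBT for every test
#' positive (true or false). Later TURBTs (recurrence, delayed detection)
#' are costed inside the Markov model.
#'
#' @param split A [classify_cohort()] row.
#' @param params A `bc_params` object (`price_dcrshp`, `cost_cystoscopy`,
#'   `cost_turbt`).
#' @return Cost in GBP per presenting patient.
#' @export
testing_cost <- function(split, params = bc_parameters()) {
  positives <- split$tp + split$fp
  if (split$strategy == "cystoscopy_only") {
    params$cost_cystoscopy + positives * params$cost_turbt
  } else {
    params$price_dcrshp +
      split$p_dcrshp_positive * params$cost_cystoscopy +
      positives * params$cost_turbt
  }
}

#' One-off testing-phase QALY loss per presenting patient
#'
#' Cystoscopy recipients lose `(1 - factor) * 0.5` QALYs in the testing
#' cycle (the cystoscopy utility value is applied over a six-month step);
#' each diagnostic TURBT costs its short decrement
#' (`dec_turbt * 7/365.25` by default).
#'
#' @inheritParams testing_cost
#' @return QALY loss (>= 0) per presenting patient.
#' @export
testing_disutility <- function(split, params = bc_parameters()) {
  scope_loss <- (1 - params$u_cystoscopy_factor) * params$cycle_years
  turbt_loss <- params$dec_turbt * params$dur_turbt_days / 365.25
  scoped <- if (split$strategy == "cystoscopy_only") 1 else split$p_dcrshp_positive
  scoped * scope_loss + (split$tp + split$fp) * turbt_loss
}
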