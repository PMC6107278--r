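#' Evaluate one diagnostic strategy end to end
#'
#' Runs the decision tree (testing costs and disutilities, initial
#' treatment at time zero, undiscounted) and the five-year Markov cohort
#' model (discounted, half-cycle corrected) for one strategy.
#'
#' @param strategy One of [strategies()].
#' @param params A `bc_params` object.
#' @param life_table A [make_life_table()] table; built from
#'   `params$prop_male` when omitted.
#' @return One-row tibble: `strategy`, `cost`, `qalys`, `life_years`.
#' @export
#' @examples
#' evaluate_strategy("cystoscopy_only")
evaluate_strategy <- function(strategy, params = bc_parameters(),
                              life_table = make_life_table(male_fraction = params$prop_male)) {
  strategy <- match_strategy(strategy)
  split <- classify_cohort(params$prevalence, strategy, params)
  init <- initial_distribution(split, params)
  trace <- run_cohort(init, params, life_table, init_events = initial_events(split, params))
  rewards <- accumulate_rewards(trace, params)
  tibble::tibble(
    strategy = strategy,
    cost = rewards$cost + testing_cost(split, params),
    qalys = rewards$qalys - testing_disutility(split, params),
    life_years = rewards$life_years
  )
}

#' Evaluate both strategies
#'
#' @inheritParams evaluate_strategy
#' @return Two-row tibble (one per strategy) of discounted cost, QALYs
#'   and life years per presenting patient.
#' @export
evaluate_strategies <- function(params = bc_parameters(),
                                life_table = make_life_table(male_fraction = params$prop_male)) {
  dplyr::bind_rows(
    evaluate_strategy("cystoscopy_only", params, life_table),
    evaluate_strategy("dcrshp_triage", params, life_table)
  )
}

#' Incremental cost-effectiveness of one strategy against a reference
#'
#' Computes incremental cost, QALYs and life years of `alt` over `ref`,
#' the ICER where defined, and a dominance flag: `"alt dominant"` when
#' `alt` is cheaper and at least as effective, `"alt dominated"` in the
#' converse case, `"icer"` otherwise (`"equal"` when both deltas vanish;
#' a pure cost difference at equal QALYs is dominance by cost).
#'
#' @param ref,alt One-row tibbles from [evaluate_strategy()].
#' @return One-row tibble with `delta_cost`, `delta_qalys`, `delta_ly`,
#'   `icer`, `dominance`.
#' @export
icer <- function(ref, alt) {
  dc <- alt$cost - ref$cost
  dq <- alt$qalys - ref$qalys
  dl <- alt$life_years - ref$life_years
  dominance <- if (dq == 0 && dc == 0) {
    "equal"
  } else if (dq == 0) {
    if (dc < 0) "alt dominant" else "alt dominated"
  } else if (dc <= 0 && dq > 0) {
    "alt dominant"
  } else if (dc >= 0 && dq < 0) {
    "alt dominated"
  } else {
    "icer"
  }
  tibble::tibble(
    delta_cost = dc, delta_qalys = dq, delta_ly = dl,
    icer = if (dq != 0) dc / dq else NA_real_,
    dominance = dominance
  )
}

#' Net monetary benefit
#'
#' `NMB = QALYs * WTP - cost`.
#'
#' @param result One-row tibble with `cost` and `qalys` (vectorised over
#'   rows).
#' @param wtp Willingness to pay per QALY (>= 0).
#' @return Numeric vector of NMB values.
#' @export
nmb <- function(result, wtp) {
  if (any(wtp < 0)) rlang::abort("`wtp` must be non-negative.")
  result$qalys * wtp - result$cost
}

#' Base-case comparison table
#'
#' Evaluates both strategies and lays the results out as an incremental
#' cost-effectiveness table (cost, incremental cost, QALYs, incremental
#' QALYs, ICER, life years, incremental life years, NMB at `wtp`).
#'
#' @inheritParams evaluate_strategy
#' @param wtp Willingness to pay per QALY for the NMB column.
#' @return A `cea_comparison` tibble, one row per strategy.
#' @export
#' @examples
#' compare_strategies()
compare_strategies <- function(params = bc_parameters(), wtp = 20000,
                               life_table = make_life_table(male_fraction = params$prop_male)) {
  res <- evaluate_strategies(params, life_table)
  inc <- icer(res[1, ], res[2, ])
  out <- res |>
    dplyr::mutate(
      delta_cost = c(NA, inc$delta_cost),
      delta_qalys = c(NA, inc$delta_qalys),
      delta_ly = c(NA, inc$delta_ly),
      icer = c(NA, inc$icer),
      dominance = c(NA, inc$dominance),
      nmb = nmb(res, wtp),
      wtp = wtp
    )
  class(out) <- c("cea_comparison", class(out))
  out
}

#' @export
print.cea_comparison <- function(x, ...) {
  cat("Cost-effectiveness comparison (WTP £", format(x$wtp[1], big.mark = ","),
      " per QALY)\n", sep = "")
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' Glance at a comparison
#'
#' @param x A [compare_strategies()] result.
#' @param ... Unused.
#' @return One-row tibble: incremental quantities, ICER, dominance and
#'   incremental NMB of the triage strategy over cystoscopy.
#' @export
glance.cea_comparison <- function(x, ...) {
  tibble::tibble(
    delta_cost = x$delta_cost[2],
    delta_qalys = x$delta_qalys[2],
    delta_ly = x$delta_ly[2],
    icer = x$icer[2],
    dominance = x$dominance[2],
    inc_nmb = x$nmb[2] - x$nmb[1],
    wtp = x$wtp[1]
  )
}

#' Export a comparison table to CSV
#' @param x A [compare_strategies()] result.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_comparison_csv <- function(x, path) {
  utils::write.csv(tibble::as_tibble(x), path, row.names = FALSE)
  invisible(x)
}
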