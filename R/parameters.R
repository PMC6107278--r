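#' Prevalence studies of bladder cancer in haematuria patients
#'
#' The three published haematuria-clinic series used to inform the
#' base-case prevalence, as cases over patients investigated.
#'
#' @return A tibble with columns `study`, `cases`, `n`.
#' @export
#' @examples
#' aggregate_prevalence(prevalence_studies())
prevalence_studies <- function() {
  tibble::tibble(
    study = c("haematuria clinic A", "haematuria clinic B", "rapid diagnosis clinic"),
    cases = c(230, 485, 156),
    n = c(1930, 4020, 778)
  )
}

#' Pool prevalence across studies
#'
#' Aggregates study-level case counts into the pooled proportion
#' `sum(cases) / sum(n)`; invariant to study order.
#'
#' @param studies A data frame with columns `cases` and `n` (one row per
#'   study), e.g. [prevalence_studies()].
#' @return The pooled prevalence as a single probability.
#' @export
aggregate_prevalence <- function(studies) {
  if (!is.data.frame(studies) || nrow(studies) == 0) {
    rlang::abort("`studies` must be a non-empty data frame with columns `cases` and `n`.")
  }
  if (!all(c("cases", "n") %in% names(studies))) {
    rlang::abort("`studies` must have columns `cases` and `n`.")
  }
  if (any(studies$n <= 0) || any(studies$cases < 0) || any(studies$cases > studies$n)) {
    rlang::abort("Each study needs 0 <= cases <= n and n > 0.")
  }
  sum(studies$cases) / sum(studies$n)
}

# Six-month surveillance schedule, one value per model cycle 1..10.
# Clinic-protocol roundings to the 6-month grid:
#  - LR NMIBC: cystoscopy at 3 months then annually -> 1 scope in cycle 1,
#    0.5/cycle thereafter.
#  - HR NMIBC on BCG: scopes 3-monthly for 2y, 4-monthly in y3, annual after;
#    BCG 3 vials every 3 months for 3 years -> 6 vials/cycle, cycles 1..6;
#    annual CT urogram.
#  - Post-cystectomy states: CT 4-monthly in y1, 6-monthly y2-3, annual after.
default_schedules <- function(n_cycles = 10) {
  pad <- function(x) {
    if (length(x) >= n_cycles) x[seq_len(n_cycles)] else c(x, rep(x[length(x)], n_cycles - length(x)))
  }
  list(
    scopes_lr = pad(c(1, rep(0.5, 9))),
    scopes_hr_bcg = pad(c(2, 2, 2, 2, 1.5, 1.5, rep(0.5, 4))),
    bcg_vials = pad(c(rep(6, 6), rep(0, 4))),
    ct_hr_bcg = pad(rep(0.5, 10)),
    ct_cyst = pad(c(1.5, 1.5, 1, 1, 1, 1, rep(0.5, 4)))
  )
}

base_parameter_list <- function() {
  list(
    # epidemiology / test accuracy
    prevalence = aggregate_prevalence(prevalence_studies()),
    sens_dcrshp = 57 / 63,
    spec_dcrshp = 31 / 39,
    sens_cysto = 145 / 148,
    spec_cysto = 562 / 599,
    prop_male = 0.796,
    start_age = 60,
    # diagnosis split over presenting stage (counts /192)
    split_lr = 105 / 192,
    split_hr_bcg = 47 / 192,
    split_hr_cyst = 13 / 192,
    split_mibc = 14 / 192,
    split_met = 13 / 192,
    # six-month transition probabilities
    recur_lr = 0.0638,
    recur_hr_bcg = 0.1393,
    prog_hr_bcg_mibc = 0.030,
    prog_hr_bcg_met = 0.010,
    prog_hr_cyst_met = 0.030,
    prog_mibc_met_early = 0.0771,
    prog_mibc_met_late = 0.0060,
    mort_bc_remission = 0.0048,
    mort_bc_mibc_early = 0.0497,
    mort_bc_mibc_late = 0.0327,
    mort_bc_met = 0.236,
    prop_recur_cystectomy = 9 / 52,
    mort_cystectomy = 96 / 4484,
    mort_turbt = 0.008,
    # false-negative track
    rr_untreated = 2.56,
    fn_detect_year1 = 0.5,
    fn_detect_year2 = 0.75,
    well_bc_death = FALSE,
    # costs (GBP, 2014)
    cost_cystectomy = 9816,
    cost_turbt = 2435,
    cost_palliative_day = 160.46,
    palliative_days = 135,
    charge_palliative_per_day = FALSE,
    cost_cisplatin_vial = 50.22,
    chemo_vials_per_course = 3,
    cost_ct = 395,
    cost_cystoscopy = 537,
    cost_bcg_vial = 71.61,
    price_dcrshp = 465.48,
    # utilities, decrements and event probabilities
    u_well = 1.0,
    u_cancer = 0.78,
    u_cystoscopy_factor = 0.997,
    dec_turbt = 0.1,
    dur_turbt_days = 7,
    dec_bcg_induction = 0.02,
    dur_bcg_induction_days = 42,
    dec_bcg_complication = 0.2,
    p_bcg_complication = 0.286,
    u_cystectomy_periop = 0.8,
    dur_cystectomy_days = 60,
    dec_cyst_complication = 0.3,
    p_cyst_complication = 0.267,
    u_impotence = 0.91,
    p_impotence = 0.59,
    u_post_cystectomy = 0.96,
    dec_chemo = 0.36,
    dur_chemo_days = 103,
    u_met_responsive = 0.62,
    u_met_unresponsive = 0.3,
    p_chemo_response = 0.425,
    # analysis settings
    discount_rate = 0.035,
    horizon_years = 5,
    cycle_years = 0.5,
    schedules = default_schedules()
  )
}

#' Build the base-case parameter set
#'
#' Assembles every model input at its point estimate, optionally
#' overriding named fields. All probabilities are six-month values unless
#' the name says otherwise; costs are GBP (2014); the diagnosis split is
#' the observed stage mix at presentation (counts out of 192 incident
#' cases).
#'
#' @param overrides Named list of parameter overrides; unknown names are
#'   an error. `schedules` may override the per-cycle surveillance
#'   schedule list.
#' @param config Optional path to a YAML file whose top-level keys mirror
#'   parameter names (applied before `overrides`).
#' @return A `bc_params` object (named list).
#' @export
#' @examples
#' p <- bc_parameters()
#' p$prevalence
#' bc_parameters(list(price_dcrshp = 0))$price_dcrshp
bc_parameters <- function(overrides = NULL, config = NULL) {
  params <- base_parameter_list()
  apply_overrides <- function(params, o, where) {
    if (is.null(o)) return(params)
    if (!is.list(o) || (length(o) > 0 && is.null(names(o)))) {
      rlang::abort("Overrides must be a named list.")
    }
    unknown <- setdiff(names(o), names(params))
    if (length(unknown)) {
      rlang::abort(paste0(
        "Unknown parameter name", if (length(unknown) > 1) "s", " in ", where, ": ",
        paste(unknown, collapse = ", ")
      ))
    }
    utils::modifyList(params, o)
  }
  if (!is.null(config)) {
    cfg <- yaml::read_yaml(config)
    cfg$provenance <- NULL # read-only subkey
    params <- apply_overrides(params, cfg, "config file")
  }
  params <- apply_overrides(params, overrides, "`overrides`")
  validate_params(params)
  structure(params, class = "bc_params")
}

validate_params <- function(p) {
  probs <- c(
    "prevalence", "sens_dcrshp", "spec_dcrshp", "sens_cysto", "spec_cysto",
    "prop_male", "split_lr", "split_hr_bcg", "split_hr_cyst", "split_mibc",
    "split_met", "recur_lr", "recur_hr_bcg", "prog_hr_bcg_mibc",
    "prog_hr_bcg_met", "prog_hr_cyst_met", "prog_mibc_met_early",
    "prog_mibc_met_late", "mort_bc_remission", "mort_bc_mibc_early",
    "mort_bc_mibc_late", "mort_bc_met", "prop_recur_cystectomy",
    "mort_cystectomy", "mort_turbt", "fn_detect_year1", "fn_detect_year2",
    "u_cystoscopy_factor", "p_bcg_complication", "u_cystectomy_periop",
    "p_cyst_complication", "u_impotence", "p_impotence", "u_post_cystectomy",
    "u_met_responsive", "u_met_unresponsive",
    "p_chemo_response", "u_well", "u_cancer"
  )
  for (nm in probs) {
    v <- p[[nm]]
    if (!is.numeric(v) || any(v < 0) || any(v > 1)) {
      rlang::abort(paste0("Parameter `", nm, "` must be a probability in [0, 1]."))
    }
  }
  split_sum <- p$split_lr + p$split_hr_bcg + p$split_hr_cyst + p$split_mibc + p$split_met
  if (abs(split_sum - 1) > 1e-9) {
    rlang::abort("The diagnosis split must sum to 1.")
  }
  costs <- grep("^cost_|^price_", names(p), value = TRUE)
  for (nm in costs) {
    if (p[[nm]] < 0) rlang::abort(paste0("Cost `", nm, "` must be non-negative."))
  }
  if (p$rr_untreated < 1) {
    rlang::abort("`rr_untreated` must be >= 1 (untreated disease cannot progress slower).")
  }
  if (p$fn_detect_year2 < p$fn_detect_year1) {
    rlang::abort("Cumulative detection must be non-decreasing across years.")
  }
  invisible(p)
}

#' @export
print.bc_params <- function(x, ...) {
  cat("<bc_params> bladder-cancer triage cost-utility model parameters\n")
  cat(sprintf(
    "  prevalence %.4f | triage se/sp %.3f/%.3f | cystoscopy se/sp %.3f/%.3f\n",
    x$prevalence, x$sens_dcrshp, x$spec_dcrshp, x$sens_cysto, x$spec_cysto
  ))
  cat(sprintf(
    "  triage-test price £%.2f | horizon %gy, %gy cycles, %.1f%% discount\n",
    x$price_dcrshp, x$horizon_years, x$cycle_years, 100 * x$discount_rate
  ))
  invisible(x)
}

#' Full parameter catalogue with provenance
#'
#' One row per model input: point value, PSA distribution kind and
#' parameters, and the data source it was taken from.
#'
#' @param params A `bc_params` object (default: base case).
#' @return A tibble with columns `parameter`, `value`, `distribution`,
#'   `dist_params`, `source`.
#' @export
parameter_catalogue <- function(params = bc_parameters()) {
  specs <- psa_distributions(params)
  src <- parameter_sources()
  scalar <- names(params)[vapply(params, function(v) is.numeric(v) && length(v) == 1, TRUE)]
  tibble::tibble(parameter = scalar) |>
    dplyr::mutate(
      value = purrr::map_dbl(.data$parameter, ~ params[[.x]]),
      distribution = purrr::map_chr(.data$parameter, function(nm) {
        if (nm %in% names(specs)) specs[[nm]]$kind else "fixed"
      }),
      dist_params = purrr::map_chr(.data$parameter, function(nm) {
        if (!nm %in% names(specs)) return("")
        pp <- specs[[nm]]$params
        paste(names(pp), signif(unname(pp), 6), sep = "=", collapse = "; ")
      }),
      source = purrr::map_chr(.data$parameter, ~ src[[.x]] %||% "model/analysis setting")
    )
}

#' Export the parameter catalogue to CSV
#' @param path Output file path.
#' @inheritParams parameter_catalogue
#' @return The catalogue tibble, invisibly.
#' @export
write_catalogue_csv <- function(path, params = bc_parameters()) {
  cat_tbl <- parameter_catalogue(params)
  utils::write.csv(cat_tbl, path, row.names = FALSE)
  invisible(cat_tbl)
}

parameter_sources <- function() {
  list(
    prevalence = "pooled 871/6728 across three haematuria-clinic series",
    sens_dcrshp = "triage-test accuracy study, 57/63",
    spec_dcrshp = "triage-test accuracy study, 31/39",
    sens_cysto = "cystoscopy accuracy study, 145/148",
    spec_cysto = "cystoscopy accuracy study, 562/599",
    prop_male = "haematuria clinic series, 619/778",
    split_lr = "regional patient data, 105/192",
    split_hr_bcg = "regional patient data, 47/192",
    split_hr_cyst = "regional patient data, 13/192",
    split_mibc = "regional patient data, 14/192",
    split_met = "regional patient data, 13/192",
    recur_lr = "6-month recurrence, 95% CI 0.0622-0.0654",
    recur_hr_bcg = "6-month recurrence, 95% CI 0.1368-0.1417",
    prog_hr_bcg_mibc = "20/80 progressed, median 26.7 months",
    prog_hr_bcg_met = "5/80 progressed, median 18.2 months",
    prog_hr_cyst_met = "18/72 progressed, median 25.9 months",
    prog_mibc_met_early = "32% progression at 5 years (n = 1054)",
    prog_mibc_met_late = "progression beyond 5 years (n = 1054)",
    mort_bc_remission = "74/1529 weighted 5-year cancer deaths in remission states",
    mort_bc_mibc_early = "60% 5-year survival (n = 1054)",
    mort_bc_mibc_late = "43% 10-year survival (n = 1054)",
    mort_bc_met = "6.8% 5-year survival in metastatic disease",
    prop_recur_cystectomy = "9/52 recurrences proceeding to cystectomy",
    mort_cystectomy = "30-day mortality 96/4484",
    mort_turbt = "10/1250 procedural mortality",
    rr_untreated = "relative risk untreated vs treated progression, 2.56 (SE 1 assumed)",
    fn_detect_year1 = "assumed 50% of missed cases found in year 1",
    fn_detect_year2 = "assumed 75% cumulative by year 2",
    cost_cystectomy = "NHS reference costs, cystectomy with urinary diversion",
    cost_turbt = "HTA model cost, inflated to 2014",
    cost_palliative_day = "NHS reference costs, same-day specialist palliative care",
    palliative_days = "assumed 135 days of palliative care in metastatic disease",
    u_cancer = "bladder-cancer health-state utility 0.78 (0.52-1), assumed; applied to NMIBC and undiagnosed states",
    cost_cisplatin_vial = "BNF cisplatin 100mg/100ml vial",
    chemo_vials_per_course = "3 cycles per chemotherapy course",
    cost_ct = "CT abdomen/pelvis, inflated",
    cost_cystoscopy = "HTA model cost, inflated to 2014",
    cost_bcg_vial = "BNF OncoTICE 12.5mg vial",
    price_dcrshp = "free parameter: candidate unit price of the triage test",
    u_cystoscopy_factor = "cystoscopy utility 0.997 (0.95-1) per 6-month step",
    dec_turbt = "TURBT decrement 0.1 (SE 0.02) over 7 days",
    dec_bcg_induction = "BCG induction decrement 0.02 (0-0.3) over 6 weeks",
    dec_bcg_complication = "BCG complication decrement 0.2 (0-0.4) over 6 months",
    p_bcg_complication = "BCG complication probability 0.286 (0.18-0.67)",
    u_cystectomy_periop = "peri-cystectomy utility 0.8 (0.5-1) over 60 days",
    dec_cyst_complication = "short-term complication decrement 0.3 (0-0.6) over 60 days",
    p_cyst_complication = "short-term complication probability 0.267 (0.2-0.304)",
    u_impotence = "post-cystectomy impotence utility 0.91 (0.69-1)",
    p_impotence = "impotence probability 0.59 (0.33-1)",
    u_post_cystectomy = "post-cystectomy state utility 0.96 (0.72-1)",
    dec_chemo = "chemotherapy decrement 0.36 (0.2-0.9) over 103 days",
    u_met_responsive = "metastases responsive to chemotherapy, 0.62 (0.31-0.93)",
    u_met_unresponsive = "metastases unresponsive, 0.3 (0.13-0.62)",
    p_chemo_response = "response probability 0.425 (0.381-0.57)",
    discount_rate = "3.5% per year for costs and outcomes",
    horizon_years = "5-year model horizon",
    cycle_years = "6-month Markov cycle",
    start_age = "cohort enters at age 60"
  )
}
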