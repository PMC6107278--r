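#' PSA distribution specifications for the uncertain parameters
#'
#' Builds the per-parameter uncertainty specifications used by the
#' probabilistic sensitivity analysis:
#' * count-backed probabilities (test accuracies, prevalence, procedure
#'   mortalities, recurrence-to-cystectomy fraction) as
#'   [beta_from_counts()];
#' * range-backed utilities and event probabilities as Beta via
#'   [se_from_range()] + [beta_from_moments()];
#' * recurrence probabilities (printed with CIs, no counts) likewise via
#'   the SE-from-range Beta;
#' * utility decrements as [lognormal_for_decrement()];
#' * the untreated-progression relative risk as a natural-scale
#'   log-normal (mean 2.56, SE 1) truncated below at 1;
#' * the diagnosis split as a Dirichlet over its counts.
#'
#' Six-month probabilities that the sources derive from survival times
#' rather than direct counts (progression and cancer-death rates) carry no
#' usable uncertainty at the six-month scale and are held fixed, as are
#' all unit costs.
#'
#' @param params A `bc_params` object.
#' @return Named list of `dist_spec` objects.
#' @export
psa_distributions <- function(params = bc_parameters()) {
  beta_range <- function(mean, lo, hi) beta_from_moments(mean, se_from_range(lo, hi))
  list(
    sens_dcrshp = beta_from_counts(57, 6),
    spec_dcrshp = beta_from_counts(31, 8),
    sens_cysto = beta_from_counts(145, 3),
    spec_cysto = beta_from_counts(562, 37),
    prevalence = beta_from_counts(871, 6728 - 871),
    mort_turbt = beta_from_counts(10, 1240),
    mort_cystectomy = beta_from_counts(96, 4484 - 96),
    prop_recur_cystectomy = beta_from_counts(9, 52 - 9),
    diagnosis_split = dirichlet_from_counts(
      c(split_lr = 105, split_hr_bcg = 47, split_hr_cyst = 13,
        split_mibc = 14, split_met = 13)
    ),
    recur_lr = beta_range(params$recur_lr, 0.0622, 0.0654),
    recur_hr_bcg = beta_range(params$recur_hr_bcg, 0.1368, 0.1417),
    u_cystoscopy_factor = beta_range(params$u_cystoscopy_factor, 0.95, 1),
    u_cystectomy_periop = beta_range(params$u_cystectomy_periop, 0.5, 1),
    u_impotence = beta_range(params$u_impotence, 0.69, 1),
    u_post_cystectomy = beta_range(params$u_post_cystectomy, 0.72, 1),
    u_cancer = beta_range(params$u_cancer, 0.52, 1),
    u_met_responsive = beta_range(params$u_met_responsive, 0.31, 0.93),
    u_met_unresponsive = beta_range(params$u_met_unresponsive, 0.13, 0.62),
    p_bcg_complication = beta_range(params$p_bcg_complication, 0.18, 0.67),
    p_cyst_complication = beta_range(params$p_cyst_complication, 0.2, 0.304),
    p_impotence = beta_range(params$p_impotence, 0.33, 1),
    p_chemo_response = beta_range(params$p_chemo_response, 0.381, 0.57),
    dec_turbt = lognormal_for_decrement(params$dec_turbt, 0.02),
    dec_bcg_induction = lognormal_for_decrement(params$dec_bcg_induction, se_from_range(0, 0.3)),
    dec_bcg_complication = lognormal_for_decrement(params$dec_bcg_complication, se_from_range(0, 0.4)),
    dec_cyst_complication = lognormal_for_decrement(params$dec_cyst_complication, se_from_range(0, 0.6)),
    dec_chemo = lognormal_for_decrement(params$dec_chemo, se_from_range(0.2, 0.9)),
    rr_untreated = lognormal_from_moments(2.56, 1, lower = 1)
  )
}

#' Draw one parameter set from the PSA distributions
#'
#' Samples every spec and returns a valid `bc_params` with the drawn
#' values substituted; probabilities are left on the Beta support, the
#' relative risk is truncated below at 1, and Dirichlet draws replace the
#' whole diagnosis split. A fixed seed gives an identical draw.
#'
#' @param base A `bc_params` object.
#' @param specs Named list of `dist_spec`s (default [psa_distributions()]).
#'   The name `diagnosis_split` is expanded into the five split fields.
#' @param seed Optional integer seed for this single draw.
#' @return A `bc_params` object.
#' @export
sample_parameter_set <- function(base = bc_parameters(), specs = psa_distributions(base),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  draw <- draw_parameter_matrix(specs, n = 1)
  apply_draw(base, draw[1, ])
}

#' Draw a matrix of PSA parameter values
#'
#' @param specs Named list of `dist_spec`s.
#' @param n Number of joint draws.
#' @return An `n x p` numeric matrix; multivariate specs contribute one
#'   column per component.
#' @export
draw_parameter_matrix <- function(specs, n) {
  cols <- purrr::imap(specs, function(spec, nm) {
    x <- sample_dist(spec, n)
    if (is.matrix(x)) x else matrix(x, ncol = 1, dimnames = list(NULL, nm))
  })
  out <- do.call(cbind, unname(cols))
  if (anyNA(out)) rlang::abort("PSA draw produced missing values.")
  out
}

# Substitute one draw (named numeric vector) into a parameter set.
apply_draw <- function(base, draw) {
  p <- unclass(base)
  split_cols <- grep("^split_", names(draw), value = TRUE)
  if (length(split_cols)) {
    draw[split_cols] <- draw[split_cols] / sum(draw[split_cols])
  }
  for (nm in names(draw)) {
    if (!nm %in% names(p)) {
      rlang::abort(paste0("Sampled parameter `", nm, "` is not a model parameter."))
    }
    p[[nm]] <- unname(draw[[nm]])
  }
  p$rr_untreated <- max(1, p$rr_untreated)
  validate_params(p)
  structure(p, class = "bc_params")
}
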