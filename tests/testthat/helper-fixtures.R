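# Shared fixtures, built lazily and cached for the test session.

.fixture_env <- new.env(parent = emptyenv())

base_params <- function() {
  if (is.null(.fixture_env$params)) .fixture_env$params <- bc_parameters()
  .fixture_env$params
}

base_life_table <- function() {
  if (is.null(.fixture_env$lt)) {
    .fixture_env$lt <- make_life_table(male_fraction = base_params()$prop_male)
  }
  .fixture_env$lt
}

# A deathless, event-free parameter set: no disease dynamics at all.
null_dynamics_params <- function() {
  bc_parameters(list(
    recur_lr = 0, recur_hr_bcg = 0, prog_hr_bcg_mibc = 0, prog_hr_bcg_met = 0,
    prog_hr_cyst_met = 0, prog_mibc_met_early = 0, prog_mibc_met_late = 0,
    mort_bc_remission = 0, mort_bc_mibc_early = 0, mort_bc_mibc_late = 0,
    mort_bc_met = 0, mort_cystectomy = 0, mort_turbt = 0, rr_untreated = 1
  ))
}

# Effectively zero all-cause mortality.
null_life_table <- function() {
  make_life_table(h0_male = 1e-12, h0_female = 1e-12, slope = 0)
}

# Shared moderate-size PSA sample for the sensitivity/VOI tests.
shared_psa <- function() {
  if (is.null(.fixture_env$psa)) {
    .fixture_env$psa <- run_psa(base_params(), n = 1500, seed = 42,
                                life_table = base_life_table())
  }
  .fixture_env$psa
}

# Synthetic PSA-sample object with prescribed per-draw net benefits,
# encoded as costs (NB = -cost) so they hold at every WTP.
synthetic_sample <- function(nb_cysto, nb_triage, draws = NULL) {
  n <- length(nb_cysto)
  structure(
    list(
      draws = draws %||% tibble::tibble(dummy = seq_len(n)),
      outcomes = tibble::tibble(
        draw = rep(seq_len(n), each = 2),
        strategy = rep(c("cystoscopy_only", "dcrshp_triage"), n),
        cost = -as.numeric(rbind(nb_cysto, nb_triage)),
        qalys = 0,
        life_years = 0
      ),
      n = n, seed = NA_integer_
    ),
    class = "psa_sample"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
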