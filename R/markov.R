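#' Markov state space
#'
#' Thirteen states: never-cancer `well`; diagnosed cancer states
#' (`lr` low-risk NMIBC, `hr_bcg` high-risk NMIBC on BCG, `hr_cyst`
#' high-risk NMIBC post-cystectomy, `mibc` muscle-invasive
#' post-cystectomy, `met` metastatic); undiagnosed mirrors `u_*` for the
#' false-negative track; and the absorbing `dead_bc` / `dead_oc`
#' (bladder-cancer vs other-cause or procedural death).
#'
#' @return Character vector of state names, in matrix order.
#' @export
model_states <- function() {
  c("well", "lr", "hr_bcg", "hr_cyst", "mibc", "met",
    "u_lr", "u_hr_bcg", "u_hr_cyst", "u_mibc", "u_met",
    "dead_bc", "dead_oc")
}

event_names <- function() {
  c("turbt", "cystectomy", "cyst_survivor", "bcg_entry", "chemo_course",
    "met_entry", "detection", "recurrence")
}

#' Per-cycle detection probability for undiagnosed (false-negative) cases
#'
#' Missed cases are found as haematuria persists: cumulatively 50% by the
#' end of year 1, 75% by year 2, all thereafter. The per-six-month
#' conditional probabilities reproducing that schedule are
#' `1 - sqrt(0.5)` in cycles 1-4 and 1 from cycle 5 on.
#'
#' @param cycle Cycle index (1-based; the transition entering cycle
#'   `cycle`). Detection is undefined at cycle 0 (testing happens then).
#' @param params A `bc_params` object (cumulative `fn_detect_year1/2`).
#' @return Conditional detection probability for that cycle.
#' @export
detection_schedule <- function(cycle, params = bc_parameters()) {
  if (any(cycle < 1)) {
    rlang::abort("Detection is undefined at cycle 0; testing happens at time zero.")
  }
  c1 <- params$fn_detect_year1
  c2 <- params$fn_detect_year2
  per1 <- 1 - sqrt(1 - c1)
  per2 <- 1 - sqrt((1 - c2) / (1 - c1))
  out <- ifelse(cycle <= 2, per1, ifelse(cycle <= 4, per2, 1))
  out
}

# Derived constants shared across cycles.
precompute_dynamics <- function(params) {
  p <- params
  rr <- p$rr_untreated
  cap <- function(x) pmin(1, x)
  list(
    p = p,
    tm = p$mort_turbt,
    cm = p$mort_cystectomy,
    rc = p$prop_recur_cystectomy,
    bcr = p$mort_bc_remission,
    horizon_cycles = round(p$horizon_years / p$cycle_years),
    u_bcr = cap(rr * p$mort_bc_remission),
    u_prog_hr_mibc = cap(rr * p$prog_hr_bcg_mibc),
    u_prog_hr_met = cap(rr * p$prog_hr_bcg_met),
    u_prog_cyst_met = cap(rr * p$prog_hr_cyst_met),
    u_prog_mibc_met = cap(rr * c(p$prog_mibc_met_early, p$prog_mibc_met_late)),
    u_mort_mibc = cap(rr * c(p$mort_bc_mibc_early, p$mort_bc_mibc_late)),
    u_mort_met = cap(rr * p$mort_bc_met),
    detect = detection_schedule(seq_len(max(1, round(p$horizon_years / p$cycle_years))), p)
  )
}

# One cycle's transition matrix and per-unit-mass event intensities.
# `cycle` is 1-based (transition from cycle-1 to cycle); q is the
# six-month all-cause death probability applied, competing-risk style, to
# the residual in-state mass only, so disease-specific probabilities are
# preserved exactly.
cycle_components <- function(dyn, cycle, q) {
  p <- dyn$p
  s <- model_states()
  ns <- length(s)
  P <- matrix(0, ns, ns, dimnames = list(s, s))
  E <- matrix(0, ns, length(event_names()), dimnames = list(s, event_names()))
  early <- cycle <= dyn$horizon_cycles
  pmm <- if (early) p$prog_mibc_met_early else p$prog_mibc_met_late
  pmd <- if (early) p$mort_bc_mibc_early else p$mort_bc_mibc_late
  u_pmm <- dyn$u_prog_mibc_met[if (early) 1 else 2]
  u_pmd <- dyn$u_mort_mibc[if (early) 1 else 2]
  d <- if (cycle <= length(dyn$detect)) dyn$detect[cycle] else 1
  tm <- dyn$tm; cm <- dyn$cm; rc <- dyn$rc; bcr <- dyn$bcr

  settle <- function(state, stay) {
    if (stay < -1e-12) {
      rlang::abort(paste0(
        "Transition probabilities out of state `", state,
        "` exceed 1 at cycle ", cycle, "."
      ))
    }
    stay <- max(stay, 0)
    P[state, state] <<- stay * (1 - q)
    P[state, "dead_oc"] <<- P[state, "dead_oc"] + stay * q
  }

  # well: no disease dynamics (optionally residual cancer-death risk)
  wd <- if (isTRUE(p$well_bc_death)) bcr else 0
  P["well", "dead_bc"] <- wd
  settle("well", 1 - wd)

  # recurrence in a diagnosed NMIBC state: TURBT, a fraction converts to
  # the cystectomy pathway, the rest remain in-state
  recur_block <- function(state, r) {
    E[state, "recurrence"] <<- r
    E[state, "turbt"] <<- E[state, "turbt"] + r
    dead <- r * tm
    surv <- r * (1 - tm)
    E[state, "cystectomy"] <<- E[state, "cystectomy"] + surv * rc
    dead <- dead + surv * rc * cm
    conv <- surv * rc * (1 - cm)
    E[state, "cyst_survivor"] <<- E[state, "cyst_survivor"] + conv
    P[state, "hr_cyst"] <<- P[state, "hr_cyst"] + conv
    P[state, "dead_oc"] <<- P[state, "dead_oc"] + dead
    surv * (1 - rc) # recurrence survivors who remain in-state
  }

  # lr
  stay_rec <- recur_block("lr", p$recur_lr)
  P["lr", "dead_bc"] <- bcr
  settle("lr", 1 - p$recur_lr - bcr + stay_rec)

  # hr_bcg
  stay_rec <- recur_block("hr_bcg", p$recur_hr_bcg)
  pm <- p$prog_hr_bcg_mibc
  E["hr_bcg", "turbt"] <- E["hr_bcg", "turbt"] + pm
  P["hr_bcg", "dead_oc"] <- P["hr_bcg", "dead_oc"] + pm * tm
  s1 <- pm * (1 - tm)
  E["hr_bcg", "cystectomy"] <- E["hr_bcg", "cystectomy"] + s1
  P["hr_bcg", "dead_oc"] <- P["hr_bcg", "dead_oc"] + s1 * cm
  s2 <- s1 * (1 - cm)
  E["hr_bcg", "cyst_survivor"] <- E["hr_bcg", "cyst_survivor"] + s2
  E["hr_bcg", "chemo_course"] <- E["hr_bcg", "chemo_course"] + s2
  P["hr_bcg", "mibc"] <- s2
  pt <- p$prog_hr_bcg_met
  E["hr_bcg", "turbt"] <- E["hr_bcg", "turbt"] + pt
  P["hr_bcg", "dead_oc"] <- P["hr_bcg", "dead_oc"] + pt * tm
  P["hr_bcg", "met"] <- pt * (1 - tm)
  E["hr_bcg", "met_entry"] <- pt * (1 - tm)
  P["hr_bcg", "dead_bc"] <- bcr
  settle("hr_bcg", 1 - p$recur_hr_bcg - pm - pt - bcr + stay_rec)

  # hr_cyst (post-cystectomy: no TURBT on progression)
  P["hr_cyst", "met"] <- p$prog_hr_cyst_met
  E["hr_cyst", "met_entry"] <- p$prog_hr_cyst_met
  P["hr_cyst", "dead_bc"] <- bcr
  settle("hr_cyst", 1 - p$prog_hr_cyst_met - bcr)

  # mibc (post-cystectomy)
  P["mibc", "met"] <- pmm
  E["mibc", "met_entry"] <- pmm
  P["mibc", "dead_bc"] <- pmd
  settle("mibc", 1 - pmm - pmd)

  # met
  P["met", "dead_bc"] <- p$mort_bc_met
  settle("met", 1 - p$mort_bc_met)

  # undiagnosed mirrors: detection first (TURBT + counterpart entry
  # bundle), then untreated dynamics at relative risk `rr_untreated`
  detect_block <- function(state, counterpart, bundle) {
    E[state, "detection"] <<- d
    E[state, "turbt"] <<- E[state, "turbt"] + d
    dead <- d * tm
    surv <- d * (1 - tm)
    if (bundle %in% c("cystectomy", "mibc")) {
      E[state, "cystectomy"] <<- E[state, "cystectomy"] + surv
      dead <- dead + surv * cm
      surv <- surv * (1 - cm)
      E[state, "cyst_survivor"] <<- E[state, "cyst_survivor"] + surv
      if (bundle == "mibc") E[state, "chemo_course"] <<- E[state, "chemo_course"] + surv
    }
    if (bundle == "bcg") E[state, "bcg_entry"] <<- surv
    if (bundle == "met") E[state, "met_entry"] <<- surv
    P[state, counterpart] <<- P[state, counterpart] + surv
    P[state, "dead_oc"] <<- P[state, "dead_oc"] + dead
    1 - d # undetected mass
  }

  U <- detect_block("u_lr", "lr", "none")
  P["u_lr", "dead_bc"] <- U * dyn$u_bcr
  settle("u_lr", U * (1 - dyn$u_bcr))

  U <- detect_block("u_hr_bcg", "hr_bcg", "bcg")
  P["u_hr_bcg", "u_mibc"] <- U * dyn$u_prog_hr_mibc
  P["u_hr_bcg", "u_met"] <- U * dyn$u_prog_hr_met
  P["u_hr_bcg", "dead_bc"] <- U * dyn$u_bcr
  settle("u_hr_bcg", U * (1 - dyn$u_prog_hr_mibc - dyn$u_prog_hr_met - dyn$u_bcr))

  U <- detect_block("u_hr_cyst", "hr_cyst", "cystectomy")
  P["u_hr_cyst", "u_met"] <- U * dyn$u_prog_cyst_met
  P["u_hr_cyst", "dead_bc"] <- U * dyn$u_bcr
  settle("u_hr_cyst", U * (1 - dyn$u_prog_cyst_met - dyn$u_bcr))

  U <- detect_block("u_mibc", "mibc", "mibc")
  P["u_mibc", "u_met"] <- U * u_pmm
  P["u_mibc", "dead_bc"] <- U * u_pmd
  settle("u_mibc", U * (1 - u_pmm - u_pmd))

  U <- detect_block("u_met", "met", "met")
  P["u_met", "dead_bc"] <- U * dyn$u_mort_met
  settle("u_met", U * (1 - dyn$u_mort_met))

  # absorbing states
  P["dead_bc", "dead_bc"] <- 1
  P["dead_oc", "dead_oc"] <- 1

  list(P = P, E = E)
}

#' Transition matrix for one cycle
#'
#' Six-month transition probabilities over the full state space for a
#' given cycle, with disease-specific probabilities applied first and
#' age-specific all-cause mortality applied to the residual in-state mass
#' (rows are never rescaled; a negative residual is an error naming the
#' state).
#'
#' @param params A `bc_params` object.
#' @param cycle 1-based cycle index of the transition.
#' @param life_table A [make_life_table()] table.
#' @return A named square matrix; every row sums to 1.
#' @export
build_transition_matrix <- function(params, cycle, life_table = make_life_table(male_fraction = params$prop_male)) {
  stopifnot(cycle >= 1)
  dyn <- precompute_dynamics(params)
  age <- params$start_age + (cycle - 1) * params$cycle_years
  q <- life_table_qx(life_table, age)
  cycle_components(dyn, cycle, q)$P
}

#' Initial state occupancy after testing and first treatment
#'
#' Maps the decision-tree split into the Markov state space: true
#' positives enter the diagnosed states in the diagnosis-split
#' proportions (less cystectomy mortality in the cystectomy groups);
#' false negatives enter the undiagnosed mirrors; true negatives and
#' (post-TURBT) false positives start well. The diagnostic work-up itself
#' carries costs and disutilities but no procedural mortality; procedure
#' mortality applies to procedures occurring within the Markov cycles
#' (and to the time-zero cystectomy, which determines state entry).
#'
#' @param split A [classify_cohort()] row.
#' @param params A `bc_params` object.
#' @return Named occupancy vector over [model_states()], summing to 1.
#' @export
initial_distribution <- function(split, params = bc_parameters()) {
  s <- model_states()
  x <- stats::setNames(numeric(length(s)), s)
  cm <- params$mort_cystectomy
  splits <- c(
    lr = params$split_lr, hr_bcg = params$split_hr_bcg,
    hr_cyst = params$split_hr_cyst, mibc = params$split_mibc,
    met = params$split_met
  )
  x["well"] <- split$tn + split$fp
  x["lr"] <- split$tp * splits["lr"]
  x["hr_bcg"] <- split$tp * splits["hr_bcg"]
  x["hr_cyst"] <- split$tp * splits["hr_cyst"] * (1 - cm)
  x["mibc"] <- split$tp * splits["mibc"] * (1 - cm)
  x["met"] <- split$tp * splits["met"]
  x[c("u_lr", "u_hr_bcg", "u_hr_cyst", "u_mibc", "u_met")] <- split$fn * splits
  x["dead_oc"] <- split$tp * (splits["hr_cyst"] + splits["mibc"]) * cm
  x
}

# Treatment delivered at model entry (time zero, undiscounted): entry
# bundles for the true-positive stage mix. The initial diagnostic TURBT
# cost/decrement for all test positives is charged by the testing-phase
# functions.
initial_events <- function(split, params) {
  cm <- params$mort_cystectomy
  e <- stats::setNames(numeric(length(event_names())), event_names())
  tp <- split$tp
  e["bcg_entry"] <- tp * params$split_hr_bcg
  cyst <- tp * (params$split_hr_cyst + params$split_mibc)
  e["cystectomy"] <- cyst
  e["cyst_survivor"] <- cyst * (1 - cm)
  e["chemo_course"] <- tp * params$split_mibc * (1 - cm)
  e["met_entry"] <- tp * params$split_met
  e
}

#' Run the cohort through the Markov model
#'
#' Applies the cycle transition matrices over the model horizon and
#' records state occupancy and event flows (TURBTs, cystectomies, BCG
#' starts, chemotherapy courses, metastasis entries, detections,
#' recurrences) per cycle.
#'
#' @param init Initial occupancy vector over [model_states()] (sums to 1).
#' @param params A `bc_params` object.
#' @param life_table A [make_life_table()] table.
#' @param init_events Optional named vector of time-zero event counts
#'   (from the initial treatment bundle).
#' @return A `cohort_trace`: list with `occupancy`
#'   ((cycles+1) x states matrix), `flows` (cycles x events matrix,
#'   time-zero events in row 0 attribute `init_events`), and `params`.
#' @export
run_cohort <- function(init, params = bc_parameters(),
                       life_table = make_life_table(male_fraction = params$prop_male),
                       init_events = NULL) {
  s <- model_states()
  stopifnot(length(init) == length(s))
  if (abs(sum(init) - 1) > 1e-9) {
    rlang::abort("`init` must sum to 1.")
  }
  dyn <- precompute_dynamics(params)
  n_cycles <- dyn$horizon_cycles
  occ <- matrix(0, n_cycles + 1, length(s), dimnames = list(0:n_cycles, s))
  flows <- matrix(0, n_cycles, length(event_names()),
                  dimnames = list(1:n_cycles, event_names()))
  # surveillance/treatment schedules are clocked from state entry, so the
  # occupancy of the schedule-bearing states is decomposed by tenure
  # (cycles since entering the state)
  ss <- schedule_states()
  tenure <- matrix(0, length(ss), n_cycles + 1, dimnames = list(ss, NULL))
  tenure[, 1] <- init[match(ss, s)]
  sched_occ <- lapply(ss, function(st) matrix(0, n_cycles, n_cycles))
  names(sched_occ) <- ss
  x <- as.numeric(init)
  occ[1, ] <- x
  for (j in seq_len(n_cycles)) {
    age <- params$start_age + (j - 1) * params$cycle_years
    q <- life_table_qx(life_table, age)
    cc <- cycle_components(dyn, j, q)
    flows[j, ] <- x %*% cc$E
    x_new <- as.numeric(x %*% cc$P)
    if (abs(sum(x_new) - 1) > 1e-9) {
      rlang::abort("Mass conservation violated in the cohort engine.")
    }
    for (st in ss) {
      i <- match(st, s)
      stay <- cc$P[i, i]
      inflow <- x_new[i] - x[i] * stay
      start <- tenure[st, ]
      pos <- seq_len(n_cycles) # schedule position = tenure + 1
      occ_at <- start[pos] * (1 + stay) / 2
      occ_at[1] <- occ_at[1] + inflow / 2 # half-cycle presence of entrants
      sched_occ[[st]][j, ] <- occ_at
      tenure[st, ] <- c(inflow, start[pos] * stay)
    }
    x <- x_new
    occ[j + 1, ] <- x
  }
  structure(
    list(
      occupancy = occ, flows = flows, sched_occ = sched_occ,
      init_events = init_events %||% stats::setNames(numeric(length(event_names())), event_names()),
      params = params
    ),
    class = "cohort_trace"
  )
}

schedule_states <- function() c("lr", "hr_bcg", "hr_cyst", "mibc")

#' @export
print.cohort_trace <- function(x, ...) {
  nc <- nrow(x$flows)
  cat("<cohort_trace> ", nc, " six-month cycles, ", ncol(x$occupancy), " states\n", sep = "")
  alive <- 1 - rowSums(x$occupancy[, c("dead_bc", "dead_oc")])
  cat(sprintf("  alive at horizon: %.4f\n", alive[nc + 1]))
  invisible(x)
}

#' Tidy a cohort trace
#'
#' @param x A `cohort_trace`.
#' @param ... Unused.
#' @return Long tibble: `cycle`, `state`, `occupancy`.
#' @export
tidy.cohort_trace <- function(x, ...) {
  occ <- tibble::as_tibble(x$occupancy)
  occ$cycle <- as.integer(rownames(x$occupancy))
  tidyr::pivot_longer(occ, -"cycle", names_to = "state", values_to = "occupancy")
}

# Per-state standing utilities (per year of occupancy).
state_utilities <- function(p) {
  u_pc <- p$u_post_cystectomy * (p$p_impotence * p$u_impotence + (1 - p$p_impotence))
  u_met <- p$p_chemo_response * p$u_met_responsive +
    (1 - p$p_chemo_response) * p$u_met_unresponsive
  c(well = p$u_well, lr = p$u_cancer, hr_bcg = p$u_cancer,
    hr_cyst = u_pc, mibc = u_pc, met = u_met,
    u_lr = p$u_cancer, u_hr_bcg = p$u_cancer,
    u_hr_cyst = p$u_cancer, u_mibc = p$u_cancer,
    # untreated metastatic disease receives no chemotherapy, so it takes
    # the unresponsive-disease utility
    u_met = p$u_met_unresponsive, dead_bc = 0, dead_oc = 0)
}

# Per-event one-off costs and QALY decrements.
event_values <- function(p) {
  list(
    cost = c(
      turbt = p$cost_turbt,
      cystectomy = p$cost_cystectomy,
      cyst_survivor = 0,
      bcg_entry = 0,
      chemo_course = p$chemo_vials_per_course * p$cost_cisplatin_vial,
      met_entry = p$cost_palliative_day *
        (if (isTRUE(p$charge_palliative_per_day)) p$palliative_days else 1),
      detection = 0, recurrence = 0
    ),
    dec = c(
      turbt = p$dec_turbt * p$dur_turbt_days / 365.25,
      cystectomy = 0,
      cyst_survivor = (1 - p$u_cystectomy_periop) * p$dur_cystectomy_days / 365.25 +
        p$p_cyst_complication * p$dec_cyst_complication * p$dur_cystectomy_days / 365.25,
      bcg_entry = p$dec_bcg_induction * p$dur_bcg_induction_days / 365.25 +
        p$p_bcg_complication * p$dec_bcg_complication * p$cycle_years,
      chemo_course = p$dec_chemo * p$dur_chemo_days / 365.25,
      met_entry = 0, detection = 0, recurrence = 0
    )
  )
}

# Per-schedule-position costs and disutilities for the schedule-bearing
# states (position 1 = first cycle after entering the state).
schedule_values <- function(p, n_cycles) {
  sch <- p$schedules
  scope_loss <- (1 - p$u_cystoscopy_factor) * p$cycle_years
  k <- seq_len(n_cycles)
  list(
    cost = list(
      lr = sch$scopes_lr[k] * p$cost_cystoscopy,
      hr_bcg = sch$scopes_hr_bcg[k] * p$cost_cystoscopy +
        sch$bcg_vials[k] * p$cost_bcg_vial + sch$ct_hr_bcg[k] * p$cost_ct,
      hr_cyst = sch$ct_cyst[k] * p$cost_ct,
      mibc = sch$ct_cyst[k] * p$cost_ct
    ),
    dis = list(
      lr = sch$scopes_lr[k] * scope_loss,
      hr_bcg = sch$scopes_hr_bcg[k] * scope_loss,
      hr_cyst = rep(0, n_cycles),
      mibc = rep(0, n_cycles)
    )
  )
}

# Per-cycle costs and disutilities attached to plain occupancy:
# metastatic disease, where responsive patients receive a chemotherapy
# course (3 cisplatin cycles) every six months.
surveillance_matrices <- function(p, n_cycles) {
  s <- model_states()
  cost <- matrix(0, n_cycles, length(s), dimnames = list(NULL, s))
  dis <- matrix(0, n_cycles, length(s), dimnames = list(NULL, s))
  cost[, "met"] <- p$p_chemo_response * p$chemo_vials_per_course * p$cost_cisplatin_vial
  dis[, "met"] <- p$p_chemo_response * p$dec_chemo * p$dur_chemo_days / 365.25
  list(cost = cost, dis = dis)
}

#' Accumulate discounted costs, QALYs and life years over a trace
#'
#' Per-cycle state rewards use half-cycle-corrected occupancy (the mean
#' of the start- and end-of-cycle vectors) and are discounted at the
#' cycle midpoint; event flows are discounted at the same midpoint.
#' Time-zero entry bundles attached to the trace are undiscounted.
#'
#' @param trace A [run_cohort()] result.
#' @param params A `bc_params` object (defaults to the trace's).
#' @param discount_rate Annual discount rate (default from `params`).
#' @param half_cycle Apply half-cycle correction (default `TRUE`).
#' @return One-row tibble: `cost`, `qalys`, `life_years`.
#' @export
accumulate_rewards <- function(trace, params = trace$params,
                               discount_rate = params$discount_rate,
                               half_cycle = TRUE) {
  p <- params
  occ <- trace$occupancy
  n_cycles <- nrow(trace$flows)
  u <- state_utilities(p)
  ev <- event_values(p)
  surv <- surveillance_matrices(p, n_cycles)
  alive <- !model_states() %in% c("dead_bc", "dead_oc")
  h <- if (half_cycle) (occ[1:n_cycles, , drop = FALSE] + occ[2:(n_cycles + 1), , drop = FALSE]) / 2
       else occ[1:n_cycles, , drop = FALSE]
  df <- (1 + discount_rate)^(-(seq_len(n_cycles) - 0.5) * p$cycle_years)
  sv <- schedule_values(p, n_cycles)
  sched_cost <- sched_dis <- numeric(n_cycles)
  for (st in schedule_states()) {
    sched_cost <- sched_cost + trace$sched_occ[[st]] %*% sv$cost[[st]]
    sched_dis <- sched_dis + trace$sched_occ[[st]] %*% sv$dis[[st]]
  }
  qaly_cycles <- p$cycle_years * (h %*% u) - rowSums(h * surv$dis) -
    sched_dis - trace$flows %*% ev$dec
  cost_cycles <- rowSums(h * surv$cost) + sched_cost + trace$flows %*% ev$cost
  ly_cycles <- p$cycle_years * rowSums(h[, alive, drop = FALSE])
  e0 <- trace$init_events
  tibble::tibble(
    cost = sum(df * cost_cycles) + sum(e0 * ev$cost),
    qalys = sum(df * qaly_cycles) - sum(e0 * ev$dec),
    life_years = sum(df * ly_cycles)
  )
}
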