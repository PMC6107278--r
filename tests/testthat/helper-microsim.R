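# Independent per-patient microsimulation oracle for the cohort engine.
#
# Simulates individual patients through the same generative story the
# cohort model integrates analytically: decision-tree classification,
# time-zero treatment bundles, then six-month cycles of recurrence,
# progression, delayed detection, disease-specific and all-cause death.
# Accounting conventions mirror the engine (half-cycle-corrected state
# rewards, mid-cycle discounting, entry-clocked schedules) so that the
# microsimulation mean is an unbiased estimate of the cohort result.
# Everything here is written against the model's parameter values, not
# its code paths.

microsim_strategy <- function(strategy, params, life_table, n_patients, seed) {
  set.seed(seed)
  p <- params
  st_names <- c("well", "lr", "hr_bcg", "hr_cyst", "mibc", "met",
                "u_lr", "u_hr_bcg", "u_hr_cyst", "u_mibc", "u_met",
                "dead_bc", "dead_oc")
  code <- function(nm) match(nm, st_names)
  splits <- c(p$split_lr, p$split_hr_bcg, p$split_hr_cyst, p$split_mibc, p$split_met)
  u_pc <- p$u_post_cystectomy * (p$p_impotence * p$u_impotence + (1 - p$p_impotence))
  u_met_mix <- p$p_chemo_response * p$u_met_responsive +
    (1 - p$p_chemo_response) * p$u_met_unresponsive
  util <- c(p$u_well, p$u_cancer, p$u_cancer, u_pc, u_pc, u_met_mix,
            rep(p$u_cancer, 4), p$u_met_unresponsive, 0, 0)
  dec_turbt <- p$dec_turbt * p$dur_turbt_days / 365.25
  dec_cyst <- (1 - p$u_cystectomy_periop) * p$dur_cystectomy_days / 365.25 +
    p$p_cyst_complication * p$dec_cyst_complication * p$dur_cystectomy_days / 365.25
  dec_bcg <- p$dec_bcg_induction * p$dur_bcg_induction_days / 365.25 +
    p$p_bcg_complication * p$dec_bcg_complication * p$cycle_years
  dec_chemo <- p$dec_chemo * p$dur_chemo_days / 365.25
  cost_chemo <- p$chemo_vials_per_course * p$cost_cisplatin_vial
  cost_pall <- p$cost_palliative_day *
    (if (isTRUE(p$charge_palliative_per_day)) p$palliative_days else 1)
  scope_loss <- (1 - p$u_cystoscopy_factor) * p$cycle_years
  n_cycles <- round(p$horizon_years / p$cycle_years)
  sch <- p$schedules
  sched_cost <- list(
    lr = sch$scopes_lr * p$cost_cystoscopy,
    hr_bcg = sch$scopes_hr_bcg * p$cost_cystoscopy +
      sch$bcg_vials * p$cost_bcg_vial + sch$ct_hr_bcg * p$cost_ct,
    hr_cyst = sch$ct_cyst * p$cost_ct,
    mibc = sch$ct_cyst * p$cost_ct
  )
  sched_dis <- list(
    lr = sch$scopes_lr * scope_loss,
    hr_bcg = sch$scopes_hr_bcg * scope_loss,
    hr_cyst = rep(0, n_cycles), mibc = rep(0, n_cycles)
  )
  sched_codes <- vapply(names(sched_cost), code, 1L)

  cost <- numeric(n_patients)
  qaly <- numeric(n_patients)
  ly <- numeric(n_patients)

  # --- decision tree -------------------------------------------------
  diseased <- stats::runif(n_patients) < p$prevalence
  pos_c <- stats::runif(n_patients) <
    ifelse(diseased, p$sens_cysto, 1 - p$spec_cysto)
  if (strategy == "cystoscopy_only") {
    scoped <- rep(TRUE, n_patients)
    positive <- pos_c
    cost <- cost + p$cost_cystoscopy
  } else {
    pos_d <- stats::runif(n_patients) <
      ifelse(diseased, p$sens_dcrshp, 1 - p$spec_dcrshp)
    scoped <- pos_d
    positive <- pos_d & pos_c
    cost <- cost + p$price_dcrshp + scoped * p$cost_cystoscopy
  }
  qaly <- qaly - scoped * scope_loss
  tp <- diseased & positive
  fp <- !diseased & positive
  fn <- diseased & !positive
  cost <- cost + (tp | fp) * p$cost_turbt
  qaly <- qaly - (tp | fp) * dec_turbt

  stage <- integer(n_patients)
  stage[diseased] <- sample.int(5, sum(diseased), replace = TRUE, prob = splits)
  state <- rep(code("well"), n_patients)
  state[tp] <- c(code("lr"), code("hr_bcg"), code("hr_cyst"), code("mibc"),
                 code("met"))[stage[tp]]
  state[fn] <- c(code("u_lr"), code("u_hr_bcg"), code("u_hr_cyst"),
                 code("u_mibc"), code("u_met"))[stage[fn]]

  # time-zero treatment bundles (undiscounted)
  is_bcg0 <- tp & stage == 2
  qaly <- qaly - is_bcg0 * dec_bcg
  needs_cyst0 <- tp & stage %in% c(3, 4)
  cost <- cost + needs_cyst0 * p$cost_cystectomy
  died_cyst0 <- needs_cyst0 & stats::runif(n_patients) < p$mort_cystectomy
  surv_cyst0 <- needs_cyst0 & !died_cyst0
  qaly <- qaly - surv_cyst0 * dec_cyst
  is_mibc0 <- surv_cyst0 & stage == 4
  cost <- cost + is_mibc0 * cost_chemo
  qaly <- qaly - is_mibc0 * dec_chemo
  is_met0 <- tp & stage == 5
  cost <- cost + is_met0 * cost_pall
  state[died_cyst0] <- code("dead_oc")

  tenure <- integer(n_patients) # cycles since entering the current state

  per1 <- 1 - sqrt(1 - p$fn_detect_year1)
  per2 <- 1 - sqrt((1 - p$fn_detect_year2) / (1 - p$fn_detect_year1))
  counterpart <- stats::setNames(
    c(code("lr"), code("hr_bcg"), code("hr_cyst"), code("mibc"), code("met")),
    c("u_lr", "u_hr_bcg", "u_hr_cyst", "u_mibc", "u_met")
  )

  for (j in seq_len(n_cycles)) {
    df <- (1 + p$discount_rate)^(-(j - 0.5) * p$cycle_years)
    q <- life_table_qx(life_table, p$start_age + (j - 1) * p$cycle_years)
    d <- if (j <= 2) per1 else if (j <= 4) per2 else 1
    start_state <- state
    start_tenure <- tenure
    alive <- !start_state %in% c(code("dead_bc"), code("dead_oc"))
    new_state <- state
    moved <- rep(FALSE, n_patients)
    ev_cost <- numeric(n_patients)
    ev_dec <- numeric(n_patients)

    do_turbt <- function(idx) {
      ev_cost[idx] <<- ev_cost[idx] + p$cost_turbt
      ev_dec[idx] <<- ev_dec[idx] + dec_turbt
      idx[stats::runif(length(idx)) < p$mort_turbt] # those who die
    }
    do_cystectomy <- function(idx) {
      ev_cost[idx] <<- ev_cost[idx] + p$cost_cystectomy
      dead <- idx[stats::runif(length(idx)) < p$mort_cystectomy]
      surv <- setdiff(idx, dead)
      ev_dec[surv] <<- ev_dec[surv] + dec_cyst
      list(dead = dead, surv = surv)
    }

    # diagnosed NMIBC states: recurrence / progression / cancer death
    for (st in c("lr", "hr_bcg")) {
      idx <- which(start_state == code(st))
      if (!length(idx)) next
      r <- if (st == "lr") p$recur_lr else p$recur_hr_bcg
      probs <- if (st == "hr_bcg") {
        c(r, p$mort_bc_remission, p$prog_hr_bcg_mibc, p$prog_hr_bcg_met)
      } else {
        c(r, p$mort_bc_remission, 0, 0)
      }
      u <- stats::runif(length(idx))
      cum <- cumsum(probs)
      recur <- idx[u < cum[1]]
      bcdead <- idx[u >= cum[1] & u < cum[2]]
      tomibc <- idx[u >= cum[2] & u < cum[3]]
      tomet <- idx[u >= cum[3] & u < cum[4]]
      new_state[bcdead] <- code("dead_bc"); moved[bcdead] <- TRUE
      if (length(recur)) {
        dead <- do_turbt(recur)
        new_state[dead] <- code("dead_oc"); moved[dead] <- TRUE
        surv <- setdiff(recur, dead)
        conv <- surv[stats::runif(length(surv)) < p$prop_recur_cystectomy]
        if (length(conv)) {
          res <- do_cystectomy(conv)
          new_state[res$dead] <- code("dead_oc"); moved[res$dead] <- TRUE
          new_state[res$surv] <- code("hr_cyst"); moved[res$surv] <- TRUE
        }
      }
      if (length(tomibc)) {
        dead <- do_turbt(tomibc)
        new_state[dead] <- code("dead_oc"); moved[dead] <- TRUE
        surv <- setdiff(tomibc, dead)
        res <- do_cystectomy(surv)
        new_state[res$dead] <- code("dead_oc"); moved[res$dead] <- TRUE
        ev_cost[res$surv] <- ev_cost[res$surv] + cost_chemo
        ev_dec[res$surv] <- ev_dec[res$surv] + dec_chemo
        new_state[res$surv] <- code("mibc"); moved[res$surv] <- TRUE
      }
      if (length(tomet)) {
        dead <- do_turbt(tomet)
        new_state[dead] <- code("dead_oc"); moved[dead] <- TRUE
        surv <- setdiff(tomet, dead)
        ev_cost[surv] <- ev_cost[surv] + cost_pall
        new_state[surv] <- code("met"); moved[surv] <- TRUE
      }
    }

    # post-cystectomy and metastatic states
    for (st in c("hr_cyst", "mibc", "met")) {
      idx <- which(start_state == code(st))
      if (!length(idx)) next
      pr_met <- switch(st, hr_cyst = p$prog_hr_cyst_met,
                       mibc = p$prog_mibc_met_early, met = 0)
      pr_dead <- switch(st, hr_cyst = p$mort_bc_remission,
                        mibc = p$mort_bc_mibc_early, met = p$mort_bc_met)
      u <- stats::runif(length(idx))
      tomet <- idx[u < pr_met]
      bcdead <- idx[u >= pr_met & u < pr_met + pr_dead]
      new_state[bcdead] <- code("dead_bc"); moved[bcdead] <- TRUE
      ev_cost[tomet] <- ev_cost[tomet] + cost_pall
      new_state[tomet] <- code("met"); moved[tomet] <- TRUE
    }

    # undiagnosed mirrors: detection first, then untreated dynamics
    rr <- p$rr_untreated
    for (st in names(counterpart)) {
      idx <- which(start_state == code(st))
      if (!length(idx)) next
      det <- idx[stats::runif(length(idx)) < d]
      und <- setdiff(idx, det)
      if (length(det)) {
        dead <- do_turbt(det)
        new_state[dead] <- code("dead_oc"); moved[dead] <- TRUE
        surv <- setdiff(det, dead)
        if (st %in% c("u_hr_cyst", "u_mibc") && length(surv)) {
          res <- do_cystectomy(surv)
          new_state[res$dead] <- code("dead_oc"); moved[res$dead] <- TRUE
          surv <- res$surv
          if (st == "u_mibc") {
            ev_cost[surv] <- ev_cost[surv] + cost_chemo
            ev_dec[surv] <- ev_dec[surv] + dec_chemo
          }
        }
        if (st == "u_hr_bcg") ev_dec[surv] <- ev_dec[surv] + dec_bcg
        if (st == "u_met") ev_cost[surv] <- ev_cost[surv] + cost_pall
        new_state[surv] <- counterpart[st]; moved[surv] <- TRUE
      }
      if (length(und)) {
        pr_mibc <- if (st == "u_hr_bcg") min(1, rr * p$prog_hr_bcg_mibc) else 0
        pr_met <- switch(st,
          u_hr_bcg = min(1, rr * p$prog_hr_bcg_met),
          u_hr_cyst = min(1, rr * p$prog_hr_cyst_met),
          u_mibc = min(1, rr * p$prog_mibc_met_early), 0)
        pr_dead <- switch(st,
          u_mibc = min(1, rr * p$mort_bc_mibc_early),
          u_met = min(1, rr * p$mort_bc_met),
          min(1, rr * p$mort_bc_remission))
        u <- stats::runif(length(und))
        tomibc <- und[u < pr_mibc]
        tomet <- und[u >= pr_mibc & u < pr_mibc + pr_met]
        bcdead <- und[u >= pr_mibc + pr_met & u < pr_mibc + pr_met + pr_dead]
        new_state[tomibc] <- code("u_mibc"); moved[tomibc] <- TRUE
        new_state[tomet] <- code("u_met"); moved[tomet] <- TRUE
        new_state[bcdead] <- code("dead_bc"); moved[bcdead] <- TRUE
      }
    }

    # all-cause mortality on those remaining in-state
    stayers <- which(alive & !moved)
    oc <- stayers[stats::runif(length(stayers)) < q]
    new_state[oc] <- code("dead_oc")

    # rewards: half-cycle corrected state occupancy, mid-cycle discounting
    end_alive <- !new_state %in% c(code("dead_bc"), code("dead_oc"))
    occ_w <- (alive + (alive & end_alive)) / 2
    u_half <- (util[start_state] * alive + util[new_state] * (alive & end_alive)) / 2
    qaly <- qaly + df * (p$cycle_years * u_half - ev_dec)
    ly <- ly + df * p$cycle_years * occ_w
    cost <- cost + df * ev_cost
    # metastatic chemotherapy stream on half-cycle occupancy
    met_w <- ((start_state == code("met")) * alive +
              (new_state == code("met")) * (alive & end_alive)) / 2
    cost <- cost + df * met_w * p$p_chemo_response * cost_chemo
    qaly <- qaly - df * met_w * p$p_chemo_response * dec_chemo
    # entry-clocked surveillance schedules
    for (snm in names(sched_codes)) {
      sc <- sched_codes[[snm]]
      started <- alive & start_state == sc
      stayed <- started & new_state == sc
      pos <- pmin(start_tenure + 1L, n_cycles)
      w <- (started + stayed) / 2
      entered <- (new_state == sc) & !started & end_alive
      cost <- cost + df * (w * sched_cost[[snm]][pos] + 0.5 * entered * sched_cost[[snm]][1])
      qaly <- qaly - df * (w * sched_dis[[snm]][pos] + 0.5 * entered * sched_dis[[snm]][1])
    }

    tenure <- ifelse(new_state == start_state, tenure + 1L, 0L)
    state <- new_state
  }

  list(
    cost = mean(cost), qalys = mean(qaly), life_years = mean(ly),
    se_cost = stats::sd(cost) / sqrt(n_patients),
    se_qalys = stats::sd(qaly) / sqrt(n_patients),
    se_ly = stats::sd(ly) / sqrt(n_patients)
  )
}
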