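test_that("detection schedule reproduces the cumulative 50/75/100% milestones", {
  p <- base_params()
  d <- detection_schedule(1:6, p)
  expect_equal(prod(1 - d[1:2]), 0.5)
  expect_equal(1 - prod(1 - d[1:4]), 0.75)
  expect_equal(d[5], 1)
  expect_equal(d[1], 1 - sqrt(0.5))
  expect_error(detection_schedule(0, p), "cycle 0")
})

test_that("transition rows are probability vectors at every cycle", {
  p <- base_params()
  lt <- base_life_table()
  for (cycle in 1:10) {
    P <- build_transition_matrix(p, cycle, lt)
    expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-10)
    expect_true(all(P >= 0 & P <= 1))
  }
  P <- build_transition_matrix(p, 1, lt)
  expect_equal(P["dead_bc", "dead_bc"], 1)
  expect_equal(P["dead_oc", "dead_oc"], 1)
  # untreated progression inflated by the relative risk before the
  # detection and all-cause adjustments
  d <- detection_schedule(1, p)
  expect_equal(P["u_hr_bcg", "u_mibc"] / (1 - d), min(1, 2.56 * 0.030))
  # inconsistent parameters are named, not silently rescaled
  bad <- bc_parameters(list(prog_hr_bcg_mibc = 0.6, prog_hr_bcg_met = 0.5))
  expect_error(build_transition_matrix(bad, 1, lt), "hr_bcg")
})

test_that("null dynamics leave the cohort in place except detection flows", {
  p <- null_dynamics_params()
  lt <- null_life_table()
  P <- build_transition_matrix(p, 1, lt)
  for (st in c("well", "lr", "hr_bcg", "hr_cyst", "mibc", "met")) {
    expect_equal(P[st, st], 1)
  }
  d <- detection_schedule(1, p)
  expect_equal(P["u_lr", "u_lr"], 1 - d)
  expect_equal(P["u_lr", "lr"], d)
  # an all-well cohort with no mortality never moves
  init <- stats::setNames(numeric(13), model_states())
  init["well"] <- 1
  tr <- run_cohort(init, p, lt)
  expect_equal(unname(tr$occupancy[11, "well"]), 1)
})

test_that("initial occupancy maps the decision tree into the state space", {
  p <- base_params()
  # a pure true-positive cohort lands on the diagnosis split, less
  # time-zero cystectomy mortality in the cystectomy groups
  sp <- tibble::tibble(strategy = "cystoscopy_only", tp = 1, fp = 0, tn = 0,
                       fn = 0, p_dcrshp_positive = 1, prevalence = 1)
  x <- initial_distribution(sp, p)
  expect_equal(sum(x), 1)
  expect_equal(unname(x["lr"]), 105 / 192)
  expect_equal(unname(x["hr_cyst"]), 13 / 192 * (1 - 96 / 4484))
  expect_equal(unname(x["dead_oc"]), (13 + 14) / 192 * 96 / 4484)
  # disease-free cohort with a perfect test starts well
  pp <- bc_parameters(list(spec_cysto = 1))
  sp0 <- classify_cohort(0, "cystoscopy_only", pp)
  x0 <- initial_distribution(sp0, pp)
  expect_equal(unname(x0["well"]), 1)
  # false negatives mirror the diagnosis split
  spf <- tibble::tibble(strategy = "dcrshp_triage", tp = 0, fp = 0, tn = 0.5,
                        fn = 0.5, p_dcrshp_positive = 0, prevalence = 0.5)
  xf <- initial_distribution(spf, p)
  expect_equal(unname(xf["u_lr"]), 0.5 * 105 / 192)
})

test_that("mass is conserved and death states are absorbing along the trace", {
  p <- base_params()
  sp <- classify_cohort(p$prevalence, "cystoscopy_only", p)
  tr <- run_cohort(initial_distribution(sp, p), p, base_life_table())
  expect_equal(unname(rowSums(tr$occupancy)), rep(1, 11), tolerance = 1e-9)
  dead <- tr$occupancy[, "dead_bc"] + tr$occupancy[, "dead_oc"]
  expect_true(all(diff(dead) >= 0))
  expect_true(all(diff(tr$occupancy[, "dead_bc"]) >= 0))
  # undiagnosed states are emptied once detection is certain (cycle 5 on)
  undiag <- rowSums(tr$occupancy[, c("u_lr", "u_hr_bcg", "u_hr_cyst",
                                     "u_mibc", "u_met")])
  expect_equal(unname(undiag[7:11]), rep(0, 5))
  # with no false negatives the undiagnosed track never fills
  sp2 <- tibble::tibble(strategy = "cystoscopy_only", tp = 0.2, fp = 0.1,
                        tn = 0.7, fn = 0, p_dcrshp_positive = 1, prevalence = 0.2)
  tr2 <- run_cohort(initial_distribution(sp2, p), p, base_life_table())
  expect_equal(max(tr2$occupancy[, c("u_lr", "u_hr_bcg", "u_hr_cyst",
                                     "u_mibc", "u_met")]), 0)
})

test_that("detection halves the undiagnosed mass by the end of year one", {
  p <- null_dynamics_params()
  init <- stats::setNames(numeric(13), model_states())
  init["u_lr"] <- 0.4
  init["well"] <- 0.6
  tr <- run_cohort(init, p, null_life_table())
  expect_equal(unname(tr$occupancy[3, "u_lr"]), 0.4 * 0.5)
  expect_equal(unname(tr$occupancy[3, "lr"]), 0.4 * 0.5)
})

test_that("rewards reduce to closed forms in degenerate settings", {
  # full health, no deaths, no discounting: 5 life years and 5 QALYs
  p <- bc_parameters(list(discount_rate = 0))
  init <- stats::setNames(numeric(13), model_states())
  init["well"] <- 1
  tr <- run_cohort(init, p, null_life_table())
  r <- accumulate_rewards(tr, p)
  expect_equal(r$life_years, 5)
  expect_equal(r$qalys, 5)
  expect_equal(r$cost, 0)
  # discounting at 3.5%: the mid-cycle annuity, matched to 1e-10
  p2 <- base_params()
  tr2 <- run_cohort(init, p2, null_life_table())
  r2 <- accumulate_rewards(tr2, p2)
  annuity <- sum(0.5 * 1.035^(-((1:10) - 0.5) / 2))
  expect_equal(r2$life_years, annuity, tolerance = 1e-10)
  # one TURBT across the whole cohort costs its 7-day decrement
  ev <- stats::setNames(numeric(8), c("turbt", "cystectomy", "cyst_survivor",
                                      "bcg_entry", "chemo_course", "met_entry",
                                      "detection", "recurrence"))
  ev["turbt"] <- 1
  tr3 <- run_cohort(init, p, null_life_table(), init_events = ev)
  r3 <- accumulate_rewards(tr3, p)
  expect_equal(r$qalys - r3$qalys, 0.1 * 7 / 365.25)
  expect_equal(r3$cost, 2435)
})

test_that("with unit relative risk the undiagnosed track mirrors the diagnosed one", {
  # detection suppressed over the first two years (it forces a move at
  # cycle 5 regardless) and recurrence/procedure mortality off, so the
  # two tracks share identical dynamics while undetected
  p <- bc_parameters(list(rr_untreated = 1, recur_lr = 0, recur_hr_bcg = 0,
                          mort_turbt = 0, mort_cystectomy = 0,
                          fn_detect_year1 = 0, fn_detect_year2 = 0))
  lt <- base_life_table()
  init_d <- stats::setNames(numeric(13), model_states())
  init_d[c("lr", "hr_bcg", "hr_cyst", "mibc", "met")] <- c(105, 47, 13, 14, 13) / 192
  init_u <- stats::setNames(numeric(13), model_states())
  init_u[c("u_lr", "u_hr_bcg", "u_hr_cyst", "u_mibc", "u_met")] <- c(105, 47, 13, 14, 13) / 192
  tr_d <- run_cohort(init_d, p, lt)
  tr_u <- run_cohort(init_u, p, lt)
  pairs <- list(c("lr", "u_lr"), c("hr_bcg", "u_hr_bcg"),
                c("hr_cyst", "u_hr_cyst"), c("mibc", "u_mibc"), c("met", "u_met"))
  for (pr in pairs) {
    expect_equal(unname(tr_u$occupancy[1:5, pr[2]]),
                 unname(tr_d$occupancy[1:5, pr[1]]), tolerance = 1e-12)
  }
  expect_equal(unname(tr_u$occupancy[1:5, "dead_bc"]),
               unname(tr_d$occupancy[1:5, "dead_bc"]), tolerance = 1e-12)
})

test_that("discounted QALYs never exceed undiscounted QALYs or life years", {
  set.seed(77)
  lt <- base_life_table()
  for (i in 1:10) {
    p <- sample_parameter_set(base_params())
    sp <- classify_cohort(p$prevalence, sample(strategies(), 1), p)
    tr <- run_cohort(initial_distribution(sp, p), p, lt,
                     init_events = triagecea:::initial_events(sp, p))
    disc <- accumulate_rewards(tr, p)
    undisc <- accumulate_rewards(tr, p, discount_rate = 0)
    expect_lte(disc$qalys, undisc$qalys + 1e-12)
    expect_lte(undisc$qalys, undisc$life_years + 1e-12)
    expect_lte(undisc$life_years, p$horizon_years + 1e-12)
  }
})

test_that("a cohort trace tidies into long cycle-state occupancy", {
  p <- base_params()
  sp <- classify_cohort(p$prevalence, "cystoscopy_only", p)
  tr <- run_cohort(initial_distribution(sp, p), p, base_life_table())
  tidied <- tidy(tr)
  expect_equal(nrow(tidied), 11 * 13)
  expect_equal(sort(unique(tidied$state)), sort(model_states()))
  expect_equal(sum(tidied$occupancy[tidied$cycle == 0]), 1, tolerance = 1e-12)
})
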