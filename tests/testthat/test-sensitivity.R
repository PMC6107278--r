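test_that("closed-form threshold price matches the bisection root", {
  p <- base_params()
  lt <- base_life_table()
  cf <- threshold_price(p, 20000, life_table = lt)
  bi <- threshold_price(p, 20000, method = "bisection", tol = 0.005, life_table = lt)
  expect_lt(abs(cf - bi), 0.01)
  # and on perturbed parameter sets
  set.seed(13)
  for (i in 1:5) {
    pp <- sample_parameter_set(p)
    cf <- threshold_price(pp, 20000, life_table = lt)
    if (cf > 0) {
      bi <- threshold_price(pp, 20000, method = "bisection", tol = 0.005, life_table = lt)
      expect_lt(abs(cf - bi), 0.01)
    }
  }
  # a triage arm that can never break even is flagged, not extrapolated:
  # poor triage sensitivity at a very high WTP makes the QALYs forgone
  # by missed cancers outweigh any testing-cost saving
  hopeless <- bc_parameters(list(sens_dcrshp = 0.5, spec_dcrshp = 0.5))
  thr <- threshold_price(hopeless, 5e5, life_table = lt)
  expect_equal(as.numeric(thr), 0)
  expect_true(isTRUE(attr(thr, "not_cost_effective")))
})

test_that("incremental QALYs fall with prevalence and cross zero once", {
  sw <- prevalence_sweep(base_params(), grid = seq(0, 0.2, by = 0.01),
                         life_table = base_life_table())
  expect_gt(sw$delta_qalys[sw$prevalence == 0], 0)
  expect_true(all(diff(sw$delta_qalys) < 0))
  cross <- attr(sw, "crossover")
  expect_true(is.finite(cross))
  expect_gt(cross, 0)
  expect_lt(cross, 0.2)
  # interpolation helper finds the bracketed root
  expect_equal(triagecea:::interpolate_zero(c(0, 1), c(1, -1)), 0.5)
})

test_that("the two-way frontier is consistent with the threshold price", {
  p <- base_params()
  lt <- base_life_table()
  tw <- two_way_price_prevalence(p, prevalence_grid = c(0.05, p$prevalence, 0.14),
                                 life_table = lt)
  thr <- threshold_price(p, 20000, life_table = lt)
  expect_equal(tw$max_price[2], as.numeric(thr), tolerance = 1e-8)
  expect_true(all(tw$max_price >= 0))
  expect_true(is.logical(tw$effective))
})

test_that("a kinder cystoscopy shrinks the triage advantage monotonically", {
  sw <- cysto_disutility_sweep(base_params(), grid = seq(0.95, 1, by = 0.005),
                               life_table = base_life_table())
  expect_equal(nrow(sw), 11)
  expect_true(all(diff(sw$delta_qalys) < 0))
  base_row <- cysto_disutility_sweep(base_params(), grid = 0.997,
                                     life_table = base_life_table())
  res <- evaluate_strategies(base_params(), base_life_table())
  expect_equal(base_row$delta_qalys, res$qalys[2] - res$qalys[1])
})

test_that("PSA runs are seed-reproducible and degenerate to the base case", {
  p <- base_params()
  lt <- base_life_table()
  a <- run_psa(p, n = 25, seed = 9, life_table = lt)
  b <- run_psa(p, n = 25, seed = 9, life_table = lt)
  expect_identical(a$outcomes, b$outcomes)
  expect_identical(a$draws, b$draws)
  # all-fixed specs with a fixed price reproduce the deterministic result
  fixed_specs <- list(prevalence = dist_fixed(p$prevalence))
  one <- run_psa(p, n = 1, seed = 1, specs = fixed_specs,
                 price_spec = p$price_dcrshp, life_table = lt)
  expect_equal(one$outcomes[, c("cost", "qalys", "life_years")],
               evaluate_strategies(p, lt)[, c("cost", "qalys", "life_years")])
})

test_that("sampled PSA inputs keep their Beta means through the pipeline", {
  ps <- shared_psa()
  specs <- psa_distributions(base_params())
  for (nm in c("sens_dcrshp", "spec_dcrshp")) {
    se <- stats::sd(ps$draws[[nm]]) / sqrt(ps$n)
    expect_lt(abs(mean(ps$draws[[nm]]) - dist_mean(specs[[nm]])), 3 * se)
  }
  expect_false(anyNA(ps$outcomes))
})

test_that("CEAC probabilities are complementary and hit their limits", {
  # a single-draw sample yields a step curve of 0/1 values
  one <- synthetic_sample(nb_cysto = 5, nb_triage = 7)
  cv <- ceac(one, wtp_grid = c(0, 1))
  expect_true(all(cv$probability %in% c(0, 1)))
  # known synthetic fractions at the WTP extremes
  set.seed(21)
  n <- 400
  dc <- stats::rnorm(n) # delta cost (triage - cysto)
  dq <- stats::rnorm(n) # delta qalys
  smp <- synthetic_sample(nb_cysto = rep(0, n), nb_triage = -dc)
  smp$outcomes$qalys[smp$outcomes$strategy == "dcrshp_triage"] <- dq
  smp$outcomes$cost[smp$outcomes$strategy == "dcrshp_triage"] <- dc
  smp$outcomes$qalys[smp$outcomes$strategy == "cystoscopy_only"] <- 0
  smp$outcomes$cost[smp$outcomes$strategy == "cystoscopy_only"] <- 0
  cv <- ceac(smp, wtp_grid = c(0, 1e9))
  p0 <- cv$probability[cv$wtp == 0 & cv$strategy == "dcrshp_triage"]
  expect_equal(p0, mean(dc < 0))
  pinf <- cv$probability[cv$wtp == 1e9 & cv$strategy == "dcrshp_triage"]
  expect_equal(pinf, mean(dq > 0))
  # complementarity across strategies at every grid point
  cv2 <- ceac(shared_psa(), wtp_grid = c(0, 20000, 50000))
  sums <- tapply(cv2$probability, cv2$wtp, sum)
  expect_equal(as.numeric(sums), rep(1, 3))
  expect_true(all(cv2$probability >= 0 & cv2$probability <= 1))
})
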