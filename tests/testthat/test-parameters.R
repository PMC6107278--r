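test_that("prevalence pooling equals the summed count ratio, in any order", {
  studies <- prevalence_studies()
  pooled <- aggregate_prevalence(studies)
  expect_equal(pooled, 871 / 6728)
  expect_equal(round(100 * pooled, 2), 12.95)
  expect_equal(aggregate_prevalence(studies[c(3, 1, 2), ]), pooled)
  expect_equal(round(aggregate_prevalence(studies[1, ]), 5), 0.11917)
  expect_equal(aggregate_prevalence(tibble::tibble(cases = 0, n = 100)), 0)
  expect_error(aggregate_prevalence(studies[0, ]), "non-empty")
  expect_error(aggregate_prevalence(tibble::tibble(cases = 5, n = 0)), "n > 0")
})

test_that("base-case parameter set reproduces the printed point values", {
  p <- base_params()
  expect_equal(p$prevalence, 871 / 6728)
  expect_equal(round(p$sens_cysto, 3), 0.980)
  expect_equal(round(p$spec_cysto, 3), 0.938)
  expect_equal(round(p$sens_dcrshp, 3), 0.905)
  expect_equal(round(p$spec_dcrshp, 3), 0.795)
  split <- c(p$split_lr, p$split_hr_bcg, p$split_hr_cyst, p$split_mibc, p$split_met)
  expect_equal(split, c(105, 47, 13, 14, 13) / 192)
  expect_equal(sum(split), 1)
  expect_equal(p$rr_untreated, 2.56)
  expect_equal(p$cost_cystoscopy, 537)
})

test_that("overrides replace single fields and reject unknown names", {
  p <- bc_parameters(list(price_dcrshp = 100))
  expect_equal(p$price_dcrshp, 100)
  base <- base_params()
  same <- setdiff(names(base), "price_dcrshp")
  expect_identical(unclass(p)[same], unclass(base)[same])
  p2 <- bc_parameters(list(prevalence = 0.05))
  expect_equal(classify_cohort(p2$prevalence, "cystoscopy_only", p2)$prevalence, 0.05)
  expect_error(bc_parameters(list(not_a_parameter = 1)), "Unknown parameter")
  expect_error(bc_parameters(list(prevalence = 1.5)), "probability")
  expect_error(bc_parameters(list(rr_untreated = 0.5)), "rr_untreated")
})

test_that("YAML config mirrors parameter names and ignores provenance", {
  cfg <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("price_dcrshp: 250.5", "prevalence: 0.08",
               "provenance:", "  note: read-only"), cfg)
  p <- bc_parameters(config = cfg)
  expect_equal(p$price_dcrshp, 250.5)
  expect_equal(p$prevalence, 0.08)
  # explicit overrides win over the config file
  expect_equal(bc_parameters(list(prevalence = 0.1), config = cfg)$prevalence, 0.1)
})

test_that("the parameter catalogue carries values, distributions and sources", {
  cat_tbl <- parameter_catalogue(base_params())
  expect_true(all(c("parameter", "value", "distribution", "dist_params", "source")
                  %in% names(cat_tbl)))
  expect_true(all(c("prevalence", "sens_dcrshp", "cost_turbt", "rr_untreated")
                  %in% cat_tbl$parameter))
  expect_equal(cat_tbl$distribution[cat_tbl$parameter == "cost_turbt"], "fixed")
  expect_equal(cat_tbl$distribution[cat_tbl$parameter == "sens_dcrshp"], "beta_counts")
  path <- withr::local_tempfile(fileext = ".csv")
  write_catalogue_csv(path, base_params())
  expect_equal(nrow(utils::read.csv(path)), nrow(cat_tbl))
})

test_that("PSA parameter draws are reproducible and keep the set valid", {
  base <- base_params()
  a <- sample_parameter_set(base, seed = 123)
  b <- sample_parameter_set(base, seed = 123)
  expect_identical(a, b)
  expect_true(a$rr_untreated >= 1)
  expect_equal(a$split_lr + a$split_hr_bcg + a$split_hr_cyst + a$split_mibc + a$split_met, 1)
  # all-fixed specs return the base values unchanged
  fixed <- list(prevalence = dist_fixed(base$prevalence),
                sens_dcrshp = dist_fixed(base$sens_dcrshp))
  expect_identical(sample_parameter_set(base, fixed, seed = 1), base)
})

test_that("sampled accuracies match their Beta means in the long run", {
  set.seed(5)
  draws <- draw_parameter_matrix(psa_distributions(base_params()), 1e4)
  for (nm in c("sens_dcrshp", "sens_cysto", "prevalence")) {
    se <- stats::sd(draws[, nm]) / sqrt(nrow(draws))
    target <- dist_mean(psa_distributions(base_params())[[nm]])
    expect_lt(abs(mean(draws[, nm]) - target), 3 * se)
  }
  expect_false(anyNA(draws))
})

test_that("the synthetic life table is monotone, bounded and sex-consistent", {
  lt <- make_life_table()
  expect_true(all(lt$qx > 0 & lt$qx < 1))
  expect_true(all(diff(lt$qx) >= 0))
  # plausible six-month magnitude at age 60 for a 4:1 male cohort
  expect_gt(life_table_qx(lt, 60), 0.003)
  expect_lt(life_table_qx(lt, 60), 0.006)
  m <- make_life_table(male_fraction = 1)
  f <- make_life_table(male_fraction = 0)
  mix <- make_life_table(male_fraction = 0.5)
  expect_true(all(m$qx > f$qx))
  expect_true(all(mix$qx > f$qx & mix$qx < m$qx))
  expect_equal(mix$qx, (m$qx + f$qx) / 2)
  # lookup holds beyond the final row and errors below are avoided
  expect_equal(life_table_qx(lt, 150), lt$qx[nrow(lt)])
  expect_error(make_life_table(start_age = 70, end_age = 60))
})
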