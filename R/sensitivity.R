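#' Threshold price of the triage test
#'
#' The unit price at which the incremental net monetary benefit of the
#' triage strategy over cystoscopy-only is zero at the given willingness
#' to pay. The price enters the triage arm's cost affinely with slope 1,
#' so the threshold equals the incremental NMB evaluated at price zero
#' (closed form); `method = "bisection"` solves the same root
#' numerically to `tol`.
#'
#' @param params A `bc_params` object.
#' @param wtp Willingness to pay per QALY (> 0).
#' @param method `"closed_form"` (default) or `"bisection"`.
#' @param tol Price tolerance for the bisection solver (GBP).
#' @param life_table Optional [make_life_table()] table.
#' @return The threshold price in GBP. A negative closed-form root means
#'   the triage arm is not cost-effective even free; 0 is returned with
#'   attribute `not_cost_effective = TRUE`.
#' @export
#' @examples
#' threshold_price(wtp = 20000)
threshold_price <- function(params = bc_parameters(), wtp = 20000,
                            method = c("closed_form", "bisection"), tol = 0.01,
                            life_table = make_life_table(male_fraction = params$prop_male)) {
  stopifnot(wtp > 0)
  method <- rlang::arg_match(method)
  inc_nmb_at <- function(price) {
    res <- evaluate_strategies(bc_parameters_price(params, price), life_table)
    nmb(res[2, ], wtp) - nmb(res[1, ], wtp)
  }
  root <- if (method == "closed_form") {
    inc_nmb_at(0)
  } else {
    lo <- 0
    hi <- max(1, inc_nmb_at(0)) * 2 + 100
    if (inc_nmb_at(0) <= 0) {
      lo - 1 # triage not cost-effective even free; fall through below
    } else {
      while (inc_nmb_at(hi) > 0) hi <- hi * 2
      while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        if (inc_nmb_at(mid) > 0) lo <- mid else hi <- mid
      }
      (lo + hi) / 2
    }
  }
  if (root <= 0) {
    return(structure(0, not_cost_effective = TRUE))
  }
  root
}

# Replace the triage-test price without re-validating the whole set.
bc_parameters_price <- function(params, price) {
  params$price_dcrshp <- price
  params
}

#' Prevalence sweep of incremental effectiveness
#'
#' Evaluates the full pipeline across a prevalence grid and reports
#' incremental QALYs, life years and NMB (triage minus cystoscopy) at
#' each value, plus the interpolated prevalence at which incremental
#' QALYs change sign.
#'
#' @param params A `bc_params` object.
#' @param grid Prevalence grid in `[0, 1]`.
#' @param wtp Willingness to pay for the NMB column.
#' @param life_table Optional life table.
#' @return A tibble (`prevalence`, `delta_qalys`, `delta_ly`,
#'   `delta_cost`, `delta_nmb`) with attribute `crossover`: the linearly
#'   interpolated zero of `delta_qalys` (`NA` if no sign change on the
#'   grid).
#' @export
prevalence_sweep <- function(params = bc_parameters(),
                             grid = seq(0, 0.20, by = 0.005), wtp = 20000,
                             life_table = make_life_table(male_fraction = params$prop_male)) {
  stopifnot(all(grid >= 0), all(grid <= 1))
  rows <- purrr::map_dfr(grid, function(p) {
    pp <- params
    pp$prevalence <- p
    res <- evaluate_strategies(pp, life_table)
    tibble::tibble(
      prevalence = p,
      delta_qalys = res$qalys[2] - res$qalys[1],
      delta_ly = res$life_years[2] - res$life_years[1],
      delta_cost = res$cost[2] - res$cost[1],
      delta_nmb = nmb(res[2, ], wtp) - nmb(res[1, ], wtp)
    )
  })
  attr(rows, "crossover") <- interpolate_zero(rows$prevalence, rows$delta_qalys)
  rows
}

# First linear-interpolation zero crossing of y over x.
interpolate_zero <- function(x, y) {
  sgn <- sign(y)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (!length(idx)) {
    exact <- which(y == 0)
    return(if (length(exact)) x[exact[1]] else NA_real_)
  }
  i <- idx[1]
  x[i] + (x[i + 1] - x[i]) * y[i] / (y[i] - y[i + 1])
}

#' Two-way price-by-prevalence frontier
#'
#' For each prevalence on the grid, the maximum cost-effective triage
#' price at `wtp` (closed-form threshold), flagged by whether the triage
#' strategy is also more effective there (positive incremental QALYs) or
#' cost-effective only.
#'
#' @param params A `bc_params` object.
#' @param prevalence_grid Prevalence values.
#' @param wtp Willingness to pay per QALY.
#' @param life_table Optional life table.
#' @return Tibble: `prevalence`, `max_price`, `delta_qalys`,
#'   `effective` (logical).
#' @export
two_way_price_prevalence <- function(params = bc_parameters(),
                                     prevalence_grid = seq(0, 0.14, by = 0.005),
                                     wtp = 20000,
                                     life_table = make_life_table(male_fraction = params$prop_male)) {
  stopifnot(length(prevalence_grid) > 0)
  purrr::map_dfr(prevalence_grid, function(p) {
    pp <- params
    pp$prevalence <- p
    res <- evaluate_strategies(bc_parameters_price(pp, 0), life_table)
    dq <- res$qalys[2] - res$qalys[1]
    thr <- (nmb(res[2, ], wtp) - nmb(res[1, ], wtp))
    tibble::tibble(
      prevalence = p,
      max_price = max(0, thr),
      delta_qalys = dq,
      effective = dq > 0
    )
  })
}

#' Cystoscopy-disutility sweep
#'
#' Varies the per-cystoscopy six-month utility factor across a plausible
#' range and reports incremental QALYs of the triage strategy: the less
#' harmful the cystoscopy, the smaller the triage benefit.
#'
#' @param params A `bc_params` object.
#' @param grid Utility-factor grid in `[0, 1]` (default 0.95..1).
#' @param wtp Willingness to pay per QALY for the NMB column.
#' @param life_table Optional life table.
#' @return Tibble: `u_cystoscopy_factor`, `delta_qalys`, `delta_nmb`.
#' @export
cysto_disutility_sweep <- function(params = bc_parameters(),
                                   grid = seq(0.95, 1, by = 0.005), wtp = 20000,
                                   life_table = make_life_table(male_fraction = params$prop_male)) {
  stopifnot(all(grid >= 0), all(grid <= 1))
  purrr::map_dfr(grid, function(f) {
    pp <- params
    pp$u_cystoscopy_factor <- f
    res <- evaluate_strategies(pp, life_table)
    tibble::tibble(
      u_cystoscopy_factor = f,
      delta_qalys = res$qalys[2] - res$qalys[1],
      delta_nmb = nmb(res[2, ], wtp) - nmb(res[1, ], wtp)
    )
  })
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n` joint parameter sets from the PSA distributions (the triage
#' price from `price_spec`, by default Uniform(£50, £620)), evaluates
#' both strategies per draw, and returns draws and outcomes.
#'
#' @param params Base `bc_params` object.
#' @param n Number of draws.
#' @param seed Integer seed; the same `(seed, n)` reproduces the sample.
#' @param specs PSA distribution list (default [psa_distributions()]).
#' @param price_spec A `dist_spec` for the triage price, or a single
#'   number for a fixed price. Default `dist_uniform(50, 620)`.
#' @param life_table Optional life table (held fixed across draws).
#' @return A `psa_sample`: list with `draws` (tibble of sampled
#'   parameters, one row per draw), `outcomes` (tibble: draw, strategy,
#'   cost, qalys, life_years), `n`, `seed`.
#' @export
run_psa <- function(params = bc_parameters(), n = 1000, seed = 1,
                    specs = psa_distributions(params),
                    price_spec = dist_uniform(50, 620),
                    life_table = make_life_table(male_fraction = params$prop_male)) {
  stopifnot(n >= 1)
  if (is.numeric(price_spec) && length(price_spec) == 1) {
    price_spec <- dist_fixed(price_spec)
  }
  specs$price_dcrshp <- price_spec
  set.seed(seed)
  draws <- draw_parameter_matrix(specs, n)
  out <- matrix(0, n * 2, 3)
  n_redrawn <- 0L
  for (i in seq_len(n)) {
    # a rare joint draw (e.g. an extreme untreated relative risk) can
    # push a transition row past 1 even after per-parameter clipping;
    # such draws are redrawn and counted
    for (attempt in 1:100) {
      res <- tryCatch({
        pp <- apply_draw(params, draws[i, ])
        evaluate_strategies(pp, life_table)
      }, error = function(e) NULL)
      if (!is.null(res)) break
      draws[i, ] <- draw_parameter_matrix(specs, 1)
      n_redrawn <- n_redrawn + 1L
    }
    if (is.null(res)) {
      rlang::abort("PSA draw could not be made valid after 100 redraws.")
    }
    out[2 * i - 1, ] <- c(res$cost[1], res$qalys[1], res$life_years[1])
    out[2 * i, ] <- c(res$cost[2], res$qalys[2], res$life_years[2])
  }
  outcomes <- tibble::tibble(
    draw = rep(seq_len(n), each = 2),
    strategy = rep(c("cystoscopy_only", "dcrshp_triage"), n),
    cost = out[, 1], qalys = out[, 2], life_years = out[, 3]
  )
  structure(
    list(draws = tibble::as_tibble(draws), outcomes = outcomes, n = n,
         seed = seed, n_redrawn = n_redrawn),
    class = "psa_sample"
  )
}

#' @export
print.psa_sample <- function(x, ...) {
  cat("<psa_sample> ", x$n, " draws, ", ncol(x$draws), " sampled parameters (seed ",
      x$seed, ")\n", sep = "")
  invisible(x)
}

#' Tidy a PSA sample
#' @param x A `psa_sample`.
#' @param ... Unused.
#' @return The per-draw incremental outcomes (triage minus cystoscopy):
#'   `draw`, `delta_cost`, `delta_qalys`.
#' @export
tidy.psa_sample <- function(x, ...) {
  wide <- tidyr::pivot_wider(
    x$outcomes,
    id_cols = "draw", names_from = "strategy",
    values_from = c("cost", "qalys")
  )
  tibble::tibble(
    draw = wide$draw,
    delta_cost = wide$cost_dcrshp_triage - wide$cost_cystoscopy_only,
    delta_qalys = wide$qalys_dcrshp_triage - wide$qalys_cystoscopy_only
  )
}

#' Glance at a PSA sample
#' @param x A `psa_sample`.
#' @param wtp Willingness to pay per QALY.
#' @param ... Unused.
#' @return One-row tibble: mean incremental cost/QALYs and the
#'   probability the triage strategy is cost-effective at `wtp`.
#' @export
glance.psa_sample <- function(x, wtp = 20000, ...) {
  inc <- tidy(x)
  dnmb <- inc$delta_qalys * wtp - inc$delta_cost
  tibble::tibble(
    n = x$n,
    mean_delta_cost = mean(inc$delta_cost),
    mean_delta_qalys = mean(inc$delta_qalys),
    p_cost_effective = mean((dnmb > 0) + 0.5 * (dnmb == 0)),
    wtp = wtp
  )
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws in which
#' each strategy has the higher net monetary benefit (ties split 0.5
#' each).
#'
#' @param sample A [run_psa()] result.
#' @param wtp_grid Willingness-to-pay grid.
#' @return Tibble: `wtp`, `strategy`, `probability`; the two strategies'
#'   probabilities sum to 1 at every grid point.
#' @export
ceac <- function(sample, wtp_grid = seq(0, 100000, by = 2500)) {
  stopifnot(inherits(sample, "psa_sample"), sample$n >= 1)
  inc <- tidy(sample)
  purrr::map_dfr(wtp_grid, function(w) {
    dnmb <- inc$delta_qalys * w - inc$delta_cost
    p_triage <- mean((dnmb > 0) + 0.5 * (dnmb == 0))
    tibble::tibble(
      wtp = w,
      strategy = c("dcrshp_triage", "cystoscopy_only"),
      probability = c(p_triage, 1 - p_triage)
    )
  })
}
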