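#' Net monetary benefit against triage-test price
#'
#' NMB of both strategies at a willingness to pay, as the triage price
#' varies; the curves cross at the threshold price.
#'
#' @param params A `bc_params` object.
#' @param price_grid Price grid in GBP.
#' @param wtp Willingness to pay per QALY.
#' @return A ggplot object.
#' @export
plot_nmb_price <- function(params = bc_parameters(),
                           price_grid = seq(0, 1000, by = 50), wtp = 20000) {
  lt <- make_life_table(male_fraction = params$prop_male)
  dat <- purrr::map_dfr(price_grid, function(pr) {
    res <- evaluate_strategies(bc_parameters_price(params, pr), lt)
    res$nmb <- nmb(res, wtp)
    res$price <- pr
    res
  })
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$price, y = .data$nmb, colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Triage-test price (GBP)", y = "Net monetary benefit (GBP)",
      colour = NULL,
      title = sprintf("NMB at WTP £%s per QALY", format(wtp, big.mark = ","))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a prevalence sweep
#'
#' @param sweep A [prevalence_sweep()] result.
#' @return A ggplot object of incremental QALYs against prevalence with
#'   the zero line and interpolated crossover marked.
#' @export
plot_prevalence_sweep <- function(sweep) {
  cross <- attr(sweep, "crossover")
  gg <- ggplot2::ggplot(sweep, ggplot2::aes(x = .data$prevalence, y = .data$delta_qalys)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(
      x = "Prevalence of bladder cancer", y = "Incremental QALYs (triage - cystoscopy)"
    ) +
    ggplot2::theme_minimal()
  if (!is.na(cross)) {
    gg <- gg + ggplot2::geom_vline(xintercept = cross, linetype = 3)
  }
  gg
}

#' Cost-effectiveness plane from a PSA sample
#'
#' @param x A [run_psa()] result.
#' @param wtp Willingness to pay drawn as a reference line.
#' @param ... Unused.
#' @return A ggplot object of per-draw incremental cost against
#'   incremental QALYs.
#' @export
autoplot.psa_sample <- function(x, wtp = 20000, ...) {
  inc <- tidy(x)
  ggplot2::ggplot(inc, ggplot2::aes(x = .data$delta_qalys, y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.5) +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = 2) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey50") +
    ggplot2::labs(
      x = "Incremental QALYs (triage - cystoscopy)",
      y = "Incremental cost (GBP)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param curve A [ceac()] tibble.
#' @return A ggplot object.
#' @export
plot_ceac <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$wtp, y = .data$probability,
                                      colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Willingness to pay per QALY (GBP)",
      y = "Probability cost-effective", colour = NULL
    ) +
    ggplot2::theme_minimal()
}
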