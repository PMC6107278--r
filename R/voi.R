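# Net-benefit matrix (draws x strategies) from a PSA sample.
nb_matrix <- function(sample, wtp) {
  wide <- tidyr::pivot_wider(
    sample$outcomes,
    id_cols = "draw", names_from = "strategy", values_from = c("cost", "qalys")
  )
  cbind(
    cystoscopy_only = wide$qalys_cystoscopy_only * wtp - wide$cost_cystoscopy_only,
    dcrshp_triage = wide$qalys_dcrshp_triage * wtp - wide$cost_dcrshp_triage
  )
}

#' Expected value of perfect information
#'
#' The mean-max identity on the PSA net-benefit sample:
#' `EVPI = mean(max over strategies of NB) - max over strategies of
#' mean(NB)` — the expected gain, per presenting patient, from resolving
#' all parameter uncertainty before choosing a strategy.
#'
#' @param sample A [run_psa()] result (or any object with an `outcomes`
#'   tibble of per-draw costs and QALYs per strategy).
#' @param wtp Willingness to pay per QALY.
#' @return EVPI in GBP per patient (non-negative).
#' @export
evpi <- function(sample, wtp = 20000) {
  nb <- nb_matrix(sample, wtp)
  mean(pmax(nb[, 1], nb[, 2])) - max(colMeans(nb))
}

#' Expected value of perfect parameter information
#'
#' Nonparametric regression estimator: per strategy, the net benefit is
#' regressed on the parameter subset with an additive penalised spline
#' basis ([mgcv::gam()]; low-order tensor-free smooths, basis dimension
#' capped relative to `sqrt(n)`); the fitted values estimate the
#' conditional expectation of NB given the subset, and
#' `EVPPI = mean(max fitted) - max(mean fitted)`.
#'
#' Constant columns in the subset are dropped with a warning; with no
#' informative column left the EVPPI is 0.
#'
#' @param sample A [run_psa()] result.
#' @param subset Character vector of sampled-parameter names (columns of
#'   `sample$draws`).
#' @param wtp Willingness to pay per QALY.
#' @return EVPPI in GBP per patient, with attribute `diagnostics`
#'   (basis size and residual variance per strategy).
#' @export
evppi <- function(sample, subset, wtp = 20000) {
  stopifnot(length(subset) >= 1)
  missing_cols <- setdiff(subset, colnames(sample$draws))
  if (length(missing_cols)) {
    rlang::abort(paste0(
      "Not sampled parameters: ", paste(missing_cols, collapse = ", ")
    ))
  }
  X <- as.data.frame(sample$draws[, subset, drop = FALSE])
  constant <- vapply(X, function(v) stats::var(v) == 0, TRUE)
  if (any(constant)) {
    rlang::warn(paste0(
      "Dropping constant column(s): ", paste(names(X)[constant], collapse = ", ")
    ))
    X <- X[, !constant, drop = FALSE]
  }
  nb <- nb_matrix(sample, wtp)
  if (ncol(X) == 0) {
    out <- 0
    attr(out, "diagnostics") <- tibble::tibble(
      strategy = colnames(nb), basis_size = 0L, residual_variance = apply(nb, 2, stats::var)
    )
    return(out)
  }
  n <- nrow(X)
  k_base <- if (ncol(X) <= 3) max(4L, min(10L, floor(sqrt(n)))) else 4L
  names(X) <- paste0("x", seq_len(ncol(X)))
  terms <- vapply(names(X), function(nm) {
    ku <- length(unique(X[[nm]]))
    if (ku < 4) nm else sprintf("s(%s, k = %d)", nm, min(k_base, ku - 1L))
  }, "")
  rhs <- paste(terms, collapse = " + ")
  fitted <- matrix(0, n, ncol(nb))
  diag_rows <- vector("list", ncol(nb))
  for (j in seq_len(ncol(nb))) {
    dat <- X
    dat$nb <- nb[, j]
    fit <- mgcv::gam(stats::as.formula(paste("nb ~", rhs)), data = dat)
    fitted[, j] <- stats::fitted(fit)
    diag_rows[[j]] <- tibble::tibble(
      strategy = colnames(nb)[j],
      basis_size = length(stats::coef(fit)),
      residual_variance = stats::var(stats::residuals(fit))
    )
  }
  out <- mean(apply(fitted, 1, max)) - max(colMeans(fitted))
  out <- max(0, out)
  attr(out, "diagnostics") <- dplyr::bind_rows(diag_rows)
  out
}

#' Value-of-information summary table
#'
#' EVPI plus EVPPI for a list of parameter subsets across one or more
#' willingness-to-pay values.
#'
#' @param sample A [run_psa()] result.
#' @param subsets Named list of character vectors of parameter names.
#' @param wtp Vector of willingness-to-pay values.
#' @return Tibble: `wtp`, `quantity` (`"evpi"` or the subset name),
#'   `value` (GBP per patient).
#' @export
voi_table <- function(sample, subsets = list(), wtp = 20000) {
  purrr::map_dfr(wtp, function(w) {
    rows <- tibble::tibble(wtp = w, quantity = "evpi", value = evpi(sample, w))
    if (length(subsets)) {
      rows <- dplyr::bind_rows(rows, purrr::imap_dfr(subsets, function(cols, nm) {
        tibble::tibble(wtp = w, quantity = nm, value = as.numeric(evppi(sample, cols, w)))
      }))
    }
    rows
  })
}
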