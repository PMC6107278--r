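#' Standard error from a reported range
#'
#' Converts a reported (lower, upper) uncertainty range into a standard
#' error under the usual normal-approximation reading of the range as a
#' 95% interval: `SE = (upper - lower) / (2 * 1.96)`.
#'
#' @param lower,upper Numeric vectors, `upper >= lower`.
#' @return Numeric vector of standard errors.
#' @export
#' @examples
#' se_from_range(0.95, 1)
se_from_range <- function(lower, upper) {
  if (any(!is.finite(lower)) || any(!is.finite(upper))) {
    rlang::abort("`lower` and `upper` must be finite numbers.")
  }
  if (any(upper < lower)) {
    rlang::abort("`upper` must be >= `lower`.")
  }
  (upper - lower) / (2 * 1.96)
}

#' Beta distribution from mean and standard deviation
#'
#' Method-of-moments fit of a Beta distribution: solves
#' `mean = alpha / (alpha + beta)` and the Beta variance identity for
#' `(alpha, beta)`.
#'
#' @param mean Mean in (0, 1).
#' @param sd Standard deviation; must satisfy `sd^2 < mean * (1 - mean)`.
#' @return A `dist_spec` of kind `"beta_moments"`.
#' @export
#' @examples
#' beta_from_moments(0.5, 0.1)
beta_from_moments <- function(mean, sd) {
  stopifnot(length(mean) == 1, length(sd) == 1)
  if (!is.finite(mean) || mean <= 0 || mean >= 1) {
    rlang::abort("`mean` must lie strictly inside (0, 1).")
  }
  if (!is.finite(sd) || sd < 0) {
    rlang::abort("`sd` must be a non-negative number.")
  }
  if (sd^2 >= mean * (1 - mean)) {
    rlang::abort(
      "Infeasible moments: sd^2 must be < mean * (1 - mean) for a Beta distribution."
    )
  }
  if (sd == 0) {
    return(dist_fixed(mean))
  }
  nu <- mean * (1 - mean) / sd^2 - 1
  dist_spec(
    kind = "beta_moments",
    params = c(alpha = mean * nu, beta = (1 - mean) * nu),
    point = mean
  )
}

#' Beta distribution from observed counts
#'
#' Parameterises a Beta as `Beta(successes, failures)`, so the mean equals
#' the observed proportion `successes / (successes + failures)` exactly
#' (no +1 pseudo-counts; switch `pseudo = 1` for the Bayesian-uniform
#' variant).
#'
#' @param successes,failures Non-negative counts, not both zero.
#' @param pseudo Pseudo-count added to both cells (default 0).
#' @return A `dist_spec` of kind `"beta_counts"`. When one cell is zero
#'   (a degenerate, point-mass-like fit) the spec carries a
#'   `degenerate = TRUE` attribute.
#' @export
#' @examples
#' beta_from_counts(57, 6) # triage-test sensitivity 57/63
beta_from_counts <- function(successes, failures, pseudo = 0) {
  stopifnot(length(successes) == 1, length(failures) == 1)
  if (successes < 0 || failures < 0 || successes + failures == 0) {
    rlang::abort("Counts must be non-negative and not both zero.")
  }
  a <- successes + pseudo
  b <- failures + pseudo
  spec <- dist_spec(
    kind = "beta_counts",
    params = c(alpha = a, beta = b),
    point = successes / (successes + failures)
  )
  spec$degenerate <- (a == 0 || b == 0)
  spec
}

#' Log-normal distribution for a utility decrement
#'
#' Method-of-moments log-normal on the magnitude of a (positive)
#' utility decrement: `sigma^2 = log(1 + (sd/mean)^2)`,
#' `mu = log(mean) - sigma^2 / 2`, so draws are positive with the
#' requested natural-scale mean and standard deviation.
#'
#' @param mean_decrement Positive magnitude of the decrement.
#' @param sd Standard error of the decrement (>= 0).
#' @return A `dist_spec` of kind `"lognormal_decrement"`.
#' @export
#' @examples
#' lognormal_for_decrement(0.1, 0.02) # TURBT decrement
lognormal_for_decrement <- function(mean_decrement, sd) {
  stopifnot(length(mean_decrement) == 1, length(sd) == 1)
  if (!is.finite(mean_decrement) || mean_decrement <= 0) {
    rlang::abort("`mean_decrement` must be a positive magnitude.")
  }
  if (!is.finite(sd) || sd < 0) {
    rlang::abort("`sd` must be non-negative.")
  }
  if (sd == 0) {
    return(dist_fixed(mean_decrement))
  }
  sigma2 <- log(1 + (sd / mean_decrement)^2)
  dist_spec(
    kind = "lognormal_decrement",
    params = c(meanlog = log(mean_decrement) - sigma2 / 2, sdlog = sqrt(sigma2)),
    point = mean_decrement
  )
}

#' Fixed (degenerate) distribution
#'
#' @param value The fixed value.
#' @return A `dist_spec` of kind `"fixed"`.
#' @export
dist_fixed <- function(value) {
  stopifnot(length(value) == 1, is.finite(value))
  dist_spec(kind = "fixed", params = c(value = value), point = value)
}

#' Log-normal distribution on the natural scale
#'
#' Method-of-moments log-normal for a positive quantity such as a relative
#' risk, with optional truncation from below (draws under `lower` are set
#' to `lower`).
#'
#' @param mean Natural-scale mean (> 0).
#' @param sd Natural-scale standard deviation (> 0).
#' @param lower Optional lower truncation bound.
#' @return A `dist_spec` of kind `"lognormal"`.
#' @export
lognormal_from_moments <- function(mean, sd, lower = -Inf) {
  stopifnot(mean > 0, sd > 0)
  sigma2 <- log(1 + (sd / mean)^2)
  spec <- dist_spec(
    kind = "lognormal",
    params = c(meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2)),
    point = mean
  )
  spec$lower <- lower
  spec
}

#' Uniform distribution
#'
#' @param min,max Bounds, `max >= min`.
#' @param point Base-case value reported alongside draws (defaults to the
#'   midpoint).
#' @return A `dist_spec` of kind `"uniform"`.
#' @export
dist_uniform <- function(min, max, point = (min + max) / 2) {
  stopifnot(max >= min)
  dist_spec(kind = "uniform", params = c(min = min, max = max), point = point)
}

#' Dirichlet distribution from counts
#'
#' Multivariate analogue of [beta_from_counts()] for a vector of mutually
#' exclusive fractions; draws sum to one.
#'
#' @param counts Named vector of positive counts.
#' @return A `dist_spec` of kind `"dirichlet"`; its point value is the
#'   normalised count vector.
#' @export
dirichlet_from_counts <- function(counts) {
  if (any(counts <= 0)) rlang::abort("All Dirichlet counts must be positive.")
  dist_spec(kind = "dirichlet", params = counts, point = counts / sum(counts))
}

dist_spec <- function(kind, params, point) {
  structure(
    list(kind = kind, params = params, point = point),
    class = "dist_spec"
  )
}

#' @export
print.dist_spec <- function(x, ...) {
  cat(
    "<dist_spec> ", x$kind, "(",
    paste(names(x$params), signif(unname(x$params), 6), sep = " = ", collapse = ", "),
    "), point = ", paste(signif(x$point, 6), collapse = " "), "\n",
    sep = ""
  )
  invisible(x)
}

#' Sample from a distribution specification
#'
#' Draws use the current RNG state; seed outside (e.g. `withr::with_seed`)
#' for reproducibility.
#'
#' @param spec A `dist_spec`.
#' @param n Number of draws.
#' @return Numeric vector of length `n`, or an `n x k` matrix for
#'   Dirichlet specs.
#' @export
sample_dist <- function(spec, n = 1) {
  stopifnot(inherits(spec, "dist_spec"))
  switch(spec$kind,
    fixed = rep(spec$params[["value"]], n),
    beta_counts = ,
    beta_moments = {
      a <- spec$params[["alpha"]]
      b <- spec$params[["beta"]]
      if (a == 0) rep(0, n) else if (b == 0) rep(1, n) else stats::rbeta(n, a, b)
    },
    lognormal_decrement = ,
    lognormal = {
      x <- stats::rlnorm(n, spec$params[["meanlog"]], spec$params[["sdlog"]])
      if (!is.null(spec$lower) && is.finite(spec$lower)) x <- pmax(x, spec$lower)
      x
    },
    uniform = stats::runif(n, spec$params[["min"]], spec$params[["max"]]),
    dirichlet = {
      k <- length(spec$params)
      g <- matrix(stats::rgamma(n * k, shape = rep(spec$params, each = n)), nrow = n)
      colnames(g) <- names(spec$params)
      g / rowSums(g)
    },
    rlang::abort(paste0("Unknown distribution kind: ", spec$kind))
  )
}

#' Theoretical mean of a distribution specification
#' @param spec A `dist_spec`.
#' @return The distribution mean (before any truncation).
#' @export
dist_mean <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  switch(spec$kind,
    fixed = spec$params[["value"]],
    beta_counts = ,
    beta_moments = spec$params[["alpha"]] / (spec$params[["alpha"]] + spec$params[["beta"]]),
    lognormal_decrement = ,
    lognormal = exp(spec$params[["meanlog"]] + spec$params[["sdlog"]]^2 / 2),
    uniform = (spec$params[["min"]] + spec$params[["max"]]) / 2,
    dirichlet = spec$params / sum(spec$params),
    rlang::abort(paste0("Unknown distribution kind: ", spec$kind))
  )
}
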