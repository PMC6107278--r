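#' Synthetic all-cause mortality life table
#'
#' Builds a sex-weighted six-month all-cause death probability table on a
#' half-year age grid from a Gompertz hazard, as a stand-in for a national
#' statistics life table (this is a synthetic fixture, not observed
#' mortality data). Sex-specific hazards
#' `h(a) = h0 * exp(slope * (a - 60))` are integrated over each six-month
#' interval and mixed as `male_fraction * q_m + (1 - male_fraction) * q_f`.
#'
#' Default calibration (`h0` at age 60: male 0.0087/y, female 0.0056/y,
#' slope 0.095/y) matches the magnitude of the UK interim life tables
#' around 2014 (annual q(60) about 0.0087 for men and 0.0056 for women),
#' giving a mixed six-month probability near 0.004 at age 60.
#'
#' @param start_age,end_age Age range in years (`start_age < end_age`).
#' @param male_fraction Proportion male in the cohort.
#' @param h0_male,h0_female Baseline annual hazards at age 60.
#' @param slope Gompertz log-hazard slope per year of age.
#' @return A tibble of class `life_table` with columns `age` (interval
#'   start, half-year grid) and `qx` (six-month death probability).
#' @export
#' @examples
#' lt <- make_life_table()
#' head(lt)
make_life_table <- function(start_age = 60, end_age = 100, male_fraction = 0.796,
                            h0_male = 0.0087, h0_female = 0.0056, slope = 0.095) {
  stopifnot(start_age < end_age, male_fraction >= 0, male_fraction <= 1,
            h0_male > 0, h0_female > 0, slope >= 0)
  age <- seq(start_age, end_age - 0.5, by = 0.5)
  # integral of h0 * exp(slope (a - 60)) over [age, age + 0.5]
  cum_haz <- function(h0) {
    if (slope == 0) return(rep(h0 * 0.5, length(age)))
    h0 / slope * (exp(slope * (age + 0.5 - 60)) - exp(slope * (age - 60)))
  }
  q_m <- 1 - exp(-cum_haz(h0_male))
  q_f <- 1 - exp(-cum_haz(h0_female))
  out <- tibble::tibble(age = age, qx = male_fraction * q_m + (1 - male_fraction) * q_f)
  class(out) <- c("life_table", class(out))
  out
}

#' Look up the six-month death probability at an age
#'
#' @param life_table A [make_life_table()] tibble.
#' @param age Age in years (vectorised); ages beyond the table are held at
#'   the last row.
#' @return Six-month death probabilities.
#' @export
life_table_qx <- function(life_table, age) {
  idx <- pmin(pmax(floor((age - life_table$age[1]) * 2) + 1, 1L), nrow(life_table))
  life_table$qx[idx]
}
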