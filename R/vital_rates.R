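#' Male signal expression
#'
#' A male's signal conveys his viability, degraded multiplicatively by the
#' environmental disruption: `signal = viability * (1 - disruption)`. With no
#' disruption the signal equals viability exactly (an honest signal); as
#' disruption grows, the disparity between the signals of males of differing
#' viability shrinks, vanishing at full disruption. The signal is computed
#' once at birth and never updated.
#'
#' @param viability Viability trait value(s) in \[0, 1\].
#' @param disruption Disruption magnitude in \[0, 1\].
#' @return Signal value(s) in \[0, 1\].
#' @examples
#' signal_expression(0.8, 0)    # honest: 0.8
#' signal_expression(0.6, 0.5)  # 0.3
#' @export
signal_expression <- function(viability, disruption) {
  check_unit(viability, "viability")
  check_unit(disruption, "disruption")
  viability * (1 - disruption)
}

#' Density-dependent juvenile survival
#'
#' Per-step juvenile survival declines linearly with the juvenile count and
#' reaches zero at carrying capacity:
#' `max(0, 1 - juvenile_count / carrying_capacity)`.
#'
#' @param juvenile_count Number of juveniles alive at the start of the
#'   ageing/death phase.
#' @param carrying_capacity Juvenile carrying capacity.
#' @return Survival probability in \[0, 1\].
#' @examples
#' juvenile_survival_prob(500, 2000)  # 0.75
#' @export
juvenile_survival_prob <- function(juvenile_count, carrying_capacity) {
  if (any(juvenile_count < 0)) stop("'juvenile_count' must be non-negative")
  if (any(carrying_capacity <= 0)) stop("'carrying_capacity' must be positive")
  pmax(0, 1 - juvenile_count / carrying_capacity)
}

#' Senescent adult survival
#'
#' Adults die with a probability that grows quadratically with age, offset by
#' the survival advantage of viability:
#' `1 - clamp(age^2 / senescence - viability_effect * viability, 0, 1)`.
#' The hazard is clamped so the result is a valid Bernoulli parameter; young
#' high-viability adults therefore experience no mortality at all, and the
#' age term dominates as individuals senesce.
#'
#' @param age Age in steps (non-negative).
#' @param viability Viability trait value(s) in \[0, 1\].
#' @param viability_effect Strength of the viability survival advantage.
#' @param senescence Scales the effect of age on survival.
#' @return Survival probability in \[0, 1\].
#' @examples
#' adult_survival_prob(200, 0, 0.3, 100000)  # 0.6
#' adult_survival_prob(200, 1, 0.3, 100000)  # 0.9
#' @export
adult_survival_prob <- function(age, viability, viability_effect = 0.3,
                                senescence = 100000) {
  if (any(age < 0)) stop("'age' must be non-negative")
  check_unit(viability, "viability")
  check_unit(viability_effect, "viability_effect")
  if (any(senescence <= 0)) stop("'senescence' must be positive")
  hazard <- pmin(pmax(age^2 / senescence - viability_effect * viability, 0), 1)
  1 - hazard
}

check_unit <- function(x, what) {
  if (!is.numeric(x) || anyNA(x))
    stop("'", what, "' must be numeric with no missing values")
  if (any(x < 0 | x > 1))
    stop("'", what, "' must lie in [0, 1]")
  invisible(x)
}
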