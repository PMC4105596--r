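#' Mean allelic value at one inherited slot
#'
#' The reported observable of a run: the arithmetic mean, over all living
#' individuals (both sexes, juveniles included), of the allele at one
#' inherited slot of one trait. The paternally inherited slot is the default
#' observable; the maternally inherited slot gives equivalent results and is
#' recorded alongside for that check.
#'
#' @param state A `sim_state`.
#' @param trait `"viability"` or `"preference"`.
#' @param slot `"paternal"` (default) or `"maternal"`.
#' @return The mean allelic value, in \[0, 1\].
#' @export
mean_paternal_allele <- function(state, trait = c("viability", "preference"),
                                 slot = c("paternal", "maternal")) {
  trait <- match.arg(trait)
  slot <- match.arg(slot)
  if (nrow(state$pop) == 0)
    stop("allelic means are undefined for an empty population")
  col <- paste0(if (trait == "viability") "viab" else "pref",
                "_allele_", if (slot == "paternal") "pat" else "mat")
  mean(state$pop[, col])
}

#' Capture a time-point record
#'
#' Summarises the current state into one observer record: counts (total,
#' males, females, juveniles) and the four allele means (paternal and
#' maternal slot of both traits) over all living individuals, plus the mean
#' male signal. Captures are taken at the top of the scheduled step, before
#' any sub-model runs, so time-point A reflects the state immediately prior
#' to disruption onset and B the state at the last disrupted step.
#'
#' @param state A `sim_state`.
#' @param label Time-point label, one of `"A"`, `"B"`, `"C1"`, `"C2"`.
#' @param p A `sim_params` object (supplies `maturity_age` for the juvenile
#'   count).
#' @return A one-row data frame; `NULL` for an empty population (extinction
#'   is recorded instead of a time-point).
#' @export
capture_timepoint <- function(state, label, p = sim_params()) {
  stopifnot(label %in% c("A", "B", "C1", "C2"))
  pop <- state$pop
  if (nrow(pop) == 0) return(NULL)
  male <- pop[, "sex"] == 1
  data.frame(
    label = label,
    t = as.integer(state$t),
    n = nrow(pop),
    n_males = sum(male),
    n_females = sum(!male),
    n_juveniles = sum(pop[, "age"] < p$maturity_age),
    mean_pref_pat = mean(pop[, "pref_allele_pat"]),
    mean_pref_mat = mean(pop[, "pref_allele_mat"]),
    mean_viab_pat = mean(pop[, "viab_allele_pat"]),
    mean_viab_mat = mean(pop[, "viab_allele_mat"]),
    mean_signal_males = if (any(male)) mean(pop[male, "signal"]) else NA_real_,
    stringsAsFactors = FALSE)
}

#' Estimate generation time from a birth log
#'
#' The model does not define a generation directly; the estimator used here
#' is the mean maternal age at birth over logged birth events (one event per
#' delivered litter), restricted to the burn-in when `burn_in` is given.
#'
#' @param birth_log Data frame with columns `t` (step of the birth event) and
#'   `mother_age` (the mother's age at delivery).
#' @param burn_in If non-`NULL`, only events with `t < burn_in` are used.
#' @return Estimated generation time in steps.
#' @export
estimate_generation_time <- function(birth_log, burn_in = NULL) {
  if (!is.data.frame(birth_log) ||
      !all(c("t", "mother_age") %in% names(birth_log)))
    stop("'birth_log' must be a data frame with columns 't' and 'mother_age'")
  if (!is.null(burn_in)) birth_log <- birth_log[birth_log$t < burn_in, ]
  if (nrow(birth_log) == 0)
    stop("no birth events logged; generation time is undefined")
  mean(birth_log$mother_age)
}

#' Audit the internal consistency of a state
#'
#' Asserts every structural invariant an individual must satisfy: alleles in
#' \[0, 1\], traits equal to allele means, signals defined for males only and
#' non-negative, males never pregnant, pregnant females carrying a complete
#' set of four stored mate alleles with gestation in
#' `1:gestation_length`, and non-pregnant females with cleared mate alleles.
#' Intended to be run after every phase in tests.
#'
#' @param state A `sim_state`.
#' @param p A `sim_params` object.
#' @return `TRUE` invisibly; stops with a description on the first violation.
#' @export
audit_state <- function(state, p = sim_params()) {
  pop <- state$pop
  if (nrow(pop) == 0) return(invisible(TRUE))
  fail <- function(...) stop("state audit: ", ...)
  al <- pop[, c("viab_allele_mat", "viab_allele_pat",
                "pref_allele_mat", "pref_allele_pat")]
  if (anyNA(al) || any(al < 0 | al > 1)) fail("allele out of [0, 1] or NA")
  if (max(abs(pop[, "viability"] -
              (pop[, "viab_allele_mat"] + pop[, "viab_allele_pat"]) / 2)) >
      1e-12) fail("viability != mean of its alleles")
  if (max(abs(pop[, "preference"] -
              (pop[, "pref_allele_mat"] + pop[, "pref_allele_pat"]) / 2)) >
      1e-12) fail("preference != mean of its alleles")
  if (any(pop[, "age"] < 0) || any(pop[, "age"] %% 1 != 0))
    fail("ages must be non-negative integers")
  male <- pop[, "sex"] == 1
  if (any(pop[male, "pregnant"] != 0)) fail("pregnant male")
  if (anyNA(pop[male, "signal"]) || any(pop[male, "signal"] < 0))
    fail("male signal missing or negative")
  if (any(!is.na(pop[!male, "signal"]))) fail("female carries a signal")
  preg <- pop[, "pregnant"] == 1
  stored <- pop[, c("mate_viab_mat", "mate_viab_pat",
                    "mate_pref_mat", "mate_pref_pat"), drop = FALSE]
  if (any(preg)) {
    s <- stored[preg, , drop = FALSE]
    if (anyNA(s) || any(s < 0 | s > 1))
      fail("pregnant female with incomplete or invalid stored mate alleles")
    g <- pop[preg, "gestation"]
    if (any(g < 1 | g > p$gestation_length))
      fail("gestation outside 1:gestation_length")
  }
  if (any(!is.na(stored[!preg, ])))
    fail("non-pregnant individual with stored mate alleles")
  if (anyDuplicated(pop[, "id"]) > 0) fail("duplicate individual ids")
  invisible(TRUE)
}
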