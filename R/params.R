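#' Model parameters
#'
#' Construct the full parameter set for a simulation run. Defaults are the
#' published guppy-like life-history values: a time step corresponds to one
#' day, gestation lasts 27 steps, litter sizes are Poisson with mean 6,
#' individuals mature at 60 steps, density dependence acts on juveniles
#' through a carrying capacity of 2000, and the survival advantage of the
#' viability trait is scaled by 0.3. Mutation redraws a transmitted allele
#' uniformly on (0, 1); the preference gene mutates at 0.001 (the low
#' setting; 0.01 is the high setting) and the viability gene at 0.05.
#'
#' @param gestation_length Steps a female is pregnant before giving birth.
#' @param fecundity_lambda Mean litter size (Poisson).
#' @param senescence Scales the effect of age on adult survival.
#' @param maturity_age Age (steps) at which individuals mature.
#' @param carrying_capacity Juvenile carrying capacity for density-dependent
#'   juvenile mortality.
#' @param viability_effect Strength of the viability survival advantage,
#'   in \[0, 1\].
#' @param preference_mutation Per-allele transmission mutation probability for
#'   the preference gene.
#' @param viability_mutation Per-allele transmission mutation probability for
#'   the viability gene.
#' @param disruption Magnitude of signal disruption in \[0, 1\] applied during
#'   the disruption window.
#' @param disruption_duration Length (steps) of the disruption window.
#' @param burn_in Disruption-free establishment period (steps) before the
#'   window opens.
#' @param post_c1 Steps after the window closes at which the first recovery
#'   time-point (C1) is sampled.
#' @param post_c2 Steps after the window closes at which the final recovery
#'   time-point (C2) is sampled; the run ends there.
#' @param init_males,init_females Founder counts.
#' @param init_age_max Upper bound of the discrete-uniform founder ages.
#' @param seed Optional RNG seed attached to the parameter set; used by
#'   [run_single()] when no seed argument is given.
#' @return A validated `sim_params` list.
#' @seealso [validate_params()], [disruption_schedule()], [run_single()]
#' @examples
#' p <- sim_params(disruption = 0.4, disruption_duration = 2000)
#' p$carrying_capacity
#' @export
sim_params <- function(gestation_length = 27,
                       fecundity_lambda = 6,
                       senescence = 100000,
                       maturity_age = 60,
                       carrying_capacity = 2000,
                       viability_effect = 0.3,
                       preference_mutation = 0.001,
                       viability_mutation = 0.05,
                       disruption = 0,
                       disruption_duration = 500,
                       burn_in = 20000,
                       post_c1 = 10000,
                       post_c2 = 30000,
                       init_males = 75,
                       init_females = 75,
                       init_age_max = 1000,
                       seed = NULL) {
  p <- list(gestation_length = gestation_length,
            fecundity_lambda = fecundity_lambda,
            senescence = senescence,
            maturity_age = maturity_age,
            carrying_capacity = carrying_capacity,
            viability_effect = viability_effect,
            preference_mutation = preference_mutation,
            viability_mutation = viability_mutation,
            disruption = disruption,
            disruption_duration = disruption_duration,
            burn_in = burn_in,
            post_c1 = post_c1,
            post_c2 = post_c2,
            init_males = init_males,
            init_females = init_females,
            init_age_max = init_age_max,
            seed = seed)
  class(p) <- "sim_params"
  validate_params(p)
}

#' Validate a parameter set
#'
#' Checks every field invariant (probabilities in \[0, 1\], positive integer
#' step counts, positive rates) and fails with a message naming the offending
#' field. Returns the parameter set unchanged when all invariants hold.
#'
#' @param p A `sim_params` object (or a plain named list with the same
#'   fields).
#' @return `p`, classed as `sim_params`.
#' @export
validate_params <- function(p) {
  need <- setdiff(param_names(), "seed")
  missing <- setdiff(need, names(p))
  if (length(missing) > 0)
    stop("missing parameter field(s): ", paste(missing, collapse = ", "))

  chk_scalar <- function(field) {
    x <- p[[field]]
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
      stop("parameter '", field, "' must be a single finite number")
    x
  }
  chk_prob <- function(field) {
    x <- chk_scalar(field)
    if (x < 0 || x > 1)
      stop("parameter '", field, "' must lie in [0, 1], got ", x)
  }
  chk_count <- function(field, min = 1) {
    x <- chk_scalar(field)
    if (x %% 1 != 0 || x < min)
      stop("parameter '", field, "' must be an integer >= ", min, ", got ", x)
  }
  chk_pos <- function(field) {
    x <- chk_scalar(field)
    if (x <= 0)
      stop("parameter '", field, "' must be positive, got ", x)
  }

  for (f in c("viability_effect", "preference_mutation",
              "viability_mutation", "disruption")) chk_prob(f)
  for (f in c("gestation_length", "maturity_age", "carrying_capacity",
              "disruption_duration", "burn_in", "post_c1", "post_c2",
              "init_males", "init_females")) chk_count(f)
  chk_count("init_age_max", min = 0)
  chk_pos("fecundity_lambda")
  chk_pos("senescence")
  if (!is.null(p$seed)) {
    s <- p$seed
    if (!is.numeric(s) || length(s) != 1 || !is.finite(s) || s %% 1 != 0)
      stop("parameter 'seed' must be NULL or a single integer")
  }
  unknown <- setdiff(names(p), param_names())
  if (length(unknown) > 0)
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "))
  class(p) <- "sim_params"
  p
}

param_names <- function() {
  c("gestation_length", "fecundity_lambda", "senescence", "maturity_age",
    "carrying_capacity", "viability_effect", "preference_mutation",
    "viability_mutation", "disruption", "disruption_duration", "burn_in",
    "post_c1", "post_c2", "init_males", "init_females", "init_age_max",
    "seed")
}

#' Modify a parameter set
#'
#' Returns a copy of `p` with the named fields replaced, re-validated.
#'
#' @param p A `sim_params` object.
#' @param ... Named fields to replace.
#' @return A validated `sim_params` object.
#' @examples
#' p <- modify_params(sim_params(), disruption = 0.7, preference_mutation = 0.01)
#' @export
modify_params <- function(p, ...) {
  upd <- list(...)
  if (length(upd) == 0) return(p)
  if (is.null(names(upd)) || any(names(upd) == ""))
    stop("all replacement fields must be named")
  unknown <- setdiff(names(upd), param_names())
  if (length(unknown) > 0)
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "))
  q <- unclass(p)
  for (nm in names(upd)) q[[nm]] <- upd[[nm]]
  class(q) <- "sim_params"
  validate_params(q)
  q
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  for (nm in param_names()) {
    v <- x[[nm]]
    cat(sprintf("  %-20s %s\n", nm, if (is.null(v)) "NULL" else format(v)))
  }
  invisible(x)
}
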