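#' Population matrix column names
#'
#' The population is stored as a numeric matrix with one row per living
#' individual and these 16 columns. `sex` is 1 for males and 0 for females;
#' ages and gestation counters are integer-valued; `signal` is `NA` for
#' females; the four `mate_*` columns hold the alleles of the mated male and
#' are `NA` unless the female is pregnant.
#'
#' @return Character vector of column names, in matrix order.
#' @export
pop_columns <- function() {
  c("sex", "age", "viab_allele_mat", "viab_allele_pat",
    "pref_allele_mat", "pref_allele_pat", "viability", "preference",
    "signal", "pregnant", "gestation",
    "mate_viab_mat", "mate_viab_pat", "mate_pref_mat", "mate_pref_pat", "id")
}

new_state <- function(pop, t = 0, disruption = 0, next_id = NULL) {
  if (is.null(next_id))
    next_id <- if (nrow(pop) > 0) max(pop[, "id"]) + 1 else 1
  structure(list(pop = pop, t = as.integer(t), disruption = disruption,
                 next_id = next_id),
            class = "sim_state")
}

#' Build a population state from per-individual data
#'
#' Convenience constructor, mainly for constructing small synthetic
#' populations in tests and examples. Any column of [pop_columns()] that is
#' not supplied is filled with its natural default: traits as allele means,
#' male signals via [signal_expression()] at the given disruption, females
#' non-pregnant with empty mate-allele slots, ids sequential.
#'
#' @param df A data frame with at least `sex` and `age`, and optionally any
#'   other population column.
#' @param t Simulation clock for the new state.
#' @param disruption Disruption value used to fill missing male signals.
#' @return A `sim_state` object.
#' @export
make_state <- function(df, t = 0, disruption = 0) {
  n <- nrow(df)
  if (!all(c("sex", "age") %in% names(df)))
    stop("'df' must contain at least 'sex' and 'age'")
  get_col <- function(nm, default) {
    if (nm %in% names(df)) as.numeric(df[[nm]]) else rep_len(default, n)
  }
  sex <- as.numeric(df$sex)
  if (!all(sex %in% c(0, 1))) stop("'sex' must be coded 0 (female) / 1 (male)")
  va_m <- get_col("viab_allele_mat", 0.5)
  va_p <- get_col("viab_allele_pat", 0.5)
  pr_m <- get_col("pref_allele_mat", 0.5)
  pr_p <- get_col("pref_allele_pat", 0.5)
  viab <- if ("viability" %in% names(df)) as.numeric(df$viability)
          else express_trait(va_m, va_p)
  pref <- if ("preference" %in% names(df)) as.numeric(df$preference)
          else express_trait(pr_m, pr_p)
  sig <- if ("signal" %in% names(df)) as.numeric(df$signal)
         else ifelse(sex == 1, signal_expression(viab, disruption), NA_real_)
  sig[sex == 0] <- NA_real_
  preg <- get_col("pregnant", 0)
  preg[sex == 1] <- 0
  gest <- get_col("gestation", 0)
  gest[preg == 0] <- 0
  mate_default <- ifelse(preg == 1, 0.5, NA_real_)
  pop <- cbind(sex = sex, age = as.numeric(df$age),
               viab_allele_mat = va_m, viab_allele_pat = va_p,
               pref_allele_mat = pr_m, pref_allele_pat = pr_p,
               viability = viab, preference = pref, signal = sig,
               pregnant = preg, gestation = gest,
               mate_viab_mat = get_col("mate_viab_mat", mate_default),
               mate_viab_pat = get_col("mate_viab_pat", mate_default),
               mate_pref_mat = get_col("mate_pref_mat", mate_default),
               mate_pref_pat = get_col("mate_pref_pat", mate_default),
               id = get_col("id", seq_len(n)))
  pop[pop[, "pregnant"] == 0, c("mate_viab_mat", "mate_viab_pat",
                                "mate_pref_mat", "mate_pref_pat")] <- NA_real_
  new_state(pop, t = t, disruption = disruption)
}

#' @export
print.sim_state <- function(x, ...) {
  pop <- x$pop
  cat(sprintf("<sim_state> t = %d, %d individuals (%d males, %d females), disruption = %g\n",
              as.integer(x$t), nrow(pop), sum(pop[, "sex"] == 1),
              sum(pop[, "sex"] == 0), x$disruption))
  invisible(x)
}

#' Initialize a founder population
#'
#' Creates the founding population: `init_males` males and `init_females`
#' females with ages drawn discrete-uniformly on `[0, init_age_max]` and all
#' four alleles drawn Uniform(0, 1). Traits are the allele means. Mature
#' females (age above `maturity_age`) are pregnant with probability 0.5;
#' pregnant founders get a gestation drawn uniformly from
#' `1:gestation_length` and four random stored mate alleles. Males fix their
#' signal with no disruption (the schedule starts disruption-free).
#'
#' @param p A `sim_params` object.
#' @return A `sim_state` at `t = 0`.
#' @export
initialize_population <- function(p) {
  validate_params(p)
  n <- p$init_males + p$init_females
  sex <- c(rep(1, p$init_males), rep(0, p$init_females))
  age <- sample.int(p$init_age_max + 1L, n, replace = TRUE) - 1
  va_m <- runif(n); va_p <- runif(n)
  pr_m <- runif(n); pr_p <- runif(n)
  viab <- express_trait(va_m, va_p)
  pref <- express_trait(pr_m, pr_p)
  sig <- ifelse(sex == 1, signal_expression(viab, 0), NA_real_)
  mature_f <- sex == 0 & age > p$maturity_age
  preg <- as.numeric(mature_f & runif(n) < 0.5)
  gest <- ifelse(preg == 1,
                 sample.int(p$gestation_length, n, replace = TRUE), 0)
  stored <- function() ifelse(preg == 1, runif(n), NA_real_)
  pop <- cbind(sex = sex, age = age,
               viab_allele_mat = va_m, viab_allele_pat = va_p,
               pref_allele_mat = pr_m, pref_allele_pat = pr_p,
               viability = viab, preference = pref, signal = sig,
               pregnant = preg, gestation = gest,
               mate_viab_mat = stored(), mate_viab_pat = stored(),
               mate_pref_mat = stored(), mate_pref_pat = stored(),
               id = seq_len(n))
  new_state(pop, t = 0, disruption = 0, next_id = n + 1)
}

#' Disruption schedule
#'
#' Derives the run schedule from a parameter set. The disruption window opens
#' at the end of the burn-in (time-point A), stays at `disruption` for
#' `disruption_duration` steps, and closes at time-point B; recovery
#' time-points C1 and C2 follow `post_c1` and `post_c2` steps after B, and
#' the run ends at C2.
#'
#' @param p A `sim_params` object.
#' @return A `disruption_schedule` list with elements `burn_in`, `level`,
#'   `duration`, and the time-points `A`, `B`, `C1`, `C2`, plus `end`
#'   (`== C2`).
#' @export
disruption_schedule <- function(p) {
  validate_params(p)
  B <- p$burn_in + p$disruption_duration
  structure(list(burn_in = p$burn_in, level = p$disruption,
                 duration = p$disruption_duration,
                 A = p$burn_in, B = B, C1 = B + p$post_c1,
                 C2 = B + p$post_c2, end = B + p$post_c2),
            class = "disruption_schedule")
}

#' @export
print.disruption_schedule <- function(x, ...) {
  cat(sprintf("<disruption_schedule> level %g for steps [%d, %d); A=%d B=%d C1=%d C2=end=%d\n",
              x$level, x$A, x$B, x$A, x$B, x$C1, x$C2))
  invisible(x)
}

#' Disruption value at a time step
#'
#' Zero before the burn-in ends, the scheduled level while the window is
#' open, and zero again from time-point B onwards.
#'
#' @param t Step(s), non-negative.
#' @param sched A `disruption_schedule`.
#' @return Disruption value(s) in \[0, 1\].
#' @examples
#' sched <- disruption_schedule(sim_params(disruption = 0.5))
#' update_disruption(c(0, 20000, 20500), sched)
#' @export
update_disruption <- function(t, sched) {
  if (any(t < 0)) stop("'t' must be non-negative")
  ifelse(t >= sched$A & t < sched$B, sched$level, 0)
}

#' Ageing and death phase
#'
#' The juvenile count is cached once at phase start; juveniles survive with
#' [juvenile_survival_prob()], adults with [adult_survival_prob()]. Survivors
#' age one step; the dead are removed (a pregnant female's brood dies with
#' her).
#'
#' @param state A `sim_state`.
#' @param p A `sim_params` object.
#' @return The updated `sim_state` (clock unchanged; [sim_step()] advances it).
#' @export
ageing_and_death <- function(state, p) {
  state$pop <- .phase_ageing_death_cpp(state$pop, unclass(p))
  state
}

#' Reproduction phase
#'
#' Pregnant females at full term deliver a Poisson(`fecundity_lambda`) litter
#' (offspring sex 1:1, genomes by Mendelian transmission with mutation,
#' age 0); newborn males fix their signal with the state's current disruption
#' value. Mothers reset to non-pregnant with cleared mate alleles. Pregnant
#' females short of term advance gestation by one step.
#'
#' @inheritParams ageing_and_death
#' @param log_births If `TRUE`, a data frame of birth events (`t`,
#'   `mother_age`) is attached as `attr(state, "births")`.
#' @return The updated `sim_state`.
#' @export
reproduction <- function(state, p, log_births = FALSE) {
  res <- .phase_reproduction_cpp(state$pop, unclass(p), state$disruption,
                                 state$next_id, log_births,
                                 as.integer(state$t))
  state$pop <- res$pop
  state$next_id <- res$next_id
  if (log_births)
    attr(state, "births") <- data.frame(t = res$birth_t,
                                        mother_age = res$birth_age)
  state
}

#' Mating phase
#'
#' Each mature non-pregnant female mates with a male drawn uniformly from the
#' mature males whose signal is at least her preference (signal ties
#' included). With no acceptable male she forgoes mating this step — the
#' opportunity cost of choosiness. Males are not depleted: several females
#' may pick the same male. Mating sets `pregnant = 1`, `gestation = 1` and
#' stores the male's four alleles.
#'
#' @inheritParams ageing_and_death
#' @return The updated `sim_state`.
#' @export
mating <- function(state, p) {
  state$pop <- .phase_mating_cpp(state$pop, unclass(p))
  state
}

#' Advance the simulation one step
#'
#' Executes the four sub-models in their fixed order — disruption update,
#' ageing and death, reproduction, mating — then advances the clock.
#'
#' @inheritParams ageing_and_death
#' @param sched A `disruption_schedule` (defaults to the one implied by `p`).
#' @return The updated `sim_state` with `t` advanced by one.
#' @export
sim_step <- function(state, p, sched = disruption_schedule(p)) {
  state$disruption <- update_disruption(state$t, sched)
  state <- ageing_and_death(state, p)
  state <- reproduction(state, p)
  state <- mating(state, p)
  state$t <- as.integer(state$t) + 1L
  state
}

# Advance a state by many steps inside the compiled run loop. Consumes the
# RNG exactly as the equivalent sequence of sim_step() calls.
advance <- function(state, p, sched, n_steps, capture_at = integer(0),
                    log_births = FALSE) {
  t_end <- as.integer(state$t + n_steps)
  res <- .sim_run_cpp(state$pop, unclass(p), state$next_id,
                      as.integer(state$t), t_end, sched$burn_in, sched$level,
                      sched$duration, as.integer(capture_at), log_births)
  out <- new_state(res$pop, t = res$t, disruption = res$disruption,
                   next_id = res$next_id)
  attr(out, "extinct") <- res$extinct
  attr(out, "extinction_time") <- res$extinction_time
  attr(out, "records") <- res$records
  if (log_births)
    attr(out, "births") <- data.frame(t = res$birth_t,
                                      mother_age = res$birth_age)
  out
}
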