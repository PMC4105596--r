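# Shared fixtures. Long-horizon burn-in runs are computed once per test
# session and memoised, since several suites read the same established
# populations. Seeds are fixed constants derived from a single base.

.fixture_cache <- new.env(parent = emptyenv())

BURNIN_SEED_BASE <- 20260928

#' n memoised default-parameter burn-in runs (seeds derive_seed(base,0,0,i))
std_burnin_runs <- function(n) {
  runs <- get0("burnin_runs", envir = .fixture_cache, ifnotfound = list())
  if (length(runs) < n) {
    for (i in seq(length(runs) + 1, n)) {
      runs[[i]] <- run_burn_in(sim_params(),
                               seed = derive_seed(BURNIN_SEED_BASE, 0, 0, i),
                               log_births = (i == 1))
    }
    assign("burnin_runs", runs, envir = .fixture_cache)
  }
  runs[seq_len(n)]
}

# Small parameter set for fast structural tests: same biology, short horizon.
tiny_params <- function(...) {
  modify_params(sim_params(burn_in = 100, disruption_duration = 30,
                           post_c1 = 50, post_c2 = 150),
                ...)
}

in_unit <- function(x) all(x >= 0 & x <= 1)

#' Memoised reduced disruption grid: 3 levels x 3 durations x 20 replicates,
#' same seeds at both preference-mutation settings.
std_reduced_grid <- function(pm) {
  key <- paste0("grid_", pm)
  tab <- get0(key, envir = .fixture_cache, ifnotfound = NULL)
  if (is.null(tab)) {
    spec <- sweep_spec(disruption_levels = c(0.1, 0.4, 0.7),
                       durations = c(500, 2000, 5000),
                       replicates = 20, preference_mutation = pm,
                       seed_base = BURNIN_SEED_BASE)
    tab <- run_sweep(spec)
    assign(key, tab, envir = .fixture_cache)
  }
  tab
}

# A deterministic adult population: all columns valid, nobody pregnant.
adult_state <- function(n, sex = rep(c(1, 0), length.out = n), age = 100,
                        viab_allele = 0.8, pref_allele = 0.5,
                        signal = NULL, t = 0, disruption = 0) {
  df <- data.frame(sex = sex, age = age,
                   viab_allele_mat = viab_allele, viab_allele_pat = viab_allele,
                   pref_allele_mat = pref_allele, pref_allele_pat = pref_allele)
  if (!is.null(signal)) df$signal <- signal
  make_state(df, t = t, disruption = disruption)
}
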