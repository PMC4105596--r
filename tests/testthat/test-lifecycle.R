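test_that("initialization produces the specified founder composition", {
  p <- sim_params()
  set.seed(10)
  state <- initialize_population(p)
  pop <- state$pop
  expect_equal(nrow(pop), 150)
  expect_equal(sum(pop[, "sex"] == 1), 75)
  expect_equal(sum(pop[, "sex"] == 0), 75)
  expect_true(all(pop[, "pregnant"][pop[, "sex"] == 1] == 0))
  immature_f <- pop[, "sex"] == 0 & pop[, "age"] <= p$maturity_age
  expect_true(all(pop[immature_f, "pregnant"] == 0))
  preg <- pop[, "pregnant"] == 1
  expect_true(all(pop[preg, "gestation"] >= 1 &
                  pop[preg, "gestation"] <= p$gestation_length))
  males <- pop[, "sex"] == 1
  expect_equal(pop[males, "signal"], pop[males, "viability"])  # honest at t = 0
  audit_state(state, p)
})

test_that("mean founder age matches the discrete-uniform draw", {
  p <- sim_params()
  set.seed(11)
  ages <- unlist(lapply(1:200, function(i) initialize_population(p)$pop[, "age"]))
  expect_lt(abs(mean(ages) - 500), 20)
  expect_true(all(ages == floor(ages)))
  expect_true(all(ages >= 0 & ages <= 1000))
})

test_that("the disruption schedule switches exactly at the window bounds", {
  p <- sim_params(disruption = 0.5, disruption_duration = 2000)
  sched <- disruption_schedule(p)
  expect_equal(update_disruption(0, sched), 0)
  expect_equal(update_disruption(19999, sched), 0)
  expect_equal(update_disruption(20000, sched), 0.5)
  expect_equal(update_disruption(21999, sched), 0.5)
  expect_equal(update_disruption(22000, sched), 0)
  expect_equal(sched$C1, sched$B + 10000)
  expect_equal(sched$C2, sched$B + 30000)
  expect_equal(sched$end, sched$C2)
})

test_that("juveniles all die when the snapshot count reaches carrying capacity", {
  p <- sim_params(carrying_capacity = 100)
  state <- adult_state(120, sex = rep(0, 120), age = 10)  # 120 juveniles
  set.seed(12)
  out <- ageing_and_death(state, p)
  expect_equal(nrow(out$pop), 0)
})

test_that("young high-viability adults face zero senescent mortality", {
  # hazard clamps at zero while age^2/senescence < viability_effect * viability
  p <- sim_params()
  state <- adult_state(500, age = 60, viab_allele = 0.8)
  set.seed(13)
  out <- ageing_and_death(state, p)
  expect_equal(nrow(out$pop), 500)
  expect_true(all(out$pop[, "age"] == 61))
})

test_that("realized adult mortality matches the survival curve", {
  p <- sim_params()
  n <- 1e4
  ages <- sample(60:400, n, replace = TRUE)
  viab <- runif(n)
  state <- make_state(data.frame(sex = rep(1, n), age = ages,
                                 viab_allele_mat = viab, viab_allele_pat = viab))
  expected <- mean(1 - adult_survival_prob(ages, viab, p$viability_effect,
                                           p$senescence))
  set.seed(14)
  out <- ageing_and_death(state, p)
  realized <- 1 - nrow(out$pop) / n
  sigma <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(realized - expected), 4 * sigma)
})

test_that("litter size and offspring sex ratio follow the fecundity model", {
  p <- sim_params()
  n <- 1e5
  mothers <- data.frame(sex = rep(0, n), age = 100, pregnant = 1,
                        gestation = p$gestation_length,
                        mate_viab_mat = 0.5, mate_viab_pat = 0.5,
                        mate_pref_mat = 0.5, mate_pref_pat = 0.5)
  state <- make_state(mothers)
  set.seed(15)
  out <- reproduction(state, p)
  newborn <- out$pop[out$pop[, "age"] == 0, , drop = FALSE]
  expect_lt(abs(nrow(newborn) / n - 6), 0.03)      # Poisson-mean oracle
  expect_lt(abs(mean(newborn[, "sex"]) - 0.5), 0.007)  # binomial oracle
  # mothers reset
  mothers_after <- out$pop[out$pop[, "age"] > 0, ]
  expect_true(all(mothers_after[, "pregnant"] == 0))
  expect_true(all(is.na(mothers_after[, "mate_viab_mat"])))
})

test_that("gestation short of term increments without a birth", {
  p <- sim_params()
  state <- make_state(data.frame(sex = 0, age = 100, pregnant = 1,
                                 gestation = 5,
                                 mate_viab_mat = 0.5, mate_viab_pat = 0.5,
                                 mate_pref_mat = 0.5, mate_pref_pat = 0.5))
  out <- reproduction(state, p)
  expect_equal(nrow(out$pop), 1)
  expect_equal(unname(out$pop[1, "gestation"]), 6)
  expect_equal(unname(out$pop[1, "pregnant"]), 1)
})

test_that("newborn males fix their signal with the current disruption", {
  p <- sim_params()
  state <- make_state(data.frame(sex = rep(0, 50), age = 100, pregnant = 1,
                                 gestation = p$gestation_length,
                                 mate_viab_mat = 0.5, mate_viab_pat = 0.5,
                                 mate_pref_mat = 0.5, mate_pref_pat = 0.5),
                      disruption = 0.4)
  set.seed(16)
  out <- reproduction(state, p)
  sons <- out$pop[out$pop[, "age"] == 0 & out$pop[, "sex"] == 1, , drop = FALSE]
  expect_gt(nrow(sons), 0)
  expect_equal(sons[, "signal"], sons[, "viability"] * (1 - 0.4))
})

test_that("females pick uniformly among acceptable males and skip when none", {
  p <- sim_params()
  n_f <- 1e4
  state <- make_state(data.frame(
    sex = c(1, 1, 1, rep(0, n_f)),
    age = 100,
    viab_allele_mat = c(0.4, 0.6, 0.7, rep(0.5, n_f)),
    viab_allele_pat = c(0.4, 0.6, 0.7, rep(0.5, n_f)),
    pref_allele_mat = 0.5, pref_allele_pat = 0.5))
  # male signals are 0.4 / 0.6 / 0.7; female preference is 0.5
  set.seed(17)
  out <- mating(state, p)
  mated <- out$pop[out$pop[, "sex"] == 0 & out$pop[, "pregnant"] == 1, ]
  expect_equal(nrow(mated), n_f)
  expect_true(all(mated[, "gestation"] == 1))
  chosen <- mated[, "mate_viab_mat"]
  expect_true(all(chosen %in% c(0.6, 0.7)))  # 0.4-male is never acceptable
  expect_lt(abs(mean(chosen == 0.6) - 0.5), 0.02)  # uniform-choice oracle

  # no acceptable male: preference above every signal
  lonely <- make_state(data.frame(
    sex = c(1, 0), age = 100,
    viab_allele_mat = c(0.3, 0.5), viab_allele_pat = c(0.3, 0.5),
    pref_allele_mat = c(0.5, 0.9), pref_allele_pat = c(0.5, 0.9)))
  out2 <- mating(lonely, p)
  expect_equal(sum(out2$pop[, "pregnant"]), 0)

  # preference zero: every mature male is acceptable, immature males are not
  open <- make_state(data.frame(
    sex = c(1, 1, 0), age = c(100, 10, 100),
    viab_allele_mat = 0.01, viab_allele_pat = 0.01,
    pref_allele_mat = 0, pref_allele_pat = 0))
  set.seed(18)
  out3 <- mating(open, p)
  f <- out3$pop[, "sex"] == 0
  expect_equal(unname(out3$pop[f, "pregnant"]), 1)
})

test_that("a step advances the clock and an empty population stays empty", {
  p <- sim_params()
  sched <- disruption_schedule(p)
  empty <- make_state(data.frame(sex = numeric(0), age = numeric(0)))
  out <- sim_step(empty, p, sched)
  expect_equal(nrow(out$pop), 0)
  expect_equal(out$t, 1)
})

test_that("a lone female without males never reproduces", {
  p <- sim_params()
  sched <- disruption_schedule(p)
  state <- adult_state(1, sex = 0, age = 70)
  set.seed(19)
  for (k in 1:50) state <- sim_step(state, p, sched)
  expect_equal(sum(state$pop[, "pregnant"]), 0)
  expect_equal(sum(state$pop[, "age"] == 0), 0)
})

test_that("deaths precede births within a step: newborns are safe at capacity", {
  p <- sim_params(carrying_capacity = 50)
  df <- data.frame(sex = c(rep(1, 60), rep(0, 5)),
                   age = c(rep(10, 60), rep(100, 5)),
                   pregnant = c(rep(0, 60), rep(1, 5)),
                   gestation = c(rep(0, 60), rep(p$gestation_length, 5)),
                   mate_viab_mat = 0.5, mate_viab_pat = 0.5,
                   mate_pref_mat = 0.5, mate_pref_pat = 0.5)
  state <- make_state(df)
  old_ids <- state$pop[state$pop[, "age"] < p$maturity_age, "id"]
  set.seed(20)
  out <- sim_step(state, p, disruption_schedule(p))
  # every standing juvenile died (count was over capacity at phase start) ...
  expect_false(any(out$pop[, "id"] %in% old_ids))
  # ... while the litters delivered later in the same step are untouched
  newborn <- out$pop[out$pop[, "age"] == 0, , drop = FALSE]
  expect_gt(nrow(newborn), 0)
})

test_that("a male's signal never changes after birth, even across disruption", {
  p <- tiny_params(disruption = 0.8)
  sched <- disruption_schedule(p)
  set.seed(21)
  state <- initialize_population(p)
  before <- state$pop[state$pop[, "sex"] == 1, c("id", "signal")]
  for (k in 1:110) state <- sim_step(state, p, sched)  # crosses onset at t=100
  after <- state$pop[state$pop[, "sex"] == 1, c("id", "signal")]
  shared <- intersect(before[, "id"], after[, "id"])
  expect_gt(length(shared), 0)
  expect_equal(after[match(shared, after[, "id"]), "signal"],
               before[match(shared, before[, "id"]), "signal"])
})

test_that("juvenile counts stay bounded below carrying capacity at equilibrium", {
  p <- sim_params()
  sched <- disruption_schedule(p)
  set.seed(22)
  state <- initialize_population(p)
  juv <- integer(0)
  for (k in 1:5000) {
    state <- sim_step(state, p, sched)
    juv[k] <- sum(state$pop[, "age"] < p$maturity_age)
  }
  tail_juv <- juv[2501:5000]
  expect_true(all(tail_juv < p$carrying_capacity))
  expect_gt(min(tail_juv), 0)
  expect_gt(sd(tail_juv), 0)  # fluctuates about a level rather than exploding
})

test_that("the compiled run loop and R-level stepping are bit-identical", {
  p <- tiny_params(disruption = 0.6)
  sched <- disruption_schedule(p)
  set.seed(23)
  s1 <- initialize_population(p)
  s1 <- matesim:::advance(s1, p, sched, 120)
  set.seed(23)
  s2 <- initialize_population(p)
  for (k in 1:120) s2 <- sim_step(s2, p, sched)
  expect_identical(s1$pop, s2$pop)
  expect_identical(s1$t, s2$t)
})

test_that("the wallflower trap drives a deterministic extinction", {
  # every female (and stored mate pair) carries preference alleles of 1 and
  # preference cannot mutate: no male signal ever reaches the threshold
  p <- sim_params(preference_mutation = 0, disruption = 0.5,
                  disruption_duration = 5000)
  set.seed(24)
  state <- initialize_population(p)
  state$pop[, c("pref_allele_mat", "pref_allele_pat")] <- 1
  state$pop[, "preference"] <- 1
  preg <- state$pop[, "pregnant"] == 1
  state$pop[preg, c("mate_pref_mat", "mate_pref_pat")] <- 1
  sched <- disruption_schedule(p)
  out <- matesim:::advance(state, p, sched, sched$end)
  expect_true(attr(out, "extinct"))
  expect_lt(attr(out, "extinction_time"), sched$end)
})
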