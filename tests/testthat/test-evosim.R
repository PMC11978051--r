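fast_mut <- mutation_params()
params0 <- model_params(100, 1, 0)

test_that("identical configuration and seed reproduce the trajectory bitwise", {
  run <- function() {
    run_simulation(list(m = 1, alpha = 0), params0, vance_model,
                   telegraph_schedule(fusion_env(0.5, "e1"),
                                      fusion_env(2.2, "e2"), 0.5, 50),
                   fast_mut, n_cycles = 2000, seed = 99)
  }
  a <- run()
  b <- run()
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$final, b$final)
  c <- run_simulation(list(m = 1, alpha = 0), params0, vance_model,
                      telegraph_schedule(fusion_env(0.5, "e1"),
                                         fusion_env(2.2, "e2"), 0.5, 50),
                      fast_mut, n_cycles = 2000, seed = 100)
  expect_false(identical(a$trajectory, c$trajectory))
})

test_that("a seed is mandatory", {
  expect_error(
    run_simulation(list(m = 1, alpha = 0), params0, vance_model,
                   fusion_env(1), fast_mut, n_cycles = 10),
    class = "fusevol_config_error")
})

test_that("mutation events arrive with geometric waiting times", {
  # alpha pinned: one trait process at rate mu; gaps between events should
  # be geometric with mean 1/mu
  mut <- mutation_params(mu = 0.05)
  sim <- run_simulation(list(m = 1, alpha = 0), params0, vance_model,
                        fusion_env(1), mut, n_cycles = 6e4, seed = 12,
                        evolve = "m", record_every = 1000)
  gaps <- diff(sim$events$mutation_cycles)
  expect_gt(length(gaps), 1000)
  expect_equal(mean(gaps), 1 / 0.05, tolerance = 0.1)
  # goodness of fit against the geometric law on binned gap lengths
  # (chi-squared handles the discreteness that trips up a plain KS test)
  breaks <- c(seq(1, 61, by = 5), Inf)
  obs <- table(cut(gaps, breaks, right = FALSE))
  # bin [a, b) holds gaps a..b-1, i.e. rgeom values a-1..b-2
  up <- stats::pgeom(breaks[-1] - 2, 0.05)
  lo <- stats::pgeom(breaks[-length(breaks)] - 2, 0.05)
  chi <- suppressWarnings(stats::chisq.test(as.numeric(obs), p = up - lo))
  expect_gt(chi$p.value, 0.01)
})

test_that("mutation proposals respect the trait boundaries", {
  mut <- mutation_params()
  # a minus proposal from alpha = 0 is discarded (no new genotype)
  pop <- population_state(m = 1, alpha = 0, f = 1)
  set.seed(1)
  n_after <- replicate(200, nrow(mutate_population(pop, mut, "alpha")))
  expect_true(all(n_after <= 2))
  expect_true(any(n_after == 1)) # minus proposals consumed
  expect_true(any(n_after == 2)) # plus proposals accepted
  # accepted mass mutants land exactly one step away
  set.seed(2)
  out <- mutate_population(pop, mut, "m")
  expect_true(all(vapply(abs(out$m - 1), function(d) {
    min(abs(d - c(0, mut$delta_m))) < 1e-12
  }, logical(1))))
  # plastic genotypes: exactly one of the four traits perturbed
  popp <- population_state(m1 = 1, alpha1 = 0.1, m2 = 1, alpha2 = 0.1, f = 1)
  set.seed(3)
  for (i in 1:50) {
    out <- mutate_population(popp, mut,
                             c("m1", "alpha1", "m2", "alpha2"))
    if (nrow(out) == 2) {
      changed <- abs(unlist(out[2, 1:4]) - unlist(popp[1, 1:4])) > 1e-15
      expect_identical(sum(changed), 1L)
    }
  }
})

test_that("coincident genotypes are merged", {
  pop <- population_state(m = c(1, 1 + 2e-13), alpha = c(0, 0),
                          f = c(0.5, 0.5))
  res <- fusevol:::merge_genotypes(as.matrix(pop[, 1:2]), pop$f)
  expect_identical(nrow(res$traits), 1L)
  expect_equal(sum(res$f), 1)
})

test_that("environment schedules drive the simulator as declared", {
  e1 <- fusion_env(0.5, "env1")
  e2 <- fusion_env(2.2, "env2")
  # scheduled: env1 strictly before the switch cycle, env2 after
  sched <- env_schedule(e1, e2, mode = "scheduled", switch_cycles = 500)
  sim <- run_simulation(list(m = 1, alpha = 0), params0, vance_model, sched,
                        fast_mut, n_cycles = 1000, seed = 5, evolve = "m")
  tr <- sim$trajectory
  expect_true(all(tr$env[tr$cycle < 500] == "env1"))
  expect_true(all(tr$env[tr$cycle >= 500] == "env2"))
  # symmetric telegraph occupancy ~ 1/2
  ts <- env_schedule(e1, e2, mode = "telegraph", lambda_12 = 0.01,
                     lambda_21 = 0.01)
  set.seed(8)
  state <- 1L
  occ <- integer(2e4)
  for (i in seq_along(occ)) {
    state <- environment_step(ts, i, state)
    occ[i] <- state
  }
  expect_equal(mean(occ == 1L), 0.5, tolerance = 0.05)
  # asymmetric telegraph hits its target occupancy over a long horizon
  ts7 <- telegraph_schedule(e1, e2, p1 = 0.7, tau1 = 70)
  state <- 1L
  n1 <- 0
  for (i in 1:2e5) {
    state <- environment_step(ts7, i, state)
    if (state == 1L) n1 <- n1 + 1
  }
  expect_equal(n1 / 2e5, 0.7, tolerance = 0.01)
})

test_that("trait means stay within the extant trait hull and cycles increase", {
  sim <- run_simulation(list(m = 1, alpha = 0), params0, vance_model,
                        fusion_env(1.5), fast_mut, n_cycles = 3000, seed = 2)
  tr <- sim$trajectory
  expect_true(all(diff(tr$cycle) > 0))
  expect_true(all(tr$mean_m > 0))
  expect_true(all(tr$var_m >= -1e-12))
  expect_true(all(tr$survival_fraction >= 0 & tr$survival_fraction <= 1))
})

test_that("ESS estimation averages the stationary window", {
  # constant trajectory: exact mean, zero sd
  sim <- list(trajectory = tibble::tibble(cycle = 1:100, env = "e",
                                          n_genotypes = 1,
                                          mean_m = 1.5, var_m = 0,
                                          survival_fraction = 0.5))
  class(sim) <- "fusion_sim"
  ess <- estimate_ess(sim)
  expect_equal(ess$mean, 1.5)
  expect_equal(ess$sd, 0)
  expect_true(ess$stationary)
  # drifting trajectory flags non-stationarity
  sim$trajectory$mean_m <- seq(0, 10, length.out = 100)
  expect_warning(estimate_ess(sim), class = "fusevol_nonstationary")
  expect_error(estimate_ess(sim, burn_in_fraction = 0.999),
               class = "fusevol_domain_error")
})

test_that("simulated drift direction follows the selection gradient", {
  # far from the optimum the mean mass must move towards it
  sim <- run_simulation(list(m = 0.4, alpha = 0), params0, vance_model,
                        fusion_env(1.5), fast_mut, n_cycles = 2e4, seed = 17,
                        evolve = "m", record_every = 100)
  tr <- sim$trajectory
  p <- ad_params(1.5, 0, 100, 1)
  checkpoints <- seq(1, nrow(tr) - 10, length.out = 20)
  agree <- 0
  strong <- 0
  for (i in round(checkpoints)) {
    g <- gradient_m(tr$mean_m[i], 0, p)
    drift <- tr$mean_m[i + 10] - tr$mean_m[i]
    if (abs(g) > 0.2) {
      strong <- strong + 1
      if (sign(drift) == sign(g)) agree <- agree + 1
    }
  }
  expect_gt(strong, 5)
  expect_gte(agree / strong, 0.8)
})

test_that("the simulator recovers the fixed-environment optimum mass", {
  # short parameter-recovery run; the full protocol lives with the
  # acceptance checks
  sim <- run_simulation(list(m = 0.9, alpha = 0), params0, vance_model,
                        fusion_env(0.7), fast_mut, n_cycles = 4e4, seed = 23,
                        evolve = "m", record_every = 10)
  ess <- estimate_ess(sim, burn_in_fraction = 0.5)
  expect_equal(ess$mean[ess$trait == "m"], 0.7, tolerance = 0.1)
})

test_that("extinction terminates the run with a flagged record", {
  tl <- survival_model("threshold_linear", m_min = 5)
  sim <- run_simulation(list(m = 1, alpha = 0), params0, tl, fusion_env(1),
                        fast_mut, n_cycles = 100, seed = 1, evolve = "m")
  expect_equal(sim$status, "extinct")
  expect_lt(nrow(sim$trajectory), 100)
})

test_that("the genotype cap raises a configuration error", {
  mut <- mutation_params(mu = 0.5, prune_threshold = 0)
  expect_error(
    run_simulation(list(m = 1, alpha = 0), params0, vance_model,
                   fusion_env(1), mut, n_cycles = 1e4, seed = 4,
                   evolve = "m", max_genotypes = 3L),
    class = "fusevol_config_error")
})
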