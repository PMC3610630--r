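test_that("configuration validation rejects invalid probabilities", {
  expect_error(abm_config(m = 1.5))
  expect_error(abm_config(growth = growth_law(g0 = 3, K = 1, nstar = 0.2)),
               "probabilities")
  expect_error(abm_config(growth = growth_law(g0 = 0.2, K = 2, nstar = 0.2)),
               "K must be 1")
})

test_that("with no migration and silent demography the state is invariant", {
  cfg <- abm_config(n_sites = 20, N = 10, m = 0,
                    growth = growth_law(g0 = 0.2, K = 1, nstar = 0.2),
                    birth_prob = function(rho, f) 0,
                    death_prob = function(rho, f) 0)
  st <- abm_init(cfg, fraction = 0.5, f0 = 0.4)
  set.seed(1)
  st2 <- st
  for (k in 1:50) st2 <- abm_step(st2, cfg)
  expect_identical(st2$coop, st$coop)
  expect_identical(st2$def, st$def)
})

test_that("an all-cooperator site only ever produces cooperators", {
  cfg <- abm_config(n_sites = 10, N = 20, m = 0)
  st <- abm_init(cfg, fraction = 1, f0 = 0)
  set.seed(2)
  for (k in 1:200) st <- abm_step(st, cfg)
  expect_true(all(st$def == 0))
  expect_gt(sum(st$coop), 0)
})

test_that("demographic events change a site total by at most one", {
  cfg <- abm_config(n_sites = 6, N = 15, m = 0)
  st <- abm_init(cfg, fraction = 1, f0 = 0.3)
  set.seed(3)
  for (k in 1:100) {
    st2 <- abm_step(st, cfg)
    dn <- (st2$coop + st2$def) - (st$coop + st$def)
    expect_true(all(abs(dn) <= 1))
    st <- st2
  }
})

test_that("migration conserves the total population exactly", {
  cfg <- abm_config(n_sites = 30, N = 12, m = 1,
                    birth_prob = function(rho, f) 0,
                    death_prob = function(rho, f) 0)
  st <- abm_init(cfg, fraction = 0.5, f0 = 0.5)
  tot0 <- sum(st$coop) + sum(st$def)
  ctot0 <- sum(st$coop)
  set.seed(4)
  for (k in 1:100) st <- abm_step(st, cfg)
  expect_equal(sum(st$coop) + sum(st$def), tot0)
  expect_equal(sum(st$coop), ctot0)   # composition untouched by migration
})

test_that("interaction matrix reproduces the linear selection difference", {
  sl <- selection_law(s = 0.2, f_high = 0.4, f_low = -0.5, n_c = 0.3)
  for (n in c(0.1, 0.8)) {
    A <- interaction_matrix(sl, n)
    for (f in c(0, 0.3, 0.9)) {
      piC <- A["C", "C"] * (1 - f) + A["C", "D"] * f
      piD <- A["D", "C"] * (1 - f) + A["D", "D"] * f
      expect_equal(piD - piC, 0.2 * (sl$fstar(n) - f), tolerance = 1e-12)
    }
  }
})

test_that("single-site density fluctuates around the stable fixed point", {
  # the birth-death drift g0 rho (1-rho)(rho-rho*) has stable equilibrium
  # rho = 1; the long-run mean density should sit near it
  cfg <- abm_config(n_sites = 2, N = 100, m = 0,
                    growth = growth_law(g0 = 0.25, K = 1, nstar = 0.2),
                    selection = selection_law(s = 0))
  st <- abm_init(cfg, fraction = 1, f0 = 0)
  set.seed(6)
  # burn-in, then time-average
  out <- abm_advance(st$coop, st$def, 200 * cfg$N, cfg$N, 0, 0.25, 0.2, 0,
                     0, 0.3, 0, 0.35, FALSE)
  dens <- numeric(300)
  for (k in seq_along(dens)) {
    out <- abm_advance(out$coop, out$def, 10 * cfg$N, cfg$N, 0, 0.25, 0.2, 0,
                       0, 0.3, 0, 0.35, FALSE)
    dens[k] <- out$coop[1] / cfg$N
  }
  expect_equal(mean(dens), 1, tolerance = 0.05)
})

test_that("compiled and reference steppers agree in distribution", {
  # same moments of the single-site demographic chain under matched laws
  cfg <- abm_config(n_sites = 2, N = 30, m = 0,
                    growth = growth_law(g0 = 0.25, K = 1, nstar = 0.2),
                    selection = selection_law(s = 0.1, f_high = 0.3,
                                              f_low = -1, n_c = 0.35))
  run_mean <- function(stepper) {
    st <- abm_init(cfg, fraction = 1, f0 = 0.3)
    acc <- 0
    for (k in 1:2000) { st <- stepper(st); acc <- acc + st$coop[1] + st$def[1] }
    acc / 2000
  }
  set.seed(8)
  m_r <- run_mean(function(st) abm_step(st, cfg))
  set.seed(8)
  m_c <- run_mean(function(st) {
    out <- abm_advance(st$coop, st$def, 1L, cfg$N, cfg$m, 0.25, 0.2, 0,
                       0.1, 0.3, -1, 0.35, FALSE)
    structure(list(coop = out$coop, def = out$def,
                   generation = st$generation), class = "abm_state")
  })
  expect_equal(m_r, m_c, tolerance = 0.05)
})

test_that("zero growth produces no systematic front advance", {
  cfg <- abm_config(n_sites = 60, N = 15, m = 0.5,
                    growth = growth_law(g0 = 0, K = 1, nstar = 0.2),
                    selection = selection_law(s = 0))
  set.seed(10)
  vs <- replicate(5, {
    run <- run_abm(cfg, abm_init(cfg, fraction = 0.4, f0 = 0),
                   max_generations = 150, record_every = 5,
                   stop_fraction = 2)
    estimate_velocity(run$trace, window = 1)$v
  })
  expect_lt(abs(mean(vs)), 0.02)
})

test_that("large-capacity fronts approach the matched PDE speed", {
  cfg <- abm_config(n_sites = 260, N = 120, m = 0.5,
                    growth = growth_law(g0 = 0.2, K = 1, nstar = 0.2),
                    selection = selection_law(s = 0))
  set.seed(12)
  run <- run_abm(cfg, abm_init(cfg, fraction = 0.12, f0 = 0),
                 max_generations = 1500, record_every = 10,
                 stop_fraction = 0.9)
  v <- estimate_velocity(run$trace, window = 1/2)$v
  vC <- sqrt((cfg$m / 2) * 0.2 / 2) * (1 - 2 * 0.2)
  expect_lt(abs(v - vC) / vC, 0.1)
})

test_that("a deterministic-splitting preset splits in every replicate", {
  cfg <- abm_config(n_sites = 200, N = 40, m = 0.5,
                    growth = growth_law(g0 = 0.2, K = 1, nstar = 0.2,
                                        nstar_slope = 0.3),
                    selection = selection_law(s = 0.08, f_high = 0.3,
                                              f_low = -1, n_c = 0.8))
  set.seed(14)
  for (r in 1:3) {
    run <- run_abm(cfg, abm_init(cfg, 0.15), max_generations = 1200,
                   record_every = 5, stop_fraction = 2)
    expect_false(is.na(detect_stochastic_split(run$trace, config = cfg)))
  }
})

test_that("split detection works on constructed traces and is cadence-stable", {
  mk_trace <- function(tt, lag) structure(
    data.frame(t = tt, x_coop = 50 + 0.1 * tt, x_def = 50 + 0.1 * tt - lag,
               lag = lag),
    class = c("front_trace", "data.frame"))
  tt <- seq(0, 1000, by = 5)
  # defectors pinned to the front: no split
  expect_true(is.na(detect_stochastic_split(mk_trace(tt, rep(2, length(tt))),
                                            width_threshold = 15)))
  # linearly opening gap crosses the threshold at t = 300
  lag <- pmax(0, 0.05 * (tt - 0))
  t_det <- detect_stochastic_split(mk_trace(tt, lag), width_threshold = 15)
  expect_equal(t_det, 300, tolerance = 5)
  # same replicate re-analyzed at twice the cadence: same detection time
  cfg <- presets("abm_stochastic")
  set.seed(16)
  run1 <- run_abm(cfg, abm_init(cfg, 0.15), max_generations = 800,
                  record_every = 5, stop_fraction = 2)
  set.seed(16)
  run2 <- run_abm(cfg, abm_init(cfg, 0.15), max_generations = 800,
                  record_every = 2.5, stop_fraction = 2)
  t1 <- detect_stochastic_split(run1$trace, config = cfg)
  t2 <- detect_stochastic_split(run2$trace, config = cfg)
  if (!is.na(t1) && !is.na(t2)) expect_lt(abs(t1 - t2), 6)
  else expect_equal(is.na(t1), is.na(t2))
})

test_that("the waiting-time experiment is reproducible under a fixed seed", {
  cfg <- presets("abm_stochastic")
  set.seed(31)
  a <- splitting_time_experiment(cfg, N_values = 8, replicates = 4,
                                 max_generations = 600)
  set.seed(31)
  b <- splitting_time_experiment(cfg, N_values = 8, replicates = 4,
                                 max_generations = 600)
  expect_identical(a, b)
  expect_true(all(c("N", "m", "mean_T", "sem", "n_split", "n_censored",
                    "all_censored") %in% names(a)))
})
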