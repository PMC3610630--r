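test_that("expansion velocity: stall at the symmetric cubic and diffusion scaling", {
  p_half <- model_params(growth = growth_law(nstar = 0.5))
  expect_equal(expansion_velocity(p_half)$v, 0)
  p1 <- model_params(D = 1, growth = growth_law(nstar = 0.2))
  p2 <- model_params(D = 2, growth = growth_law(nstar = 0.2))
  expect_equal(expansion_velocity(p2)$v / expansion_velocity(p1)$v, sqrt(2))
})

test_that("expansion velocity is strictly decreasing in the Allee threshold", {
  vs <- vapply(seq(0, 0.45, by = 0.05), function(ns)
    expansion_velocity(model_params(growth = growth_law(nstar = ns)))$v, 0)
  expect_true(all(diff(vs) < 0))
})

test_that("pushed and pulled regimes join continuously at nstar = -K/2", {
  v_at <- function(ns) expansion_velocity(
    model_params(growth = growth_law(nstar = ns)))
  expect_equal(v_at(-0.5 + 1e-9)$regime, "pushed")
  expect_equal(v_at(-0.5 - 1e-9)$regime, "pulled")
  expect_equal(v_at(-0.5 + 1e-9)$v, v_at(-0.5 - 1e-9)$v, tolerance = 1e-6)
})

test_that("front profile has the stated limits, centering, and width scaling", {
  p <- model_params(growth = growth_law(g0 = 1.5, K = 0.8, nstar = 0.2))
  expect_equal(as.numeric(front_profile(-50, p)), 0.8, tolerance = 1e-10)
  expect_equal(as.numeric(front_profile(50, p)), 0, tolerance = 1e-10)
  expect_equal(as.numeric(front_profile(0, p)), 0.4)
  w1 <- front_width(model_params(growth = growth_law(g0 = 1)))
  w2 <- front_width(model_params(growth = growth_law(g0 = 0.5)))
  expect_equal(w2 / w1, sqrt(2))
})

test_that("the exact profile satisfies the comoving steady state equation", {
  p <- model_params(D = 1.3, growth = growth_law(g0 = 0.8, K = 1.1,
                                                 nstar = 0.3))
  v <- expansion_velocity(p)$v
  w <- front_width(p)
  dz <- 0.005 * w
  z <- seq(-8 * w, 8 * w, by = dz)
  u <- as.numeric(front_profile(z, p))
  m <- length(z)
  i <- 3:(m - 2)
  # 5-point stencils (4th order) keep the discretization error below 1e-8
  upp <- (-u[i + 2] + 16 * u[i + 1] - 30 * u[i] + 16 * u[i - 1] - u[i - 2]) /
    (12 * dz^2)
  up <- (-u[i + 2] + 8 * u[i + 1] - 8 * u[i - 1] + u[i - 2]) / (12 * dz)
  res <- p$D * upp + v * up + u[i] * p$growth$g(u[i], 0)
  expect_lt(max(abs(res)), 1e-8)
})

test_that("invasion velocity: zero selection, diffusion scaling, non-invadable flag", {
  mk <- function(D, s, f_low = 0.3) model_params(D = D,
    growth = growth_law(nstar = 0.2),
    selection = selection_law(s = max(s, 1e-12), f_high = 0.3,
                              f_low = f_low, n_c = 0.1))
  expect_equal(invasion_velocity(model_params(
    selection = selection_law(s = 0)))$v, 0)
  expect_false(invasion_velocity(model_params(
    selection = selection_law(s = 0)))$invades)
  expect_equal(invasion_velocity(mk(4, 0.1))$v / invasion_velocity(mk(1, 0.1))$v,
               2)
  # fstar <= 0 at the bulk: defectors cannot invade
  p_neg <- model_params(growth = growth_law(nstar = 0.2),
    selection = selection_law(s = 0.1, f_high = 0.3, f_low = -0.4, n_c = 2))
  expect_false(invasion_velocity(p_neg)$invades)
  expect_equal(invasion_velocity(p_neg)$v, 0)
})

test_that("decoupled mixed velocity reduces to the expansion velocity", {
  # growth independent of f: the preferred frequency drops out
  p <- model_params(growth = growth_law(nstar = 0.2),
                    selection = selection_law(s = 0.1, f_high = 0.3,
                                              f_low = 0.3))
  expect_equal(mixed_velocity_decoupled(p)$v, expansion_velocity(p, 0)$v)
  # f-dependent growth: v_M < v_C when the Allee threshold worsens with f
  p2 <- decoupled_params(0.3)
  expect_lt(mixed_velocity_decoupled(p2)$v, expansion_velocity(p2, 0)$v)
  expect_equal(mixed_velocity_decoupled(p2)$v,
               expansion_velocity(p2, 0.3)$v)
  expect_error(mixed_velocity_decoupled(default_params()),
               "density-independent")
})

test_that("velocities are invariant under nondimensional rescaling", {
  # x -> x/c, t -> t/tau leaves physics fixed if D -> D c^2/tau and
  # rates -> rates/tau; velocities must then scale by c/tau exactly
  cc <- 2.5; tau <- 3
  p <- model_params(D = 1, growth = growth_law(g0 = 1, nstar = 0.2),
                    selection = selection_law(s = 0.04, f_high = 0.3,
                                              f_low = 0.3))
  ps <- model_params(D = cc^2 / tau,
                     growth = growth_law(g0 = 1 / tau, nstar = 0.2),
                     selection = selection_law(s = 0.04 / tau, f_high = 0.3,
                                               f_low = 0.3))
  expect_equal(expansion_velocity(ps)$v,
               (cc / tau) * expansion_velocity(p)$v, tolerance = 1e-12)
  expect_equal(invasion_velocity(ps)$v,
               (cc / tau) * invasion_velocity(p)$v, tolerance = 1e-12)
})

test_that("hypergeometric evaluation matches closed forms", {
  y <- c(0.05, 0.3, 0.65, 0.9, 0.99)
  expect_equal(hyp2f1(1, 1, 2, y), -log(1 - y) / y, tolerance = 1e-12)
  expect_equal(hyp2f1(0.7, 1.4, 1.4, y), (1 - y)^(-0.7), tolerance = 1e-12)
  expect_equal(hyp2f1(-2, 1.5, 1.1, y),
               1 - 2 * 1.5 / 1.1 * y + (1.5 * 2.5) / (1.1 * 2.1) * y^2,
               tolerance = 1e-12)
})

test_that("exact splitting threshold: forced-mixed regime and monotone flip", {
  mk <- function(n_c, s = 0.05) model_params(
    growth = growth_law(g0 = 1, K = 1, nstar = 0.05),
    selection = selection_law(s = s, f_high = 0.5, f_low = 0, n_c = n_c,
                              nonviable_below_nc = TRUE))
  # defectors at least as fast as cooperators: never splits
  fast <- model_params(growth = growth_law(nstar = 0.45),
    selection = selection_law(s = 0.5, f_high = 0.9, n_c = 0.3,
                              nonviable_below_nc = TRUE))
  res <- splitting_threshold_exact(fast)
  expect_false(res$splits)
  expect_equal(res$margin, -Inf)
  # verdict flips as n_c crosses the critical density
  crit <- splitting_threshold_exact(mk(0.05))$n_c_crit
  expect_false(splitting_threshold_exact(mk(crit - 0.01))$splits)
  expect_true(splitting_threshold_exact(mk(crit + 0.01))$splits)
  expect_lt(splitting_threshold_exact(mk(crit - 0.01))$margin, 0)
  expect_gt(splitting_threshold_exact(mk(crit + 0.01))$margin, 0)
})

test_that("severity of required selection grows as v_D approaches v_C", {
  # raising s (hence v_D) toward v_C pushes the critical density toward K
  crit_at <- function(s) splitting_threshold_exact(model_params(
    growth = growth_law(g0 = 1, K = 1, nstar = 0.05),
    selection = selection_law(s = s, f_high = 0.5, f_low = 0, n_c = 0.5,
                              nonviable_below_nc = TRUE)))$n_c_crit
  crits <- vapply(c(0.02, 0.08, 0.14, 0.19), crit_at, 0)
  expect_true(all(diff(crits) > 0))
})

test_that("exact threshold requires the special case", {
  expect_error(splitting_threshold_exact(default_params()), "special case")
  p <- model_params(growth = growth_law(nstar = 0.2, nstar_slope = 0.3),
    selection = selection_law(s = 0.05, f_high = 0.5, n_c = 0.3,
                              nonviable_below_nc = TRUE))
  expect_error(splitting_threshold_exact(p), "frequency-independent")
})
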