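test_that("grid construction enforces the explicit stability bound", {
  p <- model_params()
  g <- wave_grid(L = 10, params = p)
  expect_lte(g$dt, g$dx^2 / (2 * p$D))
  expect_error(wave_grid(L = 10, dx = 0.1, dt = 0.01, params = p),
               "stability bound")
  expect_equal(g$nx, round(g$L / g$dx))
})

test_that("a uniform equilibrium state is a fixed point of the stepper", {
  p <- decoupled_params(0.3)
  g <- wave_grid(L = 5, dx = 0.1, params = p)
  Kf <- p$growth$K(0.3)
  st <- structure(list(t = 0, c = rep(Kf * 0.7, g$nx),
                       d = rep(Kf * 0.3, g$nx)), class = "wave_state")
  st2 <- ftcs_step(st, p, g)
  expect_equal(st2$c, st$c, tolerance = 1e-13)
  expect_equal(st2$d, st$d, tolerance = 1e-13)
})

test_that("pure diffusion conserves total mass under no-flux boundaries", {
  p <- model_params(growth = growth_law(g0 = 0, nstar = 0.2),
                    selection = selection_law(s = 0))
  g <- wave_grid(L = 10, dx = 0.1, params = p)
  set.seed(5)
  st <- structure(list(t = 0, c = runif(g$nx), d = runif(g$nx)),
                  class = "wave_state")
  mass0 <- sum(st$c + st$d) * g$dx
  for (k in 1:200) st <- ftcs_step(st, p, g)
  expect_equal(sum(st$c + st$d) * g$dx, mass0, tolerance = 1e-12)
})

test_that("one step matches a dense-matrix implementation of the stencil", {
  p <- default_params()
  g <- wave_grid(L = 4, dx = 0.1, params = p)
  nx <- g$nx
  # dense one-step operator: I + dt D L with reflecting ghost cells
  L <- diag(-2, nx); L[cbind(1:(nx - 1), 2:nx)] <- 1
  L[cbind(2:nx, 1:(nx - 1))] <- 1
  L[1, 1] <- -1; L[nx, nx] <- -1
  L <- L / g$dx^2
  set.seed(9)
  cc <- runif(nx, 0, 1); d <- runif(nx, 0, 0.5)
  st <- structure(list(t = 0, c = cc, d = d), class = "wave_state")
  st2 <- ftcs_step(st, p, g)
  r <- local_rates_cd(cc, d, p)
  expect_equal(st2$c, cc + g$dt * (p$D * as.numeric(L %*% cc) + r$dc_dt),
               tolerance = 1e-13)
  expect_equal(st2$d, d + g$dt * (p$D * as.numeric(L %*% d) + r$dd_dt),
               tolerance = 1e-13)
})

test_that("compiled and reference engines advance identically", {
  p <- default_params()
  g <- wave_grid(L = 30, dx = 0.2, params = p)
  init <- initial_condition("occupied_left_fraction", fraction = 0.3)
  r_cpp <- run_wave(p, g, init, max_time = 2, stop_fraction = 0.99,
                    engine = "cpp", record_every = 2)
  r_ref <- run_wave(p, g, init, max_time = 2, stop_fraction = 0.99,
                    engine = "r", record_every = 2)
  expect_equal(r_cpp$state$c, r_ref$state$c, tolerance = 1e-12)
  expect_equal(r_cpp$state$d, r_ref$state$d, tolerance = 1e-12)
})

test_that("front position: step profile, empty habitat, and root-finding oracle", {
  p <- model_params()
  g <- wave_grid(L = 10, dx = 0.05, params = p)
  step_prof <- ifelse(g$x < 5, 1, 0)
  expect_lt(abs(front_position(step_prof, g) - 5), g$dx)
  expect_true(is.na(front_position(rep(0, g$nx), g)))
  # logistic profile: compare with bisection on the interpolant
  prof <- 1 / (1 + exp((g$x - 6) / 0.4))
  xf <- front_position(prof, g)
  interp <- function(x) approx(g$x, prof, xout = x)$y - 0.5
  root <- uniroot(interp, c(4, 8), tol = 1e-10)$root
  expect_equal(xf, root, tolerance = 1e-6)
})

test_that("velocity estimation matches the normal-equations oracle", {
  tt <- seq(1, 100, by = 1)
  tr <- function(x) structure(
    data.frame(t = tt, x_coop = x, x_def = NA_real_, lag = NA_real_),
    class = c("front_trace", "data.frame"))
  # exact linear motion
  est <- estimate_velocity(tr(3 + 0.37 * tt), window = 1)
  expect_equal(est$v, 0.37, tolerance = 1e-12)
  expect_lt(est$stderr, 1e-12)
  # constant positions
  expect_equal(estimate_velocity(tr(rep(7, 100)), window = 1)$v, 0)
  # noisy data against explicit normal equations
  set.seed(21)
  x <- 1 + 0.2 * tt + rnorm(100, sd = 0.3)
  est <- estimate_velocity(tr(x), window = 1)
  X <- cbind(1, tt)
  beta <- solve(t(X) %*% X, t(X) %*% x)
  expect_equal(est$v, beta[2], tolerance = 1e-10)
})

test_that("a symmetric Allee threshold stalls the front", {
  p <- model_params(growth = growth_law(nstar = 0.5),
                    selection = selection_law(s = 0))
  g <- wave_grid(L = 40, dx = 0.15, params = p)
  run <- run_wave(p, g, initial_condition("occupied_left_fraction",
                                          fraction = 0.4, f0 = 0),
                  max_time = 40, stop_fraction = 0.95)
  expect_equal(run$status, "stalled")
  rep <- classify_outcome(run, p)
  expect_equal(rep$verdict, "stalled")
})

test_that("frequency stays within [0,1] and cooperation is enriched at the front", {
  pr <- presets("mixed_wave")
  p <- pr$params
  w <- front_width(p)
  g <- wave_grid(L = 120 * w, dx = 0.15 * w, params = p)
  run <- run_wave(p, g, pr$init, stop_fraction = 0.9)
  st <- run$state
  n <- st$c + st$d
  f <- ifelse(n > 1e-9, st$d / pmax(n, 1e-300), 0)
  expect_true(all(f >= -1e-12 & f <= 1 + 1e-12))
  expect_lte(max(n), 1.001 * p$growth$K(0))
  # defector frequency at the front region is below the bulk frequency
  xf <- front_position(st$c, g)
  front_cells <- which(g$x > xf - 2 * w & g$x < xf + 2 * w & n > 1e-6)
  bulk_cells <- which(g$x < 0.3 * xf & n > 0.5)
  f_front <- sum(st$d[front_cells]) / sum(n[front_cells])
  f_bulk <- sum(st$d[bulk_cells]) / sum(n[bulk_cells])
  expect_lt(f_front, f_bulk)
})

test_that("halving dx changes the measured expansion velocity by < 0.5%", {
  p <- model_params(growth = growth_law(nstar = 0.2),
                    selection = selection_law(s = 0))
  w <- front_width(p)
  v_at <- function(dxf) {
    g <- wave_grid(L = 120 * w, dx = dxf * w, params = p)
    run <- run_wave(p, g, initial_condition("occupied_left_fraction",
                                            fraction = 0.1, f0 = 0),
                    stop_fraction = 0.9)
    estimate_velocity(run$trace)$v
  }
  v1 <- v_at(0.2); v2 <- v_at(0.1)
  expect_lt(abs(v1 - v2) / v2, 0.005)
})

test_that("blow-up is reported with a diagnostic instead of silent corruption", {
  p <- model_params(growth = growth_law(g0 = 1, nstar = 0.2),
                    selection = selection_law(s = 0))
  # force instability: dt at the stability bound with strong reaction
  g <- wave_grid(L = 20, dx = 0.5, dt = 0.5^2 / 2, params = p)
  st <- structure(list(t = 0, c = c(rep(1, g$nx / 2),
                                    rep(0, g$nx - g$nx / 2)) +
                         0.5 * sin(seq_len(g$nx)),
                       d = rep(0, g$nx)), class = "wave_state")
  st$c <- pmax(st$c, 0)
  expect_error(run_wave(p, g, st, max_time = 50, stop_fraction = 2,
                        engine = "cpp"),
               "blow-up")
})
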