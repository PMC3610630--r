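# shared small parameter sets for the tests

default_params <- function() {
  model_params(D = 1,
               growth = growth_law(g0 = 1, K = 1, nstar = 0.2,
                                   nstar_slope = 0.3),
               selection = selection_law(s = 0.1, f_high = 0.3, f_low = -1,
                                         n_c = 0.45, smooth_eps = 0.02))
}

# density-independent selection (decoupled evolutionary dynamics)
decoupled_params <- function(fstar = 0.3) {
  model_params(D = 1,
               growth = growth_law(g0 = 1, K = 1, nstar = 0.15,
                                   nstar_slope = 0.4),
               selection = selection_law(s = 0.1, f_high = fstar,
                                         f_low = fstar, n_c = 0.2))
}

# small 0-D explicit Euler integrator, used as an independent oracle
euler_nf <- function(n0, f0, params, dt, steps) {
  n <- n0; f <- f0
  for (k in seq_len(steps)) {
    r <- local_rates_nf(n, f, params)
    n <- n + dt * r$dn_dt
    f <- min(1, max(0, f + dt * r$df_dt))
  }
  c(n = n, f = f)
}

euler_cd <- function(c0, d0, params, dt, steps) {
  cc <- c0; d <- d0
  for (k in seq_len(steps)) {
    r <- local_rates_cd(cc, d, params)
    cc <- max(0, cc + dt * r$dc_dt)
    d <- max(0, d + dt * r$dd_dt)
  }
  c(c = cc, d = d)
}
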