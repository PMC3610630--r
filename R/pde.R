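#' Discretization grid for the FTCS solver
#'
#' Uniform cell-centered grid on `[0, L]` with explicit-scheme time step.
#' The forward-time centered-space scheme is stable for
#' `dt <= dx^2 / (2 D)`; the default uses 40% of that bound.
#'
#' @param L habitat length.
#' @param dx spatial step; default one tenth of the front width of `params`.
#' @param dt time step; default `0.4 * dx^2 / (2 D)`.
#' @param params a [model_params()] (used for the defaults and the stability
#'   check).
#' @return An object of class `wave_grid` with fields `L`, `dx`, `dt`, `x`
#'   (cell centers) and `nx`.
#' @export
wave_grid <- function(L, dx = NULL, dt = NULL, params = model_params()) {
  if (is.null(dx)) dx <- 0.1 * front_width(params)
  stopifnot(L > 0, is.finite(dx), dx > 0)
  dt_max <- dx^2 / (2 * params$D)
  if (is.null(dt)) dt <- 0.4 * dt_max
  if (dt > dt_max)
    stop(sprintf("dt = %g violates the FTCS stability bound dx^2/(2D) = %g",
                 dt, dt_max))
  nx <- round(L / dx)
  structure(list(L = L, dx = dx, dt = dt, nx = nx,
                 x = (seq_len(nx) - 0.5) * dx,
                 stability_margin = dt / dt_max),
            class = "wave_grid")
}

#' Initial condition specification
#'
#' Three canonical starting states, all with the occupied region at local
#' equilibrium:
#' \describe{
#' \item{`occupied_left_fraction`}{a mixed (or pure, `f0 = 0`) population at
#'   density `K(f0)` occupying the left `fraction` of the habitat, empty
#'   elsewhere; the default for expansion and mixed waves.}
#' \item{`defectors_left_fraction`}{cooperators fill the whole habitat at
#'   carrying capacity; defectors at equilibrium frequency are present only
#'   in the left `fraction` (the genetic invasion wave).}
#' \item{`engineered_pure_cooperator_strip`}{a mixed population on the left
#'   `fraction`, then a strip of pure cooperators of width `strip_width` at
#'   carrying capacity, then empty habitat (probes transient splitting).}
#' }
#'
#' @param kind one of the three kinds above.
#' @param fraction occupied fraction of the habitat, in `(0, 1)`.
#' @param f0 initial defector frequency of the mixed region; default: the
#'   preferred frequency at carrying capacity.
#' @param strip_width width of the pure-cooperator strip (length units).
#' @return An object of class `initial_condition`.
#' @export
initial_condition <- function(kind = c("occupied_left_fraction",
                                       "defectors_left_fraction",
                                       "engineered_pure_cooperator_strip"),
                              fraction = 0.1, f0 = NULL, strip_width = NULL) {
  kind <- match.arg(kind)
  stopifnot(fraction > 0, fraction < 1)
  if (kind == "engineered_pure_cooperator_strip" && is.null(strip_width))
    stop("strip_width is required for the engineered strip")
  structure(list(kind = kind, fraction = fraction, f0 = f0,
                 strip_width = strip_width),
            class = "initial_condition")
}

#' Build the discretized initial wave state
#'
#' @param init an [initial_condition()].
#' @param params a [model_params()].
#' @param grid a [wave_grid()].
#' @return An object of class `wave_state` with fields `t`, `c`, `d`.
#' @export
make_state <- function(init, params, grid) {
  K0 <- params$growth$K(0)
  f0 <- init$f0
  if (is.null(f0)) f0 <- max(0, min(1, params$selection$fstar(K0)))
  Kf <- params$growth$K(f0)
  x <- grid$x
  cc <- numeric(grid$nx); d <- numeric(grid$nx)
  left <- x < init$fraction * grid$L
  if (init$kind == "occupied_left_fraction") {
    cc[left] <- Kf * (1 - f0); d[left] <- Kf * f0
  } else if (init$kind == "defectors_left_fraction") {
    cc[] <- K0
    cc[left] <- Kf * (1 - f0); d[left] <- Kf * f0
  } else {
    strip <- x >= init$fraction * grid$L &
             x < init$fraction * grid$L + init$strip_width
    cc[left] <- Kf * (1 - f0); d[left] <- Kf * f0
    cc[strip] <- K0
  }
  structure(list(t = 0, c = cc, d = d), class = "wave_state")
}

#' One FTCS step (reference implementation)
#'
#' Advances a [wave_state] by one time step of the explicit forward-time
#' centered-space scheme: a centered second difference for the diffusion of
#' each species separately (reflecting ghost cells implement the no-flux
#' boundaries) plus the local reaction rates of [local_rates_cd()].  This is
#' the vectorized R reference used by the tests; [run_wave()] runs the same
#' update in compiled code.
#'
#' @param state a `wave_state`.
#' @param params a [model_params()].
#' @param grid a [wave_grid()].
#' @return The advanced `wave_state`.
#' @export
ftcs_step <- function(state, params, grid) {
  cc <- state$c; d <- state$d; nx <- grid$nx
  lap <- function(u) {
    (c(u[1], u[-nx]) - 2 * u + c(u[-1], u[nx])) / grid$dx^2
  }
  r <- local_rates_cd(cc, d, params)
  cc2 <- cc + grid$dt * (params$D * lap(cc) + r$dc_dt)
  d2  <- d  + grid$dt * (params$D * lap(d)  + r$dd_dt)
  clip <- 1e-12 * params$growth$K(0)
  for (u in list(cc2, d2)) {
    if (any(!is.finite(u)) || any(u < -clip))
      stop("numerical blow-up: negative density or non-finite value; ",
           "check the stability margin")
  }
  cc2[cc2 < 0] <- 0; d2[d2 < 0] <- 0
  if (params$selection$pars$nonviable_below_nc)
    d2[cc2 + d2 < params$selection$pars$n_c] <- 0
  structure(list(t = state$t + grid$dt, c = cc2, d = d2),
            class = "wave_state")
}

#' Front position of a density profile
#'
#' The front is the rightmost point where the density reaches half of its
#' bulk value, linearly interpolated between cells.  The bulk value is
#' estimated as the mean over the leftmost 5% of occupied cells.
#'
#' @param profile per-cell density.
#' @param grid a [wave_grid()].
#' @param bulk_value optional externally supplied bulk density; estimated
#'   from the profile when `NULL`.
#' @return Front position, or `NA_real_` when the profile lies everywhere
#'   below half of the bulk value (undefined front — not an error).
#' @export
front_position <- function(profile, grid, bulk_value = NULL) {
  occ <- which(profile > 1e-9 * max(profile, 1e-300))
  if (!length(occ) || max(profile) <= 0) return(NA_real_)
  if (is.null(bulk_value)) {
    n_bulk <- max(1L, round(0.05 * max(occ)))
    bulk_value <- mean(profile[seq_len(n_bulk)])
  }
  if (bulk_value <= 0) return(NA_real_)
  half <- bulk_value / 2
  idx <- which(profile >= half)
  if (!length(idx)) return(NA_real_)
  i <- max(idx)
  if (i >= grid$nx) return(grid$x[i])
  grid$x[i] + grid$dx * (profile[i] - half) / (profile[i] - profile[i + 1])
}

#' Integrate the coupled wave equations and track the fronts
#'
#' Runs the FTCS scheme from an initial condition until the cooperator front
#' has spread into `stop_fraction` of the habitat or `max_time` is reached,
#' recording cooperator and defector front positions at a regular cadence.
#'
#' Two formulations are available: the primary species form (`"cd"`), which
#' needs no special handling where the density vanishes, and the
#' density-frequency form (`"nf"`), which carries the gradient-coupling
#' advection term `2 D (\partial_x n / n) \partial_x f` explicitly and is
#' used to validate the equivalence of the two formulations.
#'
#' @param params a [model_params()] (parametric laws for the compiled
#'   engine; arbitrary callables fall back to the R engine).
#' @param grid a [wave_grid()].
#' @param init an [initial_condition()] or a ready `wave_state`.
#' @param stop_fraction stop once the cooperator front passes this fraction
#'   of `L` (default 0.95).
#' @param max_time maximum integration time; default scales the habitat
#'   crossing time at the pure-cooperator velocity.
#' @param record_every recording interval in time units; default gives
#'   about 400 samples.
#' @param engine `"auto"` (compiled when the laws are parametric), `"cpp"`
#'   or `"r"`.
#' @param formulation `"cd"` (species densities; default) or `"nf"`
#'   (density-frequency validation path).
#' @param snapshot_every optional interval for storing full profiles.
#' @param stop_on which front drives the stopping rule and the stall check:
#'   `"auto"` (defectors for the `defectors_left_fraction` initial
#'   condition, cooperators otherwise), `"cooperators"` or `"defectors"`.
#' @return A list of class `wave_run` with the final `state`, a `trace`
#'   data.frame (`t`, `x_coop`, `x_def`, `lag`), the run `status`
#'   (`"reached_fraction"`, `"max_time"` or `"stalled"`), and optional
#'   `snapshots`.
#' @export
run_wave <- function(params, grid, init, stop_fraction = 0.95,
                     max_time = NULL, record_every = NULL,
                     engine = c("auto", "cpp", "r"),
                     formulation = c("cd", "nf"),
                     snapshot_every = NULL,
                     stop_on = c("auto", "cooperators", "defectors")) {
  engine <- match.arg(engine)
  formulation <- match.arg(formulation)
  stop_on <- match.arg(stop_on)
  if (stop_on == "auto")
    stop_on <- if (inherits(init, "initial_condition") &&
                   init$kind == "defectors_left_fraction") "defectors"
               else "cooperators"
  state <- if (inherits(init, "wave_state")) init else
    make_state(init, params, grid)
  vref <- max(abs(expansion_velocity(params, 0)$v),
              0.05 * sqrt(params$D * params$growth$g0(0)))
  if (is.null(max_time)) {
    if (vref <= 0)
      stop("max_time must be given explicitly when the growth rate is zero")
    max_time <- 4 * grid$L / vref
  }
  if (is.null(record_every)) record_every <- max_time / 400
  use_cpp <- engine == "cpp" || (engine == "auto" && is_parametric(params))
  if (engine == "cpp" && !is_parametric(params))
    stop("compiled engine requires parametric laws")

  steps_per_rec <- max(1L, round(record_every / grid$dt))
  n_rec_max <- ceiling(max_time / (steps_per_rec * grid$dt))
  K0 <- params$growth$K(0)
  gp <- params$growth$pars; sp <- params$selection$pars
  clip <- 1e-12 * K0

  ts <- numeric(0); xc <- numeric(0); xd <- numeric(0)
  snaps <- if (!is.null(snapshot_every)) list() else NULL
  next_snap <- 0
  status <- "max_time"
  cc <- state$c; d <- state$d; tt <- state$t
  if (formulation == "nf") { nn <- cc + d; ff <- ifelse(nn > 0, d / nn, 0) }

  for (rec in seq_len(n_rec_max)) {
    if (use_cpp) {
      if (formulation == "cd") {
        out <- ftcs_advance_cd(cc, d, steps_per_rec, grid$dx, grid$dt,
                               params$D, gp$g0, gp$K, gp$nstar,
                               gp$nstar_slope, gp$K_slope, gp$g0_slope,
                               sp$s, sp$f_high, sp$f_low, sp$n_c,
                               sp$smooth_eps, sp$nonviable_below_nc, clip)
        if (out$blowup)
          stop(sprintf("numerical blow-up at t ~ %g; stability margin %g",
                       tt + out$bad_step * grid$dt, grid$stability_margin))
        cc <- out$c; d <- out$d
      } else {
        out <- ftcs_advance_nf(nn, ff, steps_per_rec, grid$dx, grid$dt,
                               params$D, gp$g0, gp$K, gp$nstar,
                               gp$nstar_slope, gp$K_slope, gp$g0_slope,
                               sp$s, sp$f_high, sp$f_low, sp$n_c,
                               sp$smooth_eps, sp$nonviable_below_nc, clip,
                               1e-8 * K0)
        if (out$blowup)
          stop(sprintf("numerical blow-up at t ~ %g; stability margin %g",
                       tt + out$bad_step * grid$dt, grid$stability_margin))
        nn <- out$n; ff <- out$f
        cc <- nn * (1 - ff); d <- nn * ff
      }
    } else {
      st <- structure(list(t = tt, c = cc, d = d), class = "wave_state")
      for (k in seq_len(steps_per_rec)) st <- ftcs_step(st, params, grid)
      cc <- st$c; d <- st$d
    }
    tt <- tt + steps_per_rec * grid$dt
    ts <- c(ts, tt)
    xc <- c(xc, front_position(cc, grid))
    xd <- c(xd, front_position(d, grid))
    if (!is.null(snapshot_every) && tt >= next_snap) {
      snaps[[length(snaps) + 1L]] <- list(t = tt, c = cc, d = d)
      next_snap <- next_snap + snapshot_every
    }
    x_stop <- if (stop_on == "defectors") tail(xd, 1) else tail(xc, 1)
    if (!is.na(x_stop) && x_stop >= stop_fraction * grid$L) {
      status <- "reached_fraction"; break
    }
    if (tt >= max_time) break
  }
  xs <- if (stop_on == "defectors") xd else xc
  adv <- if (all(is.na(xs))) 0 else max(xs, na.rm = TRUE) - xs[!is.na(xs)][1]
  if (length(xs) && adv < 2 * front_width(params)) status <- "stalled"
  trace <- data.frame(t = ts, x_coop = xc, x_def = xd, lag = xc - xd)
  class(trace) <- c("front_trace", "data.frame")
  structure(list(state = structure(list(t = tt, c = cc, d = d),
                                   class = "wave_state"),
                 trace = trace, status = status, grid = grid,
                 snapshots = snaps),
            class = "wave_run")
}

#' Least-squares front velocity from a front trace
#'
#' Fits position against time over the final `window` fraction of the trace.
#' For pulled (KPP-type) fronts, whose instantaneous velocity converges to
#' the asymptotic value only like `1/t`, `pulled = TRUE` augments the fit
#' with `log(t)` and `1/sqrt(t)` correction terms so that the linear
#' coefficient estimates the asymptotic velocity.
#'
#' @param trace a `front_trace` data.frame from [run_wave()].
#' @param window final fraction of the time series to fit (default 1/3).
#' @param species `"cooperators"` or `"defectors"`.
#' @param pulled logical; include slow-convergence correction terms.
#' @return A list with `v` (velocity) and `stderr`.
#' @export
estimate_velocity <- function(trace, window = 1/3,
                              species = c("cooperators", "defectors"),
                              pulled = FALSE) {
  species <- match.arg(species)
  xcol <- if (species == "cooperators") trace$x_coop else trace$x_def
  keep <- !is.na(xcol)
  tt <- trace$t[keep]; xx <- xcol[keep]
  if (!length(tt)) stop("no defined front positions in the trace")
  sel <- tt >= max(tt) - window * (max(tt) - min(tt))
  if (sum(sel) < 10) stop("fewer than 10 trace points in the fit window")
  tt <- tt[sel]; xx <- xx[sel]
  fit <- if (pulled) lm(xx ~ tt + log(tt) + I(1 / sqrt(tt)))
         else lm(xx ~ tt)
  sm <- suppressWarnings(summary(fit))$coefficients
  list(v = unname(coef(fit)["tt"]), stderr = unname(sm["tt", "Std. Error"]))
}

# slope of lag vs t over a sub-interval [a, b] of the trace (fractions)
lag_slope <- function(trace, a, b) {
  keep <- !is.na(trace$lag)
  tt <- trace$t[keep]; ll <- trace$lag[keep]
  t0 <- min(tt); t1 <- max(tt)
  sel <- tt >= t0 + a * (t1 - t0) & tt <= t0 + b * (t1 - t0)
  if (sum(sel) < 5) return(NA_real_)
  unname(coef(lm(ll[sel] ~ tt[sel]))[2])
}

#' Classify the outcome of a mixed-wave run
#'
#' Decides between the qualitative outcomes of a range expansion:
#' \describe{
#' \item{`"split"`}{the cooperator-defector lag grows linearly without
#'   decelerating: the wave has split into a pure-cooperator expansion wave
#'   and a defector invasion wave.}
#' \item{`"transient"`}{the lag first grew substantially and then shrank
#'   back to a bounded plateau (defectors caught up).}
#' \item{`"mixed"`}{both fronts travel together at a common velocity.}
#' \item{`"stalled"`}{the expansion front did not advance.}
#' \item{`"pure_expansion"`}{no defectors were present at any time.}
#' }
#' The velocity tie-break scale is `eps_v = 3 *` the larger standard error
#' of the two velocity fits (scale-free, so it sharpens automatically on
#' longer runs).  Because transient dynamics decay slowly near the splitting
#' threshold, a lag that is still growing but decelerating (final-window lag
#' growth rate below 60% of the mid-window rate) is not classified as split.
#'
#' @param run a `wave_run` from [run_wave()] (or a bare `front_trace` plus
#'   `params`).
#' @param params the [model_params()] of the run.
#' @param window final fraction for velocity fits.
#' @param eps_v velocity tolerance; default `3 * max(stderr)`.
#' @return A list of class `split_report`: `verdict`, `v_coop`, `v_def`,
#'   `lag_rate`, `eps_v`.
#' @export
classify_outcome <- function(run, params, window = 1/3, eps_v = NULL) {
  trace <- if (inherits(run, "wave_run")) run$trace else run
  status <- if (inherits(run, "wave_run")) run$status else "max_time"
  if (status == "stalled")
    return(structure(list(verdict = "stalled", v_coop = 0, v_def = 0,
                          lag_rate = 0, eps_v = NA_real_),
                     class = "split_report"))
  vc <- estimate_velocity(trace, window, "cooperators")
  if (all(is.na(trace$x_def))) {   # single-species expansion run
    return(structure(list(verdict = "pure_expansion", v_coop = vc$v,
                          v_def = NA_real_, lag_rate = NA_real_,
                          eps_v = NA_real_),
                     class = "split_report"))
  }
  vd <- tryCatch(estimate_velocity(trace, window, "defectors"),
                 error = function(e) list(v = NA_real_, stderr = NA_real_))
  if (is.na(vd$v)) {
    # defectors were present but their front fell below half-bulk for the
    # whole fit window: the wave has shed them
    return(structure(list(verdict = "split", v_coop = vc$v, v_def = NA_real_,
                          lag_rate = NA_real_, eps_v = NA_real_),
                     class = "split_report"))
  }
  if (is.null(eps_v)) eps_v <- 3 * max(vc$stderr, vd$stderr)
  rate_fin <- lag_slope(trace, 2/3, 1)
  rate_mid <- lag_slope(trace, 1/3, 2/3)
  lag_ok <- !is.na(trace$lag)
  lag_fin <- mean(tail(trace$lag[lag_ok], max(5, round(0.05 * sum(lag_ok)))))
  lag_max <- max(trace$lag[lag_ok])
  w <- front_width(params)
  sustained <- !is.na(rate_fin) && rate_fin > eps_v &&
    (is.na(rate_mid) || rate_fin >= 0.6 * rate_mid)
  verdict <- if (vc$v - vd$v > eps_v && sustained) "split"
    else if (lag_max - lag_fin > 2 * w) "transient"
    else "mixed"
  structure(list(verdict = verdict, v_coop = vc$v, v_def = vd$v,
                 lag_rate = rate_fin, eps_v = eps_v),
            class = "split_report")
}

#' @export
print.split_report <- function(x, ...) {
  cat(sprintf("<split_report> verdict = %s (v_coop = %.4g, v_def = %.4g, lag rate = %.3g)\n",
              x$verdict, x$v_coop, x$v_def, x$lag_rate))
  invisible(x)
}
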