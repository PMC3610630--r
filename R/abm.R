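#' Configuration of the individual-based lattice model
#'
#' A one-dimensional lattice of `n_sites` sites, each with carrying
#' capacity `N`.  One time step consists of one possible migration event
#' and one possible reproduction-or-death event at every site (swept left
#' to right); `steps_per_generation` time steps (default `N`, one
#' demographic event per individual per generation on average) make a
#' generation.
#'
#' The demographic probabilities are, with local density `rho = n/N` and
#' Allee fraction `rho* = nstar(f)`,
#' \deqn{P_{birth} = g_0 (1 + \rho^*) \rho^2, \qquad
#'       P_{death} = g_0 (\rho^3 + \rho^* \rho),}
#' so the per-generation drift `N (P_b - P_d) = g_0 n (1-\rho)(\rho-\rho^*)`
#' reproduces the cubic Allee growth law (time in generations, capacity 1).
#' Deaths remove a uniformly chosen resident; a birth is a cooperator with
#' the payoff-share probability built from the interaction matrix of
#' [interaction_matrix()], mimicking linear frequency-dependent selection.
#' Migration moves one uniformly chosen organism to a uniformly chosen
#' neighbor with event probability `m n / N`, so the continuum limit is
#' diffusion with `D = m/2` (site spacings squared per generation).
#' Custom birth/death laws can be injected as functions of `(rho, f)` for
#' the R reference stepper.
#'
#' @param n_sites number of lattice sites.
#' @param N per-site carrying capacity (individuals).
#' @param m migration probability scale, in `[0, 1]`.
#' @param growth a [growth_law()] with `K = 1` (densities are per-capacity).
#' @param selection a [selection_law()] with densities in units of `N`.
#' @param steps_per_generation default `N`.
#' @param birth_prob,death_prob optional injected laws `function(rho, f)`
#'   (R engine only).
#' @return An object of class `abm_config`.
#' @export
abm_config <- function(n_sites = 220, N = 20, m = 0.5,
                       growth = growth_law(g0 = 0.2, K = 1, nstar = 0.2,
                                           nstar_slope = 0.3),
                       selection = selection_law(s = 0.08, f_high = 0.3,
                                                 f_low = -1, n_c = 0.35),
                       steps_per_generation = N,
                       birth_prob = NULL, death_prob = NULL) {
  stopifnot(n_sites >= 2, N >= 1, m >= 0, m <= 1)
  if (growth$pars$K != 1)
    stop("ABM growth law uses densities in units of the site capacity; K must be 1")
  cfg <- structure(list(n_sites = n_sites, N = N, m = m, growth = growth,
                        selection = selection,
                        steps_per_generation = steps_per_generation,
                        birth_prob = birth_prob, death_prob = death_prob),
                   class = "abm_config")
  # probabilities must be valid over the statistically reachable band of
  # densities (the stepper gives death priority in the far tail above it)
  pb <- abm_birth_prob(cfg); pd <- abm_death_prob(cfg)
  rho <- seq(0, 1.2, by = 0.05); f <- seq(0, 1, by = 0.25)
  gridp <- expand.grid(rho = rho, f = f)
  pbv <- mapply(pb, gridp$rho, gridp$f); pdv <- mapply(pd, gridp$rho, gridp$f)
  if (any(pbv < 0 | pbv > 1 | pdv < 0 | pdv > 1 | pbv + pdv > 1))
    stop("birth/death probabilities leave [0,1] for reachable states; ",
         "reduce g0 or adjust the laws")
  cfg
}

abm_birth_prob <- function(config) {
  if (!is.null(config$birth_prob)) return(config$birth_prob)
  g0 <- config$growth$pars$g0
  nsf <- config$growth$nstar
  function(rho, f) max(0, g0 * (1 + nsf(f)) * rho^2)
}

abm_death_prob <- function(config) {
  if (!is.null(config$death_prob)) return(config$death_prob)
  g0 <- config$growth$pars$g0
  nsf <- config$growth$nstar
  function(rho, f) max(0, g0 * (rho^3 + nsf(f) * rho))
}

#' Interaction matrix of the birth payoff-share rule
#'
#' The 2x2 matrix `A` with entries indexed by (C, D) whose payoff shares
#' reproduce linear frequency-dependent selection with preferred defector
#' frequency `fstar(n)`:
#' `A_CC = A_CD = 1`, `A_DC = 1 + s fstar(n)`,
#' `A_DD = 1 - s (1 - fstar(n))`, so that the defector-cooperator payoff
#' difference is `s (fstar(n) - f)`.
#'
#' @param selection a [selection_law()].
#' @param n local density (in units of the site capacity).
#' @return A 2x2 numeric matrix with dimnames C, D.
#' @export
interaction_matrix <- function(selection, n) {
  s <- selection$s(n); fst <- selection$fstar(n)
  matrix(c(1, 1, 1 + s * fst, 1 - s * (1 - fst)), 2, 2, byrow = TRUE,
         dimnames = list(c("C", "D"), c("C", "D")))
}

#' Initial ABM state
#'
#' Occupies the left `fraction` of the lattice at local equilibrium:
#' each occupied site holds `N` individuals with defector frequency `f0`
#' (binomially partitioned deterministically by rounding).
#'
#' @param config an [abm_config()].
#' @param fraction occupied left fraction.
#' @param f0 initial defector frequency (default: preferred frequency at
#'   capacity).
#' @return An object of class `abm_state` with integer fields `coop`,
#'   `def` and `generation`.
#' @export
abm_init <- function(config, fraction = 0.2, f0 = NULL) {
  if (is.null(f0)) f0 <- max(0, min(1, config$selection$fstar(1)))
  occ <- seq_len(max(1L, round(fraction * config$n_sites)))
  coop <- integer(config$n_sites); def <- integer(config$n_sites)
  def[occ] <- as.integer(round(f0 * config$N))
  coop[occ] <- as.integer(config$N) - def[occ]
  structure(list(coop = coop, def = def, generation = 0),
            class = "abm_state")
}

#' One ABM time step (reference implementation)
#'
#' A single lattice sweep — one possible migration event then one possible
#' demographic event per site — in pure R, used to test the update logic
#' and to run injected birth/death laws.  [run_abm()] advances the same
#' dynamics in compiled code.
#'
#' @param state an `abm_state`.
#' @param config an [abm_config()].
#' @return The advanced `abm_state` (time advances by `1/steps_per_generation`
#'   generations).
#' @export
abm_step <- function(state, config) {
  C <- state$coop; Dd <- state$def
  ns <- config$n_sites; N <- config$N
  pb <- abm_birth_prob(config); pd <- abm_death_prob(config)
  sel <- config$selection
  for (i in seq_len(ns)) {            # migration sweep
    n <- C[i] + Dd[i]
    if (n == 0) next
    if (runif(1) < config$m * n / N) {
      j <- if (runif(1) < 0.5) i - 1 else i + 1
      if (j < 1) j <- 2
      if (j > ns) j <- ns - 1
      if (runif(1) * n < C[i]) { C[i] <- C[i] - 1L; C[j] <- C[j] + 1L }
      else { Dd[i] <- Dd[i] - 1L; Dd[j] <- Dd[j] + 1L }
    }
  }
  for (i in seq_len(ns)) {            # demographic sweep
    n <- C[i] + Dd[i]
    if (n == 0) next
    rho <- n / N; f <- Dd[i] / n
    u <- runif(1)
    pbi <- pb(rho, f); pdi <- pd(rho, f)
    pdi <- min(pdi, 1)
    pbi <- min(pbi, 1 - pdi)   # death priority far above capacity
    if (u < pbi) {
      A <- interaction_matrix(sel, rho)
      piC <- A["C", "C"] * (1 - f) + A["C", "D"] * f
      piD <- max(0, A["D", "C"] * (1 - f) + A["D", "D"] * f)
      wc <- (1 - f) * piC; wd <- f * piD
      pc <- if (wc + wd > 0) wc / (wc + wd) else 1
      if (runif(1) < pc) C[i] <- C[i] + 1L else Dd[i] <- Dd[i] + 1L
    } else if (u < pbi + pdi) {
      if (runif(1) * n < C[i]) C[i] <- max(0L, C[i] - 1L)
      else Dd[i] <- max(0L, Dd[i] - 1L)
    }
    if (sel$pars$nonviable_below_nc && (C[i] + Dd[i]) / N < sel$pars$n_c)
      Dd[i] <- 0L
  }
  structure(list(coop = C, def = Dd,
                 generation = state$generation + 1 / config$steps_per_generation),
            class = "abm_state")
}

#' Run the individual-based simulation
#'
#' Advances whole-lattice time steps in compiled code, recording cooperator
#' and defector front positions (half-bulk crossings of the count profiles
#' scaled by `N`) every `record_every` generations.
#'
#' Randomness uses R's global generator: call `set.seed()` before running
#' for reproducible trajectories.
#'
#' @param config an [abm_config()] (default laws only; injected laws run
#'   through [abm_step()]).
#' @param init an `abm_state` from [abm_init()].
#' @param max_generations run length in generations.
#' @param record_every recording cadence in generations (default 1).
#' @param stop_fraction stop early once the cooperator front passes this
#'   fraction of the lattice (default 0.9).
#' @return A list of class `abm_run`: final `state`, `trace` data.frame
#'   (`t` in generations, `x_coop`, `x_def`, `lag`) and `status`
#'   (`"max_generations"`, `"reached_fraction"` or `"extinct"`).
#' @export
run_abm <- function(config, init = abm_init(config), max_generations = 1000,
                    record_every = 1, stop_fraction = 0.9) {
  if (!is.null(config$birth_prob) || !is.null(config$death_prob))
    stop("injected birth/death laws run through abm_step(), not run_abm()")
  gp <- config$growth$pars; sp <- config$selection$pars
  steps_chunk <- max(1L, round(record_every * config$steps_per_generation))
  n_chunks <- ceiling(max_generations * config$steps_per_generation / steps_chunk)
  grid <- structure(list(L = config$n_sites, dx = 1, nx = config$n_sites,
                         x = seq_len(config$n_sites) - 0.5),
                    class = "wave_grid")
  C <- init$coop; Dd <- init$def
  gen <- init$generation
  ts <- numeric(0); xc <- numeric(0); xd <- numeric(0)
  status <- "max_generations"
  for (ch in seq_len(n_chunks)) {
    out <- abm_advance(C, Dd, steps_chunk, config$N, config$m,
                       gp$g0, gp$nstar, gp$nstar_slope,
                       sp$s, sp$f_high, sp$f_low, sp$n_c,
                       sp$nonviable_below_nc)
    C <- out$coop; Dd <- out$def
    gen <- gen + steps_chunk / config$steps_per_generation
    ts <- c(ts, gen)
    xc <- c(xc, front_position(C / config$N, grid))
    xd <- c(xd, front_position(Dd / config$N, grid))
    if (sum(C) + sum(Dd) == 0) { status <- "extinct"; break }
    if (!is.na(tail(xc, 1)) && tail(xc, 1) >= stop_fraction * config$n_sites) {
      status <- "reached_fraction"; break
    }
  }
  trace <- data.frame(t = ts, x_coop = xc, x_def = xd, lag = xc - xd)
  class(trace) <- c("front_trace", "data.frame")
  structure(list(state = structure(list(coop = C, def = Dd,
                                        generation = gen),
                                   class = "abm_state"),
                 trace = trace, status = status, config = config),
            class = "abm_run")
}

#' Detect stochastic wave splitting in an ABM trace
#'
#' Stochastic splitting is a rare-fluctuation event in which a defector-free
#' region opens between the defector and cooperator fronts and, because the
#' expansion is faster than the invasion (`v_C > v_D`), keeps growing.  It
#' is detected as the earliest generation at which the front lag exceeds a
#' width threshold and stays above it for a confirmation window.
#'
#' @param trace a `front_trace` from [run_abm()].
#' @param width_threshold lag threshold in lattice units; default 3x the
#'   deterministic invasion-front width `sqrt(D / (s_eff f_high))` supplied
#'   via `config`, or 10 sites if no config is given.
#' @param confirm_window confirmation window in generations (default 100).
#' @param config optional [abm_config()] used for the default threshold.
#' @return The splitting generation, or `NA_real_` if none qualifies.
#' @export
detect_stochastic_split <- function(trace, width_threshold = NULL,
                                    confirm_window = 100, config = NULL) {
  if (is.null(width_threshold)) {
    if (!is.null(config)) {
      Dg <- config$m / 2
      s_eff <- config$selection$pars$s * config$growth$pars$g0 *
        (1 + config$growth$pars$nstar)
      width_threshold <- 3 * sqrt(Dg / (s_eff * config$selection$pars$f_high))
    } else width_threshold <- 10
  }
  lag <- trace$lag; tt <- trace$t
  # treat an undefined defector front with a defined cooperator front as
  # an unbounded lag (defectors extinct behind an advancing front)
  lag[is.na(trace$x_def) & !is.na(trace$x_coop)] <- Inf
  ok <- !is.na(lag)
  above <- lag >= width_threshold & ok
  cand <- which(above)
  for (i in cand) {
    inwin <- tt >= tt[i] & tt <= tt[i] + confirm_window
    if (all(above[inwin])) return(tt[i])
  }
  NA_real_
}

#' Waiting-time experiment for stochastic splitting
#'
#' For each per-site capacity `N`, runs replicate simulations until
#' stochastic splitting is detected or the generation budget is exhausted,
#' and reports the mean waiting time with the standard deviation of the
#' mean.  Replicates that never split are right-censored and counted
#' separately rather than dropped; a row whose replicates are all censored
#' is flagged.  The average waiting time grows steeply with `N` (and with
#' the migration probability `m`) because larger populations have smaller
#' number fluctuations.
#'
#' @param config base [abm_config()]; `N` is overridden per row.
#' @param N_values per-site capacities to test.
#' @param replicates replicates per capacity.
#' @param max_generations censoring horizon.
#' @param record_every trace cadence in generations.
#' @param m optional migration probability override.
#' @return A data.frame with columns `N`, `m`, `mean_T`, `sem`,
#'   `n_split`, `n_censored`, `all_censored`.
#' @export
splitting_time_experiment <- function(config, N_values, replicates = 20,
                                      max_generations = 2000,
                                      record_every = 5, m = NULL) {
  rows <- lapply(N_values, function(N) {
    cfg <- config
    cfg$N <- N
    cfg$steps_per_generation <- N
    if (!is.null(m)) cfg$m <- m
    times <- numeric(0); censored <- 0L
    for (r in seq_len(replicates)) {
      run <- run_abm(cfg, abm_init(cfg), max_generations = max_generations,
                     record_every = record_every, stop_fraction = 2)
      tsplit <- detect_stochastic_split(run$trace, config = cfg)
      if (is.na(tsplit)) censored <- censored + 1L
      else times <- c(times, tsplit)
    }
    data.frame(N = N, m = cfg$m,
               mean_T = if (length(times)) mean(times) else NA_real_,
               sem = if (length(times) > 1) sd(times) / sqrt(length(times))
                     else NA_real_,
               n_split = length(times), n_censored = censored,
               all_censored = censored == replicates)
  })
  do.call(rbind, rows)
}
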