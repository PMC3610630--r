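#' Frequency-dependent Allee growth law
#'
#' Defines the ecological half of the model: the per-capita growth rate
#' \deqn{g(n, f) = g_0(f)\,\bigl(1 - n/K(f)\bigr)\,\bigl(n/K(f) - n^*(f)/K(f)\bigr),}
#' the cubic growth law with carrying capacity `K`, Allee threshold `nstar`
#' (the minimal density required for growth when positive) and overall rate
#' magnitude `g0`.  Each parameter may depend linearly on the defector
#' frequency `f`; the Allee threshold is typically an increasing function of
#' `f` because a certain density of cooperators is required to produce enough
#' public goods for the population to grow.
#'
#' `nstar/K` in `(0, 1/2)` is a strong Allee effect; `nstar < 0` a weak or
#' absent one.  Fronts are pushed (velocity set by the bulk nonlinearity) for
#' `nstar/K > -1/2` and pulled (velocity set by the linear leading edge)
#' below that.
#'
#' @param g0 growth-rate magnitude at `f = 0` (1/time), `> 0`.
#' @param K carrying capacity at `f = 0` (density), `> 0`.
#' @param nstar Allee threshold at `f = 0` (density), `< K`.
#' @param nstar_slope,K_slope,g0_slope linear coefficients of the dependence
#'   of each parameter on the defector frequency, e.g.
#'   `nstar(f) = nstar + nstar_slope * f`.  Defaults 0 (constants).
#' @return An object of class `growth_law` with callable fields `g0(f)`,
#'   `K(f)`, `nstar(f)` and the per-capita rate `g(n, f)`.
#' @examples
#' gl <- growth_law(g0 = 1, K = 1, nstar = 0.2, nstar_slope = 0.3)
#' gl$g(gl$K(0), 0)      # zero at carrying capacity
#' gl$g(gl$nstar(0.5), 0.5)  # zero at the Allee threshold
#' @export
growth_law <- function(g0 = 1, K = 1, nstar = 0.2,
                       nstar_slope = 0, K_slope = 0, g0_slope = 0) {
  stopifnot(is.numeric(g0), g0 >= 0, is.numeric(K), K > 0, is.numeric(nstar))
  pars <- list(g0 = g0, K = K, nstar = nstar, nstar_slope = nstar_slope,
               K_slope = K_slope, g0_slope = g0_slope)
  g0f    <- function(f) g0 + g0_slope * f
  Kf     <- function(f) K + K_slope * f
  nstarf <- function(f) nstar + nstar_slope * f
  law <- list(
    g0 = g0f, K = Kf, nstar = nstarf, pars = pars,
    g = function(n, f) {
      kk <- Kf(f)
      g0f(f) * (1 - n / kk) * (n / kk - nstarf(f) / kk)
    })
  class(law) <- "growth_law"
  # validity over the whole frequency simplex
  fchk <- seq(0, 1, length.out = 11)
  if (any(Kf(fchk) <= 0)) stop("K(f) must be positive for all f in [0,1]")
  if (any(g0f(fchk) < 0)) stop("g0(f) must be non-negative for all f in [0,1]")
  if (any(nstarf(fchk) >= Kf(fchk)))
    stop("nstar(f) must be below K(f) for all f in [0,1]")
  law
}

#' Density-dependent frequency-dependent selection law
#'
#' Defines the evolutionary half of the model: the relative growth rate of
#' defectors \deqn{w(n, f) = s(n)\,\bigl(f^*(n) - f\bigr),} the weak-selection
#' (linear) form of frequency-dependent selection, with preferred defector
#' frequency `fstar` switching from a high value at high population density
#' (defectors exploit an established population) to a low -- possibly
#' negative -- value below a critical density `n_c` (cooperators are favored
#' where public goods are scarce):
#' \deqn{f^*(n) = f_{high}\,\Theta(n - n_c) + f_{low}\,\Theta(n_c - n),}
#' with `Theta` the Heaviside step, implemented right-continuous
#' (`Theta(0) = 1`).  The step may be smoothed over a density width
#' `smooth_eps` using a logistic sigmoid, which improves the convergence of
#' the spectral splitting predictor; `smooth_eps = 0` keeps the sharp step.
#'
#' `nonviable_below_nc = TRUE` selects the exactly solvable special case in
#' which defectors are not merely disfavored but non-viable below `n_c`: the
#' PDE solver removes defectors wherever `n < n_c` and the spectral predictor
#' imposes an absorbing condition at the point of the front where the density
#' crosses `n_c`.  In that case `f_low` is ignored.
#'
#' @param s selection strength (1/time), `>= 0`.  A single number (the usual
#'   case) or a function of density for the slower R integration path.
#' @param f_high preferred defector frequency above `n_c`, in `(0, 1)`.
#' @param f_low preferred defector frequency below `n_c`; `<= f_high`, may be
#'   negative (defectors selected against at low density).
#' @param n_c critical density at which selection switches (density units).
#' @param smooth_eps logistic smoothing width of the step, in density units.
#' @param nonviable_below_nc logical; see Details.
#' @return An object of class `selection_law` with callable fields
#'   `s(n)`, `fstar(n)` and `w(n, f)`.
#' @examples
#' sl <- selection_law(s = 0.1, f_high = 0.3, f_low = -1, n_c = 0.5)
#' sl$fstar(c(0.2, 0.8))
#' sl$w(0.8, sl$fstar(0.8))  # zero at the preferred frequency
#' @export
selection_law <- function(s = 0.1, f_high = 0.3, f_low = 0, n_c = 0.2,
                          smooth_eps = 0, nonviable_below_nc = FALSE) {
  if (is.numeric(s)) stopifnot(length(s) == 1L, s >= 0)
  stopifnot(f_high > 0, f_high < 1, f_low <= f_high, n_c >= 0, smooth_eps >= 0)
  pars <- list(s = if (is.numeric(s)) s else NA_real_,
               f_high = f_high, f_low = f_low, n_c = n_c,
               smooth_eps = smooth_eps, nonviable_below_nc = nonviable_below_nc)
  sfun <- if (is.function(s)) s else function(n) rep_len(pars$s, length(n))
  fstarf <- function(n) {
    if (smooth_eps > 0)
      f_low + (f_high - f_low) / (1 + exp(-(n - n_c) / smooth_eps))
    else
      ifelse(n >= n_c, f_high, f_low)   # right-continuous step
  }
  law <- list(
    s = sfun, fstar = fstarf, pars = pars,
    w = function(n, f) sfun(n) * (fstarf(n) - f))
  class(law) <- "selection_law"
  law
}

#' Bundle of model parameters
#'
#' @param D diffusion constant (length^2/time), the same for both alleles
#'   because population and genetic spreading are driven by the same
#'   migration process.
#' @param growth a [growth_law()].
#' @param selection a [selection_law()].
#' @return An object of class `model_params`.
#' @examples
#' p <- model_params(D = 1, growth_law(), selection_law())
#' @export
model_params <- function(D = 1, growth = growth_law(),
                         selection = selection_law()) {
  stopifnot(is.numeric(D), length(D) == 1L, D > 0,
            inherits(growth, "growth_law"), inherits(selection, "selection_law"))
  structure(list(D = D, growth = growth, selection = selection),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  gp <- x$growth$pars; sp <- x$selection$pars
  cat("<model_params>\n")
  cat(sprintf("  D = %g\n", x$D))
  cat(sprintf("  growth:    g0 = %g, K = %g, nstar(f) = %g + %g f\n",
              gp$g0, gp$K, gp$nstar, gp$nstar_slope))
  cat(sprintf("  selection: s = %g, f* = %g above n_c = %g, %s below\n",
              sp$s, sp$f_high, sp$n_c,
              if (sp$nonviable_below_nc) "defectors non-viable"
              else sprintf("f* = %g", sp$f_low)))
  invisible(x)
}

# TRUE when every law is in the parametric family the C++ kernels implement
is_parametric <- function(params) {
  !is.na(params$selection$pars$s)
}

#' Local (non-spatial) reaction rates in density-frequency form
#'
#' Time derivatives of population density `n` and defector frequency `f`
#' under the coupled model, without the spatial terms:
#' \deqn{\dot n = n\,g(n, f), \qquad \dot f = f\,(1 - f)\,w(n, f).}
#' The logistic prefactor `f (1 - f)` pins the boundaries of the frequency
#' simplex: `df/dt = 0` at `f = 0` and `f = 1`.  At `n = 0` the frequency is
#' undefined and both rates are defined to be zero.
#'
#' @param n population density, `>= 0` (vectorized).
#' @param f defector frequency in `[0, 1]` (vectorized).
#' @param params a [model_params()].
#' @return A list with numeric components `dn_dt` and `df_dt`.
#' @examples
#' p <- model_params()
#' local_rates_nf(p$growth$K(0.2), 0.2, p)
#' @export
local_rates_nf <- function(n, f, params) {
  if (any(n < 0)) stop("density n must be non-negative")
  if (any(f < 0 | f > 1)) stop("frequency f must lie in [0, 1]")
  dn <- n * params$growth$g(n, f)
  df <- f * (1 - f) * params$selection$w(n, f)
  zero <- n == 0
  dn[zero] <- 0; df[zero] <- 0
  list(dn_dt = dn, df_dt = df)
}

#' Local reaction rates in species (cooperator, defector) form
#'
#' The same local dynamics as [local_rates_nf()] written for the cooperator
#' and defector densities `c = n (1 - f)` and `d = n f`:
#' \deqn{\dot c = c\,[g(n,f) - f\,w(n,f)], \qquad
#'       \dot d = d\,[g(n,f) + (1 - f)\,w(n,f)].}
#' The two forms are exact algebraic transforms of one another:
#' `dn/dt = dc/dt + dd/dt` and `df/dt = (dd/dt - f dn/dt)/n` wherever
#' `n > 0`.  At `c + d = 0` the frequency is undefined and both rates are
#' zero by convention.
#'
#' @param c cooperator density, `>= 0` (vectorized).
#' @param d defector density, `>= 0` (vectorized).
#' @param params a [model_params()].
#' @return A list with numeric components `dc_dt` and `dd_dt`.
#' @export
local_rates_cd <- function(c, d, params) {
  if (any(c < 0) || any(d < 0)) stop("densities must be non-negative")
  n <- c + d
  f <- ifelse(n > 0, d / n, 0)
  g <- params$growth$g(n, f)
  w <- params$selection$w(n, f)
  dc <- c * (g - f * w)
  dd <- d * (g + (1 - f) * w)
  zero <- n == 0
  dc[zero] <- 0; dd[zero] <- 0
  list(dc_dt = dc, dd_dt = dd)
}

#' Serialize model parameters to a flat key-value list
#'
#' The flat form round-trips through JSON (or YAML) config files used by the
#' command-line driver.  Only parametric laws (numeric `s`) serialize.
#'
#' @param params a [model_params()].
#' @return A named list of scalars.
#' @seealso [params_from_config()]
#' @export
params_to_config <- function(params) {
  if (!is_parametric(params))
    stop("only parametric laws (numeric s) can be serialized")
  gp <- params$growth$pars; sp <- params$selection$pars
  c(list(D = params$D), gp, sp)
}

#' Rebuild model parameters from a flat key-value list
#'
#' @param config a named list as produced by [params_to_config()]; unknown
#'   keys are an error.
#' @return A [model_params()].
#' @export
params_from_config <- function(config) {
  known <- c("D", "g0", "K", "nstar", "nstar_slope", "K_slope", "g0_slope",
             "s", "f_high", "f_low", "n_c", "smooth_eps", "nonviable_below_nc")
  extra <- setdiff(names(config), known)
  if (length(extra)) stop("unknown config keys: ", paste(extra, collapse = ", "))
  get0 <- function(key, default) if (is.null(config[[key]])) default else config[[key]]
  model_params(
    D = get0("D", 1),
    growth = growth_law(g0 = get0("g0", 1), K = get0("K", 1),
                        nstar = get0("nstar", 0.2),
                        nstar_slope = get0("nstar_slope", 0),
                        K_slope = get0("K_slope", 0),
                        g0_slope = get0("g0_slope", 0)),
    selection = selection_law(s = get0("s", 0.1),
                              f_high = get0("f_high", 0.3),
                              f_low = get0("f_low", 0),
                              n_c = get0("n_c", 0.2),
                              smooth_eps = get0("smooth_eps", 0),
                              nonviable_below_nc = get0("nonviable_below_nc", FALSE)))
}
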