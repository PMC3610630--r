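#' Expansion velocity of a single-allele wave
#'
#' Closed-form asymptotic velocity of a range-expansion wave under the cubic
#' Allee growth law with the model parameters evaluated at a fixed defector
#' frequency `f`.  In the pushed regime (`nstar/K > -1/2`) the velocity is
#' exact:
#' \deqn{v_C = \sqrt{D g_0 / 2}\,\bigl(1 - 2 n^*/K\bigr),}
#' so a population exactly at `nstar = K/2` stalls (the cubic is symmetric
#' under `n -> K - n` there) and a deeper Allee effect always slows the
#' front.  For `nstar/K <= -1/2` the front is pulled and the velocity is the
#' linear-spreading value \eqn{2\sqrt{D g_0 |n^*|/K}} set by the leading
#' edge; the returned `regime` flags which expression was used.
#'
#' @param params a [model_params()].
#' @param f defector frequency at which the growth parameters are evaluated
#'   (default 0: pure cooperators).
#' @return A list with `v` (velocity), `regime` (`"pushed"` or `"pulled"`)
#'   and the evaluated `g0`, `K`, `nstar`.
#' @examples
#' expansion_velocity(model_params())          # pushed Allee front
#' @export
expansion_velocity <- function(params, f = 0) {
  gl <- params$growth
  g0 <- gl$g0(f); K <- gl$K(f); ns <- gl$nstar(f); D <- params$D
  a <- ns / K
  if (a > -0.5) {
    list(v = sqrt(D * g0 / 2) * (1 - 2 * a), regime = "pushed",
         g0 = g0, K = K, nstar = ns)
  } else {
    list(v = 2 * sqrt(D * g0 * (-a)), regime = "pulled",
         g0 = g0, K = K, nstar = ns)
  }
}

#' Characteristic front width of the expansion wave
#'
#' The density profile relaxes from `K` to 0 over a width
#' \eqn{w = \sqrt{2 D / g_0}}; halving `g0` widens the front by `sqrt(2)`.
#'
#' @inheritParams expansion_velocity
#' @return Front width (length units).
#' @export
front_width <- function(params, f = 0) {
  sqrt(2 * params$D / params$growth$g0(f))
}

#' Exact comoving front profile of the Allee expansion wave
#'
#' In the pushed regime the stationary profile in the comoving coordinate
#' `zeta` is known exactly:
#' \deqn{n(\zeta) = \frac{K}{1 + e^{\zeta / w}}, \qquad w = \sqrt{2D/g_0},}
#' centered so that `n(0) = K/2` (the half-maximum convention used for front
#' tracking).  It satisfies the comoving steady state
#' `D n'' + v n' + n g(n) = 0` with `v` from [expansion_velocity()].
#'
#' @param zeta comoving coordinate(s); negative values are behind the front.
#' @inheritParams expansion_velocity
#' @return Numeric vector of densities with attribute `width` (the front
#'   width `w`).
#' @examples
#' front_profile(0, model_params())   # = K/2
#' @export
front_profile <- function(zeta, params, f = 0) {
  ev <- expansion_velocity(params, f)
  if (ev$regime != "pushed")
    stop("exact profile is only available in the pushed regime")
  w <- front_width(params, f)
  structure(ev$K / (1 + exp(zeta / w)), width = w)
}

#' Invasion velocity of defectors into an established population
#'
#' When defectors are rare in a population of cooperators at density `n`,
#' their frequency grows at rate `s(n) fstar(n)` and spreads as a pulled
#' (KPP) front with the linear-spreading velocity
#' \deqn{v_D = 2 \sqrt{D\, s(n)\, f^*(n)}.}
#' If `fstar(n) <= 0` defectors cannot invade and the velocity is 0 with
#' `invades = FALSE`.
#'
#' @param params a [model_params()].
#' @param n density of the resident population (default: carrying capacity
#'   at `f = 0`).
#' @return A list with `v` and logical `invades`.
#' @examples
#' invasion_velocity(model_params())
#' @export
invasion_velocity <- function(params, n = params$growth$K(0)) {
  s <- params$selection$s(n)
  fst <- params$selection$fstar(n)
  if (s <= 0 || fst <= 0) return(list(v = 0, invades = FALSE))
  list(v = 2 * sqrt(params$D * s * fst), invades = TRUE)
}

#' Mixed-wave velocity in the decoupled-selection limit
#'
#' When selection is density-independent (`f_low == f_high`, or a smoothing
#' width spanning all densities) the composition relaxes to `f = f*`
#' everywhere, the evolutionary dynamics decouple, and the mixed wave is a
#' single-allele expansion with the growth parameters evaluated at
#' `f = f*`.  Because the Allee threshold (and possibly `K`, `g0`) worsen
#' with `f`, the mixed wave is never faster than the pure-cooperator wave.
#'
#' @param params a [model_params()] with density-independent selection.
#' @return As [expansion_velocity()].
#' @export
mixed_velocity_decoupled <- function(params) {
  sp <- params$selection$pars
  if (!isTRUE(all.equal(sp$f_high, sp$f_low)))
    stop("mixed_velocity_decoupled requires density-independent selection ",
         "(f_low == f_high)")
  expansion_velocity(params, f = sp$f_high)
}

# First zero in y of the lambda = 0 comoving eigenfunction for the exactly
# solvable case, in the scaled variable y = 1 - n/K in (0, 1):
#   psi(y) = y^p (1-y)^q 2F1(p+q-1, p+q+2; 2p+1; y)
# with p = sqrt(beta^2 - betaD^2), q = sqrt((1-beta)^2 - betaD^2), and
# beta = v_C / sqrt(2 D g0), betaD = v_D / sqrt(2 D g0).
exact_psi0 <- function(y, beta, betaD) {
  p <- sqrt(beta^2 - betaD^2)
  q <- sqrt((1 - beta)^2 - betaD^2)
  y^p * (1 - y)^q * hyp2f1(p + q - 1, p + q + 2, 2 * p + 1, y)
}

exact_first_zero <- function(beta, betaD) {
  ys <- seq(1e-6, 1 - 1e-9, length.out = 4096)
  vals <- exact_psi0(ys, beta, betaD)
  i <- which(vals <= 0)[1]
  if (is.na(i)) return(NA_real_)
  uniroot(exact_psi0, c(ys[i - 1], ys[i]), beta = beta, betaD = betaD,
          tol = 1e-12)$root
}

#' Exact splitting threshold for the solvable special case
#'
#' In the special case with constant selection strength, constant preferred
#' defector frequency `f_high` above the critical density, defectors
#' non-viable below it (an absorbing condition where the front density
#' crosses `n_c`), and frequency-independent ecological parameters, the
#' rare-defector eigenproblem at the cooperator front can be solved in
#' closed form.  Writing `beta = v_C / sqrt(2 D g0)` and
#' `betaD = v_D / sqrt(2 D g0)`, the marginal (`lambda = 0`) eigenfunction
#' on the exact front profile is
#' \deqn{\psi(y) = y^{p} (1-y)^{q}\,
#'   {}_2F_1\!\bigl(p+q-1,\, p+q+2;\, 2p+1;\, y\bigr),}
#' with `y = 1 - n/K`, `p = sqrt(beta^2 - betaD^2)` and
#' `q = sqrt((1-beta)^2 - betaD^2)`.  A bound state with `lambda >= 0`
#' (a steady mixed wave) exists precisely when the absorbing point
#' `y_c = 1 - n_c/K` lies beyond the first zero `y_0` of `psi`; splitting
#' occurs when `y_c < y_0`, i.e. for
#' \deqn{n_c > K\,(1 - y_0).}
#' As `v_D` approaches `v_C` from below, `y_0 -> 0` and the critical density
#' required for splitting approaches `K`: splitting becomes impossible.
#' When `v_D >= v_C` defectors catch up by definition and no splitting
#' occurs for any `n_c`.
#'
#' @param params a [model_params()] whose selection law has
#'   `nonviable_below_nc = TRUE` and whose growth law is
#'   frequency-independent (zero slopes).
#' @return A list with logical `splits`, `margin` (signed distance
#'   `(n_c - n_c_crit)/K`, positive when splitting), `n_c_crit` (the critical
#'   density threshold) and the dimensionless `beta`, `betaD`.
#' @examples
#' p <- model_params(
#'   growth = growth_law(nstar = 0.05),
#'   selection = selection_law(s = 0.05, f_high = 0.5, n_c = 0.1,
#'                             nonviable_below_nc = TRUE))
#' splitting_threshold_exact(p)
#' @export
splitting_threshold_exact <- function(params) {
  gp <- params$growth$pars; sp <- params$selection$pars
  if (!sp$nonviable_below_nc)
    stop("splitting_threshold_exact applies to the special case ",
         "with nonviable_below_nc = TRUE")
  if (gp$nstar_slope != 0 || gp$K_slope != 0 || gp$g0_slope != 0)
    stop("splitting_threshold_exact requires frequency-independent growth")
  ev <- expansion_velocity(params, 0)
  if (ev$regime != "pushed")
    stop("splitting_threshold_exact requires a pushed cooperator front")
  vC <- ev$v
  vD <- invasion_velocity(params, n = gp$K)$v
  scale <- sqrt(2 * params$D * gp$g0)
  beta <- vC / scale; betaD <- vD / scale
  if (vD >= vC)
    return(list(splits = FALSE, margin = -Inf, n_c_crit = NA_real_,
                beta = beta, betaD = betaD))
  y0 <- exact_first_zero(beta, betaD)
  if (is.na(y0))   # psi never vanishes: no n_c in (0, K) allows a split
    return(list(splits = FALSE, margin = -Inf, n_c_crit = NA_real_,
                beta = beta, betaD = betaD))
  n_c_crit <- gp$K * (1 - y0)
  margin <- (sp$n_c - n_c_crit) / gp$K
  list(splits = margin > 0, margin = margin, n_c_crit = n_c_crit,
       beta = beta, betaD = betaD)
}
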