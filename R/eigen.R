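#' Stationary cooperator front in the comoving frame
#'
#' Builds the discretized front profile `n(zeta)` and frame velocity used by
#' the spectral splitting predictor.  By default the exact pushed-front
#' profile is used (valid because near the splitting transition the
#' expansion front is populated almost exclusively by cooperators); a
#' converged PDE profile can be supplied instead for parameter sets outside
#' the exactly solvable family.
#'
#' @param params a [model_params()].
#' @param f frequency at which the growth parameters are evaluated
#'   (default 0).
#' @param span_widths half-width of the truncated domain in units of the
#'   front width (default 15; the effective potential plateaus
#'   exponentially off the front).
#' @param points_per_width grid resolution (default 40).
#' @param profile `"exact"` or a function `n(zeta)` (e.g. an interpolant of
#'   a converged numerical front centered at half maximum).
#' @return An object of class `comoving_frontier` with fields `zeta`, `n`,
#'   `v`, `width`, `dz`.
#' @export
comoving_frontier <- function(params, f = 0, span_widths = 15,
                              points_per_width = 40, profile = "exact") {
  w <- front_width(params, f)
  ev <- expansion_velocity(params, f)
  dz <- w / points_per_width
  zeta <- seq(-span_widths * w, span_widths * w, by = dz)
  n <- if (is.function(profile)) profile(zeta) else front_profile(zeta, params, f)
  if (any(diff(n) > 1e-12)) stop("front profile must be monotone decreasing")
  K <- params$growth$K(f)
  if (abs(n[1] - K) > 0.01 * K || n[length(n)] > 0.01 * K)
    stop("truncated domain does not reach the bulk/empty plateaus; ",
         "increase span_widths")
  structure(list(zeta = zeta, n = as.numeric(n), v = ev$v, width = w,
                 dz = dz, K = K),
            class = "comoving_frontier")
}

#' Effective advection and growth felt by rare defectors at the front
#'
#' In the frame comoving with the cooperator front, the migration coupling
#' to the density gradient, `2 D (n'/n) f'`, acts on the defector frequency
#' as an advection towards the bulk with speed
#' `advection(zeta) = -2 D n'(zeta)/n(zeta) >= 0`, and — once the advection
#' is written in conservative form — as an effective growth
#' `growth(zeta) = -d/dzeta [2 D n'/n] >= 0`.  On the exact front profile
#' these are `sqrt(2 D g0) (1 - n/K)` and `g0 (n/K)(1 - n/K)`: the growth
#' term peaks at the middle of the front where `n = K/2` (`zeta = 0`).
#'
#' @param frontier a [comoving_frontier()].
#' @param params a [model_params()].
#' @return A list with numeric vectors `advection`, `growth`, the raw
#'   log-derivative `a = 2 D n'/n`, and the (possibly truncated) index range
#'   used.
#' @export
effective_terms <- function(frontier, params) {
  n <- frontier$n; dz <- frontier$dz; D <- params$D
  keep <- n > 1e-12 * frontier$K
  if (!all(keep)) {
    warning("front profile touches zero inside the domain; truncating")
    keep_idx <- seq_len(max(which(keep)))
  } else keep_idx <- seq_along(n)
  n <- n[keep_idx]
  m <- length(n)
  # central differences inside, second-order one-sided at the ends
  ddz <- function(u) c((-3 * u[1] + 4 * u[2] - u[3]) / (2 * dz),
                       (u[3:m] - u[1:(m - 2)]) / (2 * dz),
                       (3 * u[m] - 4 * u[m - 1] + u[m - 2]) / (2 * dz))
  dndz <- ddz(n)
  a <- 2 * D * dndz / n
  dadz <- ddz(a)
  list(advection = -a, growth = -dadz, a = a, idx = keep_idx)
}

#' Schroedinger potential of the rare-defector eigenproblem
#'
#' Linearizing the comoving defector-frequency dynamics about `f = 0` gives
#' the operator `L = D d^2/dzeta^2 + (v + a) d/dzeta + s(n) fstar(n)` with
#' `a = 2 D n'/n`.  The Liouville substitution
#' `f = psi exp(-integral (v + a)/(2D) dzeta)` brings the eigenproblem
#' `L f = lambda f` to canonical self-adjoint form
#' `lambda psi = D psi'' - U psi` with
#' \deqn{U(\zeta) = \frac{(v + a)^2}{4 D} + \frac{a'}{2} - s(n) f^*(n).}
#' Behind the front `U(-\infty) = (v_C^2 - v_D^2)/(4D)`, positive exactly
#' when cooperators spread faster than defectors invade; ahead of the front
#' `U` is positive when defectors are sufficiently disfavored at low
#' density.  In between the `a'/2` term digs a potential well centered on
#' the front; a steady mixed wave exists precisely when the well supports a
#' bound state with `lambda >= 0`.
#'
#' For a sharp Heaviside preferred-frequency step the potential is smoothed
#' over one grid cell (in density units) unless the selection law carries
#' its own smoothing width, since a discontinuous potential degrades
#' spectral convergence without affecting bound-state existence.
#'
#' @param frontier a [comoving_frontier()].
#' @param params a [model_params()].
#' @return A list with `zeta`, `U`, `advection`, `growth`, `n` on the
#'   (possibly truncated) grid.
#' @export
schroedinger_potential <- function(frontier, params) {
  et <- effective_terms(frontier, params)
  idx <- et$idx
  zeta <- frontier$zeta[idx]; n <- frontier$n[idx]
  D <- params$D; v <- frontier$v
  sp <- params$selection$pars
  sfun <- params$selection$s
  eps <- sp$smooth_eps
  if (eps <= 0) eps <- 5e-3 * frontier$K   # fixed, grid-independent default
  fst <- sp$f_low + (sp$f_high - sp$f_low) / (1 + exp(-(n - sp$n_c) / eps))
  U <- (v + et$a)^2 / (4 * D) + (-et$growth) / 2 - sfun(n) * fst
  list(zeta = zeta, U = U, advection = et$advection, growth = et$growth,
       n = n)
}

# Largest eigenvalue of the symmetric tridiagonal discretization of
# H = D d^2/dz^2 - U with Dirichlet ends, by Sturm-sequence bisection.
tridiag_lambda_max <- function(U, dz, D, tol = 1e-12) {
  ni <- length(U) - 2L
  dmain <- -2 * D / dz^2 - U[2:(length(U) - 1)]
  off2 <- (D / dz^2)^2
  count_gt <- function(lam) {
    dd <- dmain[1] - lam
    cnt <- as.integer(dd > 0)
    for (i in 2:ni) {
      dd <- (dmain[i] - lam) - off2 / dd
      if (dd == 0) dd <- .Machine$double.xmin
      cnt <- cnt + (dd > 0)
    }
    cnt
  }
  hi <- max(-dmain) + 2 * D / dz^2   # Gershgorin upper bound
  lo <- -max(abs(dmain)) - 2 * D / dz^2
  while (hi - lo > tol * max(1, abs(hi), abs(lo))) {
    mid <- (lo + hi) / 2
    if (count_gt(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Thomas solve of (H - sigma I) x = b for the same tridiagonal H.
tridiag_shift_solve <- function(U, dz, D, sigma, b) {
  ni <- length(b)
  diag_ <- -2 * D / dz^2 - U - sigma
  off <- D / dz^2
  cp <- numeric(ni); dp <- numeric(ni)
  cp[1] <- off / diag_[1]; dp[1] <- b[1] / diag_[1]
  for (i in 2:ni) {
    denom <- diag_[i] - off * cp[i - 1]
    cp[i] <- off / denom
    dp[i] <- (b[i] - off * dp[i - 1]) / denom
  }
  x <- numeric(ni); x[ni] <- dp[ni]
  for (i in (ni - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

#' Largest eigenvalue and bound state of the canonical operator
#'
#' Computes the largest eigenvalue of `H = D d^2/dzeta^2 - U(zeta)` on the
#' truncated domain with decaying (Dirichlet) boundary values, using
#' Sturm-sequence bisection on the symmetric tridiagonal discretization,
#' and recovers the eigenfunction by shifted inverse iteration.  The
#' eigenfunction is returned normalized (`sum(psi^2) * dz = 1`).
#'
#' @param U potential values on a uniform grid (including the two boundary
#'   points, which are treated as Dirichlet).
#' @param dz grid spacing.
#' @param D diffusion constant.
#' @return A list with `lambda` and normalized `psi` (same length as `U`,
#'   zero at the ends).
#' @export
max_eigenvalue <- function(U, dz, D = 1) {
  stopifnot(length(U) > 10, dz > 0, D > 0)
  lam <- tridiag_lambda_max(U, dz, D)
  Ui <- U[2:(length(U) - 1)]
  b <- rep(1, length(Ui))
  x <- b / sqrt(sum(b^2))
  for (k in 1:50) {
    x_new <- tridiag_shift_solve(Ui, dz, D, lam + 1e-10, x)
    x_new <- x_new / sqrt(sum(x_new^2))
    if (max(abs(abs(x_new) - abs(x))) < 1e-12) { x <- x_new; break }
    x <- x_new
  }
  if (sum(x) < 0) x <- -x
  psi <- c(0, x, 0)
  psi <- psi / sqrt(sum(psi^2) * dz)
  list(lambda = lam, psi = psi)
}

#' Bound-state necessary condition and integral identity
#'
#' Multiplying `lambda psi = D psi'' - U psi` by `psi` and integrating by
#' parts gives
#' `lambda Int psi^2 + D Int (psi')^2 + Int U psi^2 = 0`:
#' since the first two terms are non-negative for `lambda >= 0`, a bound
#' state with non-negative eigenvalue requires a region where `U < 0`.
#' The identity is checked in its discrete form (exact for the tridiagonal
#' operator up to round-off).
#'
#' @param U potential on the grid.
#' @param eig result of [max_eigenvalue()] for this `U`.
#' @param dz grid spacing.
#' @param D diffusion constant.
#' @return A list with `well_exists` (`min(U) < 0`), `residual` (relative
#'   residual of the integral identity) and `ok` (both conditions for a
#'   bound state with `lambda >= 0`).
#' @export
necessary_condition <- function(U, eig, dz, D = 1) {
  psi <- eig$psi
  grad2 <- sum(diff(psi)^2) / dz       # D' Dirichlet gradient sum * dz
  lhs <- eig$lambda * sum(psi^2) * dz + D * grad2 + sum(U * psi^2) * dz
  scale <- abs(eig$lambda) * sum(psi^2) * dz + D * grad2 +
    sum(abs(U) * psi^2) * dz
  residual <- abs(lhs) / max(scale, 1e-300)
  list(well_exists = min(U) < 0, residual = residual,
       ok = min(U) < 0 && residual < 1e-6)
}

#' Spectral splitting prediction
#'
#' The full pipeline of the splitting criterion: closed-form front velocity
#' and profile, effective comoving terms, Schroedinger potential, largest
#' eigenvalue.  A steady mixed wave exists if and only if the operator has
#' a bound state with `lambda_max > 0`; the wave splits into a
#' pure-cooperator expansion followed by a defector invasion when
#' `lambda_max <= 0`.  When the defector invasion is at least as fast as
#' the cooperator expansion (`v_D >= v_C`) defectors always catch up and
#' the mixed regime is forced regardless of the eigenvalue.
#'
#' Convergence is verified by halving the grid step; the margin is reported
#' as `lambda_max` in units of the selection strength so that parameter
#' sweeps are comparable.
#'
#' @param params a [model_params()].
#' @param boundary `"decaying"` (Dirichlet at the truncated domain ends) or
#'   `"absorbing"` (Dirichlet where the front density crosses `n_c`;
#'   automatic when the selection law has `nonviable_below_nc = TRUE`).
#' @param span_widths,points_per_width domain truncation and resolution,
#'   passed to [comoving_frontier()].
#' @param profile as in [comoving_frontier()].
#' @return A list of class `eigen_result`: `splits`, `lambda_max`, `margin`
#'   (`lambda_max / s`), `v_C`, `v_D`, `regime`, `U`, `zeta`, `psi`.
#' @examples
#' p <- model_params(selection = selection_law(s = 0.1, f_high = 0.3,
#'                                             f_low = -1, n_c = 0.7))
#' predict_splitting(p)$splits
#' @export
predict_splitting <- function(params, boundary = c("decaying", "absorbing"),
                              span_widths = 15, points_per_width = 40,
                              profile = "exact") {
  boundary <- match.arg(boundary)
  sp <- params$selection$pars
  if (sp$nonviable_below_nc) boundary <- "absorbing"
  ev <- expansion_velocity(params, 0)
  vC <- ev$v
  vD <- invasion_velocity(params, n = params$growth$K(0))$v
  if (vC <= vD)
    return(structure(list(splits = FALSE, lambda_max = NA_real_,
                          margin = NA_real_, v_C = vC, v_D = vD,
                          regime = "defectors_catch_up"),
                     class = "eigen_result"))
  w <- front_width(params, 0)
  K <- params$growth$K(0)
  s_scale <- params$selection$s(K)
  one_pass <- function(ppw) {
    dz <- w / ppw
    if (boundary == "absorbing") {
      # place a node exactly at zeta_c where the exact profile crosses n_c,
      # so the Dirichlet cut converges at the scheme's second order
      if (is.function(profile))
        stop("absorbing boundary requires the exact front profile")
      y_c <- 1 - sp$n_c / K
      if (y_c <= 0 || y_c >= 1)
        stop("n_c must lie strictly inside (0, K) for the absorbing case")
      zeta_c <- w * log(y_c / (1 - y_c))
      zeta <- seq(zeta_c, -span_widths * w, by = -dz)
      zeta <- rev(zeta)
      n <- front_profile(zeta, params, 0)
      dndz <- -n * (1 - n / K) / w          # exact profile derivative
      a <- 2 * params$D * dndz / n
      dadz <- -2 * params$D / w^2 * (n / K) * (1 - n / K)
      U <- (ev$v + a)^2 / (4 * params$D) + dadz / 2 -
        params$selection$s(n) * sp$f_high
      eig <- max_eigenvalue(U, dz, params$D)
      list(lambda = eig$lambda, eig = eig, U = U, zeta = zeta, dz = dz)
    } else {
      fr <- comoving_frontier(params, 0, span_widths, ppw, profile)
      pot <- schroedinger_potential(fr, params)
      eig <- max_eigenvalue(pot$U, fr$dz, params$D)
      list(lambda = eig$lambda, eig = eig, U = pot$U, zeta = pot$zeta,
           dz = fr$dz)
    }
  }
  p1 <- one_pass(points_per_width)
  p2 <- one_pass(2 * points_per_width)
  lam <- (4 * p2$lambda - p1$lambda) / 3    # Richardson (second-order scheme)
  if (abs(p2$lambda - p1$lambda) / 3 > 1e-3 * max(abs(lam), s_scale))
    stop(sprintf("eigenvalue not converged under grid halving: %g vs %g",
                 p1$lambda, p2$lambda))
  structure(list(splits = lam <= 0, lambda_max = lam,
                 margin = lam / s_scale, v_C = vC, v_D = vD,
                 regime = ev$regime, U = p2$U, zeta = p2$zeta,
                 psi = p2$eig$psi, dz = p2$dz),
            class = "eigen_result")
}

#' @export
print.eigen_result <- function(x, ...) {
  if (identical(x$regime, "defectors_catch_up")) {
    cat(sprintf("<eigen_result> v_D = %.4g >= v_C = %.4g: mixed regime forced\n",
                x$v_D, x$v_C))
  } else {
    cat(sprintf("<eigen_result> lambda_max = %.5g (margin %.3g s): %s\n",
                x$lambda_max, x$margin,
                if (x$splits) "wave splits" else "steady mixed wave"))
  }
  invisible(x)
}
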