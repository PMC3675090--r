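#' Effective stretching strain along the cell axis
#'
#' A cell oriented at angle \eqn{\theta} to the stretch axis feels only the
#' strain component resolved along its long axis. With substrate Poisson
#' ratio \eqn{\nu} the transverse contraction contributes with opposite sign:
#' \deqn{\epsilon_a = \epsilon_A (\cos^2\theta - \nu \sin^2\theta).}
#' The result is even and \eqn{\pi}-periodic in \eqn{\theta}, and is negative
#' (compression along the cell) when \eqn{\nu \sin^2\theta > \cos^2\theta};
#' for \eqn{\nu = 0.5} the zero-strain direction is
#' \eqn{\theta^* = \arctan\sqrt{2} \approx 54.7^\circ}.
#'
#' @param theta Orientation angle(s) in radians.
#' @param amplitude Applied strain amplitude \eqn{\epsilon_A} (>= 0).
#' @param nu Poisson ratio of the substrate, in \eqn{[0, 0.5]}.
#' @return Effective strain amplitude(s) along the cell axis.
#' @examples
#' effective_strain(0, 0.1)                  # 0.1
#' effective_strain(pi / 2, 0.1, nu = 0.5)   # -0.05
#' @export
effective_strain <- function(theta, amplitude, nu = 0) {
  stopifnot(all(amplitude >= 0), all(nu >= 0), all(nu <= 0.5))
  w <- cos(theta)^2 - nu * sin(theta)^2
  w[abs(w) < 1e-14] <- 0  # exact zero at the perpendicular/zero-strain angle
  amplitude * w
}

#' Strain-stiffening factor of the substrate modulus
#'
#' Elastomeric and biopolymer substrates are nearly linear at small strain
#' and stiffen following a power law of index 3/2 beyond a critical strain:
#' \deqn{s(\epsilon) = \max\{1, (|\epsilon| / \epsilon_c)^{3/2}\}.}
#' The factor multiplies the bond-substrate spring constant, is continuous at
#' the threshold, even in strain, and identically 1 for a linear substrate
#' (\code{eps_c = Inf}).
#'
#' @param eps Instantaneous strain (signed; only the magnitude matters).
#' @param eps_c Critical strain (> 0, possibly \code{Inf}).
#' @return Stiffening factor(s) >= 1.
#' @export
stiffening_factor <- function(eps, eps_c) {
  stopifnot(all(eps_c > 0))
  r <- abs(eps) / eps_c
  ifelse(is.finite(eps_c) & r >= 1, r^1.5, 1)
}

# strain waveform w(tau) in [0,1] (cosine) or [-1,1] (sine) and its rate
waveform_value <- function(protocol, tau) {
  if (is_static(protocol)) return(rep(0, length(tau)))
  switch(protocol$waveform,
         cosine = (1 - cos(protocol$omega * tau)) / 2,
         sine   = sin(protocol$omega * tau))
}

waveform_rate <- function(protocol, tau) {
  if (is_static(protocol)) return(rep(0, length(tau)))
  switch(protocol$waveform,
         cosine = protocol$omega * sin(protocol$omega * tau) / 2,
         sine   = protocol$omega * cos(protocol$omega * tau))
}

#' Instantaneous strain felt by a stress fiber
#'
#' @param tau Normalized time(s).
#' @param protocol A [stretch_protocol()].
#' @param theta Cell orientation (radians).
#' @param params A [model_params()] (supplies the Poisson ratio).
#' @return \eqn{\epsilon_f(\tau) = \epsilon_a \cdot w(\Omega\tau)} where
#'   \eqn{w} is the protocol waveform.
#' @export
fiber_strain <- function(tau, protocol, theta, params = model_params()) {
  effective_strain(theta, protocol$amplitude, params$nu) *
    waveform_value(protocol, tau)
}

#' Force generated within a contracting filament
#'
#' Each filament is modeled as a constant contractile (motor) force in
#' parallel with a Maxwell element: a spring of normalized stiffness
#' \eqn{\hat k} in series with a dashpot, with relaxation rate \eqn{\gamma}.
#' The total normalized force is \eqn{\hat F(\tau) = 1 + \hat F_v(\tau)} with
#' the viscoelastic branch obeying
#' \deqn{d\hat F_v/d\tau + \gamma \hat F_v = \hat k \, d\epsilon_f/d\tau.}
#' Under a static stretch the branch relaxes completely and
#' \eqn{\hat F \equiv 1} regardless of the stretch magnitude.
#'
#' \code{method = "numeric"} integrates the initial-value problem from
#' \code{fv0} (a fresh attachment starts unloaded, \code{fv0 = 0});
#' \code{method = "closed"} returns the steady-periodic solution. For the
#' sine waveform that is
#' \eqn{\hat F_v = \hat k \epsilon_a [\Omega^2 \sin\Omega\tau +
#' \gamma\Omega\cos\Omega\tau] / (\gamma^2 + \Omega^2)} with oscillation
#' amplitude \eqn{\hat k \epsilon_a \Omega / \sqrt{\gamma^2 + \Omega^2}};
#' for the raised cosine the amplitude is half that. The two methods agree
#' once the transient has decayed (\eqn{\tau \gg 1/\gamma}).
#'
#' @param tau Sorted vector of normalized times.
#' @param protocol A [stretch_protocol()].
#' @param theta Cell orientation (radians).
#' @param params A [model_params()].
#' @param fv0 Initial viscoelastic force for the numeric solution.
#' @param method "numeric" or "closed".
#' @return Vector of total filament forces \eqn{\hat F(\tau)}.
#' @export
filament_force <- function(tau, protocol, theta, params = model_params(),
                           fv0 = 0, method = c("numeric", "closed")) {
  method <- match.arg(method)
  eps_a <- effective_strain(theta, protocol$amplitude, params$nu)
  if (is_static(protocol) || eps_a == 0) {
    if (method == "numeric" && fv0 != 0) {
      return(1 + fv0 * exp(-params$gamma * (tau - tau[1])))
    }
    return(rep(1, length(tau)))
  }
  om <- protocol$omega
  g <- params$gamma
  if (method == "closed") {
    amp <- params$k_hat * eps_a
    fv <- switch(protocol$waveform,
      sine   = amp * (om^2 * sin(om * tau) + g * om * cos(om * tau)) / (g^2 + om^2),
      cosine = (amp * om / 2) * (g * sin(om * tau) - om * cos(om * tau)) / (g^2 + om^2))
    return(1 + fv)
  }
  rhs <- function(t, y, p) {
    list(params$k_hat * eps_a * waveform_rate(protocol, t) - g * y)
  }
  out <- deSolve::ode(y = fv0, times = tau, func = rhs, parms = NULL,
                      method = "lsoda", rtol = 1e-9, atol = 1e-12,
                      hmax = min(0.5, 2 * pi / om / 50))
  1 + out[, 2]
}

#' Energy reduction of a single ligand-receptor bond
#'
#' The binding energy gain that enters the Bell dissociation factor has three
#' contributions: the baseline gain \eqn{g_0} of an unreinforced bond, the
#' reinforcement energy \eqn{a u} from plaque proteins recruited in
#' proportion to the per-bond filament density \eqn{u = \zeta/\xi}, and the
#' elastic energy \eqn{(\beta/s)(u\hat F)^2} stored in stretching the
#' bond-substrate spring by the average per-bond load \eqn{F_b = u \hat F}:
#' \deqn{\hat G = g_0 + a u - (\beta/s) (u \hat F)^2.}
#' The more the energy is reduced (larger \eqn{\hat G}), the slower the bond
#' dissociates. With no filaments (\eqn{\zeta = 0}) the result is exactly
#' \eqn{g_0}.
#'
#' @param xi Bond density in \eqn{[0, 1]}.
#' @param zeta Filament density (>= 0).
#' @param f_hat Instantaneous filament force \eqn{\hat F}.
#' @param s Stiffening factor (>= 1).
#' @param params A [model_params()].
#' @param xi_floor Degenerate-state guard: if \code{xi <= xi_floor} while
#'   \code{zeta > 0} the load ratio is not evaluable and the cell must be
#'   treated as detached; a condition of class
#'   \code{"cellreorient_detached"} is signaled.
#' @return Energy reduction(s) \eqn{\hat G} in kT.
#' @examples
#' p <- model_params()
#' energy_reduction(0.5, 0, 1, 1, p)    # g0 = -5
#' energy_reduction(0.4, 0.8, 1, 1, p)  # u = 2: -5 + 7 - 2.4 = -0.4
#' @export
energy_reduction <- function(xi, zeta, f_hat, s, params = model_params(),
                             xi_floor = 1e-6) {
  if (any(zeta > 0 & xi <= xi_floor)) {
    cond <- structure(class = c("cellreorient_detached", "error", "condition"),
                      list(message = "bond density at or below floor with filaments present: cell is detached",
                           call = sys.call()))
    stop(cond)
  }
  u <- ifelse(zeta == 0, 0, zeta / xi)
  params$g0 + params$a * u - (params$beta / s) * (u * f_hat)^2
}

#' Right-hand side of the FA/SF kinetic equations
#'
#' Normalized first-order kinetics with Bell-type dissociation:
#' \deqn{d\xi/d\tau = (1 - \xi) - \xi e^{-\hat G}, \qquad
#'       d\zeta/d\tau = c\,\xi - d\,\zeta.}
#' Bond formation fills the unoccupied fraction at unit rate; dissociation is
#' exponentially accelerated as the energy reduction shrinks. Filament growth
#' is proportional to the bond density. \eqn{\hat G} is evaluated with the
#' instantaneous filament force and stiffening factor at time \code{tau}.
#'
#' @param state Named vector or list with elements \code{xi}, \code{zeta} and
#'   optionally \code{fv} (viscoelastic branch force). If \code{fv} is absent
#'   the steady-periodic closed-form force is used.
#' @param tau Normalized time.
#' @param theta Cell orientation (radians).
#' @param protocol A [stretch_protocol()].
#' @param params A [model_params()].
#' @return Named vector \code{c(dxi, dzeta)}.
#' @export
kinetics_rhs <- function(state, tau, theta, protocol, params = model_params()) {
  xi <- state[["xi"]]; zeta <- state[["zeta"]]
  f_hat <- if (!is.null(state[["fv"]]) && !is.na(state[["fv"]])) {
    1 + state[["fv"]]
  } else {
    filament_force(tau, protocol, theta, params, method = "closed")
  }
  eps_f <- fiber_strain(tau, protocol, theta, params)
  s <- stiffening_factor(eps_f, params$eps_c)
  g <- energy_reduction(xi, zeta, f_hat, s, params)
  c(dxi = (1 - xi) - xi * exp(-g),
    dzeta = params$c * xi - params$d * zeta)
}

#' Closed-form steady state on a static substrate
#'
#' On an unstretched substrate the filament force is 1 and the stiffening
#' factor is 1, the filament-to-bond ratio relaxes to \eqn{u_{ss} = c/d}, and
#' the bond density solves a logistic balance:
#' \deqn{\hat G_{ss} = g_0 + a u_{ss} - \beta u_{ss}^2, \qquad
#'       \xi_{ss} = \frac{1}{1 + e^{-\hat G_{ss}}}, \qquad
#'       \zeta_{ss} = u_{ss}\,\xi_{ss}.}
#' \eqn{\xi_{ss}} decreases exponentially as the substrate becomes more
#' compliant (larger \eqn{\beta}).
#'
#' @param params A [model_params()].
#' @return A list with \code{xi_ss}, \code{zeta_ss}, \code{u_ss}, \code{g_ss}.
#' @examples
#' steady_state_densities(model_params())          # xi ~ 0.401, zeta ~ 0.801
#' steady_state_densities(model_params(c = 0.1))   # Rho-inhibited: xi ~ 0.109
#' @export
steady_state_densities <- function(params = model_params()) {
  u <- params$c / params$d
  g <- params$g0 + params$a * u - params$beta * u^2
  xi <- 1 / (1 + exp(-g))
  list(xi_ss = xi, zeta_ss = u * xi, u_ss = u, g_ss = g)
}

#' Reinforcement-feedback compliance threshold
#'
#' The substrate compliance at which the energy reduction stops growing with
#' the per-bond filament load at steady state,
#' \eqn{d\hat G/du = a - 2\beta u_{ss} = 0}, i.e.
#' \eqn{\beta^* = a d / (2 c)}. Beyond this point a dip in bond density
#' raises the per-bond load and *lowers* the bond energy, a destabilizing
#' feedback; the linear (eigenvalue) instability of the full two-variable
#' system sets in somewhat above it (see [classify_fixed_point()]).
#'
#' @param params A [model_params()].
#' @return The compliance threshold \eqn{\beta^*}.
#' @export
critical_beta <- function(params = model_params()) {
  params$a * params$d / (2 * params$c)
}

#' Linear stability of the static steady state
#'
#' Evaluates the Jacobian of the static kinetics at
#' \eqn{(\xi_{ss}, \zeta_{ss})} by central differences and labels the fixed
#' point by the sign of the largest real part of its eigenvalues. On soft
#' substrates the steady state is unstable: any small fluctuation makes the
#' bond and filament densities collapse to zero.
#'
#' @param params A [model_params()].
#' @param delta Relative step for the central differences.
#' @return A list with \code{label} ("stable" or "unstable"),
#'   \code{eigenvalues}, \code{jacobian}, \code{beta_star} (the analytic
#'   reinforcement-feedback threshold from [critical_beta()]), and the fixed
#'   point \code{xi_ss}, \code{zeta_ss}.
#' @examples
#' classify_fixed_point(model_params(beta = 0.6))$label  # "stable"
#' classify_fixed_point(model_params(beta = 1.1))$label  # "unstable"
#' @export
classify_fixed_point <- function(params = model_params(), delta = 1e-6) {
  ss <- steady_state_densities(params)
  static <- stretch_protocol(0, 0, params$kon_per_s)
  f <- function(xi, zeta) {
    kinetics_rhs(list(xi = xi, zeta = zeta, fv = 0), 0, 0, static, params)
  }
  x0 <- ss$xi_ss; z0 <- ss$zeta_ss
  hx <- delta * max(abs(x0), 1); hz <- delta * max(abs(z0), 1)
  J <- cbind((f(x0 + hx, z0) - f(x0 - hx, z0)) / (2 * hx),
             (f(x0, z0 + hz) - f(x0, z0 - hz)) / (2 * hz))
  dimnames(J) <- list(c("dxi", "dzeta"), c("xi", "zeta"))
  ev <- eigen(J, only.values = TRUE)$values
  list(label = if (max(Re(ev)) < 0) "stable" else "unstable",
       eigenvalues = ev, jacobian = J,
       beta_star = critical_beta(params),
       xi_ss = x0, zeta_ss = z0)
}

#' Numeric stable-to-unstable transition in substrate compliance
#'
#' Bisection on the eigenvalue label of [classify_fixed_point()] over a
#' compliance interval.
#'
#' @param params A [model_params()] (its \code{beta} is ignored).
#' @param lower,upper Bracketing compliances; the label must differ between
#'   them.
#' @param tol Bisection tolerance.
#' @return The compliance at which the largest eigenvalue real part crosses
#'   zero.
#' @export
stability_transition_beta <- function(params = model_params(),
                                      lower = 0.5, upper = 1.5, tol = 1e-4) {
  lab <- function(b) {
    p <- params; p$beta <- b
    classify_fixed_point(p)$label
  }
  if (lab(lower) != "stable" || lab(upper) != "unstable") {
    stop("interval [", lower, ", ", upper, "] does not bracket the transition")
  }
  while (upper - lower > tol) {
    mid <- (lower + upper) / 2
    if (lab(mid) == "stable") lower <- mid else upper <- mid
  }
  (lower + upper) / 2
}
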