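# Internal solver RHS over the extended state (xi, zeta, fv). The Bell
# exponent is capped so that terminal runaways stay finite until the
# hard-floor root stops the integration.
cell_rhs <- function(tau, y, env) {
  xi <- y[1L]; zeta <- y[2L]; fv <- y[3L]
  eps_f <- env$eps_a * waveform_value_num(env, tau)
  s <- if (is.finite(env$eps_c) && abs(eps_f) >= env$eps_c) {
    (abs(eps_f) / env$eps_c)^1.5
  } else 1
  u <- zeta / max(xi, env$xi_floor)
  g <- env$g0 + env$a * u - (env$beta / s) * (u * (1 + fv))^2
  list(c((1 - xi) - xi * exp(min(-g, env$exp_cap)),
         env$c * xi - env$d * zeta,
         env$k_hat * env$eps_a * waveform_rate_num(env, tau) - env$gamma * fv))
}

waveform_value_num <- function(env, tau) {
  if (env$omega == 0) return(0)
  if (env$cosine) (1 - cos(env$omega * tau)) / 2 else sin(env$omega * tau)
}

waveform_rate_num <- function(env, tau) {
  if (env$omega == 0) return(0)
  if (env$cosine) env$omega * sin(env$omega * tau) / 2
  else env$omega * cos(env$omega * tau)
}

solver_env <- function(theta, protocol, params, control) {
  eps_a <- effective_strain(theta, protocol$amplitude, params$nu)
  list2env(list(
    eps_a = eps_a,
    omega = if (eps_a == 0) 0 else protocol$omega,
    cosine = protocol$waveform == "cosine",
    c = params$c, d = params$d, g0 = params$g0, a = params$a,
    beta = params$beta, k_hat = params$k_hat, gamma = params$gamma,
    eps_c = params$eps_c,
    xi_floor = control$xi_floor, exp_cap = control$exp_cap
  ), parent = emptyenv())
}

#' Integrate a single cell at fixed orientation
#'
#' Solves the coupled bond/filament/force kinetics under a stretch protocol
#' from fresh-attachment initial conditions, with collapse detection.
#' Collapse (runaway disassembly, interpreted as detachment) is declared when
#' the bond density stays below \code{control$collapse_threshold} for one
#' full forcing period (instantaneously on a static substrate), or when it
#' falls to \code{control$hard_floor}, whichever happens first. Detection is
#' armed only after \code{control$arming_time}, because the nucleation
#' transient from \code{zeta0 = 0} legitimately passes through low bond
#' densities while the filament pool builds up. Past collapse both densities
#' are held at zero.
#'
#' @param theta Cell orientation (radians).
#' @param protocol A [stretch_protocol()].
#' @param params A [model_params()].
#' @param tau_end Integration horizon (normalized time).
#' @param xi0,zeta0 Initial densities; default to the values in
#'   \code{control}.
#' @param control A [sim_control()].
#' @return An object of class \code{cell_trajectory}: a data.frame with
#'   columns \code{tau}, \code{xi}, \code{zeta}, \code{f_hat} and attributes
#'   \code{collapse_time} (NA if no collapse), \code{collapsed},
#'   \code{theta}, \code{protocol}, \code{params}.
#' @examples
#' \donttest{
#' tr <- integrate_cell(0, stretch_protocol(0, 0), model_params(), tau_end = 300)
#' tail(tr, 1)  # converges to xi ~ 0.401, zeta ~ 0.801
#' }
#' @export
integrate_cell <- function(theta, protocol, params = model_params(),
                           tau_end = 500, xi0 = NULL, zeta0 = NULL,
                           control = sim_control()) {
  stopifnot(tau_end > 0)
  if (is.null(xi0)) xi0 <- control$xi0
  if (is.null(zeta0)) zeta0 <- control$zeta0
  stopifnot(xi0 > 0, xi0 <= 1, zeta0 >= 0)
  env <- solver_env(theta, protocol, params, control)
  hmax <- hmax_for(protocol, theta, params, control)
  grid <- seq(0, tau_end, by = control$dt)
  if (grid[length(grid)] < tau_end) grid <- c(grid, tau_end)
  y0 <- c(xi0, zeta0, 0)

  arm <- min(control$arming_time, tau_end)
  g1 <- grid[grid <= arm]
  if (length(g1) < 2L || g1[length(g1)] < arm) g1 <- c(g1, arm)
  o1 <- run_lsoda(y0, g1, env, control, hmax, root = FALSE)

  hard_stop <- NA_real_
  y_arm <- o1[nrow(o1), 2:4]
  if (tau_end > arm) {
    if (y_arm[1L] <= control$hard_floor) {
      hard_stop <- arm
      out <- o1
    } else {
      g2 <- grid[grid >= arm]
      if (g2[1L] > arm) g2 <- c(arm, g2)
      o2 <- run_lsoda(y_arm, g2, env, control, hmax, root = TRUE)
      troot <- attr(o2, "troot")
      if (!is.null(troot) && length(troot)) hard_stop <- troot[1L]
      out <- rbind(o1[o1[, 1L] < arm, , drop = FALSE], o2)
    }
  } else {
    out <- o1
  }

  tau <- out[, 1L]; xi <- out[, 2L]; zeta <- out[, 3L]; fv <- out[, 4L]
  # sustained sub-threshold dwell (one forcing period; any crossing if static)
  period <- if (env$omega > 0) 2 * pi / env$omega else 0
  collapse_time <- sustained_crossing(tau, xi, control$collapse_threshold,
                                      arm, period)
  if (!is.na(hard_stop)) {
    collapse_time <- min(collapse_time, hard_stop, na.rm = TRUE)
  }

  # extend to the full grid with densities held at zero past collapse
  if (!is.na(collapse_time) || tau[length(tau)] < tau_end - 1e-9) {
    keep <- if (is.na(collapse_time)) rep(TRUE, length(tau)) else tau <= collapse_time
    padded <- grid[grid > max(tau[keep])]
    tau <- c(tau[keep], padded)
    xi <- c(xi[keep], rep(0, length(padded)))
    zeta <- c(zeta[keep], rep(0, length(padded)))
    fv <- c(fv[keep], rep(0, length(padded)))
  }
  xi <- pmin(pmax(xi, 0), 1)
  zeta <- pmax(zeta, 0)

  structure(data.frame(tau = tau, xi = xi, zeta = zeta, f_hat = 1 + fv),
            collapse_time = collapse_time,
            collapsed = !is.na(collapse_time),
            theta = theta, protocol = protocol, params = params,
            control = control,
            class = c("cell_trajectory", "data.frame"))
}

run_lsoda <- function(y0, times, env, control, hmax, root) {
  args <- list(y = y0, times = times, func = cell_rhs, parms = env,
               rtol = control$rtol, atol = control$atol, hmax = hmax)
  out <- try(suppressWarnings({
    if (root) {
      do.call(deSolve::lsodar,
              c(args, list(rootfunc = function(t, y, p) y[1L] - control$hard_floor)))
    } else {
      do.call(deSolve::lsoda, args)
    }
  }), silent = TRUE)
  if (inherits(out, "try-error")) {
    stop("ODE solver failure (not a collapse): ", attr(out, "condition")$message)
  }
  out
}

# first time at which x stays below `thr` for at least `dwell` (0 = any
# crossing), considering only times >= arm
sustained_crossing <- function(tau, x, thr, arm, dwell) {
  below <- x < thr & tau >= arm
  if (!any(below)) return(NA_real_)
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    t0 <- tau[starts[k]]
    t1 <- tau[ends[k]]
    closed <- ends[k] < length(tau)  # run ended by recovery, not by horizon
    if ((t1 - t0 >= dwell) || !closed) return(t0)
  }
  NA_real_
}

#' @export
print.cell_trajectory <- function(x, ...) {
  ct <- attr(x, "collapse_time")
  cat(sprintf("Cell trajectory: theta = %.1f deg, %d time points to tau = %g\n",
              attr(x, "theta") * 180 / pi, nrow(x), x$tau[nrow(x)]))
  if (!is.na(ct)) {
    cat(sprintf("  collapsed (detached) at tau = %.2f\n", ct))
  } else {
    cat(sprintf("  attached throughout; final xi = %.4f, zeta = %.4f\n",
                x$xi[nrow(x)], x$zeta[nrow(x)]))
  }
  invisible(x)
}

#' Long-time average filament density at one orientation
#'
#' Integrates the cell and returns the time-averaged filament density after
#' the transient: 0 if the cell collapses within the horizon; the converged
#' value for a static protocol; otherwise the mean of \eqn{\zeta} over an
#' integer number of complete stretch cycles after discarding
#' \code{max(transient_discard, one period)}. For quasi-static protocols
#' whose period exceeds the default horizon, one warm-up period is discarded
#' and one full period averaged.
#'
#' @inheritParams integrate_cell
#' @param tau_end Horizon; automatically extended for quasi-static protocols.
#' @return Scalar \eqn{\bar\zeta} with attributes \code{collapse_time} and
#'   \code{stable}.
#' @export
long_time_average_density <- function(theta, protocol, params = model_params(),
                                      tau_end = 500, control = sim_control()) {
  eps_a <- effective_strain(theta, protocol$amplitude, params$nu)
  static_like <- is_static(protocol) || eps_a == 0
  period <- if (static_like) 0 else 2 * pi / protocol$omega
  discard <- max(control$transient_discard, period)
  if (!static_like && discard + period > tau_end) {
    tau_end <- discard + period  # quasi-static: warm-up + one full cycle
  }
  tr <- integrate_cell(theta, protocol, params, tau_end = tau_end,
                       control = control)
  ct <- attr(tr, "collapse_time")
  if (!is.na(ct)) {
    return(structure(0, collapse_time = ct, stable = FALSE))
  }
  if (static_like) {
    sel <- tr$tau >= tau_end - 50
    zbar <- mean(tr$zeta[sel])
  } else {
    ncyc <- floor((tau_end - discard) / period)
    sel <- tr$tau >= discard & tr$tau < discard + ncyc * period
    zbar <- mean(tr$zeta[sel])
  }
  structure(zbar, collapse_time = NA_real_, stable = TRUE)
}

#' Sweep the long-time average filament density over orientations
#'
#' The per-orientation long-time average \eqn{\bar\zeta(\theta)} is the
#' quantity that decides where a cell settles: orientations where adhesion
#' collapses are uninhabitable, and among stable orientations the cell is
#' hypothesized to prefer the one maximizing the stress-fiber density.
#'
#' @inheritParams integrate_cell
#' @param thetas Orientations in radians, within \eqn{[0, \pi/2]} (results
#'   extend by symmetry: \eqn{\bar\zeta} is even and \eqn{\pi}-periodic).
#' @param tau_end Horizon passed to [long_time_average_density()].
#' @return An object of class \code{angle_sweep}: a data.frame with columns
#'   \code{theta}, \code{theta_deg}, \code{zeta_bar}, \code{stable},
#'   \code{collapse_time}, with attribute \code{preferred_theta} (the argmax
#'   of \eqn{\bar\zeta}).
#' @export
angle_sweep <- function(protocol, params = model_params(),
                        thetas = seq(0, pi / 2, by = 2 * pi / 180),
                        tau_end = 500, control = sim_control()) {
  stopifnot(length(thetas) >= 1)
  rows <- lapply(thetas, function(th) {
    zb <- long_time_average_density(th, protocol, params, tau_end, control)
    data.frame(theta = th, theta_deg = th * 180 / pi,
               zeta_bar = as.numeric(zb),
               stable = attr(zb, "stable"),
               collapse_time = attr(zb, "collapse_time"))
  })
  out <- do.call(rbind, rows)
  structure(out,
            preferred_theta = out$theta[which.max(out$zeta_bar)],
            protocol = protocol, params = params,
            class = c("angle_sweep", "data.frame"))
}

#' @export
print.angle_sweep <- function(x, ...) {
  pr <- attr(x, "preferred_theta")
  cat(sprintf("Angle sweep over %d orientations: %d stable\n",
              nrow(x), sum(x$stable)))
  cat(sprintf("  preferred orientation (argmax zeta_bar): %.1f deg (zeta_bar = %.3f)\n",
              pr * 180 / pi, max(x$zeta_bar)))
  NextMethod()
}
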