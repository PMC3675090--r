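#' Wrap orientations to the half circle
#'
#' Cell orientation is a nematic (headless) quantity: angles live on
#' \eqn{(-\pi/2, \pi/2]} with period \eqn{\pi}.
#'
#' @param theta Angle(s) in radians.
#' @return Equivalent angle(s) in \eqn{(-\pi/2, \pi/2]}.
#' @export
wrap_angle <- function(theta) {
  out <- theta
  need <- theta <= -pi / 2 | theta > pi / 2
  w <- (theta[need] + pi / 2) %% pi - pi / 2
  out[need] <- ifelse(w == -pi / 2, pi / 2, w)
  out
}

#' Rotational-diffusion hop
#'
#' Between losing adhesion at one orientation and nucleating a new focal
#' complex at the next, a detached cell rotates diffusively; over the
#' nucleation interval \eqn{t_0} the mean-square angular deviation is
#' \eqn{2 D_r t_0}, so each hop is
#' \eqn{\theta' = \theta + \sqrt{2 D_r t_0}\, N} with \eqn{N} standard
#' normal, wrapped to the half circle. Uses the current R random stream.
#'
#' @param theta Current orientation(s), radians.
#' @param policy A [reorientation_policy()].
#' @return New orientation(s) in \eqn{(-\pi/2, \pi/2]}.
#' @export
rotate_hop <- function(theta, policy = reorientation_policy()) {
  wrap_angle(theta + sqrt(2 * policy$Dr * policy$t0) *
               stats::rnorm(length(theta)))
}

#' Nematic order parameter
#'
#' \eqn{S = \langle \cos 2\theta \rangle} over the population: +1 when all
#' cells are parallel to the stretch axis, -1 when all are perpendicular, 0
#' for a perfectly random orientation distribution.
#'
#' @param thetas Non-empty vector of orientations (radians).
#' @return Scalar in \eqn{[-1, 1]}.
#' @export
order_parameter <- function(thetas) {
  if (length(thetas) == 0L) stop("order_parameter() requires at least one angle")
  mean(cos(2 * thetas))
}

#' Deterministic per-angle response table
#'
#' The attached-phase kinetics at fixed orientation are deterministic, so the
#' outcome of every Monte Carlo trial is fully determined by the orientation.
#' This precomputes, on a grid of the folded angle \eqn{|\theta| \in [0,
#' 90^\circ]}, whether a freshly attached cell survives the trial window and,
#' if not, when it collapses, plus the long-time average filament density of
#' surviving orientations.
#'
#' @param protocol A [stretch_protocol()].
#' @param params A [model_params()].
#' @param policy A [reorientation_policy()] (supplies the trial window).
#' @param resolution_deg Angular grid spacing in degrees.
#' @param control A [sim_control()].
#' @return A data.frame of class \code{angle_response_table} with columns
#'   \code{theta_deg}, \code{stable}, \code{collapse_time}, \code{zeta_bar}.
#' @export
angle_response_table <- function(protocol, params = model_params(),
                                 policy = reorientation_policy(),
                                 resolution_deg = 1,
                                 control = sim_control()) {
  th_deg <- seq(0, 90, by = resolution_deg)
  rows <- lapply(th_deg, function(td) {
    zb <- long_time_average_density(td * pi / 180, protocol, params,
                                    tau_end = policy$trial_time,
                                    control = control)
    data.frame(theta_deg = td, stable = attr(zb, "stable"),
               collapse_time = attr(zb, "collapse_time"),
               zeta_bar = as.numeric(zb))
  })
  structure(do.call(rbind, rows),
            resolution_deg = resolution_deg,
            class = c("angle_response_table", "data.frame"))
}

table_lookup <- function(table, theta) {
  res <- attr(table, "resolution_deg")
  fold <- abs(wrap_angle(theta)) * 180 / pi
  idx <- round(fold / res) + 1L
  idx[idx > nrow(table)] <- nrow(table)
  idx
}

#' Population reorientation Monte Carlo
#'
#' Simulates \code{n_cells} independent cells, each starting at a uniformly
#' random orientation, through the orientation-search loop: attach (nucleate
#' a focal complex and develop FA/SF under the stretch protocol); if the
#' adhesion collapses, detach at the collapse time, hop by rotational
#' diffusion, advance the clock by the nucleation interval \eqn{t_0} and try
#' again; a cell that survives a full trial window is settled and its
#' orientation frozen. The ensemble order parameter \eqn{S(\tau)} is sampled
#' by zero-order hold on a uniform grid.
#'
#' Attached-phase outcomes are deterministic given the orientation and are
#' taken from a precomputed [angle_response_table()] (computed here if not
#' supplied). Seed the R random stream (\code{set.seed}) for reproducible
#' traces.
#'
#' @param n_cells Number of cells (>= 1).
#' @param protocol A [stretch_protocol()].
#' @param params A [model_params()].
#' @param policy A [reorientation_policy()].
#' @param tau_end Population horizon (normalized time).
#' @param n_grid Number of output grid points.
#' @param table Optional precomputed [angle_response_table()].
#' @param control A [sim_control()].
#' @return An object of class \code{population_trace}: a list with
#'   \code{tau} (grid), \code{S}, \code{n_settled}, \code{theta} (cell x
#'   time matrix), \code{settled} (logical), \code{settle_time}, and the
#'   response \code{table}.
#' @export
simulate_population <- function(n_cells = 100,
                                protocol = stretch_protocol(0.1, 1),
                                params = model_params(),
                                policy = reorientation_policy(),
                                tau_end = 60000, n_grid = 200,
                                table = NULL, control = sim_control()) {
  stopifnot(n_cells >= 1, tau_end > 0, n_grid >= 2)
  if (is.null(table)) {
    table <- angle_response_table(protocol, params, policy, control = control)
  }
  sig <- sqrt(2 * policy$Dr * policy$t0)
  grid <- seq(0, tau_end, length.out = n_grid)
  theta_mat <- matrix(NA_real_, n_cells, n_grid)
  settle_time <- rep(NA_real_, n_cells)

  for (i in seq_len(n_cells)) {
    th <- stats::runif(1, -pi / 2, pi / 2)
    clock <- 0
    ev_t <- 0
    ev_th <- th
    while (clock < tau_end) {
      row <- table_lookup(table, th)
      ct <- table$collapse_time[row]
      if (table$stable[row]) {
        settle_time[i] <- clock + policy$trial_time
        break
      }
      clock <- clock + ct + policy$t0
      th <- wrap_angle(th + sig * stats::rnorm(1))
      ev_t <- c(ev_t, clock)
      ev_th <- c(ev_th, th)
    }
    theta_mat[i, ] <- ev_th[findInterval(grid, ev_t)]
  }
  settled <- !is.na(settle_time) & settle_time <= tau_end
  if (!any(settled)) {
    warning("no cell settled within the horizon; consider a longer tau_end")
  }
  S <- colMeans(cos(2 * theta_mat))
  n_settled <- vapply(grid, function(g) {
    sum(!is.na(settle_time) & settle_time <= g)
  }, integer(1))
  structure(list(tau = grid, S = S, n_settled = n_settled,
                 theta = theta_mat, settled = settled,
                 settle_time = settle_time, table = table,
                 protocol = protocol, params = params, policy = policy),
            class = "population_trace")
}

#' @export
print.population_trace <- function(x, ...) {
  n <- nrow(x$theta)
  cat(sprintf("Population trace: %d cells over tau = [0, %g]\n",
              n, max(x$tau)))
  cat(sprintf("  settled: %d/%d; S(0) = %.3f -> S(end) = %.3f\n",
              sum(x$settled), n, x$S[1], x$S[length(x$S)]))
  invisible(x)
}

#' Steady-state order parameter of a trace
#'
#' Mean of \eqn{S(\tau)} over the final fraction of the grid.
#'
#' @param trace A [simulate_population()] result.
#' @param tail_fraction Fraction of the grid to average over.
#' @return Scalar \eqn{S_\infty} estimate.
#' @export
steady_state_order <- function(trace, tail_fraction = 0.25) {
  n <- length(trace$S)
  mean(trace$S[seq.int(ceiling(n * (1 - tail_fraction)) + 1L, n)])
}

#' Fit the characteristic decay time of the order parameter
#'
#' Least-squares fit of the three-parameter exponential
#' \deqn{S(\tau) = S_\infty + (S_0 - S_\infty) e^{-\tau/\tau_c}}
#' to an order-parameter time series, as used to quantify reorientation
#' kinetics in stretch experiments.
#'
#' @param trace A \code{population_trace}, or a data.frame/list with elements
#'   \code{tau} and \code{S}.
#' @return A list with \code{tau_c}, \code{s0}, \code{s_inf},
#'   \code{residual} (root mean squared) and the \code{fit} object.
#' @export
fit_characteristic_time <- function(trace) {
  tau <- trace$tau
  S <- trace$S
  stopifnot(length(tau) == length(S), length(S) >= 4)
  if (abs(S[length(S)] - S[1]) <= 0.1) {
    stop("no clear decay in S (|S_end - S_start| <= 0.1); refusing to fit")
  }
  model <- function(par, tau) par[1] + (par[2] - par[1]) * exp(-tau / par[3])
  fit <- minpack.lm::nls.lm(
    par = c(s_inf = S[length(S)], s0 = S[1], tau_c = max(tau) / 4),
    fn = function(par) S - model(par, tau),
    lower = c(-1.5, -1.5, max(tau) * 1e-4),
    upper = c(1.5, 1.5, max(tau) * 100),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  if (!fit$info %in% 1:3) {
    stop("exponential fit did not converge: ", fit$message)
  }
  co <- fit$par
  list(tau_c = unname(co["tau_c"]), s0 = unname(co["s0"]),
       s_inf = unname(co["s_inf"]),
       residual = sqrt(mean(fit$fvec^2)), fit = fit)
}
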