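#' Normalized model parameters
#'
#' Constructs the set of dimensionless constants of the coupled focal-adhesion
#' (FA) / stress-fiber (SF) model. All rates are normalized by the bond
#' association rate \eqn{k_{on}}, all energies by \eqn{k_B T}, and both areal
#' densities by their maxima, so every field is dimensionless. Defaults are the
#' estimated physiological values for a spindle-shaped cell on an elastomeric
#' substrate.
#'
#' @param c Normalized association rate of stress fibers (filament growth is
#'   proportional to bond density with this rate constant). Default 0.2; use
#'   0.1 for Rho-inhibited cells, whose SF assembly machinery is suppressed.
#' @param d Normalized dissociation rate of stress fibers. The SF relaxation
#'   time is \code{1/d} in normalized time units. Default 0.1.
#' @param g0 Baseline energy reduction (in kT) gained by forming a single
#'   ligand-receptor bond in the absence of any stress fibers. Negative:
#'   membrane fluctuations and glycocalyx repulsion make an unreinforced bond
#'   unfavorable, so no stable adhesion forms without SFs. Default -5.
#' @param a Interaction energy (kT) between one bond and the reinforcing
#'   plaque protein, whose density is proportional to the filament density.
#'   Default 3.5.
#' @param beta Substrate-compliance parameter: the elastic energy stored in
#'   the bond-substrate spring per unit squared per-bond force. Larger beta
#'   means a softer substrate; the physiological range is roughly 0.03-3.
#'   Default 0.6.
#' @param k_hat Normalized spring constant of a contracting filament (elastic
#'   force per unit strain, in units of the motor stall force). Default 15.
#' @param gamma Ratio of the elastic to the viscous coefficient of the
#'   filament's Maxwell branch; \code{1/gamma} is the force relaxation time in
#'   normalized units. Default 0.5.
#' @param eps_c Critical substrate strain above which strain stiffening (a
#'   3/2 power law in the modulus) sets in. \code{Inf} encodes a linearly
#'   elastic substrate. Default 0.04.
#' @param nu Poisson ratio of the substrate, in \eqn{[0, 0.5]}. Default 0.
#' @param kon_per_s Bond association rate in 1/s. It only enters when
#'   converting a physical stretching frequency in Hz into the normalized
#'   angular frequency; the default 6.25 makes one normalized time unit equal
#'   0.16 s, so the SF turnover time 1/d = 10 corresponds to ~1.6 s.
#'
#' @return An object of class \code{model_params} (a named list).
#' @seealso [stretch_protocol()], [steady_state_densities()]
#' @examples
#' p <- model_params()
#' p_rho <- model_params(c = 0.1)  # Rho-inhibited cells
#' @export
model_params <- function(c = 0.2, d = 0.1, g0 = -5, a = 3.5, beta = 0.6,
                         k_hat = 15, gamma = 0.5, eps_c = 0.04, nu = 0,
                         kon_per_s = 6.25) {
  p <- list(c = c, d = d, g0 = g0, a = a, beta = beta, k_hat = k_hat,
            gamma = gamma, eps_c = eps_c, nu = nu, kon_per_s = kon_per_s)
  validate_model_params(p)
  structure(p, class = "model_params")
}

validate_model_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
  for (nm in names(p)) {
    if (!num1(p[[nm]])) stop("model_params field '", nm, "' must be a single number")
  }
  if (p$c <= 0) stop("SF association rate c must be > 0")
  if (p$d <= 0) stop("SF dissociation rate d must be > 0")
  if (p$k_hat < 0) stop("filament spring constant k_hat must be >= 0")
  if (p$gamma <= 0) stop("elastic/viscous ratio gamma must be > 0")
  if (p$eps_c <= 0) stop("critical stiffening strain eps_c must be > 0 (use Inf for a linear substrate)")
  if (p$nu < 0 || p$nu > 0.5) stop("Poisson ratio nu must lie in [0, 0.5]")
  if (p$beta < 0) stop("substrate compliance beta must be >= 0")
  if (p$kon_per_s <= 0) stop("kon_per_s must be > 0")
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Normalized FA/SF model parameters\n")
  cat(sprintf("  SF kinetics:      c = %g, d = %g (u_ss = c/d = %g)\n",
              x$c, x$d, x$c / x$d))
  cat(sprintf("  bond energy:      g0 = %g kT, reinforcement a = %g kT\n", x$g0, x$a))
  cat(sprintf("  substrate:        beta = %g, eps_c = %s, nu = %g\n",
              x$beta, if (is.finite(x$eps_c)) format(x$eps_c) else "Inf (linear)", x$nu))
  cat(sprintf("  filament:         k_hat = %g, gamma = %g\n", x$k_hat, x$gamma))
  cat(sprintf("  time base:        kon = %g /s (1 tau = %.3g s)\n",
              x$kon_per_s, 1 / x$kon_per_s))
  invisible(x)
}

#' Cyclic stretch protocol
#'
#' Describes the substrate strain history. The default waveform is a
#' nonnegative raised cosine, \eqn{\epsilon(\tau) = \epsilon_A (1 -
#' \cos\Omega\tau)/2}: the substrate is stretched from zero to the amplitude
#' and back every cycle, as stretch devices apply it. A signed sinusoid
#' \eqn{\epsilon_A \sin\Omega\tau} is available via \code{waveform = "sine"}.
#' The physical frequency in Hz is converted to the normalized angular
#' frequency \eqn{\Omega = 2\pi f / k_{on}}.
#'
#' @param amplitude Peak substrate strain \eqn{\epsilon_A} as a fraction
#'   (0.10 for a 10\% stretch). Must be >= 0.
#' @param frequency_hz Stretching frequency in Hz; 0 means a static substrate.
#' @param kon_per_s Bond association rate in 1/s used for the Hz-to-Omega
#'   conversion; must match the value in [model_params()].
#' @param waveform \code{"cosine"} (raised cosine, default) or \code{"sine"}.
#'
#' @return An object of class \code{stretch_protocol} with fields
#'   \code{amplitude}, \code{frequency_hz}, \code{omega}, \code{waveform}.
#' @examples
#' stretch_protocol(0.10, 1)          # 10 percent at 1 Hz, Omega ~ 1.005
#' stretch_protocol(0, 0)             # static
#' @export
stretch_protocol <- function(amplitude = 0.1, frequency_hz = 1,
                             kon_per_s = 6.25,
                             waveform = c("cosine", "sine")) {
  waveform <- match.arg(waveform)
  stopifnot(is.numeric(amplitude), length(amplitude) == 1L, amplitude >= 0,
            is.numeric(frequency_hz), length(frequency_hz) == 1L,
            frequency_hz >= 0, kon_per_s > 0)
  structure(list(amplitude = amplitude,
                 frequency_hz = frequency_hz,
                 omega = 2 * pi * frequency_hz / kon_per_s,
                 waveform = waveform),
            class = "stretch_protocol")
}

#' @export
print.stretch_protocol <- function(x, ...) {
  if (x$omega == 0 || x$amplitude == 0) {
    cat(sprintf("Static stretch protocol (amplitude %g)\n", x$amplitude))
  } else {
    cat(sprintf("Cyclic stretch: amplitude %g%%, %g Hz (Omega = %.4g), %s waveform\n",
                100 * x$amplitude, x$frequency_hz, x$omega, x$waveform))
  }
  invisible(x)
}

is_static <- function(protocol) protocol$omega == 0 || protocol$amplitude == 0

#' Reorientation policy for the population Monte Carlo
#'
#' Parameters of the orientation-search loop: a detached cell hops by a
#' normally distributed angle with variance \eqn{2 D_r t_0} in the nucleation
#' interval \eqn{t_0}, re-attaches, and is assessed for up to
#' \code{trial_time}; a cell that survives the full trial is settled and its
#' orientation frozen.
#'
#' @param t0 Normalized nucleation/hop interval for a nascent focal complex.
#'   Default 0.2.
#' @param Dr Normalized rotational diffusion coefficient (rad^2 per unit
#'   normalized time). Whole-cell rotation is much slower than FA/SF
#'   remodeling; the default 5e-3 puts whole-population reorientation at
#'   10^4-10^5 normalized time units.
#' @param trial_time Maximum attached assessment window per trial (normalized
#'   time). Must be at least several SF relaxation times. Default 500.
#'
#' @return An object of class \code{reorientation_policy}.
#' @export
reorientation_policy <- function(t0 = 0.2, Dr = 5e-3, trial_time = 500) {
  stopifnot(t0 > 0, Dr >= 0, trial_time >= 50)
  structure(list(t0 = t0, Dr = Dr, trial_time = trial_time),
            class = "reorientation_policy")
}

#' @export
print.reorientation_policy <- function(x, ...) {
  cat(sprintf("Reorientation policy: t0 = %g, Dr = %g rad^2/tau (hop sd %.3g deg), trial_time = %g\n",
              x$t0, x$Dr, sqrt(2 * x$Dr * x$t0) * 180 / pi, x$trial_time))
  invisible(x)
}

#' Numerical controls for trajectory integration
#'
#' @param rtol,atol Relative and absolute solver tolerances (lsoda).
#' @param steps_per_period Lower bound on time resolution of the forcing: the
#'   maximum solver step is \code{period / steps_per_period}, capped at
#'   \code{hmax_cap}.
#' @param hmax_cap Absolute cap on the solver step (also used for static
#'   protocols).
#' @param dt Output grid spacing for trajectories.
#' @param collapse_threshold Bond density below which, sustained over one full
#'   forcing period (or instantaneously on a static substrate), the cell is
#'   declared detached. Default 0.02: collapsed states sit near 1e-3 while the
#'   weakest stable state retained (Rho-inhibited, ~0.11) is 5x above.
#' @param arming_time Collapse detection is armed only after this time: the
#'   nucleation transient from \code{zeta0 = 0} legitimately passes below the
#'   threshold while the filament pool builds up. Default 20 (two SF
#'   relaxation times).
#' @param hard_floor Bond density at which the trajectory is absorbed at zero
#'   (runaway disassembly), terminating integration.
#' @param xi_floor Bond density below which the per-bond load ratio
#'   \eqn{u = \zeta/\xi} is no longer evaluated (degenerate-state guard).
#' @param exp_cap Cap on the Bell exponent \eqn{-\hat G} inside the solver;
#'   only active during terminal runaway.
#' @param xi0,zeta0 Initial bond and filament densities at (re)attachment: a
#'   nascent focal complex provides a nonzero bond density while stress
#'   fibers assemble only afterwards.
#' @param transient_discard Time discarded before long-time averaging (at
#'   least one forcing period is always discarded).
#'
#' @return An object of class \code{sim_control}.
#' @export
sim_control <- function(rtol = 1e-6, atol = 1e-12, steps_per_period = 50,
                        hmax_cap = 0.5, dt = 0.25,
                        collapse_threshold = 0.02, arming_time = 20,
                        hard_floor = 0.002, xi_floor = 1e-6, exp_cap = 20,
                        xi0 = 0.3, zeta0 = 0, transient_discard = 200) {
  stopifnot(rtol > 0, atol > 0, steps_per_period > 0, hmax_cap > 0, dt > 0,
            collapse_threshold > 0, arming_time >= 0,
            hard_floor > 0, hard_floor < collapse_threshold,
            xi_floor > 0, exp_cap > 0, xi0 > 0, xi0 <= 1, zeta0 >= 0,
            transient_discard >= 0)
  structure(list(rtol = rtol, atol = atol, steps_per_period = steps_per_period,
                 hmax_cap = hmax_cap, dt = dt,
                 collapse_threshold = collapse_threshold,
                 arming_time = arming_time, hard_floor = hard_floor,
                 xi_floor = xi_floor, exp_cap = exp_cap,
                 xi0 = xi0, zeta0 = zeta0,
                 transient_discard = transient_discard),
            class = "sim_control")
}

# solver step cap: resolve the forcing cycle without throttling slow protocols
hmax_for <- function(protocol, theta, params, control) {
  eps_a <- effective_strain(theta, protocol$amplitude, params$nu)
  if (is_static(protocol) || eps_a == 0) return(control$hmax_cap)
  min(control$hmax_cap, 2 * pi / protocol$omega / control$steps_per_period)
}
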