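#' Default run configuration
#'
#' A flat, fully serializable set of keys covering the model parameters, the
#' stretch protocol, the reorientation policy and the run controls. Defaults
#' reproduce the estimated parameter table: c=0.2, d=0.1, g0=-5, a=3.5,
#' beta=0.6, k_hat=15, gamma=0.5, eps_c=0.04, t0=0.2, nu=0.
#'
#' @return A named list of class \code{run_config}.
#' @export
default_config <- function() {
  structure(list(
    # model parameters
    c = 0.2, d = 0.1, g0 = -5, a = 3.5, beta = 0.6, k_hat = 15,
    gamma = 0.5, eps_c = 0.04, nu = 0, kon_per_s = 6.25,
    # protocol
    amplitude = 0.1, frequency_hz = 1, waveform = "cosine",
    linear_substrate = FALSE,
    # policy
    t0 = 0.2, Dr = 5e-3, trial_time = 500, seed = 1,
    # run controls
    tau_end = 500, pop_tau_end = 60000, n_cells = 100, n_replicates = 10,
    theta_min_deg = 0, theta_max_deg = 90, theta_step_deg = 2,
    beta_min = 0, beta_max = 3, beta_step = 0.05,
    xi0 = 0.3, zeta0 = 0, collapse_threshold = 0.02,
    out_dir = "."
  ), class = "run_config")
}

config_key_types <- function() {
  cfg <- default_config()
  vapply(cfg, function(x) class(x)[1], character(1))
}

#' Read a run configuration file
#'
#' Flat \code{key = value} format, one pair per line; \code{#} starts a
#' comment. Strains may be given as fractions (\code{0.10}) or percentages
#' (\code{10\%}). Unknown keys are rejected. Values omitted from the file
#' keep their defaults.
#'
#' @param path File path.
#' @return A validated \code{run_config}.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- default_config()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop("malformed config line (expected 'key = value'): ", ln)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    cfg[key] <- list(parse_config_value(key, val))
  }
  validate_config(cfg)
}

parse_config_value <- function(key, val) {
  types <- config_key_types()
  if (!key %in% names(types)) {
    stop("unknown configuration key: '", key, "'")
  }
  val <- gsub('^"|"$', "", val)
  switch(types[[key]],
    character = val,
    logical = as.logical(val),
    numeric = parse_strain(val))
}

#' Parse a strain or plain numeric value
#'
#' Accepts plain numbers, \code{"Inf"}, and percentages (\code{"10\%"} gives
#' 0.10).
#'
#' @param x Character or numeric scalar.
#' @return Numeric scalar.
#' @export
parse_strain <- function(x) {
  if (is.numeric(x)) return(x)
  x <- trimws(x)
  if (grepl("%$", x)) return(as.numeric(sub("%$", "", x)) / 100)
  as.numeric(x)
}

#' Validate a run configuration
#'
#' Rejects unknown keys and conflicting settings: asking for a linear
#' substrate while specifying a finite critical strain is a contradiction
#' and is refused with a message naming both keys.
#'
#' @param cfg A config list.
#' @param explicit Optional character vector of keys that were explicitly
#'   set (for conflict detection from the CLI); defaults to all.
#' @return The validated \code{run_config} (with \code{eps_c} forced to
#'   \code{Inf} when \code{linear_substrate} is set).
#' @export
validate_config <- function(cfg, explicit = names(cfg)) {
  known <- names(default_config())
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste0("'", unknown, "'", collapse = ", "))
  }
  if (isTRUE(cfg$linear_substrate)) {
    if ("eps_c" %in% explicit && is.finite(cfg$eps_c)) {
      stop("conflicting settings: 'linear_substrate = TRUE' contradicts ",
           "finite 'eps_c = ", cfg$eps_c, "'; set one or the other")
    }
    cfg$eps_c <- Inf
  }
  validate_model_params(config_params(cfg))
  stopifnot(cfg$amplitude >= 0, cfg$frequency_hz >= 0,
            cfg$n_cells >= 1, cfg$n_replicates >= 1,
            cfg$theta_step_deg > 0, cfg$beta_step > 0)
  structure(cfg, class = "run_config")
}

#' Write a run configuration file
#'
#' The written file reads back to identical values.
#'
#' @param cfg A \code{run_config}.
#' @param path File path.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(cfg, path) {
  fmt <- function(x) {
    if (is.character(x)) paste0('"', x, '"')
    else if (is.logical(x)) as.character(x)
    else format(x, digits = 17)
  }
  writeLines(paste(names(cfg), "=", vapply(cfg, fmt, character(1))), path)
  invisible(path)
}

config_params <- function(cfg) {
  model_params(c = cfg$c, d = cfg$d, g0 = cfg$g0, a = cfg$a, beta = cfg$beta,
               k_hat = cfg$k_hat, gamma = cfg$gamma, eps_c = cfg$eps_c,
               nu = cfg$nu, kon_per_s = cfg$kon_per_s)
}

config_protocol <- function(cfg) {
  stretch_protocol(cfg$amplitude, cfg$frequency_hz, cfg$kon_per_s,
                   cfg$waveform)
}

config_policy <- function(cfg) {
  reorientation_policy(cfg$t0, cfg$Dr, cfg$trial_time)
}

config_control <- function(cfg) {
  sim_control(xi0 = cfg$xi0, zeta0 = cfg$zeta0,
              collapse_threshold = cfg$collapse_threshold)
}

config_thetas <- function(cfg) {
  seq(cfg$theta_min_deg, cfg$theta_max_deg, by = cfg$theta_step_deg) * pi / 180
}

write_provenance <- function(cfg, name, out_dir) {
  info <- list(subcommand = name,
               tool = "cellreorient",
               version = as.character(utils::packageVersion("cellreorient")),
               seed = cfg$seed,
               config = unclass(cfg))
  path <- file.path(out_dir, paste0(name, "_provenance.json"))
  jsonlite::write_json(info, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run one analysis subcommand
#'
#' Dispatches the package's main computations and writes CSV results plus a
#' JSON provenance file (full configuration echo, seed and tool version)
#' into \code{out_dir}:
#' \describe{
#'   \item{steady-state}{closed-form \eqn{\xi_{ss}, \zeta_{ss}} over a
#'     compliance grid.}
#'   \item{stability}{eigenvalues and stability label over the compliance
#'     grid, plus the analytic and numeric transition compliances.}
#'   \item{simulate-cell}{a single-cell trajectory at \code{theta_min_deg}.}
#'   \item{angle-sweep}{\eqn{\bar\zeta(\theta)} over the configured angle
#'     grid.}
#'   \item{population}{order-parameter time series and a JSON summary with
#'     \eqn{S_\infty}, the fitted decay time, and the replicate SD.}
#' }
#'
#' @param name Subcommand name.
#' @param cfg A validated \code{run_config}.
#' @param out_dir Output directory (created if missing); defaults to
#'   \code{cfg$out_dir}.
#' @return Invisible list of written file paths.
#' @export
run_subcommand <- function(name = c("steady-state", "stability",
                                    "simulate-cell", "angle-sweep",
                                    "population"),
                           cfg = default_config(), out_dir = cfg$out_dir) {
  name <- match.arg(name)
  cfg <- validate_config(cfg)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  params <- config_params(cfg)
  files <- c(provenance = write_provenance(cfg, name, out_dir))

  if (name == "steady-state") {
    betas <- seq(cfg$beta_min, cfg$beta_max, by = cfg$beta_step)
    rows <- lapply(betas, function(b) {
      p <- params; p$beta <- b
      ss <- steady_state_densities(p)
      data.frame(beta = b, xi_ss = ss$xi_ss, zeta_ss = ss$zeta_ss,
                 g_ss = ss$g_ss)
    })
    path <- file.path(out_dir, "steady_state.csv")
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
    files <- c(files, steady_state = path)
  } else if (name == "stability") {
    betas <- seq(cfg$beta_min, cfg$beta_max, by = cfg$beta_step)
    rows <- lapply(betas, function(b) {
      p <- params; p$beta <- b
      cl <- classify_fixed_point(p)
      data.frame(beta = b, label = cl$label,
                 max_re_eigenvalue = max(Re(cl$eigenvalues)),
                 xi_ss = cl$xi_ss)
    })
    tab <- do.call(rbind, rows)
    path <- file.path(out_dir, "stability.csv")
    utils::write.csv(tab, path, row.names = FALSE)
    trans <- if (any(tab$label == "stable") && any(tab$label == "unstable")) {
      stability_transition_beta(params,
                                lower = max(tab$beta[tab$label == "stable"][1], min(tab$beta)),
                                upper = tab$beta[tab$label == "unstable"][1])
    } else NA_real_
    spath <- file.path(out_dir, "stability_summary.json")
    jsonlite::write_json(list(beta_star_analytic = critical_beta(params),
                              beta_transition_numeric = trans),
                         spath, auto_unbox = TRUE, digits = NA)
    files <- c(files, stability = path, summary = spath)
  } else if (name == "simulate-cell") {
    tr <- integrate_cell(cfg$theta_min_deg * pi / 180, config_protocol(cfg),
                         params, tau_end = cfg$tau_end,
                         control = config_control(cfg))
    path <- file.path(out_dir, "trajectory.csv")
    utils::write.csv(as.data.frame(tr), path, row.names = FALSE)
    files <- c(files, trajectory = path)
  } else if (name == "angle-sweep") {
    sw <- angle_sweep(config_protocol(cfg), params, config_thetas(cfg),
                      tau_end = cfg$tau_end, control = config_control(cfg))
    path <- file.path(out_dir, "angle_sweep.csv")
    utils::write.csv(data.frame(theta_deg = sw$theta_deg,
                                zeta_bar = sw$zeta_bar,
                                stable = sw$stable,
                                collapse_time = sw$collapse_time),
                     path, row.names = FALSE)
    files <- c(files, angle_sweep = path)
  } else if (name == "population") {
    set.seed(cfg$seed)
    policy <- config_policy(cfg)
    protocol <- config_protocol(cfg)
    control <- config_control(cfg)
    tab <- angle_response_table(protocol, params, policy, control = control)
    traces <- lapply(seq_len(cfg$n_replicates), function(r) {
      simulate_population(cfg$n_cells, protocol, params, policy,
                          tau_end = cfg$pop_tau_end, table = tab,
                          control = control)
    })
    tr1 <- traces[[1]]
    path <- file.path(out_dir, "population_S.csv")
    utils::write.csv(data.frame(tau = tr1$tau, S = tr1$S,
                                n_settled = tr1$n_settled),
                     path, row.names = FALSE)
    tpath <- file.path(out_dir, "population_theta.csv")
    theta_wide <- as.data.frame(t(tr1$theta))
    names(theta_wide) <- paste0("cell_", seq_len(ncol(theta_wide)))
    utils::write.csv(cbind(tau = tr1$tau, theta_wide), tpath,
                     row.names = FALSE)
    s_inf <- vapply(traces, steady_state_order, numeric(1))
    tau_c <- vapply(traces, function(tr) {
      out <- try(fit_characteristic_time(tr), silent = TRUE)
      if (inherits(out, "try-error")) NA_real_ else out$tau_c
    }, numeric(1))
    spath <- file.path(out_dir, "population_summary.json")
    jsonlite::write_json(list(
      S_infinity = mean(s_inf), S_infinity_sd = stats::sd(s_inf),
      tau_c = mean(tau_c, na.rm = TRUE),
      tau_c_sd = stats::sd(tau_c, na.rm = TRUE),
      n_replicates = cfg$n_replicates, seed = cfg$seed,
      settled_fraction = mean(vapply(traces, function(tr) mean(tr$settled),
                                     numeric(1))),
      config = unclass(cfg)), spath, auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    files <- c(files, population_S = path, population_theta = tpath,
               summary = spath)
  }
  invisible(files)
}
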