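#' Sampler configuration
#'
#' Collects every tunable of the Langevin/bias driver with the defaults
#' of the bundled Muller-Brown benchmark.  All values carry the package
#' unit system (kJ/mol, fs, K; see the package help page).
#'
#' @param dt integration time step, fs.
#' @param steps total number of steps.
#' @param stride trajectory output interval, steps.
#' @param temperature thermostat temperature, K.
#' @param friction Langevin friction of the physical particle, 1/fs.
#' @param mass physical particle mass, atomic units (electron masses).
#' @param bias one of `"none"`, `"mtd"`, `"wtm"`, `"eabf"`,
#'   `"wtm-eabf"`.  The metadynamics variants act directly on the CV;
#'   the eABF variants act on the extended variable lambda only.
#' @param hill_height initial Gaussian hill height, kJ/mol.
#' @param hill_sigma Gaussian hill standard deviation, CV units.
#' @param hill_interval steps between hill depositions.
#' @param delta_T well-tempered effective temperature, K; `Inf` gives
#'   plain (untempered) metadynamics.
#' @param ext_mass inertia of the extended variable (amu-scale units;
#'   heavy relative to the physical particle so lambda moves
#'   quasi-adiabatically).
#' @param ext_sigma thermal coupling width sigma, CV units.  The spring
#'   constant is \eqn{k = k_B T / \sigma^2}.
#' @param ext_friction Langevin friction of the extended variable, 1/fs.
#' @param stabilize logical; apply the jump correction that translates
#'   lambda by any single-step CV change larger than `ext_sigma`, keeping
#'   the coupling potential continuous across CV discontinuities.
#' @param conf_k one-sided harmonic confinement stiffness on the
#'   distance from the path, kJ/mol per unit^2; `0` disables.
#' @param conf_d0 confinement onset distance.
#' @param grid_min,grid_max,grid_bin CV bias-grid range and bin width.
#' @param abf_nfull ABF linear ramp: the biasing force is fully applied
#'   in bins with at least this many samples.
#' @param lambda_wall_k harmonic wall stiffness keeping lambda on the
#'   grid, kJ/mol per unit^2.
#' @param path_update_interval steps between adaptive path updates;
#'   `0` freezes the path.
#' @param tau half-life of the current-path weight at updates, in
#'   update events (`0` = no memory).
#' @param path_smooth neighbour smoothing applied at each path update.
#' @param pmf_interval steps between stored bias-grid snapshots
#'   (`0` disables snapshots).
#' @param fp_threshold progress value whose first crossing is recorded
#'   as the first-passage (escape) time.
#' @return A `"sampler_config"` list.
#' @export
sampler_config <- function(dt = 0.5, steps = 1e6, stride = 10,
                           temperature = 50, friction = 0.001,
                           mass = 200,
                           bias = c("wtm-eabf", "none", "mtd", "wtm", "eabf"),
                           hill_height = 0.01, hill_sigma = 0.05,
                           hill_interval = 25, delta_T = 5000,
                           ext_mass = 25, ext_sigma = 0.01,
                           ext_friction = 0.001, stabilize = TRUE,
                           conf_k = 0, conf_d0 = 0.1,
                           grid_min = -0.1, grid_max = 1.1,
                           grid_bin = 0.01, abf_nfull = 50,
                           lambda_wall_k = NULL,
                           path_update_interval = 20000, tau = 0,
                           path_smooth = 0.1, pmf_interval = 20000,
                           fp_threshold = 0.8) {
  bias <- match.arg(bias)
  stopifnot(dt > 0, steps >= 1, stride >= 1, temperature > 0,
            friction >= 0, mass > 0, hill_sigma > 0, hill_interval >= 1,
            ext_mass > 0, ext_sigma > 0, ext_friction >= 0,
            grid_bin > 0, grid_max > grid_min, abf_nfull >= 1)
  if (is.null(lambda_wall_k))
    lambda_wall_k <- .kB*temperature/ext_sigma^2
  structure(list(dt = dt, steps = steps, stride = as.integer(stride),
                 temperature = temperature, friction = friction,
                 mass = mass, bias = bias, hill_height = hill_height,
                 hill_sigma = hill_sigma,
                 hill_interval = as.integer(hill_interval),
                 delta_T = delta_T, ext_mass = ext_mass,
                 ext_sigma = ext_sigma, ext_friction = ext_friction,
                 stabilize = isTRUE(stabilize), conf_k = conf_k,
                 conf_d0 = conf_d0, grid_min = grid_min,
                 grid_max = grid_max, grid_bin = grid_bin,
                 abf_nfull = abf_nfull, lambda_wall_k = lambda_wall_k,
                 path_update_interval = path_update_interval, tau = tau,
                 path_smooth = path_smooth, pmf_interval = pmf_interval,
                 fp_threshold = fp_threshold),
            class = "sampler_config")
}

#' @export
print.sampler_config <- function(x, ...) {
  cat("<sampler_config>\n")
  cat(sprintf("  %g steps of %g fs at %g K (friction %g/fs), bias '%s'\n",
              x$steps, x$dt, x$temperature, x$friction, x$bias))
  if (x$bias %in% c("eabf", "wtm-eabf"))
    cat(sprintf("  extended: mass %g, sigma %g, friction %g/fs, stabilize %s\n",
                x$ext_mass, x$ext_sigma, x$ext_friction, x$stabilize))
  if (x$bias %in% c("mtd", "wtm", "wtm-eabf"))
    cat(sprintf("  hills: h0 %g kJ/mol, sigma %g, every %d steps, deltaT %g K\n",
                x$hill_height, x$hill_sigma, x$hill_interval, x$delta_T))
  cat(sprintf("  grid [%g, %g] bin %g; path update every %g steps\n",
              x$grid_min, x$grid_max, x$grid_bin, x$path_update_interval))
  invisible(x)
}

bias_code <- function(bias) {
  match(bias, c("none", "mtd", "wtm", "eabf", "wtm-eabf")) - 1L
}

#' Run a biased Langevin simulation
#'
#' Integrates a particle in an analytic potential with BAOAB Langevin
#' dynamics, evaluates the path CV (or the first coordinate when no
#' path is given), applies the configured bias engine, accumulates the
#' bias grid and adaptive-path statistics, and records trajectory
#' frames.  With the extended-system bias modes a fictitious particle
#' lambda is harmonically coupled to the CV and all biasing forces act
#' on lambda only; the optional stabilization correction keeps the
#' coupling potential continuous when the CV jumps discontinuously at
#' path updates or shortcuts.
#'
#' @param potential a `"potential"` object.
#' @param config a [sampler_config()].
#' @param path optional [cv_path()]; if omitted the CV is the first
#'   coordinate.
#' @param x0 initial coordinates (defaults to the origin).
#' @param v0 optional initial velocities; by default drawn from the
#'   Maxwell-Boltzmann distribution at `temperature`.
#' @param seed optional integer seed (calls [set.seed()]); identical
#'   seeds give bit-identical trajectories.
#' @return A `"path_sim"` object: list with `trajectory` (data frame),
#'   `grid` (a `"bias_grid"`), `path_init`/`path_final`/`path_snapshots`,
#'   `grid_snapshots`, `first_passage` (fs, `NA` if the threshold was
#'   never crossed), the `config` and `potential` used, and counters.
#' @export
run_simulation <- function(potential, config = sampler_config(),
                           path = NULL, x0 = NULL, v0 = NULL,
                           seed = NULL) {
  stopifnot(inherits(potential, "potential"),
            inherits(config, "sampler_config"))
  if (!is.null(seed)) set.seed(seed)
  dim <- potential$dim
  if (is.null(x0)) x0 <- numeric(dim)
  stopifnot(length(x0) == dim)
  has_v0 <- !is.null(v0)
  if (!has_v0) v0 <- numeric(dim)
  pm <- if (is.null(path)) NULL else unclass(cv_path(unclass(path)))

  cfg <- list(dt = config$dt, steps = config$steps, stride = config$stride,
              temperature = config$temperature, friction = config$friction,
              mass = config$mass*.AMU_PER_ME,
              bias_mode = bias_code(config$bias),
              hill_height = config$hill_height,
              hill_sigma = config$hill_sigma,
              hill_interval = config$hill_interval,
              delta_T = if (is.finite(config$delta_T)) config$delta_T else 0,
              ext_mass = config$ext_mass, ext_sigma = config$ext_sigma,
              stabilize = config$stabilize, conf_k = config$conf_k,
              conf_d0 = config$conf_d0, grid_min = config$grid_min,
              grid_max = config$grid_max, grid_bin = config$grid_bin,
              abf_nfull = config$abf_nfull,
              path_update_interval = config$path_update_interval,
              tau = config$tau, path_smooth = config$path_smooth,
              pmf_interval = config$pmf_interval,
              fp_threshold = config$fp_threshold,
              lambda_wall_k = config$lambda_wall_k,
              ext_friction = config$ext_friction)
  raw <- cpp_run_sim(potential$code, potential$par, dim, as.numeric(x0),
                     as.numeric(v0), has_v0, pm, cfg)

  coord_names <- if (dim == 1) "x" else c("x", "y", "z")[seq_len(dim)]
  cn <- c("step", "time_fs", coord_names, "s", "d", "lambda",
          "epot", "ebias", "temp", "epoch")
  traj <- as.data.frame(raw$traj)
  names(traj) <- cn

  grid <- new_bias_grid(raw$grid$min, raw$grid$bin, raw$grid$n,
                        config$abf_nfull,
                        count = raw$grid$count, fsum = raw$grid$fsum,
                        ubias = raw$grid$ubias, dubias = raw$grid$dubias)

  snaps <- NULL
  if (length(raw$grid_snapshot_times)) {
    snaps <- list(time_fs = raw$grid_snapshot_times,
                  count = raw$grid_snapshot_count,
                  fsum = raw$grid_snapshot_fsum,
                  ubias = raw$grid_snapshot_ubias)
  }
  structure(list(trajectory = traj,
                 potential = potential, config = config,
                 path_init = if (is.null(pm)) NULL else cv_path(pm),
                 path_final = if (is.null(raw$final_path)) NULL
                              else cv_path(raw$final_path),
                 path_snapshots = raw$path_snapshots,
                 path_snapshot_times = raw$path_snapshot_times,
                 grid = grid, grid_snapshots = snaps,
                 first_passage = if (raw$first_passage < 0) NA_real_
                                 else raw$first_passage,
                 n_hill_skipped = raw$n_hill_skipped,
                 n_stab = raw$n_stab, n_switch = raw$n_switch,
                 mean_ext = raw$mean_ext),
            class = "path_sim")
}

#' @export
print.path_sim <- function(x, ...) {
  tr <- x$trajectory
  cat(sprintf("<path_sim> %s on %s: %d frames, %.1f ps\n",
              x$config$bias, x$potential$name, nrow(tr),
              max(tr$time_fs)/1000))
  cat(sprintf("  mean T %.1f K, s range [%.3f, %.3f], first passage %s\n",
              mean(tr$temp), min(tr$s), max(tr$s),
              if (is.na(x$first_passage)) "none"
              else sprintf("%.1f ps", x$first_passage/1000)))
  invisible(x)
}

#' @export
summary.path_sim <- function(object, ...) {
  tr <- object$trajectory
  rt <- try(rolling_temperature(object), silent = TRUE)
  out <- list(bias = object$config$bias,
              potential = object$potential$name,
              time_ps = max(tr$time_fs)/1000,
              frames = nrow(tr),
              mean_temp = mean(tr$temp),
              max_rolling_temp = if (inherits(rt, "try-error")) NA_real_
                                 else max(rt, na.rm = TRUE),
              first_passage_ps = if (is.na(object$first_passage)) NA_real_
                                 else object$first_passage/1000,
              s_range = range(tr$s),
              n_path_updates = length(object$path_snapshots),
              n_stabilizations = object$n_stab)
  class(out) <- "summary.path_sim"
  out
}

#' @export
print.summary.path_sim <- function(x, ...) {
  cat(sprintf("%s run, %.1f ps (%d frames)\n", x$bias, x$time_ps, x$frames))
  cat(sprintf("  mean temperature     %8.1f K\n", x$mean_temp))
  cat(sprintf("  max rolling temp     %8.1f K\n", x$max_rolling_temp))
  cat(sprintf("  first passage        %8s\n",
              if (is.na(x$first_passage_ps)) "none"
              else sprintf("%.1f ps", x$first_passage_ps)))
  cat(sprintf("  s range              [%.3f, %.3f]\n",
              x$s_range[1], x$s_range[2]))
  cat(sprintf("  path updates         %8d\n", x$n_path_updates))
  cat(sprintf("  stabilization events %8d\n", x$n_stabilizations))
  invisible(x)
}

#' @export
plot.path_sim <- function(x, which = c("trajectory", "temperature"), ...) {
  which <- match.arg(which)
  tr <- x$trajectory
  if (which == "trajectory") {
    plot(tr$time_fs/1000, tr$s, type = "l", xlab = "time (ps)",
         ylab = "s", ...)
    if (!all(is.na(tr$lambda)))
      lines(tr$time_fs/1000, tr$lambda, col = adjustcolor("red", 0.5))
  } else {
    rt <- rolling_temperature(x)
    plot(tr$time_fs/1000, rt, type = "l", xlab = "time (ps)",
         ylab = "rolling T (K)", ...)
    abline(h = x$config$temperature, lty = 2)
  }
  invisible(x)
}

#' Rolling average of the instantaneous temperature
#'
#' Moving average of the physical particle's kinetic temperature
#' (`dim` degrees of freedom; the extended particle is excluded) over a
#' time window.
#'
#' @param sim a `"path_sim"`.
#' @param window_fs averaging window, fs (default 1 ps).
#' @return Numeric vector aligned with the trajectory frames; the first
#'   `window - 1` entries are `NA`.
#' @export
rolling_temperature <- function(sim, window_fs = 1000) {
  stopifnot(inherits(sim, "path_sim"))
  spacing <- sim$config$dt*sim$config$stride
  if (window_fs < spacing)
    stop("window shorter than the frame spacing")
  w <- max(1L, round(window_fs/spacing))
  as.numeric(stats::filter(sim$trajectory$temp, rep(1/w, w), sides = 1))
}

#' First-passage (escape) time
#'
#' First simulation time at which the progress coordinate exceeds a
#' threshold.  For the threshold the run was configured with, the value
#' recorded at full step resolution is returned; other thresholds are
#' evaluated from the stored frames.
#'
#' @param sim a `"path_sim"`.
#' @param threshold progress threshold.
#' @return Time in fs, or `NA` if never crossed.
#' @export
first_passage <- function(sim, threshold = sim$config$fp_threshold) {
  stopifnot(inherits(sim, "path_sim"))
  if (identical(threshold, sim$config$fp_threshold))
    return(sim$first_passage)
  i <- which(sim$trajectory$s > threshold)[1]
  if (is.na(i)) NA_real_ else sim$trajectory$time_fs[i]
}

# ---------------------------------------------------------------------------
# Elementary force/bias operations (reference implementations of the
# formulas used inside the compiled driver)
# ---------------------------------------------------------------------------

#' Harmonic coupling between the CV and the extended variable
#'
#' The extended potential adds \eqn{\frac{k}{2} (s - \lambda)^2} with
#' stiffness \eqn{k = k_B T / \sigma^2}, so that sigma is the thermal
#' width of lambda about the CV.  The spring acts equally and oppositely
#' on lambda and (through the CV gradient) on the physical coordinates.
#'
#' @param s CV value.
#' @param grad_s CV gradient with respect to the physical coordinates.
#' @param lambda extended variable.
#' @param sigma thermal coupling width.
#' @param temperature K.
#' @return List with `f_coords` (force on the physical coordinates),
#'   `f_lambda`, `energy` (kJ/mol) and the stiffness `k`.
#' @export
coupling_forces <- function(s, grad_s, lambda, sigma, temperature) {
  stopifnot(sigma > 0, temperature > 0)
  k <- .kB*temperature/sigma^2
  ext <- s - lambda
  list(f_coords = -k*ext*grad_s, f_lambda = k*ext,
       energy = 0.5*k*ext^2, k = k)
}

#' Stabilization correction for discontinuous CVs
#'
#' When the CV changes by more than the thermal coupling width within a
#' single step -- the signature of a path update or a path shortcut --
#' the extended variable is translated by the same jump, so the spring
#' extension and with it the coupling potential are continuous across
#' the discontinuity.  Ordinary dynamics (sub-sigma changes) are left
#' untouched, as is the lambda velocity.
#'
#' @param lambda_prev extended variable before the correction.
#' @param s_prev,s_curr CV value at the previous and current step.
#' @param sigma thermal coupling width (jump threshold).
#' @return The corrected lambda.
#' @export
stabilize_lambda <- function(lambda_prev, s_prev, s_curr, sigma) {
  if (abs(s_curr - s_prev) > sigma) lambda_prev + (s_curr - s_prev)
  else lambda_prev
}

#' One-sided harmonic confinement of the distance from the path
#'
#' Zero inside `d <= d0`; beyond `d0` a harmonic restraint with
#' stiffness `k_conf` pushes back along `-grad_d`.  Force and energy are
#' continuous at `d0`.
#'
#' @param d distance from the path (non-negative).
#' @param grad_d gradient of the distance with respect to the physical
#'   coordinates.
#' @param d0 onset distance.
#' @param k_conf stiffness, kJ/mol per unit^2.
#' @return List with `force` (on the physical coordinates) and `energy`.
#' @export
confinement_force <- function(d, grad_d, d0, k_conf) {
  stopifnot(d >= 0)
  if (d <= d0) {
    list(force = 0*grad_d, energy = 0)
  } else {
    list(force = -k_conf*(d - d0)*grad_d,
         energy = 0.5*k_conf*(d - d0)^2)
  }
}
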