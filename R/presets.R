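# Frozen experiment presets for the Muller-Brown benchmark and the
# comparison utilities around them.

#' Experiment presets on the Muller-Brown benchmark
#'
#' Frozen configurations of the numerical benchmark: a single particle
#' at 50 K on the Muller-Brown surface (B = 1 kJ/mol), 500 ps
#' (10^6 steps of 0.5 fs) of Langevin dynamics with friction
#' 0.001/fs, a 30-node guess path obtained by linear interpolation
#' between the shallow lower-right minimum (start, s = 0) and the deep
#' upper-left minimum (s = 1), updated every 10 ps, and Gaussian hills
#' of initial height 0.01 kJ/mol and width 0.05 added every 25 steps on
#' a grid of bin width 0.01 spanning -0.1..1.1.  The well-tempered
#' variants scale hills with an effective temperature of 5000 K; the
#' extended-system variants couple lambda with sigma = 0.01 and an ABF
#' ramp that is fully applied beyond 50 samples per bin.
#'
#' Available presets:
#' \describe{
#'   \item{`mb-mtd`}{adaptive-path metadynamics (hills on `s`).}
#'   \item{`mb-wtm`}{adaptive-path well-tempered metadynamics.}
#'   \item{`mb-eabf`}{adaptive-path WTM-eABF without stabilization.}
#'   \item{`mb-eabf-stabilized`}{adaptive-path WTM-eABF with the jump
#'     stabilization.}
#'   \item{`mb-static`}{stabilized WTM-eABF along the static linear
#'     guess path (no path updates), the scenario used to demonstrate
#'     MBAR reweighting onto the converged path.}
#' }
#'
#' @param name preset name.
#' @return List with the `potential`, initial `path`, start point `x0`
#'   and the [sampler_config()].
#' @export
preset_config <- function(name = c("mb-mtd", "mb-wtm", "mb-eabf",
                                   "mb-eabf-stabilized", "mb-static")) {
  name <- tryCatch(match.arg(name),
                   error = function(e)
                     stop("unknown preset '", name[1], "'; available: ",
                          "mb-mtd, mb-wtm, mb-eabf, ",
                          "mb-eabf-stabilized, mb-static",
                          call. = FALSE))
  pot <- muller_brown(1)
  path <- guess_path(pot, n_nodes = 30)
  x0 <- unclass(path)[1, ]
  # mild distance confinement is applied in the extended-system presets
  # to curb path shortcutting; the direct MtD/WTM presets and the
  # static-path reweighting scenario sample unconfined
  cfg <- switch(name,
    "mb-mtd" = sampler_config(bias = "mtd", delta_T = Inf,
                                stabilize = FALSE, conf_k = 0),
    "mb-wtm" = sampler_config(bias = "wtm", delta_T = 5000,
                                stabilize = FALSE, conf_k = 0),
    "mb-eabf" = sampler_config(bias = "wtm-eabf", delta_T = 5000,
                                 stabilize = FALSE,
                                 conf_k = 100, conf_d0 = 0.2),
    "mb-eabf-stabilized" = sampler_config(bias = "wtm-eabf",
                                            delta_T = 5000,
                                            stabilize = TRUE,
                                            conf_k = 100, conf_d0 = 0.2),
    "mb-static" = sampler_config(bias = "wtm-eabf", delta_T = 5000,
                                   stabilize = TRUE, conf_k = 0,
                                   path_update_interval = 0))
  list(name = name, potential = pot, path = path, x0 = x0, config = cfg)
}

#' Run a benchmark preset and write its artifact bundle
#'
#' Runs the preset with the given seed and writes plain-text artifacts
#' to `out_dir`: the resolved configuration, the trajectory, path
#' snapshots (10 ps cadence), the final free-energy profile
#' (mean-force integration for eABF runs, bias inversion otherwise),
#' the CV-quality criterion profile, and a machine-readable JSON
#' summary with the escape time, final PMF RMSE against the NEB
#' reference, and the maximum 1 ps rolling temperature.
#'
#' @param name preset name (see [preset_config()]).
#' @param seed integer seed.
#' @param out_dir output directory (created if missing).
#' @param reference optional NEB reference path; computed on the fly if
#'   omitted.
#' @return Invisibly, the summary list (also written to
#'   `summary.json`).
#' @export
run_preset <- function(name, seed, out_dir, reference = NULL) {
  pc <- preset_config(name)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- run_simulation(pc$potential, pc$config, path = pc$path,
                        x0 = pc$x0, seed = seed)
  if (is.null(reference))
    reference <- neb_optimize(pc$potential, pc$path)
  ref_profile <- mep_energy_profile(pc$potential, reference)
  ref_fun <- attr(ref_profile, "fun")

  prof <- preset_profile(sim)
  crit <- criterion_profile(sim)
  rt <- rolling_temperature(sim)
  rmse <- fep_rmse(prof, ref_fun, range = c(0.05, 0.95),
                   max_undefined = 5)

  write_config(pc$config, file.path(out_dir, "config.txt"))
  write_trajectory(sim, file.path(out_dir, "trajectory.tsv"))
  if (length(sim$path_snapshots))
    write_path_snapshots(c(list(unclass(sim$path_init)), sim$path_snapshots),
                         c(0, sim$path_snapshot_times),
                         file.path(out_dir, "path_snapshots.txt"))
  write_path(sim$path_final, file.path(out_dir, "path_final.txt"))
  write_pmf(prof, file.path(out_dir, "pmf.txt"))
  write_pmf(crit, file.path(out_dir, "criterion.txt"))

  summary <- list(preset = name, seed = seed,
                  escape_time_ps = if (is.na(sim$first_passage)) NA
                                   else sim$first_passage/1000,
                  pmf_rmse_kJmol = if (is.finite(rmse)) rmse else NA,
                  max_rolling_temp_K = max(rt, na.rm = TRUE),
                  mean_temp_K = mean(sim$trajectory$temp),
                  n_stabilizations = sim$n_stab,
                  n_path_updates = length(sim$path_snapshots))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(c(summary, list(sim = sim, reference = reference)))
}

# default profile estimator for a preset run: mean-force integration
# for extended-system runs, bias inversion for MtD/WTM
preset_profile <- function(sim) {
  if (sim$config$bias %in% c("eabf", "wtm-eabf"))
    pmf_from_forces(sim$grid, min_count = 10)
  else
    pmf_from_wtm(sim$grid, sim$config$temperature, sim$config$delta_T)
}

#' Compare summaries of preset runs
#'
#' Tabulates escape times, maximum rolling temperatures and PMF RMS
#' errors across runs, with per-preset means and standard errors
#' (sample SD over sqrt of the replica count).
#'
#' @param ... summary lists from [run_preset()] (or a single list of
#'   them).
#' @return A data frame with one row per run plus aggregate rows, of
#'   class `"run_comparison"`.
#' @export
compare_runs <- function(...) {
  runs <- list(...)
  if (length(runs) == 1 && is.null(runs[[1]]$preset)) runs <- runs[[1]]
  if (length(runs) < 2) stop("need at least two run summaries")
  df <- do.call(rbind, lapply(runs, function(r)
    data.frame(preset = r$preset, seed = r$seed,
               escape_time_ps = r$escape_time_ps %||% NA,
               pmf_rmse_kJmol = r$pmf_rmse_kJmol %||% NA,
               max_rolling_temp_K = r$max_rolling_temp_K %||% NA)))
  agg <- do.call(rbind, lapply(split(df, df$preset), function(g) {
    data.frame(preset = g$preset[1], seed = NA,
               escape_time_ps = mean(g$escape_time_ps),
               pmf_rmse_kJmol = mean(g$pmf_rmse_kJmol),
               max_rolling_temp_K = mean(g$max_rolling_temp_K),
               se_escape = sd(g$escape_time_ps)/sqrt(nrow(g)),
               n = nrow(g))
  }))
  structure(list(runs = df, aggregate = agg), class = "run_comparison")
}

#' @export
print.run_comparison <- function(x, ...) {
  cat("runs:\n"); print(x$runs, row.names = FALSE)
  cat("aggregate:\n"); print(x$aggregate, row.names = FALSE)
  invisible(x)
}

#' CV-quality criterion profile
#'
#' Monitors the quantity \eqn{D_S(z) = \langle \nabla S \cdot \nabla U
#' \rangle_{S=z}} — the conditional mean of the physical force projected
#' on the CV gradient, binned along the progress coordinate.  Because
#' all applied biases act through `s` (or lambda) only, they cancel in
#' the conditional average, and for an ideal CV the quantity crosses
#' zero exactly at the transition state.  Bins without samples are
#' undefined.
#'
#' @param sim a `"path_sim"`.
#' @param path the path used for the projection; default the run's
#'   final path (frames are re-projected onto it).
#' @param breaks bin boundaries along `s`.
#' @param sub frame subsampling stride.
#' @return A data frame with columns `center`, `ds` (kJ/mol per CV
#'   unit), `count`, wrapped as a [fep()]-like object for plotting via
#'   its `energy` column equal to `ds`.
#' @export
criterion_profile <- function(sim, path = sim$path_final,
                              breaks = seq(-0.105, 1.105, by = 0.02),
                              sub = 1) {
  stopifnot(inherits(sim, "path_sim"))
  tr <- sim$trajectory[seq(1, nrow(sim$trajectory), by = sub), ]
  coord_cols <- setdiff(names(tr), c("step", "time_fs", "s", "d",
                                     "lambda", "epot", "ebias", "temp",
                                     "epoch"))
  X <- as.matrix(tr[, coord_cols, drop = FALSE])
  if (is.null(path)) {
    sval <- tr$s
    gs <- matrix(0, nrow(tr), ncol(X)); gs[, 1] <- 1
  } else {
    loc <- cpp_path_locate(unclass(cv_path(unclass(path))), X)
    sval <- loc$s
    gs <- loc$grad_s
  }
  G <- cpp_potential_eval(sim$potential$code, sim$potential$par, X)$gradient
  fproj <- rowSums(G*gs)
  acc <- criterion_accumulator(breaks)
  acc <- criterion_update(acc, sval, fproj)
  criterion_evaluate(acc)
}

#' Accumulator for the CV-quality criterion
#'
#' Low-level interface underlying [criterion_profile()]: create an
#' accumulator over `s` bins, feed it frames (progress values and the
#' projection of the potential gradient on the CV gradient), and
#' evaluate per-bin means.  Empty bins evaluate to `NA`.
#'
#' @param breaks bin boundaries along the progress coordinate.
#' @return `criterion_accumulator()` returns the accumulator;
#'   `criterion_update()` the updated accumulator;
#'   `criterion_evaluate()` a data frame with `center`, `ds`, `count`.
#' @export
criterion_accumulator <- function(breaks) {
  structure(list(breaks = breaks,
                 sum = numeric(length(breaks) - 1),
                 count = numeric(length(breaks) - 1)),
            class = "criterion_accumulator")
}

#' @rdname criterion_accumulator
#' @param acc a `"criterion_accumulator"`.
#' @param s progress value(s) of the frame(s).
#' @param force_proj projection(s) of the potential gradient onto the
#'   CV gradient, kJ/mol per CV unit.
#' @export
criterion_update <- function(acc, s, force_proj) {
  stopifnot(inherits(acc, "criterion_accumulator"),
            length(s) == length(force_proj))
  idx <- findInterval(s, acc$breaks, rightmost.closed = TRUE)
  ok <- idx >= 1 & idx < length(acc$breaks)
  tt <- tapply(force_proj[ok], idx[ok], sum)
  cc <- table(idx[ok])
  acc$sum[as.integer(names(tt))] <- acc$sum[as.integer(names(tt))] + tt
  acc$count[as.integer(names(cc))] <- acc$count[as.integer(names(cc))] + cc
  acc
}

#' @rdname criterion_accumulator
#' @export
criterion_evaluate <- function(acc) {
  stopifnot(inherits(acc, "criterion_accumulator"))
  cen <- (acc$breaks[-1] + acc$breaks[-length(acc$breaks)])/2
  ds <- ifelse(acc$count > 0, acc$sum/pmax(acc$count, 1), NA_real_)
  out <- data.frame(center = cen, energy = ds, count = acc$count,
                    ci95 = NA_real_)
  attr(out, "coord") <- "s"
  class(out) <- c("fep", "data.frame")
  out
}
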