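# Time-resolved free-energy profiles and convergence against a
# reference curve.

#' Free-energy profile at each stored bias-grid snapshot
#'
#' Rebuilds the mean-force-integrated profile (eABF runs) or the bias
#' inversion (MtD/WTM runs) from every grid snapshot recorded during
#' the run (`pmf_interval` in [sampler_config()]).
#'
#' @param sim a `"path_sim"` run with grid snapshots.
#' @param min_count minimum samples per bin for the force estimator.
#' @return List with `time_fs` and `profiles` (a list of [fep()]s).
#' @export
pmf_series <- function(sim, min_count = 20) {
  stopifnot(inherits(sim, "path_sim"))
  gs <- sim$grid_snapshots
  if (is.null(gs)) stop("run was configured without grid snapshots")
  force_based <- sim$config$bias %in% c("eabf", "wtm-eabf")
  profiles <- lapply(seq_along(gs$time_fs), function(i) {
    g <- sim$grid
    g$count <- gs$count[i, ]
    g$fsum <- gs$fsum[i, ]
    g$ubias <- gs$ubias[i, ]
    if (force_based) {
      if (all(g$count < min_count)) return(NULL)
      pmf_from_forces(g, min_count = min_count)
    } else {
      if (all(g$ubias == 0)) return(NULL)
      pmf_from_wtm(g, sim$config$temperature, sim$config$delta_T)
    }
  })
  list(time_fs = gs$time_fs, profiles = profiles)
}

#' Earliest time after which the profile stays close to a reference
#'
#' Evaluates the RMS deviation of the time-resolved profile against a
#' reference energy curve over a progress range at every snapshot and
#' returns the earliest time after which it remains below `tol`
#' through the end of the run.  Snapshots whose profile does not yet
#' cover the range count as not converged.
#'
#' @param sim a `"path_sim"` with grid snapshots.
#' @param reference reference curve: a function of the progress
#'   coordinate or a [fep()] (e.g. from [mep_energy_profile()]).
#' @param tol RMSE threshold, kJ/mol.
#' @param range progress range of the comparison.
#' @param min_count minimum samples per bin.
#' @param max_undefined tolerated undefined bins inside the range.
#' @return List with `time_ps` (earliest stable time in ps; the total
#'   run length if the criterion is never met, flagged by
#'   `converged = FALSE`), and the per-snapshot `rmse` series.
#' @export
convergence_time <- function(sim, reference, tol = 1, range = c(0.05, 0.95),
                             min_count = 20, max_undefined = 0) {
  ser <- pmf_series(sim, min_count = min_count)
  rmse <- vapply(ser$profiles, function(p) {
    if (is.null(p)) return(Inf)
    fep_rmse(p, reference, range = range, max_undefined = max_undefined)
  }, numeric(1))
  ok <- is.finite(rmse) & rmse < tol
  n <- length(ok)
  total_ps <- max(ser$time_fs)/1000
  if (!any(ok)) {
    return(list(time_ps = total_ps, converged = FALSE,
                time_fs = ser$time_fs, rmse = rmse))
  }
  last_bad <- max(c(0, which(!ok)))
  if (last_bad == n) {
    list(time_ps = total_ps, converged = FALSE,
         time_fs = ser$time_fs, rmse = rmse)
  } else {
    list(time_ps = ser$time_fs[last_bad + 1]/1000, converged = TRUE,
         time_fs = ser$time_fs, rmse = rmse)
  }
}
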