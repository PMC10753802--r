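# Guess paths and the nudged-elastic-band reference optimizer.

#' Straight guess path between two minima
#'
#' Builds an equidistant straight-line path between two selected minima
#' of a potential.  If `ends` is not given, the minima are located with
#' [stationary_points()] and the pair with the largest separation is
#' used, ordered so that the path starts at the higher-energy
#' (shallower) of the two.
#'
#' @param potential a 2D `"potential"`.
#' @param n_nodes number of path nodes.
#' @param ends optional 2x2 matrix (rows: start and end point),
#'   bypassing the minimum search.
#' @param lower,upper search box passed to [stationary_points()].
#' @return A [cv_path()] with `n_nodes` equally spaced nodes.
#' @export
guess_path <- function(potential, n_nodes = 30, ends = NULL,
                       lower = c(-1.8, -0.5), upper = c(1.2, 2.2)) {
  if (is.null(ends)) {
    sp <- stationary_points(potential, lower, upper)
    mins <- sp[sp$type == "min", , drop = FALSE]
    if (nrow(mins) < 2)
      stop("fewer than two minima found; supply `ends` explicitly")
    best <- c(1, 2); bestd <- -1
    for (i in seq_len(nrow(mins) - 1)) for (j in (i + 1):nrow(mins)) {
      dd <- (mins$x[i] - mins$x[j])^2 + (mins$y[i] - mins$y[j])^2
      if (dd > bestd) { bestd <- dd; best <- c(i, j) }
    }
    a <- mins[best[1], ]; b <- mins[best[2], ]
    # start from the shallower basin
    if (a$energy < b$energy) { tmp <- a; a <- b; b <- tmp }
    ends <- rbind(c(a$x, a$y), c(b$x, b$y))
  }
  ends <- as.matrix(ends)
  stopifnot(nrow(ends) == 2, ncol(ends) == potential$dim)
  t <- seq(0, 1, length.out = n_nodes)
  cv_path(outer(1 - t, ends[1, ]) + outer(t, ends[2, ]))
}

#' Nudged elastic band optimization of a minimum-energy path
#'
#' Standard NEB with the improved tangent estimate: each interior image
#' feels the true force perpendicular to the local tangent plus a
#' spring force along it, and the band is relaxed with a damped
#' steepest-descent (quick-min) integrator until the maximum
#' perpendicular true force falls below `tol`.  Endpoints are fixed.
#'
#' @param potential a `"potential"`.
#' @param path starting [cv_path()] (e.g. from [guess_path()]).
#' @param k_spring spring constant between images, kJ/mol per unit^2.
#' @param tol convergence threshold on the maximum perpendicular force,
#'   kJ/mol per unit.
#' @param maxit maximum iterations.
#' @param step_size descent step.
#' @return A [cv_path()] with attributes `energy` (per-node energies),
#'   `iterations` and `max_force`.  Errors if not converged.
#' @export
neb_optimize <- function(potential, path, k_spring = 100, tol = 0.1,
                         maxit = 50000, step_size = 2e-3) {
  stopifnot(inherits(potential, "potential"))
  P <- unclass(cv_path(unclass(path)))
  M <- nrow(P)
  vel <- P*0
  mperp <- Inf
  for (it in seq_len(maxit)) {
    ev <- cpp_potential_eval(potential$code, potential$par, P)
    E <- ev$energy; G <- ev$gradient
    Frc <- P*0
    mperp <- 0
    for (i in 2:(M - 1)) {
      tp <- P[i + 1, ] - P[i, ]
      tm <- P[i, ] - P[i - 1, ]
      if (E[i + 1] > E[i] && E[i] > E[i - 1]) tau <- tp
      else if (E[i + 1] < E[i] && E[i] < E[i - 1]) tau <- tm
      else {
        dmax <- max(abs(E[i + 1] - E[i]), abs(E[i - 1] - E[i]))
        dmin <- min(abs(E[i + 1] - E[i]), abs(E[i - 1] - E[i]))
        tau <- if (E[i + 1] > E[i - 1]) tp*dmax + tm*dmin
               else tp*dmin + tm*dmax
      }
      tau <- tau/sqrt(sum(tau^2))
      fperp <- -G[i, ] + sum(G[i, ]*tau)*tau
      fspr <- k_spring*(sqrt(sum(tp^2)) - sqrt(sum(tm^2)))*tau
      Frc[i, ] <- fperp + fspr
      mperp <- max(mperp, sqrt(sum(fperp^2)))
    }
    if (mperp < tol) break
    # quick-min: keep velocity only along the force
    vdotf <- sum(vel*Frc)
    vel <- if (vdotf > 0) Frc*vdotf/sum(Frc*Frc) else vel*0
    vel <- vel + step_size*Frc
    P <- P + step_size*vel
  }
  if (mperp >= tol)
    stop(sprintf("NEB did not converge in %d iterations (max perpendicular force %.3g > %.3g)",
                 maxit, mperp, tol))
  # equidistant nodes, so the geometric progress coordinate of the
  # returned path coincides with fractional arc length
  P <- cpp_reparametrize(P)
  out <- cv_path(P)
  attr(out, "energy") <- cpp_potential_eval(potential$code, potential$par, P)$energy
  attr(out, "iterations") <- it
  attr(out, "max_force") <- mperp
  out
}

#' Energy profile along a path
#'
#' Samples the potential energy densely along the piecewise-linear
#' curve through the path nodes, parameterized by fractional arc length
#' (matching the progress coordinate on an equidistant path).
#'
#' @param potential a `"potential"`.
#' @param path a [cv_path()].
#' @param n number of sample points.
#' @param shift subtract the minimum so the curve starts at zero.
#' @return Data frame with columns `s` and `energy`, plus an attribute
#'   `fun` holding the interpolating function.
#' @export
mep_energy_profile <- function(potential, path, n = 2001, shift = TRUE) {
  P <- unclass(cv_path(unclass(path)))
  seg <- sqrt(rowSums((P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2))
  cs <- c(0, cumsum(seg))
  L <- cs[length(cs)]
  tt <- seq(0, L, length.out = n)
  X <- sapply(seq_len(ncol(P)), function(j) approx(cs, P[, j], tt)$y)
  E <- cpp_potential_eval(potential$code, potential$par, as.matrix(X))$energy
  if (shift) E <- E - min(E)
  out <- data.frame(s = tt/L, energy = E)
  attr(out, "fun") <- approxfun(out$s, out$energy)
  out
}
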