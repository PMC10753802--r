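# Bias grids and free-energy profile estimators.

new_bias_grid <- function(gmin, bin, n, nfull, count = NULL, fsum = NULL,
                          ubias = NULL, dubias = NULL) {
  z <- numeric(n)
  structure(list(min = gmin, bin = bin, n = as.integer(n), nfull = nfull,
                 count = count %||% z, fsum = fsum %||% z,
                 ubias = ubias %||% z, dubias = dubias %||% z),
            class = "bias_grid")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bias grid over a one-dimensional CV
#'
#' Holds per-bin sample counts, the force-sum accumulator of the ABF
#' estimator, and the (well-tempered) metadynamics bias potential with
#' its derivative.  [run_simulation()] returns a populated grid;
#' `bias_grid()` builds an empty one for the low-level operations
#' [deposit_hill()] and [abf_force()].
#'
#' @param min,max,bin grid range and bin width (CV units).
#' @param nfull ABF ramp: number of samples per bin at which the
#'   biasing force is fully applied.
#' @return A `"bias_grid"` object.
#' @export
bias_grid <- function(min = -0.1, max = 1.1, bin = 0.01, nfull = 50) {
  n <- ceiling((max - min)/bin - 1e-9)
  new_bias_grid(min, bin, n, nfull)
}

#' @export
print.bias_grid <- function(x, ...) {
  cat(sprintf("<bias_grid> %d bins of %g on [%g, %g]; %g samples, max bias %.3f kJ/mol\n",
              x$n, x$bin, x$min, x$min + x$n*x$bin, sum(x$count),
              max(x$ubias)))
  invisible(x)
}

#' Bin centers of a bias grid
#' @param grid a `"bias_grid"`.
#' @return Numeric vector of bin centers.
#' @export
grid_centers <- function(grid) {
  grid$min + (seq_len(grid$n) - 0.5)*grid$bin
}

#' Deposit a (well-tempered) metadynamics hill
#'
#' Adds a Gaussian of width `sigma` to the grid bias potential.  With a
#' finite effective temperature `delta_T` the height is scaled by
#' \eqn{\exp[-U_{bias}(\xi)/(k_B \Delta T)]} (well-tempered
#' metadynamics); `delta_T = Inf` keeps the full height (plain
#' metadynamics).  Hills centred outside the grid are skipped with a
#' warning.
#'
#' @param grid a `"bias_grid"`.
#' @param center hill centre (current CV or lambda value).
#' @param height initial hill height h0, kJ/mol.
#' @param sigma hill standard deviation, CV units.
#' @param delta_T effective bias temperature, K.
#' @return The updated grid.
#' @export
deposit_hill <- function(grid, center, height, sigma, delta_T = Inf) {
  stopifnot(inherits(grid, "bias_grid"))
  if (center < grid$min || center > grid$min + grid$n*grid$bin) {
    warning("hill centre outside the bias grid; hill skipped")
    return(grid)
  }
  h <- if (is.finite(delta_T))
    height*exp(-grid_interp(grid, grid$ubias, center)/(.kB*delta_T))
  else height
  cen <- grid_centers(grid)
  du <- cen - center
  g <- h*exp(-du^2/(2*sigma^2))
  grid$ubias <- grid$ubias + g
  grid$dubias <- grid$dubias + du/sigma^2*g
  grid
}

# linear interpolation between bin centers, clamped at the edges
grid_interp <- function(grid, values, x) {
  u <- (x - grid$min)/grid$bin - 0.5
  u <- pmin(pmax(u, 0), grid$n - 1)
  j <- pmin(floor(u), grid$n - 2)
  t <- u - j
  (1 - t)*values[j + 1] + t*values[j + 2]
}

#' Ramped adaptive biasing force
#'
#' Returns the biasing force applied to lambda at a grid point: the
#' per-bin mean of the accumulated free-energy-gradient samples, scaled
#' by the linear ramp \eqn{R(N) = \min(1, N/N_{full})}.  Empty bins give
#' zero force.
#'
#' @param grid a `"bias_grid"`.
#' @param lambda position of the extended variable.
#' @return Force in kJ/mol per CV unit.
#' @export
abf_force <- function(grid, lambda) {
  stopifnot(inherits(grid, "bias_grid"))
  j <- floor((lambda - grid$min)/grid$bin) + 1
  if (j < 1 || j > grid$n || grid$count[j] == 0) return(0)
  ramp <- min(1, grid$count[j]/grid$nfull)
  ramp*grid$fsum[j]/grid$count[j]
}

# ---------------------------------------------------------------------------
# Free-energy profiles
# ---------------------------------------------------------------------------

#' Free-energy profiles
#'
#' A `"fep"` object is a data frame with bin centers, the free energy
#' (kJ/mol, shifted so the minimum over defined bins is zero), per-bin
#' counts, and optional 95% confidence half-widths.  Bins without data
#' are `NA`, never zero-filled.
#'
#' @param center bin centers.
#' @param energy free energies, kJ/mol (`NA` for undefined bins).
#' @param count per-bin sample counts (weights).
#' @param ci95 optional 95% confidence half-widths.
#' @param coord name of the coordinate.
#' @return A `"fep"` data frame.
#' @export
fep <- function(center, energy, count = NA_real_, ci95 = NA_real_,
                coord = "s") {
  stopifnot(length(center) == length(energy))
  if (any(is.finite(energy))) energy <- energy - min(energy, na.rm = TRUE)
  out <- data.frame(center = center, energy = energy, count = count,
                    ci95 = ci95)
  attr(out, "coord") <- coord
  class(out) <- c("fep", "data.frame")
  out
}

#' @export
print.fep <- function(x, ...) {
  ok <- is.finite(x$energy)
  cat(sprintf("<fep> %d bins (%d defined) along '%s'; range %.2f kJ/mol\n",
              nrow(x), sum(ok), attr(x, "coord"),
              if (any(ok)) diff(range(x$energy[ok])) else NA))
  invisible(x)
}

#' @export
plot.fep <- function(x, add = FALSE, col = "black", ...) {
  if (!add) {
    plot(x$center, x$energy, type = "l", col = col,
         xlab = attr(x, "coord"), ylab = "A (kJ/mol)", ...)
  } else lines(x$center, x$energy, col = col, ...)
  if (any(is.finite(x$ci95))) {
    ok <- is.finite(x$energy) & is.finite(x$ci95)
    polygon(c(x$center[ok], rev(x$center[ok])),
            c(x$energy[ok] - x$ci95[ok], rev(x$energy[ok] + x$ci95[ok])),
            border = NA, col = adjustcolor(col, 0.2))
  }
  invisible(x)
}

#' PMF by inversion of the (well-tempered) metadynamics bias
#'
#' At convergence the metadynamics bias potential compensates the free
#' energy, so \eqn{A = -U_{bias}} for plain metadynamics and
#' \eqn{A = -\frac{T + \Delta T}{\Delta T} U_{bias}} for the
#' well-tempered variant.
#'
#' @param grid a `"bias_grid"` with deposited bias.
#' @param temperature simulation temperature, K.
#' @param delta_T well-tempered effective temperature, K (`Inf` for the
#'   plain metadynamics limit).
#' @return A [fep()].
#' @export
pmf_from_wtm <- function(grid, temperature, delta_T = Inf) {
  stopifnot(inherits(grid, "bias_grid"))
  if (all(grid$ubias == 0)) stop("bias grid is empty: no hills deposited")
  fac <- if (is.finite(delta_T)) (temperature + delta_T)/delta_T else 1
  fep(grid_centers(grid), -fac*grid$ubias, count = grid$count)
}

#' PMF by integration of the mean force
#'
#' Trapezoidal integration of the per-bin mean force accumulated by the
#' eABF estimator.  Bins with fewer than `min_count` samples are
#' undefined; the profile is integrated separately over each contiguous
#' block of defined bins (gaps stay `NA`).
#'
#' @param grid a `"bias_grid"` with force samples.
#' @param min_count minimum samples per bin.
#' @return A [fep()].
#' @export
pmf_from_forces <- function(grid, min_count = 1) {
  stopifnot(inherits(grid, "bias_grid"))
  if (all(grid$count == 0)) stop("bias grid holds no force samples")
  cen <- grid_centers(grid)
  ok <- grid$count >= min_count
  mf <- ifelse(ok, grid$fsum/pmax(grid$count, 1), NA_real_)
  A <- rep(NA_real_, grid$n)
  i <- 1
  while (i <= grid$n) {
    if (!ok[i]) { i <- i + 1; next }
    j <- i
    while (j < grid$n && ok[j + 1]) j <- j + 1
    block <- i:j
    A[block] <- cumsum(c(0, 0.5*(mf[block][-1] + mf[block][-length(block)])*grid$bin))
    i <- j + 1
  }
  fep(cen, A, count = grid$count)
}

#' PMF from a (weighted) histogram
#'
#' \eqn{A(z) = -k_B T \ln \sum_n w_n \delta_{bin}(z_n)}; empty bins are
#' undefined.  With `blocks > 1` the profile is recomputed on
#' contiguous trajectory blocks and a 95% confidence half-width per bin
#' is estimated from the block spread.
#'
#' @param values coordinate samples.
#' @param temperature K.
#' @param breaks bin boundaries (vector) as in [cut()].
#' @param weights optional per-frame weights (default uniform).
#' @param blocks number of blocks for the confidence estimate.
#' @return A [fep()].
#' @export
pmf_from_histogram <- function(values, temperature, breaks,
                               weights = NULL, blocks = 1) {
  n <- length(values)
  if (is.null(weights)) weights <- rep(1/n, n)
  stopifnot(length(weights) == n)
  cen <- (breaks[-1] + breaks[-length(breaks)])/2
  idx <- findInterval(values, breaks, rightmost.closed = TRUE)
  inr <- idx >= 1 & idx < length(breaks)
  h <- rep(0, length(cen))
  tt <- tapply(weights[inr], idx[inr], sum)
  h[as.integer(names(tt))] <- tt
  A <- ifelse(h > 0, -.kB*temperature*log(h), NA_real_)
  ci <- rep(NA_real_, length(cen))
  if (blocks > 1 && n >= 2*blocks) {
    bid <- ceiling(seq_along(values)/ (n/blocks))
    Ab <- sapply(seq_len(blocks), function(b) {
      sel <- bid == b
      hb <- rep(0, length(cen))
      tb <- tapply(weights[sel & inr], idx[sel & inr], sum)
      if (length(tb)) hb[as.integer(names(tb))] <- tb
      ifelse(hb > 0, -.kB*temperature*log(hb/sum(weights[sel])), NA_real_)
    })
    nb <- rowSums(is.finite(Ab))
    sdb <- apply(Ab, 1, sd, na.rm = TRUE)
    ci <- ifelse(nb >= 2, qt(0.975, pmax(nb - 1, 1))*sdb/sqrt(nb), NA_real_)
  }
  fep(cen, A, count = h*n, ci95 = ci)
}

#' Assign trajectory frames to lambda windows
#'
#' Maps every frame to the nearest window centre (ties go to the lower
#' index).  Counts are conserved: every frame is assigned exactly once.
#'
#' @param lambda per-frame lambda values.
#' @param centers window centres (sorted).
#' @return List with `index` (per-frame window index) and `counts`.
#' @export
assign_windows <- function(lambda, centers) {
  stopifnot(length(centers) >= 1, !is.unsorted(centers))
  mids <- (centers[-1] + centers[-length(centers)])/2
  # findInterval with left-closed mids: ties at a midpoint go down
  idx <- findInterval(lambda, mids, left.open = TRUE) + 1
  counts <- tabulate(idx, nbins = length(centers))
  list(index = idx, counts = counts)
}

#' Reweighted PMF from unbiased frame weights
#'
#' Histogram PMF of an arbitrary per-frame coordinate under externally
#' supplied unbiased weights (e.g. from [mbar_solve()]), enabling the
#' profile to be mapped onto any CV of choice — in particular onto the
#' converged path.
#'
#' @param weights unbiased per-frame weights (normalized internally).
#' @param coord per-frame coordinate values.
#' @param breaks bin boundaries.
#' @param temperature K.
#' @param blocks number of blocks for the confidence estimate.
#' @return A [fep()].
#' @export
reweighted_pmf <- function(weights, coord, breaks, temperature,
                           blocks = 1) {
  stopifnot(length(weights) == length(coord))
  pmf_from_histogram(coord, temperature, breaks,
                     weights = weights/sum(weights), blocks = blocks)
}

#' Barrier and reaction free energy from a profile
#'
#' \eqn{\Delta A^\ddagger} is the profile maximum between the reactant
#' and product minima minus the reactant minimum; \eqn{\Delta A} is the
#' product minimum minus the reactant minimum.  This is the plain
#' profile barrier (max-minus-min extraction).
#'
#' @param profile a [fep()].
#' @param reactant,product length-2 coordinate ranges.
#' @return List with `barrier` and `delta_A`, kJ/mol.
#' @export
barrier_from_pmf <- function(profile, reactant, product) {
  stopifnot(inherits(profile, "fep"))
  cen <- profile$center; A <- profile$energy
  rsel <- cen >= reactant[1] & cen <= reactant[2]
  psel <- cen >= product[1] & cen <= product[2]
  if (!any(rsel) || !any(psel))
    stop("reactant or product range contains no bins")
  if (any(!is.finite(A[rsel])) || any(!is.finite(A[psel])))
    stop("undefined bins inside the reactant or product range")
  ri <- which(rsel)[which.min(A[rsel])]
  pi <- which(psel)[which.min(A[psel])]
  between <- if (ri <= pi) ri:pi else pi:ri
  if (any(!is.finite(A[between])))
    stop("undefined bins between the reactant and product minima")
  list(barrier = max(A[between]) - A[ri], delta_A = A[pi] - A[ri])
}

#' RMS deviation between a profile and a reference curve
#'
#' Both the profile and the reference are shifted to a zero minimum
#' over the compared range before the RMSE is taken.  If more than
#' `max_undefined` bins in the range are undefined the deviation is
#' reported as `Inf` (the profile does not yet cover the range).
#'
#' @param profile a [fep()].
#' @param reference function mapping coordinate to reference energy, or
#'   a second [fep()] (interpolated linearly).
#' @param range length-2 coordinate range of the comparison.
#' @param max_undefined tolerated number of undefined bins in range.
#' @return RMSE in kJ/mol (possibly `Inf`).
#' @export
fep_rmse <- function(profile, reference, range = c(0.05, 0.95),
                     max_undefined = 0) {
  stopifnot(inherits(profile, "fep"))
  if (inherits(reference, "fep")) {
    ok <- is.finite(reference$energy)
    reference <- approxfun(reference$center[ok], reference$energy[ok])
  }
  sel <- profile$center >= range[1] & profile$center <= range[2]
  A <- profile$energy[sel]
  if (sum(!is.finite(A)) > max_undefined) return(Inf)
  A <- A - min(A, na.rm = TRUE)
  ref <- reference(profile$center[sel])
  ref <- ref - min(ref, na.rm = TRUE)
  sqrt(mean((A - ref)^2, na.rm = TRUE))
}
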