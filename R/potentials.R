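#' Analytic test potentials
#'
#' Constructors for the analytic potentials used as physical systems in
#' desk-scale simulations: the two-dimensional Muller-Brown surface, an
#' n-dimensional harmonic well, and a one-dimensional quartic double
#' well.  All expose exact energies and analytic gradients through
#' [potential_energy()].
#'
#' @details
#' The Muller-Brown surface is the canonical four-term sum of
#' anisotropic Gaussians
#' \deqn{U(x, y) = B \sum_{k=1}^{4} A_k \exp[a_k (x-x_k)^2 +
#'   b_k (x-x_k)(y-y_k) + c_k (y-y_k)^2]}
#' with the classic constants \eqn{A = (-200, -100, -170, 15)},
#' \eqn{a = (-1, -1, -6.5, 0.7)}, \eqn{b = (0, 0, 11, 0.6)},
#' \eqn{c = (-10, -10, -6.5, 0.7)}, centres \eqn{(1,0)}, \eqn{(0,0.5)},
#' \eqn{(-0.5,1.5)}, \eqn{(-1,1)}, and a global energy scale `B` in
#' kJ/mol.  It has three minima connected by two saddle points; the
#' global minimum sits near \eqn{(-0.558, 1.442)}.
#'
#' The double well is \eqn{U(x) = h\,[(x/w)^2 - 1]^2}: minima at
#' \eqn{\pm w}, barrier height exactly `height` at \eqn{x = 0}.
#'
#' @param B global energy scale of the Muller-Brown surface, kJ/mol.
#' @param k vector of force constants (kJ/mol per unit length squared),
#'   one per dimension.
#' @param height barrier height of the double well, kJ/mol.
#' @param half_width half distance between the two minima.
#' @return An object of class `"potential"`.
#' @examples
#' pot <- muller_brown()
#' potential_energy(pot, c(-0.558, 1.442))
#' @export
muller_brown <- function(B = 1) {
  stopifnot(is.numeric(B), length(B) == 1, B > 0)
  new_potential("muller_brown", 1L, c(B = B), 2L)
}

#' @rdname muller_brown
#' @export
harmonic_well <- function(k = 100) {
  stopifnot(is.numeric(k), length(k) >= 1, all(k > 0))
  new_potential("harmonic_well", 2L, k, length(k))
}

#' @rdname muller_brown
#' @export
double_well <- function(height = 10, half_width = 1) {
  stopifnot(height > 0, half_width > 0)
  new_potential("double_well", 3L, c(height = height, half_width = half_width), 1L)
}

new_potential <- function(name, code, par, dim) {
  structure(list(name = name, code = code, par = unname(par),
                 par_names = names(par), dim = as.integer(dim)),
            class = "potential")
}

#' @export
print.potential <- function(x, ...) {
  cat("<potential>", x$name, sprintf("(%dD)\n", x$dim))
  if (!is.null(x$par_names)) {
    cat("  parameters:",
        paste(sprintf("%s = %g", x$par_names, x$par), collapse = ", "), "\n")
  } else {
    cat("  parameters:", paste(signif(x$par, 6), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Evaluate a potential and its analytic gradient
#'
#' @param potential a [muller_brown()], [harmonic_well()] or
#'   [double_well()] object.
#' @param x coordinate vector, or a matrix with one point per row.
#' @return For a single point, a list with `energy` (kJ/mol) and
#'   `gradient` (kJ/mol per unit length, same dimension as `x`).  For a
#'   matrix, a list with an `energy` vector and a `gradient` matrix.
#' @export
potential_energy <- function(potential, x) {
  stopifnot(inherits(potential, "potential"))
  single <- is.null(dim(x))
  X <- if (single) matrix(as.numeric(x), nrow = 1) else as.matrix(x)
  if (ncol(X) != potential$dim) {
    stop(sprintf("dimension mismatch: potential '%s' is %dD, point has %d coordinates",
                 potential$name, potential$dim, ncol(X)))
  }
  out <- cpp_potential_eval(potential$code, potential$par, X)
  if (single) list(energy = out$energy[1], gradient = out$gradient[1, ])
  else out
}

#' Locate and classify stationary points of a 2D potential
#'
#' Scans a bounding box with a grid of Newton starts on the analytic
#' gradient (Jacobian by central differences of the gradient), collects
#' converged roots, removes duplicates, and classifies each point by the
#' eigenvalue signs of the numerical Hessian.
#'
#' @param potential a 2D `"potential"` object.
#' @param lower,upper numeric length-2 bounds of the search box.
#' @param n_grid number of Newton starting points per axis.
#' @param tol gradient-norm threshold for acceptance.
#' @return A data frame with columns `x`, `y`, `energy`, `type`
#'   (`"min"`, `"saddle"` or `"max"`), sorted by energy.  May have zero
#'   rows.
#' @export
stationary_points <- function(potential, lower = c(-1.8, -0.5),
                              upper = c(1.2, 2.2), n_grid = 25,
                              tol = 1e-8) {
  stopifnot(inherits(potential, "potential"), potential$dim == 2L)
  gx <- seq(lower[1], upper[1], length.out = n_grid)
  gy <- seq(lower[2], upper[2], length.out = n_grid)
  Z <- as.matrix(expand.grid(x = gx, y = gy))
  h <- 1e-6
  # batched Newton iterations on grad U = 0
  for (iter in 1:60) {
    G <- cpp_potential_eval(potential$code, potential$par, Z)$gradient
    Gxp <- cpp_potential_eval(potential$code, potential$par, sweep(Z, 2, c(h, 0), "+"))$gradient
    Gxm <- cpp_potential_eval(potential$code, potential$par, sweep(Z, 2, c(h, 0), "-"))$gradient
    Gyp <- cpp_potential_eval(potential$code, potential$par, sweep(Z, 2, c(0, h), "+"))$gradient
    Gym <- cpp_potential_eval(potential$code, potential$par, sweep(Z, 2, c(0, h), "-"))$gradient
    H11 <- (Gxp[, 1] - Gxm[, 1])/(2*h); H12 <- (Gyp[, 1] - Gym[, 1])/(2*h)
    H21 <- (Gxp[, 2] - Gxm[, 2])/(2*h); H22 <- (Gyp[, 2] - Gym[, 2])/(2*h)
    det <- H11*H22 - H12*H21
    det[abs(det) < 1e-12] <- NA
    dx <- -( H22*G[, 1] - H12*G[, 2])/det
    dy <- -(-H21*G[, 1] + H11*G[, 2])/det
    step <- cbind(dx, dy)
    step[!is.finite(step)] <- 0
    # damp very large steps to keep iterates in a sane region
    nrm <- sqrt(rowSums(step^2))
    fac <- ifelse(nrm > 0.25, 0.25/nrm, 1)
    Z <- Z + step*fac
  }
  G <- cpp_potential_eval(potential$code, potential$par, Z)$gradient
  gn <- sqrt(rowSums(G^2))
  ok <- is.finite(gn) & gn <= tol &
    Z[, 1] >= lower[1] & Z[, 1] <= upper[1] &
    Z[, 2] >= lower[2] & Z[, 2] <= upper[2]
  Z <- Z[ok, , drop = FALSE]
  if (nrow(Z) == 0) {
    return(data.frame(x = numeric(0), y = numeric(0),
                      energy = numeric(0), type = character(0)))
  }
  # deduplicate
  keyp <- paste(round(Z[, 1], 5), round(Z[, 2], 5))
  Z <- Z[!duplicated(keyp), , drop = FALSE]
  keep <- rep(TRUE, nrow(Z))
  for (i in seq_len(nrow(Z))) {
    if (!keep[i]) next
    if (i < nrow(Z)) {
      dup <- which(keep & seq_len(nrow(Z)) > i &
                   sqrt(rowSums(sweep(Z, 2, Z[i, ])^2)) < 1e-4)
      keep[dup] <- FALSE
    }
  }
  Z <- Z[keep, , drop = FALSE]
  # classify by Hessian eigenvalues
  typ <- character(nrow(Z)); en <- numeric(nrow(Z))
  for (i in seq_len(nrow(Z))) {
    z <- Z[i, ]
    Hm <- matrix(0, 2, 2)
    for (j in 1:2) {
      e <- c(0, 0); e[j] <- h
      gp <- potential_energy(potential, z + e)$gradient
      gm <- potential_energy(potential, z - e)$gradient
      Hm[, j] <- (gp - gm)/(2*h)
    }
    ev <- eigen((Hm + t(Hm))/2, symmetric = TRUE, only.values = TRUE)$values
    typ[i] <- if (all(ev > 0)) "min" else if (all(ev < 0)) "max" else "saddle"
    en[i] <- potential_energy(potential, z)$energy
  }
  out <- data.frame(x = Z[, 1], y = Z[, 2], energy = en, type = typ)
  out[order(out$energy), , drop = FALSE]
}
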