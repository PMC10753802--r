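#' Paths in collective-variable space
#'
#' A path is an ordered string of at least three nodes in CV space,
#' stored as a numeric matrix (one node per row) of class `"cv_path"`.
#' It defines the geometric progress coordinate `s` (0 at the first
#' node, 1 at the last) and the distance coordinate `d` evaluated by
#' [path_locate()].
#'
#' @param nodes numeric matrix, one node per row; at least 3 rows.
#' @return A `"cv_path"` object (a matrix with a class attribute).
#' @export
cv_path <- function(nodes) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  if (nrow(nodes) < 3) stop("a path needs at least 3 nodes")
  seg <- sqrt(rowSums((nodes[-1, , drop = FALSE] -
                       nodes[-nrow(nodes), , drop = FALSE])^2))
  if (any(seg < 1e-12)) stop("invalid path: duplicate consecutive nodes")
  structure(nodes, class = c("cv_path", "matrix"))
}

#' @export
print.cv_path <- function(x, ...) {
  seg <- sqrt(rowSums((x[-1, , drop = FALSE] - x[-nrow(x), , drop = FALSE])^2))
  cat(sprintf("<cv_path> %d nodes in %dD, arc length %.4f\n",
              nrow(x), ncol(x), sum(seg)))
  invisible(x)
}

#' Project points onto a path: progress, distance, gradients
#'
#' Implements the geometric path CV.  For a point `z`, the closest node
#' `m` is found (ties resolved toward the lower index) and the progress
#' is computed from the closed form
#' \deqn{s = \frac{1}{M-1}\left[m +
#'   \frac{\sqrt{(v_1 v_3)^2 - |v_3|^2(|v_1|^2-|v_2|^2)} - (v_1 v_3)}
#'        {2 |v_3|^2} - \frac{1}{2}\right]}
#' with \eqn{v_1 = z_m - z}, \eqn{v_2 = z - z_{m-1}},
#' \eqn{v_3 = z_{m+1} - z_m}; beyond the path ends the node string is
#' extended by one linearly extrapolated ghost node and the result is
#' clamped to \eqn{[-0.1, 1.1]}.  The distance `d` is the perpendicular
#' distance to the line through the segment joining the closest and
#' second-closest nodes, and `P` is the projection onto that line.
#' Gradients of `s` and `d` with respect to `z` are analytic.
#'
#' @param path a [cv_path()].
#' @param z a coordinate vector, or a matrix of points (one per row).
#' @return For a single point, a list with scalar `m` (zero-based
#'   closest-node index), `side` (+1 if `z` lies before the closest node
#'   along the path, -1 otherwise), `s`, `d`, and vectors `P`,
#'   `grad_s`, `grad_d`.  For a matrix input the fields are vectors /
#'   matrices over points.
#' @export
path_locate <- function(path, z) {
  path <- cv_path(unclass(path))
  single <- is.null(dim(z))
  Z <- if (single) matrix(as.numeric(z), nrow = 1) else as.matrix(z)
  if (ncol(Z) != ncol(path)) stop("dimension mismatch between path and points")
  out <- cpp_path_locate(unclass(path), Z)
  if (single) {
    list(m = out$m[1], side = out$side[1], s = out$s[1], d = out$d[1],
         P = out$P[1, ], grad_s = out$grad_s[1, ], grad_d = out$grad_d[1, ])
  } else out
}

#' Reparametrize a path to equidistant nodes
#'
#' Redistributes the interior nodes along the piecewise-linear curve
#' through the current nodes so that all segments have equal length.
#' Endpoints and total arc length are preserved; the operation is
#' idempotent to numerical precision.
#'
#' @param path a [cv_path()].
#' @return The reparametrized `"cv_path"`.
#' @export
path_reparametrize <- function(path) {
  path <- cv_path(unclass(path))
  cv_path(cpp_reparametrize(unclass(path)))
}

#' Accumulate samples for an adaptive path update
#'
#' Between updates, each sampled CV-space point contributes a weight to
#' the two nodes bracketing its continuous node coordinate
#' \eqn{\sigma = s (M-1)} (tent weights \eqn{1-f} and \eqn{f}, nonzero
#' for exactly those two nodes) together with its displacement from the
#' path \eqn{z - P(z)}.  [path_apply_update()] then moves every interior
#' node by the weighted mean displacement, optionally damped by a memory
#' weight of the current path whose half-life is `tau` update events,
#' applies neighbour smoothing, and reparametrizes.  Endpoints stay
#' fixed.
#'
#' @param path a [cv_path()].
#' @param tau half-life (in update events) of the weight carried by the
#'   current path; `0` disables memory so each update moves nodes by the
#'   plain weighted mean displacement.
#' @param smooth neighbour-smoothing strength (0 to 1) applied at
#'   each update: node i is pulled by `smooth/2` toward the midpoint of
#'   its neighbours.
#' @return `path_accumulator()` returns an accumulator object;
#'   `path_accumulate()` returns the updated accumulator;
#'   `path_apply_update()` returns a list with the new `path` and the
#'   reset `accumulator`.
#' @export
path_accumulator <- function(path, tau = 0, smooth = 0) {
  path <- cv_path(unclass(path))
  M <- nrow(path)
  structure(list(W = numeric(M), D = matrix(0, M, ncol(path)),
                 mem = numeric(M), n = 0L, tau = tau, smooth = smooth,
                 M = M, dim = ncol(path)),
            class = "path_accumulator")
}

#' @rdname path_accumulator
#' @param acc a `"path_accumulator"`.
#' @param z sampled point(s) in CV space (vector or matrix).
#' @export
path_accumulate <- function(acc, path, z) {
  stopifnot(inherits(acc, "path_accumulator"))
  path <- cv_path(unclass(path))
  Z <- if (is.null(dim(z))) matrix(as.numeric(z), nrow = 1) else as.matrix(z)
  loc <- cpp_path_locate(unclass(path), Z)
  M <- acc$M
  for (i in seq_len(nrow(Z))) {
    sc <- min(max(loc$s[i], 0), 1)
    sig <- sc*(M - 1)
    i0 <- min(floor(sig), M - 2)
    f <- sig - i0
    disp <- Z[i, ] - loc$P[i, ]
    acc$W[i0 + 1] <- acc$W[i0 + 1] + (1 - f)
    acc$W[i0 + 2] <- acc$W[i0 + 2] + f
    acc$D[i0 + 1, ] <- acc$D[i0 + 1, ] + (1 - f)*disp
    acc$D[i0 + 2, ] <- acc$D[i0 + 2, ] + f*disp
    acc$n <- acc$n + 1L
  }
  acc
}

#' @rdname path_accumulator
#' @export
path_apply_update <- function(path, acc) {
  stopifnot(inherits(acc, "path_accumulator"))
  path <- cv_path(unclass(path))
  if (nrow(path) != acc$M || ncol(path) != acc$dim)
    stop("accumulator was built against a different path layout")
  out <- cpp_path_update(unclass(path), acc$W, acc$D, acc$mem,
                         acc$tau, acc$smooth)
  acc$W[] <- 0; acc$D[] <- 0; acc$n <- 0L
  acc$mem <- out$mem
  list(path = cv_path(out$nodes), accumulator = acc)
}
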