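# Shared fixtures and independent oracles used across the test files.

# central finite-difference gradient of a potential
fd_gradient <- function(pot, x, h = 1e-6) {
  vapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- h
    (potential_energy(pot, x + e)$energy -
     potential_energy(pot, x - e)$energy)/(2*h)
  }, numeric(1))
}

# arc-length-ratio progress oracle: fraction of the polyline arc length
# at the orthogonal projection of z onto the (extended) polyline
arc_length_s <- function(nodes, z) {
  nodes <- as.matrix(nodes)
  M <- nrow(nodes)
  seg <- nodes[-1, , drop = FALSE] - nodes[-M, , drop = FALSE]
  lens <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(lens))
  best_d <- Inf; best_arc <- NA
  for (i in seq_len(M - 1)) {
    v <- seg[i, ]
    t <- sum((z - nodes[i, ])*v)/sum(v^2)
    t <- min(max(t, 0), 1)
    p <- nodes[i, ] + t*v
    d <- sqrt(sum((z - p)^2))
    if (d < best_d) { best_d <- d; best_arc <- cum[i] + t*lens[i] }
  }
  best_arc/cum[M]
}

# dense polyline for reparametrization checks
dense_polyline <- function(nodes, n = 20001) {
  nodes <- as.matrix(nodes)
  seg <- sqrt(rowSums((nodes[-1, , drop = FALSE] -
                       nodes[-nrow(nodes), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  tt <- seq(0, cum[length(cum)], length.out = n)
  sapply(seq_len(ncol(nodes)), function(j) approx(cum, nodes[, j], tt)$y)
}

# distance from a point to a dense polyline
dist_to_polyline <- function(poly, z) {
  min(sqrt(rowSums(sweep(poly, 2, z)^2)))
}

# the two Muller-Brown minima bracketing the full transition,
# refined by local minimization (independent of stationary_points())
mb_minima <- function(pot = muller_brown()) {
  f <- function(x) potential_energy(pot, x)$energy
  g <- function(x) potential_energy(pot, x)$gradient
  deep <- optim(c(-0.5, 1.4), f, g, method = "BFGS",
                control = list(reltol = 1e-14))
  shallow <- optim(c(0.6, 0.0), f, g, method = "BFGS",
                   control = list(reltol = 1e-14))
  list(deep = deep$par, shallow = shallow$par,
       deep_energy = deep$value, shallow_energy = shallow$value)
}

# short-run config for fast sampler tests
short_config <- function(...) {
  args <- modifyList(list(steps = 2e4, stride = 10, pmf_interval = 0,
                          path_update_interval = 0), list(...))
  do.call(sampler_config, args)
}
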