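test_that("progress and distance on a straight equidistant path", {
  p <- cv_path(rbind(c(0, 0), c(1, 0), c(2, 0)))
  # on a node: fractional node position
  loc <- path_locate(p, c(1, 0))
  expect_equal(loc$s, 0.5, tolerance = 1e-12)
  expect_equal(loc$d, 0, tolerance = 1e-12)
  # between nodes: fractional arc length
  loc <- path_locate(p, c(0.75, 0))
  expect_equal(loc$s, 0.375, tolerance = 1e-12)
  # perpendicular offset leaves s unchanged; d is the point-line distance
  loc <- path_locate(p, c(0.75, 0.2))
  expect_equal(loc$s, 0.375, tolerance = 1e-12)
  expect_equal(loc$d, 0.2, tolerance = 1e-12)
})

test_that("s equals fractional arc length on straight equidistant paths", {
  set.seed(7)
  dirv <- c(2, 1)/sqrt(5)
  p0 <- c(-1, 0.5)
  nodes <- t(sapply(seq(0, 3, length.out = 7), function(t) p0 + t*dirv))
  p <- cv_path(nodes)
  for (i in 1:50) {
    t <- runif(1, 0.05, 2.95)
    off <- runif(1, -0.3, 0.3)
    z <- p0 + t*dirv + off*c(-dirv[2], dirv[1])
    loc <- path_locate(p, z)
    expect_equal(loc$s, arc_length_s(nodes, p0 + t*dirv), tolerance = 1e-9)
    expect_equal(loc$d, abs(off), tolerance = 1e-9)
  }
})

test_that("s is strictly increasing along the node sequence", {
  # a curved path (quarter circle plus straight tail)
  th <- seq(0, pi/2, length.out = 8)
  nodes <- cbind(cos(th), sin(th))
  nodes <- rbind(nodes, c(-0.5, 1), c(-1, 1))
  p <- path_reparametrize(cv_path(nodes))
  sv <- path_locate(p, unclass(p))$s
  expect_true(all(diff(sv) > 0))
  expect_equal(sv[1], 0, tolerance = 1e-12)
  expect_equal(sv[length(sv)], 1, tolerance = 1e-12)
})

test_that("d vanishes on the polyline between nodes", {
  th <- seq(0, pi/2, length.out = 9)
  p <- cv_path(cbind(cos(th), sin(th)))
  for (i in 1:8) {
    for (t in c(0.25, 0.5, 0.75)) {
      z <- (1 - t)*p[i, ] + t*p[i + 1, ]
      expect_lt(path_locate(p, z)$d, 1e-10)
    }
  }
})

test_that("grad_s and grad_d match central finite differences", {
  th <- seq(0, pi/2, length.out = 10)
  p <- path_reparametrize(cv_path(cbind(1.5*cos(th), sin(th))))
  set.seed(11)
  h <- 1e-7
  checked <- 0
  for (i in 1:80) {
    z <- c(runif(1, -0.2, 1.6), runif(1, -0.2, 1.2))
    loc <- path_locate(p, z)
    # skip clamp region, node-equidistance ties and on-path points where
    # the distance gradient direction is undefined
    if (loc$s <= -0.099 || loc$s >= 1.099 || loc$d < 1e-3) next
    lp <- path_locate(p, z + c(h, 0)); lm <- path_locate(p, z - c(h, 0))
    if (lp$m != loc$m || lm$m != loc$m) next   # active-branch switch
    up <- path_locate(p, z + c(0, h)); um <- path_locate(p, z - c(0, h))
    if (up$m != loc$m || um$m != loc$m) next
    gs_fd <- c(lp$s - lm$s, up$s - um$s)/(2*h)
    gd_fd <- c(lp$d - lm$d, up$d - um$d)/(2*h)
    expect_lt(max(abs(loc$grad_s - gs_fd))/max(abs(gs_fd), 1e-3), 1e-5)
    expect_lt(max(abs(loc$grad_d - gd_fd))/max(abs(gd_fd), 1e-3), 1e-5)
    checked <- checked + 1
  }
  expect_gt(checked, 30)
})

test_that("reparametrization equalizes segments and preserves the curve", {
  # trivial arithmetic case
  p <- path_reparametrize(cv_path(rbind(c(0, 0), c(0.2, 0), c(2, 0))))
  expect_equal(unclass(p), rbind(c(0, 0), c(1, 0), c(2, 0)),
               tolerance = 1e-12, ignore_attr = TRUE)

  # nonuniformly sampled quarter circle
  th <- sort(c(0, pi/2, runif(10, 0, pi/2)))
  nodes <- cbind(cos(th), sin(th))
  rp <- path_reparametrize(cv_path(nodes))
  seg <- sqrt(rowSums(diff(unclass(rp))^2))
  expect_lt(diff(range(seg))/mean(seg), 1e-6)
  # endpoints preserved
  expect_equal(rp[1, ], nodes[1, ], ignore_attr = TRUE)
  expect_equal(rp[nrow(rp), ], nodes[nrow(nodes), ], ignore_attr = TRUE)
  # total arc length preserved up to the small corner-cutting of
  # re-chording a curved polyline
  expect_equal(sum(seg), sum(sqrt(rowSums(diff(nodes)^2))),
               tolerance = 5e-3)
  # new nodes lie on the original polyline
  poly <- dense_polyline(nodes)
  for (i in seq_len(nrow(rp)))
    expect_lt(dist_to_polyline(poly, rp[i, ]), 1e-3)
  # idempotent
  rp2 <- path_reparametrize(rp)
  expect_equal(unclass(rp2), unclass(rp), tolerance = 1e-9)
  # already equidistant path unchanged
  pe <- cv_path(cbind(seq(0, 2, 0.5), 0))
  expect_equal(unclass(path_reparametrize(pe)), unclass(pe),
               tolerance = 1e-12)
})

test_that("degenerate paths are rejected", {
  expect_error(cv_path(rbind(c(0, 0), c(0, 0), c(1, 0))), "duplicate")
  expect_error(path_locate(cv_path(rbind(c(0, 0), c(1, 0), c(2, 0))),
                           c(1, 2, 3)), "dimension mismatch")
  expect_error(cv_path(rbind(c(0, 0))), "at least 3 nodes")
})

test_that("update accumulator weights touch exactly the two bracketing nodes", {
  p <- cv_path(cbind(seq(0, 2, 0.5), 0))
  acc <- path_accumulator(p)
  # a sample exactly on a node contributes zero displacement
  acc1 <- path_accumulate(acc, p, c(1, 0))
  expect_equal(sum(abs(acc1$D)), 0)
  expect_equal(sum(acc1$W > 0), 1)     # tent weight all on one node
  # off-node samples touch exactly two nodes with tent weights
  set.seed(3)
  for (k in 1:20) {
    acc2 <- path_accumulate(path_accumulator(p), p,
                            c(runif(1, 0.05, 1.95), runif(1, -0.2, 0.2)))
    expect_lte(sum(acc2$W > 0), 2)
    expect_equal(sum(acc2$W), 1, tolerance = 1e-12)
  }
  # k samples: at most 2k nonzero-weight node touches
  acck <- path_accumulator(p)
  for (k in 1:5)
    acck <- path_accumulate(acck, p, c(runif(1, 0.1, 1.9), 0.1))
  expect_lte(sum(acck$W > 0), 10)
  expect_equal(acck$n, 5L)
})

test_that("hand-computed single-sample update matches the accumulator", {
  p <- cv_path(rbind(c(0, 0), c(1, 0), c(2, 0)))
  z <- c(0.75, 0.3)
  acc <- path_accumulate(path_accumulator(p), p, z)
  # by hand: s = 0.375 -> sigma = 0.75, bracketing nodes 0 and 1 with
  # tent weights 0.25 and 0.75; displacement z - P = (0, 0.3)
  expect_equal(acc$W, c(0.25, 0.75, 0), tolerance = 1e-12)
  expect_equal(acc$D[1, ], c(0, 0.25*0.3), tolerance = 1e-12)
  expect_equal(acc$D[2, ], c(0, 0.75*0.3), tolerance = 1e-12)
})

test_that("path update moves the middle node by the mean displacement", {
  p <- cv_path(rbind(c(0, 0), c(1, 0), c(2, 0)))
  acc <- path_accumulator(p, tau = 0, smooth = 0)
  # samples uniformly offset +0.2 in y near the middle node
  for (x in seq(0.9, 1.1, length.out = 21))
    acc <- path_accumulate(acc, p, c(x, 0.2))
  upd <- path_apply_update(p, acc)
  newp <- unclass(upd$path)
  expect_gt(newp[2, 2], 0)
  # direct formula evaluation: weighted mean displacement in y is 0.2
  # (every sample has pure +0.2 y displacement); reparametrization keeps
  # the middle node on the updated polyline
  accd <- path_accumulate(path_accumulator(p), p, c(1, 0.2))
  raw <- unclass(p); raw[2, 2] <- raw[2, 2] + accd$D[2, 2]/accd$W[2]
  expect_equal(raw[2, 2], 0.2, tolerance = 1e-12)
  # endpoints never move
  expect_equal(newp[1, ], c(0, 0), ignore_attr = TRUE)
  expect_equal(newp[3, ], c(2, 0), ignore_attr = TRUE)
})

test_that("empty accumulator or on-path samples leave the path unchanged", {
  th <- seq(0, pi/2, length.out = 8)
  p <- path_reparametrize(cv_path(cbind(cos(th), sin(th))))
  acc <- path_accumulator(p)
  upd <- path_apply_update(p, acc)
  expect_equal(unclass(upd$path), unclass(p), tolerance = 1e-12)
  # samples exactly on the path: displacements vanish
  for (i in 2:7) acc <- path_accumulate(acc, p, p[i, ])
  upd <- path_apply_update(p, acc)
  expect_equal(unclass(upd$path), unclass(p), tolerance = 1e-9)
})

test_that("tau memory damps the update", {
  p <- cv_path(rbind(c(0, 0), c(1, 0), c(2, 0)))
  mk <- function(tau) {
    acc <- path_accumulator(p, tau = tau)
    # two update rounds with identical data; memory builds after round 1
    for (r in 1:2) {
      for (x in seq(0.9, 1.1, length.out = 11))
        acc <- path_accumulate(acc, p, c(x, 0.3))
      res <- path_apply_update(p, acc)
      acc <- res$accumulator
    }
    res$path[2, 2]
  }
  expect_lt(mk(5), mk(0))   # with memory the second update is damped
})
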