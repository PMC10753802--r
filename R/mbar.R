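# Multistate Bennett acceptance ratio estimator and the lambda-window
# decomposition of extended-system trajectories.

#' Solve the MBAR equations
#'
#' Self-consistent estimation of the reduced free energies \eqn{f_k} of
#' `K` biased states from the reduced energy matrix
#' \eqn{u_{nk} = \beta U_k(x_n)} of every frame evaluated in every
#' state, and of the unbiased weight of every frame.  The solver
#' minimizes the standard MBAR objective with Newton steps (gradient
#' and Hessian from the weight matrix) guarded by objective-based
#' backtracking, falling back to self-consistent iteration steps when
#' the Newton step does not improve.
#'
#' @param u numeric matrix, frames in rows, states in columns: reduced
#'   (dimensionless) bias energy of each frame in each state.  A
#'   constant added to all entries of a row leaves the result unchanged.
#' @param N_k number of frames sampled from each state
#'   (`sum(N_k) == nrow(u)`).
#' @param tol convergence tolerance on the free-energy update.
#' @param maxit maximum number of iterations.
#' @return An `"mbar_fit"`: list with `f` (reduced free energies, first
#'   state gauged to zero), `weights` (positive, sum to one),
#'   `log_denom`, `iterations`, `residual` (max norm of the gradient of
#'   the MBAR objective, in frames), and `converged`.
#' @export
mbar_solve <- function(u, N_k, tol = 1e-8, maxit = 10000) {
  u <- as.matrix(u)
  K <- ncol(u); n <- nrow(u)
  stopifnot(length(N_k) == K, sum(N_k) == n, all(N_k > 0))
  if (K == 1) {
    # single state: unbiased weights are proportional to exp(+u)
    lw <- u[, 1] - max(u[, 1])
    w <- exp(lw); w <- w/sum(w)
    return(structure(list(f = 0, weights = w, log_denom = -u[, 1],
                          N_k = N_k, iterations = 0L, residual = 0,
                          converged = TRUE), class = "mbar_fit"))
  }
  lognk <- log(N_k)
  negu <- -u
  fk <- numeric(K)
  obj <- function(f) sum(lse_rows(sweep(negu, 2, lognk + f, "+"))) - sum(N_k*f)
  Fcur <- obj(fk)
  it <- 0L
  repeat {
    it <- it + 1L
    B <- sweep(negu, 2, lognk + fk, "+")
    ld <- lse_rows(B)
    W <- exp(B - ld)
    g <- colSums(W) - N_k
    if (max(abs(g)) < tol*n) break
    d <- numeric(K)
    H <- -crossprod(W)
    diag(H) <- diag(H) + colSums(W)
    sol <- try(solve(H[-1, -1, drop = FALSE] + diag(1e-12, K - 1), -g[-1]),
               silent = TRUE)
    if (inherits(sol, "try-error")) {
      fnew <- -apply(negu - ld, 2, lse_vec)
      fnew <- fnew - fnew[1]
      d <- fnew - fk
    } else d[-1] <- sol
    improved <- FALSE
    step <- 1
    for (h in 1:30) {
      ft <- fk + step*d; ft <- ft - ft[1]
      Ft <- obj(ft)
      if (is.finite(Ft) && Ft <= Fcur) {
        fk <- ft; Fcur <- Ft; improved <- TRUE; break
      }
      step <- step/2
    }
    if (!improved) {
      fnew <- -apply(negu - ld, 2, lse_vec)
      fnew <- fnew - fnew[1]
      Ft <- obj(fnew)
      if (is.finite(Ft) && Ft < Fcur) { fk <- fnew; Fcur <- Ft }
      else break
    }
    if (it >= maxit) break
  }
  B <- sweep(negu, 2, lognk + fk, "+")
  ld <- lse_rows(B)
  Wfin <- exp(B - ld)
  res <- max(abs(colSums(Wfin) - N_k))
  if (res > 1e-4*n) {
    stop(sprintf(paste0("MBAR failed to converge (residual %.2e): ",
                        "windows likely lack pairwise overlap"), res))
  }
  # overlap diagnostic: the state graph implied by shared frame weight
  # must be connected, otherwise relative free energies are undefined
  adj <- crossprod(Wfin) > 1e-8
  comp <- rep(0L, K); comp[1] <- 1L; queue <- 1L
  while (length(queue)) {
    k <- queue[1]; queue <- queue[-1]
    nb <- which(adj[k, ] & comp == 0L)
    comp[nb] <- 1L
    queue <- c(queue, nb)
  }
  if (any(comp == 0L)) {
    stop(sprintf(paste0("MBAR windows lack pairwise overlap: %d of %d ",
                        "states are disconnected from the first"),
                 sum(comp == 0L), K))
  }
  w <- exp(-ld); w <- w/sum(w)
  structure(list(f = fk, weights = w, log_denom = ld, N_k = N_k,
                 iterations = it, residual = res,
                 converged = res < 1e-8*n),
            class = "mbar_fit")
}

lse_rows <- function(B) {
  mx <- apply(B, 1, max)
  mx + log(rowSums(exp(B - mx)))
}

lse_vec <- function(col) {
  mx <- max(col)
  mx + log(sum(exp(col - mx)))
}

#' @export
print.mbar_fit <- function(x, ...) {
  cat(sprintf("<mbar_fit> %d states, %d frames; %d iterations, residual %.2e\n",
              length(x$f), length(x$weights), x$iterations, x$residual))
  invisible(x)
}

#' Build the lambda-window MBAR problem from a simulation
#'
#' Decomposes an extended-system trajectory into biased states with
#' constant \eqn{\lambda = \lambda_i}: frames are grouped by path epoch
#' (runs of updates during which the path moved less than `path_tol`
#' share one representative path) and, within an epoch, by the nearest
#' lambda window centre on a grid of the given `spacing`.  The reduced
#' energy of frame `n` in state `k` is the coupling energy
#' \eqn{(s_{e(k)}(x_n) - \lambda_k)^2 / (2\sigma^2)} evaluated with the
#' path of state `k`'s epoch, plus the confinement energy when the run
#' used one.  States with fewer than `min_frames` frames are dropped
#' (with their frames) and a warning is issued.
#'
#' @param sim a `"path_sim"` from an eABF-type run.
#' @param spacing lambda window spacing.
#' @param min_frames minimum frames per state.
#' @param sub frame subsampling stride (every `sub`-th frame enters the
#'   MBAR problem; consecutive frames are strongly correlated, so
#'   modest subsampling loses little information).
#' @param path_tol maximum node displacement within one path epoch
#'   group.
#' @param max_time_fs optionally restrict to frames up to this time.
#' @return List with the reduced energy matrix `u`, state counts `N_k`,
#'   per-state `lambda` and `epoch_group`, the retained `frames` data
#'   frame, and the representative `paths`.
#' @export
mbar_windows <- function(sim, spacing = 0.02, min_frames = 40, sub = 5,
                         path_tol = 0.05, max_time_fs = Inf) {
  stopifnot(inherits(sim, "path_sim"))
  if (!sim$config$bias %in% c("eabf", "wtm-eabf"))
    stop("lambda windows require an extended-system (eABF) run")
  tr <- sim$trajectory
  tr <- tr[tr$time_fs <= max_time_fs, , drop = FALSE]
  tr <- tr[seq(1, nrow(tr), by = sub), , drop = FALSE]
  sigma <- sim$config$ext_sigma

  coord_cols <- setdiff(names(tr), c("step", "time_fs", "s", "d",
                                     "lambda", "epot", "ebias", "temp",
                                     "epoch"))
  X <- as.matrix(tr[, coord_cols, drop = FALSE])

  paths_all <- c(list(unclass(sim$path_init)), sim$path_snapshots)
  if (is.null(sim$path_init)) {
    # coordinate CV: a single trivial epoch, s = x
    grp <- rep(1L, nrow(tr))
    S <- matrix(tr$s, ncol = 1)
    rep_paths <- list(NULL)
  } else {
    mg <- merge_path_epochs(paths_all, path_tol)
    grp <- mg$group[tr$epoch + 1]
    rep_paths <- mg$paths
    gs <- sort(unique(grp))
    S <- matrix(0, nrow(tr), length(gs))
    for (j in seq_along(gs))
      S[, j] <- cpp_path_locate(rep_paths[[gs[j]]], X)$s
    grp <- match(grp, gs)
    rep_paths <- rep_paths[gs]
  }

  lam_i <- round(tr$lambda/spacing)
  key <- paste(grp, lam_i)
  tab <- table(key)
  keep <- names(tab)[tab >= min_frames]
  if (length(keep) < length(tab)) {
    dropped <- sum(tab[!names(tab) %in% keep])
    warning(sprintf("dropped %d sparse lambda windows (%d frames)",
                    sum(!names(tab) %in% keep), dropped))
  }
  use <- key %in% keep
  if (!any(use)) stop("no lambda window has enough frames")
  tr <- tr[use, , drop = FALSE]
  S <- S[use, , drop = FALSE]
  grp <- grp[use]; key <- key[use]

  ks <- sort(unique(key))
  kgrp <- as.numeric(sub(" .*", "", ks))
  klam <- as.numeric(sub(".* ", "", ks))*spacing
  N_k <- as.numeric(table(factor(key, levels = ks)))

  u <- matrix(0, nrow(tr), length(ks))
  bconf <- 0
  if (sim$config$conf_k > 0) {
    dd <- pmax(tr$d - sim$config$conf_d0, 0)
    bconf <- 0.5*sim$config$conf_k*dd^2/(.kB*sim$config$temperature)
  }
  for (k in seq_along(ks))
    u[, k] <- (S[, kgrp[k]] - klam[k])^2/(2*sigma^2) + bconf

  # connectivity pre-check: relative free energies are defined only
  # within a connected component of the state-overlap graph; keep the
  # largest component and drop the rest with a warning
  K <- length(ks)
  if (K > 1) {
    B <- sweep(-u, 2, log(N_k), "+")
    mxr <- apply(B, 1, max)
    ld0 <- mxr + log(rowSums(exp(B - mxr)))
    W0 <- exp(B - ld0)
    adj <- crossprod(W0) > 1e-4
    comp <- integer(K); cc <- 0L
    for (k in seq_len(K)) if (comp[k] == 0L) {
      cc <- cc + 1L; q <- k; comp[k] <- cc
      while (length(q)) {
        i <- q[1]; q <- q[-1]
        nb <- which(adj[i, ] & comp == 0L)
        comp[nb] <- cc; q <- c(q, nb)
      }
    }
    if (cc > 1L) {
      sizes <- vapply(seq_len(cc), function(c0) sum(N_k[comp == c0]), 0)
      keepc <- which.max(sizes)
      warning(sprintf(paste0("lambda windows form %d disconnected ",
                             "components; keeping the largest ",
                             "(%d of %d states, %.0f%% of frames)"),
                      cc, sum(comp == keepc), K,
                      100*sizes[keepc]/sum(sizes)))
      ksel <- comp == keepc
      fuse <- key %in% ks[ksel]     # frames sampled from kept states
      u <- u[fuse, ksel, drop = FALSE]
      tr <- tr[fuse, , drop = FALSE]
      N_k <- as.numeric(table(factor(key[fuse], levels = ks[ksel])))
      klam <- klam[ksel]; kgrp <- kgrp[ksel]
    }
  }
  list(u = u, N_k = N_k, lambda = klam, epoch_group = kgrp,
       frames = tr, paths = rep_paths)
}

merge_path_epochs <- function(paths, tol = 0.05) {
  grp <- integer(length(paths))
  grp[1] <- 1
  rep_paths <- list(paths[[1]])
  for (e in seq_along(paths)[-1]) {
    last <- rep_paths[[length(rep_paths)]]
    if (max(abs(paths[[e]] - last)) < tol) {
      grp[e] <- length(rep_paths)
    } else {
      rep_paths[[length(rep_paths) + 1]] <- paths[[e]]
      grp[e] <- length(rep_paths)
    }
  }
  list(group = grp, paths = rep_paths)
}

#' MBAR-reweighted PMF along an arbitrary path
#'
#' Convenience wrapper: builds the lambda-window problem with
#' [mbar_windows()], solves it with [mbar_solve()], projects the
#' retained frames onto `path` (defaulting to the final adapted path),
#' and histograms the unbiased weights into a free-energy profile.
#'
#' @param sim a `"path_sim"` from an eABF-type run.
#' @param path the path to project onto (a [cv_path()] or node matrix);
#'   default: the run's final path.
#' @param breaks histogram bin boundaries for the profile.
#' @param blocks number of blocks for the confidence estimate.
#' @param ... passed to [mbar_windows()].
#' @return A [fep()] with an `mbar` attribute holding the fit.
#' @export
mbar_pmf <- function(sim, path = sim$path_final,
                     breaks = seq(-0.105, 1.105, by = 0.01),
                     blocks = 1, ...) {
  win <- mbar_windows(sim, ...)
  fit <- mbar_solve(win$u, win$N_k)
  coord_cols <- setdiff(names(win$frames),
                        c("step", "time_fs", "s", "d", "lambda", "epot",
                          "ebias", "temp", "epoch"))
  X <- as.matrix(win$frames[, coord_cols, drop = FALSE])
  snew <- if (is.null(path)) win$frames$s
          else cpp_path_locate(unclass(cv_path(unclass(path))), X)$s
  out <- reweighted_pmf(fit$weights, snew, breaks,
                        sim$config$temperature, blocks = blocks)
  attr(out, "mbar") <- fit
  out
}
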