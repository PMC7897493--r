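## Markov state model estimation and validation: transition counting,
## ergodic trimming, reversible TPM estimation, implied timescales,
## propagation, convergence scans and GMRQ cross-validation scoring.

#' Count state-to-state transitions
#'
#' Sliding-window counting (every frame is a window start) at the given lag;
#' windows never span trajectory boundaries. Trajectories shorter than
#' `lag + 1` frames contribute nothing.
#'
#' @param dtrajs a [discrete_trajectory()] or list of them.
#' @param lag lag in frames (>= 1).
#' @param n_states size of the label space; defaults to the maximum over the
#'   trajectories.
#' @return Count matrix C (n_states x n_states).
#' @export
count_transitions <- function(dtrajs, lag, n_states = NULL) {
  dtrajs <- as_traj_list(dtrajs)
  lag <- as.integer(lag)
  if (lag < 1L) stop("lag must be >= 1 frame")
  lens <- vapply(dtrajs, function(d) length(d$labels), integer(1))
  if (all(lens <= lag)) stop("all trajectories are shorter than the lag")
  if (is.null(n_states)) {
    n_states <- max(vapply(dtrajs, function(d) d$n_states, integer(1)))
  }
  count_pairs_cpp(unlist(lapply(dtrajs, function(d) d$labels)),
                  lens, lag, as.integer(n_states))
}

#' Restrict a count matrix to its largest ergodic component
#'
#' Keeps the largest strongly connected component of the directed graph of
#' positive counts (ties broken by total counts).
#'
#' @param C non-negative square count matrix.
#' @return List with `C` (restricted matrix) and `state_map` (original state
#'   index of each retained state).
#' @export
trim_ergodic <- function(C) {
  stopifnot(nrow(C) == ncol(C), all(C >= 0))
  g <- igraph::graph_from_adjacency_matrix((C > 0) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    mass <- vapply(best, function(b) {
      idx <- which(comp$membership == b)
      sum(C[idx, idx])
    }, numeric(1))
    best <- best[which.max(mass)]
  }
  keep <- which(comp$membership == best)
  if (!length(keep)) stop("empty ergodic component")
  list(C = C[keep, keep, drop = FALSE], state_map = keep)
}

#' Estimate a transition probability matrix
#'
#' Reversible mode symmetrizes the counts, `(C + t(C)) / 2`, before row
#' normalization, so detailed balance holds exactly and the stationary
#' distribution is the normalized symmetrized row sum. Non-reversible mode
#' row-normalizes `C` directly and takes the stationary distribution from
#' the leading left eigenvector.
#'
#' @param C irreducible count matrix (e.g. from [trim_ergodic()]).
#' @param reversible enforce detailed balance (default TRUE).
#' @param lag lag in frames used to build `C`.
#' @param frame_stride ns per frame.
#' @param state_map original state ids of the rows of `C`.
#' @return An object of class `TransitionModel`: `counts`, `tpm`, `pi`,
#'   `eigenvalues` (descending, leading value 1), `lag_frames`, `lag_ns`,
#'   `state_map`, `reversible`.
#' @export
estimate_tpm <- function(C, reversible = TRUE, lag = 1L, frame_stride = 1,
                         state_map = seq_len(nrow(C))) {
  Cs <- if (reversible) (C + t(C)) / 2 else C
  rs <- rowSums(Cs)
  if (any(rs == 0)) stop("zero count row for state ", which(rs == 0)[1],
                         "; trim the counts first")
  tpm <- Cs / rs
  if (reversible) {
    pi_ <- rs / sum(rs)
    # similarity-symmetrized spectrum: real eigenvalues
    s <- sqrt(pi_)
    sym <- tpm * (s %o% (1 / s))
    sym <- (sym + t(sym)) / 2
    ev <- eigen(sym, symmetric = TRUE, only.values = TRUE)$values
  } else {
    e <- eigen(t(tpm))
    lead <- which.max(Re(e$values))
    v <- Re(e$vectors[, lead])
    pi_ <- abs(v) / sum(abs(v))
    ev <- Re(e$values)[order(-Re(e$values))]
  }
  structure(list(counts = C, tpm = tpm, pi = pi_,
                 eigenvalues = sort(ev, decreasing = TRUE),
                 lag_frames = as.integer(lag), lag_ns = lag * frame_stride,
                 state_map = state_map, reversible = reversible),
            class = "TransitionModel")
}

#' Build a Markov state model from discrete trajectories
#'
#' Convenience pipeline: count at the given lag, trim to the largest ergodic
#' component, and estimate the TPM.
#'
#' @inheritParams count_transitions
#' @inheritParams estimate_tpm
#' @return A `TransitionModel`.
#' @export
build_msm <- function(dtrajs, lag, reversible = TRUE, n_states = NULL) {
  dtrajs <- as_traj_list(dtrajs)
  C <- count_transitions(dtrajs, lag, n_states)
  tr <- trim_ergodic(C)
  estimate_tpm(tr$C, reversible = reversible, lag = lag,
               frame_stride = dtrajs[[1]]$frame_stride,
               state_map = tr$state_map)
}

#' @export
print.TransitionModel <- function(x, ...) {
  cat(sprintf("<TransitionModel> %d states, lag %.3g ns, %s\n",
              nrow(x$tpm), x$lag_ns,
              if (x$reversible) "reversible" else "non-reversible"))
  invisible(x)
}

#' Implied relaxation timescales
#'
#' For each lag, `t_k = -lag / log(mu_k)` for the eigenvalues `mu_k`,
#' k = 2..n_timescales + 1, of the TPM estimated at that lag. Non-positive
#' eigenvalues yield `NA` (undefined at that lag); eigenvalues at or above 1
#' yield `Inf`. Standard errors, when requested, come from a trajectory
#' bootstrap.
#'
#' @param dtrajs a [discrete_trajectory()] or list of them.
#' @param lags integer vector of lags in frames.
#' @param n_timescales number of timescales per lag.
#' @param reversible passed to [estimate_tpm()].
#' @param n_boot bootstrap replicates for standard errors (0 disables).
#' @param seed RNG seed for the bootstrap.
#' @return Data frame with columns `lag_frames`, `lag_ns`, `k`,
#'   `timescale_ns`, `se_ns` (class `TimescaleTable`).
#' @export
implied_timescales <- function(dtrajs, lags, n_timescales = 5L,
                               reversible = TRUE, n_boot = 0L, seed = 1L) {
  dtrajs <- as_traj_list(dtrajs)
  stride <- dtrajs[[1]]$frame_stride
  one <- function(dt, lag) {
    m <- build_msm(dt, lag, reversible = reversible)
    mu <- m$eigenvalues[-1]
    mu <- mu[seq_len(min(n_timescales, length(mu)))]
    ts <- rep(NA_real_, n_timescales)
    for (k in seq_along(mu)) {
      ts[k] <- if (is.na(mu[k]) || mu[k] <= 0) NA_real_
      else if (mu[k] >= 1) Inf
      else -lag * stride / log(mu[k])
    }
    ts
  }
  rows <- list()
  if (n_boot > 0L) set.seed(seed)
  for (lag in lags) {
    ts <- one(dtrajs, lag)
    se <- rep(NA_real_, n_timescales)
    if (n_boot > 0L) {
      boot <- replicate(n_boot, {
        idx <- sample.int(length(dtrajs), replace = TRUE)
        tryCatch(one(dtrajs[idx], lag), error = function(e)
          rep(NA_real_, n_timescales))
      })
      if (is.null(dim(boot))) boot <- matrix(boot, nrow = n_timescales)
      se <- apply(boot, 1, stats::sd, na.rm = TRUE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      lag_frames = lag, lag_ns = lag * stride, k = 2:(n_timescales + 1L),
      timescale_ns = ts, se_ns = se)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("TimescaleTable", "data.frame")
  out
}

#' Propagate a state distribution
#'
#' Row-vector convention: `p_n = p_0 T^n`. Probability mass is conserved.
#'
#' @param model a `TransitionModel`.
#' @param p0 initial distribution over the model's states.
#' @param n number of lag steps (>= 0).
#' @return Distribution after n steps.
#' @export
propagate <- function(model, p0, n) {
  k <- nrow(model$tpm)
  if (length(p0) != k) stop("p0 has wrong dimension")
  if (any(p0 < 0) || abs(sum(p0) - 1) > 1e-8) {
    stop("p0 must be a probability distribution")
  }
  p <- matrix(p0, nrow = 1)
  for (i in seq_len(n)) p <- p %*% model$tpm
  drop(p)
}

#' Sampling-convergence scan over truncated datasets
#'
#' Rebuilds the timescale estimate on datasets truncated to the leading
#' fraction of each trajectory and reports the slowest implied timescale per
#' (fraction, lag). Cells where the truncated data cannot support the
#' estimate (lag too long, disconnected chain) are flagged rather than
#' raising.
#'
#' @param dtrajs a [discrete_trajectory()] or list of them.
#' @param keep_fractions fractions in (0, 1] of each trajectory to keep.
#' @param lags lags in frames.
#' @param reversible passed through.
#' @return Data frame with `fraction`, `lag_frames`, `slowest_timescale_ns`,
#'   `flagged`.
#' @export
convergence_scan <- function(dtrajs, keep_fractions = c(0.7, 0.8, 0.9, 1.0),
                             lags, reversible = TRUE) {
  dtrajs <- as_traj_list(dtrajs)
  if (any(keep_fractions <= 0 | keep_fractions > 1)) {
    stop("keep_fractions must lie in (0, 1]")
  }
  rows <- list()
  for (f in keep_fractions) {
    trunc <- lapply(dtrajs, function(d) {
      n <- max(1L, floor(f * length(d$labels)))
      discrete_trajectory(d$labels[seq_len(n)], d$frame_stride, d$n_states,
                          d$id)
    })
    for (lag in lags) {
      ts <- tryCatch({
        tab <- implied_timescales(trunc, lag, n_timescales = 1L,
                                  reversible = reversible)
        tab$timescale_ns[1]
      }, error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        fraction = f, lag_frames = lag, slowest_timescale_ns = ts,
        flagged = is.na(ts))
    }
  }
  do.call(rbind, rows)
}

#' Evaluate a generalized Rayleigh quotient on a discretized dataset
#'
#' Scores a fixed set of candidate slow-mode vectors on the symmetrized
#' transition counts of `dtrajs`: the trace of the quotient of the lagged
#' against the instantaneous (diagonal) count quadratic forms. States with no
#' counts are dropped with a warning.
#'
#' @param V numeric matrix (n_states x m) of candidate eigenvectors.
#' @param dtrajs discretized trajectories to score on.
#' @param msm_lag lag in frames.
#' @param n_states label-space size (rows of `V`).
#' @return The scalar score; equals the sum of the top-m transition-matrix
#'   eigenvalues when `V` holds the eigenvectors estimated from the same
#'   data.
#' @export
gmrq_evaluate <- function(V, dtrajs, msm_lag, n_states = nrow(V)) {
  C <- count_transitions(dtrajs, msm_lag, n_states = n_states)
  Cs <- (C + t(C)) / 2
  seen <- which(rowSums(Cs) > 0)
  if (length(seen) < n_states) {
    warning(sprintf("%d state(s) unseen in the evaluation data; dropped",
                    n_states - length(seen)))
  }
  Vs <- V[seen, , drop = FALSE]
  Cs <- Cs[seen, seen, drop = FALSE]
  num <- crossprod(Vs, Cs %*% Vs)
  den <- crossprod(Vs, rowSums(Cs) * Vs)
  sum(diag(solve(den, num)))
}

# top-m generalized eigenvectors of (Csym, D) with D = diag(rowSums(Csym))
.gen_eigvec <- function(Csym, m) {
  rs <- rowSums(Csym)
  s <- sqrt(rs)
  sym <- Csym / (s %o% s)
  sym <- (sym + t(sym)) / 2
  e <- eigen(sym, symmetric = TRUE)
  v <- e$vectors[, seq_len(m), drop = FALSE] / s
  list(values = e$values[seq_len(m)], vectors = v)
}

#' Generalized matrix Rayleigh quotient cross-validation score
#'
#' Per trial, the trajectories are split at random into equal train/test
#' halves; the tICA projection, k-centers discretization and reversible
#' count matrices are fitted on the training half, and the score is the
#' generalized Rayleigh quotient of the training eigenvectors evaluated on
#' the test counts (sum over the top `m` modes, the stationary mode
#' included). With train = test the score equals the sum of the top `m`
#' transition-matrix eigenvalues. Test states never visited in training are
#' dropped with a warning - the connectivity caveat of sequential-transition
#' datasets.
#'
#' @param ftrajs list of [feature_trajectory()] objects (>= 2).
#' @param tica_lag tICA correlation lag in ns.
#' @param n_components retained tICA components.
#' @param k number of k-centers microstates.
#' @param msm_lag MSM lag in frames.
#' @param m number of slow modes scored (stationary mode included).
#' @param n_trials number of random splits.
#' @param seed RNG seed.
#' @param ridge tICA ridge.
#' @return Data frame with `trial`, `train_score`, `test_score`; attributes
#'   `mean_test`, `se_test`.
#' @export
gmrq_score <- function(ftrajs, tica_lag = 20, n_components = 4L, k = 90L,
                       msm_lag = 5L, m = 2L, n_trials = 50L, seed = 1L,
                       ridge = 1e-6) {
  ftrajs <- as_traj_list(ftrajs, "FeatureTrajectory")
  if (length(ftrajs) < 2L) stop("need at least two trajectories to split")
  set.seed(seed)
  fit_half <- function(idx) {
    tica <- fit_tica(ftrajs[idx], lag = tica_lag, n_components = n_components,
                     ridge = ridge)
    proj <- lapply(ftrajs[idx], function(t) tica_transform(tica, t))
    cl <- kcenters_fit(proj, k = k)
    list(tica = tica, clusters = cl,
         dtrajs = lapply(proj, function(p) assign_clusters(cl, p)))
  }
  rows <- lapply(seq_len(n_trials), function(trial) {
    idx <- sample(seq_along(ftrajs))
    half <- floor(length(idx) / 2)
    train <- idx[seq_len(half)]
    test <- idx[(half + 1):length(idx)]
    fit <- fit_half(train)
    C <- count_transitions(fit$dtrajs, msm_lag, n_states = k)
    Cs <- (C + t(C)) / 2
    seen <- which(rowSums(Cs) > 0)
    ge <- .gen_eigvec(Cs[seen, seen, drop = FALSE], m)
    V <- matrix(0, k, m)
    V[seen, ] <- ge$vectors
    proj_test <- lapply(ftrajs[test], function(t) tica_transform(fit$tica, t))
    dt_test <- lapply(proj_test, function(p) assign_clusters(fit$clusters, p))
    data.frame(trial = trial,
               train_score = sum(ge$values),
               test_score = gmrq_evaluate(V, dt_test, msm_lag, k))
  })
  out <- do.call(rbind, rows)
  attr(out, "mean_test") <- mean(out$test_score)
  attr(out, "se_test") <- stats::sd(out$test_score) / sqrt(n_trials)
  out
}
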