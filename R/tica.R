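#' Fit time-lagged independent component analysis
#'
#' Estimates the slowest linear collective coordinates of a set of feature
#' trajectories by solving the generalized symmetric eigenproblem of the
#' symmetrized time-lagged covariance against the (ridge-stabilized)
#' instantaneous covariance. Lagged pairs never span trajectory boundaries;
#' per-trajectory moment matrices are accumulated in a fixed (id-sorted)
#' order so the fit is independent of input ordering.
#'
#' @param trajs a [feature_trajectory()] or list of them (equal stride and
#'   feature names).
#' @param lag correlation lag in ns.
#' @param n_components number of components to retain.
#' @param ridge relative ridge added to the instantaneous covariance diagonal
#'   (`ridge * trace(C0)/d`); 0 disables.
#' @return An object of class `TicaModel`: fields `mean`, `c0`, `ctau`,
#'   `lag_ns`, `eigenvalues` (descending), `components` (columns, orthonormal
#'   under the `c0` metric), `n_components`, `feature_names`.
#' @export
fit_tica <- function(trajs, lag = 20, n_components = 4L, ridge = 1e-6) {
  trajs <- as_traj_list(trajs, "FeatureTrajectory")
  stride <- trajs[[1]]$frame_stride
  fn <- trajs[[1]]$feature_names
  for (tr in trajs) {
    if (!identical(tr$feature_names, fn)) stop("feature names differ across trajectories")
    if (abs(tr$frame_stride - stride) > 1e-12) stop("frame strides differ")
  }
  d <- length(fn)
  if (n_components > d) stop("n_components exceeds feature count")
  lag_frames <- as.integer(round(lag / stride))
  if (lag_frames < 1L) stop("lag shorter than one frame")
  shortest <- min(vapply(trajs, function(t) nrow(t$data), integer(1)))
  if (lag_frames >= shortest) {
    stop(sprintf("lag (%d frames) must be shorter than the shortest trajectory (%d frames)",
                 lag_frames, shortest))
  }
  ids <- vapply(seq_along(trajs), function(i) {
    if (is.null(trajs[[i]]$id)) sprintf("zz%06d", i) else trajs[[i]]$id
  }, character(1))
  ord <- order(ids)

  sxx <- matrix(0, d, d); sxy <- matrix(0, d, d)
  sx <- numeric(d); n_pairs <- 0
  for (i in ord) {
    x <- trajs[[i]]$data
    n <- nrow(x)
    head_ <- x[seq_len(n - lag_frames), , drop = FALSE]
    tail_ <- x[(lag_frames + 1):n, , drop = FALSE]
    sx <- sx + colSums(head_) + colSums(tail_)
    sxx <- sxx + crossprod(head_) + crossprod(tail_)
    sxy <- sxy + crossprod(head_, tail_)
    n_pairs <- n_pairs + (n - lag_frames)
  }
  mu <- sx / (2 * n_pairs)
  c0 <- sxx / (2 * n_pairs) - tcrossprod(mu)
  ct <- sxy / n_pairs
  ct <- (ct + t(ct)) / 2 - tcrossprod(mu)
  if (ridge > 0) c0 <- c0 + diag(ridge * sum(diag(c0)) / d, d)

  e0 <- eigen(c0, symmetric = TRUE)
  if (min(e0$values) <= 1e-12 * max(e0$values)) {
    stop("instantaneous covariance is singular; supply a positive ridge")
  }
  whiten <- e0$vectors %*% diag(1 / sqrt(e0$values), d) %*% t(e0$vectors)
  em <- eigen(whiten %*% ct %*% whiten, symmetric = TRUE)
  comp <- whiten %*% em$vectors[, seq_len(n_components), drop = FALSE]
  colnames(comp) <- paste0("tic", seq_len(n_components))
  rownames(comp) <- fn
  structure(list(mean = stats::setNames(mu, fn), c0 = c0, ctau = ct,
                 lag_ns = lag_frames * stride,
                 eigenvalues = em$values,
                 components = comp, n_components = as.integer(n_components),
                 feature_names = fn),
            class = "TicaModel")
}

#' Project a feature trajectory onto the slowest components
#'
#' Mean-centers the data with the model means and projects onto the retained
#' components; column k of the output is the k-th slowest coordinate.
#'
#' @param model a `TicaModel` from [fit_tica()].
#' @param traj a [feature_trajectory()] with matching feature names.
#' @return A [feature_trajectory()] with `n_components` columns.
#' @export
tica_transform <- function(model, traj) {
  if (!identical(traj$feature_names, model$feature_names)) {
    stop("feature names do not match the tICA model")
  }
  proj <- sweep(traj$data, 2, model$mean) %*% model$components
  feature_trajectory(proj, frame_stride = traj$frame_stride,
                     feature_names = colnames(model$components), id = traj$id)
}

#' @export
print.TicaModel <- function(x, ...) {
  cat(sprintf("<TicaModel> lag %.3g ns, %d/%d components\n", x$lag_ns,
              x$n_components, length(x$feature_names)))
  cat("top eigenvalues:", paste(round(utils::head(x$eigenvalues, 5), 4),
                                collapse = ", "), "\n")
  invisible(x)
}
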