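#' Pool projected trajectories into one data matrix
#'
#' Frames are pooled by lexical trajectory id, then frame index, which fixes
#' the deterministic starting frame of the k-centers traversal.
#'
#' @param trajs a [feature_trajectory()] or list of them.
#' @return List with the pooled `data` matrix and per-frame `traj`/`frame`
#'   indices.
#' @export
pool_frames <- function(trajs) {
  trajs <- as_traj_list(trajs, "FeatureTrajectory")
  ids <- vapply(seq_along(trajs), function(i) {
    if (is.null(trajs[[i]]$id)) sprintf("zz%06d", i) else trajs[[i]]$id
  }, character(1))
  ord <- order(ids)
  data <- do.call(rbind, lapply(trajs[ord], function(t) t$data))
  list(data = data,
       traj = rep(ord, vapply(trajs[ord], function(t) nrow(t$data), integer(1))),
       frame = unlist(lapply(trajs[ord], function(t) seq_len(nrow(t$data)))))
}

#' Greedy k-centers clustering
#'
#' Farthest-point traversal under the Euclidean metric: the first center is
#' the first pooled frame, and each subsequent center is the point with
#' maximal distance to its nearest existing center (ties broken by lowest
#' index). The covering radius of the result is at most twice the optimal
#' k-center radius.
#'
#' @param data numeric matrix of pooled frames, a [feature_trajectory()], or
#'   a list of them.
#' @param k number of centers.
#' @param seed RNG seed, used only when `random_start = TRUE`.
#' @param random_start start from a random frame instead of the first.
#' @return An object of class `ClusterModel`: `centers` (k x d),
#'   `center_index` (rows of the pooled data), `k`, `metric`,
#'   `covering_radius`.
#' @export
kcenters_fit <- function(data, k, seed = NULL, random_start = FALSE) {
  if (!is.matrix(data)) data <- pool_frames(data)$data
  n <- nrow(data)
  if (k < 1L || k > n) stop("k must be in [1, number of frames]")
  start <- 1L
  if (random_start) {
    if (!is.null(seed)) set.seed(seed)
    start <- sample.int(n, 1L)
  }
  centers <- integer(k)
  centers[1] <- start
  dmin <- sqrt(rowSums(sweep(data, 2, data[start, ])^2))
  if (k > 1L) {
    for (j in 2:k) {
      nxt <- which.max(dmin)
      if (dmin[nxt] == 0) {
        stop("k exceeds the number of distinct points (", j - 1L,
             " distinct centers found)")
      }
      centers[j] <- nxt
      dj <- sqrt(rowSums(sweep(data, 2, data[nxt, ])^2))
      dmin <- pmin(dmin, dj)
    }
  }
  structure(list(centers = data[centers, , drop = FALSE],
                 center_index = centers, k = as.integer(k),
                 metric = "euclidean", covering_radius = max(dmin)),
            class = "ClusterModel")
}

#' Assign frames to their nearest cluster center
#'
#' Ties are broken by the lowest center index.
#'
#' @param model a `ClusterModel` from [kcenters_fit()].
#' @param traj a [feature_trajectory()] (or bare matrix) with the model's
#'   dimensionality.
#' @return A [discrete_trajectory()] of center labels (or an integer vector
#'   for a bare matrix).
#' @export
assign_clusters <- function(model, traj) {
  x <- if (inherits(traj, "FeatureTrajectory")) traj$data else as.matrix(traj)
  if (ncol(x) != ncol(model$centers)) {
    stop(sprintf("dimension mismatch: data has %d columns, centers have %d",
                 ncol(x), ncol(model$centers)))
  }
  cc <- model$centers
  d2 <- outer(rowSums(x^2), rowSums(cc^2), "+") - 2 * x %*% t(cc)
  labels <- max.col(-d2, ties.method = "first")
  if (inherits(traj, "FeatureTrajectory")) {
    discrete_trajectory(labels, frame_stride = traj$frame_stride,
                        n_states = model$k, id = traj$id)
  } else as.integer(labels)
}

#' @export
print.ClusterModel <- function(x, ...) {
  cat(sprintf("<ClusterModel> k = %d (%s), covering radius %.4g\n",
              x$k, x$metric, x$covering_radius))
  invisible(x)
}
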