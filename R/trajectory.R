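#' Discrete state trajectory
#'
#' A time-ordered vector of integer state labels with a fixed frame stride,
#' the elementary object consumed by the Markov-state-model estimators.
#'
#' @param labels integer vector of 1-based state labels.
#' @param frame_stride time per frame in ns.
#' @param n_states number of states in the label space; defaults to
#'   `max(labels)`.
#' @param id optional source identifier (trajectory name).
#' @return An object of class `DiscreteTrajectory`.
#' @export
discrete_trajectory <- function(labels, frame_stride = 0.1, n_states = NULL,
                                id = NULL) {
  labels <- as.integer(labels)
  if (length(labels) < 1L) stop("trajectory must contain at least one frame")
  if (anyNA(labels)) stop("trajectory labels contain NA")
  if (is.null(n_states)) n_states <- max(labels)
  if (any(labels < 1L) || any(labels > n_states)) {
    bad <- which(labels < 1L | labels > n_states)[1L]
    stop(sprintf("label out of range [1, %d] at frame %d", n_states, bad))
  }
  stopifnot(is.numeric(frame_stride), frame_stride > 0)
  structure(list(labels = labels, frame_stride = frame_stride,
                 n_states = as.integer(n_states), id = id),
            class = "DiscreteTrajectory")
}

#' @export
length.DiscreteTrajectory <- function(x) length(x$labels)

#' @export
print.DiscreteTrajectory <- function(x, ...) {
  cat(sprintf("<DiscreteTrajectory> %d frames, %d states, %.3g ns/frame%s\n",
              length(x$labels), x$n_states, x$frame_stride,
              if (is.null(x$id)) "" else paste0(", id=", x$id)))
  invisible(x)
}

#' Feature trajectory
#'
#' A frames-by-features numeric matrix with named columns and a frame stride.
#'
#' @param mat numeric matrix (frames x features).
#' @param frame_stride time per frame in ns.
#' @param feature_names character vector, one per column; defaults to the
#'   matrix column names.
#' @param id optional source identifier.
#' @return An object of class `FeatureTrajectory`.
#' @export
feature_trajectory <- function(mat, frame_stride = 0.1, feature_names = NULL,
                               id = NULL) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "double"
  if (is.null(feature_names)) feature_names <- colnames(mat)
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(mat)))
  if (length(feature_names) != ncol(mat)) {
    stop("feature_names length must equal the number of columns")
  }
  if (anyNA(mat) || any(!is.finite(mat))) stop("features contain missing or non-finite values")
  colnames(mat) <- feature_names
  stopifnot(frame_stride > 0)
  structure(list(data = mat, frame_stride = frame_stride,
                 feature_names = feature_names, id = id),
            class = "FeatureTrajectory")
}

#' @export
dim.FeatureTrajectory <- function(x) dim(x$data)

#' @export
print.FeatureTrajectory <- function(x, ...) {
  cat(sprintf("<FeatureTrajectory> %d frames x %d features, %.3g ns/frame\n",
              nrow(x$data), ncol(x$data), x$frame_stride))
  invisible(x)
}

as_traj_list <- function(x, what = "DiscreteTrajectory") {
  if (inherits(x, what)) return(list(x))
  if (!is.list(x) || !all(vapply(x, inherits, logical(1), what))) {
    stop(sprintf("expected a %s or a list of them", what))
  }
  x
}
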