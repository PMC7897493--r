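## Synthetic generator for rotation-coupled sliding dynamics.
##
## The ground truth is a discrete-time Markov chain over micro-wells grouped
## by base-pair site on a short duplex segment. Each site carries one
## "interrogated" well (enzyme engaged with the inspected base pair) and,
## by default, one "transit" well (enzyme between adjacent sites). Rates come
## from Metropolis/Kramers detailed balance on the well depths, so deeper
## wells carry more stationary mass by construction.

# canonical B-DNA constants shared with the structure fixtures
.BDNA <- list(rise = 3.38, twist = 34.3, p_radius = 9.4)

#' Build a ground-truth sliding model
#'
#' Constructs the kinetic + emission model used by the synthetic-trajectory
#' generator: a row-stochastic transition matrix over micro-wells arranged on
#' a 1-D ladder of base-pair sites (nearest-neighbour sliding only), with the
#' lesion-containing site the deepest free-energy well under the defaults.
#'
#' Default site weights follow the nine-state equilibrium populations of the
#' sliding study this package models (S1..S9 = 4.1, 15.3, 8.8, 10.5, 18.4,
#' 12.7, 11.1, 11.0, 8.1 percent), so the mismatch-interrogating site S5
#' (bp 12) is thermodynamically favoured.
#'
#' @param n_sites number of base-pair sites (default 9, labelled bp8..bp16).
#' @param micro_per_site wells per site: 1 interrogated + (micro_per_site - 1)
#'   transit wells.
#' @param site_weights relative stationary weight per site (positive).
#' @param lesion_site site index carrying the G.T mispair; defaults to the
#'   heaviest site.
#' @param delta_transit free-energy penalty (kT) of a transit well relative to
#'   its site's interrogated well.
#' @param barrier_intra,barrier_slide barrier heights (kT) above the zero
#'   energy reference for intra-site and site-to-site hops; must be positive.
#' @param attempt_rate per-step attempt prefactor in (0, 1); scaled so rows
#'   remain stochastic.
#' @param depth_floor depth (kT) assigned to the shallowest interrogated well.
#' @param frame_stride time per chain step in ns.
#' @param n_noise_features count of pure-noise emission channels appended to
#'   the informative ones.
#' @return An object of class `GroundTruthSlidingModel` with fields
#'   `tpm_true`, `pi_true`, `site_of_state`, `well_type`, `well_position`,
#'   `emission_mean`, `emission_sd`, `lesion_site`, `site_labels`,
#'   `frame_stride`.
#' @export
build_sliding_model <- function(n_sites = 9L, micro_per_site = 2L,
                                site_weights = NULL, lesion_site = NULL,
                                delta_transit = 1.5,
                                barrier_intra = 0.5, barrier_slide = 0.7,
                                attempt_rate = 0.5, depth_floor = NULL,
                                frame_stride = 0.1, n_noise_features = 2L) {
  n_sites <- as.integer(n_sites)
  micro_per_site <- as.integer(micro_per_site)
  if (n_sites < 2L) stop("n_sites must be >= 2")
  if (micro_per_site < 1L) stop("micro_per_site must be >= 1")
  if (is.null(site_weights)) {
    site_weights <- if (n_sites == 9L) {
      c(4.1, 15.3, 8.8, 10.5, 18.4, 12.7, 11.1, 11.0, 8.1) / 100
    } else rep(1 / n_sites, n_sites)
  }
  if (length(site_weights) != n_sites || any(site_weights <= 0)) {
    stop("site_weights must be positive, one per site")
  }
  if (is.null(lesion_site)) lesion_site <- which.max(site_weights)
  if (any(c(delta_transit, barrier_intra, barrier_slide) <= 0) && micro_per_site > 1L) {
    stop("well depths and barrier heights must be positive")
  }
  if (barrier_intra <= 0 || barrier_slide <= 0) {
    stop("well depths and barrier heights must be positive")
  }
  if (is.null(depth_floor)) {
    depth_floor <- if (micro_per_site > 1L) delta_transit + 0.5 else 1.0
  }

  # depths (kT): interrogated wells track the site weights; transit wells sit
  # delta_transit above their interrogated well
  w <- site_weights / sum(site_weights)
  depth_I <- log(w) - min(log(w)) + depth_floor
  n_states <- n_sites * micro_per_site
  depth <- numeric(n_states)
  site_of_state <- integer(n_states)
  well_type <- character(n_states)
  well_position <- numeric(n_states)
  idx <- 0L
  for (s in seq_len(n_sites)) {
    for (m in seq_len(micro_per_site)) {
      idx <- idx + 1L
      site_of_state[idx] <- s
      if (m == 1L) {
        depth[idx] <- depth_I[s]
        well_type[idx] <- "interrogated"
        well_position[idx] <- s
      } else {
        depth[idx] <- depth_I[s] - delta_transit
        well_type[idx] <- "transit"
        well_position[idx] <- s + 0.5
      }
    }
  }
  if (any(depth <= 0)) stop("well depths must be positive; raise depth_floor")

  # linear chain of wells: ... I_s - T_s,1 - ... - T_s,m-1 - I_{s+1} ...
  # Metropolis/Kramers hop probability p_ij = nu * exp(-(B_e + depth_i)),
  # which satisfies detailed balance for pi ~ exp(depth).
  tpm <- matrix(0, n_states, n_states)
  for (i in seq_len(n_states - 1L)) {
    j <- i + 1L
    inter <- site_of_state[i] != site_of_state[j]
    B <- if (inter) barrier_slide else barrier_intra
    tpm[i, j] <- attempt_rate * exp(-(B + depth[i]))
    tpm[j, i] <- attempt_rate * exp(-(B + depth[j]))
  }
  rs <- rowSums(tpm)
  if (any(rs >= 1)) stop("attempt_rate too large: off-diagonal mass >= 1 in row ",
                         which(rs >= 1)[1])
  diag(tpm) <- 1 - rs

  pi_true <- exp(depth) / sum(exp(depth))

  model <- structure(list(
    n_sites = n_sites, micro_per_site = micro_per_site,
    tpm_true = tpm, pi_true = pi_true,
    site_of_state = site_of_state, well_type = well_type,
    well_position = well_position,
    lesion_site = as.integer(lesion_site),
    site_labels = paste0("bp", seq_len(n_sites) + 7L),
    frame_stride = frame_stride,
    depth = depth,
    emission_mean = NULL, emission_sd = NULL, feature_names = NULL
  ), class = "GroundTruthSlidingModel")

  em <- .default_emissions(model, n_noise_features)
  model$emission_mean <- em$mean
  model$emission_sd <- em$sd
  model$feature_names <- em$names

  validate_sliding_model(model)
  model
}

# rotation-coupled emission means: longitudinal coordinate advances by one
# helical rise per site, the angular pair by one helical twist; a groove
# penetration channel separates interrogated from transit wells.
.default_emissions <- function(model, n_noise_features) {
  pos <- model$well_position
  theta <- .BDNA$twist * pi / 180 * pos
  m <- cbind(long = .BDNA$rise * pos,
             cos_rot = cos(theta), sin_rot = sin(theta),
             groove_pen = ifelse(model$well_type == "interrogated", 2.0, 0.0))
  s <- matrix(rep(c(1.0, 0.25, 0.25, 0.6), each = nrow(m)), nrow(m))
  nms <- colnames(m)
  if (n_noise_features > 0L) {
    m <- cbind(m, matrix(0, nrow(m), n_noise_features))
    s <- cbind(s, matrix(1.0, nrow(m), n_noise_features))
    nms <- c(nms, paste0("noise", seq_len(n_noise_features)))
  }
  colnames(m) <- nms
  list(mean = m, sd = s, names = nms)
}

#' Validate a ground-truth sliding model
#'
#' Checks row-stochasticity, non-negativity, irreducibility, the
#' nearest-neighbour sliding topology, and (for default construction) that
#' the lesion site holds the maximum stationary site mass.
#'
#' @param model a `GroundTruthSlidingModel`.
#' @return The model, invisibly; errors name the offending row or component.
#' @export
validate_sliding_model <- function(model) {
  tpm <- model$tpm_true
  if (any(tpm < 0)) stop("negative transition probability in row ",
                         which(apply(tpm, 1, function(r) any(r < 0)))[1])
  bad <- which(abs(rowSums(tpm) - 1) > 1e-12)
  if (length(bad)) stop("row ", bad[1], " of tpm_true does not sum to 1")
  g <- igraph::graph_from_adjacency_matrix((tpm > 0) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  if (comp$no != 1L) {
    stop("chain is reducible: ", comp$no,
         " strongly connected components (largest has ",
         max(comp$csize), " states)")
  }
  # nearest-neighbour sliding: positive off-diagonal entries only between
  # wells of the same or adjacent sites
  off <- which(tpm > 0 & row(tpm) != col(tpm))
  ds <- abs(model$site_of_state[row(tpm)[off]] - model$site_of_state[col(tpm)[off]])
  if (any(ds > 1)) stop("transition connects non-adjacent sites")
  invisible(model)
}

#' Stationary site occupancies of a sliding model
#'
#' @param model a `GroundTruthSlidingModel`.
#' @return Named numeric vector: stationary probability mass per site.
#' @export
site_stationary <- function(model) {
  out <- tapply(model$pi_true, model$site_of_state, sum)
  stats::setNames(as.numeric(out), model$site_labels)
}

#' Sample discrete trajectories from the ground-truth chain
#'
#' Each trajectory is an exact realization of `tpm_true`, started from an
#' independent draw of the stationary distribution. Identical seeds give
#' identical output.
#'
#' @param model a `GroundTruthSlidingModel`.
#' @param n_traj number of trajectories (>= 1).
#' @param n_frames frames per trajectory (>= 2).
#' @param seed integer RNG seed.
#' @return List of [discrete_trajectory()] objects.
#' @export
sample_discrete_trajectories <- function(model, n_traj = 252L, n_frames = 1000L,
                                         seed = 1L) {
  if (n_traj < 1L) stop("n_traj must be >= 1")
  if (n_frames < 2L) stop("n_frames must be >= 2")
  set.seed(seed)
  cum <- t(apply(model$tpm_true, 1, cumsum))
  cum[, ncol(cum)] <- 1
  starts <- sample.int(length(model$pi_true), n_traj, replace = TRUE,
                       prob = model$pi_true)
  lapply(seq_len(n_traj), function(i) {
    labs <- sample_chain_cpp(cum, as.integer(n_frames), as.integer(starts[i]))
    discrete_trajectory(labs, frame_stride = model$frame_stride,
                        n_states = length(model$pi_true),
                        id = sprintf("traj%03d", i))
  })
}

#' Emit Gaussian features for a discrete trajectory
#'
#' Row t is drawn from Normal(emission_mean[state_t], diag(emission_sd^2)).
#' The default means encode rotation-coupled sliding: the longitudinal
#' channel advances by 3.38 A per site and the (cos, sin) angular pair by
#' 34.3 degrees per site.
#'
#' @param model a `GroundTruthSlidingModel`.
#' @param dtraj a [discrete_trajectory()] whose labels index the model wells.
#' @param seed integer RNG seed.
#' @return A [feature_trajectory()].
#' @export
emit_features <- function(model, dtraj, seed = 1L) {
  labs <- dtraj$labels
  n_states <- nrow(model$emission_mean)
  if (any(labs < 1L | labs > n_states)) {
    bad <- which(labs < 1L | labs > n_states)[1]
    stop(sprintf("state label %d out of range at frame %d", labs[bad], bad))
  }
  set.seed(seed)
  n <- length(labs); d <- ncol(model$emission_mean)
  noise <- matrix(stats::rnorm(n * d), n, d) * model$emission_sd[labs, , drop = FALSE]
  feature_trajectory(model$emission_mean[labs, , drop = FALSE] + noise,
                     frame_stride = dtraj$frame_stride,
                     feature_names = model$feature_names, id = dtraj$id)
}

#' Generate a full synthetic dataset
#'
#' Convenience wrapper: samples `n_traj` discrete trajectories and emits the
#' matching feature trajectories, with per-trajectory seeds derived from the
#' master seed.
#'
#' @inheritParams sample_discrete_trajectories
#' @return List with elements `dtrajs` and `ftrajs`.
#' @export
generate_dataset <- function(model, n_traj = 252L, n_frames = 1000L, seed = 1L) {
  dtrajs <- sample_discrete_trajectories(model, n_traj, n_frames, seed)
  ftrajs <- lapply(seq_along(dtrajs), function(i) {
    emit_features(model, dtrajs[[i]], seed = (seed + 7919L * i) %% .Machine$integer.max)
  })
  list(dtrajs = dtrajs, ftrajs = ftrajs)
}

#' @export
print.GroundTruthSlidingModel <- function(x, ...) {
  cat(sprintf("<GroundTruthSlidingModel> %d sites x %d wells, lesion site %s\n",
              x$n_sites, x$micro_per_site, x$site_labels[x$lesion_site]))
  cat("site stationary mass:\n")
  print(round(site_stationary(x), 4))
  invisible(x)
}
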