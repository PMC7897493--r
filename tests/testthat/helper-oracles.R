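# Independent oracles and small constructors shared across the suite.

# stationary distribution by power iteration (oracle, independent of eigen)
power_iter_stationary <- function(tpm, iters = 20000L, tol = 1e-14) {
  p <- rep(1 / nrow(tpm), nrow(tpm))
  for (i in seq_len(iters)) {
    p2 <- drop(p %*% tpm)
    if (max(abs(p2 - p)) < tol) return(p2)
    p <- p2
  }
  p
}

# hand-built sliding-model shell for chains given directly as a TPM
chain_model <- function(tpm, frame_stride = 0.1) {
  structure(list(tpm_true = tpm, pi_true = power_iter_stationary(tpm),
                 frame_stride = frame_stride,
                 site_of_state = seq_len(nrow(tpm)),
                 well_type = rep("interrogated", nrow(tpm)),
                 n_sites = nrow(tpm), micro_per_site = 1L,
                 emission_mean = diag(nrow(tpm)),
                 emission_sd = matrix(0, nrow(tpm), nrow(tpm)),
                 feature_names = paste0("f", seq_len(nrow(tpm)))),
            class = "GroundTruthSlidingModel")
}

# reversible transition model straight from a symmetric count matrix
model_from_counts <- function(C, lag = 1L, stride = 1) {
  estimate_tpm(C, reversible = TRUE, lag = lag, frame_stride = stride)
}

# quick structure frame from coordinate triples
make_frame <- function(xyz, name = NULL, elem = "C", resid = "X",
                       resno = NULL, chain = "Z") {
  xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  n <- nrow(xyz)
  structure_frame(data.frame(
    name = if (is.null(name)) paste0("A", seq_len(n)) else name,
    elem = rep_len(elem, n), resid = rep_len(resid, n),
    resno = if (is.null(resno)) seq_len(n) else resno,
    chain = rep_len(chain, n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
}

# apply a random rigid rotation + translation to a frame
random_rigid <- function(frame, seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  R <- matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
    2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
    2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
    1 - 2 * (q[2]^2 + q[3]^2)), 3, 3, byrow = TRUE)
  t_ <- rnorm(3, sd = 10)
  xyz <- as.matrix(frame[, c("x", "y", "z")]) %*% t(R)
  frame$x <- xyz[, 1] + t_[1]
  frame$y <- xyz[, 2] + t_[2]
  frame$z <- xyz[, 3] + t_[3]
  frame
}

# random-direction quadrature SASA: independent reference for the
# deterministic golden-spiral implementation
mc_sasa_oracle <- function(frame, selection = seq_len(nrow(frame)),
                           probe = 1.4, n_points = 3000L, seed = 1L) {
  set.seed(seed)
  vdw <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.52, P = 1.8, S = 1.8)
  radii <- vdw[frame$elem] + probe
  xyz <- as.matrix(frame[, c("x", "y", "z")])
  g <- matrix(rnorm(3 * n_points), n_points, 3)
  pts <- g / sqrt(rowSums(g^2))
  total <- 0
  for (i in selection) {
    sp <- sweep(pts * radii[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in seq_len(nrow(xyz))) {
      if (j == i) next
      acc <- acc & rowSums(sweep(sp, 2, xyz[j, ])^2) >= radii[j]^2
    }
    total <- total + 4 * pi * radii[i]^2 * mean(acc)
  }
  total
}

# exact hitting time from state `from` until first visit to set `to`
hitting_time <- function(tpm, from, to) {
  k <- nrow(tpm)
  rest <- setdiff(seq_len(k), to)
  m <- solve(diag(length(rest)) - tpm[rest, rest, drop = FALSE],
             rep(1, length(rest)))
  mm <- rep(0, k)
  mm[rest] <- m
  mm[from]
}
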