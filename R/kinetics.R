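## Macrostate lumping (PCCA+), transition path theory, and Monte-Carlo /
## linear-algebra mean-first-passage-time estimation with bootstrap errors.

# right eigenvectors of a reversible TPM via the pi-symmetrized form
.right_eigvec <- function(model, m) {
  pi_ <- model$pi
  s <- sqrt(pi_)
  sym <- model$tpm * (s %o% (1 / s))
  sym <- (sym + t(sym)) / 2
  e <- eigen(sym, symmetric = TRUE)
  list(values = e$values[seq_len(m)],
       vectors = e$vectors[, seq_len(m), drop = FALSE] / s,
       gap_next = if (ncol(e$vectors) > m) e$values[m + 1] else NA_real_)
}

#' PCCA+ macrostate lumping
#'
#' Spectral lumping of a reversible transition model into `n_macro`
#' metastable macrostates. The top `n_macro` right eigenvectors span an
#' (n_macro - 1)-simplex; memberships are obtained by mapping the extreme
#' rows (simplex vertices, found by a farthest-row orthogonalization sweep)
#' to the unit vertices. Crisp labels take the maximal membership; macro
#' populations sum the stationary distribution over members.
#'
#' @param model a reversible `TransitionModel`.
#' @param n_macro number of macrostates (2..n_states).
#' @return An object of class `MacrostateModel`: `assignment` (crisp micro ->
#'   macro labels), `membership` (k x n_macro, rows sum to 1), `n_macro`,
#'   `populations`, `pi_micro`, `state_map`.
#' @export
pcca_lump <- function(model, n_macro) {
  if (!isTRUE(model$reversible)) stop("PCCA+ requires a reversible model")
  k <- nrow(model$tpm)
  n_macro <- as.integer(n_macro)
  if (n_macro < 2L || n_macro > k) stop("n_macro must be in [2, n_states]")
  e <- .right_eigvec(model, n_macro)
  if (!is.na(e$gap_next) && abs(e$values[n_macro] - e$gap_next) < 1e-10) {
    stop("eigenvalue degeneracy at the spectral cut; choose a different n_macro")
  }
  X <- e$vectors
  X[, 1] <- 1  # stationary eigenvector, fixed sign/scale
  # farthest-row vertex search (simplex vertices of the eigenvector rows)
  idx <- integer(n_macro)
  W <- X
  idx[1] <- which.max(rowSums(W^2))
  W <- sweep(W, 2, W[idx[1], ])
  for (j in seq_len(n_macro - 1L)) {
    nrm <- sqrt(rowSums(W^2))
    idx[j + 1L] <- which.max(nrm)
    v <- W[idx[j + 1L], ] / nrm[idx[j + 1L]]
    W <- W - (W %*% v) %*% t(v)
  }
  A <- solve(X[idx, , drop = FALSE])
  chi <- X %*% A
  chi[chi < 0] <- 0
  chi <- chi / rowSums(chi)
  lab <- max.col(chi, ties.method = "first")
  pops <- vapply(seq_len(n_macro), function(a) sum(model$pi[lab == a]),
                 numeric(1))
  structure(list(assignment = lab, membership = chi, n_macro = n_macro,
                 populations = pops, pi_micro = model$pi,
                 state_map = model$state_map),
            class = "MacrostateModel")
}

#' Build a crisp macrostate model from a fixed assignment
#'
#' Useful to lump by a known mapping (e.g. ground-truth site of each well, or
#' to reuse one PCCA+ assignment across bootstrap resamples).
#'
#' @param assignment integer macro label per micro state.
#' @param pi_micro stationary distribution over micro states (for
#'   populations); optional.
#' @return A `MacrostateModel`.
#' @export
macrostates_from_assignment <- function(assignment, pi_micro = NULL) {
  assignment <- as.integer(assignment)
  n_macro <- max(assignment)
  chi <- diag(n_macro)[assignment, , drop = FALSE]
  pops <- if (is.null(pi_micro)) rep(NA_real_, n_macro) else
    vapply(seq_len(n_macro), function(a) sum(pi_micro[assignment == a]),
           numeric(1))
  structure(list(assignment = assignment, membership = chi,
                 n_macro = n_macro, populations = pops, pi_micro = pi_micro,
                 state_map = seq_along(assignment)),
            class = "MacrostateModel")
}

#' @export
print.MacrostateModel <- function(x, ...) {
  cat(sprintf("<MacrostateModel> %d micro -> %d macro\n",
              length(x$assignment), x$n_macro))
  if (!anyNA(x$populations)) {
    cat("populations:", paste(round(x$populations, 4), collapse = " "), "\n")
  }
  invisible(x)
}

#' Forward and backward committor probabilities
#'
#' The forward committor solves the harmonic system
#' `q_i = sum_j T_ij q_j` on the intermediate states with `q = 0` on A and
#' `q = 1` on B; the backward committor solves the analogue for the
#' time-reversed chain. For a reversible model `q- = 1 - q+`.
#'
#' @param model a `TransitionModel`.
#' @param A,B disjoint nonempty source and sink state sets (indices into the
#'   model's active states).
#' @return An object of class `TPTResult` with `qplus`, `qminus`, `A`, `B`.
#' @export
committors <- function(model, A, B) {
  k <- nrow(model$tpm)
  A <- unique(as.integer(A)); B <- unique(as.integer(B))
  if (!length(A) || !length(B)) stop("A and B must be nonempty")
  if (length(intersect(A, B))) stop("A and B must be disjoint")
  if (any(c(A, B) < 1L | c(A, B) > k)) stop("state set out of range")
  Tm <- model$tpm
  I <- setdiff(seq_len(k), union(A, B))
  qp <- numeric(k); qp[B] <- 1
  if (length(I)) {
    M <- diag(length(I)) - Tm[I, I, drop = FALSE]
    rhs <- rowSums(Tm[I, B, drop = FALSE])
    sol <- tryCatch(solve(M, rhs), error = function(e)
      stop("committor system singular (disconnected intermediates: ",
           paste(utils::head(I, 5), collapse = ","), " ...)"))
    qp[I] <- sol
  }
  # time-reversed chain: Tb_ij = pi_j T_ji / pi_i
  Tb <- t(Tm) * ((1 / model$pi) %o% model$pi)
  qm <- numeric(k); qm[A] <- 1
  if (length(I)) {
    M <- diag(length(I)) - Tb[I, I, drop = FALSE]
    rhs <- rowSums(Tb[I, A, drop = FALSE])
    qm[I] <- solve(M, rhs)
  }
  structure(list(qplus = qp, qminus = qm, A = A, B = B,
                 pi = model$pi, tpm = Tm),
            class = "TPTResult")
}

#' Net reactive flux and total A -> B flux
#'
#' Gross reactive flux `f_ij = pi_i q-_i T_ij q+_j` (i != j); net flux
#' `F_ij = max(0, f_ij - f_ji)`; total flux = sum of net flux out of A.
#' Flux is conserved at every intermediate state.
#'
#' @param model a `TransitionModel`.
#' @param A,B source and sink state sets.
#' @return A `TPTResult` with added `flux` (net flux matrix, per lag step)
#'   and `total_flux`.
#' @export
net_flux <- function(model, A, B) {
  tpt <- committors(model, A, B)
  k <- nrow(model$tpm)
  f <- (tpt$pi * tpt$qminus) %o% tpt$qplus * model$tpm
  diag(f) <- 0
  F_ <- f - t(f)
  F_[F_ < 0] <- 0
  tpt$flux <- F_
  tpt$total_flux <- sum(F_[tpt$A, setdiff(seq_len(k), tpt$A), drop = FALSE])
  tpt
}

# widest (maximum-bottleneck) path from any state in A to any in B on the
# non-negative capacity matrix F; returns NULL when no path exists
.widest_path <- function(F_, A, B) {
  k <- nrow(F_)
  width <- rep(-Inf, k); width[A] <- Inf
  prev <- rep(NA_integer_, k)
  done <- rep(FALSE, k)
  repeat {
    cand <- which(!done & width > -Inf)
    if (!length(cand)) break
    u <- cand[which.max(width[cand])]
    done[u] <- TRUE
    if (u %in% B) next
    for (v in which(F_[u, ] > 0)) {
      w <- min(width[u], F_[u, v])
      if (w > width[v]) {
        width[v] <- w
        prev[v] <- u
      }
    }
  }
  reach <- B[width[B] > 0]
  if (!length(reach)) return(NULL)
  end <- reach[which.max(width[reach])]
  path <- end
  while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
  list(path = path, bottleneck = width[end])
}

#' Decompose the net flux into ranked pathways
#'
#' Iterative bottleneck decomposition: repeatedly extract the A -> B path
#' whose minimum-edge (bottleneck) flux is maximal, record it, subtract its
#' bottleneck flux from every edge on it, and continue until `n_paths`
#' pathways are found or the flux is exhausted.
#'
#' @param tpt a `TPTResult` from [net_flux()].
#' @param n_paths maximum number of pathways.
#' @return Data-frame-like list of pathways: each has `states` (state
#'   sequence), `flux`, `share` (fraction of the total flux).
#' @export
top_pathways <- function(tpt, n_paths = 10L) {
  if (is.null(tpt$flux)) stop("run net_flux() first")
  F_ <- tpt$flux
  out <- list()
  for (i in seq_len(n_paths)) {
    wp <- .widest_path(F_, tpt$A, tpt$B)
    if (is.null(wp) || wp$bottleneck <= 1e-15) break
    out[[i]] <- list(states = wp$path, flux = wp$bottleneck,
                     share = wp$bottleneck / tpt$total_flux)
    for (j in seq_len(length(wp$path) - 1L)) {
      F_[wp$path[j], wp$path[j + 1L]] <-
        F_[wp$path[j], wp$path[j + 1L]] - wp$bottleneck
    }
  }
  if (!length(out)) warning("no A -> B pathway carries positive flux")
  structure(out, class = "PathwayList")
}

#' @export
print.PathwayList <- function(x, ...) {
  for (p in x) {
    cat(sprintf("%5.1f%%  %s\n", 100 * p$share,
                paste(p$states, collapse = " -> ")))
  }
  invisible(x)
}

#' Monte-Carlo trajectory of a transition model
#'
#' Exact simulation of the estimated chain, started from its stationary
#' distribution (or a given state); deterministic given the seed. At the
#' production settings of this package the default corresponds to a 10-ms
#' trajectory at a 30-ns lag.
#'
#' @param model a `TransitionModel`.
#' @param n_steps chain length (default `round(1e7/30)`, i.e. 10 ms of 30-ns
#'   steps).
#' @param seed RNG seed.
#' @param start optional fixed start state.
#' @return A [discrete_trajectory()] with `frame_stride = model$lag_ns`.
#' @export
mc_trajectory <- function(model, n_steps = round(1e7 / 30), seed = 1L,
                          start = NULL) {
  if (n_steps < 1) stop("n_steps must be >= 1")
  set.seed(seed)
  if (is.null(start)) {
    start <- sample.int(length(model$pi), 1L, prob = model$pi)
  }
  cum <- t(apply(model$tpm, 1, cumsum))
  cum[, ncol(cum)] <- 1
  labs <- sample_chain_cpp(cum, as.integer(n_steps), as.integer(start))
  discrete_trajectory(labs, frame_stride = model$lag_ns,
                      n_states = nrow(model$tpm), id = "mc")
}

#' Macrostate MFPTs and populations from a Monte-Carlo trajectory
#'
#' For each ordered macro pair (a, b), the mean over entries into a (frames
#' where the walker arrives in a from another macrostate, plus a stationary
#' start in a) of the elapsed steps until the first visit to b, times the
#' lag. Populations are macro state frequencies. Pairs observed fewer than
#' `min_events` times are flagged.
#'
#' @param mc a [discrete_trajectory()] from [mc_trajectory()] (micro labels).
#' @param lumping a `MacrostateModel` mapping micro to macro states.
#' @param lag_ns time per MC step in ns (defaults to the trajectory stride).
#' @param min_events flag threshold for passage-event counts.
#' @return An object of class `KineticsResult`: `mfpt_ns` (n_macro x
#'   n_macro, 0 on the diagonal), `n_events`, `flagged`, `populations`.
#' @export
mfpt_from_mc <- function(mc, lumping, lag_ns = mc$frame_stride,
                         min_events = 10L) {
  macro <- lumping$assignment[mc$labels]
  n <- length(macro)
  m <- lumping$n_macro
  mfpt <- matrix(0, m, m)
  nev <- matrix(0L, m, m)
  occ <- tabulate(macro, nbins = m)
  pops <- occ / n
  where <- lapply(seq_len(m), function(b) which(macro == b))
  for (a in seq_len(m)) {
    ent <- which(macro == a & c(TRUE, macro[-n] != a))
    for (b in seq_len(m)) {
      if (a == b) next
      idx <- where[[b]]
      if (!length(idx) || !length(ent)) {
        mfpt[a, b] <- NA_real_
        next
      }
      j <- findInterval(ent - 0.5, idx) + 1L
      ok <- j <= length(idx)
      if (!any(ok)) {
        mfpt[a, b] <- NA_real_
        next
      }
      steps <- idx[j[ok]] - ent[ok]
      mfpt[a, b] <- mean(steps) * lag_ns
      nev[a, b] <- sum(ok)
    }
  }
  flagged <- (nev < min_events) & (row(nev) != col(nev))
  structure(list(mfpt_ns = mfpt, n_events = nev, flagged = flagged,
                 populations = pops,
                 settings = list(n_steps = n, lag_ns = lag_ns)),
            class = "KineticsResult")
}

#' Exact macrostate MFPTs by linear algebra
#'
#' Solves the first-passage system `m = lag + T m` restricted off the target
#' macrostate for micro MFPTs, then averages over the stationary entry
#' distribution into the source macrostate (probability of arriving in micro
#' state i of a from outside a, under stationary flow) - the same averaging
#' convention as [mfpt_from_mc()]. Serves as the deterministic cross-check
#' of the Monte-Carlo estimator.
#'
#' @param model an irreducible `TransitionModel`.
#' @param lumping a `MacrostateModel` over the model's states.
#' @return A `KineticsResult` with exact `mfpt_ns` and stationary
#'   `populations`.
#' @export
mfpt_exact <- function(model, lumping) {
  Tm <- model$tpm
  k <- nrow(Tm)
  lab <- lumping$assignment
  if (length(lab) != k) stop("lumping does not match the model's state count")
  m <- lumping$n_macro
  lag <- model$lag_ns
  micro_mfpt <- matrix(0, k, m)  # expected time to reach macro b from micro i
  for (b in seq_len(m)) {
    tgt <- which(lab == b)
    rest <- setdiff(seq_len(k), tgt)
    if (!length(rest)) next
    M <- diag(length(rest)) - Tm[rest, rest, drop = FALSE]
    sol <- tryCatch(solve(M, rep(lag, length(rest))), error = function(e)
      stop("singular first-passage restriction for macrostate ", b))
    micro_mfpt[rest, b] <- sol
  }
  pi_ <- model$pi
  mfpt <- matrix(0, m, m)
  for (a in seq_len(m)) {
    ia <- which(lab == a)
    out <- which(lab != a)
    # stationary entry distribution into a
    w <- colSums(Tm[out, ia, drop = FALSE] * pi_[out])
    if (sum(w) == 0) w <- pi_[ia]
    w <- w / sum(w)
    for (b in seq_len(m)) {
      if (a == b) next
      mfpt[a, b] <- sum(w * micro_mfpt[ia, b])
    }
  }
  pops <- vapply(seq_len(m), function(a) sum(pi_[lab == a]), numeric(1))
  structure(list(mfpt_ns = mfpt, n_events = NULL, flagged = NULL,
                 populations = pops,
                 settings = list(lag_ns = lag, exact = TRUE)),
            class = "KineticsResult")
}

#' @export
print.KineticsResult <- function(x, ...) {
  cat("<KineticsResult> populations:",
      paste(round(x$populations, 4), collapse = " "), "\n")
  cat("MFPT (ns):\n")
  print(round(x$mfpt_ns, 1))
  invisible(x)
}

#' Bootstrap errors for MFPTs and populations
#'
#' Generates `n_lists` trajectory lists (resampled with replacement), and for
#' each rebuilds counts -> reversible TPM -> Monte-Carlo trajectory ->
#' macrostate MFPTs and populations under a fixed micro -> macro assignment.
#' Resamples whose largest ergodic component loses a whole macrostate are
#' redrawn (at most `max_retries` times, logged via warning). Reports the
#' mean and the standard deviation over lists as the standard error.
#'
#' @param dtrajs micro-state [discrete_trajectory()] list.
#' @param lumping a `MacrostateModel` whose assignment covers the full micro
#'   label space.
#' @param lag MSM lag in frames.
#' @param n_lists number of bootstrap lists (default 100).
#' @param list_size trajectories per list (default: all).
#' @param mc_steps Monte-Carlo trajectory length per list.
#' @param seed RNG seed.
#' @param resample set FALSE to reuse the full dataset in every list
#'   (recovers the point estimate when `n_lists = 1`).
#' @param max_retries redraw budget for disconnected resamples.
#' @return List with `mfpt_mean`, `mfpt_se`, `pop_mean`, `pop_se` and the
#'   per-list results in `lists`.
#' @export
bootstrap_kinetics <- function(dtrajs, lumping, lag, n_lists = 100L,
                               list_size = NULL, mc_steps = round(1e7 / 30),
                               seed = 1L, resample = TRUE, max_retries = 10L) {
  dtrajs <- as_traj_list(dtrajs)
  if (is.null(list_size)) list_size <- length(dtrajs)
  set.seed(seed)
  n_states <- max(vapply(dtrajs, function(d) d$n_states, integer(1)))
  full_macro <- sort(unique(lumping$assignment))
  one_list <- function(li) {
    for (try_ in seq_len(max_retries + 1L)) {
      idx <- if (resample) sample.int(length(dtrajs), list_size,
                                      replace = TRUE) else seq_along(dtrajs)
      C <- count_transitions(dtrajs[idx], lag, n_states = n_states)
      tr <- trim_ergodic(C)
      macro_seen <- sort(unique(lumping$assignment[tr$state_map]))
      if (identical(macro_seen, full_macro)) break
      if (try_ > max_retries) {
        warning("bootstrap list ", li,
                ": disconnected after max retries; using largest component")
        break
      }
      warning("bootstrap list ", li, ": resample disconnected; redrawing")
    }
    model <- estimate_tpm(tr$C, reversible = TRUE, lag = lag,
                          frame_stride = dtrajs[[1]]$frame_stride,
                          state_map = tr$state_map)
    sub_lump <- macrostates_from_assignment(
      lumping$assignment[tr$state_map], pi_micro = model$pi)
    mc_seed <- sample.int(.Machine$integer.max, 1L)
    mc <- mc_trajectory(model, n_steps = mc_steps, seed = mc_seed)
    res <- mfpt_from_mc(mc, sub_lump)
    # re-embed into the full macro label space (sub result is indexed by the
    # original macro numbers up to the largest one present)
    m_all <- max(full_macro)
    n_sub <- nrow(res$mfpt_ns)
    mf <- matrix(NA_real_, m_all, m_all)
    mf[seq_len(n_sub), seq_len(n_sub)] <- res$mfpt_ns
    pp <- rep(NA_real_, m_all)
    pp[seq_len(n_sub)] <- res$populations
    list(mfpt = mf, pop = pp)
  }
  lists <- lapply(seq_len(n_lists), one_list)
  mf_arr <- simplify2array(lapply(lists, `[[`, "mfpt"))
  pop_arr <- do.call(rbind, lapply(lists, `[[`, "pop"))
  list(mfpt_mean = apply(mf_arr, c(1, 2), mean, na.rm = TRUE),
       mfpt_se = apply(mf_arr, c(1, 2), stats::sd, na.rm = TRUE),
       pop_mean = colMeans(pop_arr, na.rm = TRUE),
       pop_se = apply(pop_arr, 2, stats::sd, na.rm = TRUE),
       lists = lists)
}
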