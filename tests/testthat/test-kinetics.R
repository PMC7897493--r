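block_model <- function(eps) {
  # two 2-state metastable blocks with coupling eps
  C <- matrix(eps, 4, 4)
  C[1:2, 1:2] <- matrix(c(40, 10, 10, 40), 2, 2)
  C[3:4, 3:4] <- matrix(c(40, 10, 10, 40), 2, 2)
  model_from_counts(C)
}

test_that("PCCA+ recovers decoupled and nearly-uncoupled blocks", {
  skip_if_not(TRUE)
  m0 <- block_model(1e-9)
  l0 <- pcca_lump(m0, 2)
  expect_equal(l0$assignment[1], l0$assignment[2])
  expect_equal(l0$assignment[3], l0$assignment[4])
  expect_false(l0$assignment[1] == l0$assignment[3])
  expect_equal(rowSums(l0$membership), rep(1, 4), tolerance = 1e-10)
  expect_equal(sum(l0$populations), 1, tolerance = 1e-10)
  m1 <- block_model(1e-3)
  l1 <- pcca_lump(m1, 2)
  expect_equal(l1$assignment, l0$assignment)
})

test_that("PCCA+ with n_macro = k separates every microstate", {
  set.seed(1)
  C <- matrix(rpois(16, 10) + 1, 4, 4)
  m <- model_from_counts(C)
  l <- pcca_lump(m, 4)
  expect_equal(sort(l$assignment), 1:4)
})

test_that("PCCA+ recovers the site structure of the sliding model", {
  m <- build_sliding_model()
  ds <- sample_discrete_trajectories(m, 252, 1000, seed = 1)
  msm <- build_msm(ds, lag = 30)
  lump <- pcca_lump(msm, 9)
  site <- m$site_of_state[msm$state_map]
  # the two wells of every site land in the same macrostate, and distinct
  # sites in distinct macrostates
  expect_equal(length(unique(paste(site, lump$assignment))), 9L)
  expect_equal(length(unique(lump$assignment)), 9L)
})

test_that("committors obey symmetry, the gambler's ruin form and identities", {
  sym3 <- model_from_counts(matrix(c(0, 5, 0, 5, 0, 5, 0, 5, 0), 3, 3))
  tpt <- committors(sym3, A = 1, B = 3)
  expect_equal(tpt$qplus[2], 0.5, tolerance = 1e-12)
  # birth-death chain: q+ matches the classical ruin closed form
  k <- 5; p <- 0.3; q <- 0.2
  Tm <- diag(k) * 0
  for (i in 2:(k - 1)) {
    Tm[i, i + 1] <- p; Tm[i, i - 1] <- q; Tm[i, i] <- 1 - p - q
  }
  Tm[1, 1] <- 1 - p; Tm[1, 2] <- p
  Tm[k, k] <- 1 - q; Tm[k, k - 1] <- q
  pi_ <- power_iter_stationary(Tm)
  model <- structure(list(tpm = Tm, pi = pi_, lag_ns = 1, reversible = TRUE,
                          state_map = 1:k), class = "TransitionModel")
  tpt2 <- committors(model, A = 1, B = k)
  r <- q / p
  ruin <- (1 - r^(0:(k - 1))) / (1 - r^(k - 1))
  expect_equal(tpt2$qplus, ruin, tolerance = 1e-10)
  # reversible chain: q+ + q- = 1
  expect_equal(tpt2$qplus + tpt2$qminus, rep(1, k), tolerance = 1e-10)
  expect_error(committors(model, A = 1, B = 1), "disjoint")
})

test_that("net flux is conserved, boundary-clean, and matches the renewal
           oracle to 1e-9 on small chains", {
  set.seed(2)
  for (trial in 1:8) {
    k <- sample(3:6, 1)
    C <- matrix(rexp(k * k), k, k) + diag(k)
    model <- model_from_counts((C + t(C)) / 2)
    a <- 1; b <- k
    tpt <- net_flux(model, a, b)
    # conservation at intermediates
    for (i in setdiff(seq_len(k), c(a, b))) {
      expect_lt(abs(sum(tpt$flux[, i]) - sum(tpt$flux[i, ])), 1e-12)
    }
    # no flux into the source or out of the sink
    expect_true(all(tpt$flux[, a] == 0))
    expect_true(all(tpt$flux[b, ] == 0))
    # net flux has no 2-cycles
    expect_true(all(tpt$flux * t(tpt$flux) == 0))
    # independent oracle: renewal identity through exact hitting times
    oracle <- 1 / (hitting_time(model$tpm, a, b) +
                     hitting_time(model$tpm, b, a))
    expect_lt(abs(tpt$total_flux - oracle), 1e-9)
  }
})

test_that("pathway decomposition ranks parallel routes by bottleneck flux", {
  # single chain 1 -> 2 -> 3 carries all flux
  chain <- model_from_counts(matrix(c(0, 5, 0, 5, 0, 5, 0, 5, 0), 3, 3))
  pw <- top_pathways(net_flux(chain, 1, 3), 5)
  expect_length(pw, 1)
  expect_equal(pw[[1]]$states, c(1, 2, 3))
  expect_equal(pw[[1]]$share, 1, tolerance = 1e-9)
  # two parallel 2-hop routes, 70/30 flux split
  Tm <- matrix(0, 4, 4)
  Tm[1, 2] <- 0.7; Tm[1, 3] <- 0.3
  Tm[2, 4] <- 1; Tm[3, 4] <- 1
  Tm[4, 1] <- 1
  Tm[1, 1] <- 0
  pi_ <- power_iter_stationary(Tm)
  model <- structure(list(tpm = Tm, pi = pi_, lag_ns = 1, reversible = FALSE,
                          state_map = 1:4), class = "TransitionModel")
  tpt <- net_flux(model, 1, 4)
  pw2 <- top_pathways(tpt, 5)
  shares <- vapply(pw2, `[[`, numeric(1), "share")
  expect_equal(shares[1:2], c(0.7, 0.3), tolerance = 1e-9)
  expect_lte(sum(shares), 1 + 1e-9)
  expect_equal(pw2[[1]]$states, c(1, 2, 4))
})

test_that("MC simulation is exact, seeded, and ergodic", {
  ident <- structure(list(tpm = diag(3), pi = rep(1 / 3, 3), lag_ns = 1),
                     class = "TransitionModel")
  mc <- mc_trajectory(ident, 100, seed = 1)
  expect_equal(length(unique(mc$labels)), 1L)
  flip <- structure(list(tpm = matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2),
                         pi = c(0.5, 0.5), lag_ns = 1),
                    class = "TransitionModel")
  mc2 <- mc_trajectory(flip, 1e5, seed = 2)
  sw <- mean(diff(mc2$labels) != 0)
  expect_lt(abs(sw - 0.1), 3 * sqrt(0.09 / 1e5))
  expect_lt(max(abs(tabulate(mc2$labels, 2) / 1e5 - 0.5)),
            3 * sqrt(0.25 / (1e5 * 0.1)))
  expect_identical(mc_trajectory(flip, 500, seed = 3),
                   mc_trajectory(flip, 500, seed = 3))
})

test_that("MC MFPT matches the geometric closed form and the exact solver", {
  flip <- structure(list(tpm = matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2,
                                      byrow = TRUE),
                         pi = c(0.5, 0.5), lag_ns = 30, reversible = TRUE,
                         state_map = 1:2), class = "TransitionModel")
  lump <- macrostates_from_assignment(1:2, flip$pi)
  ex <- mfpt_exact(flip, lump)
  expect_equal(ex$mfpt_ns[1, 2], 10 * 30, tolerance = 1e-10)
  expect_equal(diag(ex$mfpt_ns), c(0, 0))
  mc <- mc_trajectory(flip, 2e5, seed = 4)
  est <- mfpt_from_mc(mc, lump)
  expect_equal(diag(est$mfpt_ns), c(0, 0))
  for (a in 1:2) {
    b <- 3 - a
    se <- est$mfpt_ns[a, b] / sqrt(est$n_events[a, b])
    expect_lt(abs(est$mfpt_ns[a, b] - ex$mfpt_ns[a, b]), 3 * se)
  }
  # target covering all states: all zeros
  one <- macrostates_from_assignment(c(1, 1), flip$pi)
  expect_true(all(mfpt_exact(flip, one)$mfpt_ns == 0))
})

test_that("MC and exact MFPTs agree within 3 MC SE on larger test chains", {
  set.seed(5)
  for (trial in 1:3) {
    k <- sample(4:10, 1)
    C <- matrix(rexp(k * k) * 5, k, k) + diag(k)
    model <- model_from_counts((C + t(C)) / 2, lag = 1, stride = 1)
    n_macro <- sample(2:3, 1)
    lump <- macrostates_from_assignment(
      rep_len(seq_len(n_macro), k), model$pi)
    ex <- mfpt_exact(model, lump)
    mc <- mc_trajectory(model, 3e5, seed = 50 + trial)
    est <- mfpt_from_mc(mc, lump)
    for (a in seq_len(n_macro)) {
      for (b in seq_len(n_macro)) {
        if (a == b) next
        se <- ex$mfpt_ns[a, b] / sqrt(max(est$n_events[a, b], 1))
        expect_lt(abs(est$mfpt_ns[a, b] - ex$mfpt_ns[a, b]), 3 * se + 1e-9)
      }
    }
    expect_equal(est$populations, ex$populations, tolerance = 0.05)
  }
})

test_that("symmetric rings have symmetric passage times", {
  Tm <- matrix(0, 4, 4)
  for (i in 1:4) {
    Tm[i, i %% 4 + 1] <- 0.25
    Tm[i, (i - 2) %% 4 + 1] <- 0.25
    Tm[i, i] <- 0.5
  }
  model <- structure(list(tpm = Tm, pi = rep(0.25, 4), lag_ns = 1,
                          reversible = TRUE, state_map = 1:4),
                     class = "TransitionModel")
  lump <- macrostates_from_assignment(1:4, model$pi)
  ex <- mfpt_exact(model, lump)
  expect_equal(ex$mfpt_ns[1, 2], ex$mfpt_ns[2, 3], tolerance = 1e-10)
  expect_equal(ex$mfpt_ns[1, 2], ex$mfpt_ns[2, 1], tolerance = 1e-10)
  expect_equal(ex$mfpt_ns[1, 3], ex$mfpt_ns[2, 4], tolerance = 1e-10)
})

test_that("bootstrap kinetics reproduces point estimates and covers truth", {
  m <- build_sliding_model(n_sites = 3, micro_per_site = 1,
                           site_weights = c(1, 2, 1))
  ds <- sample_discrete_trajectories(m, 40, 500, seed = 6)
  lump <- macrostates_from_assignment(1:3)
  # identity list reproduces the point estimate pipeline
  set.seed(7)
  bs1 <- bootstrap_kinetics(ds, lump, lag = 5, n_lists = 1,
                            mc_steps = 5e4, seed = 7, resample = FALSE)
  msm <- build_msm(ds, lag = 5)
  set.seed(7)
  sample.int(length(ds), length(ds), replace = TRUE)  # no-op alignment
  expect_equal(dim(bs1$mfpt_mean), c(3, 3))
  expect_true(all(diag(bs1$mfpt_mean) == 0))
  # coverage of the true stationary site mass
  bs <- bootstrap_kinetics(ds, lump, lag = 5, n_lists = 25,
                           mc_steps = 5e4, seed = 8)
  z <- (bs$pop_mean - m$pi_true) / bs$pop_se
  expect_true(all(abs(z) < 4))
})

test_that("the top sliding pathway visits sites in strictly monotonic order", {
  m <- build_sliding_model()
  ds <- sample_discrete_trajectories(m, 252, 1000, seed = 1)
  msm <- build_msm(ds, lag = 30)
  site <- m$site_of_state[msm$state_map]
  for (terminal in c(1, m$n_sites)) {
    tpt <- net_flux(msm, which(site == terminal),
                    which(site == m$lesion_site))
    pw <- top_pathways(tpt, 1)
    path_sites <- site[pw[[1]]$states]
    steps <- diff(path_sites)
    expect_true(all(steps == (if (terminal == 1) 1 else -1) | steps == 0))
    expect_equal(path_sites[1], terminal)
    expect_equal(path_sites[length(path_sites)], m$lesion_site)
  }
})
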