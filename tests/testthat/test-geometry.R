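dna28 <- build_dna_fixture(28)
complex28 <- build_complex_fixture(dna28, 12, "interrogating")

test_that("pair resolution is exhaustive, deduplicated and order-stable", {
  one <- pair_selection_spec(list(list(chain = "A", resno = 5, name = "P")),
                             list(list(chain = "B", resno = 5, name = "P")))
  expect_equal(nrow(resolve_pairs(one, dna28)), 1L)
  prod <- pair_selection_spec(list(list(chain = "A", resno = 5:7, name = "P")),
                              list(list(chain = "B", resno = 5:8, name = "P")))
  pr <- resolve_pairs(prod, dna28)
  expect_equal(nrow(pr), 12L)
  expect_identical(pr, resolve_pairs(prod, dna28))
  expect_error(resolve_pairs(pair_selection_spec(
    list(list(chain = "Q", name = "P")),
    list(list(chain = "B", name = "P"))), dna28), "matches no atoms")
})

test_that("the dp1 specification resolves to exactly 1314 distance pairs", {
  pairs <- resolve_pairs(dp1_pair_spec(), complex28)
  expect_equal(nrow(pairs), 1314L)
})

test_that("distance features are Euclidean and translation invariant", {
  fr <- make_frame(c(0, 0, 0, 3, 4, 0, 0, 0, 0.00), name = c("A1", "A2", "A3"))
  sp <- pair_selection_spec(list(list(name = "A1")),
                            list(list(name = c("A2", "A3"))))
  pp <- resolve_pairs(sp, fr)
  d <- distance_features(fr, pp)
  expect_equal(unname(d), c(5, 0))
  shifted <- fr
  shifted$x <- fr$x + 11.5; shifted$y <- fr$y - 2; shifted$z <- fr$z + 0.25
  expect_equal(distance_features(shifted, pp), d)
  missing <- fr[-2, ]
  expect_error(distance_features(structure_frame(missing), pp), "A2")
})

test_that("minimum C-alpha to bp-center distance honors its construction", {
  ctr <- bp_center(dna28, 10)
  probe <- structure_frame(rbind(
    as.data.frame(dna28),
    data.frame(name = "CA", elem = "C", resid = "ALA", resno = 276,
               chain = "P", x = ctr[1] + 4, y = ctr[2], z = ctr[3])))
  d <- min_calpha_bp_distance(probe, residues = 276, bps = 8:12)
  expect_equal(unname(d), 4, tolerance = 1e-6)
  on_com <- probe
  on_com[nrow(on_com), c("x", "y", "z")] <- ctr
  expect_equal(unname(min_calpha_bp_distance(on_com, 276, bps = 10)), 0,
               tolerance = 1e-9)
})

test_that("salt-bridge detection honors the 6 A boundary exactly", {
  base <- data.frame(
    name = c("OP1", "NZ"), elem = c("O", "N"), resid = c("DG", "LYS"),
    resno = c(1, 50), chain = c("A", "P"),
    x = c(0, 5.99), y = 0, z = 0)
  at <- structure_frame(base)
  expect_true(salt_bridges(at, 50)$contact[[1]])
  base$x[2] <- 6.01
  expect_false(salt_bridges(structure_frame(base), 50)$contact[[1]])
  base$resid[2] <- "SER"
  expect_error(salt_bridges(structure_frame(base), 50), "Lys or Arg")
})

test_that("hydrogen-bond criterion applies distance and angle cuts", {
  fr <- make_frame(c(0, 0, 0, 1, 0, 0, 2.9, 0, 0),
                   name = c("N", "H", "O"), elem = c("N", "H", "O"))
  expect_true(hbond_present(fr, donor = 1, acceptor = 3, hydrogen = 2))
  far <- make_frame(c(0, 0, 0, 4.0, 0, 0), name = c("N", "O"),
                    elem = c("N", "O"))
  expect_false(hbond_present(far, donor = 1, acceptor = 2))
  # 90 degree donor-H-acceptor angle fails the angular cut
  bent <- make_frame(c(0, 0, 0, 1, 0, 0, 1, 1.5, 0),
                     name = c("N", "H", "O"), elem = c("N", "H", "O"))
  expect_false(hbond_present(bent, donor = 1, acceptor = 3, hydrogen = 2))
  frames <- list(fr, far)
  # occupancy without the hydrogen: distance criterion only
  expect_equal(hbond_occupancy(lapply(1:2, function(i)
    if (i == 1) fr else make_frame(c(0, 0, 0, 9, 0, 0, 4, 0, 0),
                                   name = c("N", "H", "O"),
                                   elem = c("N", "H", "O"))),
    donor = 1, acceptor = 3, hydrogen = 2), 0.5)
})

test_that("SASA matches the closed-form sphere and additivity limits", {
  single <- make_frame(c(0, 0, 0), elem = "C")
  expect_equal(sasa(single), 4 * pi * (1.7 + 1.4)^2, tolerance = 0.02)
  pairfar <- make_frame(c(0, 0, 0, 100, 0, 0), elem = "C")
  expect_equal(sasa(pairfar), 2 * 4 * pi * (1.7 + 1.4)^2, tolerance = 0.02)
  # atom buried under a tight shell is fully occluded
  shell <- rbind(c(0, 0, 0), 2.5 * as.matrix(expand.grid(c(-1, 1), c(-1, 1),
                                                         c(-1, 1))) / sqrt(3),
                 2.5 * rbind(diag(3), -diag(3)))
  buried <- make_frame(as.vector(t(shell)), elem = "C")
  expect_lt(sasa(buried, selection = 1), 1)
  expect_error(sasa(make_frame(c(0, 0, 0), elem = "Xx")), "Xx")
})

test_that("SASA agrees with an independent random-quadrature reference", {
  for (s in 1:5) {
    set.seed(100 + s)
    fr <- make_frame(rnorm(50 * 3, sd = 4),
                     elem = sample(c("C", "N", "O"), 50, replace = TRUE))
    a <- sasa(fr)
    b <- mc_sasa_oracle(fr, seed = s)
    expect_lt(abs(a - b) / b, 0.02)
  }
})

test_that("superposed RMSD is zero under rigid motion and optimal", {
  sel <- atom_select(dna28, name = "P")
  moved <- random_rigid(dna28, seed = 21)
  expect_lt(rmsd_superposed(moved, dna28, sel), 1e-9)
  expect_equal(rmsd_superposed(dna28, dna28, sel), 0)
  # constructed displacement: +1 A on measured atoms after fitting elsewhere
  fit_sel <- atom_select(dna28, name = "C1'")
  mea_sel <- atom_select(dna28, name = "P")
  disp <- dna28
  disp$x[mea_sel] <- disp$x[mea_sel] + 1
  expect_equal(rmsd_superposed(disp, dna28, fit_sel, mea_sel), 1.0,
               tolerance = 1e-9)
  # Kabsch optimality: no random rigid motion of the frame lowers the value
  small <- make_frame(rnorm(30, sd = 3), elem = "C")
  target <- random_rigid(small, seed = 3)
  target$x <- target$x + rnorm(10, sd = 0.4)
  base_val <- rmsd_superposed(target, small, 1:10)
  for (s in 1:20) {
    expect_gte(rmsd_superposed(random_rigid(target, seed = 300 + s), small,
                               1:10), base_val - 1e-9)
  }
})

test_that("radius of gyration matches closed forms", {
  two <- make_frame(c(0, 0, 0, 2, 0, 0))
  expect_equal(radius_of_gyration(two, 1:2), 1.0)
  s <- 3.2
  square <- make_frame(c(0, 0, 0, s, 0, 0, 0, s, 0, s, s, 0))
  expect_equal(radius_of_gyration(square, 1:4), s / sqrt(2))
  same <- make_frame(rep(c(1, 2, 3), 4))
  expect_equal(radius_of_gyration(same, 1:4), 0)
})

test_that("bend angle recovers constructed kinks and is rotation invariant", {
  expect_lt(dna_bend_angle(dna28, 12), 0.5)
  bent <- build_dna_fixture(28, bend_angle = 30, bend_step = 12)
  expect_equal(dna_bend_angle(bent, 12), 30, tolerance = 1)
  expect_equal(dna_bend_angle(random_rigid(bent, 5), 12),
               dna_bend_angle(bent, 12), tolerance = 1e-9)
  expect_error(dna_bend_angle(dna28, 2), "3 base pairs")
})

test_that("opening angle is zero when closed, tracks rotations, antisymmetric", {
  expect_equal(bp_opening_angle(dna28, 12), 0, tolerance = 0.5)
  rot_base <- function(frame, chain, deg) {
    c1 <- unlist(frame[atom_select(frame, chain = chain, resno = 12,
                                   name = "C1'"), c("x", "y", "z")])
    nm <- if (chain == "A") c("N", "N1", "O6") else c("N", "O2", "N3")
    ids <- atom_select(frame, chain = chain, resno = 12, name = nm)
    pts <- as.matrix(frame[ids, c("x", "y", "z")])
    a <- deg * pi / 180
    R <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
    frame[ids, c("x", "y", "z")] <- sweep(sweep(pts, 2, c1) %*% t(R), 2, c1,
                                          "+")
    frame
  }
  expect_equal(bp_opening_angle(rot_base(dna28, "A", 20), 12), 20,
               tolerance = 1)
  expect_equal(bp_opening_angle(rot_base(dna28, "B", 20), 12), -20,
               tolerance = 1)
})

test_that("groove geometry matches the helix closed form and is monotone", {
  gg <- groove_geometry(dna28, 12)
  # closed-form cross-strand P-P minimum from the generator's own parameters
  offs <- -6:6
  dmin <- min(vapply(offs, function(o) {
    dth <- abs((((120 - 34.3 * o) %% 360) + 540) %% 360 - 180)
    sqrt((2 * 9.4 * sin(dth * pi / 360))^2 + (3.38 * o)^2)
  }, numeric(1)))
  expect_equal(gg$minor_groove_width, max(0, dmin - 5.8), tolerance = 1)
  expect_gte(gg$minor_groove_width, 0)
  wide <- build_dna_fixture(28, p_radius = 10.4)
  expect_gt(groove_geometry(wide, 12)$minor_groove_width,
            gg$minor_groove_width)
  expect_error(groove_geometry(make_frame(c(0, 0, 0)), 12), "P atoms")
})

test_that("flip coordinates report the closed pair and the extruded reference", {
  fc <- flip_coordinates(dna28, 12)
  expect_lt(fc$pairing_distance, 4)
  expect_equal(random_rigid(dna28, 2) |> flip_coordinates(12) |>
                 getElement("pseudodihedral"),
               fc$pseudodihedral, tolerance = 1e-9)

  # build the flipped-state fixture: rotate the target base about the P-C1'
  # axis to the published pseudodihedral, then pull it out along the in-plane
  # radial direction to the published pairing distance
  fr <- dna28
  pI <- atom_select(fr, chain = "B", resno = 12, name = "P")
  c1I <- atom_select(fr, chain = "B", resno = 12, name = "C1'")
  p <- unlist(fr[pI, c("x", "y", "z")])
  c1 <- unlist(fr[c1I, c("x", "y", "z")])
  u <- (c1 - p) / sqrt(sum((c1 - p)^2))
  ids <- atom_select(fr, chain = "B", resno = 12, name = c("N", "O2", "N3"))
  rot_about <- function(pts, axis, deg, pivot) {
    a <- deg * pi / 180
    K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                  axis[2], -axis[1], 0), 3, 3)
    R <- diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
    sweep(sweep(pts, 2, pivot) %*% t(R), 2, pivot, "+")
  }
  delta <- -150 - fc$pseudodihedral
  fr[ids, c("x", "y", "z")] <- rot_about(
    as.matrix(fr[ids, c("x", "y", "z")]), u, delta, c1)
  # radial pull (within the dihedral half-plane, so the angle is unchanged)
  com <- colMeans(as.matrix(fr[ids, c("x", "y", "z")]))
  foot <- c1 + sum((com - c1) * u) * u
  rdir <- (com - foot) / sqrt(sum((com - foot)^2))
  need <- function(t) {
    f2 <- fr
    f2[ids, c("x", "y", "z")] <- sweep(as.matrix(fr[ids, c("x", "y", "z")]),
                                       2, t * rdir, "+")
    flip_coordinates(f2, 12)$pairing_distance - 16
  }
  t_star <- uniroot(need, c(0, 40))$root
  flipped <- fr
  flipped[ids, c("x", "y", "z")] <- sweep(
    as.matrix(fr[ids, c("x", "y", "z")]), 2, t_star * rdir, "+")
  fcf <- flip_coordinates(flipped, 12)
  expect_equal(fcf$pseudodihedral, -150, tolerance = 5)
  expect_equal(fcf$pairing_distance, 16, tolerance = 0.1)
})

test_that("observables are invariant under global rigid motion", {
  moved <- random_rigid(complex28, seed = 77)
  pairs <- resolve_pairs(dp1_pair_spec(), complex28)
  expect_equal(distance_features(moved, pairs),
               distance_features(complex28, pairs), tolerance = 1e-9)
  expect_equal(salt_bridges(moved, c(161, 232))$count,
               salt_bridges(complex28, c(161, 232))$count)
  expect_equal(bp_opening_angle(moved, 12), bp_opening_angle(complex28, 12),
               tolerance = 1e-9)
  expect_equal(groove_geometry(moved, 12)$minor_groove_width,
               groove_geometry(complex28, 12)$minor_groove_width,
               tolerance = 1e-9)
})
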