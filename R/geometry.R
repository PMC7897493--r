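## Structural observables: distance-pair featurizer, salt bridges, hydrogen
## bonds, SASA, RMSD, radius of gyration, DNA bend / opening / groove
## geometry, and base-flip coordinates.

atom_id <- function(frame, idx) {
  paste(frame$chain[idx], frame$resno[idx], frame$name[idx], sep = "/")
}

.resolve_ids <- function(frame, ids) {
  key <- paste(frame$chain, frame$resno, frame$name, sep = "/")
  idx <- match(ids, key)
  if (anyNA(idx)) stop("atom not found in frame: ", ids[which(is.na(idx))[1]])
  idx
}

#' Pair selection specification
#'
#' Describes two atom groups, each a list of [atom_select()] argument lists;
#' resolving the spec against a reference produces every A-vs-B pair once in
#' deterministic order.
#'
#' @param group_a,group_b lists of selector argument lists (fields `chain`,
#'   `resno`, `name`, `resid`, `elem` as in [atom_select()]).
#' @return An object of class `PairSelectionSpec`.
#' @export
pair_selection_spec <- function(group_a, group_b) {
  stopifnot(is.list(group_a), is.list(group_b),
            length(group_a) >= 1, length(group_b) >= 1)
  structure(list(group_a = group_a, group_b = group_b),
            class = "PairSelectionSpec")
}

.resolve_group <- function(frame, selectors, label) {
  idx <- integer(0)
  for (k in seq_along(selectors)) {
    sel <- do.call(atom_select, c(list(frame), selectors[[k]]))
    if (!length(sel)) {
      stop(sprintf("selector %d of %s matches no atoms (%s)", k, label,
                   paste(names(selectors[[k]]),
                         vapply(selectors[[k]], function(v)
                           paste(utils::head(v, 4), collapse = ","),
                           character(1)),
                         sep = "=", collapse = "; ")))
    }
    idx <- c(idx, sel)
  }
  idx[!duplicated(idx)]
}

#' Resolve a pair selection against a reference structure
#'
#' @param spec a [pair_selection_spec()].
#' @param ref a reference [structure_frame()].
#' @return Data frame with one row per (a, b) pair: atom ids `a`, `b` and the
#'   reference row indices `ai`, `bi`; class `PairList`.
#' @export
resolve_pairs <- function(spec, ref) {
  a <- .resolve_group(ref, spec$group_a, "group A")
  b <- .resolve_group(ref, spec$group_b, "group B")
  pairs <- data.frame(ai = rep(a, each = length(b)),
                      bi = rep(b, times = length(a)))
  pairs$a <- atom_id(ref, pairs$ai)
  pairs$b <- atom_id(ref, pairs$bi)
  key <- paste(pairs$a, pairs$b)
  pairs <- pairs[!duplicated(key), ]
  rownames(pairs) <- NULL
  class(pairs) <- c("PairList", "data.frame")
  pairs
}

#' The dp1 distance-pair specification
#'
#' The canonical tICA input feature set: all distances between the 18 DNA
#' backbone phosphorus atoms of base pairs 8-16 and (i) the 54 C-alpha atoms
#' of protein motifs K107-K122, P141-H158, T196-D202, P270-A282 and (ii) the
#' 19 side-chain heavy atoms of R275, Q278 and F279 - 1314 pairs in total.
#'
#' @param dna_chains the two DNA strand chain ids.
#' @param protein_chain protein chain id.
#' @param bps base-pair range of the sliding segment.
#' @return A [pair_selection_spec()].
#' @export
dp1_pair_spec <- function(dna_chains = c("A", "B"), protein_chain = "P",
                          bps = 8:16) {
  pair_selection_spec(
    group_a = list(list(chain = dna_chains, resno = bps, name = "P")),
    group_b = list(
      list(chain = protein_chain, resno = c(107:122, 141:158, 196:202, 270:282),
           name = "CA"),
      list(chain = protein_chain, resno = 275,
           name = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2")),
      list(chain = protein_chain, resno = 278,
           name = c("CB", "CG", "CD", "OE1", "NE2")),
      list(chain = protein_chain, resno = 279,
           name = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"))))
}

#' Distance features for one frame
#'
#' Euclidean distances (A) for a resolved pair list, in pair-list order.
#' Atoms are matched by chain/residue/name, so the pair list can be resolved
#' once on a reference and applied to any conformer.
#'
#' @param frame a [structure_frame()].
#' @param pairs a `PairList` from [resolve_pairs()].
#' @return Named numeric vector of distances.
#' @export
distance_features <- function(frame, pairs) {
  ai <- .resolve_ids(frame, pairs$a)
  bi <- .resolve_ids(frame, pairs$b)
  d <- sqrt(rowSums((coords(frame, ai) - coords(frame, bi))^2))
  names(d) <- paste(pairs$a, pairs$b, sep = "--")
  d
}

#' Featurize a sequence of frames
#'
#' @param frames list of [structure_frame()] conformers.
#' @param pairs a `PairList`.
#' @param frame_stride ns per frame.
#' @return A [feature_trajectory()] of pairwise distances.
#' @export
featurize_frames <- function(frames, pairs, frame_stride = 0.1) {
  mat <- t(vapply(frames, distance_features, numeric(nrow(pairs)),
                  pairs = pairs))
  feature_trajectory(mat, frame_stride = frame_stride)
}

#' Minimum C-alpha to base-pair-center distances
#'
#' For each listed protein residue, the minimum distance from its C-alpha to
#' the centers of the given base pairs.
#'
#' @param frame a [structure_frame()].
#' @param residues protein residue numbers (default the intercalation-loop
#'   tip A274-Q278).
#' @param bps base-pair indices.
#' @param protein_chain,dna_chains chain ids.
#' @return Named numeric vector (A), one entry per residue.
#' @export
min_calpha_bp_distance <- function(frame, residues = 274:278, bps,
                                   protein_chain = "P",
                                   dna_chains = c("A", "B")) {
  centers <- t(vapply(bps, function(b) bp_center(frame, b, dna_chains),
                      numeric(3)))
  out <- vapply(residues, function(r) {
    idx <- atom_select(frame, chain = protein_chain, resno = r, name = "CA")
    if (!length(idx)) stop("no CA atom for residue ", r)
    min(sqrt(rowSums(sweep(centers, 2, coords(frame, idx[1])[1, ])^2)))
  }, numeric(1))
  stats::setNames(out, paste0("res", residues))
}

#' Salt-bridge contacts between basic residues and the DNA backbone
#'
#' A residue contributes one contact iff the minimum distance from its basic
#' side-chain nitrogen(s) (Lys NZ; Arg NH1/NH2) to any DNA backbone oxygen
#' (OP1/O1P, OP2/O2P, O3', O5') is at or below the cutoff.
#'
#' @param frame a [structure_frame()].
#' @param residues protein residue numbers; each must be LYS or ARG.
#' @param cutoff distance cutoff in A (default 6).
#' @param protein_chain,dna_chains chain ids.
#' @return List with `count` (number of residues in contact) and `contact`
#'   (named logical per residue).
#' @export
salt_bridges <- function(frame, residues, cutoff = 6,
                         protein_chain = "P", dna_chains = c("A", "B")) {
  o_idx <- atom_select(frame, chain = dna_chains, name = .BACKBONE_O)
  if (!length(o_idx)) stop("no DNA backbone O atoms found")
  o_xyz <- coords(frame, o_idx)
  contact <- vapply(residues, function(r) {
    rows <- atom_select(frame, chain = protein_chain, resno = r)
    if (!length(rows)) stop("residue ", r, " not found")
    resid <- frame$resid[rows[1]]
    want <- switch(resid, LYS = "NZ", ARG = c("NH1", "NH2"),
                   stop("residue ", r, " (", resid, ") is not Lys or Arg"))
    n_idx <- atom_select(frame, chain = protein_chain, resno = r, name = want)
    if (!length(n_idx)) stop("residue ", r, " lacks atoms ",
                             paste(want, collapse = "/"))
    n_xyz <- coords(frame, n_idx)
    dmin <- min(sqrt(outer(rowSums(n_xyz^2), rowSums(o_xyz^2), "+") -
                       2 * n_xyz %*% t(o_xyz)))
    dmin <= cutoff
  }, logical(1))
  names(contact) <- paste0("res", residues)
  list(count = sum(contact), contact = contact)
}

.resolve_atom <- function(frame, id) {
  if (is.numeric(id)) return(as.integer(id))
  idx <- do.call(atom_select, c(list(frame), id))
  if (length(idx) != 1L) stop("atom spec matches ", length(idx), " atoms")
  idx
}

#' Geometric hydrogen-bond test
#'
#' True iff the donor-acceptor heavy-atom distance is at most 3.5 A and,
#' when a hydrogen position is supplied, the donor-H-acceptor angle is at
#' least 120 degrees.
#'
#' @param frame a [structure_frame()].
#' @param donor,acceptor atom index or selector list (single N or O atom).
#' @param hydrogen optional hydrogen atom index/selector.
#' @param dist_cut,angle_cut criterion parameters (A, degrees).
#' @return Logical.
#' @export
hbond_present <- function(frame, donor, acceptor, hydrogen = NULL,
                          dist_cut = 3.5, angle_cut = 120) {
  d <- coords(frame, .resolve_atom(frame, donor))[1, ]
  a <- coords(frame, .resolve_atom(frame, acceptor))[1, ]
  if (sqrt(sum((d - a)^2)) > dist_cut) return(FALSE)
  if (!is.null(hydrogen)) {
    h <- coords(frame, .resolve_atom(frame, hydrogen))[1, ]
    v1 <- d - h; v2 <- a - h
    ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                               sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
    if (ang < angle_cut) return(FALSE)
  }
  TRUE
}

#' Hydrogen-bond occupancy over frames
#'
#' @param frames list of [structure_frame()] conformers.
#' @inheritParams hbond_present
#' @return Fraction of frames in which the bond is present.
#' @export
hbond_occupancy <- function(frames, donor, acceptor, hydrogen = NULL,
                            dist_cut = 3.5, angle_cut = 120) {
  mean(vapply(frames, hbond_present, logical(1), donor = donor,
              acceptor = acceptor, hydrogen = hydrogen,
              dist_cut = dist_cut, angle_cut = angle_cut))
}

.VDW <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.52, P = 1.8, S = 1.8)

# deterministic quasi-uniform sphere points (golden spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent accessible surface area (Shrake-Rupley)
#'
#' Probe-sphere quadrature SASA: each atom's solvent sphere (van der Waals
#' radius + probe) is sampled at a fixed point count and a point counts as
#' accessible when outside every other atom's solvent sphere. All atoms in
#' the frame occlude; only the selection's accessible area is summed.
#'
#' @param frame a [structure_frame()].
#' @param selection integer atom indices whose area is reported (default all).
#' @param probe probe radius in A (default 1.4).
#' @param n_points quadrature points per atom (default 960).
#' @return Total accessible area in A^2.
#' @export
sasa <- function(frame, selection = seq_len(nrow(frame)), probe = 1.4,
                 n_points = 960L) {
  elems <- frame$elem
  unknown <- setdiff(unique(elems), names(.VDW))
  if (length(unknown)) stop("unknown element(s) for radius lookup: ",
                            paste(unknown, collapse = ", "))
  radii <- .VDW[elems] + probe
  xyz <- coords(frame)
  pts <- sphere_points(n_points)
  total <- 0
  for (i in selection) {
    ri <- radii[i]
    # neighbours able to occlude atom i
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (radii + ri)^2 & seq_along(d2) != i)
    if (!length(nb)) {
      total <- total + 4 * pi * unname(ri)^2
      next
    }
    sp <- sweep(pts * ri, 2, xyz[i, ], "+")
    occluded <- rep(FALSE, n_points)
    for (j in nb) {
      occluded <- occluded |
        rowSums(sweep(sp, 2, xyz[j, ])^2) < radii[j]^2
      if (all(occluded)) break
    }
    total <- total + 4 * pi * ri^2 * mean(!occluded)
  }
  as.numeric(total)
}

kabsch <- function(x, y) {
  # rotation + translation mapping x onto y, least squares
  cx <- colMeans(x); cy <- colMeans(y)
  s <- svd(crossprod(sweep(x, 2, cx), sweep(y, 2, cy)))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, cx = cx, cy = cy)
}

#' RMSD after least-squares superposition
#'
#' Rigidly superposes `frame` onto `reference` using the fit selection
#' (Kabsch rotation + translation), then reports the root-mean-square
#' deviation over the measure selection. Atoms are matched between the two
#' structures by chain/residue/name.
#'
#' @param frame,reference [structure_frame()] objects sharing the selected
#'   atoms.
#' @param fit_selection,measure_selection integer indices into `reference`
#'   (e.g. from [atom_select()]); `measure_selection` defaults to the fit
#'   selection.
#' @return RMSD in A.
#' @export
rmsd_superposed <- function(frame, reference, fit_selection,
                            measure_selection = fit_selection) {
  fit_ids <- atom_id(reference, fit_selection)
  mea_ids <- atom_id(reference, measure_selection)
  if (length(fit_selection) < 3) stop("fit selection needs >= 3 atoms")
  xf <- coords(frame, .resolve_ids(frame, fit_ids))
  yf <- coords(reference, fit_selection)
  tr <- kabsch(xf, yf)
  xm <- coords(frame, .resolve_ids(frame, mea_ids))
  ym <- coords(reference, measure_selection)
  xs <- sweep(sweep(xm, 2, tr$cx) %*% t(tr$R), 2, tr$cy, "+")
  sqrt(mean(rowSums((xs - ym)^2)))
}

#' Radius of gyration
#'
#' Mass-unweighted Rg about the selection centroid.
#'
#' @param frame a [structure_frame()].
#' @param selection integer atom indices (>= 2 atoms).
#' @return Rg in A.
#' @export
radius_of_gyration <- function(frame, selection) {
  if (length(selection) < 2) stop("need at least 2 atoms")
  x <- coords(frame, selection)
  sqrt(mean(rowSums(sweep(x, 2, colMeans(x))^2)))
}

.fit_axis <- function(centers) {
  # principal direction through a run of bp centers, oriented 5'->3'
  c0 <- colMeans(centers)
  v <- svd(sweep(centers, 2, c0))$v[, 1]
  if (sum(v * (centers[nrow(centers), ] - centers[1, ])) < 0) v <- -v
  v
}

#' DNA bend angle at a base-pair step
#'
#' Angle between the best-fit axes of the upstream and downstream helical
#' arms (`arm` base pairs on each side of `step`), from base-pair centers.
#'
#' @param frame a [structure_frame()].
#' @param step base-pair step index (bend between `step` and `step + 1`).
#' @param arm base pairs per arm (>= 3).
#' @param dna_chains strand chain ids.
#' @return Bend angle in degrees, in `[0, 180)`.
#' @export
dna_bend_angle <- function(frame, step, arm = 6L, dna_chains = c("A", "B")) {
  if (arm < 3) stop("arm must be >= 3 base pairs")
  bps <- sort(unique(frame$resno[frame$chain %in% dna_chains]))
  up <- bps[bps <= step]; up <- utils::tail(up, arm)
  dn <- bps[bps > step]; dn <- utils::head(dn, arm)
  if (length(up) < 3 || length(dn) < 3) {
    stop("need >= 3 base pairs on each side of the step")
  }
  cu <- t(vapply(up, function(b) bp_center(frame, b, dna_chains), numeric(3)))
  cd <- t(vapply(dn, function(b) bp_center(frame, b, dna_chains), numeric(3)))
  vu <- .fit_axis(cu); vd <- .fit_axis(cd)
  acos(pmin(1, pmax(-1, sum(vu * vd)))) * 180 / pi
}

.local_axis <- function(frame, bp, dna_chains) {
  bps <- sort(unique(frame$resno[frame$chain %in% dna_chains]))
  prev <- if ((bp - 1) %in% bps) bp_center(frame, bp - 1, dna_chains) else NULL
  nxt <- if ((bp + 1) %in% bps) bp_center(frame, bp + 1, dna_chains) else NULL
  here <- bp_center(frame, bp, dna_chains)
  v <- if (!is.null(prev) && !is.null(nxt)) nxt - prev
  else if (!is.null(nxt)) nxt - here
  else if (!is.null(prev)) here - prev
  else stop("no neighbouring base pair to define the local helix axis")
  v / sqrt(sum(v^2))
}

#' Base-pair opening angle
#'
#' Signed in-plane splay of the two glycosidic C1'->N vectors away from the
#' closed-pair geometry. For each base the reference direction points from
#' its C1' to the C1'-C1' midpoint; the deviation angle is measured in the
#' plane orthogonal to the local helix axis (right-handed about that axis),
#' and the opening is the first-strand deviation minus the second-strand
#' deviation, so it is zero for the ideal closed pair, grows as the bases
#' splay toward the grooves, and changes sign when the roles of the strands
#' are exchanged.
#'
#' @param frame a [structure_frame()].
#' @param bp base-pair index.
#' @param dna_chains strand chain ids (first entry is the reference strand).
#' @return Opening angle in degrees.
#' @export
bp_opening_angle <- function(frame, bp, dna_chains = c("A", "B")) {
  get1 <- function(chain, name) {
    idx <- atom_select(frame, chain = chain, resno = bp, name = name)
    if (!length(idx)) stop("base pair ", bp, " missing ", name,
                           " on chain ", chain)
    coords(frame, idx[1])[1, ]
  }
  c1a <- get1(dna_chains[1], "C1'"); na <- get1(dna_chains[1], "N")
  c1b <- get1(dna_chains[2], "C1'"); nb <- get1(dna_chains[2], "N")
  axis <- .local_axis(frame, bp, dna_chains)
  mid <- (c1a + c1b) / 2
  proj <- function(v) v - sum(v * axis) * axis
  signed <- function(c1, n) {
    u0 <- proj(mid - c1); u1 <- proj(n - c1)
    atan2(sum(axis * .cross(u0, u1)), sum(u0 * u1)) * 180 / pi
  }
  signed(c1a, na) - signed(c1b, nb)
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Minor-groove width and depth at a site
#'
#' Width: minimum cross-strand P-P distance within the minor-groove register
#' around `site`, minus 5.8 A (two phosphate radii), floored at zero.
#' Depth: distance from the site's base-pair center to the midpoint of the
#' minimizing P-P pair.
#'
#' @param frame a [structure_frame()].
#' @param site base-pair index.
#' @param window bp context searched on each side (default 6).
#' @param dna_chains strand chain ids.
#' @return List with `minor_groove_width`, `minor_groove_depth`, `site`
#'   (class `GrooveGeometry`).
#' @export
groove_geometry <- function(frame, site, window = 6L,
                            dna_chains = c("A", "B")) {
  rng <- (site - window):(site + window)
  pa <- atom_select(frame, chain = dna_chains[1], resno = rng, name = "P")
  pb <- atom_select(frame, chain = dna_chains[2], resno = rng, name = "P")
  if (!length(pa) || !length(pb)) stop("missing backbone P atoms around site ",
                                       site)
  xa <- coords(frame, pa); xb <- coords(frame, pb)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  # the groove register at the site: only pairs centered on it
  mid_bp <- outer(frame$resno[pa], frame$resno[pb], "+") / 2
  d2[abs(mid_bp - site) > 2] <- Inf
  if (all(!is.finite(d2))) stop("no cross-strand P pair registered at site ",
                                site)
  k <- arrayInd(which.min(d2), dim(d2))
  dmin <- sqrt(max(0, d2[k]))
  midpt <- (xa[k[1], ] + xb[k[2], ]) / 2
  structure(list(minor_groove_width = max(0, dmin - 5.8),
                 minor_groove_depth = sqrt(sum((bp_center(frame, site,
                                                          dna_chains) - midpt)^2)),
                 site = site),
            class = "GrooveGeometry")
}

dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross(b1, b2); n2 <- .cross(b2, b3)
  m1 <- .cross(n1, b2 / sqrt(sum(b2^2)))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

#' Base-flip reaction coordinates
#'
#' Pairing distance: distance between the center of the target thymine's
#' O2/N3 atoms and the center of the opposing guanine's N1/O6 atoms.
#' Pseudodihedral: dihedral over four centers - the 5'-flanking base-pair
#' center, the target nucleotide's P, its sugar reference (C1'), and its
#' base center - reported in (-180, 180] degrees.
#'
#' @param frame a [structure_frame()].
#' @param bp target base-pair index (the mispaired T and opposing G).
#' @param dna_chains strand chain ids; the strand carrying O2/N3 at `bp` is
#'   taken as the target nucleotide.
#' @return List with `pseudodihedral` (deg) and `pairing_distance` (A).
#' @export
flip_coordinates <- function(frame, bp, dna_chains = c("A", "B")) {
  sel <- function(names_, chain = dna_chains) {
    idx <- atom_select(frame, chain = chain, resno = bp, name = names_)
    if (!length(idx)) stop("base pair ", bp, " missing atoms ",
                           paste(names_, collapse = "/"))
    idx
  }
  t_edge <- sel(c("O2", "N3"))
  g_edge <- sel(c("N1", "O6"))
  pairing <- sqrt(sum((colMeans(coords(frame, t_edge)) -
                         colMeans(coords(frame, g_edge)))^2))
  t_chain <- frame$chain[t_edge[1]]
  p_idx <- atom_select(frame, chain = t_chain, resno = bp, name = "P")
  if (!length(p_idx)) stop("target nucleotide at bp ", bp, " has no P atom")
  sugar <- atom_select(frame, chain = t_chain, resno = bp, name = "C1'")
  if (!length(sugar)) stop("target nucleotide at bp ", bp, " has no C1'")
  base_idx <- atom_select(frame, chain = t_chain, resno = bp,
                          name = c("O2", "N3", "N"))
  flank <- bp_center(frame, bp - 1, dna_chains)
  list(pseudodihedral = dihedral(flank, coords(frame, p_idx[1])[1, ],
                                 coords(frame, sugar[1])[1, ],
                                 colMeans(coords(frame, base_idx))),
       pairing_distance = pairing)
}
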