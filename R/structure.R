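#' Labelled 3-D structure frame
#'
#' Carrier for atomic coordinates with PDB-style labelling, used by the
#' geometry operators and the idealized fixtures. One frame = one model.
#'
#' @param atoms data.frame with columns `name` (atom name), `elem` (element
#'   symbol), `resid` (residue name), `resno` (residue number), `chain`,
#'   `x`, `y`, `z` (Angstrom).
#' @param time frame time in ns.
#' @return An object of class `StructureFrame` (a data.frame).
#' @export
structure_frame <- function(atoms, time = 0) {
  need <- c("name", "elem", "resid", "resno", "chain", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("missing atom columns: ", paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms)[, need]
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) stop("non-finite coordinates")
  key <- paste(atoms$chain, atoms$resno, atoms$name)
  if (anyDuplicated(key)) {
    stop("duplicate atom name within a residue: ", key[duplicated(key)][1])
  }
  attr(atoms, "time") <- time
  class(atoms) <- c("StructureFrame", "data.frame")
  atoms
}

#' Select atoms of a structure frame
#'
#' All given conditions are combined with AND; `NULL` means no constraint.
#' `name` accepts exact atom names; alternative spellings (e.g. OP1/O1P) can
#' be passed together.
#'
#' @param frame a [structure_frame()].
#' @param chain,resno,name,resid optional vectors of admissible values.
#' @param elem optional element filter.
#' @return Integer row indices into `frame`, in frame order.
#' @export
atom_select <- function(frame, chain = NULL, resno = NULL, name = NULL,
                        resid = NULL, elem = NULL) {
  keep <- rep(TRUE, nrow(frame))
  if (!is.null(chain)) keep <- keep & frame$chain %in% chain
  if (!is.null(resno)) keep <- keep & frame$resno %in% resno
  if (!is.null(name))  keep <- keep & frame$name %in% name
  if (!is.null(resid)) keep <- keep & frame$resid %in% resid
  if (!is.null(elem))  keep <- keep & frame$elem %in% elem
  which(keep)
}

coords <- function(frame, idx = NULL) {
  m <- as.matrix(frame[, c("x", "y", "z")])
  if (!is.null(idx)) m <- m[idx, , drop = FALSE]
  m
}

# DNA strand chains used by the fixtures and default selections
.DNA_CHAINS <- c("A", "B")
.BASE_EDGE_ATOMS <- c("N1", "O6", "O2", "N3")
.BACKBONE_O <- c("OP1", "O1P", "OP2", "O2P", "O3'", "O5'")

#' Base-pair center
#'
#' Center of mass (unweighted) of the pairing-edge base atoms of base pair
#' `bp` (atoms N1/O6 on one strand and O2/N3 on the other); falls back to the
#' C1' midpoint when no base-edge atoms are present.
#'
#' @param frame a [structure_frame()].
#' @param bp base-pair index (residue number on both DNA chains).
#' @param dna_chains the two strand chain ids.
#' @return Numeric length-3 coordinate.
#' @export
bp_center <- function(frame, bp, dna_chains = .DNA_CHAINS) {
  idx <- atom_select(frame, chain = dna_chains, resno = bp,
                     name = .BASE_EDGE_ATOMS)
  if (!length(idx)) {
    idx <- atom_select(frame, chain = dna_chains, resno = bp, name = "C1'")
  }
  if (!length(idx)) stop("base pair ", bp, ": no base or C1' atoms found")
  colMeans(coords(frame, idx))
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

# Rodrigues rotation of points (n x 3) about unit axis u through pivot p
rotate_about <- function(pts, u, deg, pivot = c(0, 0, 0)) {
  a <- deg * pi / 180
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
  sweep(sweep(pts, 2, pivot) %*% t(R), 2, pivot, "+")
}

#' Build an idealized bent B-DNA duplex fixture
#'
#' Schematic duplex with one reference atom per structural role: backbone P
#' (with OP1/OP2 oxygens), ribose C1', glycosidic nitrogen `N`, and
#' pairing-edge base atoms (N1/O6 on strand A, O2/N3 on strand B). Geometry
#' follows canonical B-form values (rise 3.38 A, twist 34.3 deg, P radial
#' distance 9.4 A); base-pair centers lie on the helix axis. 5'-terminal
#' nucleotides (strand A residue 1, strand B residue `n_bp`) carry no
#' phosphate. A kink of `bend_angle` degrees can be introduced at base-pair
#' step `bend_step` by rotating the downstream arm.
#'
#' @param n_bp number of base pairs (>= 4).
#' @param bend_angle kink angle in degrees, 0 <= angle < 90.
#' @param bend_step interior bp index at which the two helical arms meet.
#' @param rise,twist,p_radius helix parameters (A, deg, A).
#' @return A [structure_frame()].
#' @export
build_dna_fixture <- function(n_bp = 28L, bend_angle = 0, bend_step = NULL,
                              rise = 3.38, twist = 34.3, p_radius = 9.4) {
  n_bp <- as.integer(n_bp)
  if (n_bp < 4L) stop("n_bp must be >= 4")
  if (bend_angle < 0 || bend_angle >= 90) stop("bend_angle must be in [0, 90)")
  if (bend_angle > 0) {
    if (is.null(bend_step)) stop("bend_step required when bend_angle > 0")
    if (bend_step <= 1L || bend_step >= n_bp) {
      stop("bend_step must be interior (1 < bend_step < n_bp)")
    }
  }
  gamma_p <- 60    # P azimuth (deg) from the minor-groove bisector
  r_c1 <- 5.9
  rows <- list()
  add <- function(name, elem, resid, resno, chain, p) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, elem = elem, resid = resid, resno = resno,
      chain = chain, x = p[1], y = p[2], z = p[3])
  }
  for (i in seq_len(n_bp)) {
    R <- rot_z(twist * (i - 1))
    z <- rise * (i - 1)
    ctr <- c(0, 0, z)
    for (s in c(1, -1)) {
      chain <- if (s > 0) "A" else "B"
      resid <- if (s > 0) "DG" else "DT"
      # phosphate + oxygens; 5' terminus carries no P
      has_p <- if (s > 0) i > 1L else i < n_bp
      if (has_p) {
        pP <- as.numeric(R %*% c(p_radius * cos(s * gamma_p * pi / 180),
                                 p_radius * sin(s * gamma_p * pi / 180), 0)) +
          c(0, 0, z)
        u_rad <- c(pP[1], pP[2], 0) / sqrt(pP[1]^2 + pP[2]^2)
        add("P", "P", resid, i, chain, pP)
        add("OP1", "O", resid, i, chain, pP + 1.48 * u_rad)
        add("OP2", "O", resid, i, chain, pP + c(0, 0, s * 1.48))
      }
      # ribose C1' diametric (schematic), so the C1' midpoint is on the axis
      c1 <- as.numeric(R %*% c(0, s * r_c1, 0)) + ctr
      add("C1'", "C", resid, i, chain, c1)
      # glycosidic nitrogen points from C1' toward the bp center
      u <- (ctr - c1); u <- u / sqrt(sum(u^2))
      add("N", "N", resid, i, chain, c1 + 1.5 * u)
      # pairing-edge atoms straddle the bp center along the C1'-C1' axis
      v <- as.numeric(R %*% c(0, -1, 0))      # A -> B direction
      if (s > 0) {
        add("N1", "N", resid, i, chain, ctr - 1.5 * v * 1 + c(0, 0, 0.3))
        add("O6", "O", resid, i, chain, ctr - 1.5 * v * 1 - c(0, 0, 0.3))
      } else {
        add("O2", "O", resid, i, chain, ctr + 1.5 * v + c(0, 0, 0.3))
        add("N3", "N", resid, i, chain, ctr + 1.5 * v - c(0, 0, 0.3))
      }
    }
  }
  atoms <- do.call(rbind, rows)
  frame <- structure_frame(atoms)
  if (bend_angle > 0) {
    pivot <- c(0, 0, rise * (bend_step - 1))
    axis <- as.numeric(rot_z(twist * (bend_step - 1)) %*% c(1, 0, 0))
    down <- frame$resno > bend_step
    coords_new <- rotate_about(coords(frame, which(down)), axis, bend_angle,
                               pivot)
    frame$x[down] <- coords_new[, 1]
    frame$y[down] <- coords_new[, 2]
    frame$z[down] <- coords_new[, 3]
  }
  frame
}

# residue names for the pseudo-protein probe; ALA where unlisted
.PROBE_RESNAMES <- c(`107` = "LYS", `122` = "LYS", `141` = "PRO", `158` = "HIS",
                     `161` = "LYS", `196` = "THR", `202` = "ASP", `232` = "LYS",
                     `270` = "PRO", `274` = "ALA", `275` = "ARG", `277` = "ALA",
                     `278` = "GLN", `279` = "PHE", `281` = "ARG", `282` = "ALA")
.SIDECHAINS <- list(
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"))

#' Build a pseudo-protein / DNA complex fixture
#'
#' Adds a schematic glycosylase probe (chain `P`) to a DNA fixture: C-alpha
#' atoms for the DNA-binding motifs (residues 107-122, 141-158, 196-202,
#' 270-282), full side-chain heavy atoms for R275/Q278/F279, and basic
#' side-chain nitrogens for the salt-bridge residues K161, K232, R275 and
#' R281. In the `interrogating` pose the basic nitrogens sit within 6 A of a
#' DNA backbone oxygen near `site`; in the `transit` pose all sit beyond 6 A.
#' Construction is fully deterministic.
#'
#' @param dna a DNA [structure_frame()] (e.g. [build_dna_fixture()]).
#' @param site interrogated base-pair index.
#' @param pose `"interrogating"` or `"transit"`.
#' @return A [structure_frame()] containing DNA plus probe atoms.
#' @export
build_complex_fixture <- function(dna, site, pose = c("interrogating", "transit")) {
  pose <- match.arg(pose)
  if (!site %in% dna$resno) stop("site ", site, " not present in the duplex")
  ctr <- bp_center(dna, site)
  # minor-groove bisector direction at `site` (local +x rotated by the twist)
  twist_here <- 34.3 * (site - 1)
  d <- as.numeric(rot_z(twist_here) %*% c(1, 0, 0))
  ez <- c(0, 0, 1)
  rows <- list()
  add <- function(name, elem, resid, resno, p) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, elem = elem, resid = resid, resno = resno,
      chain = "P", x = p[1], y = p[2], z = p[3])
  }
  resname <- function(r) {
    nm <- .PROBE_RESNAMES[as.character(r)]
    if (is.na(nm)) "ALA" else unname(nm)
  }
  # C-alpha backbone of the DNA-binding motifs on an arc outside the groove
  motif_res <- c(107:122, 141:158, 196:202, 270:282)
  for (k in seq_along(motif_res)) {
    r <- motif_res[k]
    ang <- (k - 1) * 4 * pi / 180
    p <- ctr + (12 + 0.05 * k) * (cos(ang) * d +
                                  sin(ang) * as.numeric(rot_z(90) %*% d)) +
      ez * (0.3 * (k - length(motif_res) / 2))
    add("CA", "C", resname(r), r, p)
  }
  add("CA", "C", "LYS", 161, ctr + 14 * d + 2 * ez)
  add("CA", "C", "LYS", 232, ctr + 14 * d - 2 * ez)
  # side-chain heavy atoms for R275 / Q278 / F279 clustered near the groove
  for (r in c(275, 278, 279)) {
    sc <- .SIDECHAINS[[resname(r)]]
    # R275's guanidinium nitrogens are placed by the pose anchors below
    if (r == 275) sc <- setdiff(sc, c("NH1", "NH2"))
    base <- ctr + 9 * d + (r - 277) * 1.2 * ez
    for (j in seq_along(sc)) {
      add(sc[j], substr(sc[j], 1, 1), resname(r), r,
          base + 0.9 * j * d + 0.4 * j * as.numeric(rot_z(90) %*% d))
    }
  }
  # basic nitrogens defining the salt-bridge state of the pose
  anchors <- list(
    list(res = 161, name = "NZ",  o_chain = "A", o_bp = site),
    list(res = 232, name = "NZ",  o_chain = "B", o_bp = site),
    list(res = 275, name = "NH1", o_chain = "A", o_bp = min(site + 1, max(dna$resno))),
    list(res = 281, name = "NH1", o_chain = "B", o_bp = max(site - 1, 1)))
  for (a in anchors) {
    if (pose == "interrogating") {
      oid <- atom_select(dna, chain = a$o_chain, resno = a$o_bp, name = "OP1")
      if (!length(oid)) oid <- atom_select(dna, chain = a$o_chain,
                                           resno = a$o_bp, name = "OP2")
      o <- coords(dna, oid[1])[1, ]
      out <- o - ctr; out[3] <- 0; out <- out / sqrt(sum(out^2))
      p <- o + 3.5 * out
    } else {
      p <- ctr + 14 * d + (a$res %% 7) * 0.8 * ez
    }
    add(a$name, "N", resname(a$res), a$res, p)
    if (a$name == "NH1") add("NH2", "N", resname(a$res), a$res, p + c(0.9, 0.9, 0.9))
  }
  dna_df <- as.data.frame(dna)
  dna_df <- dna_df[, c("name", "elem", "resid", "resno", "chain", "x", "y", "z")]
  structure_frame(rbind(dna_df, do.call(rbind, rows)))
}
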