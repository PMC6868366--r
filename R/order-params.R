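#' Labeled coordinate frame of a duplex region
#'
#' Holds named atoms (residue id, atom name, position in nm) of the region
#' around a rolling purine base, plus the positions of nearby water oxygen
#' atoms. This is the substrate for all geometric order parameters.
#'
#' @param atoms Data frame with columns `residue_id`, `atom_name`, `x`, `y`,
#'   `z` (nm).
#' @param water_oxygens Matrix (n x 3) of water-oxygen positions in nm, or
#'   NULL.
#' @param box Optional 3-vector of box lengths (nm).
#' @return An object of class `labeled_frame`.
#' @export
labeled_frame <- function(atoms, water_oxygens = NULL, box = NULL) {
  need <- c("residue_id", "atom_name", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("labeled_frame: atoms must have columns ",
         paste(need, collapse = ", "))
  key <- paste(atoms$residue_id, atoms$atom_name)
  if (anyDuplicated(key))
    stop("labeled_frame: duplicated (residue_id, atom_name): ",
         key[duplicated(key)][1])
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("labeled_frame: atom positions must be finite")
  if (is.null(water_oxygens)) water_oxygens <- matrix(numeric(0), 0, 3)
  water_oxygens <- as.matrix(water_oxygens)
  stopifnot(ncol(water_oxygens) == 3L)
  structure(list(atoms = atoms, water_oxygens = water_oxygens, box = box),
            class = "labeled_frame")
}

#' @export
print.labeled_frame <- function(x, ...) {
  cat("labeled_frame:", nrow(x$atoms), "atoms in",
      length(unique(x$atoms$residue_id)), "residues,",
      nrow(x$water_oxygens), "water oxygens\n")
  invisible(x)
}

#' Look up an atom position
#'
#' @param frame A [labeled_frame()].
#' @param residue,name Residue id and atom name.
#' @return Numeric 3-vector (nm).
#' @export
atom_position <- function(frame, residue, name) {
  i <- which(frame$atoms$residue_id == residue & frame$atoms$atom_name == name)
  if (length(i) != 1L)
    stop("atom not found in frame: residue '", residue, "', atom '", name, "'")
  as.numeric(frame$atoms[i, c("x", "y", "z")])
}

#' Default hydrogen-bond atom-pair assignment
#'
#' The three hydrogen bonds characterizing the pairing geometry of an A-T
#' pair: `d_BP` uses the bond present in both geometries (adenine N6 to
#' thymine O4), `d_WC` the Watson-Crick specific bond (adenine N1 to thymine
#' N3), and `d_HG` the Hoogsteen-specific bond through the purine 5-ring
#' (adenine N7 to thymine N3). Exposed as data so alternative assignments
#' can be dropped in.
#'
#' @param adenine,thymine Residue ids of the rolling adenine and its paired
#'   thymine.
#' @return Named list of atom pairs; each pair is a list of two
#'   `c(residue, atom)` character vectors.
#' @export
default_hbond_pairs <- function(adenine = "4DA'", thymine = "9DT") {
  list(d_BP = list(c(adenine, "N6"), c(thymine, "O4")),
       d_WC = list(c(adenine, "N1"), c(thymine, "N3")),
       d_HG = list(c(adenine, "N7"), c(thymine, "N3")))
}

#' Hydrogen-bond distances of the base pair
#'
#' @param frame A [labeled_frame()].
#' @param pair_map Atom-pair assignment as returned by
#'   [default_hbond_pairs()].
#' @return Named numeric vector `d_BP`, `d_WC`, `d_HG` (nm).
#' @export
hbond_distances <- function(frame, pair_map = default_hbond_pairs()) {
  vapply(pair_map, function(pr) {
    p1 <- atom_position(frame, pr[[1]][1], pr[[1]][2])
    p2 <- atom_position(frame, pr[[2]][1], pr[[2]][2])
    sqrt(sum((p1 - p2)^2))
  }, numeric(1))
}

#' Combined hydrogen-bond progress coordinate
#'
#' `lambda = arctan2(d_WC, d_HG)`: low (about 0.46 rad) when the
#' Watson-Crick bond is formed and the Hoogsteen distance is long, high
#' (about 1.11 rad) in the Hoogsteen geometry. Strictly increasing in
#' `d_WC`, strictly decreasing in `d_HG`, and invariant under a common
#' rescaling of both distances.
#'
#' @param d_WC,d_HG Hydrogen-bond distances (nm); vectorized.
#' @return Angle(s) in radians, in (0, pi/2) for positive distances.
#' @export
lambda_from_distances <- function(d_WC, d_HG) {
  if (any(d_WC < 0 | d_HG < 0))
    stop("lambda_from_distances: distances must be non-negative")
  if (any(d_WC == 0 & d_HG == 0))
    stop("lambda_from_distances: angle undefined when both distances are zero")
  atan2(d_WC, d_HG)
}

#' Glycosidic dihedral angle chi
#'
#' Signed dihedral over atoms O4', C1', N9, C4 of the rolling purine: the
#' rotation about the glycosidic bond that distinguishes the anti
#' (Watson-Crick) from the syn (Hoogsteen) orientation of the base.
#'
#' @param frame A [labeled_frame()].
#' @param residue Residue id of the rolling base.
#' @return Dihedral in degrees, in (-180, 180].
#' @export
glycosidic_chi <- function(frame, residue = "4DA'") {
  p <- lapply(c("O4'", "C1'", "N9", "C4"),
              function(a) atom_position(frame, residue, a))
  dihedral_angle(p[[1]], p[[2]], p[[3]], p[[4]])
}

# standard signed dihedral (IUPAC convention, cis = 0), degrees in (-180, 180]
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-12 || sqrt(sum(n2^2)) < 1e-12)
    stop("dihedral undefined: three consecutive atoms are collinear")
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Standard atomic masses by leading element letter
#'
#' @return Named numeric vector of masses (u) keyed by the first letter of
#'   the atom name.
#' @export
standard_masses <- function() {
  c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06)
}

atom_masses <- function(names, masses = standard_masses()) {
  el <- substr(names, 1, 1)
  unknown <- setdiff(unique(el), names(masses))
  if (length(unknown))
    stop("no mass for element(s) inferred from atom names: ",
         paste(unknown, collapse = ", "))
  unname(masses[el])
}

selection_com <- function(frame, selection, masses = standard_masses()) {
  pos <- t(vapply(selection, function(s) atom_position(frame, s[1], s[2]),
                  numeric(3)))
  m <- atom_masses(vapply(selection, `[`, "", 2), masses)
  colSums(pos * m) / sum(m)
}

base_plane_normal <- function(frame, residue = "4DA'") {
  n3 <- atom_position(frame, residue, "N3")
  n1 <- atom_position(frame, residue, "N1")
  n7 <- atom_position(frame, residue, "N7")
  bp <- cross3(n1 - n3, n7 - n3)
  if (sqrt(sum(bp^2)) < 1e-12)
    stop("base atoms N1, N3, N7 are collinear; base plane undefined")
  bp
}

#' Base opening angle theta
#'
#' Signed angle with vertex at II between I. the center of mass of the
#' rolling base, II. the center of mass of the flanking phosphate groups
#' and III. the center of mass of the neighboring base pairs. Near 0 when
#' the base center of mass lies toward the duplex core (stacked, as in both
#' WC and HG states), strongly negative when the base has flipped toward
#' solvent. The sign is the sign of `(v_II_I x v_II_III) . n_ref`; by
#' default `n_ref` is the rolling base's own plane normal (from N3, N1,
#' N7), which makes the signed angle invariant under rigid motions of the
#' whole frame.
#'
#' @param frame A [labeled_frame()].
#' @param selections List of three selections `I`, `II`, `III`; each is a
#'   list of `c(residue, atom)` character vectors.
#' @param masses Named mass table, see [standard_masses()].
#' @param n_ref Reference normal (3-vector), or NULL for the base-plane
#'   default.
#' @param residue Rolling-base residue id (used for the default `n_ref`).
#' @return Signed angle in degrees.
#' @export
opening_theta <- function(frame, selections, masses = standard_masses(),
                          n_ref = NULL, residue = "4DA'") {
  stopifnot(length(selections) == 3L)
  if (any(lengths(selections) == 0L))
    stop("opening_theta: all three selections must be non-empty")
  coms <- lapply(selections, selection_com, frame = frame, masses = masses)
  v1 <- coms[[1]] - coms[[2]]
  v2 <- coms[[3]] - coms[[2]]
  l1 <- sqrt(sum(v1^2)); l2 <- sqrt(sum(v2^2))
  if (l1 < 1e-12 || l2 < 1e-12)
    stop("opening_theta: zero-length arm; selections I/III coincide with II")
  ang <- acos(max(-1, min(1, sum(v1 * v2) / (l1 * l2)))) * 180 / pi
  if (is.null(n_ref)) n_ref <- base_plane_normal(frame, residue)
  s <- sign(sum(cross3(v1, v2) * n_ref))
  if (s == 0) s <- 1
  s * ang
}

#' Base rolling angle phi
#'
#' Angle between the base-plane normal `bp` (cross product of the N3 to N1
#' and N3 to N7 vectors of the rolling base) and the helix-axis proxy `bb`
#' (the vector between the phosphorus atoms of the terminal residues).
#' Tracks the orientation of the base independently of its position, and
#' unlike the glycosidic angle stays well defined while the base is outside
#' the duplex. The unsigned angle (0 to 180 degrees) is signed by
#' `sign((bp x bb) . r)` with `r` the vector from the duplex-core center of
#' mass (all atoms outside the rolling residue) to the base center of mass,
#' covering (-180, 180].
#'
#' @param frame A [labeled_frame()].
#' @param residue Rolling-base residue id.
#' @param bb_atoms List of two `c(residue, atom)` selections defining the
#'   backbone vector (defaults to the P atoms of residues DG11 and DC11').
#' @param masses Named mass table.
#' @return Signed angle in degrees in (-180, 180].
#' @export
rolling_phi <- function(frame, residue = "4DA'",
                        bb_atoms = list(c("DG11", "P"), c("DC11'", "P")),
                        masses = standard_masses()) {
  bp <- base_plane_normal(frame, residue)
  p1 <- atom_position(frame, bb_atoms[[1]][1], bb_atoms[[1]][2])
  p2 <- atom_position(frame, bb_atoms[[2]][1], bb_atoms[[2]][2])
  bb <- p2 - p1
  lb <- sqrt(sum(bb^2))
  if (lb < 1e-12) stop("rolling_phi: backbone atoms coincide")
  ang <- acos(max(-1, min(1, sum(bp * bb) / (sqrt(sum(bp^2)) * lb)))) * 180 / pi
  base_idx <- frame$atoms$residue_id == residue
  if (!any(base_idx) || all(base_idx))
    stop("rolling_phi: frame must contain the rolling residue and a core")
  base_sel <- frame$atoms[base_idx, ]
  core_sel <- frame$atoms[!base_idx, ]
  com_of <- function(df) {
    m <- atom_masses(df$atom_name, masses)
    colSums(as.matrix(df[, c("x", "y", "z")]) * m) / sum(m)
  }
  r <- com_of(base_sel) - com_of(core_sel)
  s <- sign(sum(cross3(bp, bb) * r))
  if (s == 0) s <- 1
  ang <- s * ang
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Count water oxygens around an atom
#'
#' Number of water oxygen atoms strictly within `cutoff` of the center atom
#' (default: within 0.6 nm, the hydration count used to detect solvent
#' exposure of the rolling base around its N6 atom).
#'
#' @param frame A [labeled_frame()].
#' @param center_atom `c(residue, atom)` of the center (default the rolling
#'   adenine's N6).
#' @param cutoff Radius in nm (default 0.6); strict inequality.
#' @return Non-negative integer count.
#' @export
count_waters <- function(frame, center_atom = c("4DA'", "N6"), cutoff = 0.6) {
  ctr <- atom_position(frame, center_atom[1], center_atom[2])
  if (nrow(frame$water_oxygens) == 0L) return(0L)
  d2 <- rowSums(sweep(frame$water_oxygens, 2, ctr)^2)
  sum(d2 < cutoff^2)
}

#' Full order-parameter vector of a frame
#'
#' @param frame A [labeled_frame()].
#' @param theta_selections Selections for [opening_theta()] (see there); if
#'   NULL, `theta` is omitted.
#' @param pair_map Hydrogen-bond pair assignment.
#' @param residue Rolling-base residue id.
#' @return Named list: `d_BP`, `d_WC`, `d_HG` (nm), `lambda` (rad), `chi`,
#'   `theta`, `phi` (degrees), `n_water` (integer).
#' @export
order_param_vector <- function(frame, theta_selections = NULL,
                               pair_map = default_hbond_pairs(),
                               residue = "4DA'") {
  d <- hbond_distances(frame, pair_map)
  out <- list(d_BP = d[["d_BP"]], d_WC = d[["d_WC"]], d_HG = d[["d_HG"]],
              lambda = lambda_from_distances(d[["d_WC"]], d[["d_HG"]]),
              chi = glycosidic_chi(frame, residue),
              theta = if (!is.null(theta_selections))
                opening_theta(frame, theta_selections, residue = residue)
              else NA_real_,
              phi = rolling_phi(frame, residue),
              n_water = count_waters(frame, c(residue, "N6")))
  out
}
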