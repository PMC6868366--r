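#' Build a synthetic base-pair frame with prescribed order parameters
#'
#' Constructs a `labeled_frame` (a synthetic stand-in for an MD snapshot)
#' on which the geometric order parameters evaluate to the requested
#' targets: hydrogen-bond distances `d_BP`, `d_WC`, `d_HG`, glycosidic
#' angle `chi`, opening angle `theta`, rolling angle `phi`, and a given
#' number of water oxygens inside the hydration cutoff. The construction is
#' deterministic (no randomness) and exact to numerical round-off, so a
#' round trip through the order-parameter functions recovers the targets.
#'
#' Geometry: a planar idealized adenine (residue `4DA'`) fixes the base
#' plane; the thymine N3 is placed at the intersection of the spheres of
#' radius `d_WC` around N1 and `d_HG` around N7 (an error if the spheres do
#' not intersect); the sugar atoms realizing `chi` are placed by rotation
#' about the glycosidic axis; the backbone P atoms realize `phi` against
#' the base-plane normal; three single-atom pseudo-selections realize
#' `theta`; `n_waters` oxygens are placed on a deterministic spiral inside
#' the cutoff sphere around N6 (plus `n_waters_outside` beyond it).
#'
#' @param d_BP,d_WC,d_HG Target hydrogen-bond distances (nm).
#' @param chi,theta,phi Target angles (degrees).
#' @param n_waters Water oxygens inside the cutoff sphere around N6.
#' @param n_waters_outside Additional oxygens placed outside the cutoff.
#' @param cutoff Hydration cutoff (nm), default 0.6.
#' @return A list of class `pair_fixture`: `frame` (the [labeled_frame()]),
#'   `theta_selections` (to pass to [opening_theta()]), and `targets`.
#' @export
build_fixture <- function(d_BP = 0.29, d_WC = 0.30, d_HG = 0.60,
                          chi = -120, theta = -5, phi = 10,
                          n_waters = 0, n_waters_outside = 0,
                          cutoff = 0.6) {
  if (any(c(d_BP, d_WC, d_HG) < 0))
    stop("build_fixture: distances must be non-negative")
  A <- "4DA'"; T_ <- "9DT"
  atoms <- list()
  add <- function(res, name, p) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      residue_id = res, atom_name = name, x = p[1], y = p[2], z = p[3])
  }

  # planar idealized adenine, base plane z = 0; N1-N7 distance ~0.43 nm
  C4 <- c(0, 0, 0);        N9 <- c(0.14, 0, 0)
  N3 <- c(-0.12, -0.12, 0); N1 <- c(-0.10, 0.26, 0)
  N7 <- c(0.30, 0.10, 0);  N6 <- c(0.02, 0.46, 0)
  for (nm in c("C4", "N9", "N3", "N1", "N7", "N6"))
    add(A, nm, get(nm))

  # thymine N3 at the two-sphere intersection in the base plane
  e <- N7 - N1; L <- sqrt(sum(e^2)); e <- e / L
  a <- (d_WC^2 - d_HG^2 + L^2) / (2 * L)
  h2 <- d_WC^2 - a^2
  if (h2 < 0)
    stop("build_fixture: inconsistent targets; spheres of radius d_WC and ",
         "d_HG around N1 and N7 (", format(L, digits = 3),
         " nm apart) do not intersect")
  pdir <- cross3(c(0, 0, 1), e)         # in-plane perpendicular
  TN3 <- N1 + a * e + sqrt(h2) * pdir
  add(T_, "N3", TN3)
  # thymine O4 at d_BP from adenine N6, placed outward in the plane
  add(T_, "O4", N6 + d_BP * (N6 - N9) / sqrt(sum((N6 - N9)^2)))

  # sugar atoms realizing the glycosidic dihedral O4'-C1'-N9-C4
  u <- c(0.6, 0, 0.8)                   # glycosidic axis C1' - N9 direction
  C1p <- N9 + 0.15 * u
  wref <- C4 - N9
  wref <- wref - sum(wref * u) * u      # perpendicular reference (cis side)
  wref <- wref / sqrt(sum(wref^2))
  place_o4p <- function(ang) {
    v <- rot_axis(wref, u, ang * pi / 180)
    C1p + 0.05 * u + 0.14 * v
  }
  O4p <- place_o4p(chi)
  d <- dihedral_angle(O4p, C1p, N9, C4)
  if (abs(angdiff(d, chi)) > 1e-8) O4p <- place_o4p(-chi)
  add(A, "O4'", O4p)
  add(A, "C1'", C1p)

  # backbone P atoms realizing phi against the base normal bp
  bp <- cross3(N1 - N3, N7 - N3)
  bph <- bp / sqrt(sum(bp^2))
  perp <- cross3(bph, c(1, 0, 0))
  perp <- perp / sqrt(sum(perp^2))
  bbdir <- cos(abs(phi) * pi / 180) * bph + sin(abs(phi) * pi / 180) * perp
  P1 <- c(0.9, -0.6, -0.2)
  add("DG11", "P", P1)
  add("DC11'", "P", P1 + 0.8 * bbdir)

  # pseudo-selections realizing theta (single atoms, vertex at II)
  II <- c(2.0, 0, 0); ex <- c(1, 0, 0); ey <- c(0, 1, 0)
  III <- II + 0.5 * ex
  m <- abs(theta) * pi / 180
  place_I <- function(dsign)
    II + 0.5 * (cos(m) * ex + dsign * sin(m) * ey)
  add("DUMII", "CEN", II)
  add("DUMIII", "CEN", III)
  add("DUMI", "CEN", place_I(1))
  theta_sel <- list(I = list(c("DUMI", "CEN")),
                    II = list(c("DUMII", "CEN")),
                    III = list(c("DUMIII", "CEN")))
  atoms_df <- do.call(rbind, atoms)
  fr <- labeled_frame(atoms_df)
  got <- opening_theta(fr, theta_sel, residue = A)
  if (abs(angdiff(got, theta)) > 1e-8) {
    atoms_df[atoms_df$residue_id == "DUMI", c("x", "y", "z")] <- place_I(-1)
    fr <- labeled_frame(atoms_df)
  }

  # fix the sign of phi: if the core center of mass gives the wrong sign,
  # add a balancing anchor atom that moves the core COM to the mirrored side
  got_phi <- rolling_phi(fr, residue = A)
  if (abs(angdiff(got_phi, phi)) > 1e-8) {
    base_idx <- atoms_df$residue_id == A
    com_of <- function(df) {
      mm <- atom_masses(df$atom_name)
      colSums(as.matrix(df[, c("x", "y", "z")]) * mm) / sum(mm)
    }
    base_com <- com_of(atoms_df[base_idx, ])
    core <- atoms_df[!base_idx, ]
    mcore <- sum(atom_masses(core$atom_name))
    r_old <- base_com - com_of(core)
    # target core COM: reflect r through the plane spanned by bp and bb,
    # implemented as flipping the component of r along (bp x bb)
    n <- cross3(bp, 0.8 * bbdir)
    n <- n / sqrt(sum(n^2))
    r_new <- r_old - 2 * sum(r_old * n) * n
    m_anchor <- atom_masses("CEN")
    target_com <- base_com - r_new
    p_anchor <- ((mcore + m_anchor) * target_com -
                   mcore * com_of(core)) / m_anchor
    atoms_df <- rbind(atoms_df, data.frame(
      residue_id = "DUMA", atom_name = "CEN",
      x = p_anchor[1], y = p_anchor[2], z = p_anchor[3]))
    fr <- labeled_frame(atoms_df)
    got_phi <- rolling_phi(fr, residue = A)
    if (abs(angdiff(got_phi, phi)) > 1e-6)
      stop("build_fixture: could not realize the requested phi sign")
  }

  waters <- place_waters(atom_position(fr, A, "N6"), n_waters,
                         n_waters_outside, cutoff)
  fr <- labeled_frame(atoms_df, water_oxygens = waters)

  structure(list(frame = fr, theta_selections = theta_sel,
                 targets = list(d_BP = d_BP, d_WC = d_WC, d_HG = d_HG,
                                chi = chi, theta = theta, phi = phi,
                                n_waters = n_waters, cutoff = cutoff)),
            class = "pair_fixture")
}

# deterministic Fibonacci-spiral placement of water oxygens around a center
place_waters <- function(center, n_in, n_out, cutoff) {
  n <- n_in + n_out
  if (n == 0L) return(NULL)
  i <- seq_len(n)
  golden <- pi * (3 - sqrt(5))
  zfrac <- 1 - 2 * (i - 0.5) / n
  rad <- sqrt(pmax(0, 1 - zfrac^2))
  dirs <- cbind(rad * cos(golden * i), rad * sin(golden * i), zfrac)
  r <- c(if (n_in) cutoff * 0.9 * (seq_len(n_in) / (n_in + 1))^(1 / 3),
         if (n_out) cutoff * (1.1 + 0.2 * seq_len(n_out)))
  sweep(dirs * r, 2, center, `+`)
}

# rotate vector v about unit axis u by angle (Rodrigues)
rot_axis <- function(v, u, angle) {
  u <- u / sqrt(sum(u^2))
  v * cos(angle) + cross3(u, v) * sin(angle) +
    u * sum(u * v) * (1 - cos(angle))
}

# signed smallest difference between two angles in degrees
angdiff <- function(a, b) {
  d <- (a - b) %% 360
  if (d > 180) d <- d - 360
  d
}

#' Apply a rigid motion to a labeled frame
#'
#' Rotates every atom and water position by `R` and then translates by `t`.
#' Used to verify that all order parameters are invariant under rigid
#' motions of the whole frame.
#'
#' @param frame A [labeled_frame()].
#' @param R 3x3 rotation matrix.
#' @param t Translation 3-vector.
#' @return The transformed `labeled_frame`.
#' @export
transform_frame <- function(frame, R = diag(3), t = c(0, 0, 0)) {
  xyz <- as.matrix(frame$atoms[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% t(R), 2, t, `+`)
  atoms <- frame$atoms
  atoms[, c("x", "y", "z")] <- xyz
  w <- frame$water_oxygens
  if (nrow(w)) w <- sweep(w %*% t(R), 2, t, `+`)
  labeled_frame(atoms, water_oxygens = w, box = frame$box)
}

#' Random rotation matrix
#'
#' Uniform random rotation built from a normalized quaternion; draws from
#' the current RNG state.
#'
#' @return A 3x3 rotation matrix.
#' @export
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
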