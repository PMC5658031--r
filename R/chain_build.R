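# Internal-coordinate (torsion) to Cartesian backbone construction.

#' Standard backbone geometry constants
#'
#' Bond lengths (Angstrom) and bond angles (degrees) used by the chain
#' builder.  These are the standard idealized backbone values; any entry can
#' be overridden, or a full table loaded from a YAML file with
#' [load_geometry_constants()].
#'
#' @param ... Named overrides of individual constants.
#' @return Named list: `b_n_ca`, `b_ca_c`, `b_c_n`, `b_c_o` (bond lengths) and
#'   `ang_n_ca_c`, `ang_ca_c_n`, `ang_c_n_ca`, `ang_ca_c_o` (angles).
#' @export
backbone_geometry <- function(...) {
  g <- list(
    b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
    ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
    ang_ca_c_o = 120.8
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(g))
    if (length(bad)) stop("unknown geometry constants: ", paste(bad, collapse = ", "))
    g[names(over)] <- over
  }
  g
}

#' Load backbone geometry constants from a YAML file
#' @param path YAML file with any subset of the [backbone_geometry()] keys.
#' @return Full constants list with the file's overrides applied.
#' @export
load_geometry_constants <- function(path) {
  do.call(backbone_geometry, yaml::read_yaml(path))
}

# NeRF atom placement: position of d given positions a, b, c, the bond length
# c-d, the bond angle b-c-d (deg) and the dihedral a-b-c-d (deg).
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180; chi <- dihedral * pi / 180
  d_loc <- bond * c(-cos(ang), sin(ang) * cos(chi), sin(ang) * sin(chi))
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  M <- cbind(bc, m, n)
  as.vector(c + M %*% d_loc)
}

#' Build a backbone chain from torsion angles
#'
#' Sequential internal-to-Cartesian construction of an `L`-residue backbone
#' with the requested phi/psi/omega torsions and idealized bond geometry.
#' The defaults (+135, -135, 180 degrees) give the extended conformation the
#' reconstruction pipeline uses as its neutral test-time input; the
#' conventional extended state (phi -135, psi +135) is available by passing
#' those values explicitly.  The carbonyl O is placed in the peptide plane,
#' trans to the next backbone N.
#'
#' @param sequence Target one-letter sequence (`L >= 2`).
#' @param phi,psi,omega Torsions in degrees; scalars or length-`L` vectors
#'   (`phi[1]` and the last `psi`/`omega` entries are undefined by geometry
#'   and ignored where not needed).
#' @param constants Geometry constants from [backbone_geometry()].
#' @param id Label for the structure.
#' @return A [backbone_structure()] whose measured dihedrals equal the
#'   requested torsions.
#' @export
build_extended_chain <- function(sequence, phi = 135, psi = -135, omega = 180,
                                 constants = backbone_geometry(), id = "extended") {
  sequence <- split_sequence(sequence)
  L <- length(sequence)
  if (L < 2) stop("need at least 2 residues")
  phi <- rep_len(phi, L); psi <- rep_len(psi, L); omega <- rep_len(omega, L)
  g <- constants
  N <- CA <- C <- O <- matrix(0, L, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  t1 <- pi - g$ang_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$b_ca_c * c(cos(t1), sin(t1), 0)
  for (i in seq_len(L - 1)) {
    N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ], g$b_c_n, g$ang_ca_c_n, psi[i])
    CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ], g$b_n_ca, g$ang_c_n_ca, omega[i])
    C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], g$b_ca_c, g$ang_n_ca_c, phi[i + 1])
  }
  for (i in seq_len(L)) {
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], g$b_c_o, g$ang_ca_c_o, psi[i] - 180)
  }
  coords <- array(0, c(L, 4, 3))
  coords[, 1, ] <- N; coords[, 2, ] <- CA; coords[, 3, ] <- C; coords[, 4, ] <- O
  backbone_structure(sequence, coords, id = id)
}

#' Measure the backbone torsions of a structure
#'
#' @param structure A [backbone_structure()].
#' @return A tibble with columns `resno`, `phi`, `psi`, `omega` (degrees;
#'   `NA` where undefined at the termini).
#' @export
backbone_torsions <- function(structure) {
  validate_backbone(structure)
  L <- n_residues(structure)
  co <- structure$coords
  phi <- psi <- omg <- rep(NA_real_, L)
  for (i in seq_len(L)) {
    if (i > 1)
      phi[i] <- measure_dihedral(co[i - 1, "C", ], co[i, "N", ], co[i, "CA", ], co[i, "C", ])
    if (i < L) {
      psi[i] <- measure_dihedral(co[i, "N", ], co[i, "CA", ], co[i, "C", ], co[i + 1, "N", ])
      omg[i] <- measure_dihedral(co[i, "CA", ], co[i, "C", ], co[i + 1, "N", ], co[i + 1, "CA", ])
    }
  }
  tibble::tibble(resno = seq_len(L), phi = phi, psi = psi, omega = omg)
}
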