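# Superposition, RMSD, coordinate normalization and dihedral measurement.

#' Min-max normalization scale
#'
#' One isotropic scale maps Angstrom coordinates into the unit box:
#' `x_new = (x - xmin) / (xmax - xmin)`.  The compression ratio
#' `N = xmax - xmin` shrinks every pairwise distance by exactly `1/N`, so the
#' normalized data set preserves relative geometry and a single inverse maps
#' model output back to Angstrom.
#'
#' @param xmin,xmax Global minimum and maximum coordinate component (Angstrom),
#'   `xmax > xmin`.
#' @return An object of class `norm_scale` with fields `xmin`, `xmax`, `N`.
#' @export
norm_scale <- function(xmin, xmax) {
  if (!is.finite(xmin) || !is.finite(xmax) || xmax <= xmin)
    stop("invalid scale: need finite xmax > xmin")
  structure(list(xmin = xmin, xmax = xmax, N = xmax - xmin),
            class = "norm_scale")
}

check_scale <- function(scale) {
  if (!inherits(scale, "norm_scale") || !isTRUE(scale$N > 0))
    stop("scale must be a norm_scale with N > 0")
  invisible(scale)
}

#' @export
print.norm_scale <- function(x, ...) {
  cat(sprintf("<norm_scale> xmin = %.3f, xmax = %.3f, N = %.3f A\n",
              x$xmin, x$xmax, x$N))
  invisible(x)
}

#' Fit a normalization scale over one or more coordinate sets
#'
#' The bounds are the global minimum and maximum over every coordinate
#' component of every supplied set (one isotropic scale for all axes and all
#' structures).  Vacant (zero-filled) positions of backbone structures are
#' excluded: they are placeholders, not atoms.
#'
#' @param ... Backbone structures, numeric matrices or numeric vectors.
#' @return A [norm_scale()].
#' @export
fit_scale <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "backbone_structure")) sets <- sets[[1]]
  if (length(sets) == 0) stop("no coordinate sets supplied")
  vals <- unlist(lapply(sets, function(s) {
    if (inherits(s, "backbone_structure")) {
      as.vector(s$coords[!s$vacant, , , drop = FALSE])
    } else as.vector(s)
  }))
  if (!length(vals) || !all(is.finite(vals))) stop("no finite coordinates supplied")
  if (max(vals) == min(vals))
    stop("degenerate coordinate set: all values equal (N would be 0)")
  norm_scale(min(vals), max(vals))
}

#' Normalize coordinates into the unit box
#' @param x Numeric vector, matrix or array of Angstrom values.
#' @param scale A [norm_scale()].
#' @return `(x - xmin) / N`, same shape as `x`.
#' @export
normalize_coords <- function(x, scale) {
  check_scale(scale)
  (x - scale$xmin) / scale$N
}

#' Map unit-box coordinates back to Angstrom
#' @inheritParams normalize_coords
#' @return `x * N + xmin`, same shape as `x`.
#' @export
denormalize_coords <- function(x, scale) {
  check_scale(scale)
  x * scale$N + scale$xmin
}

as_points <- function(x, atoms = "CA") {
  if (inherits(x, "backbone_structure")) {
    if (identical(atoms, "CA")) ca_xyz(x) else backbone_xyz(x)
  } else {
    m <- as.matrix(x)
    if (ncol(m) != 3) stop("point sets must be n x 3")
    m
  }
}

#' Root-mean-square deviation of two paired point sets
#'
#' `sqrt(mean(squared Euclidean deviation))` over paired atoms, with no
#' superposition applied: the inputs are compared as given.
#'
#' @param a,b `n x 3` matrices (Angstrom) or backbone structures (CA atoms).
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b) {
  a <- as_points(a); b <- as_points(b)
  if (nrow(a) != nrow(b)) stop("point sets differ in size")
  if (nrow(a) == 0) stop("empty point sets")
  sqrt(sum((a - b)^2) / nrow(a))
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Closed-form SVD solution for the proper rotation and translation that
#' minimize the RMSD of `mobile` onto `reference` over the included
#' positions, with reflection correction.
#'
#' @param mobile,reference `n x 3` point matrices or backbone structures
#'   (CA atoms).
#' @param mask Optional logical or integer subset of positions to fit on;
#'   at least 3 non-collinear points must remain.
#' @return An object of class `superposition`: `rotation` (3x3, det +1),
#'   `translation` (length 3) such that `y = x %*% t(rotation) + translation`,
#'   and `rmsd_after`, the RMSD over the included positions after transform.
#' @export
kabsch_superpose <- function(mobile, reference, mask = NULL) {
  m <- as_points(mobile); r <- as_points(reference)
  if (nrow(m) != nrow(r)) stop("point sets differ in size")
  if (!is.null(mask)) { m_f <- m[mask, , drop = FALSE]; r_f <- r[mask, , drop = FALSE] }
  else { m_f <- m; r_f <- r }
  if (nrow(m_f) < 3) stop("fewer than 3 usable points for superposition")
  mu_m <- colMeans(m_f); mu_r <- colMeans(r_f)
  A <- sweep(m_f, 2, mu_m); B <- sweep(r_f, 2, mu_r)
  sv_a <- svd(A)
  if (sv_a$d[2] < 1e-8 * max(sv_a$d[1], 1))
    stop("degenerate (collinear) point configuration")
  H <- crossprod(A, B)                 # 3 x 3
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- as.vector(mu_r - R %*% mu_m)
  fit <- sweep(m_f %*% t(R), 2, tr, `+`)
  structure(list(rotation = R, translation = tr,
                 rmsd_after = rmsd(fit, r_f)),
            class = "superposition")
}

#' Apply a superposition to points or a structure
#' @param sp A `superposition` from [kabsch_superpose()].
#' @param x `n x 3` matrix or [backbone_structure()] (all four atoms moved).
#' @return Transformed object of the same type.
#' @export
apply_superposition <- function(sp, x) {
  stopifnot(inherits(sp, "superposition"))
  if (inherits(x, "backbone_structure")) {
    pts <- sweep(backbone_xyz(x) %*% t(sp$rotation), 2, sp$translation, `+`)
    return(set_backbone_xyz(x, pts))
  }
  sweep(as_points(x) %*% t(sp$rotation), 2, sp$translation, `+`)
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd_after = %.4f A\n", x$rmsd_after))
  invisible(x)
}

#' CA RMSD after optimal superposition
#'
#' Convenience wrapper: Kabsch-fits `mobile` onto `reference` over the CA
#' atoms of mutually non-vacant residues and returns the resulting RMSD.
#'
#' @inheritParams kabsch_superpose
#' @return RMSD in Angstrom.
#' @export
superposed_ca_rmsd <- function(mobile, reference) {
  mask <- NULL
  if (inherits(mobile, "backbone_structure") &&
      inherits(reference, "backbone_structure"))
    mask <- !(mobile$vacant | reference$vacant)
  m <- as_points(mobile); r <- as_points(reference)
  if (!is.null(mask)) { m <- m[mask, , drop = FALSE]; r <- r[mask, , drop = FALSE] }
  kabsch_superpose(m, r)$rmsd_after
}

#' Signed dihedral angle of four points
#'
#' Right-handed (IUPAC) convention; result in degrees in `(-180, 180]`.
#'
#' @param p1,p2,p3,p4 Numeric length-3 points (Angstrom).
#' @return Dihedral angle in degrees.
#' @export
measure_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10)
    stop("degenerate geometry: three consecutive points are collinear")
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  ang <- atan2(-sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
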