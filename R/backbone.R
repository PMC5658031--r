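# Backbone structure container: per-residue N/CA/C/O coordinates plus sequence.

#' Backbone atom names, in the fixed within-residue order
#' @keywords internal
BACKBONE_ATOMS <- c("N", "CA", "C", "O")

# The 20 standard residues in alphabetical one-letter order (A = 1 ... Y = 20).
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct a backbone structure
#'
#' The universal structural currency of the package: a protein backbone as an
#' `L x 4 x 3` coordinate array (residues by atoms N, CA, C, O by x/y/z, in
#' Angstrom) together with the one-letter amino-acid sequence.  Positions that
#' are structurally "vacant" (unaligned template positions whose coordinates
#' are zero-filled) carry a logical flag so that superposition and RMSD
#' routines can exclude them.
#'
#' @param sequence One-letter amino-acid codes: a single string or a character
#'   vector of single letters, length `L >= 2`.
#' @param coords Numeric array of dimension `c(L, 4, 3)`, or an `(4*L) x 3`
#'   matrix in residue-major N, CA, C, O order.  All values must be finite.
#' @param id Free-text label.
#' @param vacant Logical vector of length `L` flagging zero-filled positions;
#'   defaults to all `FALSE`.
#' @return An object of class `backbone_structure`.
#' @examples
#' ch <- build_extended_chain("AG")
#' n_residues(ch)
#' @export
backbone_structure <- function(sequence, coords, id = "", vacant = NULL) {
  sequence <- split_sequence(sequence)
  L <- length(sequence)
  if (L < 2) stop("a backbone structure needs at least 2 residues")
  if (is.matrix(coords)) {
    if (nrow(coords) != 4 * L || ncol(coords) != 3)
      stop("coordinate matrix must be (4*L) x 3")
    coords <- array(aperm(array(t(coords), c(3, 4, L)), c(3, 2, 1)), c(L, 4, 3))
  }
  if (!is.array(coords) || !identical(dim(coords), c(L, 4L, 3L)))
    stop("coords must be an L x 4 x 3 array matching the sequence length")
  if (!all(is.finite(coords))) stop("all coordinates must be finite")
  dimnames(coords) <- list(NULL, BACKBONE_ATOMS, c("x", "y", "z"))
  vacant <- vacant %||% rep(FALSE, L)
  if (length(vacant) != L) stop("vacant flag length must equal L")
  structure(
    list(id = as.character(id), sequence = sequence,
         coords = coords, vacant = as.logical(vacant)),
    class = "backbone_structure"
  )
}

split_sequence <- function(sequence) {
  if (length(sequence) == 1 && nchar(sequence) > 1)
    sequence <- strsplit(sequence, "")[[1]]
  toupper(as.character(sequence))
}

#' Number of residues in a backbone structure
#' @param x A `backbone_structure`.
#' @return Integer residue count `L`.
#' @export
n_residues <- function(x) length(x$sequence)

#' Extract C-alpha coordinates
#' @param x A `backbone_structure`.
#' @return `L x 3` numeric matrix of CA positions (Angstrom).
#' @export
ca_xyz <- function(x) {
  m <- x$coords[, "CA", , drop = FALSE]
  matrix(m, ncol = 3, dimnames = list(NULL, c("x", "y", "z")))
}

#' Extract all backbone coordinates as a point set
#' @param x A `backbone_structure`.
#' @return `(4*L) x 3` matrix, residue-major in N, CA, C, O order.
#' @export
backbone_xyz <- function(x) {
  L <- n_residues(x)
  m <- matrix(aperm(x$coords, c(3, 2, 1)), nrow = 3)
  t(m)[seq_len(4 * L), , drop = FALSE]
}

# Replace the full coordinate set from a (4L) x 3 point matrix.
set_backbone_xyz <- function(x, pts) {
  L <- n_residues(x)
  stopifnot(nrow(pts) == 4 * L, ncol(pts) == 3)
  x$coords <- array(aperm(array(t(pts), c(3, 4, L)), c(3, 2, 1)), c(L, 4, 3))
  dimnames(x$coords) <- list(NULL, BACKBONE_ATOMS, c("x", "y", "z"))
  x
}

#' @export
print.backbone_structure <- function(x, ...) {
  cat(sprintf("<backbone_structure> %s: %d residues (%d vacant)\n",
              if (nzchar(x$id)) x$id else "(unnamed)",
              n_residues(x), sum(x$vacant)))
  cat("  sequence:", paste(x$sequence, collapse = ""), "\n")
  invisible(x)
}

#' Coerce a backbone structure to a tidy per-atom tibble
#' @param x A `backbone_structure`.
#' @param ... Unused.
#' @return A tibble with columns `resno`, `resid`, `atom`, `x`, `y`, `z`,
#'   `vacant`.
#' @export
as_atom_tibble <- function(x, ...) {
  L <- n_residues(x)
  pts <- backbone_xyz(x)
  tibble::tibble(
    resno = rep(seq_len(L), each = 4),
    resid = rep(x$sequence, each = 4),
    atom = rep(BACKBONE_ATOMS, L),
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    vacant = rep(x$vacant, each = 4)
  )
}

validate_backbone <- function(x) {
  stopifnot(inherits(x, "backbone_structure"))
  L <- n_residues(x)
  if (L < 2) stop("invalid backbone structure: L < 2")
  if (!identical(dim(x$coords), c(L, 4L, 3L)))
    stop("invalid backbone structure: coordinate block count != L")
  if (!all(is.finite(x$coords))) stop("invalid backbone structure: non-finite coordinates")
  invisible(x)
}
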