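# Flat feature representation: L*(12+1) values per conformation --
# 12 normalized backbone coordinates plus one residue-type channel per
# residue, residue-major.

#' Encode residue types as numeric values in [0, 1]
#'
#' Each of the 20 standard residues maps to `index / 20`, where `index` is its
#' 1-based position in alphabetical one-letter order (A = 1, ..., Y = 20).
#' Nonstandard or unknown codes map to 0.
#'
#' @param sequence One-letter codes (string or character vector).
#' @return Numeric vector of length `L`, values in `[0, 1]`.
#' @examples
#' encode_residue_types("AXY")  # 0.05, 0, 1
#' @export
encode_residue_types <- function(sequence) {
  sequence <- split_sequence(sequence)
  if (length(sequence) == 0) stop("sequence must be non-empty")
  idx <- match(sequence, AA_ALPHABET)
  ifelse(is.na(idx), 0, idx / 20)
}

# Positions of the residue-type channel within a length-13L feature vector.
residue_channel_idx <- function(L) seq(13, 13 * L, by = 13)

# Positions of the 12 coordinate channels of given residues.
coord_channel_idx <- function(residues, L = NULL) {
  as.vector(outer(1:12, (residues - 1) * 13, `+`))
}

#' Convert a backbone structure to a flat feature vector
#'
#' Coordinates are min-max normalized into the unit box under `scale` and laid
#' out residue-major: for each residue
#' `N.x, N.y, N.z, CA.x, ..., O.z, aa_code` (13 values).  The 12 coordinate
#' channels of vacant (zero-filled) residues are set to 0, preserving the
#' zero-fill convention in feature space.
#'
#' @param structure A [backbone_structure()].
#' @param scale A [norm_scale()].
#' @return Numeric vector of length `13 * L`.
#' @export
structure_to_features <- function(structure, scale) {
  validate_backbone(structure)
  check_scale(scale)
  L <- n_residues(structure)
  coords <- normalize_coords(backbone_xyz(structure), scale)  # (4L) x 3
  block <- matrix(t(coords), nrow = 12)                       # 12 x L
  if (any(structure$vacant)) block[, structure$vacant] <- 0
  as.vector(rbind(block, encode_residue_types(structure$sequence)))
}

#' Convert a flat feature vector back to a backbone structure
#'
#' Inverse of [structure_to_features()]: coordinate channels are denormalized
#' from the unit box to Angstrom; the residue-type channel is discarded in
#' favour of the supplied sequence.
#'
#' @param features Numeric vector of length `13 * length(sequence)`.
#' @param scale The [norm_scale()] the features were encoded under.
#' @param sequence Target one-letter sequence.
#' @param vacant Optional logical flags; flagged residues are restored to
#'   all-zero Angstrom coordinates (the zero-fill convention).
#' @param id Label for the resulting structure.
#' @return A [backbone_structure()].
#' @export
features_to_structure <- function(features, scale, sequence, vacant = NULL,
                                  id = "") {
  sequence <- split_sequence(sequence)
  L <- length(sequence)
  if (length(features) != 13 * L)
    stop("feature length ", length(features), " does not match 13 * L = ", 13 * L)
  check_scale(scale)
  block <- matrix(features, nrow = 13)[1:12, , drop = FALSE]  # 12 x L
  pts <- denormalize_coords(matrix(as.vector(block), ncol = 3, byrow = TRUE), scale)
  s <- backbone_structure(sequence, pts, id = id, vacant = vacant)
  if (any(s$vacant)) s$coords[s$vacant, , ] <- 0
  s
}

#' Map a template onto the target through an alignment
#'
#' Produces a structure of exactly the target length: aligned positions copy
#' the template's backbone coordinates, unaligned ("vacant") positions are
#' zero-filled and flagged, and template residues outside the alignment are
#' discarded.
#'
#' @param template A [backbone_structure()].
#' @param alignment Integer vector of length `L_target`; entry `i` is the
#'   1-based template residue aligned to target position `i`, or `NA` for a
#'   vacant position.
#' @param target_sequence Optional target sequence (defaults to the template
#'   residue at aligned positions and `"X"` at vacant ones).
#' @return A [backbone_structure()] of target length with `vacant` flags set.
#' @export
pad_or_trim_template <- function(template, alignment, target_sequence = NULL) {
  validate_backbone(template)
  Lt <- length(alignment)
  if (Lt < 2) stop("alignment must cover a target of length >= 2")
  mapped <- alignment[!is.na(alignment)]
  if (length(mapped) && (min(mapped) < 1 || max(mapped) > n_residues(template)))
    stop("alignment index out of template range")
  coords <- array(0, c(Lt, 4, 3))
  vac <- is.na(alignment)
  coords[!vac, , ] <- template$coords[alignment[!vac], , ]
  seqs <- if (!is.null(target_sequence)) split_sequence(target_sequence) else {
    s <- rep("X", Lt); s[!vac] <- template$sequence[alignment[!vac]]; s
  }
  if (length(seqs) != Lt) stop("target sequence length does not match alignment")
  backbone_structure(seqs, coords, id = template$id, vacant = vac)
}
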