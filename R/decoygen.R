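# Decoy ensemble generation: synthetic natives, torsion-space perturbation
# with RMSD banding, feature corruption for denoising training, and import of
# externally generated decoys.

#' Generate a synthetic native backbone
#'
#' Builds a native-like backbone from idealized secondary-structure torsions
#' (helix -57/-47, strand -135/+135) with small Gaussian torsion jitter, for
#' fully self-contained experiments and tests.  The `mixed` motif alternates
#' helix and strand segments joined by short loops.  The result is
#' deterministic for a given seed and clash-checked at the CA level (no
#' non-neighbour CA pair closer than 3 Angstrom).
#'
#' @param length Number of residues (`>= 8`).
#' @param motif One of `"mixed"`, `"helix"`, `"strand"`.
#' @param seed Integer RNG seed.
#' @param jitter_sd Torsion jitter, degrees (default 3).
#' @return A [backbone_structure()] with a deterministic pseudo-random
#'   sequence over the 20 standard residues.
#' @export
generate_synthetic_native <- function(length, motif = c("mixed", "helix", "strand"),
                                      seed = 1, jitter_sd = 3) {
  motif <- match.arg(motif)
  if (length < 8) stop("synthetic natives need length >= 8")
  with_seed(seed, {
    seqs <- sample(AA_ALPHABET, length, replace = TRUE)
    base <- switch(motif,
      helix = matrix(c(-57, -47), length, 2, byrow = TRUE),
      strand = matrix(c(-135, 135), length, 2, byrow = TRUE),
      mixed = mixed_motif_torsions(length))
    for (attempt in 1:50) {
      phi <- base[, 1] + rnorm(length, 0, jitter_sd)
      psi <- base[, 2] + rnorm(length, 0, jitter_sd)
      omg <- rep(180, length) + rnorm(length, 0, jitter_sd / 3)
      s <- build_extended_chain(seqs, phi = phi, psi = psi, omega = omg,
                                id = sprintf("synthetic_%s_L%d_seed%d", motif, length, seed))
      if (!has_ca_clash(s)) return(s)
    }
    stop("could not build a clash-free synthetic native in 50 attempts")
  })
}

# Alternating helix/strand blocks with 2-residue loop joints.
mixed_motif_torsions <- function(L) {
  tor <- matrix(NA_real_, L, 2)
  i <- 1; helix <- TRUE
  while (i <= L) {
    block <- min(if (helix) 12L else 8L, L - i + 1L)
    tor[i:(i + block - 1L), ] <- matrix(
      if (helix) c(-57, -47) else c(-135, 135), block, 2, byrow = TRUE)
    i <- i + block
    if (i <= L) {                          # loop joint
      joint <- min(2L, L - i + 1L)
      tor[i:(i + joint - 1L), ] <- matrix(c(-75, 145), joint, 2, byrow = TRUE)
      i <- i + joint
    }
    helix <- !helix
  }
  tor
}

has_ca_clash <- function(s, min_dist = 3.0) {
  ca <- ca_xyz(s)
  d <- as.matrix(stats::dist(ca))
  d[abs(row(d) - col(d)) <= 1] <- Inf
  any(d < min_dist)
}

# Rotate the downstream part of the chain about a phi or psi bond axis at a
# pivot residue (a "pivot move" in torsion space, applied in Cartesian form).
# `pts` is the residue-major (4L) x 3 point matrix from backbone_xyz().
pivot_rotate <- function(pts, pivot, bond = c("phi", "psi"), angle_deg,
                         movable = NULL) {
  bond <- match.arg(bond)
  L <- nrow(pts) %/% 4
  base <- (pivot - 1L) * 4L
  if (bond == "phi") {
    p0 <- pts[base + 1L, ]; p1 <- pts[base + 2L, ]          # N -> CA axis
    rows <- c(base + 3L, base + 4L)                         # C, O of pivot
  } else {
    p0 <- pts[base + 2L, ]; p1 <- pts[base + 3L, ]          # CA -> C axis
    rows <- base + 4L                                       # O of pivot
  }
  if (pivot < L) rows <- c(rows, (base + 5L):(4L * L))
  if (!is.null(movable)) rows <- intersect(rows, movable)
  axis <- p1 - p0; axis <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1], -axis[2], axis[1], 0),
              3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)    # Rodrigues
  moved <- sweep(pts[rows, , drop = FALSE], 2, p1)
  pts[rows, ] <- sweep(moved %*% t(R), 2, p1, `+`)
  pts
}

#' Generate an RMSD-banded decoy ensemble
#'
#' Emulates the role of an external decoy generator: produces `n` perturbed
#' conformations of the native whose superposed CA RMSD to the native lies in
#' `rmsd_band`, spread approximately uniformly across the band.  Each decoy is
#' grown by random phi/psi pivot rotations at random residues until its RMSD
#' reaches a per-decoy target drawn uniformly from the band; the kick size
#' shrinks near the target to limit overshoot.  An optional Gaussian
#' Cartesian jitter can be added on top.
#'
#' @param native A [backbone_structure()].
#' @param n Number of decoys (`>= 1`).
#' @param rmsd_band Numeric `c(low, high)` in Angstrom, `0 < low < high`.
#' @param seed Integer RNG seed; the same seed reproduces the set exactly.
#' @param cart_jitter_sd Per-coordinate Gaussian jitter in Angstrom
#'   (default 0 = off; applied before the final RMSD check).
#' @param max_tries Retry budget across the whole set (default `50 * n`).
#' @return A `decoy_set`: list with `template_id`, `decoys` (list of
#'   structures), `rmsd_to_native` (superposed CA RMSD, Angstrom), `seed`,
#'   `rmsd_band`.
#' @export
generate_decoys <- function(native, n, rmsd_band = c(3, 13), seed = 1,
                            cart_jitter_sd = 0, max_tries = 50 * n) {
  validate_backbone(native)
  if (n < 1) stop("n must be >= 1")
  low <- rmsd_band[1]; high <- rmsd_band[2]
  if (!(low > 0 && high > low)) stop("rmsd_band must satisfy 0 < low < high")
  L <- n_residues(native)
  pts_native <- backbone_xyz(native)
  nonvac <- which(!native$vacant)
  if (length(nonvac) < 4) stop("too few non-vacant residues to perturb")
  ca_rows <- (nonvac - 1L) * 4L + 2L
  ca_ref <- ca_xyz(native)[nonvac, , drop = FALSE]
  # vacant (zero-filled) positions stay put: they are placeholders, not atoms
  movable <- as.vector(outer(1:4, (nonvac - 1L) * 4L, `+`))
  pivot_pool <- nonvac[-c(1L, length(nonvac))]
  with_seed(seed, {
    decoys <- vector("list", n)
    rmsds <- numeric(n)
    tries <- 0L
    i <- 1L
    while (i <= n) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("RMSD band (", low, ", ", high, ") unreachable within the retry budget")
      target <- runif(1, low, high)
      ceiling_rmsd <- min(high, target + 0.5)
      pts <- pts_native
      cur <- 0; ok <- FALSE
      for (kick in 1:2000) {
        sd_deg <- 12 * max(0.03, min(1, (target - cur) / 2))
        pts_try <- pivot_rotate(pts, pivot_pool[sample.int(length(pivot_pool), 1)],
                                if (runif(1) < 0.5) "phi" else "psi",
                                rnorm(1, 0, sd_deg), movable = movable)
        cur_try <- kabsch_superpose(pts_try[ca_rows, , drop = FALSE],
                                    ca_ref)$rmsd_after
        if (cur_try > ceiling_rmsd) next   # reject overshooting kick
        pts <- pts_try; cur <- cur_try
        if (cur >= target) { ok <- TRUE; break }
      }
      if (!ok || cur < low) next
      if (cart_jitter_sd > 0) {
        pts[movable, ] <- pts[movable, ] +
          matrix(rnorm(3 * length(movable), 0, cart_jitter_sd), length(movable))
        cur <- kabsch_superpose(pts[ca_rows, , drop = FALSE], ca_ref)$rmsd_after
        if (cur < low || cur > high) next
      }
      d <- set_backbone_xyz(native, pts)
      d$id <- sprintf("%s_decoy%04d", native$id, i)
      decoys[[i]] <- d
      rmsds[i] <- cur
      i <- i + 1L
    }
    structure(list(template_id = native$id, decoys = decoys,
                   rmsd_to_native = rmsds, seed = seed, rmsd_band = rmsd_band),
              class = "decoy_set")
  })
}

#' @export
print.decoy_set <- function(x, ...) {
  cat(sprintf("<decoy_set> %s: %d decoys, CA RMSD %.2f-%.2f A (seed %d)\n",
              x$template_id, length(x$decoys),
              min(x$rmsd_to_native), max(x$rmsd_to_native), x$seed))
  invisible(x)
}

#' Mask feature coordinates to zero (denoising corruption)
#'
#' Each coordinate entry is independently set to 0 with probability `p`;
#' residue-type channels are never corrupted.  Masking to zero mirrors the
#' zero-fill convention used for vacant template positions.
#'
#' @param features Numeric feature vector of length `13 * L`, or a matrix
#'   with such rows.
#' @param p Masking probability in `[0, 1]`.
#' @param seed Integer RNG seed.
#' @return Corrupted copy of `features`.
#' @export
corrupt_input <- function(features, p, seed = 1) {
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  if (p == 0) return(features)
  mat <- is.matrix(features)
  X <- if (mat) features else matrix(features, nrow = 1)
  if (ncol(X) %% 13 != 0) stop("feature length must be a multiple of 13")
  L <- ncol(X) %/% 13
  coord_cols <- setdiff(seq_len(ncol(X)), residue_channel_idx(L))
  with_seed(seed, {
    mask <- matrix(runif(nrow(X) * length(coord_cols)) < p,
                   nrow(X), length(coord_cols))
    X[, coord_cols][mask] <- 0
  })
  if (mat) X else as.vector(X)
}

#' Import externally generated decoys from a directory of PDB files
#'
#' A hook for ensembles produced by an external decoy generator.  Files are
#' read in sorted order; the CA RMSD of each decoy to `native` is recomputed
#' after superposition.
#'
#' @param dir Directory containing `.pdb` files.
#' @param native The native [backbone_structure()] the decoys belong to.
#' @param strict If `TRUE` (default) a length-mismatched file is an error;
#'   otherwise it is skipped with a message.
#' @return A `decoy_set`.
#' @export
import_external_decoys <- function(dir, native, strict = TRUE) {
  validate_backbone(native)
  files <- sort(list.files(dir, pattern = "\\.pdb$", full.names = TRUE))
  if (!length(files)) stop("no PDB files found in '", dir, "'")
  decoys <- list(); rmsds <- numeric(0)
  for (f in files) {
    d <- read_pdb(f, strict = strict)
    if (n_residues(d) != n_residues(native)) {
      if (strict) stop("decoy '", f, "' length ", n_residues(d),
                       " does not match native length ", n_residues(native))
      message("import_external_decoys: skipping length-mismatched '", f, "'")
      next
    }
    decoys[[length(decoys) + 1L]] <- d
    rmsds <- c(rmsds, superposed_ca_rmsd(d, native))
  }
  if (!length(decoys)) stop("no usable decoys in '", dir, "'")
  structure(list(template_id = native$id, decoys = decoys,
                 rmsd_to_native = rmsds, seed = NA_integer_,
                 rmsd_band = range(rmsds)),
            class = "decoy_set")
}

#' Write a decoy set as numbered PDB files plus a manifest
#'
#' @param decoy_set A `decoy_set`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path (`manifest.tsv`: decoy id, file,
#'   CA RMSD to native, seed).
#' @export
write_decoy_set <- function(decoy_set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(decoy_set$decoys)
  files <- sprintf("decoy_%04d.pdb", seq_len(n))
  for (i in seq_len(n))
    write_pdb(decoy_set$decoys[[i]], file.path(dir, files[i]))
  manifest <- data.frame(
    decoy_id = vapply(decoy_set$decoys, function(d) d$id, character(1)),
    file = files,
    rmsd_to_native = sprintf("%.6f", decoy_set$rmsd_to_native),
    seed = decoy_set$seed
  )
  path <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
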