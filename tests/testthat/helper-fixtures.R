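# Shared fixtures and independent oracles, all built in code.

# Hand-written two-residue PDB (ALA, GLY): 8 backbone ATOM records.
two_residue_pdb_text <- function() {
  c("ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       2.458   2.000   3.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       3.009   3.421   3.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       2.400   4.400   3.350  1.00  0.00           O",
    "ATOM      5  N   GLY A   2       4.300   3.600   2.650  1.00  0.00           N",
    "ATOM      6  CA  GLY A   2       4.950   4.900   2.550  1.00  0.00           C",
    "ATOM      7  C   GLY A   2       6.400   4.800   2.100  1.00  0.00           C",
    "ATOM      8  O   GLY A   2       7.000   3.750   1.900  1.00  0.00           O",
    "TER       9      GLY A   2",
    "END")
}

two_residue_coords <- function() {
  matrix(c(1.000, 2.000, 3.000,
           2.458, 2.000, 3.000,
           3.009, 3.421, 3.000,
           2.400, 4.400, 3.350,
           4.300, 3.600, 2.650,
           4.950, 4.900, 2.550,
           6.400, 4.800, 2.100,
           7.000, 3.750, 1.900), ncol = 3, byrow = TRUE)
}

write_fixture_pdb <- function(lines = two_residue_pdb_text()) {
  path <- withr::local_tempfile(fileext = ".pdb",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Brute-force rigid-fit oracle: minimize RMSD over Euler-angle rotations with
# multi-start numerical optimization (independent of the SVD solution).
brute_force_min_rmsd <- function(mobile, reference, n_starts = 24) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  euler_rot <- function(v) {
    ca <- cos(v[1]); sa <- sin(v[1]); cb <- cos(v[2]); sb <- sin(v[2])
    cg <- cos(v[3]); sg <- sin(v[3])
    Rz1 <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, byrow = TRUE)
    Rz2 <- matrix(c(cg, -sg, 0, sg, cg, 0, 0, 0, 1), 3, byrow = TRUE)
    Rz1 %*% Ry %*% Rz2
  }
  obj <- function(v) sqrt(mean(rowSums((A %*% t(euler_rot(v)) - B)^2)))
  best <- Inf
  set.seed(1234)
  starts <- rbind(c(0, 0, 0), matrix(runif(3 * (n_starts - 1), -pi, pi),
                                     ncol = 3))
  for (i in seq_len(nrow(starts))) {
    o <- stats::optim(starts[i, ], obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}

# Exhaustive GDT oracle for small point sets (n <= 12): max fraction over all
# residue subsets whose least-squares fit brings every subset atom within the
# cutoff.
exhaustive_gdt <- function(model_ca, native_ca, cutoff) {
  n <- nrow(model_ca)
  stopifnot(n <= 12)
  best <- 0L
  for (k in n:3) {
    if (k <= best) break
    for (sel in utils::combn(n, k, simplify = FALSE)) {
      sp <- tryCatch(kabsch_superpose(model_ca[sel, , drop = FALSE],
                                      native_ca[sel, , drop = FALSE]),
                     error = function(e) NULL)
      if (is.null(sp)) next
      fit <- sweep(model_ca[sel, , drop = FALSE] %*% t(sp$rotation), 2,
                   sp$translation, `+`)
      if (all(sqrt(rowSums((fit - native_ca[sel, , drop = FALSE])^2)) <= cutoff)) {
        best <- k
        break
      }
    }
  }
  best / n
}

# Fixture with an exactly superimposable half and a hopelessly displaced half.
half_good_fixture <- function(cutoff = 2) {
  native <- generate_synthetic_native(10, "helix", seed = 11)
  model <- native
  set.seed(7)
  for (i in 6:10) {
    shift <- stats::rnorm(3)
    shift <- shift / sqrt(sum(shift^2)) * (40 * cutoff + i * 15)
    model$coords[i, , ] <- sweep(model$coords[i, , ], 2, shift, `+`)
  }
  list(model = model, native = native)
}

# Small random rigid transform.
random_rigid <- function(seed) {
  set.seed(seed)
  v <- runif(3, -pi, pi)
  ca <- cos(v[1]); sa <- sin(v[1]); cb <- cos(v[2]); sb <- sin(v[2])
  cg <- cos(v[3]); sg <- sin(v[3])
  R <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, byrow = TRUE) %*%
    matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, byrow = TRUE) %*%
    matrix(c(cg, -sg, 0, sg, cg, 0, 0, 0, 1), 3, byrow = TRUE)
  list(R = R, t = runif(3, -20, 20))
}

# A tiny trained-enough model fixture for reconstruction plumbing tests.
tiny_trained_model <- function() {
  nat <- generate_synthetic_native(16, "helix", seed = 21)
  ds <- generate_decoys(nat, 12, c(1, 4), seed = 22)
  decoys <- lapply(ds$decoys, function(d)
    apply_superposition(kabsch_superpose(ca_xyz(d), ca_xyz(nat)), d))
  scale <- fit_scale(c(list(nat), decoys))
  inputs <- do.call(rbind, lapply(decoys, structure_to_features, scale = scale))
  labels <- matrix(structure_to_features(nat, scale), nrow = nrow(inputs),
                   ncol = ncol(inputs), byrow = TRUE)
  training <- list(inputs = inputs, labels = labels, scale = scale,
                   include = prsda:::coord_channel_idx(seq_len(16)),
                   mask_residues = rep(TRUE, 16), reference = nat,
                   centroid = colMeans(backbone_xyz(nat)),
                   decoy_sets = list(ds))
  cfg <- pipeline_config(pretrain_epochs = 3, finetune_epochs = 15, seed = 23)
  suppressMessages(list(model = train_model(training, cfg), native = nat,
                        config = cfg))
}
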