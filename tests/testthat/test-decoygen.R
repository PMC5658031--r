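test_that("synthetic natives are deterministic, native-like and clash-free", {
  a <- generate_synthetic_native(30, "helix", seed = 1)
  b <- generate_synthetic_native(30, "helix", seed = 1)
  expect_identical(a$coords, b$coords)
  expect_identical(a$sequence, b$sequence)
  ca <- ca_xyz(a)
  expect_equal(sqrt(rowSums(diff(ca)^2)), rep(3.8, 29), tolerance = 0.05)
  m <- generate_synthetic_native(60, "mixed", seed = 2)
  expect_s3_class(m, "backbone_structure")
  expect_true(all(is.finite(m$coords)))
  dmat <- as.matrix(dist(ca_xyz(m)))
  dmat[abs(row(dmat) - col(dmat)) <= 1] <- Inf
  expect_true(all(dmat >= 3.0))
  expect_error(generate_synthetic_native(5), "length >= 8")
})

test_that("decoy ensembles respect the RMSD band and are reproducible", {
  nat <- generate_synthetic_native(40, "mixed", seed = 3)
  ds <- generate_decoys(nat, 25, c(2, 8), seed = 7)
  expect_length(ds$decoys, 25)
  expect_true(all(ds$rmsd_to_native >= 2 & ds$rmsd_to_native <= 8))
  # recorded RMSDs match independent recomputation
  recomputed <- vapply(ds$decoys, superposed_ca_rmsd, numeric(1),
                       reference = nat)
  expect_equal(ds$rmsd_to_native, recomputed, tolerance = 1e-6)
  # every decoy keeps the template's length and sequence
  for (d in ds$decoys) {
    expect_equal(n_residues(d), 40)
    expect_identical(d$sequence, nat$sequence)
  }
  ds2 <- generate_decoys(nat, 25, c(2, 8), seed = 7)
  expect_identical(lapply(ds$decoys, `[[`, "coords"),
                   lapply(ds2$decoys, `[[`, "coords"))
  expect_error(generate_decoys(nat, 0, c(2, 8)), ">= 1")
  expect_error(generate_decoys(nat, 1, c(5, 2)), "0 < low < high")
})

test_that("decoy RMSDs cover the band approximately uniformly", {
  nat <- generate_synthetic_native(40, "mixed", seed = 3)
  ds <- generate_decoys(nat, 120, c(2, 8), seed = 11)
  thirds <- table(cut(ds$rmsd_to_native, breaks = seq(2, 8, length.out = 4),
                      include.lowest = TRUE))
  expect_true(all(thirds / 120 >= 0.20))
})

test_that("an unreachable RMSD band errors out within the retry budget", {
  nat <- generate_synthetic_native(10, "helix", seed = 4)
  # a 10-residue helix cannot reach a 30-40 A superposed CA RMSD
  expect_error(generate_decoys(nat, 2, c(30, 40), seed = 1, max_tries = 4),
               "unreachable")
})

test_that("input corruption masks coordinates only, at the requested rate", {
  nat <- generate_synthetic_native(10, "mixed", seed = 5)
  sc <- fit_scale(nat)
  f <- structure_to_features(nat, sc)
  expect_identical(corrupt_input(f, 0, seed = 1), f)
  aa_idx <- prsda:::residue_channel_idx(10)
  all_zero <- corrupt_input(f, 1, seed = 1)
  expect_equal(unname(all_zero[-aa_idx]), rep(0, 120))
  expect_identical(all_zero[aa_idx], f[aa_idx])
  expect_error(corrupt_input(f, 1.5), "\\[0, 1\\]")
  # masked fraction over many seeds stays within 3 binomial SDs of p
  L <- 1200 %/% 13 + 1                      # 93 residues -> 1209 features
  big <- structure_to_features(generate_synthetic_native(L, "mixed", seed = 6),
                               fit_scale(generate_synthetic_native(L, "mixed", seed = 6)))
  big[big == 0] <- 1e-6                     # make zeros attributable to masking
  n_coord <- 12 * L
  fracs <- vapply(1:100, function(s) {
    cm <- corrupt_input(big, 0.3, seed = s)
    sum(cm[-prsda:::residue_channel_idx(L)] == 0) / n_coord
  }, numeric(1))
  p <- 0.3
  tol <- 3 * sqrt(p * (1 - p) / (100 * n_coord))
  expect_lt(abs(mean(fracs) - p), tol)
})

test_that("external decoy import recomputes RMSDs and validates lengths", {
  nat <- generate_synthetic_native(12, "helix", seed = 8)
  ds <- generate_decoys(nat, 3, c(1, 3), seed = 9)
  dir <- withr::local_tempdir()
  write_decoy_set(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  imp <- import_external_decoys(dir, nat)
  expect_length(imp$decoys, 3)
  expect_equal(sort(imp$rmsd_to_native), sort(ds$rmsd_to_native),
               tolerance = 1e-3)   # PDB round trip is 1e-3 A precision
  # a decoy identical to the native has zero RMSD
  dir2 <- withr::local_tempdir()
  write_pdb(nat, file.path(dir2, "native_copy.pdb"))
  imp2 <- import_external_decoys(dir2, nat)
  expect_equal(imp2$rmsd_to_native, 0, tolerance = 1e-3)
  expect_error(import_external_decoys(withr::local_tempdir(), nat),
               "no PDB files")
  # length mismatch: error in strict mode, skipped in lenient mode
  short <- generate_synthetic_native(8, "helix", seed = 10)
  write_pdb(short, file.path(dir2, "short.pdb"))
  expect_error(import_external_decoys(dir2, nat), "does not match")
  lenient <- suppressMessages(import_external_decoys(dir2, nat, strict = FALSE))
  expect_length(lenient$decoys, 1)
})
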