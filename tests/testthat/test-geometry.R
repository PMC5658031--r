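test_that("rmsd matches closed-form values and behaves like a metric", {
  a <- matrix(c(0, 0, 0), 1)
  expect_equal(rmsd(a, a), 0)
  expect_equal(rmsd(a, matrix(c(3, 4, 0), 1)), 5)
  two <- matrix(c(0, 0, 0, 1, 0, 0), 2, byrow = TRUE)
  two_off <- matrix(c(0, 0, 0, 1, 2, 0), 2, byrow = TRUE)
  expect_equal(rmsd(two, two_off), sqrt(2))
  expect_error(rmsd(two, a), "differ in size")
  set.seed(10)
  for (i in 1:20) {
    x <- matrix(rnorm(15), 5); y <- matrix(rnorm(15), 5); z <- matrix(rnorm(15), 5)
    expect_equal(rmsd(x, y), rmsd(y, x))
    expect_gte(rmsd(x, z) + 1e-12, abs(rmsd(x, y) - rmsd(y, z)))
    expect_lte(rmsd(x, z), rmsd(x, y) + rmsd(y, z) + 1e-12)
  }
})

test_that("Kabsch superposition recovers rigid motions exactly", {
  set.seed(2)
  pts <- matrix(rnorm(18, sd = 4), 6)
  same <- kabsch_superpose(pts, pts)
  expect_equal(same$rotation, diag(3), tolerance = 1e-9)
  expect_equal(same$translation, rep(0, 3), tolerance = 1e-9)
  expect_equal(same$rmsd_after, 0, tolerance = 1e-9)
  shifted <- kabsch_superpose(sweep(pts, 2, c(1, 1, 1), `+`), pts)
  expect_equal(shifted$rmsd_after, 0, tolerance = 1e-9)
  # rotation is always proper orthogonal
  rr <- random_rigid(3)
  sp <- kabsch_superpose(sweep(pts %*% t(rr$R), 2, rr$t, `+`), pts)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  expect_equal(crossprod(sp$rotation), diag(3), tolerance = 1e-9)
  expect_equal(sp$rmsd_after, 0, tolerance = 1e-9)
})

test_that("Kabsch rmsd_after matches a brute-force rotational search", {
  set.seed(8)
  for (i in 1:5) {
    ref <- matrix(rnorm(15, sd = 3), 5)
    mob <- ref + matrix(rnorm(15, sd = 0.7), 5)
    rr <- random_rigid(i)
    mob <- sweep(mob %*% t(rr$R), 2, rr$t, `+`)
    expect_equal(kabsch_superpose(mob, ref)$rmsd_after,
                 brute_force_min_rmsd(mob, ref), tolerance = 1e-4)
  }
})

test_that("superposition is invariant to rigid pre-transforms of the mobile set", {
  set.seed(4)
  ref <- matrix(rnorm(24, sd = 5), 8)
  mob <- ref + matrix(rnorm(24, sd = 1), 8)
  base <- kabsch_superpose(mob, ref)$rmsd_after
  for (i in 1:5) {
    rr <- random_rigid(100 + i)
    moved <- sweep(mob %*% t(rr$R), 2, rr$t, `+`)
    expect_equal(kabsch_superpose(moved, ref)$rmsd_after, base,
                 tolerance = 1e-9)
  }
})

test_that("degenerate superposition inputs are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
  expect_error(kabsch_superpose(matrix(rnorm(6), 2), matrix(rnorm(6), 2)),
               "fewer than 3")
})

test_that("the normalization scale reproduces the distance-shrinkage law", {
  sc <- fit_scale(c(2, 4, 10))
  expect_equal(sc$xmin, 2); expect_equal(sc$xmax, 10); expect_equal(sc$N, 8)
  sc10 <- norm_scale(-5, 5)
  expect_equal(sc10$N, 10)
  expect_equal(normalize_coords(-5, sc10), 0)
  expect_equal(normalize_coords(5, sc10), 1)
  p1 <- c(0, 0, 0); p2 <- c(3, 4, 0)
  d_norm <- sqrt(sum((normalize_coords(p1, sc10) - normalize_coords(p2, sc10))^2))
  expect_equal(d_norm, 0.5)
  expect_error(fit_scale(rep(0, 10)), "degenerate")
  # property: normalized distance * N equals the original distance (1e-12 rel)
  set.seed(6)
  for (i in 1:50) {
    sc <- norm_scale(runif(1, -50, 0), runif(1, 1, 80))
    a <- rnorm(3, sd = 20); b <- rnorm(3, sd = 20)
    d0 <- sqrt(sum((a - b)^2))
    dn <- sqrt(sum((normalize_coords(a, sc) - normalize_coords(b, sc))^2))
    expect_equal(dn * sc$N, d0, tolerance = 1e-12)
    expect_equal(denormalize_coords(normalize_coords(a, sc), sc), a,
                 tolerance = 1e-12)
  }
})

test_that("dihedral measurement follows the right-handed convention", {
  # planar cis arrangement -> 0, trans -> 180
  expect_equal(measure_dihedral(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)), 0)
  expect_equal(measure_dihedral(c(-1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)), 180)
  expect_error(measure_dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
  # dual-formula oracle: arccos magnitude + triple-product sign
  set.seed(12)
  for (i in 1:25) {
    p <- matrix(rnorm(12, sd = 2), 4)
    b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
    n1 <- prsda:::cross3(b1, b2); n2 <- prsda:::cross3(b2, b3)
    cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
    mag <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    sgn <- sign(sum(prsda:::cross3(n1, n2) * b2))
    expected <- if (sgn == 0) mag else sgn * mag
    got <- measure_dihedral(p[1, ], p[2, ], p[3, ], p[4, ])
    expect_equal(got, expected, tolerance = 1e-9)
  }
})

test_that("GDT scores constructed fixtures exactly and is monotone in cutoff", {
  nat <- generate_synthetic_native(12, "mixed", seed = 9)
  expect_equal(gdt(nat, nat, 2), 1.0)
  expect_equal(gdt_ts(nat, nat), 1.0)
  moved <- nat
  moved$coords <- moved$coords + 100
  expect_equal(gdt(moved, nat, 2), 1.0)

  hg <- half_good_fixture(cutoff = 2)
  expect_equal(gdt(hg$model, hg$native, 2), 0.5)
  expect_equal(gdt_ts(hg$model, hg$native), 0.5)
  expect_equal(exhaustive_gdt(ca_xyz(hg$model), ca_xyz(hg$native), 2), 0.5)

  # monotone non-decreasing in cutoff; gdt_ts bounded below by gdt at 1 A
  d <- generate_decoys(nat, 1, c(1.5, 4), seed = 10)$decoys[[1]]
  cuts <- c(0.5, 1, 2, 4, 8, 16)
  vals <- vapply(cuts, function(ct) gdt(d, nat, ct), numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_gte(gdt_ts(d, nat), gdt(d, nat, 1))
})

test_that("the GDT heuristic agrees with exhaustive enumeration on small decoys", {
  nat <- generate_synthetic_native(10, "mixed", seed = 13)
  for (s in 1:3) {
    d <- generate_decoys(nat, 1, c(1, 3), seed = 30 + s)$decoys[[1]]
    for (ct in c(1, 2, 4)) {
      expect_equal(gdt(d, nat, ct),
                   exhaustive_gdt(ca_xyz(d), ca_xyz(nat), ct))
    }
  }
})
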