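rot_z <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0),
                           c(0, 0, 1))

test_that("Kabsch superposition recovers exact rigid motions", {
  set.seed(1)
  ref <- matrix(rnorm(30), ncol = 3)
  same <- kabsch_superpose(ref, ref)
  expect_equal(same$rotation, diag(3), tolerance = 1e-9)
  expect_lt(same$rmsd_fit, 1e-9)
  moved <- ref %*% t(rot_z(pi / 2))
  fit <- kabsch_superpose(moved, ref)
  expect_lt(fit$rmsd_fit, 1e-9)
  expect_equal(fit$transformed, ref, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  coll <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch_superpose(coll, coll), "degenerate")
})

test_that("Kabsch optimum matches an independent least-squares oracle", {
  skip_if_not_installed("bio3d")
  set.seed(7)
  ref <- matrix(rnorm(30), ncol = 3)
  mob <- ref %*% t(rot_z(0.8)) + matrix(rnorm(30, sd = 0.3), ncol = 3)
  ours <- kabsch_superpose(mob, ref)
  xyz_fit <- bio3d::fit.xyz(fixed = as.numeric(t(ref)),
                            mobile = as.numeric(t(mob)),
                            fixed.inds = 1:30, mobile.inds = 1:30)
  oracle <- sqrt(mean(rowSums((matrix(xyz_fit, ncol = 3, byrow = TRUE) -
                                 ref)^2)))
  expect_equal(ours$rmsd_fit, oracle, tolerance = 1e-6)
})

test_that("binding RMSD behaves as a superposition-based anchor deviation", {
  p <- toy_params()
  frame <- toy_frame(p)
  expect_equal(binding_rmsd(frame$coords, frame$coords, frame$anchors,
                            frame$receptor), 0)
  # anchors rigidly translated with the receptor unmoved: exactly d
  shifted <- frame$coords
  shifted[frame$ligand, ] <- sweep(shifted[frame$ligand, ], 2, c(3, 0, 4), "+")
  expect_equal(binding_rmsd(shifted, frame$coords, frame$anchors,
                            frame$receptor), 5)
  # arbitrary pose: equals the independently coded rms after superposition
  set.seed(3)
  arb <- frame$coords + matrix(rnorm(21, sd = 2), ncol = 3)
  fit <- kabsch_superpose(arb, frame$coords, frame$receptor)
  manual <- sqrt(mean(rowSums((fit$transformed[frame$anchors, ] -
                                 frame$coords[frame$anchors, ])^2)))
  expect_equal(binding_rmsd(arb, frame$coords, frame$anchors,
                            frame$receptor), manual)
  # invariance under a rigid motion applied jointly to the whole frame
  Rm <- rot_z(1.1)
  moved <- sweep(arb %*% t(Rm), 2, c(5, -2, 7), "+")
  expect_equal(binding_rmsd(moved, frame$coords, frame$anchors,
                            frame$receptor),
               binding_rmsd(arb, frame$coords, frame$anchors,
                            frame$receptor),
               tolerance = 1e-9)
})

test_that("toy binding RMSD agrees with the generic Kabsch route", {
  p <- toy_params()
  ens <- make_initial_ensemble(20, p, seed = 9)
  pc <- toy_pcoord(ens, p)
  ref <- toy_frame(p)
  via_kabsch <- vapply(seq_len(20), function(i) {
    fr <- toy_frame(p, ens[i, ])
    binding_rmsd(fr$coords, ref$coords, ref$anchors, ref$receptor)
  }, 0)
  expect_equal(pc[, "binding_rmsd"], via_kabsch, tolerance = 1e-9)
})

test_that("minimum separation matches the exhaustive pair scan", {
  expect_equal(min_separation(rbind(c(0, 0, 0)), rbind(c(0, 0, 7.5))), 7.5)
  overlapping <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_equal(min_separation(overlapping, overlapping), 0)
  set.seed(11)
  a <- matrix(rnorm(150), ncol = 3)
  b <- matrix(rnorm(150, mean = 2), ncol = 3)
  brute <- min(apply(a, 1, function(x)
    apply(b, 1, function(y) sqrt(sum((x - y)^2)))))
  expect_equal(min_separation(a, b), brute)
  expect_error(min_separation(a[0, , drop = FALSE], b), "nonempty")
})

test_that("xyz tables round-trip and match the toy reference frame", {
  ref_file <- system.file("extdata", "toy_bound_reference.xyz",
                          package = "wepath")
  ref <- read_xyz(ref_file)
  fr <- toy_frame(toy_params())
  expect_equal(unname(ref), unname(fr$coords))
  expect_identical(rownames(ref), rownames(fr$coords))
  tmp <- tempfile(fileext = ".xyz")
  write_xyz(ref, tmp)
  expect_equal(read_xyz(tmp), ref)
  # superposing the file reference onto itself is exact
  expect_equal(binding_rmsd(ref, ref, fr$anchors, fr$receptor), 0)
  bare <- tempfile(fileext = ".xyz")
  writeLines("0 0 0\n1 0 0\n0 1 0", bare)
  expect_identical(dim(read_xyz(bare)), c(3L, 3L))
})

test_that("preparatory scheme has the stated 45-cell layout", {
  sch <- preparatory_scheme()
  expect_identical(n_bins(sch), 45L)
  expect_identical(assign_bin(c(0.05, 0), sch), 1L)
  expect_identical(assign_bin(c(2.95, 0), sch), 30L)
  expect_identical(assign_bin(c(3.2, 0), sch), 31L)
  expect_identical(assign_bin(c(10, 0), sch), assign_bin(c(1e6, 0), sch))
  expect_identical(assign_bin(c(10, 0), sch), 45L)
})

test_that("binding scheme stages differ only beyond contact", {
  s1 <- binding_scheme(1)
  s2 <- binding_scheme(2)
  expect_error(binding_scheme(3), "stage")
  expect_identical(n_bins(s1), 142L)
  expect_identical(n_bins(s2), 72L)
  # the boundary value 5 falls on the non-contact side
  expect_gt(assign_bin(cbind(5, 30), s2), 71L)
  # stage 2 merges the whole non-contact region into one cell
  far <- cbind(c(5, 8, 30), c(0.3, 25, 59))
  expect_identical(length(unique(assign_bin(far, s2))), 1L)
  expect_identical(length(unique(assign_bin(far, s1))), 3L)
  # in-contact assignments agree between the stages
  near <- cbind(runif(50, 0, 4.999), runif(50, 0, 70))
  expect_identical(assign_bin(near, s1), assign_bin(near, s2))
})

test_that("bin assignment partitions the coordinate space", {
  set.seed(5)
  for (sch in list(preparatory_scheme(), binding_scheme(1),
                   binding_scheme(2))) {
    pc <- cbind(runif(500, 0, 80), runif(500, 0, 80))
    idx <- assign_bin(pc, sch)
    expect_true(all(idx >= 1 & idx <= n_bins(sch)))
    expect_identical(length(idx), 500L)
  }
  # edge values go to the upper cell
  sch <- bin_scheme_1d(c(0, 1, 2))
  expect_identical(assign_bin(1, sch), 2L)
  # matches a brute-force linear scan of the edges
  edges <- sort(runif(20, 0, 10))
  sch2 <- bin_scheme_1d(edges)
  x <- runif(300, 0, 12)
  scan <- vapply(x, function(v) max(1L, sum(edges <= v)), 1L)
  expect_identical(assign_bin(matrix(x), sch2), scan)
  expect_error(assign_bin(c(NaN, 1), sch), "finite|NaN")
})
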