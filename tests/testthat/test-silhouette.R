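test_that("TriTaHI arithmetic matches the definition on a constructed silhouette", {
  # rectangle silhouette with known trigonid/talonid heights: 2 and 1, length 5
  pts <- rbind(c(0, 0), c(5, 0), c(5, 2), c(4, 2), c(3, 2),
               c(2, 1), c(1, 1), c(0, 1))
  sil <- new("Silhouette2D", points = pts, outline = pts,
             baseline = rbind(c(5, 0), c(0, 0)), splitFraction = 0.5,
             hTri = 2, hTal = 1, lMax = 5)
  expect_equal(computeTriTaHI(sil), 0.2)
  # recomputation with an explicit split gives the same
  expect_equal(computeTriTaHI(sil, split_fraction = 0.5), 0.2)
})

test_that("the silhouette finds the generator's peaks and baseline", {
  crown <- twinPeakCrown(hMesial = 1, hDistal = 0.5, wall = 0.4)
  sil <- suppressWarnings(lingualSilhouette(crown))
  # the taller (mesial) generator peak is recovered within mesh resolution:
  # peak height 1 above the crown plane, walls drop 0.4 to the baseline
  expect_equal(sil@hTri, 1.4, tolerance = 0.02)
  expect_equal(sil@hTal, 0.9, tolerance = 0.02)
  expect_equal(sil@lMax, 2, tolerance = 1e-6)
  # supplied baseline endpoints are used verbatim after projection
  bp <- rbind(c(1, 0, -0.4), c(-1, 0, -0.4))
  sil2 <- lingualSilhouette(crown, baseline_points = bp)
  expect_equal(unname(sil2@baseline), bp[, c(1, 3)], ignore_attr = TRUE)
  expect_error(lingualSilhouette(toothMesh(matrix(numeric(0), 0, 3),
                                           matrix(integer(0), 0, 3))),
               "empty mesh")
})

test_that("TriTaHI is symmetric for twin peaks and exactly antisymmetric", {
  sym <- twinPeakCrown(1, 1)
  expect_equal(suppressWarnings(computeTriTaHI(lingualSilhouette(sym))), 0,
               tolerance = 1e-6)
  crown <- twinPeakCrown(1, 0.5)
  t0 <- suppressWarnings(computeTriTaHI(lingualSilhouette(crown)))
  mir <- toothMesh(meshVertices(crown) %*% diag(c(-1, 1, 1)),
                   meshFaces(crown)[, c(1, 3, 2)], oriented = TRUE)
  t1 <- suppressWarnings(computeTriTaHI(lingualSilhouette(mir)))
  expect_equal(t1, -t0, tolerance = 1e-12)
  expect_gt(t0, 0)           # taller trigonid => positive sign
})

test_that("TriTaHI is invariant to scale, translation and in-plane rotation", {
  crown <- twinPeakCrown(1, 0.5)
  t0 <- suppressWarnings(computeTriTaHI(lingualSilhouette(crown)))
  expect_equal(suppressWarnings(
    computeTriTaHI(lingualSilhouette(scaleMesh(crown, 4)))), t0,
    tolerance = 1e-9)
  expect_equal(suppressWarnings(
    computeTriTaHI(lingualSilhouette(translateMesh(crown, c(3, -2, 7))))), t0,
    tolerance = 1e-9)
  # rotation within the x-z plane, baseline endpoints transforming with it
  th <- 20 * pi / 180
  R <- rbind(c(cos(th), 0, -sin(th)), c(0, 1, 0), c(sin(th), 0, cos(th)))
  rot <- toothMesh(meshVertices(crown) %*% t(R), meshFaces(crown),
                   oriented = TRUE)
  bp0 <- suppressWarnings(lingualSilhouette(crown))@baseline
  bp <- cbind(bp0[, 1], 0, bp0[, 2]) %*% t(R)
  tR <- computeTriTaHI(lingualSilhouette(rot, baseline_points = bp))
  expect_equal(tR, t0, tolerance = 1e-9)
})

test_that("TriTaHI grows monotonically with the cusp-height difference", {
  vals <- vapply(c(0, 0.3, 0.6), function(d) {
    suppressWarnings(computeTriTaHI(lingualSilhouette(
      twinPeakCrown(hMesial = 0.7 + d / 2, hDistal = 0.7 - d / 2))))
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("the dasyurid-like preset exceeds the tall-trigonid band", {
  dasy <- generateTooth(crownPreset("dasyurid-v1"))
  expect_gt(suppressWarnings(computeTriTaHI(lingualSilhouette(dasy))), 0.26)
})

test_that("degenerate split fractions are rejected", {
  crown <- twinPeakCrown()
  sil <- suppressWarnings(lingualSilhouette(crown))
  expect_error(computeTriTaHI(sil, split_fraction = 1))
  expect_error(computeTriTaHI(sil, split_fraction = 0))
  expect_error(lingualSilhouette(crown, split_fraction = 1.2))
})
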