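# Geometry oracles with closed-form expectations: sphere total curvature
# energy = 8*pi (scale-free), hemisphere relief = ln(sqrt(2)), flat patches
# carry zero energy/relief/complexity.

test_that("DNE matches the closed-sphere oracle and vanishes on flat patches", {
  sph <- icosphereMesh(4)
  res <- computeDNE(sph)
  expect_lt(abs(res$dne / (8 * pi) - 1), 0.05)
  expect_true(all(res$field$convex))          # a sphere is convex everywhere
  expect_equal(computeDNE(flatGridMesh())$dne, 0)
})

test_that("DNE is scale invariant and convex DNE <= total with saddles", {
  crown <- twinPeakCrown(resolution = 40)
  d1 <- computeDNE(crown)$dne
  d2 <- computeDNE(scaleMesh(crown, 2))$dne
  expect_lt(abs(d2 / d1 - 1), 1e-6)
  # monkey-saddle-like surface: concave regions exist, so convex < total
  g <- flatGridMesh(40, 2, 2)
  v <- meshVertices(g)
  x <- v[, 1] - 1; y <- v[, 2] - 1
  saddle <- toothMesh(cbind(v[, 1], v[, 2], 0.4 * (x^3 - 3 * x * y^2)),
                      meshFaces(g), oriented = TRUE)
  tot <- computeDNE(saddle, variant = "total")$dne
  cvx <- computeDNE(saddle, variant = "convex")$dne
  expect_lt(cvx, tot)
  expect_gt(cvx, 0)
  # sphere: convex variant equals the total
  sph <- icosphereMesh(3)
  expect_equal(computeDNE(sph, variant = "convex")$dne,
               computeDNE(sph, variant = "total")$dne)
})

test_that("winding-inconsistent meshes are rejected by DNE", {
  g <- flatGridMesh(5)
  f <- meshFaces(g)
  f[2, ] <- f[2, c(1, 3, 2)]
  bad <- toothMesh(meshVertices(g), f)
  expect_error(computeDNE(bad), "orientation error")
})

test_that("outline area matches the disc oracle and flags degenerate input", {
  expect_equal(outlineArea(unitSquareMesh()), 1.0, tolerance = 1e-12)
  hemi <- hemisphereMesh(30, 120)
  expect_lt(abs(outlineArea(hemi) / pi - 1), 0.01)
  line <- toothMesh(cbind(seq(0, 1, length.out = 5), 0, c(0, 1, 0, 1, 0)),
                    rbind(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_error(outlineArea(line), "collinear")
})

test_that("relief index matches flat and hemisphere oracles, scale invariant", {
  expect_equal(computeRFI(unitSquareMesh()), 0, tolerance = 1e-12)
  hemi <- hemisphereMesh(40, 160)      # ~12.6k faces
  expect_lt(abs(computeRFI(hemi) / log(sqrt(2)) - 1), 0.01)
  crown <- twinPeakCrown(resolution = 40)
  expect_lt(abs(computeRFI(scaleMesh(crown, 3)) - computeRFI(crown)), 1e-6)
})

test_that("ariaDNE is near-constant on a sphere, zero on a plane, warns on epsilon", {
  sph <- icosphereMesh(4)
  res <- computeAriaDNE(sph)
  expect_lt(res$ariaDNE_CV, 0.1)
  expect_gt(res$ariaDNE, 0)
  flat <- flatGridMesh(25)
  expect_warning(resF <- computeAriaDNE(flat), "near-zero curvature")
  expect_lt(resF$ariaDNE, 1e-6)
  expect_equal(resF$ariaDNE_CV, 0)
  expect_warning(computeAriaDNE(icosphereMesh(2), epsilon = 0.2),
                 "outside the recommended range")
  expect_error(suppressWarnings(computeAriaDNE(icosphereMesh(2),
                                               epsilon = 0.001)),
               "bandwidth error")
})

test_that("ariaDNE agrees with DNE on smooth crowns and is scale invariant", {
  crown <- generateTooth(crownSpec(
    length_x = 2, width_y = 1.6,
    cusps = data.frame(x = c(-0.4, 0.45), y = c(-0.15, 0.1),
                       height = c(0.5, 0.35), sigma = c(0.45, 0.4)),
    wall_depth = 0, grid_resolution = 72))
  d <- computeDNE(crown)$dne
  a <- computeAriaDNE(crown)$ariaDNE
  expect_lt(abs(a / d - 1), 0.15)
  a2 <- computeAriaDNE(scaleMesh(crown, 2.5))$ariaDNE
  expect_lt(abs(a2 / a - 1), 1e-6)
})

test_that("OPCR counts one patch per sector for a radial cusp, none when flat", {
  cusp <- generateTooth(crownSpec(length_x = 2, width_y = 2,
    cusps = data.frame(x = 0, y = 0, height = 1, sigma = 0.3),
    wall_depth = 0, grid_resolution = 60))
  expect_equal(as.numeric(computeOPCR(cusp)), 8)
  expect_equal(as.numeric(computeOPCR(flatGridMesh())), 0)
})

test_that("OPCR approaches 32 for four well-separated cusps", {
  cusp4 <- generateTooth(crownSpec(length_x = 4, width_y = 4,
    cusps = data.frame(x = c(-1, -1, 1, 1), y = c(-1, 1, -1, 1),
                       height = 1, sigma = 0.18),
    wall_depth = 0, grid_resolution = 100))
  o <- as.numeric(computeOPCR(cusp4))
  expect_gte(o, 30)
  expect_lte(o, 36)
})

test_that("OPCR is scale invariant and stable under arbitrary z-rotation", {
  cusp <- generateTooth(crownSpec(length_x = 2, width_y = 1.6,
    cusps = data.frame(x = c(-0.5, 0.4), y = c(0.1, -0.2),
                       height = c(0.9, 0.6), sigma = c(0.2, 0.25)),
    wall_depth = 0, grid_resolution = 60))
  o0 <- as.numeric(computeOPCR(cusp))
  expect_equal(as.numeric(computeOPCR(scaleMesh(cusp, 4))), o0)
  for (ang in c(13.7, 118.2, 261.9)) {
    oR <- as.numeric(computeOPCR(rotateMeshZ(cusp, ang)))
    expect_lt(abs(oR - o0) / o0, 0.05)
  }
})

test_that("lnOA shifts by exactly 2 ln s under uniform scaling", {
  crown <- twinPeakCrown(resolution = 40)
  oa1 <- log(outlineArea(crown))
  oa2 <- log(outlineArea(scaleMesh(crown, 3)))
  expect_equal(oa2 - oa1, 2 * log(3), tolerance = 1e-9)
})

test_that("metric profiles carry all fields, failure tags, and known flats", {
  prof <- measureProfile(unitSquareMesh(),
                         metrics = c("rfi", "dne", "opcr", "lnOA"))
  m <- profileMetrics(prof)
  expect_named(m, c("rfi", "dne", "convexDNE", "ariaDNE", "ariaDNE_CV",
                    "opcr", "lnOA", "tritahi"))
  expect_equal(unname(m[c("rfi", "dne", "opcr", "lnOA")]), c(0, 0, 0, 0))
  # un-requested metrics stay NA; failing metrics are tagged, not fatal
  expect_true(is.na(m[["ariaDNE"]]))
  profAll <- suppressWarnings(measureProfile(unitSquareMesh()))
  expect_true("tritahi" %in% names(profAll@failures) ||
                !is.na(profileMetrics(profAll)[["tritahi"]]))
})

test_that("the sharp tall-cusped preset lands in the high-relief band", {
  sharp <- generateTooth(crownPreset("insectivore-sharp-v1"))
  expect_gt(computeRFI(sharp), 0.56)
  blunt <- generateTooth(crownPreset("folivore-blunt-v1"))
  expect_lt(computeRFI(blunt), computeRFI(sharp))
})

test_that("metrics respond monotonically to the generator ladder", {
  feats <- function(sigma = 0.25, height = 0.9, n = 1) {
    xs <- if (n == 1) 0 else seq(-0.6, 0.6, length.out = n)
    m <- generateTooth(crownSpec(length_x = 2, width_y = 1.6,
      cusps = data.frame(x = xs, y = 0, height = height, sigma = sigma),
      wall_depth = 0, grid_resolution = 60, seed = 2))
    m
  }
  # sharper cusps (smaller sigma) => higher DNE and ariaDNE
  dnes <- vapply(c(0.4, 0.3, 0.22), function(s) computeDNE(feats(sigma = s))$dne,
                 numeric(1))
  arias <- vapply(c(0.4, 0.3, 0.22),
                  function(s) computeAriaDNE(feats(sigma = s))$ariaDNE,
                  numeric(1))
  expect_true(all(diff(dnes) > 0))
  expect_true(all(diff(arias) > 0))
  # taller cusps => higher relief
  rfis <- vapply(c(0.4, 0.8, 1.2), function(h) computeRFI(feats(height = h)),
                 numeric(1))
  expect_true(all(diff(rfis) > 0))
  # more cusps => higher OPCR
  opcrs <- vapply(c(1, 2, 3),
                  function(n) as.numeric(computeOPCR(feats(n = n, sigma = 0.15))),
                  numeric(1))
  expect_true(all(diff(opcrs) > 0))
})
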