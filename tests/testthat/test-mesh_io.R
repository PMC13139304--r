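test_that("minimal ASCII PLY ingests with the right counts", {
  tmp <- tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0",
               "element vertex 3",
               "property float x", "property float y", "property float z",
               "element face 1",
               "property list uchar int vertex_indices",
               "end_header",
               "0 0 0", "1 0 0", "0 1 0", "3 0 1 2"), tmp)
  m <- suppressMessages(readMesh(tmp))
  expect_equal(nVertices(m), 3L)
  expect_equal(nFaces(m), 1L)
  expect_equal(meshFaces(m), matrix(c(1L, 2L, 3L), 1))
})

test_that("write/read round-trips are the identity for all three formats", {
  mesh <- generateTooth(crownSpec(grid_resolution = 12, wall_depth = 0.3))
  for (fmt in c("ply", "obj", "off")) {
    tmp <- tempfile(fileext = paste0(".", fmt))
    writeMesh(mesh, tmp, format = fmt)
    back <- suppressMessages(readMesh(tmp, format = fmt))
    expect_equal(meshVertices(back), unname(meshVertices(mesh)),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_identical(unname(meshFaces(back)), unname(meshFaces(mesh)))
  }
})

test_that("binary little-endian PLY is read", {
  mesh <- unitSquareMesh()
  tmp <- tempfile(fileext = ".ply")
  con <- file(tmp, "wb")
  writeChar(paste0("ply\nformat binary_little_endian 1.0\n",
                   "element vertex 4\n",
                   "property float x\nproperty float y\nproperty float z\n",
                   "element face 2\n",
                   "property list uchar int vertex_indices\n",
                   "end_header\n"), con, eos = NULL)
  for (i in 1:4)
    writeBin(as.numeric(meshVertices(mesh)[i, ]), con, size = 4,
             endian = "little")
  for (i in 1:2) {
    writeBin(as.raw(3), con)
    writeBin(as.integer(meshFaces(mesh)[i, ] - 1L), con, size = 4,
             endian = "little")
  }
  close(con)
  back <- suppressMessages(readMesh(tmp))
  expect_equal(meshVertices(back), unname(meshVertices(mesh)),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(unname(meshFaces(back)), unname(meshFaces(mesh)))
})

test_that("malformed inputs raise named, informative errors", {
  # out-of-range face index, naming the face
  tmp <- tempfile(fileext = ".off")
  writeLines(c("OFF", "3 1 0", "0 0 0", "1 0 0", "0 1 0", "3 0 1 9"), tmp)
  expect_error(suppressMessages(readMesh(tmp)), "out-of-range")
  # zero faces
  tmp2 <- tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0"), tmp2)
  expect_error(suppressMessages(readMesh(tmp2)), "empty mesh")
  # unknown format tag on write
  expect_error(writeMesh(unitSquareMesh(), tempfile(fileext = ".stl")),
               "unknown mesh format")
  # missing file
  expect_error(readMesh(tempfile()), "does not exist")
})

test_that("validation rejects invariant violations and accepts valid meshes", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(toothMesh(v, rbind(c(1, 1, 2))), "repeated vertex")
  expect_error(toothMesh(v, rbind(c(1, 2, 4))), "out-of-range")
  vz <- rbind(v, c(2, 0, 0))
  expect_error(toothMesh(rbind(v, c(0.5, 0, 0)), rbind(c(1, 2, 4))),
               "degenerate")
  # winding inconsistency: one face flipped
  grid <- flatGridMesh(4)
  f <- meshFaces(grid)
  f[1, ] <- f[1, c(1, 3, 2)]
  bad <- toothMesh(meshVertices(grid), f)
  expect_error(validateMesh(bad), "winding")
  # generated corpora all pass
  for (s in 1:4) {
    spec <- crownSpec(cusps = data.frame(x = runif(2, -0.5, 0.5),
                                         y = runif(2, -0.4, 0.4),
                                         height = runif(2, 0.2, 1),
                                         sigma = runif(2, 0.15, 0.4)),
                      grid_resolution = 15, wall_depth = s %% 2 * 0.3,
                      seed = s)
    expect_true(validateMesh(generateTooth(spec)))
  }
})
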