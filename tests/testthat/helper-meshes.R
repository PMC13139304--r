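# Mesh fixtures built in code: icosphere (closed), structured hemisphere
# (clean circular boundary), flat grids. Used by geometry oracles.

icosphereMesh <- function(subdiv = 3, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid <- new.env()
    nv <- nrow(v)
    getMid <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(mid[[key]])) return(mid[[key]])
      v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
      nv <<- nv + 1
      mid[[key]] <- nv
      nv
    }
    nf <- matrix(0L, 0, 3)
    for (r in seq_len(nrow(f))) {
      a <- f[r, 1]; b <- f[r, 2]; c_ <- f[r, 3]
      ab <- getMid(a, b); bc <- getMid(b, c_); ca <- getMid(c_, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  toothMesh(v, f, oriented = TRUE)
}

# Structured polar-grid hemisphere: rings of constant latitude, m points per
# ring, apex fan. Boundary is a clean m-gon circle at the equator.
hemisphereMesh <- function(rings = 40, perRing = 160, radius = 1) {
  v <- matrix(c(0, 0, radius), 1, 3)
  for (i in seq_len(rings)) {
    th <- (i / rings) * (pi / 2)       # polar angle from apex
    ang <- 2 * pi * (seq_len(perRing) - 1) / perRing
    v <- rbind(v, cbind(radius * sin(th) * cos(ang),
                        radius * sin(th) * sin(ang),
                        radius * cos(th)))
  }
  idx <- function(ring, k) 1L + (ring - 1L) * perRing + ((k - 1L) %% perRing) + 1L
  f <- matrix(0L, 0, 3)
  f <- rbind(f, cbind(1L, idx(1, seq_len(perRing)), idx(1, seq_len(perRing) + 1)))
  for (ring in seq_len(rings - 1)) {
    k <- seq_len(perRing)
    f <- rbind(f,
               cbind(idx(ring, k), idx(ring + 1, k), idx(ring + 1, k + 1)),
               cbind(idx(ring, k), idx(ring + 1, k + 1), idx(ring, k + 1)))
  }
  toothMesh(v, f, oriented = TRUE)
}

flatGridMesh <- function(n = 15, lengthX = 1, widthY = 1, z = 0) {
  xs <- seq(0, lengthX, length.out = n)
  ys <- seq(0, widthY, length.out = n)
  g <- expand.grid(x = xs, y = ys)
  v <- cbind(g$x, g$y, z)
  idx <- function(i, j) (j - 1L) * n + i
  i <- rep(seq_len(n - 1L), n - 1L)
  j <- rep(seq_len(n - 1L), each = n - 1L)
  f <- rbind(cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
             cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  toothMesh(v, f, oriented = TRUE)
}

unitSquareMesh <- function() {
  toothMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
            rbind(c(1, 2, 3), c(1, 3, 4)), oriented = TRUE)
}

# Convenience crowns used across tests.
twinPeakCrown <- function(hMesial = 1, hDistal = 0.5, sigma = 0.22,
                          resolution = 70, wall = 0.4, seed = 1L) {
  generateTooth(crownSpec(
    length_x = 2, width_y = 1.2,
    cusps = data.frame(x = c(0.5, -0.5), y = 0,
                       height = c(hMesial, hDistal), sigma = sigma),
    wall_depth = wall, grid_resolution = resolution, seed = seed))
}
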