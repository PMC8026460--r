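## Independent oracles used across the suite. These deliberately share no
## code with the package implementation.

## Brute-force flood fill: fixpoint label propagation with matrix shifts.
## Returns the 4-connected component of pixels within `tol` of the seed
## intensity that contains the seed.
bruteFloodFill <- function(img, seed, tol = 0) {
  ok <- abs(img - img[seed[1], seed[2]]) <= tol
  reg <- matrix(FALSE, nrow(img), ncol(img))
  reg[seed[1], seed[2]] <- TRUE
  repeat {
    grown <- reg
    grown[-1, ] <- grown[-1, ] | reg[-nrow(reg), ]
    grown[-nrow(reg), ] <- grown[-nrow(reg), ] | reg[-1, ]
    grown[, -1] <- grown[, -1] | reg[, -ncol(reg)]
    grown[, -ncol(reg)] <- grown[, -ncol(reg)] | reg[, -1]
    grown <- grown & ok
    if (identical(grown, reg)) return(reg)
    reg <- grown
  }
}

## Number of 4-connected components of a binary matrix (brute force).
countComponents4 <- function(bw) {
  n <- 0L
  todo <- bw
  while (any(todo)) {
    seed <- which(todo, arr.ind = TRUE)[1L, ]
    comp <- bruteFloodFill(ifelse(todo, 1, 0), seed, 0)
    todo <- todo & !comp
    n <- n + 1L
  }
  n
}

## Icosphere: subdivided icosahedron projected to radius r, outward
## oriented TriangleMesh.
icosphere <- function(r = 1, subdiv = 2, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  norm2 <- function(m) m / sqrt(rowSums(m^2))
  v <- norm2(v)
  for (s in seq_len(subdiv)) {
    cache <- new.env()
    midpt <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      if (!is.null(cache[[key]])) return(cache[[key]])
      v <<- rbind(v, norm2(matrix(v[i, ] + v[j, ], 1)))
      cache[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 0, 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
      ab <- midpt(a, b); bc <- midpt(b, cc); ca <- midpt(cc, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc),
                  c(ab, bc, ca))
    }
    f <- nf
  }
  verts <- sweep(v * r, 2, center, "+")
  mesh <- new("TriangleMesh", vertices = verts, faces = f)
  ## guarantee outward orientation
  a <- verts[f[, 1], ]; b <- verts[f[, 2], ]; cc <- verts[f[, 3], ]
  s <- sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
           a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
           a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1]))
  if (s < 0) mesh@faces <- f[, c(1, 3, 2)]
  mesh
}

## Rasterized solid ball of radius r (mm) at isotropic spacing (mm),
## voxel centres on a symmetric grid.
rasterBall <- function(r, spacing) {
  cs <- seq(-(r + 2 * spacing), r + 2 * spacing, by = spacing)
  n <- length(cs)
  g <- expand.grid(x = cs, y = cs, z = cs)
  array(g$x^2 + g$y^2 + g$z^2 <= r^2, c(n, n, n))
}

## Uniform random rotation matrix (det +1).
randomRotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

## Rigidly transform a LandmarkSet.
transformLandmarks <- function(set, R = diag(3), t = c(0, 0, 0)) {
  co <- landmarkCoords(set)
  landmarkSet(sweep(co %*% t(R), 2, t, "+"), subject = subjectId(set),
              validate = FALSE)
}

## Rotation about an axis by angle (degrees), Rodrigues form.
axisRotation <- function(axis, deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

## Shoelace area of a closed (row, col) polygon.
shoelace <- function(b) {
  n <- nrow(b)
  abs(sum(b[-n, 1] * b[-1, 2] - b[-1, 1] * b[-n, 2])) / 2
}

## Shared fitted templates (computed once per test run).
femaleTemplate <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- buildTemplate(defaultMeasureTargets("female"))
    cache
  }
})
maleTemplate <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- buildTemplate(defaultMeasureTargets("male"))
    cache
  }
})
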