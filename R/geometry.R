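triangleMesh <- function(vertices, faces) {
  storage.mode(faces) <- "integer"
  new("TriangleMesh", vertices = unname(as.matrix(vertices)),
      faces = unname(as.matrix(faces)))
}

#' Signed volume of a closed triangle mesh
#'
#' Sum of signed tetrahedron volumes; positive for a watertight mesh with
#' outward-oriented faces.
#'
#' @param mesh a [TriangleMesh-class].
#' @return volume (mm^3).
#' @export
meshVolume <- function(mesh) {
  v <- mesh@vertices
  f <- mesh@faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  d <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) +
      a[, 2] * (b[, 3] * d[, 1] - b[, 1] * d[, 3]) +
      a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])) / 6
}

#' Watertightness and orientation check
#'
#' A closed, consistently oriented mesh has every undirected edge shared
#' by exactly two faces and every directed edge used exactly once.
#'
#' @param mesh a [TriangleMesh-class].
#' @return TRUE/FALSE.
#' @export
isWatertight <- function(mesh) {
  f <- mesh@faces
  ed <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  directed <- paste(ed[, 1], ed[, 2])
  if (anyDuplicated(directed)) return(FALSE)
  undirected <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  all(table(undirected) == 2L)
}

# icosahedron + repeated 4-way subdivision, projected to the unit sphere
unitIcosphere <- function(subdivisions) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    cache <- new.env(hash = TRUE, parent = emptyenv())
    verts <- v
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (verts[i, ] + verts[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      verts <<- rbind(verts, m)
      idx <- nrow(verts)
      cache[[key]] <- idx
      idx
    }
    nf <- matrix(0L, nrow(f) * 4, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; d <- f[i, 3]
      ab <- midpoint(a, b); bd <- midpoint(b, d); da <- midpoint(d, a)
      nf[(i - 1) * 4 + 1:4, ] <- rbind(c(a, ab, da), c(b, bd, ab),
                                       c(d, da, bd), c(ab, bd, da))
    }
    v <- verts
    f <- nf
  }
  list(vertices = v, faces = f)
}

#' Oblate-spheroid tumour mesh
#'
#' Watertight icosphere scaled to semi-axes (a, a, c): the idealized
#' flattened-ellipsoid tumour shape (e.g. diameter 1 mm, height 0.5 mm
#' means a = 0.5, c = 0.25). Mesh volume converges to (4/3) pi a^2 c with
#' subdivision.
#'
#' @param center 3-vector (mm).
#' @param semi_axes numeric: either `c(a, c)` or `c(a, a, c)` (mm).
#' @param subdivisions icosphere subdivision level (>= 1; default 3 gives
#'   1280 faces, volume within ~0.2%).
#' @return a [TriangleMesh-class].
#' @examples
#' m <- makeOblateSpheroid(c(0, 0, 0), c(0.5, 0.25))
#' meshVolume(m) # ~ 4/3 * pi * 0.5^2 * 0.25
#' @export
makeOblateSpheroid <- function(center, semi_axes, subdivisions = 3L) {
  if (length(semi_axes) == 2) semi_axes <- semi_axes[c(1, 1, 2)]
  if (any(semi_axes <= 0)) stop("semi-axes must be positive")
  if (subdivisions < 1) stop("subdivisions must be >= 1")
  s <- unitIcosphere(as.integer(subdivisions))
  v <- sweep(sweep(s$vertices, 2, semi_axes, "*"), 2, center, "+")
  triangleMesh(v, s$faces)
}

#' Axis-aligned cuboid mesh
#'
#' @param center 3-vector (mm).
#' @param size edge lengths, scalar or 3-vector (mm).
#' @return a watertight, outward-oriented [TriangleMesh-class] (12
#'   triangles).
#' @export
makeCuboidMesh <- function(center, size) {
  if (length(size) == 1) size <- rep(size, 3)
  if (any(size <= 0)) stop("size must be positive")
  h <- size / 2
  sgn <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  v <- sweep(sweep(sgn, 2, h, "*"), 2, center, "+")
  # outward-oriented faces of the +/- unit cube with vertex order
  # (x fastest): 1=(---) 2=(+--) 3=(-+-) 4=(++-) 5=(--+) 6=(+-+) 7=(-++) 8=(+++)
  f <- rbind(
    c(1, 3, 4), c(1, 4, 2),   # z lo
    c(5, 6, 8), c(5, 8, 7),   # z hi
    c(1, 2, 6), c(1, 6, 5),   # y lo
    c(3, 7, 8), c(3, 8, 4),   # y hi
    c(1, 5, 7), c(1, 7, 3),   # x lo
    c(2, 4, 8), c(2, 8, 6))   # x hi
  triangleMesh(v, f)
}

#' Disc light source (triangle fan)
#'
#' A planar circular emitter approximated by an n_fan-triangle fan.
#' Emission points are sampled uniformly over the fan's area; the emission
#' direction is the surface normal.
#'
#' @param center disc centre (mm).
#' @param radius disc radius (mm).
#' @param n_fan number of fan triangles (>= 3; default 16).
#' @param power radiant power (W).
#' @param direction emission direction (normalized internally; default
#'   straight down, `c(0, 0, -1)`).
#' @return a [LightSource-class].
#' @export
makeDiscSource <- function(center, radius, n_fan = 16L, power = 1,
                           direction = c(0, 0, -1)) {
  if (radius <= 0) stop("radius must be positive")
  if (n_fan < 3) stop("n_fan must be >= 3")
  direction <- direction / sqrt(sum(direction^2))
  # rim vertices in the plane perpendicular to direction
  a <- if (abs(direction[3]) < 0.999) c(0, 0, 1) else c(1, 0, 0)
  u <- c(a[2] * direction[3] - a[3] * direction[2],
         a[3] * direction[1] - a[1] * direction[3],
         a[1] * direction[2] - a[2] * direction[1])
  u <- u / sqrt(sum(u^2))
  v <- c(direction[2] * u[3] - direction[3] * u[2],
         direction[3] * u[1] - direction[1] * u[3],
         direction[1] * u[2] - direction[2] * u[1])
  th <- 2 * pi * (seq_len(n_fan) - 1) / n_fan
  rim <- t(vapply(th, function(t0)
    center + radius * (cos(t0) * u + sin(t0) * v), numeric(3)))
  verts <- rbind(center, rim)
  faces <- cbind(1L, 1L + seq_len(n_fan), 1L + c(seq_len(n_fan)[-1], 1L))
  new("LightSource", mesh = triangleMesh(verts, faces),
      center = as.numeric(center), radius = as.numeric(radius),
      n_fan = as.integer(n_fan), direction = direction,
      power = as.numeric(power))
}

#' Planar area of a mesh (sum of triangle areas)
#'
#' @param mesh a [TriangleMesh-class].
#' @return area (mm^2).
#' @export
meshArea <- function(mesh) {
  v <- mesh@vertices
  f <- mesh@faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Sample emission points on a light source
#'
#' Area-uniform points on the source's triangle fan, as used by the
#' transport engine's emitter.
#'
#' @param source a [LightSource-class].
#' @param n number of points.
#' @return n x 3 matrix (mm). Uses R's RNG; `set.seed()` for
#'   reproducibility.
#' @export
sampleSourcePoints <- function(source, n) {
  v <- source@mesh@vertices
  f <- source@mesh@faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  area <- sqrt(cx^2 + cy^2 + cz^2) / 2
  tri <- sample.int(nrow(f), n, replace = TRUE, prob = area)
  b1 <- stats::runif(n)
  b2 <- stats::runif(n)
  flip <- b1 + b2 > 1
  b1[flip] <- 1 - b1[flip]
  b2[flip] <- 1 - b2[flip]
  v[f[tri, 1], , drop = FALSE] + b1 * e1[tri, , drop = FALSE] +
    b2 * e2[tri, , drop = FALSE]
}

#' Read a triangle mesh from STL (ASCII or binary)
#'
#' Vertices closer than `tol` are merged so the result can be tested for
#' watertightness.
#'
#' @param path STL file.
#' @param tol vertex merge tolerance (mm).
#' @return a [TriangleMesh-class].
#' @export
readSTL <- function(path, tol = 1e-8) {
  con <- file(path, "rb")
  head <- readBin(con, "raw", 80)
  close(con)
  is_ascii <- identical(rawToChar(head[1:5]), "solid") &&
    !any(head == as.raw(0))
  tris <- if (is_ascii) readSTLascii(path) else readSTLbinary(path)
  soupToMesh(tris, tol)
}

readSTLascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vx <- grep("^\\s*vertex", lines, value = TRUE)
  xyz <- do.call(rbind, lapply(strsplit(trimws(vx), "\\s+"), function(p)
    as.numeric(p[2:4])))
  if (nrow(xyz) %% 3 != 0) stop("malformed ASCII STL: vertex count not 3n")
  xyz
}

readSTLbinary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  nt <- readBin(con, "integer", 1, size = 4, endian = "little")
  out <- matrix(0, nt * 3, 3)
  for (i in seq_len(nt)) {
    rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
    out[(i - 1) * 3 + 1:3, ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
    readBin(con, "raw", 2)
  }
  out
}

soupToMesh <- function(xyz, tol) {
  key <- paste(round(xyz[, 1] / tol), round(xyz[, 2] / tol),
               round(xyz[, 3] / tol))
  idx <- match(key, unique(key))
  verts <- xyz[!duplicated(key), , drop = FALSE]
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  triangleMesh(verts, faces)
}

#' Write a triangle mesh as ASCII STL
#'
#' @param mesh a [TriangleMesh-class].
#' @param path output file.
#' @param name solid name.
#' @return `path`, invisibly.
#' @export
writeSTL <- function(mesh, path, name = "mesh") {
  v <- mesh@vertices
  f <- mesh@faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; d <- v[f[i, 3], ]
    nrm <- c((b[2] - a[2]) * (d[3] - a[3]) - (b[3] - a[3]) * (d[2] - a[2]),
             (b[3] - a[3]) * (d[1] - a[1]) - (b[1] - a[1]) * (d[3] - a[3]),
             (b[1] - a[1]) * (d[2] - a[2]) - (b[2] - a[2]) * (d[1] - a[1]))
    nn <- sqrt(sum(nrm^2))
    if (nn > 0) nrm <- nrm / nn
    writeLines(c(
      sprintf("  facet normal %.9g %.9g %.9g", nrm[1], nrm[2], nrm[3]),
      "    outer loop",
      sprintf("      vertex %.9g %.9g %.9g", a[1], a[2], a[3]),
      sprintf("      vertex %.9g %.9g %.9g", b[1], b[2], b[3]),
      sprintf("      vertex %.9g %.9g %.9g", d[1], d[2], d[3]),
      "    endloop",
      "  endfacet"), con)
  }
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}
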