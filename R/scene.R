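#' Construct a voxel grid
#'
#' @param extent domain bounds (mm): a 3 x 2 matrix (rows x,y,z; cols
#'   lo,hi), or a single `c(lo, hi)` applied to all axes.
#' @param n_cells cells per axis (scalar or 3-vector).
#' @return a [VoxelGrid-class].
#' @export
voxelGridDef <- function(extent, n_cells) {
  if (is.null(dim(extent))) extent <- matrix(rep(extent, 3), 3, 2,
                                             byrow = TRUE)
  if (length(n_cells) == 1) n_cells <- rep(n_cells, 3)
  new("VoxelGrid", extent = unname(as.matrix(extent)),
      n_cells = as.integer(n_cells))
}

#' Construct a scene entity
#'
#' Built-in shapes carry analytic parameters (used exactly by the
#' transport engine) alongside their generated triangle mesh; arbitrary
#' meshes (e.g. from [readSTL()]) are used as-is.
#'
#' @param label entity name.
#' @param shape "cuboid", "ellipsoid" or "mesh".
#' @param material material name (must exist in the scene).
#' @param priority integer nesting priority; the highest-priority entity
#'   containing a point supplies the medium there.
#' @param center,size cuboid centre and edge lengths (mm).
#' @param semi_axes ellipsoid semi-axes `c(a, b, c)` or `c(a, c)` for an
#'   oblate spheroid (mm).
#' @param mesh a [TriangleMesh-class] for shape = "mesh".
#' @param subdivisions icosphere refinement for ellipsoids.
#' @return an [Entity-class].
#' @export
entity <- function(label, shape = c("cuboid", "ellipsoid", "mesh"), material,
                   priority, center = c(0, 0, 0), size = NULL,
                   semi_axes = NULL, mesh = NULL, subdivisions = 3L) {
  shape <- match.arg(shape)
  params <- list(center = as.numeric(center))
  if (shape == "cuboid") {
    if (is.null(size)) stop("cuboid entity needs 'size'")
    if (length(size) == 1) size <- rep(size, 3)
    params$size <- as.numeric(size)
    mesh <- makeCuboidMesh(center, size)
  } else if (shape == "ellipsoid") {
    if (is.null(semi_axes)) stop("ellipsoid entity needs 'semi_axes'")
    if (length(semi_axes) == 2) semi_axes <- semi_axes[c(1, 1, 2)]
    params$semi_axes <- as.numeric(semi_axes)
    mesh <- makeOblateSpheroid(center, semi_axes, subdivisions)
  } else {
    if (is.null(mesh)) stop("mesh entity needs 'mesh'")
    params <- list()
  }
  new("Entity", label = label, shape = shape, params = params, mesh = mesh,
      material = material, priority = as.integer(priority))
}

#' Assemble a scene
#'
#' @param materials named list of [OpticalMaterial-class]; names are the
#'   keys entities refer to.
#' @param entities list of [Entity-class].
#' @param source a [LightSource-class].
#' @param grid a [VoxelGrid-class].
#' @param ambient material name filling space outside all entities
#'   (default "air"; must exist in `materials`).
#' @return a [Scene-class].
#' @export
scene <- function(materials, entities, source, grid, ambient = "air") {
  new("Scene", materials = materials, entities = entities, ambient = ambient,
      source = source, grid = grid)
}

insideEntity <- function(e, point) {
  switch(e@shape,
    cuboid = {
      h <- e@params$size / 2
      all(abs(point - e@params$center) <= h)
    },
    ellipsoid = {
      sum(((point - e@params$center) / e@params$semi_axes)^2) <= 1
    },
    as.logical(insideMeshC(e@mesh@vertices, e@mesh@faces - 1L,
                           matrix(point, 1, 3))))
}

#' Material at a point
#'
#' Resolves the innermost (highest-priority) entity containing the point;
#' unclaimed space gets the ambient material.
#'
#' @param scn a [Scene-class].
#' @param point 3-vector (mm); must lie inside the domain.
#' @return the [OpticalMaterial-class] at the point.
#' @export
mediumAt <- function(scn, point) {
  ext <- scn@grid@extent
  if (any(point < ext[, 1]) || any(point > ext[, 2]))
    stop("point lies outside the scene domain")
  ord <- order(vapply(scn@entities, function(e) e@priority, 1L),
               decreasing = TRUE)
  for (e in scn@entities[ord])
    if (insideEntity(e, point)) return(scn@materials[[e@material]])
  scn@materials[[scn@ambient]]
}

#' Nearest boundary along a ray
#'
#' Scans every entity's triangle mesh (and the domain box) for the
#' nearest intersection beyond the self-intersection guard, returning the
#' interface normal oriented against the ray and the materials on the
#' near and far side.
#'
#' @param scn a [Scene-class].
#' @param origin ray origin (mm).
#' @param direction unit direction.
#' @param eps minimum accepted hit distance (mm).
#' @return `NULL` if nothing is hit, else a list with `distance` (mm),
#'   `normal` (against the ray), `entity` (label, or "domain"),
#'   `material_near`, `material_far` ([OpticalMaterial-class]s on the
#'   origin and far side of the interface).
#' @export
rayIntersect <- function(scn, origin, direction, eps = 1e-9) {
  direction <- direction / sqrt(sum(direction^2))
  best <- NULL
  for (e in scn@entities) {
    h <- rayMeshC(e@mesh@vertices, e@mesh@faces - 1L, origin, direction, eps)
    if (h$hit && (is.null(best) || h$distance < best$distance))
      best <- list(distance = h$distance, normal = h$normal,
                   entity = e@label)
  }
  ext <- scn@grid@extent
  hd <- rayBoxR(origin, direction, ext[, 1], ext[, 2], eps)
  if (!is.null(hd) && (is.null(best) || hd$distance < best$distance))
    best <- list(distance = hd$distance, normal = hd$normal,
                 entity = "domain")
  if (is.null(best)) return(NULL)
  hitp <- origin + best$distance * direction
  nudge <- 1e-6
  near <- origin + max(best$distance - nudge, 0) * direction
  far <- origin + (best$distance + nudge) * direction
  best$material_near <- tryCatch(mediumAt(scn, near), error = function(e) NULL)
  best$material_far <- tryCatch(mediumAt(scn, far), error = function(e) NULL)
  best$point <- hitp
  best
}

rayBoxR <- function(p, d, lo, hi, eps) {
  tmin <- -Inf; tmax <- Inf; axmin <- NA; axmax <- NA
  for (a in 1:3) {
    if (d[a] != 0) {
      t1 <- (lo[a] - p[a]) / d[a]
      t2 <- (hi[a] - p[a]) / d[a]
      if (t1 > t2) { tmp <- t1; t1 <- t2; t2 <- tmp }
      if (t1 > tmin) { tmin <- t1; axmin <- a }
      if (t2 < tmax) { tmax <- t2; axmax <- a }
    } else if (p[a] < lo[a] || p[a] > hi[a]) return(NULL)
  }
  if (tmax < tmin) return(NULL)
  if (tmin > eps) { t <- tmin; ax <- axmin }
  else if (tmax > eps) { t <- tmax; ax <- axmax }
  else return(NULL)
  nrm <- numeric(3)
  nrm[ax] <- if (d[ax] > 0) -1 else 1
  list(distance = t, normal = nrm)
}

# Flatten a Scene into the plain list the C++ engine consumes. Converts
# cm^-1 -> mm^-1 once, sorts entities by descending priority, and encodes
# built-in shapes analytically.
flattenScene <- function(scn) {
  matNames <- names(scn@materials)
  M <- t(vapply(scn@materials, function(m)
    c(m@mu_a / 10, m@mu_s / 10, m@g, m@n), numeric(4)))
  ord <- order(vapply(scn@entities, function(e) e@priority, 1L),
               decreasing = TRUE)
  ents <- lapply(scn@entities[ord], function(e) {
    mi <- match(e@material, matNames)
    if (e@shape == "cuboid") {
      lo <- e@params$center - e@params$size / 2
      hi <- e@params$center + e@params$size / 2
      list(shape = 0L, material = mi, params = c(lo, hi))
    } else if (e@shape == "ellipsoid") {
      list(shape = 1L, material = mi,
           params = c(e@params$center, e@params$semi_axes))
    } else {
      list(shape = 2L, material = mi, params = numeric(6),
           vertices = e@mesh@vertices,
           faces = e@mesh@faces - 1L)
    }
  })
  ext <- scn@grid@extent
  list(domain = c(ext[, 1], ext[, 2]),
       materials = unname(M),
       ambient = match(scn@ambient, matNames),
       entities = ents,
       material_names = matNames)
}

# triangle soup of the source fan as an nT x 9 matrix (v0, v1, v2)
sourceTriangles <- function(src) {
  v <- src@mesh@vertices
  f <- src@mesh@faces
  cbind(v[f[, 1], , drop = FALSE], v[f[, 2], , drop = FALSE],
        v[f[, 3], , drop = FALSE])
}

#' Per-voxel material map
#'
#' Material name at each voxel centre of a grid.
#'
#' @param scn a [Scene-class].
#' @param grid a [VoxelGrid-class] (default: the scene's grid).
#' @return integer array (dim = n_cells) of indices into
#'   `names(scn@materials)`, with the names attached as attribute
#'   "materials".
#' @export
materialGrid <- function(scn, grid = scn@grid) {
  fs <- flattenScene(scn)
  fs$domain <- c(grid@extent[, 1], grid@extent[, 2])
  idx <- classifyGridC(fs, grid@n_cells)
  arr <- array(idx, dim = grid@n_cells)
  attr(arr, "materials") <- fs$material_names
  arr
}

#' Logical mask of voxels inside an entity
#'
#' @param e an [Entity-class].
#' @param grid a [VoxelGrid-class].
#' @return logical array over voxel centres.
#' @export
entityMask <- function(e, grid) {
  cx <- voxelCenters(grid, 1)
  cy <- voxelCenters(grid, 2)
  cz <- voxelCenters(grid, 3)
  n <- grid@n_cells
  if (e@shape == "ellipsoid") {
    c0 <- e@params$center; s <- e@params$semi_axes
    ux <- ((cx - c0[1]) / s[1])^2
    uy <- ((cy - c0[2]) / s[2])^2
    uz <- ((cz - c0[3]) / s[3])^2
    outer(outer(ux, uy, "+"), uz, "+") <= 1
  } else if (e@shape == "cuboid") {
    c0 <- e@params$center; h <- e@params$size / 2
    mx <- abs(cx - c0[1]) <= h[1]
    my <- abs(cy - c0[2]) <= h[2]
    mz <- abs(cz - c0[3]) <= h[3]
    outer(outer(mx, my, "&"), mz, "&")
  } else {
    pts <- as.matrix(expand.grid(cx, cy, cz))
    array(insideMeshC(e@mesh@vertices, e@mesh@faces - 1L, pts), dim = n)
  }
}
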