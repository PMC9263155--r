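# Incremental (Bowyer-Watson) 3D Delaunay triangulation of the necrotic
# point cloud, convex-hull extraction, and voxelization of the hull
# interior.
#
# Robustness: voxel-grid point clouds are massively cospherical, so a
# deterministic tiny jitter (fixed internal seed, ~1e-8 of the cloud
# extent) is added before triangulation — a reproducible symbolic
# perturbation that leaves the voxelized hull unchanged at any realistic
# spacing.

# circumcenters and squared radii of tetrahedra (rows of verts index matrix)
circumSpheres <- function(V, tets) {
  a <- V[tets[, 1], , drop = FALSE]
  u <- V[tets[, 2], , drop = FALSE] - a
  v <- V[tets[, 3], , drop = FALSE] - a
  w <- V[tets[, 4], , drop = FALSE] - a
  cross <- function(p, q) cbind(p[, 2] * q[, 3] - p[, 3] * q[, 2],
                                p[, 3] * q[, 1] - p[, 1] * q[, 3],
                                p[, 1] * q[, 2] - p[, 2] * q[, 1])
  vxw <- cross(v, w); wxu <- cross(w, u); uxv <- cross(u, v)
  den <- 2 * rowSums(u * vxw)
  num <- rowSums(u * u) * vxw + rowSums(v * v) * wxu + rowSums(w * w) * uxv
  cc <- a + num / den
  r2 <- rowSums((cc - a)^2)
  bad <- !is.finite(den) | abs(den) < 1e-300
  r2[bad] <- Inf
  list(center = cc, r2 = r2)
}

#' Incremental Bowyer-Watson 3D Delaunay triangulation
#'
#' Starts from an enclosing super-tetrahedron and inserts points one at a
#' time: all tetrahedra whose circumsphere contains the new point are
#' identified and carved out, the polygonal cavity is re-triangulated by
#' fanning its boundary faces to the new point, and finally every cell
#' sharing a super-tetrahedron vertex is removed. The result satisfies the
#' empty-circumsphere property; its boundary faces form the convex hull of
#' the input points.
#'
#' @param points n x 3 matrix, n >= 4, not all coplanar.
#' @param jitter relative magnitude of the deterministic symbolic
#'   perturbation (default 1e-6 of the cloud extent; 0 disables it).
#' @return a [TetMesh-class] (vertices are the original, unjittered points).
#' @export
delaunay3d <- function(points, jitter = 1e-6) {
  P <- rbind(points)
  storage.mode(P) <- "double"
  n <- nrow(P)
  if (n < 4L) stop("delaunay3d requires >= 4 points; handle lower-dimensional input in 2D")
  ctr <- colMeans(P)
  if (qr(sweep(P, 2, ctr), tol = 1e-10)$rank < 3L)
    stop("points are coplanar; handle lower-dimensional input in 2D")
  scale <- max(apply(P, 2, function(c) diff(range(c))), 1)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(20571L)
  ord <- sample.int(n)   # randomized insertion order (deterministic)
  Pj <- P
  if (jitter > 0)
    Pj <- P + matrix(stats::runif(3 * n, -1, 1), n, 3) * jitter * scale
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  # super-tetrahedron comfortably enclosing the cloud
  m <- 10 * scale
  super <- rbind(ctr + c(0, 0, 3 * m),
                 ctr + c(-2 * m, -m, -m),
                 ctr + c(2 * m, -m, -m),
                 ctr + c(0, 2 * m, -m))
  V <- rbind(super, Pj)
  tets <- matrix(1:4, 1, 4)
  cs <- circumSpheres(V, tets)
  cc <- cs$center; r2 <- cs$r2
  baryInside <- function(tetRows, p) {
    # smallest barycentric coordinate of p in each tet (vectorized)
    a <- V[tetRows[, 1], , drop = FALSE]; b <- V[tetRows[, 2], , drop = FALSE]
    c3 <- V[tetRows[, 3], , drop = FALSE]; d4 <- V[tetRows[, 4], , drop = FALSE]
    det4 <- function(p1, p2, p3, p4) {
      u <- p2 - p1; v <- p3 - p1; w <- p4 - p1
      u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
      u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
      u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])
    }
    pm <- matrix(p, nrow(tetRows), 3, byrow = TRUE)
    d0 <- det4(a, b, c3, d4)
    l1 <- det4(pm, b, c3, d4) / d0
    l2 <- det4(a, pm, c3, d4) / d0
    l3 <- det4(a, b, pm, d4) / d0
    l4 <- det4(a, b, c3, pm) / d0
    pmin(pmin(l1, l2), pmin(l3, l4))
  }
  for (ip in ord) {
    p <- V[4L + ip, ]
    d2 <- (cc[, 1] - p[1])^2 + (cc[, 2] - p[2])^2 + (cc[, 3] - p[3])^2
    bad <- which(d2 < r2 * (1 + 1e-12))
    if (!length(bad))  # numeric safety net: the containing tet always counts
      bad <- which.max(baryInside(tets, p))
    # keep only the face-connected cavity component containing p: guards
    # against spurious members from the huge circumspheres of slivers
    mb <- baryInside(tets[bad, , drop = FALSE], p)
    seedTet <- which.max(mb)
    if (length(bad) > 1L) {
      bFaces <- rbind(tets[bad, c(1, 2, 3), drop = FALSE],
                      tets[bad, c(1, 2, 4), drop = FALSE],
                      tets[bad, c(1, 3, 4), drop = FALSE],
                      tets[bad, c(2, 3, 4), drop = FALSE])
      bFaces <- sort3(bFaces)
      fkey <- faceKey(bFaces, n + 4L)
      owner <- rep(seq_along(bad), times = 4L)
      grp <- split(owner, fkey)
      reach <- logical(length(bad)); reach[seedTet] <- TRUE
      queue <- seedTet
      adj <- lapply(seq_along(bad), function(i) integer(0))
      for (g in grp) if (length(g) == 2L) {
        adj[[g[1]]] <- c(adj[[g[1]]], g[2])
        adj[[g[2]]] <- c(adj[[g[2]]], g[1])
      }
      while (length(queue)) {
        i <- queue[[1]]; queue <- queue[-1]
        nb <- adj[[i]][!reach[adj[[i]]]]
        reach[nb] <- TRUE
        queue <- c(queue, nb)
      }
      bad <- bad[reach]
    }
    faces <- rbind(tets[bad, c(1, 2, 3), drop = FALSE],
                   tets[bad, c(1, 2, 4), drop = FALSE],
                   tets[bad, c(1, 3, 4), drop = FALSE],
                   tets[bad, c(2, 3, 4), drop = FALSE])
    faces <- sort3(faces)
    key <- faceKey(faces, n + 4L)
    once <- !(duplicated(key) | duplicated(key, fromLast = TRUE))
    cavity <- faces[once, , drop = FALSE]
    newTets <- cbind(cavity, 4L + ip)
    ncs <- circumSpheres(V, newTets)
    keepT <- setdiff(seq_len(nrow(tets)), bad)
    tets <- rbind(tets[keepT, , drop = FALSE], newTets)
    cc <- rbind(cc[keepT, , drop = FALSE], ncs$center)
    r2 <- c(r2[keepT], ncs$r2)
  }
  real <- rowSums(tets <= 4L) == 0
  tets <- tets[real, , drop = FALSE] - 4L
  bf <- boundaryFacesOf(tets)
  new("TetMesh", vertices = P, tetrahedra = tets, boundaryFaces = bf)
}

# row-wise sort of 3-column index matrices (vectorized)
sort3 <- function(f) {
  lo <- pmin(f[, 1], f[, 2], f[, 3])
  hi <- pmax(f[, 1], f[, 2], f[, 3])
  mid <- f[, 1] + f[, 2] + f[, 3] - lo - hi
  cbind(lo, mid, hi)
}

faceKey <- function(sortedFaces, nv) {
  (sortedFaces[, 1] * (nv + 1) + sortedFaces[, 2]) * (nv + 1) +
    sortedFaces[, 3]
}

# faces (sorted triples) occurring exactly once among the tetrahedra
boundaryFacesOf <- function(tets) {
  if (!nrow(tets)) return(matrix(integer(), 0, 3))
  faces <- rbind(tets[, c(1, 2, 3), drop = FALSE],
                 tets[, c(1, 2, 4), drop = FALSE],
                 tets[, c(1, 3, 4), drop = FALSE],
                 tets[, c(2, 3, 4), drop = FALSE])
  faces <- sort3(faces)
  key <- faceKey(faces, max(faces))
  once <- !(duplicated(key) | duplicated(key, fromLast = TRUE))
  faces[once, , drop = FALSE]
}

#' Total volume of a tetrahedral mesh
#'
#' @param mesh a [TetMesh-class].
#' @return volume in mm^3.
#' @export
meshVolume <- function(mesh) {
  V <- mesh@vertices; tt <- mesh@tetrahedra
  if (!nrow(tt)) return(0)
  a <- V[tt[, 1], , drop = FALSE]
  u <- V[tt[, 2], , drop = FALSE] - a
  v <- V[tt[, 3], , drop = FALSE] - a
  w <- V[tt[, 4], , drop = FALSE] - a
  det3 <- u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
          u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
          u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])
  sum(abs(det3)) / 6
}

#' World-coordinate point cloud of necrotic voxels
#'
#' Maps every necrotic pixel of the accepted oriented masks to world
#' coordinates; duplicate points on the shared axis column are removed.
#' With `contourOnly = TRUE` (default) only mask-boundary pixels are kept —
#' an exact optimization for convex-hull purposes, since interior points
#' can never contribute to the hull.
#'
#' @param masks list of binary [OrientedSlice-class] masks.
#' @param axis an [ApplicatorAxis-class].
#' @param contourOnly drop pixels whose 4-neighborhood is fully necrotic.
#' @return m x 3 matrix of world mm points.
#' @export
necroticPointCloud <- function(masks, axis, contourOnly = TRUE) {
  pts <- matrix(numeric(), 0, 3)
  for (s in masks) {
    m <- s@pixels != 0
    if (!any(m)) next
    keep <- m
    if (contourOnly) {
      pad <- rbind(FALSE, cbind(FALSE, m, FALSE), FALSE)
      nr <- nrow(m)
      inner <- pad[2:(nr + 1), 2:(ncol(m) + 1)] &
        pad[1:nr, 2:(ncol(m) + 1)] & pad[3:(nr + 2), 2:(ncol(m) + 1)] &
        pad[2:(nr + 1), 1:ncol(m)] & pad[2:(nr + 1), 3:(ncol(m) + 2)]
      keep <- m & !inner
    }
    idx <- which(keep, arr.ind = TRUE)
    pts <- rbind(pts, sliceToWorld(s, idx, axis))
  }
  unique(round(pts, 9))
}

#' Voxelize the convex hull of a tetrahedral mesh
#'
#' The boundary faces of the union of Delaunay tetrahedra form the convex
#' hull of the input cloud; a voxel is marked necrotic iff its center lies
#' inside or on the hull (half-space test against every face plane, with a
#' tolerance absorbing the symbolic perturbation).
#'
#' @param mesh a [TetMesh-class] from [delaunay3d()].
#' @param grid target [VoxelGrid-class] geometry.
#' @param tol inclusion tolerance in mm (default 1e-3: far above the
#'   symbolic perturbation, far below any voxel size).
#' @return binary VoxelGrid.
#' @export
hullAndFill <- function(mesh, grid, tol = 1e-3) {
  d <- gridDim(grid)
  vals <- array(0, dim = d)
  if (!nrow(mesh@boundaryFaces))
    return(withGridValues(grid, vals))
  V <- mesh@vertices
  inner <- colMeans(V)
  axes <- gridAxes(grid)
  # restrict to the hull bounding box
  xi <- which(axes$x >= min(V[, 1]) - tol & axes$x <= max(V[, 1]) + tol)
  yi <- which(axes$y >= min(V[, 2]) - tol & axes$y <= max(V[, 2]) + tol)
  zi <- which(axes$z >= min(V[, 3]) - tol & axes$z <= max(V[, 3]) + tol)
  if (!length(xi) || !length(yi) || !length(zi))
    return(withGridValues(grid, vals))
  q <- cbind(rep(axes$x[xi], times = length(yi) * length(zi)),
             rep(rep(axes$y[yi], each = length(xi)), times = length(zi)),
             rep(axes$z[zi], each = length(xi) * length(yi)))
  inside <- rep(TRUE, nrow(q))
  for (f in seq_len(nrow(mesh@boundaryFaces))) {
    tri <- mesh@boundaryFaces[f, ]
    a <- V[tri[1], ]; b <- V[tri[2], ]; cpt <- V[tri[3], ]
    nrm <- c((b[2] - a[2]) * (cpt[3] - a[3]) - (b[3] - a[3]) * (cpt[2] - a[2]),
             (b[3] - a[3]) * (cpt[1] - a[1]) - (b[1] - a[1]) * (cpt[3] - a[3]),
             (b[1] - a[1]) * (cpt[2] - a[2]) - (b[2] - a[2]) * (cpt[1] - a[1]))
    if (sum(nrm * (inner - a)) > 0) nrm <- -nrm     # make outward
    nn <- sqrt(sum(nrm^2))
    if (nn < 1e-300) next
    nrm <- nrm / nn
    inside <- inside &
      ((q[, 1] - a[1]) * nrm[1] + (q[, 2] - a[2]) * nrm[2] +
       (q[, 3] - a[3]) * nrm[3] <= tol)
    if (!any(inside)) break
  }
  sub <- array(0, dim = c(length(xi), length(yi), length(zi)))
  sub[inside] <- 1
  vals[xi, yi, zi] <- sub
  withGridValues(grid, vals)
}

#' Delaunay convex-hull reconstruction of the necrosis volume
#'
#' Point cloud from the accepted masks, Bowyer-Watson triangulation, hull
#' voxelization. By construction the result is convex: any deformation of
#' the necrosis (for example by a heat-sink vessel) is bridged over.
#'
#' @inheritParams necroticPointCloud
#' @param grid target [VoxelGrid-class] geometry.
#' @return binary VoxelGrid (empty when the cloud is degenerate).
#' @export
delaunayReconstruct <- function(masks, axis, grid, contourOnly = TRUE) {
  pts <- necroticPointCloud(masks, axis, contourOnly)
  if (nrow(pts) < 4L)
    return(withGridValues(grid, array(0, dim = gridDim(grid))))
  mesh <- tryCatch(delaunay3d(pts), error = function(e) NULL)
  if (is.null(mesh))
    return(withGridValues(grid, array(0, dim = gridDim(grid))))
  hullAndFill(mesh, grid)
}
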