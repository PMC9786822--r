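# 3D shape features. Surface area and mesh volume come from a triangulated
# iso-surface of the mask indicator at the 0.5 level, extracted by marching
# tetrahedra (each grid cube split into six tetrahedra; within a tetrahedron
# the field is linear, so the iso-surface is a planar cut and both the cut
# triangles and the clipped inside volume are exact). The binary indicator is
# first Gaussian-smoothed (sigma = 0.8 voxels by default) so the mesh tracks
# the underlying smooth boundary instead of the voxel staircase, which would
# otherwise bias the surface area upward by ~9% on spheres.

# corner offsets of a grid cube, and a 6-tetrahedron decomposition
.CUBE_CORNERS <- matrix(c(0,0,0, 1,0,0, 1,1,0, 0,1,0,
                          0,0,1, 1,0,1, 1,1,1, 0,1,1),
                        ncol = 3, byrow = TRUE)
.CUBE_TETS <- matrix(c(1,6,2,7, 1,2,3,7, 1,3,4,7,
                       1,4,8,7, 1,8,5,7, 1,5,6,7), ncol = 4, byrow = TRUE)

.tri_area <- function(p1, p2, p3) {
  u <- p2 - p1; v <- p3 - p1
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  0.5 * sqrt(sum(cr^2))
}

.tet_volume <- function(v) {
  abs(det(rbind(v[2, ] - v[1, ], v[3, ] - v[1, ], v[4, ] - v[1, ]))) / 6
}

# vectorised geometry helpers on N x 3 point matrices
.cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}
.tri_areas <- function(p1, p2, p3) {
  cr <- .cross3(p2 - p1, p3 - p1)
  0.5 * sqrt(rowSums(cr^2))
}
.tet_volumes <- function(a, b, c4, d4) {
  abs(rowSums((b - a) * .cross3(c4 - a, d4 - a))) / 6
}

# iso-surface area and enclosed volume of field f (3D array, physical voxel
# spacing sp) at level iso, by marching tetrahedra; vectorised over the
# mixed cubes, grouped by inside/outside case
.mesh_area_volume <- function(f, sp, iso = 0.5) {
  d <- dim(f)
  sub <- function(dx, dy, dz) {
    f[(1 + dx):(d[1] - 1 + dx), (1 + dy):(d[2] - 1 + dy), (1 + dz):(d[3] - 1 + dz)]
  }
  corner_vals <- lapply(seq_len(8), function(c8) {
    o <- .CUBE_CORNERS[c8, ]; sub(o[1], o[2], o[3])
  })
  cmax <- Reduce(pmax, corner_vals)
  cmin <- Reduce(pmin, corner_vals)
  mixed <- which(cmax >= iso & cmin < iso)
  area <- 0
  volume <- sum(cmin >= iso) * prod(sp)   # fully-inside cubes
  if (length(mixed) == 0) return(list(area = area, volume = volume))
  cubes <- coords_of(mixed, pmax(d - 1L, 1L))
  vals8 <- vapply(corner_vals, function(v) v[mixed], numeric(length(mixed)))
  if (is.null(dim(vals8))) vals8 <- matrix(vals8, nrow = 1)
  base <- (cubes - 1) * rep(sp, each = nrow(cubes))
  corn_phys <- .CUBE_CORNERS * rep(sp, each = 8)
  nmix <- nrow(cubes)
  # expand to 6 tets per cube
  for (t in seq_len(6)) {
    tv <- .CUBE_TETS[t, ]
    fv <- vals8[, tv, drop = FALSE]                 # nmix x 4
    inside <- fv >= iso
    ni <- rowSums(inside)
    verts <- lapply(1:4, function(k) base + rep(corn_phys[tv[k], ], each = nmix))
    tetv <- prod(sp) / 6
    volume <- volume + sum(ni == 4) * tetv
    ipts <- function(rows, a, b) {
      # interpolation point on edge a-b for the selected rows
      tt <- (iso - fv[rows, a]) / (fv[rows, b] - fv[rows, a])
      verts[[a]][rows, , drop = FALSE] +
        tt * (verts[[b]][rows, , drop = FALSE] - verts[[a]][rows, , drop = FALSE])
    }
    # ni == 1: one inside vertex a (4 subcases)
    for (a in 1:4) {
      rows <- which(ni == 1 & inside[, a])
      if (length(rows) == 0) next
      outs <- setdiff(1:4, a)
      p1 <- ipts(rows, a, outs[1]); p2 <- ipts(rows, a, outs[2]); p3 <- ipts(rows, a, outs[3])
      area <- area + sum(.tri_areas(p1, p2, p3))
      tfrac <- (iso - fv[rows, a])^3 /
        ((fv[rows, outs[1]] - fv[rows, a]) * (fv[rows, outs[2]] - fv[rows, a]) *
         (fv[rows, outs[3]] - fv[rows, a]))
      volume <- volume + tetv * sum(tfrac)
    }
    # ni == 3: one outside vertex o (4 subcases)
    for (o in 1:4) {
      rows <- which(ni == 3 & !inside[, o])
      if (length(rows) == 0) next
      ins <- setdiff(1:4, o)
      p1 <- ipts(rows, ins[1], o); p2 <- ipts(rows, ins[2], o); p3 <- ipts(rows, ins[3], o)
      area <- area + sum(.tri_areas(p1, p2, p3))
      sfrac <- (iso - fv[rows, o])^3 /
        ((fv[rows, ins[1]] - fv[rows, o]) * (fv[rows, ins[2]] - fv[rows, o]) *
         (fv[rows, ins[3]] - fv[rows, o]))
      volume <- volume + tetv * sum(1 - sfrac)
    }
    # ni == 2: inside pair (a, b), outside (c, d) (6 subcases)
    pairs <- rbind(c(1,2), c(1,3), c(1,4), c(2,3), c(2,4), c(3,4))
    for (pr in seq_len(6)) {
      a <- pairs[pr, 1]; b <- pairs[pr, 2]
      rows <- which(ni == 2 & inside[, a] & inside[, b])
      if (length(rows) == 0) next
      od <- setdiff(1:4, c(a, b)); cc <- od[1]; dd <- od[2]
      pac <- ipts(rows, a, cc); pad <- ipts(rows, a, dd)
      pbc <- ipts(rows, b, cc); pbd <- ipts(rows, b, dd)
      area <- area + sum(.tri_areas(pac, pad, pbd)) + sum(.tri_areas(pac, pbd, pbc))
      va <- verts[[a]][rows, , drop = FALSE]; vb <- verts[[b]][rows, , drop = FALSE]
      # inside wedge = prism (a, pac, pad) -- (b, pbc, pbd), three tets
      volume <- volume + sum(.tet_volumes(va, pac, pad, vb)) +
        sum(.tet_volumes(pac, pad, vb, pbc)) +
        sum(.tet_volumes(pad, vb, pbc, pbd))
    }
  }
  list(area = area, volume = volume)
}

.max_pairwise <- function(pts) {
  if (nrow(pts) < 2) return(0)
  # work on the convex hull footprint via range pruning when large
  if (nrow(pts) > 1500) {
    keep <- unique(unlist(lapply(1:3, function(k) {
      c(which.min(pts[, k]), which.max(pts[, k]))
    })))
    # coarse prune: keep extreme shell by distance from centroid
    ctr <- colMeans(pts)
    dc <- sqrt(rowSums((pts - rep(ctr, each = nrow(pts)))^2))
    keep <- union(keep, which(dc >= stats::quantile(dc, 1 - 1500 / nrow(pts))))
    pts <- pts[keep, , drop = FALSE]
  }
  max(stats::dist(pts))
}

#' 3D shape features (14 features)
#'
#' Mesh-based surface area, volume and sphericity, maximum diameters, and
#' principal-axis lengths of the lesion mask. Axis lengths are four times the
#' square roots of the principal eigenvalues of the voxel-coordinate
#' covariance; with fewer than 3 non-collinear voxels the degenerate
#' eigenvalues are 0 and `Elongation`/`Flatness` fall back to 0.
#'
#' @param mask an [roi_mask] (nonempty)
#' @param spacing voxel spacing override (mm); defaults to the mask's
#' @param mesh_sigma Gaussian sd (voxels) for indicator anti-aliasing
#' @return named numeric vector of 14 features
#' @export
shape3d_features <- function(mask, spacing = NULL, mesh_sigma = 0.8) {
  stopifnot(inherits(mask, "roi_mask"))
  sp <- spacing %||% mask$spacing
  idx <- which(mask$data == 1)
  if (length(idx) == 0) stop("mask is empty")
  d <- dim(mask$data)
  coords <- coords_of(idx, d)
  n <- length(idx)

  if (n == 1) {
    # voxel-cube boundary fallback
    a <- 2 * (sp[1] * sp[2] + sp[1] * sp[3] + sp[2] * sp[3])
    v <- prod(sp)
    return(c(MeshVolume = v, VoxelVolume = v, SurfaceArea = a,
             SurfaceVolumeRatio = a / v,
             Sphericity = (36 * pi * v^2)^(1 / 3) / a,
             Maximum3DDiameter = 0, Maximum2DDiameterSlice = 0,
             Maximum2DDiameterColumn = 0, Maximum2DDiameterRow = 0,
             MajorAxisLength = 0, MinorAxisLength = 0, LeastAxisLength = 0,
             Elongation = 0, Flatness = 0))
  }

  # crop to bounding box with margin for meshing
  pad <- max(3L, ceiling(3 * mesh_sigma))
  lo <- pmax(apply(coords, 2, min) - pad, 1L)
  hi <- pmin(apply(coords, 2, max) + pad, d)
  sub <- mask$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  subf <- array(as.numeric(sub), dim(sub))
  # zero-pad so the iso-surface always closes
  pd <- dim(subf) + 2L * pad
  fpad <- array(0, pd)
  fpad[pad + seq_len(dim(subf)[1]), pad + seq_len(dim(subf)[2]),
       pad + seq_len(dim(subf)[3])] <- subf
  fsm <- if (mesh_sigma > 0) gauss_smooth3d(fpad, mesh_sigma) else fpad
  # guard: heavy smoothing of tiny masks can push the whole field under the
  # iso level; fall back to the raw indicator
  if (max(fsm) < 0.5) fsm <- fpad
  mv <- .mesh_area_volume(fsm, sp, iso = 0.5)
  surface_area <- mv$area
  mesh_volume <- mv$volume

  voxel_volume <- n * prod(sp)
  sphericity <- if (surface_area > 0) {
    (36 * pi * mesh_volume^2)^(1 / 3) / surface_area
  } else 0

  phys <- coords * rep(sp, each = n)
  # boundary voxels: any of the 6 face neighbours missing
  inmask <- logical(prod(d)); inmask[idx] <- TRUE
  face_offs <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  nb_count <- rep(0L, n)
  for (r in seq_len(6)) {
    nbi <- shift_index(coords, face_offs[r, ], d)
    nb_count <- nb_count + (!is.na(nbi) & inmask[pmax(nbi, 1L)])
  }
  bnd <- phys[nb_count < 6L, , drop = FALSE]
  if (nrow(bnd) == 0) bnd <- phys
  max3d <- .max_pairwise(bnd)
  max_in_plane <- function(drop_axis) {
    planes <- split.data.frame(bnd, bnd[, drop_axis])
    m <- vapply(planes, function(pp) {
      .max_pairwise(pp[, setdiff(1:3, drop_axis), drop = FALSE])
    }, numeric(1))
    if (length(m) == 0) 0 else max(m)
  }
  max2d_slice <- max_in_plane(3)   # in-plane (x, y), per axial slice
  max2d_col <- max_in_plane(2)     # (x, z), per coronal plane
  max2d_row <- max_in_plane(1)     # (y, z), per sagittal plane

  ev <- if (n >= 2) {
    cm <- stats::cov(phys) * (n - 1) / n
    pmax(eigen(cm, symmetric = TRUE, only.values = TRUE)$values, 0)
  } else c(0, 0, 0)
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2]); least <- 4 * sqrt(ev[3])
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0
  flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0

  c(MeshVolume = mesh_volume,
    VoxelVolume = voxel_volume,
    SurfaceArea = surface_area,
    SurfaceVolumeRatio = surface_area / max(mesh_volume, 1e-12),
    Sphericity = sphericity,
    Maximum3DDiameter = max3d,
    Maximum2DDiameterSlice = max2d_slice,
    Maximum2DDiameterColumn = max2d_col,
    Maximum2DDiameterRow = max2d_row,
    MajorAxisLength = major,
    MinorAxisLength = minor,
    LeastAxisLength = least,
    Elongation = elong,
    Flatness = flat)
}
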