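# Shared low-level helpers: float32 rounding, neighbourhood offsets,
# 26-connected component labelling, seeded sub-streams.

#' Round doubles to the nearest single-precision float
#'
#' Gradient-boosted tree libraries store split thresholds and compare feature
#' values in single precision; reproducing their routing exactly requires
#' rounding both sides of the comparison the same way.
#'
#' @param v numeric vector
#' @return numeric vector, each element the closest float32 value
#' @keywords internal
float32 <- function(v) {
  readBin(writeBin(as.numeric(v), raw(), size = 4),
          what = "numeric", size = 4, n = length(v))
}

# The 13 unique 3D direction offsets (of the 26-neighbourhood, one per
# antipodal pair), ordered lexicographically.
unique_directions <- function() {
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- d[rowSums(abs(d)) > 0, , drop = FALSE]
  # keep one of each antipodal pair: first nonzero component positive
  keep <- apply(d, 1, function(r) {
    nz <- r[r != 0]
    nz[1] > 0
  })
  unname(d[keep, , drop = FALSE])
}

# All 26 neighbour offsets.
all_neighbour_offsets <- function() {
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  unname(d[rowSums(abs(d)) > 0, , drop = FALSE])
}

# Linear indices of in-grid voxels after shifting coordinates `coords`
# (n x 3, 1-based) by `off`; returns NA where the shift leaves the grid.
shift_index <- function(coords, off, dim3) {
  x <- coords[, 1] + off[1]
  y <- coords[, 2] + off[2]
  z <- coords[, 3] + off[3]
  ok <- x >= 1 & x <= dim3[1] & y >= 1 & y <= dim3[2] & z >= 1 & z <= dim3[3]
  idx <- rep(NA_integer_, nrow(coords))
  idx[ok] <- x[ok] + (y[ok] - 1L) * dim3[1] + (z[ok] - 1L) * dim3[1] * dim3[2]
  idx
}

coords_of <- function(idx, dim3) {
  idx0 <- idx - 1L
  x <- idx0 %% dim3[1]
  y <- (idx0 %/% dim3[1]) %% dim3[2]
  z <- idx0 %/% (dim3[1] * dim3[2])
  cbind(x + 1L, y + 1L, z + 1L)
}

#' Label 26-connected components of a set of voxels
#'
#' @param mask logical or 0/1 3D array
#' @param values optional integer array; when given, voxels are connected only
#'   when they also share the same value (used for gray-level zones)
#' @return integer array of component labels (0 outside the mask)
#' @keywords internal
label_components_26 <- function(mask, values = NULL) {
  dim3 <- dim(mask)
  idx <- which(mask != 0)
  lab <- array(0L, dim3)
  if (length(idx) == 0) return(lab)
  coords <- coords_of(idx, dim3)
  inmask <- logical(prod(dim3))
  inmask[idx] <- TRUE
  pos <- integer(prod(dim3))        # voxel linear index -> node id
  pos[idx] <- seq_along(idx)
  offs <- all_neighbour_offsets()
  # half the offsets suffice for an undirected edge list
  offs <- offs[seq_len(nrow(offs) / 2), , drop = FALSE]
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    nb <- shift_index(coords, offs[r, ], dim3)
    ok <- !is.na(nb) & inmask[pmax(nb, 1L)]
    if (!is.null(values)) ok <- ok & values[idx] == values[pmax(nb, 1L)]
    if (any(ok)) {
      from <- c(from, which(ok))
      to <- c(to, pos[nb[ok]])
    }
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

# Derive a reproducible per-unit seed from a base seed (kept within 32-bit
# signed range so it is always a valid R seed).
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 7919 + as.double(i) * 104729) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
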