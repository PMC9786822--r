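# Independent brute-force oracles. Every texture-matrix oracle enumerates
# voxels/pairs/zones directly with nested loops, sharing no code with the
# package implementations.

# all 26 neighbour offsets, and the 13 unique (one per antipodal pair)
.oracle_offsets26 <- local({
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[rowSums(abs(g)) > 0, ])
})
.oracle_offsets13 <- .oracle_offsets26[apply(.oracle_offsets26, 1, function(r) {
  nz <- r[r != 0]; nz[1] > 0
}), ]

# levels: integer array with NA outside the mask
oracle_glcm <- function(levels, off) {
  d <- dim(levels)
  Ng <- max(levels, na.rm = TRUE)
  M <- matrix(0, Ng, Ng)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    a <- levels[x, y, z]
    if (is.na(a)) next
    p <- c(x, y, z) + off
    if (any(p < 1) || any(p > d)) next
    b <- levels[p[1], p[2], p[3]]
    if (is.na(b)) next
    M[a, b] <- M[a, b] + 1
  }
  M + t(M)   # symmetrised counts
}

oracle_glrlm <- function(levels, off) {
  d <- dim(levels)
  Ng <- max(levels, na.rm = TRUE)
  runs <- list()
  seen <- array(FALSE, d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    a <- levels[x, y, z]
    if (is.na(a)) next
    # start of a run iff the previous voxel along `off` is not a same-level
    # in-mask voxel
    prev <- c(x, y, z) - off
    if (!any(prev < 1) && !any(prev > d)) {
      b <- levels[prev[1], prev[2], prev[3]]
      if (!is.na(b) && b == a) next
    }
    len <- 0
    p <- c(x, y, z)
    while (!any(p < 1) && !any(p > d) && !is.na(levels[p[1], p[2], p[3]]) &&
           levels[p[1], p[2], p[3]] == a) {
      len <- len + 1
      p <- p + off
    }
    runs[[length(runs) + 1]] <- c(a, len)
  }
  rr <- do.call(rbind, runs)
  L <- max(rr[, 2])
  M <- matrix(0, Ng, L)
  for (i in seq_len(nrow(rr))) M[rr[i, 1], rr[i, 2]] <- M[rr[i, 1], rr[i, 2]] + 1
  M
}

# flood fill over 26-connected equal-level voxels
oracle_glszm <- function(levels) {
  d <- dim(levels)
  Ng <- max(levels, na.rm = TRUE)
  visited <- array(FALSE, d)
  zones <- list()
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (visited[x, y, z] || is.na(levels[x, y, z])) next
    lv <- levels[x, y, z]
    stack <- list(c(x, y, z))
    visited[x, y, z] <- TRUE
    size <- 0
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      for (r in seq_len(nrow(.oracle_offsets26))) {
        q <- p + .oracle_offsets26[r, ]
        if (any(q < 1) || any(q > d)) next
        if (visited[q[1], q[2], q[3]]) next
        b <- levels[q[1], q[2], q[3]]
        if (is.na(b) || b != lv) next
        visited[q[1], q[2], q[3]] <- TRUE
        stack[[length(stack) + 1]] <- q
      }
    }
    zones[[length(zones) + 1]] <- c(lv, size)
  }
  zz <- do.call(rbind, zones)
  M <- matrix(0, Ng, max(zz[, 2]))
  for (i in seq_len(nrow(zz))) M[zz[i, 1], zz[i, 2]] <- M[zz[i, 1], zz[i, 2]] + 1
  M
}

oracle_ngtdm <- function(levels) {
  d <- dim(levels)
  Ng <- max(levels, na.rm = TRUE)
  n_i <- numeric(Ng); s_i <- numeric(Ng)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    a <- levels[x, y, z]
    if (is.na(a)) next
    nb <- c()
    for (r in seq_len(nrow(.oracle_offsets26))) {
      q <- c(x, y, z) + .oracle_offsets26[r, ]
      if (any(q < 1) || any(q > d)) next
      b <- levels[q[1], q[2], q[3]]
      if (!is.na(b)) nb <- c(nb, b)
    }
    if (length(nb) == 0) next
    n_i[a] <- n_i[a] + 1
    s_i[a] <- s_i[a] + abs(a - mean(nb))
  }
  list(n = n_i, s = s_i)
}

oracle_gldm <- function(levels, alpha = 0) {
  d <- dim(levels)
  Ng <- max(levels, na.rm = TRUE)
  sizes <- c()
  levs <- c()
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    a <- levels[x, y, z]
    if (is.na(a)) next
    dep <- 0
    for (r in seq_len(nrow(.oracle_offsets26))) {
      q <- c(x, y, z) + .oracle_offsets26[r, ]
      if (any(q < 1) || any(q > d)) next
      b <- levels[q[1], q[2], q[3]]
      if (!is.na(b) && abs(b - a) <= alpha) dep <- dep + 1
    }
    sizes <- c(sizes, dep + 1)
    levs <- c(levs, a)
  }
  M <- matrix(0, Ng, max(sizes))
  for (i in seq_along(sizes)) M[levs[i], sizes[i]] <- M[levs[i], sizes[i]] + 1
  M
}

# DeLong oracle: full placement matrices by all-pairs enumeration
oracle_delong <- function(scores_a, scores_b, labels) {
  ci <- which(labels == 1); cj <- which(labels == 0)
  m <- length(ci); n <- length(cj)
  psi <- function(x, y) if (x > y) 1 else if (x == y) 0.5 else 0
  comp <- function(s) {
    V10 <- numeric(m); V01 <- numeric(n)
    for (i in seq_len(m)) V10[i] <- mean(vapply(cj, function(j) psi(s[ci[i]], s[j]), 0))
    for (j in seq_len(n)) V01[j] <- mean(vapply(ci, function(i) psi(s[i], s[cj[j]]), 0))
    list(V10 = V10, V01 = V01, auc = mean(V10))
  }
  A <- comp(scores_a); B <- comp(scores_b)
  s10 <- stats::cov(cbind(A$V10, B$V10))
  s01 <- stats::cov(cbind(A$V01, B$V01))
  vd <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
        (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  z <- (A$auc - B$auc) / sqrt(vd)
  list(auc_a = A$auc, auc_b = B$auc, var_diff = vd, z = z,
       p = 2 * stats::pnorm(-abs(z)))
}

# enumerated digital ball mask {||x - c|| <= r}, unit spacing
oracle_ball_mask <- function(r, pad = 3) {
  n <- as.integer(2 * r + 1 + 2 * pad)
  ax <- seq_len(n) - (n + 1) / 2
  arr <- array(0L, c(n, n, n))
  for (x in seq_len(n)) for (y in seq_len(n)) for (z in seq_len(n)) {
    if (ax[x]^2 + ax[y]^2 + ax[z]^2 <= r^2) arr[x, y, z] <- 1L
  }
  arr
}

# random small discretised ROI (levels array with NA holes) + matching
# volume/mask pair that reproduces it through discretize()
random_small_roi <- function(seed, max_dim = 8, Ng = 4) {
  set.seed(seed)
  d <- sample(2:max_dim, 3, replace = TRUE)
  lev <- array(sample.int(Ng, prod(d), replace = TRUE), d)
  keep <- array(runif(prod(d)) < 0.7, d)
  if (!any(keep)) keep[1] <- TRUE
  lev[!keep] <- NA
  # anchor the minimum at level 1 so discretize() reproduces the levels
  lev <- lev - min(lev, na.rm = TRUE) + 1L
  lev
}

# build a discretized_roi for the package functions from a level array
disc_from_levels <- function(lev) {
  vol <- image_volume(array(ifelse(is.na(lev), 0, as.numeric(lev)), dim(lev)),
                      c(1, 1, 1), "DWI")
  msk <- roi_mask(array(as.integer(!is.na(lev)), dim(lev)), c(1, 1, 1))
  discretize(vol, msk, bin_width = 1)
}
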