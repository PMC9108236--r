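# Shared fixtures and independent oracles for the test suite.

unit_grid <- function(dim = c(20, 20, 20), spacing = c(1, 1, 1),
                      origin = c(0, 0, 0)) {
  image_volume(array(0, dim), spacing, origin)
}

mask_on <- function(grid, idx = NULL) {
  m <- array(FALSE, dim(grid$data))
  if (!is.null(idx)) m[idx] <- TRUE
  binary_structure(m, grid, label = "test")
}

cube_structure <- function(grid, from, to) {
  m <- array(FALSE, dim(grid$data))
  m[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- TRUE
  binary_structure(m, grid, label = "cube")
}

random_structure <- function(grid, p = 0.1, seed = 1) {
  set.seed(seed)
  d <- dim(grid$data)
  binary_structure(array(runif(prod(d)) < p, d), grid, label = "random")
}

# random blob-like mask: a few random spheres, more surface-like than
# salt-and-pepper noise
random_blobs <- function(grid, n_blobs = 3, r_range = c(2, 5), seed = 1) {
  set.seed(seed)
  d <- dim(grid$data)
  g <- gdmrt:::grid_of(grid)
  X <- cbind(rep(seq_len(d[1]), times = d[2] * d[3]),
             rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
             rep(seq_len(d[3]), each = d[1] * d[2]))
  Xmm <- sweep((X - 1) %*% diag(g$spacing), 2, g$origin, "+")
  m <- rep(FALSE, prod(d))
  ext <- (d - 1) * g$spacing
  for (i in seq_len(n_blobs)) {
    ctr <- g$origin + runif(3, 0.25, 0.75) * ext
    r <- runif(1, r_range[1], r_range[2])
    m <- m | (rowSums(sweep(Xmm, 2, ctr)^2) <= r^2)
  }
  binary_structure(array(m, d), grid, label = "blobs")
}

# ---- independent oracles ------------------------------------------------

# boundary voxels found by explicit neighbour lookup in linear index space
oracle_boundary <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  ai <- arrayInd(idx, d)
  on_bnd <- rep(FALSE, length(idx))
  for (k in 1:3) for (s in c(-1L, 1L)) {
    nb <- ai
    nb[, k] <- nb[, k] + s
    outside <- nb[, k] < 1L | nb[, k] > d[k]
    lin <- 1L + (nb[, 1] - 1L) + d[1] * ((nb[, 2] - 1L) + d[2] * (nb[, 3] - 1L))
    lin[outside] <- NA_integer_
    val <- rep(FALSE, length(idx))
    val[!outside] <- mask[lin[!outside]]
    on_bnd <- on_bnd | !val
  }
  out <- array(FALSE, d)
  out[idx[on_bnd]] <- TRUE
  out
}

# all-pairs symmetric average boundary distance (O(n^2))
oracle_h_ave <- function(a, b) {
  g <- gdmrt:::grid_of(a)
  pa <- (which(oracle_boundary(a$mask), arr.ind = TRUE) - 1) %*% diag(g$spacing)
  pb <- (which(oracle_boundary(b$mask), arr.ind = TRUE) - 1) %*% diag(g$spacing)
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  d2[d2 < 0] <- 0
  dmat <- sqrt(d2)
  0.5 * (mean(apply(dmat, 1, min)) + mean(apply(dmat, 2, min)))
}

oracle_dice <- function(a, b) {
  ia <- which(a$mask); ib <- which(b$mask)
  2 * length(intersect(ia, ib)) / (length(ia) + length(ib))
}

# brute-force box Minkowski sum: OR over every voxel offset of the
# outward-voxelized kernel
oracle_box_expand <- function(s, margin) {
  sp <- s$spacing
  cv <- function(mm, pitch) ceiling(mm / pitch - 0.1)
  neg <- c(cv(margin$right, sp[1]), cv(margin$anterior, sp[2]),
           cv(margin$inferior, sp[3]))
  pos <- c(cv(margin$left, sp[1]), cv(margin$posterior, sp[2]),
           cv(margin$superior, sp[3]))
  d <- dim(s$mask)
  out <- array(FALSE, d)
  idx <- which(s$mask, arr.ind = TRUE)
  for (ox in -neg[1]:pos[1]) for (oy in -neg[2]:pos[2]) for (oz in -neg[3]:pos[3]) {
    sh <- idx
    sh[, 1] <- sh[, 1] + ox; sh[, 2] <- sh[, 2] + oy; sh[, 3] <- sh[, 3] + oz
    keep <- sh[, 1] >= 1 & sh[, 1] <= d[1] & sh[, 2] >= 1 & sh[, 2] <= d[2] &
      sh[, 3] >= 1 & sh[, 3] <= d[3]
    out[sh[keep, , drop = FALSE]] <- TRUE
  }
  out
}

# brute-force isotropic expansion: voxel kept iff min distance to any mask
# voxel centre is <= r
oracle_iso_expand <- function(s, r_mm) {
  g <- gdmrt:::grid_of(s)
  d <- dim(s$mask)
  P <- (which(s$mask, arr.ind = TRUE) - 1) %*% diag(g$spacing)
  X <- (which(array(TRUE, d), arr.ind = TRUE) - 1) %*% diag(g$spacing)
  out <- logical(nrow(X))
  chunk <- 4096L
  for (i0 in seq(1L, nrow(X), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nrow(X))
    d2 <- outer(rowSums(X[i0:i1, , drop = FALSE]^2), rowSums(P^2), "+") -
      2 * X[i0:i1, , drop = FALSE] %*% t(P)
    out[i0:i1] <- apply(d2, 1, min) <= r_mm^2 + 1e-9
  }
  array(out, d)
}

# ---- cached phantom pipeline runs (shared across test files) ------------

.phantom_cache <- new.env(parent = emptyenv())

phantom_run <- function(seed, noise_sd = 20) {
  key <- sprintf("s%d_n%g", seed, noise_sd)
  if (!is.null(.phantom_cache[[key]])) return(.phantom_cache[[key]])
  ph <- generate_series(phantom_spec(seed = seed, noise_sd = noise_sd))
  reg <- suppressWarnings(register_study(ph))
  targets <- build_target_set(ph$study$ctv, reg$vectors, iso_margin_mm = 2)
  run <- list(ph = ph, reg = reg, targets = targets)
  .phantom_cache[[key]] <- run
  run
}

contains <- function(outer, inner) !any(inner$mask & !outer$mask)
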