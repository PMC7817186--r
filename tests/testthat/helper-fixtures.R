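# Shared fixtures, all built in code.

# single sphere in a cube grid
single_sphere_spec <- function(grid = 48L, radius_vox = 10, pitch = 218.5,
                               ri = 1.360) {
  phantom_spec(
    shape = rep(grid, 3L), pitch = pitch,
    effector = phantom_cell(center = c(0, 0, 0), radius = radius_vox * pitch,
                            cyto_ri = ri, core_radius = 0),
    target = phantom_cell(center = c(grid * pitch * 0.4, 0, 0), radius = 0,
                          cyto_ri = ri))
}

# two equal spheres touching/overlapping along a given axis
equal_spheres_spec <- function(grid = 48L, radius = 1850, sep_frac = 0.97,
                               axis = c(1, 0, 0), pitch = 218.5,
                               ri = c(1.360, 1.360), seed = 1L) {
  u <- axis / sqrt(sum(axis^2))
  s <- 2 * radius * sep_frac
  phantom_spec(
    shape = rep(grid, 3L), pitch = pitch,
    effector = phantom_cell(center = -u * s / 2, radius = radius,
                            cyto_ri = ri[1], core_radius = 0),
    target = phantom_cell(center = u * s / 2, radius = radius,
                          cyto_ri = ri[2], core_radius = 0),
    seed = seed)
}

# random blob mask (union of a few random balls)
random_blob <- function(dm, n_balls = 3L, seed = 1L) {
  set.seed(seed)
  m <- array(FALSE, dm)
  idx <- arrayInd(seq_len(prod(dm)), dm)
  for (b in seq_len(n_balls)) {
    ctr <- runif(3, 2, dm - 1)
    r <- runif(1, 1.5, max(2, min(dm) / 3))
    d2 <- (idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2 +
      (idx[, 3] - ctr[3])^2
    m[d2 <= r^2] <- TRUE
  }
  m
}

# exhaustive nearest-background-voxel distance (oracle for the EDT)
brute_force_edt <- function(mask) {
  dm <- dim(mask)
  out <- array(0, dm)
  bg <- arrayInd(which(!mask), dm)
  if (nrow(bg) == 0L) {
    out[mask] <- Inf
    return(out)
  }
  for (v in which(mask)) {
    p <- arrayInd(v, dm)
    out[v] <- sqrt(min((bg[, 1] - p[1])^2 + (bg[, 2] - p[2])^2 +
                         (bg[, 3] - p[3])^2))
  }
  out
}

# brute-force signed distance target
brute_force_signed <- function(eff, tar) {
  d <- brute_force_edt(eff | tar)
  out <- array(0, dim(eff))
  out[eff] <- d[eff]
  out[tar] <- -d[tar]
  out
}
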