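# Synthetic two-cell conjugate phantoms with exact ground truth: an RI
# volume, effector/target masks, the signed distance map, the true contact
# disc, and (for time-lapse series) per-frame kinematic state following
# saturating-hyperbola kinetics for contact area and centre-of-mass motion.

#' Specification of a two-cell conjugate phantom
#'
#' Describes two quasi-spherical cells (cytoplasm + concentric nucleus-like
#' core + optional high-RI granules) in a medium. Coordinates are nm in
#' (z, y, x) order relative to the grid centre.
#'
#' @param shape grid shape (z, y, x) in voxels.
#' @param pitch voxel size in nm (scalar or length-3).
#' @param medium_ri RI of the medium.
#' @param effector,target per-cell lists with fields `center` (nm,
#'   length 3), `radius` (nm), `cyto_ri`, `core_ri`, `core_radius` (nm),
#'   `granule_n`, `granule_radius` (nm), `granule_ri`. Missing fields take
#'   the defaults of `phantom_cell()`.
#' @param separation optional centre-to-centre distance (nm); when given,
#'   the target centre is moved along the effector-to-target axis so the
#'   centres are exactly this far apart.
#' @param antialias integer edge supersampling factor for the RI volume
#'   (1 = hard voxel-centre rasterization).
#' @param seed integer seed governing granule placement and any noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), pitch = 218.5,
                         medium_ri = 1.337,
                         effector = phantom_cell(center = c(-2650, 0, 0),
                                                 radius = 2600,
                                                 cyto_ri = 1.360),
                         target = phantom_cell(center = c(2650, 0, 0),
                                               radius = 2600,
                                               cyto_ri = 1.350),
                         separation = NULL, antialias = 1L, seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  pitch <- expand_pitch(pitch)
  cells <- list(effector = complete_cell(effector, medium_ri),
                target = complete_cell(target, medium_ri))
  if (!is.null(separation)) {
    u <- cells$target$center - cells$effector$center
    nu <- sqrt(sum(u^2))
    if (nu == 0) u <- c(1, 0, 0) else u <- u / nu
    cells$target$center <- cells$effector$center + separation * u
  }
  structure(list(shape = shape, pitch = pitch, medium_ri = medium_ri,
                 effector = cells$effector, target = cells$target,
                 antialias = as.integer(antialias), seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @param center,radius,cyto_ri,core_ri,core_radius,granule_n,granule_radius,granule_ri
#'   cell geometry and compartment RIs; see `phantom_spec()`.
#' @export
phantom_cell <- function(center = c(0, 0, 0), radius = 2600,
                         cyto_ri = 1.360, core_ri = NULL,
                         core_radius = NULL, granule_n = 0L,
                         granule_radius = 300, granule_ri = NULL) {
  list(center = as.numeric(center), radius = radius, cyto_ri = cyto_ri,
       core_ri = core_ri, core_radius = core_radius,
       granule_n = as.integer(granule_n), granule_radius = granule_radius,
       granule_ri = granule_ri)
}

complete_cell <- function(cell, medium_ri) {
  cell$core_ri <- cell$core_ri %||% (cell$cyto_ri + 0.005)
  cell$core_radius <- cell$core_radius %||% (0.5 * cell$radius)
  cell$granule_ri <- cell$granule_ri %||% (cell$cyto_ri + 0.015)
  if (cell$radius < 0) stop_istomo("radius must be >= 0",
                                   "istomo_value_error")
  if (cell$radius > 0 && cell$cyto_ri <= medium_ri)
    stop_istomo("cell RI must exceed the medium RI (positive contrast)",
                "istomo_value_error")
  cell
}

# Squared distance of every voxel centre to `center` (nm).
dist2_grid <- function(dm, pitch, center) {
  cr <- voxel_coords(dm, pitch)
  za <- (cr[[1]] - center[1])^2
  ya <- (cr[[2]] - center[2])^2
  xa <- (cr[[3]] - center[3])^2
  outer(outer(za, ya, "+"), xa, "+")
}

sample_granules <- function(cell, other, rng_state) {
  if (cell$granule_n < 1L || cell$radius <= 0) return(NULL)
  out <- matrix(0, 0, 3)
  rmax <- cell$radius - cell$granule_radius
  tries <- 0L
  while (nrow(out) < cell$granule_n && tries < 1000L) {
    tries <- tries + 1L
    p <- runif(3, -1, 1) * rmax
    if (sum(p^2) > rmax^2) next
    gpos <- cell$center + p
    # keep granules clear of the partner cell so rigid motion stays valid
    if (other$radius > 0 &&
        sum((gpos - other$center)^2) <
          (other$radius + cell$granule_radius)^2) next
    out <- rbind(out, gpos)
  }
  out
}

rasterize_conjugate <- function(spec) {
  dm <- spec$shape
  pitch <- spec$pitch
  eff <- spec$effector
  tar <- spec$target
  for (cell in list(eff, tar)) {
    if (cell$radius <= 0) next
    half <- dm * pitch / 2
    if (any(abs(cell$center) + cell$radius > half - 2 * pitch))
      stop_istomo("cell does not fit inside the grid with a 2-voxel margin",
                  "istomo_geometry_error")
  }

  d2e <- dist2_grid(dm, pitch, eff$center)
  d2t <- dist2_grid(dm, pitch, tar$center)
  in_e <- if (eff$radius > 0) d2e <= eff$radius^2 else array(FALSE, dm)
  in_t <- if (tar$radius > 0) d2t <= tar$radius^2 else array(FALSE, dm)
  both <- in_e & in_t
  if (any(both)) {
    # overlap voxels go to the nearer centre; effector wins exact ties
    to_t <- both & (d2t < d2e)
    in_e[both & !to_t] <- TRUE
    in_e[to_t] <- FALSE
    in_t[both & to_t] <- TRUE
    in_t[both & !to_t] <- FALSE
  }

  ri <- array(spec$medium_ri, dm)
  fill_cell <- function(ri, inside, d2, cell) {
    ri[inside] <- cell$cyto_ri
    if (cell$core_radius > 0 && cell$core_ri > 0)
      ri[inside & (d2 <= cell$core_radius^2)] <- cell$core_ri
    ri
  }
  ri <- fill_cell(ri, in_e, d2e, eff)
  ri <- fill_cell(ri, in_t, d2t, tar)

  gran <- list(effector = spec$granules_effector,
               target = spec$granules_target)
  if (is.null(gran$effector) && is.null(gran$target)) {
    gran <- with_seed(spec$seed,
                      list(effector = sample_granules(eff, tar, NULL),
                           target = sample_granules(tar, eff, NULL)))
  }
  add_granules <- function(ri, gpos, cell, inside) {
    if (is.null(gpos) || nrow(gpos) == 0) return(ri)
    for (i in seq_len(nrow(gpos))) {
      d2g <- dist2_grid(dm, pitch, gpos[i, ])
      ri[inside & (d2g <= cell$granule_radius^2)] <- cell$granule_ri
    }
    ri
  }
  ri <- add_granules(ri, gran$effector, eff, in_e)
  ri <- add_granules(ri, gran$target, tar, in_t)

  if (spec$antialias > 1L) {
    ri <- antialias_edges(ri, spec, in_e | in_t)
  }
  list(ri = ri, in_e = in_e, in_t = in_t, granules = gran)
}

# Partial-volume refinement of boundary voxels by subvoxel supersampling
# (cytoplasm/medium boundary only; compartments are interior).
antialias_edges <- function(ri, spec, inside) {
  dm <- spec$shape
  pitch <- spec$pitch
  s <- spec$antialias
  cr <- voxel_coords(dm, pitch)
  offs <- (seq_len(s) - (s + 1) / 2) / s
  sub <- as.matrix(expand.grid(z = offs * pitch[1], y = offs * pitch[2],
                               x = offs * pitch[3]))
  halfdiag <- sqrt(sum(pitch^2)) / 2
  for (cell in list(spec$effector, spec$target)) {
    if (cell$radius <= 0) next
    d <- sqrt(dist2_grid(dm, pitch, cell$center)) - cell$radius
    edge <- which(abs(d) <= halfdiag & !(inside & d > 0))
    if (!length(edge)) next
    idx <- arrayInd(edge, dm)
    pos <- cbind(cr[[1]][idx[, 1]], cr[[2]][idx[, 2]], cr[[3]][idx[, 3]])
    for (j in seq_along(edge)) {
      pts <- sweep(sub, 2, pos[j, ], "+")
      frac <- mean(rowSums(sweep(pts, 2, cell$center, "-")^2) <=
                     cell$radius^2)
      base <- spec$medium_ri
      ri[edge[j]] <- base + frac * (cell$cyto_ri - base)
    }
  }
  ri
}

# True contact-disc mask: voxels on the radical plane of the two spheres,
# within the analytic disc radius, within half a voxel of the plane.
contact_disc <- function(spec) {
  eff <- spec$effector
  tar <- spec$target
  dm <- spec$shape
  pitch <- spec$pitch
  empty <- array(FALSE, dm)
  if (eff$radius <= 0 || tar$radius <= 0)
    return(list(mask = empty, radius = 0, center = NULL, axis = NULL))
  u <- tar$center - eff$center
  s <- sqrt(sum(u^2))
  if (s <= 0 || s >= eff$radius + tar$radius)
    return(list(mask = empty, radius = 0, center = NULL, axis = NULL))
  u <- u / s
  x1 <- (s^2 + eff$radius^2 - tar$radius^2) / (2 * s)
  a <- sqrt(max(eff$radius^2 - x1^2, 0))
  pc <- eff$center + x1 * u
  cr <- voxel_coords(dm, pitch)
  ax <- outer(outer((cr[[1]] - pc[1]) * u[1], (cr[[2]] - pc[2]) * u[2], "+"),
              (cr[[3]] - pc[3]) * u[3], "+")
  d2 <- dist2_grid(dm, pitch, pc)
  rad2 <- d2 - ax^2
  pax <- sqrt(sum((pitch * u)^2))
  list(mask = abs(ax) <= pax / 2 & rad2 <= a^2, radius = a, center = pc,
       axis = u)
}

#' Generate a two-cell conjugate phantom with ground truth
#'
#' Rasterizes the RI volume and returns it with exact truth: disjoint cell
#' masks, the signed Euclidean distance map, the contact-disc description,
#' and the kinematic state (centres, centroids, disc radius).
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_truth` with fields `tom`
#'   ([tomogram()]), `pair` ([cell_mask_pair()]), `distmap`
#'   ([build_signed_distance_target()] output), `interface` (contact-disc
#'   mask), and `state`.
#' @export
make_conjugate <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  ras <- rasterize_conjugate(spec)
  pair <- cell_mask_pair(ras$in_e, ras$in_t, pitch = spec$pitch)
  disc <- contact_disc(spec)
  tom <- tomogram(ras$ri, pitch = spec$pitch, medium_ri = spec$medium_ri)
  structure(list(
    tom = tom, pair = pair,
    distmap = build_signed_distance_target(pair),
    interface = disc$mask,
    state = list(effector_center = spec$effector$center,
                 target_center = spec$target$center,
                 radii = c(effector = spec$effector$radius,
                           target = spec$target$radius),
                 disc_radius_nm = disc$radius,
                 disc_center = disc$center, axis = disc$axis,
                 granules = ras$granules)),
    class = "phantom_truth")
}

#' Kinetics specification for a time-lapse conjugate
#'
#' Saturating-hyperbola kinetics `y(t) = y_max * t / (t + tau_half)` for the
#' contact area and for each cell's density-weighted centre-of-mass
#' displacement. Defaults are the fitted values of the measured effector
#' (CAR-T) / target conjugate kinetics, so synthetic series resemble the
#' measured ones.
#'
#' @param a_max saturation contact area (um^2).
#' @param tau_area half-saturation time of the area (s).
#' @param dd_max length-2 saturation displacements (effector, target) in um.
#' @param tau_disp length-2 half-saturation times (s).
#' @param frame_interval frame spacing (s); measured series used 3-8 s.
#' @param duration series length (s).
#' @param noise_sd additive Gaussian RI noise per frame (0 = noiseless).
#' @param effector_direction unit direction (z, y, x) of the effector
#'   centroid motion; the default points along the initial conjugate axis,
#'   toward the target (the effector pushes into and displaces its
#'   target), which keeps the area-derived separation and both
#'   displacement magnitudes jointly realizable.
#' @return An object of class `kinetics_spec`.
#' @export
kinetics_spec <- function(a_max = 106.16, tau_area = 39.63,
                          dd_max = c(7.48, 1.74),
                          tau_disp = c(37.84, 14.56),
                          frame_interval = 3, duration = 300,
                          noise_sd = 0,
                          effector_direction = c(1, 0, 0)) {
  stopifnot(a_max > 0, tau_area > 0, all(dd_max >= 0), all(tau_disp > 0),
            frame_interval > 0, duration > 0, noise_sd >= 0)
  u <- effector_direction / sqrt(sum(effector_direction^2))
  structure(list(a_max = a_max, tau_area = tau_area, dd_max = dd_max,
                 tau_disp = tau_disp, frame_interval = frame_interval,
                 duration = duration, noise_sd = noise_sd,
                 effector_direction = u),
            class = "kinetics_spec")
}

hyperbola <- function(t, ymax, tau) ymax * t / (t + tau)

# Centre separation s (nm) giving contact-disc area A_um2 for radii r1, r2.
separation_for_area <- function(A_um2, r1, r2) {
  if (A_um2 <= 0) return(r1 + r2)
  a <- sqrt(A_um2 / pi) * 1000
  if (a >= min(r1, r2))
    stop_istomo("requested contact area exceeds the cells' cross-section",
                "istomo_geometry_error")
  da <- function(s) {
    x1 <- (s^2 + r1^2 - r2^2) / (2 * s)
    sqrt(pmax(r1^2 - x1^2, 0)) - a
  }
  # disc radius decreases monotonically from min(r1, r2) down to 0 on
  # [sqrt(|r1^2 - r2^2|), r1 + r2]; bracket the root there
  lo <- max(sqrt(abs(r1^2 - r2^2)), 1e-3 * (r1 + r2))
  uniroot(da, c(lo, r1 + r2), tol = 1e-9 * (r1 + r2))$root
}

# Centroid shift of a sphere truncated by the radical plane, weighted by the
# compartment densities (RI contrast). Exact for spherically layered cells.
truncation_offset <- function(cell, medium_ri, x1) {
  if (x1 >= cell$radius) return(0)
  rho_c <- cell$cyto_ri - medium_ri
  rho_k <- cell$core_ri - medium_ri
  a2 <- cell$radius^2 - x1^2
  h <- cell$radius - x1
  v_cap <- pi * h^2 * (3 * cell$radius - h) / 3
  v_core <- 4 / 3 * pi * cell$core_radius^3
  v_sph <- 4 / 3 * pi * cell$radius^3
  mass <- rho_c * (v_sph - v_cap - v_core) + rho_k * v_core
  if (x1 < cell$core_radius)
    stop_istomo("contact plane cuts the nucleus-like core; shrink the core",
                "istomo_geometry_error")
  moment <- rho_c * pi * a2^2 / 4
  moment / mass
}

#' Generate a time-lapse conjugate series with hyperbolic kinetics
#'
#' Frame `t` realizes a contact-disc area `A(t) = a_max t / (t + tau_area)`
#' (two spheres interpenetrating to the depth that yields that disc) and
#' density-weighted centroid displacements `dd(t)` for both cells. The
#' effector centroid moves along `effector_direction`; the target direction
#' is solved each frame so its displacement magnitude matches while the
#' centre separation honours the area. Motion is confined to the (z, y)
#' plane.
#'
#' @param spec a [phantom_spec()] whose two cells are initially separated
#'   along z; granule-free cells keep the centroid kinematics exact.
#' @param kin a [kinetics_spec()].
#' @return List of [make_conjugate()] truths, one per frame, each with
#'   `state$time`, `state$prescribed` (area, displacements) attached.
#' @export
make_timelapse <- function(spec, kin) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(kin, "kinetics_spec"))
  r1 <- spec$effector$radius
  r2 <- spec$target$radius
  times <- seq(0, kin$duration, by = kin$frame_interval)
  u_e <- kin$effector_direction

  # initial geometry: just touching, conjugate axis along +z
  s0 <- r1 + r2
  c_e0 <- spec$effector$center
  c_t0 <- c_e0 + c(s0, 0, 0)
  th_prev <- 0

  # granule offsets sampled once, moved rigidly with each cell
  gpair <- with_seed(spec$seed, {
    ge <- sample_granules(spec$effector, spec$target, NULL)
    gt <- sample_granules(spec$target, spec$effector, NULL)
    list(ge, gt)
  })
  g_e <- gpair[[1]]
  g_t <- gpair[[2]]
  rel <- function(g, c0) if (is.null(g)) NULL else sweep(g, 2, c0)
  g_e <- rel(g_e, c_e0)
  g_t <- rel(g_t, c_t0)

  frames <- vector("list", length(times))
  for (i in seq_along(times)) {
    t <- times[i]
    A_t <- hyperbola(t, kin$a_max, kin$tau_area)
    dd_e <- hyperbola(t, kin$dd_max[1], kin$tau_disp[1]) * 1000
    dd_t <- hyperbola(t, kin$dd_max[2], kin$tau_disp[2]) * 1000
    s_t <- separation_for_area(A_t, r1, r2)
    x1 <- (s_t^2 + r1^2 - r2^2) / (2 * s_t)
    x2 <- s_t - x1
    off_e <- truncation_offset(spec$effector, spec$medium_ri, x1)
    off_t <- truncation_offset(spec$target, spec$medium_ri, x2)

    cent_e <- c_e0 + dd_e * u_e
    th <- th_prev
    for (pass in 1:2) {
      w <- function(th) c(cos(th), sin(th), 0)
      c_e <- cent_e + off_e * w(th)
      fobj <- function(th2) {
        ct <- c_e + (s_t + off_t) * w(th2)
        sqrt(sum((ct - c_t0)^2)) - dd_t
      }
      th <- solve_angle(fobj, th_prev)
    }
    axis <- c(cos(th), sin(th), 0)
    c_e <- cent_e + off_e * axis
    c_t <- c_e + s_t * axis
    th_prev <- th

    fr_spec <- spec
    fr_spec$effector$center <- c_e
    fr_spec$target$center <- c_t
    abs_g <- function(g, c) if (is.null(g)) NULL else sweep(g, 2, c, "+")
    fr_spec$granules_effector <- abs_g(g_e, c_e)
    fr_spec$granules_target <- abs_g(g_t, c_t)
    truth <- make_conjugate(fr_spec)
    if (kin$noise_sd > 0) {
      truth$tom$values <- truth$tom$values + with_seed(
        spec$seed + i,
        array(rnorm(length(truth$tom$values), sd = kin$noise_sd),
              dim(truth$tom$values)))
    }
    truth$tom$timestamp <- t
    truth$state$time <- t
    truth$state$prescribed <- list(area_um2 = A_t, dd_effector_um = dd_e / 1000,
                                   dd_target_um = dd_t / 1000)
    truth$state$centroids <- list(effector = cent_e,
                                  target = c_t + off_t * axis)
    frames[[i]] <- truth
  }
  frames
}

# Find the root of f nearest th0 by bracketing on a local scan.
solve_angle <- function(f, th0) {
  grid <- th0 + seq(-pi / 2, pi / 2, length.out = 241)
  v <- vapply(grid, f, numeric(1))
  sgn <- sign(v)
  flips <- which(sgn[-1] * sgn[-length(sgn)] <= 0)
  if (!length(flips)) {
    if (min(abs(v)) < 1e-6) return(grid[which.min(abs(v))])
    stop_istomo("no consistent conjugate geometry for the requested kinetics",
                "istomo_geometry_error")
  }
  best <- flips[which.min(abs(grid[flips] - th0))]
  uniroot(f, c(grid[best], grid[best + 1]), tol = 1e-10)$root
}
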