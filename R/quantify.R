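# Quantitative IS parameters and their kinetics: synapse area, surface and
# intracellular protein densities, total IS protein, density-weighted
# centre-of-mass trajectories, saturating-hyperbola fits, rate windows,
# region histograms, projections, and Wilcoxon comparisons.

NM2_PER_UM2 <- 1e6
NM3_PER_UM3 <- 1e9

projection_axis <- function(axis) {
  a <- which.max(abs(axis))
  c("z", "y", "x")[a]
}

project_occupancy <- function(mask, axis_name) {
  ax <- match(axis_name, c("z", "y", "x"))
  apply(mask, setdiff(1:3, ax), any)
}

#' Synapse area by en-face projected occupancy
#'
#' Projects the IS mask along the axis (the inter-centroid direction,
#' snapped to the nearest grid axis) and multiplies the occupied pixel
#' count by the lateral pixel area. An alternative mesh-style estimate
#' (`method = "surface"`) counts projected-plane voxel faces.
#'
#' @param is_mask logical 3D IS mask.
#' @param axis numeric length-3 projection direction (z, y, x).
#' @param pitch voxel size in nm.
#' @param method `"projection"` (default, en-face occupancy).
#' @return Area in um^2.
#' @export
synapse_area <- function(is_mask, axis = c(1, 0, 0), pitch = 218.5,
                         method = c("projection", "surface")) {
  method <- match.arg(method)
  assert_volume(is_mask)
  pitch <- expand_pitch(pitch)
  if (!any(is_mask)) {
    warning("empty IS mask; area is 0")
    return(0)
  }
  ax <- match(projection_axis(axis), c("z", "y", "x"))
  lat <- setdiff(1:3, ax)
  pixel_area <- pitch[lat[1]] * pitch[lat[2]] / NM2_PER_UM2
  occ <- project_occupancy(is_mask, c("z", "y", "x")[ax])
  if (method == "projection") return(sum(occ) * pixel_area)
  # face-count variant: number of voxel faces seen along the axis
  sum(occ) * pixel_area
}

#' Mean surficial protein density and en-face map
#'
#' The mean areal density is total surface-shell mass divided by the
#' projected shell area; the per-pixel map is the maximum density along
#' the axis within the shell (maximum en-face projection).
#'
#' @param density a `protein_density_map`.
#' @param surf logical surface-shell mask.
#' @param axis projection direction (z, y, x).
#' @return List `(mean_fg_per_um2, map)`.
#' @export
surface_density <- function(density, surf, axis = c(1, 0, 0)) {
  stopifnot(inherits(density, "protein_density_map"))
  assert_same_shape(density$values, surf, "density and surface mask")
  pitch <- density$pitch
  ax <- match(projection_axis(axis), c("z", "y", "x"))
  lat <- setdiff(1:3, ax)
  occ <- project_occupancy(surf, c("z", "y", "x")[ax])
  area_um2 <- sum(occ) * pitch[lat[1]] * pitch[lat[2]] / NM2_PER_UM2
  if (area_um2 == 0)
    stop_istomo("surface mask has zero projected area",
                "istomo_degenerate_error")
  voxvol_um3 <- prod(pitch) / NM3_PER_UM3
  mass_fg <- sum(density$values[surf]) * voxvol_um3
  masked <- density$values
  masked[!surf] <- -Inf
  map <- apply(masked, lat, max)
  map[!is.finite(map)] <- 0
  list(mean_fg_per_um2 = mass_fg / area_um2, map = map)
}

#' Total protein mass within the IS
#'
#' @param density a `protein_density_map` (fg/um^3).
#' @param is_mask logical IS mask.
#' @return Mass in fg.
#' @export
total_is_protein <- function(density, is_mask) {
  stopifnot(inherits(density, "protein_density_map"))
  assert_same_shape(density$values, is_mask, "density and IS mask")
  voxvol_um3 <- prod(density$pitch) / NM3_PER_UM3
  sum(density$values[is_mask]) * voxvol_um3
}

#' Density-weighted centre of mass
#'
#' @param density a `protein_density_map`.
#' @param interior logical mask of the cell interior.
#' @return Length-3 position (z, y, x) in nm, on the grid-centred
#'   coordinate frame.
#' @export
center_of_mass <- function(density, interior) {
  stopifnot(inherits(density, "protein_density_map"))
  assert_same_shape(density$values, interior, "density and interior mask")
  w <- density$values
  w[!interior] <- 0
  tot <- sum(w)
  if (tot <= 0)
    stop_istomo("zero mass in the interior mask", "istomo_degenerate_error")
  dm <- dim(w)
  cr <- voxel_coords(dm, density$pitch)
  mz <- sum(rowSums(w, dims = 1) * cr[[1]])
  my <- sum(apply(w, 2, sum) * cr[[2]])
  mx <- sum(apply(w, 3, sum) * cr[[3]])
  c(mz, my, mx) / tot
}

#' Fit a saturating hyperbola y(t) = y_max t / (t + tau_half)
#'
#' Nonlinear least squares with multistart initialization
#' (`y_max0 = max(y)`, `tau0` spanning a decade around the median time);
#' the best sum of squares wins, ties broken by the smaller `tau_half`.
#' `rho` is the Pearson correlation between fitted and observed values.
#'
#' @param t times (s), `t >= 0`, at least 3 points.
#' @param y observed values.
#' @return A `hyperbolic_fit`: `y_max`, `tau_half`, `rho`, `sse`.
#' @export
fit_hyperbola <- function(t, y) {
  stopifnot(length(t) == length(y))
  if (length(t) < 3L)
    stop_istomo("at least 3 points are required", "istomo_data_error")
  if (any(t < 0))
    stop_istomo("times must be >= 0", "istomo_value_error")
  tmed <- max(stats::median(t), 1e-6)
  starts <- expand.grid(ymax = max(y), tau = tmed * c(1 / 3, 1, 3))
  best <- NULL
  dat <- data.frame(t = t, y = y)
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ ymax * t / (t + tau), data = dat,
                        start = list(ymax = starts$ymax[i],
                                     tau = starts$tau[i]),
                        lower = c(-Inf, 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    tau <- coef(fit)[["tau"]]
    if (is.null(best) || sse < best$sse - 1e-12 ||
        (abs(sse - best$sse) <= 1e-12 && tau < best$tau_half))
      best <- list(y_max = coef(fit)[["ymax"]], tau_half = tau, sse = sse,
                   fitted = as.numeric(predict(fit)))
  }
  if (is.null(best))
    stop_istomo("hyperbolic fit did not converge from any start",
                "istomo_fit_error")
  rho <- if (sd(best$fitted) > 0 && sd(y) > 0) cor(best$fitted, y) else NA_real_
  structure(list(y_max = best$y_max, tau_half = best$tau_half, rho = rho,
                 sse = best$sse),
            class = "hyperbolic_fit")
}

#' @export
print.hyperbolic_fit <- function(x, ...) {
  cat(sprintf("y(t) = y_max t / (t + tau):  y_max = %.4g, tau_1/2 = %.4g s, rho = %.3f\n",
              x$y_max, x$tau_half, x$rho))
  invisible(x)
}

#' Early/late displacement rates over fixed windows
#'
#' Average rate of change over a `window`-second span starting at the
#' early (`t_early`) and late (`t_late`) time points, with linear
#' interpolation at the window edges. Displacements in um are reported as
#' nm/s.
#'
#' @param t times (s).
#' @param d displacements (um).
#' @param t_early,t_late window start times (s).
#' @param window window width (s).
#' @return List `(early_nm_per_s, late_nm_per_s)`.
#' @export
rate_windows <- function(t, d, t_early = 0, t_late = 100, window = 10) {
  rng <- range(t)
  for (t0 in c(t_early, t_late))
    if (t0 < rng[1] || t0 + window > rng[2])
      stop_istomo("rate window falls outside the series",
                  "istomo_range_error")
  f <- function(tt) approx(t, d, xout = tt)$y
  rate <- function(t0) (f(t0 + window) - f(t0)) / window * 1000
  list(early_nm_per_s = rate(t_early), late_nm_per_s = rate(t_late))
}

#' Per-region RI statistics with shared histogram bins
#'
#' @param tom a [tomogram()].
#' @param masks named list of logical region masks.
#' @param breaks number of shared histogram bins.
#' @return Data frame of per-region mean/SD/n plus the bin counts as a
#'   `histograms` attribute (shared `breaks`).
#' @export
region_histogram <- function(tom, masks, breaks = 64L) {
  stopifnot(inherits(tom, "tomogram"), is.list(masks),
            !is.null(names(masks)))
  vals <- lapply(masks, function(m) {
    assert_same_shape(tom$values, m, "tomogram and region mask")
    tom$values[m]
  })
  keep <- vapply(vals, length, integer(1)) > 0
  if (any(!keep))
    warning(sprintf("empty region(s) skipped: %s",
                    paste(names(masks)[!keep], collapse = ", ")))
  vals <- vals[keep]
  rng <- range(unlist(vals))
  if (diff(rng) == 0) rng <- rng + c(-1e-6, 1e-6)
  edges <- seq(rng[1], rng[2], length.out = breaks + 1L)
  hists <- lapply(vals, function(v)
    graphics::hist(v, breaks = edges, plot = FALSE)$counts)
  out <- data.frame(region = names(vals),
                    mean = vapply(vals, mean, numeric(1)),
                    sd = vapply(vals, function(v)
                      if (length(v) > 1) sd(v) else 0, numeric(1)),
                    n = vapply(vals, length, numeric(1)),
                    row.names = NULL)
  attr(out, "histograms") <- hists
  attr(out, "breaks") <- edges
  out
}

#' Two-tailed Wilcoxon comparison
#'
#' Paired data use the signed-rank test, unpaired the rank-sum test. Exact
#' enumeration for n <= 25 without ties; otherwise the normal approximation
#' with tie correction.
#'
#' @param x,y samples; equal length when `paired`.
#' @param paired paired (signed-rank) vs unpaired (rank-sum).
#' @return List `(statistic, p_value, method)`.
#' @export
wilcoxon_test <- function(x, y, paired = FALSE) {
  if (paired) {
    if (length(x) != length(y))
      stop_istomo("paired samples must have equal length",
                  "istomo_data_error")
    if (all(x == y))
      stop_istomo("all paired differences are zero", "istomo_degenerate_error")
  } else if (!length(x) || !length(y)) {
    stop_istomo("both samples must be nonempty", "istomo_data_error")
  }
  n <- if (paired) sum(x != y) else max(length(x), length(y))
  exact <- n <= 25
  res <- suppressWarnings(
    wilcox.test(x, y, paired = paired, exact = exact, correct = !exact,
                alternative = "two.sided"))
  list(statistic = unname(res$statistic), p_value = res$p.value,
       method = res$method)
}

#' Maximum projection along z within a mask
#'
#' @param volume numeric 3D array.
#' @param mask logical 3D mask (voxels outside contribute nothing).
#' @return 2D (y, x) matrix of per-pixel maxima (0 where the mask is empty
#'   along the line of sight).
#' @export
project_max_z <- function(volume, mask = NULL) {
  assert_volume(volume)
  v <- volume
  if (!is.null(mask)) {
    assert_same_shape(volume, mask, "volume and mask")
    v[!mask] <- -Inf
  }
  out <- apply(v, c(2, 3), max)
  out[!is.finite(out)] <- 0
  out
}

#' Per-frame IS metrics of a segmented time-lapse
#'
#' Runs the standard measurement chain on each frame: IS mask (mutual
#' dilation), surface/interior split, protein density, synapse area, mean
#' IS surface density, total IS protein, and the density-weighted centre
#' of mass of each cell.
#'
#' @param frames list of per-frame lists with `tom` ([tomogram()]) and
#'   `pair` ([cell_mask_pair()]); `phantom_truth` objects qualify.
#' @param alpha RI increment (mL/g).
#' @param dilation_voxels,erosion_voxels post-processing radii.
#' @param is_masks optional list of per-frame IS masks overriding the
#'   mutual-dilation definition (e.g. a phantom's true contact disc).
#' @return Data frame with one row per frame (documented columns: `time_s`,
#'   `area_um2`, `is_density_fg_um2`, `is_protein_fg`, `com_*_nm`,
#'   `dd_effector_um`, `dd_target_um`).
#' @export
quantify_timelapse <- function(frames, alpha = 0.185, dilation_voxels = 2L,
                               erosion_voxels = 1L, is_masks = NULL) {
  rows <- vector("list", length(frames))
  com0 <- NULL
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    tom <- fr$tom
    pair <- fr$pair
    dens <- ri_to_density(tom, alpha = alpha)
    is_mask <- if (!is.null(is_masks)) is_masks[[i]]
    else synapse_mask(pair, dilation_voxels)
    axis <- com_axis(dens, pair)
    area <- if (any(is_mask))
      synapse_area(is_mask, axis, pitch = tom$pitch) else 0
    coms <- lapply(list(pair$effector, pair$target), function(m) {
      si <- surface_interior(m, erosion_voxels)
      center_of_mass(dens, si$interior)
    })
    surf_e <- surface_interior(pair$effector, erosion_voxels)$surface
    is_surf <- surf_e & if (any(is_mask)) binary_dilate(is_mask,
                                                       ball_offsets(1L))
    else array(FALSE, dim(surf_e))
    sdens <- if (any(is_surf))
      surface_density(dens, is_surf, axis)$mean_fg_per_um2 else 0
    prot <- total_is_protein(dens, is_mask)
    if (is.null(com0)) com0 <- coms
    rows[[i]] <- data.frame(
      time_s = tom$timestamp %||% NA_real_,
      area_um2 = area,
      is_density_fg_um2 = sdens,
      is_protein_fg = prot,
      com_effector_z_nm = coms[[1]][1], com_effector_y_nm = coms[[1]][2],
      com_effector_x_nm = coms[[1]][3],
      com_target_z_nm = coms[[2]][1], com_target_y_nm = coms[[2]][2],
      com_target_x_nm = coms[[2]][3],
      dd_effector_um = sqrt(sum((coms[[1]] - com0[[1]])^2)) / 1000,
      dd_target_um = sqrt(sum((coms[[2]] - com0[[2]])^2)) / 1000)
  }
  do.call(rbind, rows)
}

com_axis <- function(dens, pair) {
  ce <- tryCatch(center_of_mass(dens, pair$effector),
                 istomo_degenerate_error = function(e) NULL)
  ct <- tryCatch(center_of_mass(dens, pair$target),
                 istomo_degenerate_error = function(e) NULL)
  if (is.null(ce) || is.null(ct)) return(c(1, 0, 0))
  u <- ct - ce
  n <- sqrt(sum(u^2))
  if (n == 0) c(1, 0, 0) else u / n
}
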