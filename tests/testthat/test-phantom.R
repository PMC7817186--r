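test_that("phantom generation is deterministic and respects its invariants", {
  sp <- equal_spheres_spec(grid = 32L, radius = 1300, seed = 7L)
  sp$effector$granule_n <- 3L
  a <- make_conjugate(sp)
  b <- make_conjugate(sp)
  expect_identical(a$tom$values, b$tom$values)
  expect_identical(a$pair$effector, b$pair$effector)

  # every contrast voxel belongs to exactly one cell
  fg <- a$tom$values > a$tom$medium_ri + 1e-6
  expect_true(all(fg == (a$pair$effector | a$pair$target)))
  expect_false(any(a$pair$effector & a$pair$target))

  # distance map consistent with masks
  expect_true(all(a$distmap$values[a$pair$effector] > 0))
  expect_true(all(a$distmap$values[a$pair$target] < 0))
  expect_true(all(a$distmap$values[!fg] == 0))
})

test_that("zero-radius cells give a uniform volume and empty masks", {
  sp <- phantom_spec(shape = c(16, 16, 16),
                     effector = phantom_cell(radius = 0, cyto_ri = 1.36),
                     target = phantom_cell(radius = 0, cyto_ri = 1.35))
  tr <- make_conjugate(sp)
  expect_true(all(tr$tom$values == sp$medium_ri))
  expect_false(any(tr$pair$effector))
  expect_false(any(tr$pair$target))
})

test_that("rasterized sphere volume matches the analytic ball within 2%", {
  tr <- make_conjugate(single_sphere_spec(grid = 48L, radius_vox = 10))
  vol <- sum(tr$pair$effector)
  expect_lt(abs(vol - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.02)
})

test_that("contact interface voxels are equidistant from both centres", {
  sp <- equal_spheres_spec(grid = 40L, radius = 1600, sep_frac = 0.9)
  tr <- make_conjugate(sp)
  expect_gt(sum(tr$interface), 0)
  idx <- arrayInd(which(tr$interface), dim(tr$interface))
  crd <- istomo:::voxel_coords(dim(tr$interface), sp$pitch)
  pos <- cbind(crd[[1]][idx[, 1]], crd[[2]][idx[, 2]], crd[[3]][idx[, 3]])
  de <- sqrt(rowSums(sweep(pos, 2, sp$effector$center)^2))
  dt <- sqrt(rowSums(sweep(pos, 2, sp$target$center)^2))
  expect_lt(max(abs(de - dt)), sp$pitch[1])  # within one voxel

  expect_error(
    make_conjugate(phantom_spec(shape = c(16, 16, 16),
                                effector = phantom_cell(radius = 5000,
                                                        cyto_ri = 1.36))),
    class = "istomo_geometry_error")
})

test_that("time-lapse frames realize the prescribed hyperbolic kinetics", {
  dk <- istomo:::desk_timelapse(1L)
  kin <- dk$kin
  kin$duration <- 120
  kin$frame_interval <- 6
  frames <- make_timelapse(dk$spec, kin)

  # t = 0: just touching, empty contact disc
  expect_lt(frames[[1]]$state$disc_radius_nm, 1)
  expect_equal(frames[[1]]$state$prescribed$area_um2, 0)

  # realized (continuous) disc area follows A(t) essentially exactly
  for (fr in frames[c(3, 11, 21)]) {
    a_realized <- pi * fr$state$disc_radius_nm^2 / 1e6
    expect_equal(a_realized, fr$state$prescribed$area_um2, tolerance = 1e-6)
  }

  # at t = tau_half the disc area is A_max / 2 (within a voxel-area quantum)
  i_half <- which.min(abs(seq(0, 120, 6) - kin$tau_area))
  a_half <- pi * frames[[i_half]]$state$disc_radius_nm^2 / 1e6
  t_half <- frames[[i_half]]$state$time
  expect_lt(abs(a_half - kin$a_max * t_half / (t_half + kin$tau_area)),
            (218.5 / 1000)^2)

  # noiseless measured centroid displacement tracks the prescription
  tab <- quantify_timelapse(frames,
                            is_masks = lapply(frames, `[[`, "interface"))
  pre_e <- vapply(frames, function(f) f$state$prescribed$dd_effector_um,
                  numeric(1))
  pre_t <- vapply(frames, function(f) f$state$prescribed$dd_target_um,
                  numeric(1))
  expect_lt(max(abs(tab$dd_effector_um - pre_e)) * 1000 / 218.5, 0.2)
  expect_lt(max(abs(tab$dd_target_um - pre_t)) * 1000 / 218.5, 0.2)
})

test_that("realized kinetics converge as the voxel pitch shrinks", {
  area_err <- function(pitch, grid) {
    sp <- phantom_spec(
      shape = rep(grid, 3L), pitch = pitch,
      effector = phantom_cell(center = c(-2900, 0, 0), radius = 2800,
                              cyto_ri = 1.360, core_radius = 1100),
      target = phantom_cell(center = c(2900, 0, 0), radius = 2800,
                            cyto_ri = 1.350, core_radius = 1100))
    kin <- kinetics_spec(a_max = 8, tau_area = 40, dd_max = c(0.8, 0.3),
                         tau_disp = c(38, 15), frame_interval = 30,
                         duration = 90)
    frames <- make_timelapse(sp, kin)
    errs <- vapply(frames[-1], function(fr) {
      a_meas <- synapse_area(fr$interface, fr$state$axis, pitch = pitch)
      abs(a_meas - fr$state$prescribed$area_um2) /
        fr$state$prescribed$area_um2
    }, numeric(1))
    mean(errs)
  }
  coarse <- area_err(218.5, 60L)
  fine <- area_err(109.25, 120L)
  expect_lt(fine, coarse)          # converging
  expect_lt(fine, 0.6 * coarse)    # at roughly first order or better
})

test_that("granules stay inside their cell and raise the local RI", {
  sp <- equal_spheres_spec(grid = 32L, radius = 1300, seed = 5L)
  sp$effector$granule_n <- 4L
  sp$effector$granule_ri <- 1.375
  tr <- make_conjugate(sp)
  gmask <- tr$tom$values >= 1.375 - 1e-9
  expect_gt(sum(gmask), 0)
  expect_true(all(tr$pair$effector[gmask]))
})
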