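test_that("synapse area is projected occupancy times pixel area", {
  dm <- c(12, 12, 12)
  sheet <- array(FALSE, dm)
  sheet[2:11, 2:11, 5] <- TRUE  # 10 x 10 sheet perpendicular to x
  expect_equal(synapse_area(sheet, axis = c(0, 0, 1), pitch = 218.5),
               100 * 0.2185^2, tolerance = 1e-12)
  expect_warning(a0 <- synapse_area(array(FALSE, dm), c(0, 0, 1)), "empty")
  expect_equal(a0, 0)
  # thickening the sheet along the projection axis changes nothing
  sheet2 <- sheet
  sheet2[2:11, 2:11, 6] <- TRUE
  expect_equal(synapse_area(sheet2, c(0, 0, 1), 218.5),
               synapse_area(sheet, c(0, 0, 1), 218.5))
})

test_that("surface density follows the slab formula and is linear", {
  dm <- c(8, 8, 8)
  shell <- array(FALSE, dm)
  shell[4, , ] <- TRUE  # flat 1-voxel shell perpendicular to z
  mk <- function(c0) {
    structure(list(values = array(c0, dm), alpha = 0.185,
                   medium_ri = 1.337, pitch = rep(218.5, 3)),
              class = "protein_density_map")
  }
  sd1 <- surface_density(mk(100), shell, axis = c(1, 0, 0))
  expect_equal(sd1$mean_fg_per_um2, 100 * 0.2185, tolerance = 1e-12)
  expect_equal(surface_density(mk(0), shell, c(1, 0, 0))$mean_fg_per_um2, 0)
  expect_equal(surface_density(mk(200), shell, c(1, 0, 0))$mean_fg_per_um2,
               2 * sd1$mean_fg_per_um2)
  # the en-face map is the maximum along the axis within the shell
  expect_equal(dim(sd1$map), c(8L, 8L))
  expect_true(all(sd1$map == 100))
  expect_error(surface_density(mk(1), array(FALSE, dm), c(1, 0, 0)),
               class = "istomo_degenerate_error")
})

test_that("total IS protein is mass integration over the mask", {
  dm <- c(10, 10, 10)
  dens <- structure(list(values = array(100, dm), alpha = 0.185,
                         medium_ri = 1.337, pitch = rep(218.5, 3)),
                    class = "protein_density_map")
  m <- array(FALSE, dm)
  m[1:10, 1:10, 1:10][seq_len(1000)] <- TRUE
  voxvol <- 0.2185^3
  expect_equal(total_is_protein(dens, m), 1000 * 100 * voxvol,
               tolerance = 1e-12)
  expect_equal(total_is_protein(dens, array(FALSE, dm)), 0)
  # additive over disjoint components
  a <- array(FALSE, dm); a[1:3, 1, 1] <- TRUE
  b <- array(FALSE, dm); b[1, 5:9, 9] <- TRUE
  expect_equal(total_is_protein(dens, a | b),
               total_is_protein(dens, a) + total_is_protein(dens, b))
})

test_that("centre of mass obeys the lever rule and translation equivariance", {
  dm <- c(9, 9, 9)
  v <- array(0, dm)
  v[5, 5, 3] <- 1
  v[5, 5, 7] <- 3
  dens <- structure(list(values = v, alpha = 0.185, medium_ri = 1.337,
                         pitch = rep(1, 3)),
                    class = "protein_density_map")
  com <- center_of_mass(dens, v > 0)
  expect_equal(com[3], (-2 * 1 + 2 * 3) / 4)  # x = 3 on the lever scale

  tr <- make_conjugate(single_sphere_spec(grid = 32L, radius_vox = 7))
  d2 <- ri_to_density(tr$tom)
  com2 <- center_of_mass(d2, tr$pair$effector)
  expect_lt(max(abs(com2 - c(0, 0, 0))), 0.1 * 218.5)

  # translating the mass translates the COM by exactly k * pitch
  v3 <- array(0, dm)
  v3[2:4, 2:4, 2:4] <- runif(27) + 0.5
  v3s <- array(0, dm)
  v3s[4:6, 2:4, 2:4] <- v3[2:4, 2:4, 2:4]
  mk <- function(x) structure(list(values = x, alpha = 0.185,
                                   medium_ri = 1.337, pitch = rep(218.5, 3)),
                              class = "protein_density_map")
  expect_equal(center_of_mass(mk(v3s), v3s > 0) -
                 center_of_mass(mk(v3), v3 > 0),
               c(2 * 218.5, 0, 0), tolerance = 1e-9)
  expect_error(center_of_mass(mk(array(0, dm)), array(TRUE, dm)),
               class = "istomo_degenerate_error")
})

test_that("hyperbolic fits recover noiseless parameters to 1e-6", {
  t <- seq(0, 300, by = 3)
  for (par in list(c(106.16, 39.63), c(7.48, 37.84), c(1.74, 14.56))) {
    y <- par[1] * t / (t + par[2])
    f <- fit_hyperbola(t, y)
    expect_equal(f$y_max, par[1], tolerance = 1e-6)
    expect_equal(f$tau_half, par[2], tolerance = 1e-6)
    expect_equal(f$rho, 1, tolerance = 1e-9)
    # half-max identity on the fitted curve
    expect_equal(f$y_max * f$tau_half / (f$tau_half + f$tau_half),
                 f$y_max / 2)
  }
  expect_error(fit_hyperbola(c(0, 3), c(0, 1)), class = "istomo_data_error")
})

test_that("fits stay accurate under measurement noise", {
  t <- seq(0, 300, by = 3)
  y0 <- 106.16 * t / (t + 39.63)
  set.seed(11)
  errs <- replicate(100, {
    y <- y0 + rnorm(length(t), sd = 0.02 * 106.16)
    abs(fit_hyperbola(t, y)$tau_half - 39.63) / 39.63
  })
  expect_lt(median(errs), 0.05)
})

test_that("rate windows interpolate displacement slopes", {
  t <- seq(0, 150, by = 3)
  rw <- rate_windows(t, 0.004 * t)  # linear, 4 nm/s in um units
  expect_equal(rw$early_nm_per_s, 4, tolerance = 1e-9)
  expect_equal(rw$late_nm_per_s, 4, tolerance = 1e-9)

  d <- 7.48 * t / (t + 37.84)
  rw2 <- rate_windows(t, d)
  expect_gt(rw2$early_nm_per_s, rw2$late_nm_per_s)

  rw3 <- rate_windows(t, rep(1.5, length(t)))
  expect_equal(rw3$early_nm_per_s, 0)
  expect_error(rate_windows(seq(0, 50, 5), seq(0, 50, 5) * 0.01),
               class = "istomo_range_error")
})

test_that("region histograms share bins and respect the phantom ordering", {
  sp <- equal_spheres_spec(grid = 32L, radius = 1300,
                           ri = c(1.360, 1.350), seed = 3L)
  sp$effector$granule_n <- 4L
  sp$effector$granule_ri <- 1.377
  tr <- make_conjugate(sp)
  gmask <- tr$tom$values >= 1.377 - 1e-9
  regions <- list(body = tr$pair$effector & !gmask, granules = gmask,
                  background = tr$tom$values <= 1.337)
  h <- region_histogram(tr$tom, regions)
  expect_gt(h$mean[h$region == "granules"], h$mean[h$region == "body"])
  expect_equal(h$sd[h$region == "background"], 0)
  # disjoint-region additivity: counts of the union = sum of counts
  hists <- attr(h, "histograms")
  hu <- region_histogram(tr$tom,
                         list(all = regions$body | regions$granules))
  expect_equal(sum(hists$body) + sum(hists$granules), sum(attr(hu, "histograms")$all))
  expect_warning(region_histogram(tr$tom, list(a = tr$pair$effector,
                                               b = array(FALSE, dim(gmask)))),
                 "empty")
})

test_that("Wilcoxon comparisons are exact for small untied samples", {
  w <- wilcoxon_test(c(2, 4, 6, 8, 10), c(1, 2, 3, 4, 5), paired = TRUE)
  expect_equal(w$p_value, 0.0625)  # 2 / 2^5
  expect_error(wilcoxon_test(1:4, 1:4, paired = TRUE),
               class = "istomo_degenerate_error")
  w2 <- wilcoxon_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w2$p_value, 0.1)    # 2 / C(6, 3)
  expect_error(wilcoxon_test(numeric(0), 1:3),
               class = "istomo_data_error")
})

test_that("max-z projection is masked, idempotent and locates voxels", {
  dm <- c(6, 7, 8)
  v <- array(0, dm)
  v[3, 4, 5] <- 2
  pm <- project_max_z(v)
  expect_equal(pm[4, 5], 2)
  expect_equal(sum(pm != 0), 1)
  slab <- array(1.5, dm)
  expect_true(all(project_max_z(slab) == 1.5))
  # projecting an already-flat field changes nothing
  expect_equal(max(pm), max(project_max_z(array(pm, c(1, dim(pm))))))
})

test_that("density-derived quantities scale linearly with 1/alpha", {
  tr <- make_conjugate(equal_spheres_spec(grid = 24L, radius = 1000,
                                          sep_frac = 0.95))
  is_mask <- synapse_mask(tr$pair, 2L)
  m1 <- total_is_protein(ri_to_density(tr$tom, alpha = 0.185), is_mask)
  m2 <- total_is_protein(ri_to_density(tr$tom, alpha = 0.37), is_mask)
  expect_equal(m1, 2 * m2, tolerance = 1e-12)
})
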