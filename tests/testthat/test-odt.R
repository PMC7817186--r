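test_that("a zero-contrast phantom scatters nothing", {
  tz <- tomogram(array(1.337, c(24, 24, 24)))
  hz <- forward_scatter(tz, volume_metadata(n_illuminations = 3L))
  psi <- istomo:::rytov_set(hz)$fields
  expect_lt(max(vapply(psi, function(f) max(Mod(f)), numeric(1))), 1e-9)
})

test_that("a thin homogeneous slab delays the phase by 2 pi dn d / lambda", {
  n <- array(1.337, c(64, 64, 64))
  n[30:33, , ] <- 1.340  # 4-voxel slab, dn = 0.003
  hs <- forward_scatter(tomogram(n, pitch = 218.5),
                        volume_metadata(n_illuminations = 1L))
  psi <- istomo:::rytov_set(hs)$fields[[1]]
  expected <- 2 * pi * 0.003 * 4 * 218.5 / 532
  expect_equal(mean(Im(psi)), expected, tolerance = 2e-3)
})

test_that("the forward spectrum of a ball matches its closed-form transform", {
  pitch <- 218.5
  Rs <- 1500
  dn <- 0.01
  nm <- 1.337
  sp <- phantom_spec(
    shape = c(64, 64, 64), pitch = pitch,
    effector = phantom_cell(center = c(0, 0, 0), radius = Rs,
                            cyto_ri = nm + dn, core_radius = 0),
    target = phantom_cell(center = c(5000, 0, 0), radius = 0,
                          cyto_ri = 1.35),
    antialias = 3L)
  tr <- make_conjugate(sp)
  k0 <- 2 * pi / 532
  km <- k0 * nm
  f0 <- k0^2 * ((nm + dn)^2 - nm^2)
  Fhat <- fft(k0^2 * (tr$tom$values^2 - nm^2)) * pitch^3
  dm <- rep(64L, 3)
  kl <- 2 * pi * istomo:::fft_freq(64, pitch)
  kyg <- matrix(kl, 64, 64)
  kxg <- t(kyg)
  pass <- kyg^2 + kxg^2 <= (k0 * 1.2)^2
  kz <- sqrt(pmax(km^2 - kyg^2 - kxg^2, 0))
  idx <- istomo:::spectrum_indices(kz - km, kyg, kxg, dm, rep(pitch, 3),
                                   pass)
  ok <- which(!is.na(idx))
  dk <- 2 * pi / (64 * pitch)
  iz <- round((kz - km) / dk)[ok]
  iy <- round(kyg / dk)[ok]
  ix <- round(kxg / dk)[ok]
  qn <- dk * sqrt(iz^2 + iy^2 + ix^2)
  ball <- ifelse(qn < 1e-12, f0 * 4 / 3 * pi * Rs^3,
                 f0 * 4 * pi * (sin(qn * Rs) - qn * Rs * cos(qn * Rs)) /
                   qn^3)
  ctr <- 32.5  # ball centre in voxel coordinates
  phase <- exp(-2i * pi * (iz + iy + ix) * (ctr - 1) / 64)
  rel <- sqrt(mean(Mod(Fhat[idx[ok]] - ball * phase)^2)) /
    sqrt(mean(Mod(ball)^2))
  expect_lt(rel, 0.02)
})

test_that("forward scattering flags contrast beyond the Rytov validity bound", {
  n <- array(1.337, c(16, 16, 16))
  n[8, 8, 8] <- 1.40
  expect_warning(forward_scatter(tomogram(n), volume_metadata(n_illuminations = 1L)),
                 "weak-scattering")
  expect_error(forward_scatter(tomogram(n), volume_metadata(n_illuminations = 1L),
                               strict = TRUE),
               class = "istomo_validity_error")
})

test_that("off-axis demodulation recovers amplitude and phase", {
  N <- 64
  R <- outer(exp(2i * pi * 16 * (0:(N - 1)) / N),
             exp(2i * pi * 12 * (0:(N - 1)) / N))
  # reference-only field: flat amplitude 1, flat phase 0
  r <- retrieve_field(Mod(1 + R)^2, c(16, 12))
  expect_lt(sd(r$amplitude), 1e-12)
  expect_equal(mean(r$amplitude), 1, tolerance = 1e-12)
  expect_lt(diff(range(r$phase - mean(r$phase))), 1e-10)

  # known smooth Gaussian phase recovered to < 1e-3 rad RMS
  g <- matrix(seq(-1, 1, length.out = N), N, N)
  phi <- 2.5 * exp(-(g^2 + t(g)^2) / 0.18)
  r2 <- retrieve_field(Mod(exp(1i * phi) + R)^2, c(16, 12))
  ph <- r2$phase - mean(r2$phase - phi)
  expect_lt(sqrt(mean((ph - phi)^2)), 1e-3)

  expect_error(retrieve_field(Mod(1 + R)^2, c(0, 0)),
               class = "istomo_carrier_error")
})

test_that("the Rytov field is the unwrapped complex log of total/incident", {
  u <- matrix(exp(0.3 + 0.4i), 8, 8)
  expect_lt(max(Mod(rytov_field(u, u))), 1e-12)

  inc <- matrix(1 + 0i, 32, 32)
  g <- matrix(seq(-1, 1, length.out = 32), 32, 32)
  phi <- 2.0 * exp(-(g^2 + t(g)^2) / 0.5)
  psi <- rytov_field(inc * exp(1i * phi), inc)
  expect_lt(max(abs(Im(psi) - phi)), 1e-9)

  # smooth phase spanning > 2 pi is unwrapped correctly
  phi2 <- 7 * exp(-(g^2 + t(g)^2) / 0.6)
  psi2 <- rytov_field(inc * exp(1i * phi2), inc)
  expect_lt(max(abs(Im(psi2) - phi2)), 1e-6)

  expect_error(rytov_field(inc, inc * 0), class = "istomo_division_error")
})

test_that("spectrum mapping fills the Ewald caps consistently", {
  sp <- single_sphere_spec(grid = 32L, radius_vox = 5, ri = 1.347)
  tr <- make_conjugate(sp)
  # DC of the normal-incidence field maps to the spectrum origin
  hs1 <- forward_scatter(tr$tom, volume_metadata(n_illuminations = 1L))
  acc1 <- map_to_spectrum(hs1)
  expect_gt(acc1$counts[1, 1, 1], 0)

  # occupancy grows with the number of illuminations
  counts <- vapply(c(1L, 9L, 25L, 49L), function(nil) {
    acc <- map_to_spectrum(forward_scatter(tr$tom,
                                           volume_metadata(n_illuminations = nil)))
    sum(acc$counts > 0)
  }, numeric(1))
  expect_true(all(diff(counts) > 0))

  # a point scatterer reconstructs at its true location
  n <- array(1.337, c(32, 32, 32))
  n[17, 15, 19] <- 1.347
  hp <- forward_scatter(tomogram(n), volume_metadata())
  rec <- regularize_nonneg(map_to_spectrum(hp), iterations = 0)
  peak <- arrayInd(which.max(rec$values), dim(rec$values))
  expect_true(all(abs(peak - c(17, 15, 19)) <= 1))
})

test_that("non-negativity regularization behaves as an alternating projection", {
  sp <- single_sphere_spec(grid = 32L, radius_vox = 6, ri = 1.357)
  tr <- make_conjugate(sp)
  acc <- map_to_spectrum(forward_scatter(tr$tom, volume_metadata()))
  rec0 <- regularize_nonneg(acc, iterations = 0)
  rec <- regularize_nonneg(acc, iterations = 40)

  sup <- tr$pair$effector
  rmse0 <- sqrt(mean((rec0$values[sup] - tr$tom$values[sup])^2))
  rmse <- sqrt(mean((rec$values[sup] - tr$tom$values[sup])^2))
  expect_lt(rmse, rmse0)
  expect_gte(min(rec$values - rec$medium_ri), -1e-9)

  # measured-frequency fidelity after the final replacement step
  meas <- acc$counts > 0
  vals <- acc$spectrum
  vals[meas] <- vals[meas] / acc$counts[meas]
  expect_lt(max(Mod(attr(rec, "spectrum")[meas] - vals[meas])), 1e-9)

  # axial elongation of a point reconstruction (missing cone)
  n <- array(1.337, c(64, 64, 64))
  n[33, 33, 33] <- 1.342
  rp <- regularize_nonneg(map_to_spectrum(
    forward_scatter(tomogram(n, pitch = 60), volume_metadata())),
    iterations = 0)
  fwhm <- function(v) {
    v <- pmax(v, 0) / max(v)
    sum(v >= 0.5)
  }
  expect_gt(fwhm(rp$values[, 33, 33] - 1.337),
            fwhm(rp$values[33, , 33] - 1.337))
})

test_that("fully sampled non-negative input is a fixed point", {
  # build an accumulator whose spectrum is fully occupied
  sp <- single_sphere_spec(grid = 16L, radius_vox = 3, ri = 1.347)
  tr <- make_conjugate(sp)
  k0 <- 2 * pi / 532
  f <- k0^2 * (tr$tom$values^2 - tr$tom$medium_ri^2)
  acc <- structure(list(spectrum = fft(f) * prod(tr$tom$pitch),
                        counts = array(1L, dim(f)),
                        n_discarded = 0L, pitch = tr$tom$pitch,
                        wavelength = 532, medium_ri = tr$tom$medium_ri),
                   class = "spectrum_accumulator")
  rec <- regularize_nonneg(acc, iterations = 5)
  expect_equal(rec$values, tr$tom$values, tolerance = 1e-9)
})

test_that("resolution bounds follow the Nyquist-period formulas", {
  expect_equal(compute_resolution(volume_metadata())$lateral_nm,
               532 / (2 * 2.4), tolerance = 1e-12)
  expect_equal(compute_resolution(volume_metadata(na_illumination = 0))$lateral_nm,
               532 / 2.4, tolerance = 1e-12)
  r <- compute_resolution(volume_metadata())
  expect_gte(r$axial_nm, r$lateral_nm)
  # periods increase monotonically as the apertures close
  nas <- seq(1.2, 0.2, by = -0.2)
  lats <- vapply(nas, function(na)
    compute_resolution(volume_metadata(na_illumination = na,
                                       na_detection = na))$lateral_nm,
    numeric(1))
  expect_true(all(diff(lats) > 0))
  expect_error(compute_resolution(volume_metadata(na_detection = 1.4),
                                  medium_ri = 1.337),
               class = "istomo_domain_error")
  # the detection-only axial variant is also available
  expect_gt(compute_resolution(volume_metadata(),
                               variant = "detection")$axial_nm,
            0)
})

test_that("RI-to-density conversion is the linear RI-increment rule", {
  mk <- function(dn) tomogram(array(1.337 + dn, c(4, 4, 4)))
  expect_equal(ri_to_density(mk(0))$values[1], 0)
  expect_equal(ri_to_density(mk(0.0185), alpha = 0.185)$values[1], 100)
  expect_equal(ri_to_density(mk(0.00185), alpha = 0.185)$values[1], 10)
  # linear and invertible where not clamped
  d1 <- ri_to_density(mk(0.004))$values[1]
  d2 <- ri_to_density(mk(0.008))$values[1]
  expect_equal(d2, 2 * d1)
  # negative contrast clamps to zero with a logged count
  neg <- ri_to_density(mk(-0.002))
  expect_equal(neg$values[1], 0)
  expect_equal(attr(neg, "clamped"), 64L)
})
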