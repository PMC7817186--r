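# Optical diffraction tomography: first-order (Rytov) forward model and the
# matching inverse via the Fourier diffraction theorem, plus missing-cone
# regularization by non-negativity, theoretical resolution bounds, and the
# RI-to-protein-density conversion.
#
# Conventions. k0 = 2*pi/lambda (vacuum, rad/nm); km = k0 * n_m. The object
# function is f(r) = k0^2 (n(r)^2 - n_m^2), non-negative for cells in
# medium. Each retrieved 2D field samples the object's 3D spectrum on the
# Ewald cap K - k_i with the Wolf weight i/(2 kz); the discrete forward
# model reads the phantom's DFT at the nearest spectrum grid point, and the
# reconstruction deposits at that same point, so the two form a consistent
# transform pair. Fields are (y, x) matrices; volumes (z, y, x).

illumination_directions <- function(meta, medium_ri) {
  n <- meta$n_illuminations
  dirs <- matrix(0, n, 3)
  dirs[1, ] <- c(1, 0, 0)
  if (n > 1) {
    sin_t <- meta$na_illumination / medium_ri
    if (sin_t > 1)
      stop_istomo("illumination NA exceeds the medium RI",
                  "istomo_domain_error")
    cos_t <- sqrt(1 - sin_t^2)
    phi <- 2 * pi * (seq_len(n - 1) - 1) / (n - 1)
    dirs[-1, ] <- cbind(cos_t, sin_t * sin(phi), sin_t * cos(phi))
  }
  dirs
}

hologram_set <- function(fields, directions, wavelength, pitch, medium_ri,
                         shape, kind = c("total", "rytov")) {
  kind <- match.arg(kind)
  stopifnot(length(fields) == nrow(directions))
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-9))
    stop_istomo("illumination directions must be unit vectors",
                "istomo_value_error")
  structure(list(fields = fields, directions = directions,
                 wavelength = wavelength, pitch = expand_pitch(pitch),
                 medium_ri = medium_ri, shape = as.integer(shape),
                 kind = kind),
            class = "hologram_set")
}

# Incident plane wave at the z = 0 measurement plane (voxel index 1 layer).
incident_field <- function(dir, km, dm, pitch) {
  y <- (seq_len(dm[2]) - 1) * pitch[2]
  x <- (seq_len(dm[3]) - 1) * pitch[3]
  outer(exp(1i * km * dir[2] * y), exp(1i * km * dir[3] * x))
}

#' Simulate angle-scanned fields from a phantom (first-order forward model)
#'
#' For each illumination on the standard layout (one normal-incidence beam
#' plus a cone at the illumination NA, azimuthally uniform), synthesizes the
#' complex transmitted field by sampling the phantom's scattering-potential
#' spectrum on the corresponding Ewald cap. Valid only for weak scatterers
#' (max RI contrast <= 0.05); stronger contrast triggers a warning, or an
#' error with `strict = TRUE`.
#'
#' @param truth a `phantom_truth` or a [tomogram()].
#' @param meta a [volume_metadata()].
#' @param carrier optional integer off-axis carrier (cycles across the
#'   field, `c(y, x)`); when given, real off-axis holograms are attached.
#' @param strict escalate the weak-scattering warning to an error.
#' @return A `hologram_set` of total complex fields (plus `holograms` when
#'   a carrier is requested).
#' @export
forward_scatter <- function(truth, meta, carrier = NULL, strict = FALSE) {
  tom <- if (inherits(truth, "phantom_truth")) truth$tom else truth
  stopifnot(inherits(tom, "tomogram"), inherits(meta, "volume_metadata"))
  n <- tom$values
  nm <- tom$medium_ri
  contrast <- max(n) - nm
  if (contrast > 0.05) {
    msg <- sprintf("max RI contrast %.3f exceeds the weak-scattering bound 0.05",
                   contrast)
    if (strict) stop_istomo(msg, "istomo_validity_error") else warning(msg)
  }
  dm <- dim(n)
  pitch <- tom$pitch
  k0 <- 2 * pi / meta$wavelength
  km <- k0 * nm
  f <- k0^2 * (n^2 - nm^2)
  Fhat <- fft(f) * prod(pitch)
  dirs <- illumination_directions(meta, nm)

  ky <- 2 * pi * fft_freq(dm[2], pitch[2])
  kx <- 2 * pi * fft_freq(dm[3], pitch[3])
  kyg <- matrix(ky, dm[2], dm[3])
  kxg <- matrix(kx, dm[2], dm[3], byrow = TRUE)
  klat2 <- kyg^2 + kxg^2
  pass <- klat2 <= min((k0 * meta$na_detection)^2, km^2)
  kz <- sqrt(pmax(km^2 - klat2, 0))

  fields <- vector("list", nrow(dirs))
  for (j in seq_len(nrow(dirs))) {
    ki <- km * dirs[j, ]
    Us <- matrix(0i, dm[2], dm[3])
    idx <- spectrum_indices(kz - ki[1], kyg - ki[2], kxg - ki[3], dm, pitch,
                            pass)
    ok <- !is.na(idx)
    Us[ok] <- (1i / (2 * kz[ok])) * Fhat[idx[ok]]
    u_r <- fft(Us, inverse = TRUE) / (dm[2] * pitch[2] * dm[3] * pitch[3])
    u_inc <- incident_field(dirs[j, ], km, dm, pitch)
    psi <- u_r / u_inc
    fields[[j]] <- u_inc * exp(psi)
  }
  hs <- hologram_set(fields, dirs, meta$wavelength, pitch, nm, dm, "total")
  if (!is.null(carrier)) hs$holograms <- synth_holograms(hs, carrier)
  hs
}

# Flattened indices into the 3D spectrum grid for scattering vectors
# (qz, qy, qx); NA where the vector falls outside the grid or `pass` fails.
spectrum_indices <- function(qz, qy, qx, dm, pitch, pass) {
  dk <- 2 * pi / (dm * pitch)
  iz <- round(qz / dk[1])
  iy <- round(qy / dk[2])
  ix <- round(qx / dk[3])
  ok <- pass &
    iz >= -floor((dm[1] - 1) / 2) & iz <= floor((dm[1] - 1) / 2) &
    iy >= -floor((dm[2] - 1) / 2) & iy <= floor((dm[2] - 1) / 2) &
    ix >= -floor((dm[3] - 1) / 2) & ix <= floor((dm[3] - 1) / 2)
  idx <- rep(NA_real_, length(qz))
  wrap <- function(i, n) ifelse(i < 0, i + n, i)
  idx[ok] <- 1 + wrap(iz[ok], dm[1]) +
    dm[1] * (wrap(iy[ok], dm[2]) + dm[2] * wrap(ix[ok], dm[3]))
  idx
}

#' Synthesize off-axis holograms from complex fields
#'
#' @param hs a `hologram_set` of total fields.
#' @param carrier integer carrier frequency `c(y, x)` in cycles across the
#'   field of view.
#' @return List of real hologram matrices `|u + R|^2`.
#' @export
synth_holograms <- function(hs, carrier) {
  dm <- dim(hs$fields[[1]])
  yi <- (seq_len(dm[1]) - 1) / dm[1]
  xi <- (seq_len(dm[2]) - 1) / dm[2]
  R <- outer(exp(2i * pi * carrier[1] * yi), exp(2i * pi * carrier[2] * xi))
  lapply(hs$fields, function(u) Mod(u + R)^2)
}

# Phase-derivative quality map used to guide unwrapping: high where the
# wrapped phase is locally smooth.
phase_quality <- function(wrapped) {
  wrap_pi <- function(x) (x + pi) %% (2 * pi) - pi
  gy <- wrap_pi(diff(wrapped))
  gx <- wrap_pi(t(diff(t(wrapped))))
  q <- matrix(0, nrow(wrapped), ncol(wrapped))
  q[-1, ] <- q[-1, ] + gy^2
  q[-nrow(q), ] <- q[-nrow(q), ] + gy^2
  q[, -1] <- q[, -1] + gx^2
  q[, -ncol(q)] <- q[, -ncol(q)] + gx^2
  -q
}

unwrap_phase2 <- function(wrapped) {
  cpp_unwrap2(wrapped, phase_quality(wrapped))
}

#' Retrieve a complex field from an off-axis hologram
#'
#' Demodulates by Fourier side-band cropping: the spectrum is shifted so the
#' carrier side-band sits at DC, low-pass filtered, and inverse transformed;
#' the phase is then unwrapped in 2D (quality-guided).
#'
#' @param hologram real matrix `|u + R|^2`.
#' @param carrier integer carrier `c(y, x)` in cycles across the field; its
#'   magnitude must exceed the field bandwidth for the side-band to separate.
#' @param bandwidth crop radius in frequency indices (default: half the
#'   carrier magnitude).
#' @return List with `field` (complex), `amplitude` and `phase` (unwrapped).
#' @export
retrieve_field <- function(hologram, carrier, bandwidth = NULL) {
  dm <- dim(hologram)
  cmag <- sqrt(sum(carrier^2))
  if (cmag < 2)
    stop_istomo("carrier frequency not separable from the baseband",
                "istomo_carrier_error")
  bandwidth <- bandwidth %||% floor(cmag / 2)
  if (bandwidth < 1 || bandwidth > cmag - 1)
    stop_istomo("side-band bandwidth overlaps the baseband",
                "istomo_carrier_error")
  G <- fft(hologram)
  # the u R* side-band (the unconjugated field) sits at -carrier; shift it
  # to DC
  sh <- function(i, n, c) ((i - 1 - c) %% n) + 1
  G <- G[sh(seq_len(dm[1]), dm[1], carrier[1]),
         sh(seq_len(dm[2]), dm[2], carrier[2])]
  fy <- fft_freq(dm[1]) * dm[1]
  fx <- fft_freq(dm[2]) * dm[2]
  mask <- outer(fy^2, fx^2, "+") <= bandwidth^2
  u <- fft(G * mask, inverse = TRUE) / length(G)
  phase <- unwrap_phase2(Arg(u))
  list(field = u, amplitude = Mod(u), phase = phase)
}

#' Rytov field of a measured total field
#'
#' Complex logarithm of `total / incident`: the real part is the
#' log-amplitude, the imaginary part the 2D-unwrapped phase delay.
#'
#' @param total,incident complex matrices of one shape.
#' @return Complex matrix `log|t/i| + i * unwrap(arg(t/i))`.
#' @export
rytov_field <- function(total, incident) {
  assert_same_shape(total, incident, "total and incident fields")
  if (any(Mod(incident) == 0))
    stop_istomo("incident field contains zeros", "istomo_division_error")
  ratio <- total / incident
  log(Mod(ratio)) + 1i * unwrap_phase2(Arg(ratio))
}

rytov_set <- function(hs) {
  if (hs$kind == "rytov") return(hs)
  km <- 2 * pi / hs$wavelength * hs$medium_ri
  hs$fields <- lapply(seq_along(hs$fields), function(j) {
    u_inc <- incident_field(hs$directions[j, ], km, hs$shape, hs$pitch)
    rytov_field(hs$fields[[j]], u_inc)
  })
  hs$kind <- "rytov"
  hs
}

#' Map Rytov fields onto the 3D scattering spectrum
#'
#' Places each field's 2D transform on the Ewald half-sphere cap of its
#' illumination; overlapping contributions are averaged via occupancy
#' counts. Frequencies beyond the detection NA or outside the grid are
#' discarded and counted.
#'
#' @param hs a `hologram_set` (total fields are Rytov-transformed first).
#' @param na_detection detection NA limiting the accepted lateral
#'   frequencies.
#' @return A `spectrum_accumulator`: complex `spectrum`, integer `counts`,
#'   `n_discarded`, and the physical metadata.
#' @export
map_to_spectrum <- function(hs, na_detection = 1.2) {
  stopifnot(inherits(hs, "hologram_set"))
  hs <- rytov_set(hs)
  dm <- hs$shape
  pitch <- hs$pitch
  k0 <- 2 * pi / hs$wavelength
  km <- k0 * hs$medium_ri

  ky <- 2 * pi * fft_freq(dm[2], pitch[2])
  kx <- 2 * pi * fft_freq(dm[3], pitch[3])
  kyg <- matrix(ky, dm[2], dm[3])
  kxg <- matrix(kx, dm[2], dm[3], byrow = TRUE)
  klat2 <- kyg^2 + kxg^2
  pass <- klat2 <= min((k0 * na_detection)^2, km^2)
  kz <- sqrt(pmax(km^2 - klat2, 0))

  spec <- array(0i, dm)
  counts <- array(0L, dm)
  discarded <- 0L
  for (j in seq_along(hs$fields)) {
    ki <- km * hs$directions[j, ]
    u_inc <- incident_field(hs$directions[j, ], km, dm, pitch)
    Us <- fft(u_inc * hs$fields[[j]]) * pitch[2] * pitch[3]
    idx <- spectrum_indices(kz - ki[1], kyg - ki[2], kxg - ki[3], dm, pitch,
                            pass)
    ok <- !is.na(idx)
    discarded <- discarded + sum(!ok)
    vals <- Us[ok] * (2 * kz[ok]) / 1i
    ii <- idx[ok]
    # accumulate (duplicated indices within one cap are averaged too)
    for (grp in split(seq_along(ii), ii)) {
      at <- ii[grp[1]]
      spec[at] <- spec[at] + sum(vals[grp])
      counts[at] <- counts[at] + length(grp)
    }
  }
  structure(list(spectrum = spec, counts = counts,
                 n_discarded = discarded, pitch = pitch,
                 wavelength = hs$wavelength, medium_ri = hs$medium_ri),
            class = "spectrum_accumulator")
}

#' Reconstruct a tomogram with non-negativity regularization
#'
#' Gerchberg-Papoulis-style alternating projections: clamp the RI contrast
#' to be non-negative in object space, then restore the measured Fourier
#' samples. Fills the missing cone left by the limited illumination/
#' detection apertures. `iterations = 0` returns the unregularized
#' inversion.
#'
#' @param acc a `spectrum_accumulator` from [map_to_spectrum()].
#' @param iterations maximum number of projection iterations.
#' @param tolerance stop when the relative object change drops below this.
#' @return A [tomogram()]; attributes `history` (relative changes) and
#'   `spectrum` (the final measured-value-restored spectrum).
#' @export
regularize_nonneg <- function(acc, iterations = 100L, tolerance = 1e-6) {
  stopifnot(inherits(acc, "spectrum_accumulator"), iterations >= 0)
  dm <- dim(acc$spectrum)
  vvol <- prod(acc$pitch)
  k0 <- 2 * pi / acc$wavelength
  meas <- acc$counts > 0L
  vals <- acc$spectrum
  vals[meas] <- vals[meas] / acc$counts[meas]

  to_object <- function(V) Re(fft(V, inverse = TRUE)) / length(V) / vvol
  f <- to_object(vals)
  history <- numeric(0)
  Vfin <- vals
  if (iterations > 0) {
    for (it in seq_len(iterations)) {
      f_prev <- f
      f_cl <- pmax(f, 0)
      V <- fft(f_cl) * vvol
      V[meas] <- vals[meas]
      Vfin <- V
      f <- to_object(V)
      rel <- sqrt(sum((f - f_prev)^2)) / max(sqrt(sum(f_prev^2)), 1e-300)
      history <- c(history, rel)
      if (rel < tolerance) break
    }
    f <- pmax(f, 0)
  }
  n <- sqrt(pmax(acc$medium_ri^2 + f / k0^2, 0))
  out <- tomogram(array(n, dm), pitch = acc$pitch,
                  medium_ri = acc$medium_ri)
  attr(out, "history") <- history
  attr(out, "spectrum") <- Vfin
  out
}

#' Theoretical resolution bounds (Nyquist sampling periods)
#'
#' Lateral period `lambda / (2 (NA_ill + NA_det))`. The axial period uses
#' either both cones (`variant = "sum"`) or the detection cone alone
#' (`variant = "detection"`), since the axial support depends on how the
#' illumination scan fills the Ewald shells.
#'
#' @param meta a [volume_metadata()].
#' @param medium_ri RI of the medium.
#' @param variant axial formula variant.
#' @return List with `lateral_nm`, `axial_nm`, `variant`.
#' @export
compute_resolution <- function(meta, medium_ri = 1.337,
                               variant = c("sum", "detection")) {
  variant <- match.arg(variant)
  nm <- medium_ri
  if (meta$na_illumination > nm || meta$na_detection > nm)
    stop_istomo("NA exceeds the medium RI", "istomo_domain_error")
  lam <- meta$wavelength
  lateral <- lam / (2 * (meta$na_illumination + meta$na_detection))
  cone <- function(na) nm - sqrt(nm^2 - na^2)
  axial <- switch(variant,
    sum = lam / (2 * (cone(meta$na_illumination) +
                        cone(meta$na_detection))),
    detection = lam / (2 * cone(meta$na_detection)))
  list(lateral_nm = lateral, axial_nm = axial, variant = variant)
}

#' Convert RI contrast to protein density
#'
#' Applies the linear RI increment: `c(v) = (n(v) - n_m) / alpha`, reported
#' in fg/um^3 (1 g/mL = 1000 fg/um^3). Negative contrasts clamp to zero;
#' the clamped-voxel count is attached as attribute `clamped`.
#'
#' @param tom a [tomogram()].
#' @param alpha RI increment dRI/dc in mL/g.
#' @return A `protein_density_map`: `values` (fg/um^3), `alpha`,
#'   `medium_ri`, `pitch`.
#' @export
ri_to_density <- function(tom, alpha = 0.185) {
  stopifnot(inherits(tom, "tomogram"))
  if (alpha <= 0) stop_istomo("alpha must be > 0", "istomo_value_error")
  contrast <- tom$values - tom$medium_ri
  clamped <- sum(contrast < 0)
  contrast[contrast < 0] <- 0
  out <- structure(list(values = contrast / alpha * 1000,
                        alpha = alpha, medium_ri = tom$medium_ri,
                        pitch = tom$pitch),
                   class = "protein_density_map")
  attr(out, "clamped") <- clamped
  out
}
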