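# Volume file I/O. The native container is an ImageJ-compatible 32-bit float
# TIFF stack (one page per z-slice, axis order z, y, x) plus a JSON sidecar
# ("<file>.json") carrying the physical metadata. Because float TIFF samples
# are stored in [0, 1], values are affinely mapped with a power-of-two scale
# recorded in the sidecar; the mapping itself introduces no rounding beyond
# the float32 quantization inherent to the format.

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

vol_to_pages <- function(values) {
  lapply(seq_len(dim(values)[1]), function(z) values[z, , ])
}

pages_to_vol <- function(pages) {
  dm <- dim(pages[[1]])
  arr <- array(0, c(length(pages), dm[1], dm[2]))
  for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
  arr
}

# affine storage mapping: offset = min(v, 0-floor), power-of-two scale
write_float_tiff <- function(values, path, meta = list()) {
  offset <- min(values, 0)
  rng <- max(values - offset, 1e-12)
  scale <- 2^ceiling(log2(rng))
  stored <- (values - offset) / scale
  suppressWarnings(
    tiff::writeTIFF(vol_to_pages(stored), path, bits.per.sample = 32L,
                    reduce = FALSE))
  write_sidecar(path, c(meta, list(offset = offset, scale = scale)))
  invisible(path)
}

read_float_tiff <- function(path, min_pages = 2L) {
  if (!file.exists(path))
    stop_istomo(sprintf("file not found: %s", path), "istomo_io_error")
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = FALSE),
                    error = function(e)
                      stop_istomo(sprintf("unreadable TIFF: %s (%s)", path,
                                          conditionMessage(e)),
                                  "istomo_format_error"))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < min_pages)
    stop_istomo("input is not a 3D stack (fewer than 2 pages)",
                "istomo_shape_error")
  if (length(dim(pages[[1]])) != 2L)
    stop_istomo("TIFF pages must be single-channel 2D slices",
                "istomo_shape_error")
  meta <- read_sidecar(path)
  v <- pages_to_vol(pages)
  if (!is.null(meta))
    v <- v * (meta$scale %||% 1) + (meta$offset %||% 0)
  list(values = v, meta = meta)
}

#' Write / read an RI tomogram
#'
#' Writes the volume as a multi-page 32-bit float TIFF with a JSON sidecar
#' holding pitch, medium RI, timestamp and the affine storage mapping.
#' `read_tomogram()` restores the values and metadata; if the sidecar is
#' missing (e.g. a foreign TIFF), metadata are filled from `defaults` with
#' a warning.
#'
#' @param tom a [tomogram()].
#' @param path output `.tif`/`.tiff` path.
#' @return `write_tomogram()` returns `path` invisibly; `read_tomogram()`
#'   returns a [tomogram()].
#' @export
write_tomogram <- function(tom, path) {
  stopifnot(inherits(tom, "tomogram"))
  write_float_tiff(tom$values, path,
                   list(kind = "tomogram", pitch_nm = tom$pitch,
                        medium_ri = tom$medium_ri,
                        timestamp = tom$timestamp))
}

#' @rdname write_tomogram
#' @param defaults a [run_config()] supplying pitch and medium RI when the
#'   sidecar is absent.
#' @export
read_tomogram <- function(path, defaults = run_config()) {
  r <- read_float_tiff(path)
  meta <- r$meta
  if (is.null(meta)) {
    warning(sprintf(paste0("no metadata sidecar for %s; using pitch %.1f nm",
                           " and medium RI %.3f from the run configuration"),
                    path, defaults$volume$pitch_nm[1],
                    defaults$volume$medium_ri))
    meta <- list(pitch_nm = defaults$volume$pitch_nm,
                 medium_ri = defaults$volume$medium_ri, timestamp = NULL)
  }
  tomogram(r$values, pitch = meta$pitch_nm, medium_ri = meta$medium_ri,
           timestamp = meta$timestamp)
}

#' Write / read a signed distance map
#'
#' Same float-TIFF container as tomograms; values are in voxel units with
#' the pitch recorded in the sidecar.
#'
#' @param sdm a `signed_distance_map`.
#' @param path output `.tif` path.
#' @export
write_distmap <- function(sdm, path) {
  stopifnot(inherits(sdm, "signed_distance_map"))
  write_float_tiff(sdm$values, path,
                   list(kind = "distmap", pitch_nm = sdm$pitch))
}

#' @rdname write_distmap
#' @export
read_distmap <- function(path, defaults = run_config()) {
  r <- read_float_tiff(path)
  pitch <- r$meta$pitch_nm %||% defaults$volume$pitch_nm
  structure(list(values = r$values, pitch = expand_pitch(pitch)),
            class = "signed_distance_map")
}

#' Write / read a segmentation mask set
#'
#' Stores the effector/target masks and the synapse (IS) mask in one 8-bit
#' multi-label TIFF. Because the IS mask may legitimately overlap the
#' dilated cell masks, labels are bit flags (1 effector, 2 target, 4 IS),
#' which makes the round trip lossless; the flag legend is written to the
#' sidecar.
#'
#' @param pair a [cell_mask_pair()].
#' @param is_mask logical 3D synapse mask of the same shape (may be empty).
#' @param path output `.tif` path.
#' @return `write_mask_set()` returns `path` invisibly; `read_mask_set()`
#'   returns `list(pair, is_mask)`.
#' @export
write_mask_set <- function(pair, is_mask, path) {
  stopifnot(inherits(pair, "cell_mask_pair"))
  assert_same_shape(pair$effector, is_mask, "cell masks and IS mask")
  lab <- 1 * pair$effector + 2 * pair$target + 4 * is_mask
  suppressWarnings(
    tiff::writeTIFF(vol_to_pages(lab / 255), path, bits.per.sample = 8L,
                    reduce = FALSE))
  write_sidecar(path, list(kind = "mask_set", pitch_nm = pair$pitch,
                           encoding = "bitflags",
                           flags = list(effector = 1, target = 2, is = 4)))
  invisible(path)
}

#' @rdname write_mask_set
#' @param defaults a [run_config()] supplying the pitch when the sidecar is
#'   absent.
#' @export
read_mask_set <- function(path, defaults = run_config()) {
  if (!file.exists(path))
    stop_istomo(sprintf("file not found: %s", path), "istomo_io_error")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lab <- round(pages_to_vol(pages) * 255)
  meta <- read_sidecar(path)
  pitch <- meta$pitch_nm %||% defaults$volume$pitch_nm
  flag <- function(bit) array(bitwAnd(lab, bit) > 0, dim(lab))
  list(pair = cell_mask_pair(flag(1), flag(2), pitch = pitch),
       is_mask = flag(4))
}

#' Write / read an angle-scanned field set
#'
#' Complex fields are stored as interleaved real/imaginary float pages
#' (2 pages per illumination); directions and physical metadata go to the
#' sidecar.
#'
#' @param hs a `hologram_set`.
#' @param path output `.tif` path.
#' @export
write_hologram_set <- function(hs, path) {
  stopifnot(inherits(hs, "hologram_set"))
  n <- length(hs$fields)
  dmf <- dim(hs$fields[[1]])
  stack <- array(0, c(2L * n, dmf))
  for (j in seq_len(n)) {
    stack[2L * j - 1L, , ] <- Re(hs$fields[[j]])
    stack[2L * j, , ] <- Im(hs$fields[[j]])
  }
  write_float_tiff(stack, path,
                   list(kind = "hologram_set", kindof = hs$kind,
                        directions = hs$directions,
                        wavelength_nm = hs$wavelength,
                        pitch_nm = hs$pitch, medium_ri = hs$medium_ri,
                        shape = hs$shape))
}

#' @rdname write_hologram_set
#' @export
read_hologram_set <- function(path) {
  r <- read_float_tiff(path)
  meta <- r$meta
  if (is.null(meta) || !identical(meta$kind, "hologram_set"))
    stop_istomo("not a stored field set (missing sidecar)",
                "istomo_format_error")
  n <- dim(r$values)[1] / 2L
  fields <- lapply(seq_len(n), function(j)
    r$values[2L * j - 1L, , ] + 1i * r$values[2L * j, , ])
  hologram_set(fields, matrix(unlist(meta$directions), ncol = 3),
               meta$wavelength_nm, meta$pitch_nm, meta$medium_ri,
               meta$shape, kind = meta$kindof)
}
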