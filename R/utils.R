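# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_istomo <- function(msg, class) {
  stop(structure(class = c(class, "istomo_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

assert_volume <- function(x, name = deparse(substitute(x))) {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop_istomo(sprintf("`%s` must be a 3D array", name), "istomo_shape_error")
  invisible(x)
}

assert_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b)))
    stop_istomo(sprintf("%s must share one shape (%s vs %s)", what,
                        paste(dim(a), collapse = "x"),
                        paste(dim(b), collapse = "x")),
                "istomo_shape_error")
  invisible(TRUE)
}

# Per-axis pitch as a length-3 (z, y, x) vector in nm.
expand_pitch <- function(pitch) {
  pitch <- as.numeric(pitch)
  if (length(pitch) == 1L) pitch <- rep(pitch, 3L)
  if (length(pitch) != 3L || any(!is.finite(pitch)) || any(pitch <= 0))
    stop_istomo("pitch must be 1 or 3 positive finite values (nm)",
                "istomo_value_error")
  pitch
}

# Offsets (z, y, x) of the digital Euclidean ball of radius r voxels.
ball_offsets <- function(r) {
  r <- as.integer(round(r))
  if (r < 0L) stop_istomo("radius must be >= 0", "istomo_value_error")
  g <- expand.grid(z = -r:r, y = -r:r, x = -r:r)
  g <- g[g$z^2 + g$y^2 + g$x^2 <= r^2, , drop = FALSE]
  as.matrix(g)
}

# 6-connected cross of radius r (r steps along each axis).
cross_offsets <- function(r) {
  r <- as.integer(round(r))
  out <- rbind(c(0L, 0L, 0L))
  if (r >= 1L)
    for (k in seq_len(r))
      out <- rbind(out,
                   c(k, 0L, 0L), c(-k, 0L, 0L),
                   c(0L, k, 0L), c(0L, -k, 0L),
                   c(0L, 0L, k), c(0L, 0L, -k))
  storage.mode(out) <- "integer"
  out
}

# Exact Euclidean distance of foreground voxels to the nearest background
# voxel centre (physical units given `spacing`, voxel units by default).
edt <- function(mask, spacing = c(1, 1, 1)) {
  assert_volume(mask)
  d <- cpp_edt(as.logical(mask), dim(mask), as.numeric(spacing))
  array(d, dim(mask))
}

# Distance of every voxel to the nearest voxel of `mask` (the feature set).
feature_distance <- function(mask, spacing = c(1, 1, 1)) {
  edt(!mask, spacing = spacing)
}

binary_dilate <- function(mask, offsets) {
  assert_volume(mask)
  array(cpp_morph(as.logical(mask), dim(mask), offsets, TRUE), dim(mask))
}

binary_erode <- function(mask, offsets) {
  assert_volume(mask)
  array(cpp_morph(as.logical(mask), dim(mask), offsets, FALSE), dim(mask))
}

binary_close <- function(mask, offsets) {
  neg <- offsets
  neg[] <- -neg
  binary_erode(binary_dilate(mask, offsets), neg)
}

label_components <- function(mask, connectivity = 26L) {
  assert_volume(mask)
  array(cpp_label(as.logical(mask), dim(mask), as.integer(connectivity)),
        dim(mask))
}

keep_largest_component <- function(mask, connectivity = 26L) {
  lab <- label_components(mask, connectivity)
  if (max(lab) <= 1L) return(list(mask = mask, removed = 0L))
  counts <- tabulate(lab[lab > 0L])
  keep <- which.max(counts)
  list(mask = lab == keep, removed = sum(mask) - counts[keep])
}

gaussian_smooth <- function(vol, sigma) {
  assert_volume(vol)
  array(cpp_gauss3(as.numeric(vol), dim(vol), sigma), dim(vol))
}

# Run `expr` under its own seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# DFT sample frequencies (cycles per unit), fftfreq convention.
fft_freq <- function(n, d = 1) {
  idx <- c(seq(0L, floor((n - 1) / 2)), seq(-floor(n / 2), -1L))
  idx / (n * d)
}

# Voxel-centre coordinate grids (nm) for a volume, centred on the grid.
voxel_coords <- function(dm, pitch) {
  lapply(1:3, function(a) (seq_len(dm[a]) - (dm[a] + 1) / 2) * pitch[a])
}
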