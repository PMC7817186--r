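# Classical annotation: the 4-hyper-parameter seeded-watershed pipeline used
# to produce training labels, and STAPLE consensus over repeated
# annotations.

#' Annotation hyper-parameters
#'
#' The four manual choices of the classical labelling pipeline: per-cell
#' seed locations, the RI threshold defining cell boundaries, the
#' morphological merge radius for over-segmented grains, and the Gaussian
#' smoothing width.
#'
#' @param seeds list of two integer matrices (voxel coordinates, rows =
#'   `(z, y, x)`), one per cell: first effector, then target.
#' @param ri_threshold RI value above which a voxel is foreground.
#' @param dilation_size radius (voxels) of the Euclidean-ball closing that
#'   merges fragmented grains.
#' @param gaussian_sigma Gaussian smoothing SD in voxels.
#' @return An object of class `annotation_params`.
#' @export
annotation_params <- function(seeds, ri_threshold = 1.345,
                              dilation_size = 1L, gaussian_sigma = 1) {
  if (!is.list(seeds) || length(seeds) != 2L)
    stop_istomo("exactly two seed groups (effector, target) are required",
                "istomo_seed_error")
  seeds <- lapply(seeds, function(s) {
    s <- if (is.null(dim(s))) matrix(s, nrow = 1) else as.matrix(s)
    storage.mode(s) <- "integer"
    if (ncol(s) != 3L)
      stop_istomo("seeds must be (z, y, x) voxel coordinates",
                  "istomo_seed_error")
    s
  })
  if (dilation_size < 0 || gaussian_sigma < 0)
    stop_istomo("dilation_size and gaussian_sigma must be >= 0",
                "istomo_value_error")
  structure(list(seeds = seeds, ri_threshold = ri_threshold,
                 dilation_size = as.integer(dilation_size),
                 gaussian_sigma = gaussian_sigma),
            class = "annotation_params")
}

seed_index <- function(s, dm) {
  if (any(s < 1L) || any(s[, 1] > dm[1]) || any(s[, 2] > dm[2]) ||
      any(s[, 3] > dm[3]))
    stop_istomo("seed outside the volume grid", "istomo_seed_error")
  s[, 1] + dm[1] * (s[, 2] - 1L + dm[2] * (s[, 3] - 1L))
}

#' Watershed annotation of a two-cell conjugate
#'
#' The classical pipeline: Gaussian smoothing, RI thresholding, Euclidean-
#' ball closing to merge over-segmented grains, then a marker-based 3D
#' watershed on the negated distance transform of the foreground, flooded
#' from the two seed groups. Labels are keyed effector/target by seed
#' identity.
#'
#' @param tom a [tomogram()].
#' @param params an [annotation_params()].
#' @return A [cell_mask_pair()].
#' @export
annotate_cells <- function(tom, params) {
  stopifnot(inherits(tom, "tomogram"), inherits(params, "annotation_params"))
  if (params$ri_threshold <= tom$medium_ri)
    stop_istomo("ri_threshold must exceed the medium RI",
                "istomo_value_error")
  dm <- dim(tom$values)
  sm <- gaussian_smooth(tom$values, params$gaussian_sigma)
  fg <- sm > params$ri_threshold
  if (params$dilation_size > 0)
    fg <- binary_close(fg, ball_offsets(params$dilation_size))
  if (!any(fg))
    stop_istomo("empty segmentation: no voxel exceeds the RI threshold",
                "istomo_empty_error")

  markers <- array(0L, dm)
  for (k in 1:2) {
    idx <- seed_index(params$seeds[[k]], dm)
    if (any(!fg[idx]))
      stop_istomo("seed lies outside the thresholded foreground",
                  "istomo_seed_error")
    markers[idx] <- k
  }
  d <- edt(fg)  # distance to background, in voxels
  cent <- t(vapply(params$seeds, function(s) colMeans(s) - 1, numeric(3)))
  lab <- array(cpp_watershed(as.numeric(-d), markers, fg, dm, cent), dm)
  cell_mask_pair(lab == 1L, lab == 2L, pitch = tom$pitch)
}

#' STAPLE consensus over repeated binary annotations
#'
#' Simultaneous truth and performance level estimation: an EM algorithm that
#' alternates between the posterior probability of the latent true mask
#' (E-step) and each rater's sensitivity `p` and specificity `q` (M-step).
#' The prior is the mean foreground fraction of the input masks.
#'
#' @param masks list of logical 3D arrays of one shape (one per rater).
#' @param max_iter,tol EM stopping controls (parameter change below `tol`).
#' @return A `staple_result`: `probability` (posterior truth map),
#'   `consensus` (probability >= 0.5), `p`, `q`, `iterations`,
#'   `log_likelihood` (per-iteration trace, non-decreasing).
#' @export
staple_consensus <- function(masks, max_iter = 100L, tol = 1e-6) {
  if (!is.list(masks) || length(masks) < 1L)
    stop_istomo("at least one rater mask is required", "istomo_value_error")
  dm <- dim(masks[[1]])
  for (m in masks) assert_same_shape(masks[[1]], m, "rater masks")
  D <- vapply(masks, function(m) as.numeric(m), numeric(prod(dm)))
  if (all(D == 0))
    stop_istomo("all rater masks are empty", "istomo_degenerate_error")
  R <- ncol(D)
  prior <- mean(D)
  p <- rep(0.9, R)
  q <- rep(0.9, R)
  eps <- 1e-12
  loglik <- numeric(0)

  for (it in seq_len(max_iter)) {
    lp <- D %*% log(pmax(p, eps)) + (1 - D) %*% log(pmax(1 - p, eps))
    lq <- (1 - D) %*% log(pmax(q, eps)) + D %*% log(pmax(1 - q, eps))
    a <- prior * exp(lp)
    b <- (1 - prior) * exp(lq)
    w <- as.numeric(a / (a + b))
    loglik <- c(loglik, sum(log(a + b)))
    sw <- sum(w)
    p_new <- as.numeric(crossprod(D, w)) / max(sw, eps)
    q_new <- as.numeric(crossprod(1 - D, 1 - w)) / max(length(w) - sw, eps)
    delta <- max(abs(c(p_new - p, q_new - q)))
    p <- pmin(pmax(p_new, eps), 1 - eps)
    q <- pmin(pmax(q_new, eps), 1 - eps)
    if (delta < tol) break
  }
  prob <- array(w, dm)
  structure(list(probability = prob, consensus = prob >= 0.5,
                 p = pmin(p + 0, 1), q = pmin(q + 0, 1),
                 iterations = length(loglik), log_likelihood = loglik),
            class = "staple_result")
}
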