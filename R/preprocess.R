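#' Construct a 3D volume
#'
#' A light container for a spatial intensity grid: a 3D array with per-axis
#' voxel spacing in mm. Array dims are `(nx, ny, nz)`.
#'
#' @param data 3D numeric array.
#' @param spacing numeric length-3, mm per voxel along each axis.
#' @param origin numeric length-3 physical origin in mm.
#' @return an object of class `volume3d`.
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) stopf("volume3d data must be a 3D array")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("spacing must be 3 strictly positive finite values")
  if (any(!is.finite(data))) stopf("volume intensities must be finite")
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<volume3d> %s voxels @ %s mm, range [%.3g, %.3g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

# cubic B-spline kernel
bspline3 <- function(t) {
  t <- abs(t)
  ifelse(t < 1, (4 - 6 * t^2 + 3 * t^3) / 6,
         ifelse(t < 2, (2 - t)^3 / 6, 0))
}

# Solve the cubic B-spline interpolation system (1/6, 4/6, 1/6) along the
# first dimension of matrix s (columns are independent signals), with mirror
# boundary c[-1] = c[1]. Thomas algorithm.
bspline_prefilter_mat <- function(s) {
  n <- nrow(s)
  if (n < 3L) return(s)
  a <- rep(1 / 6, n); b <- rep(4 / 6, n); cc <- rep(1 / 6, n)
  a[1] <- 0; cc[1] <- 2 / 6; a[n] <- 2 / 6; cc[n] <- 0
  cp <- numeric(n)
  dp <- matrix(0, n, ncol(s))
  cp[1] <- cc[1] / b[1]
  dp[1, ] <- s[1, ] / b[1]
  for (i in 2:n) {
    m <- b[i] - a[i] * cp[i - 1]
    cp[i] <- cc[i] / m
    dp[i, ] <- (s[i, ] - a[i] * dp[i - 1, ]) / m
  }
  x <- dp
  for (i in (n - 1):1) x[i, ] <- dp[i, ] - cp[i] * x[i + 1, ]
  x
}

# weight matrix mapping n_in B-spline coefficients to n_out samples at
# continuous input-index positions pos (0-based); edge replication via clamp
bspline_weights <- function(pos, n_in) {
  W <- matrix(0, length(pos), n_in)
  base <- floor(pos)
  for (off in -1:2) {
    m <- base + off
    w <- bspline3(pos - m)
    mc <- pmin(pmax(m, 0), n_in - 1)
    W[cbind(seq_along(pos), mc + 1)] <- W[cbind(seq_along(pos), mc + 1)] + w
  }
  W
}

apply_axis <- function(a, fun, axis) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = d[axis])
  m <- fun(m)
  out <- array(m, dim = c(nrow(m), d[perm[2]], d[perm[3]]))
  aperm(out, order(perm))
}

#' Resample a volume to isotropic spacing
#'
#' Intensities are interpolated with a cubic B-spline (interpolating spline
#' with mirror boundary prefilter, edge replication at the borders); the
#' physical extent is preserved to within one voxel. Masks must use
#' [resample_nearest()] instead.
#'
#' @param vol a [volume3d()].
#' @param target_spacing scalar target spacing in mm (default 1).
#' @return a [volume3d()] with spacing `(t, t, t)`.
#' @export
resample_isotropic <- function(vol, target_spacing = 1) {
  stopifnot(inherits(vol, "volume3d"))
  if (target_spacing <= 0) stopf("target_spacing must be positive")
  sp <- vol$spacing
  if (all(abs(sp - target_spacing) < 1e-12)) return(vol)
  d_in <- dim(vol$data)
  d_out <- pmax(1L, as.integer(round(d_in * sp / target_spacing)))
  a <- vol$data
  for (axis in 1:3) a <- apply_axis(a, bspline_prefilter_mat, axis)
  for (axis in 1:3) {
    pos <- (seq_len(d_out[axis]) - 1) * target_spacing / sp[axis]
    W <- bspline_weights(pos, d_in[axis])
    a <- apply_axis(a, function(m) W %*% m, axis)
  }
  volume3d(a, spacing = rep(target_spacing, 3), origin = vol$origin)
}

#' Nearest-neighbour resampling (for binary masks)
#'
#' @inheritParams resample_isotropic
#' @return a [volume3d()] at the target spacing with values from the nearest
#'   source voxel.
#' @export
resample_nearest <- function(vol, target_spacing = 1) {
  stopifnot(inherits(vol, "volume3d"))
  sp <- vol$spacing
  if (all(abs(sp - target_spacing) < 1e-12)) return(vol)
  d_in <- dim(vol$data)
  d_out <- pmax(1L, as.integer(round(d_in * sp / target_spacing)))
  ix <- lapply(1:3, function(axis) {
    pos <- (seq_len(d_out[axis]) - 1) * target_spacing / sp[axis]
    pmin(pmax(as.integer(round(pos)) + 1L, 1L), d_in[axis])
  })
  volume3d(vol$data[ix[[1]], ix[[2]], ix[[3]], drop = FALSE],
           spacing = rep(target_spacing, 3), origin = vol$origin)
}

#' Window and scale CT intensities
#'
#' Clips Hounsfield units to the lung window `[-1200, 600]` and maps the
#' result affinely onto `[0, 255]`.
#'
#' @param vol a [volume3d()] in HU.
#' @param lo,hi window bounds in HU.
#' @return a [volume3d()] with intensities in `[0, 255]`.
#' @export
window_scale <- function(vol, lo = -1200, hi = 600) {
  stopifnot(inherits(vol, "volume3d"), hi > lo)
  v <- pmin(pmax(vol$data, lo), hi)
  volume3d(255 * (v - lo) / (hi - lo), spacing = vol$spacing, origin = vol$origin)
}

#' Crop a fixed-size cube around a mask
#'
#' The cube is centred on the mask's intensity-unweighted voxel centroid
#' (rounded to the nearest voxel); regions falling outside the grid are padded
#' with `pad` (the windowed background value, 0, by default). With disjoint
#' mask components the anchor is the centroid of their union.
#'
#' @param vol a [volume3d()] (expected at 1 mm isotropic, windowed).
#' @param mask a [volume3d()] of 0/1 with the same dims as `vol`.
#' @param size_mm cube edge length in mm (default 40).
#' @param pad padding value for out-of-grid voxels.
#' @return a [volume3d()] with dims `(size, size, size)`.
#' @export
crop_cube <- function(vol, mask, size_mm = 40, pad = 0) {
  stopifnot(inherits(vol, "volume3d"), inherits(mask, "volume3d"))
  if (!identical(dim(vol$data), dim(mask$data)))
    stopf("volume and mask dims differ")
  w <- which(mask$data > 0.5, arr.ind = TRUE)
  if (nrow(w) == 0L) stopf("empty mask: cannot crop")
  size <- as.integer(round(size_mm / vol$spacing[1]))
  centre <- as.integer(round(colMeans(w)))
  half <- size %/% 2L
  out <- array(pad, dim = rep(size, 3))
  d <- dim(vol$data)
  src <- dst <- vector("list", 3)
  for (axis in 1:3) {
    from <- centre[axis] - half
    idx <- from + seq_len(size) - 1L
    ok <- idx >= 1L & idx <= d[axis]
    src[[axis]] <- idx[ok]
    dst[[axis]] <- which(ok)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    vol$data[src[[1]], src[[2]], src[[3]], drop = FALSE]
  volume3d(out, spacing = vol$spacing)
}

#' Min-max normalize a cube to [0, 1]
#'
#' A constant cube cannot be rescaled; it is returned as all zeros with a
#' warning (division-by-zero guard).
#'
#' @param cube a [volume3d()].
#' @return a [volume3d()] with values in `[0, 1]`.
#' @export
normalize_unit <- function(cube) {
  stopifnot(inherits(cube, "volume3d"))
  r <- range(cube$data)
  if (diff(r) == 0) {
    warnf("constant cube: normalized output set to all zeros")
    return(volume3d(array(0, dim(cube$data)), spacing = cube$spacing))
  }
  volume3d((cube$data - r[1]) / diff(r), spacing = cube$spacing)
}

#' Preprocess one volume/mask pair into a unit cube
#'
#' Applies the fixed pipeline order: isotropic resampling (B-spline for the
#' image, nearest-neighbour for the mask), HU windowing to `[0, 255]`,
#' centroid-anchored cube cropping, and per-cube min-max normalization.
#'
#' @param vol raw HU [volume3d()].
#' @param mask binary [volume3d()] of the same geometry.
#' @param size_mm cube edge in mm.
#' @param target_spacing isotropic spacing in mm.
#' @return list with `cube` (normalized [volume3d()]) and `mask` (cropped
#'   binary [volume3d()] on the same grid).
#' @export
preprocess_pair <- function(vol, mask, size_mm = 40, target_spacing = 1) {
  v <- resample_isotropic(vol, target_spacing)
  m <- resample_nearest(mask, target_spacing)
  v <- window_scale(v)
  cube <- crop_cube(v, m, size_mm = size_mm, pad = 0)
  mask_cube <- crop_cube(m, m, size_mm = size_mm, pad = 0)
  list(cube = normalize_unit(cube), mask = mask_cube)
}

#' Preprocess both phases of a lesion case
#'
#' @param case a `lesion_case` from [generate_cohort()] or [read_cohort()].
#' @param size_mm cube edge in mm.
#' @return list with `pre` and `post`, each as in [preprocess_pair()].
#' @export
preprocess_case <- function(case, size_mm = 40) {
  list(pre = preprocess_pair(case$pre_volume, case$pre_mask, size_mm),
       post = preprocess_pair(case$post_volume, case$post_mask, size_mm))
}
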