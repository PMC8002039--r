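#' Volume series container
#'
#' A 4-D voxel array (x, y, z, t) with voxel sizes in mm, a world origin
#' (mm coordinate of the first voxel; voxel indices are 0-based in world
#' computations) and the repetition time.
#'
#' @param data 4-D (or 3-D, promoted to a single volume) numeric array.
#' @param voxdim voxel size per axis, mm.
#' @param origin world coordinate of voxel (0, 0, 0), mm.
#' @param tr repetition time, s.
#' @return object of class `fes_volume_series`.
#' @export
volume_series <- function(data, voxdim = c(2, 2, 2), origin = c(0, 0, 0),
                          tr = 3) {
  if (length(dim(data)) == 3) dim(data) <- c(dim(data), 1)
  stopifnot(length(dim(data)) == 4, all(voxdim > 0))
  structure(list(data = data, voxdim = voxdim, origin = origin, tr = tr),
            class = "fes_volume_series")
}

#' Read / write volumes as NIfTI
#'
#' Round-trips a [volume_series()] through NIfTI using the voxel sizes and a
#' diagonal affine built from `voxdim` and `origin`.
#'
#' @param vol a `fes_volume_series`.
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume_nifti` returns a `fes_volume_series`.
#' @export
write_volume_nifti <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  img <- RNifti::`pixdim<-`(img, c(vol$voxdim, vol$tr))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @param path file path.
#' @param tr repetition time if not recoverable from the header.
#' @export
read_volume_nifti <- function(path, tr = 3) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  d <- dim(img)
  if (length(d) == 3) dim(img) <- c(d, 1)
  volume_series(as.array(img), voxdim = pd[1:3], origin = c(0, 0, 0),
                tr = if (length(pd) >= 4 && pd[4] > 0) pd[4] else tr)
}

#' Spherical region specification
#'
#' @param label region label.
#' @param center mm world coordinates (length 3).
#' @param radius sphere radius, mm (default 4).
#' @return object of class `fes_roi_spec`.
#' @export
roi_spec <- function(label, center, radius = 4) {
  stopifnot(radius > 0, length(center) == 3)
  structure(list(label = label, center = as.numeric(center), radius = radius),
            class = "fes_roi_spec")
}

# 1-D discrete Gaussian kernel for a FWHM in mm on a given voxel pitch.
gauss_kernel_1d <- function(fwhm_mm, vox_mm) {
  sd_vox <- fwhm_mm / 2.3548 / vox_mm
  if (sd_vox == 0) return(1)
  r <- max(1L, ceiling(4 * sd_vox))
  k <- exp(-0.5 * ((-r:r) / sd_vox)^2)
  k / sum(k)
}

# Convolve a 3-D array along one axis with zero padding; optionally
# renormalize by the convolution of a ones-array so constants are preserved
# at the boundary.
conv_axis <- function(arr, k, axis, renormalize = TRUE) {
  if (length(k) == 1) return(arr)
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  x <- aperm(arr, perm)
  n <- d[axis]
  m <- matrix(x, nrow = n)
  r <- (length(k) - 1) / 2
  pad <- matrix(0, r, ncol(m))
  mp <- rbind(pad, m, pad)
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) {
    out <- out + k[j] * mp[(j - 1) + seq_len(n), , drop = FALSE]
  }
  if (renormalize) {
    ones <- c(rep(0, r), rep(1, n), rep(0, r))
    w <- stats::filter(ones, k, sides = 2)[r + seq_len(n)]
    out <- out / w
  }
  x <- array(out, dim(x))
  aperm(x, order(perm))
}

#' Gaussian smoothing of a volume series
#'
#' Per-volume separable 3-D convolution with an isotropic Gaussian of the
#' given full width at half maximum; the kernel standard deviation is
#' fwhm/2.3548 mm, converted to voxels per axis. Boundaries use zero padding
#' with renormalization (on by default) so constant images are preserved.
#'
#' @param vol a [volume_series()].
#' @param fwhm full width at half maximum, mm; 0 returns the input unchanged.
#' @param renormalize renormalize the kernel mass at the boundary.
#' @return smoothed `fes_volume_series`.
#' @export
gaussian_smooth <- function(vol, fwhm, renormalize = TRUE) {
  if (fwhm < 0) stop("fwhm must be nonnegative")
  if (fwhm == 0) return(vol)
  ks <- lapply(1:3, function(ax) gauss_kernel_1d(fwhm, vol$voxdim[ax]))
  d <- dim(vol$data)
  out <- vol$data
  for (t in seq_len(d[4])) {
    v <- out[, , , t, drop = TRUE]
    dim(v) <- d[1:3]
    for (ax in 1:3) v <- conv_axis(v, ks[[ax]], ax, renormalize)
    out[, , , t] <- v
  }
  vol$data <- out
  vol
}

# World mm coordinates of every voxel center (0-based indices).
voxel_grid_mm <- function(dims, voxdim, origin) {
  list(x = origin[1] + (seq_len(dims[1]) - 1) * voxdim[1],
       y = origin[2] + (seq_len(dims[2]) - 1) * voxdim[2],
       z = origin[3] + (seq_len(dims[3]) - 1) * voxdim[3])
}

#' Select per-region activation maxima under a minimum-separation rule
#'
#' For each region (in declared order) the largest value of the statistic map
#' inside the region's mask is taken, subject to a pairwise Euclidean
#' distance of at least `min_separation` mm from the maxima already selected;
#' on conflict the next-highest admissible voxel is taken (greedy,
#' deterministic).
#'
#' @param stat_map 3-D statistic array.
#' @param masks named list of binary 3-D arrays, one per region, processed in
#'   order.
#' @param min_separation minimum pairwise distance, mm.
#' @param voxdim,origin geometry of the map.
#' @param radius radius recorded in the returned [roi_spec()]s, mm.
#' @return named list of `fes_roi_spec`.
#' @export
select_maxima <- function(stat_map, masks, min_separation = 8,
                          voxdim = c(2, 2, 2), origin = c(0, 0, 0),
                          radius = 4) {
  stopifnot(min_separation >= 0)
  g <- voxel_grid_mm(dim(stat_map), voxdim, origin)
  chosen <- list()
  centers <- NULL
  for (lab in names(masks)) {
    mask <- masks[[lab]]
    if (sum(mask != 0) == 0) stop("empty mask for region ", lab)
    idx <- which(mask != 0)
    ord <- idx[order(stat_map[idx], decreasing = TRUE)]
    found <- FALSE
    for (v in ord) {
      co <- arrayInd(v, dim(stat_map))
      mm <- c(g$x[co[1]], g$y[co[2]], g$z[co[3]])
      ok <- is.null(centers) ||
        all(sqrt(colSums((t(centers) - mm)^2)) >= min_separation)
      if (ok) {
        chosen[[lab]] <- roi_spec(lab, mm, radius)
        centers <- rbind(centers, mm)
        found <- TRUE
        break
      }
    }
    if (!found) {
      stop("no admissible voxel for region ", lab,
           " under the ", min_separation, " mm separation rule")
    }
  }
  chosen
}

#' First eigenvariate of a spherical region
#'
#' First principal temporal component of the voxel-by-time matrix inside the
#' sphere (voxel series demeaned over time), scaled so its standard deviation
#' matches that of the mean ROI series and signed so its correlation with the
#' mean ROI series is nonnegative. The mean of the mean ROI series is added
#' back so the summary lives on the signal scale.
#'
#' @param vol a [volume_series()].
#' @param roi a [roi_spec()].
#' @return numeric time series of length `dim(vol$data)[4]`.
#' @export
first_eigenvariate <- function(vol, roi) {
  d <- dim(vol$data)
  g <- voxel_grid_mm(d[1:3], vol$voxdim, vol$origin)
  dx <- (g$x - roi$center[1])^2
  dy <- (g$y - roi$center[2])^2
  dz <- (g$z - roi$center[3])^2
  inside <- outer(outer(dx, dy, `+`), dz, `+`) <= roi$radius^2
  nv <- sum(inside)
  if (nv == 0) stop("sphere of radius ", roi$radius, " mm at (",
                    paste(roi$center, collapse = ", "),
                    ") contains no voxel")
  Y <- matrix(vol$data, prod(d[1:3]), d[4])[as.vector(inside), , drop = FALSE]
  Y <- t(Y)                                   # time x voxels
  mean_series <- rowMeans(Y)
  Yc <- sweep(Y, 2, colMeans(Y), `-`)         # demean each voxel over time
  sv <- svd(Yc, nu = 1, nv = 0)
  e <- sv$u[, 1]
  if (stats::sd(e) > 0 && stats::sd(mean_series) > 0) {
    e <- e * stats::sd(mean_series - mean(mean_series)) / stats::sd(e)
  }
  if (sum(e * (mean_series - mean(mean_series))) < 0) e <- -e
  e + mean(mean_series)
}
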