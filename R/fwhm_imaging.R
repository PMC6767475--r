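# Radius estimation from 3D signal-void volumes by the full-width-at-half-
# maximum (FWHM) rule. Vessels appear dark (the cast lumen gives no signal)
# against a bright gadolinium-gel background; the diameter is read off an
# intensity profile perpendicular to the vessel as the distance between the
# two half-level crossings of the dip.

# trilinear interpolation at mm coordinates; voxel i is centred at
# (i - 0.5) * voxel_size. Points outside the grid return NA.
.trilinear <- function(vol, voxel_size, pts) {
  dims <- dim(vol)
  g <- pts / voxel_size + 0.5   # continuous voxel-index coordinates
  out <- rep(NA_real_, nrow(pts))
  i0 <- floor(g)
  f <- g - i0
  ok <- i0[, 1L] >= 1 & i0[, 1L] < dims[1L] &
        i0[, 2L] >= 1 & i0[, 2L] < dims[2L] &
        i0[, 3L] >= 1 & i0[, 3L] < dims[3L]
  if (!any(ok)) return(out)
  i0 <- i0[ok, , drop = FALSE]
  fx <- f[ok, 1L]; fy <- f[ok, 2L]; fz <- f[ok, 3L]
  at <- function(dx, dy, dz)
    vol[cbind(i0[, 1L] + dx, i0[, 2L] + dy, i0[, 3L] + dz)]
  out[ok] <-
    at(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(1, 0, 0) * fx       * (1 - fy) * (1 - fz) +
    at(0, 1, 0) * (1 - fx) * fy       * (1 - fz) +
    at(0, 0, 1) * (1 - fx) * (1 - fy) * fz       +
    at(1, 1, 0) * fx       * fy       * (1 - fz) +
    at(1, 0, 1) * fx       * (1 - fy) * fz       +
    at(0, 1, 1) * (1 - fx) * fy       * fz       +
    at(1, 1, 1) * fx       * fy       * fz
  out
}

#' Read / write phantom volumes as NIfTI
#'
#' Thin wrappers around the RNifti package for moving intensity volumes
#' (e.g. [generate_vessel_phantom()] output) to and from disk with their
#' voxel size in the header. RNifti must be installed.
#'
#' @param volume 3D intensity array.
#' @param voxel_size isotropic voxel size, mm.
#' @param path NIfTI file path (`.nii`).
#' @return `write_volume_nifti` returns `path` invisibly;
#'   `read_volume_nifti` returns a list with `intensity` and `voxel_size`.
#' @export
write_volume_nifti <- function(volume, voxel_size, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("NIfTI support needs the RNifti package")
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- rep(voxel_size, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("NIfTI support needs the RNifti package")
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)
  if (length(unique(round(vox[1:3], 9))) != 1L)
    warning("anisotropic voxels; using the first dimension")
  list(intensity = array(as.numeric(img), dim = dim(img)),
       voxel_size = vox[1L])
}

#' Sample an intensity profile perpendicular to a vessel
#'
#' Trilinearly interpolates the volume along a line through `point` in the
#' in-plane direction `direction`, from `-half_length` to `+half_length`.
#'
#' @param volume 3D intensity array.
#' @param voxel_size isotropic voxel size, mm.
#' @param point profile centre in mm coordinates (3-vector).
#' @param direction in-plane unit direction of the profile (should be
#'   perpendicular to the vessel tangent; normalized internally).
#' @param half_length half profile length, mm.
#' @param step sample spacing, mm; must not exceed `half_length`.
#' @return data frame with `s` (signed offset, mm) and `intensity` (`NA`
#'   outside the volume, with attribute `truncated = TRUE` if any sample
#'   fell outside).
#' @export
perpendicular_profile <- function(volume, voxel_size, point, direction,
                                  half_length, step) {
  if (step > half_length) stop("step exceeds half_length")
  d <- .unit(direction)
  s <- seq(-half_length, half_length, by = step)
  pts <- cbind(point[1L] + s * d[1L], point[2L] + s * d[2L],
               point[3L] + s * d[3L])
  val <- .trilinear(volume, voxel_size, pts)
  structure(data.frame(s = s, intensity = val),
            truncated = anyNA(val))
}

#' Full width at half maximum of a signal-void profile
#'
#' Locates the dip minimum, estimates the background level from the outer
#' 25% of samples on each side (unless given), sets the half level midway
#' between background and vessel level, and returns the distance between the
#' two half-level crossings, each located by linear interpolation between
#' samples. Because the half level is defined relative to the two plateau
#' levels, the width is invariant to affine intensity changes.
#'
#' @param profile data frame from [perpendicular_profile()] (columns `s`,
#'   `intensity`).
#' @param background background (gel) level; default: mean of the outer
#'   quarter of finite samples.
#' @param vessel vessel (void) level; default: the profile minimum.
#' @return width in mm, or `NA` (no crossing on one side, or a monotone
#'   profile with no dip).
#' @export
fwhm_width <- function(profile, background = NULL, vessel = NULL) {
  s <- profile$s[is.finite(profile$intensity)]
  v <- profile$intensity[is.finite(profile$intensity)]
  n <- length(v)
  if (n < 5L) return(NA_real_)
  if (is.null(background)) {
    k <- max(1L, floor(n * 0.125))   # outer 25% = 12.5% each tail
    background <- mean(c(v[seq_len(k)], v[seq.int(n - k + 1L, n)]))
  }
  if (is.null(vessel)) vessel <- min(v)
  half <- (background + vessel) / 2
  imin <- which.min(v)
  if (v[imin] >= half) return(NA_real_)
  cross <- function(idx_from, idx_to) {
    # walk outward from the minimum until the profile rises through `half`
    ii <- seq(idx_from, idx_to)
    for (j in seq_len(length(ii) - 1L)) {
      a <- ii[j]; b <- ii[j + 1L]
      if (v[a] < half && v[b] >= half) {
        return(s[a] + (s[b] - s[a]) * (half - v[a]) / (v[b] - v[a]))
      }
    }
    NA_real_
  }
  left <- if (imin > 1L) cross(imin, 1L) else NA_real_
  right <- if (imin < n) cross(imin, n) else NA_real_
  if (!is.finite(left) || !is.finite(right)) return(NA_real_)
  abs(right - left)
}

# orthonormal in-plane basis perpendicular to a tangent
.plane_basis <- function(tangent) {
  t <- .unit(tangent)
  ref <- if (abs(t[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- .unit(c(t[2L] * ref[3L] - t[3L] * ref[2L],
               t[3L] * ref[1L] - t[1L] * ref[3L],
               t[1L] * ref[2L] - t[2L] * ref[1L]))
  v <- c(t[2L] * u[3L] - t[3L] * u[2L],
         t[3L] * u[1L] - t[1L] * u[3L],
         t[1L] * u[2L] - t[2L] * u[1L])
  list(u = u, v = v)
}

#' FWHM radius at a centerline node
#'
#' Averages the half-FWHM width over `n_directions` evenly spaced in-plane
#' directions perpendicular to the vessel tangent. Estimates with a diameter
#' below two voxels are flagged unreliable (at least two voxels are needed
#' to measure a diameter), as are nodes where the per-direction widths
#' spread by more than 25% of their mean.
#'
#' @inheritParams perpendicular_profile
#' @param tangent vessel tangent at the node (3-vector).
#' @param n_directions number of in-plane directions (default 8).
#' @param half_length half profile length, mm (default 10 voxels).
#' @param step profile sample spacing, mm (default a quarter voxel).
#' @return list with `radius` (mm, `NA` if most directions fail),
#'   `n_valid`, `reliable` (two-voxel rule), `spread_flag`.
#' @export
radius_at_node <- function(volume, voxel_size, point, tangent,
                           n_directions = 8L,
                           half_length = 10 * voxel_size,
                           step = voxel_size / 4) {
  basis <- .plane_basis(tangent)
  theta <- pi * (seq_len(n_directions) - 1L) / n_directions
  widths <- vapply(theta, function(a) {
    dirn <- cos(a) * basis$u + sin(a) * basis$v
    prof <- perpendicular_profile(volume, voxel_size, point, dirn,
                                  half_length, step)
    fwhm_width(prof)
  }, numeric(1))
  ok <- is.finite(widths)
  if (sum(ok) < n_directions / 2)
    return(list(radius = NA_real_, n_valid = sum(ok), reliable = FALSE,
                spread_flag = TRUE))
  w <- widths[ok]
  radius <- mean(w) / 2
  list(radius = radius,
       n_valid = sum(ok),
       reliable = 2 * radius >= 2 * voxel_size,
       spread_flag = (max(w) - min(w)) / mean(w) > 0.25)
}
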