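# Image pre-processing chain: anterior-posterior landmark crop, registration
# of post-contrast series to the pre-contrast volume, resampling to a target
# (cohort-median) spacing and carrying the last post-contrast series forward.

#' Crop an examination or mask in the anterior-posterior direction
#'
#' Keeps the voxels whose anterior-posterior (axis 2) world coordinate lies
#' in the window from `margin_anterior_mm` anterior of the nipple to
#' `margin_posterior_mm` posterior of the intermammary cleft (defaults:
#' 10 mm and 50 mm), clipped to the image. All volumes of a series are
#' cropped identically and the other axes are untouched, so a mask passed
#' through the same crop stays voxel-aligned with the image.
#'
#' @param x a [dce_series()] or [tumor_mask()].
#' @param landmarks a [breast_landmarks()].
#' @param margin_anterior_mm window margin anterior of the nipple (mm).
#' @param margin_posterior_mm window margin posterior of the cleft (mm).
#' @return object of the same class, cropped along axis 2.
#' @export
crop_breast_region <- function(x, landmarks, margin_anterior_mm = 10,
                               margin_posterior_mm = 50) {
  stopifnot(inherits(landmarks, "breast_landmarks"))
  lo <- landmarks$nipple_y - margin_anterior_mm
  hi <- landmarks$intermammary_cleft_y + margin_posterior_mm
  yc <- axis_coords(x, 2L)
  keep <- which(yc >= lo & yc <= hi)
  if (length(keep) == 0L)
    stop("crop window [", lo, ", ", hi, "] mm is empty after clipping")
  idx <- seq(min(keep), max(keep))
  new_origin <- x$origin
  new_origin[2] <- yc[idx[1]]
  if (inherits(x, "dce_series")) {
    vols <- lapply(x$volumes, function(v) v[, idx, , drop = FALSE])
    dce_series(vols, x$spacing, new_origin)
  } else if (inherits(x, "tumor_mask")) {
    tumor_mask(x$grid[, idx, , drop = FALSE], x$spacing, new_origin)
  } else stop("unsupported object for crop_breast_region")
}

# Subvoxel shift estimate by FFT phase correlation (per-axis parabolic
# refinement of the correlation peak). Returns the shift s such that
# moving(x) ~ reference(x - s), in voxel units.
#' @noRd
phase_correlation_shift <- function(ref, mov) {
  d <- dim(ref)
  f1 <- fft(ref)
  f2 <- fft(mov)
  cp <- f1 * Conj(f2)
  denom <- Mod(cp)
  denom[denom < .Machine$double.eps] <- .Machine$double.eps
  r <- Re(fft(cp / denom, inverse = TRUE))
  peak <- arrayInd(which.max(r), d)
  shift <- numeric(3)
  for (a in 1:3) {
    i <- peak[a]
    ip <- if (i == d[a]) 1L else i + 1L
    im <- if (i == 1L) d[a] else i - 1L
    sel <- function(j) {
      q <- peak; q[a] <- j
      r[q[1], q[2], q[3]]
    }
    y0 <- sel(im); y1 <- sel(i); y2 <- sel(ip)
    denom2 <- y0 - 2 * y1 + y2
    frac <- if (abs(denom2) > .Machine$double.eps) 0.5 * (y0 - y2) / denom2 else 0
    frac <- max(-0.5, min(0.5, frac))
    s <- (i - 1) + frac
    if (s > d[a] / 2) s <- s - d[a]
    shift[a] <- -s    # correlation peaks at minus the planted shift
  }
  shift
}

# 3x4 voxel-space affine for a rigid transform: rotation (radians, about the
# volume centre, applied in x-y, x-z, y-z order) followed by translation, in
# voxel units. Maps output 0-based indices to source indices.
#' @noRd
rigid_matrix <- function(par, d) {
  tr <- par[1:3]
  ang <- if (length(par) > 3) par[4:6] else c(0, 0, 0)
  cz <- cos(ang[1]); sz <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cx <- cos(ang[3]); sx <- sin(ang[3])
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  R <- Rz %*% Ry %*% Rx
  ctr <- (d - 1) / 2
  cbind(R, as.numeric(ctr - R %*% ctr + tr))
}

#' @noRd
apply_voxel_affine <- function(vol, M, mode = c("linear", "nearest"),
                               out_dim = dim(vol), fill = 0) {
  mode <- match.arg(mode)
  .cpp_resample_affine(as.numeric(vol), as.integer(dim(vol)), M,
                       as.integer(out_dim),
                       if (mode == "nearest") 1L else 0L, fill)
}

# Mutual information between two volumes over `bins` equal-width bins.
#' @noRd
mutual_information <- function(a, b, bins = 32) {
  br_a <- seq(min(a), max(a), length.out = bins + 1)
  br_b <- seq(min(b), max(b), length.out = bins + 1)
  ia <- findInterval(a, br_a, rightmost.closed = TRUE, all.inside = TRUE)
  ib <- findInterval(b, br_b, rightmost.closed = TRUE, all.inside = TRUE)
  joint <- tabulate((ia - 1) * bins + ib, nbins = bins * bins) / length(a)
  pa <- tabulate(ia, nbins = bins) / length(a)
  pb <- tabulate(ib, nbins = bins) / length(b)
  nz <- joint > 0
  pij <- joint[nz]
  i <- ((seq_len(bins * bins) - 1) %/% bins + 1)[nz]
  j <- ((seq_len(bins * bins) - 1) %% bins + 1)[nz]
  sum(pij * log(pij / (pa[i] * pb[j])))
}

#' Register post-contrast volumes to the pre-contrast volume
#'
#' Aligns every post-contrast volume to the pre-contrast grid behind a
#' pluggable backend contract. The default `"translation"` backend estimates
#' a per-volume translation by FFT phase correlation with subvoxel parabolic
#' refinement and resamples trilinearly; the `"rigid"` backend optimizes a
#' translation-plus-rotation transform by maximizing mutual information
#' (Nelder-Mead, 32-bin joint histogram). The pre-contrast volume and the
#' output geometry are unchanged.
#'
#' @param series a [dce_series()] with at least one post-contrast volume.
#' @param backend `"translation"` (default) or `"rigid"`, or a function
#'   `function(reference, moving)` returning the registered moving volume
#'   (external backends plug in here).
#' @param verbose if `TRUE`, message the estimated parameters per volume.
#' @return the registered [dce_series()], with the per-volume transform
#'   parameters in attribute `"transforms"`.
#' @export
register_series <- function(series, backend = c("translation", "rigid"),
                            verbose = FALSE) {
  stopifnot(inherits(series, "dce_series"))
  if (length(series$volumes) < 2L) stop("need at least 2 volumes to register")
  ref <- series$volumes[[1]]
  if (sd(ref) == 0)
    stop("registration failure: reference volume has no structure")
  custom <- is.function(backend)
  if (!custom) backend <- match.arg(backend)
  out <- series$volumes
  transforms <- vector("list", length(out))
  for (k in seq_along(out)[-1]) {
    mov <- series$volumes[[k]]
    if (custom) {
      out[[k]] <- backend(ref, mov)
      transforms[[k]] <- "external"
      next
    }
    if (sd(mov) == 0)
      stop("registration failure for series ", k - 1L,
           ": no overlapping structure")
    if (backend == "translation") {
      s <- phase_correlation_shift(ref, mov)
      if (any(abs(s) >= dim(ref)))
        stop("registration failure for series ", k - 1L, ": no overlap")
      M <- cbind(diag(3), s)
      out[[k]] <- apply_voxel_affine(mov, M, "linear")
      transforms[[k]] <- list(type = "translation", shift_voxels = s)
    } else {
      obj <- function(par) {
        w <- apply_voxel_affine(mov, rigid_matrix(par, dim(ref)), "linear")
        -mutual_information(as.numeric(ref), as.numeric(w))
      }
      # translation initialization from phase correlation, then full rigid
      init <- c(phase_correlation_shift(ref, mov), 0, 0, 0)
      fit <- optim(init, obj, method = "Nelder-Mead",
                   control = list(maxit = 400, reltol = 1e-8))
      out[[k]] <- apply_voxel_affine(mov, rigid_matrix(fit$par, dim(ref)),
                                     "linear")
      transforms[[k]] <- list(type = "rigid", par = fit$par)
    }
    if (verbose) message("series ", k - 1L, ": ",
                         paste(signif(unlist(transforms[[k]][-1]), 4),
                               collapse = ", "))
  }
  res <- dce_series(out, series$spacing, series$origin)
  attr(res, "transforms") <- transforms
  res
}

#' Resample an examination or mask to a target voxel spacing
#'
#' The output grid preserves the physical extent within one voxel: the new
#' shape is `round(shape * spacing / target)` (at least 1), and the grid is
#' centred on the same physical field of view. Images are interpolated
#' trilinearly; masks use nearest-neighbour and therefore stay binary.
#'
#' @param x a [dce_series()] or [tumor_mask()].
#' @param target_spacing numeric(3) target spacing in mm (all > 0).
#' @return resampled object of the same class.
#' @export
resample_to_spacing <- function(x, target_spacing) {
  if (length(target_spacing) != 3L || any(target_spacing <= 0))
    stop("target_spacing must be 3 positive reals")
  sp <- x$spacing
  if (all(sp == target_spacing)) return(x)
  d <- if (inherits(x, "tumor_mask")) dim(x$grid) else dim(x$volumes[[1]])
  new_dim <- pmax(1L, as.integer(round(d * sp / target_spacing)))
  new_origin <- x$origin - sp / 2 + target_spacing / 2
  M <- cbind(diag(target_spacing / sp),
             (new_origin - x$origin) / sp)
  if (inherits(x, "dce_series")) {
    vols <- lapply(x$volumes, function(v)
      apply_voxel_affine(v, M, "linear", out_dim = new_dim))
    dce_series(vols, target_spacing, new_origin)
  } else if (inherits(x, "tumor_mask")) {
    g <- apply_voxel_affine(x$grid + 0, M, "nearest", out_dim = new_dim)
    tumor_mask(g > 0.5, target_spacing, new_origin)
  } else stop("unsupported object for resample_to_spacing")
}

#' Carry the last post-contrast series forward to a fixed count
#'
#' Examinations with fewer than `target_post_count` post-contrast series get
#' copies of the last acquired series appended until the count is reached;
#' acquired volumes are not modified and examinations already at (or above)
#' the target are returned unchanged, making the operation idempotent.
#'
#' @param series a [dce_series()] with at least one post-contrast volume.
#' @param target_post_count desired number of post-contrast series.
#' @return a [dce_series()] with exactly `max(n_post, target_post_count)`
#'   post-contrast volumes.
#' @export
carry_forward <- function(series, target_post_count = 5L) {
  stopifnot(inherits(series, "dce_series"))
  np <- n_post(series)
  if (np < 1L) stop("carry_forward requires at least one post-contrast volume")
  if (np >= target_post_count) return(series)
  last <- series$volumes[[length(series$volumes)]]
  extra <- rep(list(last), target_post_count - np)
  dce_series(c(series$volumes, extra), series$spacing, series$origin)
}

#' Componentwise median voxel spacing of a cohort
#'
#' @param cohort non-empty list of [dce_series()].
#' @return numeric(3): per-axis median spacing (mm); the median of an
#'   even-length list is the mean of the middle two values.
#' @export
median_spacing <- function(cohort) {
  if (length(cohort) == 0L) stop("median_spacing requires a non-empty cohort")
  sps <- vapply(cohort, function(s) s$spacing, numeric(3))
  apply(sps, 1, median)
}
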