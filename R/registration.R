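# Mapping stack coordinates into the frame of a region label volume.
# Atlas-agnostic: any integer label volume plus name table is accepted.
# Points are (z, y, x) in micrometers on the stack side and float voxel
# coordinates on the atlas side; voxels are half-open, [v, v + 1).

#' Create a 3D affine transform
#'
#' @param linear 3x3 matrix (the linear part), acting on `(z, y, x)` columns.
#' @param offset Length-3 offset vector.
#' @return An object of class `affine3d`.
#' @export
affine3d <- function(linear = diag(3), offset = c(0, 0, 0)) {
  linear <- matrix(as.numeric(linear), 3, 3)
  offset <- as.numeric(offset)
  stopifnot(length(offset) == 3)
  if (abs(det(linear)) <= 1e-12) {
    stop("invalid-transform: linear part must be invertible", call. = FALSE)
  }
  structure(list(linear = linear, offset = offset), class = "affine3d")
}

#' @export
print.affine3d <- function(x, ...) {
  cat("<affine3d> linear:\n")
  print(signif(x$linear, 6))
  cat("offset:", paste(signif(x$offset, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Invert a 3D affine transform
#'
#' @param transform An `affine3d`.
#' @return The inverse `affine3d`.
#' @export
invert_affine3d <- function(transform) {
  li <- solve(transform$linear)
  affine3d(li, -li %*% transform$offset)
}

#' Estimate an affine transform from paired landmarks
#'
#' Least-squares fit of `A %*% p_moving + b ~ p_fixed` over >= 4 non-coplanar
#' landmark pairs; with noiseless pairs from a true affine the recovery is
#' exact to machine precision. An intensity-based refinement mode (normalized
#' correlation ascent from an initial transform over a downsampled grid) is
#' available as a best-effort alternative when no landmarks exist.
#'
#' @param moving Numeric matrix (n x 3) of `(z, y, x)` points in the moving
#'   (stack) frame, or a `section_stack` when `mode = "intensity"`.
#' @param fixed Numeric matrix (n x 3) of corresponding points in the fixed
#'   (atlas voxel) frame, or a `label_volume` template when
#'   `mode = "intensity"`.
#' @param mode `"landmarks"` (default) or `"intensity"`.
#' @param init Initial `affine3d` for intensity mode.
#' @return An `affine3d`.
#' @export
estimate_affine <- function(moving, fixed, mode = c("landmarks", "intensity"),
                            init = affine3d()) {
  mode <- match.arg(mode)
  if (mode == "intensity") {
    return(estimate_affine_intensity(moving, fixed, init))
  }
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  stopifnot(ncol(moving) == 3, ncol(fixed) == 3, nrow(moving) == nrow(fixed))
  n <- nrow(moving)
  if (n < 4) {
    stop("degenerate-landmarks: at least 4 landmark pairs are required", call. = FALSE)
  }
  centered <- scale(moving, scale = FALSE)
  if (qr(centered)$rank < 3) {
    stop("degenerate-landmarks: landmark set is coplanar", call. = FALSE)
  }
  X <- cbind(moving, 1)
  # one least-squares solve per output coordinate
  coef <- solve(crossprod(X), crossprod(X, fixed)) # 4 x 3
  affine3d(t(coef[1:3, ]), coef[4, ])
}

# best-effort intensity refinement: normalized correlation between the
# transformed stack midplane density and the template labels, Nelder-Mead
# over the 12 affine parameters on a coarse voxel grid
estimate_affine_intensity <- function(stack, template, init = affine3d()) {
  stopifnot(inherits(template, "label_volume"))
  vol <- stack_to_volume_density(stack)
  tpl <- (template$labels > 0) * 1
  dims_t <- dim(tpl)
  # sample a coarse grid of foreground-ish points in the moving volume
  idx <- which(vol > stats::quantile(vol, 0.9))
  if (!length(idx)) return(init)
  idx <- idx[seq(1, length(idx), length.out = min(2000, length(idx)))]
  co <- arrayInd(idx, dim(vol)) - 1
  v <- vol[idx]
  spacing <- c(stack$thickness_um, stack$pixel_size_um, stack$pixel_size_um)
  pts_um <- sweep(co, 2, spacing, `*`)
  obj <- function(par) {
    tr <- affine3d(matrix(par[1:9], 3, 3), par[10:12])
    vox <- map_points(pts_um, tr)
    f <- floor(vox)
    ok <- f[, 1] >= 0 & f[, 1] < dims_t[1] & f[, 2] >= 0 & f[, 2] < dims_t[2] &
      f[, 3] >= 0 & f[, 3] < dims_t[3]
    if (sum(ok) < 10) return(1e6)
    tv <- tpl[f[ok, , drop = FALSE] + 1]
    if (sd(tv) == 0 || sd(v[ok]) == 0) return(1e6)
    -stats::cor(tv, v[ok]) + (1 - mean(ok))
  }
  par0 <- c(as.vector(init$linear), init$offset)
  fit <- optim(par0, obj, method = "Nelder-Mead",
               control = list(maxit = 400, reltol = 1e-8))
  affine3d(matrix(fit$par[1:9], 3, 3), fit$par[10:12])
}

stack_to_volume_density <- function(stack) {
  ch <- names(stack$sections[[1]]$channels)[1]
  imgs <- lapply(stack$sections, function(s) s$channels[[ch]])
  arr <- array(0, dim = c(length(imgs), dim(imgs[[1]])))
  for (i in seq_along(imgs)) arr[i, , ] <- imgs[[i]]
  arr
}

#' Map points through a 3D affine transform
#'
#' Applies `A %*% p + b` to each row; returns float coordinates (no rounding).
#'
#' @param points Numeric matrix (n x 3) of `(z, y, x)` points.
#' @param transform An `affine3d`.
#' @return Numeric matrix (n x 3) of transformed points.
#' @export
map_points <- function(points, transform) {
  stopifnot(inherits(transform, "affine3d"))
  points <- matrix(as.numeric(as.matrix(points)), ncol = 3)
  t(transform$linear %*% t(points) + transform$offset)
}

#' Assign region labels to points in atlas voxel coordinates
#'
#' Float voxel coordinates are floored (voxels are half-open, `[v, v + 1)`);
#' points outside the volume — including exactly on the upper face — get the
#' background label 0.
#'
#' @param points Numeric matrix (n x 3) of `(z, y, x)` voxel coordinates.
#' @param atlas A `label_volume`.
#' @return Integer vector of region labels.
#' @export
assign_regions <- function(points, atlas) {
  stopifnot(inherits(atlas, "label_volume"))
  points <- matrix(as.numeric(as.matrix(points)), ncol = 3)
  d <- dim(atlas$labels)
  f <- floor(points)
  ok <- f[, 1] >= 0 & f[, 1] < d[1] & f[, 2] >= 0 & f[, 2] < d[2] &
    f[, 3] >= 0 & f[, 3] < d[3]
  out <- integer(nrow(points))
  if (any(ok)) out[ok] <- atlas$labels[f[ok, , drop = FALSE] + 1]
  out
}

#' Affine transform mapping a stack's physical frame into atlas voxels
#'
#' Convenience constructor for the common case where sections correspond to
#' known atlas z-slices: scales micrometer coordinates by the atlas voxel
#' spacing and applies an optional voxel offset.
#'
#' @param atlas A `label_volume`.
#' @param offset_vox Optional voxel offset `c(z, y, x)`.
#' @return An `affine3d`.
#' @export
stack_to_atlas_affine <- function(atlas, offset_vox = c(0, 0, 0)) {
  affine3d(diag(1 / atlas$spacing_um), offset_vox)
}
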