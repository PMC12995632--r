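# Assembly of segmented sections into labeled voxel volumes (separate soma
# and axon layers) and lossless export for external 3D viewers.

#' Rasterize soma detections into a binary mask
#'
#' @param detections A `soma_detections` tibble for one section.
#' @param dim Image dimensions `c(nrow, ncol)`.
#' @param mode `"mask"` (union of the watershed masks) or `"centroid_disk"`
#'   (disks of `radius_px` around centroids).
#' @param radius_px Disk radius for `"centroid_disk"`.
#' @return Logical matrix.
#' @export
detections_to_mask <- function(detections, dim, mode = c("mask", "centroid_disk"),
                               radius_px = 3) {
  mode <- match.arg(mode)
  m <- matrix(FALSE, dim[1], dim[2])
  if (!nrow(detections)) return(m)
  if (mode == "mask" && "pixels" %in% names(detections)) {
    for (px in detections$pixels) {
      m[px[, c("y", "x"), drop = FALSE] + 1] <- TRUE
    }
  } else {
    for (k in seq_len(nrow(detections))) {
      cy <- detections$y[k]; cx <- detections$x[k]
      ys <- max(0, floor(cy - radius_px)):min(dim[1] - 1, ceiling(cy + radius_px))
      xs <- max(0, floor(cx - radius_px)):min(dim[2] - 1, ceiling(cx + radius_px))
      d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
      m[ys + 1, xs + 1] <- m[ys + 1, xs + 1] | (d2 <= radius_px^2)
    }
  }
  m
}

#' Assemble segmented sections into a render volume
#'
#' Resamples per-section soma and axon masks through their section transforms
#' (nearest-neighbour, preserving 0/1 values) into the common reference frame
#' and stacks them along z as separate binary layers with anisotropic
#' spacing (z = section thickness, xy = pixel size).
#'
#' @param seg_results List (one element per section) of lists with elements
#'   `soma_mask` and/or `axon_mask` (logical matrices of a common shape).
#' @param transforms `NULL` (identity), or a tibble with `theta_deg`,
#'   `dx_px`, `dy_px` per section (as returned by [rigid_align()]).
#' @param spacing_um Voxel spacing `c(z, y, x)` in micrometers (default
#'   50 um sections at 1.82 um/px).
#' @param underlay Optional `label_volume` stored alongside the layers.
#' @return An object of class `render_volume`: named binary layers (3D
#'   arrays, z first), spacing, optional underlay.
#' @export
build_volume <- function(seg_results, transforms = NULL,
                         spacing_um = c(z = 50, y = 1.82, x = 1.82),
                         underlay = NULL) {
  stopifnot(length(seg_results) >= 1)
  get_dim <- function(s) {
    m <- if (!is.null(s$soma_mask)) s$soma_mask else s$axon_mask
    if (is.null(m)) stop("invalid-input: each section needs soma_mask or axon_mask",
                         call. = FALSE)
    dim(m)
  }
  d <- get_dim(seg_results[[1]])
  for (s in seg_results) {
    if (!all(get_dim(s) == d)) {
      stop("invalid-input: section mask shapes differ", call. = FALSE)
    }
  }
  nz <- length(seg_results)
  layers <- list(
    somata = array(FALSE, dim = c(nz, d)),
    axons = array(FALSE, dim = c(nz, d))
  )
  for (i in seq_len(nz)) {
    tr <- if (is.null(transforms)) {
      rigid_transform(0, 0, 0)
    } else {
      rigid_transform(transforms$theta_deg[i], transforms$dx_px[i], transforms$dy_px[i])
    }
    ident <- tr$theta_deg == 0 && tr$dx_px == 0 && tr$dy_px == 0
    for (nm in c("somata", "axons")) {
      src <- switch(nm, somata = seg_results[[i]]$soma_mask,
                    axons = seg_results[[i]]$axon_mask)
      if (is.null(src)) next
      m <- (src > 0) * 1
      if (!ident) m <- warp_rigid(m, tr, interp = "nearest")
      layers[[nm]][i, , ] <- m > 0
    }
  }
  structure(list(layers = layers,
                 spacing_um = setNames(as.numeric(spacing_um), c("z", "y", "x")),
                 underlay = underlay),
            class = "render_volume")
}

#' @export
print.render_volume <- function(x, ...) {
  d <- dim(x$layers[[1]])
  cat(sprintf("<render_volume> %d x %d x %d voxels, spacing (%.2f, %.2f, %.2f) um\n",
              d[1], d[2], d[3], x$spacing_um[1], x$spacing_um[2], x$spacing_um[3]))
  for (nm in names(x$layers)) {
    cat(sprintf("  layer %-8s: %d foreground voxels\n", nm, sum(x$layers[[nm]])))
  }
  invisible(x)
}

#' Export a render volume to disk
#'
#' Writes one file per layer: multi-page TIFF (`<stem>_<layer>.tif`, one page
#' per z-slice) or NIfTI-1 (`<stem>_<layer>.nii.gz`) with the voxel spacing
#' encoded in the header. Binary layers round-trip losslessly.
#'
#' @param volume A `render_volume`.
#' @param stem Output path stem (directory must exist).
#' @param format `"tiff"` or `"nifti"`.
#' @return Invisibly, the written file paths (named by layer).
#' @export
export_volume <- function(volume, stem, format = c("tiff", "nifti")) {
  if (!is.character(format) || !all(format %in% c("tiff", "nifti"))) {
    stop("invalid-format: format must be \"tiff\" or \"nifti\"", call. = FALSE)
  }
  format <- match.arg(format)
  stopifnot(inherits(volume, "render_volume"))
  paths <- character(0)
  for (nm in names(volume$layers)) {
    arr <- volume$layers[[nm]] * 1
    if (format == "tiff") {
      path <- paste0(stem, "_", nm, ".tif")
      pages <- lapply(seq_len(dim(arr)[1]), function(z) arr[z, , ])
      tiff::writeTIFF(pages, path, bits.per.sample = 8)
    } else {
      path <- paste0(stem, "_", nm, ".nii.gz")
      # NIfTI axis order is (x, y, z)
      img <- RNifti::asNifti(aperm(arr, c(3, 2, 1)))
      RNifti::pixdim(img) <- volume$spacing_um[c("x", "y", "z")]
      RNifti::writeNifti(img, path)
    }
    paths[nm] <- path
  }
  invisible(paths)
}

#' Read a render volume back from disk
#'
#' @param stem Path stem used at export time.
#' @param format `"tiff"` or `"nifti"`.
#' @param layers Layer names to read (default somata and axons).
#' @param spacing_um Spacing to record for TIFF input (NIfTI carries its own).
#' @return A `render_volume`.
#' @export
read_volume <- function(stem, format = c("tiff", "nifti"),
                        layers = c("somata", "axons"),
                        spacing_um = c(z = 50, y = 1.82, x = 1.82)) {
  format <- match.arg(format)
  out <- list()
  for (nm in layers) {
    if (format == "tiff") {
      pages <- tiff::readTIFF(paste0(stem, "_", nm, ".tif"), all = TRUE)
      if (!is.list(pages)) pages <- list(pages)
      arr <- array(FALSE, dim = c(length(pages), dim(pages[[1]])))
      for (z in seq_along(pages)) arr[z, , ] <- pages[[z]] > 0.5
      out[[nm]] <- arr
    } else {
      img <- RNifti::readNifti(paste0(stem, "_", nm, ".nii.gz"))
      spacing_um <- rev(RNifti::pixdim(img))
      names(spacing_um) <- c("z", "y", "x")
      out[[nm]] <- aperm(as.array(img), c(3, 2, 1)) > 0.5
    }
  }
  structure(list(layers = out,
                 spacing_um = setNames(as.numeric(spacing_um), c("z", "y", "x")),
                 underlay = NULL),
            class = "render_volume")
}
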