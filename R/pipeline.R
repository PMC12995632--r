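# End-to-end convenience wrappers: stack -> aligned stack -> detections ->
# atlas regions -> count table -> genotype comparison.

#' Affine from stack pixel coordinates into atlas voxel coordinates
#'
#' For stacks whose sections correspond to consecutive atlas z-slices at the
#' atlas's own in-plane resolution: converts (z, y, x) micrometer coordinates
#' to voxel coordinates and shifts by half a voxel so that pixel centers
#' (integer coordinates) land in the matching half-open voxel.
#'
#' @param atlas A `label_volume`.
#' @return An `affine3d`.
#' @export
pixel_to_voxel_affine <- function(atlas) {
  affine3d(diag(1 / atlas$spacing_um), c(0.5, 0.5, 0.5))
}

#' Detection coordinates in micrometers
#'
#' @param detections A `soma_detections` tibble.
#' @param metadata Stack metadata (for `z_index` lookup by `section_id`).
#' @param pixel_size_um,thickness_um Physical calibration.
#' @return Matrix (n x 3) of `(z, y, x)` in micrometers.
#' @export
detections_to_um <- function(detections, metadata, pixel_size_um = 1.82,
                             thickness_um = 50) {
  z_index <- metadata$z_index[match(detections$section_id, metadata$section_id)]
  cbind(z = (z_index - 1) * thickness_um,
        y = detections$y * pixel_size_um,
        x = detections$x * pixel_size_um)
}

#' Quantify one animal's stack against an atlas
#'
#' Runs the per-stack pipeline: optional rigid alignment (on the counterstain
#' channel), soma detection on the reporter channel of every aligned section,
#' mapping of detection centroids into atlas voxels, region assignment, and
#' the per-region count table with explicit zeros.
#'
#' @param stack A `section_stack`.
#' @param atlas A `label_volume` whose z-slices correspond to the stack's
#'   `z_index` values.
#' @param align Align the stack first? (default TRUE)
#' @param ref_index Reference section for alignment (default: middle).
#' @param channel Reporter channel used for detection.
#' @param d_min,d_max,background_radius,min_peak Soma detector settings (see
#'   [detect_somata()]).
#' @param max_shift_px,max_rot_deg,refine_stride Alignment settings (see
#'   [rigid_align()]).
#' @return List: `counts` (a `section_counts` tibble), `detections` (with a
#'   `region` column), `transforms`, `seg_results` (per-section soma masks,
#'   ready for [build_volume()]).
#' @export
quantify_stack <- function(stack, atlas, align = TRUE,
                           ref_index = ceiling(n_sections(stack) / 2),
                           channel = "green", d_min = 4, d_max = 20,
                           background_radius = 15, min_peak = 10,
                           max_shift_px = 24, max_rot_deg = 12,
                           refine_stride = 2) {
  stopifnot(inherits(stack, "section_stack"), inherits(atlas, "label_volume"))
  transforms <- tibble::tibble(section_id = stack$metadata$section_id,
                               theta_deg = 0, dx_px = 0, dy_px = 0)
  if (align) {
    al <- rigid_align(stack, ref_index = ref_index, max_shift_px = max_shift_px,
                      max_rot_deg = max_rot_deg, refine_stride = refine_stride)
    stack <- al$stack
    transforms <- al$transforms
  }
  det_list <- vector("list", n_sections(stack))
  seg_results <- vector("list", n_sections(stack))
  d <- stack_dim(stack)
  for (i in seq_len(n_sections(stack))) {
    img <- stack$sections[[i]]$channels[[channel]]
    det <- detect_somata(img, d_min = d_min, d_max = d_max,
                         background_radius = background_radius,
                         min_peak = min_peak,
                         section_id = stack$metadata$section_id[i])
    det_list[[i]] <- det
    seg_results[[i]] <- list(soma_mask = detections_to_mask(det, d),
                             axon_mask = NULL)
  }
  detections <- dplyr::bind_rows(det_list)
  if (nrow(detections)) {
    pts <- detections_to_um(detections, stack$metadata,
                            pixel_size_um = stack$pixel_size_um,
                            thickness_um = stack$thickness_um)
    vox <- map_points(pts, pixel_to_voxel_affine(atlas))
    detections$region <- assign_regions(vox, atlas)
  } else {
    detections$region <- integer(0)
  }
  counts <- count_by_region(detections, detections$region, stack$metadata,
                            atlas$region_table)
  list(counts = counts, detections = detections, transforms = transforms,
       seg_results = seg_results)
}

#' Run the full study analysis
#'
#' Quantifies every stack of a (simulated or real) study and fits the
#' per-region genotype comparison.
#'
#' @param stacks Named list of `section_stack` objects (one per animal).
#' @param atlas A `label_volume`.
#' @param alpha Significance level for the comparison table.
#' @param ... Passed to [quantify_stack()].
#' @return List: `counts` (combined `section_counts`), `comparison` (a
#'   `region_comparison`), `per_stack` (per-animal pipeline outputs).
#' @export
run_study_analysis <- function(stacks, atlas, alpha = 0.05, ...) {
  per_stack <- lapply(stacks, quantify_stack, atlas = atlas, ...)
  counts <- dplyr::bind_rows(lapply(per_stack, `[[`, "counts"))
  class(counts) <- c("section_counts", setdiff(class(counts), "section_counts"))
  comparison <- compare_regions(counts, alpha = alpha)
  list(counts = counts, comparison = comparison, per_stack = per_stack)
}
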