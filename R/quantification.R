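# From segmentations to analysis-ready tables: per-region soma counts with
# explicit zeros, ROI integrated density, and the all-three-planes positivity
# rule.

#' Per-region, per-section soma count table
#'
#' One row per (region, section) for every non-background region of the
#' region table, including explicit zeros for regions with no detections —
#' dropping zero-count sections would bias the downstream mixed model upward.
#' Detections assigned the background label 0 are excluded.
#'
#' @param detections A `soma_detections` tibble (any number of sections) with
#'   a `section_id` column.
#' @param region_labels Integer vector of per-detection region labels
#'   (0 = background), aligned with `detections` rows.
#' @param metadata Tibble with one row per section: `section_id`,
#'   `animal_id`, `genotype`, `plane` (and optionally more).
#' @param region_table Tibble of `label`, `name` for all regions (e.g.
#'   `atlas$region_table`).
#' @return A tibble (class `section_counts`): `region`, `region_name`,
#'   `section_id`, `animal_id`, `genotype`, `plane`, `count`.
#' @export
count_by_region <- function(detections, region_labels, metadata, region_table) {
  stopifnot(is.data.frame(detections), is.data.frame(metadata),
            all(c("section_id", "animal_id", "genotype", "plane") %in% names(metadata)))
  if (nrow(detections) != length(region_labels)) {
    stop("region_labels must have one entry per detection", call. = FALSE)
  }
  missing_meta <- setdiff(unique(detections$section_id), metadata$section_id)
  if (length(missing_meta)) {
    stop("missing-metadata: section(s) not in metadata: ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  }
  det <- tibble::tibble(section_id = detections$section_id,
                        region = as.integer(region_labels)) |>
    dplyr::filter(.data$region != 0L)
  grid <- tidyr::expand_grid(
    region = as.integer(region_table$label),
    section_id = metadata$section_id
  )
  counted <- det |>
    dplyr::count(.data$region, .data$section_id, name = "count")
  out <- grid |>
    dplyr::left_join(counted, by = c("region", "section_id")) |>
    dplyr::mutate(count = ifelse(is.na(.data$count), 0L, .data$count)) |>
    dplyr::left_join(
      tibble::tibble(region = as.integer(region_table$label),
                     region_name = region_table$name),
      by = "region"
    ) |>
    dplyr::left_join(metadata, by = "section_id") |>
    dplyr::select("region", "region_name", "section_id", "animal_id",
                  "genotype", "plane", "count")
  class(out) <- c("section_counts", class(out))
  out
}

#' Integrated density of a region of interest
#'
#' Integrated density = ROI area (px) x mean intensity over the ROI, the
#' standard total-fluorescence measure. Optionally applies rolling-ball
#' background subtraction first.
#'
#' @param image Numeric matrix.
#' @param roi_mask Logical/0-1 matrix of the ROI (must be non-empty).
#' @param background_radius Optional rolling-ball radius applied before
#'   measuring (the conventional choice is 50 px); `NULL` measures the raw
#'   image.
#' @param roi_id,section_id Identifiers echoed into the output.
#' @return A one-row tibble: `roi_id`, `section_id`, `area_px`,
#'   `mean_intensity`, `integrated_density`, `background_corrected`.
#' @export
integrated_density <- function(image, roi_mask, background_radius = NULL,
                               roi_id = "roi1", section_id = NA_character_) {
  stopifnot(is.matrix(image), all(dim(roi_mask) == dim(image)))
  sel <- roi_mask > 0
  if (!any(sel)) stop("empty-roi: the ROI mask has no pixels", call. = FALSE)
  img <- image
  corrected <- FALSE
  if (!is.null(background_radius)) {
    img <- rolling_ball(image, background_radius)$corrected
    corrected <- TRUE
  }
  area <- sum(sel)
  mean_int <- mean(img[sel])
  tibble::tibble(
    roi_id = roi_id, section_id = section_id,
    area_px = area, mean_intensity = mean_int,
    integrated_density = area * mean_int,
    background_corrected = corrected
  )
}

#' Region positivity calls per plane
#'
#' Operational definition of "signal present": a region is positive within a
#' plane when it has at least `min_count` detections (or, optionally, any
#' axon-mask pixels) in any section of that plane.
#'
#' @param counts A `section_counts` tibble.
#' @param min_count Minimum per-section count that counts as signal.
#' @return Tibble of distinct (`region`, `plane`) pairs with signal.
#' @export
plane_positivity <- function(counts, min_count = 1) {
  counts |>
    dplyr::filter(.data$count >= min_count) |>
    dplyr::distinct(.data$region, .data$plane)
}

#' Cross-plane consistency rule
#'
#' A region is confirmed positive only if signal was observed in every
#' required histological plane; regions short of that are reported as
#' unconfirmed with their missing planes listed.
#'
#' @param observations Tibble with columns `region` and `plane` (one row per
#'   observed region-plane pair), e.g. from [plane_positivity()].
#' @param required_planes Character vector of planes that must all be present
#'   (default coronal, sagittal, horizontal).
#' @return Tibble: `region`, `confirmed` (logical), `missing_planes`
#'   (comma-separated string, empty when confirmed).
#' @export
cross_plane_consistency <- function(observations,
                                    required_planes = c("coronal", "sagittal", "horizontal")) {
  stopifnot(is.data.frame(observations))
  if (!nrow(observations)) {
    return(tibble::tibble(region = integer(), confirmed = logical(),
                          missing_planes = character()))
  }
  bad <- setdiff(unique(observations$plane), required_planes)
  if (length(bad)) {
    stop("plane name(s) outside the required set: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  observations |>
    dplyr::distinct(.data$region, .data$plane) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      confirmed = all(required_planes %in% .data$plane),
      missing_planes = paste(setdiff(required_planes, .data$plane), collapse = ","),
      .groups = "drop"
    )
}
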