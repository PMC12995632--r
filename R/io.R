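# File interchange: 8-bit grayscale PNGs for section stacks, multi-page
# 16-bit TIFF for label volumes, CSV/JSON for tables, transforms and
# parameter echoes.

#' Write a section stack as per-section PNG files
#'
#' One 8-bit grayscale PNG per section per channel, named
#' `<stem>_z<index>_<channel>.png`, plus `<stem>_metadata.csv`.
#'
#' @param stack A `section_stack`.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem.
#' @return Invisibly, the written image paths.
#' @export
write_section_stack <- function(stack, dir, stem = "stack") {
  stopifnot(inherits(stack, "section_stack"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (i in seq_len(n_sections(stack))) {
    z <- stack$metadata$z_index[i]
    for (ch in names(stack$sections[[i]]$channels)) {
      img <- stack$sections[[i]]$channels[[ch]]
      img8 <- pmin(pmax(round(img), 0), 255) / 255
      path <- file.path(dir, sprintf("%s_z%03d_%s.png", stem, z, ch))
      png::writePNG(img8, path)
      paths <- c(paths, path)
    }
  }
  utils::write.csv(stack$metadata, file.path(dir, paste0(stem, "_metadata.csv")),
                   row.names = FALSE)
  invisible(paths)
}

#' Read a section stack written by [write_section_stack()]
#'
#' @param dir Directory containing the PNGs and metadata CSV.
#' @param stem File-name stem used at write time.
#' @param pixel_size_um,thickness_um Physical calibration to record.
#' @return A `section_stack` (working images in `[0, 255]`).
#' @export
read_section_stack <- function(dir, stem = "stack", pixel_size_um = 1.82,
                               thickness_um = 50) {
  meta <- utils::read.csv(file.path(dir, paste0(stem, "_metadata.csv")),
                          stringsAsFactors = FALSE)
  meta <- tibble::as_tibble(meta)
  files <- list.files(dir, pattern = paste0("^", stem, "_z\\d+_.*\\.png$"))
  chans <- unique(sub(paste0("^", stem, "_z\\d+_(.*)\\.png$"), "\\1", files))
  sections <- lapply(meta$z_index, function(z) {
    ch <- lapply(setNames(chans, chans), function(cc) {
      img <- png::readPNG(file.path(dir, sprintf("%s_z%03d_%s.png", stem, z, cc)))
      if (length(dim(img)) == 3) img <- img[, , 1]
      img * 255
    })
    list(channels = ch)
  })
  structure(list(sections = sections, metadata = meta,
                 pixel_size_um = pixel_size_um, thickness_um = thickness_um),
            class = "section_stack")
}

#' Write a label volume as multi-page 16-bit TIFF plus region-name CSV
#'
#' @param atlas A `label_volume`.
#' @param path Output TIFF path; the region table goes to
#'   `<path without extension>_regions.csv`.
#' @return Invisibly, `path`.
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "label_volume"))
  pages <- lapply(seq_len(dim(atlas$labels)[1]),
                  function(z) atlas$labels[z, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  utils::write.csv(atlas$region_table,
                   paste0(sub("\\.tiff?$", "", path), "_regions.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' Read a label volume written by [write_atlas()]
#'
#' @param path TIFF path.
#' @param spacing_um Voxel spacing `c(z, y, x)` to record.
#' @return A `label_volume`.
#' @export
read_atlas <- function(path, spacing_um = c(z = 50, y = 1.82, x = 1.82)) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  labels <- array(0L, dim = c(length(pages), dim(pages[[1]])))
  for (z in seq_along(pages)) {
    labels[z, , ] <- as.integer(round(pages[[z]] * 65535))
  }
  rt_path <- paste0(sub("\\.tiff?$", "", path), "_regions.csv")
  region_table <- if (file.exists(rt_path)) {
    tibble::as_tibble(utils::read.csv(rt_path, stringsAsFactors = FALSE))
  } else {
    labs <- sort(setdiff(unique(as.vector(labels)), 0L))
    tibble::tibble(label = labs, name = sprintf("region_%02d", labs))
  }
  structure(list(labels = labels, region_table = region_table,
                 spacing_um = setNames(as.numeric(spacing_um), c("z", "y", "x"))),
            class = "label_volume")
}

#' Write per-section rigid transforms to JSON
#'
#' @param transforms Tibble with `section_id`, `theta_deg`, `dx_px`, `dy_px`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_transforms <- function(transforms, path) {
  jsonlite::write_json(transforms, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read per-section rigid transforms from JSON
#'
#' @param path JSON path written by [write_transforms()].
#' @return Tibble with `section_id`, `theta_deg`, `dx_px`, `dy_px`.
#' @export
read_transforms <- function(path) {
  tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Write ground truth (soma centers CSV + parameters/transforms JSON)
#'
#' @param truth A `ground_truth`.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem.
#' @return Invisibly, the written paths.
#' @export
write_ground_truth <- function(truth, dir, stem = "truth") {
  stopifnot(inherits(truth, "ground_truth"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  soma_path <- file.path(dir, paste0(stem, "_somata.csv"))
  counts_path <- file.path(dir, paste0(stem, "_counts.csv"))
  json_path <- file.path(dir, paste0(stem, "_params.json"))
  utils::write.csv(truth$somata, soma_path, row.names = FALSE)
  utils::write.csv(truth$counts, counts_path, row.names = FALSE)
  jsonlite::write_json(
    list(seed = truth$seed,
         transforms = truth$transforms,
         effect = unclass(truth$params$effect),
         noise = unclass(truth$params$noise),
         genotype = truth$params$genotype,
         rate_multiplier = truth$params$rate_multiplier),
    json_path, digits = NA, auto_unbox = TRUE
  )
  invisible(c(soma_path, counts_path, json_path))
}
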