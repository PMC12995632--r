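# Reporter-channel segmentation: a Hessian-eigenvalue tubularity filter for
# axons (bright curvilinear structures) and a classical multi-scale
# blob-detection + marker-based watershed soma detector behind a pluggable
# interface.

#' Tubularity filter parameters
#'
#' @param scales Gaussian scales (sd, px) of the multi-scale Hessian analysis.
#' @param beta Blob-suppression sensitivity (on the eigenvalue ratio term).
#' @param c Background-suppression sensitivity (on the structureness term);
#'   `NULL` (default) uses half the maximum Hessian Frobenius norm per scale.
#' @return An object of class `tubularity_params`.
#' @export
tubularity_params <- function(scales = c(1, 1.5, 2.25, 3.375), beta = 0.5, c = NULL) {
  if (!length(scales) || any(scales <= 0)) {
    stop("invalid-parameter: scales must be positive", call. = FALSE)
  }
  if (beta <= 0 || (!is.null(c) && c <= 0)) {
    stop("invalid-parameter: beta and c must be > 0", call. = FALSE)
  }
  structure(list(scales = sort(scales), beta = beta, c = c),
            class = "tubularity_params")
}

#' Hessian-eigenvalue tubularity response
#'
#' Per scale sigma, computes the scale-normalized (sigma^2) Gaussian-derivative
#' Hessian and its eigenvalues sorted |lambda1| <= |lambda2|. Bright-on-dark
#' polarity: the response is 0 wherever lambda2 >= 0, else
#' `exp(-R_B^2 / 2 beta^2) * (1 - exp(-S^2 / 2 c^2))` with
#' `R_B = |lambda1| / |lambda2|` (blob suppression) and
#' `S = sqrt(lambda1^2 + lambda2^2)` (structureness). The final map is the
#' pixelwise maximum over scales, rescaled to `[0, 1]`; the attribute
#' `best_scale` records the argmax scale per pixel.
#'
#' @param image Numeric matrix, at least 7 x 7 and larger than
#'   `2 * max(scales) + 1` in both dimensions.
#' @param params A [tubularity_params()].
#' @return Numeric matrix in `[0, 1]` with attribute `best_scale`.
#' @export
tubularity <- function(image, params = tubularity_params()) {
  stopifnot(is.matrix(image), inherits(params, "tubularity_params"))
  if (nrow(image) < 7 || ncol(image) < 7 ||
      min(dim(image)) < 2 * max(params$scales) + 1) {
    stop("invalid-parameter: image too small for the requested scales", call. = FALSE)
  }
  eigs <- lapply(params$scales, function(s) {
    h <- hessian_at_scale(image, s)
    xx <- s^2 * h$xx; yy <- s^2 * h$yy; xy <- s^2 * h$xy
    half_diff <- sqrt(((xx - yy) / 2)^2 + xy^2)
    mean_ev <- (xx + yy) / 2
    e1 <- mean_ev + half_diff
    e2 <- mean_ev - half_diff
    swap <- abs(e1) > abs(e2)
    list(l2 = ifelse(swap, e1, e2), # larger magnitude
         l1 = ifelse(swap, e2, e1))
  })
  # one background-suppression constant across all scales, so responses at
  # different scales stay comparable and the per-pixel argmax scale tracks
  # the true structure width
  s2_all <- lapply(eigs, function(e) e$l1^2 + e$l2^2)
  s_max <- max(sqrt(unlist(lapply(s2_all, max))))
  # flat image: second derivatives at numerical-noise level only
  if (s_max < 1e-9 * (max(abs(image)) + 1)) {
    out <- matrix(0, nrow(image), ncol(image))
    attr(out, "best_scale") <- matrix(params$scales[1], nrow(image), ncol(image))
    return(out)
  }
  cc <- if (is.null(params$c)) s_max / 2 else params$c
  best <- matrix(0, nrow(image), ncol(image))
  best_scale <- matrix(params$scales[1], nrow(image), ncol(image))
  for (k in seq_along(params$scales)) {
    l1 <- eigs[[k]]$l1; l2 <- eigs[[k]]$l2
    s2 <- s2_all[[k]]
    v <- matrix(0, nrow(image), ncol(image))
    ok <- l2 < 0
    if (any(ok) && cc > 0) {
      rb2 <- (l1[ok] / l2[ok])^2
      v[ok] <- exp(-rb2 / (2 * params$beta^2)) *
        (1 - exp(-s2[ok] / (2 * cc^2)))
    }
    upd <- v > best
    best[upd] <- v[upd]
    best_scale[upd] <- params$scales[k]
  }
  m <- max(best)
  if (m > 1e-12) best <- best / m else best[] <- 0
  attr(best, "best_scale") <- best_scale
  best
}

# shift a matrix by (dr, dc), padding with `fill`
shift_mat <- function(m, dr, dc, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Topological skeleton of a binary mask (Zhang-Suen thinning)
#'
#' Iterative two-subcycle thinning down to a 1-px-wide skeleton; used to
#' measure the centerline length of axon-mask components.
#'
#' @param mask Logical or 0/1 matrix.
#' @return Logical matrix of skeleton pixels.
#' @export
skeletonize <- function(mask) {
  b <- (mask > 0) * 1
  neigh <- function(b) {
    list(p2 = shift_mat(b, -1, 0), p3 = shift_mat(b, -1, 1),
         p4 = shift_mat(b, 0, 1),  p5 = shift_mat(b, 1, 1),
         p6 = shift_mat(b, 1, 0),  p7 = shift_mat(b, 1, -1),
         p8 = shift_mat(b, 0, -1), p9 = shift_mat(b, -1, -1))
  }
  for (iter in seq_len(500)) {
    changed <- FALSE
    for (step in 1:2) {
      p <- neigh(b)
      bsum <- p$p2 + p$p3 + p$p4 + p$p5 + p$p6 + p$p7 + p$p8 + p$p9
      seqs <- list(p$p2, p$p3, p$p4, p$p5, p$p6, p$p7, p$p8, p$p9, p$p2)
      a <- matrix(0, nrow(b), ncol(b))
      for (k in 1:8) a <- a + (seqs[[k]] == 0 & seqs[[k + 1]] == 1)
      if (step == 1) {
        cond <- b == 1 & bsum >= 2 & bsum <= 6 & a == 1 &
          (p$p2 * p$p4 * p$p6 == 0) & (p$p4 * p$p6 * p$p8 == 0)
      } else {
        cond <- b == 1 & bsum >= 2 & bsum <= 6 & a == 1 &
          (p$p2 * p$p4 * p$p8 == 0) & (p$p2 * p$p6 * p$p8 == 0)
      }
      if (any(cond)) {
        b[cond] <- 0
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  b > 0
}

# Otsu threshold of a numeric vector (256-bin histogram)
otsu_threshold <- function(v) {
  v <- v[is.finite(v)]
  if (!length(v) || diff(range(v)) == 0) return(Inf)
  breaks <- seq(min(v), max(v), length.out = 257)
  h <- tabulate(findInterval(v, breaks, all.inside = TRUE), nbins = 256)
  w <- h / sum(h)
  mids <- (breaks[-1] + breaks[-257]) / 2
  w1 <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[256]
  bcv <- (mu_t * w1 - mu)^2 / (w1 * (1 - w1))
  bcv[!is.finite(bcv)] <- 0
  mids[which.max(bcv)]
}

#' Segment axons from a tubularity response map
#'
#' Binarizes the response (Otsu on the nonzero response by default), removes
#' connected components whose skeleton length falls below
#' `min_skeleton_len_px`, then zeroes pixels inside the exclusion mask — the
#' deterministic, reproducible stand-in for manual removal of false positives.
#'
#' @param response Numeric matrix in `[0, 1]` (from [tubularity()]).
#' @param threshold `"otsu"` or a numeric threshold in `[0, 1]`.
#' @param min_skeleton_len_px Minimum component skeleton length (px).
#' @param exclusion_mask Optional logical/0-1 matrix of pixels to zero out.
#' @return An object of class `axon_mask`: list with `mask` (logical),
#'   `threshold`, `min_skeleton_len_px`, `exclusion_applied`, `n_retained`,
#'   `n_removed`.
#' @export
segment_axons <- function(response, threshold = "otsu",
                          min_skeleton_len_px = 10, exclusion_mask = NULL) {
  stopifnot(is.matrix(response))
  if (min(response) < -1e-9 || max(response) > 1 + 1e-9) {
    stop("invalid-parameter: response must lie in [0, 1]", call. = FALSE)
  }
  if (all(response == 0)) {
    warning("all-zero tubularity response: returning an empty axon mask")
    return(structure(list(mask = matrix(FALSE, nrow(response), ncol(response)),
                          threshold = NA_real_,
                          min_skeleton_len_px = min_skeleton_len_px,
                          exclusion_applied = !is.null(exclusion_mask),
                          n_retained = 0L, n_removed = 0L),
                     class = "axon_mask"))
  }
  thr <- if (identical(threshold, "otsu")) {
    otsu_threshold(response[response > 0])
  } else {
    as.numeric(threshold)
  }
  bin <- response >= thr & response > 0
  lab <- EBImage::bwlabel(bin * 1)
  lab <- matrix(as.integer(lab), nrow(bin), ncol(bin))
  nlab <- max(lab)
  n_removed <- 0L
  if (nlab > 0) {
    skel <- skeletonize(bin)
    skel_len <- tabulate(lab[skel], nbins = nlab)
    drop_ids <- which(skel_len < min_skeleton_len_px)
    n_removed <- length(drop_ids)
    if (n_removed) bin[lab %in% drop_ids] <- FALSE
  }
  if (!is.null(exclusion_mask)) {
    stopifnot(all(dim(exclusion_mask) == dim(bin)))
    bin[exclusion_mask > 0] <- FALSE
  }
  structure(list(mask = bin, threshold = thr,
                 min_skeleton_len_px = min_skeleton_len_px,
                 exclusion_applied = !is.null(exclusion_mask),
                 n_retained = as.integer(nlab - n_removed),
                 n_removed = as.integer(n_removed)),
            class = "axon_mask")
}

#' @export
print.axon_mask <- function(x, ...) {
  cat(sprintf("<axon_mask> %d px foreground, %d components retained, %d removed (threshold %.4g)\n",
              sum(x$mask), x$n_retained, x$n_removed, x$threshold))
  invisible(x)
}

# 3x3 neighbourhood maximum (for local-maximum seeding)
max_filter3 <- function(m) {
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- pmax(out, shift_mat(m, dr, dc, fill = -Inf))
  }
  out
}

empty_detections <- function(section_id = NA_character_) {
  tibble::tibble(section_id = character(), y = numeric(), x = numeric(),
                 diameter_px = numeric(), area_px = numeric(),
                 peak_intensity = numeric(), mean_intensity = numeric(),
                 pixels = list())
}

#' Detect somata in a reporter-channel image
#'
#' Built-in classical detector: optional rolling-ball background correction,
#' multi-scale scale-normalized Laplacian-of-Gaussian blob response,
#' local-maximum seeds (deduplicated at `d_min` spacing, ties broken by
#' response then (y, x) order), marker-based watershed masks grown inside the
#' foreground threshold, and a size filter to equivalent diameter in
#' `[d_min, d_max]`. Any plugged-in detector function must return the same
#' detection table contract.
#'
#' @param image Numeric matrix (reporter channel, working units `[0, 255]`).
#' @param d_min,d_max Soma equivalent-diameter bounds in px (defaults 4 and
#'   20 px, about 7-36 um at 1.82 um/px).
#' @param detector `"builtin"` or a function
#'   `f(image, d_min, d_max)` returning a detection tibble.
#' @param background_radius Optional rolling-ball radius applied first
#'   (e.g. 50); `NULL` skips background correction.
#' @param mask_threshold `"otsu"` or numeric threshold for the foreground
#'   mask the watershed grows into.
#' @param min_peak Minimum blob response (intensity units) for a seed.
#' @param blob_ratio_min Minimum Hessian eigenvalue magnitude ratio
#'   `|lambda1| / |lambda2|` at a seed; lower values are ridge-like (axons)
#'   and vetoed. 0 disables the veto.
#' @param section_id Section identifier carried into the output.
#' @return A tibble (class `soma_detections`) sorted by (y, x): `section_id`,
#'   centroid `y`, `x` (0-based px), `diameter_px`, `area_px`,
#'   `peak_intensity`, `mean_intensity`, and a `pixels` list-column of mask
#'   pixel coordinates.
#' @export
detect_somata <- function(image, d_min = 4, d_max = 20, detector = "builtin",
                          background_radius = NULL, mask_threshold = "otsu",
                          min_peak = 10, blob_ratio_min = 0.25,
                          section_id = NA_character_) {
  stopifnot(is.matrix(image))
  if (d_min >= d_max) {
    stop("invalid-parameter: d_min must be < d_max", call. = FALSE)
  }
  if (is.function(detector)) {
    out <- detector(image, d_min, d_max)
    req <- c("y", "x", "diameter_px", "area_px")
    if (!all(req %in% names(out))) {
      stop("plugin detector must return columns ", paste(req, collapse = ", "),
           call. = FALSE)
    }
    out$section_id <- section_id
    out <- dplyr::arrange(tibble::as_tibble(out), .data$y, .data$x)
    class(out) <- c("soma_detections", class(out))
    return(out)
  }
  img0 <- image
  if (!is.null(background_radius)) {
    img0 <- rolling_ball(image, background_radius)$corrected
  }
  # geometric scale ladder covering blob radii d_min/2 .. d_max/2
  lo <- d_min / (2 * sqrt(2)); hi <- d_max / (2 * sqrt(2))
  nsc <- max(2, ceiling(log(hi / lo) / log(1.4)) + 1)
  scales <- exp(seq(log(lo), log(hi), length.out = nsc))
  resp <- matrix(-Inf, nrow(image), ncol(image))
  hxx <- hyy <- hxy <- matrix(0, nrow(image), ncol(image))
  for (s in scales) {
    h <- hessian_at_scale(img0, s)
    r_s <- -s^2 * (h$xx + h$yy)
    upd <- r_s > resp
    resp[upd] <- r_s[upd]
    hxx[upd] <- h$xx[upd]; hyy[upd] <- h$yy[upd]; hxy[upd] <- h$xy[upd]
  }
  is_max <- resp >= max_filter3(resp) & resp > min_peak
  if (any(is_max)) {
    # ridge veto: bright blobs have comparable Hessian eigenvalues, whereas
    # points on axon-like ridges have |lambda1| << |lambda2| and would
    # otherwise be picked up as spurious somata
    half_diff <- sqrt(((hxx[is_max] - hyy[is_max]) / 2)^2 + hxy[is_max]^2)
    mean_ev <- (hxx[is_max] + hyy[is_max]) / 2
    e1 <- mean_ev + half_diff; e2 <- mean_ev - half_diff
    l2 <- ifelse(abs(e1) > abs(e2), e1, e2)
    l1 <- ifelse(abs(e1) > abs(e2), e2, e1)
    ratio <- abs(l1) / pmax(abs(l2), 1e-12)
    is_max[is_max] <- ratio >= blob_ratio_min
  }
  if (!any(is_max)) {
    out <- empty_detections()
    class(out) <- c("soma_detections", class(out))
    return(out)
  }
  idx <- which(is_max, arr.ind = TRUE)
  ord <- order(-resp[is_max], idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  # greedy seed dedup (strongest response wins, ties by (y, x) order): twin
  # maxima on one soma sit within about half a soma diameter of each other
  dedup <- max(d_min, (d_min + d_max) / 4)
  keep_y <- numeric(0); keep_x <- numeric(0)
  for (k in seq_len(nrow(idx))) {
    cy <- idx[k, 1]; cx <- idx[k, 2]
    if (!length(keep_y) ||
        min((keep_y - cy)^2 + (keep_x - cx)^2) >= dedup^2) {
      keep_y <- c(keep_y, cy); keep_x <- c(keep_x, cx)
    }
  }
  thr <- if (identical(mask_threshold, "otsu")) {
    otsu_threshold(as.vector(img0))
  } else {
    as.numeric(mask_threshold)
  }
  fg <- img0 >= thr
  seeds <- matrix(0L, nrow(image), ncol(image))
  seeds[cbind(keep_y, keep_x)] <- seq_along(keep_y)
  fg[cbind(keep_y, keep_x)] <- TRUE
  lab <- EBImage::propagate(img0 / max(img0, 1), seeds, mask = fg)
  lab <- matrix(as.integer(lab), nrow(image), ncol(image))
  hh <- nrow(image)
  idx <- which(lab > 0)
  if (!length(idx)) {
    out <- empty_detections()
    class(out) <- c("soma_detections", class(out))
    return(out)
  }
  lv <- lab[idx]
  wts <- img0[idx]
  py <- (idx - 1) %% hh        # 0-based row
  px <- (idx - 1) %/% hh       # 0-based col
  nid <- length(keep_y)
  area <- tabulate(lv, nbins = nid)
  wsum <- rowsum(wts, lv)[, 1]
  ids <- as.integer(names(wsum))
  wy <- rowsum(py * wts, lv)[, 1]
  wx <- rowsum(px * wts, lv)[, 1]
  grp <- split(seq_along(idx), lv)
  peak <- vapply(grp, function(g) max(wts[g]), numeric(1))
  diam <- 2 * sqrt(area[ids] / pi)
  keep <- diam >= d_min & diam <= d_max & wsum > 0
  out <- tibble::tibble(
    section_id = section_id,
    y = (wy / wsum)[keep], x = (wx / wsum)[keep],
    diameter_px = diam[keep], area_px = area[ids][keep],
    peak_intensity = unname(peak[keep]),
    mean_intensity = (wsum / area[ids])[keep],
    pixels = lapply(grp[keep], function(g) cbind(y = py[g], x = px[g]))
  )
  out <- dplyr::arrange(out, .data$y, .data$x)
  class(out) <- c("soma_detections", class(out))
  out
}

#' Count detected somata
#'
#' @param detections A `soma_detections` tibble (count = rows) or a list of
#'   per-section tibbles (one count per element).
#' @return Integer count, or integer vector for a list.
#' @export
count_somata <- function(detections) {
  if (is.data.frame(detections)) return(nrow(detections))
  vapply(detections, nrow, integer(1))
}
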