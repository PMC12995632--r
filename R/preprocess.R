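# Pre-segmentation chain: rigid stack alignment, median/Gaussian denoising,
# rolling-ball background subtraction, anti-aliased downsampling.
# Working images are numeric matrices in [0, 255]; quantization back to 8-bit
# happens only at export.

#' Median + Gaussian denoising
#'
#' Applies a median filter (window `median_size`) followed by a Gaussian blur
#' (`gaussian_sigma`), the standard shot-noise / read-noise cleanup for
#' fluorescence sections. `median_size = 1` and `gaussian_sigma = 0` are both
#' identity.
#'
#' @param image Numeric matrix.
#' @param median_size Odd window size (>= 1) of the median filter.
#' @param gaussian_sigma Standard deviation (px) of the Gaussian blur (>= 0).
#' @return Denoised numeric matrix.
#' @export
denoise <- function(image, median_size = 3, gaussian_sigma = 1) {
  stopifnot(is.matrix(image))
  if (median_size < 1 || median_size %% 2 == 0) {
    stop("invalid-parameter: median_size must be an odd integer >= 1", call. = FALSE)
  }
  if (gaussian_sigma < 0) {
    stop("invalid-parameter: gaussian_sigma must be >= 0", call. = FALSE)
  }
  out <- image
  if (median_size > 1) {
    rng <- range(out)
    if (diff(rng) > 0) {
      scaled <- (out - rng[1]) / diff(rng)
      filt <- EBImage::medianFilter(scaled, size = (median_size - 1) / 2)
      out <- as.matrix(filt) * diff(rng) + rng[1]
    }
  }
  if (gaussian_sigma > 0) out <- gauss_blur(out, gaussian_sigma)
  out
}

ball_element <- function(radius) {
  r <- ceiling(radius)
  off <- -r:r
  d2 <- outer(off^2, off^2, `+`)
  keep <- d2 <= radius^2
  list(
    off_r = as.integer(row(d2)[keep] - r - 1L),
    off_c = as.integer(col(d2)[keep] - r - 1L),
    height = sqrt(pmax(0, radius^2 - d2[keep]))
  )
}

#' Rolling-ball background subtraction
#'
#' Estimates the background as the upper envelope of a ball of the given
#' radius rolled under the intensity surface — equivalently, the grayscale
#' morphological opening of the image with a spherical-cap structuring
#' function — and subtracts it (clipped at 0).
#'
#' @param image Numeric matrix.
#' @param radius Ball radius in pixels (default 50).
#' @return List with `corrected`, `background`, and `radius` (parameter echo).
#' @export
rolling_ball <- function(image, radius = 50) {
  stopifnot(is.matrix(image))
  if (radius <= 0) stop("invalid-parameter: radius must be > 0", call. = FALSE)
  if (radius > nrow(image) && radius > ncol(image)) {
    warning("rolling-ball radius exceeds both image dimensions; background set to the global minimum")
    bg <- matrix(min(image), nrow(image), ncol(image))
  } else {
    se <- ball_element(radius)
    er <- gray_erode_cpp(image, se$off_r, se$off_c, se$height)
    bg <- gray_dilate_cpp(er, se$off_r, se$off_c, se$height)
  }
  corrected <- image - bg
  corrected[corrected < 0] <- 0
  list(corrected = corrected, background = bg, radius = radius)
}

downsample_image <- function(image, factor) {
  if (abs(factor - 1) < 1e-12) return(image)
  stopifnot(factor > 1)
  h <- nrow(image); w <- ncol(image)
  oh <- floor(h / factor); ow <- floor(w / factor)
  # anti-alias blur matched to the decimation factor
  smoothed <- gauss_blur(image, 0.5 * sqrt(factor^2 - 1))
  # output pixel centers mapped into input coordinates (0-based, area-consistent)
  sy <- (seq_len(oh) - 0.5) * factor - 0.5
  sx <- (seq_len(ow) - 0.5) * factor - 0.5
  y0 <- pmin(pmax(floor(sy), 0), h - 2); fy <- sy - y0
  x0 <- pmin(pmax(floor(sx), 0), w - 2); fx <- sx - x0
  fy <- pmin(pmax(fy, 0), 1); fx <- pmin(pmax(fx, 0), 1)
  a <- smoothed[cbind(rep(y0 + 1, ow), rep(x0 + 1, each = oh))]
  b <- smoothed[cbind(rep(y0 + 2, ow), rep(x0 + 1, each = oh))]
  cc <- smoothed[cbind(rep(y0 + 1, ow), rep(x0 + 2, each = oh))]
  d <- smoothed[cbind(rep(y0 + 2, ow), rep(x0 + 2, each = oh))]
  wy <- rep(fy, ow); wx <- rep(fx, each = oh)
  matrix(a * (1 - wy) * (1 - wx) + b * wy * (1 - wx) +
           cc * (1 - wy) * wx + d * wy * wx, oh, ow)
}

#' Downsample a section stack to a target pixel size
#'
#' Anti-aliased rescale of every channel of every section; refuses to
#' upsample. Pixel-size metadata is updated so downstream coordinates are in
#' the downsampled frame.
#'
#' @param stack A `section_stack`.
#' @param target_um_per_px Target pixel size (default 1.82 um/px).
#' @return The downsampled `section_stack`.
#' @export
downsample <- function(stack, target_um_per_px = 1.82) {
  stopifnot(inherits(stack, "section_stack"))
  cur <- stack$pixel_size_um
  if (target_um_per_px < cur - 1e-12) {
    stop("invalid-parameter: refusing to upsample (target pixel size below current)",
         call. = FALSE)
  }
  factor <- target_um_per_px / cur
  if (abs(factor - 1) < 1e-12) return(stack)
  out <- stack
  out$sections <- lapply(stack$sections, function(sec) {
    sec$channels <- lapply(sec$channels, downsample_image, factor = factor)
    sec
  })
  out$pixel_size_um <- target_um_per_px
  out
}

# ---- rigid stack alignment --------------------------------------------------

# block-mean decimation by 2 with a light pre-blur (pyramid level step)
pyr_down <- function(img) {
  img <- gauss_blur(img, 1)
  h <- 2 * (nrow(img) %/% 2); w <- 2 * (ncol(img) %/% 2)
  img <- img[seq_len(h), seq_len(w), drop = FALSE]
  0.25 * (img[seq(1, h, 2), seq(1, w, 2)] + img[seq(2, h, 2), seq(1, w, 2)] +
            img[seq(1, h, 2), seq(2, w, 2)] + img[seq(2, h, 2), seq(2, w, 2)])
}

# mean-squared-difference objective factory with cached output grid
make_mse_obj <- function(moving, fixed) {
  h <- nrow(fixed); w <- ncol(fixed)
  yy <- rep(0:(h - 1), times = w)
  xx <- rep(0:(w - 1), each = h)
  cy <- (h - 1) / 2; cx <- (w - 1) / 2
  fvec <- as.vector(fixed)
  npix <- h * w
  function(par) {
    # backward map through the inverse of (theta, dx, dy)
    a <- -par[1] * pi / 180
    dxi <- -(cos(a) * par[2] - sin(a) * par[3])
    dyi <- -(sin(a) * par[2] + cos(a) * par[3])
    sx <- cos(a) * (xx - cx) - sin(a) * (yy - cy) + cx + dxi
    sy <- sin(a) * (xx - cx) + cos(a) * (yy - cy) + cy + dyi
    y0 <- floor(sy); x0 <- floor(sx)
    ok <- y0 >= 0 & y0 <= h - 2 & x0 >= 0 & x0 <= w - 2
    n_ok <- sum(ok)
    if (n_ok < 0.25 * npix) return(1e12)
    y0 <- y0[ok]; x0 <- x0[ok]
    fy <- sy[ok] - y0; fx <- sx[ok] - x0
    base <- y0 + 1 + x0 * h
    v <- moving[base] * (1 - fy) * (1 - fx) +
      moving[base + 1] * fy * (1 - fx) +
      moving[base + h] * (1 - fy) * fx +
      moving[base + h + 1] * fy * fx
    mean((v - fvec[ok])^2)
  }
}

# estimate the rigid transform mapping `moving` onto `fixed` by multi-level
# grid search + Nelder-Mead refinement of the mean-squared difference
register_pair <- function(moving, fixed, max_shift = 24, max_rot = 12,
                          n_levels = NULL, final_level = 1) {
  stopifnot(all(dim(moving) == dim(fixed)))
  if (is.null(n_levels)) {
    n_levels <- 1
    d <- min(dim(fixed))
    while (d / 2 >= 24 && n_levels < 3) {
      d <- d / 2
      n_levels <- n_levels + 1
    }
  }
  final_level <- min(final_level, n_levels)
  pyr_m <- list(moving); pyr_f <- list(fixed)
  if (n_levels > 1) {
    for (l in 2:n_levels) {
      pyr_m[[l]] <- pyr_down(pyr_m[[l - 1]])
      pyr_f[[l]] <- pyr_down(pyr_f[[l - 1]])
    }
  }
  sc <- 2^(n_levels - 1)
  obj <- make_mse_obj(pyr_m[[n_levels]], pyr_f[[n_levels]])
  shift_c <- max_shift / sc
  grid <- expand.grid(
    theta = seq(-max_rot, max_rot, length.out = 2 * ceiling(max_rot / 2.5) + 1),
    dx = seq(-shift_c, shift_c, length.out = 2 * ceiling(shift_c / 2) + 1),
    dy = seq(-shift_c, shift_c, length.out = 2 * ceiling(shift_c / 2) + 1)
  )
  vals <- apply(grid, 1, function(g) obj(as.numeric(g)))
  par <- as.numeric(grid[which.min(vals), ])
  par <- optim(par, obj, method = "Nelder-Mead",
               control = list(maxit = 150, reltol = 1e-9))$par
  if (n_levels > final_level) {
    for (l in (n_levels - 1):final_level) {
      par[2:3] <- par[2:3] * 2
      obj <- make_mse_obj(pyr_m[[l]], pyr_f[[l]])
      par <- optim(par, obj, method = "Nelder-Mead",
                   control = list(maxit = 200, reltol = 1e-10))$par
    }
  }
  par[2:3] <- par[2:3] * 2^(final_level - 1)
  rigid_transform(par[1], par[2], par[3])
}

# symmetric refinement: both images are warped by half-transforms so that
# resampling smooths the noise of both sides equally (one-sided warping
# biases a least-squares objective toward half-pixel offsets, where
# interpolation reduces the warped side's noise variance)
sym_refine <- function(moving, fixed, init_par, maxit = 200, stride = 1) {
  h <- nrow(moving); w <- ncol(moving)
  ys <- seq(0, h - 1, by = stride)
  xs <- seq(0, w - 1, by = stride)
  yy <- rep(ys, times = length(xs))
  xx <- rep(xs, each = length(ys))
  cy <- (h - 1) / 2; cx <- (w - 1) / 2
  samp <- function(img, theta, dx, dy) {
    a <- -theta * pi / 180
    dxi <- -(cos(a) * dx - sin(a) * dy)
    dyi <- -(sin(a) * dx + cos(a) * dy)
    sx <- cos(a) * (xx - cx) - sin(a) * (yy - cy) + cx + dxi
    sy <- sin(a) * (xx - cx) + cos(a) * (yy - cy) + cy + dyi
    y0 <- floor(sy); x0 <- floor(sx)
    ok <- y0 >= 0 & y0 <= h - 2 & x0 >= 0 & x0 <= w - 2
    v <- rep(NA_real_, length(yy))
    i <- which(ok)
    y0 <- y0[i]; x0 <- x0[i]
    fy <- sy[i] - y0; fx <- sx[i] - x0
    base <- y0 + 1 + x0 * h # column-major linear index of (y0+1, x0+1)
    v[i] <- img[base] * (1 - fy) * (1 - fx) +
      img[base + 1] * fy * (1 - fx) +
      img[base + h] * (1 - fy) * fx +
      img[base + h + 1] * fy * fx
    v
  }
  obj <- function(par) {
    vm <- samp(moving, par[1] / 2, par[2] / 2, par[3] / 2)
    vf <- samp(fixed, -par[1] / 2, -par[2] / 2, -par[3] / 2)
    d <- vm - vf
    ok <- !is.na(d)
    if (sum(ok) < 0.25 * length(d)) return(1e12)
    mean(d[ok]^2)
  }
  par <- optim(init_par, obj, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-10))$par
  A <- rigid_transform(par[1] / 2, par[2] / 2, par[3] / 2)
  B <- rigid_transform(-par[1] / 2, -par[2] / 2, -par[3] / 2)
  compose_rigid(invert_rigid(B), A)
}

#' Rigidly align a section stack
#'
#' Estimates, for every section, the rigid transform carrying it into the
#' frame of the reference section, in two stages. (1) Neighbouring sections
#' (i with i-1 / i+1) are registered pairwise by minimizing the mean-squared
#' intensity difference over a coarse-to-fine pyramid with Nelder-Mead
#' refinement, and the pairwise transforms are composed outward from the
#' reference — the way serial sections are aligned in practice, which bounds
#' the per-step motion. (2) Each section is re-registered against the
#' pixelwise mean of the aligned stack using symmetric (half-transform)
#' resampling, which removes both chain error accumulation and the
#' interpolation-noise bias of one-sided warping. Aligned images are
#' resampled bilinearly; out-of-frame pixels are 0.
#'
#' @param stack A `section_stack`.
#' @param ref_index Reference section (its transform is identity).
#' @param channel Channel used for registration; defaults to the counterstain
#'   (`"blue"`) when present, else the first channel.
#' @param max_shift_px,max_rot_deg Search bounds for the coarse grid stage.
#' @param refine Run the symmetric refinement stage (default TRUE)?
#' @param bandpass Difference-of-Gaussians sds `c(low, high)` applied to the
#'   registration channel before matching (`NULL` to disable). Suppresses
#'   both uncorrelated pixel noise and slowly varying background, which
#'   otherwise bias a least-squares registration.
#' @param refine_stride Pixel stride of the refinement objective (default 2;
#'   1 evaluates every pixel at roughly 4x the cost for a marginal gain).
#' @return List with `stack` (aligned copy) and `transforms` (tibble of
#'   per-section `theta_deg`, `dx_px`, `dy_px` into the reference frame).
#' @export
rigid_align <- function(stack, ref_index = 1, channel = NULL,
                        max_shift_px = 24, max_rot_deg = 12, refine = TRUE,
                        bandpass = c(1.5, 8), refine_stride = 2) {
  stopifnot(inherits(stack, "section_stack"))
  n <- n_sections(stack)
  stopifnot(ref_index >= 1, ref_index <= n)
  if (is.null(channel)) {
    chs <- names(stack$sections[[1]]$channels)
    channel <- if ("blue" %in% chs) "blue" else chs[1]
  }
  raw <- lapply(stack$sections, function(s) s$channels[[channel]])
  blank <- vapply(raw, function(m) sd(m) == 0, logical(1))
  imgs <- if (is.null(bandpass)) {
    raw
  } else {
    lapply(raw, function(m) gauss_blur(m, bandpass[1]) - gauss_blur(m, bandpass[2]))
  }
  if (any(blank)) {
    warning(sprintf("blank section(s) %s: identity transform assigned",
                    paste(which(blank), collapse = ", ")))
  }
  transforms <- vector("list", n)
  transforms[[ref_index]] <- rigid_transform(0, 0, 0)
  chain <- function(indices) {
    for (i in indices) {
      prev <- i - sign(i - ref_index)
      if (blank[i] || blank[prev]) {
        pair <- rigid_transform(0, 0, 0)
      } else {
        # with the groupwise stage on, the chain only needs a good init and
        # can stop at half resolution
        pair <- register_pair(imgs[[i]], imgs[[prev]],
                              max_shift = max_shift_px, max_rot = max_rot_deg,
                              final_level = if (refine) 3 else 1)
      }
      transforms[[i]] <<- compose_rigid(transforms[[prev]], pair)
    }
  }
  if (ref_index < n) chain((ref_index + 1):n)
  if (ref_index > 1) chain((ref_index - 1):1)
  if (refine && n > 1 && !blank[ref_index]) {
    # refinement stage: each section is re-registered directly against the
    # reference section with symmetric resampling, starting from the chained
    # estimate. This keeps per-section errors independent (no accumulation
    # along the chain, no consensus-frame drift) while the chain supplies a
    # capture-range-safe initialization.
    for (i in seq_len(n)) {
      if (i == ref_index || blank[i]) next
      t0 <- transforms[[i]]
      transforms[[i]] <- sym_refine(imgs[[i]], imgs[[ref_index]],
                                    c(t0$theta_deg, t0$dx_px, t0$dy_px),
                                    maxit = 250, stride = refine_stride)
    }
  }
  out <- stack
  for (i in seq_len(n)) {
    if (i == ref_index) next
    out$sections[[i]]$channels <- lapply(
      stack$sections[[i]]$channels, warp_rigid, transform = transforms[[i]]
    )
  }
  tf <- tibble::tibble(
    section_id = stack$metadata$section_id,
    theta_deg = vapply(transforms, `[[`, numeric(1), "theta_deg"),
    dx_px = vapply(transforms, `[[`, numeric(1), "dx_px"),
    dy_px = vapply(transforms, `[[`, numeric(1), "dy_px")
  )
  list(stack = out, transforms = tf)
}
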