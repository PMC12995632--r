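# Synthetic two-channel section stacks with known ground truth.
#
# The generator emulates what the downstream analysis assumes: per-region
# Poisson soma counts with a genotype-dependent rate reduction, somata as
# isotropic Gaussian blobs, axons as smoothed random polylines with a Gaussian
# tube cross-section, a dense nuclear counterstain channel, smooth background
# plus shot/read noise, 8-bit quantization, and (optionally) per-section rigid
# misalignment whose true inverse is recorded for recovery tests.

#' Construct a genotype effect specification
#'
#' Describes the generative soma model: the expected number of somata per
#' region per section (`lambda`), the multiplicative rate reduction applied to
#' the mutant group (`rho`, 1 = no effect), and the blob/axon appearance
#' parameters.
#'
#' @param lambda Expected somata per region per section (scalar or one value
#'   per region label). Default 25, a realistic density for a strongly
#'   labelled subcortical nucleus in a downsampled section.
#' @param rho Mutant-group rate multiplier in `[0, 1]` (scalar or per region).
#'   0.5 models an approximate halving of the labelled population.
#' @param mutant_level Genotype string that receives the `rho` reduction.
#' @param soma_sd,soma_peak Gaussian soma blob scale (px) and peak intensity
#'   (8-bit units).
#' @param min_sep_px Hard-core minimum distance between soma centers (px).
#'   Counts stay Poisson: positions, never counts, are resampled.
#' @param n_axons,axon_sd,axon_peak Number of axon polylines per section,
#'   Gaussian tube cross-section sd (px) and peak intensity.
#' @return An object of class `genotype_effect`.
#' @export
genotype_effect <- function(lambda = 25, rho = 0.5, mutant_level = "ko",
                            soma_sd = 3, soma_peak = 180, min_sep_px = 8,
                            n_axons = 3, axon_sd = 1.5, axon_peak = 120) {
  if (any(lambda < 0)) stop("invalid-spec: lambda must be >= 0", call. = FALSE)
  if (any(rho < 0 | rho > 1)) stop("invalid-spec: rho must lie in [0, 1]", call. = FALSE)
  if (soma_sd <= 0 || axon_sd <= 0) stop("invalid-spec: blob sd must be > 0", call. = FALSE)
  if (soma_peak < 0 || soma_peak > 255 || axon_peak < 0 || axon_peak > 255) {
    stop("invalid-spec: peak intensity must lie in [0, 255]", call. = FALSE)
  }
  structure(list(lambda = lambda, rho = rho, mutant_level = mutant_level,
                 soma_sd = soma_sd, soma_peak = soma_peak,
                 min_sep_px = min_sep_px, n_axons = n_axons,
                 axon_sd = axon_sd, axon_peak = axon_peak),
            class = "genotype_effect")
}

#' Construct a noise specification
#'
#' @param background Constant background level (8-bit units).
#' @param bg_amp,bg_sigma Amplitude and smoothing scale (px) of the smooth
#'   background field added on top of the constant level.
#' @param shot_noise Apply Poisson shot noise (pixel value used as the mean)?
#' @param read_sd Gaussian read-noise standard deviation (8-bit units).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(background = 20, bg_amp = 6, bg_sigma = 25,
                       shot_noise = TRUE, read_sd = 4) {
  stopifnot(background >= 0, bg_amp >= 0, bg_sigma > 0, read_sd >= 0)
  structure(list(background = background, bg_amp = bg_amp, bg_sigma = bg_sigma,
                 shot_noise = isTRUE(shot_noise), read_sd = read_sd),
            class = "noise_spec")
}

#' Generate a toy region label volume
#'
#' Builds an integer-labelled 3D volume (z, y, x) that stands in for a
#' reference atlas: label 0 is background (a one-voxel in-plane border),
#' labels `1..n_regions` tile the interior either as a grid of boxes or as
#' planar Voronoi cells. Regions span the full z extent so that every section
#' samples every region, as serial sectioning through columnar territories
#' would.
#'
#' @param shape Integer vector `c(z, y, x)` of voxel dimensions.
#' @param n_regions Number of regions (>= 1).
#' @param geometry `"boxes"` or `"voronoi"`.
#' @param seed Integer seed (used by the Voronoi geometry).
#' @param spacing_um Voxel spacing `c(z, y, x)` in micrometers; defaults to
#'   50 um sections at 1.82 um/px in plane.
#' @return An object of class `label_volume`: list with `labels` (3D integer
#'   array), `region_table` (tibble of `label`, `name`), and `spacing_um`.
#' @export
generate_toy_atlas <- function(shape, n_regions, geometry = c("boxes", "voronoi"),
                               seed = 1, spacing_um = c(z = 50, y = 1.82, x = 1.82)) {
  geometry <- match.arg(geometry)
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 1)) {
    stop("invalid-spec: shape must be three positive integers (z, y, x)", call. = FALSE)
  }
  if (n_regions < 1) stop("invalid-spec: n_regions must be >= 1", call. = FALSE)
  ny <- shape[2]; nx <- shape[3]
  iy <- if (ny > 2) 2:(ny - 1) else seq_len(ny)
  ix <- if (nx > 2) 2:(nx - 1) else seq_len(nx)
  n_interior <- length(iy) * length(ix) * shape[1]
  if (n_regions > n_interior) {
    stop("invalid-spec: n_regions exceeds the interior voxel count", call. = FALSE)
  }
  plane <- matrix(0L, ny, nx)
  if (geometry == "boxes") {
    # balanced ky x kx grid with ky * kx == n_regions
    divs <- which(n_regions %% seq_len(n_regions) == 0)
    ky <- max(divs[divs <= floor(sqrt(n_regions))])
    kx <- n_regions %/% ky
    if (ky > length(iy) || kx > length(ix)) {
      ky <- 1L; kx <- n_regions
    }
    if (kx > length(ix) * length(iy)) {
      stop("invalid-spec: n_regions does not fit the in-plane interior", call. = FALSE)
    }
    ycut <- floor(seq(0, length(iy), length.out = ky + 1))
    xcut <- floor(seq(0, length(ix), length.out = kx + 1))
    lab <- 0L
    for (a in seq_len(ky)) {
      for (b in seq_len(kx)) {
        lab <- lab + 1L
        ys <- iy[(ycut[a] + 1):ycut[a + 1]]
        xs <- ix[(xcut[b] + 1):xcut[b + 1]]
        plane[ys, xs] <- lab
      }
    }
  } else {
    plane <- with_seed(seed, {
      sy <- sample(iy, n_regions, replace = length(iy) < n_regions)
      sx <- sample(ix, n_regions, replace = length(ix) < n_regions)
      # ensure distinct seed points
      tries <- 0
      while (anyDuplicated(cbind(sy, sx)) && tries < 1000) {
        d <- which(duplicated(cbind(sy, sx)))
        sy[d] <- sample(iy, length(d), replace = TRUE)
        sx[d] <- sample(ix, length(d), replace = TRUE)
        tries <- tries + 1
      }
      gy <- rep(iy, times = length(ix))
      gx <- rep(ix, each = length(iy))
      d2 <- outer(gy, sy, `-`)^2 + outer(gx, sx, `-`)^2
      lab <- max.col(-d2, ties.method = "first")
      p <- matrix(0L, ny, nx)
      p[cbind(gy, gx)] <- as.integer(lab)
      p
    })
  }
  labels <- array(0L, dim = shape)
  for (z in seq_len(shape[1])) labels[z, , ] <- plane
  region_table <- tibble::tibble(
    label = seq_len(n_regions),
    name = sprintf("region_%02d", seq_len(n_regions))
  )
  structure(list(labels = labels, region_table = region_table,
                 spacing_um = setNames(as.numeric(spacing_um), c("z", "y", "x"))),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %s voxels, %d regions, spacing (%.2f, %.2f, %.2f) um\n",
              paste(dim(x$labels), collapse = " x "), nrow(x$region_table),
              x$spacing_um[1], x$spacing_um[2], x$spacing_um[3]))
  invisible(x)
}

# stamp an additive Gaussian blob at (y, x) (0-based coords) into img
add_gaussian_blob <- function(img, y, x, sd, peak) {
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(4 * sd)
  ys <- max(0, floor(y) - r):min(h - 1, ceiling(y) + r)
  xs <- max(0, floor(x) - r):min(w - 1, ceiling(x) + r)
  if (!length(ys) || !length(xs)) return(img)
  dy2 <- (ys - y)^2
  dx2 <- (xs - x)^2
  patch <- peak * exp(-(outer(dy2, dx2, `+`)) / (2 * sd^2))
  img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] + patch
  img
}

# stamp a tube (max-combined Gaussian cross-section) along dense points
add_tube <- function(img, pts_y, pts_x, sd, peak) {
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(3 * sd)
  for (k in seq_along(pts_y)) {
    y <- pts_y[k]; x <- pts_x[k]
    ys <- max(0, floor(y) - r):min(h - 1, ceiling(y) + r)
    xs <- max(0, floor(x) - r):min(w - 1, ceiling(x) + r)
    if (!length(ys) || !length(xs)) next
    patch <- peak * exp(-(outer((ys - y)^2, (xs - x)^2, `+`)) / (2 * sd^2))
    sub <- img[ys + 1, xs + 1]
    img[ys + 1, xs + 1] <- pmax(sub, patch)
  }
  img
}

# smooth random polyline across the frame; returns dense (y, x) point matrix
random_axon_path <- function(h, w, step = 0.8) {
  k <- 6
  margin <- 3
  start_y <- runif(1, margin, h - 1 - margin)
  start_x <- runif(1, margin, w - 1 - margin)
  ang <- runif(1, 0, 2 * pi)
  seg <- max(h, w) / (k - 1)
  ys <- numeric(k); xs <- numeric(k)
  ys[1] <- start_y; xs[1] <- start_x
  for (i in 2:k) {
    ang <- ang + runif(1, -0.6, 0.6)
    ys[i] <- min(max(ys[i - 1] + seg * sin(ang), 1), h - 2)
    xs[i] <- min(max(xs[i - 1] + seg * cos(ang), 1), w - 2)
  }
  tt <- seq_len(k)
  td <- seq(1, k, by = step / seg)
  cbind(y = stats::spline(tt, ys, xout = td)$y,
        x = stats::spline(tt, xs, xout = td)$y)
}

# Smooth anatomical intensity pattern shared across sections: per-region base
# brightness (deterministic in the label) with blurred boundaries. This is the
# cross-section structural continuity real serial sections have, and what
# neighbour-based rigid alignment locks onto.
tissue_pattern <- function(slice, contrast = 40, blur_sigma = 1.5,
                           with_landmarks = TRUE) {
  h <- nrow(slice); w <- ncol(slice)
  base <- matrix(0, h, w)
  labs <- sort(unique(as.vector(slice)))
  for (l in labs) {
    if (l == 0) next
    base[slice == l] <- contrast * (0.35 + 0.65 * (((l * 37) %% 11) / 10))
  }
  if (!with_landmarks) return(gauss_blur(base, blur_sigma))
  # deterministic 2D "anatomical landmarks" (bright foci such as dense nuclear
  # clusters or fiber-tract cross-sections), identical across sections, so the
  # pattern constrains both translation axes and rotation even when the region
  # layout happens to be stripe-like
  lmk <- with_seed(derive_seed(9001, h * 131 + w), {
    m <- matrix(0, h, w)
    for (k in 1:12) {
      m <- add_gaussian_blob(m, runif(1, 0.15 * h, 0.85 * h),
                             runif(1, 0.15 * w, 0.85 * w),
                             runif(1, 3, 6), contrast * 3.75)
    }
    m
  })
  base <- base + lmk * (slice > 0)
  gauss_blur(base, blur_sigma)
}

# sample n soma centers on region pixels with a hard-core separation;
# positions (not the count) are resampled on conflicts
sample_soma_centers <- function(pix_y, pix_x, n, min_sep,
                                other_y = numeric(0), other_x = numeric(0)) {
  if (n == 0) return(cbind(y = numeric(0), x = numeric(0)))
  ys <- c(other_y, numeric(n)); xs <- c(other_x, numeric(n))
  placed <- length(other_y)
  for (i in seq_len(n)) {
    for (attempt in seq_len(200)) {
      j <- sample.int(length(pix_y), 1)
      cy <- pix_y[j] + runif(1, -0.5, 0.5)
      cx <- pix_x[j] + runif(1, -0.5, 0.5)
      if (placed == 0 ||
          min((ys[seq_len(placed)] - cy)^2 + (xs[seq_len(placed)] - cx)^2) >= min_sep^2) {
        break
      }
    }
    # keep the last draw even if separation could not be honoured: the count
    # is Poisson by construction and must not change
    placed <- placed + 1
    ys[placed] <- cy
    xs[placed] <- cx
  }
  cbind(y = tail(ys, n), x = tail(xs, n))
}

# smooth unit-variance random field; generated at quarter resolution and
# bilinearly upsampled (the field only carries structure at scale bg_sigma,
# so the coarse grid loses nothing and saves a large-kernel blur)
smooth_field <- function(h, w, sigma) {
  f <- 4
  hc <- max(8, ceiling(h / f)); wc <- max(8, ceiling(w / f))
  coarse <- gauss_blur(matrix(rnorm(hc * wc), hc, wc), sigma / f)
  s <- sd(coarse)
  if (s > 0) coarse <- coarse / s
  sy <- pmin(pmax((seq_len(h) - 0.5) / f + 0.5, 1), hc - 1e-9)
  sx <- pmin(pmax((seq_len(w) - 0.5) / f + 0.5, 1), wc - 1e-9)
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  y0 <- pmin(y0, hc - 1); x0 <- pmin(x0, wc - 1)
  a <- coarse[y0, x0]; b <- coarse[y0 + 1, x0]
  cc <- coarse[y0, x0 + 1]; d <- coarse[y0 + 1, x0 + 1]
  wy <- matrix(fy, h, w); wx <- matrix(fx, h, w, byrow = TRUE)
  a * (1 - wy) * (1 - wx) + b * wy * (1 - wx) + cc * (1 - wy) * wx + d * wy * wx
}

apply_channel_noise <- function(img, noise) {
  h <- nrow(img); w <- ncol(img)
  bg <- noise$background
  if (noise$bg_amp > 0) {
    bg <- bg + noise$bg_amp * smooth_field(h, w, noise$bg_sigma)
  }
  out <- img + bg
  out[out < 0] <- 0
  if (noise$shot_noise) {
    out <- matrix(rpois(h * w, lambda = as.vector(out)), h, w)
  }
  if (noise$read_sd > 0) out <- out + rnorm(h * w, sd = noise$read_sd)
  # 8-bit quantization
  out <- round(out)
  out[out < 0] <- 0
  out[out > 255] <- 255
  out
}

#' Generate a two-channel section stack with ground truth
#'
#' Renders one animal's serial sections from a label volume: the reporter
#' ("green") channel carries Gaussian-blob somata (Poisson counts per region,
#' rate `lambda * rho^[mutant]`) and tube-profile axons; the counterstain
#' ("blue") channel carries dense nuclear blobs. Both channels get smooth
#' background, optional shot noise, Gaussian read noise, and 8-bit
#' quantization. Sections are z-slabs of the atlas, so section-to-atlas
#' correspondence is exact by construction.
#'
#' @param atlas A `label_volume`.
#' @param effect A [genotype_effect()].
#' @param noise A [noise_spec()].
#' @param seed Integer seed; fixed `(arguments, seed)` give bitwise-identical
#'   output.
#' @param genotype Genotype string for the stack's animal; the `rho` reduction
#'   applies when it equals `effect$mutant_level`.
#' @param animal_id Animal identifier recorded in the metadata.
#' @param plane Section plane name (`"coronal"`, `"sagittal"`, `"horizontal"`).
#' @param z_indices Atlas z-slices to render (default: all).
#' @param rate_multiplier Extra multiplicative factor on `lambda` (used by
#'   [simulate_study()] for animal-level heterogeneity).
#' @return A list with `stack` (a `section_stack`) and `truth` (a
#'   `ground_truth`: soma centers, axon centerlines, true per-region counts,
#'   identity transforms, parameter echo).
#' @export
generate_section_stack <- function(atlas, effect = genotype_effect(),
                                   noise = noise_spec(), seed = 1,
                                   genotype = "het", animal_id = "a1",
                                   plane = "coronal", z_indices = NULL,
                                   rate_multiplier = 1) {
  stopifnot(inherits(atlas, "label_volume"), inherits(effect, "genotype_effect"),
            inherits(noise, "noise_spec"))
  dz <- dim(atlas$labels)[1]
  if (is.null(z_indices)) z_indices <- seq_len(dz)
  stopifnot(all(z_indices >= 1 & z_indices <= dz))
  labels <- atlas$region_table$label
  lam <- rep_len(effect$lambda, length(labels))
  rho <- rep_len(effect$rho, length(labels))
  is_mut <- identical(genotype, effect$mutant_level)
  rate <- lam * (if (is_mut) rho else 1) * rate_multiplier

  h <- dim(atlas$labels)[2]; w <- dim(atlas$labels)[3]
  sections <- vector("list", length(z_indices))
  soma_rows <- list()
  axon_list <- vector("list", length(z_indices))
  count_rows <- list()
  meta <- tibble::tibble(
    section_id = sprintf("%s_%s_s%02d", animal_id, substr(plane, 1, 3), z_indices),
    animal_id = animal_id, genotype = genotype, plane = plane,
    z_index = as.integer(z_indices)
  )

  for (si in seq_along(z_indices)) {
    z <- z_indices[si]
    sec_seed <- derive_seed(seed, si)
    slice <- atlas$labels[z, , ]
    pattern <- tissue_pattern(slice)
    # the reporter channel gets only the diffuse (landmark-free) component:
    # weak autofluorescence following the anatomy, with no blob-like foci
    pattern_diffuse <- tissue_pattern(slice, with_landmarks = FALSE)
    res <- with_seed(sec_seed, {
      green <- 0.35 * pattern_diffuse
      centers_sec <- list()
      counts_sec <- integer(length(labels))
      all_y <- numeric(0); all_x <- numeric(0)
      for (ri in seq_along(labels)) {
        pix <- which(slice == labels[ri], arr.ind = TRUE)
        if (!nrow(pix)) {
          counts_sec[ri] <- 0L
          next
        }
        n <- rpois(1, rate[ri])
        counts_sec[ri] <- n
        # separation is enforced section-wide (somata are physical bodies
        # regardless of the region boundary they sit near)
        ctr <- sample_soma_centers(pix[, 1] - 1, pix[, 2] - 1, n, effect$min_sep_px,
                                   other_y = all_y, other_x = all_x)
        if (nrow(ctr)) {
          all_y <- c(all_y, ctr[, 1]); all_x <- c(all_x, ctr[, 2])
        }
        if (nrow(ctr)) {
          for (k in seq_len(nrow(ctr))) {
            green <- add_gaussian_blob(green, ctr[k, 1], ctr[k, 2],
                                       effect$soma_sd, effect$soma_peak)
          }
          centers_sec[[ri]] <- tibble::tibble(
            label = labels[ri], y = ctr[, 1], x = ctr[, 2]
          )
        }
      }
      axons_sec <- list()
      if (effect$n_axons > 0) {
        for (k in seq_len(effect$n_axons)) {
          path <- random_axon_path(h, w)
          green <- add_tube(green, path[, 1], path[, 2], effect$axon_sd, effect$axon_peak)
          axons_sec[[k]] <- path
        }
      }
      blue <- pattern
      n_nuc <- rpois(1, 0.001 * h * w)
      if (n_nuc > 0) {
        ny <- runif(n_nuc, 0, h - 1); nx <- runif(n_nuc, 0, w - 1)
        for (k in seq_len(n_nuc)) blue <- add_gaussian_blob(blue, ny[k], nx[k], 2.5, 25)
      }
      list(green = apply_channel_noise(green, noise),
           blue = apply_channel_noise(blue, noise),
           centers = centers_sec, counts = counts_sec, axons = axons_sec)
    })
    sections[[si]] <- list(channels = list(green = res$green, blue = res$blue))
    centers <- dplyr::bind_rows(res$centers)
    if (nrow(centers)) {
      centers$section_id <- meta$section_id[si]
      centers$z_index <- as.integer(z)
      soma_rows[[si]] <- centers
    }
    axon_list[[si]] <- res$axons
    count_rows[[si]] <- tibble::tibble(
      region = labels, section_id = meta$section_id[si], count = res$counts
    )
  }

  stack <- structure(list(
    sections = sections, metadata = meta,
    pixel_size_um = unname(atlas$spacing_um["x"]),
    thickness_um = unname(atlas$spacing_um["z"])
  ), class = "section_stack")

  truth <- structure(list(
    somata = if (length(soma_rows)) dplyr::bind_rows(soma_rows) else
      tibble::tibble(label = integer(), y = numeric(), x = numeric(),
                     section_id = character(), z_index = integer()),
    axons = axon_list,
    counts = dplyr::bind_rows(count_rows),
    transforms = tibble::tibble(
      section_id = meta$section_id, theta_deg = 0, dx_px = 0, dy_px = 0
    ),
    params = list(effect = effect, noise = noise, genotype = genotype,
                  rate_multiplier = rate_multiplier),
    seed = seed
  ), class = "ground_truth")

  list(stack = stack, truth = truth)
}

#' @export
print.section_stack <- function(x, ...) {
  d <- dim(x$sections[[1]]$channels[[1]])
  cat(sprintf("<section_stack> %d sections, %d x %d px, channels: %s, %.2f um/px\n",
              length(x$sections), d[1], d[2],
              paste(names(x$sections[[1]]$channels), collapse = "/"),
              x$pixel_size_um))
  invisible(x)
}

n_sections <- function(stack) length(stack$sections)

stack_dim <- function(stack) dim(stack$sections[[1]]$channels[[1]])

#' Apply random rigid misalignment to a stack
#'
#' Perturbs every section except the reference by an independent rigid
#' transform drawn uniformly within the given bounds, and returns the true
#' transforms so alignment can be tested against them. Out-of-frame pixels are
#' filled with 0.
#'
#' @param stack A `section_stack`.
#' @param max_shift_px,max_rot_deg Uniform bounds on |dx|, |dy| (px) and the
#'   rotation angle (deg); both must be >= 0.
#' @param seed Integer seed.
#' @param ref_index Section left unperturbed (default 1).
#' @return List with `stack` (perturbed copy) and `transforms` (tibble of the
#'   applied true transforms, identity for the reference).
#' @export
apply_misalignment <- function(stack, max_shift_px, max_rot_deg, seed = 1,
                               ref_index = 1) {
  stopifnot(inherits(stack, "section_stack"),
            max_shift_px >= 0, max_rot_deg >= 0,
            ref_index >= 1, ref_index <= n_sections(stack))
  n <- n_sections(stack)
  tf <- with_seed(seed, tibble::tibble(
    section_id = stack$metadata$section_id,
    theta_deg = ifelse(seq_len(n) == ref_index, 0, runif(n, -max_rot_deg, max_rot_deg)),
    dx_px = ifelse(seq_len(n) == ref_index, 0, runif(n, -max_shift_px, max_shift_px)),
    dy_px = ifelse(seq_len(n) == ref_index, 0, runif(n, -max_shift_px, max_shift_px))
  ))
  out <- stack
  for (i in seq_len(n)) {
    if (i == ref_index) next
    tr <- rigid_transform(tf$theta_deg[i], tf$dx_px[i], tf$dy_px[i])
    out$sections[[i]]$channels <- lapply(
      stack$sections[[i]]$channels, warp_rigid, transform = tr
    )
  }
  list(stack = out, transforms = tf)
}

#' Simulate a complete two-genotype imaging study
#'
#' Generates one stack per animal (several serial sections each) for two
#' genotype groups, with animal-level rate heterogeneity (the between-animal
#' variance component the random-intercept model is there to absorb), plus
#' combined metadata and ground truth.
#'
#' @param atlas A `label_volume` whose z extent is at least `n_sections`.
#' @param effect A [genotype_effect()]; `effect$rho` may be a per-region
#'   vector to plant effects in a subset of regions.
#' @param noise A [noise_spec()].
#' @param n_animals Animals per genotype (default 3, a typical transgenic
#'   cohort size).
#' @param n_sections Serial sections per animal (default 8).
#' @param genotypes Character vector of the two genotype levels; the second
#'   must match `effect$mutant_level`.
#' @param plane Section plane recorded in the metadata.
#' @param animal_cv Coefficient of variation of the lognormal animal-level
#'   rate multiplier (default 0.05, matching an animal-level standard deviation of
#'   5 at a control mean of 100 - the variance structure the statistical design
#'   is calibrated to).
#' @param seed Integer seed.
#' @return List with `stacks` (named list of `section_stack`), `truths`
#'   (named list of `ground_truth`), `metadata` (combined tibble), and
#'   `true_counts` (combined region x section count tibble with metadata).
#' @export
simulate_study <- function(atlas, effect = genotype_effect(), noise = noise_spec(),
                           n_animals = 3, n_sections = 8,
                           genotypes = c("het", "ko"), plane = "coronal",
                           animal_cv = 0.05, seed = 1) {
  stopifnot(dim(atlas$labels)[1] >= n_sections, length(genotypes) == 2)
  sdlog <- sqrt(log(1 + animal_cv^2))
  stacks <- list(); truths <- list()
  idx <- 0
  for (g in genotypes) {
    for (a in seq_len(n_animals)) {
      idx <- idx + 1
      aid <- sprintf("%s%d", g, a)
      mult <- with_seed(derive_seed(seed, 1000 + idx),
                        exp(rnorm(1, -sdlog^2 / 2, sdlog)))
      res <- generate_section_stack(
        atlas, effect, noise, seed = derive_seed(seed, idx),
        genotype = g, animal_id = aid, plane = plane,
        z_indices = seq_len(n_sections), rate_multiplier = mult
      )
      stacks[[aid]] <- res$stack
      truths[[aid]] <- res$truth
    }
  }
  metadata <- dplyr::bind_rows(lapply(stacks, function(s) s$metadata))
  true_counts <- dplyr::bind_rows(lapply(truths, function(t) t$counts)) |>
    dplyr::left_join(metadata, by = "section_id")
  list(stacks = stacks, truths = truths, metadata = metadata,
       true_counts = true_counts)
}
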