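# Independent oracles and small fixture builders used across the suite.

# Brute-force grayscale erosion/dilation with an explicit (non-flat)
# structuring element, written directly from the definition with shifted
# matrices; independent of the package's compiled morphology kernel.
brute_erode <- function(img, se) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(Inf, h, w)
  for (k in seq_along(se$height)) {
    dr <- se$off_r[k]; dc <- se$off_c[k]
    rs <- max(1, 1 - dr):min(h, h - dr)
    cs <- max(1, 1 - dc):min(w, w - dc)
    cand <- matrix(Inf, h, w)
    cand[rs, cs] <- img[rs + dr, cs + dc] - se$height[k]
    out <- pmin(out, cand)
  }
  out
}

brute_dilate <- function(img, se) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(-Inf, h, w)
  for (k in seq_along(se$height)) {
    dr <- se$off_r[k]; dc <- se$off_c[k]
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    cand <- matrix(-Inf, h, w)
    cand[rs, cs] <- img[rs - dr, cs - dc] + se$height[k]
    out <- pmax(out, cand)
  }
  out
}

# ball structuring element as offset/height lists (mirrors the definition,
# not the package internals)
brute_ball <- function(radius) {
  r <- ceiling(radius)
  off <- -r:r
  d2 <- outer(off^2, off^2, `+`)
  keep <- d2 <= radius^2
  list(off_r = row(d2)[keep] - r - 1L,
       off_c = col(d2)[keep] - r - 1L,
       height = sqrt(pmax(0, radius^2 - d2[keep])))
}

brute_rolling_ball_background <- function(img, radius) {
  se <- brute_ball(radius)
  brute_dilate(brute_erode(img, se), se)
}

# one-to-one greedy matching of detections to true centers within `gate` px;
# returns counts for precision/recall (greedy on nearest distance is optimal
# here because phantom centers are well separated)
match_detections <- function(det, truth, gate = 2) {
  used <- rep(FALSE, nrow(det))
  tp <- 0L
  if (nrow(truth)) {
    ord <- seq_len(nrow(truth))
    for (k in ord) {
      if (!nrow(det)) break
      d2 <- (det$y - truth$y[k])^2 + (det$x - truth$x[k])^2
      d2[used] <- Inf
      j <- which.min(d2)
      if (is.finite(d2[j]) && d2[j] <= gate^2) {
        used[j] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  list(tp = tp, fp = sum(!used), fn = nrow(truth) - tp)
}

# straight horizontal Gaussian ridge through the image center
make_ridge <- function(n = 64, sd = 1.5, peak = 100, center = NULL) {
  if (is.null(center)) center <- (n - 1) / 2
  y <- 0:(n - 1)
  matrix(rep(peak * exp(-(y - center)^2 / (2 * sd^2)), n), n, n)
}

# Gaussian ridge at an arbitrary angle (degrees) through the center
make_ridge_angle <- function(n, angle_deg, sd = 1.5, peak = 100) {
  a <- angle_deg * pi / 180
  c0 <- (n - 1) / 2
  yy <- matrix(0:(n - 1), n, n)
  xx <- t(yy)
  d <- -(xx - c0) * sin(a) + (yy - c0) * cos(a)
  peak * exp(-d^2 / (2 * sd^2))
}

make_blob <- function(n = 64, sd = 1.5, peak = 100, y = NULL, x = NULL) {
  if (is.null(y)) y <- (n - 1) / 2
  if (is.null(x)) x <- (n - 1) / 2
  yy <- matrix(0:(n - 1), n, n)
  xx <- t(yy)
  peak * exp(-((yy - y)^2 + (xx - x)^2) / (2 * sd^2))
}

# stack whose sections all share one structured image (for transform tests)
make_constant_content_stack <- function(img, n = 4) {
  structure(list(
    sections = lapply(seq_len(n), function(i) list(channels = list(blue = img))),
    metadata = tibble::tibble(section_id = sprintf("s%02d", seq_len(n)),
                              animal_id = "a1", genotype = "het",
                              plane = "coronal", z_index = seq_len(n)),
    pixel_size_um = 1.82, thickness_um = 50
  ), class = "section_stack")
}

# balanced two-genotype nested design with Gaussian components (the
# stats-level generative model: animal random intercepts + residual noise)
sim_nested_gaussian <- function(mean_control = 100, diff = 0, sa2 = 25,
                                se2 = 100, n_animals = 3, n_sections = 8) {
  g <- rep(c("het", "ko"), each = n_animals * n_sections)
  a <- rep(sprintf("%s%d", rep(c("het", "ko"), each = n_animals), rep(seq_len(n_animals), 2)),
           each = n_sections)
  u <- rnorm(2 * n_animals, 0, sqrt(sa2))[as.integer(factor(a, levels = unique(a)))]
  mu <- ifelse(g == "ko", mean_control + diff, mean_control)
  data.frame(count = mu + u + rnorm(length(g), 0, sqrt(se2)),
             genotype = g, animal_id = a)
}

rigid_residual <- function(estimated, true) {
  compose_rigid(estimated, true)
}
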