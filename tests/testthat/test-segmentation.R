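test_that("tubularity vanishes on constants and prefers ridges over blobs", {
  expect_true(all(tubularity(matrix(3, 32, 32)) == 0))
  ridge <- make_ridge(64, sd = 1.5, peak = 100, center = 32)
  resp <- tubularity(ridge)
  on_ridge <- mean(resp[33, 11:54])
  off_ridge <- mean(resp[43, 11:54]) # 10 px from the centerline
  expect_gt(on_ridge, 5 * off_ridge)
  # ridge and blob of equal peak in one frame: centerline beats blob center
  comb <- matrix(0, 64, 128)
  comb[, 1:64] <- ridge
  comb[, 65:128] <- make_blob(64, sd = 1.5, peak = 100)
  respc <- tubularity(comb)
  expect_gt(respc[33, 32], 2 * respc[33, 97])
  expect_error(tubularity(matrix(1, 5, 5)), "invalid-parameter")
  expect_error(tubularity_params(beta = 0), "invalid-parameter")
})

test_that("the argmax scale tracks the tube width within one ladder step", {
  params <- tubularity_params(scales = c(1, 1.5, 2.25, 3.375, 5.0625))
  for (s_true in c(1.5, 3)) {
    ridge <- make_ridge(72, sd = s_true, peak = 100)
    resp <- tubularity(ridge, params)
    bs <- attr(resp, "best_scale")
    picked <- bs[37, 36]
    nearest <- params$scales[which.min(abs(params$scales - s_true))]
    ladder_pos <- function(v) which(params$scales == v)
    expect_lte(abs(ladder_pos(picked) - ladder_pos(nearest)), 1)
  }
})

test_that("tubularity is rotation-equivariant on ridges within 5%", {
  n <- 81
  base <- NULL
  for (ang in seq(0, 180, by = 15)) {
    img <- make_ridge_angle(n, ang, sd = 1.5, peak = 100)
    resp <- tubularity(img)
    # sample the centerline response at interior points along the ridge
    a <- ang * pi / 180
    c0 <- (n - 1) / 2
    t_par <- seq(-20, 20, by = 2)
    ys <- round(c0 + t_par * sin(a)); xs <- round(c0 + t_par * cos(a))
    v <- mean(resp[cbind(ys + 1, xs + 1)])
    if (is.null(base)) base <- v
    expect_lt(abs(v - base) / base, 0.05)
  }
})

test_that("axon segmentation keeps long components and applies exclusions", {
  expect_warning(ax0 <- segment_axons(matrix(0, 32, 32)), "empty")
  expect_equal(sum(ax0$mask), 0)
  # 5 planted long axons + 30 small speckles, min skeleton length 10
  set.seed(41)
  resp <- matrix(0, 128, 128)
  rows <- c(12, 35, 60, 85, 110)
  for (r in rows) resp[r, 20:109] <- 1 # >= 40 px long
  for (k in 1:30) {
    ry <- sample(5:124, 1); rx <- sample(5:124, 1)
    resp[ry:(ry + 1), rx:(rx + 1)] <- pmax(resp[ry:(ry + 1), rx:(rx + 1)], 0.95)
  }
  ax <- segment_axons(resp, threshold = 0.5, min_skeleton_len_px = 10)
  expect_equal(ax$n_retained, 5)
  # exclusion mask covering one planted axon removes it
  excl <- matrix(FALSE, 128, 128); excl[33:37, ] <- TRUE
  ax2 <- segment_axons(resp, threshold = 0.5, min_skeleton_len_px = 10,
                       exclusion_mask = excl)
  expect_false(any(ax2$mask[35, ]))
  # monotone masking: growing the exclusion never increases mask area
  a_small <- sum(ax2$mask)
  excl2 <- excl; excl2[58:62, ] <- TRUE
  ax3 <- segment_axons(resp, threshold = 0.5, min_skeleton_len_px = 10,
                       exclusion_mask = excl2)
  expect_lte(sum(ax3$mask), a_small)
})

test_that("skeletonization reduces a thick line to about its length", {
  m <- matrix(FALSE, 40, 80)
  m[18:22, 10:69] <- TRUE # 5 px thick, 60 px long
  sk <- skeletonize(m)
  expect_gt(sum(sk), 50)
  expect_lt(sum(sk), 70)
})

test_that("soma detection is faithful on well-separated phantoms", {
  atlas <- generate_toy_atlas(c(6, 128, 128), 1, "boxes")
  eff <- genotype_effect(lambda = 7, min_sep_px = 30, n_axons = 0)
  res <- generate_section_stack(atlas, eff, noise_spec(), seed = 17, z_indices = 1:2)
  for (i in 1:2) {
    det <- detect_somata(res$stack$sections[[i]]$channels$green,
                         background_radius = 15,
                         section_id = res$stack$metadata$section_id[i])
    tru <- res$truth$somata[res$truth$somata$section_id ==
                              res$stack$metadata$section_id[i], ]
    m <- match_detections(det, tru, gate = 2)
    expect_equal(m$fp, 0)
    expect_equal(m$fn, 0)
  }
})

test_that("blank images and degenerate parameters are rejected cleanly", {
  expect_equal(nrow(detect_somata(matrix(0, 40, 40))), 0)
  expect_error(detect_somata(matrix(0, 40, 40), d_min = 10, d_max = 5),
               "invalid-parameter")
})

test_that("two nearly coincident blobs merge into one larger detection", {
  img <- make_blob(64, sd = 3, peak = 100, y = 31.5, x = 31) +
    make_blob(64, sd = 3, peak = 100, y = 31.5, x = 32)
  two <- detect_somata(img, mask_threshold = 20, min_peak = 5)
  one <- detect_somata(make_blob(64, sd = 3, peak = 100), mask_threshold = 20,
                       min_peak = 5)
  expect_equal(nrow(two), 1)
  expect_equal(nrow(one), 1)
  expect_gt(two$area_px / one$area_px, 1.2)
})

test_that("a plugged-in detector is honoured and validated", {
  fake <- function(image, d_min, d_max) {
    tibble::tibble(y = c(5, 1), x = c(2, 3), diameter_px = 6, area_px = 28,
                   peak_intensity = 1, mean_intensity = 1)
  }
  det <- detect_somata(matrix(0, 20, 20), detector = fake, section_id = "s1")
  expect_equal(det$y, c(1, 5)) # sorted by (y, x)
  expect_true(all(det$section_id == "s1"))
  bad <- function(image, d_min, d_max) data.frame(a = 1)
  expect_error(detect_somata(matrix(0, 20, 20), detector = bad), "columns")
})

test_that("count_somata counts rows and per-section lists", {
  expect_equal(count_somata(tibble::tibble()), 0L)
  det <- detect_somata(make_blob(64, sd = 3, peak = 150), min_peak = 5)
  expect_equal(count_somata(det), 1L)
  expect_equal(count_somata(list(det, det[0, ])), c(1L, 0L))
})
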