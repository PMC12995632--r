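test_that("denoise handles identity, hot pixels, constants and bad parameters", {
  img <- matrix(0, 32, 32); img[16, 16] <- 255
  expect_identical(denoise(img, 1, 0), img)
  expect_lt(max(denoise(img, 3, 0)), 1)
  cst <- matrix(7, 20, 20)
  expect_lt(max(abs(denoise(cst, 5, 2) - 7)), 1e-9)
  expect_error(denoise(img, 4, 1), "invalid-parameter")
  expect_error(denoise(img, 3, -1), "invalid-parameter")
})

test_that("rolling ball echoes its default radius and zeroes constants", {
  expect_equal(rolling_ball(matrix(1, 60, 60))$radius, 50)
  rb <- rolling_ball(matrix(5, 40, 40), 10)
  expect_true(all(rb$corrected == 0))
  expect_true(all(abs(rb$background - 5) < 1e-9))
})

test_that("rolling ball preserves a blob peak and reconstructs off-clip pixels", {
  img <- make_blob(128, sd = 3, peak = 100)
  rb <- rolling_ball(img, 50)
  expect_lt(abs(max(rb$corrected) - 100) / 100, 0.05)
  # corrected + background reconstructs wherever no clipping occurred
  nc <- (img - rb$background) >= 0
  expect_lt(max(abs((rb$corrected + rb$background - img)[nc])), 1e-9)
})

test_that("fast rolling ball matches the brute-force opening oracle", {
  set.seed(4)
  for (radius in c(5, 12)) {
    img <- matrix(runif(64 * 64, 0, 255), 64, 64)
    fast <- rolling_ball(img, radius)$background
    brute <- brute_rolling_ball_background(img, radius)
    expect_lt(max(abs(fast - brute)), 1)
  }
})

test_that("oversized rolling-ball radius degrades to the global minimum", {
  img <- matrix(runif(100, 2, 9), 10, 10)
  expect_warning(rb <- rolling_ball(img, 50), "global minimum")
  expect_true(all(rb$background == min(img)))
})

test_that("downsampling halves dimensions, conserves flux, refuses upsampling", {
  atlas <- generate_toy_atlas(c(2, 40, 40), 1, "boxes",
                              spacing_um = c(50, 0.91, 0.91))
  stack <- generate_section_stack(atlas, genotype_effect(lambda = 4), seed = 2)$stack
  stack$pixel_size_um <- 0.91
  expect_identical(downsample(stack, 0.91), stack)
  ds <- downsample(stack, 1.82)
  expect_equal(dim(ds$sections[[1]]$channels$green), c(20, 20))
  expect_equal(ds$pixel_size_um, 1.82)
  expect_error(downsample(ds, 0.91), "invalid-parameter")
  # total intensity (sum x pixel area) conserved within 2% on a smooth image
  smooth <- make_blob(64, sd = 8, peak = 120)
  ds_img <- regionquant:::downsample_image(smooth, 2)
  flux_in <- sum(smooth)
  flux_out <- sum(ds_img) * 4
  expect_lt(abs(flux_out - flux_in) / flux_in, 0.02)
})

test_that("aligning an already-aligned stack is near-identity and idempotent", {
  atlas <- generate_toy_atlas(c(1, 96, 96), 5, "boxes")
  img <- generate_section_stack(atlas, seed = 6)$stack$sections[[1]]$channels$blue
  stack <- make_constant_content_stack(img, n = 4)
  al <- rigid_align(stack, ref_index = 2)
  expect_true(all(abs(al$transforms$theta_deg) < 0.05))
  expect_true(all(abs(al$transforms$dx_px) < 0.1))
  expect_true(all(abs(al$transforms$dy_px) < 0.1))
  # pixels move by at most interpolation tolerance
  for (i in 1:4) {
    expect_lt(max(abs(al$stack$sections[[i]]$channels$blue -
                        stack$sections[[i]]$channels$blue)), 2)
  }
})

test_that("alignment recovers known perturbations on a synthetic stack", {
  atlas <- generate_toy_atlas(c(6, 96, 96), 5, "boxes")
  stack <- generate_section_stack(atlas, seed = 8, z_indices = 1:6)$stack
  mis <- apply_misalignment(stack, 10, 5, seed = 9, ref_index = 3)
  al <- rigid_align(mis$stack, ref_index = 3)
  errs <- t(vapply(1:6, function(i) {
    tt <- rigid_transform(mis$transforms$theta_deg[i], mis$transforms$dx_px[i],
                          mis$transforms$dy_px[i])
    te <- rigid_transform(al$transforms$theta_deg[i], al$transforms$dx_px[i],
                          al$transforms$dy_px[i])
    r <- rigid_residual(te, tt)
    c(abs(r$theta_deg), abs(r$dx_px), abs(r$dy_px))
  }, numeric(3)))
  expect_lt(mean(errs[, 1]), 0.2)
  expect_lt(mean(errs[, 2:3]), 0.5)
})

test_that("single-section and blank-section stacks are handled gracefully", {
  atlas <- generate_toy_atlas(c(2, 48, 48), 2, "boxes")
  one <- generate_section_stack(atlas, seed = 2, z_indices = 1)$stack
  al1 <- rigid_align(one)
  expect_identical(al1$stack$sections, one$sections)
  expect_true(all(al1$transforms[, c("theta_deg", "dx_px", "dy_px")] == 0))
  two <- generate_section_stack(atlas, seed = 2, z_indices = 1:2)$stack
  two$sections[[2]]$channels$blue <- matrix(0, 48, 48)
  two$sections[[2]]$channels$green <- matrix(0, 48, 48)
  expect_warning(al2 <- rigid_align(two), "blank")
  expect_equal(unlist(al2$transforms[2, c("theta_deg", "dx_px", "dy_px")]),
               c(theta_deg = 0, dx_px = 0, dy_px = 0))
})
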