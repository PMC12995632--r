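test_that("toy atlas covers the trivial and multi-region cases", {
  # single region: all non-border voxels labelled 1, border 0
  a <- generate_toy_atlas(c(1, 10, 10), 1, "boxes")
  sl <- a$labels[1, , ]
  expect_true(all(sl[2:9, 2:9] == 1))
  expect_true(all(sl[c(1, 10), ] == 0) && all(sl[, c(1, 10)] == 0))
  # determinism
  expect_identical(generate_toy_atlas(c(4, 20, 20), 3, "voronoi", seed = 7),
                   generate_toy_atlas(c(4, 20, 20), 3, "voronoi", seed = 7))
  # Voronoi label histogram: exactly labels 0..4
  v <- generate_toy_atlas(c(2, 30, 30), 4, "voronoi", seed = 7)
  expect_identical(sort(unique(as.vector(v$labels))), 0:4)
  # every region occupies at least one voxel
  expect_true(all(tabulate(v$labels[v$labels > 0], nbins = 4) >= 1))
  # invalid spec
  expect_error(generate_toy_atlas(c(1, 4, 4), 100, "boxes"), "invalid-spec")
})

test_that("section stacks honour the Poisson soma model and determinism", {
  atlas <- generate_toy_atlas(c(1, 30, 30), 1, "boxes")
  # lambda = 0: no somata anywhere, counts all zero
  res0 <- generate_section_stack(atlas, genotype_effect(lambda = 0, n_axons = 0),
                                 noise_spec(), seed = 1)
  expect_equal(nrow(res0$truth$somata), 0)
  expect_true(all(res0$truth$counts$count == 0))
  # bitwise determinism of images and truth
  r1 <- generate_section_stack(atlas, seed = 11)
  r2 <- generate_section_stack(atlas, seed = 11)
  expect_identical(r1$stack$sections, r2$stack$sections)
  expect_identical(r1$truth$somata, r2$truth$somata)
  # invalid appearance specs
  expect_error(genotype_effect(soma_sd = 0), "invalid-spec")
  expect_error(genotype_effect(soma_peak = 300), "invalid-spec")
  expect_error(genotype_effect(rho = 1.2), "invalid-spec")
})

test_that("mutant-group counts follow lambda * rho (Poisson mean recovery)", {
  atlas <- generate_toy_atlas(c(200, 26, 26), 1, "boxes")
  eff <- genotype_effect(lambda = 100, rho = 0.5, n_axons = 0, min_sep_px = 0.5,
                         soma_peak = 50)
  res <- generate_section_stack(atlas, eff, noise_spec(bg_amp = 0, shot_noise = FALSE),
                                seed = 21, genotype = "ko")
  m <- mean(res$truth$counts$count)
  se <- sqrt(50 / 200)
  expect_gt(m, 50 - 3 * se)
  expect_lt(m, 50 + 3 * se)
  expect_gt(m, 45) # the coarser documented band
  expect_lt(m, 55)
})

test_that("ground truth counts equal the recorded soma centers", {
  atlas <- generate_toy_atlas(c(3, 40, 40), 4, "boxes")
  res <- generate_section_stack(atlas, genotype_effect(lambda = 6), noise_spec(), seed = 5)
  tallied <- dplyr::count(res$truth$somata, section_id, region = label, name = "n")
  joined <- dplyr::left_join(res$truth$counts, tallied,
                             by = c("section_id", "region"))
  joined$n[is.na(joined$n)] <- 0L
  expect_equal(joined$count, joined$n)
  # every center is inside the image bounds
  expect_true(all(res$truth$somata$y >= 0 & res$truth$somata$y <= 39))
  expect_true(all(res$truth$somata$x >= 0 & res$truth$somata$x <= 39))
})

test_that("misalignment respects its bounds and leaves the reference untouched", {
  atlas <- generate_toy_atlas(c(4, 32, 32), 2, "boxes")
  stack <- generate_section_stack(atlas, seed = 3)$stack
  # zero bounds: output identical, all transforms identity
  m0 <- apply_misalignment(stack, 0, 0, seed = 1)
  expect_identical(m0$stack$sections, stack$sections)
  expect_true(all(m0$transforms$theta_deg == 0 & m0$transforms$dx_px == 0 &
                    m0$transforms$dy_px == 0))
  # single-section stack unchanged
  one <- generate_section_stack(atlas, seed = 3, z_indices = 1)$stack
  m1 <- apply_misalignment(one, 10, 5, seed = 2)
  expect_identical(m1$stack$sections, one$sections)
  # bounds respected
  m2 <- apply_misalignment(stack, 10, 5, seed = 3)
  expect_true(all(abs(m2$transforms$dx_px) <= 10 & abs(m2$transforms$dy_px) <= 10))
  expect_true(all(abs(m2$transforms$theta_deg) <= 5))
  expect_true(all(m2$transforms[1, c("theta_deg", "dx_px", "dy_px")] == 0))
})

test_that("derived seeds are deterministic, distinct and leave global RNG alone", {
  expect_identical(derive_seed(42, 0:5), derive_seed(42, 0:5))
  expect_equal(length(unique(derive_seed(42, 0:100))), 101)
  set.seed(123)
  before <- .Random.seed
  invisible(generate_toy_atlas(c(2, 20, 20), 2, "voronoi", seed = 9))
  expect_identical(before, .Random.seed)
})
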