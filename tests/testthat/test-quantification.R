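meta3 <- tibble::tibble(
  section_id = c("s1", "s2", "s3"), animal_id = "a1",
  genotype = "het", plane = "coronal", z_index = 1:3
)
regions2 <- tibble::tibble(label = 1:2, name = c("R1", "R2"))

test_that("count tables emit explicit zeros and drop background detections", {
  none <- tibble::tibble(section_id = character(0))
  tab <- count_by_region(none, integer(0), meta3, regions2)
  expect_equal(nrow(tab), 6)
  expect_true(all(tab$count == 0))
  det <- tibble::tibble(section_id = c("s1", "s1", "s2", "s2"))
  tab2 <- count_by_region(det, c(1L, 0L, 2L, 2L), meta3, regions2)
  expect_equal(tab2$count[tab2$region == 1 & tab2$section_id == "s1"], 1)
  expect_equal(tab2$count[tab2$region == 2 & tab2$section_id == "s2"], 2)
  expect_equal(sum(tab2$count), 3) # the background detection is excluded
  expect_error(count_by_region(tibble::tibble(section_id = "nope"), 1L,
                               meta3, regions2), "missing-metadata")
})

test_that("counts are conserved: region totals equal non-background detections", {
  set.seed(51)
  n <- 40
  det <- tibble::tibble(section_id = sample(meta3$section_id, n, replace = TRUE))
  labs <- sample(0:2, n, replace = TRUE)
  tab <- count_by_region(det, labs, meta3, regions2)
  expect_equal(sum(tab$count), sum(labs != 0))
  per_sec <- tapply(tab$count, tab$section_id, sum)
  for (s in meta3$section_id) {
    expect_equal(unname(per_sec[s]), sum(labs != 0 & det$section_id == s))
  }
})

test_that("pipeline counts on a clean phantom equal ground truth exactly", {
  atlas <- generate_toy_atlas(c(2, 96, 96), 2, "boxes")
  eff <- genotype_effect(lambda = 5, min_sep_px = 16, n_axons = 0)
  res <- generate_section_stack(atlas, eff, noise_spec(), seed = 23, z_indices = 1:2)
  q <- quantify_stack(res$stack, atlas, align = FALSE, background_radius = 15)
  truth <- res$truth$counts[order(res$truth$counts$region, res$truth$counts$section_id), ]
  got <- q$counts[order(q$counts$region, q$counts$section_id), ]
  expect_equal(got$count, truth$count)
})

test_that("integrated density obeys its formula, linearity and additivity", {
  img <- matrix(5, 20, 20)
  mask <- matrix(FALSE, 20, 20); mask[1:2, 1:5] <- TRUE
  m <- integrated_density(img, mask)
  expect_equal(m$area_px, 10)
  expect_equal(m$mean_intensity, 5)
  expect_equal(m$integrated_density, 50)
  m2 <- integrated_density(img * 2, mask)
  expect_equal(m2$integrated_density, 100)
  # additivity over disjoint ROIs
  set.seed(52)
  rimg <- matrix(runif(400, 0, 50), 20, 20)
  a <- matrix(FALSE, 20, 20); a[3:8, 3:8] <- TRUE
  b <- matrix(FALSE, 20, 20); b[12:18, 11:19] <- TRUE
  ida <- integrated_density(rimg, a)$integrated_density
  idb <- integrated_density(rimg, b)$integrated_density
  idu <- integrated_density(rimg, a | b)$integrated_density
  expect_equal(idu, ida + idb, tolerance = 1e-12)
  expect_error(integrated_density(img, matrix(FALSE, 20, 20)), "empty-roi")
})

test_that("integrated density matches the analytic flux of a Gaussian blob", {
  sd <- 3; peak <- 80
  img <- make_blob(96, sd = sd, peak = peak)
  mask <- matrix(FALSE, 96, 96)
  yy <- matrix(0:95, 96, 96); xx <- t(yy)
  mask[(yy - 47.5)^2 + (xx - 47.5)^2 <= (6 * sd)^2] <- TRUE
  flux <- peak * 2 * pi * sd^2
  got <- integrated_density(img, mask)$integrated_density
  expect_lt(abs(got - flux) / flux, 0.02)
})

test_that("background-corrected density flags and uses the rolling ball", {
  img <- make_blob(64, sd = 3, peak = 60) + 20
  mask <- matrix(TRUE, 64, 64)
  raw <- integrated_density(img, mask)
  cor <- integrated_density(img, mask, background_radius = 50)
  expect_false(raw$background_corrected)
  expect_true(cor$background_corrected)
  expect_lt(cor$integrated_density, raw$integrated_density)
})

test_that("cross-plane confirmation requires all three planes and is monotone", {
  obs <- tibble::tibble(
    region = c(1L, 1L, 1L, 2L),
    plane = c("coronal", "sagittal", "horizontal", "sagittal")
  )
  cc <- cross_plane_consistency(obs)
  expect_true(cc$confirmed[cc$region == 1])
  expect_false(cc$confirmed[cc$region == 2])
  expect_equal(cc$missing_planes[cc$region == 2], "coronal,horizontal")
  # empty input
  expect_equal(nrow(cross_plane_consistency(obs[0, ])), 0)
  # adding a plane never removes a region from the confirmed set
  obs2 <- rbind(obs, tibble::tibble(region = 2L, plane = "coronal"))
  cc2 <- cross_plane_consistency(obs2)
  expect_true(all(cc$region[cc$confirmed] %in% cc2$region[cc2$confirmed]))
  expect_error(cross_plane_consistency(tibble::tibble(region = 1L, plane = "oblique")),
               "outside the required set")
})

test_that("plane positivity feeds the cross-plane rule", {
  counts <- tibble::tibble(
    region = c(1L, 1L, 1L, 2L, 2L, 2L),
    plane = rep(c("coronal", "sagittal", "horizontal"), 2),
    count = c(3, 1, 2, 0, 4, 0)
  )
  pos <- plane_positivity(counts)
  cc <- cross_plane_consistency(pos)
  expect_true(cc$confirmed[cc$region == 1])
  expect_false(cc$confirmed[cc$region == 2])
})
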