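test_that("the boundary fit reproduces OLS exactly (balanced, equal animal means)", {
  # construct data whose animal means are identical within genotype, so the
  # REML optimum sits at gamma = 0
  resid_pattern <- c(-9, -3, 1, 4, 7) - mean(c(-9, -3, 1, 4, 7))
  d <- data.frame(
    count = c(rep(100 + resid_pattern, 3), rep(70 + resid_pattern, 3)),
    genotype = rep(c("het", "ko"), each = 15),
    animal_id = rep(sprintf("a%d", 1:6), each = 5)
  )
  fit <- fit_random_intercept_lmm(d)
  ols <- lm(count ~ genotype, data = d)
  expect_true(fit$singular)
  expect_lt(max(abs(fit$beta - coef(ols)) / abs(coef(ols))), 1e-8)
  expect_lt(max(abs(fit$se - sqrt(diag(vcov(ols)))) / fit$se), 1e-8)
  expect_equal(fit$df, nrow(d) - 2)
})

test_that("estimates, variance components, df and p match the reference mixed-model fit", {
  skip_if_not_installed("lmerTest")
  set.seed(61)
  d <- sim_nested_gaussian(diff = -50)
  fit <- fit_random_intercept_lmm(d)
  ref <- lmerTest::lmer(count ~ genotype + (1 | animal_id), data = d, REML = TRUE)
  sc <- summary(ref)$coefficients
  vc <- as.data.frame(lme4::VarCorr(ref))$vcov
  expect_equal(unname(fit$beta[2]), sc[2, 1], tolerance = 1e-6)
  expect_equal(unname(fit$se[2]), sc[2, 2], tolerance = 1e-5)
  expect_equal(fit$df, sc[2, 3], tolerance = 1e-3)
  expect_equal(fit$p, sc[2, 5], tolerance = 1e-3)
  expect_equal(fit$sigma2_animal, vc[1], tolerance = 1e-4)
  expect_equal(fit$sigma2_resid, vc[2], tolerance = 1e-4)
  expect_equal(-2 * fit$reml_loglik, lme4::REMLcrit(ref), tolerance = 1e-6)
})

test_that("the returned variance ratio beats a dense audit grid", {
  set.seed(62)
  d <- sim_nested_gaussian(diff = -20, sa2 = 40)
  fit <- fit_random_intercept_lmm(d)
  audit <- c(0, 10^seq(-5, 5, length.out = 100))
  vals <- vapply(audit, fit$criterion_fn, numeric(1))
  expect_lte(fit$criterion_fn(fit$gamma), min(vals) + 1e-8)
})

test_that("degenerate stats inputs raise informative errors", {
  d <- sim_nested_gaussian()
  d0 <- d; d0$count <- 5
  expect_error(fit_random_intercept_lmm(d0), "degenerate-data")
  d1 <- d[d$genotype == "het", ]
  expect_error(fit_random_intercept_lmm(d1), "missing-level")
  d2 <- d; d2$animal_id <- d2$genotype # one animal per genotype
  expect_warning(fit_random_intercept_lmm(d2), "fewer than 2 animals")
})

test_that("p-value adjustment reproduces the worked example and its bounds", {
  expect_equal(adjust_pvalues(0.04, "bonferroni"), 0.04)
  expect_equal(adjust_pvalues(0.04, "bh"), 0.04)
  p <- c(0.01, 0.02, 0.03)
  expect_equal(adjust_pvalues(p, "bh"), c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(p, "bonferroni"), c(0.03, 0.06, 0.09))
  set.seed(63)
  for (rep in 1:5) {
    q <- runif(7)
    expect_true(all(adjust_pvalues(q, "bh") <= adjust_pvalues(q, "bonferroni") + 1e-12))
    expect_true(all(adjust_pvalues(q, "bh") >= q - 1e-12))
  }
  expect_error(adjust_pvalues(c(0.1, 0)), "invalid-input")
  expect_error(adjust_pvalues(1.2), "invalid-input")
})

test_that("region comparison adjusts across regions and stars the BH column", {
  set.seed(64)
  counts <- dplyr::bind_rows(lapply(1:4, function(r) {
    d <- sim_nested_gaussian(diff = if (r == 2) -60 else 0)
    d$region <- r
    d$region_name <- paste0("R", r)
    d
  }))
  cmp <- compare_regions(counts)
  expect_equal(nrow(cmp), 4)
  expect_true(all(cmp$p_bonferroni >= cmp$p_raw - 1e-12))
  expect_true(all(cmp$p_bh <= cmp$p_bonferroni + 1e-12))
  expect_true(cmp$significant_bh[cmp$region == 2])
  expect_true(all(cmp$stars[cmp$p_bh >= 0.05] == ""))
  # single region: adjusted equals raw
  one <- compare_regions(counts[counts$region == 1, ])
  expect_equal(one$p_bh, one$p_raw)
  expect_equal(one$p_bonferroni, one$p_raw)
})

test_that("all-null p-values yield no stars and no significance", {
  counts <- tibble::tibble(
    region = rep(1:3, each = 2), region_name = paste0("R", rep(1:3, each = 2)),
    count = 1, genotype = rep(c("het", "ko"), 3), animal_id = rep(c("a", "b"), 3)
  )
  # constant response: every fit fails, rows carry NA, nothing is significant
  cmp <- suppressWarnings(compare_regions(counts))
  expect_true(all(is.na(cmp$p_raw)))
  expect_true(all(!cmp$significant_bh))
  expect_true(all(cmp$stars == ""))
})

test_that("percent reduction converts the contrast scale correctly", {
  set.seed(65)
  d <- sim_nested_gaussian(diff = -50)
  fit <- fit_random_intercept_lmm(d)
  pr <- percent_reduction(fit)
  expect_equal(pr$estimate, -100 * fit$beta[[2]] / fit$beta[[1]])
  expect_gt(pr$se, 0)
  # a zero contrast gives exactly 0%
  fit0 <- fit
  fit0$beta[2] <- 0
  expect_equal(percent_reduction(fit0)$estimate, 0)
  fitz <- fit
  fitz$beta[1] <- 1e-15
  expect_error(percent_reduction(fitz), "undefined-percent")
})

test_that("tidy and glance return the expected broom-style frames", {
  set.seed(66)
  fit <- fit_random_intercept_lmm(sim_nested_gaussian(diff = -30))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("term", "estimate", "std.error", "statistic", "df", "p.value"))
  expect_equal(nrow(td), 2)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("sigma2_animal", "sigma2_resid", "p.value", "singular") %in% names(gl)))
})
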