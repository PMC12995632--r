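# Genotype comparison statistics: a random-intercept linear mixed model per
# region (sections nested in animals, so repeated sections are not treated as
# independent replicates), fitted by profiled REML with Satterthwaite
# denominator degrees of freedom, plus Bonferroni / Benjamini-Hochberg
# correction across regions.
#
# The single-random-intercept model y = X beta + Z u + e, u ~ N(0, sa2 I),
# e ~ N(0, se2 I), has V = se2 (I + gamma Z Z') with gamma = sa2 / se2; both
# beta and se2 profile out in closed form, leaving a 1-D REML criterion in
# gamma that is optimized on [0, 1e6] (negative-variance solutions clamp to
# the gamma = 0 boundary, where the fit reproduces OLS exactly).

# group-wise GLS pieces at a given gamma via the Woodbury identity:
# within a group of size n_g, V0^{-1} = I - (gamma / (1 + gamma n_g)) J
gls_pieces <- function(gamma, X, y, group_idx) {
  p <- ncol(X)
  XtViX <- matrix(0, p, p)
  XtViy <- numeric(p)
  ytViy <- 0
  logdetV0 <- 0
  for (idx in group_idx) {
    Xg <- X[idx, , drop = FALSE]
    yg <- y[idx]
    ng <- length(idx)
    w <- gamma / (1 + gamma * ng)
    sX <- colSums(Xg)
    sy <- sum(yg)
    XtViX <- XtViX + crossprod(Xg) - w * tcrossprod(sX)
    XtViy <- XtViy + crossprod(Xg, yg)[, 1] - w * sX * sy
    ytViy <- ytViy + sum(yg^2) - w * sy^2
    logdetV0 <- logdetV0 + log(1 + gamma * ng)
  }
  beta <- solve(XtViX, XtViy)
  rss <- max(ytViy - 2 * sum(beta * XtViy) + sum(beta * (XtViX %*% beta)), 1e-300)
  list(beta = beta, rss = rss, XtViX = XtViX, logdetV0 = logdetV0)
}

# -2 * profiled REML log-likelihood, up to an additive constant
reml_m2_profiled <- function(gamma, X, y, group_idx) {
  n <- length(y); p <- ncol(X)
  g <- gls_pieces(gamma, X, y, group_idx)
  (n - p) * log(g$rss) + g$logdetV0 + determinant(g$XtViX, logarithm = TRUE)$modulus[1]
}

# -2 * REML log-likelihood at explicit theta = (sa2, se2), full constants
reml_m2_theta <- function(sa2, se2, X, y, group_idx) {
  n <- length(y); p <- ncol(X)
  gamma <- sa2 / se2
  g <- gls_pieces(gamma, X, y, group_idx)
  (n - p) * log(2 * pi) + (n - p) * log(se2) + g$logdetV0 +
    determinant(g$XtViX, logarithm = TRUE)$modulus[1] + g$rss / se2
}

# contrast variance c' Var(beta) c at theta
contrast_var_theta <- function(sa2, se2, X, y, group_idx, cvec) {
  g <- gls_pieces(sa2 / se2, X, y, group_idx)
  se2 * (t(cvec) %*% solve(g$XtViX, cvec))[1]
}

#' Fit a random-intercept linear mixed model
#'
#' Models the response (counts on the identity scale, or intensities) with
#' genotype as a fixed effect and animal identity as a random intercept;
#' additional fixed covariates (e.g. section plane for intensity data) are
#' optional. Estimation is REML, profiled down to a 1-D search over the
#' variance ratio `gamma = sigma2_animal / sigma2_resid` on `[0, 1e6]`; the
#' genotype contrast is tested with a t statistic on Satterthwaite
#' denominator degrees of freedom (computed from the gradient of the
#' contrast variance in the variance components and the observed REML
#' information). Boundary fits (`gamma = 0`) are flagged singular and report
#' the OLS-equivalent test with residual df.
#'
#' @param data Data frame with the response column, a genotype column (two
#'   levels; the first factor level is the reference) and an animal-id
#'   column.
#' @param response Name of the response column (default `"count"`).
#' @param genotype_col,animal_col Column names (defaults `"genotype"`,
#'   `"animal_id"`).
#' @param covariates Optional character vector of additional fixed-effect
#'   columns.
#' @return An object of class `lmm_fit`.
#' @export
fit_random_intercept_lmm <- function(data, response = "count",
                                     genotype_col = "genotype",
                                     animal_col = "animal_id",
                                     covariates = NULL) {
  stopifnot(is.data.frame(data),
            all(c(response, genotype_col, animal_col) %in% names(data)))
  data <- as.data.frame(data)
  y <- as.numeric(data[[response]])
  if (anyNA(y)) stop("degenerate-data: response contains NA", call. = FALSE)
  if (sd(y) == 0) {
    stop("degenerate-data: response column is constant", call. = FALSE)
  }
  gt <- data[[genotype_col]]
  if (!is.factor(gt)) gt <- factor(gt)
  gt <- droplevels(gt)
  if (nlevels(gt) < 2) {
    stop("missing-level: both genotype levels must be present", call. = FALSE)
  }
  if (nlevels(gt) > 2) {
    stop("invalid-input: genotype must have exactly two levels", call. = FALSE)
  }
  animal <- factor(data[[animal_col]])
  per_geno <- tapply(animal, gt, function(a) length(unique(a)))
  if (any(per_geno < 2)) {
    warning("fewer than 2 animals in a genotype group; the random intercept is weakly identified")
  }
  fdat <- data.frame(.y = y, .genotype = gt)
  form <- ".y ~ .genotype"
  if (!is.null(covariates)) {
    for (cv in covariates) fdat[[cv]] <- data[[cv]]
    form <- paste(form, "+", paste(covariates, collapse = " + "))
  }
  X <- stats::model.matrix(stats::as.formula(form), fdat)
  n <- length(y); p <- ncol(X)
  group_idx <- split(seq_len(n), animal)

  crit <- function(gamma) reml_m2_profiled(gamma, X, y, group_idx)
  grid <- c(0, 10^seq(-4, 6, length.out = 80))
  vals <- vapply(grid, crit, numeric(1))
  i <- which.min(vals)
  if (i == 1) {
    gamma_hat <- 0
    opt_ok <- TRUE
  } else {
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    o <- optimize(crit, c(max(lo, 1e-10), hi), tol = 1e-10)
    # compare against the boundary explicitly
    if (vals[1] <= o$objective) {
      gamma_hat <- 0
    } else {
      gamma_hat <- o$minimum
    }
    opt_ok <- TRUE
  }
  g <- gls_pieces(gamma_hat, X, y, group_idx)
  se2 <- g$rss / (n - p)
  sa2 <- gamma_hat * se2
  vcov_beta <- se2 * solve(g$XtViX)
  se_beta <- sqrt(diag(vcov_beta))
  singular <- gamma_hat < 1e-8

  gidx <- 2L # genotype contrast column (intercept first by construction)
  cvec <- numeric(p); cvec[gidx] <- 1
  v_hat <- vcov_beta[gidx, gidx]
  if (singular) {
    df <- n - p
  } else {
    df <- satterthwaite_df(sa2, se2, X, y, group_idx, cvec, v_hat)
    if (!is.finite(df) || df <= 0) df <- n - p
  }
  tval <- unname(g$beta[gidx] / se_beta[gidx])
  pval <- 2 * pt(-abs(tval), df)
  m2 <- reml_m2_theta(max(sa2, 0), se2, X, y, group_idx)

  structure(list(
    beta = setNames(as.numeric(g$beta), colnames(X)),
    se = setNames(se_beta, colnames(X)),
    vcov = vcov_beta,
    sigma2_animal = sa2, sigma2_resid = se2, gamma = gamma_hat,
    df = df, t = tval, p = pval,
    reml_loglik = -m2 / 2, reml_criterion = m2,
    converged = opt_ok, singular = singular,
    n_obs = n, n_animals = nlevels(animal),
    genotype_levels = levels(gt), response = response,
    criterion_fn = crit
  ), class = "lmm_fit")
}

# Satterthwaite df: 2 v^2 / (g' A^{-1} g), with g the gradient of the
# contrast variance in theta = (sa2, se2) and A the observed REML information
satterthwaite_df <- function(sa2, se2, X, y, group_idx, cvec, v_hat) {
  vfun <- function(th) contrast_var_theta(max(th[1], 0), th[2], X, y, group_idx, cvec)
  m2fun <- function(th) reml_m2_theta(max(th[1], 0), th[2], X, y, group_idx)
  th <- c(sa2, se2)
  h <- pmax(1e-8, 1e-4 * abs(th))
  grad <- numeric(2)
  for (k in 1:2) {
    e <- numeric(2); e[k] <- h[k]
    if (th[k] - h[k] > 0 || k == 2) {
      grad[k] <- (vfun(th + e) - vfun(th - e)) / (2 * h[k])
    } else {
      grad[k] <- (vfun(th + e) - vfun(th)) / h[k]
    }
  }
  H <- matrix(0, 2, 2)
  for (k in 1:2) {
    for (l in k:2) {
      ek <- numeric(2); ek[k] <- h[k]
      el <- numeric(2); el[l] <- h[l]
      H[k, l] <- H[l, k] <-
        (m2fun(th + ek + el) - m2fun(th + ek - el) -
           m2fun(th - ek + el) + m2fun(th - ek - el)) / (4 * h[k] * h[l])
    }
  }
  info <- H / 2 # observed information = 0.5 * Hessian of (-2 loglik)
  denom <- tryCatch(drop(t(grad) %*% solve(info, grad)), error = function(e) NA_real_)
  if (!is.finite(denom) || denom <= 0) return(NA_real_)
  2 * v_hat^2 / denom
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("<lmm_fit> random-intercept LMM (REML)\n")
  cat(sprintf("  n = %d observations, %d animals%s\n", x$n_obs, x$n_animals,
              if (x$singular) " [singular: gamma = 0, OLS-equivalent]" else ""))
  cat(sprintf("  sigma2_animal = %.4g, sigma2_resid = %.4g\n",
              x$sigma2_animal, x$sigma2_resid))
  cat(sprintf("  genotype (%s vs %s): beta = %.4g (SE %.4g), t = %.3f, df = %.2f, p = %.3g\n",
              x$genotype_levels[2], x$genotype_levels[1],
              x$beta[2], x$se[2], x$t, x$df, x$p))
  invisible(x)
}

#' @export
tidy.lmm_fit <- function(x, ...) {
  k <- length(x$beta)
  tibble::tibble(
    term = names(x$beta),
    estimate = as.numeric(x$beta),
    std.error = as.numeric(x$se),
    statistic = as.numeric(x$beta / x$se),
    df = ifelse(seq_len(k) == 2, x$df, NA_real_),
    p.value = ifelse(seq_len(k) == 2, x$p, NA_real_)
  )
}

#' @export
glance.lmm_fit <- function(x, ...) {
  tibble::tibble(
    sigma2_animal = x$sigma2_animal, sigma2_resid = x$sigma2_resid,
    gamma = x$gamma, reml_loglik = x$reml_loglik,
    df = x$df, p.value = x$p, singular = x$singular,
    n_obs = x$n_obs, n_animals = x$n_animals
  )
}

#' Adjust p-values for multiple comparisons
#'
#' Bonferroni (`min(1, m p)`) or Benjamini-Hochberg step-up FDR adjustment,
#' delegated to [stats::p.adjust()]; input p-values must lie in `(0, 1]`.
#'
#' @param pvals Numeric vector of raw p-values in `(0, 1]`.
#' @param method `"bonferroni"` or `"bh"`.
#' @return Numeric vector of adjusted p-values in input order.
#' @export
adjust_pvalues <- function(pvals, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  if (any(!is.finite(pvals)) || any(pvals <= 0 | pvals > 1)) {
    stop("invalid-input: p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = if (method == "bh") "BH" else "bonferroni")
}

star_level <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Compare genotypes across regions
#'
#' Fits the random-intercept model per region, collects the raw genotype
#' p-values, applies Bonferroni and Benjamini-Hochberg corrections across
#' regions (regions whose fit fails are reported with NA and excluded from
#' the correction family), and assigns significance stars on the BH-adjusted
#' p-values (* < 0.05, ** < 0.01, *** < 0.001).
#'
#' @param counts A `section_counts` tibble (or any table with `region`,
#'   `region_name`, the response, `genotype`, `animal_id`).
#' @param alpha Significance level (default 0.05).
#' @param response Response column (default `"count"`).
#' @param covariates Optional fixed covariates passed to the per-region fit.
#' @return A tibble (class `region_comparison`): per region the genotype
#'   effect, percent change, raw and adjusted p-values, significance flags.
#' @export
compare_regions <- function(counts, alpha = 0.05, response = "count",
                            covariates = NULL) {
  stopifnot(is.data.frame(counts), "region" %in% names(counts))
  regions <- counts |>
    dplyr::distinct(.data$region,
                    region_name = if ("region_name" %in% names(counts)) {
                      .data$region_name
                    } else {
                      as.character(.data$region)
                    })
  rows <- purrr::map(seq_len(nrow(regions)), function(i) {
    sub <- counts[counts$region == regions$region[i], , drop = FALSE]
    fit <- tryCatch(
      suppressWarnings(fit_random_intercept_lmm(sub, response = response,
                                                covariates = covariates)),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      return(tibble::tibble(
        region = regions$region[i], region_name = regions$region_name[i],
        n_obs = nrow(sub), beta_intercept = NA_real_, beta_genotype = NA_real_,
        se_genotype = NA_real_, df = NA_real_, t = NA_real_,
        percent_change = NA_real_, p_raw = NA_real_, singular = NA
      ))
    }
    tibble::tibble(
      region = regions$region[i], region_name = regions$region_name[i],
      n_obs = fit$n_obs, beta_intercept = unname(fit$beta[1]),
      beta_genotype = unname(fit$beta[2]), se_genotype = unname(fit$se[2]),
      df = fit$df, t = fit$t,
      percent_change = 100 * unname(fit$beta[2]) / unname(fit$beta[1]),
      p_raw = fit$p, singular = fit$singular
    )
  })
  out <- dplyr::bind_rows(rows)
  ok <- !is.na(out$p_raw)
  out$p_bonferroni <- NA_real_
  out$p_bh <- NA_real_
  if (any(ok)) {
    out$p_bonferroni[ok] <- adjust_pvalues(out$p_raw[ok], "bonferroni")
    out$p_bh[ok] <- adjust_pvalues(out$p_raw[ok], "bh")
  }
  out$significant_bh <- !is.na(out$p_bh) & out$p_bh < alpha
  out$stars <- star_level(out$p_bh)
  attr(out, "alpha") <- alpha
  class(out) <- c("region_comparison", class(out))
  out
}

#' Percent reduction implied by a fitted model
#'
#' Converts the genotype effect to a percentage of the reference-group mean:
#' `-100 * beta_genotype / beta_intercept` (positive values = reduction in
#' the mutant group), with a delta-method standard error.
#'
#' @param fit An `lmm_fit`.
#' @return A one-row tibble: `estimate` (percent), `se`.
#' @export
percent_reduction <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  b0 <- unname(fit$beta[1]); bg <- unname(fit$beta[2])
  if (abs(b0) < 1e-12) {
    stop("undefined-percent: intercept is (numerically) zero", call. = FALSE)
  }
  est <- -100 * bg / b0
  grad <- c(100 * bg / b0^2, -100 / b0)
  se <- sqrt(drop(t(grad) %*% fit$vcov[1:2, 1:2] %*% grad))
  tibble::tibble(estimate = est, se = se)
}
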