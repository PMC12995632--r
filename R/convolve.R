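# Separable convolution with Gaussian (derivative) kernels, reflect-padded.
# These back the Hessian-eigenvalue tubularity filter and the blob detector,
# where we need scale-normalized derivatives with controlled boundary
# behaviour rather than a generic FFT filter.

gaussian_kernel <- function(sigma, order = 0, half_width = NULL) {
  stopifnot(sigma > 0, order %in% 0:2)
  if (is.null(half_width)) half_width <- max(1L, ceiling(4 * sigma))
  x <- seq(-half_width, half_width)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  switch(as.character(order),
    "0" = g,
    "1" = -x / sigma^2 * g,
    "2" = {
      k <- (x^2 - sigma^2) / sigma^4 * g
      k - sum(k) / length(k) # exact zero response on constant input
    }
  )
}

# 1-D convolution along rows (dim 1) of a matrix, reflect padding
conv_dim1 <- function(m, k) {
  hw <- (length(k) - 1L) / 2L
  h <- nrow(m)
  idx <- c(rev(seq_len(min(hw, h))), seq_len(h), h + 1 - rev(seq_len(min(hw, h))))
  if (hw > h) { # degenerate tiny images: clamp-pad
    idx <- c(rep(1L, hw - h), idx, rep(h, hw - h))
  }
  mp <- m[idx, , drop = FALSE]
  out <- matrix(0, h, ncol(m))
  for (j in seq_along(k)) {
    out <- out + k[j] * mp[j:(j + h - 1), , drop = FALSE]
  }
  out
}

# separable 2-D convolution: ky along rows (y), kx along columns (x)
conv_sep <- function(m, ky, kx) {
  t(conv_dim1(t(conv_dim1(m, ky)), kx))
}

# Gaussian blur of a matrix (reflect padding)
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  g <- gaussian_kernel(sigma, 0)
  conv_sep(m, g, g)
}

# Scale-space Hessian components at scale sigma (not yet scale-normalized)
hessian_at_scale <- function(m, sigma) {
  g0 <- gaussian_kernel(sigma, 0)
  g1 <- gaussian_kernel(sigma, 1)
  g2 <- gaussian_kernel(sigma, 2)
  list(
    yy = conv_sep(m, g2, g0),
    xx = conv_sep(m, g0, g2),
    xy = conv_sep(m, g1, g1)
  )
}
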