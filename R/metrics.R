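as_pixels <- function(x) {
  if (inherits(x, "image_grid")) x$pixels
  else if (inherits(x, "polar_image")) x$values
  else as.matrix(x)
}

#' Peak signal-to-noise ratio
#'
#' `20 * log10(sqrt(M*N) * max|f_gt| / ||f_gt - f_p||_2)`, i.e. the peak
#' (max of the reference) over the root-mean-square error, in dB. Identical
#' images give `Inf`; an all-zero reference is an error.
#'
#' @param f_gt Ground-truth image (`image_grid` or matrix).
#' @param f_p Estimated image of the same shape.
#' @param mask Optional logical matrix restricting the comparison (e.g. the
#'   field-of-view disk from [inscribed_mask()]).
#' @return PSNR in dB.
#' @export
psnr <- function(f_gt, f_p, mask = NULL) {
  a <- as_pixels(f_gt); b <- as_pixels(f_p)
  if (!all(dim(a) == dim(b))) stop("shape mismatch")
  if (!is.null(mask)) { a <- a[mask]; b <- b[mask] }
  peak <- max(abs(a))
  if (peak == 0) stop("reference image has zero peak; PSNR undefined")
  err <- sqrt(sum((a - b)^2))
  if (err == 0) return(Inf)
  20 * log10(sqrt(length(a)) * peak / err)
}

#' Structural similarity index (global statistics)
#'
#' Single-window SSIM computed from whole-image means, variances and the
#' covariance, with stability constants `c1 = (k1*L)^2`, `c2 = (k2*L)^2`,
#' `k1 = k2 = 0.03` and `L` the maximum pixel value of the reference. A
#' locally windowed mode (11x11 Gaussian, sigma 1.5, mean over windows) is
#' available for cross-checking.
#'
#' @inheritParams psnr
#' @param k1,k2 Stability constants (default 0.03 each).
#' @param L Dynamic range; defaults to `max(f_gt)`.
#' @param windowed If TRUE, compute the mean of local SSIM values instead
#'   of the global-statistics index.
#' @return SSIM scalar in `[-1, 1]`.
#' @export
ssim <- function(f_gt, f_p, mask = NULL, k1 = 0.03, k2 = 0.03, L = NULL,
                 windowed = FALSE) {
  a <- as_pixels(f_gt); b <- as_pixels(f_p)
  if (!all(dim(a) == dim(b))) stop("shape mismatch")
  if (windowed) return(ssim_windowed(a, b, mask, k1, k2, L))
  if (!is.null(mask)) { a <- a[mask]; b <- b[mask] }
  if (is.null(L)) L <- max(a)
  c1 <- (k1 * L)^2; c2 <- (k2 * L)^2
  mu_a <- mean(a); mu_b <- mean(b)
  va <- mean((a - mu_a)^2); vb <- mean((b - mu_b)^2)
  cab <- mean((a - mu_a) * (b - mu_b))
  ((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
}

ssim_windowed <- function(a, b, mask, k1, k2, L) {
  if (is.null(L)) L <- max(if (is.null(mask)) a else a[mask])
  c1 <- (k1 * L)^2; c2 <- (k2 * L)^2
  r <- 5L
  k <- exp(-((-r:r)^2) / (2 * 1.5^2)); k <- k / sum(k)
  smooth <- function(m) {
    pad <- function(n) c(rep(1, r), 1:n, rep(n, r))
    m2 <- m[pad(nrow(m)), pad(ncol(m))]
    m3 <- apply(m2, 2, function(x)
      as.vector(stats::filter(x, k, sides = 2)))[(r + 1):(r + nrow(m)), ]
    t(apply(t(m3[, ]), 2, function(x)
      as.vector(stats::filter(c(rep(x[1], r), x, rep(x[length(x)], r)),
                              k, sides = 2))[(r + 1):(r + length(x))]))
  }
  mu_a <- smooth(a); mu_b <- smooth(b)
  va <- smooth(a * a) - mu_a^2; vb <- smooth(b * b) - mu_b^2
  cab <- smooth(a * b) - mu_a * mu_b
  s <- ((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
  if (!is.null(mask)) mean(s[mask]) else mean(s)
}

#' Radial bias profile of a reconstruction error
#'
#' Mean of `est - ref` within `n_bins` equal-width concentric annuli about
#' the image center, restricted to the inscribed circle. This is the
#' quantitative face of the cupping artifact: truncated reconstructions
#' show a bias that grows from the center towards the FOV edge.
#'
#' @param est,ref Same-shape square images.
#' @param n_bins Number of annuli (>= 2).
#' @return Numeric vector of per-annulus mean residuals (center outward).
#' @export
radial_bias_profile <- function(est, ref, n_bins = 10) {
  a <- as_pixels(est); b <- as_pixels(ref)
  if (!all(dim(a) == dim(b))) stop("shape mismatch")
  if (nrow(a) != ncol(a)) stop("images must be square")
  if (n_bins < 2) stop("n_bins must be >= 2")
  n <- nrow(a)
  ctr <- (n + 1) / 2
  r <- outer(seq_len(n) - ctr, seq_len(n) - ctr, function(y, x) sqrt(x^2 + y^2))
  rmax <- (n - 1) / 2
  resid <- a - b
  bins <- pmin(floor(r / rmax * n_bins) + 1, n_bins)
  out <- numeric(n_bins)
  for (k in seq_len(n_bins)) out[k] <- mean(resid[bins == k & r <= rmax])
  out
}

#' Extract a row or column profile from an image
#'
#' @param image An `image_grid` or matrix.
#' @param along `"row"` or `"col"`.
#' @param index 1-based line index.
#' @return Numeric vector of the pixel values along the line.
#' @export
line_profile <- function(image, along = c("row", "col"), index) {
  m <- as_pixels(image)
  along <- match.arg(along)
  nmax <- if (along == "row") nrow(m) else ncol(m)
  if (index < 1 || index > nmax) stop("index out of range")
  if (along == "row") m[index, ] else m[, index]
}

#' Evaluate corrected images against references
#'
#' Computes per-image PSNR and SSIM (restricted to the field-of-view disk)
#' and aggregate statistics.
#'
#' @param est_list,ref_list Lists of same-shape `image_grid`s.
#' @param fov_only Restrict metrics to the inscribed circle (default TRUE).
#' @param method Label recorded in the report.
#' @return A `data.frame` with one row per image plus attributes
#'   `mean_psnr`, `median_psnr`, `mean_ssim`, `median_ssim`.
#' @export
metric_report <- function(est_list, ref_list, fov_only = TRUE,
                          method = "unknown") {
  stopifnot(length(est_list) == length(ref_list), length(est_list) >= 1)
  rows <- lapply(seq_along(est_list), function(i) {
    e <- est_list[[i]]; r <- ref_list[[i]]
    mk <- if (fov_only) inscribed_mask(nrow(as_pixels(r))) else NULL
    data.frame(index = i, method = method,
               psnr = psnr(r, e, mask = mk), ssim = ssim(r, e, mask = mk))
  })
  rep <- do.call(rbind, rows)
  attr(rep, "mean_psnr") <- mean(rep$psnr[is.finite(rep$psnr)])
  attr(rep, "median_psnr") <- stats::median(rep$psnr)
  attr(rep, "mean_ssim") <- mean(rep$ssim)
  attr(rep, "median_ssim") <- stats::median(rep$ssim)
  rep
}
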