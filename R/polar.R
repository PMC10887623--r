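#' Polar-resampled image
#'
#' Raster in (angle, radius) coordinates about the source-image center:
#' rows are uniformly spaced angles phi on `[0, 2*pi)`, columns radii from 0
#' to `r_max` (the inscribed-circle radius). In this layout a radially
#' decreasing cupping artifact becomes a horizontally decreasing band, so
#' the "horizontal" axis of the total-variation constraint is the radial
#' one.
#'
#' @param values Numeric `n_phi x n_rho` matrix.
#' @param center Length-2 center `c(cx, cy)` in source-image pixel
#'   coordinates (1-based column, row).
#' @param r_max Maximum sampled radius in source pixels.
#' @return An object of class `polar_image`.
#' @export
polar_image <- function(values, center, r_max) {
  stopifnot(nrow(values) >= 4, ncol(values) >= 4, r_max > 0)
  if (!all(is.finite(values))) stop("polar image contains non-finite values")
  structure(list(values = values, center = center, r_max = r_max,
                 rho_spacing = r_max / (ncol(values) - 1),
                 phi_spacing = 2 * pi / nrow(values)),
            class = "polar_image")
}

#' @export
print.polar_image <- function(x, ...) {
  cat(sprintf("<polar_image %d angles x %d radii, r_max %.3g>\n",
              nrow(x$values), ncol(x$values), x$r_max))
  invisible(x)
}

#' Cartesian-to-polar resampling
#'
#' Bilinear sampling of a square image at `(cx + rho*cos(phi),
#' cy + rho*sin(phi))` for a uniform `(phi, rho)` grid. Column 1 is
#' `rho = 0`; `r_max` is the inscribed-circle radius, so image corners are
#' discarded (truncation-FOV images are disk-supported).
#'
#' @param image A square `image_grid`.
#' @param n_rho Number of radial samples.
#' @param n_phi Number of angular samples.
#' @return A `polar_image`.
#' @export
to_polar <- function(image, n_rho = ncol(image$pixels) / 2, n_phi = 360) {
  stopifnot(inherits(image, "image_grid"))
  if (!is_square(image)) stop("polar transform requires a square image")
  n <- nrow(image$pixels)
  ctr <- (n + 1) / 2
  r_max <- (n - 1) / 2
  rho <- seq(0, r_max, length.out = n_rho)
  phi <- 2 * pi * (seq_len(n_phi) - 1) / n_phi
  P <- outer(phi, rho, function(p, r) r * cos(p))  # x offsets
  Q <- outer(phi, rho, function(p, r) r * sin(p))  # y offsets
  vals <- bilinear_sample(image$pixels, as.vector(ctr + Q), as.vector(ctr + P))
  polar_image(matrix(vals, n_phi, n_rho), center = c(ctr, ctr), r_max = r_max)
}

#' Polar-to-Cartesian resampling
#'
#' Inverse of [to_polar()]: every Cartesian pixel inside the inscribed
#' circle is bilinearly interpolated in `(rho, phi)` with wrap-around in
#' phi; pixels outside `r_max` are set to `fill`.
#'
#' @param polar A `polar_image`.
#' @param out_size Output side length in pixels (>= 16).
#' @param pixel_size Physical pixel size recorded on the output.
#' @param value_range Display window recorded on the output.
#' @param fill Value assigned outside the sampled disk.
#' @return An `image_grid`.
#' @export
from_polar <- function(polar, out_size, pixel_size = 1,
                       value_range = c(0, 1), fill = 0) {
  stopifnot(inherits(polar, "polar_image"))
  if (out_size < 16) stop("out_size must be >= 16")
  n_phi <- nrow(polar$values); n_rho <- ncol(polar$values)
  ctr <- (out_size + 1) / 2
  X <- matrix(seq_len(out_size) - ctr, out_size, out_size, byrow = TRUE)
  Y <- matrix(seq_len(out_size) - ctr, out_size, out_size)
  rho_out <- sqrt(X^2 + Y^2)                    # in output-pixel units
  phi <- atan2(Y, X) %% (2 * pi)
  # the output inscribed radius maps onto r_max of the polar raster
  rho_src <- rho_out * polar$r_max / ((out_size - 1) / 2)
  # fractional indices into the polar raster; phi wraps via an extra row
  ri <- phi / polar$phi_spacing + 1
  ci <- rho_src / polar$rho_spacing + 1
  wrapped <- rbind(polar$values, polar$values[1, , drop = FALSE])
  vals <- bilinear_sample(wrapped, as.vector(ri), as.vector(ci), fill = fill)
  out <- matrix(vals, out_size, out_size)
  out[rho_out > (out_size - 1) / 2] <- fill
  image_grid(out, pixel_size, value_range)
}
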