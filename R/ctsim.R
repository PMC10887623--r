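#' Fan-beam acquisition geometry
#'
#' Equiangular source positions over a full circle with an equidistant flat
#' detector. Distances are in the same physical units as the image pixel
#' size.
#'
#' @param n_views Number of projection views over 2*pi (default 720).
#' @param source_iso Source-to-isocenter distance.
#' @param iso_det Isocenter-to-detector distance.
#' @param n_det Number of detector channels.
#' @param det_pitch Physical channel width on the detector line.
#' @param angle_start First view angle in radians.
#' @return An object of class `fan_geometry`.
#' @export
fan_geometry <- function(n_views = 720, source_iso, iso_det, n_det,
                         det_pitch, angle_start = 0) {
  stopifnot(n_views >= 4, source_iso > 0, iso_det > 0, n_det >= 8,
            det_pitch > 0)
  structure(list(n_views = as.integer(n_views), source_iso = source_iso,
                 iso_det = iso_det, n_det = as.integer(n_det),
                 det_pitch = det_pitch, angle_start = angle_start),
            class = "fan_geometry")
}

#' Default fan geometry for a square image
#'
#' Generic diagnostic-CT-like fan: source-to-isocenter twice the physical
#' image diagonal, detector at the same distance beyond the isocenter,
#' `ceil(1.5 * size)` channels, pitch chosen so the full detector covers the
#' in-image object disk with a 10% margin.
#'
#' @param size Image side length in pixels.
#' @param pixel_size Physical pixel size.
#' @param n_views Number of views (default 720).
#' @return A [fan_geometry()].
#' @export
default_fan_geometry <- function(size, pixel_size = 1, n_views = 720) {
  diag_len <- sqrt(2) * size * pixel_size
  dso <- 2 * diag_len
  dsd <- 2 * dso
  r_cov <- 0.55 * size * pixel_size          # half-side plus 10% margin
  half_fan <- asin(min(r_cov / dso, 0.999))
  half_width <- dsd * tan(half_fan)
  n_det <- as.integer(ceiling(1.5 * size))
  fan_geometry(n_views = n_views, source_iso = dso, iso_det = dsd - dso,
               n_det = n_det, det_pitch = 2 * half_width / n_det)
}

geom_betas <- function(geom) {
  geom$angle_start + 2 * pi * (seq_len(geom$n_views) - 1) / geom$n_views
}

# physical offsets of all detector channels on the detector line
geom_det_s <- function(geom) {
  (seq_len(geom$n_det) - (geom$n_det + 1) / 2) * geom$det_pitch
}

#' Sinogram container
#'
#' Line-integral data for a [fan_geometry()]. `retained` records which
#' channel range of the full detector is actually present: truncation
#' deletes channels rather than zeroing them, so downstream code can never
#' mistake missing data for measured zeros.
#'
#' @param values Numeric `n_views x n_retained` matrix of line integrals.
#' @param geometry The acquisition [fan_geometry()].
#' @param retained Length-2 integer `c(first, last)` channel indices
#'   (1-based, within the full detector) present in `values`.
#' @return An object of class `sinogram`.
#' @export
sinogram <- function(values, geometry, retained = c(1L, geometry$n_det)) {
  stopifnot(inherits(geometry, "fan_geometry"),
            nrow(values) == geometry$n_views,
            ncol(values) == retained[2] - retained[1] + 1,
            retained[1] >= 1, retained[2] <= geometry$n_det,
            retained[1] <= retained[2])
  if (!all(is.finite(values))) stop("sinogram contains non-finite values")
  structure(list(values = values, geometry = geometry,
                 retained = as.integer(retained)),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram %d views x %d channels (retained %d..%d of %d)>\n",
              nrow(x$values), ncol(x$values), x$retained[1], x$retained[2],
              x$geometry$n_det))
  invisible(x)
}

sino_det_s <- function(sino) {
  geom_det_s(sino$geometry)[sino$retained[1]:sino$retained[2]]
}

is_truncated <- function(sino) {
  sino$retained[1] > 1 || sino$retained[2] < sino$geometry$n_det
}

#' Fan-beam forward projection
#'
#' Length-weighted line integrals along each source-to-channel ray, computed
#' by ray marching with bilinear image sampling (step = half a pixel).
#'
#' @param image A square `image_grid` whose object lies inside the scan FOV.
#' @param geom A [fan_geometry()].
#' @param step Ray sampling step (defaults to half the pixel size).
#' @return A full (untruncated) `sinogram`.
#' @export
forward_project <- function(image, geom, step = image$pixel_size / 2) {
  stopifnot(inherits(image, "image_grid"), inherits(geom, "fan_geometry"))
  if (!is_square(image)) stop("image must be square")
  r_img <- nrow(image$pixels) * image$pixel_size / 2
  dsd <- geom$source_iso + geom$iso_det
  r_fov_full <- geom$source_iso *
    sin(atan(max(abs(geom_det_s(geom))) / dsd))
  if (r_fov_full < 0.7 * r_img)
    stop("geometry does not cover the image")
  vals <- fan_project_cpp(image$pixels, image$pixel_size, geom_betas(geom),
                          geom_det_s(geom), geom$source_iso, dsd, step)
  sinogram(vals, geom)
}

#' Symmetric sinogram truncation
#'
#' Keeps `round((1 - ratio) * n_det)` central channels of the full detector;
#' removed channels are deleted, not zeroed, and the retained range is
#' updated. `ratio` is the total fraction of channels removed.
#'
#' @param sino An untruncated `sinogram`.
#' @param ratio Fraction of channels removed in total, in `[0, 1)`.
#' @return A `sinogram` with a narrowed retained range.
#' @export
truncate_sinogram <- function(sino, ratio) {
  stopifnot(inherits(sino, "sinogram"))
  if (ratio < 0 || ratio >= 1) stop("ratio must be in [0, 1)")
  if (is_truncated(sino)) stop("sinogram is already truncated")
  nd <- sino$geometry$n_det
  n_keep <- round((1 - ratio) * nd)
  if (n_keep < 8) stop("fewer than 8 channels would remain")
  if (n_keep == nd) return(sino)
  first <- floor((nd - n_keep) / 2) + 1L
  last <- first + as.integer(n_keep) - 1L
  sinogram(sino$values[, first:last, drop = FALSE], sino$geometry,
           c(first, last))
}

# Ram-Lak (ramp) filtering of cosine-weighted fan data on the virtual
# detector through the isocenter; returns the filtered view-by-channel
# matrix and the virtual-detector coordinates.
ramp_filter_fan <- function(sino) {
  geom <- sino$geometry
  dsd <- geom$source_iso + geom$iso_det
  s_iso <- sino_det_s(sino) * geom$source_iso / dsd
  ds <- geom$det_pitch * geom$source_iso / dsd
  p1 <- sweep(sino$values, 2,
              geom$source_iso / sqrt(geom$source_iso^2 + s_iso^2), `*`)
  nd <- ncol(p1)
  L <- 2^ceiling(log2(2 * nd))
  h <- numeric(L)
  lag <- c(0:(L / 2), -(L / 2 - 1):-1)
  h[lag == 0] <- 1 / (4 * ds^2)
  odd <- lag %% 2 != 0
  h[odd] <- -1 / (pi^2 * lag[odd]^2 * ds^2)
  Hf <- fft(h)
  P <- matrix(0, L, nrow(p1))
  P[1:nd, ] <- t(p1)
  Q <- Re(mvfft(mvfft(P) * Hf, inverse = TRUE)) / L
  filt <- t(Q[1:nd, , drop = FALSE]) * ds
  list(filt = filt, s_iso = s_iso)
}

# radius of the disk seen by all views through the retained channels
retained_fov_radius <- function(geom, retained) {
  dsd <- geom$source_iso + geom$iso_det
  s <- geom_det_s(geom)[retained]
  geom$source_iso * sin(atan(min(abs(s[1]), abs(s[2])) / dsd))
}

#' Filtered backprojection for fan-beam data
#'
#' Ramp (Ram-Lak) filtering with fan-beam cosine pre-weighting, followed by
#' distance-weighted backprojection with linear interpolation. The output
#' grid is a square of `out_size` pixels covering the retained field-of-view
#' disk (or an explicitly requested radius).
#'
#' @param sino A `sinogram` (possibly truncated).
#' @param out_size Output image side in pixels (>= 16).
#' @param fov_radius Optional physical radius the output grid should span;
#'   defaults to the retained field of view of `sino`.
#' @param value_range Display window recorded on the output image.
#' @return An `image_grid` of side `out_size`.
#' @export
fbp_reconstruct <- function(sino, out_size, fov_radius = NULL,
                            value_range = c(0, 1)) {
  stopifnot(inherits(sino, "sinogram"), out_size >= 16)
  geom <- sino$geometry
  if (is.null(fov_radius))
    fov_radius <- retained_fov_radius(geom, sino$retained)
  rf <- ramp_filter_fan(sino)
  px <- 2 * fov_radius / out_size
  img <- fan_fbp_backproject_cpp(rf$filt, geom_betas(geom), rf$s_iso,
                                 geom$source_iso, as.integer(out_size), px)
  image_grid(img, pixel_size = px, value_range = value_range)
}

#' Simulate a pixel-aligned (artifact, reference) pair
#'
#' `artifact` is the filtered backprojection of the truncated sinogram of
#' the phantom; `reference` is the phantom resampled onto the same grid
#' (same FOV, same size), so the pair is pixel-aligned. The pairing is meant
#' for evaluation; training uses unpaired data.
#'
#' @param phantom An `image_grid` phantom.
#' @param geom A [fan_geometry()].
#' @param ratio Truncation ratio (total fraction of channels removed).
#' @param out_size Output grid side in pixels.
#' @param noise_sd Additive Gaussian noise on the sinogram (0 = none).
#' @param seed Seed for the noise draw.
#' @return List with `artifact` and `reference` image grids.
#' @export
simulate_truncated_pair <- function(phantom, geom, ratio, out_size,
                                    noise_sd = 0, seed = 1L) {
  sino <- forward_project(phantom, geom)
  if (noise_sd > 0) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    sino$values <- sino$values + matrix(rnorm(length(sino$values), 0, noise_sd),
                                        nrow(sino$values))
  }
  sino_t <- truncate_sinogram(sino, ratio)
  artifact <- fbp_reconstruct(sino_t, out_size,
                              value_range = phantom$value_range)
  reference <- resample_to_grid(phantom, out_size, artifact$pixel_size)
  list(artifact = artifact, reference = reference)
}

#' Artifact-free reconstruction restricted to the truncated field of view
#'
#' Reconstructs from the *full* sinogram but on the grid the
#' `ratio`-truncated acquisition would cover, producing the artifact-free
#' domain images for unpaired training.
#'
#' @inheritParams simulate_truncated_pair
#' @return An `image_grid`.
#' @export
clean_reconstruction <- function(phantom, geom, ratio, out_size,
                                 noise_sd = 0, seed = 1L) {
  sino <- forward_project(phantom, geom)
  if (noise_sd > 0) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    sino$values <- sino$values + matrix(rnorm(length(sino$values), 0, noise_sd),
                                        nrow(sino$values))
  }
  nd <- geom$n_det
  n_keep <- round((1 - ratio) * nd)
  first <- floor((nd - n_keep) / 2) + 1L
  r_fov <- retained_fov_radius(geom, c(first, first + as.integer(n_keep) - 1L))
  fbp_reconstruct(sino, out_size, fov_radius = r_fov,
                  value_range = phantom$value_range)
}

#' Write / read a sinogram as TSV plus a JSON geometry sidecar
#' @param sino A `sinogram`.
#' @param path Output `.tsv` path.
#' @return `write_sinogram` returns `path`; `read_sinogram` the sinogram.
#' @export
write_sinogram <- function(sino, path) {
  data.table::fwrite(data.table::as.data.table(sino$values), path,
                     sep = "\t", col.names = FALSE)
  jsonlite::write_json(list(geometry = unclass(sino$geometry),
                            retained = sino$retained),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  v <- as.matrix(data.table::fread(path, sep = "\t", header = FALSE))
  dimnames(v) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  g <- do.call(fan_geometry, meta$geometry[c("n_views", "source_iso",
                                             "iso_det", "n_det", "det_pitch",
                                             "angle_start")])
  sinogram(v, g, meta$retained)
}
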