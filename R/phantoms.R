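#' Specification of a random ellipse phantom
#'
#' Describes a seeded, anatomy-like test object: one smooth outer body
#' ellipse of positive attenuation containing `n_inclusions` random interior
#' ellipses. Piecewise-constant objects match the assumption behind the
#' total-variation baseline; a light Gaussian blur (sigma = 0.5 px) keeps
#' projections band-limited.
#'
#' @param seed Integer seed; the phantom is a pure function of it.
#' @param size Pixels per side (>= 16).
#' @param n_inclusions Number of interior ellipses (>= 0).
#' @param body_axes Length-2 relative semi-axes of the body ellipse, as a
#'   fraction of the maximal in-grid radius.
#' @param contrast_range Ordered `c(min, max)` magnitude of inclusion
#'   contrast relative to the body value.
#' @param body_value Attenuation of the body ellipse.
#' @param hi Upper clip for pixel values (display window top).
#' @param smooth_sigma Gaussian blur sigma in pixels (0 disables).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(seed = 1L, size = 128L, n_inclusions = 5L,
                         body_axes = c(0.9, 0.75),
                         contrast_range = c(0.1, 0.6),
                         body_value = 0.3, hi = 1, smooth_sigma = 0.5) {
  stopifnot(size >= 16, n_inclusions >= 0, length(body_axes) == 2)
  if (!all(is.finite(contrast_range)) || contrast_range[1] > contrast_range[2])
    stop("contrast_range must be finite and ordered")
  structure(list(seed = as.integer(seed), size = as.integer(size),
                 n_inclusions = as.integer(n_inclusions),
                 body_axes = body_axes, contrast_range = contrast_range,
                 body_value = body_value, hi = hi,
                 smooth_sigma = smooth_sigma),
            class = "phantom_spec")
}

# separable Gaussian blur with reflected edges
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2)); k <- k / sum(k)
  pad_idx <- function(n) c(pmin(pmax(1, r:1), n), 1:n, pmax(pmin(n, n - 0:(r - 1)), 1))
  conv1 <- function(x) as.vector(stats::filter(x, k, sides = 2))[(r + 1):(length(x) - r)]
  H <- nrow(m); W <- ncol(m)
  m2 <- apply(m[pad_idx(H), , drop = FALSE], 2, conv1)
  t(apply(t(m2)[pad_idx(W), , drop = FALSE], 2, conv1))
}

#' Generate a random ellipse phantom
#'
#' Deterministic given the spec's seed. The outer body ellipse is kept fully
#' inside the grid with a margin of at least 5% of the side; inclusions are
#' clipped to the body; pixel values are clipped to `[0, hi]`.
#'
#' @param spec A [phantom_spec()].
#' @return An `image_grid` with `pixel_size = 1` and
#'   `value_range = c(0, spec$hi)`.
#' @export
make_ellipse_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$size
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  ctr <- (n + 1) / 2
  rmax <- (n - 1) / 2 * 0.95          # 5% margin to the grid edge
  X <- matrix(seq_len(n) - ctr, n, n, byrow = TRUE)
  Y <- matrix(seq_len(n) - ctr, n, n)

  theta0 <- runif(1, 0, pi)
  a0 <- spec$body_axes[1] * rmax
  b0 <- spec$body_axes[2] * rmax
  inside_ellipse <- function(cx, cy, a, b, th) {
    xr <- (X - cx) * cos(th) + (Y - cy) * sin(th)
    yr <- -(X - cx) * sin(th) + (Y - cy) * cos(th)
    (xr / a)^2 + (yr / b)^2 <= 1
  }
  body <- inside_ellipse(0, 0, a0, b0, theta0)
  img <- ifelse(body, spec$body_value, 0)

  if (spec$n_inclusions > 0) {
    for (k in seq_len(spec$n_inclusions)) {
      # centre inside the body, semi-axes a modest fraction of the body axes
      repeat {
        cx <- runif(1, -0.7 * a0, 0.7 * a0)
        cy <- runif(1, -0.7 * b0, 0.7 * b0)
        if ((cx / a0)^2 + (cy / b0)^2 <= 0.7^2) break
      }
      a <- runif(1, 0.08, 0.35) * a0
      b <- runif(1, 0.08, 0.35) * b0
      th <- runif(1, 0, pi)
      contrast <- runif(1, spec$contrast_range[1], spec$contrast_range[2]) *
        spec$body_value * sample(c(-1, 1), 1)
      sel <- inside_ellipse(cx, cy, a, b, th) & body
      img[sel] <- img[sel] + contrast
    }
  }
  img <- pmin(pmax(img, 0), spec$hi)
  img <- gauss_blur(img, spec$smooth_sigma)
  img[!body] <- 0                      # exterior stays exactly zero
  img <- pmin(pmax(img, 0), spec$hi)
  image_grid(img, pixel_size = 1, value_range = c(0, spec$hi))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Build an unpaired artifact/clean dataset on disk
#'
#' Emulates the unpaired training regime: artifact-affected training images
#' and artifact-free training images are generated from *disjoint* phantom
#' seeds, so the train split carries no cross-domain pairing information.
#' Test entries keep their same-phantom ground-truth reference for
#' evaluation only. Artifact images are filtered backprojections of
#' symmetrically truncated fan-beam sinograms; clean images are filtered
#' backprojections of the full sinograms of *other* phantoms, restricted to
#' the same field of view; references are the phantoms resampled onto the
#' reconstruction grid.
#'
#' @param n_train,n_test Number of phantoms per role (>= 1).
#' @param spec_template A [phantom_spec()] whose seed is ignored; per-image
#'   seeds are derived from `seed`.
#' @param geometry A [fan_geometry()] or NULL for defaults matched to
#'   `spec_template$size`.
#' @param ratio Total fraction of detector channels removed by truncation.
#' @param out_dir Output directory (created).
#' @param out_size Reconstruction grid side (default `spec_template$size`).
#' @param seed Base seed from which all per-image seeds derive.
#' @param noise_sd Optional additive Gaussian noise on sinograms (0 = none).
#' @return A `dataset_manifest` (also written to `out_dir/manifest.json`).
#' @export
build_unpaired_dataset <- function(n_train, n_test, spec_template,
                                   geometry = NULL, ratio = 0.3,
                                   out_dir, out_size = spec_template$size,
                                   seed = 1L, noise_sd = 0) {
  stopifnot(n_train >= 1, n_test >= 1, inherits(spec_template, "phantom_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(geometry)) geometry <- default_fan_geometry(spec_template$size)

  # disjoint seed blocks per role, all derived from the base seed
  base <- as.integer(seed) * 1000L
  seeds_art   <- base + seq_len(n_train)
  seeds_clean <- base + 500000L + seq_len(n_train)
  seeds_test  <- base + 900000L + seq_len(n_test)

  entries <- list()
  add <- function(id, role, file, sd, split) {
    entries[[length(entries) + 1L]] <<- list(id = id, role = role,
                                             file = file, seed = sd,
                                             split = split)
  }
  gen <- function(sd) {
    sp <- spec_template; sp$seed <- as.integer(sd)
    make_ellipse_phantom(sp)
  }

  for (i in seq_len(n_train)) {
    ph <- gen(seeds_art[i])
    pr <- simulate_truncated_pair(ph, geometry, ratio, out_size,
                                  noise_sd = noise_sd, seed = seeds_art[i])
    f <- sprintf("train_artifact_%03d.tsv", i)
    write_image(pr$artifact, file.path(out_dir, f))
    add(sprintf("tr_art_%03d", i), "artifact", f, seeds_art[i], "train")
  }
  for (i in seq_len(n_train)) {
    ph <- gen(seeds_clean[i])
    cl <- clean_reconstruction(ph, geometry, ratio, out_size,
                               noise_sd = noise_sd, seed = seeds_clean[i])
    f <- sprintf("train_clean_%03d.tsv", i)
    write_image(cl, file.path(out_dir, f))
    add(sprintf("tr_cln_%03d", i), "clean", f, seeds_clean[i], "train")
  }
  for (i in seq_len(n_test)) {
    ph <- gen(seeds_test[i])
    pr <- simulate_truncated_pair(ph, geometry, ratio, out_size,
                                  noise_sd = noise_sd, seed = seeds_test[i])
    fa <- sprintf("test_artifact_%03d.tsv", i)
    fr <- sprintf("test_reference_%03d.tsv", i)
    write_image(pr$artifact, file.path(out_dir, fa))
    write_image(pr$reference, file.path(out_dir, fr))
    add(sprintf("te_%03d", i), "artifact", fa, seeds_test[i], "test")
    add(sprintf("te_%03d", i), "reference", fr, seeds_test[i], "test")
  }

  manifest <- structure(list(root = normalizePath(out_dir),
                             entries = entries,
                             geometry = unclass(geometry), ratio = ratio,
                             out_size = out_size, seed = as.integer(seed),
                             noise_sd = noise_sd,
                             spec_template = unclass(spec_template)),
                        class = "dataset_manifest")
  jsonlite::write_json(unclass(manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}

#' Read a dataset manifest written by [build_unpaired_dataset()]
#' @param dir Dataset directory containing `manifest.json`.
#' @return A `dataset_manifest`.
#' @export
read_manifest <- function(dir) {
  m <- jsonlite::read_json(file.path(dir, "manifest.json"),
                           simplifyVector = FALSE)
  m$root <- normalizePath(dir)
  m$ratio <- as.numeric(m$ratio); m$out_size <- as.integer(m$out_size)
  structure(m, class = "dataset_manifest")
}

#' Select manifest entries by role and split
#' @param manifest A `dataset_manifest`.
#' @param role One of `"artifact"`, `"clean"`, `"reference"`.
#' @param split `"train"` or `"test"`.
#' @return List of entries.
#' @export
manifest_entries <- function(manifest, role, split) {
  Filter(function(e) e$role == role && e$split == split, manifest$entries)
}
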