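as_tensor <- function(x) {
  if (inherits(x, "polar_image")) x <- x$values
  if (inherits(x, "image_grid")) x <- x$pixels
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  x
}

as_plane <- function(x) matrix(x, dim(x)[1], dim(x)[2])

#' Build the implicit disentanglement model
#'
#' One shared encoder maps inputs to a latent feature space in which
#' content and artifact features are separable but never dimension-
#' partitioned; decoder `G` extracts only content features (artifact
#' removal), decoder `Gt` decodes all features (reconstruction / artifact
#' synthesis); two patch discriminators judge artifact-free and
#' artifact-affected images respectively. Weight initialization is seeded
#' normal(0, 0.02).
#'
#' @param cfg A [net_config()].
#' @param use_polar If TRUE the networks operate on polar rasters and use
#'   circular padding along the angular axis (reflective along radius);
#'   otherwise reflective padding on both axes.
#' @return An object of class `disentangle_model`.
#' @export
build_model <- function(cfg = net_config(), use_polar = TRUE) {
  stopifnot(inherits(cfg, "net_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  bc <- cfg$base_channels
  m <- list(
    encoder = build_net(encoder_spec(bc), cfg$init_sd),
    dec_content = build_net(decoder_spec(bc), cfg$init_sd),
    dec_full = build_net(decoder_spec(bc), cfg$init_sd),
    disc_D = build_net(discriminator_spec(bc), cfg$init_sd),
    disc_Dt = build_net(discriminator_spec(bc), cfg$init_sd),
    cfg = cfg,
    mode_r = if (use_polar) "circular" else "reflect",
    mode_c = "reflect",
    use_polar = use_polar)
  class(m) <- "disentangle_model"
  m
}

#' @export
print.disentangle_model <- function(x, ...) {
  cat(sprintf(paste0("<disentangle_model base_channels %d, %s padding, ",
                     "%d generator + %d discriminator parameters>\n"),
              x$cfg$base_channels,
              if (x$use_polar) "polar (circular-angle)" else "Cartesian",
              n_params(x$encoder) + n_params(x$dec_content) +
                n_params(x$dec_full),
              n_params(x$disc_D) + n_params(x$disc_Dt)))
  invisible(x)
}

check_divisible <- function(x) {
  d <- dim(x)
  if (d[1] %% 8 != 0 || d[2] %% 8 != 0)
    stop("spatial dimensions must be divisible by 8 (three stride-2 stages)")
}

#' Encode an image into the shared latent space
#'
#' @param model A [build_model()] result.
#' @param x Matrix, `polar_image` or H x W x 1 array with both spatial
#'   dimensions divisible by 8, values in the normalized window `[-1, 1]`.
#' @param want_cache Internal: also return the activation cache.
#' @return Latent feature array of dim `c(H/8, W/8, 4 * base_channels)`.
#' @export
encode <- function(model, x, want_cache = FALSE) {
  x <- as_tensor(x); check_divisible(x)
  r <- net_forward(model$encoder, x, model$mode_r, model$mode_c)
  if (want_cache) r else r$y
}

#' Decode content features into an artifact-free image (decoder G)
#'
#' @param model The model.
#' @param l Latent feature array.
#' @param want_cache Internal: also return the activation cache.
#' @return Matrix of size `8 * dim(l)[1:2]`, values in `(-1, 1)`.
#' @export
decode_content <- function(model, l, want_cache = FALSE) {
  r <- net_forward(model$dec_content, l, model$mode_r, model$mode_c)
  if (want_cache) r else as_plane(r$y)
}

#' Decode all (content + artifact) features (decoder Gt)
#'
#' @inheritParams decode_content
#' @return Matrix of size `8 * dim(l)[1:2]`, values in `(-1, 1)`.
#' @export
decode_full <- function(model, l, want_cache = FALSE) {
  r <- net_forward(model$dec_full, l, model$mode_r, model$mode_c)
  if (want_cache) r else as_plane(r$y)
}

#' Separate the artifact features by a short connection
#'
#' `t_I = l_I - encode(I_hat_p)`: what the full encoding carries beyond the
#' encoding of the artifact-removed image is, by construction, the artifact
#' part of the latent code.
#'
#' @param model The model.
#' @param l_I Latent encoding of the artifact-affected input.
#' @param I_hat_p The artifact-removed image `decode_content(l_I)`.
#' @return Latent-shaped artifact code `t_I`.
#' @export
extract_artifact_code <- function(model, l_I, I_hat_p) {
  lh <- encode(model, I_hat_p)
  if (!all(dim(lh) == dim(l_I))) stop("latent shape mismatch")
  l_I - lh
}

#' Synthesize an artifact-affected image from an artifact code
#'
#' `J_hat_pt = decode_full(t_I + l_J)`: pairs the artifact features pulled
#' from one image with the content features of another, producing the
#' synthetic paired data that substitutes for supervision.
#'
#' @param model The model.
#' @param t_I Artifact code from [extract_artifact_code()].
#' @param l_J Latent encoding of an artifact-free image.
#' @return Matrix with simulated truncation artifacts.
#' @export
synthesize_artifacted <- function(model, t_I, l_J) {
  if (!all(dim(t_I) == dim(l_J))) stop("latent shape mismatch")
  decode_full(model, t_I + l_J)
}

#' Patch discriminator scores
#'
#' Four stride-2 convolutions plus a scoring convolution give one raw
#' score per (roughly 70x70-input) patch; spatial score-map size is the
#' input size divided by 16.
#'
#' @param model The model.
#' @param x Image matrix / array in the normalized window.
#' @param which `"D"` (artifact-free judge) or `"Dt"` (artifact judge).
#' @param want_cache Internal: also return the activation cache.
#' @return Score-map matrix.
#' @export
discriminate <- function(model, x, which = c("D", "Dt"),
                         want_cache = FALSE) {
  which <- match.arg(which)
  net <- if (which == "D") model$disc_D else model$disc_Dt
  r <- net_forward(net, as_tensor(x), model$mode_r, model$mode_c)
  if (want_cache) r else as_plane(r$y)
}

#' One full training pass through the cycle
#'
#' Populates every image and latent the objectives need, using the shared
#' encoder for all four encodings:
#' `l_I = E(I_pt)`, `I_hat_p = G(l_I)`, `t_I = l_I - E(I_hat_p)`,
#' `I_tilde_pt = Gt(l_I)`, `l_J = E(J_p)`, `J_tilde_p = G(l_J)`,
#' `J_hat_pt = Gt(t_I + l_J)`, `J_hat_p = G(E(J_hat_pt))`.
#'
#' @param model The model.
#' @param I_pt Artifact-affected input (matrix, normalized window).
#' @param J_p Artifact-free input of the same shape.
#' @param want_cache Internal: keep activation caches for backprop.
#' @return A `cycle_bundle` list with all images (matrices), latents, and
#'   (optionally) caches.
#' @export
forward_cycle <- function(model, I_pt, J_p, want_cache = FALSE) {
  I_pt <- as_plane(as_tensor(I_pt)); J_p <- as_plane(as_tensor(J_p))
  if (!all(dim(I_pt) == dim(J_p))) stop("inputs must share the polar grid")
  eI  <- encode(model, I_pt, want_cache = TRUE)
  gI  <- decode_content(model, eI$y, want_cache = TRUE)
  I_hat_p <- as_plane(gI$y)
  eIh <- encode(model, I_hat_p, want_cache = TRUE)
  t_I <- eI$y - eIh$y
  gtI <- decode_full(model, eI$y, want_cache = TRUE)
  eJ  <- encode(model, J_p, want_cache = TRUE)
  gJ  <- decode_content(model, eJ$y, want_cache = TRUE)
  gtJ <- decode_full(model, t_I + eJ$y, want_cache = TRUE)
  J_hat_pt <- as_plane(gtJ$y)
  eJh <- encode(model, J_hat_pt, want_cache = TRUE)
  gJh <- decode_content(model, eJh$y, want_cache = TRUE)
  b <- list(I_pt = I_pt, J_p = J_p,
            I_hat_p = I_hat_p, I_tilde_pt = as_plane(gtI$y),
            J_tilde_p = as_plane(gJ$y), t_I = t_I,
            J_hat_pt = J_hat_pt, J_hat_p = as_plane(gJh$y),
            l_I = eI$y, l_J = eJ$y, l_Ihat = eIh$y, l_Jhat = eJh$y)
  if (want_cache)
    b$caches <- list(eI = eI$caches, gI = gI$caches, eIh = eIh$caches,
                     gtI = gtI$caches, eJ = eJ$caches, gJ = gJ$caches,
                     gtJ = gtJ$caches, eJh = eJh$caches, gJh = gJh$caches)
  class(b) <- "cycle_bundle"
  b
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single-file archive holding all network weights, the
#' architecture config, the normalization window and every seed needed to
#' reproduce the run.
#'
#' @param model The model.
#' @param path Output file path.
#' @param window Length-2 normalization window mapped to `[-1, 1]`.
#' @param extra Optional named list stored alongside (train config, log).
#' @return `save_checkpoint` returns `path`; `load_checkpoint` a list with
#'   `model`, `window` and `extra`.
#' @export
save_checkpoint <- function(model, path, window = c(0, 1), extra = list()) {
  saveRDS(list(model = model, window = window, extra = extra,
               format = "detrunc-ckpt-1"), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "detrunc-ckpt-1")) stop("not a model checkpoint")
  ck
}
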