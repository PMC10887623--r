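#' Training configuration
#'
#' Defaults follow the published protocol where stated (Adam, learning rate
#' 1e-4; loss weights adv 1, art 5, rec 5, cycle 10, tv 100) and GAN
#' convention elsewhere (Adam moments 0.5/0.999, 1:1 discriminator-to-
#' generator updates, least-squares adversarial form).
#'
#' @param iterations Number of training iterations (one D step + one G step
#'   each).
#' @param lr Learning rate for all Adam optimizers.
#' @param betas Adam moment parameters.
#' @param batch_size Independent unpaired draws per iteration.
#' @param seed Master seed (weights, sampling).
#' @param weights A [loss_weights()].
#' @param net A [net_config()].
#' @param adv_form `"lsgan"` or `"bce"`.
#' @param use_polar Train on polar rasters (TRUE) or raw Cartesian images.
#' @param n_phi,n_rho Polar grid size; `NULL` derives `n_rho` from the
#'   image size (`size/2` rounded down to a multiple of 8).
#' @param log_every Record losses every this many iterations.
#' @param enabled Named logical vector toggling loss components
#'   (`rec`, `art`, `cycle`, `tv`); used by [ablation_variant()].
#' @return An object of class `train_config`.
#' @export
train_config <- function(iterations = 2000, lr = 1e-4,
                         betas = c(0.5, 0.999), batch_size = 4, seed = 1L,
                         weights = loss_weights(), net = net_config(),
                         adv_form = c("lsgan", "bce"), use_polar = TRUE,
                         n_phi = 360L, n_rho = NULL, log_every = 10L,
                         enabled = c(rec = TRUE, art = TRUE, cycle = TRUE,
                                     tv = TRUE)) {
  stopifnot(lr > 0, iterations >= 1, batch_size >= 1)
  adv_form <- match.arg(adv_form)
  structure(list(iterations = as.integer(iterations), lr = lr,
                 betas = betas, batch_size = as.integer(batch_size),
                 seed = as.integer(seed), weights = weights, net = net,
                 adv_form = adv_form, use_polar = use_polar,
                 n_phi = n_phi, n_rho = n_rho,
                 log_every = as.integer(log_every), enabled = enabled),
            class = "train_config")
}

#' Ablation variants of the training configuration
#'
#' Reproduces the component-wise build-up of the method: Var1 trains with
#' the adversarial losses only; Var2 adds self-reconstruction; Var3 adds
#' artifact consistency; Var4 adds cycle consistency; Var5 moves training
#' from Cartesian to polar rasters; Var6 (the full method) adds the
#' horizontal TV constraint. Var1-Var4 bypass the polar transform.
#'
#' @param cfg Base [train_config()] (its weights are used for the enabled
#'   components).
#' @param name One of `"Var1"` ... `"Var6"`.
#' @return A modified `train_config`.
#' @export
ablation_variant <- function(cfg, name) {
  stopifnot(inherits(cfg, "train_config"))
  variants <- list(
    Var1 = list(enabled = c(rec = FALSE, art = FALSE, cycle = FALSE, tv = FALSE), polar = FALSE),
    Var2 = list(enabled = c(rec = TRUE, art = FALSE, cycle = FALSE, tv = FALSE), polar = FALSE),
    Var3 = list(enabled = c(rec = TRUE, art = TRUE, cycle = FALSE, tv = FALSE), polar = FALSE),
    Var4 = list(enabled = c(rec = TRUE, art = TRUE, cycle = TRUE, tv = FALSE), polar = FALSE),
    Var5 = list(enabled = c(rec = TRUE, art = TRUE, cycle = TRUE, tv = FALSE), polar = TRUE),
    Var6 = list(enabled = c(rec = TRUE, art = TRUE, cycle = TRUE, tv = TRUE), polar = TRUE))
  if (!name %in% names(variants)) stop("unknown variant: ", name)
  v <- variants[[name]]
  cfg$enabled <- v$enabled
  cfg$use_polar <- v$polar
  cfg
}

effective_weights <- function(cfg) {
  w <- cfg$weights
  for (nm in names(cfg$enabled)) if (!cfg$enabled[[nm]]) w[[nm]] <- 0
  w
}

# sign(a)/length(a): gradient of mean(|a|)
signgrad <- function(a) sign(a) / length(a)

gan_gen_score_grad <- function(s, form) {
  if (form == "lsgan") 2 * (s - 1) / length(s)
  else -1 / (1 + exp(s)) / length(s)          # d/ds mean(softplus(-s))
}

gan_disc_score_grads <- function(real, fake, form) {
  if (form == "lsgan")
    list(real = 2 * (real - 1) / length(real), fake = 2 * fake / length(fake))
  else
    list(real = -1 / (1 + exp(real)) / length(real),
         fake = 1 / (1 + exp(-fake)) / length(fake))
}

tv_horizontal_grad <- function(u) {
  W <- ncol(u)
  d <- u[, -1, drop = FALSE] - u[, -W, drop = FALSE]
  D <- 2 * d / (nrow(u) * (W - 1))
  g <- matrix(0, nrow(u), W)
  g[, 1] <- -D[, 1]
  if (W > 2) g[, 2:(W - 1)] <- D[, 1:(W - 2), drop = FALSE] - D[, 2:(W - 1), drop = FALSE]
  g[, W] <- D[, W - 1]
  g
}

as3 <- function(m) array(m, c(dim(m), 1L))

adam_init <- function(net) {
  lapply(net$layers, function(l) lapply(l$par, function(p) {
    z <- p; z[] <- 0; list(m = z, v = z)
  }))
}

adam_step <- function(net, grads, state, lr, b1, b2, t, eps = 1e-8) {
  bc1 <- 1 - b1^t; bc2 <- 1 - b2^t
  for (i in seq_along(net$layers)) {
    for (nm in names(net$layers[[i]]$par)) {
      g <- grads[[i]][[nm]]
      st <- state[[i]][[nm]]
      st$m <- b1 * st$m + (1 - b1) * g
      st$v <- b2 * st$v + (1 - b2) * g^2
      state[[i]][[nm]] <- st
      net$layers[[i]]$par[[nm]] <- net$layers[[i]]$par[[nm]] -
        lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
    }
  }
  list(net = net, state = state)
}

# one generator update on one unpaired image pair; returns loss terms and
# gradient structures for encoder, dec_content, dec_full. A precomputed
# cycle bundle (with caches) may be passed to avoid repeating the forward.
generator_pass <- function(model, I_pt, J_p, w, form, bundle = NULL) {
  b <- if (is.null(bundle)) forward_cycle(model, I_pt, J_p, want_cache = TRUE)
       else bundle
  N <- length(b$I_pt)
  mr <- model$mode_r; mc <- model$mode_c

  sD <- discriminate(model, b$I_hat_p, "D", want_cache = TRUE)
  sDt <- discriminate(model, b$J_hat_pt, "Dt", want_cache = TRUE)

  terms <- list(
    adv_D = gan_loss_gen(sD$y, form),
    adv_Dt = gan_loss_gen(sDt$y, form),
    rec = reconstruction_loss(b),
    art = artifact_consistency_loss(b),
    cycle = cycle_loss(b),
    tv = tv_horizontal_loss(b$I_pt, b$I_hat_p))

  gE <- NULL; gG <- NULL; gGt <- NULL
  art_resid <- (b$I_pt - b$I_hat_p) - (b$J_hat_pt - b$J_p)

  # cycle: J_hat_p -> G -> E -> J_hat_pt
  g_Jhat_pt <- matrix(0, nrow(b$I_pt), ncol(b$I_pt))
  if (w$cycle > 0) {
    r <- net_backward(model$dec_content, b$caches$gJh,
                      as3(w$cycle * signgrad(b$J_hat_p - b$J_p)), mr, mc)
    gG <- grads_add(gG, r$grads)
    r2 <- net_backward(model$encoder, b$caches$eJh, r$gx, mr, mc)
    gE <- grads_add(gE, r2$grads)
    g_Jhat_pt <- g_Jhat_pt + as_plane(r2$gx)
  }
  # artifact consistency: d/dJ_hat_pt mean|(I - Ihat) - (Jhat_pt - J)|
  if (w$art > 0)
    g_Jhat_pt <- g_Jhat_pt - w$art * signgrad(art_resid)
  # adversarial on the synthesized artifact image
  if (w$adv > 0) {
    rD <- net_backward(model$disc_Dt, sDt$caches,
                       array(w$adv * gan_gen_score_grad(sDt$y, form),
                             dim(sDt$y)), mr, mc)
    g_Jhat_pt <- g_Jhat_pt + as_plane(rD$gx)
  }

  # J_hat_pt = Gt(t_I + l_J)
  r <- net_backward(model$dec_full, b$caches$gtJ, as3(g_Jhat_pt), mr, mc)
  gGt <- grads_add(gGt, r$grads)
  g_tI <- r$gx
  g_lJ <- r$gx

  # self-reconstruction of J through G
  if (w$rec > 0) {
    r <- net_backward(model$dec_content, b$caches$gJ,
                      as3(w$rec * signgrad(b$J_tilde_p - b$J_p)), mr, mc)
    gG <- grads_add(gG, r$grads)
    g_lJ <- g_lJ + r$gx
  }
  r <- net_backward(model$encoder, b$caches$eJ, g_lJ, mr, mc)
  gE <- grads_add(gE, r$grads)

  # self-reconstruction of I through Gt
  g_lI <- array(0, dim(b$l_I))
  if (w$rec > 0) {
    r <- net_backward(model$dec_full, b$caches$gtI,
                      as3(w$rec * signgrad(b$I_tilde_pt - b$I_pt)), mr, mc)
    gGt <- grads_add(gGt, r$grads)
    g_lI <- g_lI + r$gx
  }

  # t_I = l_I - E(I_hat_p): split the artifact-code gradient
  g_lI <- g_lI + g_tI
  r <- net_backward(model$encoder, b$caches$eIh, -g_tI, mr, mc)
  gE <- grads_add(gE, r$grads)
  g_Ihat <- as_plane(r$gx)

  if (w$art > 0) g_Ihat <- g_Ihat - w$art * signgrad(art_resid)
  if (w$tv > 0)
    g_Ihat <- g_Ihat - w$tv * tv_horizontal_grad(b$I_pt - b$I_hat_p)
  if (w$adv > 0) {
    rD <- net_backward(model$disc_D, sD$caches,
                       array(w$adv * gan_gen_score_grad(sD$y, form),
                             dim(sD$y)), mr, mc)
    g_Ihat <- g_Ihat + as_plane(rD$gx)
  }

  r <- net_backward(model$dec_content, b$caches$gI, as3(g_Ihat), mr, mc)
  gG <- grads_add(gG, r$grads)
  g_lI <- g_lI + r$gx
  r <- net_backward(model$encoder, b$caches$eI, g_lI, mr, mc)
  gE <- grads_add(gE, r$grads)

  list(terms = terms, gE = gE, gG = gG, gGt = gGt, bundle = b)
}

# one discriminator update on the (detached) fakes of a bundle
discriminator_pass <- function(model, I_pt, J_p, I_hat_p, J_hat_pt, form) {
  mr <- model$mode_r; mc <- model$mode_c
  sDr <- discriminate(model, J_p, "D", want_cache = TRUE)
  sDf <- discriminate(model, I_hat_p, "D", want_cache = TRUE)
  sDtr <- discriminate(model, I_pt, "Dt", want_cache = TRUE)
  sDtf <- discriminate(model, J_hat_pt, "Dt", want_cache = TRUE)
  gD1 <- gan_disc_score_grads(sDr$y, sDf$y, form)
  gD2 <- gan_disc_score_grads(sDtr$y, sDtf$y, form)
  gD <- grads_add(
    net_backward(model$disc_D, sDr$caches, array(gD1$real, dim(sDr$y)), mr, mc)$grads,
    net_backward(model$disc_D, sDf$caches, array(gD1$fake, dim(sDf$y)), mr, mc)$grads)
  gDt <- grads_add(
    net_backward(model$disc_Dt, sDtr$caches, array(gD2$real, dim(sDtr$y)), mr, mc)$grads,
    net_backward(model$disc_Dt, sDtf$caches, array(gD2$fake, dim(sDtf$y)), mr, mc)$grads)
  list(loss_D = gan_loss_disc(sDr$y, sDf$y, form),
       loss_Dt = gan_loss_disc(sDtr$y, sDtf$y, form),
       gD = gD, gDt = gDt)
}

normalize_window <- function(imgs, probs = c(0.005, 0.995)) {
  as.numeric(quantile(unlist(lapply(imgs, function(m) as.vector(m))), probs))
}

norm_to_window <- function(m, win) 2 * (m - win[1]) / (win[2] - win[1]) - 1
denorm_from_window <- function(m, win) (m + 1) / 2 * (win[2] - win[1]) + win[1]

prep_input <- function(img, cfg, win) {
  m <- if (cfg$use_polar) {
    size <- nrow(img$pixels)
    n_rho <- if (is.null(cfg$n_rho)) max(16L, (size %/% 2) %/% 8 * 8) else cfg$n_rho
    to_polar(img, n_rho = n_rho, n_phi = cfg$n_phi)$values
  } else img$pixels
  norm_to_window(m, win)
}

#' Train the artifact-removal model on an unpaired dataset
#'
#' Alternating optimization: one discriminator step (both judges) then one
#' generator step (shared encoder and both decoders) per iteration, with
#' independent unpaired draws from the artifact and clean training domains.
#' Training aborts with an error if any loss becomes non-finite.
#'
#' @param manifest A `dataset_manifest` from [build_unpaired_dataset()] or
#'   [read_manifest()].
#' @param cfg A [train_config()].
#' @param out_dir Optional run directory for the checkpoint and the
#'   per-iteration loss log (JSONL).
#' @param verbose Print progress every few hundred iterations.
#' @return List with `checkpoint` (model, window, config) and `log`
#'   (data.frame of loss terms).
#' @export
train <- function(manifest, cfg = train_config(), out_dir = NULL,
                  verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"))
  arts <- manifest_entries(manifest, "artifact", "train")
  clns <- manifest_entries(manifest, "clean", "train")
  if (length(arts) == 0 || length(clns) == 0)
    stop("manifest must contain both training domains")

  art_imgs <- lapply(arts, function(e) read_image(file.path(manifest$root, e$file)))
  cln_imgs <- lapply(clns, function(e) read_image(file.path(manifest$root, e$file)))
  win <- normalize_window(c(lapply(art_imgs, `[[`, "pixels"),
                            lapply(cln_imgs, `[[`, "pixels")))

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  net_cfg <- cfg$net; net_cfg$seed <- cfg$seed
  model <- build_model(net_cfg, use_polar = cfg$use_polar)
  set.seed(cfg$seed + 1L)

  art_t <- lapply(art_imgs, prep_input, cfg = cfg, win = win)
  cln_t <- lapply(cln_imgs, prep_input, cfg = cfg, win = win)
  d <- dim(art_t[[1]])
  if (any(d %% 8 != 0) || any(d < 32))
    stop("network inputs must have dimensions >= 32 and divisible by 8; ",
         "got ", d[1], "x", d[2], " (adjust n_phi/n_rho or image size)")

  w <- effective_weights(cfg)
  stateE <- adam_init(model$encoder); stateG <- adam_init(model$dec_content)
  stateGt <- adam_init(model$dec_full)
  stateD <- adam_init(model$disc_D); stateDt <- adam_init(model$disc_Dt)
  b1 <- cfg$betas[1]; b2 <- cfg$betas[2]
  log_rows <- list()

  for (it in seq_len(cfg$iterations)) {
    ia <- sample.int(length(art_t), cfg$batch_size, replace = TRUE)
    ic <- sample.int(length(cln_t), cfg$batch_size, replace = TRUE)

    # ---- shared forward, then discriminator step (fakes detached) ----
    gD <- NULL; gDt <- NULL; lD <- 0; lDt <- 0
    bundles <- vector("list", cfg$batch_size)
    for (k in seq_len(cfg$batch_size)) {
      bnd <- forward_cycle(model, art_t[[ia[k]]], cln_t[[ic[k]]],
                           want_cache = TRUE)
      bundles[[k]] <- bnd
      dp <- discriminator_pass(model, bnd$I_pt, bnd$J_p, bnd$I_hat_p,
                               bnd$J_hat_pt, cfg$adv_form)
      gD <- grads_add(gD, dp$gD); gDt <- grads_add(gDt, dp$gDt)
      lD <- lD + dp$loss_D; lDt <- lDt + dp$loss_Dt
    }
    sc <- 1 / cfg$batch_size
    r <- adam_step(model$disc_D, grads_scale(gD, sc), stateD, cfg$lr, b1, b2, it)
    model$disc_D <- r$net; stateD <- r$state
    r <- adam_step(model$disc_Dt, grads_scale(gDt, sc), stateDt, cfg$lr, b1, b2, it)
    model$disc_Dt <- r$net; stateDt <- r$state

    # ---- generator step (updated discriminators, frozen during G) ----
    gE <- NULL; gG <- NULL; gGt <- NULL
    terms_acc <- NULL
    for (k in seq_len(cfg$batch_size)) {
      gp <- generator_pass(model, art_t[[ia[k]]], cln_t[[ic[k]]], w,
                           cfg$adv_form, bundle = bundles[[k]])
      bundles[[k]] <- NULL
      gE <- grads_add(gE, gp$gE); gG <- grads_add(gG, gp$gG)
      gGt <- grads_add(gGt, gp$gGt)
      tt <- unlist(gp$terms)
      terms_acc <- if (is.null(terms_acc)) tt else terms_acc + tt
    }
    terms_acc <- terms_acc / cfg$batch_size
    rep <- total_objective(as.list(terms_acc)[c("adv_D", "adv_Dt", "rec",
                                                "art", "cycle", "tv")], w)
    r <- adam_step(model$encoder, grads_scale(gE, sc), stateE, cfg$lr, b1, b2, it)
    model$encoder <- r$net; stateE <- r$state
    r <- adam_step(model$dec_content, grads_scale(gG, sc), stateG, cfg$lr, b1, b2, it)
    model$dec_content <- r$net; stateG <- r$state
    r <- adam_step(model$dec_full, grads_scale(gGt, sc), stateGt, cfg$lr, b1, b2, it)
    model$dec_full <- r$net; stateGt <- r$state

    if (!is.finite(rep$total) || !is.finite(lD) || !is.finite(lDt))
      stop("training diverged: non-finite loss at iteration ", it)

    if (it %% cfg$log_every == 0 || it == 1 || it == cfg$iterations) {
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(iter = it, disc_D = lD * sc, disc_Dt = lDt * sc,
                   adv_D = terms_acc[["adv_D"]], adv_Dt = terms_acc[["adv_Dt"]],
                   rec = terms_acc[["rec"]], art = terms_acc[["art"]],
                   cycle = terms_acc[["cycle"]], tv = terms_acc[["tv"]],
                   total = rep$total)
      if (verbose && (it %% (cfg$log_every * 20) == 0 || it == 1))
        message(sprintf("iter %d total %.4f rec %.4f cycle %.4f",
                        it, rep$total, terms_acc[["rec"]],
                        terms_acc[["cycle"]]))
    }
  }
  log <- do.call(rbind, log_rows)
  ckpt <- list(model = model, window = win, extra = list(cfg = cfg, log = log),
               format = "detrunc-ckpt-1")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    saveRDS(ckpt, file.path(out_dir, "checkpoint.rds"))
    jsonlite::stream_out(log, file(file.path(out_dir, "train_log.jsonl")),
                         verbose = FALSE)
  }
  list(checkpoint = ckpt, log = log)
}

#' Remove truncation artifacts from an image with a trained model
#'
#' Polar-transforms the input (if the checkpoint was trained in polar
#' space), normalizes to the training window, and applies the
#' artifact-removal pathway `decode_content(encode(.))`. In the default
#' `"residual"` mode the artifact estimate (input minus network output,
#' a radially smooth field) is resampled back to Cartesian space and
#' subtracted from the original image, so full-resolution content never
#' passes through the polar round trip; `"direct"` mode resamples the
#' network output itself. Pixels outside the inscribed field-of-view disk
#' are passed through from the input.
#'
#' @param image A square `image_grid`.
#' @param ckpt A checkpoint from [train()] or [load_checkpoint()].
#' @param mode `"residual"` (default) or `"direct"`.
#' @return An `image_grid` of the same size.
#' @export
remove_artifacts <- function(image, ckpt, mode = c("residual", "direct")) {
  stopifnot(inherits(image, "image_grid"))
  mode <- match.arg(mode)
  if (!is_square(image)) stop("image must be square")
  model <- ckpt$model
  cfg <- ckpt$extra$cfg
  win <- ckpt$window
  if (isTRUE(cfg$use_polar)) {
    m <- prep_input(image, cfg, win)
    out_pol <- decode_content(model, encode(model, m))
    pol <- to_polar(image, n_rho = ncol(m), n_phi = nrow(m))
    res <- image$pixels
    msk <- inscribed_mask(nrow(res))
    if (mode == "residual") {
      # artifact estimate in physical units (the window map is affine, so
      # differences rescale by the slope only)
      pol$values <- (m - out_pol) * (win[2] - win[1]) / 2
      corr <- from_polar(pol, nrow(res), image$pixel_size,
                         image$value_range)
      res[msk] <- image$pixels[msk] - corr$pixels[msk]
    } else {
      pol$values <- denorm_from_window(out_pol, win)
      out <- from_polar(pol, nrow(res), image$pixel_size, image$value_range)
      res[msk] <- out$pixels[msk]
    }
  } else {
    m <- norm_to_window(image$pixels, win)
    out <- decode_content(model, encode(model, m))
    if (mode == "residual") res <- image$pixels - (m - out) * (win[2] - win[1]) / 2
    else res <- denorm_from_window(out, win)
  }
  image_grid(res, image$pixel_size, image$value_range)
}
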