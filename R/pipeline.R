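#' Assemble a full run configuration
#'
#' Composes the phantom template, acquisition geometry, truncation ratio,
#' polar grid, network and training settings into one schema-checked
#' object. The resolved configuration is serialized into every run
#' directory so each artifact on disk is reconstructible from config plus
#' seeds.
#'
#' @param out_dir Run directory.
#' @param seed Global seed; all stage seeds derive from it.
#' @param size Phantom side in pixels.
#' @param n_train,n_test Images per training domain / test pairs.
#' @param n_inclusions Interior ellipses per phantom.
#' @param ratio Truncation ratio.
#' @param n_views Projection views over 2*pi.
#' @param out_size Reconstruction grid side.
#' @param iterations,base_channels,batch_size,lr Training shorthands.
#' @param n_phi,n_rho Polar grid (NULL derives `n_rho` from image size).
#' @param use_polar Train in polar space.
#' @param adv_form Adversarial formulation.
#' @param weights A [loss_weights()].
#' @param tv A [tv_config()] for the TV baseline.
#' @param noise_sd Additive sinogram noise.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, size = 64L, n_train = 50L,
                       n_test = 10L, n_inclusions = 4L, ratio = 0.3,
                       n_views = 720L, out_size = size, iterations = 500L,
                       base_channels = 16L, batch_size = 1L, lr = 1e-4,
                       n_phi = 64L, n_rho = NULL, use_polar = TRUE,
                       adv_form = "lsgan", weights = loss_weights(),
                       tv = tv_config(), noise_sd = 0) {
  stopifnot(is.character(out_dir), length(out_dir) == 1)
  if (ratio < 0 || ratio >= 1) stop("config error: ratio must be in [0,1)")
  if (size < 16) stop("config error: size must be >= 16")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 size = as.integer(size), n_train = as.integer(n_train),
                 n_test = as.integer(n_test),
                 n_inclusions = as.integer(n_inclusions), ratio = ratio,
                 n_views = as.integer(n_views),
                 out_size = as.integer(out_size),
                 iterations = as.integer(iterations),
                 base_channels = as.integer(base_channels),
                 batch_size = as.integer(batch_size), lr = lr,
                 n_phi = as.integer(n_phi), n_rho = n_rho,
                 use_polar = use_polar, adv_form = adv_form,
                 weights = weights, tv = tv, noise_sd = noise_sd),
            class = "run_config")
}

as_train_config <- function(cfg) {
  train_config(iterations = cfg$iterations, lr = cfg$lr,
               batch_size = cfg$batch_size, seed = cfg$seed,
               weights = cfg$weights,
               net = net_config(base_channels = cfg$base_channels,
                                seed = cfg$seed),
               adv_form = cfg$adv_form, use_polar = cfg$use_polar,
               n_phi = cfg$n_phi, n_rho = cfg$n_rho)
}

regen_test_sinogram <- function(manifest, entry, cfg) {
  tpl <- manifest$spec_template
  sp <- phantom_spec(seed = entry$seed, size = tpl$size,
                     n_inclusions = tpl$n_inclusions,
                     body_axes = unlist(tpl$body_axes),
                     contrast_range = unlist(tpl$contrast_range),
                     body_value = tpl$body_value, hi = tpl$hi,
                     smooth_sigma = tpl$smooth_sigma)
  ph <- make_ellipse_phantom(sp)
  gl <- manifest$geometry
  geom <- fan_geometry(gl$n_views, gl$source_iso, gl$iso_det, gl$n_det,
                       gl$det_pitch, gl$angle_start)
  sino <- forward_project(ph, geom)
  truncate_sinogram(sino, manifest$ratio)
}

#' Run the simulation / training / evaluation pipeline
#'
#' Executes the requested stages in dependency order, each reading only
#' prior-stage outputs under `cfg$out_dir`:
#' `simulate` builds the unpaired dataset; `train` fits the model;
#' `infer` applies it to the test images; `baseline` runs the
#' extrapolation and TV comparators on re-generated test sinograms;
#' `evaluate` writes a per-image metric table (`metrics.csv`) covering
#' every estimate present.
#'
#' @param cfg A [run_config()].
#' @param stages Character subset of
#'   `c("simulate", "train", "infer", "baseline", "evaluate")`.
#' @return The run directory, invisibly; `evaluate` also writes
#'   `metrics.csv` and returns the table in the `metrics` attribute.
#' @export
run_pipeline <- function(cfg, stages = c("simulate", "train", "infer",
                                         "baseline", "evaluate")) {
  stopifnot(inherits(cfg, "run_config"), length(stages) >= 1)
  known <- c("simulate", "train", "infer", "baseline", "evaluate")
  if (!all(stages %in% known))
    stop("config error: unknown stage(s): ",
         paste(setdiff(stages, known), collapse = ", "))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(cfg), file.path(cfg$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  data_dir <- file.path(cfg$out_dir, "data")
  est_dir <- file.path(cfg$out_dir, "estimates")
  base_dir <- file.path(cfg$out_dir, "baseline")
  metrics <- NULL

  for (st in known[known %in% stages]) {
    if (st == "simulate") {
      geom <- default_fan_geometry(cfg$size, n_views = cfg$n_views)
      build_unpaired_dataset(cfg$n_train, cfg$n_test,
                             phantom_spec(size = cfg$size,
                                          n_inclusions = cfg$n_inclusions),
                             geom, cfg$ratio, data_dir,
                             out_size = cfg$out_size, seed = cfg$seed,
                             noise_sd = cfg$noise_sd)
    } else if (st == "train") {
      if (!file.exists(file.path(data_dir, "manifest.json")))
        stop("data error: no dataset present; run the simulate stage first")
      man <- read_manifest(data_dir)
      train(man, as_train_config(cfg), out_dir = cfg$out_dir)
    } else if (st == "infer") {
      ckpt_path <- file.path(cfg$out_dir, "checkpoint.rds")
      if (!file.exists(ckpt_path))
        stop("data error: no checkpoint present; run the train stage first")
      ck <- load_checkpoint(ckpt_path)
      man <- read_manifest(data_dir)
      dir.create(est_dir, showWarnings = FALSE)
      for (e in manifest_entries(man, "artifact", "test")) {
        img <- read_image(file.path(man$root, e$file))
        write_image(remove_artifacts(img, ck),
                    file.path(est_dir, sub("artifact", "corrected", e$file)))
      }
    } else if (st == "baseline") {
      if (!file.exists(file.path(data_dir, "manifest.json")))
        stop("data error: no dataset present; run the simulate stage first")
      man <- read_manifest(data_dir)
      dir.create(base_dir, showWarnings = FALSE)
      for (e in manifest_entries(man, "artifact", "test")) {
        sino <- regen_test_sinogram(man, e, cfg)
        ex <- extrapolate_and_reconstruct(sino, cfg$out_size)
        tvr <- tv_reconstruct(sino, cfg$tv, cfg$out_size)
        write_image(ex, file.path(base_dir,
                                  sub("artifact", "extrap", e$file)))
        write_image(tvr, file.path(base_dir, sub("artifact", "tv", e$file)))
      }
    } else if (st == "evaluate") {
      man <- read_manifest(data_dir)
      refs <- manifest_entries(man, "reference", "test")
      arts <- manifest_entries(man, "artifact", "test")
      ref_imgs <- lapply(refs, function(e)
        read_image(file.path(man$root, e$file)))
      candidates <- list(
        input = lapply(arts, function(e)
          read_image(file.path(man$root, e$file))))
      grab <- function(dir, tag) {
        fs <- vapply(arts, function(e)
          file.path(dir, sub("artifact", tag, e$file)), "")
        if (all(file.exists(fs))) lapply(fs, read_image) else NULL
      }
      candidates$corrected <- grab(est_dir, "corrected")
      candidates$extrapolation <- grab(base_dir, "extrap")
      candidates$tv <- grab(base_dir, "tv")
      candidates <- Filter(Negate(is.null), candidates)
      if (identical(names(candidates), "input"))
        stop("data error: no estimates present; run infer/baseline first")
      tabs <- lapply(names(candidates), function(nm)
        metric_report(candidates[[nm]], ref_imgs, method = nm))
      metrics <- do.call(rbind, tabs)
      utils::write.csv(metrics, file.path(cfg$out_dir, "metrics.csv"),
                       row.names = FALSE)
      prof <- data.frame(
        position = seq_len(cfg$out_size),
        reference = line_profile(ref_imgs[[1]], "row",
                                 cfg$out_size %/% 2),
        input = line_profile(candidates$input[[1]], "row",
                             cfg$out_size %/% 2))
      if (!is.null(candidates$corrected))
        prof$corrected <- line_profile(candidates$corrected[[1]], "row",
                                       cfg$out_size %/% 2)
      utils::write.csv(prof, file.path(cfg$out_dir, "profiles.csv"),
                       row.names = FALSE)
    }
  }
  out <- cfg$out_dir
  attr(out, "metrics") <- metrics
  invisible(out)
}
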