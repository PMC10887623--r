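tiny_dataset <- function(dir, n_train = 4, n_test = 2, seed = 5,
                         ratio = 0.5) {
  build_unpaired_dataset(n_train, n_test, phantom_spec(size = 64,
                                                       n_inclusions = 3),
                         default_fan_geometry(64, n_views = 90),
                         ratio = ratio, out_dir = dir, seed = seed)
}

tiny_cfg <- function(iterations = 10, seed = 2, ...) {
  train_config(iterations = iterations, batch_size = 1, seed = seed,
               net = net_config(base_channels = 4),
               n_phi = 64L, n_rho = 32L, log_every = 1L, ...)
}

test_that("a short training run completes with finite losses", {
  dir <- withr::local_tempdir()
  man <- tiny_dataset(dir)
  r <- train(man, tiny_cfg(10))
  expect_equal(nrow(r$log), 10)
  expect_true(all(is.finite(as.matrix(r$log))))
  expect_s3_class(r$checkpoint$model, "disentangle_model")
  expect_length(r$checkpoint$window, 2)
})

test_that("training is reproducible from the seed", {
  dir <- withr::local_tempdir()
  man <- tiny_dataset(dir)
  r1 <- train(man, tiny_cfg(6, seed = 7))
  r2 <- train(man, tiny_cfg(6, seed = 7))
  expect_equal(r1$log, r2$log, tolerance = 1e-12)
  r3 <- train(man, tiny_cfg(6, seed = 8))
  expect_false(isTRUE(all.equal(r1$log$total, r3$log$total)))
})

test_that("the training loop never touches test-split reference images", {
  dir <- withr::local_tempdir()
  man <- tiny_dataset(dir)
  for (e in manifest_entries(man, "reference", "test"))
    unlink(file.path(man$root, e$file))
  expect_no_error(train(man, tiny_cfg(2)))
})

test_that("ablation variants toggle exactly the stated components", {
  base <- tiny_cfg(5)
  v6 <- ablation_variant(base, "Var6")
  expect_identical(v6$enabled, base$enabled)
  expect_true(v6$use_polar)
  v1 <- ablation_variant(base, "Var1")
  w1 <- detrunc:::effective_weights(v1)
  expect_equal(w1$rec + w1$art + w1$cycle + w1$tv, 0)
  expect_gt(w1$adv, 0)
  expect_false(v1$use_polar)
  v4 <- ablation_variant(base, "Var4")
  v5 <- ablation_variant(base, "Var5")
  expect_identical(v4$enabled, v5$enabled)
  expect_false(v4$use_polar); expect_true(v5$use_polar)
  expect_error(ablation_variant(base, "Var7"), "unknown")
})

test_that("inference preserves shape and the out-of-FOV pixels", {
  dir <- withr::local_tempdir()
  man <- tiny_dataset(dir)
  r <- train(man, tiny_cfg(3))
  img <- read_image(file.path(man$root,
                              manifest_entries(man, "artifact", "test")[[1]]$file))
  out <- remove_artifacts(img, r$checkpoint)
  expect_equal(dim(out$pixels), dim(img$pixels))
  expect_true(all(is.finite(out$pixels)))
  outside <- !inscribed_mask(64)
  expect_identical(out$pixels[outside], img$pixels[outside])
  expect_error(remove_artifacts(image_grid(matrix(0, 32, 64)), r$checkpoint),
               "square")
})

test_that("repeated application tends towards idempotence", {
  dir <- withr::local_tempdir()
  man <- tiny_dataset(dir)
  r <- train(man, tiny_cfg(30))
  img <- read_image(file.path(man$root,
                              manifest_entries(man, "artifact", "test")[[1]]$file))
  once <- remove_artifacts(img, r$checkpoint)
  twice <- remove_artifacts(once, r$checkpoint)
  d1 <- sqrt(mean((once$pixels - img$pixels)^2))
  d2 <- sqrt(mean((twice$pixels - once$pixels)^2))
  # soft property at this scale: the second pass moves the image far less
  # than the first correction did; logged, not hard-asserted beyond a
  # generous factor
  expect_lt(d2, 1.5 * d1)
})

test_that("cartesian (Var1-style) training also runs end to end", {
  dir <- withr::local_tempdir()
  man <- tiny_dataset(dir)
  cfg <- ablation_variant(tiny_cfg(3), "Var1")
  r <- train(man, cfg)
  expect_true(all(is.finite(as.matrix(r$log))))
  img <- read_image(file.path(man$root,
                              manifest_entries(man, "artifact", "test")[[1]]$file))
  out <- remove_artifacts(img, r$checkpoint)
  expect_equal(dim(out$pixels), c(64, 64))
})
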