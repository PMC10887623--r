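random_bundle <- function(seed = 1, H = 12, W = 10) {
  set.seed(seed)
  f <- function() matrix(rnorm(H * W), H, W)
  structure(list(I_pt = f(), J_p = f(), I_hat_p = f(), I_tilde_pt = f(),
                 J_tilde_p = f(), J_hat_pt = f(), J_hat_p = f()),
            class = "cycle_bundle")
}

test_that("least-squares GAN losses vanish at their fixed points", {
  ones <- matrix(1, 4, 4); zeros <- matrix(0, 4, 4)
  expect_equal(gan_loss_disc(ones, zeros, "lsgan"), 0)
  expect_equal(gan_loss_gen(ones, "lsgan"), 0)
  # and are positive away from them
  expect_gt(gan_loss_disc(zeros, ones, "lsgan"), 0)
  expect_gt(gan_loss_gen(zeros, "lsgan"), 0)
})

test_that("GAN losses match naive per-element computation", {
  set.seed(3)
  real <- matrix(rnorm(20), 4); fake <- matrix(rnorm(20), 4)
  naive_disc <- mean((real - 1)^2) + mean(fake^2)
  expect_rel_equal(gan_loss_disc(real, fake, "lsgan"), naive_disc)
  expect_rel_equal(gan_loss_gen(fake, "lsgan"), mean((fake - 1)^2))
  # logistic form agrees with direct sigmoid cross-entropy
  sig <- function(x) 1 / (1 + exp(-x))
  expect_rel_equal(gan_loss_gen(fake, "bce"), -mean(log(sig(fake))))
  expect_rel_equal(gan_loss_disc(real, fake, "bce"),
                   -mean(log(sig(real))) - mean(log(1 - sig(fake))))
})

test_that("reconstruction loss: zero fixed point, offset case, naive oracle", {
  b <- random_bundle(1)
  b$I_tilde_pt <- b$I_pt; b$J_tilde_p <- b$J_p
  expect_equal(reconstruction_loss(b), 0)
  b$I_tilde_pt <- b$I_pt + 0.37
  expect_rel_equal(reconstruction_loss(b), 0.37)
  b <- random_bundle(2)
  naive <- mean(abs(b$I_tilde_pt - b$I_pt)) + mean(abs(b$J_tilde_p - b$J_p))
  expect_rel_equal(reconstruction_loss(b), naive)
})

test_that("artifact consistency loss: fixed point, one-sided residual, oracle", {
  b <- random_bundle(3)
  resid <- matrix(rnorm(120), 12)
  b$I_hat_p <- b$I_pt - resid
  b$J_hat_pt <- b$J_p + resid
  expect_lt(artifact_consistency_loss(b), 1e-12)
  b$I_hat_p <- b$I_pt
  expect_rel_equal(artifact_consistency_loss(b), mean(abs(resid)))
  b <- random_bundle(4)
  naive <- mean(abs((b$I_pt - b$I_hat_p) - (b$J_hat_pt - b$J_p)))
  expect_rel_equal(artifact_consistency_loss(b), naive)
})

test_that("cycle loss: fixed point, offset, naive oracle", {
  b <- random_bundle(5)
  b$J_hat_p <- b$J_p
  expect_equal(cycle_loss(b), 0)
  b$J_hat_p <- b$J_p - 0.21
  expect_rel_equal(cycle_loss(b), 0.21)
  b <- random_bundle(6)
  expect_rel_equal(cycle_loss(b), mean(abs(b$J_hat_p - b$J_p)))
})

test_that("horizontal TV loss: flat field, column step, double-loop oracle", {
  H <- 7; W <- 9
  expect_equal(tv_horizontal_loss(matrix(3, H, W), matrix(1, H, W)), 0)
  # single step of height h between adjacent columns
  h <- 0.8
  u <- matrix(0, H, W); u[, 5:W] <- h
  expect_rel_equal(tv_horizontal_loss(u, matrix(0, H, W)), h^2 / (W - 1))
  set.seed(7)
  u <- matrix(rnorm(H * W), H, W)
  naive <- 0
  for (i in 1:H) for (j in 1:(W - 1)) naive <- naive + (u[i, j + 1] - u[i, j])^2
  naive <- naive / (H * (W - 1))
  expect_rel_equal(tv_horizontal_loss(u, matrix(0, H, W)), naive)
  expect_error(tv_horizontal_loss(matrix(1, 4, 1), matrix(0, 4, 1)), "width")
})

test_that("total objective is the stated weighted sum", {
  w <- loss_weights()
  zero <- list(adv_D = 0, adv_Dt = 0, rec = 0, art = 0, cycle = 0, tv = 0)
  expect_equal(total_objective(zero, w)$total, 0)
  # unit value for each of the five objective components; the adversarial
  # component is the sum of its two discriminator terms
  unit <- list(adv_D = 0.5, adv_Dt = 0.5, rec = 1, art = 1, cycle = 1,
               tv = 1)
  # 1*1 + 5 + 5 + 10 + 100
  expect_rel_equal(total_objective(unit, w)$total, 121)
  set.seed(8)
  terms <- as.list(setNames(runif(6), names(zero)))
  ww <- loss_weights(adv = 0.5, art = 2, rec = 3, cycle = 4, tv = 7)
  naive <- 0.5 * (terms$adv_D + terms$adv_Dt) + 2 * terms$art +
    3 * terms$rec + 4 * terms$cycle + 7 * terms$tv
  expect_rel_equal(total_objective(terms, ww)$total, naive)
  # doubling the tv weight doubles only the tv contribution
  w2 <- loss_weights(tv = 200)
  expect_rel_equal(total_objective(unit, w2)$total - total_objective(unit, w)$total,
                   100)
  expect_error(total_objective(modifyList(unit, list(tv = NaN)), w),
               "non-finite")
})
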