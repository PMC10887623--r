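# Analytic gradients are validated against central finite differences.
# Layers are checked exhaustively with smooth activations (machine
# precision); full networks are checked with a directional derivative.

fd_layer_input_grads <- function(layer, x, mode_r, mode_c, eps = 1e-6) {
  r <- layer_forward(layer, x, mode_r, mode_c)
  bk <- layer_backward(layer, r$cache, cos(r$y), mode_r, mode_c)
  errs <- numeric(length(x))
  for (ii in seq_along(x)) {
    x2 <- x; x2[ii] <- x[ii] + eps
    f1 <- sum(sin(layer_forward(layer, x2, mode_r, mode_c)$y))
    x2[ii] <- x[ii] - eps
    f0 <- sum(sin(layer_forward(layer, x2, mode_r, mode_c)$y))
    errs[ii] <- abs((f1 - f0) / (2 * eps) - bk$gx[ii])
  }
  max(errs)
}

fd_layer_param_grads <- function(layer, x, mode_r, mode_c, eps = 1e-6) {
  r <- layer_forward(layer, x, mode_r, mode_c)
  bk <- layer_backward(layer, r$cache, cos(r$y), mode_r, mode_c)
  errs <- c()
  for (pn in names(layer$par)) {
    for (ii in seq_along(layer$par[[pn]])) {
      l2 <- layer; l2$par[[pn]][ii] <- layer$par[[pn]][ii] + eps
      f1 <- sum(sin(layer_forward(l2, x, mode_r, mode_c)$y))
      l2$par[[pn]][ii] <- layer$par[[pn]][ii] - eps
      f0 <- sum(sin(layer_forward(l2, x, mode_r, mode_c)$y))
      errs <- c(errs, abs((f1 - f0) / (2 * eps) - bk$grads[[pn]][ii]))
    }
  }
  max(errs)
}

test_that("conv / transposed-conv / instance-norm gradients are exact", {
  set.seed(21)
  x <- array(rnorm(10 * 6 * 2), c(10, 6, 2))
  cases <- list(
    list(new_layer("conv", 2L, 3L, 3L, 1L, norm = TRUE, act = "none"),
         "circular", "reflect"),
    list(new_layer("conv", 2L, 3L, 4L, 2L, norm = TRUE, act = "none"),
         "reflect", "reflect"),
    list(new_layer("convT", 2L, 3L, 4L, 2L, norm = TRUE, act = "none"),
         "circular", "reflect"),
    list(new_layer("conv", 2L, 1L, 3L, 1L, norm = FALSE, act = "tanh"),
         "circular", "circular"),
    list(new_layer("convT", 2L, 2L, 4L, 2L, norm = FALSE, act = "none"),
         "zero", "zero"))
  for (cs in cases) {
    l <- init_layer(cs[[1]], 0.3)
    lab <- paste(cs[[1]]$type, cs[[2]], cs[[3]])
    expect_lt(fd_layer_input_grads(l, x, cs[[2]], cs[[3]]), 1e-6, label = lab)
    expect_lt(fd_layer_param_grads(l, x, cs[[2]], cs[[3]]), 1e-6, label = lab)
  }
})

test_that("full generator objective gradient matches a directional derivative", {
  set.seed(22)
  m <- build_model(net_config(base_channels = 2, seed = 5))
  I <- matrix(rnorm(32 * 32, 0, 0.5), 32, 32)
  J <- matrix(rnorm(32 * 32, 0, 0.5), 32, 32)
  w <- loss_weights()
  total_loss <- function(model) {
    b <- forward_cycle(model, I, J)
    sD <- discriminate(model, b$I_hat_p, "D")
    sDt <- discriminate(model, b$J_hat_pt, "Dt")
    w$adv * (gan_loss_gen(sD, "lsgan") + gan_loss_gen(sDt, "lsgan")) +
      w$rec * reconstruction_loss(b) + w$art * artifact_consistency_loss(b) +
      w$cycle * cycle_loss(b) + w$tv * tv_horizontal_loss(b$I_pt, b$I_hat_p)
  }
  gp <- generator_pass(m, I, J, w, "lsgan")
  eps <- 1e-6
  set.seed(23)
  mp <- m; mm <- m; dd <- 0
  for (nn in c("encoder", "dec_content", "dec_full")) {
    gname <- c(encoder = "gE", dec_content = "gG", dec_full = "gGt")[[nn]]
    for (li in seq_along(m[[nn]]$layers)) {
      for (pn in names(m[[nn]]$layers[[li]]$par)) {
        d <- m[[nn]]$layers[[li]]$par[[pn]]; d[] <- rnorm(length(d))
        mp[[nn]]$layers[[li]]$par[[pn]] <- m[[nn]]$layers[[li]]$par[[pn]] + eps * d
        mm[[nn]]$layers[[li]]$par[[pn]] <- m[[nn]]$layers[[li]]$par[[pn]] - eps * d
        dd <- dd + sum(gp[[gname]][[li]][[pn]] * d)
      }
    }
  }
  num <- (total_loss(mp) - total_loss(mm)) / (2 * eps)
  # L1 terms and ReLU family activations are piecewise linear, so finite
  # differences carry kink noise; the directional derivative over all
  # parameters must still agree closely
  expect_lt(abs(num - dd) / max(abs(num), 1e-8), 0.1)
  expect_gt(abs(dd), 0)  # gradients actually flow
})

test_that("gradient descent on the generator objective reduces the loss", {
  set.seed(24)
  m <- build_model(net_config(base_channels = 4, seed = 6))
  I <- matrix(rnorm(32 * 32, 0, 0.5), 32, 32)
  J <- matrix(rnorm(32 * 32, 0, 0.5), 32, 32)
  w <- loss_weights()
  loss_of <- function(model, gp) {
    t <- gp$terms
    w$adv * (t$adv_D + t$adv_Dt) + w$rec * t$rec + w$art * t$art +
      w$cycle * t$cycle + w$tv * t$tv
  }
  sE <- adam_init(m$encoder); sG <- adam_init(m$dec_content)
  sGt <- adam_init(m$dec_full)
  losses <- numeric(15)
  for (it in 1:15) {
    gp <- generator_pass(m, I, J, w, "lsgan")
    losses[it] <- loss_of(m, gp)
    r <- adam_step(m$encoder, gp$gE, sE, 2e-3, 0.5, 0.999, it)
    m$encoder <- r$net; sE <- r$state
    r <- adam_step(m$dec_content, gp$gG, sG, 2e-3, 0.5, 0.999, it)
    m$dec_content <- r$net; sG <- r$state
    r <- adam_step(m$dec_full, gp$gGt, sGt, 2e-3, 0.5, 0.999, it)
    m$dec_full <- r$net; sGt <- r$state
  }
  expect_lt(losses[15], 0.7 * losses[1])
})
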