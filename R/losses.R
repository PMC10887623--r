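#' Loss weights for the training objective
#'
#' Weighted sum of the adversarial, artifact-consistency, reconstruction,
#' cycle-consistency and horizontal total-variation terms. Defaults follow
#' the training protocol: adversarial weights 1.0, artifact and
#' reconstruction 5.0, cycle 10.0, TV 100.0.
#'
#' @param adv,art,rec,cycle,tv Nonnegative finite scalars.
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(adv = 1, art = 5, rec = 5, cycle = 10, tv = 100) {
  w <- c(adv = adv, art = art, rec = rec, cycle = cycle, tv = tv)
  if (!all(is.finite(w)) || any(w < 0)) stop("weights must be finite and >= 0")
  structure(as.list(w), class = "loss_weights")
}

mean_l1 <- function(a, b) mean(abs(a - b))

#' Generator-side and discriminator-side GAN objectives
#'
#' `form = "lsgan"` (default) uses least squares: real scores are pushed to
#' 1 and fake scores to 0 by the discriminator, while the generator pushes
#' fake scores to 1. `form = "bce"` is the logistic cross-entropy
#' formulation on raw (pre-sigmoid) scores.
#'
#' @param fake Score map of generated images.
#' @param real Score map of real images.
#' @param form `"lsgan"` or `"bce"`.
#' @return Scalar loss.
#' @export
gan_loss_gen <- function(fake, form = c("lsgan", "bce")) {
  form <- match.arg(form)
  if (form == "lsgan") mean((fake - 1)^2)
  else mean(log1p(exp(-fake)))                 # -log sigmoid(fake)
}

#' @rdname gan_loss_gen
#' @export
gan_loss_disc <- function(real, fake, form = c("lsgan", "bce")) {
  form <- match.arg(form)
  if (form == "lsgan") mean((real - 1)^2) + mean(fake^2)
  else mean(log1p(exp(-real))) + mean(log1p(exp(fake)))
}

#' Self-reconstruction loss
#'
#' Mean L1 between each input and its same-domain reconstruction: the
#' artifact-affected input against its full-feature decoding, and the
#' artifact-free input against its content decoding.
#'
#' @param bundle A cycle bundle from [forward_cycle()].
#' @return Scalar loss (>= 0).
#' @export
reconstruction_loss <- function(bundle) {
  mean_l1(bundle$I_tilde_pt, bundle$I_pt) + mean_l1(bundle$J_tilde_p, bundle$J_p)
}

#' Artifact consistency loss
#'
#' Mean L1 between the artifact residual removed from the artifact-affected
#' input, `I_pt - I_hat_p`, and the artifact residual added to the
#' artifact-free input, `J_hat_pt - J_p`. Ties the synthesized artifact to
#' the one actually separated.
#'
#' @inheritParams reconstruction_loss
#' @return Scalar loss (>= 0).
#' @export
artifact_consistency_loss <- function(bundle) {
  mean_l1(bundle$I_pt - bundle$I_hat_p, bundle$J_hat_pt - bundle$J_p)
}

#' Cycle consistency loss
#'
#' Mean L1 between the artifact-free input and its recovery after the
#' add-artifact / remove-artifact round trip, forming synthetic paired
#' supervision for the artifact-removal pathway.
#'
#' @inheritParams reconstruction_loss
#' @return Scalar loss (>= 0).
#' @export
cycle_loss <- function(bundle) {
  mean_l1(bundle$J_hat_p, bundle$J_p)
}

#' Horizontal (radial) total-variation loss
#'
#' On the difference image `u = I_pt - I_hat_p` in polar layout (rows =
#' angle, columns = radius), the mean squared forward difference along the
#' radial (column) axis: `sum((u[i,j+1] - u[i,j])^2) / (H * (W - 1))`.
#' Penalizes radially varying residuals, the signature of cupping.
#'
#' @param I_pt,I_hat_p Same-shape matrices (input and its artifact-removed
#'   version) in polar layout.
#' @return Scalar loss (>= 0).
#' @export
tv_horizontal_loss <- function(I_pt, I_hat_p) {
  u <- as_pixels(I_pt) - as_pixels(I_hat_p)
  if (ncol(u) < 2) stop("width must be >= 2")
  d <- u[, -1, drop = FALSE] - u[, -ncol(u), drop = FALSE]
  sum(d^2) / (nrow(u) * (ncol(u) - 1))
}

#' Combine loss terms into the weighted training objective
#'
#' @param terms Named list with scalars `adv_D`, `adv_Dt`, `rec`, `art`,
#'   `cycle`, `tv`.
#' @param weights A [loss_weights()].
#' @return A `loss_report`: the per-term values plus the weighted `total` =
#'   `adv*(adv_D + adv_Dt) + art*art + rec*rec + cycle*cycle + tv*tv`.
#' @export
total_objective <- function(terms, weights) {
  stopifnot(inherits(weights, "loss_weights"))
  need <- c("adv_D", "adv_Dt", "rec", "art", "cycle", "tv")
  if (!all(need %in% names(terms))) stop("missing loss terms")
  vals <- unlist(terms[need])
  if (!all(is.finite(vals))) stop("non-finite loss term: training diverged")
  total <- weights$adv * (terms$adv_D + terms$adv_Dt) +
    weights$art * terms$art + weights$rec * terms$rec +
    weights$cycle * terms$cycle + weights$tv * terms$tv
  structure(c(terms[need], list(total = total)), class = "loss_report")
}
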