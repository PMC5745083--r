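# Synthetic two-channel retina images with known ground truth.
#
# The adult fly retina is a near-hexagonal lattice of ommatidia; each R7
# photoreceptor stochastically adopts the ON state (Rh4 reporter) with some
# probability and otherwise the OFF state (Rh3 reporter). The generator
# renders each R7 as an isotropic 2-D Gaussian spot into exactly one of the
# two channels, then corrupts both channels with a smooth multiplicative
# illumination field (the artifact class a homomorphic filter removes) and
# additive Gaussian noise.

#' Simulation settings for synthetic retina images
#'
#' @param seed Integer seed; the generator is a pure function of the config.
#' @param n_rows,n_cols Hexagonal lattice dimensions. The default 15 x 14
#'   yields 210 R7s, comfortably above the 100-cell scoring floor used for
#'   real retinas.
#' @param on_fraction Probability that an R7 is ON (Rh4). Default 0.65,
#'   a typical wild-type ON proportion for this mosaic.
#' @param spot_sigma Gaussian spot standard deviation in pixels.
#' @param spacing Lattice spacing (pixels) between neighbouring R7 centers.
#' @param spot_amplitude Peak spot intensity above background.
#' @param background Baseline intensity added to both channels (keeps the
#'   rasters strictly positive so the log-domain filter is well defined).
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param illum_amplitude Strength of the smooth multiplicative illumination
#'   gradient (0 disables it).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_rows = 15L, n_cols = 14L,
                       on_fraction = 0.65, spot_sigma = 3,
                       spacing = 16, spot_amplitude = 800,
                       background = 60, noise_sd = 15,
                       illum_amplitude = 0.3) {
  if (!is.numeric(n_rows) || !is.numeric(n_cols) ||
      n_rows < 1 || n_cols < 1) {
    stop("lattice dimensions must be positive integers", call. = FALSE)
  }
  stopifnot_scalar_prob(on_fraction, "on_fraction")
  if (spot_sigma <= 0) stop("`spot_sigma` must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (spacing <= 0) stop("`spacing` must be > 0", call. = FALSE)
  structure(list(seed = as.integer(seed), n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols), on_fraction = on_fraction,
                 spot_sigma = spot_sigma, spacing = spacing,
                 spot_amplitude = spot_amplitude, background = background,
                 noise_sd = noise_sd, illum_amplitude = illum_amplitude),
            class = "sim_config")
}

#' Two-channel retina image container
#'
#' @param rh3,rh4 Numeric matrices of equal shape with finite, non-negative
#'   intensities: the OFF (Rh3) and ON (Rh4) reporter channels.
#' @return An object of class `retina_image`.
#' @export
retina_image <- function(rh3, rh4) {
  if (!is.matrix(rh3) || !is.matrix(rh4) ||
      !identical(dim(rh3), dim(rh4))) {
    stop("`rh3` and `rh4` must be matrices of identical shape",
         call. = FALSE)
  }
  if (!all(is.finite(rh3)) || !all(is.finite(rh4)) ||
      min(rh3) < 0 || min(rh4) < 0) {
    stop("channel intensities must be finite and non-negative",
         call. = FALSE)
  }
  structure(list(rh3 = rh3, rh4 = rh4), class = "retina_image")
}

#' Generate a synthetic retina image with ground truth
#'
#' Renders a hexagonal mosaic of Gaussian R7 spots, each assigned ON
#' (rendered in the Rh4 channel) with probability `on_fraction` and OFF
#' (Rh3 channel) otherwise, then applies a multiplicative illumination
#' gradient and additive noise to both channels.
#'
#' @param config A [sim_config()].
#' @param render If `FALSE`, skip rasterisation and return only the ground
#'   truth (identities are drawn from the same RNG stream either way, so the
#'   truth matches the rendered image for a given config).
#' @return A list with components `image` (a [retina_image()], or `NULL`
#'   when `render = FALSE`) and `truth`, a list holding `centers` (n x 2
#'   matrix of 0-based row/col pixel coordinates), `identities` (factor
#'   `"ON"`/`"OFF"`), `on_fraction_true`, and `border` (logical, spots whose
#'   disk of radius 2 sigma leaves the image).
#' @export
generate_retina_image <- function(config, render = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    sp <- config$spacing
    margin <- 2.5 * config$spot_sigma + 2
    rowstep <- sp * sqrt(3) / 2
    ij <- expand.grid(i = seq_len(config$n_rows) - 1L,
                      j = seq_len(config$n_cols) - 1L)
    cy <- margin + ij$i * rowstep
    cx <- margin + ij$j * sp + (ij$i %% 2) * sp / 2
    # slight positional jitter: real ommatidial lattices are not perfect
    n <- nrow(ij)
    cy <- cy + rnorm(n, 0, 0.05 * sp)
    cx <- cx + rnorm(n, 0, 0.05 * sp)
    height <- ceiling(max(cy) + margin)
    width <- ceiling(max(cx) + margin)
    on <- runif(n) < config$on_fraction
    rad <- 2 * config$spot_sigma
    border <- cy < rad | cx < rad | cy > height - 1 - rad | cx > width - 1 - rad
    truth <- list(centers = cbind(row = cy, col = cx),
                  identities = factor(ifelse(on, "ON", "OFF"),
                                      levels = c("OFF", "ON")),
                  on_fraction_true = mean(on),
                  border = border)
    if (!render) return(list(image = NULL, truth = truth))

    render_channel <- function(keep) {
      img <- matrix(0, height, width)
      half <- ceiling(3 * config$spot_sigma)
      for (s in which(keep)) {
        r0 <- max(1L, floor(cy[s]) - half); r1 <- min(height, ceiling(cy[s]) + half)
        c0 <- max(1L, floor(cx[s]) - half); c1 <- min(width, ceiling(cx[s]) + half)
        if (r0 > r1 || c0 > c1) next
        rr <- r0:r1; cc <- c0:c1
        gy <- exp(-((rr - 1 - cy[s])^2) / (2 * config$spot_sigma^2))
        gx <- exp(-((cc - 1 - cx[s])^2) / (2 * config$spot_sigma^2))
        img[rr, cc] <- img[rr, cc] + config$spot_amplitude * outer(gy, gx)
      }
      img
    }
    rh3 <- render_channel(!on)
    rh4 <- render_channel(on)

    # smooth multiplicative illumination: low-order polynomial field
    u <- (seq_len(height) - 1) / max(1, height - 1) - 0.5
    v <- (seq_len(width) - 1) / max(1, width - 1) - 0.5
    field <- 1 + config$illum_amplitude *
      (outer(u, rep(1, width)) * 0.8 + outer(rep(1, height), v) * 0.6 +
         outer(u, v) * 0.9)
    field <- field / mean(field)

    finish <- function(img) {
      img <- (img + config$background) * field
      img <- img + matrix(rnorm(height * width, 0, config$noise_sd),
                          height, width)
      pmax(img, 0)
    }
    list(image = retina_image(finish(rh3), finish(rh4)), truth = truth)
  })
}
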