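# Automated R7 photoreceptor identification and ON/OFF counting.
#
# The chain mirrors the classic microscopy recipe: homomorphic denoising
# (log-domain high-pass removes multiplicative illumination) + Gaussian
# blur, Canny edge detection, convex-hull rough segmentation of edge
# components, region-based active-contour refinement, marker-controlled
# watershed partitioning, size/eccentricity filtering, and per-region
# two-channel intensity classification.

#' Segmentation parameters
#'
#' All numeric knobs of the counting chain, with defaults tuned on the
#' synthetic retina generator; the operator sequence is fixed, every
#' numeric setting is configurable here.
#'
#' @param homomorphic_cutoff Normalized spatial frequency of the log-domain
#'   high-pass (0 disables the homomorphic stage).
#' @param gaussian_sigma Post-filter Gaussian blur SD in pixels.
#' @param canny_low,canny_high Hysteresis thresholds as fractions of the
#'   maximum gradient magnitude; `0 < low < high`.
#' @param contour_iterations Active-contour refinement steps.
#' @param min_area,max_area Region area bounds in pixels^2.
#' @param max_center_distance Maximum centroid distance from the image
#'   center, as a fraction of the half-diagonal, in (0, 1].
#' @param intensity_percentile Percentile of each channel used as its
#'   normalization denominator.
#' @param ambiguity_margin Normalized-mean difference below which a region
#'   is called AMBIGUOUS rather than RH3/RH4.
#' @param marker_min_distance Minimum Chebyshev distance (pixels) between
#'   watershed seed maxima.
#' @param min_scored Minimum RH3+RH4 regions for a retina to be scorable.
#' @return An object of class `seg_params`.
#' @export
seg_params <- function(homomorphic_cutoff = 0.03, gaussian_sigma = 1.5,
                       canny_low = 0.08, canny_high = 0.20,
                       contour_iterations = 5L,
                       min_area = 8, max_area = 500,
                       max_center_distance = 0.95,
                       intensity_percentile = 99,
                       ambiguity_margin = 0.05,
                       marker_min_distance = 4L,
                       min_scored = 100L) {
  if (!(canny_low > 0 && canny_low < canny_high)) {
    stop("need 0 < canny_low < canny_high", call. = FALSE)
  }
  if (!(min_area < max_area)) stop("need min_area < max_area", call. = FALSE)
  if (!(max_center_distance > 0 && max_center_distance <= 1)) {
    stop("`max_center_distance` must lie in (0, 1]", call. = FALSE)
  }
  structure(as.list(environment()), class = "seg_params")
}

# ---- low-level raster helpers ----------------------------------------

# separable Gaussian blur with edge renormalization (kernel rows re-sum to
# one near the borders, so constants stay constant)
gauss_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  half <- max(1L, ceiling(3 * sigma))
  band_matrix <- function(n) {
    idx <- seq_len(n)
    K <- outer(idx, idx, function(i, j) {
      d <- abs(i - j)
      ifelse(d <= half, exp(-d^2 / (2 * sigma^2)), 0)
    })
    K / rowSums(K)
  }
  Kr <- band_matrix(nrow(mat))
  Kc <- band_matrix(ncol(mat))
  Kr %*% mat %*% t(Kc)
}

#' Homomorphic denoising
#'
#' Log-transforms the (offset-positive) raster and subtracts the bulk of
#' its Gaussian low-pass component — a log-domain high-emphasis filter that
#' removes the multiplicative illumination field while keeping cell-scale
#' structure — then exponentiates back and finishes with a Gaussian blur.
#' The low-pass scale is `1 / (2 * pi * cutoff)` pixels, and the spatial
#' (edge-renormalized) convolution avoids the wrap-around ringing an FFT
#' implementation would add at image borders.
#'
#' @param channel Non-negative intensity matrix with finite entries.
#' @param cutoff Normalized cutoff frequency of the high-pass (0 skips the
#'   log-domain stage: identity up to the blur).
#' @param gaussian_sigma Blur SD in pixels (0 skips the blur).
#' @param low_gain Residual gain of the low-frequency band (default 0.25;
#'   1 would keep it untouched).
#' @return Denoised matrix of the same shape.
#' @export
homomorphic_denoise <- function(channel, cutoff = 0.03,
                                gaussian_sigma = 1.5, low_gain = 0.25) {
  if (!all(is.finite(channel))) {
    stop("input raster contains non-finite values", call. = FALSE)
  }
  out <- channel
  if (cutoff > 0) {
    # offset only as needed to be strictly positive before the log;
    # shifting an already-positive image would distort the multiplicative
    # model the filter assumes
    offset <- if (min(channel) <= 0) 1 - min(channel) else 0
    lg <- log(channel + offset)
    lp <- gauss_blur(lg, 1 / (2 * pi * cutoff))
    out <- exp(lg - (1 - low_gain) * (lp - mean(lp)))
  }
  gauss_blur(out, gaussian_sigma)
}

# ---- Canny edges ------------------------------------------------------

shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Canny edge detection
#'
#' Sobel gradients, non-maximum suppression along the quantized gradient
#' direction, and hysteresis thresholding: pixels above `canny_high` (as a
#' fraction of the maximum gradient magnitude) seed edges which grow
#' through connected pixels above `canny_low`.
#'
#' @param channel Denoised intensity matrix.
#' @param canny_low,canny_high Thresholds as fractions of the maximum
#'   gradient magnitude, `0 < low < high`.
#' @return Logical matrix of edge pixels (thin curves).
#' @export
detect_boundaries <- function(channel, canny_low = 0.08,
                              canny_high = 0.20) {
  if (!(canny_low > 0 && canny_low < canny_high)) {
    stop("need 0 < canny_low < canny_high", call. = FALSE)
  }
  m <- channel
  # Sobel
  gx <- shift_mat(m, 0, -1) - shift_mat(m, 0, 1) +
    0.5 * (shift_mat(m, -1, -1) - shift_mat(m, -1, 1) +
             shift_mat(m, 1, -1) - shift_mat(m, 1, 1))
  gy <- shift_mat(m, -1, 0) - shift_mat(m, 1, 0) +
    0.5 * (shift_mat(m, -1, -1) - shift_mat(m, 1, -1) +
             shift_mat(m, -1, 1) - shift_mat(m, 1, 1))
  mag <- sqrt(gx^2 + gy^2)
  mmax <- max(mag)
  if (mmax == 0) return(matrix(FALSE, nrow(m), ncol(m)))
  # non-maximum suppression along quantized gradient direction
  ang <- atan2(gy, gx) %% pi
  bin <- findInterval(ang, c(pi / 8, 3 * pi / 8, 5 * pi / 8, 7 * pi / 8)) %% 4
  # bin 0: horizontal gradient -> compare left/right; 1: diagonal /;
  # bin 2: vertical gradient -> compare up/down; 3: diagonal \
  nbr <- list(c(0, 1), c(-1, 1), c(1, 0), c(1, 1))
  keep <- matrix(FALSE, nrow(m), ncol(m))
  for (b in 0:3) {
    d <- nbr[[b + 1L]]
    n1 <- shift_mat(mag, d[1], d[2])
    n2 <- shift_mat(mag, -d[1], -d[2])
    keep <- keep | (bin == b & mag >= n1 & mag >= n2)
  }
  strong <- keep & (mag >= canny_high * mmax)
  weak <- keep & (mag >= canny_low * mmax)
  .cpp_hysteresis(strong, weak)
}

# ---- rough segmentation ----------------------------------------------

# fill the convex hull of a point set (0-based row/col) on an nr x nc grid;
# returns a 2-col matrix of 0-based pixel coordinates
fill_convex_hull <- function(pts, nr, nc) {
  if (nrow(pts) < 3L) return(pts)
  hull <- pts[chull(pts[, 2L], pts[, 1L]), , drop = FALSE]
  nh <- nrow(hull)
  if (nh < 3L) return(pts)
  # orientation-agnostic: points must fall on the same side of every edge
  # as the hull's signed area indicates
  nxt <- c(seq_len(nh)[-1L], 1L)
  area2 <- sum((hull[, 2L] * hull[nxt, 1L]) - (hull[nxt, 2L] * hull[, 1L]))
  sgn <- if (area2 >= 0) 1 else -1
  r0 <- max(0L, floor(min(hull[, 1L]))); r1 <- min(nr - 1L, ceiling(max(hull[, 1L])))
  c0 <- max(0L, floor(min(hull[, 2L]))); c1 <- min(nc - 1L, ceiling(max(hull[, 2L])))
  grid <- expand.grid(row = r0:r1, col = c0:c1)
  inside <- rep(TRUE, nrow(grid))
  for (i in seq_len(nh)) {
    a <- hull[i, ]; b <- hull[nxt[i], ]
    cross <- (b[2L] - a[2L]) * (grid$row - a[1L]) -
      (b[1L] - a[1L]) * (grid$col - a[2L])
    inside <- inside & sgn * cross >= -1e-9
  }
  as.matrix(grid[inside, c("row", "col"), drop = FALSE])
}

#' Rough segmentation by convex hulls of edge components
#'
#' Labels 8-connected components of the edge map and fills the convex hull
#' of each, yielding one candidate cell region per closed (or nearly
#' closed) contour.
#'
#' @param edges Logical edge matrix from [detect_boundaries()].
#' @param min_component Minimum edge pixels for a component to seed a
#'   candidate (default 6; suppresses speckle).
#' @return List of candidate regions, each a list with `pixels` (2-column
#'   matrix of 0-based row/col coordinates).
#' @export
rough_segment <- function(edges, min_component = 6L) {
  # label a 1-px dilation so arcs separated by the small gaps non-maximum
  # suppression leaves behind still form one contour; hulls are built from
  # the original edge pixels only
  lab <- .cpp_label_components(dilate_mask(edges, 1L))
  ids <- setdiff(unique(as.vector(lab)), 0L)
  nr <- nrow(edges); nc <- ncol(edges)
  out <- list()
  for (id in ids) {
    idx <- which(lab == id & edges, arr.ind = TRUE)
    if (nrow(idx) < min_component) next
    pts <- cbind(idx[, 1L] - 1L, idx[, 2L] - 1L)
    out[[length(out) + 1L]] <- list(pixels = fill_convex_hull(pts, nr, nc))
  }
  out
}

# ---- active-contour refinement ---------------------------------------

# region mask helpers: regions carry 0-based coordinates
region_mask <- function(pixels, nr, nc) {
  m <- matrix(FALSE, nr, nc)
  m[pixels[, 1L] + 1L + pixels[, 2L] * nr] <- TRUE
  m
}

dilate_mask <- function(m, times = 1L) {
  for (i in seq_len(times)) {
    m <- m | shift_mat(m, 1, 0, FALSE) | shift_mat(m, -1, 0, FALSE) |
      shift_mat(m, 0, 1, FALSE) | shift_mat(m, 0, -1, FALSE) |
      shift_mat(m, 1, 1, FALSE) | shift_mat(m, 1, -1, FALSE) |
      shift_mat(m, -1, 1, FALSE) | shift_mat(m, -1, -1, FALSE)
  }
  m
}

#' Region-based active-contour refinement
#'
#' A Chan-Vese-style binary evolution: at each step a pixel (within a
#' bounded dilation of the input hull) joins the region if its intensity is
#' closer to the current region mean than to the local background mean.
#' With zero iterations the regions pass through unchanged.
#'
#' @param regions Candidate regions from [rough_segment()].
#' @param channel Denoised intensity matrix the contours evolve on.
#' @param contour_iterations Maximum refinement steps.
#' @param max_dilate Bound (pixels) on how far a contour may expand beyond
#'   its input hull.
#' @return Refined region list in the same format.
#' @export
refine_contours <- function(regions, channel, contour_iterations = 5L,
                            max_dilate = 2L) {
  if (contour_iterations <= 0L || length(regions) == 0L) return(regions)
  nr <- nrow(channel); nc <- ncol(channel)
  pad <- max_dilate + 2L
  lapply(regions, function(reg) {
    px <- reg$pixels
    # work on the cropped bounding box (plus the dilation margin)
    r0 <- max(0L, min(px[, 1L]) - pad); r1 <- min(nr - 1L, max(px[, 1L]) + pad)
    c0 <- max(0L, min(px[, 2L]) - pad); c1 <- min(nc - 1L, max(px[, 2L]) + pad)
    sub <- channel[(r0:r1) + 1L, (c0:c1) + 1L, drop = FALSE]
    snr <- nrow(sub); snc <- ncol(sub)
    mask <- matrix(FALSE, snr, snc)
    mask[(px[, 1L] - r0) + 1L + (px[, 2L] - c0) * snr] <- TRUE
    domain <- dilate_mask(mask, max_dilate)
    ring <- dilate_mask(domain, 2L) & !domain
    bg <- if (any(ring)) mean(sub[ring]) else min(sub)
    cur <- mask
    for (it in seq_len(contour_iterations)) {
      mu <- mean(sub[cur])
      nxt <- domain & (abs(sub - mu) < abs(sub - bg))
      if (!any(nxt)) break
      if (identical(nxt, cur)) { cur <- nxt; break }
      cur <- nxt
    }
    if (!any(cur)) return(reg)
    idx <- which(cur, arr.ind = TRUE)
    list(pixels = cbind(idx[, 1L] - 1L + r0, idx[, 2L] - 1L + c0))
  })
}

# ---- watershed --------------------------------------------------------

# strict local maxima of a matrix within Chebyshev radius `min_distance`,
# restricted to `mask`; returns 1-based index matrix
local_maxima <- function(mat, min_distance = 4L, mask = NULL) {
  mx <- mat
  for (i in seq_len(min_distance)) {
    mx <- pmax(mx, shift_mat(mx, 1, 0, -Inf), shift_mat(mx, -1, 0, -Inf),
               shift_mat(mx, 0, 1, -Inf), shift_mat(mx, 0, -1, -Inf),
               shift_mat(mx, 1, 1, -Inf), shift_mat(mx, 1, -1, -Inf),
               shift_mat(mx, -1, 1, -Inf), shift_mat(mx, -1, -1, -Inf))
  }
  is_max <- mat == mx
  if (!is.null(mask)) is_max <- is_max & mask
  which(is_max, arr.ind = TRUE)
}

#' Marker-controlled watershed partition
#'
#' Floods the combined-intensity image from seed markers in order of
#' decreasing intensity, assigning every masked pixel to exactly one label
#' and splitting touching cells along intensity valleys.
#'
#' @param image A [retina_image()].
#' @param regions Refined regions supplying the flooding mask (their
#'   union) and, when `markers` is `NULL`, the seeds (local maxima of the
#'   summed channels within the mask).
#' @param markers Optional integer matrix of seed labels (> 0) to override
#'   the automatic maxima.
#' @param marker_min_distance Minimum Chebyshev spacing of automatic seeds.
#' @return Integer label matrix (0 = background). A warning is emitted and
#'   an all-zero labeling returned when no seeds exist.
#' @export
watershed_partition <- function(image, regions, markers = NULL,
                                marker_min_distance = 4L) {
  stopifnot(inherits(image, "retina_image"))
  combined <- image$rh3 + image$rh4
  nr <- nrow(combined); nc <- ncol(combined)
  if (length(regions) == 0L && is.null(markers)) {
    warning("no seed regions: empty labeling")
    return(matrix(0L, nr, nc))
  }
  mask <- matrix(FALSE, nr, nc)
  for (reg in regions) mask <- mask | region_mask(reg$pixels, nr, nc)
  if (is.null(markers)) {
    sm <- gauss_blur(combined, 1)
    pk <- local_maxima(sm, marker_min_distance, mask)
    if (nrow(pk) == 0L) {
      warning("no seeds found: empty labeling")
      return(matrix(0L, nr, nc))
    }
    markers <- matrix(0L, nr, nc)
    markers[pk] <- seq_len(nrow(pk))
  } else {
    mask <- mask | markers > 0L
  }
  .cpp_watershed(combined, markers, mask)
}

# ---- filtering and classification ------------------------------------

label_stats <- function(labels) {
  ids <- sort(setdiff(unique(as.vector(labels)), 0L))
  if (length(ids) == 0L) {
    return(data.frame(label = integer(0L), area = integer(0L),
                      centroid_row = numeric(0L), centroid_col = numeric(0L)))
  }
  idx <- which(labels > 0L, arr.ind = TRUE)
  lab <- labels[labels > 0L]
  area <- as.integer(table(factor(lab, levels = ids)))
  cr <- tapply(idx[, 1L] - 1, factor(lab, levels = ids), mean)
  cc <- tapply(idx[, 2L] - 1, factor(lab, levels = ids), mean)
  data.frame(label = ids, area = area,
             centroid_row = as.numeric(cr), centroid_col = as.numeric(cc))
}

#' Filter labeled regions by size and distance from the image center
#'
#' Removes regions outside `[min_area, max_area]` or with centroid farther
#' than `max_center_distance` (as a fraction of the image half-diagonal)
#' from the image center — the guard against artifacts from retinal
#' curvature at the image periphery. Never adds regions; relaxing the
#' bounds to `(0, Inf)` and distance to 1 retains everything.
#'
#' @param labels Integer label matrix.
#' @param min_area,max_area Area bounds in pixels^2.
#' @param max_center_distance Fraction of the half-diagonal, in (0, 1].
#' @return The label matrix with excluded regions zeroed.
#' @export
filter_regions <- function(labels, min_area = 8, max_area = 500,
                           max_center_distance = 0.95) {
  st <- label_stats(labels)
  if (nrow(st) == 0L) return(labels)
  nr <- nrow(labels); nc <- ncol(labels)
  ctr <- c((nr - 1) / 2, (nc - 1) / 2)
  half_diag <- sqrt(sum(ctr^2))
  dist <- sqrt((st$centroid_row - ctr[1L])^2 + (st$centroid_col - ctr[2L])^2)
  drop <- st$label[st$area < min_area | st$area > max_area |
                     dist > max_center_distance * half_diag]
  if (length(drop)) labels[labels %in% drop] <- 0L
  labels
}

#' Classify labeled regions as RH3, RH4 or ambiguous
#'
#' Each region's mean intensity in each channel is normalized to a
#' background-corrected contrast,
#' `(mean - median(channel)) / (percentile(channel) - median(channel))`,
#' computed over the whole image. The median estimates the channel's
#' background and the high percentile its signal level, so a channel with
#' no true signal (all cells OFF in that reporter) normalizes to ~0
#' instead of letting noise win. The region is called for the channel with
#' the larger contrast, or AMBIGUOUS when the two differ by at most
#' `ambiguity_margin`.
#'
#' @param labels Filtered integer label matrix.
#' @param image A [retina_image()].
#' @param intensity_percentile Normalization percentile (default 99).
#' @param ambiguity_margin Call margin on the normalized scale.
#' @return Data frame of class `r7_regions`: `label`, `area`,
#'   `centroid_row`, `centroid_col`, `mean_rh3`, `mean_rh4`, `norm_rh3`,
#'   `norm_rh4`, `call`.
#' @export
classify_regions <- function(labels, image, intensity_percentile = 99,
                             ambiguity_margin = 0.05) {
  stopifnot(inherits(image, "retina_image"))
  st <- label_stats(labels)
  m3 <- stats::median(image$rh3)
  m4 <- stats::median(image$rh4)
  q3 <- as.numeric(quantile(image$rh3, intensity_percentile / 100)) - m3
  q4 <- as.numeric(quantile(image$rh4, intensity_percentile / 100)) - m4
  if (q3 <= 0) stop("zero normalization denominator in channel rh3",
                    call. = FALSE)
  if (q4 <= 0) stop("zero normalization denominator in channel rh4",
                    call. = FALSE)
  if (nrow(st) == 0L) {
    st$mean_rh3 <- st$mean_rh4 <- st$norm_rh3 <- st$norm_rh4 <- numeric(0L)
    st$call <- character(0L)
    class(st) <- c("r7_regions", "data.frame")
    return(st)
  }
  fac <- factor(labels[labels > 0L], levels = st$label)
  st$mean_rh3 <- as.numeric(tapply(image$rh3[labels > 0L], fac, mean))
  st$mean_rh4 <- as.numeric(tapply(image$rh4[labels > 0L], fac, mean))
  st$norm_rh3 <- (st$mean_rh3 - m3) / q3
  st$norm_rh4 <- (st$mean_rh4 - m4) / q4
  diff <- st$norm_rh4 - st$norm_rh3
  st$call <- ifelse(diff > ambiguity_margin, "RH4",
                    ifelse(diff < -ambiguity_margin, "RH3", "AMBIGUOUS"))
  class(st) <- c("r7_regions", "data.frame")
  st
}

# ---- end-to-end -------------------------------------------------------

#' Count the ON/OFF photoreceptor mosaic of a retina image
#'
#' Runs the full chain — homomorphic denoising of both channels, Canny
#' edges on the combined image, convex-hull rough segmentation,
#' active-contour refinement, watershed partitioning, size/center
#' filtering, and two-channel classification — and tallies RH3 (OFF), RH4
#' (ON) and ambiguous regions. Deterministic for fixed inputs.
#'
#' @param image A [retina_image()].
#' @param params A [seg_params()].
#' @return An object of class `mosaic_count`: list with `n_rh3`, `n_rh4`,
#'   `n_ambiguous`, `pct_on` (`100 * n_rh4 / (n_rh3 + n_rh4)`, `NA` when no
#'   region is called), `scorable` (at least `min_scored` called regions),
#'   and the per-region `regions` data frame.
#' @export
count_mosaic <- function(image, params = seg_params()) {
  stopifnot(inherits(image, "retina_image"), inherits(params, "seg_params"))
  d3 <- homomorphic_denoise(image$rh3, params$homomorphic_cutoff,
                            params$gaussian_sigma)
  d4 <- homomorphic_denoise(image$rh4, params$homomorphic_cutoff,
                            params$gaussian_sigma)
  combined <- d3 + d4
  edges <- detect_boundaries(combined, params$canny_low, params$canny_high)
  rough <- rough_segment(edges)
  refined <- refine_contours(rough, combined, params$contour_iterations)
  denoised <- retina_image(pmax(d3, 0), pmax(d4, 0))
  labels <- watershed_partition(denoised, refined,
                                marker_min_distance = params$marker_min_distance)
  labels <- filter_regions(labels, params$min_area, params$max_area,
                           params$max_center_distance)
  regions <- classify_regions(labels, image, params$intensity_percentile,
                              params$ambiguity_margin)
  n3 <- sum(regions$call == "RH3")
  n4 <- sum(regions$call == "RH4")
  structure(list(n_rh3 = n3, n_rh4 = n4,
                 n_ambiguous = sum(regions$call == "AMBIGUOUS"),
                 pct_on = if (n3 + n4 > 0) 100 * n4 / (n3 + n4) else NA_real_,
                 scorable = (n3 + n4) >= params$min_scored,
                 regions = regions),
            class = "mosaic_count")
}

#' @export
print.mosaic_count <- function(x, ...) {
  cat(sprintf(
    "<mosaic_count> RH3 (OFF): %d  RH4 (ON): %d  ambiguous: %d  %%ON: %s%s\n",
    x$n_rh3, x$n_rh4, x$n_ambiguous,
    ifelse(is.na(x$pct_on), "NA", sprintf("%.1f", x$pct_on)),
    if (x$scorable) "" else "  [below scoring floor]"))
  invisible(x)
}

#' Mean intensity within circular regions of interest
#'
#' @param channel Intensity matrix.
#' @param centers n x 2 matrix of 0-based (row, col) ROI centers.
#' @param radius ROI radius in pixels (> 0).
#' @return Numeric vector of per-ROI mean intensities, in input order.
#'   An ROI entirely outside the image raises an error naming its index.
#' @export
roi_mean_intensity <- function(channel, centers, radius) {
  if (radius <= 0) stop("`radius` must be > 0", call. = FALSE)
  centers <- matrix(centers, ncol = 2L)
  nr <- nrow(channel); nc <- ncol(channel)
  vapply(seq_len(nrow(centers)), function(i) {
    cr <- centers[i, 1L]; cc <- centers[i, 2L]
    r0 <- max(0, floor(cr - radius)); r1 <- min(nr - 1, ceiling(cr + radius))
    c0 <- max(0, floor(cc - radius)); c1 <- min(nc - 1, ceiling(cc + radius))
    if (r0 > r1 || c0 > c1) {
      stop(sprintf("ROI %d lies entirely outside the image", i),
           call. = FALSE)
    }
    g <- expand.grid(row = r0:r1, col = c0:c1)
    g <- g[(g$row - cr)^2 + (g$col - cc)^2 <= radius^2, , drop = FALSE]
    if (nrow(g) == 0L) {
      stop(sprintf("ROI %d covers no pixel centers", i), call. = FALSE)
    }
    mean(channel[cbind(g$row + 1L, g$col + 1L)])
  }, numeric(1L))
}
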