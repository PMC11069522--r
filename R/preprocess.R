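# Gaze-stream preprocessing: screen-to-image mapping, Gaussian density maps,
# area-normalised region weights, and the per-trial weight table.

#' Map screen-coordinate gaze samples onto the stimulus image
#'
#' Subtracts the centred-placement offset
#' `((screen_w - img_w) / 2, (screen_h - img_h) / 2)` and discards samples
#' falling outside the image rectangle (discarded, not clipped: clipping
#' would pile spurious mass onto border regions). Coordinates are 0-based
#' with origin top-left and pixel centres at integer positions.
#'
#' @param stream Data frame with screen-pixel columns `x` and `y`.
#' @param screen_dims `c(width, height)` of the screen (default 1920 x 1080).
#' @param image_dims `c(width, height)` of the stimulus (default 412 x 558).
#' @return The stream rows that fall on the image, with `x`, `y` rewritten to
#'   image coordinates.
#' @examples
#' screen_to_image(data.frame(x = 960, y = 540))  # image centre (206, 279)
#' @export
screen_to_image <- function(stream, screen_dims = c(1920, 1080),
                            image_dims = c(412, 558)) {
  if (any(image_dims > screen_dims))
    stop("image larger than screen", call. = FALSE)
  ox <- (screen_dims[1] - image_dims[1]) / 2
  oy <- (screen_dims[2] - image_dims[2]) / 2
  x <- stream$x - ox
  y <- stream$y - oy
  keep <- x >= 0 & x <= image_dims[1] - 1 & y >= 0 & y <= image_dims[2] - 1
  out <- stream[keep, , drop = FALSE]
  out$x <- x[keep]
  out$y <- y[keep]
  out
}

# 1-D Gaussian kernel band matrix (n x n), truncated at 4 SD and renormalised
# so the kernel sums to 1. Cached per (n, sigma).
.kernel_cache <- new.env(parent = emptyenv())
.gauss_band <- function(n, sigma) {
  key <- sprintf("%d_%g", n, sigma)
  if (!is.null(.kernel_cache[[key]])) return(.kernel_cache[[key]])
  r <- ceiling(4 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  idx <- seq_len(n)
  d <- outer(idx, idx, "-")
  K <- matrix(0, n, n)
  inb <- abs(d) <= r
  K[inb] <- k[d[inb] + r + 1]
  .kernel_cache[[key]] <- K
  K
}

#' Gaussian-smoothed gaze density map
#'
#' Accumulates one unit per sample at its (rounded) pixel, convolves with an
#' isotropic Gaussian of the given SD (truncated at 4 SD, kernel
#' renormalised; zero padding at the borders), and divides by the total so
#' the surface sums to 1. An empty sample list yields an all-zero map.
#'
#' @param samples Data frame with image-coordinate columns `x`, `y` (0-based).
#' @param image_dims `c(width, height)` in pixels.
#' @param sigma Gaussian SD in pixels (default 10).
#' @return Numeric matrix (height x width, row = y + 1); non-negative, sums
#'   to 1 when at least one sample is present.
#' @export
density_map <- function(samples, image_dims = c(412, 558), sigma = 10) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  W <- as.integer(image_dims[1]); H <- as.integer(image_dims[2])
  M <- matrix(0, H, W)
  if (nrow(samples) > 0) {
    px <- pmin(pmax(round(samples$x), 0), W - 1)
    py <- pmin(pmax(round(samples$y), 0), H - 1)
    idx <- py + 1 + px * H
    tab <- tabulate(idx, H * W)
    M[] <- tab
    M <- .gauss_band(H, sigma) %*% M %*% .gauss_band(W, sigma)
    M <- M / sum(M)
  }
  M
}

#' Area-normalised raw region weights from a density map
#'
#' For each facial region, the accumulated density over the region's pixels
#' divided by the region's pixel area: the mean per-pixel gaze weight of the
#' region.
#'
#' @param density Density matrix from [density_map()] (height x width).
#' @param masks A `region_mask` of matching dimensions.
#' @return Named numeric vector of 6 raw weights (per-pixel scale).
#' @export
region_weights <- function(density, masks) {
  stopifnot(inherits(masks, "region_mask"))
  if (nrow(density) != masks$height || ncol(density) != masks$width)
    stop("density and masks dimensions differ", call. = FALSE)
  areas <- region_areas(masks)
  if (any(areas == 0)) stop("empty region in mask", call. = FALSE)
  w <- vapply(1:6, function(r) sum(density[masks$labels == r]), numeric(1))
  stats::setNames(w / areas, .REGIONS)
}

#' Rescale raw region weights to the unit dwell-weight scale
#'
#' Converts the six raw area-normalised weights into the dwell weights
#' \eqn{G_n} the ZIB model consumes: values below `epsilon * max(raw)` are
#' zeroed (Gaussian smoothing otherwise leaks a trace of mass into every
#' region, making an exact zero impossible and starving the Bernoulli part),
#' the remainder is divided by the sum of the six raw weights so the trial's
#' weights sum to 1 (or 0 for an all-zero trial), and any weight reaching 1
#' is clamped to `1 - epsilon` to stay inside the Beta support.
#'
#' @param raw Numeric vector of 6 non-negative raw weights.
#' @param epsilon Relative zeroing threshold and clamp margin (default 1e-6).
#' @return Numeric vector of 6 weights in `[0, 1 - epsilon]`, summing to at
#'   most 1.
#' @export
unify_scale <- function(raw, epsilon = 1e-6) {
  if (any(raw < 0)) stop("raw weights must be non-negative", call. = FALSE)
  if (all(raw == 0)) return(stats::setNames(numeric(6), names(raw)))
  total <- sum(raw)
  g <- ifelse(raw < epsilon * max(raw), 0, raw / total)
  pmin(g, 1 - epsilon)
}

#' Build the region-weight table from a dataset bundle
#'
#' For a weight-fidelity bundle the generated weights pass through untouched.
#' For a gaze-fidelity bundle every trial's stream is mapped to image
#' coordinates, smoothed into a density map, reduced to area-normalised
#' region weights and rescaled with [unify_scale()], yielding six rows per
#' trial.
#'
#' @param bundle A `zib_experiment` from [generate_experiment()], or a list
#'   with elements `gaze`, `masks`, `config` in the same layout.
#' @param sigma Density-map Gaussian SD in pixels (default 10).
#' @param epsilon Passed to [unify_scale()].
#' @return Region-weight table: data frame with `participant_id`, `image_id`,
#'   `condition`, `impression`, `region`, `G`.
#' @export
build_weight_table <- function(bundle, sigma = 10, epsilon = 1e-6) {
  if (is.null(bundle$gaze)) return(bundle$weights)
  gaze <- bundle$gaze
  key <- interaction(gaze$participant_id, gaze$image_id, gaze$condition,
                     gaze$impression, drop = TRUE)
  image_dims <- c(bundle$config$width, bundle$config$height)
  rows <- lapply(split(gaze, key), function(tr) {
    mask <- bundle$masks[[tr$image_id[1]]]
    if (is.null(mask))
      stop("no mask for image ", tr$image_id[1], call. = FALSE)
    s <- screen_to_image(tr, screen_dims = bundle$config$screen,
                         image_dims = image_dims)
    d <- density_map(s, image_dims, sigma)
    g <- unify_scale(region_weights(d, mask), epsilon)
    data.frame(participant_id = tr$participant_id[1],
               image_id = tr$image_id[1], condition = tr$condition[1],
               impression = tr$impression[1], region = .REGIONS,
               G = unname(g), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
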