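#' Generate a synthetic participant panel
#'
#' Draws Big Five scores for `n` participants. By default each trait is drawn
#' independently and uniformly from the 7-point grid 1..7, the least
#' structured choice on the questionnaire scale; any discrete support can be
#' substituted via `levels`.
#'
#' @param n Number of participants (>= 1).
#' @param seed Integer seed; same `(n, seed)` reproduces the same table.
#' @param levels Numeric vector of admissible scores, within `[1, 7]`.
#' @return Data frame with `participant_id` and one column per trait in
#'   [big_five_traits()] order.
#' @examples
#' generate_participants(5, seed = 1)
#' @export
generate_participants <- function(n, seed = 1, levels = 1:7) {
  if (length(n) != 1 || !is.finite(n) || n < 1)
    stop("n must be a positive count", call. = FALSE)
  if (any(levels < 1) || any(levels > 7))
    stop("score levels must lie in [1, 7]", call. = FALSE)
  n <- as.integer(n)
  set.seed(seed)
  scores <- matrix(sample(levels, n * 5L, replace = TRUE), n, 5L,
                   dimnames = list(NULL, .TRAITS))
  cbind(data.frame(participant_id = sprintf("P%03d", seq_len(n)),
                   stringsAsFactors = FALSE),
        as.data.frame(scores))
}

#' Aperture model for restricted viewing
#'
#' Circular aperture around the cursor: fully transparent within
#' `hard_radius_px`, with a Gaussian fall-off of scale `falloff_px` beyond it,
#' so visibility is ~0 past `hard_radius_px + 3 * falloff_px`. The default
#' (40 px hard radius, 40 px fall-off) corresponds to a ~2 degree viewing
#' window at a 60 cm monitor distance; [restricted_aperture()] provides the
#' presets used by the two experimental conditions.
#'
#' @param hard_radius_px Radius of full visibility, in pixels.
#' @param falloff_px Gaussian edge scale, in pixels.
#' @return Object of class `aperture_model` with a `visibility(r)` function.
#' @export
aperture_model <- function(hard_radius_px = 40, falloff_px = 40) {
  stopifnot(hard_radius_px > 0, falloff_px > 0)
  structure(list(
    hard_radius_px = hard_radius_px,
    falloff_px = falloff_px,
    visibility = function(r) {
      v <- exp(-((pmax(r, hard_radius_px) - hard_radius_px)^2) /
                 (2 * falloff_px^2))
      ifelse(r <= hard_radius_px, 1, v)
    }), class = "aperture_model")
}

#' Aperture presets for the two restriction levels
#'
#' @param experiment 1 for the narrow (~2 degree, 40 px) aperture, 2 for the
#'   wider (~3 degree, 60 px) aperture; the 3-degree radius is scaled linearly
#'   from the ~80 px total extent of the 2-degree window.
#' @return An [aperture_model()].
#' @export
restricted_aperture <- function(experiment = 1) {
  switch(as.character(experiment),
         "1" = aperture_model(40, 40),
         "2" = aperture_model(60, 60),
         stop("experiment must be 1 or 2", call. = FALSE))
}

# Rasterise a filled ellipse into a label matrix, writing code only over
# background (keeps regions disjoint by construction).
.fill_ellipse <- function(labels, cx, cy, rx, ry, code) {
  H <- nrow(labels); W <- ncol(labels)
  xs <- pmax(0, floor(cx - rx)):pmin(W - 1, ceiling(cx + rx))
  ys <- pmax(0, floor(cy - ry)):pmin(H - 1, ceiling(cy + ry))
  gx <- outer(rep(1, length(ys)), xs)
  gy <- outer(ys, rep(1, length(xs)))
  inside <- ((gx - cx) / rx)^2 + ((gy - cy) / ry)^2 <= 1
  sub <- labels[ys + 1, xs + 1, drop = FALSE]
  sub[inside & sub == 0L] <- code
  labels[ys + 1, xs + 1] <- sub
  labels
}

.fill_rect <- function(labels, x0, x1, y0, y1, code) {
  H <- nrow(labels); W <- ncol(labels)
  xs <- pmax(0, round(x0)):pmin(W - 1, round(x1))
  ys <- pmax(0, round(y0)):pmin(H - 1, round(y1))
  sub <- labels[ys + 1, xs + 1, drop = FALSE]
  sub[sub == 0L] <- code
  labels[ys + 1, xs + 1] <- sub
  labels
}

#' Generate a synthetic facial-region mask
#'
#' Places the six facial regions (eyes, nose, mouth, eyebrows, glabella,
#' forehead) as disjoint ellipses/rectangles in a plausible frontal-face
#' layout on a stimulus canvas: forehead above eyebrows above eyes, glabella
#' between the eyebrows, nose central, mouth lowest. Each `image_id` receives
#' a small seeded jitter so layouts differ across stimuli, standing in for
#' hand-drawn per-photograph masks. Region codes are 1..6 in [face_regions()]
#' order; 0 is background.
#'
#' @param image_id Identifier of the stimulus image.
#' @param width,height Canvas size in pixels (default 412 x 558, the stimulus
#'   size).
#' @param seed Integer seed for the per-image jitter.
#' @return Object of class `region_mask`: list with `image_id`, `width`,
#'   `height` and an integer `labels` matrix (height x width, row = y).
#' @export
generate_face_layout <- function(image_id, width = 412, height = 558,
                                 seed = 1) {
  if (width < 80 || height < 120)
    stop("canvas too small to place six disjoint facial regions",
         call. = FALSE)
  # per-image jitter stream: combine seed with a stable hash of image_id
  h <- sum(utf8ToInt(as.character(image_id)) * seq_along(utf8ToInt(as.character(image_id))))
  set.seed((as.integer(seed) * 131L + h) %% .Machine$integer.max)
  jx <- function(s) stats::rnorm(1, 0, s)
  W <- as.integer(width); H <- as.integer(height)
  labels <- matrix(0L, H, W)
  ex <- 0.17 * W   # eye half-offset from midline
  # order: smaller/critical regions first so nothing eats them
  labels <- .fill_ellipse(labels, 0.5 * W + jx(0.005 * W),
                          0.305 * H + jx(0.003 * H),
                          0.055 * W, 0.028 * H, 5L)          # glabella
  for (s in c(-1, 1)) {
    cx <- 0.5 * W + s * (ex + jx(0.005 * W))
    labels <- .fill_ellipse(labels, cx, 0.295 * H + jx(0.003 * H),
                            0.095 * W, 0.018 * H, 4L)        # eyebrows
    labels <- .fill_ellipse(labels, cx, 0.40 * H + jx(0.003 * H),
                            0.085 * W, 0.032 * H, 1L)        # eyes
  }
  labels <- .fill_ellipse(labels, 0.5 * W + jx(0.004 * W),
                          0.55 * H + jx(0.004 * H),
                          0.07 * W, 0.085 * H, 2L)           # nose
  labels <- .fill_ellipse(labels, 0.5 * W + jx(0.004 * W),
                          0.72 * H + jx(0.004 * H),
                          0.12 * W, 0.04 * H, 3L)            # mouth
  labels <- .fill_rect(labels, 0.27 * W + jx(0.006 * W), 0.73 * W + jx(0.006 * W),
                       0.12 * H + jx(0.004 * H), 0.235 * H, 6L)  # forehead
  areas <- tabulate(labels[labels > 0], 6L)
  if (any(areas == 0))
    stop("canvas too small to place six disjoint facial regions",
         call. = FALSE)
  structure(list(image_id = as.character(image_id), width = W, height = H,
                 labels = labels), class = "region_mask")
}

#' Pixel areas of the six regions of a mask
#'
#' @param mask A `region_mask`.
#' @return Named integer vector of pixel counts, in [face_regions()] order.
#' @export
region_areas <- function(mask) {
  stopifnot(inherits(mask, "region_mask"))
  stats::setNames(tabulate(mask$labels[mask$labels > 0], 6L), .REGIONS)
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("Facial region mask '%s' (%d x %d px)\n", x$image_id,
              x$width, x$height))
  print(region_areas(x))
  invisible(x)
}

# Target points for sample placement in a region: the region centroid, or the
# left/right component centroids for bilateral regions whose joint centroid
# falls outside the region (eyes, eyebrows).
.region_targets <- function(mask, code) {
  idx <- which(mask$labels == code, arr.ind = TRUE)
  x <- idx[, 2] - 1; y <- idx[, 1] - 1
  cx <- mean(x); cy <- mean(y)
  on_region <- mask$labels[round(cy) + 1, round(cx) + 1] == code
  if (on_region) return(cbind(x = cx, y = cy))
  left <- x < cx
  rbind(c(mean(x[left]), mean(y[left])), c(mean(x[!left]), mean(y[!left])))
}

#' Trial design descriptor
#'
#' @param participant_id,image_id Identifiers.
#' @param condition `"free"` or `"restricted"`.
#' @param impression Impression-rating item (one of [big_five_traits()]).
#' @param duration_s Observation time in seconds (default 3).
#' @param sample_rate_hz Eye-tracker sampling rate (default 120).
#' @return Object of class `trial_design`. The per-trial sample budget is
#'   `duration_s * sample_rate_hz` (360 by default).
#' @export
trial_design <- function(participant_id, image_id,
                         condition = c("free", "restricted"),
                         impression = "conscientiousness",
                         duration_s = 3, sample_rate_hz = 120) {
  condition <- match.arg(condition)
  if (!impression %in% .TRAITS)
    stop("impression must be a Big Five item", call. = FALSE)
  stopifnot(duration_s > 0, sample_rate_hz > 0)
  structure(list(participant_id = as.character(participant_id),
                 image_id = as.character(image_id), condition = condition,
                 impression = impression, duration_s = duration_s,
                 sample_rate_hz = sample_rate_hz),
            class = "trial_design")
}

#' Draw one trial's region dwell weights from the generative ZIB model
#'
#' For each region: compute `q` and `mu` through [link_q()] / [link_mu()] with
#' the supplied random effects, draw the Bernoulli indicator, and on success a
#' Beta(`phi * mu`, `phi * (1 - mu)`) weight (clamped below 1). Uses the
#' current RNG state; seed externally for reproducibility.
#'
#' @param params A [zib_params()] shared by all regions, or a list of 6 (one
#'   per region in [face_regions()] order).
#' @param personality_row Numeric vector of 5 trait scores in `[1, 7]`, or a
#'   one-row slice of a personality table.
#' @param subject_effect,picture_effect Numeric vectors
#'   `c(bern = ..., beta = ...)`: the realised random effects of this
#'   participant / image (default zero).
#' @return Named numeric vector of 6 weights in `[0, 1)`.
#' @export
sample_trial_weights <- function(params, personality_row,
                                 subject_effect = c(bern = 0, beta = 0),
                                 picture_effect = c(bern = 0, beta = 0)) {
  if (inherits(params, "zib_params")) params <- rep(list(params), 6)
  stopifnot(length(params) == 6)
  if (is.data.frame(personality_row))
    personality_row <- as.numeric(personality_row[1, .TRAITS])
  if (any(personality_row < 1) || any(personality_row > 7))
    stop("trait scores must lie in [1, 7]", call. = FALSE)
  w <- numeric(6)
  for (r in 1:6) {
    p <- params[[r]]
    q <- link_q(personality_row, p$alpha_bern, p$beta_bern,
                subject_effect[["bern"]], picture_effect[["bern"]])
    if (!is.finite(q)) stop("non-finite linear predictor", call. = FALSE)
    if (stats::rbinom(1, 1, q) == 1) {
      mu <- link_mu(personality_row, p$alpha_beta, p$beta_beta,
                    subject_effect[["beta"]], picture_effect[["beta"]])
      sh <- beta_shapes(p$phi, mu)
      w[r] <- min(stats::rbeta(1, sh$a, sh$b), 1 - 1e-6)
    }
  }
  stats::setNames(w, .REGIONS)
}

#' Synthesise a gaze stream realising target region dwell weights
#'
#' Allocates the trial's sample budget (`duration_s * sample_rate_hz`) across
#' regions proportionally to `target_weights`, with the remainder spent on
#' background pixels (transitions). Region samples are placed at the region's
#' target point(s) (centroid, or the two component centroids of bilateral
#' regions) plus isotropic Gaussian jitter, in screen coordinates with the
#' stimulus centred on screen. Under the free condition the sample order is
#' shuffled (saccade-like jumps); under the restricted condition the samples
#' are ordered as a cursor path that starts at the canvas centre and visits
#' regions sequentially, the single-trajectory reading of cursor-contingent
#' viewing where gaze follows the aperture.
#'
#' @param trial A [trial_design()].
#' @param target_weights Numeric vector of 6 dwell allocations summing to at
#'   most 1 (any excess is rescaled).
#' @param masks A `region_mask` for the trial's image.
#' @param aperture An [aperture_model()] for the restricted condition, or
#'   `NULL` (free viewing). Recorded as an attribute; the collapsed
#'   gaze-equals-cursor trajectory does not itself depend on the aperture
#'   radius.
#' @param seed Integer seed.
#' @param jitter_sd Isotropic jitter SD around target points, in pixels
#'   (default 10).
#' @param screen Screen size in pixels, default `c(1920, 1080)`.
#' @return Data frame with columns `t`, `x`, `y` (screen coordinates,
#'   origin top-left, 0-based) and the trial fields as columns; at most
#'   `duration_s * sample_rate_hz` rows, timestamps strictly increasing in
#'   `[0, duration_s)`.
#' @export
generate_gaze_stream <- function(trial, target_weights, masks, aperture = NULL,
                                 seed = 1, jitter_sd = 10,
                                 screen = c(1920, 1080)) {
  stopifnot(inherits(trial, "trial_design"), inherits(masks, "region_mask"))
  w <- as.numeric(target_weights)
  if (length(w) != 6 || any(w < 0))
    stop("target_weights must be 6 non-negative values", call. = FALSE)
  if (sum(w) > 1) w <- w / sum(w)
  set.seed(seed)
  n <- round(trial$duration_s * trial$sample_rate_hz)
  counts <- round(w * n)
  while (sum(counts) > n) counts[which.max(counts)] <- counts[which.max(counts)] - 1L
  n_bg <- n - sum(counts)
  off_x <- (screen[1] - masks$width) / 2
  off_y <- (screen[2] - masks$height) / 2
  pieces <- list()
  for (r in which(counts > 0)) {
    tg <- .region_targets(masks, r)
    if (nrow(tg) == 0) stop("empty region selected", call. = FALSE)
    pick <- rep_len(seq_len(nrow(tg)), counts[r])
    pieces[[length(pieces) + 1]] <- data.frame(
      region = r,
      x = tg[pick, 1] + stats::rnorm(counts[r], 0, jitter_sd),
      y = tg[pick, 2] + stats::rnorm(counts[r], 0, jitter_sd))
  }
  if (n_bg > 0) {
    bg <- which(masks$labels == 0L, arr.ind = TRUE)
    k <- bg[sample.int(nrow(bg), n_bg, replace = TRUE), , drop = FALSE]
    pieces[[length(pieces) + 1]] <- data.frame(
      region = 0, x = k[, 2] - 1, y = k[, 1] - 1)
  }
  s <- do.call(rbind, pieces)
  if (trial$condition == "free") {
    s <- s[sample.int(nrow(s)), ]
  } else {
    # cursor path: visit regions in order of distance from the canvas centre
    cx <- masks$width / 2; cy <- masks$height / 2
    key <- vapply(split(seq_len(nrow(s)), s$region), function(ix)
      sqrt((mean(s$x[ix]) - cx)^2 + (mean(s$y[ix]) - cy)^2), numeric(1))
    ord <- order(key[as.character(s$region)], s$region)
    s <- s[ord, ]
  }
  out <- data.frame(participant_id = trial$participant_id,
                    image_id = trial$image_id,
                    condition = trial$condition,
                    impression = trial$impression,
                    t = (seq_len(nrow(s)) - 1) / trial$sample_rate_hz,
                    x = s$x + off_x, y = s$y + off_y)
  attr(out, "aperture") <- aperture
  out
}

#' Experiment configuration for the synthetic generator
#'
#' Defaults reproduce the study design: 42 participants, 10 images per
#' impression item, the 5 Big Five impression items (50 trials per participant
#' per condition), free and restricted conditions, 3 s of 120 Hz gaze on a
#' 412 x 558 stimulus centred in a 1920 x 1080 screen.
#'
#' @param participants Number of participants.
#' @param images_per_impression Images fixed to each impression item.
#' @param impressions Impression items (subset of [big_five_traits()]).
#' @param conditions Viewing conditions to generate.
#' @param fidelity `"weights"` (emit region dwell weights directly from the
#'   generative model) or `"gaze"` (additionally synthesise gaze streams so
#'   the preprocessing stage can be exercised end to end).
#' @param duration_s,sample_rate_hz Trial length and sampling rate.
#' @param width,height Stimulus canvas in pixels.
#' @param screen Screen size in pixels.
#' @param jitter_sd Gaze placement jitter (pixels), gaze fidelity only.
#' @param aperture Aperture preset for the restricted condition (see
#'   [restricted_aperture()]).
#' @param trials_per_condition Optional cross-check: if supplied it must equal
#'   `images_per_impression * length(impressions)`.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(participants = 42, images_per_impression = 10,
                              impressions = big_five_traits(),
                              conditions = c("free", "restricted"),
                              fidelity = c("weights", "gaze"),
                              duration_s = 3, sample_rate_hz = 120,
                              width = 412, height = 558,
                              screen = c(1920, 1080), jitter_sd = 10,
                              aperture = restricted_aperture(1),
                              trials_per_condition = NULL) {
  fidelity <- match.arg(fidelity)
  stopifnot(participants >= 1, images_per_impression >= 1,
            all(impressions %in% .TRAITS),
            all(conditions %in% c("free", "restricted")))
  n_trials <- images_per_impression * length(impressions)
  if (!is.null(trials_per_condition) && trials_per_condition != n_trials)
    stop(sprintf(
      "inconsistent config: %d images x %d impressions != %d trials per condition",
      images_per_impression, length(impressions), trials_per_condition),
      call. = FALSE)
  structure(list(participants = as.integer(participants),
                 images_per_impression = as.integer(images_per_impression),
                 impressions = impressions, conditions = conditions,
                 fidelity = fidelity, duration_s = duration_s,
                 sample_rate_hz = sample_rate_hz,
                 width = as.integer(width), height = as.integer(height),
                 screen = as.integer(screen), jitter_sd = jitter_sd,
                 aperture = aperture,
                 trials_per_condition = n_trials),
            class = "experiment_config")
}

# Baseline per-region rates of the default ground truth: probability of any
# dwell (q at the scale midpoint) and mean dwell share given dwell (mu).
.BASE_Q <- c(eyes = 0.85, nose = 0.80, mouth = 0.60, eyebrows = 0.50,
             glabella = 0.45, forehead = 0.70)
.BASE_MU <- c(eyes = 0.35, nose = 0.25, mouth = 0.15, eyebrows = 0.08,
              glabella = 0.05, forehead = 0.12)

#' Ground-truth parameters for the synthetic experiment
#'
#' Builds one [zib_params()] per (condition, impression, region). Baseline
#' rates give each region a realistic dwell probability and dwell share at
#' the trait-scale midpoint; under the restricted condition the dwell
#' probabilities are shifted up (+0.5 logit), reflecting that an aperture
#' forces at least a brief visit to most regions. With `effect = "moderate"`
#' each cell receives one nonzero Bernoulli coefficient (|0.3| logit per
#' scale point) and one nonzero Beta coefficient (|0.15|) on seeded traits;
#' `effect = "null"` plants all coefficients at zero. Intercepts absorb the
#' planted effect at the midpoint profile so baseline rates are preserved.
#'
#' @param config An [experiment_config()].
#' @param seed Integer seed for the trait/sign choices.
#' @param effect `"moderate"` or `"null"`.
#' @param phi Beta precision of the truth (default 10).
#' @param sigma Random-effect scale of the truth (default 0.8).
#' @return Object of class `zib_truth`: list with `params` (named by
#'   `condition|impression|region`), realised `effects` per cell, and the
#'   generating `seed`.
#' @export
default_ground_truth <- function(config, seed = 1,
                                 effect = c("moderate", "null"),
                                 phi = 10, sigma = 0.8) {
  effect <- match.arg(effect)
  set.seed(seed)
  params <- list(); effects <- list()
  subj <- sprintf("P%03d", seq_len(config$participants))
  n_img <- config$images_per_impression * length(config$impressions)
  imgs_all <- sprintf("img%03d", seq_len(n_img))
  for (cond in config$conditions) {
    shift <- if (cond == "restricted") 0.5 else 0
    for (ii in seq_along(config$impressions)) {
      imp <- config$impressions[ii]
      imgs <- imgs_all[((ii - 1) * config$images_per_impression + 1):
                         (ii * config$images_per_impression)]
      for (reg in .REGIONS) {
        bb <- numeric(5); bB <- numeric(5)
        if (effect == "moderate") {
          bb[sample.int(5, 1)] <- sample(c(-0.3, 0.3), 1)
          bB[sample.int(5, 1)] <- sample(c(-0.15, 0.15), 1)
        }
        p <- zib_params(
          alpha_bern = stats::qlogis(.BASE_Q[[reg]]) + shift - sum(bb * 4),
          beta_bern = bb,
          alpha_beta = stats::qlogis(.BASE_MU[[reg]]) - sum(bB * 4),
          beta_beta = bB,
          phi = phi,
          sigma_subj_bern = sigma, sigma_pic_bern = sigma,
          sigma_subj_beta = sigma, sigma_pic_beta = sigma)
        key <- paste(cond, imp, reg, sep = "|")
        params[[key]] <- p
        effects[[key]] <- list(
          r_subj_bern = stats::setNames(stats::rnorm(length(subj), 0, sigma), subj),
          r_pic_bern = stats::setNames(stats::rnorm(length(imgs), 0, sigma), imgs),
          r_subj_beta = stats::setNames(stats::rnorm(length(subj), 0, sigma), subj),
          r_pic_beta = stats::setNames(stats::rnorm(length(imgs), 0, sigma), imgs))
      }
    }
  }
  structure(list(params = params, effects = effects, seed = as.integer(seed)),
            class = "zib_truth")
}

#' Generate a complete synthetic experiment
#'
#' Produces a reproducible dataset bundle with the statistical structure the
#' ZIB analysis assumes: a participant panel, per-image region masks, and
#' dwell weights drawn from a ground-truth ZIB model per (condition,
#' impression, region) cell with realised participant/image random effects.
#' At `"gaze"` fidelity every trial additionally gets a synthetic 120 Hz gaze
#' stream realising its drawn weights, so the preprocessing stage can be
#' tested end to end.
#'
#' @param config An [experiment_config()].
#' @param seed Integer root seed; the whole bundle is a pure function of
#'   `(config, seed)`.
#' @param truth Optional [default_ground_truth()]-style object; built with
#'   `effect = "moderate"` when missing.
#' @return Object of class `zib_experiment`: list with `personality`, `masks`
#'   (named list of `region_mask`), `weights` (the region-weight table; at
#'   gaze fidelity these are the planted per-trial allocations), `gaze`
#'   (data frame of samples, or `NULL`), `truth`, `config`, `seed`.
#' @export
generate_experiment <- function(config = experiment_config(), seed = 1,
                                truth = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(truth)) truth <- default_ground_truth(config, seed = seed)
  personality <- generate_participants(config$participants, seed = seed)
  n_img <- config$images_per_impression * length(config$impressions)
  imgs_all <- sprintf("img%03d", seq_len(n_img))
  masks <- lapply(imgs_all, generate_face_layout, width = config$width,
                  height = config$height, seed = seed)
  names(masks) <- imgs_all

  set.seed(seed)
  rows <- list()
  for (cond in config$conditions) {
    for (ii in seq_along(config$impressions)) {
      imp <- config$impressions[ii]
      imgs <- imgs_all[((ii - 1) * config$images_per_impression + 1):
                         (ii * config$images_per_impression)]
      keys <- paste(cond, imp, .REGIONS, sep = "|")
      pars <- truth$params[keys]
      effs <- truth$effects[keys]
      grid <- expand.grid(si = seq_len(nrow(personality)),
                          img = imgs, stringsAsFactors = FALSE)
      P <- as.matrix(personality[grid$si, .TRAITS])
      w <- matrix(0, nrow(grid), 6)
      for (r in 1:6) {
        p <- pars[[r]]; e <- effs[[r]]
        rs_b <- e$r_subj_bern[personality$participant_id[grid$si]]
        rp_b <- e$r_pic_bern[grid$img]
        rs_B <- e$r_subj_beta[personality$participant_id[grid$si]]
        rp_B <- e$r_pic_beta[grid$img]
        q <- link_q(P, p$alpha_bern, p$beta_bern, rs_b, rp_b)
        mu <- link_mu(P, p$alpha_beta, p$beta_beta, rs_B, rp_B)
        z <- stats::rbinom(nrow(grid), 1, q)
        sh <- beta_shapes(p$phi, mu)
        w[, r] <- ifelse(z == 1,
                         pmin(stats::rbeta(nrow(grid), sh$a, sh$b), 1 - 1e-6),
                         0)
      }
      rows[[length(rows) + 1]] <- data.frame(
        participant_id = rep(personality$participant_id[grid$si], 6),
        image_id = rep(grid$img, 6),
        condition = cond, impression = imp,
        region = rep(.REGIONS, each = nrow(grid)),
        G = as.vector(w), stringsAsFactors = FALSE)
    }
  }
  weights <- do.call(rbind, rows)
  rownames(weights) <- NULL

  gaze <- NULL
  if (config$fidelity == "gaze") {
    trials <- unique(weights[, c("participant_id", "image_id", "condition",
                                 "impression")])
    wide <- stats::reshape(weights, idvar = c("participant_id", "image_id",
                                              "condition", "impression"),
                           timevar = "region", direction = "wide")
    streams <- vector("list", nrow(trials))
    for (k in seq_len(nrow(trials))) {
      tr <- trials[k, ]
      wrow <- wide[wide$participant_id == tr$participant_id &
                     wide$image_id == tr$image_id &
                     wide$condition == tr$condition &
                     wide$impression == tr$impression,
                   paste0("G.", .REGIONS)]
      td <- trial_design(tr$participant_id, tr$image_id, tr$condition,
                         tr$impression, config$duration_s,
                         config$sample_rate_hz)
      streams[[k]] <- generate_gaze_stream(
        td, as.numeric(wrow), masks[[tr$image_id]],
        aperture = if (tr$condition == "restricted") config$aperture,
        seed = (as.numeric(seed) * 1009 + k) %% 2147483647,
        jitter_sd = config$jitter_sd, screen = config$screen)
    }
    gaze <- do.call(rbind, streams)
    rownames(gaze) <- NULL
  }
  structure(list(personality = personality, masks = masks, weights = weights,
                 gaze = gaze, truth = truth, config = config,
                 seed = as.integer(seed)),
            class = "zib_experiment")
}

#' @export
print.zib_experiment <- function(x, ...) {
  cat("Synthetic gaze experiment bundle\n")
  cat(sprintf("  %d participants, %d images, conditions: %s, fidelity: %s\n",
              nrow(x$personality), length(x$masks),
              paste(x$config$conditions, collapse = "/"), x$config$fidelity))
  cat(sprintf("  weight rows: %d%s, seed %d\n", nrow(x$weights),
              if (!is.null(x$gaze)) sprintf(", gaze samples: %d", nrow(x$gaze))
              else "", x$seed))
  invisible(x)
}
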