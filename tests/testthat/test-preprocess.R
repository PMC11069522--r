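test_that("screen-to-image mapping centres the stimulus and discards off-image samples", {
  # screen centre maps to image centre
  s <- screen_to_image(data.frame(x = 960, y = 540))
  expect_equal(c(s$x, s$y), c(206, 279))
  # the centred-placement offset: (1920-412)/2 = 754, (1080-558)/2 = 261
  s <- screen_to_image(data.frame(x = 754, y = 261))
  expect_equal(c(s$x, s$y), c(0, 0))
  # off-image samples are dropped, not clipped
  s <- screen_to_image(data.frame(x = c(0, 960), y = c(0, 540)))
  expect_equal(nrow(s), 1)
  expect_error(screen_to_image(data.frame(x = 1, y = 1),
                               screen_dims = c(100, 100)), "larger")
})

test_that("density maps are normalised Gaussian surfaces", {
  dims <- c(101, 121)
  # single central sample: unit mass, symmetric unimodal blob at the sample
  d <- density_map(data.frame(x = 50, y = 60), dims, sigma = 10)
  expect_equal(sum(d), 1)
  expect_true(all(d >= 0))
  expect_equal(as.vector(which(d == max(d), arr.ind = TRUE)), c(61, 51))
  # zero samples: all-zero map
  expect_equal(sum(density_map(data.frame(x = numeric(), y = numeric()),
                               dims)), 0)
  # two far-apart samples: two local maxima, ~half the mass within 3 sigma of each
  d2 <- density_map(data.frame(x = c(60, 260), y = c(150, 150)), c(321, 301),
                    sigma = 10)
  xs <- matrix(0:320, 301, 321, byrow = TRUE)
  ys <- matrix(0:300, 301, 321)
  m1 <- sum(d2[(xs - 60)^2 + (ys - 150)^2 <= 30^2])
  m2 <- sum(d2[(xs - 260)^2 + (ys - 150)^2 <= 30^2])
  # each blob holds mass 0.5, of which ~98.9% lies within 3 sigma
  expect_equal(m1, 0.5 * (1 - exp(-4.5)), tolerance = 0.01)
  expect_equal(m2, 0.5 * (1 - exp(-4.5)), tolerance = 0.01)
  p1 <- which(d2[, 1:161] == max(d2[, 1:161]), arr.ind = TRUE)
  p2 <- which(d2[, 162:321] == max(d2[, 162:321]), arr.ind = TRUE)
  expect_equal(unname(p1[1, ]), c(151, 61))        # (y=150, x=60)
  expect_equal(unname(p2[1, ]), c(151, 260 - 161 + 1))  # (y=150, x=260)
})

test_that("region weights divide accumulated density by pixel area", {
  mask <- generate_face_layout("img001", 206, 279, seed = 2)
  # all-zero density -> six zeros
  expect_equal(unname(region_weights(matrix(0, 279, 206), mask)), numeric(6))
  # uniform density: area division cancels, every region gets 1/(W*H)
  u <- matrix(1 / (206 * 279), 279, 206)
  expect_equal(unname(region_weights(u, mask)), rep(1 / (206 * 279), 6))
  # all mass inside the mouth -> mouth weight 1/area, others 0
  areas <- region_areas(mask)
  dm <- matrix(0, 279, 206)
  dm[mask$labels == 3] <- 1 / areas["mouth"]
  w <- region_weights(dm, mask)
  expect_equal(unname(w["mouth"]), unname(1 / areas["mouth"]))
  expect_equal(unname(w[c("eyes", "nose", "eyebrows", "glabella", "forehead")]),
               numeric(5))
  expect_error(region_weights(matrix(0, 10, 10), mask), "dimensions")
})

test_that("relabelling regions permutes region weights identically", {
  mask <- generate_face_layout("img001", 206, 279, seed = 2)
  set.seed(8)
  d <- density_map(data.frame(x = runif(200, 0, 205), y = runif(200, 0, 278)),
                   c(206, 279), sigma = 5)
  w <- region_weights(d, mask)
  # swap codes of eyes (1) and mouth (3)
  perm <- mask
  perm$labels[mask$labels == 1L] <- 3L
  perm$labels[mask$labels == 3L] <- 1L
  wp <- region_weights(d, perm)
  expect_equal(unname(wp["eyes"]), unname(w["mouth"]))
  expect_equal(unname(wp["mouth"]), unname(w["eyes"]))
  expect_equal(wp[c("nose", "eyebrows", "glabella", "forehead")],
               w[c("nose", "eyebrows", "glabella", "forehead")])
})

test_that("unify_scale produces model-ready weights", {
  expect_equal(unify_scale(numeric(6)), numeric(6))
  expect_equal(unify_scale(c(2, 2, 0, 0, 0, 0)), c(0.5, 0.5, 0, 0, 0, 0))
  # one dominant value is clamped just below 1
  g <- unify_scale(c(5, 0, 0, 0, 0, 0))
  expect_equal(g[1], 1 - 1e-6)
  # sub-epsilon traces are zeroed so the Bernoulli part stays meaningful
  g <- unify_scale(c(1, 1e-9, 0, 0, 0, 0))
  expect_equal(g[2], 0)
  expect_true(sum(g) <= 1)
  expect_error(unify_scale(c(-1, 0, 0, 0, 0, 0)), "non-negative")
})

test_that("weight tables pass weight-fidelity bundles through untouched", {
  b <- make_weight_dataset(participants = 2, images = 2, seed = 4)
  expect_identical(build_weight_table(b), b$weights)
})

test_that("gaze-fidelity preprocessing recovers the planted dwell allocations", {
  cfg <- experiment_config(participants = 2, images_per_impression = 2,
                           impressions = c("openness", "neuroticism"),
                           conditions = c("free", "restricted"),
                           fidelity = "gaze")
  b <- generate_experiment(cfg, seed = 21)
  rec <- build_weight_table(b)
  # 2 participants x 2 conditions x 2 impressions x 2 images x 6 regions
  expect_equal(nrow(rec), 2 * 2 * 2 * 2 * 6)
  expect_true(all(rec$G >= 0 & rec$G <= 1 - 1e-6))
  trial_sums <- tapply(rec$G, paste(rec$participant_id, rec$image_id,
                                    rec$condition, rec$impression), sum)
  expect_true(all(trial_sums <= 1 + 1e-12))
  # align recovered weights with the planted allocations
  key <- function(d) paste(d$participant_id, d$image_id, d$condition,
                           d$impression, d$region)
  w <- b$weights$G[match(key(rec), key(b$weights))]
  # planted allocation on the pipeline's area-normalised scale
  areas <- sapply(b$masks, region_areas)
  expected <- unlist(lapply(seq(1, nrow(rec), by = 6), function(i) {
    ix <- i:(i + 5)
    unify_scale(w[ix] / areas[, rec$image_id[i]])
  }))
  expect_gt(cor(rec$G, expected), 0.9)
  # a stream concentrated on the eyes puts its maximum weight on the eyes
  mask <- b$masks[[1]]
  td <- trial_design("P001", mask$image_id, "free")
  s <- generate_gaze_stream(td, c(0.95, 0, 0, 0, 0, 0), mask, seed = 9)
  d <- density_map(screen_to_image(s, c(1920, 1080),
                                   c(mask$width, mask$height)),
                   c(mask$width, mask$height))
  g <- unify_scale(region_weights(d, mask))
  expect_equal(unname(which.max(g)), 1)
})
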