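test_that("participant generation respects the design and the seed", {
  p <- generate_participants(42, seed = 1)
  expect_equal(nrow(p), 42)
  expect_equal(names(p), c("participant_id", big_five_traits()))
  scores <- as.matrix(p[, big_five_traits()])
  expect_true(all(scores >= 1 & scores <= 7))
  expect_false(anyDuplicated(p$participant_id) > 0)
  # minimal case and seeded determinism
  expect_equal(nrow(generate_participants(1, seed = 7)), 1)
  expect_identical(generate_participants(10, seed = 3),
                   generate_participants(10, seed = 3))
  expect_false(identical(generate_participants(10, seed = 3),
                         generate_participants(10, seed = 4)))
  expect_error(generate_participants(0), "positive")
})

test_that("face layouts place six disjoint nonempty regions plausibly", {
  m <- generate_face_layout("img001", 412, 558, seed = 3)
  areas <- region_areas(m)
  expect_true(all(areas > 0))
  expect_lt(sum(areas), 412 * 558)  # background remains
  expect_setequal(unique(as.vector(m$labels)), 0:6)
  # vertical anatomy: forehead above eyebrows above eyes above nose above mouth
  mean_y <- vapply(1:6, function(r)
    mean(which(m$labels == r, arr.ind = TRUE)[, 1]), numeric(1))
  names(mean_y) <- face_regions()
  expect_true(mean_y["forehead"] < mean_y["eyebrows"])
  expect_true(mean_y["eyebrows"] < mean_y["eyes"])
  expect_true(mean_y["eyes"] < mean_y["nose"])
  expect_true(mean_y["nose"] < mean_y["mouth"])
  # distinct images get jittered layouts; same id is reproducible
  m2 <- generate_face_layout("img002", 412, 558, seed = 3)
  expect_false(identical(m$labels, m2$labels))
  expect_identical(m$labels,
                   generate_face_layout("img001", 412, 558, seed = 3)$labels)
  expect_error(generate_face_layout("x", 20, 20), "too small")
})

test_that("trial weight draws follow the generative ZIB distribution", {
  # degenerate Bernoulli: q ~ 0 -> all zeros; q ~ 1 -> all weights in (0,1)
  p0 <- zib_params(alpha_bern = -700)
  expect_equal(unname(sample_trial_weights(p0, rep(4, 5))), numeric(6))
  p1 <- zib_params(alpha_bern = 700, alpha_beta = 0, phi = 2)
  w <- sample_trial_weights(p1, rep(4, 5))
  expect_true(all(w > 0 & w < 1))
  # empirical nonzero fraction and nonzero mean converge to q and mu
  q_true <- 0.7; mu_true <- 0.3
  pq <- zib_params(alpha_bern = qlogis(q_true), alpha_beta = qlogis(mu_true),
                   phi = 10)
  set.seed(99)
  draws <- t(replicate(1700, sample_trial_weights(pq, rep(4, 5))))
  x <- as.vector(draws)  # 10200 iid ZIB draws
  se_q <- sqrt(q_true * (1 - q_true) / length(x))
  expect_lt(abs(mean(x > 0) - q_true), 3 * se_q)
  nz <- x[x > 0]
  se_mu <- sd(nz) / sqrt(length(nz))
  expect_lt(abs(mean(nz) - mu_true), 3 * se_mu)
  expect_error(sample_trial_weights(pq, rep(9, 5)), "\\[1, 7\\]")
})

test_that("gaze streams realise the requested allocation and budget", {
  mask <- generate_face_layout("img001", 412, 558, seed = 3)
  td <- trial_design("P001", "img001", "free")
  # full budget: 3 s at 120 Hz = 360 samples, strictly increasing timestamps
  s <- generate_gaze_stream(td, c(1, 0, 0, 0, 0, 0), mask, seed = 5)
  expect_equal(nrow(s), 360)
  expect_true(all(diff(s$t) > 0))
  expect_true(all(s$t >= 0 & s$t < td$duration_s))
  # all-eyes allocation: >= 95% of samples within 3 * jitter of an eye target
  tg <- zibgaze:::.region_targets(mask, 1L)
  sx <- s$x - (1920 - 412) / 2; sy <- s$y - (1080 - 558) / 2
  d <- sapply(seq_len(nrow(tg)), function(i)
    sqrt((sx - tg[i, 1])^2 + (sy - tg[i, 2])^2))
  expect_gt(mean(apply(d, 1, min) <= 30), 0.95)
  # zero allocation: every sample sits on an off-face (background) pixel
  s0 <- generate_gaze_stream(td, numeric(6), mask, seed = 5)
  ix <- cbind(round(s0$y - (1080 - 558) / 2) + 1, round(s0$x - (1920 - 412) / 2) + 1)
  expect_true(all(mask$labels[ix] == 0))
  # restricted condition produces an ordered path over the same counts
  tdr <- trial_design("P001", "img001", "restricted")
  sr <- generate_gaze_stream(tdr, c(0.5, 0.3, 0, 0, 0, 0), mask,
                             aperture = restricted_aperture(1), seed = 5)
  expect_equal(nrow(sr), 360)
})

test_that("experiment bundles replicate the design and are seed-stable", {
  cfg <- experiment_config(participants = 3)
  b <- generate_experiment(cfg, seed = 11)
  # 5 impressions x 10 images = 50 trials per participant per condition
  trials <- unique(b$weights[, c("participant_id", "image_id", "condition",
                                 "impression")])
  counts <- table(trials$participant_id, trials$condition)
  expect_true(all(counts == 50))
  expect_equal(nrow(b$weights), 3 * 2 * 50 * 6)
  expect_true(all(b$weights$G >= 0 & b$weights$G < 1))
  # byte-identical regeneration under the same config + seed
  b2 <- generate_experiment(cfg, seed = 11)
  expect_identical(b$weights, b2$weights)
  expect_identical(b$personality, b2$personality)
  # minimal design: 1 participant, 1 image, 1 impression, free only
  cfg1 <- experiment_config(participants = 1, images_per_impression = 1,
                            impressions = "openness", conditions = "free")
  b1 <- generate_experiment(cfg1, seed = 1)
  expect_equal(nrow(b1$weights), 6)  # one trial, six region rows
  # inconsistent trial count is rejected
  expect_error(experiment_config(images_per_impression = 9,
                                 trials_per_condition = 50),
               "inconsistent config")
})

test_that("aperture visibility is 1 inside the hard radius and decays outside", {
  ap <- aperture_model(40, 40)
  expect_equal(ap$visibility(c(0, 20, 40)), c(1, 1, 1))
  v <- ap$visibility(c(50, 80, 160))
  expect_true(all(diff(v) < 0))
  expect_lt(ap$visibility(40 + 3 * 40), 0.02)
  expect_equal(restricted_aperture(2)$hard_radius_px, 60)
})
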