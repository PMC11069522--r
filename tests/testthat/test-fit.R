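test_that("sampler configuration validates and counts retained draws", {
  cfg <- mcmc_config()
  expect_equal(cfg$chains, 4)
  expect_equal(cfg$iterations, 2000)
  expect_equal(cfg$warmup, 1000)
  expect_equal(cfg$thin, 1)
  expect_error(mcmc_config(warmup = 2000, iterations = 2000), "warmup")
  expect_error(mcmc_config(chains = 0), "chains")
  expect_error(mcmc_config(iterations = 1050, warmup = 1000, thin = 20),
               "multiple")
})

test_that("the MH backend returns finite draws with the configured shape", {
  b <- make_weight_dataset(participants = 5, images = 2, seed = 8)
  slice <- b$weights[b$weights$region == "eyes", ][1:10, ]
  fit <- fit_zib(slice, b$personality,
                 config = mcmc_config(chains = 1, iterations = 20,
                                      warmup = 10, seed = 5),
                 backend = "mh")
  expect_s3_class(fit, "zib_fit")
  expect_equal(n_draws(fit), 10)
  expect_true(all(is.finite(as.matrix(fit))))
  expect_true(all(as.matrix(fit)[, "phi"] > 0))
  # thinning halves the retained draws
  fit2 <- fit_zib(slice, b$personality,
                  config = mcmc_config(chains = 2, iterations = 30,
                                       warmup = 10, thin = 2, seed = 5),
                  backend = "mh")
  expect_equal(n_draws(fit2), 2 * 10)
})

test_that("both backends are reproducible under a fixed seed", {
  b <- make_weight_dataset(participants = 6, images = 3, seed = 12)
  slice <- b$weights[b$weights$region == "nose", ]
  for (bk in c("jags", "mh")) {
    f1 <- fit_zib(slice, b$personality,
                  config = mcmc_config(chains = 2, iterations = 60,
                                       warmup = 30, seed = 77), backend = bk)
    f2 <- fit_zib(slice, b$personality,
                  config = mcmc_config(chains = 2, iterations = 60,
                                       warmup = 30, seed = 77), backend = bk)
    expect_identical(f1$draws, f2$draws)
  }
})

test_that("the two samplers agree on the posterior of a common slice", {
  b <- make_weight_dataset(participants = 12, images = 6, seed = 3)
  slice <- b$weights[b$weights$region == "eyes", ]
  fj <- fit_zib(slice, b$personality,
                config = mcmc_config(chains = 2, iterations = 1500,
                                     warmup = 500, seed = 1),
                backend = "jags")
  fm <- fit_zib(slice, b$personality,
                config = mcmc_config(chains = 2, iterations = 6000,
                                     warmup = 3000, seed = 2),
                backend = "mh")
  # posterior means agree within one posterior SD (Monte Carlo noise at this
  # chain length); a likelihood or prior mismatch shows up as multi-SD shifts
  nm <- c(sprintf("beta_bern[%s]", big_five_traits()),
          sprintf("beta_beta[%s]", big_five_traits()), "phi")
  sj <- summary(fj, fixed_only = TRUE)
  mj <- setNames(sj$mean, sj$parameter)[nm]
  sdj <- setNames(sj$sd, sj$parameter)[nm]
  sm <- summary(fm, fixed_only = TRUE)
  mm <- setNames(sm$mean, sm$parameter)[nm]
  expect_true(all(abs(mj - mm) < pmax(1 * sdj, 0.02)))
})

test_that("fit_zib enforces a single-cell slice and complete scores", {
  b <- make_weight_dataset(participants = 4, images = 2, seed = 9)
  expect_error(fit_zib(b$weights, b$personality), "multiple values")
  expect_error(fit_zib(b$weights, b$personality,
                       scope = list(region = "nostril")), "no data")
  slice <- b$weights[b$weights$region == "eyes", ]
  pers_missing <- b$personality[-1, ]
  expect_error(fit_zib(slice, pers_missing,
                       config = mcmc_config(chains = 1, iterations = 20,
                                            warmup = 10), backend = "mh"),
               "without personality")
})

test_that("an all-zero slice warns and falls back to the prior for the Beta part", {
  pers <- generate_participants(4, seed = 2)
  slice <- data.frame(participant_id = rep(pers$participant_id, 2),
                      image_id = rep(c("img001", "img002"), each = 4),
                      G = 0)
  expect_warning(
    fit <- fit_zib(slice, pers,
                   config = mcmc_config(chains = 1, iterations = 200,
                                        warmup = 100, seed = 4),
                   backend = "mh"),
    "all weights")
  draws <- as.matrix(fit)
  expect_true(all(is.finite(draws)))
  # with no positive data, phi stays near its Exponential(0.1) prior mean
  expect_equal(mean(draws[, "phi"]), 10, tolerance = 5)
})

test_that("relabelling participants leaves fixed-effect posteriors unchanged", {
  b <- make_weight_dataset(participants = 10, images = 5, seed = 15)
  slice <- b$weights[b$weights$region == "mouth", ]
  cfg <- mcmc_config(chains = 2, iterations = 1200, warmup = 400, seed = 31)
  f1 <- fit_zib(slice, b$personality, config = cfg)
  # permute participant ids consistently in data and scores
  ids <- unique(slice$participant_id)
  set.seed(1)
  new_ids <- setNames(sample(sprintf("Q%03d", seq_along(ids))), ids)
  slice2 <- slice
  slice2$participant_id <- unname(new_ids[slice$participant_id])
  pers2 <- b$personality
  pers2$participant_id <- unname(new_ids[pers2$participant_id])
  f2 <- fit_zib(slice2, pers2, config = cfg)
  nm <- c("alpha_bern", sprintf("beta_bern[%s]", big_five_traits()),
          "alpha_beta", sprintf("beta_beta[%s]", big_five_traits()))
  s1 <- summary(f1); s2 <- summary(f2)
  m1 <- setNames(s1$mean, s1$parameter)[nm]
  m2 <- setNames(s2$mean, s2$parameter)[nm]
  sd1 <- setNames(s1$sd, s1$parameter)[nm]
  expect_true(all(abs(m1 - m2) < pmax(1 * sd1, 0.02)))
})

test_that("fit methods expose coefficients, predictions and simulations", {
  b <- make_weight_dataset(participants = 8, images = 4, seed = 6)
  slice <- b$weights[b$weights$region == "glabella", ]
  fit <- fit_zib(slice, b$personality,
                 config = mcmc_config(chains = 2, iterations = 300,
                                      warmup = 100, seed = 3))
  expect_output(print(fit), "zero-inflated Beta fit")
  co <- coef(fit, part = "bern")
  expect_length(co, 6)
  expect_true(all(is.finite(co)))
  pr <- predict(fit, newdata = rbind(rep(3, 5), rep(5, 5)))
  expect_equal(nrow(pr), 4)  # 2 profiles x {q, mu}
  expect_true(all(pr$mean > 0 & pr$mean < 1))
  expect_true(all(pr$hdi_low <= pr$mean & pr$mean <= pr$hdi_high))
  sims <- simulate(fit, nsim = 50, seed = 1)
  expect_equal(dim(sims), c(50, 1))
  expect_true(all(sims >= 0 & sims < 1))
  expect_identical(simulate(fit, nsim = 10, seed = 2),
                   simulate(fit, nsim = 10, seed = 2))
  s <- summary(fit)
  expect_s3_class(s, "summary.zib_fit")
  expect_output(print(s), "ZIB fit summary")
})
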