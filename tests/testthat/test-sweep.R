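# Helpers: a set of six single-region fake fits sharing one scope.
make_region_fits <- function(condition = "free", means_by_region = NULL,
                             n = 400, sd = 0.05, seed = 1) {
  lapply(seq_along(face_regions()), function(r) {
    reg <- face_regions()[r]
    means <- if (is.null(means_by_region)) list() else means_by_region[[reg]]
    base <- setNames(as.list(rep(0, 12)),
                     c("alpha_bern", "alpha_beta",
                       sprintf("beta_bern[%s]", big_five_traits()),
                       sprintf("beta_beta[%s]", big_five_traits())))
    base[names(means)] <- means
    fake_fit(noise_chains(4, n, base, sd = sd, seed = seed + r),
             scope = list(condition = condition,
                          impression = "conscientiousness", region = reg))
  })
}

test_that("sweeps evaluate the links draw-wise on the trait grid", {
  # all-zero coefficients -> flat curves at 0.5
  fits <- make_region_fits(sd = 1e-8)
  sw <- trait_sweep(fits, "conscientiousness")
  expect_equal(sw$grid, 1:7)
  expect_true(all(abs(sw$summary$mean - 0.5) < 1e-6))
  expect_equal(nrow(sw$summary), 6 * 7 * 2)  # regions x grid x {q, mu}
  expect_true(all(sw$summary$mean > 0 & sw$summary$mean < 1))
  # positive swept-trait coefficient -> strictly increasing q curve
  up <- make_region_fits(means_by_region = setNames(rep(list(
    list("beta_bern[conscientiousness]" = 0.8)), 6), face_regions()),
    sd = 0.02, seed = 3)
  swu <- trait_sweep(up, "conscientiousness")
  for (reg in face_regions()) {
    qc <- swu$summary[swu$summary$region == reg &
                        swu$summary$statistic == "q", ]
    expect_true(all(diff(qc$mean[order(qc$trait_value)]) > 0))
  }
})

test_that("a point-mass posterior reproduces the closed-form link curves", {
  means <- list("alpha_bern" = 0.4, "beta_bern[conscientiousness]" = 0.3,
                "beta_bern[openness]" = -0.2,
                "alpha_beta" = -1, "beta_beta[conscientiousness]" = 0.1)
  fits <- make_region_fits(means_by_region = setNames(rep(list(means), 6),
                                                      face_regions()),
                           n = 10, sd = 0, seed = 2)
  sw <- trait_sweep(fits, "conscientiousness", fixed_value = 3)
  q_expect <- plogis(0.4 + 0.3 * (1:7) + (-0.2) * 3)
  mu_expect <- plogis(-1 + 0.1 * (1:7))
  eyes_q <- sw$summary[sw$summary$region == "eyes" &
                         sw$summary$statistic == "q", ]
  eyes_mu <- sw$summary[sw$summary$region == "eyes" &
                          sw$summary$statistic == "mu", ]
  expect_equal(eyes_q$mean[order(eyes_q$trait_value)], q_expect)
  expect_equal(eyes_mu$mean[order(eyes_mu$trait_value)], mu_expect)
  # non-swept traits really are fixed at the stated value, not the midpoint
  sw4 <- trait_sweep(fits, "conscientiousness", fixed_value = 4)
  eyes_q4 <- sw4$summary[sw4$summary$region == "eyes" &
                           sw4$summary$statistic == "q", ]
  expect_equal(eyes_q4$mean[order(eyes_q4$trait_value)],
               plogis(0.4 + 0.3 * (1:7) + (-0.2) * 4))
})

test_that("sweep summaries are draw-wise, never plug-in means", {
  # strongly skewed posterior: plogis(mean(draws)) != mean(plogis(draws))
  set.seed(9)
  skew <- list("alpha_bern" = 0)
  fits <- lapply(face_regions(), function(reg) {
    ch <- lapply(1:4, function(i) {
      m <- matrix(rexp(300, 0.5) - 1, 300, 1,
                  dimnames = list(NULL, "alpha_bern"))
      m
    })
    fake_fit(ch, scope = list(condition = "free",
                              impression = "conscientiousness", region = reg))
  })
  sw <- trait_sweep(fits, "conscientiousness")
  draws <- do.call(rbind, fits[[1]]$draws)[, "alpha_bern"]
  drawwise <- mean(plogis(draws))
  plugin <- plogis(mean(draws))
  q1 <- sw$summary$mean[sw$summary$region == "eyes" &
                          sw$summary$statistic == "q" &
                          sw$summary$trait_value == 1]
  expect_equal(q1, drawwise, tolerance = 1e-10)
  expect_gt(abs(drawwise - plugin), 0.02)  # the two estimators truly differ here
})

test_that("condition differences are paired by draw and antisymmetric", {
  free <- make_region_fits("free", sd = 0.1, seed = 11)
  restr <- make_region_fits("restricted", sd = 0.1, seed = 12)
  sf <- trait_sweep(free, "conscientiousness")
  sr <- trait_sweep(restr, "conscientiousness")
  # identical sweeps -> exactly zero difference
  d0 <- condition_difference(sr, sr)
  expect_true(all(d0$summary$mean == 0))
  expect_true(all(d0$summary$hdi_low == 0 & d0$summary$hdi_high == 0))
  # antisymmetry, pointwise in the draws
  d1 <- condition_difference(sr, sf)
  d2 <- condition_difference(sf, sr)
  expect_equal(d1$draws$q, -d2$draws$q)
  expect_equal(d1$summary$mean, -d2$summary$mean)
  expect_true(all(d1$summary$mean > -1 & d1$summary$mean < 1))
  # a planted constant q offset is recovered in the difference curves
  base <- setNames(rep(list(list("alpha_bern" = 0)), 6), face_regions())
  shift <- setNames(rep(list(list("alpha_bern" = qlogis(0.7))), 6),
                    face_regions())
  s0 <- trait_sweep(make_region_fits("free", base, sd = 0.02, seed = 13),
                    "conscientiousness")
  s1 <- trait_sweep(make_region_fits("restricted", shift, sd = 0.02, seed = 14),
                    "conscientiousness")
  dd <- condition_difference(s1, s0)
  expect_equal(mean(dd$summary$mean[dd$summary$statistic == "q"]),
               0.2, tolerance = 0.01)
  # incompatible sweeps are refused
  s_other <- trait_sweep(make_region_fits("restricted", shift, sd = 0.02,
                                          seed = 14), "openness")
  expect_error(condition_difference(s_other, s0), "not compatible")
})

test_that("sweep export writes deterministic CSVs and optional plots", {
  fits <- make_region_fits(sd = 0.05, seed = 21)
  sw <- trait_sweep(fits, "conscientiousness")
  dir <- withr::local_tempdir()
  f1 <- export_sweep(sw, file.path(dir, "sweep1"))
  tab <- read.csv(f1)
  expect_equal(nrow(tab), 84)  # 6 regions x 7 grid points x 2 statistics
  f2 <- export_sweep(sw, file.path(dir, "sweep2"))
  expect_identical(readLines(f1), readLines(f2))
  fp <- export_sweep(sw, file.path(dir, "sweep3"), plot = TRUE)
  expect_true(all(file.exists(fp)))
  expect_length(fp, 3)  # csv + q png + mu png
})
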