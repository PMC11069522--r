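# Shared fixtures and independent oracles for the test suite.

# Small weight-level dataset from a known ZIB truth: one condition, one
# impression, all six regions; slicing one region gives a single-cell fit.
make_weight_dataset <- function(participants = 20, images = 10, seed = 1,
                                effect = "moderate") {
  cfg <- experiment_config(participants = participants,
                           images_per_impression = images,
                           impressions = "conscientiousness",
                           conditions = "free", fidelity = "weights")
  truth <- default_ground_truth(cfg, seed = seed, effect = effect)
  bundle <- generate_experiment(cfg, seed = seed, truth = truth)
  bundle
}

# One cached fit of the default sampler configuration on a well-specified
# synthetic slice (20 participants x 10 images, moderate effects), shared by
# the tests that exercise the stated default settings.
.fixture_env <- new.env(parent = emptyenv())
shared_default_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    bundle <- make_weight_dataset(seed = 101)
    .fixture_env$fit <- fit_zib(bundle$weights, bundle$personality,
                                scope = list(region = "eyes"),
                                config = mcmc_config(seed = 202))
  }
  .fixture_env$fit
}

# Independent brute-force log-posterior oracle: scalar loops, explicit
# density formulas (no calls into the package's likelihood code).
oracle_log_posterior <- function(params, effects, data, personality,
                                 fixed_sd = 10, scale_shape = 10,
                                 scale_rate = 10, phi_rate = 0.1) {
  traits <- c("extraversion", "agreeableness", "conscientiousness",
              "neuroticism", "openness")
  lnorm <- function(x, s) -0.5 * log(2 * pi) - log(s) - 0.5 * (x / s)^2
  lgam <- function(x, sh, ra) sh * log(ra) - lgamma(sh) + (sh - 1) * log(x) - ra * x
  total <- 0
  if (nrow(data) > 0) {
    for (i in seq_len(nrow(data))) {
      row <- data[i, ]
      p <- personality[personality$participant_id == row$participant_id, ]
      lp_q <- params$alpha_bern
      lp_m <- params$alpha_beta
      for (k in seq_along(traits)) {
        lp_q <- lp_q + params$beta_bern[[k]] * p[[traits[k]]]
        lp_m <- lp_m + params$beta_beta[[k]] * p[[traits[k]]]
      }
      lp_q <- lp_q + effects$r_subj_bern[[row$participant_id]] +
        effects$r_pic_bern[[row$image_id]]
      lp_m <- lp_m + effects$r_subj_beta[[row$participant_id]] +
        effects$r_pic_beta[[row$image_id]]
      q <- 1 / (1 + exp(-lp_q))
      if (row$G == 0) {
        total <- total + log(1 - q)
      } else {
        mu <- 1 / (1 + exp(-lp_m))
        a <- params$phi * mu
        b <- params$phi * (1 - mu)
        total <- total + log(q) + lgamma(a + b) - lgamma(a) - lgamma(b) +
          (a - 1) * log(row$G) + (b - 1) * log(1 - row$G)
      }
    }
  }
  for (x in c(params$alpha_bern, params$beta_bern,
              params$alpha_beta, params$beta_beta))
    total <- total + lnorm(x, fixed_sd)
  total <- total + log(phi_rate) - phi_rate * params$phi
  for (s in c(params$sigma_subj_bern, params$sigma_pic_bern,
              params$sigma_subj_beta, params$sigma_pic_beta))
    total <- total + lgam(s, scale_shape, scale_rate)
  for (r in effects$r_subj_bern) total <- total + lnorm(r, params$sigma_subj_bern)
  for (r in effects$r_pic_bern) total <- total + lnorm(r, params$sigma_pic_bern)
  for (r in effects$r_subj_beta) total <- total + lnorm(r, params$sigma_subj_beta)
  for (r in effects$r_pic_beta) total <- total + lnorm(r, params$sigma_pic_beta)
  total
}

# Exhaustive-search HDI oracle: check every window of the required size.
oracle_hdi <- function(x, mass = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- ceiling(mass * n)
  best <- c(x[1], x[m]); bw <- x[m] - x[1]
  for (s in seq_len(n - m + 1)) {
    w <- x[s + m - 1] - x[s]
    if (w < bw) { bw <- w; best <- c(x[s], x[s + m - 1]) }
  }
  best
}

# A minimal hand-built zib_fit for diagnostics/sweep tests: draws supplied
# per chain for the fixed effects, zeros for everything else.
fake_fit <- function(chains, scope = list(condition = "free",
                                          impression = "conscientiousness",
                                          region = "eyes"),
                     participants = "P001", images = "img001") {
  pnames <- zibgaze:::.zib_param_names(participants, images)
  draws <- lapply(chains, function(ch) {
    m <- matrix(0, nrow(ch), length(pnames), dimnames = list(NULL, pnames))
    m[, colnames(ch)] <- ch
    if (!"phi" %in% colnames(ch)) m[, "phi"] <- 10
    sig <- c("sigma_subj_bern", "sigma_pic_bern", "sigma_subj_beta",
             "sigma_pic_beta")
    for (s in setdiff(sig, colnames(ch))) m[, s] <- 1
    m
  })
  structure(list(draws = draws, parameters = pnames, scope = scope,
                 config = mcmc_config(chains = length(draws),
                                      iterations = 2 * nrow(draws[[1]]),
                                      warmup = nrow(draws[[1]])),
                 prior = zib_prior(), backend = "fake",
                 participants = participants, images = images,
                 n_obs = 0L, n_pos = 0L, data_digest = "fake"),
            class = "zib_fit")
}

# Chains of iid noise around given means for fake_fit inputs.
noise_chains <- function(n_chains, n, means, sd = 0.05, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_chains), function(i) {
    m <- sapply(names(means), function(p) rnorm(n, means[[p]], sd))
    colnames(m) <- names(means)
    m
  })
}
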