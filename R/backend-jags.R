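# JAGS backend for fit_zib().
#
# The model is written with mean-centred predictors: the sampled intercept is
# the centred-scale one, given its exact implied prior Normal(sum(beta * m),
# fixed_sd) so that the joint prior on (raw intercept, coefficients) is
# unchanged (change of variables with unit Jacobian). Raw-scale intercepts
# are recovered as derived nodes. Both random-effect factors are
# hierarchically centred (exact, unit Jacobian) and the linear predictor is
# split between them so no fixed effect appears at the row level: the subject
# node is ds_i = beta' P_i + r_subj_i with prior Normal(beta' P_i, sigma_subj)
# -- the trait scores are subject-level predictors, so placing them in the
# subject prior mean gives the coefficients conjugate normal conditionals --
# and the picture node is dp_j = intercept + r_pic_j with prior
# Normal(intercept, sigma_pic); the row-level predictor is ds_i + dp_j. This
# removes the slow couplings of the naive parameterisation (coefficients vs
# subject effects, intercept vs picture effects). The Bernoulli indicator
# z = (G > 0) and the positive weights factorise the ZIB likelihood exactly
# into a Bernoulli regression on all rows plus a Beta regression on the
# positive rows.

.jags_model_string <- function(has_pos) {
  beta_block <- if (has_pos) "
  for (m in 1:Npos) {
    gpos[m] ~ dbeta(sh_a[m], sh_b[m])
    sh_a[m] <- phi * mu[m]
    sh_b[m] <- phi * (1 - mu[m])
    logit(mu[m]) <- ds_beta[subjpos[m]] + dp_beta[picpos[m]]
  }
" else ""
  paste0("model {
  for (m in 1:N) {
    z[m] ~ dbern(q[m])
    logit(q[m]) <- ds_bern[subj[m]] + dp_bern[pic[m]]
  }
", beta_block, "
  for (k in 1:5) {
    b_bern[k] ~ dnorm(0, tau_fixed)
    b_beta[k] ~ dnorm(0, tau_fixed)
  }
  ac_bern ~ dnorm(inprod(b_bern[], mcol[]), tau_fixed)
  ac_beta ~ dnorm(inprod(b_beta[], mcol[]), tau_fixed)
  alpha_bern <- ac_bern - inprod(b_bern[], mcol[])
  alpha_beta <- ac_beta - inprod(b_beta[], mcol[])
  for (i in 1:I) {
    ds_bern[i] ~ dnorm(inprod(b_bern[], Pc_subj[i, ]),
                       pow(sigma_subj_bern, -2))
    ds_beta[i] ~ dnorm(inprod(b_beta[], Pc_subj[i, ]),
                       pow(sigma_subj_beta, -2))
    rs_bern[i] <- ds_bern[i] - inprod(b_bern[], Pc_subj[i, ])
    rs_beta[i] <- ds_beta[i] - inprod(b_beta[], Pc_subj[i, ])
  }
  for (j in 1:J) {
    dp_bern[j] ~ dnorm(ac_bern, pow(sigma_pic_bern, -2))
    dp_beta[j] ~ dnorm(ac_beta, pow(sigma_pic_beta, -2))
    rp_bern[j] <- dp_bern[j] - ac_bern
    rp_beta[j] <- dp_beta[j] - ac_beta
  }
  sigma_subj_bern ~ dgamma(scale_shape, scale_rate)
  sigma_pic_bern ~ dgamma(scale_shape, scale_rate)
  sigma_subj_beta ~ dgamma(scale_shape, scale_rate)
  sigma_pic_beta ~ dgamma(scale_shape, scale_rate)
  phi ~ dexp(phi_rate)
}")
}

.fit_zib_jags <- function(des, config, prior, quiet = TRUE) {
  has_pos <- length(des$pos) > 0
  # subject-level score matrix (traits are constant within participant)
  P_subj <- des$P[match(seq_along(des$subj_levels), des$subj), , drop = FALSE]
  mcol <- colMeans(P_subj)
  dat <- list(N = des$n, z = des$z, mcol = mcol,
              Pc_subj = sweep(P_subj, 2, mcol),
              subj = des$subj, pic = des$pic,
              I = length(des$subj_levels), J = length(des$pic_levels),
              tau_fixed = 1 / prior$fixed_sd^2,
              scale_shape = prior$scale_shape, scale_rate = prior$scale_rate,
              phi_rate = prior$phi_rate)
  if (has_pos) {
    # clamp a hair inside (0, 1): upstream weights may sit exactly at 1-1e-6
    dat$Npos <- length(des$pos)
    dat$gpos <- pmin(pmax(des$g[des$pos], 1e-9), 1 - 1e-9)
    dat$subjpos <- des$subj[des$pos]
    dat$picpos <- des$pic[des$pos]
  }
  # the glm module provides block samplers for the conjugate normal
  # sub-graphs created by the hierarchical centring
  try(rjags::load.module("glm", quiet = TRUE), silent = TRUE)
  seeds <- .chain_seeds(config$seed, config$chains)
  inits <- lapply(seeds, function(s)
    list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = s))
  n_adapt <- max(100L, config$warmup %/% 2L)
  n_burn <- config$warmup - n_adapt
  model <- rjags::jags.model(textConnection(.jags_model_string(has_pos)),
                             data = dat, inits = inits,
                             n.chains = config$chains, n.adapt = n_adapt,
                             quiet = TRUE)
  if (n_burn > 0)
    stats::update(model, n.iter = n_burn,
                  progress.bar = if (quiet) "none" else "text")
  monitor <- c("alpha_bern", "b_bern", "alpha_beta", "b_beta", "phi",
               "sigma_subj_bern", "sigma_pic_bern",
               "sigma_subj_beta", "sigma_pic_beta",
               "rs_bern", "rp_bern", "rs_beta", "rp_beta")
  samp <- rjags::coda.samples(model, monitor,
                              n.iter = config$iterations - config$warmup,
                              thin = config$thin,
                              progress.bar = if (quiet) "none" else "text")
  lapply(samp, function(ch) .rename_jags_draws(as.matrix(ch), des))
}

# Map JAGS column names onto the package's canonical parameter names and
# column order.
.rename_jags_draws <- function(m, des) {
  jn <- colnames(m)
  jags_names <- c("alpha_bern", paste0("b_bern[", 1:5, "]"),
                  "alpha_beta", paste0("b_beta[", 1:5, "]"),
                  "phi",
                  "sigma_subj_bern", "sigma_pic_bern",
                  "sigma_subj_beta", "sigma_pic_beta",
                  paste0("rs_bern[", seq_along(des$subj_levels), "]"),
                  paste0("rp_bern[", seq_along(des$pic_levels), "]"),
                  paste0("rs_beta[", seq_along(des$subj_levels), "]"),
                  paste0("rp_beta[", seq_along(des$pic_levels), "]"))
  idx <- match(jags_names, jn)
  if (anyNA(idx)) stop("unexpected JAGS monitor layout", call. = FALSE)
  out <- m[, idx, drop = FALSE]
  colnames(out) <- .zib_param_names(des$subj_levels, des$pic_levels)
  out
}
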