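# Self-contained blocked adaptive random-walk Metropolis backend.
#
# Targets the same posterior as zib_log_posterior() (phi and the four scales
# are sampled on the log scale with the Jacobian included). Blocks:
#   - Bernoulli-part fixed effects (6-dim joint, adaptive covariance)
#   - Beta-part fixed effects (6-dim joint, adaptive covariance)
#   - log phi, and each log sigma (scalar)
#   - random effects, updated in parallel: conditional on everything else the
#     posterior factorises over participants (and over images), so
#     independent scalar proposals accepted element-wise are a valid sweep.
# Proposal scales adapt by Robbins-Monro during warmup only.

.fit_zib_mh <- function(des, config, prior, quiet = TRUE) {
  seeds <- .chain_seeds(config$seed, config$chains)
  lapply(seq_len(config$chains), function(ch)
    .mh_chain(des, config, prior, seeds[ch]))
}

.mh_chain <- function(des, config, prior, seed) {
  set.seed(seed)
  I <- length(des$subj_levels); J <- length(des$pic_levels)
  pos <- des$pos
  P <- des$P; z <- des$z; g <- pmin(pmax(des$g, 1e-9), 1 - 1e-9)
  gpos <- g[pos]; Ppos <- P[pos, , drop = FALSE]
  subj <- des$subj; pic <- des$pic
  subjpos <- subj[pos]; picpos <- pic[pos]
  has_pos <- length(pos) > 0

  llik_bern <- function(th, rs, rp) {
    eta <- th[1] + drop(P %*% th[-1]) + rs[subj] + rp[pic]
    sum(ifelse(z == 1L, stats::plogis(eta, log.p = TRUE),
               stats::plogis(-eta, log.p = TRUE)))
  }
  llik_beta <- function(th, phi, rs, rp) {
    if (!has_pos) return(0)
    mu <- stats::plogis(th[1] + drop(Ppos %*% th[-1]) + rs[subjpos] + rp[picpos])
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    sum(stats::dbeta(gpos, phi * mu, phi * (1 - mu), log = TRUE))
  }
  # per-group log likelihood sums, as length-I (or -J) vectors
  grp_ll_bern <- function(th, rs, rp, ngrp, grp) {
    eta <- th[1] + drop(P %*% th[-1]) + rs[subj] + rp[pic]
    ll <- ifelse(z == 1L, stats::plogis(eta, log.p = TRUE),
                 stats::plogis(-eta, log.p = TRUE))
    v <- numeric(ngrp); v[sort(unique(grp))] <- rowsum(ll, grp)[, 1]; v
  }
  grp_ll_beta <- function(th, phi, rs, rp, ngrp, grp) {
    v <- numeric(ngrp)
    if (!has_pos) return(v)
    mu <- stats::plogis(th[1] + drop(Ppos %*% th[-1]) + rs[subjpos] + rp[picpos])
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    ll <- stats::dbeta(gpos, phi * mu, phi * (1 - mu), log = TRUE)
    v[sort(unique(grp))] <- rowsum(ll, grp)[, 1]; v
  }
  prior_fixed <- function(th) sum(stats::dnorm(th, 0, prior$fixed_sd, log = TRUE))

  # state
  th_b <- c(stats::qlogis(max(mean(z), 0.05)) , numeric(5))
  th_B <- c(if (has_pos) stats::qlogis(mean(gpos)) else 0, numeric(5))
  lphi <- log(10); lsig <- rep(0, 4)
  rs_b <- numeric(I); rp_b <- numeric(J); rs_B <- numeric(I); rp_B <- numeric(J)

  # adaptation state
  s_thb <- 0.1; s_thB <- 0.1; s_phi <- 0.3; s_sig <- rep(0.3, 4)
  s_rsb <- 0.5; s_rpb <- 0.5; s_rsB <- 0.5; s_rpB <- 0.5
  cov_b <- diag(c(1, rep(0.04, 5))); cov_B <- diag(c(1, rep(0.04, 5)))
  mean_b <- th_b; mean_B <- th_B; n_adapt <- 0

  n_ret <- (config$iterations - config$warmup) %/% config$thin
  pnames <- .zib_param_names(des$subj_levels, des$pic_levels)
  out <- matrix(NA_real_, n_ret, length(pnames), dimnames = list(NULL, pnames))
  ret <- 0

  chol_or_diag <- function(S) tryCatch(chol(S + 1e-10 * diag(nrow(S))),
                                       error = function(e) diag(sqrt(diag(S))))
  L_b <- chol_or_diag(cov_b); L_B <- chol_or_diag(cov_B)

  lp_bern_cur <- llik_bern(th_b, rs_b, rp_b)
  lp_beta_cur <- llik_beta(th_B, exp(lphi), rs_B, rp_B)

  for (it in seq_len(config$iterations)) {
    adapting <- it <= config$warmup
    rm_step <- 1 / sqrt(50 + it)

    # Bernoulli fixed-effect block
    prop <- th_b + s_thb * drop(stats::rnorm(6) %*% L_b)
    lp_prop <- llik_bern(prop, rs_b, rp_b)
    lacc <- lp_prop + prior_fixed(prop) - lp_bern_cur - prior_fixed(th_b)
    acc <- is.finite(lacc) && log(stats::runif(1)) < lacc
    if (acc) { th_b <- prop; lp_bern_cur <- lp_prop }
    if (adapting) s_thb <- exp(log(s_thb) + rm_step * ((acc) - 0.234))

    # Beta fixed-effect block
    prop <- th_B + s_thB * drop(stats::rnorm(6) %*% L_B)
    lp_prop <- llik_beta(prop, exp(lphi), rs_B, rp_B)
    lacc <- lp_prop + prior_fixed(prop) - lp_beta_cur - prior_fixed(th_B)
    acc <- is.finite(lacc) && log(stats::runif(1)) < lacc
    if (acc) { th_B <- prop; lp_beta_cur <- lp_prop }
    if (adapting) s_thB <- exp(log(s_thB) + rm_step * ((acc) - 0.234))

    # log phi
    prop <- lphi + s_phi * stats::rnorm(1)
    lp_prop <- llik_beta(th_B, exp(prop), rs_B, rp_B)
    lacc <- lp_prop + stats::dexp(exp(prop), prior$phi_rate, log = TRUE) + prop -
      (lp_beta_cur + stats::dexp(exp(lphi), prior$phi_rate, log = TRUE) + lphi)
    acc <- is.finite(lacc) && log(stats::runif(1)) < lacc
    if (acc) { lphi <- prop; lp_beta_cur <- lp_prop }
    if (adapting) s_phi <- exp(log(s_phi) + rm_step * ((acc) - 0.44))

    # random effects: element-wise parallel scalar MH
    upd_ll <- function(cur, s, ngrp, ll_fun, sigma) {
      prop <- cur + s * stats::rnorm(ngrp)
      ll_cur <- ll_fun(cur); ll_prop <- ll_fun(prop)
      lacc <- ll_prop - ll_cur +
        stats::dnorm(prop, 0, sigma, log = TRUE) -
        stats::dnorm(cur, 0, sigma, log = TRUE)
      take <- log(stats::runif(ngrp)) < lacc & is.finite(lacc)
      list(x = ifelse(take, prop, cur), rate = mean(take))
    }
    sig <- exp(lsig)
    u <- upd_ll(rs_b, s_rsb, I,
                function(x) grp_ll_bern(th_b, x, rp_b, I, subj), sig[1])
    rs_b <- u$x
    if (adapting) s_rsb <- exp(log(s_rsb) + rm_step * (u$rate - 0.44))
    u <- upd_ll(rp_b, s_rpb, J,
                function(x) grp_ll_bern(th_b, rs_b, x, J, pic), sig[2])
    rp_b <- u$x
    if (adapting) s_rpb <- exp(log(s_rpb) + rm_step * (u$rate - 0.44))
    u <- upd_ll(rs_B, s_rsB, I,
                function(x) grp_ll_beta(th_B, exp(lphi), x, rp_B, I, subjpos),
                sig[3])
    rs_B <- u$x
    if (adapting) s_rsB <- exp(log(s_rsB) + rm_step * (u$rate - 0.44))
    u <- upd_ll(rp_B, s_rpB, J,
                function(x) grp_ll_beta(th_B, exp(lphi), rs_B, x, J, picpos),
                sig[4])
    rp_B <- u$x
    if (adapting) s_rpB <- exp(log(s_rpB) + rm_step * (u$rate - 0.44))
    lp_bern_cur <- llik_bern(th_b, rs_b, rp_b)
    lp_beta_cur <- llik_beta(th_B, exp(lphi), rs_B, rp_B)

    # log sigmas: conditional involves only the effect vector and the prior
    effs <- list(rs_b, rp_b, rs_B, rp_B)
    for (k in 1:4) {
      prop <- lsig[k] + s_sig[k] * stats::rnorm(1)
      r <- effs[[k]]
      lacc <- sum(stats::dnorm(r, 0, exp(prop), log = TRUE)) +
        stats::dgamma(exp(prop), prior$scale_shape, prior$scale_rate, log = TRUE) + prop -
        (sum(stats::dnorm(r, 0, exp(lsig[k]), log = TRUE)) +
           stats::dgamma(exp(lsig[k]), prior$scale_shape, prior$scale_rate, log = TRUE) +
           lsig[k])
      acc <- is.finite(lacc) && log(stats::runif(1)) < lacc
      if (acc) lsig[k] <- prop
      if (adapting) s_sig[k] <- exp(log(s_sig[k]) + rm_step * ((acc) - 0.44))
    }

    # covariance adaptation for the joint blocks
    if (adapting) {
      n_adapt <- n_adapt + 1
      d_b <- th_b - mean_b; mean_b <- mean_b + d_b / n_adapt
      cov_b <- cov_b + (tcrossprod(d_b, th_b - mean_b) - cov_b) / n_adapt
      d_B <- th_B - mean_B; mean_B <- mean_B + d_B / n_adapt
      cov_B <- cov_B + (tcrossprod(d_B, th_B - mean_B) - cov_B) / n_adapt
      if (n_adapt %% 100 == 0 && n_adapt >= 200) {
        L_b <- chol_or_diag((cov_b + t(cov_b)) / 2)
        L_B <- chol_or_diag((cov_B + t(cov_B)) / 2)
      }
    }

    if (it > config$warmup && (it - config$warmup) %% config$thin == 0) {
      ret <- ret + 1
      out[ret, ] <- c(th_b, th_B, exp(lphi), exp(lsig), rs_b, rp_b, rs_B, rp_B)
    }
  }
  out
}
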