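#' Zero-inflated Beta model parameters
#'
#' Container for the parameters of one ZIB regression: a Bernoulli
#' ("was the region looked at?") part and a Beta ("how much?") part, each with
#' an intercept and five trait coefficients on the logit scale, a shared Beta
#' precision \eqn{\phi}, and the scales of the crossed participant / image
#' random effects of both parts. One such parameter set describes one
#' (condition, impression, region) cell.
#'
#' @param alpha_bern,alpha_beta Intercepts (logit scale) of the Bernoulli and
#'   Beta parts.
#' @param beta_bern,beta_beta Numeric vectors of 5 trait coefficients (logit
#'   scale), ordered as [big_five_traits()]; names are attached if missing.
#' @param phi Beta precision \eqn{\phi > 0}; the Beta shapes are
#'   \eqn{a = \phi\mu}, \eqn{b = \phi(1-\mu)}.
#' @param sigma_subj_bern,sigma_pic_bern,sigma_subj_beta,sigma_pic_beta
#'   Positive scales of the participant and image random effects.
#' @return An object of class `zib_params`.
#' @examples
#' p <- zib_params(alpha_bern = 1, beta_bern = c(0, 0, 0.3, 0, 0))
#' p$phi
#' @export
zib_params <- function(alpha_bern = 0, beta_bern = numeric(5),
                       alpha_beta = 0, beta_beta = numeric(5),
                       phi = 10,
                       sigma_subj_bern = 1, sigma_pic_bern = 1,
                       sigma_subj_beta = 1, sigma_pic_beta = 1) {
  beta_bern <- .as_trait_vector(beta_bern, "beta_bern")
  beta_beta <- .as_trait_vector(beta_beta, "beta_beta")
  stopifnot(is.finite(alpha_bern), is.finite(alpha_beta),
            all(is.finite(beta_bern)), all(is.finite(beta_beta)))
  if (!is.finite(phi) || phi <= 0) stop("phi must be > 0", call. = FALSE)
  scales <- c(sigma_subj_bern, sigma_pic_bern, sigma_subj_beta, sigma_pic_beta)
  if (any(!is.finite(scales)) || any(scales <= 0))
    stop("random-effect scales must be > 0", call. = FALSE)
  structure(list(alpha_bern = alpha_bern, beta_bern = beta_bern,
                 alpha_beta = alpha_beta, beta_beta = beta_beta,
                 phi = phi,
                 sigma_subj_bern = sigma_subj_bern,
                 sigma_pic_bern = sigma_pic_bern,
                 sigma_subj_beta = sigma_subj_beta,
                 sigma_pic_beta = sigma_pic_beta),
            class = "zib_params")
}

.as_trait_vector <- function(x, what) {
  if (length(x) != 5L)
    stop(what, " must have 5 elements (one per Big Five trait)", call. = FALSE)
  x <- as.numeric(x)
  names(x) <- .TRAITS
  x
}

#' @export
print.zib_params <- function(x, ...) {
  cat("ZIB parameters\n")
  cat("  Bernoulli part: alpha =", format(x$alpha_bern, digits = 4),
      " beta =", paste(format(x$beta_bern, digits = 3), collapse = " "), "\n")
  cat("  Beta part:      alpha =", format(x$alpha_beta, digits = 4),
      " beta =", paste(format(x$beta_beta, digits = 3), collapse = " "), "\n")
  cat("  phi =", format(x$phi, digits = 4),
      " sigmas =", paste(format(unlist(x[6:9]), digits = 3), collapse = " "), "\n")
  invisible(x)
}

.linpred <- function(scores, alpha, beta, r_subj, r_pic) {
  scores <- if (is.matrix(scores)) scores else matrix(scores, nrow = 1)
  drop(alpha + scores %*% beta + r_subj + r_pic)
}

#' Bernoulli-part link: probability of looking at a region
#'
#' Inverse-logit of the Bernoulli-part linear predictor: intercept + trait
#' coefficients times the participant's Big Five scores + participant and
#' image random effects.
#'
#' @param scores Numeric vector of 5 trait scores (1-7 scale), or an n x 5
#'   matrix of score rows.
#' @param alpha_bern Intercept (logit scale).
#' @param beta_bern Vector of 5 trait coefficients.
#' @param r_subj,r_pic Random-effect offsets (default 0; recycled).
#' @return Probability (or vector of probabilities) in (0, 1). Computed with a
#'   numerically stable logistic; extreme predictors saturate without
#'   overflow.
#' @examples
#' link_q(rep(0, 5), 0, numeric(5))            # 0.5
#' link_q(c(0, 0, 0, 0, 1), 0, c(0, 0, 0, 0, 1.479))
#' @export
link_q <- function(scores, alpha_bern, beta_bern, r_subj = 0, r_pic = 0) {
  stats::plogis(.linpred(scores, alpha_bern, beta_bern, r_subj, r_pic))
}

#' Beta-part link: mean dwell weight given the region was looked at
#'
#' Same inverse-logit structure as [link_q()], with the Beta-part intercept
#' and coefficients; returns the Beta mean \eqn{\mu \in (0,1)}.
#'
#' @inheritParams link_q
#' @param alpha_beta Intercept (logit scale).
#' @param beta_beta Vector of 5 trait coefficients.
#' @return Beta mean (or vector) in (0, 1).
#' @export
link_mu <- function(scores, alpha_beta, beta_beta, r_subj = 0, r_pic = 0) {
  stats::plogis(.linpred(scores, alpha_beta, beta_beta, r_subj, r_pic))
}

#' Beta shape parameters from precision and mean
#'
#' The mean/precision parameterisation of the Beta distribution:
#' \eqn{a = \phi\mu}, \eqn{b = \phi(1-\mu)}, so the implied mean is
#' \eqn{a/(a+b) = \mu} and \eqn{a + b = \phi}.
#'
#' @param phi Precision, > 0. Vectorised.
#' @param mu Mean, in (0, 1). Vectorised.
#' @return List with components `a` and `b`.
#' @examples
#' beta_shapes(10, 0.3)  # a = 3, b = 7
#' @export
beta_shapes <- function(phi, mu) {
  if (any(!is.finite(phi)) || any(phi <= 0))
    stop("phi must be > 0", call. = FALSE)
  if (any(!is.finite(mu)) || any(mu <= 0) || any(mu >= 1))
    stop("mu must be in (0, 1)", call. = FALSE)
  list(a = phi * mu, b = phi * (1 - mu))
}

#' Zero-inflated Beta log density
#'
#' Log density of the ZIB distribution: a point mass of probability
#' \eqn{1 - q} at 0, and \eqn{q \times \mathrm{Beta}(a, b)} on (0, 1).
#'
#' @param g Observed dwell weight(s), in `[0, 1)`.
#' @param q Probability of a nonzero weight, in (0, 1).
#' @param a,b Beta shape parameters, > 0.
#' @return Log density, vectorised over the longest argument.
#' @examples
#' zib_logpdf(0, 0.25, 1, 1)    # log(0.75)
#' zib_logpdf(0.5, 0.5, 1, 1)   # log(0.5)
#' @export
zib_logpdf <- function(g, q, a, b) {
  if (any(!is.finite(g)) || any(g < 0) || any(g >= 1))
    stop("g must lie in [0, 1)", call. = FALSE)
  if (any(q <= 0) || any(q >= 1)) stop("q must lie in (0, 1)", call. = FALSE)
  if (any(a <= 0) || any(b <= 0)) stop("a and b must be > 0", call. = FALSE)
  n <- max(length(g), length(q), length(a), length(b))
  g <- rep_len(g, n); q <- rep_len(q, n)
  a <- rep_len(a, n); b <- rep_len(b, n)
  out <- numeric(n)
  zero <- g == 0
  out[zero] <- log1p(-q[zero])
  if (any(!zero))
    out[!zero] <- log(q[!zero]) +
      stats::dbeta(g[!zero], a[!zero], b[!zero], log = TRUE)
  out
}

#' Prior configuration for the ZIB model
#'
#' Fixed effects (both intercepts and all trait coefficients) get independent
#' Normal(0, `fixed_sd`) priors. The four random-effect scales get
#' Gamma(`scale_shape`, `scale_rate`) priors (shape/rate; default mean 1), and
#' each random effect is Normal(0, its scale). The Beta precision \eqn{\phi}
#' gets an Exponential(`phi_rate`) prior (default mean 10).
#'
#' @param fixed_sd Standard deviation of the Normal prior on fixed effects.
#' @param scale_shape,scale_rate Shape and rate of the Gamma prior on the
#'   random-effect scales.
#' @param phi_rate Rate of the Exponential prior on \eqn{\phi}.
#' @return An object of class `zib_prior`.
#' @export
zib_prior <- function(fixed_sd = 10, scale_shape = 10, scale_rate = 10,
                      phi_rate = 0.1) {
  stopifnot(fixed_sd > 0, scale_shape > 0, scale_rate > 0, phi_rate > 0)
  structure(list(fixed_sd = fixed_sd, scale_shape = scale_shape,
                 scale_rate = scale_rate, phi_rate = phi_rate),
            class = "zib_prior")
}

#' Zero random effects for a data slice
#'
#' Convenience constructor of an all-zero random-effect set matching the
#' participants and images present in a weight-table slice.
#'
#' @param data A weight-table slice with `participant_id` and `image_id`.
#' @return List with named vectors `r_subj_bern`, `r_pic_bern`,
#'   `r_subj_beta`, `r_pic_beta`.
#' @export
zero_effects <- function(data) {
  subj <- sort(unique(as.character(data$participant_id)))
  pic <- sort(unique(as.character(data$image_id)))
  zs <- stats::setNames(numeric(length(subj)), subj)
  zp <- stats::setNames(numeric(length(pic)), pic)
  list(r_subj_bern = zs, r_pic_bern = zp, r_subj_beta = zs, r_pic_beta = zp)
}

# Align a personality table to the participant_id order of a data slice,
# returning the n x 5 raw-score matrix.
.score_matrix <- function(data, personality) {
  idx <- match(as.character(data$participant_id),
               as.character(personality$participant_id))
  if (anyNA(idx))
    stop("participants in data without personality scores: ",
         paste(unique(data$participant_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  as.matrix(personality[idx, .TRAITS, drop = FALSE])
}

#' Log posterior density of the ZIB model on a data slice
#'
#' Sum of the ZIB log likelihood over the rows of a single
#' (condition, impression, region) slice, plus the log priors: Normal(0,
#' `fixed_sd`) on intercepts and trait coefficients, Normal(0, sigma) on every
#' random effect with Gamma priors on the four sigmas, and an Exponential
#' prior on \eqn{\phi}. This is the density the MCMC backends target (up to
#' the samplers' internal parameterisation).
#'
#' @param params A [zib_params()] object.
#' @param effects Random-effect values as produced by [zero_effects()]:
#'   named vectors covering every participant and image in `data`.
#' @param data Weight-table slice: data frame with `participant_id`,
#'   `image_id` and `G` (plus any other columns, ignored).
#' @param personality Personality table with `participant_id` and the five
#'   trait columns.
#' @param prior A [zib_prior()] object.
#' @return Scalar log posterior (unnormalised). An empty slice returns the
#'   prior-only value.
#' @export
zib_log_posterior <- function(params, effects, data, personality,
                              prior = zib_prior()) {
  stopifnot(inherits(params, "zib_params"), inherits(prior, "zib_prior"))
  lp <- 0
  if (nrow(data) > 0) {
    g <- data$G
    if (any(!is.finite(g)) || any(g < 0) || any(g >= 1))
      stop("weights G must lie in [0, 1)", call. = FALSE)
    P <- .score_matrix(data, personality)
    rs_b <- effects$r_subj_bern[as.character(data$participant_id)]
    rp_b <- effects$r_pic_bern[as.character(data$image_id)]
    rs_B <- effects$r_subj_beta[as.character(data$participant_id)]
    rp_B <- effects$r_pic_beta[as.character(data$image_id)]
    if (anyNA(rs_b) || anyNA(rp_b) || anyNA(rs_B) || anyNA(rp_B))
      stop("effects do not cover every participant/image in data",
           call. = FALSE)
    q <- link_q(P, params$alpha_bern, params$beta_bern, rs_b, rp_b)
    mu <- link_mu(P, params$alpha_beta, params$beta_beta, rs_B, rp_B)
    sh <- beta_shapes(params$phi, mu)
    lp <- lp + sum(zib_logpdf(g, q, sh$a, sh$b))
  }
  fixed <- c(params$alpha_bern, params$beta_bern,
             params$alpha_beta, params$beta_beta)
  lp <- lp + sum(stats::dnorm(fixed, 0, prior$fixed_sd, log = TRUE))
  lp <- lp + stats::dexp(params$phi, prior$phi_rate, log = TRUE)
  sig <- c(params$sigma_subj_bern, params$sigma_pic_bern,
           params$sigma_subj_beta, params$sigma_pic_beta)
  lp <- lp + sum(stats::dgamma(sig, prior$scale_shape, prior$scale_rate,
                               log = TRUE))
  lp <- lp + sum(stats::dnorm(effects$r_subj_bern, 0, params$sigma_subj_bern,
                              log = TRUE))
  lp <- lp + sum(stats::dnorm(effects$r_pic_bern, 0, params$sigma_pic_bern,
                              log = TRUE))
  lp <- lp + sum(stats::dnorm(effects$r_subj_beta, 0, params$sigma_subj_beta,
                              log = TRUE))
  lp <- lp + sum(stats::dnorm(effects$r_pic_beta, 0, params$sigma_pic_beta,
                              log = TRUE))
  lp
}
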