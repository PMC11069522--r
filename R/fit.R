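#' MCMC sampler configuration
#'
#' Defaults follow common practice for this model class: 4 chains, 2000
#' iterations each with the first 1000 as warm-up, no thinning, yielding
#' 4 x 1000 = 4000 retained draws.
#'
#' @param chains Number of chains (>= 1).
#' @param iterations Total iterations per chain, including warm-up.
#' @param warmup Warm-up (adaptation + burn-in) iterations, < `iterations`.
#' @param thin Thinning interval (>= 1); `(iterations - warmup)` must be a
#'   multiple of `thin`.
#' @param seed Integer seed; all chain-level RNG streams are derived from it.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 4, iterations = 2000, warmup = 1000,
                        thin = 1, seed = 1) {
  chains <- as.integer(chains); iterations <- as.integer(iterations)
  warmup <- as.integer(warmup); thin <- as.integer(thin)
  if (chains < 1) stop("chains must be >= 1", call. = FALSE)
  if (warmup >= iterations) stop("warmup must be < iterations", call. = FALSE)
  if (thin < 1) stop("thin must be >= 1", call. = FALSE)
  if ((iterations - warmup) %% thin != 0)
    stop("(iterations - warmup) must be a multiple of thin", call. = FALSE)
  structure(list(chains = chains, iterations = iterations, warmup = warmup,
                 thin = thin, seed = as.integer(seed)),
            class = "mcmc_config")
}

#' @export
print.mcmc_config <- function(x, ...) {
  cat(sprintf("MCMC config: %d chains, %d iterations (%d warmup), thin %d, seed %d\n",
              x$chains, x$iterations, x$warmup, x$thin, x$seed))
  cat(sprintf("  retained draws: %d x %d = %d\n", x$chains,
              (x$iterations - x$warmup) %/% x$thin,
              x$chains * (x$iterations - x$warmup) %/% x$thin))
  invisible(x)
}

# Per-chain RNG seeds derived from the root seed (kept below 2^31).
.chain_seeds <- function(seed, chains) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, chains)
}

# Assemble the design arrays for one scope slice.
.zib_design <- function(data, personality) {
  g <- data$G
  if (any(!is.finite(g)) || any(g < 0) || any(g >= 1))
    stop("weights G must lie in [0, 1)", call. = FALSE)
  P <- .score_matrix(data, personality)
  subj_levels <- sort(unique(as.character(data$participant_id)))
  pic_levels <- sort(unique(as.character(data$image_id)))
  list(g = g, z = as.integer(g > 0), P = P,
       subj = match(as.character(data$participant_id), subj_levels),
       pic = match(as.character(data$image_id), pic_levels),
       subj_levels = subj_levels, pic_levels = pic_levels,
       n = length(g), pos = which(g > 0))
}

# Canonical parameter names for a fit with the given grouping levels.
.zib_param_names <- function(subj_levels, pic_levels) {
  c("alpha_bern", paste0("beta_bern[", .TRAITS, "]"),
    "alpha_beta", paste0("beta_beta[", .TRAITS, "]"),
    "phi",
    "sigma_subj_bern", "sigma_pic_bern", "sigma_subj_beta", "sigma_pic_beta",
    paste0("r_subj_bern[", subj_levels, "]"),
    paste0("r_pic_bern[", pic_levels, "]"),
    paste0("r_subj_beta[", subj_levels, "]"),
    paste0("r_pic_beta[", pic_levels, "]"))
}

#' Fit the hierarchical zero-inflated Beta model to one data slice
#'
#' Fits the ZIB regression of dwell weight on the five personality traits for
#' a single (condition, impression, region) cell, with crossed participant and
#' image random effects on both model parts. Each cell is fit independently,
#' matching the per-area, per-impression reporting structure of this design.
#'
#' Two samplers are available. The default `"jags"` backend runs the model in
#' JAGS (via \pkg{rjags}); predictors are mean-centred internally for mixing
#' and the intercept draws are mapped back to the raw 1-7 score scale, an
#' exact reparameterisation. The `"mh"` backend is a self-contained blocked
#' adaptive random-walk Metropolis sampler targeting [zib_log_posterior()]
#' directly; it is slower per effective draw and mainly serves as an
#' independent cross-check.
#'
#' @param data A region-weight table (columns `participant_id`, `image_id`,
#'   `G`, and optionally `condition`, `impression`, `region`).
#' @param personality Personality table with `participant_id` and the five
#'   trait columns on the raw 1-7 scale (entered uncentred into the model).
#' @param scope Optional named list/vector with any of `condition`,
#'   `impression`, `region`; `data` is filtered to it. After filtering the
#'   slice must be a single cell.
#' @param config An [mcmc_config()].
#' @param prior A [zib_prior()].
#' @param backend `"jags"` (default) or `"mh"`.
#' @param quiet Suppress sampler progress output.
#' @return An object of class `zib_fit` with per-chain draw matrices for all
#'   fixed effects, \eqn{\phi}, the four random-effect scales and every
#'   random effect. If every weight in the slice is zero the Beta part is
#'   informed only by its prior and a warning is issued.
#' @seealso [summary.zib_fit()], [check_convergence()], [significance_table()],
#'   [trait_sweep()]
#' @export
fit_zib <- function(data, personality, scope = NULL, config = mcmc_config(),
                    prior = zib_prior(), backend = c("jags", "mh"),
                    quiet = TRUE) {
  backend <- match.arg(backend)
  stopifnot(inherits(config, "mcmc_config"), inherits(prior, "zib_prior"))
  if (!is.null(scope)) {
    scope <- as.list(scope)
    for (f in intersect(names(scope), c("condition", "impression", "region")))
      data <- data[data[[f]] == scope[[f]], , drop = FALSE]
  }
  if (nrow(data) == 0) stop("no data in the requested scope", call. = FALSE)
  for (f in c("condition", "impression", "region"))
    if (f %in% names(data) && length(unique(data[[f]])) > 1L)
      stop("data slice spans multiple values of '", f,
           "'; fit one (condition, impression, region) cell at a time",
           call. = FALSE)
  scope <- list(
    condition = if ("condition" %in% names(data)) as.character(data$condition[1]) else NA_character_,
    impression = if ("impression" %in% names(data)) as.character(data$impression[1]) else NA_character_,
    region = if ("region" %in% names(data)) as.character(data$region[1]) else NA_character_)
  des <- .zib_design(data, personality)
  if (length(des$pos) == 0)
    warning("all weights in this slice are zero; the Beta part is identified only by its prior")
  draws <- switch(backend,
                  jags = .fit_zib_jags(des, config, prior, quiet),
                  mh = .fit_zib_mh(des, config, prior, quiet))
  structure(list(draws = draws, parameters = colnames(draws[[1]]),
                 scope = scope, config = config, prior = prior,
                 backend = backend,
                 participants = des$subj_levels, images = des$pic_levels,
                 n_obs = des$n, n_pos = length(des$pos),
                 data_digest = sprintf("n%d_sum%.10g", des$n, sum(des$g))),
            class = "zib_fit")
}

#' Number of retained posterior draws in a fit
#'
#' @param fit A `zib_fit`.
#' @return Total retained draws (chains x retained per chain).
#' @export
n_draws <- function(fit) {
  stopifnot(inherits(fit, "zib_fit"))
  sum(vapply(fit$draws, nrow, integer(1)))
}

#' Pooled draw matrix of a fit
#'
#' @param x A `zib_fit`.
#' @param ... Unused.
#' @return Matrix (total draws x parameters), chains stacked in order, draw
#'   order preserved within chain.
#' @export
as.matrix.zib_fit <- function(x, ...) do.call(rbind, x$draws)

#' @export
print.zib_fit <- function(x, ...) {
  cat("Hierarchical zero-inflated Beta fit (", x$backend, " backend)\n", sep = "")
  cat(sprintf("  scope: condition=%s impression=%s region=%s\n",
              x$scope$condition, x$scope$impression, x$scope$region))
  cat(sprintf("  data: %d observations (%d nonzero), %d participants, %d images\n",
              x$n_obs, x$n_pos, length(x$participants), length(x$images)))
  cat(sprintf("  draws: %d chains x %d = %d retained\n",
              length(x$draws), nrow(x$draws[[1]]), n_draws(x)))
  invisible(x)
}

#' Posterior summary of a ZIB fit
#'
#' @param object A `zib_fit`.
#' @param mass HDI probability mass (default 0.95).
#' @param fixed_only Summarise only the fixed effects, phi and the
#'   random-effect scales (default), or every parameter.
#' @param ... Unused.
#' @return Data frame with posterior mean, sd, HDI bounds and split-Rhat per
#'   parameter, of class `summary.zib_fit`.
#' @export
summary.zib_fit <- function(object, mass = 0.95, fixed_only = TRUE, ...) {
  keep <- if (fixed_only) {
    grep("^r_", object$parameters, invert = TRUE, value = TRUE)
  } else object$parameters
  pooled <- as.matrix(object)
  out <- data.frame(
    parameter = keep,
    mean = colMeans(pooled[, keep, drop = FALSE]),
    sd = apply(pooled[, keep, drop = FALSE], 2, stats::sd),
    stringsAsFactors = FALSE, row.names = NULL)
  h <- t(vapply(keep, function(p) hdi(pooled[, p], mass), numeric(2)))
  out$hdi_low <- h[, 1]; out$hdi_high <- h[, 2]
  out$rhat <- vapply(keep, function(p)
    split_rhat(sapply(object$draws, function(d) d[, p])), numeric(1))
  attr(out, "mass") <- mass
  attr(out, "scope") <- object$scope
  class(out) <- c("summary.zib_fit", "data.frame")
  out
}

#' @export
print.summary.zib_fit <- function(x, digits = 3, ...) {
  sc <- attr(x, "scope")
  cat(sprintf("ZIB fit summary (condition=%s impression=%s region=%s), %g%% HDI\n",
              sc$condition, sc$impression, sc$region, 100 * attr(x, "mass")))
  print.data.frame(as.data.frame(lapply(x, function(col)
    if (is.numeric(col)) signif(col, digits) else col)), row.names = FALSE)
  invisible(x)
}

#' Posterior-mean coefficients of a ZIB fit
#'
#' @param object A `zib_fit`.
#' @param part `"bern"`, `"beta"` or `"all"` (default): which model part's
#'   intercept and trait coefficients to return.
#' @param ... Unused.
#' @return Named numeric vector of posterior means.
#' @export
coef.zib_fit <- function(object, part = c("all", "bern", "beta"), ...) {
  part <- match.arg(part)
  nm <- switch(part,
               bern = c("alpha_bern", paste0("beta_bern[", .TRAITS, "]")),
               beta = c("alpha_beta", paste0("beta_beta[", .TRAITS, "]")),
               all = grep("^r_", object$parameters, invert = TRUE, value = TRUE))
  colMeans(as.matrix(object)[, nm, drop = FALSE])
}

# Extract the fixed-effect draw blocks from a pooled matrix.
.fixed_draws <- function(pooled) {
  list(alpha_bern = pooled[, "alpha_bern"],
       beta_bern = pooled[, paste0("beta_bern[", .TRAITS, "]"), drop = FALSE],
       alpha_beta = pooled[, "alpha_beta"],
       beta_beta = pooled[, paste0("beta_beta[", .TRAITS, "]"), drop = FALSE],
       phi = pooled[, "phi"])
}

#' Posterior predictions of q and mu for new personality profiles
#'
#' Evaluates the Bernoulli-part probability `q` and/or Beta-part mean `mu` for
#' each posterior draw at each supplied score profile, with random effects set
#' to zero (population-level prediction), then summarises draws pointwise.
#'
#' @param object A `zib_fit`.
#' @param newdata Data frame with the five trait columns (1-7 scale), or a
#'   numeric matrix/vector of scores.
#' @param type `"q"`, `"mu"` or `"both"`.
#' @param summarise If `TRUE` (default) return pointwise posterior mean and
#'   95% HDI; otherwise return the raw draws-by-profile matrices.
#' @param mass HDI mass for the summary.
#' @param ... Unused.
#' @return If summarised, a data frame with one row per profile and statistic;
#'   else a list of draw matrices.
#' @export
predict.zib_fit <- function(object, newdata, type = c("both", "q", "mu"),
                            summarise = TRUE, mass = 0.95, ...) {
  type <- match.arg(type)
  S <- if (is.data.frame(newdata)) as.matrix(newdata[, .TRAITS, drop = FALSE])
       else if (is.matrix(newdata)) newdata
       else matrix(newdata, nrow = 1)
  if (ncol(S) != 5) stop("newdata must supply 5 trait scores per row", call. = FALSE)
  fx <- .fixed_draws(as.matrix(object))
  out <- list()
  if (type %in% c("q", "both"))
    out$q <- stats::plogis(outer(fx$alpha_bern, rep(1, nrow(S))) +
                             fx$beta_bern %*% t(S))
  if (type %in% c("mu", "both"))
    out$mu <- stats::plogis(outer(fx$alpha_beta, rep(1, nrow(S))) +
                              fx$beta_beta %*% t(S))
  if (!summarise) return(out)
  do.call(rbind, lapply(names(out), function(st) {
    m <- out[[st]]
    h <- t(apply(m, 2, hdi, mass = mass))
    data.frame(profile = seq_len(ncol(m)), statistic = st,
               mean = colMeans(m), hdi_low = h[, 1], hdi_high = h[, 2],
               row.names = NULL)
  }))
}

#' Posterior-predictive simulation of dwell weights
#'
#' Draws dwell weights from the posterior predictive: for each replicate a
#' posterior draw is selected at random and a ZIB weight is generated for each
#' supplied score profile (random effects at zero).
#'
#' @param object A `zib_fit`.
#' @param nsim Number of replicates.
#' @param seed Optional seed.
#' @param newdata Score profiles as in [predict.zib_fit()]; default a single
#'   all-4 (scale midpoint) profile.
#' @param ... Unused.
#' @return Matrix (nsim x profiles) of simulated weights in `[0, 1)`.
#' @export
simulate.zib_fit <- function(object, nsim = 1, seed = NULL,
                             newdata = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(newdata)) newdata <- matrix(rep(4, 5), nrow = 1)
  S <- if (is.data.frame(newdata)) as.matrix(newdata[, .TRAITS, drop = FALSE])
       else if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1)
  pooled <- as.matrix(object)
  idx <- sample.int(nrow(pooled), nsim, replace = TRUE)
  fx <- .fixed_draws(pooled)
  out <- matrix(0, nsim, nrow(S))
  for (s in seq_len(nsim)) {
    i <- idx[s]
    q <- stats::plogis(fx$alpha_bern[i] + drop(S %*% fx$beta_bern[i, ]))
    mu <- stats::plogis(fx$alpha_beta[i] + drop(S %*% fx$beta_beta[i, ]))
    z <- stats::rbinom(nrow(S), 1, q)
    w <- stats::rbeta(nrow(S), fx$phi[i] * mu, fx$phi[i] * (1 - mu))
    out[s, ] <- ifelse(z == 1, pmin(w, 1 - 1e-6), 0)
  }
  out
}
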