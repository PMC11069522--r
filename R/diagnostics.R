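#' Split-Rhat convergence diagnostic
#'
#' Gelman-Rubin potential scale reduction computed on half-chains: each chain
#' is split in half (the middle draw of an odd-length chain is dropped), and
#' \eqn{\hat R = \sqrt{\hat V / W}} where \eqn{W} is the mean within-half-chain
#' variance and \eqn{\hat V = \frac{n-1}{n} W + B/n} the pooled variance
#' estimate. Splitting makes the diagnostic sensitive to trends within a
#' chain, not only to disagreement between chains.
#'
#' @param draws Matrix (iterations x chains) or list of equal-length numeric
#'   vectors, one per chain; at least 2 chains of at least 4 draws.
#' @return Scalar \eqn{\hat R \ge 1} (up to floating error). Chains that are
#'   all constant and identical return 1 by convention.
#' @export
split_rhat <- function(draws) {
  if (is.list(draws)) {
    n <- unique(lengths(draws))
    if (length(n) != 1) stop("chains must have equal length", call. = FALSE)
    draws <- do.call(cbind, draws)
  }
  draws <- as.matrix(draws)
  if (ncol(draws) < 2 || nrow(draws) < 4)
    stop("need >= 2 chains of >= 4 draws", call. = FALSE)
  half <- nrow(draws) %/% 2
  splits <- cbind(draws[seq_len(half), , drop = FALSE],
                  draws[(nrow(draws) - half + 1):nrow(draws), , drop = FALSE])
  n <- nrow(splits)
  W <- mean(apply(splits, 2, stats::var))
  Bn <- stats::var(colMeans(splits))  # = B/n
  if (W == 0) return(if (Bn == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + Bn) / W)
}

#' Convergence check for a ZIB fit
#'
#' A fit counts as converged when it has at least 3 chains and every
#' parameter's split-Rhat is below the threshold.
#'
#' @param fit A `zib_fit`.
#' @param threshold Rhat threshold (default 1.1).
#' @return Object of class `zib_convergence`: data frame of per-parameter
#'   Rhat with `pass` flags, plus attributes `chains`, `max_rhat`, `passed`.
#' @export
check_convergence <- function(fit, threshold = 1.1) {
  stopifnot(inherits(fit, "zib_fit"))
  rhat <- vapply(fit$parameters, function(p)
    split_rhat(sapply(fit$draws, function(d) d[, p])), numeric(1))
  out <- data.frame(parameter = fit$parameters, rhat = unname(rhat),
                    pass = unname(rhat < threshold), row.names = NULL)
  attr(out, "chains") <- length(fit$draws)
  attr(out, "threshold") <- threshold
  attr(out, "max_rhat") <- max(rhat)
  attr(out, "passed") <- length(fit$draws) >= 3 && all(rhat < threshold)
  class(out) <- c("zib_convergence", "data.frame")
  out
}

#' @export
print.zib_convergence <- function(x, ...) {
  cat(sprintf("Convergence: %s (%d chains, max split-Rhat %.4f, threshold %.2f)\n",
              if (attr(x, "passed")) "PASS" else "FAIL",
              attr(x, "chains"), attr(x, "max_rhat"), attr(x, "threshold")))
  bad <- x[!x$pass, , drop = FALSE]
  if (nrow(bad)) {
    cat("  parameters over threshold:\n")
    print.data.frame(bad, row.names = FALSE)
  }
  invisible(x)
}

#' Highest density interval of a draw vector
#'
#' Shortest contiguous interval containing `ceiling(mass * n)` of the sorted
#' draws (the Chen-Shao sample-window construction). Ties in width are broken
#' by the lowest starting index.
#'
#' @param samples Numeric vector of posterior draws.
#' @param mass Probability mass, in (0, 1); default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
hdi <- function(samples, mass = 0.95) {
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)", call. = FALSE)
  n <- length(samples)
  if (n < ceiling(1 / (1 - mass)))
    stop("too few draws for a ", mass, " HDI", call. = FALSE)
  x <- sort(samples)
  m <- ceiling(mass * n)
  starts <- seq_len(n - m + 1)
  widths <- x[starts + m - 1] - x[starts]
  i <- which.min(widths)  # which.min takes the first minimum: lowest start
  c(lower = x[i], upper = x[i + m - 1])
}

.PREDICTOR_ABBREV <- c(extraversion = "Extra.", agreeableness = "Agree.",
                       conscientiousness = "Consc.", neuroticism = "Neuro.",
                       openness = "Open.")

#' Table of credible trait effects across fits
#'
#' Builds the standard reporting table: for each converged fit and each trait
#' coefficient of the Bernoulli and Beta parts, a row is included if and only
#' if the coefficient's HDI excludes 0. Non-converged fits are dropped with a
#' warning rather than an error, mirroring reporting practice.
#'
#' @param fits A `zib_fit` or list of them (typically one per
#'   condition/impression/region cell).
#' @param mass HDI mass (default 0.95).
#' @param threshold Split-Rhat convergence threshold for inclusion.
#' @return Data frame of class `zib_significance` with columns `model`
#'   (Bernoulli/Beta), `condition`, `impression`, `area`, `predictor`,
#'   `mean`, `hdi_low`, `hdi_high`, sorted by (model, impression, area,
#'   predictor).
#' @export
significance_table <- function(fits, mass = 0.95, threshold = 1.1) {
  if (inherits(fits, "zib_fit")) fits <- list(fits)
  rows <- list()
  for (fit in fits) {
    conv <- check_convergence(fit, threshold)
    if (!attr(conv, "passed")) {
      warning(sprintf(
        "fit (condition=%s impression=%s region=%s) not converged (max Rhat %.3f); excluded",
        fit$scope$condition, fit$scope$impression, fit$scope$region,
        attr(conv, "max_rhat")))
      next
    }
    pooled <- as.matrix(fit)
    for (part in c("bern", "beta")) {
      for (trait in .TRAITS) {
        d <- pooled[, sprintf("beta_%s[%s]", part, trait)]
        h <- hdi(d, mass)
        if (h[1] > 0 || h[2] < 0) {
          m <- mean(d)
          if (m < h[1] || m > h[2])
            message("posterior mean outside HDI for ",
                    sprintf("beta_%s[%s]", part, trait),
                    " (skewed posterior); row kept")
          rows[[length(rows) + 1]] <- data.frame(
            model = if (part == "bern") "Bernoulli" else "Beta",
            condition = fit$scope$condition,
            impression = fit$scope$impression,
            area = fit$scope$region,
            predictor = unname(.PREDICTOR_ABBREV[trait]),
            mean = m, hdi_low = unname(h[1]), hdi_high = unname(h[2]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(model = character(), condition = character(),
               impression = character(), area = character(),
               predictor = character(), mean = numeric(),
               hdi_low = numeric(), hdi_high = numeric(),
               stringsAsFactors = FALSE)
  out <- out[order(out$model, out$impression, out$area, out$predictor), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("zib_significance", "data.frame")
  out
}
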