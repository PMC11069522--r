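# Posterior trait-sweep simulations: population-level q and mu curves over a
# trait grid, and restricted-minus-free condition differences.

.sweep_summarise <- function(arr, grid, mass) {
  # arr: draws x regions x grid, per statistic
  do.call(rbind, lapply(dimnames(arr)[[2]], function(reg) {
    do.call(rbind, lapply(seq_along(grid), function(ti) {
      d <- arr[, reg, ti]
      h <- hdi(d, mass)
      data.frame(region = reg, trait_value = grid[ti], mean = mean(d),
                 hdi_low = unname(h[1]), hdi_high = unname(h[2]),
                 stringsAsFactors = FALSE)
    }))
  }))
}

#' Posterior trait sweep of focus probability and dwell frequency
#'
#' Sweeps one trait over the score grid while fixing the remaining four
#' traits at `fixed_value` (3, by convention), evaluating the Bernoulli-part
#' probability `q` and the Beta-part mean `mu` for every posterior draw of
#' every region's fit, with random effects set to 0 (population-level
#' curves). Draws are summarised pointwise (mean and HDI) only after the
#' curves are computed, never by plugging in posterior means.
#'
#' @param fits List of `zib_fit` objects covering all six regions for one
#'   (condition, impression); names are ignored, scopes are checked.
#' @param trait The swept trait (one of [big_five_traits()]).
#' @param grid Trait values to sweep (default the integer scores 1..7).
#' @param fixed_value Score assigned to the non-swept traits (default 3).
#' @param include_qmu Also compute the unconditional expected weight
#'   `q * mu` per draw (off by default).
#' @param mass HDI mass for the pointwise summaries.
#' @return Object of class `zib_sweep`: list with `condition`, `impression`,
#'   `trait`, `grid`, `fixed_value`, `draws` (per-statistic arrays of
#'   dimension draws x regions x grid) and `summary` (long data frame with
#'   columns `region`, `trait_value`, `statistic`, `mean`, `hdi_low`,
#'   `hdi_high`).
#' @export
trait_sweep <- function(fits, trait, grid = 1:7, fixed_value = 3,
                        include_qmu = FALSE, mass = 0.95) {
  if (inherits(fits, "zib_fit")) fits <- list(fits)
  if (!trait %in% .TRAITS) stop("unknown trait: ", trait, call. = FALSE)
  if (is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly increasing", call. = FALSE)
  regions <- vapply(fits, function(f) f$scope$region, character(1))
  if (!setequal(regions, .REGIONS))
    stop("fits must cover all six regions exactly once", call. = FALSE)
  fits <- fits[match(.REGIONS, regions)]
  cond <- unique(vapply(fits, function(f) f$scope$condition, character(1)))
  imp <- unique(vapply(fits, function(f) f$scope$impression, character(1)))
  if (length(cond) != 1 || length(imp) != 1)
    stop("fits must share one condition and one impression", call. = FALSE)
  nd <- unique(vapply(fits, n_draws, integer(1)))
  if (length(nd) != 1)
    stop("fits must have equal draw counts", call. = FALSE)

  profiles <- sapply(grid, function(t) {
    p <- rep(fixed_value, 5); p[match(trait, .TRAITS)] <- t; p
  })  # 5 x length(grid)
  qa <- array(NA_real_, c(nd, 6, length(grid)),
              dimnames = list(NULL, .REGIONS, grid))
  ma <- qa
  for (r in 1:6) {
    fx <- .fixed_draws(as.matrix(fits[[r]]))
    qa[, r, ] <- stats::plogis(fx$alpha_bern + fx$beta_bern %*% profiles)
    ma[, r, ] <- stats::plogis(fx$alpha_beta + fx$beta_beta %*% profiles)
  }
  draws <- list(q = qa, mu = ma)
  if (include_qmu) draws$qmu <- qa * ma
  summ <- do.call(rbind, lapply(names(draws), function(st) {
    s <- .sweep_summarise(draws[[st]], grid, mass)
    cbind(statistic = st, s)[, c("region", "trait_value", "statistic",
                                 "mean", "hdi_low", "hdi_high")]
  }))
  rownames(summ) <- NULL
  structure(list(condition = cond, impression = imp, trait = trait,
                 grid = grid, fixed_value = fixed_value, draws = draws,
                 summary = summ, mass = mass),
            class = "zib_sweep")
}

#' @export
print.zib_sweep <- function(x, ...) {
  cat(sprintf("Trait sweep: %s over %s..%s (others fixed at %g)\n",
              x$trait, min(x$grid), max(x$grid), x$fixed_value))
  cat(sprintf("  condition %s, impression %s, %d draws, statistics: %s\n",
              x$condition, x$impression, dim(x$draws[[1]])[1],
              paste(names(x$draws), collapse = ", ")))
  invisible(x)
}

#' Restricted-minus-free condition difference of two sweeps
#'
#' Subtracts the free-condition sweep from the restricted-condition sweep
#' draw by draw (chains are paired by draw index), then summarises pointwise.
#' Positive values mean the restricted condition dominates.
#'
#' @param restricted,free `zib_sweep` objects with matching impression,
#'   trait, grid, statistics and draw counts.
#' @param mass HDI mass for the summaries.
#' @return Object of class `zib_sweep_diff` with the same layout as a
#'   `zib_sweep`; differences lie in (-1, 1).
#' @export
condition_difference <- function(restricted, free, mass = 0.95) {
  stopifnot(inherits(restricted, "zib_sweep"), inherits(free, "zib_sweep"))
  if (!identical(restricted$impression, free$impression) ||
      !identical(restricted$trait, free$trait) ||
      !identical(restricted$grid, free$grid) ||
      !identical(names(restricted$draws), names(free$draws)) ||
      !identical(dim(restricted$draws[[1]]), dim(free$draws[[1]])))
    stop("sweeps are not compatible (impression/trait/grid/draws must match)",
         call. = FALSE)
  draws <- Map(function(a, b) a - b, restricted$draws, free$draws)
  summ <- do.call(rbind, lapply(names(draws), function(st) {
    s <- .sweep_summarise(draws[[st]], restricted$grid, mass)
    cbind(statistic = st, s)[, c("region", "trait_value", "statistic",
                                 "mean", "hdi_low", "hdi_high")]
  }))
  rownames(summ) <- NULL
  structure(list(condition = paste0(restricted$condition, "-", free$condition),
                 impression = restricted$impression, trait = restricted$trait,
                 grid = restricted$grid, fixed_value = restricted$fixed_value,
                 draws = draws, summary = summ, mass = mass),
            class = c("zib_sweep_diff", "zib_sweep"))
}

#' Export a sweep (or sweep difference) to CSV and optional plots
#'
#' @param result A `zib_sweep` or `zib_sweep_diff`.
#' @param path Output path prefix: `<path>.csv` is always written; with
#'   `plot = TRUE`, one `<path>_<statistic>.png` per statistic.
#' @param plot Write line-plot panels (one per region) per statistic.
#' @return Invisibly, the vector of files written.
#' @export
export_sweep <- function(result, path, plot = FALSE) {
  stopifnot(inherits(result, "zib_sweep"))
  csv <- paste0(path, ".csv")
  utils::write.csv(result$summary, csv, row.names = FALSE)
  files <- csv
  if (plot) {
    for (st in names(result$draws)) {
      f <- paste0(path, "_", st, ".png")
      grDevices::png(f, width = 900, height = 600)
      plot(result, statistic = st)
      grDevices::dev.off()
      files <- c(files, f)
    }
  }
  invisible(files)
}

#' Plot a trait sweep
#'
#' One panel per facial region: posterior-mean curve of the chosen statistic
#' against the swept trait score, with a shaded pointwise HDI band.
#'
#' @param x A `zib_sweep` or `zib_sweep_diff`.
#' @param statistic Which statistic to draw (`"q"`, `"mu"`, or `"qmu"` if
#'   computed).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly `x`.
#' @export
plot.zib_sweep <- function(x, statistic = "q", ...) {
  if (!statistic %in% names(x$draws))
    stop("statistic not computed in this sweep", call. = FALSE)
  s <- x$summary[x$summary$statistic == statistic, ]
  is_diff <- inherits(x, "zib_sweep_diff")
  old <- graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1),
                       oma = c(0, 0, 2, 0))
  on.exit(graphics::par(old))
  ylim <- range(s$hdi_low, s$hdi_high, if (is_diff) 0)
  for (reg in .REGIONS) {
    sr <- s[s$region == reg, ]
    graphics::plot(sr$trait_value, sr$mean, type = "n", ylim = ylim,
                   xlab = paste(x$trait, "score"), ylab = statistic,
                   main = reg, ...)
    graphics::polygon(c(sr$trait_value, rev(sr$trait_value)),
                      c(sr$hdi_low, rev(sr$hdi_high)),
                      col = grDevices::adjustcolor("steelblue", 0.25),
                      border = NA)
    graphics::lines(sr$trait_value, sr$mean, lwd = 2, col = "steelblue4")
    if (is_diff) graphics::abline(h = 0, lty = 2)
  }
  graphics::mtext(sprintf("%s | impression: %s | condition: %s",
                          statistic, x$impression, x$condition),
                  outer = TRUE)
  invisible(x)
}
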