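QUADRANT_LEVELS <- c("high-benefit/low-cost", "low-benefit/low-cost",
                     "low-benefit/high-cost", "high-benefit/high-cost")

#' Bivariate benefit-cost classification
#'
#' Joint classification of two 0-1 surfaces into an `n_bins` x `n_bins`
#' category grid (the machinery behind a dual-colour benefit/cost
#' overlay), plus a four-quadrant summary at the 0.5 midpoint: cells with
#' high benefit and low cost are where roads look most promising, high
#' cost and low benefit where they look most damaging. The quadrants are
#' a summary convenience over a continuous gradient, not a claim of
#' natural breakpoints.
#'
#' @param benefit,cost `rs_surface`s on one grid, both `"0-1 rescaled"`.
#' @param n_bins Number of bins per axis (default 10).
#' @return Object of class `rs_bivariate`: `benefit_bin` and `cost_bin`
#'   integer matrices in `0..n_bins-1`, a `quadrant` character matrix,
#'   and `quadrant_counts`.
#' @export
bivariate_classify <- function(benefit, cost, n_bins = 10) {
  stop_if_grid_mismatch(benefit$grid, cost$grid)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2) stop("n_bins must be >= 2")
  for (s in list(benefit, cost))
    if (any(s$values < 0 | s$values > 1, na.rm = TRUE))
      stop("validation error: inputs must be 0-1 rescaled surfaces")
  bin <- function(v) {
    b <- floor(v * n_bins)
    b[b > n_bins - 1] <- n_bins - 1  # value exactly 1.0 -> top bin
    b
  }
  bb <- bin(benefit$values); cb <- bin(cost$values)
  hb <- benefit$values >= 0.5; hc <- cost$values >= 0.5
  quad <- matrix(NA_character_, nrow(hb), ncol(hb))
  quad[hb & !hc] <- QUADRANT_LEVELS[1]
  quad[!hb & !hc] <- QUADRANT_LEVELS[2]
  quad[!hb & hc] <- QUADRANT_LEVELS[3]
  quad[hb & hc] <- QUADRANT_LEVELS[4]
  counts <- table(factor(quad[!is.na(quad)], levels = QUADRANT_LEVELS))
  structure(list(grid = benefit$grid, benefit_bin = bb, cost_bin = cb,
                 n_bins = n_bins, quadrant = quad,
                 quadrant_counts = counts),
            class = "rs_bivariate")
}

#' @export
print.rs_bivariate <- function(x, ...) {
  cat(sprintf("<rs_bivariate> %d x %d, %d bins per axis\n",
              x$grid$n_rows, x$grid$n_cols, x$n_bins))
  print(x$quadrant_counts)
  invisible(x)
}

#' Sensitivity difference map
#'
#' The effect of one substitution (different yield-gap data, max instead
#' of mean cost rule, population instead of production benefit) expressed
#' as the new minus the original 0-1 score per cell, bounded in [-1, 1].
#'
#' @param new,original `rs_surface`s on one grid, both 0-1 rescaled.
#' @param label Which substitution produced the map.
#' @return Object of class `rs_diffmap` with a `delta` matrix.
#' @export
difference_map <- function(new, original, label = "") {
  stop_if_grid_mismatch(new$grid, original$grid)
  for (s in list(new, original))
    if (any(s$values < 0 | s$values > 1, na.rm = TRUE))
      stop("validation error: inputs must be 0-1 rescaled surfaces")
  structure(list(grid = new$grid, delta = new$values - original$values,
                 label = label),
            class = "rs_diffmap")
}

#' @export
print.rs_diffmap <- function(x, ...) {
  d <- x$delta[!is.na(x$delta)]
  cat(sprintf("<rs_diffmap> '%s', delta range [%.3f, %.3f], |delta|>0.2: %.1f%%\n",
              x$label, min(d), max(d), 100 * mean(abs(d) > 0.2)))
  invisible(x)
}

#' Fraction of cells changed beyond a threshold
#'
#' The share of data cells whose score moved by strictly more than
#' `threshold` in absolute value under a substitution — the summary
#' statistic for each sensitivity test.
#'
#' @param diff An [difference_map] result.
#' @param threshold In (0, 1); default 0.2.
#' @return A proportion in [0, 1].
#' @export
changed_fraction <- function(diff, threshold = 0.2) {
  stopifnot(inherits(diff, "rs_diffmap"))
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be strictly between 0 and 1")
  d <- diff$delta[!is.na(diff$delta)]
  mean(abs(d) > threshold)
}
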