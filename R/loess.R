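## LOESS map profiling with a leave-one-out envelope, and the branch
## collapse-point estimator built on it.

#' LOESS profile of a map with optional leave-one-out envelope
#'
#' Fits a locally weighted regression through the (source position,
#' termination) scatter of a map. With `leave_one_out = TRUE` the fit is
#' repeated N times, each omitting one point, and the per-position min/max
#' envelope of the refits quantifies the profile's sensitivity to single
#' observations (widest near outliers).
#'
#' @param x Source-axis positions (at least 4 distinct values).
#' @param y Termination positions.
#' @param span LOESS span in (0, 1].
#' @param degree Local polynomial degree (default 2).
#' @param leave_one_out Compute the leave-one-out envelope?
#' @param grid Positions at which to evaluate the profile (default `x`,
#'   sorted).
#' @return An object of class `"map_profile"`: list with `x`, `y`, `grid`,
#'   `smooth`, and (when requested) `loo_lower`/`loo_upper`.
#' @export
loess_profile <- function(x, y, span = 0.75, degree = 2,
                          leave_one_out = FALSE, grid = NULL) {
  if (length(x) < 4) stop("need at least 4 points", call. = FALSE)
  if (length(unique(x)) < 2) stop("degenerate x: all positions equal", call. = FALSE)
  if (span <= 0 || span > 1) stop("span must lie in (0, 1]", call. = FALSE)
  if (is.null(grid)) grid <- sort(x)
  ctl <- stats::loess.control(surface = "direct")
  fit <- stats::loess(y ~ x, span = span, degree = degree, control = ctl)
  smooth <- as.numeric(stats::predict(fit, newdata = data.frame(x = grid)))
  out <- list(x = x, y = y, grid = grid, smooth = smooth, span = span,
              degree = degree)
  if (leave_one_out) {
    preds <- vapply(seq_along(x), function(i) {
      d <- data.frame(x = x[-i], y = y[-i])
      f <- stats::loess(y ~ x, data = d, span = span, degree = degree,
                        control = ctl)
      as.numeric(stats::predict(f, newdata = data.frame(x = grid)))
    }, numeric(length(grid)))
    out$loo_lower <- apply(preds, 1, min)
    out$loo_upper <- apply(preds, 1, max)
  }
  class(out) <- "map_profile"
  out
}

#' @export
print.map_profile <- function(x, ...) {
  cat(sprintf("LOESS map profile: %d points, span %.2f, degree %d%s\n",
              length(x$x), x$span, x$degree,
              if (!is.null(x$loo_lower)) ", with leave-one-out envelope" else ""))
  invisible(x)
}

#' @export
plot.map_profile <- function(x, ...) {
  graphics::plot(x$x, x$y, xlab = "source axis (%)",
                 ylab = "SC termination (%)", ...)
  graphics::lines(x$grid, x$smooth, lwd = 2)
  if (!is.null(x$loo_lower)) {
    graphics::lines(x$grid, x$loo_lower, lty = 2, col = "grey40")
    graphics::lines(x$grid, x$loo_upper, lty = 2, col = "grey40")
  }
  invisible(x)
}

.collapse_one <- function(x, y, branches, merge_cutoff, span) {
  if (is.null(branches)) return(NA_real_)
  groups <- split(seq_along(y), branches)
  groups <- Filter(function(i) length(i) >= 4, groups)
  if (length(groups) != 2) return(NA_real_)
  n <- length(y)
  grid <- seq_len(n)
  prof <- lapply(groups, function(idx) {
    loess_profile(x[idx], y[idx], span = span, grid = grid)$smooth
  })
  sep <- abs(prof[[1]] - prof[[2]])
  merged <- sep < merge_cutoff
  if (!any(merged[(n - 2):n])) return(NA_real_)  # branches never merge at the end
  if (all(merged)) return(NA_real_)              # no duplicated segment at all
  # onset located at the half-height crossing of the separation profile:
  # symmetric under the profile smoothing, so unbiased at a sharp merge
  half <- (max(sep) + merge_cutoff) / 2
  s <- max(which(sep >= half)) + 1
  if (s > n) return(NA_real_)
  grid[s] / n
}

#' Collapse point of a partially duplicated map
#'
#' Fits LOESS profiles separately to the two branches of a duplicated map
#' and returns the source-axis fraction beyond which the branch profiles
#' remain within `merge_cutoff` of each other (the position where the two
#' termination zones collapse into one). `NA` when the branches never merge
#' (full duplication), merge everywhere, or only one branch exists.
#'
#' @param x A [map_state()] (with `branches` supplied) or a [map_align()]
#'   ensemble (branch labels derived from the Isl2 mask).
#' @param branches Branch labels per source neuron (map_state input only).
#' @param which For ensembles: `"RC"` or `"CC"`.
#' @param merge_cutoff SC distance below which the branches count as merged
#'   (default 5, about four wild-type residual standard deviations).
#' @param span LOESS span for the per-branch profiles (default 0.3; branch
#'   profiles must track the merge corner, so the span is tighter than for
#'   whole-map smoothing).
#' @return For a map: the collapse fraction in (0, 1) or `NA`. For an
#'   ensemble: a list with per-run `fractions` and their `mean`.
#' @export
collapse_point <- function(x, branches = NULL, which = c("RC", "CC"),
                           merge_cutoff = 5, span = 0.3) {
  which <- match.arg(which)
  if (inherits(x, "map_state")) {
    m <- .map_xy(x)
    return(.collapse_one(m$x, m$y, branches, merge_cutoff, span))
  }
  stopifnot(inherits(x, "map_align"))
  fr <- vapply(x$runs, function(run) {
    map <- if (which == "RC") run$rc else run$cc
    lb <- branch_labels(run, which, x$genotype)
    m <- .map_xy(map)
    .collapse_one(m$x, m$y, lb, merge_cutoff, span)
  }, 0)
  list(fractions = fr, mean = mean(fr, na.rm = TRUE))
}
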