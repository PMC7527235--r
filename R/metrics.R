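## Map-organization statistics: intrinsic dispersion index (IDI), local
## intrinsic dispersion variation (IDV), alignment index (AI), the
## WT-derived duplication threshold, Jaccard/covariance comparison of IDV
## curves, and two-sample Kolmogorov-Smirnov map comparison.

.map_xy <- function(map) {
  if (inherits(map, "map_state")) {
    list(x = map$source_positions, y = as.numeric(map$target_of_source),
         type = map$type)
  } else {
    stop("expected a map_state", call. = FALSE)
  }
}

## LOESS residuals about the map's own profile, fitted per branch where a
## branch labeling exists (duplicated genotypes).
detrend_residuals <- function(x, y, branches = NULL, span = 0.75) {
  res <- numeric(length(y))
  groups <- if (is.null(branches)) list(seq_along(y)) else
    split(seq_along(y), branches)
  for (idx in groups) {
    if (length(idx) < 4) {
      res[idx] <- y[idx] - mean(y[idx])
      next
    }
    fit <- stats::loess(y[idx] ~ x[idx], span = span, degree = 2,
                        family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    res[idx] <- stats::residuals(fit)
  }
  res
}

#' Intrinsic dispersion index
#'
#' Within-map dispersion of the termination zones,
#' `sum((y - ybar)^2) / N`. In the default `"detrended"` mode `ybar` is the
#' map's own LOESS profile (fitted per branch when `branches` is given), so
#' the IDI is the mean squared residual scatter about the map's layout; in
#' `"literal"` mode `ybar` is the global mean termination, which for any
#' noise-free full-range map equals the variance of `1..N` (833.25 at
#' N = 100) and measures map extent rather than scatter.
#'
#' @param map A [map_state()].
#' @param mode `"detrended"` (default) or `"literal"`.
#' @param branches Optional branch labels (factor/logical per source
#'   neuron) for per-branch detrending of duplicated maps.
#' @param span LOESS span for detrending.
#' @return The dispersion index (squared SC-position units).
#' @export
idi <- function(map, mode = c("detrended", "literal"), branches = NULL,
                span = 0.75) {
  mode <- match.arg(mode)
  m <- .map_xy(map)
  dev <- if (mode == "literal") m$y - mean(m$y) else
    detrend_residuals(m$x, m$y, branches = branches, span = span)
  sum(dev^2) / length(dev)
}

#' Local intrinsic dispersion variation along the collicular axis
#'
#' Termination positions are differenced between neighboring source
#' neurons (`(y(x+1) - y(x))^2`, the windowed form of the printed sum) and
#' summed in sliding windows of `window` source neurons (step 1). Each
#' window is indexed by the collicular position its retinotopic identity
#' targets in the canonical wild-type layout (retinal windows map
#' temporal-to-rostral, V1 windows medial-to-rostral), so curves from RC
#' and CC maps share a common rostral-caudal position axis. A smooth
#' unit-slope map gives values near `window - 1`; wherever the map is
#' duplicated, neighboring source neurons terminate on different branches
#' and the curve rises far above the single-map level.
#'
#' @param map A [map_state()].
#' @param window Window width in source neurons (default 10, step 1).
#' @return A data frame of class `"idv_curve"` with columns `position`
#'   (percent of the rostral-caudal axis) and `idv`, ordered by position;
#'   the window width is attached as attribute `"window"`.
#' @export
local_idv <- function(map, window = 10) {
  m <- .map_xy(map)
  n <- length(m$y)
  if (window < 2) stop("window must be >= 2", call. = FALSE)
  if (window > n) stop("window larger than the map", call. = FALSE)
  ord <- order(m$x)
  y <- m$y[ord]
  sq <- diff(y)^2
  nw <- n - window + 1
  csum <- c(0, cumsum(sq))
  vals <- csum[(window:n)] - csum[seq_len(nw)]
  ctr <- seq_len(nw) + (window - 1) / 2
  pos <- if (identical(m$type, "CC")) ctr / n * 100 else (n + 1 - ctr) / n * 100
  o <- order(pos)
  out <- data.frame(position = pos[o], idv = vals[o])
  attr(out, "window") <- window
  class(out) <- c("idv_curve", class(out))
  out
}

#' Per-run IDV curves of an ensemble
#'
#' @param ensemble A [map_align()] ensemble.
#' @param which `"RC"` or `"CC"`.
#' @param window Window width.
#' @return A matrix (windows x runs) with the common window-center
#'   positions as attribute `"position"`.
#' @export
idv_curves <- function(ensemble, which = c("RC", "CC"), window = 10) {
  which <- match.arg(which)
  curves <- lapply(ensemble$runs, function(run) {
    local_idv(if (which == "RC") run$rc else run$cc, window = window)
  })
  m <- vapply(curves, function(cv) cv$idv, numeric(nrow(curves[[1]])))
  attr(m, "position") <- curves[[1]]$position
  m
}

#' Across-run median IDV curve
#'
#' @inheritParams idv_curves
#' @param n_runs Number of runs to use (default 10, capped).
#' @return An `"idv_curve"` data frame of per-position medians.
#' @export
idv_median_curve <- function(ensemble, which = c("RC", "CC"), window = 10,
                             n_runs = 10) {
  which <- match.arg(which)
  n_runs <- min(n_runs, ensemble$n_runs)
  sub <- ensemble
  sub$runs <- ensemble$runs[seq_len(n_runs)]
  m <- idv_curves(sub, which = which, window = window)
  out <- data.frame(position = attr(m, "position"),
                    idv = apply(m, 1, stats::median))
  attr(out, "window") <- window
  class(out) <- c("idv_curve", class(out))
  out
}

#' Wild-type duplication threshold for local IDV
#'
#' Pools the RC and CC IDV curves of a wild-type ensemble, takes the
#' per-position median across all pooled curves, and returns the minimum of
#' that median curve. IDV values above the threshold indicate a duplicated
#' map at that collicular position; values below indicate a single map.
#'
#' @param wt_ensemble A wild-type [map_align()] ensemble.
#' @param window Window width.
#' @param n_runs Runs to pool (default 10, capped).
#' @return The threshold (scalar).
#' @export
idv_threshold <- function(wt_ensemble, window = 10, n_runs = 10) {
  if (wt_ensemble$n_runs < 1) stop("empty ensemble", call. = FALSE)
  n_runs <- min(n_runs, wt_ensemble$n_runs)
  sub <- wt_ensemble
  sub$runs <- wt_ensemble$runs[seq_len(n_runs)]
  pooled <- cbind(idv_curves(sub, "RC", window), idv_curves(sub, "CC", window))
  min(apply(pooled, 1, stats::median))
}

#' First collicular position where an IDV curve exceeds a threshold
#'
#' @param curve An `"idv_curve"`.
#' @param threshold Threshold value.
#' @return Position in percent of the rostral-caudal axis, or `NA` if the
#'   curve never exceeds the threshold.
#' @export
idv_crossing <- function(curve, threshold) {
  above <- which(curve$idv > threshold)
  if (!length(above)) return(NA_real_)
  curve$position[above[1]]
}

#' Jaccard similarity of two IDV curves
#'
#' Binarizes both curves at a threshold and returns the Jaccard index
#' `|X intersect Y| / |X union Y|` of the above-threshold position sets;
#' defined as 1 when both sets are empty (identical classification).
#'
#' @param curve_a,curve_b `"idv_curve"` data frames on identical positions.
#' @param threshold Duplication threshold, typically [idv_threshold()].
#' @return Similarity in `[0, 1]`.
#' @export
idv_jaccard <- function(curve_a, curve_b, threshold) {
  if (!isTRUE(all.equal(curve_a$position, curve_b$position))) {
    stop("curves are not on the same positions", call. = FALSE)
  }
  a <- curve_a$idv > threshold
  b <- curve_b$idv > threshold
  uni <- sum(a | b)
  if (uni == 0) return(1)
  sum(a & b) / uni
}

#' Covariance of two IDV curves
#'
#' Population covariance `sum((a - abar)(b - bbar)) / N`; positive values
#' indicate a shared trend (aligned dispersion structure), negative values
#' an opposite trend.
#'
#' @inheritParams idv_jaccard
#' @return Covariance value.
#' @export
idv_covariance <- function(curve_a, curve_b) {
  a <- curve_a$idv
  b <- curve_b$idv
  if (length(a) != length(b)) stop("curves differ in length", call. = FALSE)
  mean((a - mean(a)) * (b - mean(b)))
}

## Source representation of the axon terminating at each collicular
## position, in common visual-field coordinates (retinal percent). The V1
## axis is oriented so that the wild-type RC and CC profiles superimpose:
## V1 index v represents retinal position N + 1 - v.
rep_profile <- function(map) {
  m <- .map_xy(map)
  n <- length(m$y)
  x_at_p <- m$x[order(m$y)]
  if (identical(m$type, "CC")) (n + 1) - x_at_p else x_at_p
}

#' Alignment index between paired RC and CC maps
#'
#' Pairs the retinal and cortical axons that share a collicular termination
#' zone and measures the mean absolute mismatch of their source
#' representations in common visual coordinates (the V1 axis is oriented so
#' that wild-type RC and CC profiles superimpose). 0 means every collicular
#' point receives retinal and cortical input representing the same visual
#' location; a constant representation offset of `k` gives AI = `k`.
#' Because the pairing is by termination zone, duplicated-but-aligned maps
#' (e.g. EphA3 knock-in) score as low as wild type, while a dispersed
#' cortical map over a normal retinal map scores high.
#'
#' @param rc_map,cc_map Paired [map_state()] objects of equal size.
#' @return The alignment index (source-axis units, same 1..100 scale as the
#'   SC axis).
#' @export
alignment_index <- function(rc_map, cc_map) {
  a <- rep_profile(rc_map)
  b <- rep_profile(cc_map)
  if (length(a) != length(b)) stop("maps differ in size", call. = FALSE)
  mean(abs(a - b))
}

#' Bootstrap percentile confidence interval for a median
#'
#' @param x Numeric sample (one value per run).
#' @param boot Number of resamples.
#' @param conf Confidence level.
#' @return List with `median`, `lower`, `upper`, `n`.
#' @export
median_ci <- function(x, boot = 10000, conf = 0.95) {
  med <- stats::median(x)
  if (length(x) < 2) {
    return(list(median = med, lower = med, upper = med, n = length(x)))
  }
  meds <- with_preserved_seed(1962, {
    vapply(seq_len(boot), function(i)
      stats::median(sample(x, replace = TRUE)), 0)
  })
  qs <- stats::quantile(meds, c((1 - conf) / 2, (1 + conf) / 2), names = FALSE)
  list(median = med, lower = qs[1], upper = qs[2], n = length(x))
}

#' Two-sample Kolmogorov-Smirnov comparison of termination distributions
#'
#' Classical two-sample D statistic (the supremum distance between the two
#' empirical CDFs, evaluated by sweeping the pooled sample) with the
#' large-sample critical value `c(alpha) sqrt((n + m)/(n m))`,
#' `c(0.05) = 1.358`.
#'
#' @param sample_a,sample_b Numeric samples (e.g. termination positions of
#'   a simulated and an experimentally measured map).
#' @param alpha Significance level (0.05, 0.01 or 0.001).
#' @return List with `D`, `critical`, `alpha`, `n_a`, `n_b`, `significant`.
#' @export
ks_compare <- function(sample_a, sample_b, alpha = 0.05) {
  if (!length(sample_a) || !length(sample_b)) {
    stop("samples must be non-empty", call. = FALSE)
  }
  pooled <- sort(unique(c(sample_a, sample_b)))
  Fa <- stats::ecdf(sample_a)(pooled)
  Fb <- stats::ecdf(sample_b)(pooled)
  D <- max(abs(Fa - Fb))
  c_alpha <- c("0.05" = 1.358, "0.01" = 1.628, "0.001" = 1.949)[as.character(alpha)]
  if (is.na(c_alpha)) stop("alpha must be 0.05, 0.01 or 0.001", call. = FALSE)
  n <- length(sample_a); m <- length(sample_b)
  crit <- unname(c_alpha) * sqrt((n + m) / (n * m))
  list(D = D, critical = crit, alpha = alpha, n_a = n, n_b = m,
       significant = D >= crit)
}
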