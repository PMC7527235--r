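## Synthetic map fixtures with known ground truth, used to validate the
## metrics: smooth single maps with Gaussian jitter, duplicated two-branch
## maps, partially duplicated maps with a programmed collapse point, and
## misaligned RC/CC pairs with a programmed representation shift.

#' Generate a synthetic map fixture
#'
#' All fixtures are built on the flip layout (source `x` terminating near
#' `n + 1 - x`) that the wild-type simulation converges to. Noise-free
#' fixtures are exact bijections; jittered fixtures keep continuous
#' termination values so that statistical contracts (e.g. detrended IDI
#' approaching `jitter_sd^2`) hold exactly.
#'
#' @param kind `"single"`, `"duplicated"`, `"collapsing"` or
#'   `"misaligned_pair"`.
#' @param n Map size (default 100).
#' @param jitter_sd Gaussian termination noise SD, SC units.
#' @param branch_offset SC separation between the two branches
#'   (duplicated/collapsing kinds; default `n/2`).
#' @param collapse_fraction Source-axis fraction beyond which the branches
#'   of a `"collapsing"` map are merged.
#' @param shift Representation shift of the CC member of a
#'   `"misaligned_pair"` (alignment index of the pair equals `shift` when
#'   `jitter_sd = 0`).
#' @param seed Optional seed; when given, the fixture is reproducible.
#' @return A [map_state()], or for `"misaligned_pair"` a list with
#'   elements `rc` and `cc`.
#' @export
make_fixture <- function(kind = c("single", "duplicated", "collapsing",
                                  "misaligned_pair"),
                         n = 100, jitter_sd = 0, branch_offset = n / 2,
                         collapse_fraction = 0.75, shift = 0, seed = NULL) {
  kind <- match.arg(kind)
  if (jitter_sd < 0) stop("jitter_sd must be >= 0", call. = FALSE)
  if (kind == "collapsing" &&
      (collapse_fraction <= 0 || collapse_fraction >= 1)) {
    stop("collapse_fraction must lie in (0, 1)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  x <- seq_len(n)

  finalize <- function(y, isl2 = NULL, type = "RC") {
    if (jitter_sd > 0) {
      y <- y + stats::rnorm(n, sd = jitter_sd)
      map_state(y, source_positions = x, isl2 = isl2, type = type,
                simulated = FALSE)
    } else {
      map_state(rank(y, ties.method = "first"), source_positions = x,
                isl2 = isl2, type = type, simulated = TRUE)
    }
  }

  if (kind == "single") {
    return(finalize(n + 1 - x))
  }
  if (kind %in% c("duplicated", "collapsing")) {
    isl2 <- assign_isl2(n, 0.5)
    base <- (n + 1 - x) * (n - branch_offset) / n
    sep <- if (kind == "duplicated") {
      rep(branch_offset, n)
    } else {
      # near-step taper: full separation up to the collapse point, merged
      # beyond it, with a sub-position logistic shoulder
      branch_offset * stats::plogis((collapse_fraction * n - x) / 0.25)
    }
    y <- base + ifelse(isl2, 0, sep)
    return(finalize(y, isl2 = isl2))
  }
  # misaligned_pair: flip RC map plus a CC map whose source labels are
  # shifted by `shift`, so every collicular point receives cortical input
  # representing a visual location `shift` away from its retinal input
  rc <- finalize(n + 1 - x)
  y_cc <- x
  cc <- if (jitter_sd > 0) {
    map_state(y_cc + stats::rnorm(n, sd = jitter_sd),
              source_positions = x + shift, type = "CC", simulated = FALSE)
  } else {
    map_state(y_cc, source_positions = x + shift, type = "CC",
              simulated = TRUE)
  }
  list(rc = rc, cc = cc)
}
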