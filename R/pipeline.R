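## The 3-step alignment pipeline, per run:
##   1. simulate the retino-collicular (RC) map against the endogenous
##      collicular ephrin-A gradient;
##   2. transpose the retinal ephrin-A carried by each RGC axon into the SC
##      according to the layout of that RC map;
##   3. simulate the cortico-collicular (CC) map of V1 axons against the
##      transposed ligand field.

#' Simulate an ensemble of paired retino- and cortico-collicular maps
#'
#' The main entry point. For each run a fresh Isl2 mask, initial
#' permutation and proposal stream are drawn from a per-run seed
#' (`seed + run - 1`), then the three steps above are executed. Returns a
#' classed ensemble with `print`, `summary`, `plot` and `residuals`
#' methods.
#'
#' @param genotype A genotype name understood by [genotype_spec()], or a
#'   `genotype_spec` object.
#' @param n_runs Ensemble size; default 20.
#' @param params An [energy_params()].
#' @param seed Base RNG seed; run `r` uses `seed + r - 1`.
#' @param isl2_mask Optional fixed logical mask used for every run instead
#'   of a random per-run draw.
#' @param trace Energy-trace samples per map (0 = none); see
#'   [run_mapping()].
#' @return An object of class `"map_align"`: a list with elements `runs`
#'   (each with `seed`, `isl2`, `rc`, `transposed_ligand`, `cc`),
#'   `genotype`, `params`, `n_runs`, `seed`.
#' @export
#' @examples
#' \donttest{
#' fit <- map_align("WT", n_runs = 2,
#'                  params = energy_params(iterations = 1e5), seed = 1)
#' summary(fit)
#' }
map_align <- function(genotype = "WT", n_runs = 20,
                      params = energy_params(), seed = 1,
                      isl2_mask = NULL, trace = 0) {
  if (is.character(genotype)) genotype <- genotype_spec(genotype)
  stopifnot(inherits(genotype, "genotype_spec"), n_runs >= 1)
  n <- params$n_neurons
  x <- seq_len(n)
  ligand_sc <- collicular_efna(x)
  recept_v1 <- v1_epha(x)

  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    run_seed <- seed + r - 1
    set.seed(run_seed)
    isl2 <- if (is.null(isl2_mask)) {
      assign_isl2(n, genotype$isl2_fraction)
    } else {
      rep_len(as.logical(isl2_mask), n)
    }
    recept_rgc <- retinal_epha(x, isl2, genotype)
    rc <- run_mapping(recept_rgc, ligand_sc, params,
                      source_positions = x, isl2 = isl2, type = "RC",
                      trace = trace)
    lig_t <- transpose_retinal_efna(rc, genotype)
    cc <- run_mapping(recept_v1, lig_t, params,
                      source_positions = x, type = "CC", trace = trace)
    runs[[r]] <- list(run_id = r, seed = run_seed, isl2 = isl2,
                      rc = rc, transposed_ligand = lig_t, cc = cc)
  }
  structure(list(runs = runs, genotype = genotype, params = params,
                 n_runs = n_runs, seed = seed),
            class = "map_align")
}

#' @export
print.map_align <- function(x, ...) {
  cat(sprintf("3-step map alignment ensemble: %s, %d runs, N = %d, %g proposals/map\n",
              x$genotype$name, x$n_runs, x$params$n_neurons,
              x$params$iterations))
  invisible(x)
}

## Branch labels used for per-branch detrending in duplicated genotypes:
## RC axons carry their own Isl2 flag; a CC axon inherits the flag of the
## RGC sharing its termination zone (the transposed ligand it read came
## from that axon). Only meaningful when the receptor duplication (ectopic
## EphA3) splits the map into two branches.
branch_labels <- function(run, which = c("RC", "CC"), genotype) {
  which <- match.arg(which)
  if (genotype$epha3_increment <= 0) return(NULL)
  if (which == "RC") return(run$rc$isl2)
  isl2_at_target <- logical(length(run$isl2))
  isl2_at_target[run$rc$target_of_source] <- run$isl2
  isl2_at_target[run$cc$target_of_source]
}

#' Summarize a simulated ensemble
#'
#' Computes the map-organization indices: median intrinsic dispersion index
#' of the RC and CC maps (detrended mode, over the first `n_idi` runs),
#' median alignment index (over all runs), with bootstrap percentile 95%
#' confidence intervals for each median.
#'
#' @param object A [map_align()] ensemble.
#' @param n_idi Number of runs used for the dispersion indices (default 10,
#'   capped at the ensemble size); the alignment index uses all runs.
#' @param span LOESS span for detrending.
#' @param boot Bootstrap resamples for the CIs.
#' @param ... Unused.
#' @return An object of class `"summary.map_align"`.
#' @export
summary.map_align <- function(object, n_idi = 10, span = 0.75,
                              boot = 10000, ...) {
  n_idi <- min(n_idi, object$n_runs)
  g <- object$genotype
  idi_r <- vapply(object$runs[seq_len(n_idi)], function(run)
    idi(run$rc, branches = branch_labels(run, "RC", g), span = span), 0)
  idi_c <- vapply(object$runs[seq_len(n_idi)], function(run)
    idi(run$cc, branches = branch_labels(run, "CC", g), span = span), 0)
  ai <- vapply(object$runs, function(run)
    alignment_index(run$rc, run$cc), 0)
  out <- list(
    genotype = g$name, n_runs = object$n_runs, n_idi = n_idi,
    idi_retino = median_ci(idi_r, boot = boot),
    idi_cortico = median_ci(idi_c, boot = boot),
    ai = median_ci(ai, boot = boot),
    idi_retino_runs = idi_r, idi_cortico_runs = idi_c, ai_runs = ai)
  class(out) <- "summary.map_align"
  out
}

#' @export
print.summary.map_align <- function(x, ...) {
  fmt <- function(m) sprintf("%.2f [%.2f; %.2f]", m$median, m$lower, m$upper)
  cat(sprintf("Map organization indices, %s (IDI over %d runs, AI over %d):\n",
              x$genotype, x$n_idi, x$n_runs))
  cat("  IDI retino :", fmt(x$idi_retino), "\n")
  cat("  IDI cortico:", fmt(x$idi_cortico), "\n")
  cat("  AI         :", fmt(x$ai), "\n")
  invisible(x)
}

#' Detrended residuals of an ensemble's maps
#'
#' LOESS residuals (per branch where branch structure exists) of each run's
#' RC or CC map; these are the residuals whose mean square is the detrended
#' intrinsic dispersion index.
#'
#' @param object A [map_align()] ensemble.
#' @param which `"RC"` or `"CC"`.
#' @param span LOESS span.
#' @param ... Unused.
#' @return A matrix, runs in columns.
#' @export
residuals.map_align <- function(object, which = c("RC", "CC"), span = 0.75, ...) {
  which <- match.arg(which)
  g <- object$genotype
  sapply(object$runs, function(run) {
    map <- if (which == "RC") run$rc else run$cc
    detrend_residuals(map$source_positions, map$target_of_source,
                      branches = branch_labels(run, which, g), span = span)
  })
}

#' Plot a simulated run
#'
#' Draws the RC and CC maps of one run (source axis vs termination zone;
#' open symbols Isl2-negative, filled Isl2-positive where a mask applies)
#' and optionally the run's transposed ligand.
#'
#' @param x A [map_align()] ensemble.
#' @param run Run index to draw.
#' @param which `"maps"` or `"ligand"`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.map_align <- function(x, run = 1, which = c("maps", "ligand"), ...) {
  which <- match.arg(which)
  rn <- x$runs[[run]]
  if (which == "maps") {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
    pch_rc <- ifelse(rn$isl2, 19, 1)
    graphics::plot(rn$rc$source_positions, rn$rc$target_of_source,
                   pch = pch_rc, xlab = "retina (nasal - temporal, %)",
                   ylab = "SC (rostral - caudal, %)",
                   main = paste("RC map,", x$genotype$name), ...)
    graphics::plot(rn$cc$source_positions, rn$cc$target_of_source,
                   pch = 1, xlab = "V1 axis (%)",
                   ylab = "SC (rostral - caudal, %)",
                   main = paste("CC map,", x$genotype$name), ...)
  } else {
    graphics::plot(seq_along(rn$transposed_ligand), rn$transposed_ligand,
                   type = "l", xlab = "SC (rostral - caudal, %)",
                   ylab = "transposed retinal ephrin-A",
                   main = paste("Transposed ligand,", x$genotype$name), ...)
  }
  invisible(x)
}

#' Flatten an ensemble into a long map table
#'
#' One row per axon per map, with the columns used by the delimited-text
#' serialization: `run_id`, `genotype`, `projection_type`, `source_index`,
#' `source_axis_position`, `target_position`, `isl2_positive`,
#' `receptor_level`, `ligand_at_target`.
#'
#' @param x A [map_align()] ensemble.
#' @return A data frame.
#' @export
as.data.frame.map_align <- function(x, ...) {
  rows <- lapply(x$runs, function(run) {
    one <- function(map, ptype, isl2) {
      t <- map$target_of_source
      data.frame(run_id = run$run_id, genotype = x$genotype$name,
                 projection_type = ptype,
                 source_index = seq_along(t),
                 source_axis_position = map$source_positions,
                 target_position = t,
                 isl2_positive = isl2,
                 receptor_level = map$source_receptor,
                 ligand_at_target = map$target_ligand[t])
    }
    rbind(one(run$rc, "RC", run$isl2),
          one(run$cc, "CC", NA))
  })
  do.call(rbind, rows)
}
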