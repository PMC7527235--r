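## Closed-form Eph receptor / ephrin-A ligand gradients.
##
## All gradients are evaluated on a percent-of-axis coordinate x in [0, 100].
## The simulation grid is the integer lattice 1..N (N = 100 by default),
## interpreted as percent of the axis; axis orientations are fixed as:
##   retina: 1 = nasal, 100 = temporal
##   SC:     1 = rostral, 100 = caudal
##   V1:     1 = the pole with the highest EphA level (maps rostral)

.check_axis_x <- function(x, lo = 0, hi = 100) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("axis position `x` must be finite numeric", call. = FALSE)
  }
  if (any(x < lo | x > hi)) {
    stop(sprintf("axis position out of range [%g, %g]", lo, hi), call. = FALSE)
  }
  invisible(x)
}

#' Retinal EphA receptor gradient
#'
#' Total EphA (EphA4 + EphA5 + EphA6, plus ectopic EphA3 in Isl2-positive
#' cells of EphA3 knock-in genotypes) along the nasal-temporal axis of the
#' retina: `0.14 exp(0.018 x) + 0.09 exp(0.029 x) + 1.05`, increasing
#' nasal to temporal.
#'
#' @param x Axis position(s) in percent, 0 (nasal) to 100 (temporal).
#' @param isl2_positive Logical; is the cell Isl2-positive? Recycled against
#'   `x`.
#' @param genotype A [genotype_spec()]; the `epha3_increment` is added for
#'   Isl2-positive cells.
#' @return Receptor level(s), arbitrary expression units.
#' @export
#' @examples
#' retinal_epha(0)                                  # 1.28
#' retinal_epha(0, TRUE, genotype_spec("Isl2-Epha3-homo"))  # 3.14
retinal_epha <- function(x, isl2_positive = FALSE, genotype = genotype_spec("WT")) {
  .check_axis_x(x)
  base <- 0.14 * exp(0.018 * x) + 0.09 * exp(0.029 * x) + 1.05
  base + ifelse(rep_len(isl2_positive, length(base)), genotype$epha3_increment, 0)
}

#' Retinal ephrin-A ligand gradient
#'
#' Total ephrin-A (ephrin-A2/A3/A5) carried by RGCs along the nasal-temporal
#' axis: `1.79 exp(-0.014 x) + 1.85 exp(-0.008 x) + 0.44`, decreasing nasal
#' to temporal. Isl2-positive cells of ephrin-A3 knock-in genotypes carry the
#' ectopic `efna3_increment` on top.
#'
#' @inheritParams retinal_epha
#' @return Ligand level(s), arbitrary expression units.
#' @export
retinal_efna <- function(x, isl2_positive = FALSE, genotype = genotype_spec("WT")) {
  .check_axis_x(x)
  base <- 1.79 * exp(-0.014 * x) + 1.85 * exp(-0.008 * x) + 0.44
  base + ifelse(rep_len(isl2_positive, length(base)), genotype$efna3_increment, 0)
}

#' Collicular ephrin-A ligand gradient
#'
#' Endogenous ephrin-A in the superior colliculus along the rostral-caudal
#' axis: `exp((x - 100)/100) - exp((-x - 100)/100)`, zero at the rostral
#' pole and strictly increasing caudally.
#'
#' @param x Axis position(s) in percent, 0 (rostral) to 100 (caudal).
#' @return Ligand level(s).
#' @export
collicular_efna <- function(x) {
  .check_axis_x(x)
  exp((x - 100) / 100) - exp((-x - 100) / 100)
}

#' Cortical V1 EphA receptor gradient
#'
#' EphA in V1 layer-V neurons along the mapping axis:
#' `exp(-x/100) - exp((x - 200)/100) + 1`, strictly decreasing; the x = 0
#' pole carries the highest level and maps to the rostral SC.
#'
#' @param x Axis position(s) in percent, 0 to 100.
#' @return Receptor level(s).
#' @export
v1_epha <- function(x) {
  .check_axis_x(x)
  exp(-x / 100) - exp((x - 200) / 100) + 1
}

#' Transpose the retinal ephrin-A gradient into the superior colliculus
#'
#' Retinal axons carry their ephrin-A with them, so after the
#' retino-collicular map forms, the ligand level at each collicular position
#' is the retinal ephrin-A of the RGC terminating there (map composition).
#' For a perfect wild-type flip map the result is the retinal curve flipped
#' along the axis, smoothly increasing rostral to caudal; for a duplicated
#' map the composition traverses the retinal range twice, producing a double
#' oscillatory gradient.
#'
#' @param rc_map A [map_state()] for the retino-collicular projection; must
#'   be a complete bijection onto the collicular grid.
#' @param genotype A [genotype_spec()]; for ephrin-A3 knock-in genotypes the
#'   ectopic `efna3_increment` travels with Isl2-positive axons.
#' @return Numeric vector of ligand levels indexed by collicular position
#'   `1..N`.
#' @export
transpose_retinal_efna <- function(rc_map, genotype = genotype_spec("WT")) {
  stopifnot(inherits(rc_map, "map_state"))
  t_of_s <- rc_map$target_of_source
  n <- length(t_of_s)
  if (!identical(sort(as.integer(t_of_s)), seq_len(n))) {
    stop("rc_map is not a complete bijection onto 1..N", call. = FALSE)
  }
  isl2 <- rc_map$isl2
  if (is.null(isl2)) isl2 <- rep(FALSE, n)
  carried <- retinal_efna(rc_map$source_positions, isl2, genotype)
  out <- numeric(n)
  out[t_of_s] <- carried
  out
}

#' Export gradient curves as a long table
#'
#' Evaluates the four closed-form gradients for a genotype over an integer
#' grid and returns them in long format (columns `structure`, `genotype`,
#' `position`, `species`, `isl2`, `value`), suitable for delimited-text
#' export.
#'
#' @param genotype A [genotype_spec()].
#' @param n Grid size (default 100).
#' @return A data frame.
#' @export
gradient_table <- function(genotype = genotype_spec("WT"), n = 100) {
  x <- seq_len(n)
  rows <- list(
    data.frame(structure = "retina", position = x, species = "Epha_total",
               isl2 = FALSE, value = retinal_epha(x, FALSE, genotype)),
    data.frame(structure = "retina", position = x, species = "Epha_total",
               isl2 = TRUE, value = retinal_epha(x, TRUE, genotype)),
    data.frame(structure = "retina", position = x, species = "Efna_total",
               isl2 = FALSE, value = retinal_efna(x, FALSE, genotype)),
    data.frame(structure = "retina", position = x, species = "Efna_total",
               isl2 = TRUE, value = retinal_efna(x, TRUE, genotype)),
    data.frame(structure = "SC", position = x, species = "Efna_total",
               isl2 = NA, value = collicular_efna(x)),
    data.frame(structure = "V1", position = x, species = "Epha_total",
               isl2 = NA, value = v1_epha(x))
  )
  out <- do.call(rbind, rows)
  out$genotype <- genotype$name
  out[, c("structure", "genotype", "position", "species", "isl2", "value")]
}
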