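## Genotype configuration: which ectopic guidance molecule the Isl2-positive
## half of the RGC population carries, and how much of it.

#' Genotype specification
#'
#' Builds the configuration describing the Isl2-driven knock-in
#' perturbation. Isl2-positive RGCs (a random `isl2_fraction` of the
#' population, 50% by default) carry `epha3_increment` extra EphA receptor
#' (EphA3 knock-in: 0.93 per allele) and/or `efna3_increment` extra ephrin-A
#' ligand (ephrin-A3 knock-in; the per-allele level is not published, the
#' package default is 0.44, one wild-type ephrin-A3 equivalent).
#'
#' @param name One of `"WT"`, `"Isl2-Epha3-het"`, `"Isl2-Epha3-homo"`,
#'   `"Isl2-Efna3-het"`, `"Isl2-Efna3-homo"`, or `"custom"`.
#' @param epha3_increment,efna3_increment Ectopic per-cell levels for
#'   `name = "custom"`; ignored (preset) otherwise.
#' @param isl2_fraction Fraction of RGCs that are Isl2-positive.
#' @return An object of class `"genotype_spec"`.
#' @export
#' @examples
#' genotype_spec("Isl2-Epha3-het")$epha3_increment  # 0.93
genotype_spec <- function(name = "WT", epha3_increment = 0, efna3_increment = 0,
                          isl2_fraction = 0.5) {
  presets <- list(
    "WT"              = c(epha3 = 0,    efna3 = 0),
    "Isl2-Epha3-het"  = c(epha3 = 0.93, efna3 = 0),
    "Isl2-Epha3-homo" = c(epha3 = 1.86, efna3 = 0),
    "Isl2-Efna3-het"  = c(epha3 = 0,    efna3 = 0.44),
    "Isl2-Efna3-homo" = c(epha3 = 0,    efna3 = 0.88)
  )
  if (name %in% names(presets)) {
    epha3_increment <- unname(presets[[name]]["epha3"])
    efna3_increment <- unname(presets[[name]]["efna3"])
  } else if (!identical(name, "custom")) {
    stop("unknown genotype name: ", name, call. = FALSE)
  }
  if (epha3_increment < 0 || efna3_increment < 0) {
    stop("increments must be >= 0", call. = FALSE)
  }
  if (isl2_fraction < 0 || isl2_fraction > 1) {
    stop("isl2_fraction must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(name = name,
         epha3_increment = epha3_increment,
         efna3_increment = efna3_increment,
         isl2_fraction = isl2_fraction),
    class = "genotype_spec"
  )
}

#' @export
print.genotype_spec <- function(x, ...) {
  cat("Genotype:", x$name, "\n")
  cat(sprintf("  ectopic EphA3 (Isl2+): %+.2f   ectopic ephrin-A3 (Isl2+): %+.2f\n",
              x$epha3_increment, x$efna3_increment))
  cat(sprintf("  Isl2+ fraction: %.2f\n", x$isl2_fraction))
  invisible(x)
}

#' Catalogue of named genotypes
#'
#' @return A named list of [genotype_spec()] objects for the five modeled
#'   genotypes.
#' @export
genotype_presets <- function() {
  nm <- c("WT", "Isl2-Epha3-het", "Isl2-Epha3-homo",
          "Isl2-Efna3-het", "Isl2-Efna3-homo")
  stats::setNames(lapply(nm, genotype_spec), nm)
}

#' Draw an Isl2-positive mask
#'
#' Randomly flags `round(fraction * n)` of `n` retinal positions as
#' Isl2-positive. Uses the current RNG state, so results are reproducible
#' under `set.seed()`.
#'
#' @param n Number of RGCs.
#' @param fraction Fraction to flag.
#' @return Logical vector of length `n`.
#' @export
assign_isl2 <- function(n, fraction = 0.5) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]", call. = FALSE)
  k <- round(fraction * n)
  flags <- rep(FALSE, n)
  if (k > 0) flags[sample.int(n, k)] <- TRUE
  flags
}
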