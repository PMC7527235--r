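# Simulated ensembles are expensive; build each (genotype, runs, iterations)
# combination once per test session and share it across files.

.ens_cache <- new.env(parent = emptyenv())

cached_ensemble <- function(genotype, n_runs = 10, iterations = 1e6) {
  key <- paste(genotype, n_runs, iterations, sep = "|")
  if (is.null(.ens_cache[[key]])) {
    base_seeds <- c("WT" = 101, "Isl2-Epha3-het" = 201,
                    "Isl2-Epha3-homo" = 301, "Isl2-Efna3-het" = 401,
                    "Isl2-Efna3-homo" = 501)
    .ens_cache[[key]] <- map_align(
      genotype, n_runs = n_runs,
      params = energy_params(iterations = iterations),
      seed = unname(base_seeds[genotype]))
  }
  .ens_cache[[key]]
}

# Spearman correlation of a map against the canonical monotone layout
# (flip for RC, identity for CC); |rho| near 1 means a single smooth map.
map_monotonicity <- function(map) {
  n <- length(map$target_of_source)
  ref <- if (map$type == "RC") n + 1 - seq_len(n) else seq_len(n)
  abs(cor(map$target_of_source[order(map$source_positions)], ref,
          method = "spearman"))
}

# Median separation of the two Isl2 branches' LOESS profiles over the
# rostral-caudal grid (NA when no branch structure).
branch_separation <- function(map, branches) {
  idx <- split(seq_along(map$target_of_source), branches)
  if (length(idx) != 2) return(NA_real_)
  n <- length(map$target_of_source)
  p <- lapply(idx, function(i)
    loess_profile(map$source_positions[i], map$target_of_source[i],
                  grid = seq_len(n))$smooth)
  abs(p[[1]] - p[[2]])
}
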