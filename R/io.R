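## Delimited-text serialization of map ensembles and experimental map
## tables. Tables are comma-delimited UTF-8 with a header row and a
## `#`-prefixed config-echo comment block; simulated maps use 1-based
## integer coordinates, experimental tables percent coordinates.

MAP_TABLE_COLUMNS <- c("run_id", "genotype", "projection_type",
                       "source_index", "source_axis_position",
                       "target_position", "isl2_positive",
                       "receptor_level", "ligand_at_target")

#' Write a map ensemble table
#'
#' @param x A [map_align()] ensemble or a data frame with the map-table
#'   columns (see [as.data.frame.map_align()]).
#' @param path Output file.
#' @param simulated Logical flag recorded in the header; simulated tables
#'   are validated as bijections on re-read.
#' @return Invisibly, the path.
#' @export
write_map_table <- function(x, path, simulated = TRUE) {
  df <- if (inherits(x, "map_align")) as.data.frame(x) else x
  if (!all(MAP_TABLE_COLUMNS %in% names(df))) {
    stop("missing map-table columns: ",
         paste(setdiff(MAP_TABLE_COLUMNS, names(df)), collapse = ", "),
         call. = FALSE)
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("# mapalign map table",
               paste0("# simulated=", isTRUE(simulated))), con)
  if (inherits(x, "map_align")) {
    p <- x$params
    writeLines(sprintf(
      "# genotype=%s n_runs=%d seed=%d alpha=%g gamma=%g d=%g b=%g N=%d iterations=%g",
      x$genotype$name, x$n_runs, x$seed, p$alpha, p$gamma, p$d, p$b,
      p$n_neurons, p$iterations), con)
  }
  utils::write.table(df[, MAP_TABLE_COLUMNS], con, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a map table
#'
#' Validates the documented columns, rejects duplicate
#' `(run, projection, source)` keys, and for tables flagged simulated
#' checks that each run's map is a bijection. Experimental-style sparse
#' tables (flag `simulated=FALSE` in the header) skip the bijection check.
#'
#' @param path Input file.
#' @return A data frame; the header flag is attached as attribute
#'   `"simulated"`.
#' @export
read_map_table <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  simulated <- any(grepl("simulated=TRUE", hdr, fixed = TRUE))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(MAP_TABLE_COLUMNS, names(df))
  if (length(missing)) {
    stop("map table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(df$run_id, df$projection_type, df$source_index)
  if (anyDuplicated(key)) {
    stop("duplicate (run, projection, source) key at row ",
         which(duplicated(key))[1], call. = FALSE)
  }
  if (simulated) {
    for (grp in split(df, paste(df$run_id, df$projection_type))) {
      tg <- sort(as.integer(grp$target_position))
      if (!identical(tg, seq_along(tg))) {
        bad <- grp$target_position[duplicated(grp$target_position)][1]
        stop(sprintf(
          "run %s %s map is not a bijection (offending target %s)",
          grp$run_id[1], grp$projection_type[1],
          if (is.na(bad)) "missing" else bad), call. = FALSE)
      }
    }
  }
  attr(df, "simulated") <- simulated
  df
}

#' Rebuild map states from a map-table data frame
#'
#' @param df A data frame as returned by [read_map_table()].
#' @return A list (one element per run) of lists with `rc` and/or `cc`
#'   [map_state()] objects.
#' @export
map_states_from_table <- function(df) {
  lapply(split(df, df$run_id), function(run_df) {
    out <- list()
    for (ptype in unique(run_df$projection_type)) {
      sub <- run_df[run_df$projection_type == ptype, ]
      sub <- sub[order(sub$source_index), ]
      isl2 <- if (all(is.na(sub$isl2_positive))) NULL else
        as.logical(sub$isl2_positive)
      out[[tolower(ptype)]] <- map_state(
        as.integer(sub$target_position),
        source_positions = sub$source_axis_position,
        isl2 = isl2, type = ptype,
        simulated = isTRUE(attr(df, "simulated")))
    }
    out
  })
}

#' Read an experimental map table
#'
#' Expected columns: `animal_id`, `source_axis_percent`,
#' `target_axis_percent` (sparse, non-bijective tracing data).
#'
#' @param path Input file.
#' @return A data frame.
#' @export
read_experimental_maps <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("animal_id", "source_axis_percent", "target_axis_percent")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("experimental table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}
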