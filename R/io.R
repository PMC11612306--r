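# Localization tables travel as ThunderSTORM-dialect CSV:
# header `frame,"x [nm]","y [nm]","uncertainty [nm]"` (plus optional
# truth_cluster_id), frames 1-based in files, 0-based in memory.

ts_column_aliases <- list(
  frame = c("frame"),
  x_nm = c("x [nm]", "x_nm", "x"),
  y_nm = c("y [nm]", "y_nm", "y"),
  uncertainty_nm = c("uncertainty [nm]", "uncertainty_nm", "uncertainty"),
  truth_cluster_id = c("truth_cluster_id")
)

#' Read a localization table
#'
#' Reads ThunderSTORM-dialect CSV (header `frame,"x [nm]","y [nm]"`, with
#' optional uncertainty) or a minimal `frame,x,y` file. File frames are
#' 1-based and are converted to 0-based in memory; rows are sorted by frame,
#' then x, then y. Unknown columns are preserved untouched. The simulator's
#' `truth_cluster_id` column is read when present and simply absent
#' otherwise.
#'
#' @param path Path to a CSV localization file.
#' @return A localization-table tibble (`frame`, `x_nm`, `y_nm`, optionally
#'   `uncertainty_nm`, `truth_cluster_id`, any extra columns).
#' @seealso [write_localizations()]
#' @export
read_localizations <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  nm <- names(raw)
  resolve <- function(field) {
    hit <- intersect(ts_column_aliases[[field]], nm)
    if (length(hit)) hit[1L] else NA_character_
  }
  src <- vapply(names(ts_column_aliases), resolve, character(1))
  for (field in c("frame", "x_nm", "y_nm")) {
    if (is.na(src[[field]])) {
      abort(sprintf("Missing mandatory column '%s' in %s", field, path),
            class = "tcpalm_parse_error")
    }
  }
  keep <- src[!is.na(src)]
  out <- raw
  names(out)[match(keep, names(out))] <- names(keep)
  for (field in names(keep)) {
    v <- out[[field]]
    if (!is.numeric(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(parsed) & !is.na(v))
      if (length(bad)) {
        abort(sprintf("Non-numeric value in column '%s' at data row %d of %s",
                      field, bad[1L], path),
              class = "tcpalm_parse_error")
      }
      out[[field]] <- parsed
    }
  }
  out$frame <- as.integer(out$frame) - 1L # file 1-based -> memory 0-based
  if (!is.na(src[["truth_cluster_id"]])) {
    out$truth_cluster_id <- as.integer(out$truth_cluster_id)
  }
  dplyr::arrange(tibble::as_tibble(out), .data$frame, .data$x_nm, .data$y_nm)
}

#' Write a localization table
#'
#' Writes ThunderSTORM-dialect CSV with header
#' `frame,"x [nm]","y [nm]","uncertainty [nm]"`, serializing frames 1-based
#' per the ThunderSTORM convention. A `truth_cluster_id` column, if present,
#' is appended under its own name.
#'
#' @param table A localization table (0-based `frame`, `x_nm`, `y_nm`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path) {
  out <- data.frame(
    frame = table$frame + 1L,
    x = table$x_nm,
    y = table$y_nm,
    check.names = FALSE
  )
  names(out) <- c("frame", "x [nm]", "y [nm]")
  if (!is.null(table$uncertainty_nm)) {
    out[["uncertainty [nm]"]] <- table$uncertainty_nm
  }
  if (!is.null(table$truth_cluster_id)) {
    out[["truth_cluster_id"]] <- table$truth_cluster_id
  }
  # ThunderSTORM quotes the bracketed column names in its header
  header <- paste(
    vapply(names(out), function(nm) {
      if (grepl("[ \\[]", nm)) sprintf("\"%s\"", nm) else nm
    }, character(1)),
    collapse = ","
  )
  writeLines(header, path)
  readr::write_csv(out, path, progress = FALSE, append = TRUE,
                   col_names = FALSE)
  invisible(path)
}

#' Write the ground-truth sidecar of a simulated table
#'
#' Stores cluster specs, parameters, seed, and per-cluster emitted detection
#' counts as JSON next to a simulated localization table, so downstream
#' stages can be validated against the simulation truth.
#'
#' @param table The simulated localization table.
#' @param path Output JSON path.
#' @param clusters Cluster spec tibble used in the simulation (if any).
#' @param acq,phot The parameter objects used.
#' @param seed The simulation seed.
#' @return `path`, invisibly.
#' @export
write_truth_sidecar <- function(table, path, clusters = NULL, acq = NULL,
                                phot = NULL, seed = NULL) {
  counts <- if (!is.null(table$truth_cluster_id)) {
    tab <- table(table$truth_cluster_id)
    as.list(stats::setNames(as.integer(tab), names(tab)))
  } else {
    NULL
  }
  payload <- list(
    seed = seed,
    acquisition = if (!is.null(acq)) unclass(acq) else NULL,
    photophysics = if (!is.null(phot)) unclass(phot) else NULL,
    clusters = clusters,
    detections_per_cluster = counts,
    n_rows = nrow(table)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
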