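#' Write an event log as CSV
#'
#' @param x a \code{qs_sim} object or event-log data frame.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
qs_write_log <- function(x, path) {
  log <- if (inherits(x, "qs_sim")) x$log else x
  utils::write.csv(log, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a concentration heat map
#'
#' Writes the grid field of \code{\link{qs_field_grid}} as a CSV matrix plus
#' a JSON sidecar recording the grid origin, spacing and units.
#'
#' @param field a matrix from \code{\link{qs_field_grid}}.
#' @param path CSV path; the sidecar is written next to it as
#'   \code{<path>.json}.
#' @return \code{path}, invisibly.
#' @export
qs_write_field_map <- function(field, path) {
  xs <- attr(field, "x"); ys <- attr(field, "y")
  utils::write.table(field, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(
    origin_um = c(xs[1], ys[1]),
    spacing_um = c(if (length(xs) > 1) xs[2] - xs[1] else 0,
                   if (length(ys) > 1) ys[2] - ys[1] else 0),
    nx = length(xs), ny = length(ys),
    units = "threshold units (touching-cell contributions)",
    layout = "rows index x, columns index y"
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write burst annotations as JSON
#'
#' @param bursts a data frame from \code{\link{qs_detect_bursts}}.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
qs_write_bursts <- function(bursts, path) {
  recs <- lapply(seq_len(nrow(bursts)), function(i) {
    r <- list(label = bursts$label[i], step = bursts$step[i],
              t_min = bursts$t_min[i], size = bursts$size[i])
    if (!is.null(bursts$members)) r$members <- bursts$members[[i]]
    r
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run metadata sidecar
#'
#' Writes the full parameter set, the replicate seed and the package version
#' as a JSON sidecar next to simulation outputs.
#'
#' @param sim a \code{qs_sim} object.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
qs_write_metadata <- function(sim, path) {
  p <- unclass(sim$params)
  meta <- list(params = p, seed = sim$seed,
               package = "qsburst",
               version = as.character(utils::packageVersion("qsburst")))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
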