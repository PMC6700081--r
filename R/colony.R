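#' Colony containers and initial conditions
#'
#' A colony is a plain data frame with one row per cell and columns
#' \code{id} (birth order), \code{x}, \code{y} (um), \code{lineage} (the
#' inherited seed label), \code{induced} (logical), \code{t_induced} (min,
#' \code{NA} while non-induced) and \code{step_induced} (division-step index
#' of the induction event, \code{NA} while non-induced). The simulation clock
#' and step counter are carried as attributes \code{t} and \code{step}.
#'
#' @name qs_colony
NULL

.qs_new_colony <- function(x, y, lineage, t = 0, step = 0L) {
  n <- length(x)
  col <- data.frame(
    id = seq_len(n), x = x, y = y,
    lineage = as.integer(lineage),
    induced = rep.int(FALSE, n),
    t_induced = rep.int(NA_real_, n),
    step_induced = rep.int(NA_integer_, n)
  )
  attr(col, "t") <- t
  attr(col, "step") <- step
  class(col) <- c("qs_colony", "data.frame")
  col
}

#' Poisson-disk seeding
#'
#' Draws the seed-cell count from a Poisson distribution with mean (and
#' variance) \code{rho * pi * R^2} and places the cells independently and
#' uniformly in the disk of radius \code{R} (radius \code{R * sqrt(u)},
#' uniform angle). Each seed cell receives a distinct lineage label. No cell
#' is induced at this stage; induction at t = 0 is evaluated by
#' \code{\link{qs_simulate}}.
#'
#' @param params a \code{\link{qs_params}} object.
#' @return A colony data frame (possibly with zero rows).
#' @export
qs_seed_disk <- function(params) {
  n <- stats::rpois(1, params$rho * pi * params$R^2)
  if (n == 0L) return(.qs_new_colony(numeric(0), numeric(0), integer(0)))
  r <- params$R * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  .qs_new_colony(r * cos(th), r * sin(th), seq_len(n))
}

#' Lattice seeding
#'
#' Places \code{n_cells} seed cells on a square lattice with the given
#' nearest-neighbour spacing, centred on the origin. Deterministic: consumes
#' no random numbers. With a large spacing (e.g. 200 um) the lineages grow as
#' effectively isolated clusters.
#'
#' @param n_cells number of cells; must be a perfect square unless
#'   \code{rows} and \code{cols} are given.
#' @param spacing lattice constant, um.
#' @param rows,cols optional explicit lattice shape.
#' @return A colony data frame with \code{n_cells} rows.
#' @export
qs_seed_grid <- function(n_cells = 100, spacing = 200,
                         rows = NULL, cols = NULL) {
  if (spacing <= 0) stop("spacing must be positive")
  if (is.null(rows) || is.null(cols)) {
    s <- sqrt(n_cells)
    if (s != round(s)) stop("n_cells must be a perfect square (or give rows and cols)")
    rows <- cols <- as.integer(s)
  }
  if (rows * cols != n_cells) stop("rows * cols must equal n_cells")
  gx <- (seq_len(cols) - (cols + 1) / 2) * spacing
  gy <- (seq_len(rows) - (rows + 1) / 2) * spacing
  g <- expand.grid(x = gx, y = gy)
  .qs_new_colony(g$x, g$y, seq_len(n_cells))
}

#' Write and read cell tables
#'
#' Cell tables are CSV files with unit-suffixed headers
#' (\code{id, x_um, y_um, lineage, induced, t_induced_min}); they serve both
#' as simulation snapshots and as user-supplied initial conditions.
#'
#' @param colony a colony data frame.
#' @param path file path.
#' @return \code{qs_write_cells} returns \code{path} invisibly;
#'   \code{qs_read_cells} returns a colony data frame.
#' @export
qs_write_cells <- function(colony, path) {
  out <- data.frame(
    id = colony$id,
    x_um = colony$x, y_um = colony$y,
    lineage = colony$lineage,
    induced = colony$induced,
    t_induced_min = colony$t_induced
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname qs_write_cells
#' @export
qs_read_cells <- function(path) {
  d <- utils::read.csv(path)
  col <- .qs_new_colony(d$x_um, d$y_um,
                        if (!is.null(d$lineage)) d$lineage else seq_len(nrow(d)))
  if (!is.null(d$induced)) {
    col$induced <- as.logical(d$induced)
    if (!is.null(d$t_induced_min)) col$t_induced <- d$t_induced_min
    col$step_induced[col$induced] <- 0L
  }
  col
}

#' @export
print.qs_colony <- function(x, ...) {
  cat(sprintf("Colony: %d cells, %d lineages, %d induced (t = %g min)\n",
              nrow(x), length(unique(x$lineage)), sum(x$induced),
              attr(x, "t")))
  invisible(x)
}

#' @export
plot.qs_colony <- function(x, ..., cex = 0.5) {
  graphics::plot(x$x, x$y, asp = 1, pch = 19, cex = cex,
                 col = ifelse(x$induced, "navy", "skyblue"),
                 xlab = "x [um]", ylab = "y [um]", ...)
  invisible(x)
}
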