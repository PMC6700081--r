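#' Simulation parameter set
#'
#' Construct and validate the full, immutable parameter set for a
#' quorum-sensing colony simulation. All lengths are in micrometres, times in
#' minutes (except the basal production rate \code{phi}, carried in 1/s), and
#' concentrations in threshold units: one non-induced cell contributes exactly
#' 1 at the touching distance \code{2 * r_c} (see \code{\link{qs_c_single}}).
#'
#' The inverse-square signal range \code{alpha = delta / D} can be given
#' directly or derived from a diffusion coefficient \code{D} (um^2/s) and a
#' degradation rate \code{delta} (1/s). Exactly one daughter-placement
#' scenario may be active: a fixed displacement distance \code{d_new} with a
#' uniform random azimuth, or independent Gaussian offsets with standard
#' deviation \code{sigma_str} along each axis. Simulations that only evaluate
#' static seed configurations may omit both.
#'
#' @param alpha inverse squared signal range, 1/um^2 (\code{delta / D}).
#' @param D,delta optional diffusion coefficient (um^2/s) and degradation
#'   rate (1/s); if both are given \code{alpha} is derived and, when also
#'   supplied, must agree exactly.
#' @param d_new fixed daughter displacement distance, um.
#' @param sigma_str per-axis Gaussian daughter spread, um.
#' @param eta surplus autoinducer production of induced cells; induced cells
#'   emit at rate \code{phi * (1 + eta)}.
#' @param beta_thr induction threshold in threshold units (touching-cell
#'   contributions).
#' @param r_c cell radius, um.
#' @param R initial seeding-disk radius, um.
#' @param rho initial areal cell density, cells/um^2.
#' @param gamma per-cell division rate, 1/min.
#' @param phi basal production rate, 1/s; fixed at 1 (it only renormalises
#'   time and never enters the numerics).
#' @param seeding initial condition: \code{"disk"} (Poisson number of cells
#'   uniform in the disk of radius \code{R}), \code{"grid"} (deterministic
#'   square lattice), or \code{"single"} (one cell at the origin).
#' @param grid_n,grid_spacing lattice size (perfect square) and
#'   nearest-neighbour spacing (um) for \code{seeding = "grid"}.
#' @param max_time simulation-clock cap, min.
#' @param max_cells cell-count cap (\code{Inf} for none).
#' @param stop_at optional event-based termination: stop immediately after
#'   the first induction event, or once the whole colony is induced.
#' @param rng_seed integer RNG seed for the replicate stream.
#' @param include_self logical; include a cell's own (truncated) field in its
#'   perceived concentration.
#' @param field_cutoff drop single-cell contributions below this value
#'   (0 = exact, no cutoff).
#' @param step_mode division-clock increments: \code{"deterministic"} uses
#'   \code{t_gap = 1 / (gamma * n)}; \code{"exponential"} draws
#'   exponentially-distributed gaps with rate \code{gamma * n}.
#'
#' @return An object of class \code{qs_params}: a validated named list.
#' @examples
#' p <- qs_params(alpha = 0.05, d_new = 10, eta = 1)
#' p$beta_thr  # 30, the default threshold
#' qs_params(D = 300, delta = 0.003, d_new = 10)$alpha  # 1e-05
#' @export
qs_params <- function(alpha = NULL, D = NULL, delta = NULL,
                      d_new = NULL, sigma_str = NULL,
                      eta = 0, beta_thr = 30,
                      r_c = 2.5, R = 100, rho = 0.0025,
                      gamma = 1 / 60, phi = 1,
                      seeding = c("disk", "grid", "single"),
                      grid_n = 100, grid_spacing = 200,
                      max_time = 240, max_cells = Inf,
                      stop_at = c("none", "first_induction", "full_induction"),
                      rng_seed = 1L,
                      include_self = TRUE, field_cutoff = 0,
                      step_mode = c("deterministic", "exponential")) {
  seeding <- match.arg(seeding)
  stop_at <- match.arg(stop_at)
  step_mode <- match.arg(step_mode)

  if (!is.null(D) || !is.null(delta)) {
    if (is.null(D) || is.null(delta))
      stop("both D and delta must be given to derive alpha")
    if (D <= 0 || delta <= 0) stop("D and delta must be positive")
    a_derived <- delta / D
    if (!is.null(alpha) && alpha != a_derived)
      stop("alpha conflicts with delta/D")
    alpha <- a_derived
  }
  if (is.null(alpha)) stop("alpha (or D and delta) is required")

  chk_pos <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(nm, " must be a positive finite number")
  }
  chk_pos(alpha, "alpha"); chk_pos(r_c, "r_c"); chk_pos(R, "R")
  chk_pos(gamma, "gamma"); chk_pos(beta_thr, "beta_thr")
  chk_pos(max_time, "max_time"); chk_pos(phi, "phi")
  if (rho < 0) stop("rho must be >= 0")
  if (eta < 0) stop("eta must be >= 0")
  if (!is.null(d_new) && !is.null(sigma_str))
    stop("at most one of d_new and sigma_str may be set")
  placement <- NULL
  if (!is.null(d_new)) {
    if (d_new < 0) stop("d_new must be >= 0")
    placement <- list(mode = "fixed", d_new = d_new)
  } else if (!is.null(sigma_str)) {
    if (sigma_str < 0) stop("sigma_str must be >= 0")
    placement <- list(mode = "gaussian", sigma_str = sigma_str)
  }
  if (seeding == "grid") {
    chk_pos(grid_spacing, "grid_spacing")
    if (grid_n < 1 || grid_n != round(grid_n)) stop("grid_n must be a positive integer")
  }
  if (!is.numeric(max_cells) || (is.finite(max_cells) && max_cells < 1))
    stop("max_cells must be >= 1 or Inf")
  if (field_cutoff < 0) stop("field_cutoff must be >= 0")

  # real-valued fields are stored as doubles so that a parameter set and its
  # config-file round trip compare identical
  if (!is.null(placement))
    placement[[2]] <- as.numeric(placement[[2]])
  p <- list(
    r_c = as.numeric(r_c), R = as.numeric(R), rho = as.numeric(rho),
    gamma = as.numeric(gamma), phi = as.numeric(phi),
    eta = as.numeric(eta), beta_thr = as.numeric(beta_thr),
    alpha = as.numeric(alpha),
    placement = placement,
    seeding = seeding, grid_n = as.integer(grid_n),
    grid_spacing = as.numeric(grid_spacing),
    max_time = as.numeric(max_time), max_cells = as.numeric(max_cells),
    stop_at = stop_at,
    rng_seed = as.integer(rng_seed),
    include_self = isTRUE(include_self),
    field_cutoff = as.numeric(field_cutoff),
    step_mode = step_mode
  )
  class(p) <- "qs_params"
  p
}

#' @export
print.qs_params <- function(x, ...) {
  cat("Quorum-sensing simulation parameters\n")
  cat(sprintf("  geometry : r_c = %g um, R = %g um, rho = %g /um^2\n",
              x$r_c, x$R, x$rho))
  cat(sprintf("  rates    : gamma = %g /min, phi = %g /s, eta = %g\n",
              x$gamma, x$phi, x$eta))
  cat(sprintf("  signal   : alpha = %g /um^2 (range %.3g um), beta_thr = %g\n",
              x$alpha, 1 / sqrt(x$alpha), x$beta_thr))
  if (is.null(x$placement)) {
    cat("  placement: <none> (static configurations only)\n")
  } else if (x$placement$mode == "fixed") {
    cat(sprintf("  placement: fixed d_new = %g um\n", x$placement$d_new))
  } else {
    cat(sprintf("  placement: gaussian sigma_str = %g um\n", x$placement$sigma_str))
  }
  cat(sprintf("  seeding  : %s; termination: max_time = %g min%s%s\n",
              x$seeding, x$max_time,
              if (is.finite(x$max_cells)) sprintf(", max_cells = %g", x$max_cells) else "",
              if (x$stop_at != "none") paste0(", stop at ", x$stop_at) else ""))
  cat(sprintf("  rng_seed : %d\n", x$rng_seed))
  invisible(x)
}

# scalar fields serialised to the flat config; placement is flattened to
# d_new / sigma_str, so round-tripping reconstructs the same scenario
.qs_config_fields <- c("alpha", "d_new", "sigma_str", "eta", "beta_thr",
                       "r_c", "R", "rho", "gamma", "phi",
                       "seeding", "grid_n", "grid_spacing",
                       "max_time", "max_cells", "stop_at", "rng_seed",
                       "include_self", "field_cutoff", "step_mode")

#' Write and read flat text configuration files
#'
#' The configuration format is a flat \code{key: value} mapping (a YAML
#' subset), one key per line, with numbers written at full double precision so
#' that writing and re-reading a parameter set reproduces it exactly.
#'
#' @param params a \code{\link{qs_params}} object.
#' @param path file path.
#' @return \code{qs_write_config} returns \code{path} invisibly;
#'   \code{qs_read_config} returns a validated \code{qs_params}.
#' @export
qs_write_config <- function(params, path) {
  stopifnot(inherits(params, "qs_params"))
  flat <- list()
  for (f in .qs_config_fields) {
    v <- switch(f,
      d_new = if (!is.null(params$placement) && params$placement$mode == "fixed")
        params$placement$d_new else NULL,
      sigma_str = if (!is.null(params$placement) && params$placement$mode == "gaussian")
        params$placement$sigma_str else NULL,
      params[[f]])
    if (!is.null(v)) flat[[f]] <- v
  }
  fmt <- function(v) {
    if (is.character(v)) return(v)
    if (is.logical(v)) return(if (v) "true" else "false")
    if (is.infinite(v)) return(".inf")
    if (v == round(v) && abs(v) < 2^53) return(format(v, scientific = FALSE))
    # 17 significant digits round-trip IEEE doubles exactly
    formatC(v, format = "g", digits = 17)
  }
  writeLines(paste0(names(flat), ": ", vapply(flat, fmt, "")), path)
  invisible(path)
}

#' @rdname qs_write_config
#' @export
qs_read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(qs_params, raw)
}
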