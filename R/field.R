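#' Steady-state single-cell autoinducer field
#'
#' Screened 2D diffusion around a point source relaxes to the steady-state
#' profile \code{K0(r * sqrt(alpha)) / K0(2 * r_c * sqrt(alpha))}, where
#' \code{K0} is the modified Bessel function of the second kind of order zero
#' and \code{alpha = delta / D} is the inverse squared signal range. The
#' normalisation makes the concentration exactly 1 at the centre-to-centre
#' distance of two touching cells, \code{r = 2 * r_c}; for overlapping cells
#' (\code{r <= 2 * r_c}) the profile is truncated to that value.
#'
#' @param r distance(s) from the cell centre, um; must be finite and >= 0.
#' @param alpha inverse squared signal range, 1/um^2.
#' @param r_c cell radius, um.
#' @return Concentration in threshold units, same length as \code{r}.
#' @examples
#' qs_c_single(5, alpha = 0.04)        # touching distance: exactly 1
#' qs_c_single(1, alpha = 0.04)        # overlap: truncated to 1
#' qs_c_single(10, alpha = 0.04)       # K0(2)/K0(1) ~ 0.2705
#' @export
qs_c_single <- function(r, alpha, r_c = 2.5) {
  if (alpha <= 0 || r_c <= 0) stop("alpha and r_c must be positive")
  if (any(!is.finite(r)) || any(r < 0)) stop("r must be finite and >= 0")
  sa <- sqrt(alpha)
  k0n <- besselK(2 * r_c * sa, 0)
  out <- rep.int(1, length(r))
  far <- r > 2 * r_c
  if (any(far)) out[far] <- besselK(r[far] * sa, 0) / k0n
  out
}

#' Signal range
#'
#' The typical distance a diffusing autoinducer molecule travels before
#' degradation, \code{1 / sqrt(alpha)}.
#'
#' @param alpha inverse squared signal range, 1/um^2.
#' @return Distance in um.
#' @export
qs_signal_range <- function(alpha) {
  if (any(alpha <= 0)) stop("alpha must be positive")
  1 / sqrt(alpha)
}

#' Distance at which the single-cell field decays to a given percentage
#'
#' Finds the unique distance \code{r_i >= 2 * r_c} at which
#' \code{qs_c_single} has dropped to \code{i} percent of its touching-distance
#' value. The root is bracketed by doubling and refined with
#' \code{\link[stats]{uniroot}} to a relative tolerance of 1e-10.
#'
#' @param i percentage in (0, 100].
#' @inheritParams qs_c_single
#' @return Distance in um; \code{i = 100} gives exactly \code{2 * r_c}.
#' @export
qs_percent_decay_distance <- function(i, alpha, r_c = 2.5) {
  if (i <= 0 || i > 100) stop("i must be in (0, 100]")
  if (i == 100) return(2 * r_c)
  target <- i / 100
  f <- function(r) qs_c_single(r, alpha, r_c) - target
  lo <- 2 * r_c
  hi <- 2 * r_c + 1 / sqrt(alpha)
  while (f(hi) > 0) hi <- 2 * hi
  stats::uniroot(f, c(lo, hi), tol = 1e-10 * hi)$root
}

# distance beyond which a single-cell contribution falls below tol;
# evaluated on the log scale with exponentially-scaled Bessel K0 so that the
# bracket never underflows
.qs_cutoff_radius <- function(alpha, r_c, tol) {
  if (tol <= 0) return(Inf)
  sa <- sqrt(alpha)
  x0 <- 2 * r_c * sa
  lt <- log(tol) + log(besselK(x0, 0))
  g <- function(x) log(besselK(x, 0, expon.scaled = TRUE)) - x - lt
  hi <- x0 - log(tol) + 20
  stats::uniroot(g, c(x0, hi), tol = 1e-8)$root / sa
}

# production weights: induced cells emit at (1 + eta) times the basal rate
.qs_weights <- function(induced, eta) 1 + eta * as.numeric(induced)

#' Perceived autoinducer concentration of every cell in a colony
#'
#' Superposes the steady-state single-cell fields of all colony members:
#' cell i perceives \code{sum_j w_j * c_st(d_ij)} with \code{w_j = 1 + eta}
#' for induced emitters and 1 otherwise. By the truncation rule the self term
#' (\code{d = 0}) contributes exactly \code{w_i}; it is included by default
#' and dropped when \code{params$include_self} is \code{FALSE}.
#'
#' @param colony a colony data frame (see \code{\link{qs_seed_disk}}).
#' @param params a \code{\link{qs_params}} object.
#' @param induced optional logical vector overriding the colony's induction
#'   states (used when probing hypothetical states).
#' @return Numeric vector of perceived concentrations, one per cell.
#' @export
qs_perceived <- function(colony, params, induced = NULL) {
  n <- nrow(colony)
  if (n == 0L) return(numeric(0))
  if (is.null(induced)) induced <- colony$induced
  w <- .qs_weights(induced, params$eta)
  cmat <- .qs_contrib_matrix(colony, params)
  conc <- as.numeric(cmat %*% w)
  if (!params$include_self) conc <- conc - w
  conc
}

# n x n matrix of c_st(d_ij); diagonal is 1 by truncation
.qs_contrib_matrix <- function(colony, params) {
  n <- nrow(colony)
  d <- as.matrix(stats::dist(cbind(colony$x, colony$y)))
  m <- matrix(qs_c_single(as.vector(d), params$alpha, params$r_c), n, n)
  if (params$field_cutoff > 0) m[m < params$field_cutoff] <- 0
  diag(m) <- 1
  m
}

#' Autoinducer concentration field on a rectangular grid
#'
#' Evaluates the superposed colony field at the nodes of a regular grid, for
#' heat-map export. The field is diagnostic only: induction decisions are
#' always made from the perceived concentrations at cell positions.
#'
#' @inheritParams qs_perceived
#' @param xlim,ylim grid extent, um; default: colony bounding box padded by
#'   one signal range.
#' @param nx,ny number of grid nodes per axis.
#' @return A \code{nx} by \code{ny} matrix with attributes \code{x} and
#'   \code{y} (node coordinates). An empty colony yields an all-zero field.
#' @export
qs_field_grid <- function(colony, params, xlim = NULL, ylim = NULL,
                          nx = 101, ny = 101) {
  if (is.null(xlim) || is.null(ylim)) {
    pad <- 1 / sqrt(params$alpha)
    if (nrow(colony) == 0L) {
      xlim <- c(-1, 1) * params$R; ylim <- xlim
    } else {
      xlim <- range(colony$x) + c(-pad, pad)
      ylim <- range(colony$y) + c(-pad, pad)
    }
  }
  xs <- seq(xlim[1], xlim[2], length.out = nx)
  ys <- seq(ylim[1], ylim[2], length.out = ny)
  z <- matrix(0, nx, ny)
  if (nrow(colony) > 0L) {
    w <- .qs_weights(colony$induced, params$eta)
    for (j in seq_len(ny)) {
      d <- sqrt(outer(xs - 0, colony$x, "-")^2 +
                matrix((ys[j] - colony$y)^2, nx, nrow(colony), byrow = TRUE))
      cv <- matrix(qs_c_single(as.vector(d), params$alpha, params$r_c),
                   nx, nrow(colony))
      z[, j] <- as.numeric(cv %*% w)
    }
  }
  attr(z, "x") <- xs
  attr(z, "y") <- ys
  z
}
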