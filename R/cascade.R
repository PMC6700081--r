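#' Threshold test
#'
#' Identifies every non-induced cell whose perceived concentration reaches
#' the induction threshold \code{beta_thr}. The comparison is inclusive
#' (\code{>=}), which makes integer-arithmetic fixtures exact and differs
#' from a strict comparison only on a measure-zero set of configurations.
#' The colony is not modified.
#'
#' @inheritParams qs_perceived
#' @return Integer vector of cell ids at or above threshold.
#' @export
qs_threshold_check <- function(colony, params) {
  conc <- qs_perceived(colony, params)
  colony$id[!colony$induced & conc >= params$beta_thr]
}

#' Resolve an induction cascade to its fixed point
#'
#' Repeatedly applies the threshold test and induces all cells returned,
#' until a sweep induces nobody. Because switching a cell to the induced
#' state (with surplus production \code{eta >= 0}) can never lower any
#' perceived concentration, the update operator is monotone and the final
#' induced set is the unique least fixed point: it does not depend on whether
#' cells are induced synchronously per sweep or one at a time in any order
#' (\code{order = "random"} resolves asynchronously and is provided for
#' validation).
#'
#' Induction is irreversible. All cells induced during the cascade receive
#' \code{t_induced} equal to the colony clock: sweeps are instantaneous
#' within a division step.
#'
#' @inheritParams qs_perceived
#' @param order \code{"synchronous"} (default) or \code{"random"}
#'   (asynchronous, one uniformly chosen eligible cell at a time).
#' @return A list of class \code{qs_cascade}: \code{colony} (updated),
#'   \code{newly_induced_ids} (in induction order), \code{k_t} (their
#'   count) and \code{n_sweeps} (including the final empty sweep).
#' @examples
#' tri <- qs_fixture("collinear_triple")
#' p <- qs_params(alpha = 0.04, beta_thr = 3, eta = 4, d_new = 10)
#' qs_resolve_cascade(tri, p)$k_t  # feedback induces all three cells
#' @export
qs_resolve_cascade <- function(colony, params,
                               order = c("synchronous", "random")) {
  order <- match.arg(order)
  n <- nrow(colony)
  newly <- integer(0)
  n_sweeps <- 0L
  if (n > 0L) {
    cmat <- .qs_contrib_matrix(colony, params)
    induced <- colony$induced
    w <- .qs_weights(induced, params$eta)
    conc <- as.numeric(cmat %*% w)
    if (!params$include_self) conc <- conc - w
    repeat {
      n_sweeps <- n_sweeps + 1L
      hot <- which(!induced & conc >= params$beta_thr)
      if (length(hot) == 0L) break
      if (order == "random")
        hot <- hot[sample.int(length(hot), 1L)]
      induced[hot] <- TRUE
      newly <- c(newly, colony$id[hot])
      # induced emitters gain weight eta; update all perceived fields
      dconc <- cmat[, hot, drop = FALSE] %*% rep.int(params$eta, length(hot))
      conc <- conc + as.numeric(dconc)
      if (!params$include_self) conc[hot] <- conc[hot] - params$eta
    }
    colony$induced <- induced
    is_new <- colony$id %in% newly
    colony$t_induced[is_new] <- attr(colony, "t")
    colony$step_induced[is_new] <- attr(colony, "step")
  } else {
    n_sweeps <- 1L
  }
  structure(list(colony = colony, newly_induced_ids = newly,
                 k_t = length(newly), n_sweeps = n_sweeps),
            class = "qs_cascade")
}

#' @export
print.qs_cascade <- function(x, ...) {
  cat(sprintf("Induction cascade: k_t = %d cell(s) induced in %d sweep(s)\n",
              x$k_t, x$n_sweeps))
  invisible(x)
}
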