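#' Deterministic replicate seed derivation
#'
#' Replicate seeds are a pure function of the base seed, the parameter-grid
#' point index and the replicate index, so any single run of an ensemble or
#' sweep can be reproduced in isolation.
#'
#' @param base_seed integer base seed.
#' @param point grid-point index (1-based).
#' @param replicate replicate index (1-based).
#' @param n_replicates replicates per grid point.
#' @return An integer seed.
#' @export
qs_replicate_seed <- function(base_seed, point, replicate, n_replicates) {
  as.integer(base_seed + (point - 1L) * n_replicates + (replicate - 1L))
}

#' Run an ensemble of replicate simulations
#'
#' Runs \code{n} independent replicates of the same parameter set, with
#' seeds \code{seed_base + 0:(n-1)}.
#'
#' @param params a \code{\link{qs_params}} object.
#' @param n number of replicates.
#' @param seed_base base seed; replicate i uses \code{seed_base + i - 1}.
#' @param init optional shared initial colony.
#' @return A list of \code{qs_sim} objects.
#' @export
qs_replicates <- function(params, n, seed_base = params$rng_seed, init = NULL) {
  lapply(seq_len(n) - 1L, function(i)
    qs_simulate(params, seed = as.integer(seed_base + i), init = init))
}

#' Parameter sweep with replicate-aggregated summaries
#'
#' Runs the Cartesian product of the supplied parameter axes with
#' \code{n_replicates} replicates per grid point and aggregates the
#' ensemble observables per point: mean first-induction time, induction
#' times at the headline fractions (0.25, 0.5, 0.75), mean concentration at
#' the first-induction step, relative burst size, and first-induced-cluster
#' metrics. Censored replicates are excluded from means and counted.
#'
#' @param params base \code{\link{qs_params}}.
#' @param axes named list of value vectors over any of \code{alpha},
#'   \code{eta}, \code{d_new}, \code{sigma_str}, \code{beta_thr}.
#' @param n_replicates replicates per grid point.
#' @param chi_levels induced fractions for the IT_chi columns.
#' @param out_dir optional directory: one summary row CSV per grid point is
#'   written there, and grid points whose file already exists are skipped on
#'   re-run (resume).
#' @param init optional shared initial colony passed to every run.
#' @return A data frame, one row per grid point, with the axis values and
#'   columns \code{mfpt_mean, mfpt_sd, it<chi>_mean, it<chi>_sd,
#'   c_bar_mean, c_bar_var, zeta_mean, r_col_mean, n_col_mean,
#'   n_replicates, n_censored}.
#' @export
qs_sweep <- function(params, axes, n_replicates = 20,
                     chi_levels = c(0.25, 0.5, 0.75),
                     out_dir = NULL, init = NULL) {
  if (length(axes) == 0L) stop("at least one sweep axis is required")
  ok_axes <- c("alpha", "eta", "d_new", "sigma_str", "beta_thr")
  if (!all(names(axes) %in% ok_axes))
    stop("sweep axes must be among: ", paste(ok_axes, collapse = ", "))
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  rows <- lapply(seq_len(nrow(grid)), function(g) {
    pfile <- if (is.null(out_dir)) NULL
             else file.path(out_dir, sprintf("point_%04d.csv", g))
    if (!is.null(pfile) && file.exists(pfile))
      return(utils::read.csv(pfile))
    p <- params
    for (ax in names(axes)) {
      v <- grid[[ax]][g]
      if (ax == "d_new") p$placement <- list(mode = "fixed", d_new = v)
      else if (ax == "sigma_str") p$placement <- list(mode = "gaussian", sigma_str = v)
      else p[[ax]] <- v
    }
    sims <- lapply(seq_len(n_replicates), function(r)
      qs_simulate(p, seed = qs_replicate_seed(params$rng_seed, g, r,
                                              n_replicates),
                  init = init))
    row <- cbind(grid[g, , drop = FALSE], .qs_summarise(sims, chi_levels))
    rownames(row) <- NULL
    if (!is.null(pfile)) utils::write.csv(row, pfile, row.names = FALSE)
    row
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_dir))
    utils::write.csv(out, file.path(out_dir, "summary.csv"), row.names = FALSE)
  out
}

# replicate-aggregated EnsembleSummary for one parameter point
.qs_summarise <- function(sims, chi_levels) {
  fit <- qs_mfpt(sims)
  out <- data.frame(mfpt_mean = fit$mean, mfpt_sd = fit$sd)
  for (cl in chi_levels) {
    v <- vapply(sims, qs_it_chi, numeric(1), chi_target = cl)
    ok <- !is.na(v)
    out[[sprintf("it%02d_mean", round(100 * cl))]] <-
      if (any(ok)) mean(v[ok]) else NA_real_
    out[[sprintf("it%02d_sd", round(100 * cl))]] <-
      if (sum(ok) > 1) stats::sd(v[ok]) else NA_real_
  }
  cb <- vapply(sims, function(s) {
    hit <- which(s$log$k_t > 0)
    if (length(hit) == 0L) NA_real_ else s$log$c_bar[hit[1]]
  }, numeric(1))
  out$c_bar_mean <- if (any(!is.na(cb))) mean(cb, na.rm = TRUE) else NA_real_
  out$c_bar_var <- if (sum(!is.na(cb)) > 1) stats::var(cb, na.rm = TRUE) else NA_real_
  zeta <- vapply(sims, function(s) {
    z <- qs_relative_burst_size(s)
    if (is.null(z)) NA_real_ else z$zeta
  }, numeric(1))
  out$zeta_mean <- if (any(!is.na(zeta))) mean(zeta, na.rm = TRUE) else NA_real_
  cm <- lapply(sims, qs_cluster_metrics)
  rc <- vapply(cm, function(m) if (is.null(m)) NA_real_ else m$r_col, numeric(1))
  nc <- vapply(cm, function(m) if (is.null(m)) NA_real_ else m$n_col, numeric(1))
  out$r_col_mean <- if (any(!is.na(rc))) mean(rc, na.rm = TRUE) else NA_real_
  out$n_col_mean <- if (any(!is.na(nc))) mean(nc, na.rm = TRUE) else NA_real_
  out$n_replicates <- length(sims)
  out$n_censored <- fit$n_censored
  out
}

#' Deterministic test colonies
#'
#' Small hand-checkable colonies shared across examples and tests:
#' \describe{
#'   \item{touching_pair}{two cells 5 um apart (each perceives exactly 2 in
#'     threshold units with the default cell radius).}
#'   \item{collinear_triple}{cells at x = 0, 5, 10 um: the canonical cascade
#'     fixture (the centre tips first, feedback then reaches the ends).}
#'   \item{grid_100}{100 cells on a 10 x 10 lattice, 200 um spacing
#'     (isolated-lineage setup).}
#'   \item{single_seed}{one cell at the origin.}
#'   \item{dense_blob}{19 cells hex-packed at 5 um spacing (a maximally
#'     crowded cluster).}
#' }
#'
#' @param name fixture name.
#' @return A colony data frame.
#' @export
qs_fixture <- function(name = c("touching_pair", "collinear_triple",
                                "grid_100", "single_seed", "dense_blob")) {
  name <- match.arg(name)
  switch(name,
    touching_pair = .qs_new_colony(c(0, 5), c(0, 0), 1:2),
    collinear_triple = .qs_new_colony(c(0, 5, 10), c(0, 0, 0), 1:3),
    grid_100 = qs_seed_grid(100, 200),
    single_seed = .qs_new_colony(0, 0, 1L),
    dense_blob = {
      s <- 5
      pts <- list(c(0, 0))
      for (ring in 1:2) {
        for (k in 0:(6 * ring - 1)) {
          ang <- 2 * pi * k / (6 * ring)
          pts[[length(pts) + 1L]] <- ring * s * c(cos(ang), sin(ang))
        }
      }
      m <- do.call(rbind, pts)
      .qs_new_colony(round(m[, 1], 10), round(m[, 2], 10),
                     seq_len(nrow(m)))
    })
}
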