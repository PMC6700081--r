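#' First-induction time
#'
#' Time of the earliest division step (including the t = 0 seed evaluation)
#' at which at least one cell was induced; \code{NA} if the run terminated
#' without any induction (censored).
#'
#' @param x a \code{qs_sim} object or an event-log data frame.
#' @return Time in minutes, or \code{NA_real_} if censored.
#' @export
qs_first_induction <- function(x) {
  log <- if (inherits(x, "qs_sim")) x$log else x
  hit <- which(log$k_t > 0)
  if (length(hit) == 0L) NA_real_ else log$t_min[hit[1]]
}

#' Mean first-induction time over an ensemble
#'
#' Arithmetic mean and sample standard deviation of the first-induction time
#' over the uncensored replicates of an ensemble; replicates that never
#' reach induction are counted as censored and excluded (no imputation).
#'
#' @param sims a list of \code{qs_sim} objects, or a numeric vector of
#'   first-induction times with \code{NA} for censored runs.
#' @return A list with \code{mean}, \code{sd}, \code{n}, \code{n_censored};
#'   \code{mean} is \code{NA} if every replicate is censored.
#' @examples
#' qs_mfpt(c(180, 200, NA))  # mean 190 over the two uncensored runs
#' @export
qs_mfpt <- function(sims) {
  times <- if (is.numeric(sims)) sims
           else vapply(sims, qs_first_induction, numeric(1))
  ok <- !is.na(times)
  list(mean = if (any(ok)) mean(times[ok]) else NA_real_,
       sd = if (sum(ok) > 1) stats::sd(times[ok]) else NA_real_,
       n = length(times), n_censored = sum(!ok))
}

#' Time at which a target induced fraction is reached
#'
#' The order parameter IT_chi: the earliest step time at which the induced
#' fraction \code{chi} reaches \code{chi_target}. Unlike the first-induction
#' time it depends on the surplus production \code{eta}. Ensemble means
#' aggregate over replicates exactly as \code{\link{qs_mfpt}} does.
#'
#' @inheritParams qs_first_induction
#' @param chi_target fraction in (0, 1).
#' @return Time in minutes, or \code{NA_real_} if the run never reached the
#'   target fraction.
#' @export
qs_it_chi <- function(x, chi_target) {
  if (chi_target <= 0 || chi_target >= 1) stop("chi_target must be in (0, 1)")
  log <- if (inherits(x, "qs_sim")) x$log else x
  hit <- which(log$chi >= chi_target)
  if (length(hit) == 0L) NA_real_ else log$t_min[hit[1]]
}

#' Induced fraction at a given time
#'
#' @inheritParams qs_first_induction
#' @param t time, min.
#' @return chi at the last completed division step with \code{t_min <= t}
#'   (0 if \code{t} precedes the first log entry).
#' @export
qs_chi_at <- function(x, t) {
  log <- if (inherits(x, "qs_sim")) x$log else x
  i <- findInterval(t, log$t_min)
  if (i == 0L) 0 else log$chi[i]
}

#' Colony-mean perceived concentration
#'
#' Arithmetic mean of the perceived autoinducer concentration over all cells
#' of a colony, the experimentally natural summary of the colony's field.
#'
#' @inheritParams qs_perceived
#' @return Mean concentration in threshold units.
#' @export
qs_mean_concentration <- function(colony, params) {
  if (nrow(colony) == 0L) stop("empty colony")
  mean(qs_perceived(colony, params))
}

#' Static seed-configuration concentration ensemble
#'
#' Draws fresh Poisson-disk seed configurations (no growth) for each value
#' of \code{alpha} and reports the ensemble mean and unbiased sample
#' variance of the colony-mean concentration, quantifying how sensitive the
#' mean field is to the exact spatial arrangement of seeds at each signal
#' range.
#'
#' @param params a \code{\link{qs_params}} object supplying \code{r_c},
#'   \code{R}, \code{rho}, \code{eta} and \code{include_self}.
#' @param alphas numeric vector of inverse-squared signal ranges, 1/um^2.
#' @param n_runs configurations per alpha (>= 2 for the variance).
#' @param seed RNG seed for the ensemble.
#' @return A data frame with columns \code{alpha, c_bar_mean, c_bar_var,
#'   n_runs}.
#' @export
qs_static_ensemble <- function(params, alphas, n_runs = 20,
                               seed = params$rng_seed) {
  if (n_runs < 2) stop("n_runs must be >= 2")
  set.seed(seed)
  out <- lapply(alphas, function(a) {
    pa <- params; pa$alpha <- a
    cb <- vapply(seq_len(n_runs), function(i) {
      col <- qs_seed_disk(pa)
      if (nrow(col) == 0L) return(NA_real_)
      qs_mean_concentration(col, pa)
    }, numeric(1))
    cb <- cb[!is.na(cb)]
    data.frame(alpha = a, c_bar_mean = mean(cb),
               c_bar_var = stats::var(cb), n_runs = length(cb))
  })
  do.call(rbind, out)
}

#' Detect induction bursts in an event log
#'
#' Scans the per-step induction counts \code{k_t} chronologically and flags
#' a step as a burst when its count exceeds the running mean by more than
#' \code{n_sd} standard deviations, where mean and SD are taken over all
#' division steps since the last flagged burst. The SD is floored at
#' \code{s_min} (the criterion is undefined for a degenerate sample) and at
#' least \code{min_steps} steps must have accumulated since the last burst
#' before a new one can be flagged. Flagging resets the running sample.
#'
#' @param x a \code{qs_sim} object or an event-log data frame.
#' @param n_sd detection threshold in standard deviations.
#' @param s_min floor on the running SD, cells.
#' @param min_steps minimum sample size before flagging.
#' @return A data frame with one row per burst: \code{label} (chronological
#'   ordinal), \code{step}, \code{t_min}, \code{size}. When \code{x} is a
#'   \code{qs_sim}, a list column \code{members} holds the ids of the cells
#'   induced in each burst step.
#' @export
qs_detect_bursts <- function(x, n_sd = 8, s_min = 1, min_steps = 5) {
  sim <- if (inherits(x, "qs_sim")) x else NULL
  log <- if (is.null(sim)) x else sim$log
  k <- log$k_t
  cnt <- 0L; s1 <- 0; s2 <- 0
  hits <- integer(0)
  for (i in seq_along(k)) {
    if (cnt >= min_steps) {
      m <- s1 / cnt
      s <- if (cnt > 1) sqrt(max(0, (s2 - cnt * m^2) / (cnt - 1))) else 0
      if (k[i] > m + n_sd * max(s, s_min)) {
        hits <- c(hits, i)
        cnt <- 0L; s1 <- 0; s2 <- 0
        next
      }
    }
    cnt <- cnt + 1L; s1 <- s1 + k[i]; s2 <- s2 + k[i]^2
  }
  out <- data.frame(label = seq_along(hits),
                    step = log$step[hits],
                    t_min = log$t_min[hits],
                    size = k[hits])
  if (!is.null(sim) && nrow(out)) {
    out$members <- lapply(out$step, function(s)
      sim$colony$id[!is.na(sim$colony$step_induced) &
                      sim$colony$step_induced == s])
  }
  out
}

#' Lineage (family) statistics
#'
#' Sizes and induced fractions of the cell families descending from each
#' seed cell, identified by the inherited lineage label.
#'
#' @param colony a colony data frame.
#' @return A data frame with columns \code{lineage, n, n_induced, chi}.
#' @export
qs_family_stats <- function(colony) {
  if (nrow(colony) == 0L)
    return(data.frame(lineage = integer(0), n = integer(0),
                      n_induced = integer(0), chi = numeric(0)))
  sz <- tapply(colony$induced, colony$lineage, length)
  ind <- tapply(colony$induced, colony$lineage, sum)
  data.frame(lineage = as.integer(names(sz)),
             n = as.integer(sz), n_induced = as.integer(ind),
             chi = as.numeric(ind / sz), row.names = NULL)
}

#' Ensemble histogram of induced fractions at fixed times
#'
#' Tabulates the induced fraction chi across replicates at the requested
#' snapshot times.
#'
#' @param sims list of \code{qs_sim} objects.
#' @param times snapshot times, min.
#' @param breaks histogram bin edges on [0, 1].
#' @return A data frame with columns \code{t_min, bin_lo, bin_hi, count},
#'   plus the per-replicate values as attribute \code{chi} (a
#'   \code{length(times)} by \code{length(sims)} matrix).
#' @export
qs_induction_histogram <- function(sims, times, breaks = seq(0, 1, 0.1)) {
  chi <- vapply(sims, function(s) vapply(times, function(t) qs_chi_at(s, t),
                                         numeric(1)),
                numeric(length(times)))
  chi <- matrix(chi, nrow = length(times))
  rows <- lapply(seq_along(times), function(i) {
    h <- graphics::hist(chi[i, ], breaks = breaks, plot = FALSE,
                        include.lowest = TRUE)
    data.frame(t_min = times[i], bin_lo = h$breaks[-length(h$breaks)],
               bin_hi = h$breaks[-1], count = h$counts)
  })
  out <- do.call(rbind, rows)
  attr(out, "chi") <- chi
  out
}

#' Span and size of the first-induced lineage cluster
#'
#' For a run with well-separated lineages (lattice seeding), reconstructs
#' the cluster of cells sharing the first-induced cell's lineage as it stood
#' at the first-induction step, and reports its span \code{r_col} (largest
#' member distance to the cluster centre of mass) and size \code{n_col}.
#'
#' @param sim a \code{qs_sim} object.
#' @return A list with \code{r_col} (um), \code{n_col}, \code{lineage}, or
#'   \code{NULL} for a censored (never-induced) run.
#' @export
qs_cluster_metrics <- function(sim) {
  col <- sim$colony
  hit <- which(sim$log$k_t > 0)
  if (length(hit) == 0L) return(NULL)
  s_star <- sim$log$step[hit[1]]
  first_ids <- col$id[!is.na(col$step_induced) & col$step_induced == s_star]
  lineage <- col$lineage[match(first_ids[1], col$id)]
  # cells are appended in birth order: n0 seeds + one cell per step
  n_at <- sim$n0 + s_star
  members <- col[col$id <= n_at & col$lineage == lineage, , drop = FALSE]
  cx <- mean(members$x); cy <- mean(members$y)
  r_col <- if (nrow(members) == 1L) 0
           else max(sqrt((members$x - cx)^2 + (members$y - cy)^2))
  list(r_col = r_col, n_col = nrow(members), lineage = lineage)
}

#' Relative size of the first induction burst
#'
#' The order parameter zeta of the burst phase transition: the number of
#' cells induced in the cascade at the first-induction event divided by the
#' colony size at that moment. For single-seed colonies its ensemble mean
#' rises sigmoidally with the surplus production eta, from near zero to a
#' plateau approaching 1 at long signal range.
#'
#' @param sim a \code{qs_sim} object.
#' @return A list with \code{zeta} in [0, 1], \code{burst_cells} and
#'   \code{n_colony}, or \code{NULL} for a censored run.
#' @export
qs_relative_burst_size <- function(sim) {
  hit <- which(sim$log$k_t > 0)
  if (length(hit) == 0L) return(NULL)
  k <- sim$log$k_t[hit[1]]
  n <- sim$log$n[hit[1]]
  list(zeta = k / n, burst_cells = k, n_colony = n)
}
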