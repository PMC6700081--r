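#' Daughter-cell placement
#'
#' One next-generation cell keeps the mother's position exactly; this
#' function draws the position of the displaced daughter. In \code{fixed}
#' mode the daughter sits at distance \code{d_new} from the mother at a
#' uniform random azimuth; in \code{gaussian} mode independent offsets
#' \code{Normal(0, sigma_str^2)} are applied along each axis. There is no
#' rejection and no domain clipping: daughters may leave the seeding disk.
#'
#' @param x,y mother position, um.
#' @param placement placement scenario, e.g. \code{qs_params(...)$placement}.
#' @return Numeric \code{c(x, y)} of the displaced daughter.
#' @export
qs_place_daughter <- function(x, y, placement) {
  if (is.null(placement)) stop("params carry no placement scenario")
  if (placement$mode == "fixed") {
    ang <- stats::runif(1, 0, 2 * pi)
    c(x + placement$d_new * cos(ang), y + placement$d_new * sin(ang))
  } else {
    c(x + stats::rnorm(1, 0, placement$sigma_str),
      y + stats::rnorm(1, 0, placement$sigma_str))
  }
}

#' Run a colony-growth simulation
#'
#' Runs the individual-based event loop: seed the colony, evaluate induction
#' once at t = 0 (a seed configuration may already be super-threshold), then
#' iterate division steps until termination. Each division step picks the
#' mother uniformly at random among all cells, advances the clock by
#' \code{t_gap = 1 / (gamma * n)} (with \code{n} the pre-division count;
#' per-capita exponential growth), places one daughter carrying the mother's
#' lineage, updates all perceived concentrations, and resolves the induction
#' cascade of the step.
#'
#' All randomness comes from a single stream seeded with \code{seed}, in a
#' fixed draw order: seed-cell count, seed positions (radius then angle per
#' cell), then per division step the mother index, the clock increment (only
#' in \code{step_mode = "exponential"}) and the placement draw(s). Two runs
#' with identical parameters and seed produce bit-identical event logs.
#'
#' @param params a \code{\link{qs_params}} object with an active placement
#'   scenario.
#' @param seed RNG seed for this replicate; defaults to \code{params$rng_seed}.
#' @param init optional colony data frame used as the initial condition
#'   (overrides \code{params$seeding}).
#' @return An object of class \code{qs_sim}: a list with elements
#'   \code{colony} (final state, including the maintained \code{conc}
#'   column), \code{log} (the per-step event log: \code{step, t_min,
#'   mother_id, daughter_id, k_t, chi, c_bar, n}), \code{params}, \code{seed}
#'   and \code{n0} (seed-cell count).
#' @examples
#' p <- qs_params(alpha = 0.05, d_new = 10, eta = 1, max_time = 120)
#' sim <- qs_simulate(p, seed = 1)
#' summary(sim)
#' @export
qs_simulate <- function(params, seed = params$rng_seed, init = NULL) {
  stopifnot(inherits(params, "qs_params"))
  set.seed(seed)

  init <- if (!is.null(init)) init
  else switch(params$seeding,
    disk = qs_seed_disk(params),
    grid = qs_seed_grid(params$grid_n, params$grid_spacing),
    single = .qs_new_colony(0, 0, 1L))
  n <- nrow(init)

  alpha <- params$alpha; r_c <- params$r_c
  sa <- sqrt(alpha)
  k0n <- besselK(2 * r_c * sa, 0)
  two_rc <- 2 * r_c
  eta <- params$eta; beta <- params$beta_thr
  self_term <- if (params$include_self) 1 else 0
  r_cut <- .qs_cutoff_radius(alpha, r_c, params$field_cutoff)

  cap <- max(64L, 2L * n)
  grow <- function(v, len) { length(v) <- len; v }
  xs <- grow(as.numeric(init$x), cap)
  ys <- grow(as.numeric(init$y), cap)
  lin <- grow(as.integer(init$lineage), cap)
  induced <- grow(rep.int(FALSE, n), cap); induced[is.na(induced)] <- FALSE
  t_ind <- grow(rep.int(NA_real_, n), cap)
  s_ind <- grow(rep.int(NA_integer_, n), cap)
  conc <- grow(numeric(n), cap)

  # single-cell field of one emitter at (px, py) as seen by cells 1..m
  contrib_to_all <- function(px, py, m) {
    d2 <- (xs[seq_len(m)] - px)^2 + (ys[seq_len(m)] - py)^2
    cv <- numeric(m)
    near <- d2 <= two_rc^2
    cv[near] <- 1
    if (is.finite(r_cut)) {
      idx <- which(!near & d2 <= r_cut^2)
    } else {
      idx <- which(!near)
    }
    if (length(idx)) cv[idx] <- besselK(sqrt(d2[idx]) * sa, 0) / k0n
    cv
  }

  # log storage, grown by doubling
  lcap <- 1024L
  L_step <- integer(lcap); L_t <- numeric(lcap)
  L_mid <- integer(lcap); L_did <- integer(lcap)
  L_k <- integer(lcap); L_chi <- numeric(lcap)
  L_cbar <- numeric(lcap); L_n <- integer(lcap)
  nlog <- 0L
  push_log <- function(step, t, mid, did, k, chi, cbar, nn) {
    nlog <<- nlog + 1L
    if (nlog > lcap) {
      lcap <<- 2L * lcap
      L_step <<- grow(L_step, lcap); L_t <<- grow(L_t, lcap)
      L_mid <<- grow(L_mid, lcap); L_did <<- grow(L_did, lcap)
      L_k <<- grow(L_k, lcap); L_chi <<- grow(L_chi, lcap)
      L_cbar <<- grow(L_cbar, lcap); L_n <<- grow(L_n, lcap)
    }
    L_step[nlog] <<- step; L_t[nlog] <<- t
    L_mid[nlog] <<- mid; L_did[nlog] <<- did
    L_k[nlog] <<- k; L_chi[nlog] <<- chi
    L_cbar[nlog] <<- cbar; L_n[nlog] <<- nn
  }

  t <- 0; step <- 0L
  n_induced <- 0L

  # resolve the induction cascade at the current clock; synchronous sweeps,
  # incremental O(k * n) concentration updates
  run_cascade <- function() {
    k_new <- 0L
    repeat {
      idx <- seq_len(n)
      hot <- idx[!induced[idx] & conc[idx] >= beta]
      if (length(hot) == 0L) break
      induced[hot] <<- TRUE
      t_ind[hot] <<- t
      s_ind[hot] <<- step
      k_new <- k_new + length(hot)
      for (j in hot) {
        cv <- contrib_to_all(xs[j], ys[j], n)
        conc[idx] <<- conc[idx] + eta * cv
        if (!self_term) conc[j] <<- conc[j] - eta
      }
    }
    n_induced <<- n_induced + k_new
    k_new
  }

  if (n > 0L) {
    # initial perceived field from scratch
    for (i in seq_len(n)) {
      cv <- contrib_to_all(xs[i], ys[i], n)
      cv[i] <- self_term
      conc[i] <- sum(cv)
    }
    k0_ind <- run_cascade()
    push_log(0L, 0, NA_integer_, NA_integer_, k0_ind,
             n_induced / n, mean(conc[seq_len(n)]), n)
  }

  done <- function() {
    n == 0L ||
      n >= params$max_cells ||
      (params$stop_at == "first_induction" && n_induced > 0L) ||
      (params$stop_at == "full_induction" && n_induced == n)
  }

  while (!done()) {
    mother <- sample.int(n, 1L)
    t_gap <- if (params$step_mode == "deterministic") 1 / (params$gamma * n)
             else stats::rexp(1, params$gamma * n)
    if (t + t_gap > params$max_time) break
    pos <- qs_place_daughter(xs[mother], ys[mother], params$placement)
    t <- t + t_gap
    step <- step + 1L

    if (n + 1L > cap) {
      cap <- 2L * cap
      xs <- grow(xs, cap); ys <- grow(ys, cap); lin <- grow(lin, cap)
      induced <- grow(induced, cap); induced[is.na(induced)] <- FALSE
      t_ind <- grow(t_ind, cap); s_ind <- grow(s_ind, cap)
      conc <- grow(conc, cap)
    }
    new <- n + 1L
    xs[new] <- pos[1]; ys[new] <- pos[2]
    lin[new] <- lin[mother]
    induced[new] <- FALSE; t_ind[new] <- NA_real_; s_ind[new] <- NA_integer_

    # the daughter's field raises everyone; the same (symmetric) values give
    # the daughter's own perceived concentration
    cv <- contrib_to_all(pos[1], pos[2], n)
    w <- 1 + eta * induced[seq_len(n)]
    conc[new] <- sum(w * cv) + self_term
    conc[seq_len(n)] <- conc[seq_len(n)] + cv
    n <- new

    k_t <- run_cascade()
    push_log(step, t, mother, new, k_t,
             n_induced / n, mean(conc[seq_len(n)]), n)
  }

  idx <- seq_len(n)
  colony <- data.frame(
    id = idx, x = xs[idx], y = ys[idx], lineage = lin[idx],
    induced = induced[idx], t_induced = t_ind[idx],
    step_induced = s_ind[idx], conc = conc[idx]
  )
  attr(colony, "t") <- t
  attr(colony, "step") <- step
  class(colony) <- c("qs_colony", "data.frame")

  lidx <- seq_len(nlog)
  log <- data.frame(
    step = L_step[lidx], t_min = L_t[lidx],
    mother_id = L_mid[lidx], daughter_id = L_did[lidx],
    k_t = L_k[lidx], chi = L_chi[lidx],
    c_bar = L_cbar[lidx], n = L_n[lidx]
  )

  structure(list(colony = colony, log = log, params = params,
                 seed = seed, n0 = if (nlog) L_n[1] - 0L else 0L),
            class = "qs_sim")
}

#' @export
print.qs_sim <- function(x, ...) {
  fit <- qs_first_induction(x)
  cat(sprintf(
    "qs_sim: %d -> %d cells in %.1f min (seed %d); %d induced (chi = %.3f)\n",
    x$n0, nrow(x$colony), attr(x$colony, "t"), x$seed,
    sum(x$colony$induced), mean(x$colony$induced)))
  cat(if (is.na(fit)) "  no induction before termination\n"
      else sprintf("  first induction at %.1f min\n", fit))
  invisible(x)
}

#' @export
summary.qs_sim <- function(object, ...) {
  col <- object$colony
  fam <- qs_family_stats(col)
  out <- list(
    n_cells = nrow(col), n0 = object$n0,
    t_final = attr(col, "t"),
    n_induced = sum(col$induced), chi = mean(col$induced),
    first_induction = qs_first_induction(object),
    c_bar = mean(col$conc),
    n_lineages = nrow(fam),
    largest_family = if (nrow(fam)) max(fam$n) else 0L
  )
  class(out) <- "summary.qs_sim"
  out
}

#' @export
print.summary.qs_sim <- function(x, ...) {
  cat(sprintf("Colony: %d cells (from %d seeds) after %.1f min\n",
              x$n_cells, x$n0, x$t_final))
  cat(sprintf("  induced: %d (chi = %.3f); first induction: %s min\n",
              x$n_induced, x$chi,
              if (is.na(x$first_induction)) "censored"
              else sprintf("%.1f", x$first_induction)))
  cat(sprintf("  mean perceived concentration: %.3f threshold units\n", x$c_bar))
  cat(sprintf("  lineages: %d (largest family %d cells)\n",
              x$n_lineages, x$largest_family))
  invisible(x)
}

#' @export
plot.qs_sim <- function(x, ...) {
  plot.qs_colony(x$colony,
                 main = sprintf("t = %.0f min, chi = %.2f",
                                attr(x$colony, "t"), mean(x$colony$induced)),
                 ...)
  invisible(x)
}
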