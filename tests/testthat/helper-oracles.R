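# Independent oracles used across the suite. They deliberately avoid the
# package's own code paths: K0 through its integral representation, field
# superposition by naive double loop, cascade closure by subset enumeration.

# K0(x) = integral_0^Inf exp(-x cosh t) dt
k0_oracle <- function(x) {
  vapply(x, function(xx)
    stats::integrate(function(t) exp(-xx * cosh(t)), 0, Inf,
                     rel.tol = 1e-13, abs.tol = 0)$value,
    numeric(1))
}

c_single_oracle <- function(r, alpha, r_c = 2.5) {
  ifelse(r <= 2 * r_c, 1,
         k0_oracle(r * sqrt(alpha)) / k0_oracle(2 * r_c * sqrt(alpha)))
}

# naive O(n^2) double-loop superposition
perceived_oracle <- function(colony, params) {
  n <- nrow(colony)
  w <- 1 + params$eta * as.numeric(colony$induced)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) {
      if (j == i && !params$include_self) next
      d <- sqrt((colony$x[i] - colony$x[j])^2 + (colony$y[i] - colony$y[j])^2)
      s <- s + w[j] * qs_c_single(d, params$alpha, params$r_c)
    }
    out[i] <- s
  }
  out
}

# minimal superset of the pre-existing induced set that is closed under the
# threshold rule, found by enumerating all 2^n induction-state vectors
closure_oracle <- function(colony, params) {
  n <- nrow(colony)
  stopifnot(n <= 12)
  d <- as.matrix(stats::dist(cbind(colony$x, colony$y)))
  C <- matrix(qs_c_single(as.vector(d), params$alpha, params$r_c), n, n)
  diag(C) <- 1
  S0 <- colony$induced
  subsets <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  keep <- apply(subsets, 1, function(S) all(S | !S0))
  subsets <- subsets[keep, , drop = FALSE]
  W <- 1 + params$eta * t(subsets)
  conc <- C %*% W
  if (!params$include_self) conc <- conc - W
  closed <- vapply(seq_len(ncol(conc)), function(j) {
    S <- subsets[j, ]
    all(conc[!S, j] < params$beta_thr)
  }, logical(1))
  cl <- subsets[closed, , drop = FALSE]
  minimal <- cl[which.min(rowSums(cl)), ]
  colony$id[minimal & !S0]
}

random_colony <- function(n, L = 50, n_lineages = 1L) {
  col <- qs_fixture("single_seed")[0, ]
  col <- data.frame(id = seq_len(n),
                    x = stats::runif(n, 0, L), y = stats::runif(n, 0, L),
                    lineage = rep_len(seq_len(n_lineages), n),
                    induced = rep(FALSE, n),
                    t_induced = rep(NA_real_, n),
                    step_induced = rep(NA_integer_, n))
  attr(col, "t") <- 0
  attr(col, "step") <- 0L
  class(col) <- c("qs_colony", "data.frame")
  col
}

first_induction_times <- function(params, seeds, init = NULL) {
  vapply(seeds, function(s)
    qs_first_induction(qs_simulate(params, seed = s, init = init)),
    numeric(1))
}

# censoring-aware surrogate: for runs that never induced, use the time at
# which the run stopped (a lower bound on the true first-induction time)
surrogate_times <- function(params, seeds, init = NULL) {
  vapply(seeds, function(s) {
    sim <- qs_simulate(params, seed = s, init = init)
    fit <- qs_first_induction(sim)
    if (is.na(fit)) attr(sim$colony, "t") else fit
  }, numeric(1))
}
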