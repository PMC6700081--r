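mk_log <- function(t, k, n = NULL, chi = NULL) {
  n <- if (is.null(n)) seq_along(t) + 50L else n
  chi <- if (is.null(chi)) cumsum(k) / n else chi
  data.frame(step = seq_along(t) - 1L, t_min = t,
             mother_id = NA_integer_, daughter_id = NA_integer_,
             k_t = k, chi = chi, c_bar = 1, n = n)
}

test_that("first-induction time is the earliest step with inductions", {
  log <- mk_log(t = c(0, 10, 100, 192, 200), k = c(0, 0, 0, 2, 1))
  expect_equal(qs_first_induction(log), 192)
  expect_true(is.na(qs_first_induction(mk_log(c(0, 5, 10), c(0, 0, 0)))))
  expect_equal(qs_first_induction(mk_log(c(0, 5), c(3, 0))), 0)
})

test_that("ensemble MFPT averages uncensored replicates and reports censoring", {
  out <- qs_mfpt(c(180, 200))
  expect_equal(out$mean, 190)
  expect_equal(out$sd, sqrt(200), tolerance = 1e-12)
  expect_identical(out$n_censored, 0L)

  out2 <- qs_mfpt(c(150, NA, 210))
  expect_equal(out2$mean, 180)
  expect_identical(out2$n_censored, 1L)

  out3 <- qs_mfpt(c(NA_real_, NA_real_))
  expect_true(is.na(out3$mean))
  expect_identical(out3$n_censored, 2L)
})

test_that("induction-time order parameter IT_chi reads the chi series", {
  log <- mk_log(t = c(0, 100, 225, 300), k = c(0, 1, 5, 2),
                chi = c(0, 0.1, 0.5, 0.9))
  expect_equal(qs_it_chi(log, 0.5), 225)
  expect_equal(qs_it_chi(log, 0.25), 225)
  log2 <- mk_log(t = c(0, 100), k = c(0, 1), chi = c(0, 0.2))
  expect_true(is.na(qs_it_chi(log2, 0.25)))
  expect_error(qs_it_chi(log, 0), "chi_target")
  expect_error(qs_it_chi(log, 1), "chi_target")
  expect_equal(qs_chi_at(log, 250), 0.5)
  expect_equal(qs_chi_at(log, -1), 0)
})

test_that("colony-mean concentration matches the naive oracle", {
  p <- qs_params(alpha = 0.04, d_new = 10)
  expect_equal(qs_mean_concentration(qs_fixture("single_seed"), p), 1)
  expect_equal(qs_mean_concentration(qs_fixture("touching_pair"), p), 2)
  set.seed(31)
  col <- random_colony(50, L = 60)
  col$induced[1:10] <- TRUE
  p2 <- qs_params(alpha = 0.05, d_new = 10, eta = 2)
  expect_equal(qs_mean_concentration(col, p2),
               mean(perceived_oracle(col, p2)), tolerance = 1e-12)
  expect_error(qs_mean_concentration(col[0, ], p2), "empty")
})

test_that("static seed ensembles: self-dominated limit and error handling", {
  p <- qs_params(alpha = 1, R = 100)
  se <- qs_static_ensemble(p, alphas = 1e4, n_runs = 10, seed = 5)
  # at very short signal range only overlapping cells contribute beyond self
  expect_lt(se$c_bar_mean, 1.5)
  expect_gte(se$c_bar_mean, 1)
  expect_error(qs_static_ensemble(p, 1, n_runs = 1), "n_runs")
})

test_that("burst detector flags isolated spikes and only spikes", {
  # low background then one spike
  log <- mk_log(t = 1:20, k = c(rep(c(0L, 1L), 9), 0L, 50L), n = rep(500L, 20))
  hits <- qs_detect_bursts(log)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$size, 50L)

  # constant series never exceeds m + 8 * s_min
  flat <- mk_log(t = 1:50, k = rep(2L, 50), n = rep(500L, 50))
  expect_identical(nrow(qs_detect_bursts(flat)), 0L)

  # three separated spikes -> exactly three annotations, in order
  k <- rep(0L, 60); k[c(20, 40, 58)] <- c(124L, 134L, 140L)
  k[setdiff(seq(2, 60, by = 7), c(20, 40, 58))] <- 1L
  spiky <- mk_log(t = 1:60, k = k, n = rep(2000L, 60))
  h3 <- qs_detect_bursts(spiky)
  expect_identical(h3$size, c(124L, 134L, 140L))
  expect_identical(h3$label, 1:3)
  expect_true(all(diff(h3$t_min) > 0))
})

test_that("burst membership maps back to the induced cells of the step", {
  p <- qs_params(alpha = 0.01, sigma_str = 5, eta = 3, beta_thr = 10,
                 seeding = "single", stop_at = "first_induction",
                 max_time = 1e4, field_cutoff = 1e-12)
  sim <- qs_simulate(p, seed = 32)
  hits <- qs_detect_bursts(sim)
  if (nrow(hits) > 0) {
    expect_identical(lengths(hits$members), as.integer(hits$size))
    ids <- hits$members[[1]]
    expect_true(all(sim$colony$step_induced[ids] == hits$step[1]))
  }
  # per-step induction counts always reconcile with the final state
  expect_identical(sum(sim$log$k_t), sum(sim$colony$induced))
})

test_that("family statistics partition the colony", {
  col <- random_colony(8, n_lineages = 2)
  col$lineage <- rep(c(1L, 2L), c(3, 5))
  col$induced[4:8] <- TRUE
  fam <- qs_family_stats(col)
  expect_identical(fam$n, c(3L, 5L))
  expect_identical(sum(fam$n), 8L)
  expect_equal(fam$chi, c(0, 1))
  # chi_i * n_i is always an integer count
  expect_equal(fam$chi * fam$n, round(fam$chi * fam$n))
})

test_that("induction histograms tabulate chi across replicates", {
  p <- qs_params(alpha = 0.05, d_new = 10, eta = 1, max_time = 60)
  sims <- qs_replicates(p, 4, seed_base = 41)
  h <- qs_induction_histogram(sims, times = c(30, 60))
  expect_identical(sum(h$count[h$t_min == 30]), 4L)
  expect_identical(sum(h$count[h$t_min == 60]), 4L)
  expect_true(all(dim(attr(h, "chi")) == c(2, 4)))
})

test_that("first-induced cluster span and size follow the definition", {
  colony <- random_colony(3)
  colony$x <- c(0, 10, 500); colony$y <- c(0, 0, 0)
  colony$lineage <- c(1L, 1L, 2L)
  colony$induced[1] <- TRUE
  colony$t_induced[1] <- 30; colony$step_induced[1] <- 1L
  colony$conc <- 1
  sim <- structure(list(
    colony = colony,
    log = mk_log(t = c(0, 30), k = c(0L, 1L), n = c(2L, 3L)),
    n0 = 1L), class = "qs_sim")
  # cluster = lineage-1 cells present at the first-induction step:
  # {(0,0), (10,0)}, centre of mass (5,0), span 5
  cm <- qs_cluster_metrics(sim)
  expect_equal(cm$r_col, 5)
  expect_identical(cm$n_col, 2L)
  # singleton cluster
  sim$colony <- colony[c(1, 3), ]; sim$colony$id <- c(1L, 2L)
  expect_equal(qs_cluster_metrics(sim)$r_col, 0)
  # censored run yields NULL
  sim$log$k_t <- 0L
  expect_null(qs_cluster_metrics(sim))
})

test_that("relative burst size is the first cascade over the colony size", {
  log <- mk_log(t = c(0, 10, 20), k = c(0L, 0L, 5L), n = c(48L, 49L, 50L))
  sim <- structure(list(log = log), class = "qs_sim")
  z <- qs_relative_burst_size(sim)
  expect_equal(z$zeta, 0.1)
  expect_identical(z$burst_cells, 5L)
  sim$log$k_t <- 0L
  expect_null(qs_relative_burst_size(sim))
})
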