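test_that("Poisson-disk seeding has the right count statistics and support", {
  p <- qs_params(alpha = 0.05, d_new = 10)
  set.seed(1)
  counts <- replicate(2000, nrow(qs_seed_disk(p)))
  mu <- p$rho * pi * p$R^2                      # 78.54
  se <- sqrt(mu / length(counts))
  expect_lt(abs(mean(counts) - mu), 3 * se)
  # Poisson: variance equals the mean (loose stochastic band)
  expect_lt(abs(var(counts) - mu), 6 * mu / sqrt(length(counts)))

  col <- qs_seed_disk(p)
  expect_true(all(sqrt(col$x^2 + col$y^2) <= p$R))
  expect_identical(col$lineage, seq_len(nrow(col)))
  expect_false(any(col$induced))

  p0 <- qs_params(alpha = 0.05, d_new = 10, rho = 0)
  expect_identical(nrow(qs_seed_disk(p0)), 0L)
})

test_that("area-uniform disk placement: squared radius is uniform", {
  p <- qs_params(alpha = 0.05, d_new = 10, R = 100)
  set.seed(2)
  r2 <- unlist(replicate(200, {
    col <- qs_seed_disk(p); (col$x^2 + col$y^2) / p$R^2
  }))
  ks <- suppressWarnings(stats::ks.test(r2, "punif"))
  expect_gt(ks$p.value, 1e-3)
})

test_that("lattice seeding is deterministic with exact geometry", {
  g <- qs_seed_grid(100, 200)
  expect_identical(nrow(g), 100L)
  d <- as.matrix(dist(cbind(g$x, g$y))); diag(d) <- Inf
  expect_equal(min(d), 200)                     # nearest-neighbour spacing
  expect_equal(max(apply(d, 1, min)), 200)
  expect_identical(qs_seed_grid(100, 200), g)   # no RNG consumed

  one <- qs_fixture("single_seed")
  expect_identical(c(one$x, one$y), c(0, 0))
  g4 <- qs_seed_grid(4, 10)
  d4 <- dist(cbind(g4$x, g4$y))
  expect_equal(max(d4), 10 * sqrt(2))
  expect_error(qs_seed_grid(10, 10), "perfect square")
  expect_error(qs_seed_grid(4, 0), "positive")
})

test_that("fixed-mode placement has exact distance and isotropic angles", {
  pl <- list(mode = "fixed", d_new = 10)
  set.seed(3)
  pos <- t(replicate(1e4, qs_place_daughter(2, -1, pl)))
  d <- sqrt((pos[, 1] - 2)^2 + (pos[, 2] + 1)^2)
  expect_equal(d, rep(10, 1e4), tolerance = 1e-12)
  ang <- atan2(pos[, 2] + 1, pos[, 1] - 2)
  cs <- stats::chisq.test(table(cut(ang, breaks = seq(-pi, pi, length.out = 37))))
  expect_gt(cs$p.value, 1e-3)
  expect_equal(qs_place_daughter(1, 1, list(mode = "fixed", d_new = 0)), c(1, 1))
})

test_that("gaussian-mode placement has the stated per-axis moments", {
  pl <- list(mode = "gaussian", sigma_str = 20)
  set.seed(4)
  off <- t(replicate(2e4, qs_place_daughter(0, 0, pl)))
  for (axis in 1:2) {
    expect_lt(abs(mean(off[, axis])), 3 * 20 / sqrt(nrow(off)))
    expect_lt(abs(sd(off[, axis]) - 20), 3 * 20 / sqrt(2 * nrow(off)))
  }
  expect_equal(qs_place_daughter(3, 4, list(mode = "gaussian", sigma_str = 0)),
               c(3, 4))
})

test_that("division loop: clock formula, counts and lineage conservation", {
  p <- qs_params(alpha = 0.05, d_new = 10, eta = 1, max_time = 120)
  sim <- qs_simulate(p, seed = 5)
  log <- sim$log[sim$log$step > 0, ]
  # t_gap = 1/(gamma n) with n the pre-division count; clock is their sum
  expect_equal(log$t_min, cumsum(1 / (p$gamma * (log$n - 1))),
               tolerance = 1e-12)
  # one cell per division step
  expect_identical(log$n, sim$n0 + log$step)
  expect_identical(nrow(sim$colony), sim$n0 + max(sim$log$step))
  # lineages partition the colony into the seed families
  fam <- qs_family_stats(sim$colony)
  expect_identical(nrow(fam), sim$n0)
  expect_identical(sum(fam$n), nrow(sim$colony))
  # every daughter inherits its mother's lineage
  mothers <- sim$log$mother_id[sim$log$step > 0]
  daughters <- sim$log$daughter_id[sim$log$step > 0]
  expect_identical(sim$colony$lineage[daughters], sim$colony$lineage[mothers])
})

test_that("the clock grows logarithmically in colony size (exponential growth)", {
  p <- qs_params(alpha = 1000, d_new = 10, max_time = 240,
                 field_cutoff = 1e-12)
  sim <- qs_simulate(p, seed = 6)
  log <- sim$log[sim$log$step > 0, ]
  n0 <- sim$n0
  # t(n) = (1/gamma) sum_{k=n0}^{n-1} 1/k ~ (1/gamma) log(n/n0)
  expect_equal(tail(log$t_min, 1),
               sum(1 / (p$gamma * (n0:(tail(log$n, 1) - 1)))),
               tolerance = 1e-9)
  expect_lt(abs(tail(log$t_min, 1) - log(tail(log$n, 1) / n0) / p$gamma), 1)
})

test_that("termination rules stop the run as configured", {
  p <- qs_params(alpha = 1000, d_new = 10, max_cells = 150, max_time = 1e6)
  sim <- qs_simulate(p, seed = 7)
  expect_identical(nrow(sim$colony), 150L)

  pf <- qs_params(alpha = 0.01, sigma_str = 5, eta = 3, beta_thr = 5,
                  seeding = "single", stop_at = "full_induction",
                  max_time = 1e4, field_cutoff = 1e-12)
  simf <- qs_simulate(pf, seed = 8)
  expect_identical(sum(simf$colony$induced), nrow(simf$colony))
  expect_equal(tail(simf$log$chi, 1), 1)

  pt <- qs_params(alpha = 1000, d_new = 10, max_time = 60)
  simt <- qs_simulate(pt, seed = 9)
  expect_lte(attr(simt$colony, "t"), 60)
})

test_that("a lattice colony randomises: neighbour-distance variance grows", {
  nn_var <- function(col) {
    d <- as.matrix(dist(cbind(col$x, col$y))); diag(d) <- Inf
    var(apply(d, 1, min))
  }
  for (seed in 1:3) {
    p <- qs_params(alpha = 1000, sigma_str = 10, seeding = "grid",
                   grid_n = 16, grid_spacing = 200, max_time = 1e9)
    v <- vapply(16:19, function(nc) {
      pp <- p; pp$max_cells <- nc
      nn_var(qs_simulate(pp, seed = seed)$colony)
    }, numeric(1))
    expect_true(all(diff(v) > 0))
  }
})

test_that("cell tables round-trip through CSV", {
  p <- qs_params(alpha = 0.05, d_new = 10, eta = 2, beta_thr = 3,
                 max_time = 30)
  sim <- qs_simulate(p, seed = 10)
  f <- withr::local_tempfile(fileext = ".csv")
  qs_write_cells(sim$colony, f)
  back <- qs_read_cells(f)
  expect_equal(back$x, sim$colony$x)
  expect_equal(back$y, sim$colony$y)
  expect_identical(back$lineage, sim$colony$lineage)
  expect_identical(back$induced, sim$colony$induced)
  # a read table can seed a new simulation
  sim2 <- qs_simulate(p, seed = 11, init = back)
  expect_gte(nrow(sim2$colony), nrow(back))
})
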