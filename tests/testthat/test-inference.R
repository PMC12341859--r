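test_that("parameter grids: linear spacing, geometric limbs, zero insertion", {
  g <- make_grid("linear", bounds = c(-0.1, 0.1), n = 101)
  expect_equal(length(g), 101L)
  expect_equal(unique(round(diff(g), 12)), 0.002)
  expect_true(0 %in% g)
  expect_equal(make_grid("linear", bounds = c(0, 0), n = 1), 0)
  g <- make_grid("geometric", mag = c(1e-4, 1e-1), n_per_limb = 4)
  expect_equal(length(g), 9L)
  expect_equal(g, -rev(g))
  expect_error(make_grid("geometric", mag = c(1e-4, 1e-1), n_per_limb = 4,
                         include_zero = FALSE), "include_zero")
  g <- make_grid("geometric", mag = c(1e-3, 1e-1), n_per_limb = 3,
                 signs = "pos", include_zero = FALSE)
  expect_equal(g, 10^c(-3, -2, -1))
})

make_test_setup <- function() {
  list(pop = pop_params(200, 1e-5, 1e-5),
       loci = random_loci(3, c(0, 30, 80), 20, seed = 11),
       grid = freq_grid(150),
       init = init_uniform())
}

test_that("1D scan agrees with scalar likelihood calls and neutral column", {
  su <- make_test_setup()
  s_grid <- seq(-0.05, 0.05, length.out = 7)
  surf <- scan_s(su$loci, s_grid, h = 0.5, pop = su$pop, init = su$init,
                 grid = su$grid)
  for (j in seq_along(s_grid)) {
    ll <- batch_loglik(su$loci,
                       constant_schedule(fitness_from_sh(s_grid[j], 0.5)),
                       su$pop, su$init, su$grid)
    expect_equal(surf$loglik[, j], as.numeric(ll), tolerance = 1e-12)
  }
  expect_equal(surf$neutral, surf$loglik[, 4])
  # scan at grid (0) only equals the neutral log-likelihood
  surf0 <- scan_s(su$loci, 0, h = 0.5, pop = su$pop, init = su$init,
                  grid = su$grid)
  expect_equal(drop(surf0$loglik), surf0$neutral)
  # neutrality does not depend on h
  surf1 <- scan_s(su$loci, 0, h = 1, pop = su$pop, init = su$init,
                  grid = su$grid)
  expect_equal(drop(surf0$loglik), drop(surf1$loglik))
})

test_that("2D scan is an outer product consistent with 1D sections", {
  su <- make_test_setup()
  sAa <- c(-0.02, 0, 0.02)
  sAA <- c(-0.02, 0, 0.02)
  surf <- scan_2d(su$loci, sAa, sAA, pop = su$pop, init = su$init,
                  grid = su$grid)
  for (a in seq_along(sAa)) for (b in seq_along(sAA)) {
    ll <- batch_loglik(su$loci,
                       constant_schedule(fitness(sAa[a], sAA[b])),
                       su$pop, su$init, su$grid)
    expect_equal(surf$loglik[, a, b], as.numeric(ll), tolerance = 1e-12)
  }
  # diagonal equals the h = 1 1D scan
  surf1 <- scan_s(su$loci, sAA, h = 1, pop = su$pop, init = su$init,
                  grid = su$grid)
  diag_ll <- sapply(seq_along(sAA), function(j) surf$loglik[, j, j])
  expect_equal(diag_ll, surf1$loglik, ignore_attr = TRUE)
  # 1x1 grid at the origin reduces to the neutral value
  surf0 <- scan_2d(su$loci, 0, 0, pop = su$pop, init = su$init,
                   grid = su$grid)
  expect_equal(drop(surf0$loglik), surf0$neutral)
})

# a synthetic 1D surface wrapped as the object scan_s() returns
fake_surface <- function(s, ll) {
  structure(list(s = s, h = 0.5, loglik = matrix(ll, 1), neutral = ll[s == 0],
                 ids = "locus1"), class = "lik_surface_1d")
}

test_that("off-grid MLE recovers the maximizer of a quadratic surface", {
  s <- seq(-0.05, 0.05, by = 0.005)
  r <- interpolate_mle(fake_surface(s, -(s - 0.013)^2))
  expect_equal(r$s_offgrid, 0.013, tolerance = 1e-9 / 0.013)
  expect_equal(r$s_ongrid, 0.015)
  # symmetric quadratic centred on a node stays on the node
  r <- interpolate_mle(fake_surface(s, -(s - 0.02)^2))
  expect_equal(r$s_offgrid, 0.02, tolerance = 1e-9)
  # monotone surface: boundary rule, off-grid equals on-grid
  r <- interpolate_mle(fake_surface(s, 3 * s))
  expect_equal(r$s_ongrid, 0.05)
  expect_equal(r$s_offgrid, 0.05)
  expect_true(r$boundary)
})

test_that("MLE tie-breaking is conservative toward neutrality", {
  s <- seq(-0.02, 0.02, by = 0.01)
  ll <- c(5, 7, 2, 7, 5)  # equal maxima at -0.01 and +0.01
  r <- interpolate_mle(fake_surface(s, ll))
  expect_equal(r$s_ongrid, -0.01)
  # interpolated maximum never drops below the on-grid maximum
  set.seed(9)
  for (i in 1:20) {
    ll <- cumsum(rnorm(9))
    r <- interpolate_mle(fake_surface(seq(-0.02, 0.02, by = 0.005), ll))
    expect_gte(r$loglik_max, max(ll))
  }
  expect_warning(
    r <- interpolate_mle(fake_surface(c(0, 0.01), c(1, 2))),
    "fewer than 3")
  expect_equal(r$s_offgrid, r$s_ongrid)
})

test_that("likelihood-ratio statistic is floored and chi-squared calibrated", {
  r <- lrt_pvalue(-10, -10)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  r <- lrt_pvalue(-10 + 3.841459 / 2, -10)
  expect_equal(r$p, 0.05, tolerance = 1e-4 / 0.05)
  r <- lrt_pvalue(-10.001, -10)  # interpolation artifact
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
})

test_that("Fisher's method combines replicate p-values", {
  expect_equal(fisher_combine(rep(1, 5)), 1)
  for (p in c(0.01, 0.2, 0.77)) {
    expect_equal(fisher_combine(p), p, tolerance = 1e-12)
  }
  stat <- -2 * sum(log(c(0.05, 0.05)))
  expect_equal(stat, 11.98293, tolerance = 1e-6)
  expect_equal(fisher_combine(c(0.05, 0.05)),
               pchisq(stat, 4, lower.tail = FALSE))
  expect_equal(round(fisher_combine(c(0.05, 0.05)), 4), 0.0175)
  # exchangeable and monotone
  expect_equal(fisher_combine(c(0.3, 0.02, 0.9)),
               fisher_combine(c(0.9, 0.3, 0.02)))
  expect_lt(fisher_combine(c(0.3, 0.01)), fisher_combine(c(0.3, 0.05)))
  expect_warning(fisher_combine(c(0, 0.5)), "floored")
})

test_that("onset estimation is degenerate under neutrality and beyond the window", {
  su <- make_test_setup()
  on <- estimate_onset(su$loci, onset_grid = c(0, 30, 60), s_grid = 0,
                       h = 0.5, pop = su$pop, init = su$init,
                       grid = su$grid)
  for (i in seq_along(su$loci)) {
    expect_lt(diff(range(on$loglik[i, , 1])), 1e-9)
  }
  # onset after the last sampling time leaves the window fully neutral
  on <- estimate_onset(su$loci, onset_grid = 100, s_grid = c(0.05),
                       h = 0.5, pop = su$pop, init = su$init,
                       grid = su$grid)
  ll0 <- batch_loglik(su$loci, constant_schedule(), su$pop, su$init,
                      su$grid)
  expect_equal(drop(on$loglik), as.numeric(ll0), tolerance = 1e-12)
})
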