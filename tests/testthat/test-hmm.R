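test_that("frequency grid has boundary states and tiling cells", {
  g <- freq_grid(3)
  expect_equal(g$points, c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(length(freq_grid(499)$points), 501L)
  for (g in list(freq_grid(3), freq_grid(50), freq_grid(20, refine = 3))) {
    expect_equal(g$edges[1], 0)
    expect_equal(g$edges[length(g$edges)], 1)
    expect_true(all(diff(g$points) > 0))
    expect_true(all(diff(g$edges) > 0))
    expect_equal(length(g$edges), length(g$points) + 1L)
  }
  # refinement increases density near the boundaries only
  g0 <- freq_grid(20)
  g1 <- freq_grid(20, refine = 3)
  expect_lt(min(diff(g1$points)), min(diff(g0$points)))
  expect_true(all(g0$points %in% g1$points))
  expect_error(freq_grid(2), "n_interior")
})

test_that("Gaussian moments match the one-generation and closed-form neutral variance", {
  pop <- pop_params(1e4)
  mo <- gaussian_moments(0.37, fitness(0.02, 0.05), pop, 0)
  expect_equal(mo$mean, 0.37)
  expect_equal(mo$var, 0)
  mo <- gaussian_moments(0.5, fitness(0, 0), pop, 1)
  expect_equal(mo$mean, 0.5)
  expect_equal(mo$var, 0.25 / 2e4, tolerance = 1e-12)
  # closed-form neutral Wright-Fisher variance at several x and dt
  for (x in c(0.05, 0.3, 0.8)) for (dt in c(10, 137, 500)) {
    mo <- gaussian_moments(x, fitness(0, 0), pop, dt)
    expect_equal(mo$mean, x)
    expect_lt(abs(mo$var - x * (1 - x) * (1 - (1 - 1 / 2e4)^dt)), 1e-10)
  }
})

test_that("transition matrices are stochastic, mean-preserving when neutral", {
  g <- freq_grid(500)
  pop <- pop_params(200)
  P0 <- wf_transition_matrix(g, fitness(0, 0), pop, 0)$matrix
  expect_identical(P0, diag(length(g$points)))
  for (fit in list(fitness(0, 0), fitness(0.1, 0.2), fitness(-0.05, -0.1))) {
    P <- wf_transition_matrix(g, fit, pop, 17)$matrix
    expect_true(all(P >= 0))
    expect_true(all(abs(rowSums(P) - 1) < 1e-9))
  }
  # martingale property of neutral drift
  P <- wf_transition_matrix(g, fitness(0, 0), pop, 10)$matrix
  rowmean <- drop(P %*% g$points)
  interior <- 2:(length(g$points) - 1)
  expect_lt(max(abs(rowmean[interior] - g$points[interior])), 2e-3)
  # positive selection shifts interior row means upward
  P <- wf_transition_matrix(g, fitness_from_sh(0.2, 0.5), pop, 10)$matrix
  mid <- which(g$points > 0.2 & g$points < 0.8)
  expect_true(all(drop(P %*% g$points)[mid] > g$points[mid]))
})

test_that("Chapman-Kolmogorov consistency of composed transitions", {
  g <- freq_grid(500)
  pop <- pop_params(100, 1e-6, 1e-6)
  Ta <- wf_transition_matrix(g, fitness(0, 0), pop, 30)$matrix
  Tb <- wf_transition_matrix(g, fitness(0, 0), pop, 20)$matrix
  Tab <- wf_transition_matrix(g, fitness(0, 0), pop, 50)$matrix
  expect_lt(max(rowSums(abs(Ta %*% Tb - Tab))), 5e-3)
})

test_that("binomial emissions with the missing-data convention", {
  expect_equal(emission_prob(0, 5, 0), 1)
  expect_equal(emission_prob(0.5, 2, 1), 0.5)
  expect_equal(emission_prob(0.3, 0, 0), 1)
  expect_error(emission_prob(0.3, 5, 6), "exceed")
})

test_that("initial distributions realize each kind on the grid", {
  g <- freq_grid(9)
  pop <- pop_params(100, 0.002, 0.003)
  w <- initial_distribution(init_uniform(), g, pop)
  expect_equal(sum(w), 1)
  expect_true(all(abs(diff(w[2:10])) < 1e-12))  # equal interior masses
  w <- initial_distribution(init_fixed(0), g, pop)
  expect_equal(w, c(1, rep(0, 10)))
  # fixed off-grid value splits mass linearly between neighbours
  w <- initial_distribution(init_fixed(0.125), g, pop)
  expect_equal(sum(w * g$points), 0.125)
  expect_equal(sum(w > 0), 2L)
  # stationary beta: symmetric when 4 Ne u01 = 4 Ne u10 = 1
  pops <- pop_params(100, 1 / 400, 1 / 400)
  w <- initial_distribution(init_beta(), freq_grid(20), pops)
  expect_equal(w, rev(w))
  # asymmetric case against numeric integration of the beta density
  w <- initial_distribution(init_beta(), g, pop)
  a <- 4 * 100 * 0.002
  b <- 4 * 100 * 0.003
  ora <- vapply(seq_along(w), function(j) {
    stats::integrate(function(x) dbeta(x, a, b), g$edges[j], g$edges[j + 1],
                     rel.tol = 1e-10)$value
  }, numeric(1))
  expect_equal(w, ora / sum(ora), tolerance = 1e-6)
  expect_error(initial_distribution(init_beta(), g, pop_params(100)),
               "u01")
  expect_error(init_explicit(rep(0.3, 2)), "sum to 1")
})

test_that("forward likelihood reduces to the binomial pmf for a single sample", {
  pop <- pop_params(1e4)
  g <- freq_grid(499)  # 0.5 is a grid point
  ll <- forward_loglik(temporal_samples(0, 2, 1), constant_schedule(),
                       pop, init_fixed(0.5), g)
  expect_equal(as.numeric(ll), log(0.5), tolerance = 1e-14)
  for (cnt in c(0, 3, 13, 40)) {
    ll <- forward_loglik(temporal_samples(0, 40, cnt), constant_schedule(),
                         pop, init_fixed(0.5), g)
    expect_equal(as.numeric(ll), dbinom(cnt, 40, 0.5, log = TRUE),
                 tolerance = 1e-13)
  }
})

test_that("missing data yield likelihood one and unsorted times are rejected", {
  pop <- pop_params(500)
  ll <- forward_loglik(temporal_samples(c(0, 50, 100), rep(0, 3), rep(0, 3)),
                       constant_schedule(fitness_from_sh(0.05, 0.5)),
                       pop, init_uniform(), freq_grid(100))
  expect_equal(as.numeric(ll), 0)
  expect_error(temporal_samples(c(10, 0), c(5, 5), c(1, 1)),
               "nondecreasing")
})

test_that("HMM likelihood matches the exact discrete Wright-Fisher chain at small Ne", {
  pop <- pop_params(120, 1e-6, 1e-6)
  times <- seq(0, 150, 50)
  loci <- random_loci(6, times, 30, seed = 42)
  g <- freq_grid(500)
  for (fit in list(fitness(0, 0), fitness_from_sh(0.05, 0.5),
                   fitness_from_sh(-0.04, 1))) {
    sched <- constant_schedule(fit)
    ll <- batch_loglik(loci, sched, pop, init_fixed(0.5), g)
    ex <- wf_exact_loglik(loci, sched, pop, init_fixed(0.5))
    expect_lt(max(abs(ll - ex)), 0.1)
  }
})

test_that("batch likelihood equals the per-locus path and duplicates duplicate", {
  pop <- pop_params(300, 1e-5, 1e-5)
  times <- c(0, 40, 90)
  loci <- random_loci(20, times, 25, seed = 3)
  sched <- constant_schedule(fitness_from_sh(0.03, 0.5))
  g <- freq_grid(120)
  ll <- batch_loglik(loci, sched, pop, init_uniform(), g)
  one <- vapply(loci, function(l) {
    as.numeric(forward_loglik(l, sched, pop, init_uniform(), g))
  }, numeric(1))
  expect_lt(max(abs(ll - one)), 1e-12)
  ll2 <- batch_loglik(c(loci[1], loci[1]), sched, pop, init_uniform(), g)
  expect_identical(ll2[[1]], ll2[[2]])
  bad <- c(loci[1], list(temporal_samples(c(0, 50, 90), c(5, 5, 5),
                                          c(0, 0, 0))))
  expect_error(batch_loglik(bad, sched, pop, init_uniform(), g),
               "same sampling times")
})

test_that("likelihood is invariant under allele relabeling", {
  pop <- pop_params(100, 2e-6, 1e-6)
  pop_m <- pop_params(100, 1e-6, 2e-6)
  fit <- fitness(0.03, 0.05)
  fit_m <- fitness((1 + fit$sAa) / (1 + fit$sAA) - 1,
                   1 / (1 + fit$sAA) - 1)
  loci <- random_loci(10, seq(0, 200, 50), 40, seed = 5)
  loci_m <- lapply(loci, function(l) {
    temporal_samples(l$times, l$sizes, l$sizes - l$counts, id = l$id)
  })
  g <- freq_grid(500)
  l1 <- batch_loglik(loci, constant_schedule(fit), pop, init_fixed(0.3), g)
  l2 <- batch_loglik(loci_m, constant_schedule(fit_m), pop_m,
                     init_fixed(0.7), g)
  expect_equal(as.numeric(l1), as.numeric(l2), tolerance = 1e-9)
})

test_that("log-likelihood is stable under grid refinement", {
  pop <- pop_params(150, 1e-6, 1e-6)
  loci <- random_loci(10, seq(0, 200, 50), 40, seed = 8)
  for (fit in list(fitness(0, 0), fitness_from_sh(0.05, 0.5))) {
    sched <- constant_schedule(fit)
    l500 <- batch_loglik(loci, sched, pop, init_fixed(0.5), freq_grid(500))
    l1000 <- batch_loglik(loci, sched, pop, init_fixed(0.5),
                          freq_grid(1000))
    expect_lt(max(abs(l500 - l1000)), 0.01)
  }
})
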