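#' Temporal allele-count samples at one locus
#'
#' A time series of binomial samples from the population: at each sampling
#' generation, `sizes[k]` haploid observations (two per diploid individual,
#' one per pseudo-haploid individual) of which `counts[k]` carry the focal
#' allele.  A size of 0 marks missing data at that time.
#'
#' @param times Nondecreasing sampling generations (integers).
#' @param sizes Haploid sample sizes (non-negative integers).
#' @param counts Focal-allele counts, `0 <= counts[k] <= sizes[k]`.
#' @param id Optional locus identifier.
#'
#' @return An object of class `temporal_samples`.
#' @export
temporal_samples <- function(times, sizes, counts, id = NULL) {
  stopifnot(length(times) == length(sizes), length(sizes) == length(counts))
  stopifnot(is.numeric(times), all(is.finite(times)),
            all(times == round(times)))
  if (is.unsorted(times)) stop("sampling times must be nondecreasing")
  stopifnot(all(sizes >= 0), all(sizes == round(sizes)))
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  if (any(counts > sizes)) stop("allele counts cannot exceed sample sizes")
  structure(list(times = as.numeric(times), sizes = as.numeric(sizes),
                 counts = as.numeric(counts), id = id),
            class = "temporal_samples")
}

#' Gaussian moments of the allele-frequency distribution after dt generations
#'
#' Mean and variance of the frequency after `dt` generations of
#' Wright-Fisher reproduction with selection and mutation, started from a
#' point mass at `x`.  The mean is the `dt`-fold composition of the
#' deterministic map [wf_det_step()]; the variance is propagated one
#' generation at a time by linearizing the map around the running mean and
#' adding the binomial sampling variance,
#' `v' = v * f'(m)^2 * (1 - 1/(2 Ne)) + m' (1 - m') / (2 Ne)`.
#' In the neutral mutation-free case this reproduces the exact Wright-Fisher
#' variance `x (1 - x) (1 - (1 - 1/(2 Ne))^dt)`.
#'
#' @param x Starting frequency (scalar or vector).
#' @param fit A [fitness()].
#' @param pop A [pop_params()].
#' @param dt Elapsed generations (non-negative integer).
#'
#' @return A list with components `mean` and `var`, each the length of `x`.
#' @export
gaussian_moments <- function(x, fit, pop, dt) {
  stopifnot(dt >= 0, dt == round(dt))
  m <- x
  v <- numeric(length(x))
  shrink <- 1 - 1 / (2 * pop$Ne)
  for (g in seq_len(dt)) {
    d <- wf_det_step_deriv(m, fit, pop)
    m1 <- wf_det_step(m, fit, pop)
    v <- v * d * d * shrink + m1 * (1 - m1) / (2 * pop$Ne)
    m <- m1
  }
  list(mean = m, var = pmax(v, 0))
}

# one Gaussian integration step over dt generations: row i is the Gaussian
# with moments gaussian_moments(points[i]) integrated over the grid cells;
# tail mass below 0 (above 1) is collected into the boundary state
gaussian_kernel <- function(grid, fit, pop, dt) {
  pts <- grid$points
  K <- length(pts)
  mo <- gaussian_moments(pts, fit, pop, dt)
  sdv <- sqrt(mo$var)
  P <- matrix(0, K, K)
  deg <- sdv < 1e-12
  if (any(!deg)) {
    i <- which(!deg)
    # CDF at interior cell edges; outermost edges act as -Inf / +Inf so
    # that out-of-range mass lands on the boundary states
    Z <- (matrix(grid$edges[2:K], length(i), K - 1, byrow = TRUE) -
            mo$mean[i]) / sdv[i]
    Fz <- stats::pnorm(Z)
    P[i, ] <- cbind(Fz[, 1, drop = FALSE],
                    Fz[, -1, drop = FALSE] - Fz[, -(K - 1), drop = FALSE],
                    1 - Fz[, K - 1, drop = FALSE])
  }
  if (any(deg)) {
    j <- pmin(pmax(findInterval(mo$mean[deg], grid$edges,
                                rightmost.closed = TRUE), 1L), K)
    P[cbind(which(deg), j)] <- 1
  }
  P / rowSums(P)
}

#' Transition matrix of the frequency HMM over dt generations
#'
#' The interval is sliced into sub-steps of at most `step` generations; each
#' sub-step is a Gaussian kernel (moments from [gaussian_moments()])
#' integrated over the grid cells, with tail mass falling below 0 (above 1)
#' collected into the boundary state at 0 (at 1) so drift-driven absorption
#' is retained, and the full matrix is the product of the sub-step kernels
#' (computed by binary exponentiation).  Slicing keeps each kernel close to
#' Gaussian (sub-step short relative to `Ne`) while its standard deviation
#' stays resolved by the grid; the default `step = max(1, round(0.0025 Ne))`
#' satisfies both on the default 500-point grid across the `Ne` range this
#' model targets, and is validated against the exact discrete chain
#' ([wf_exact_loglik()]) at small `Ne`.  Rows with degenerate (zero)
#' variance are a point mass on the cell containing the mean; `dt = 0`
#' yields the identity.
#'
#' @param grid A [freq_grid()].
#' @param fit A [fitness()].
#' @param pop A [pop_params()].
#' @param dt Elapsed generations (non-negative integer).
#' @param step Maximum sub-step length in generations; `NULL` for the
#'   `Ne`-scaled default.
#'
#' @return An object of class `transition_matrix`: list with the
#'   row-stochastic `matrix` (rows sum to 1 within 1e-9), `dt`, and `fit`.
#' @export
wf_transition_matrix <- function(grid, fit, pop, dt, step = NULL) {
  stopifnot(inherits(grid, "freq_grid"), dt >= 0, dt == round(dt))
  K <- length(grid$points)
  if (is.null(step)) step <- max(1, round(0.0025 * pop$Ne))
  stopifnot(step >= 1, step == round(step))
  if (dt == 0) {
    P <- diag(K)
  } else {
    step <- min(step, dt)
    q <- dt %/% step
    r <- dt %% step
    B <- gaussian_kernel(grid, fit, pop, step)
    P <- NULL
    e <- q
    while (e > 0) {
      if (e %% 2 == 1) P <- if (is.null(P)) B else P %*% B
      e <- e %/% 2
      if (e > 0) B <- B %*% B
    }
    if (r > 0) {
      Br <- gaussian_kernel(grid, fit, pop, r)
      P <- if (is.null(P)) Br else P %*% Br
    }
  }
  rs <- rowSums(P)
  if (any(abs(rs - 1) > 1e-9) || any(P < -1e-12)) {
    stop("internal error: transition matrix is not row-stochastic")
  }
  structure(list(matrix = P, dt = dt, fit = fit),
            class = "transition_matrix")
}

#' Binomial emission probability
#'
#' Probability of observing `count` focal alleles among `size` sampled
#' haploids when the population frequency is `x`.  A sample size of 0
#' (missing data) has probability 1.
#'
#' @param x Population frequency (scalar or vector).
#' @param size Haploid sample size (non-negative integer).
#' @param count Focal-allele count, `0 <= count <= size`.
#'
#' @return Probability, the length of `x`.
#' @export
emission_prob <- function(x, size, count) {
  stopifnot(size >= 0, count >= 0)
  if (count > size) stop("count cannot exceed size")
  stats::dbinom(count, size, x)
}

# L x K emission matrix for one sampling time: rows loci, cols grid points
emission_matrix <- function(counts, sizes, pts) {
  L <- length(counts)
  K <- length(pts)
  matrix(stats::dbinom(rep_len(counts, L * K), rep_len(sizes, L * K),
                       rep(pts, each = L)), L, K)
}

# split the interval (t_from, t_to] at epoch boundaries of sched;
# returns data.frame(epoch, dt) of per-epoch segments in order
split_interval <- function(sched, t_from, t_to) {
  bnd <- sched$epoch_starts
  cuts <- sort(unique(c(t_from, t_to, bnd[bnd > t_from & bnd < t_to])))
  e <- epoch_index(sched, cuts[-length(cuts)])
  data.frame(epoch = e, dt = diff(cuts))
}

# transition matrices for each inter-sample interval, composed per epoch;
# returns list over intervals, each a list of plain matrices to apply in
# order.  cache: environment keyed by "sAa_sAA_dt".
interval_matrices <- function(times, sched, pop, grid, cache = new.env()) {
  get_mat <- function(fit, dt) {
    key <- sprintf("%.17g_%.17g_%d", fit$sAa, fit$sAA, as.integer(dt))
    m <- cache[[key]]
    if (is.null(m)) {
      m <- wf_transition_matrix(grid, fit, pop, dt)$matrix
      cache[[key]] <- m
    }
    m
  }
  K <- length(times)
  out <- vector("list", K)
  if (K >= 2) {
    for (k in 2:K) {
      seg <- split_interval(sched, times[k - 1], times[k])
      seg <- seg[seg$dt > 0, , drop = FALSE]
      out[[k]] <- lapply(seq_len(nrow(seg)), function(r) {
        get_mat(sched$epoch_fitness[[seg$epoch[r]]], seg$dt[r])
      })
    }
  }
  out
}

# scaled forward recursion on precomputed emissions and interval matrices.
# emis: list over times of L x K matrices; mats: from interval_matrices().
forward_engine <- function(init_vec, emis, mats) {
  K <- length(emis)
  L <- nrow(emis[[1]])
  alpha <- matrix(init_vec, L, length(init_vec), byrow = TRUE)
  ll <- numeric(L)
  for (k in seq_len(K)) {
    if (k > 1) for (P in mats[[k]]) alpha <- alpha %*% P
    alpha <- alpha * emis[[k]]
    sc <- rowSums(alpha)
    bad <- sc <= 0 | !is.finite(sc)
    ll <- ll + ifelse(bad, -Inf, log(sc))
    sc[bad] <- 1
    alpha <- alpha / sc
    if (any(bad)) alpha[bad, ] <- 1 / ncol(alpha)
  }
  ll
}

#' Log-likelihood of temporal samples under the frequency HMM
#'
#' The forward algorithm over the discretized frequency space: the hidden
#' frequency starts from `init` at the first sampling time, transitions
#' between sampling times follow [wf_transition_matrix()] (intervals
#' spanning epoch boundaries are composed from per-epoch matrices), and each
#' sample contributes a binomial emission.  Per-step scaling is used; the
#' log-likelihood is the sum of log scale factors.
#'
#' @param samples A [temporal_samples()] object.
#' @param sched A [sel_schedule()]; its start must not exceed the first
#'   sampling time.
#' @param pop A [pop_params()].
#' @param init An [init_cond()][init_fixed].
#' @param grid A [freq_grid()]; `NULL` (default) uses [default_grid()].
#'
#' @return The log-likelihood (scalar).  `-Inf` only for data that are
#'   impossible under the model (e.g. a positive count with a point-mass
#'   initial condition at 0 and no mutation).
#' @seealso [batch_loglik()] for many loci sharing sampling times.
#' @export
forward_loglik <- function(samples, sched, pop, init, grid = NULL) {
  batch_loglik(list(samples), sched, pop, init, grid)
}

#' Vectorized log-likelihoods for many loci sharing sampling times
#'
#' Computes [forward_loglik()] for every locus at once.  All loci must share
#' one vector of sampling times (sizes and counts may differ); transition
#' matrices are computed once per (epoch, interval length) and shared across
#' loci, which is what makes genome-scale scans affordable.
#'
#' @param loci A list of [temporal_samples()] with identical `times`.
#' @inheritParams forward_loglik
#'
#' @return Numeric vector of per-locus log-likelihoods, named by locus ids
#'   when present.
#' @export
batch_loglik <- function(loci, sched, pop, init, grid = NULL) {
  if (is.null(grid)) grid <- default_grid(pop)
  stopifnot(is.list(loci), length(loci) >= 1L)
  ok <- vapply(loci, inherits, logical(1L), what = "temporal_samples")
  if (!all(ok)) stop("loci must be a list of temporal_samples")
  times <- loci[[1]]$times
  same <- vapply(loci, function(l) {
    length(l$times) == length(times) && all(l$times == times)
  }, logical(1L))
  if (!all(same)) stop("all loci must share the same sampling times")
  if (times[1] < sched$epoch_starts[1]) {
    stop("first sampling time precedes the schedule start")
  }
  counts <- do.call(rbind, lapply(loci, `[[`, "counts"))
  sizes <- do.call(rbind, lapply(loci, `[[`, "sizes"))
  pts <- grid$points
  emis <- lapply(seq_along(times), function(k) {
    emission_matrix(counts[, k], sizes[, k], pts)
  })
  mats <- interval_matrices(times, sched, pop, grid)
  ll <- forward_engine(initial_distribution(init, grid, pop), emis, mats)
  ids <- vapply(loci, function(l) if (is.null(l$id)) NA_character_ else l$id,
                character(1L))
  if (!anyNA(ids)) names(ll) <- ids
  ll
}

#' Exact log-likelihood under the discrete Wright-Fisher HMM
#'
#' Reference implementation for small populations: the hidden state is the
#' exact allele count in the population (`2 Ne + 1` states), transitions are
#' binomial Wright-Fisher reproduction applied one generation at a time, and
#' emissions are the same binomial sampling model.  No Gaussian
#' approximation and no frequency discretization is involved, so this serves
#' as an independent check of [batch_loglik()]; cost grows as `Ne^2` per
#' generation, practical for `Ne` up to a few hundred.
#'
#' @inheritParams batch_loglik
#' @param init An [init_cond()][init_fixed] of kind fixed (mass split between
#'   the two neighbouring count states when `2 Ne x0` is not an integer) or
#'   uniform (over the `2 Ne + 1` count states).
#'
#' @return Numeric vector of per-locus log-likelihoods.
#' @export
wf_exact_loglik <- function(loci, sched, pop, init) {
  stopifnot(pop$Ne == round(pop$Ne))
  N2 <- 2 * pop$Ne
  states <- 0:N2 / N2
  times <- loci[[1]]$times
  counts <- do.call(rbind, lapply(loci, `[[`, "counts"))
  sizes <- do.call(rbind, lapply(loci, `[[`, "sizes"))
  init_vec <- switch(init$kind,
    fixed = {
      v <- numeric(N2 + 1)
      j <- floor(init$x0 * N2)
      a <- init$x0 * N2 - j
      v[j + 1] <- 1 - a
      if (a > 0) v[j + 2] <- a
      v
    },
    uniform = rep(1 / (N2 + 1), N2 + 1),
    stop("exact reference supports fixed and uniform initial conditions")
  )
  # per-epoch single-generation transition matrices
  gen_mat <- lapply(sched$epoch_fitness, function(fit) {
    p <- wf_det_step(states, fit, pop)
    t(vapply(p, function(pp) stats::dbinom(0:N2, N2, pp),
             numeric(N2 + 1)))
  })
  L <- nrow(counts)
  alpha <- matrix(init_vec, L, N2 + 1, byrow = TRUE)
  ll <- numeric(L)
  for (k in seq_along(times)) {
    if (k > 1) {
      seg <- split_interval(sched, times[k - 1], times[k])
      for (r in seq_len(nrow(seg))) {
        P <- gen_mat[[seg$epoch[r]]]
        for (g in seq_len(seg$dt[r])) alpha <- alpha %*% P
      }
    }
    alpha <- alpha * emission_matrix(counts[, k], sizes[, k], states)
    sc <- rowSums(alpha)
    ll <- ll + log(sc)
    alpha <- alpha / sc
  }
  ll
}
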