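#' Replicate filters for simulated temporal samples
#'
#' Predicates applied to each simulated replicate; failing replicates are
#' redrawn, so the retained set is the conditional distribution given the
#' filter.
#'
#' @param last_segregating_pop Require the population frequency at the last
#'   sampling time to lie strictly in (0, 1).
#' @param sample_segregating Require the pooled sample count (summed over
#'   sampling times) to be strictly between 0 and the pooled size.
#' @param min_sample_maf Minimum pooled-sample minor-allele frequency, in
#'   `[0, 0.5]`; `NULL` disables.
#'
#' @return An object of class `sim_filters`.
#' @export
sim_filters <- function(last_segregating_pop = FALSE,
                        sample_segregating = FALSE,
                        min_sample_maf = NULL) {
  if (!is.null(min_sample_maf)) {
    stopifnot(min_sample_maf >= 0, min_sample_maf <= 0.5)
  }
  structure(list(last_segregating_pop = isTRUE(last_segregating_pop),
                 sample_segregating = isTRUE(sample_segregating),
                 min_sample_maf = min_sample_maf),
            class = "sim_filters")
}

#' Simulate one discrete Wright-Fisher allele-frequency trajectory
#'
#' Discrete binomial reproduction (not the Gaussian approximation used for
#' inference): each generation, `x_{t+1} = B / (2 Ne)` with
#' `B ~ Binomial(2 Ne, wf_det_step(x_t))`.
#'
#' @param x0 Initial frequency at the schedule start.
#' @param sched A [sel_schedule()].
#' @param pop A [pop_params()].
#' @param t_end Number of generations to simulate.
#'
#' @return Numeric vector of length `t_end + 1` of population frequencies.
#' @export
simulate_trajectory <- function(x0, sched, pop, t_end) {
  drop(sim_paths(x0, sched, pop, t_end, keep_traj = TRUE)$traj)
}

# vectorized WF paths across replicates; records frequencies at
# record_times (generations relative to schedule start offsets handled by
# caller) and optionally the full trajectory
sim_paths <- function(x0, sched, pop, t_end, record_times = numeric(0),
                      keep_traj = FALSE) {
  stopifnot(t_end >= 0, t_end == round(t_end))
  R <- length(x0)
  N2 <- round(2 * pop$Ne)
  g0 <- sched$epoch_starts[1]
  x <- x0
  traj <- if (keep_traj) matrix(NA_real_, R, t_end + 1) else NULL
  if (keep_traj) traj[, 1] <- x
  rec <- matrix(NA_real_, R, length(record_times))
  hit <- which(record_times == g0)
  if (length(hit)) rec[, hit] <- x
  if (t_end > 0) {
    for (g in seq_len(t_end)) {
      e <- epoch_index(sched, g0 + g - 1)
      p <- wf_det_step(x, sched$epoch_fitness[[e]], pop)
      x <- stats::rbinom(R, N2, p) / N2
      if (keep_traj) traj[, g + 1] <- x
      hit <- which(record_times == g0 + g)
      if (length(hit)) rec[, hit] <- x
    }
  }
  list(final = x, rec = rec, traj = traj)
}

# draw initial frequencies for simulation
sim_init_freq <- function(init, R, pop) {
  switch(init$kind,
    fixed = rep(init$x0, R),
    uniform = stats::runif(R),
    beta = {
      a <- 4 * pop$Ne * pop$u01
      b <- 4 * pop$Ne * pop$u10
      if (a <= 0 || b <= 0) {
        stop("stationary-beta initial condition requires u01 > 0 and u10 > 0")
      }
      stats::rbeta(R, a, b)
    },
    stop("simulation supports fixed, uniform and beta initial conditions")
  )
}

#' Simulate replicate temporal samples under piece-wise constant selection
#'
#' Draws `n_rep` independent Wright-Fisher trajectories (binomial
#' reproduction at `2 Ne` haploids per generation) from the schedule start to
#' the last sampling time, then samples `counts[k] ~ Binomial(sizes[k], x)`
#' at each sampling time.  Replicates failing the [sim_filters()] are
#' redrawn until `n_rep` are retained; the output is therefore the
#' conditional distribution given the filter, and the total number of
#' attempts is recorded.  Results are reproducible for a given `seed` (one
#' RNG stream, fixed drawing scheme).
#'
#' @param n_rep Number of replicates to retain.
#' @param sample_times Sampling generations (nondecreasing, at or after the
#'   schedule start).
#' @param sample_sizes Haploid sample sizes, recycled to the number of
#'   sampling times.
#' @param pop A [pop_params()].
#' @param sched A [sel_schedule()].
#' @param init An [init_cond()][init_fixed] of kind fixed, uniform or beta,
#'   realized at the schedule start.
#' @param filters A [sim_filters()].
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @param keep_trajectories Keep the full frequency trajectories of the
#'   retained replicates.
#' @param max_attempts Abort (with an acceptance-rate diagnostic) if the
#'   filter accepts fewer than 0.1% of this many attempted replicates.
#'
#' @return An object of class `sim_result`: `counts` (`n_rep` x times),
#'   `sizes`, `times`, `freqs` (population frequencies at the sampling
#'   times), `trajectories` (optional), `n_attempted`, `seed`.
#' @export
simulate_samples <- function(n_rep, sample_times, sample_sizes, pop, sched,
                             init = init_uniform(),
                             filters = sim_filters(), seed = NULL,
                             keep_trajectories = FALSE,
                             max_attempts = 1e6) {
  stopifnot(n_rep >= 1, n_rep == round(n_rep))
  stopifnot(!is.unsorted(sample_times),
            all(sample_times == round(sample_times)))
  if (sample_times[1] < sched$epoch_starts[1]) {
    stop("sampling times must not precede the schedule start")
  }
  sizes <- rep_len(sample_sizes, length(sample_times))
  stopifnot(all(sizes >= 0), all(sizes == round(sizes)))
  if (!is.null(seed)) set.seed(seed)
  t_end <- max(sample_times) - sched$epoch_starts[1]
  K <- length(sample_times)

  counts <- matrix(NA_real_, 0, K)
  freqs <- matrix(NA_real_, 0, K)
  trajs <- if (keep_trajectories) matrix(NA_real_, 0, t_end + 1) else NULL
  n_attempted <- 0L
  pooled_n <- sum(sizes)
  filters_active <- filters$last_segregating_pop ||
    filters$sample_segregating || !is.null(filters$min_sample_maf)
  while (nrow(counts) < n_rep) {
    need <- as.integer(n_rep - nrow(counts))
    batch <- if (filters_active) min(max(2L * need, 100L), 100000L) else need
    x0 <- sim_init_freq(init, batch, pop)
    ps <- sim_paths(x0, sched, pop, t_end, record_times = sample_times,
                    keep_traj = keep_trajectories)
    cnt <- matrix(stats::rbinom(batch * K, rep(sizes, each = batch),
                                as.vector(ps$rec)), batch, K)
    n_attempted <- n_attempted + batch
    keep <- rep(TRUE, batch)
    if (filters$last_segregating_pop) {
      xl <- ps$rec[, K]
      keep <- keep & xl > 0 & xl < 1
    }
    pooled <- rowSums(cnt)
    if (filters$sample_segregating) {
      keep <- keep & pooled > 0 & pooled < pooled_n
    }
    if (!is.null(filters$min_sample_maf)) {
      f <- pooled / pooled_n
      keep <- keep & pmin(f, 1 - f) >= filters$min_sample_maf
    }
    counts <- rbind(counts, cnt[keep, , drop = FALSE])
    freqs <- rbind(freqs, ps$rec[keep, , drop = FALSE])
    if (keep_trajectories) {
      trajs <- rbind(trajs, ps$traj[keep, , drop = FALSE])
    }
    if (n_attempted >= max_attempts && nrow(counts) < 0.001 * n_attempted) {
      stop(sprintf(
        "filter acceptance rate %.4g%% after %d attempts; aborting",
        100 * nrow(counts) / n_attempted, n_attempted))
    }
  }
  keep_n <- seq_len(n_rep)
  structure(list(counts = counts[keep_n, , drop = FALSE],
                 freqs = freqs[keep_n, , drop = FALSE],
                 sizes = sizes, times = sample_times,
                 trajectories = if (keep_trajectories) {
                   trajs[keep_n, , drop = FALSE]
                 },
                 n_attempted = n_attempted, seed = seed,
                 filters = filters, pop = pop, sched = sched),
            class = "sim_result")
}

#' Convert simulated replicates to a list of temporal samples
#'
#' @param sim A [simulate_samples()] result.
#' @param prefix Locus-ID prefix for the replicates.
#'
#' @return A list of [temporal_samples()], one per retained replicate.
#' @export
as_temporal_samples <- function(sim, prefix = "rep") {
  stopifnot(inherits(sim, "sim_result"))
  lapply(seq_len(nrow(sim$counts)), function(i) {
    temporal_samples(sim$times, sim$sizes, sim$counts[i, ],
                     id = paste0(prefix, i))
  })
}

#' Plot simulated frequency trajectories
#'
#' Population frequency against generation for a subset of replicates, with
#' the sample frequencies overlaid as points.
#'
#' @param sim A [simulate_samples()] result with `keep_trajectories = TRUE`.
#' @param reps Indices of replicates to draw (default up to 10).
#' @param file Optional PNG path; `NULL` draws on the current device.
#' @return Invisibly, `NULL`.
#' @export
plot_trajectories <- function(sim, reps = NULL, file = NULL) {
  stopifnot(inherits(sim, "sim_result"))
  if (is.null(sim$trajectories)) {
    stop("simulate with keep_trajectories = TRUE to plot trajectories")
  }
  if (is.null(reps)) reps <- seq_len(min(10L, nrow(sim$trajectories)))
  if (!is.null(file)) grDevices::png(file, width = 900, height = 500)
  gen <- sim$sched$epoch_starts[1] + 0:(ncol(sim$trajectories) - 1)
  graphics::matplot(gen, t(sim$trajectories[reps, , drop = FALSE]),
                    type = "l", lty = 1, ylim = c(0, 1),
                    xlab = "generation", ylab = "allele frequency")
  sf <- sim$counts[reps, , drop = FALSE] /
    matrix(sim$sizes, length(reps), length(sim$sizes), byrow = TRUE)
  graphics::matpoints(sim$times, t(sf), pch = 1)
  if (!is.null(file)) grDevices::dev.off()
  invisible(NULL)
}
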