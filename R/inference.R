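#' Selection-parameter grids
#'
#' Ordered grids of selection-coefficient values for likelihood scans.
#' Linear grids are evenly spaced and inclusive of both bounds.  Geometric
#' grids are log-spaced in magnitude between `mag[1]` and `mag[2]` within
#' each sign limb; with `signs = "both"` the positive limb is mirrored to
#' negative values, and 0 must then be inserted explicitly with
#' `include_zero` (a geometric grid cannot otherwise span a sign change).
#'
#' @param kind `"linear"` or `"geometric"`.
#' @param bounds Length-2 numeric bounds for a linear grid.
#' @param n Number of points of a linear grid (>= 1).
#' @param mag Length-2 positive magnitudes (smallest, largest) for a
#'   geometric grid.
#' @param n_per_limb Points per sign limb of a geometric grid.
#' @param signs `"both"`, `"pos"` or `"neg"`.
#' @param include_zero Insert 0 exactly once (geometric grids; linear grids
#'   contain 0 only if the spacing does).
#'
#' @return Increasing numeric vector of grid values.
#' @examples
#' make_grid("linear", bounds = c(-0.1, 0.1), n = 101)
#' make_grid("geometric", mag = c(1e-4, 1e-1), n_per_limb = 4)
#' @export
make_grid <- function(kind = c("linear", "geometric"),
                      bounds = NULL, n = NULL,
                      mag = NULL, n_per_limb = NULL,
                      signs = c("both", "pos", "neg"),
                      include_zero = TRUE) {
  kind <- match.arg(kind)
  if (kind == "linear") {
    stopifnot(length(bounds) == 2L, all(is.finite(bounds)),
              bounds[1] <= bounds[2], n >= 1)
    if (n == 1) {
      if (bounds[1] != bounds[2]) {
        stop("a 1-point linear grid needs equal bounds")
      }
      return(bounds[1])
    }
    return(seq(bounds[1], bounds[2], length.out = n))
  }
  signs <- match.arg(signs)
  stopifnot(length(mag) == 2L, all(mag > 0), mag[1] <= mag[2],
            n_per_limb >= 1)
  limb <- exp(seq(log(mag[1]), log(mag[2]), length.out = n_per_limb))
  g <- switch(signs, pos = limb, neg = -rev(limb),
              both = c(-rev(limb), limb))
  if (signs == "both" && !include_zero) {
    stop("a geometric grid spanning both signs requires include_zero = TRUE")
  }
  if (include_zero) g <- sort(unique(c(g, 0)))
  g
}

# internal: one-epoch constant-selection scan over precomputed emissions
scan_engine <- function(emis, times, fits, pop, init, grid) {
  cache <- new.env(parent = emptyenv())
  init_vec <- initial_distribution(init, grid, pop)
  vapply(fits, function(fit) {
    sched <- constant_schedule(fit, start = times[1])
    mats <- interval_matrices(times, sched, pop, grid, cache = cache)
    forward_engine(init_vec, emis, mats)
  }, numeric(nrow(emis[[1]])))
}

# stack a locus list into shared times + count/size matrices
stack_loci <- function(loci) {
  ok <- vapply(loci, inherits, logical(1L), what = "temporal_samples")
  if (!all(ok)) stop("loci must be a list of temporal_samples")
  times <- loci[[1]]$times
  same <- vapply(loci, function(l) {
    length(l$times) == length(times) && all(l$times == times)
  }, logical(1L))
  if (!all(same)) stop("all loci must share the same sampling times")
  ids <- vapply(seq_along(loci), function(i) {
    if (is.null(loci[[i]]$id)) paste0("locus", i) else loci[[i]]$id
  }, character(1L))
  list(times = times,
       counts = do.call(rbind, lapply(loci, `[[`, "counts")),
       sizes = do.call(rbind, lapply(loci, `[[`, "sizes")),
       ids = ids)
}

#' 1D likelihood scan over a selection-coefficient grid
#'
#' Per-locus log-likelihoods over a grid of `sAA = s` values at fixed
#' dominance `h` (so `sAa = h * s`), under constant selection from the first
#' sampling time.  Emissions are computed once and transition matrices once
#' per grid value, shared across loci.
#'
#' @param loci List of [temporal_samples()] sharing sampling times.
#' @param s_grid Numeric grid of selection coefficients (see [make_grid()]).
#' @param h Dominance coefficient.
#' @param pop A [pop_params()].
#' @param init An [init_cond()][init_fixed].
#' @param grid A [freq_grid()]; `NULL` (default) uses [default_grid()].
#'
#' @return An object of class `lik_surface_1d`: list with `s` (grid), `h`,
#'   `loglik` (loci x grid matrix), `neutral` (per-locus log-likelihood at
#'   `s = 0`), `ids`.
#' @export
scan_s <- function(loci, s_grid, h = 0.5, pop, init, grid = NULL) {
  if (is.null(grid)) grid <- default_grid(pop)
  stopifnot(is.numeric(s_grid), length(s_grid) >= 1L, !is.unsorted(s_grid))
  st <- stack_loci(loci)
  pts <- grid$points
  emis <- lapply(seq_along(st$times), function(k) {
    emission_matrix(st$counts[, k], st$sizes[, k], pts)
  })
  fits <- lapply(s_grid, fitness_from_sh, h = h)
  ll <- scan_engine(emis, st$times, fits, pop, init, grid)
  ll <- matrix(ll, nrow = nrow(st$counts))
  j0 <- which(s_grid == 0)
  neutral <- if (length(j0)) ll[, j0[1]] else {
    drop(scan_engine(emis, st$times, list(fitness(0, 0)), pop, init, grid))
  }
  structure(list(s = s_grid, h = h, loglik = ll, neutral = neutral,
                 ids = st$ids, pop = pop, init = init),
            class = "lik_surface_1d")
}

#' 2D likelihood scan over general diploid selection coefficients
#'
#' Per-locus log-likelihood surface over the outer product of an `sAa` grid
#' and an `sAA` grid.  On the diagonal `sAa = sAA` this agrees with
#' [scan_s()] at `h = 1`, and along `sAa = h * sAA` with any fixed-`h` scan.
#' Only on-grid maxima are reported for 2D surfaces.
#'
#' @param loci List of [temporal_samples()] sharing sampling times.
#' @param sAa_grid,sAA_grid Numeric grids for the two coefficients.
#' @inheritParams scan_s
#'
#' @return An object of class `lik_surface_2d`: list with `sAa`, `sAA`,
#'   `loglik` (array loci x sAa x sAA), `neutral`, `ids`.
#' @export
scan_2d <- function(loci, sAa_grid, sAA_grid, pop, init, grid = NULL) {
  if (is.null(grid)) grid <- default_grid(pop)
  st <- stack_loci(loci)
  pts <- grid$points
  emis <- lapply(seq_along(st$times), function(k) {
    emission_matrix(st$counts[, k], st$sizes[, k], pts)
  })
  combos <- expand.grid(sAa = sAa_grid, sAA = sAA_grid)
  fits <- lapply(seq_len(nrow(combos)), function(r) {
    fitness(combos$sAa[r], combos$sAA[r])
  })
  ll <- scan_engine(emis, st$times, fits, pop, init, grid)
  L <- nrow(st$counts)
  arr <- array(ll, dim = c(L, length(sAa_grid), length(sAA_grid)))
  neutral <- drop(scan_engine(emis, st$times, list(fitness(0, 0)),
                              pop, init, grid))
  structure(list(sAa = sAa_grid, sAA = sAA_grid, loglik = arr,
                 neutral = neutral, ids = st$ids, pop = pop, init = init),
            class = "lik_surface_2d")
}

#' Maximum-likelihood estimate from a 1D likelihood surface
#'
#' On-grid MLE is the argmax grid node (ties broken toward the smallest
#' `|s|`, then toward the negative value).  The off-grid MLE maximizes a
#' cubic-spline interpolant of the surface, clamped to the grid range; when
#' the argmax sits on a boundary node, or with fewer than 3 grid points, the
#' off-grid MLE equals the on-grid one.  The reported maximum is never below
#' the on-grid maximum.  The likelihood-ratio statistic against neutrality
#' and its chi-squared(1 df) p-value are included.
#'
#' @param surface A `lik_surface_1d` from [scan_s()].
#' @param locus Locus index (row of the surface).
#'
#' @return A list of class `mle_result`: `s_ongrid`, `s_offgrid`,
#'   `loglik_max`, `loglik_neutral`, `lrt`, `p_value`, `boundary` (logical),
#'   `few_points` (logical warning flag).
#' @seealso [mle_table()] for all loci at once.
#' @export
interpolate_mle <- function(surface, locus = 1L) {
  stopifnot(inherits(surface, "lik_surface_1d"))
  s <- surface$s
  ll <- surface$loglik[locus, ]
  stopifnot(all(is.finite(ll)))
  m <- max(ll)
  cand <- which(ll == m)
  # |s| compared at 12 significant digits so grid values that are equal in
  # magnitude up to floating-point noise count as ties
  j <- cand[order(signif(abs(s[cand]), 12), s[cand])][1]
  few <- length(s) < 3L
  bnd <- j == 1L || j == length(s)
  if (few || bnd) {
    s_off <- s[j]
    ll_off <- ll[j]
    if (few) warning("fewer than 3 grid points; off-grid MLE is on-grid")
  } else {
    f <- stats::splinefun(s, ll, method = "fmm")
    opt <- stats::optimize(f, lower = s[j - 1L], upper = s[j + 1L],
                           maximum = TRUE, tol = 1e-12)
    if (opt$objective >= ll[j]) {
      s_off <- min(max(opt$maximum, s[1]), s[length(s)])
      ll_off <- opt$objective
    } else {
      s_off <- s[j]
      ll_off <- ll[j]
    }
  }
  lp <- lrt_pvalue(ll_off, surface$neutral[locus])
  structure(list(s_ongrid = s[j], s_offgrid = s_off, loglik_max = ll_off,
                 loglik_neutral = surface$neutral[locus],
                 lrt = lp$statistic, p_value = lp$p,
                 boundary = bnd, few_points = few),
            class = "mle_result")
}

#' Per-locus MLE table from a 1D likelihood scan
#'
#' Applies [interpolate_mle()] to every locus of a surface.
#'
#' @param surface A `lik_surface_1d` from [scan_s()].
#'
#' @return A data.frame with columns `ID`, `s_ongrid`, `s_offgrid`,
#'   `loglik_max`, `loglik_neutral`, `lrt`, `p_value`.
#' @export
mle_table <- function(surface) {
  rows <- lapply(seq_along(surface$ids), function(i) {
    r <- interpolate_mle(surface, i)
    data.frame(ID = surface$ids[i], s_ongrid = r$s_ongrid,
               s_offgrid = r$s_offgrid, loglik_max = r$loglik_max,
               loglik_neutral = r$loglik_neutral, lrt = r$lrt,
               p_value = r$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Likelihood-ratio statistic and chi-squared p-value
#'
#' The statistic is `max(0, 2 * (max_loglik - neutral_loglik))` (floored at
#' 0, since interpolation can yield values a hair below the neutral value),
#' compared to a chi-squared distribution with 1 degree of freedom --
#' appropriate for a scan with one free selection parameter.
#'
#' @param max_loglik Maximized log-likelihood (vectorized).
#' @param neutral_loglik Log-likelihood at `sAa = sAA = 0`.
#'
#' @return List with `statistic` and `p`.
#' @export
lrt_pvalue <- function(max_loglik, neutral_loglik) {
  stat <- pmax(0, 2 * (max_loglik - neutral_loglik))
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Estimate the onset time of selection
#'
#' Evaluates the log-likelihood on a grid of candidate onset generations
#' crossed with a grid of selection coefficients, under two-epoch schedules
#' that are neutral before the onset and have fitness `(h s, s)` after.  The
#' onset estimate is the onset coordinate of the joint argmax (a marginal
#' point estimate, no profiling); ties are broken toward the smaller `|s|`,
#' then the earlier onset.
#'
#' @param loci List of [temporal_samples()] sharing sampling times.
#' @param onset_grid Candidate onset generations (within the observation
#'   window).
#' @param s_grid Selection-coefficient grid for the post-onset epoch.
#' @inheritParams scan_s
#'
#' @return List with `t0_hat` and `s_hat` (per-locus vectors), `loglik`
#'   (array loci x onset x s), `onset_grid`, `s_grid`.
#' @export
estimate_onset <- function(loci, onset_grid, s_grid, h = 0.5, pop, init,
                           grid = NULL) {
  if (is.null(grid)) grid <- default_grid(pop)
  st <- stack_loci(loci)
  stopifnot(all(onset_grid >= st$times[1]))
  pts <- grid$points
  emis <- lapply(seq_along(st$times), function(k) {
    emission_matrix(st$counts[, k], st$sizes[, k], pts)
  })
  cache <- new.env(parent = emptyenv())
  init_vec <- initial_distribution(init, grid, pop)
  L <- nrow(st$counts)
  arr <- array(NA_real_,
               dim = c(L, length(onset_grid), length(s_grid)))
  for (a in seq_along(onset_grid)) {
    for (b in seq_along(s_grid)) {
      sched <- onset_schedule(fitness_from_sh(s_grid[b], h),
                              t0 = onset_grid[a], start = st$times[1])
      mats <- interval_matrices(st$times, sched, pop, grid, cache = cache)
      arr[, a, b] <- forward_engine(init_vec, emis, mats)
    }
  }
  t0_hat <- numeric(L)
  s_hat <- numeric(L)
  for (i in seq_len(L)) {
    sl <- arr[i, , , drop = TRUE]
    sl <- matrix(sl, length(onset_grid), length(s_grid))
    m <- max(sl)
    idx <- which(sl == m, arr.ind = TRUE)
    o <- order(abs(s_grid[idx[, 2]]), s_grid[idx[, 2]],
               onset_grid[idx[, 1]])
    t0_hat[i] <- onset_grid[idx[o[1], 1]]
    s_hat[i] <- s_grid[idx[o[1], 2]]
  }
  list(t0_hat = t0_hat, s_hat = s_hat, loglik = arr,
       onset_grid = onset_grid, s_grid = s_grid, ids = st$ids)
}

#' Combine p-values across replicates with Fisher's method
#'
#' For k independent p-values, `-2 * sum(log(p))` follows a chi-squared
#' distribution with `2k` degrees of freedom under the global null; the
#' combined p-value is its upper tail.  Zero p-values are floored at 1e-300
#' with a warning.
#'
#' @param p Numeric vector of p-values in `(0, 1]`.
#'
#' @return The combined p-value.
#' @examples
#' fisher_combine(c(0.05, 0.05))  # ~0.0175
#' @export
fisher_combine <- function(p) {
  stopifnot(is.numeric(p), length(p) >= 1L, all(p >= 0), all(p <= 1))
  if (any(p == 0)) {
    warning("p-values of 0 floored at 1e-300")
    p[p == 0] <- 1e-300
  }
  stat <- -2 * sum(log(p))
  stats::pchisq(stat, df = 2 * length(p), lower.tail = FALSE)
}
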