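#' Population parameters for the Wright-Fisher model
#'
#' Bundles the fixed parameters of the single-locus Wright-Fisher model: the
#' diploid effective population size and the two per-generation recurrent
#' mutation rates.
#'
#' @param Ne Diploid effective population size (individuals, > 0).
#' @param u01 Per-generation mutation probability from allele `a` to the focal
#'   allele `A` (in `[0, 1)`).
#' @param u10 Per-generation mutation probability from `A` back to `a`
#'   (in `[0, 1)`).
#'
#' @return An object of class `pop_params`.
#' @examples
#' pop_params(Ne = 1e4, u01 = 1e-6, u10 = 1e-6)
#' @export
pop_params <- function(Ne, u01 = 0, u10 = 0) {
  stopifnot(is.numeric(Ne), length(Ne) == 1L, is.finite(Ne), Ne > 0)
  stopifnot(is.numeric(u01), length(u01) == 1L, u01 >= 0, u01 < 1)
  stopifnot(is.numeric(u10), length(u10) == 1L, u10 >= 0, u10 < 1)
  if (u01 + u10 >= 1) {
    stop("mutation rates must satisfy u01 + u10 < 1")
  }
  structure(list(Ne = Ne, u01 = u01, u10 = u10), class = "pop_params")
}

#' General diploid fitness
#'
#' Relative fitnesses of the three genotypes at a biallelic locus with focal
#' (derived) allele `A`: genotype `aa` has fitness 1, `aA` has `1 + sAa`, and
#' `AA` has `1 + sAA`.  The two selection coefficients are free parameters
#' ("general diploid selection"); see [fitness_from_sh()] for the
#' selection-plus-dominance parametrization.
#'
#' @param sAa Relative fitness advantage of the heterozygote (dimensionless;
#'   `1 + sAa` must be positive).
#' @param sAA Relative fitness advantage of the `AA` homozygote (`1 + sAA`
#'   must be positive).
#'
#' @return An object of class `diploid_fitness`.
#' @examples
#' fitness(sAa = 0.02, sAA = 0.05)
#' @export
fitness <- function(sAa = 0, sAA = 0) {
  stopifnot(is.numeric(sAa), length(sAa) == 1L, is.finite(sAa))
  stopifnot(is.numeric(sAA), length(sAA) == 1L, is.finite(sAA))
  if (1 + sAa <= 0 || 1 + sAA <= 0) {
    stop("fitnesses must be positive: require 1 + sAa > 0 and 1 + sAA > 0")
  }
  structure(list(sAa = sAa, sAA = sAA), class = "diploid_fitness")
}

#' Diploid fitness from selection and dominance coefficients
#'
#' The common one-parameter families are obtained by setting `sAa = h * s`
#' and `sAA = s`: `h = 0.5` is additive (semidominant) selection, `h = 1`
#' full dominance of `A`, `h = 0` full recessivity.
#'
#' @param s Selection coefficient of the `AA` homozygote.
#' @param h Dominance coefficient scaling the heterozygote advantage.
#'
#' @return A `diploid_fitness` with `sAa = h * s`, `sAA = s`.
#' @examples
#' fitness_from_sh(s = 0.1, h = 0.5)  # sAa = 0.05, sAA = 0.1
#' @export
fitness_from_sh <- function(s, h = 0.5) {
  stopifnot(is.numeric(s), length(s) == 1L, is.finite(s))
  stopifnot(is.numeric(h), length(h) == 1L, is.finite(h))
  fitness(sAa = h * s, sAA = s)
}

#' Piece-wise constant selection schedule
#'
#' Selection coefficients may change over time in a piece-wise constant
#' manner.  Epoch `e` spans generations `[epoch_starts[e], epoch_starts[e+1])`
#' (the last epoch is unbounded); the step from generation `g` to `g + 1`
#' uses the fitness of the epoch containing `g`.  The first entry of
#' `epoch_starts` is the analysis start.
#'
#' @param epoch_starts Strictly increasing generation times (integers); the
#'   first entry is the analysis start.
#' @param epoch_fitness A list of [fitness()] objects, one per epoch, or a
#'   single `diploid_fitness` when there is one epoch.
#'
#' @return An object of class `sel_schedule`.
#' @seealso [constant_schedule()], [onset_schedule()]
#' @examples
#' sel_schedule(c(0, 2000), list(fitness(0, 0), fitness_from_sh(0.01)))
#' @export
sel_schedule <- function(epoch_starts, epoch_fitness) {
  if (inherits(epoch_fitness, "diploid_fitness")) {
    epoch_fitness <- list(epoch_fitness)
  }
  stopifnot(is.numeric(epoch_starts), length(epoch_starts) >= 1L,
            all(is.finite(epoch_starts)))
  if (any(epoch_starts != round(epoch_starts))) {
    stop("epoch_starts must be integer generations")
  }
  if (any(diff(epoch_starts) <= 0)) {
    stop("epoch_starts must be strictly increasing")
  }
  if (length(epoch_starts) != length(epoch_fitness)) {
    stop("need exactly one fitness per epoch")
  }
  ok <- vapply(epoch_fitness, inherits, logical(1L), what = "diploid_fitness")
  if (!all(ok)) stop("epoch_fitness must be a list of diploid_fitness objects")
  structure(list(epoch_starts = as.numeric(epoch_starts),
                 epoch_fitness = epoch_fitness),
            class = "sel_schedule")
}

#' @rdname sel_schedule
#' @param fit A single [fitness()] applying over the whole analysis window.
#' @param start Analysis start, in generations.
#' @export
constant_schedule <- function(fit = fitness(0, 0), start = 0) {
  sel_schedule(start, list(fit))
}

#' @rdname sel_schedule
#' @param t0 Onset generation: neutrality before `t0`, fitness `fit` from
#'   `t0` onward.  `t0 == start` gives constant selection.
#' @export
onset_schedule <- function(fit, t0, start = 0) {
  if (t0 <= start) {
    constant_schedule(fit, start = start)
  } else {
    sel_schedule(c(start, t0), list(fitness(0, 0), fit))
  }
}

# epoch index covering generation g (vectorized over g)
epoch_index <- function(sched, g) {
  i <- findInterval(g, sched$epoch_starts)
  if (any(i < 1L)) stop("generation before the analysis start")
  i
}

#' One generation of deterministic selection and mutation
#'
#' The deterministic (infinite-population) allele-frequency map applied once
#' per generation: viability selection
#' `x_sel = (x^2 (1+sAA) + x (1-x) (1+sAa)) /
#'          (x^2 (1+sAA) + 2 x (1-x) (1+sAa) + (1-x)^2)`
#' followed by recurrent mutation
#' `x' = x_sel (1 - u10) + (1 - x_sel) u01`.
#'
#' @param x Frequency (or vector of frequencies) of the focal allele in
#'   `[0, 1]`.
#' @param fit A [fitness()] object.
#' @param pop A [pop_params()] object.
#'
#' @return The frequency (vector) after one generation, in `[0, 1]`.
#' @examples
#' wf_det_step(0.5, fitness(0.05, 0.1), pop_params(1e4))  # 0.511905
#' @export
wf_det_step <- function(x, fit, pop) {
  stopifnot(all(x >= 0 & x <= 1))
  if (fit$sAa == 0 && fit$sAA == 0) {
    xs <- x  # neutral selection is the exact identity
  } else {
    w1 <- 1 + fit$sAa
    w2 <- 1 + fit$sAA
    num <- x * x * w2 + x * (1 - x) * w1
    den <- x * x * w2 + 2 * x * (1 - x) * w1 + (1 - x)^2
    xs <- num / den
  }
  xp <- pop$u01 + xs * (1 - pop$u01 - pop$u10)
  pmin(pmax(xp, 0), 1)
}

# d/dx of wf_det_step; used by the Gaussian variance propagation
wf_det_step_deriv <- function(x, fit, pop) {
  if (fit$sAa == 0 && fit$sAA == 0) {
    return(rep(1 - pop$u01 - pop$u10, length(x)))
  }
  w1 <- 1 + fit$sAa
  w2 <- 1 + fit$sAA
  num <- x * x * w2 + x * (1 - x) * w1
  den <- x * x * w2 + 2 * x * (1 - x) * w1 + (1 - x)^2
  dnum <- 2 * x * w2 + (1 - 2 * x) * w1
  dden <- 2 * x * w2 + 2 * (1 - 2 * x) * w1 - 2 * (1 - x)
  ((dnum * den - num * dden) / den^2) * (1 - pop$u01 - pop$u10)
}

#' Deterministic allele-frequency trajectory
#'
#' Iterates [wf_det_step()] from the analysis start for `t_end` generations,
#' switching fitness at the epoch boundaries of `sched`.
#'
#' @param x0 Starting frequency at the analysis start.
#' @param sched A [sel_schedule()].
#' @param pop A [pop_params()].
#' @param t_end Number of generations to iterate (non-negative integer).
#'
#' @return Numeric vector of length `t_end + 1`; element 1 is `x0`, element
#'   `g + 1` the frequency at generation `start + g`.
#' @export
wf_det_trajectory <- function(x0, sched, pop, t_end) {
  stopifnot(t_end >= 0, t_end == round(t_end))
  out <- numeric(t_end + 1)
  out[1] <- x0
  if (t_end == 0) return(out)
  g0 <- sched$epoch_starts[1]
  x <- x0
  for (g in seq_len(t_end)) {
    e <- epoch_index(sched, g0 + g - 1)
    x <- wf_det_step(x, sched$epoch_fitness[[e]], pop)
    out[g + 1] <- x
  }
  out
}
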