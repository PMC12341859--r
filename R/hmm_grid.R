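#' Discretized allele-frequency grid
#'
#' The hidden state space of the HMM: an ordered set of frequencies in
#' `[0, 1]` including dedicated boundary states at exactly 0 and 1, together
#' with the midpoint-defined integration cells that tile `[0, 1]`.  The
#' interior points are uniformly spaced; `refine` optionally inserts
#' geometrically spaced extra points near each boundary (successively halving
#' the first/last interior spacing), which sharpens the resolution of
#' near-boundary dynamics at small `Ne * s`.
#'
#' @param n_interior Number of uniformly spaced interior points (>= 3).
#' @param refine Number of geometric refinement points to add near each
#'   boundary (0 = plain uniform grid).
#'
#' @return An object of class `freq_grid` with elements `points` (length
#'   `n_interior + 2` for `refine = 0`) and `edges` (cell boundaries,
#'   one more than `points`).
#' @examples
#' freq_grid(3)$points  # 0.00 0.25 0.50 0.75 1.00
#' @export
freq_grid <- function(n_interior = 500, refine = 0) {
  stopifnot(n_interior >= 3, n_interior == round(n_interior),
            refine >= 0, refine == round(refine))
  pts <- seq(0, 1, length.out = n_interior + 2)
  if (refine > 0) {
    d <- pts[2] - pts[1]
    extra <- d / 2^seq_len(refine)
    pts <- sort(unique(c(pts, extra, 1 - extra)))
  }
  edges <- c(0, (pts[-1] + pts[-length(pts)]) / 2, 1)
  structure(list(points = pts, edges = edges), class = "freq_grid")
}

#' Default frequency grid for a given population size
#'
#' For large populations this is the uniform [freq_grid()] with
#' `n_interior` points.  For small populations, where the true state space
#' (the `2 Ne + 1` population allele counts) is coarser than that grid, the
#' grid is instead aligned to the population lattice `i / (2 Ne)`: the
#' midpoint cells then coincide with the continuity-corrected integration
#' ranges of the count states, which removes aliasing between the Gaussian
#' kernels and the underlying lattice and measurably tightens agreement
#' with the exact discrete chain.
#'
#' @param pop A [pop_params()].
#' @param n_interior Interior points of the uniform grid used for large
#'   populations.
#'
#' @return A `freq_grid`.
#' @export
default_grid <- function(pop, n_interior = 500) {
  N2 <- round(2 * pop$Ne)
  if (N2 + 1 <= n_interior + 2 && abs(N2 - 2 * pop$Ne) < 1e-9) {
    pts <- 0:N2 / N2
    structure(list(points = pts,
                   edges = c(0, (pts[-1] + pts[-length(pts)]) / 2, 1)),
              class = "freq_grid")
  } else {
    freq_grid(n_interior)
  }
}

#' Initial conditions for the allele-frequency distribution
#'
#' The distribution of the population allele frequency at the first sampling
#' time.  Four kinds are supported:
#' * `init_fixed(x0)`: frequency known to be `x0`; on the grid, mass is split
#'   linearly between the two neighbouring grid points (all on one point when
#'   `x0` is itself a grid point).
#' * `init_uniform()`: uniform density on `[0, 1]` (mass proportional to
#'   cell width).
#' * `init_beta()`: the stationary density of the Wright-Fisher diffusion
#'   with recurrent mutation, `Beta(4 Ne u01, 4 Ne u10)`; requires both
#'   mutation rates positive.
#' * `init_explicit(weights)`: an arbitrary probability vector over the grid
#'   points.
#'
#' @param x0 Fixed initial frequency in `[0, 1]`.
#' @param weights Non-negative vector over grid points; must sum to 1 within
#'   `1e-9` (renormalized exactly).
#'
#' @return An object of class `init_cond`.
#' @seealso [initial_distribution()]
#' @export
init_fixed <- function(x0) {
  stopifnot(is.numeric(x0), length(x0) == 1L, x0 >= 0, x0 <= 1)
  structure(list(kind = "fixed", x0 = x0), class = "init_cond")
}

#' @rdname init_fixed
#' @export
init_uniform <- function() {
  structure(list(kind = "uniform"), class = "init_cond")
}

#' @rdname init_fixed
#' @export
init_beta <- function() {
  structure(list(kind = "beta"), class = "init_cond")
}

#' @rdname init_fixed
#' @export
init_explicit <- function(weights) {
  stopifnot(is.numeric(weights), all(weights >= 0))
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("explicit initial weights must sum to 1 (within 1e-9)")
  }
  structure(list(kind = "explicit", weights = weights), class = "init_cond")
}

#' Initial probability vector over a frequency grid
#'
#' Realizes an [init_cond()][init_fixed] as a probability vector over the
#' points of a [freq_grid()].
#'
#' @param init An `init_cond`.
#' @param grid A `freq_grid`.
#' @param pop A [pop_params()]; needed for the stationary-beta kind.
#'
#' @return Numeric vector over `grid$points`, summing to 1.
#' @export
initial_distribution <- function(init, grid, pop = NULL) {
  stopifnot(inherits(init, "init_cond"), inherits(grid, "freq_grid"))
  pts <- grid$points
  K <- length(pts)
  w <- switch(init$kind,
    fixed = {
      v <- numeric(K)
      j <- findInterval(init$x0, pts, rightmost.closed = TRUE)
      if (pts[j] == init$x0 || j == K) {
        v[j] <- 1
      } else {
        a <- (init$x0 - pts[j]) / (pts[j + 1] - pts[j])
        v[j] <- 1 - a
        v[j + 1] <- a
      }
      v
    },
    uniform = diff(grid$edges),
    beta = {
      if (is.null(pop)) stop("stationary-beta initial condition needs pop")
      a <- 4 * pop$Ne * pop$u01
      b <- 4 * pop$Ne * pop$u10
      if (a <= 0 || b <= 0) {
        stop("stationary-beta initial condition requires u01 > 0 and u10 > 0")
      }
      diff(stats::pbeta(grid$edges, a, b))
    },
    explicit = {
      if (length(init$weights) != K) {
        stop("explicit weights must match the grid size")
      }
      init$weights
    },
    stop("unknown initial condition kind")
  )
  w / sum(w)
}
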