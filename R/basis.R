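#' Gaussian basis set on a regular grid over the state space
#'
#' Builds a distributed population code for continuous tasks: one Gaussian
#' receptive field per grid point and per action, with width matched to the
#' grid spacing via `sigma = spacing / 2`. Each neuron `i` represents the
#' non-negative basis function `psi_i(s, a) = g_i(s) * 1[a = a_i]` in the
#' joint state-action space, where `g_i` is a (peak-normalized) Gaussian
#' centered on the neuron's grid point. Periodic dimensions (e.g. an angle)
#' use wrapped distances and image sums for overlaps.
#'
#' @param state_ranges list of `c(lower, upper)` per state dimension.
#' @param spacing grid spacing, recycled per dimension.
#' @param actions character vector of action labels.
#' @param periodic logical per dimension; a periodic dimension covers
#'   `(lower, upper]` with period `upper - lower`.
#' @return an object of class `basis_set` with fields `centers`
#'   (`n_cells x d`), `sigma`, `actions`, `cell` and `action` (per-neuron
#'   coding), `mass` (`integral of g_i`), and `volume` of the covered region.
#' @export
make_basis_grid <- function(state_ranges, spacing, actions,
                            periodic = rep(FALSE, length(state_ranges))) {
  stopifnot(all(spacing > 0), length(actions) >= 1)
  d <- length(state_ranges)
  spacing <- rep(spacing, length.out = d)
  grids <- vector("list", d)
  for (k in seq_len(d)) {
    lo <- state_ranges[[k]][1]; hi <- state_ranges[[k]][2]
    grids[[k]] <- if (periodic[k]) seq(lo + spacing[k], hi, by = spacing[k])
                  else seq(lo, hi, by = spacing[k])
  }
  centers <- as.matrix(expand.grid(grids))
  colnames(centers) <- NULL
  sigma <- spacing / 2
  n_cells <- nrow(centers)
  n_act <- length(actions)
  lower <- vapply(state_ranges, `[`, numeric(1), 1)
  upper <- vapply(state_ranges, `[`, numeric(1), 2)
  structure(list(
    type = "gaussian_grid",
    centers = centers, sigma = sigma,
    lower = lower, upper = upper, periodic = periodic,
    period = upper - lower,
    actions = actions,
    n_cells = n_cells,
    n_neurons = n_cells * n_act,
    cell = rep(seq_len(n_cells), times = n_act),
    action = rep(actions, each = n_cells),
    mass = prod(sigma * sqrt(2 * pi)),
    volume = prod(upper - lower)
  ), class = "basis_set")
}

#' Indicator basis over the state-action pairs of a finite MDP
#'
#' The degenerate basis `psi_i(s, a) = 1[s = s_i] * 1[a = a_i]`, under which
#' the function-approximation network and plasticity rules reduce exactly to
#' their tabular counterparts.
#'
#' @param m an `mdp` object.
#' @return a `basis_set` of type `"indicator"` (one cell per state; the
#'   per-neuron coding lists one neuron per state-action pair of `m`).
#' @export
indicator_basis <- function(m) {
  keep <- !(m$sa$state %in% m$terminal)  # networks carry no terminal neurons
  states <- setdiff(m$states, m$terminal)
  acts <- unique(m$sa$action[keep])
  structure(list(
    type = "indicator",
    states = states,
    mdp = m,
    actions = acts,
    n_cells = length(states),
    n_neurons = sum(keep),
    cell = match(m$sa$state[keep], states),
    action = m$sa$action[keep],
    mass = 1,
    volume = length(states)
  ), class = "basis_set")
}

#' @export
print.basis_set <- function(x, ...) {
  cat("<basis_set:", x$type, ">", x$n_cells, "cells x", length(x$actions),
      "actions =", x$n_neurons, "neurons\n")
  invisible(x)
}

# Wrapped (circular) difference for periodic dimensions.
wrap_diff <- function(delta, period) {
  delta - period * round(delta / period)
}

#' Evaluate the spatial parts of all basis cells at a set of states
#'
#' @param basis a `basis_set`.
#' @param states numeric matrix (rows = states) for Gaussian bases, or a
#'   character vector of state identifiers for indicator bases.
#' @return matrix `n_points x n_cells` of `g_i(s)` values.
#' @export
basis_cells_eval <- function(basis, states) {
  if (basis$type == "indicator") {
    out <- matrix(0, length(states), basis$n_cells)
    out[cbind(seq_along(states), match(states, basis$states))] <- 1
    return(out)
  }
  if (!is.matrix(states)) states <- matrix(states, nrow = 1)
  d <- ncol(basis$centers)
  expo <- matrix(0, nrow(states), basis$n_cells)
  for (k in seq_len(d)) {
    delta <- outer(states[, k], basis$centers[, k], "-")
    if (basis$periodic[k]) delta <- wrap_diff(delta, basis$period[k])
    expo <- expo + delta^2 / (2 * basis$sigma[k]^2)
  }
  exp(-expo)
}

#' Pairwise overlap integrals of the basis cells
#'
#' Computes `G_ij = integral of g_i(s) g_j(s) ds` in closed form. For a pair
#' of equal-width Gaussians on the real line the overlap is
#' `sigma * sqrt(pi) * exp(-(c_i - c_j)^2 / (4 sigma^2))`; the full overlap
#' is the product across dimensions. Periodic dimensions use a sum over
#' periodic images (three images suffice for `sigma << period`).
#'
#' @param basis a `basis_set`.
#' @return symmetric `n_cells x n_cells` matrix of overlaps.
#' @export
basis_overlap <- function(basis) {
  if (basis$type == "indicator") return(diag(basis$n_cells))
  d <- ncol(basis$centers)
  G <- matrix(1, basis$n_cells, basis$n_cells)
  for (k in seq_len(d)) {
    delta <- outer(basis$centers[, k], basis$centers[, k], "-")
    s <- basis$sigma[k]
    if (basis$periodic[k]) {
      per <- basis$period[k]
      gk <- 0
      for (img in -1:1)
        gk <- gk + s * sqrt(pi) * exp(-(delta + img * per)^2 / (4 * s^2))
    } else {
      gk <- s * sqrt(pi) * exp(-delta^2 / (4 * s^2))
    }
    G <- G * gk
  }
  G
}

#' Closed-form overlap of two one-dimensional Gaussian bases
#'
#' Exposed mostly so the closed form can be cross-checked against numerical
#' quadrature.
#'
#' @param c1,c2 centers.
#' @param sigma common width.
#' @return scalar overlap integral over the real line.
#' @export
gaussian_overlap_1d <- function(c1, c2, sigma) {
  sigma * sqrt(pi) * exp(-(c1 - c2)^2 / (4 * sigma^2))
}
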