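#' Unified working likelihood via Polya-Gamma augmentation
#'
#' Maps every view onto the conditionally Gaussian working form
#' \deqn{-\tfrac12 \sum \rho_{ji}(\mu_{ji}-\psi_{ji})^2 + \sum \kappa_{ji}\mu_{ji},}
#' populating the pseudo-observations \eqn{\psi}, offsets \eqn{\kappa} and
#' Polya-Gamma shapes \eqn{b} per likelihood family:
#' gaussian \eqn{\psi = x, \kappa = 0}; binomial \eqn{\psi = 0,
#' b = n_j, \kappa = x - b/2}; negative binomial \eqn{\psi = 0,
#' b = x + r_j, \kappa = x - b/2}. Deterministic.
#'
#' @param data a [bgb_multiview()] object.
#' @param zeta per-feature (or scalar) degrees-of-freedom of the
#'   Gamma(\eqn{\zeta_j/2}, \eqn{\zeta_j/2}) prior on the gaussian
#'   precisions \eqn{\rho_j}.
#' @return a list with matrices `psi`, `kappa`, `b` (p x n), the raw data
#'   `x`, the integer `type` code per feature (0 gaussian, 1 binomial,
#'   2 negative binomial) and per-feature vectors `zeta`, `trials`, `fails`.
#' @export
build_working_likelihood <- function(data, zeta = 1) {
  x <- stacked_matrix(data)
  p <- data$p; n <- data$n
  type <- match(data$likelihood,
                c("gaussian", "binomial", "negative_binomial")) - 1L
  trials <- ifelse(data$likelihood == "binomial", data$constants, 0)
  fails <- ifelse(data$likelihood == "negative_binomial", data$constants, 0)
  b <- matrix(0, p, n)
  psi <- matrix(0, p, n)
  kappa <- matrix(0, p, n)
  g <- type == 0L
  psi[g, ] <- x[g, , drop = FALSE]
  if (any(type == 1L)) {
    rows <- which(type == 1L)
    b[rows, ] <- matrix(trials[rows], length(rows), n)
    kappa[rows, ] <- x[rows, , drop = FALSE] - b[rows, , drop = FALSE] / 2
  }
  if (any(type == 2L)) {
    rows <- which(type == 2L)
    b[rows, ] <- x[rows, , drop = FALSE] + matrix(fails[rows], length(rows), n)
    kappa[rows, ] <- x[rows, , drop = FALSE] - b[rows, , drop = FALSE] / 2
  }
  # data-dependent log-likelihood constants (binomial / negative-binomial
  # combinatorial terms), computed once rather than per retained draw
  lconst <- 0
  if (any(type == 1L)) {
    rows <- which(type == 1L)
    lconst <- lconst + sum(lchoose(matrix(trials[rows], length(rows), n),
                                   x[rows, , drop = FALSE]))
  }
  if (any(type == 2L)) {
    rows <- which(type == 2L)
    xr <- x[rows, , drop = FALSE]
    lconst <- lconst + sum(lchoose(xr + fails[rows] - 1, xr))
  }
  list(psi = psi, kappa = kappa, b = b, x = x, type = type,
       zeta = rep_len(zeta, p), trials = trials, fails = fails,
       lconst = lconst)
}

#' Sample the augmentation weights rho
#'
#' Discrete rows draw \eqn{\rho_{ji} \sim PG(b_{ji}, \mu_{ji})}; gaussian
#' rows draw one per-feature precision
#' \eqn{\rho_j \sim Gamma((\zeta_j+n)/2, (\zeta_j+\sum_i(x_{ji}-\mu_{ji})^2)/2)}
#' broadcast across samples so downstream conditionals are type-agnostic.
#'
#' @param state a model state list (see [init_state()]).
#' @param wl working likelihood from [build_working_likelihood()].
#' @return the updated p x n `rho` matrix.
#' @export
sample_rho <- function(state, wl) {
  cpp_step_rho(state, wl)$rho
}
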