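#' Initialize the sampler state
#'
#' W and Z start from a rank-L truncated SVD of the row-centered working
#' data (discrete views are mapped to the linear-predictor scale by an
#' empirical logit / log transform first), m from the row means, alpha at
#' nu1, the augmented scales at 1, delta at its prior mean and Omega at a
#' pattern-compatible near-diagonal matrix. Warm-starting from the SVD
#' mixes substantially faster than a cold start; everything downstream is
#' seed-controlled.
#'
#' @param wl working likelihood list from [build_working_likelihood()].
#' @param graph a [feature_graph()] object.
#' @param hp a [bgb_hyperparameters()] object.
#' @param L number of candidate factors.
#' @return a model state list (fields `m`, `W`, `Z`, `alpha`, `tau_w_sq`,
#'   `tau_z_sq`, `delta`, `rho`, `Omega`, `Sigma`).
#' @export
init_state <- function(wl, graph, hp, L) {
  p <- nrow(wl$x); n <- ncol(wl$x)
  stopifnot(L >= 1)
  Y <- wl$x
  if (any(wl$type == 1L)) {
    rows <- which(wl$type == 1L)
    nj <- wl$trials[rows]
    Y[rows, ] <- qlogis((wl$x[rows, , drop = FALSE] + 0.5) /
                          (matrix(nj, length(rows), n) + 1))
  }
  if (any(wl$type == 2L)) {
    rows <- which(wl$type == 2L)
    Y[rows, ] <- log((wl$x[rows, , drop = FALSE] + 0.5) / wl$fails[rows])
  }
  m0 <- rowMeans(Y)
  Yc <- Y - m0
  k <- min(L, p, n)
  sv <- svd(Yc, nu = k, nv = k)
  d <- sqrt(pmax(sv$d[seq_len(k)], 0))
  W0 <- matrix(0, p, L)
  Z0 <- matrix(0, L, n)
  W0[, seq_len(k)] <- sv$u %*% diag(d, k)
  Z0[seq_len(k), ] <- diag(d, k) %*% t(sv$v)
  om <- init_omega(graph, hp$epsilon)
  list(m = m0, W = W0, Z = Z0,
       alpha = matrix(hp$nu1, p, L),
       tau_w_sq = matrix(1, p, L),
       tau_z_sq = matrix(1, L, n),
       delta = matrix(hp$nu4 / hp$nu3, L, n),
       rho = matrix(1, p, n),
       Omega = om$Omega, Sigma = om$Sigma)
}

#' Gibbs update of one row of the loading matrix W
#'
#' \eqn{w_j^T \sim N(a_j, B_j)} with
#' \eqn{B_j = (Z P_j Z^T + D_{\tau^w}^{-1})^{-1}} and
#' \eqn{a_j = B_j Z P_j(\psi_j - m_j + P_j^{-1}\kappa_j)}.
#'
#' @param j feature index (1-based); `NULL` updates all rows.
#' @param state model state list.
#' @param wl working likelihood list.
#' @return the updated W matrix.
#' @export
sample_w_row <- function(j = NULL, state, wl) {
  W <- cpp_step_w(state, wl)$W
  if (is.null(j)) return(W)
  out <- state$W
  out[j, ] <- W[j, ]
  out
}

#' Conditional posterior moments of a W row / Z column
#'
#' Deterministic mean and covariance of the Gaussian conditionals, exposed
#' for validation against independent dense-formula oracles.
#'
#' @param j feature index; `i` sample index (1-based).
#' @param state model state list.
#' @param wl working likelihood list.
#' @return list with `mean` and `cov`.
#' @export
w_row_moments <- function(j, state, wl) {
  mo <- cpp_w_row_moments(j, state, wl)
  list(mean = as.numeric(mo$mean), cov = mo$cov)
}

#' @rdname w_row_moments
#' @export
z_col_moments <- function(i, state, wl) {
  mo <- cpp_z_col_moments(i, state, wl)
  list(mean = as.numeric(mo$mean), cov = mo$cov)
}

#' Gibbs update of the augmented loading scales
#'
#' \eqn{1/(\tau^w_{jl})^2 \sim IG(|\lambda_{jl}/w_{jl}|, \lambda_{jl}^2)}
#' with \eqn{\lambda_{jl} = e^{\alpha_{jl}}}; an exactly-zero loading falls
#' back to the prior \eqn{(\tau^w_{jl})^2 \sim Exp(\lambda_{jl}^2/2)}.
#'
#' @param state model state list.
#' @return the updated `tau_w_sq` matrix.
#' @export
sample_tau_w <- function(state) cpp_step_tau_w(state)$tau_w_sq

#' Prior draw of an augmented loading scale (Laplace scale mixture)
#'
#' @param lambda Laplace rate(s).
#' @param n number of draws.
#' @return draws of \eqn{\tau^2 \sim Exp(\lambda^2/2)}.
#' @export
r_tau_w_prior <- function(lambda, n = length(lambda)) {
  rexp(n, rate = rep_len(lambda, n)^2 / 2)
}

#' Metropolis-Hastings sweep over the log-shrinkage matrix alpha
#'
#' Random-walk proposals \eqn{N(\alpha_{jl}, q)} against the target
#' \eqn{\pi(\alpha_{jl}|\cdot) \propto \lambda_{jl}^2
#'   e^{-\lambda_{jl}^2\tau_{jl}^2/2}
#'   e^{-\tilde\alpha_l^T\Omega\tilde\alpha_l/(2\nu_2)}},
#' sweeping with the latest values of the other entries.
#'
#' @param state model state list.
#' @param graph a [feature_graph()] object.
#' @param hp a [bgb_hyperparameters()] object.
#' @param q proposal variance (defaults to `hp$mh_proposal_var`).
#' @return list with the updated `alpha` and the acceptance count.
#' @export
mh_update_alpha <- function(state, graph, hp, q = hp$mh_proposal_var) {
  cpp_step_alpha(state, graph_info(graph), hyper_for_cpp(hp), q)
}

#' Gibbs update of one column of the factor matrix Z
#'
#' \eqn{\tilde z_i \sim N(c_i, D_i)} with
#' \eqn{D_i = (W^T \tilde P_i W + D_\delta D_{\tau^z}^{-1})^{-1}} and
#' \eqn{c_i = D_i W^T \tilde P_i(\tilde\psi_i - m + \tilde P_i^{-1}
#' \tilde\kappa_i)}; the prior precision of \eqn{z_{li}} is
#' \eqn{\delta_{li}/(\tau^z_{li})^2} (normal scale mixture of the
#' per-entry Laplace prior with rate \eqn{\delta_{li}}).
#'
#' @param i sample index (1-based); `NULL` updates all columns.
#' @param state model state list.
#' @param wl working likelihood list.
#' @return the updated Z matrix.
#' @export
sample_z_column <- function(i = NULL, state, wl) {
  Z <- cpp_step_z(state, wl)$Z
  if (is.null(i)) return(Z)
  out <- state$Z
  out[, i] <- Z[, i]
  out
}

#' Gibbs update of the factor scales and shrinkage rates
#'
#' \eqn{1/(\tau^z_{li})^2 \sim IG(|1/z_{li}|, \delta_{li})} then
#' \eqn{\delta_{li} \sim Gamma(\nu_4 + 3/2,
#'   \nu_3 + (\tau^z_{li})^2/2 + z_{li}^2/(2(\tau^z_{li})^2))}.
#'
#' @param state model state list.
#' @param hp a [bgb_hyperparameters()] object.
#' @return list with updated `tau_z_sq` and `delta`.
#' @export
sample_tau_z_and_delta <- function(state, hp) {
  cpp_step_tau_z_delta(state, hyper_for_cpp(hp))
}

#' Gibbs update of the location vector m
#'
#' Entries are conditionally independent:
#' \eqn{m_j \sim N(v_m \sum_i(\kappa_{ji} - \rho_{ji}(w_j^T\tilde z_i -
#' \psi_{ji})), v_m)} with
#' \eqn{v_m = (1/\sigma_m^2 + \sum_i \rho_{ji})^{-1}}.
#'
#' @param state model state list.
#' @param wl working likelihood list.
#' @param hp a [bgb_hyperparameters()] object.
#' @return the updated m vector.
#' @export
sample_m <- function(state, wl, hp) {
  as.numeric(cpp_step_m(state, wl, hyper_for_cpp(hp))$m)
}

#' One full Gibbs sweep
#'
#' Update order: rho, m, W rows, tau_w, alpha (MH), Z columns,
#' (tau_z, delta), Omega columns.
#'
#' @param state model state list.
#' @param wl working likelihood list.
#' @param graph a [feature_graph()] object.
#' @param hp a [bgb_hyperparameters()] object.
#' @param rebuild rebuild the Sigma cache by direct inversion.
#' @return the updated state (acceptance count in element `naccept`).
#' @export
gibbs_sweep <- function(state, wl, graph, hp, rebuild = FALSE) {
  cpp_sweep(state, wl, graph_info(graph), hyper_for_cpp(hp), rebuild)
}
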