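#' Model hyperparameters
#'
#' @param nu1 prior mean of the log-shrinkage parameters
#'   \eqn{\alpha_{jl} = \log\lambda_{jl}}: the overall a-priori shrinkage
#'   level of the loadings.
#' @param nu2 scale of the \eqn{\alpha} prior; smaller values concentrate
#'   all \eqn{\lambda_{jl}} around \eqn{e^{\nu_1}} (less adaptivity).
#' @param nu3 rate of the Gamma prior on the factor shrinkage rates
#'   \eqn{\delta_{li}}; smaller values give heavier tails (more adaptive).
#' @param nu4 shape of the Gamma prior on \eqn{\delta_{li}}; larger values
#'   yield a sparser factor matrix Z.
#' @param eta adaptivity of the graph-constrained Wishart prior on
#'   \eqn{\Omega}; larger values tie the posterior of \eqn{\Omega} more
#'   strongly to the prior.
#' @param epsilon correlation control: without the graph constraint the
#'   prior mode of \eqn{\Omega^{-1}} has off-diagonals near
#'   \eqn{1/(1+\epsilon)}.
#' @param sigma_m_sq prior variance of the location vector m.
#' @param zeta degrees of freedom (scalar or per-feature) of the prior on
#'   the gaussian precisions \eqn{\rho_j}.
#' @param mh_proposal_var variance q of the Metropolis random-walk proposal
#'   for \eqn{\alpha_{jl}}.
#' @param ci_level coverage of the posterior credible intervals used for
#'   bicluster extraction.
#' @param selection_rule `"excludes_zero"` selects feature j (sample i) for
#'   bicluster l when the credible interval of \eqn{w_{jl}} (\eqn{z_{li}})
#'   excludes zero; `"covers_zero"` applies the inverted rule.
#' @return an object of class `bgb_hyper`.
#' @export
bgb_hyperparameters <- function(nu1 = 0, nu2 = 0.5, nu3 = 0.1, nu4 = 8,
                                eta = 15, epsilon = 0.1, sigma_m_sq = 100,
                                zeta = 1, mh_proposal_var = 0.5,
                                ci_level = 0.95,
                                selection_rule = c("excludes_zero",
                                                   "covers_zero")) {
  selection_rule <- match.arg(selection_rule)
  stopifnot(nu2 > 0, nu3 > 0, nu4 > 0, eta > 0, epsilon > 0,
            sigma_m_sq > 0, all(zeta > 0), mh_proposal_var > 0,
            ci_level > 0, ci_level < 1)
  structure(list(nu1 = nu1, nu2 = nu2, nu3 = nu3, nu4 = nu4, eta = eta,
                 epsilon = epsilon, sigma_m_sq = sigma_m_sq, zeta = zeta,
                 mh_proposal_var = mh_proposal_var, ci_level = ci_level,
                 selection_rule = selection_rule),
            class = "bgb_hyper")
}

#' MCMC chain configuration
#'
#' @param n_chains number of independent chains (>= 2 enables the
#'   Gelman-Rubin diagnostic).
#' @param n_burnin burn-in sweeps per chain.
#' @param n_iter post-burn-in sweeps per chain.
#' @param thin keep every `thin`-th sweep.
#' @param seed integer seed; chain c uses `seed + c - 1`.
#' @param gelman_rubin_threshold convergence flag threshold on split-Rhat.
#' @param adapt_mh Robbins-Monro adaptation of the MH proposal variance
#'   during burn-in (frozen afterwards), targeting 0.44 acceptance.
#' @param rebuild_every rebuild the Sigma = Omega^-1 cache from scratch
#'   every this many sweeps to bound floating-point drift.
#' @return an object of class `bgb_chains`.
#' @export
bgb_chain_config <- function(n_chains = 2, n_burnin = 2000, n_iter = 3000,
                             thin = 3, seed = 1,
                             gelman_rubin_threshold = 1.1, adapt_mh = TRUE,
                             rebuild_every = 100) {
  stopifnot(n_chains >= 1, n_burnin >= 0, n_iter >= 0, thin >= 1,
            gelman_rubin_threshold > 1)
  structure(list(n_chains = as.integer(n_chains),
                 n_burnin = as.integer(n_burnin),
                 n_iter = as.integer(n_iter), thin = as.integer(thin),
                 seed = as.integer(seed),
                 gelman_rubin_threshold = gelman_rubin_threshold,
                 adapt_mh = isTRUE(adapt_mh),
                 rebuild_every = as.integer(rebuild_every)),
            class = "bgb_chains")
}

hyper_for_cpp <- function(hp) {
  list(nu1 = hp$nu1, nu2 = hp$nu2, nu3 = hp$nu3, nu4 = hp$nu4,
       eta = hp$eta, epsilon = hp$epsilon, sigma_m_sq = hp$sigma_m_sq,
       mh_proposal_var = hp$mh_proposal_var)
}
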