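#' Deviance information criterion of a fitted chain
#'
#' \deqn{DIC = -2\, l(X, \hat\mu) + 4\,(l(X, \hat\mu) - E[l(X, \mu)])}
#' where \eqn{l} is the original (non-augmented) log likelihood summed over
#' all entries, \eqn{\hat\mu} the posterior mean of
#' \eqn{\mu^t = m^t 1^T + W^t Z^t} over the retained draws and
#' \eqn{E[l(X,\mu)]} the average per-draw log likelihood. Gaussian rows
#' plug in the posterior-mean precision for \eqn{l(X,\hat\mu)}. Depends on
#' the chain only through the \eqn{\mu} trace, so it is invariant to factor
#' relabeling.
#'
#' @param archive a single-chain archive (e.g. `fit$chains[[1]]`).
#' @param wl working likelihood list from [build_working_likelihood()]
#'   (or a `bgb_fit`, from which both are taken).
#' @return the DIC (smaller is better).
#' @export
compute_dic <- function(archive, wl = NULL) {
  if (inherits(archive, "bgb_fit")) {
    wl <- archive$wl
    archive <- archive$chains[[1L]]
  }
  if (is.null(archive$n_kept) || archive$n_kept == 0L)
    stop("empty archive: no retained draws")
  l_hat <- cpp_loglik(wl, archive$mu_hat, archive$rho_bar)
  e_l <- mean(archive$loglik)
  -2 * l_hat + 4 * (l_hat - e_l)
}

#' Hyperparameter grid specification
#'
#' Candidate lists for the tuned parameters; all other hyperparameters are
#' taken from `base`. Duplicate cells are removed.
#'
#' @param nu1,nu3,nu4 candidate vectors.
#' @param L candidate factor counts.
#' @param base a [bgb_hyperparameters()] object of fixed values.
#' @return an object of class `bgb_grid` (a data frame of cells plus the
#'   base hyperparameters).
#' @export
bgb_grid <- function(nu1 = c(-2, -1, 0, 1, 2), nu3 = c(1, 0.1, 0.01),
                     nu4 = c(1, 2, 8, 16), L = 3:9,
                     base = bgb_hyperparameters()) {
  stopifnot(length(nu1) > 0, length(nu3) > 0, length(nu4) > 0,
            length(L) > 0, all(L >= 1))
  cells <- unique(expand.grid(nu1 = nu1, nu3 = nu3, nu4 = nu4, L = L,
                              KEEP.OUT.ATTRS = FALSE))
  structure(list(cells = cells, base = base), class = "bgb_grid")
}

#' DIC grid search with final refit
#'
#' Fits every grid cell with a shortened screening chain, records the DIC,
#' selects the smallest (ties broken by smaller L, then by lexicographic
#' hyperparameter order) and refits the winner at full chain length.
#' Screening cells run a single chain with a seed derived from the base
#' seed plus the cell index, so the grid is reproducible and could be run
#' in parallel.
#'
#' @param data a [bgb_multiview()] object.
#' @param graph a [feature_graph()] object or `NULL`.
#' @param grid a [bgb_grid()] object.
#' @param chains a [bgb_chain_config()] for the final refit.
#' @param screen_frac fraction of burn-in/iterations used for screening
#'   chains.
#' @return list with `best` (hyperparameters + L), `table` (DIC per cell,
#'   sorted ascending) and `fit` (the refit at the winning cell).
#' @export
bgb_tune <- function(data, graph = NULL, grid = bgb_grid(),
                     chains = bgb_chain_config(), screen_frac = 0.5) {
  cells <- grid$cells
  base <- grid$base
  screen <- bgb_chain_config(
    n_chains = 1,
    n_burnin = max(50L, as.integer(chains$n_burnin * screen_frac)),
    n_iter = max(50L, as.integer(chains$n_iter * screen_frac)),
    thin = chains$thin, seed = chains$seed,
    gelman_rubin_threshold = chains$gelman_rubin_threshold,
    adapt_mh = chains$adapt_mh, rebuild_every = chains$rebuild_every)
  dic <- rep(NA_real_, nrow(cells))
  fail <- character(nrow(cells))
  for (k in seq_len(nrow(cells))) {
    hp_k <- bgb_hyperparameters(
      nu1 = cells$nu1[k], nu2 = base$nu2, nu3 = cells$nu3[k],
      nu4 = cells$nu4[k], eta = base$eta, epsilon = base$epsilon,
      sigma_m_sq = base$sigma_m_sq, zeta = base$zeta,
      mh_proposal_var = base$mh_proposal_var, ci_level = base$ci_level,
      selection_rule = base$selection_rule)
    sc <- screen
    sc$seed <- screen$seed + k
    res <- tryCatch(
      bgb_fit(data, graph, L = cells$L[k], hp = hp_k, chains = sc,
              extract = FALSE),
      error = function(e) e)
    if (inherits(res, "error")) fail[k] <- conditionMessage(res)
    else dic[k] <- res$dic
  }
  if (all(is.na(dic)))
    stop("all grid fits failed: ",
         paste(unique(fail[nzchar(fail)]), collapse = "; "))
  tab <- cbind(cells,
               nu2 = base$nu2, eta = base$eta, epsilon = base$epsilon,
               DIC = dic)
  ord <- order(dic, cells$L, cells$nu1, cells$nu3, cells$nu4,
               na.last = TRUE)
  tab <- tab[ord, , drop = FALSE]
  best <- tab[1L, ]
  hp_best <- bgb_hyperparameters(
    nu1 = best$nu1, nu2 = base$nu2, nu3 = best$nu3, nu4 = best$nu4,
    eta = base$eta, epsilon = base$epsilon, sigma_m_sq = base$sigma_m_sq,
    zeta = base$zeta, mh_proposal_var = base$mh_proposal_var,
    ci_level = base$ci_level, selection_rule = base$selection_rule)
  fit <- bgb_fit(data, graph, L = best$L, hp = hp_best, chains = chains)
  list(best = list(hp = hp_best, L = best$L, DIC = best$DIC),
       table = tab, fit = fit)
}
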