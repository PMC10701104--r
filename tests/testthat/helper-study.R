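# Desk-scale reproduction protocol for the simulation study: 5 replicates
# per condition, single chains of 600 burn-in + 600 retained sweeps
# (thin 4), fixed study hyperparameters (nu2 = 0.5, eta = 15, eps = 0.1)
# and the true factor count L = 6 unless a DIC grid is requested.
# Results are memoised so criteria sharing a condition reuse the fits.

study_env <- new.env(parent = emptyenv())

study_hp <- function() bgb_hyperparameters(nu1 = 0, nu2 = 0.5, nu3 = 0.1,
                                           nu4 = 8, eta = 15, epsilon = 0.1)

study_chains <- function(seed, n_burnin = 600, n_iter = 600, thin = 4) {
  bgb_chain_config(n_chains = 1, n_burnin = n_burnin, n_iter = n_iter,
                   thin = thin, seed = seed)
}

study_replicate <- function(scenario, data_type, graph_kind, seed, L = 6) {
  dsn <- sim_design(scenario, data_type, graph_kind)
  r <- sim_replicate(dsn, seed = seed)
  # discrete-likelihood sweeps cost ~10x a gaussian sweep (one
  # Polya-Gamma draw per cell), so binomial conditions run shorter chains
  len <- if (data_type == "binomial") 400L else 600L
  fit <- bgb_fit(r$data, r$graph, L = L, hp = study_hp(),
                 chains = study_chains(seed, n_burnin = len, n_iter = len))
  m <- bicluster_metrics(fit$biclusters, r$truth, p = dsn$p, n = dsn$n)
  c(m, L_hat = fit$biclusters$L_hat)
}

# per-condition replicate metrics (rows = replicates), memoised
study_metrics <- function(scenario, data_type, graph_kind,
                          seeds = 20 + 1:5) {
  key <- paste(scenario, data_type, graph_kind,
               paste(seeds, collapse = "-"), sep = "_")
  if (!is.null(study_env[[key]])) return(study_env[[key]])
  out <- t(vapply(seeds, function(s)
    study_replicate(scenario, data_type, graph_kind, s), numeric(5)))
  study_env[[key]] <- out
  out
}
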