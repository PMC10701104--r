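#' Fit the graph-guided biclustering model by MCMC
#'
#' Runs one or more Gibbs chains (Polya-Gamma augmented likelihood,
#' Bayesian-lasso scale mixtures on W and Z, graph-constrained Wishart
#' block updates for Omega), archives thinned draws of (m, W, Z) together
#' with the original-data log-likelihood trace, attaches Gelman-Rubin
#' diagnostics when at least two chains are run, and extracts biclusters
#' from the credible intervals of the first chain.
#'
#' @param data a [bgb_multiview()] object.
#' @param graph a [feature_graph()] object, or `NULL` for the null graph
#'   (no edges).
#' @param L number of candidate factors.
#' @param hp a [bgb_hyperparameters()] object.
#' @param chains a [bgb_chain_config()] object.
#' @param extract extract biclusters after sampling.
#' @return an object of class `bgb_fit`: chains (each with draw arrays
#'   `m_draws`, `W_draws`, `Z_draws`, `loglik`, `mu_hat`, `rho_bar`),
#'   `dic`, `rhat` (split-Rhat of the log-likelihood trace, `NA` for a
#'   single chain), `converged`, and `biclusters`.
#' @export
bgb_fit <- function(data, graph = NULL, L = 6,
                    hp = bgb_hyperparameters(),
                    chains = bgb_chain_config(), extract = TRUE) {
  stopifnot(inherits(data, "bgb_multiview"))
  if (is.null(graph)) graph <- feature_graph(NULL, data)
  stopifnot(inherits(graph, "bgb_graph"), graph$p == data$p)
  wl <- build_working_likelihood(data, zeta = hp$zeta)
  gi <- graph_info(graph)
  hpc <- hyper_for_cpp(hp)
  archives <- vector("list", chains$n_chains)
  for (ch in seq_len(chains$n_chains)) {
    set.seed(chains$seed + ch - 1L)
    st <- init_state(wl, graph, hp, L)
    run <- cpp_run(st, wl, gi, hpc, chains$n_burnin, chains$n_iter,
                   chains$thin, chains$rebuild_every, chains$adapt_mh,
                   0.44)
    run$seed <- chains$seed + ch - 1L
    archives[[ch]] <- structure(run, class = "bgb_archive")
  }
  rhat <- if (chains$n_chains >= 2) {
    gelman_rubin(lapply(archives, `[[`, "loglik"))
  } else NA_real_
  fit <- structure(list(
    chains = archives, data = data, graph = graph, wl = wl, L = L,
    hp = hp, config = chains, rhat = rhat,
    converged = is.na(rhat) || rhat < chains$gelman_rubin_threshold,
    dic = if (archives[[1L]]$n_kept > 0) compute_dic(archives[[1L]], wl)
          else NA_real_),
    class = "bgb_fit")
  if (extract && archives[[1L]]$n_kept > 0)
    fit$biclusters <- extract_biclusters(fit)
  fit
}

#' @exportS3Method base::print
print.bgb_fit <- function(x, ...) {
  cat(sprintf("bgb_fit: p = %d, n = %d, L = %d, %d chain(s) x %d kept draws\n",
              x$data$p, x$data$n, x$L, length(x$chains),
              x$chains[[1L]]$n_kept))
  cat(sprintf("  DIC = %.2f, Rhat(loglik) = %s, MH acceptance = %.2f\n",
              x$dic, ifelse(is.na(x$rhat), "NA", sprintf("%.3f", x$rhat)),
              x$chains[[1L]]$accept_rate))
  if (!is.null(x$biclusters))
    cat(sprintf("  %d bicluster(s) extracted\n", x$biclusters$L_hat))
  invisible(x)
}

#' Gelman-Rubin convergence diagnostic
#'
#' Potential scale reduction: the ratio of the pooled-sample variance to
#' the mean within-chain variance, \eqn{\hat R = \sqrt{V_{pooled}/W}}.
#' Identical chains give exactly 1; chains stuck at different values give a
#' large (possibly infinite) statistic. `split = TRUE` halves each chain
#' first (sensitive to within-chain drift, at the price of not being
#' exactly 1 for identical finite chains).
#'
#' @param traces list of equal-length numeric vectors (one per chain), or a
#'   matrix with one chain per column.
#' @param split halve each chain before forming the statistic.
#' @return the Rhat statistic (may be `Inf` for degenerate traces).
#' @export
gelman_rubin <- function(traces, split = FALSE) {
  if (is.matrix(traces)) traces <- lapply(seq_len(ncol(traces)),
                                          function(k) traces[, k])
  stopifnot(length(traces) >= 2L)
  len <- unique(vapply(traces, length, 0L))
  if (length(len) != 1L) stop("chains must have equal length")
  if (split) {
    half <- floor(len / 2)
    if (half < 2L) stop("traces too short for split-Rhat")
    traces <- unlist(lapply(traces, function(x)
      list(x[seq_len(half)], x[seq.int(len - half + 1L, len)])),
      recursive = FALSE)
  }
  if (length(traces[[1L]]) < 2L) stop("traces too short")
  Wv <- mean(vapply(traces, var, 0))
  B <- var(vapply(traces, mean, 0))
  if (Wv == 0) return(if (B == 0) 1 else Inf)
  sqrt((Wv + B) / Wv)
}

#' Extract biclusters from posterior credible intervals
#'
#' Feature j belongs to bicluster l when the equal-tailed credible interval
#' of \eqn{w_{jl}} excludes zero, sample i when the interval of
#' \eqn{z_{li}} excludes zero (the `covers_zero` rule inverts both).
#' Factors whose feature set or sample set comes out empty are dropped.
#' Draws are taken from the first chain (factor labels are not aligned
#' across chains).
#'
#' @param fit a [bgb_fit()] object (or a single chain archive plus
#'   `hp`).
#' @param ci_level credible-interval coverage (defaults to the fitted
#'   `hp$ci_level`).
#' @param selection_rule overrides the fitted `hp$selection_rule`.
#' @return a [bgb_biclusters()] object.
#' @export
extract_biclusters <- function(fit, ci_level = NULL, selection_rule = NULL) {
  archive <- fit$chains[[1L]]
  hp <- fit$hp
  if (is.null(ci_level)) ci_level <- hp$ci_level
  if (is.null(selection_rule)) selection_rule <- hp$selection_rule
  if (archive$n_kept == 0L) stop("empty archive: no retained draws")
  lo <- (1 - ci_level) / 2
  hi <- 1 - lo
  Wd <- archive$W_draws # p x L x T
  Zd <- archive$Z_draws # L x n x T
  L <- dim(Wd)[2L]
  excl <- function(draws_mat) { # rows: units, cols: draws
    ql <- apply(draws_mat, 1L, quantile, probs = lo, names = FALSE)
    qh <- apply(draws_mat, 1L, quantile, probs = hi, names = FALSE)
    if (selection_rule == "excludes_zero") ql > 0 | qh < 0
    else !(ql > 0 | qh < 0)
  }
  bic <- vector("list", L)
  for (l in seq_len(L)) {
    fsel <- excl(matrix(Wd[, l, ], nrow = dim(Wd)[1L]))
    ssel <- excl(matrix(Zd[l, , ], nrow = dim(Zd)[2L]))
    bic[[l]] <- list(features = which(fsel), samples = which(ssel),
                     factor = l)
  }
  bgb_biclusters(bic, provenance = list(
    ci_level = ci_level, selection_rule = selection_rule,
    L = L, dic = if (!is.null(fit$dic)) fit$dic else NA_real_,
    seed = archive$seed))
}

#' Export per-chain scalar traces as CSV
#'
#' Writes the retained log-likelihood trace of every chain (one column per
#' chain) for external convergence tooling.
#'
#' @param fit a [bgb_fit()] object.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
export_trace <- function(fit, path) {
  tr <- do.call(cbind, lapply(fit$chains, `[[`, "loglik"))
  colnames(tr) <- paste0("chain", seq_len(ncol(tr)))
  write.csv(data.frame(draw = seq_len(nrow(tr)), tr), path,
            row.names = FALSE)
  invisible(path)
}

#' Posterior summaries of m, W and Z
#'
#' @param fit a [bgb_fit()] object.
#' @param ci_level credible-interval coverage.
#' @return named list of data frames (`m`, `W`, `Z`) with posterior means
#'   and equal-tailed interval bounds.
#' @export
posterior_summaries <- function(fit, ci_level = fit$hp$ci_level) {
  a <- fit$chains[[1L]]
  lo <- (1 - ci_level) / 2; hi <- 1 - lo
  summ <- function(mat, id) { # units x draws
    data.frame(id = id, mean = rowMeans(mat),
               lower = apply(mat, 1L, quantile, probs = lo, names = FALSE),
               upper = apply(mat, 1L, quantile, probs = hi, names = FALSE))
  }
  p <- dim(a$W_draws)[1L]; L <- dim(a$W_draws)[2L]
  n <- dim(a$Z_draws)[2L]; T <- a$n_kept
  Wm <- matrix(aperm(a$W_draws, c(1, 2, 3)), p * L, T)
  Zm <- matrix(aperm(a$Z_draws, c(1, 2, 3)), L * n, T)
  list(
    m = summ(a$m_draws, fit$data$feature_ids),
    W = summ(Wm, paste(rep(fit$data$feature_ids, L),
                       rep(seq_len(L), each = p), sep = ":")),
    Z = summ(Zm, paste(rep(seq_len(L), n),
                       rep(fit$data$sample_ids, each = L), sep = ":")))
}
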