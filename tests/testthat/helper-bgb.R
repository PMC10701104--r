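# Shared fixtures: all test inputs are generated in code.

# small gaussian multiview dataset with optional second (binomial) view
tiny_data <- function(p = 6, n = 4, seed = 42, binomial_rows = 0,
                      trials = 10) {
  set.seed(seed)
  if (binomial_rows > 0) {
    pg <- p - binomial_rows
    v1 <- bgb_view(matrix(rnorm(pg * n), pg, n,
                          dimnames = list(paste0("g", seq_len(pg)),
                                          paste0("s", seq_len(n)))))
    v2 <- bgb_view(matrix(rbinom(binomial_rows * n, trials, 0.4),
                          binomial_rows, n,
                          dimnames = list(paste0("b", seq_len(binomial_rows)),
                                          paste0("s", seq_len(n)))),
                   "binomial", constants = trials)
    bgb_multiview(list(v1, v2))
  } else {
    bgb_multiview(bgb_view(matrix(rnorm(p * n), p, n,
                                  dimnames = list(paste0("g", seq_len(p)),
                                                  paste0("s", seq_len(n))))))
  }
}

# a fully specified state for granular sampler tests
tiny_state <- function(wl, L = 2, seed = 1, graph = NULL, hp = NULL,
                       epsilon = 0.1) {
  set.seed(seed)
  p <- nrow(wl$x); n <- ncol(wl$x)
  Omega <- diag(1 + epsilon, p)
  Sigma <- diag(1 / (1 + epsilon), p)
  if (!is.null(graph) && graph$e > 0) {
    om <- init_omega(graph, epsilon)
    Omega <- om$Omega; Sigma <- om$Sigma
  }
  list(m = rnorm(p, 0, 0.3),
       W = matrix(rnorm(p * L, 0, 0.8), p, L),
       Z = matrix(rnorm(L * n, 0, 0.8), L, n),
       alpha = matrix(rnorm(p * L, 0, 0.2), p, L),
       tau_w_sq = matrix(rexp(p * L) + 0.3, p, L),
       tau_z_sq = matrix(rexp(L * n) + 0.3, L, n),
       delta = matrix(rexp(L * n) + 0.5, L, n),
       rho = matrix(rexp(p * n) + 0.5, p, n),
       Omega = Omega, Sigma = Sigma)
}

default_hp <- function(...) bgb_hyperparameters(...)

# null-graph object for a dataset
null_graph <- function(data) feature_graph(NULL, data)

# independent dense-formula posterior moments for a W row (direct
# translation of the conditional: B = (Z P Z^T + D^-1)^-1, a = B Z P t)
oracle_w_row_moments <- function(j, state, wl) {
  rho <- state$rho[j, ]
  P <- diag(rho, length(rho))
  Dinv <- diag(1 / state$tau_w_sq[j, ], ncol(state$W))
  B <- solve(state$Z %*% P %*% t(state$Z) + Dinv)
  target <- wl$psi[j, ] - state$m[j] + wl$kappa[j, ] / rho
  a <- B %*% state$Z %*% P %*% target
  list(mean = as.numeric(a), cov = B)
}

# dense-formula moments for a Z column; the prior precision of z_li is
# delta_li / tau_li^2
oracle_z_col_moments <- function(i, state, wl) {
  rho <- state$rho[, i]
  P <- diag(rho, length(rho))
  Dinv <- diag(state$delta[, i] / state$tau_z_sq[, i], ncol(state$W))
  D <- solve(t(state$W) %*% P %*% state$W + Dinv)
  target <- wl$psi[, i] - state$m + wl$kappa[, i] / rho
  cc <- D %*% t(state$W) %*% P %*% target
  list(mean = as.numeric(cc), cov = D)
}

# enumerate the cells of a bicluster as "f:s" strings (oracle helper)
cells_of <- function(b) {
  if (!length(b$features) || !length(b$samples)) return(character(0))
  as.vector(outer(b$features, b$samples, paste, sep = ":"))
}

# brute-force metrics by cell enumeration (and permutation search for the
# assignment when collections are small)
oracle_metrics <- function(est, tru, p, n) {
  est <- if (inherits(est, "bgb_biclusters")) est$biclusters else est
  tru <- if (inherits(tru, "bgb_biclusters")) tru$biclusters else tru
  jac <- function(a, b) {
    ca <- cells_of(a); cb <- cells_of(b)
    if (!length(ca) && !length(cb)) return(0)
    length(intersect(ca, cb)) / length(union(ca, cb))
  }
  J <- outer(seq_along(est), seq_along(tru),
             Vectorize(function(k, l) jac(est[[k]], tru[[l]])))
  rel <- mean(apply(J, 1, max))
  rec <- mean(apply(J, 2, max))
  ke <- length(est); kt <- length(tru); kk <- max(ke, kt)
  perms <- gtools_permutations(kk)
  best <- -Inf; best_perm <- NULL
  for (r in seq_len(nrow(perms))) {
    s <- 0
    for (k in seq_len(ke)) {
      l <- perms[r, k]
      if (l <= kt) s <- s + J[k, l]
    }
    if (s > best) { best <- s; best_perm <- perms[r, ] }
  }
  inter <- 0
  for (k in seq_len(ke)) {
    l <- best_perm[k]
    if (l <= kt)
      inter <- inter + length(intersect(cells_of(est[[k]]),
                                        cells_of(tru[[l]])))
  }
  allcells <- unique(unlist(c(lapply(est, cells_of), lapply(tru, cells_of))))
  c(relevance = rel, recovery = rec,
    consensus_score = best / kk,
    clustering_accuracy = if (!length(allcells)) 0
                          else inter / length(allcells))
}

# all permutations of 1..k (k small)
gtools_permutations <- function(k) {
  if (k == 1) return(matrix(1))
  sub <- gtools_permutations(k - 1)
  out <- matrix(0L, 0, k)
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

random_bicluster_set <- function(nb, p, n, allow_empty = FALSE) {
  lapply(seq_len(nb), function(k) {
    nf <- sample.int(max(p %/% 2, 1), 1)
    ns <- sample.int(max(n %/% 2, 1), 1)
    if (allow_empty && runif(1) < 0.2) nf <- 0
    list(features = sort(sample.int(p, nf)),
         samples = sort(sample.int(n, ns)))
  })
}
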