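#' Benchmark simulation design
#'
#' The two standard scenarios: `sim1` has six disjoint 50-feature loading
#' blocks (features `1+50(l-1)` to `50l` per factor l); `sim2` has
#' overlapping blocks (features `1+48(l-1)` to `min(48(l-1)+63, 300)`), so
#' adjacent factors share 15 features. Factor rows are non-zero on samples
#' `1+15(l-1)` to `15l` in both. Non-zero magnitudes are N(2, 0.1^2) with
#' random sign; gaussian data add N(0, 4) noise, binomial data draw
#' Binomial(n_j, logit^-1(WZ)) with trials uniform on 10..30. The working
#' graphs range from uninformative to noisy: `G1` null graph; `G2`
#' within-pathway edges only (pathways = the loading blocks); `G3` adds
#' across-pathway noise edges with probability 0.1 (capped at the `G2`
#' edge count); `G4` replaces each within-pathway edge by a random
#' across-pathway edge with probability 0.5.
#'
#' @param scenario `"sim1"` (non-overlapping) or `"sim2"` (overlapping).
#' @param data_type `"gaussian"` or `"binomial"`.
#' @param graph_kind one of `"G1"`..`"G4"`.
#' @param n,p,L sample, feature and factor counts.
#' @param effect_mean,effect_sd distribution of non-zero magnitudes.
#' @param noise_var gaussian noise variance.
#' @param trials_range inclusive range of binomial trial counts.
#' @param g3_prob across-pathway edge probability for `G3`.
#' @param g4_prob replacement probability for `G4`.
#' @param g3_cap cap the number of `G3` noise edges at the `G2` edge count
#'   (keeps the noise level comparable across replicates).
#' @param topology within-pathway edge topology: `"tree_plus"` (random
#'   spanning tree plus random extra edges up to `target_degree`),
#'   `"tree"`, `"chain"`, or `"dense"` (complete).
#' @param target_degree target mean degree for `"tree_plus"`.
#' @param w_block sim1 loading-block size (study value 50).
#' @param w_step,w_width sim2 loading-block stride and width (study values
#'   48 and 63, giving a 15-feature overlap between adjacent factors).
#' @param z_block factor sample-block size (study value 15).
#' @return an object of class `bgb_sim_design`.
#' @export
sim_design <- function(scenario = c("sim1", "sim2"),
                       data_type = c("gaussian", "binomial"),
                       graph_kind = c("G2", "G1", "G3", "G4"),
                       n = 90, p = 300, L = 6,
                       effect_mean = 2, effect_sd = 0.1, noise_var = 4,
                       trials_range = c(10, 30), g3_prob = 0.1,
                       g4_prob = 0.5, g3_cap = TRUE,
                       topology = c("tree_plus", "tree", "chain", "dense"),
                       target_degree = 4,
                       w_block = 50, w_step = 48, w_width = 63,
                       z_block = 15) {
  scenario <- match.arg(scenario)
  if (scenario == "sim1") stopifnot(L * w_block <= p)
  stopifnot(L * z_block <= n)
  structure(list(scenario = scenario,
                 data_type = match.arg(data_type),
                 graph_kind = match.arg(graph_kind),
                 n = n, p = p, L = L, effect_mean = effect_mean,
                 effect_sd = effect_sd, noise_var = noise_var,
                 trials_range = trials_range, g3_prob = g3_prob,
                 g4_prob = g4_prob, g3_cap = isTRUE(g3_cap),
                 topology = match.arg(topology),
                 target_degree = target_degree,
                 w_block = w_block, w_step = w_step, w_width = w_width,
                 z_block = z_block),
            class = "bgb_sim_design")
}

# 1-based feature index block of factor l
sim_feature_block <- function(design, l) {
  if (design$scenario == "sim1") {
    f0 <- 1 + design$w_block * (l - 1)
    f1 <- design$w_block * l
  } else {
    f0 <- 1 + design$w_step * (l - 1)
    f1 <- design$w_step * (l - 1) + design$w_width
  }
  seq.int(f0, min(f1, design$p))
}

sim_sample_block <- function(design, l) {
  seq.int(1 + design$z_block * (l - 1), min(design$z_block * l, design$n))
}

#' Generate the ground-truth loading and factor matrices
#'
#' @param design a [sim_design()] object.
#' @return list with `W` (p x L), `Z` (L x n) and `truth`, the true
#'   [bgb_biclusters()].
#' @export
sim_truth <- function(design) {
  p <- design$p; n <- design$n; L <- design$L
  W <- matrix(0, p, L)
  Z <- matrix(0, L, n)
  bic <- vector("list", L)
  for (l in seq_len(L)) {
    fb <- sim_feature_block(design, l)
    sb <- sim_sample_block(design, l)
    W[fb, l] <- rnorm(length(fb), design$effect_mean, design$effect_sd) *
      sample(c(-1, 1), length(fb), replace = TRUE)
    Z[l, sb] <- rnorm(length(sb), design$effect_mean, design$effect_sd) *
      sample(c(-1, 1), length(sb), replace = TRUE)
    bic[[l]] <- list(features = fb, samples = sb)
  }
  list(W = W, Z = Z, truth = bgb_biclusters(bic))
}

#' Generate data from a simulation truth
#'
#' @param design a [sim_design()] object.
#' @param truth output of [sim_truth()].
#' @return a single-view [bgb_multiview()] object (the true location
#'   vector is zero).
#' @export
sim_data <- function(design, truth) {
  mu <- truth$W %*% truth$Z
  p <- design$p; n <- design$n
  if (design$data_type == "gaussian") {
    x <- mu + matrix(rnorm(p * n, 0, sqrt(design$noise_var)), p, n)
    v <- bgb_view(x, "gaussian")
  } else {
    nj <- sample(seq.int(design$trials_range[1L], design$trials_range[2L]),
                 p, replace = TRUE)
    x <- matrix(rbinom(p * n, rep(nj, n), plogis(as.vector(mu))), p, n)
    v <- bgb_view(x, "binomial", constants = nj)
  }
  bgb_multiview(list(v))
}

# random spanning tree + extra edges within one pathway (1-based indices)
pathway_edges <- function(members, topology, target_degree) {
  k <- length(members)
  if (k < 2) return(matrix(integer(0), 0, 2))
  if (topology == "chain")
    return(cbind(members[-k], members[-1L]))
  if (topology == "dense")
    return(t(utils::combn(members, 2L)))
  ord <- sample(members)
  tree <- cbind(ord[vapply(2:k, function(i) sample.int(i - 1L, 1L), 0L)],
                ord[2:k])
  edges <- cbind(pmin(tree[, 1L], tree[, 2L]), pmax(tree[, 1L], tree[, 2L]))
  if (topology == "tree_plus") {
    target <- max(k - 1L, round(target_degree * k / 2))
    all_pairs <- t(utils::combn(members, 2L))
    key <- paste(all_pairs[, 1L], all_pairs[, 2L])
    have <- key %in% paste(edges[, 1L], edges[, 2L])
    extra_n <- min(target - nrow(edges), sum(!have))
    if (extra_n > 0) {
      pick <- sample(which(!have), extra_n)
      edges <- rbind(edges, all_pairs[pick, , drop = FALSE])
    }
  }
  edges
}

#' Generate a working graph for a simulation design
#'
#' @param design a [sim_design()] object.
#' @param truth output of [sim_truth()] (pathways are the non-zero feature
#'   blocks of W).
#' @param data the matching [bgb_multiview()] object (for identifiers).
#' @return a [feature_graph()] object.
#' @export
sim_graph <- function(design, truth, data) {
  L <- design$L
  pathways <- lapply(seq_len(L), function(l) which(truth$W[, l] != 0))
  if (design$graph_kind == "G1")
    return(feature_graph(NULL, data))
  within <- do.call(rbind, lapply(pathways, pathway_edges,
                                  topology = design$topology,
                                  target_degree = design$target_degree))
  within <- unique(cbind(pmin(within[, 1L], within[, 2L]),
                         pmax(within[, 1L], within[, 2L])))
  # pathway co-membership lookup (sim2 pathways overlap)
  memb <- matrix(FALSE, design$p, L)
  for (l in seq_len(L)) memb[pathways[[l]], l] <- TRUE
  same_pathway <- function(a, b) any(memb[a, ] & memb[b, ])
  draw_across <- function(n_edges, forbid) {
    out <- matrix(integer(0), 0, 2)
    seen <- forbid
    while (nrow(out) < n_edges) {
      a <- sample.int(design$p, 1L); b <- sample.int(design$p, 1L)
      if (a == b) next
      e <- c(min(a, b), max(a, b))
      key <- paste(e[1L], e[2L])
      if (key %in% seen || same_pathway(e[1L], e[2L])) next
      out <- rbind(out, e)
      seen <- c(seen, key)
    }
    out
  }
  wkey <- paste(within[, 1L], within[, 2L])
  edges <- switch(design$graph_kind,
    G2 = within,
    G3 = {
      shared <- (memb %*% t(memb)) > 0
      n_cross <- sum(!shared[upper.tri(shared)])
      n_add <- rbinom(1L, n_cross, design$g3_prob)
      if (design$g3_cap) n_add <- min(n_add, nrow(within))
      rbind(within, draw_across(n_add, wkey))
    },
    G4 = {
      replace_it <- runif(nrow(within)) < design$g4_prob
      kept <- within[!replace_it, , drop = FALSE]
      acc <- draw_across(sum(replace_it),
                         paste(kept[, 1L], kept[, 2L]))
      rbind(kept, acc)
    })
  feature_graph(edges, data)
}

#' Generate a full simulation replicate
#'
#' @param design a [sim_design()] object.
#' @param seed integer seed for the replicate.
#' @return list with `data`, `graph`, `truth` (a [bgb_biclusters()]),
#'   `W`, `Z` and the design.
#' @export
sim_replicate <- function(design, seed = 1) {
  set.seed(seed)
  tr <- sim_truth(design)
  data <- sim_data(design, tr)
  graph <- sim_graph(design, tr, data)
  list(data = data, graph = graph, truth = tr$truth, W = tr$W, Z = tr$Z,
       design = design, seed = seed)
}
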