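#' Jaccard index between two biclusters
#'
#' A bicluster is treated as the set of (feature, sample) cells in the
#' outer product of its feature set and sample set; the index is
#' \eqn{|a \cap b| / |a \cup b|} with the convention 0 for two empty sets.
#'
#' @param a,b `list(features = <int>, samples = <int>)` pairs.
#' @return a number in `[0, 1]`.
#' @export
bicluster_jaccard <- function(a, b) {
  na <- length(a$features) * length(a$samples)
  nb <- length(b$features) * length(b$samples)
  if (na == 0 && nb == 0) return(0)
  inter <- length(intersect(a$features, b$features)) *
    length(intersect(a$samples, b$samples))
  inter / (na + nb - inter)
}

as_bicluster_list <- function(x) {
  if (inherits(x, "bgb_biclusters")) x$biclusters else x
}

jaccard_matrix <- function(est, truth) {
  outer(seq_along(est), seq_along(truth),
        Vectorize(function(k, l) bicluster_jaccard(est[[k]], truth[[l]])))
}

#' Relevance and recovery of an estimated bicluster set
#'
#' Relevance (Rel) is the mean over estimated biclusters of the best
#' Jaccard match against any true bicluster: how well the estimates
#' represent the truth. Recovery (Rec) is the mean over true biclusters of
#' the best match among the estimates: how completely the truth is
#' recovered. `Rec(A, B) = Rel(B, A)` by definition. An empty estimated
#' set gives `Rel = Rec = 0` by convention.
#'
#' @param estimated,truth [bgb_biclusters()] objects or plain lists of
#'   `list(features, samples)` pairs.
#' @return named vector `c(relevance =, recovery =)`.
#' @export
relevance_recovery <- function(estimated, truth) {
  est <- as_bicluster_list(estimated)
  tru <- as_bicluster_list(truth)
  if (!length(est) || !length(tru))
    return(c(relevance = 0, recovery = 0))
  J <- jaccard_matrix(est, tru)
  c(relevance = mean(apply(J, 1L, max)),
    recovery = mean(apply(J, 2L, max)))
}

# Maximum-weight one-to-one assignment between rows and columns of a
# non-negative score matrix (rectangular allowed; unmatched units score 0).
# Solved as a maximum-weight bipartite matching.
hungarian_match <- function(score) {
  nr <- nrow(score); nc <- ncol(score)
  if (nr == 0 || nc == 0) return(integer(0))
  idx <- which(score > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(rep(NA_integer_, nr))
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, nr), rep(TRUE, nc)),
    edges = as.vector(t(cbind(idx[, 1L], nr + idx[, 2L]))))
  mm <- igraph::max_bipartite_match(
    g, weights = score[idx])
  match <- mm$matching[seq_len(nr)]
  out <- rep(NA_integer_, nr)
  ok <- !is.na(match)
  out[ok] <- as.integer(match[ok]) - nr
  out
}

#' Consensus score and clustering accuracy
#'
#' Both metrics first match estimated to true biclusters one-to-one by a
#' maximum-weight (Hungarian) assignment on the pairwise Jaccard matrix.
#' The consensus score is the matched Jaccard total divided by
#' `max(L_hat, L_true)` (optionally by `L_true`). The clustering accuracy
#' `CA = 1 - CE` is the size-weighted variant: the total number of cells in
#' matched intersections divided by the number of cells in the union of
#' all biclusters of both collections, so large biclusters weigh more.
#'
#' @param estimated,truth bicluster sets as in [relevance_recovery()].
#' @param p,n data dimensions (needed to enumerate cells for CA).
#' @param cs_denominator `"max"` divides CS by `max(L_hat, L_true)`,
#'   `"truth"` by `L_true`.
#' @return named vector `c(consensus_score =, clustering_accuracy =)`.
#' @export
consensus_and_ca <- function(estimated, truth, p, n,
                             cs_denominator = c("max", "truth")) {
  cs_denominator <- match.arg(cs_denominator)
  est <- as_bicluster_list(estimated)
  tru <- as_bicluster_list(truth)
  if (!length(est) || !length(tru))
    return(c(consensus_score = 0, clustering_accuracy = 0))
  J <- jaccard_matrix(est, tru)
  asg <- hungarian_match(J)
  matched <- which(!is.na(asg))
  cs_num <- sum(J[cbind(matched, asg[matched])])
  denom <- if (cs_denominator == "max") max(length(est), length(tru))
           else length(tru)
  inter_cells <- 0
  for (k in matched) {
    l <- asg[k]
    inter_cells <- inter_cells +
      length(intersect(est[[k]]$features, tru[[l]]$features)) *
      length(intersect(est[[k]]$samples, tru[[l]]$samples))
  }
  mask <- matrix(FALSE, p, n)
  for (b in c(est, tru))
    if (length(b$features) && length(b$samples))
      mask[b$features, b$samples] <- TRUE
  union_cells <- sum(mask)
  c(consensus_score = cs_num / denom,
    clustering_accuracy = if (union_cells == 0) 0
                          else inter_cells / union_cells)
}

#' All four bicluster-comparison metrics
#'
#' @inheritParams consensus_and_ca
#' @return named vector with `relevance`, `recovery`, `consensus_score`,
#'   `clustering_accuracy`.
#' @export
bicluster_metrics <- function(estimated, truth, p, n,
                              cs_denominator = "max") {
  c(relevance_recovery(estimated, truth),
    consensus_and_ca(estimated, truth, p, n,
                     cs_denominator = cs_denominator))
}
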