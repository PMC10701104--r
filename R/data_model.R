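#' Single-modality view of a multi-view dataset
#'
#' Wraps one feature-by-sample matrix together with its likelihood family
#' and the type-specific constants: the number of trials `n_j` for binomial
#' features, the number of failures `r_j` for negative-binomial features.
#'
#' @param x numeric matrix, features in rows, samples in columns. Row names
#'   are used as feature identifiers (generated when absent), column names
#'   as sample identifiers.
#' @param likelihood one of `"gaussian"`, `"binomial"`,
#'   `"negative_binomial"`.
#' @param constants per-feature vector of constants: trials for binomial
#'   (positive integers), failures for negative binomial (positive reals).
#'   A scalar is recycled across features. Ignored for gaussian views.
#' @return an object of class `bgb_view`.
#' @export
bgb_view <- function(x, likelihood = c("gaussian", "binomial",
                                       "negative_binomial"),
                     constants = NULL) {
  likelihood <- match.arg(likelihood)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("missing entries are not supported")
  p <- nrow(x)
  if (likelihood == "gaussian") {
    constants <- rep(NA_real_, p)
  } else {
    if (is.null(constants))
      stop(sprintf("'%s' view requires per-feature constants", likelihood))
    constants <- rep_len(as.numeric(constants), p)
    if (any(x != round(x)) || any(x < 0))
      stop(sprintf("'%s' entries must be non-negative integers", likelihood))
    if (likelihood == "binomial") {
      if (any(constants < 1) || any(constants != round(constants)))
        stop("binomial trial counts n_j must be integers >= 1")
      if (any(x > constants))
        stop("binomial entries must lie in [0, n_j]")
    } else if (any(constants <= 0)) {
      stop("negative-binomial failure counts r_j must be > 0")
    }
  }
  if (is.null(rownames(x)))
    rownames(x) <- sprintf("f%0*d", nchar(p), seq_len(p))
  if (is.null(colnames(x)))
    colnames(x) <- sprintf("s%0*d", nchar(ncol(x)), seq_len(ncol(x)))
  structure(list(x = x, likelihood = likelihood, constants = constants),
            class = "bgb_view")
}

#' Multi-view (multi-omics) data container
#'
#' Stacks one or more [bgb_view()] objects measured on the same samples.
#' Sample columns are aligned by identifier to the order of the first view;
#' every view must contain exactly the same sample identifiers. Feature
#' identifiers must be globally unique across views.
#'
#' @param views a list of [bgb_view()] objects (a single view may be passed
#'   directly).
#' @return an object of class `bgb_multiview` with elements `views`,
#'   `feature_ids`, `sample_ids`, `H` (number of modalities), `p_h`
#'   (per-view feature counts), `p`, `n`, and per-feature vectors
#'   `modality`, `likelihood`, `constants`.
#' @export
bgb_multiview <- function(views) {
  if (inherits(views, "bgb_view")) views <- list(views)
  if (!length(views) || !all(vapply(views, inherits, TRUE, "bgb_view")))
    stop("'views' must be a list of bgb_view objects")
  sample_ids <- colnames(views[[1L]]$x)
  for (h in seq_along(views)) {
    ids <- colnames(views[[h]]$x)
    if (!setequal(ids, sample_ids) || anyDuplicated(ids))
      stop("sample identifiers do not match across views")
    views[[h]]$x <- views[[h]]$x[, sample_ids, drop = FALSE]
  }
  feature_ids <- unlist(lapply(views, function(v) rownames(v$x)),
                        use.names = FALSE)
  if (anyDuplicated(feature_ids))
    stop("feature identifiers must be globally unique across views")
  p_h <- vapply(views, function(v) nrow(v$x), 0L)
  structure(list(
    views = views,
    feature_ids = feature_ids,
    sample_ids = sample_ids,
    H = length(views),
    p_h = p_h,
    p = sum(p_h),
    n = length(sample_ids),
    modality = rep(seq_along(views), p_h),
    likelihood = rep(vapply(views, `[[`, "", "likelihood"), p_h),
    constants = unlist(lapply(views, `[[`, "constants"), use.names = FALSE)
  ), class = "bgb_multiview")
}

#' @exportS3Method base::print
print.bgb_multiview <- function(x, ...) {
  cat(sprintf("bgb_multiview: %d modalities, p = %d features, n = %d samples\n",
              x$H, x$p, x$n))
  for (h in seq_len(x$H))
    cat(sprintf("  view %d: %s, %d features\n", h,
                x$views[[h]]$likelihood, x$p_h[h]))
  invisible(x)
}

#' Stacked data matrix of a multi-view object
#'
#' @param data a [bgb_multiview()] object.
#' @return the p x n matrix of all views stacked in order.
#' @export
stacked_matrix <- function(data) {
  do.call(rbind, lapply(data$views, `[[`, "x"))
}

read_matrix_file <- function(path) {
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path)
    rn <- readLines(paste0(stem, "_features.txt"))
    cn <- readLines(paste0(stem, "_samples.txt"))
    dimnames(m) <- list(rn, cn)
    return(m)
  }
  sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, row.names = 1,
                   check.names = FALSE)
  as.matrix(df)
}

#' Read one or more delimited matrix files into a multi-view object
#'
#' Each file must be a CSV/TSV with a header row of sample identifiers and
#' a first column of feature identifiers, or a MatrixMarket `.mtx` file with
#' `<stem>_features.txt` / `<stem>_samples.txt` sidecar identifier lists.
#'
#' @param paths character vector of file paths, one per view.
#' @param likelihoods character vector (recycled) of per-view likelihoods.
#' @param constants list (recycled) of per-view constants vectors/scalars
#'   (`NULL` for gaussian views).
#' @return a [bgb_multiview()] object.
#' @export
read_views <- function(paths, likelihoods = "gaussian", constants = NULL) {
  H <- length(paths)
  likelihoods <- rep_len(likelihoods, H)
  if (is.null(constants)) constants <- vector("list", H)
  if (!is.list(constants)) constants <- list(constants)
  constants <- rep_len(constants, H)
  views <- lapply(seq_len(H), function(h) {
    bgb_view(read_matrix_file(paths[h]), likelihoods[h], constants[[h]])
  })
  bgb_multiview(views)
}

#' Undirected feature graph over a multi-view dataset
#'
#' Prior biological knowledge: an undirected graph on the features whose
#' edges indicate that the connected features should receive correlated
#' shrinkage (and hence tend to enter biclusters together). Edges across
#' modalities are not allowed, self loops are dropped, and duplicate /
#' reversed edges are merged.
#'
#' @param edges a 2-column matrix or data frame of feature-identifier pairs
#'   (or of integer feature indices), possibly empty, or a p x p (0/1 or
#'   logical) adjacency matrix.
#' @param data the [bgb_multiview()] object the graph refers to.
#' @return an object of class `bgb_graph` with elements `nodes`, `edges`
#'   (2-column integer matrix of feature indices, i < j), `adjacency`
#'   (sparse symmetric pattern matrix) and `e` (edge count).
#' @export
feature_graph <- function(edges = NULL, data) {
  p <- data$p
  ids <- data$feature_ids
  if (is.null(edges) || (is.matrix(edges) && nrow(edges) == 0L &&
                         ncol(edges) != p)) {
    em <- matrix(integer(0), 0, 2)
  } else if ((is.matrix(edges) || inherits(edges, "Matrix")) &&
             nrow(edges) == p && ncol(edges) == p) {
    adj <- edges != 0
    if (!isSymmetric(as.matrix(adj)))
      stop("adjacency matrix must be symmetric")
    idx <- which(as.matrix(adj) & upper.tri(adj), arr.ind = TRUE)
    em <- cbind(idx[, 1L], idx[, 2L])
  } else {
    edges <- as.matrix(edges)
    if (nrow(edges) == 0L) {
      em <- matrix(integer(0), 0, 2)
    } else {
      if (ncol(edges) != 2L) stop("edge list must have two columns")
      if (is.character(edges)) {
        a <- match(edges[, 1L], ids)
        b <- match(edges[, 2L], ids)
        if (anyNA(a) || anyNA(b)) {
          bad <- unique(c(edges[, 1L][is.na(a)], edges[, 2L][is.na(b)]))
          stop("unknown feature identifier(s) in edge list: ",
               paste(head(bad, 5L), collapse = ", "))
        }
      } else {
        a <- as.integer(edges[, 1L]); b <- as.integer(edges[, 2L])
        if (any(a < 1L | a > p) || any(b < 1L | b > p))
          stop("edge indices out of range")
      }
      keep <- a != b
      em <- unique(cbind(pmin(a[keep], b[keep]), pmax(a[keep], b[keep])))
    }
  }
  if (nrow(em)) {
    mod <- data$modality
    if (any(mod[em[, 1L]] != mod[em[, 2L]]))
      stop("edges across modalities are not allowed")
  }
  adjacency <- Matrix::sparseMatrix(
    i = c(em[, 1L], em[, 2L]), j = c(em[, 2L], em[, 1L]),
    x = 1, dims = c(p, p),
    dimnames = list(ids, ids))
  structure(list(nodes = ids, edges = em, adjacency = adjacency,
                 e = nrow(em), modality = data$modality, p = p),
            class = "bgb_graph")
}

#' @exportS3Method base::print
print.bgb_graph <- function(x, ...) {
  cat(sprintf("bgb_graph: %d nodes, %d edges\n", x$p, x$e))
  invisible(x)
}

#' Read a feature graph from an edge-list or adjacency file
#'
#' @param path a 2-column TSV edge list over feature identifiers (no
#'   header), or a MatrixMarket `.mtx` adjacency matrix in feature order.
#' @param data the [bgb_multiview()] object the graph refers to.
#' @return a [feature_graph()] object.
#' @export
read_graph <- function(path, data) {
  if (grepl("\\.mtx$", path)) {
    adj <- Matrix::readMM(path)
    if (nrow(adj) != data$p)
      stop("adjacency dimension does not match the data")
    return(feature_graph(as.matrix(adj) != 0, data))
  }
  info <- file.info(path)
  if (is.na(info$size)) stop("graph file not found: ", path)
  if (info$size == 0L)
    return(feature_graph(NULL, data))
  el <- read.table(path, header = FALSE, sep = "\t",
                   colClasses = "character")
  if (nrow(el) == 0L) return(feature_graph(NULL, data))
  feature_graph(as.matrix(el[, 1:2]), data)
}

#' Set of extracted biclusters
#'
#' @param biclusters list of `list(features = <int>, samples = <int>)`
#'   pairs; pairs with an empty feature or sample set are dropped.
#' @param provenance optional list of metadata (hyperparameters, DIC, seed).
#' @return an object of class `bgb_biclusters` with `L_hat` retained pairs.
#' @export
bgb_biclusters <- function(biclusters, provenance = NULL) {
  keep <- vapply(biclusters,
                 function(b) length(b$features) > 0L && length(b$samples) > 0L,
                 TRUE)
  biclusters <- lapply(biclusters[keep], function(b)
    list(features = as.integer(sort(b$features)),
         samples = as.integer(sort(b$samples)),
         factor = if (is.null(b$factor)) NA_integer_ else as.integer(b$factor)))
  structure(list(biclusters = biclusters, L_hat = length(biclusters),
                 provenance = provenance),
            class = "bgb_biclusters")
}

#' @exportS3Method base::print
print.bgb_biclusters <- function(x, ...) {
  cat(sprintf("bgb_biclusters: %d bicluster(s)\n", x$L_hat))
  for (k in seq_len(x$L_hat))
    cat(sprintf("  [%d] %d features x %d samples\n", k,
                length(x$biclusters[[k]]$features),
                length(x$biclusters[[k]]$samples)))
  invisible(x)
}

#' Write fitted results to a directory
#'
#' Writes `biclusters.json`, one membership CSV per bicluster, posterior
#' summaries of `W`, `Z` and `m` (means and credible bounds), and the DIC
#' table when present.
#'
#' @param biclusters a [bgb_biclusters()] object.
#' @param path output directory (created if needed).
#' @param summaries optional named list of data frames (e.g. posterior
#'   summaries, DIC table) written as `<name>.csv`.
#' @return invisibly, the paths written.
#' @export
write_results <- function(biclusters, path, summaries = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  out <- character(0)
  bj <- file.path(path, "biclusters.json")
  payload <- list(
    L_hat = biclusters$L_hat,
    biclusters = lapply(biclusters$biclusters, function(b)
      list(features = b$features, samples = b$samples)),
    provenance = biclusters$provenance)
  jsonlite::write_json(payload, bj, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  out <- c(out, bj)
  for (k in seq_len(biclusters$L_hat)) {
    fp <- file.path(path, sprintf("bicluster_%02d.csv", k))
    b <- biclusters$biclusters[[k]]
    nmax <- max(length(b$features), length(b$samples))
    df <- data.frame(
      feature_index = c(b$features, rep(NA, nmax - length(b$features))),
      sample_index = c(b$samples, rep(NA, nmax - length(b$samples))))
    write.csv(df, fp, row.names = FALSE)
    out <- c(out, fp)
  }
  for (nm in names(summaries)) {
    fp <- file.path(path, paste0(nm, ".csv"))
    write.csv(summaries[[nm]], fp, row.names = FALSE)
    out <- c(out, fp)
  }
  invisible(out)
}

#' Read a bicluster set written by [write_results()]
#'
#' @param path the output directory or the `biclusters.json` file itself.
#' @return a [bgb_biclusters()] object.
#' @export
read_biclusters <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "biclusters.json")
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  bl <- payload$biclusters
  if (is.data.frame(bl)) {
    bl <- lapply(seq_len(nrow(bl)), function(k)
      list(features = unlist(bl$features[k]), samples = unlist(bl$samples[k])))
  } else if (length(bl) == 0L) {
    bl <- list()
  }
  bgb_biclusters(bl, provenance = payload$provenance)
}
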