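# Sample clustering: PCA -> KNN graph -> Louvain communities, plus
# cluster-composition summaries.

#' Principal component analysis of scaled expression
#'
#' SVD-based PCA of a feature-scaled matrix (features x samples, already
#' centered per feature, e.g. [log_zscale()] output).  Scores are returned
#' for the first `n_pc` components; the sign of each component is fixed by
#' making its largest-magnitude loading positive.
#'
#' @param scaled_matrix features x samples matrix or `abundance_matrix`,
#'   z-scored per feature upstream.
#' @param n_pc number of components (default 5).
#' @return list of class `pca_result`: `scores` (samples x n_pc),
#'   `loadings` (features x n_pc), `explained_variance` and
#'   `prop_variance` per PC.
#' @export
pca <- function(scaled_matrix, n_pc = 5) {
  m <- .values(scaled_matrix)
  x <- t(m)  # samples x features
  if (n_pc > min(dim(x)))
    stop(sprintf("n_pc = %d exceeds min(dim) = %d", n_pc, min(dim(x))),
         call. = FALSE)
  sv <- svd(x)
  flip <- vapply(seq_len(n_pc), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, 0)
  flip[flip == 0] <- 1
  scores <- sweep(sv$u[, seq_len(n_pc), drop = FALSE] %*%
                    diag(sv$d[seq_len(n_pc)], n_pc), 2, flip, "*")
  loadings <- sweep(sv$v[, seq_len(n_pc), drop = FALSE], 2, flip, "*")
  rownames(scores) <- rownames(x)
  rownames(loadings) <- colnames(x)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(n_pc))
  ev <- sv$d^2 / max(1, nrow(x) - 1)
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = ev[seq_len(n_pc)],
                 prop_variance = (sv$d^2 / sum(sv$d^2))[seq_len(n_pc)],
                 d = sv$d),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d samples, %d PCs (%.1f%% variance)\n",
              nrow(x$scores), ncol(x$scores), 100 * sum(x$prop_variance)))
  invisible(x)
}

#' K-nearest-neighbor graph in PC space
#'
#' Connects each sample to its `k` nearest neighbors by Euclidean distance
#' in PC-score space; the directed neighbor relation is symmetrized into
#' an undirected graph and each edge is weighted by the Jaccard overlap of
#' the two endpoints' neighbor sets (shared-nearest-neighbor weight).
#'
#' @param scores samples x dims matrix, or a [pca_result()].
#' @param k neighbors per sample; must be < n samples.
#' @return An undirected weighted [igraph][igraph::graph] object with one
#'   vertex per sample.
#' @export
knn_graph <- function(scores, k = 20, metric = "euclidean") {
  if (inherits(scores, "pca_result")) scores <- scores$scores
  n <- nrow(scores)
  if (k >= n) stop(sprintf("k = %d must be < n samples = %d", k, n),
                   call. = FALSE)
  d <- as.matrix(dist(scores, method = metric))
  # k nearest, ties broken by index for determinism
  nbr <- lapply(seq_len(n), function(i) {
    ord <- order(d[i, -i])
    idx <- seq_len(n)[-i][ord]
    idx[seq_len(k)]
  })
  sets <- lapply(seq_len(n), function(i) c(i, nbr[[i]]))
  edges <- do.call(rbind, lapply(seq_len(n), function(i)
    cbind(pmin(i, nbr[[i]]), pmax(i, nbr[[i]]))))
  edges <- unique(edges)
  w <- vapply(seq_len(nrow(edges)), function(r) {
    a <- sets[[edges[r, 1]]]
    b <- sets[[edges[r, 2]]]
    length(intersect(a, b)) / length(union(a, b))
  }, 0)
  ids <- rownames(scores)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  g <- igraph::graph_from_data_frame(
    data.frame(from = ids[edges[, 1]], to = ids[edges[, 2]], weight = w),
    directed = FALSE,
    vertices = data.frame(name = ids))
  g
}

#' Louvain community clustering of the sample graph
#'
#' Modularity-based (Louvain) community detection on the weighted KNN
#' graph.  Deterministic for a fixed seed; cluster labels are renumbered
#' 1..K in decreasing order of cluster size.
#'
#' @param graph weighted undirected graph from [knn_graph()].
#' @param resolution modularity resolution (1.0 = classic modularity;
#'   larger values favor more clusters).
#' @param seed RNG seed for the (stochastic) community search.
#' @return list of class `cluster_assignment`: `labels` (named integer
#'   vector, contiguous from 1), `k`, `parameters`.
#' @export
community_clusters <- function(graph, resolution = 1.0, seed = 1) {
  if (igraph::vcount(graph) == 0) stop("empty graph", call. = FALSE)
  comm <- with_seed(seed, igraph::cluster_louvain(graph,
                                                  resolution = resolution))
  memb <- igraph::membership(comm)
  sizes <- table(memb)
  new_id <- setNames(seq_along(sizes),
                     names(sizes)[order(-as.vector(sizes),
                                        as.numeric(names(sizes)))])
  labels <- setNames(as.integer(new_id[as.character(memb)]), names(memb))
  structure(list(labels = labels, k = length(sizes),
                 parameters = list(resolution = resolution, seed = seed)),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d samples in %d clusters (sizes %s)\n",
              length(x$labels), x$k,
              paste(table(x$labels), collapse = ", ")))
  invisible(x)
}

#' Cluster composition versus a metadata field
#'
#' Cross-tabulates cluster assignment against a metadata category (e.g.
#' cell subtype or cohort) and tests independence with a chi-square test;
#' when any expected cell count is below 5 the p-value is computed by
#' Monte-Carlo simulation instead of the asymptotic distribution.
#'
#' @param assignment a [community_clusters()] result or named label vector.
#' @param metadata data.frame with a `sample_id` column.
#' @param field metadata column to tabulate.
#' @param seed RNG seed for the simulated p-value fallback.
#' @return list with `counts` (clusters x categories), `proportions`
#'   (within-cluster), `p` (NA when the test is undefined), and
#'   `n_excluded` samples without metadata.
#' @export
cluster_composition <- function(assignment, metadata, field, seed = 1) {
  labels <- if (inherits(assignment, "cluster_assignment"))
    assignment$labels else assignment
  if (!field %in% names(metadata))
    stop("field not in metadata: ", field, call. = FALSE)
  m <- match(names(labels), metadata$sample_id)
  n_excluded <- sum(is.na(m))
  if (n_excluded > 0)
    message(n_excluded, " sample(s) without metadata excluded")
  keep <- !is.na(m)
  cat_v <- metadata[[field]][m[keep]]
  counts <- table(cluster = labels[keep], category = cat_v)
  props <- counts / rowSums(counts)
  p <- NA_real_
  if (ncol(counts) > 1 && nrow(counts) > 1) {
    exp_counts <- outer(rowSums(counts), colSums(counts)) / sum(counts)
    p <- if (any(exp_counts < 5)) {
      with_seed(seed, chisq.test(counts, simulate.p.value = TRUE,
                                 B = 10000)$p.value)
    } else {
      chisq.test(counts)$p.value
    }
  }
  list(counts = counts, proportions = props, p = p,
       n_excluded = n_excluded)
}
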