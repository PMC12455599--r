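#' Low-dimensional spatial embedding of one SVG cluster
#'
#' The default `smoothed_pca` method replaces each gene's spot vector by a
#' Gaussian-kernel-weighted neighborhood average (bandwidth set from a
#' quantile of the nonzero pairwise distances) and then takes spot-wise
#' principal components of the smoothed gene set, so the components
#' emphasize spatially coherent variation. `pca` skips the smoothing;
#' `external` loads precomputed scores (e.g. from a dedicated spatial PCA
#' tool) from delimited text with a leading spot_id column.
#'
#' @param expr [expression_matrix()] restricted to one gene cluster.
#' @param coords aligned [spatial_coords()].
#' @param n_pcs components to return; default 5. Truncated with a warning
#'   when the cluster has fewer genes.
#' @param method `"smoothed_pca"`, `"pca"`, or `"external"`.
#' @param bandwidth_quantile quantile of the nonzero distance distribution
#'   used as smoothing bandwidth; default 0.05 (neighborhood scale).
#' @param bandwidth optional absolute bandwidth overriding
#'   `bandwidth_quantile`; as it tends to 0 the smoothing tends to the
#'   identity and `smoothed_pca` reduces to plain `pca`.
#' @param external_path scores file for `method = "external"`.
#' @return A `cluster_embedding`: spots x `n_pcs` score matrix with a
#'   `method` attribute; columns ordered by decreasing explained variance.
#' @export
embed_cluster <- function(expr, coords, n_pcs = 5,
                          method = c("smoothed_pca", "pca", "external"),
                          bandwidth_quantile = 0.05, bandwidth = NULL,
                          external_path = NULL) {
  method <- match.arg(method)
  N <- ncol(expr)
  if (method == "external") {
    if (is.null(external_path)) stop("external method needs external_path")
    dt <- data.table::fread(external_path, header = TRUE)
    sc <- as.matrix(dt[, -1L, drop = FALSE])
    if (nrow(sc) != N)
      stop("external embedding has ", nrow(sc), " rows but data has ",
           N, " spots")
    sc <- sc[match(colnames(expr), as.character(dt[[1L]])), , drop = FALSE]
    return(structure(sc, class = c("cluster_embedding", "matrix", "array"),
                     method = "external"))
  }
  Y <- unclass(expr)
  if (nrow(Y) < n_pcs) {
    warning("cluster has ", nrow(Y), " genes; truncating n_pcs")
    n_pcs <- nrow(Y)
  }
  if (method == "smoothed_pca") {
    D <- pairwise_distances(coords)
    bw <- if (!is.null(bandwidth)) bandwidth else
      as.numeric(stats::quantile(D[D > 0], bandwidth_quantile))
    if (bw <= 0) stop("bandwidth must be positive")
    W <- exp(-D^2 / (2 * bw^2))
    W <- W / rowSums(W)
    Y <- Y %*% t(W)                           # neighborhood-averaged genes
  }
  Xs <- t(Y)
  Xs <- sweep(Xs, 2L, colMeans(Xs))
  pc <- stats::prcomp(Xs, center = FALSE)
  sc <- pc$x[, seq_len(min(n_pcs, ncol(pc$x))), drop = FALSE]
  rownames(sc) <- colnames(expr)
  structure(sc, class = c("cluster_embedding", "matrix", "array"),
            method = method)
}

#' Aggregate per-cluster embeddings into the final embedding
#'
#' Column-wise concatenation of the per-cluster score blocks; each block is
#' rescaled to unit total variance so no single (large) gene cluster can
#' dominate the spot-clustering distance by scale alone.
#'
#' @param embeddings list of [embed_cluster()] results sharing the spot
#'   axis; names identify the contributing clusters.
#' @return An `aggregated_embedding` matrix (spots x total components) with
#'   a `provenance` attribute (data.frame of cluster and component index).
#' @export
aggregate_embeddings <- function(embeddings) {
  if (length(embeddings) == 0L) stop("no embeddings to aggregate")
  N <- nrow(embeddings[[1L]])
  if (!all(vapply(embeddings, nrow, integer(1)) == N))
    stop("embeddings have mismatched spot counts")
  nm <- names(embeddings)
  if (is.null(nm)) nm <- as.character(seq_along(embeddings))
  blocks <- list(); prov <- list()
  for (i in seq_along(embeddings)) {
    B <- unclass(embeddings[[i]])
    tv <- sum(apply(B, 2L, stats::var))
    if (tv > 0) B <- B / sqrt(tv)
    blocks[[i]] <- B
    prov[[i]] <- data.frame(cluster = nm[i], component = seq_len(ncol(B)),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(cbind, blocks)
  structure(out, class = c("aggregated_embedding", "matrix", "array"),
            provenance = do.call(rbind, prov))
}

# Shared-nearest-neighbor graph on embedding rows: k nearest neighbors by
# Euclidean distance, edges weighted by Jaccard overlap of neighbor sets.
snn_graph <- function(emb, k = 20L) {
  N <- nrow(emb)
  k <- min(k, N - 1L)
  D <- as.matrix(stats::dist(emb))
  nn <- matrix(0L, N, k)
  for (i in seq_len(N)) {
    ord <- order(D[i, ], seq_len(N))         # ties broken by index
    nn[i, ] <- ord[ord != i][seq_len(k)]
  }
  inc <- Matrix::sparseMatrix(i = rep(seq_len(N), each = k),
                              j = as.vector(t(nn)), x = 1, dims = c(N, N))
  shared <- Matrix::tcrossprod(inc)           # common neighbors
  shared <- as(shared, "TsparseMatrix")
  keep <- shared@i < shared@j
  ii <- shared@i[keep] + 1L; jj <- shared@j[keep] + 1L
  jac <- shared@x[keep] / (2 * k - shared@x[keep])
  ok <- jac > 1 / (2 * k)                     # prune near-zero overlaps
  g <- igraph::make_empty_graph(n = N, directed = FALSE)
  if (any(ok))
    g <- igraph::add_edges(g, rbind(ii[ok], jj[ok]), weight = jac[ok])
  g
}

#' Cluster spots into spatial domains
#'
#' Builds a shared-nearest-neighbor graph on the embedding rows and applies
#' community detection. In `known_k` mode the resolution is binary-searched
#' until exactly `k_d` communities are found (Walktrap instead cuts its
#' dendrogram at `k_d`); in `unknown_k` mode the fixed `resolution` is used
#' (default 1).
#'
#' @param embedding [aggregate_embeddings()] result (or any spots x p
#'   matrix).
#' @param mode `"unknown_k"` or `"known_k"`.
#' @param k_d target number of domains (required for `known_k`).
#' @param resolution resolution parameter for `unknown_k`; default 1.
#' @param method `"leiden"`, `"louvain"`, or `"walktrap"`.
#' @param seed RNG seed; default 0.
#' @param snn_k neighbors for the SNN graph; default 20.
#' @param max_iter resolution-search iterations; default 50.
#' @return A `domain_labels` integer vector (0-based contiguous labels) with
#'   `k_d`, `method`, and `resolution` attributes.
#' @export
cluster_spots <- function(embedding, mode = c("unknown_k", "known_k"),
                          k_d = NULL, resolution = 1.0,
                          method = c("leiden", "louvain", "walktrap"),
                          seed = 0L, snn_k = 20L, max_iter = 50L) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  if (mode == "known_k" && is.null(k_d)) stop("known_k mode requires k_d")
  emb <- unclass(embedding)
  if (all(apply(emb, 2L, function(v) diff(range(v))) == 0)) {
    lab <- rep(0L, nrow(emb))
    names(lab) <- rownames(emb)
    return(structure(lab, class = "domain_labels", k_d = 1L,
                     method = method, resolution = resolution))
  }
  g <- snn_graph(emb, k = snn_k)
  run <- function(res) {
    old <- if (exists(".Random.seed", envir = .GlobalEnv))
      get(".Random.seed", envir = .GlobalEnv) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old))
      assign(".Random.seed", old, envir = .GlobalEnv))
    cl <- switch(method,
      leiden = igraph::cluster_leiden(g, objective_function = "modularity",
                                      resolution = res, n_iterations = 10L),
      louvain = igraph::cluster_louvain(g, resolution = res),
      walktrap = igraph::cluster_walktrap(g))
    cl
  }
  if (method == "walktrap") {
    cl <- run(1)
    memb <- if (mode == "known_k")
      igraph::cut_at(cl, no = min(k_d, igraph::vcount(g)))
    else igraph::membership(cl)
  } else if (mode == "unknown_k") {
    memb <- igraph::membership(run(resolution))
  } else {
    lo <- 1e-4; hi <- 10; memb <- NULL; best <- NULL
    for (it in seq_len(max_iter)) {
      mid <- sqrt(lo * hi)
      m <- igraph::membership(run(mid))
      nk <- length(unique(m))
      if (is.null(best) || abs(nk - k_d) < best$diff)
        best <- list(memb = m, diff = abs(nk - k_d), res = mid)
      if (nk == k_d) { memb <- m; resolution <- mid; break }
      if (nk < k_d) lo <- mid else hi <- mid
    }
    if (is.null(memb)) {
      warning("could not reach exactly ", k_d, " domains; best achieved ",
              k_d + best$diff * sign(1), " off by ", best$diff)
      memb <- best$memb; resolution <- best$res
    }
  }
  lab <- as.integer(factor(memb)) - 1L
  names(lab) <- rownames(emb)
  structure(lab, class = "domain_labels", k_d = length(unique(lab)),
            method = method, resolution = resolution)
}

#' Per-cluster embedding arm of the domain detection pipeline
#'
#' For each non-singleton SVG cluster, computes a spatial embedding
#' ([embed_cluster()], five components by default), aggregates the blocks,
#' and clusters spots.
#'
#' @param expr [expression_matrix()] covering the SVGs.
#' @param coords aligned [spatial_coords()].
#' @param clusters `gene_clusters` data.frame from [cluster_svgs()].
#' @param n_pcs components per cluster; default 5.
#' @param include_singletons include singleton-flagged clusters; default
#'   `FALSE`.
#' @param embed_method,bandwidth_quantile passed to [embed_cluster()].
#' @param ... passed to [cluster_spots()].
#' @return A list with `labels` ([cluster_spots()] result), `embedding`,
#'   and `embeddings` (per-cluster list).
#' @export
detect_domains <- function(expr, coords, clusters, n_pcs = 5,
                           include_singletons = FALSE,
                           embed_method = "smoothed_pca",
                           bandwidth_quantile = 0.05, ...) {
  keep <- if (include_singletons) clusters else
    clusters[!clusters$singleton, , drop = FALSE]
  if (nrow(keep) == 0L) stop("no non-singleton gene clusters to embed")
  embeddings <- list()
  for (cid in sort(unique(keep$cluster))) {
    ids <- keep$gene_id[keep$cluster == cid]
    sub <- expression_matrix(unclass(expr)[ids, , drop = FALSE],
                             normalized = TRUE)
    embeddings[[as.character(cid)]] <-
      embed_cluster(sub, coords, n_pcs = n_pcs, method = embed_method,
                    bandwidth_quantile = bandwidth_quantile)
  }
  agg <- aggregate_embeddings(embeddings)
  labels <- cluster_spots(agg, ...)
  list(labels = labels, embedding = agg, embeddings = embeddings)
}

#' Baseline comparator: one embedding from the top SVGs
#'
#' The conventional arm used in all comparisons: a single spatial embedding
#' computed from the top `n_top_svgs` SVGs ranked by combined p-value, with
#' `n_pcs` components, followed by the same spot clustering.
#'
#' @param expr [expression_matrix()].
#' @param coords aligned [spatial_coords()].
#' @param svg_table [detect_svgs()] result.
#' @param n_top_svgs SVGs to embed; default 3000 (all detected SVGs when
#'   fewer are available).
#' @param n_pcs embedding components; default 20.
#' @param embed_method,bandwidth_quantile passed to [embed_cluster()].
#' @param ... passed to [cluster_spots()].
#' @return A list with `labels` and `embedding`.
#' @export
baseline_pipeline <- function(expr, coords, svg_table, n_top_svgs = 3000,
                              n_pcs = 20, embed_method = "smoothed_pca",
                              bandwidth_quantile = 0.05, ...) {
  svgs <- svg_table[svg_table$is_svg, , drop = FALSE]
  if (nrow(svgs) == 0L) stop("no detected SVGs for the baseline arm")
  if (nrow(svgs) < n_top_svgs) {
    warning("only ", nrow(svgs), " SVGs available; using all")
    n_top_svgs <- nrow(svgs)
  }
  ids <- svgs$gene_id[order(svgs$p_combined)][seq_len(n_top_svgs)]
  sub <- expression_matrix(unclass(expr)[ids, , drop = FALSE],
                           normalized = TRUE)
  emb <- embed_cluster(sub, coords, n_pcs = n_pcs, method = embed_method,
                       bandwidth_quantile = bandwidth_quantile)
  labels <- cluster_spots(unclass(emb), ...)
  list(labels = labels, embedding = emb)
}
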