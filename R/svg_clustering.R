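#' Select genes correlated with a target SVG
#'
#' Marginal Pearson correlation tests of the target against every other
#' detected SVG, Benjamini-Hochberg adjusted across the candidates for this
#' target; members are candidates with adjusted p at or below `alpha`.
#'
#' @param expr_svgs [expression_matrix()] restricted to detected SVGs.
#' @param target gene id of the SVG under consideration.
#' @param alpha selection level on the BH-adjusted correlation p-values.
#' @param method `"cor_test"` (Pearson test, default), `"spearman"`
#'   (rank-based test), or `"abs_r"` (threshold `|r| >= alpha` directly).
#' @return A `related_set` list: `target`, `members`, and a data.frame of
#'   per-candidate statistics (`gene_id`, `r`, `p_adj`).
#' @export
select_related <- function(expr_svgs, target, alpha = 0.05,
                           method = c("cor_test", "spearman", "abs_r")) {
  method <- match.arg(method)
  Y <- unclass(expr_svgs)
  if (!target %in% rownames(Y)) stop("target is not in the SVG set")
  y <- Y[target, ]
  if (stats::sd(y) == 0) stop("zero-variance target gene")
  others <- setdiff(rownames(Y), target)
  if (length(others) == 0L)
    return(structure(list(target = target, members = character(0),
                          stats = data.frame(gene_id = character(0),
                                             r = numeric(0),
                                             p_adj = numeric(0))),
                     class = "related_set"))
  M <- Y[others, , drop = FALSE]
  if (method == "spearman") {
    y_r <- rank(y)
    M <- t(apply(M, 1L, rank))
    r <- as.numeric(stats::cor(y_r, t(M)))
  } else {
    r <- as.numeric(stats::cor(y, t(M)))
  }
  r[is.na(r)] <- 0
  N <- length(y)
  if (method == "abs_r") {
    members <- others[abs(r) >= alpha]
    p_adj <- rep(NA_real_, length(r))
  } else {
    tt <- abs(r) * sqrt((N - 2) / pmax(1 - r^2, 1e-300))
    p <- 2 * stats::pt(tt, df = N - 2, lower.tail = FALSE)
    p_adj <- stats::p.adjust(p, method = "BH")
    members <- others[p_adj <= alpha]
  }
  structure(list(target = target, members = members,
                 stats = data.frame(gene_id = others, r = r, p_adj = p_adj,
                                    stringsAsFactors = FALSE)),
            class = "related_set")
}

#' Principal-component covariates from a related gene set
#'
#' With three or fewer related genes the member expression vectors are used
#' directly (raw mode, `k_j = 0`); with more, the top spot-wise principal
#' components of the centered member matrix are taken, keeping the smallest
#' number that explains at least `var_threshold` of the total variance.
#'
#' @param expr_members [expression_matrix()] (or matrix) restricted to the
#'   related set, genes x spots.
#' @param var_threshold cumulative explained-variance target; default 0.8.
#' @return A list with `covariates` (spots x columns) and `k_j` (number of
#'   PCs; 0 in raw mode).
#' @export
pc_covariates <- function(expr_members, var_threshold = 0.8) {
  M <- unclass(expr_members)
  if (nrow(M) < 1L) stop("empty related set")
  if (nrow(M) <= 3L)
    return(list(covariates = t(M), k_j = 0L))
  Xs <- t(M)                                  # spots x genes
  Xs <- sweep(Xs, 2L, colMeans(Xs))
  tv <- sum(Xs^2)
  if (tv <= 0) stop("related set has zero total variance")
  pc <- stats::prcomp(Xs, center = FALSE)
  frac <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  k_j <- which(frac >= var_threshold)[1L]
  list(covariates = pc$x[, seq_len(k_j), drop = FALSE], k_j = as.integer(k_j))
}

#' Covariate-adjusted spatial re-test of one SVG
#'
#' Re-runs the variance-component score test with the related-gene
#' covariates (PCs or raw members) in the mean model; an SVG that stays
#' significant after adjustment carries a spatial pattern its peers do not
#' explain.
#'
#' @param y target expression vector.
#' @param covariates spots x columns matrix from [pc_covariates()], or
#'   `NULL` for an intercept-only refit.
#' @param kernel_eig a [kernel_bank_eigen()] decomposition.
#' @param combine p-value combiner, as in [detect_svgs()].
#' @return A list with `p_adjusted` (combined), `p_kernel`, `k_used`
#'   (covariate columns actually retained), and `degenerate`.
#' @export
adjusted_test <- function(y, covariates, kernel_eig,
                          combine = c("cauchy", "minp")) {
  combine <- match.arg(combine)
  N <- length(y)
  X <- matrix(1, N, 1L)
  if (!is.null(covariates) && NCOL(covariates) > 0L) {
    X <- cbind(X, as.matrix(covariates))
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      warning("dropping collinear covariate columns")
      keep <- qrX$pivot[seq_len(qrX$rank)]
      if (!(1L %in% keep)) keep <- c(1L, keep[-length(keep)])
      X <- X[, sort(keep), drop = FALSE]
    }
  }
  fit <- fit_null(y, X)
  if (fit$degenerate)
    return(list(p_adjusted = 1, p_kernel = rep(1, length(kernel_eig)),
                k_used = ncol(X) - 1L, degenerate = TRUE))
  pk <- vapply(kernel_eig, function(ke) score_test(fit, ke)$p_value,
               numeric(1))
  comb_fun <- if (combine == "cauchy") combine_cauchy else combine_minp
  list(p_adjusted = comb_fun(pk), p_kernel = pk, k_used = ncol(X) - 1L,
       degenerate = FALSE)
}

#' Build the SVG dependency graph
#'
#' Nodes are detected SVGs. Every SVG whose adjusted test is no longer
#' significant (`unique_pattern = FALSE`) contributes edges to the
#' non-unique members of its related set, weighted by `|Pearson r|`;
#' parallel edges are merged keeping the maximum weight. Unique-pattern
#' SVGs carry a spatial signal their peers do not explain, are excluded
#' from every edge, and therefore always form singleton sets.
#'
#' @param svg_ids character vector of SVG gene ids (graph nodes).
#' @param related named list of [select_related()] results (one per SVG).
#' @param unique_pattern named logical vector (one entry per SVG).
#' @return An undirected weighted [igraph::graph] with vertex names.
#' @export
build_graph <- function(svg_ids, related, unique_pattern) {
  edges <- list()
  for (j in svg_ids) {
    if (isTRUE(unique_pattern[[j]])) next
    rs <- related[[j]]
    members <- rs$members[!vapply(rs$members, function(g)
      isTRUE(unique_pattern[[g]]), logical(1))]
    if (length(members) == 0L) next
    w <- abs(rs$stats$r[match(members, rs$stats$gene_id)])
    edges[[j]] <- data.frame(a = j, b = members, w = w,
                             stringsAsFactors = FALSE)
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(svg_ids), name = svg_ids)
  if (length(edges)) {
    ed <- do.call(rbind, edges)
    key <- ifelse(ed$a < ed$b, paste(ed$a, ed$b), paste(ed$b, ed$a))
    agg <- tapply(ed$w, key, max)
    ab <- do.call(rbind, strsplit(names(agg), " ", fixed = TRUE))
    g <- igraph::add_edges(g, as.vector(t(cbind(ab[, 1L], ab[, 2L]))),
                           weight = as.numeric(agg))
  }
  g
}

#' Leiden clustering of the SVG dependency graph
#'
#' Modularity optimization on the weighted graph; isolated nodes become
#' singletons and clusters smaller than `min_size` are flagged as
#' singleton-like (labels are retained).
#'
#' @param graph dependency graph from [build_graph()].
#' @param resolution Leiden resolution parameter; default 1.
#' @param seed RNG seed for the (stochastic) refinement; default 0.
#' @param min_size clusters below this size are flagged; default 5.
#' @return A `gene_clusters` data.frame: `gene_id`, `cluster`, `singleton`.
#' @export
cluster_genes <- function(graph, resolution = 1.0, seed = 0L, min_size = 5L) {
  if (igraph::vcount(graph) == 0L) stop("empty graph")
  old <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
  cl <- igraph::cluster_leiden(graph, objective_function = "modularity",
                               resolution = resolution, n_iterations = 10L)
  memb <- igraph::membership(cl)
  sizes <- table(memb)
  out <- data.frame(gene_id = igraph::V(graph)$name,
                    cluster = as.integer(memb),
                    singleton = as.integer(sizes[as.character(memb)]) < min_size,
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_clusters", "data.frame")
  attr(out, "n_clusters") <- length(sizes)
  attr(out, "min_size") <- min_size
  out
}

#' Cluster detected SVGs by spatial pattern
#'
#' Step 2 of the framework: for every detected SVG, select correlated peer
#' SVGs, re-test with their principal components as covariates, call
#' unique-pattern genes by BH on the adjusted combined p-values (same FDR
#' level as step 1), build the weighted dependency graph, and Leiden-cluster
#' it.
#'
#' @param expr [expression_matrix()] covering at least the SVGs.
#' @param svg_table result of [detect_svgs()].
#' @param kernel_eig the [kernel_bank_eigen()] used in step 1.
#' @param alpha related-gene selection level; default 0.05.
#' @param var_threshold PC explained-variance target; default 0.8.
#' @param fdr step-2 BH level for the unique-pattern call; defaults to the
#'   step-1 level stored on `svg_table`.
#' @param drop_ratio minimum fraction of a gene's log10 significance that
#'   must survive the covariate adjustment for the gene to be called
#'   unique-pattern (in addition to passing BH at `fdr`); default 0.5.
#'   Genes whose peers explain their pattern lose orders of magnitude of
#'   significance, while genuinely unique patterns are barely attenuated.
#' @param selection related-gene selection method, see [select_related()].
#' @param resolution,seed,min_size passed to [cluster_genes()].
#' @param combine p-value combiner, as in [detect_svgs()].
#' @return A list with `clusters` (a `gene_clusters` data.frame augmented
#'   with `k_j`, `p_adjusted`, `q_adjusted`, `unique_pattern`), `graph`,
#'   `related`, and `adjusted`.
#' @export
cluster_svgs <- function(expr, svg_table, kernel_eig, alpha = 0.05,
                         var_threshold = 0.8, fdr = NULL, drop_ratio = 0.5,
                         selection = "cor_test", resolution = 1.0,
                         seed = 0L, min_size = 5L,
                         combine = c("cauchy", "minp")) {
  combine <- match.arg(combine)
  if (is.null(fdr)) fdr <- attr(svg_table, "fdr")
  if (is.null(fdr)) fdr <- 0.05
  svg_ids <- svg_table$gene_id[svg_table$is_svg]
  if (length(svg_ids) < 2L)
    stop("need at least two detected SVGs to cluster")
  Y <- unclass(expr)[svg_ids, , drop = FALSE]
  expr_svgs <- expression_matrix(Y, normalized = TRUE)
  related <- list(); adjusted <- list()
  for (j in svg_ids) {
    rs <- select_related(expr_svgs, j, alpha = alpha, method = selection)
    related[[j]] <- rs
    if (length(rs$members) == 0L) {
      adjusted[[j]] <- adjusted_test(Y[j, ], NULL, kernel_eig, combine)
      adjusted[[j]]$k_j <- 0L
    } else {
      pcc <- pc_covariates(Y[rs$members, , drop = FALSE], var_threshold)
      adjusted[[j]] <- adjusted_test(Y[j, ], pcc$covariates, kernel_eig,
                                     combine)
      adjusted[[j]]$k_j <- pcc$k_j
    }
  }
  p_adj <- vapply(adjusted, `[[`, numeric(1), "p_adjusted")
  q_adj <- stats::p.adjust(p_adj, method = "BH")
  p_orig <- svg_table$p_combined[match(svg_ids, svg_table$gene_id)]
  retained <- log10(pmax(p_adj, 1e-15)) / log10(pmax(p_orig, 1e-15))
  unique_pattern <- q_adj <= fdr & retained >= drop_ratio
  names(unique_pattern) <- svg_ids
  graph <- build_graph(svg_ids, related, unique_pattern)
  clusters <- cluster_genes(graph, resolution = resolution, seed = seed,
                            min_size = min_size)
  idx <- match(clusters$gene_id, svg_ids)
  clusters$k_j <- vapply(adjusted, `[[`, integer(1), "k_j")[idx]
  clusters$p_adjusted <- p_adj[idx]
  clusters$q_adjusted <- q_adj[idx]
  clusters$unique_pattern <- unique_pattern[idx]
  list(clusters = clusters, graph = graph, related = related,
       adjusted = adjusted)
}
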