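test_that("select_related finds planted partners and perfect duplicates", {
  set.seed(31)
  n <- 300
  z <- rnorm(n)
  Y <- rbind(t1 = z,
             dup = z,                                     # exact copy
             partner = 0.9 * scale(z)[, 1] + sqrt(1 - 0.81) * rnorm(n),
             ind1 = rnorm(n), ind2 = rnorm(n))
  e <- expression_matrix(Y, normalized = TRUE)
  rs <- select_related(e, "t1")
  expect_true(all(c("dup", "partner") %in% rs$members))
  expect_false(rs$target %in% rs$members)
  expect_error(select_related(e, "absent"), "not in the SVG set")
  e0 <- expression_matrix(rbind(a = rep(1, 10), b = rnorm(10)),
                          normalized = TRUE)
  expect_error(select_related(e0, "a"), "zero-variance")
})

test_that("independent genes are rarely selected as related", {
  set.seed(32)
  hits <- 0L
  for (r in 1:20) {
    Y <- matrix(rnorm(8 * 400), 8, 400,
                dimnames = list(paste0("g", 1:8), NULL))
    e <- expression_matrix(Y, normalized = TRUE)
    rs <- select_related(e, "g1")
    if (length(rs$members) > 0) hits <- hits + 1L
  }
  expect_lte(hits, 5L)   # BH at 0.05 over 7 candidates, 20 replicates
})

test_that("pc_covariates follows the 80%-variance rule", {
  set.seed(33)
  # five identical genes: PC1 explains everything
  Y <- matrix(rep(rnorm(100), 5), 5, 100, byrow = TRUE,
              dimnames = list(paste0("g", 1:5), NULL))
  out <- pc_covariates(Y)
  expect_equal(out$k_j, 1L)
  # three or fewer members: raw mode
  out3 <- pc_covariates(Y[1:3, ])
  expect_equal(out3$k_j, 0L)
  expect_equal(ncol(out3$covariates), 3L)
  # planted spectrum: variance fractions (0.79, 0.16, 0.05) need 2 PCs
  n <- 400
  Q <- qr.Q(qr(matrix(rnorm(n * 3), n, 3)))
  S <- Q %*% diag(sqrt(c(0.79, 0.16, 0.05) * n))
  A <- matrix(rnorm(3 * 6), 3, 6)
  A <- qr.Q(qr(t(A)))[, 1:3]                 # orthonormal gene loadings
  M <- t(S %*% t(A))                          # 6 genes x n spots
  rownames(M) <- paste0("g", 1:6)
  out6 <- pc_covariates(M, var_threshold = 0.8)
  expect_equal(out6$k_j, 2L)
})

test_that("adjusted test removes peer-explained spatial signal", {
  set.seed(34)
  n <- 250
  co <- random_coords(n, seed = 34)
  keig <- kernel_bank_eigen(make_kernel_bank(co))
  pat <- pattern_value(2, unclass(co))
  y <- 1.5 * pat + rnorm(n, sd = 0.5)
  # unadjusted: strongly significant
  p0 <- adjusted_test(y, NULL, keig)$p_adjusted
  expect_lt(p0, 1e-4)
  # peers carrying the same pattern explain it away
  peers <- t(sapply(1:5, function(i) 1.5 * pat + rnorm(n, sd = 0.5)))
  pcc <- pc_covariates(peers)
  p1 <- adjusted_test(y, pcc$covariates, keig)$p_adjusted
  expect_gt(p1, 0.01)
  # an orthogonal pattern survives adjustment
  y2 <- 1.5 * pattern_value(5, unclass(co)) + rnorm(n, sd = 0.5)
  p2 <- adjusted_test(y2, pcc$covariates, keig)$p_adjusted
  expect_lt(p2, 1e-3)
  # self-regression is degenerate
  expect_equal(adjusted_test(y, cbind(y), keig)$p_adjusted, 1)
})

test_that("graph construction follows the literal edge rule", {
  rel <- list(
    g1 = list(target = "g1", members = "g2",
              stats = data.frame(gene_id = c("g2", "g3"), r = c(0.8, 0.1),
                                 p_adj = c(0.001, 0.9))),
    g2 = list(target = "g2", members = character(0),
              stats = data.frame(gene_id = character(0), r = numeric(0),
                                 p_adj = numeric(0))),
    g3 = list(target = "g3", members = "g1",
              stats = data.frame(gene_id = c("g1", "g2"), r = c(0.5, 0.2),
                                 p_adj = c(0.01, 0.5))))
  up <- c(g1 = FALSE, g2 = FALSE, g3 = TRUE)
  g <- build_graph(c("g1", "g2", "g3"), rel, up)
  expect_equal(igraph::vcount(g), 3L)
  expect_equal(igraph::ecount(g), 1L)       # g3 unique: no outgoing edge
  expect_equal(igraph::E(g)$weight, 0.8)
  expect_equal(igraph::degree(g, "g3"), c(g3 = 0))
  # symmetric pair listing each other collapses to one max-weight edge
  rel2 <- list(
    a = list(target = "a", members = "b",
             stats = data.frame(gene_id = "b", r = 0.6, p_adj = 0.01)),
    b = list(target = "b", members = "a",
             stats = data.frame(gene_id = "a", r = -0.7, p_adj = 0.01)))
  g2 <- build_graph(c("a", "b"), rel2, c(a = FALSE, b = FALSE))
  expect_equal(igraph::ecount(g2), 1L)
  expect_equal(igraph::E(g2)$weight, 0.7)
})

test_that("leiden gene clustering recovers cliques and singletons", {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, 9, name = paste0("g", 1:9))
  cl1 <- t(combn(1:4, 2)); cl2 <- t(combn(5:8, 2))
  g <- igraph::add_edges(g, t(rbind(cl1, cl2)), weight = 1)
  out <- cluster_genes(g, seed = 0, min_size = 3)
  expect_equal(length(unique(out$cluster)), 3L)
  expect_length(unique(out$cluster[1:4]), 1L)
  expect_length(unique(out$cluster[5:8]), 1L)
  expect_true(out$singleton[9])              # isolated node
  expect_false(any(out$singleton[1:8]))
  # determinism at fixed seed
  out2 <- cluster_genes(g, seed = 0, min_size = 3)
  expect_identical(out, out2)
  expect_error(cluster_genes(igraph::make_empty_graph(0, FALSE)), "empty")
})

test_that("leiden matches exhaustive maximum-modularity search on a toy", {
  set.seed(35)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, 8, name = paste0("g", 1:8))
  edges <- rbind(c(1, 2), c(1, 3), c(2, 3), c(3, 4),
                 c(4, 5), c(5, 6), c(5, 7), c(6, 7), c(7, 8))
  w <- c(0.9, 0.8, 0.85, 0.2, 0.15, 0.9, 0.8, 0.95, 0.7)
  g <- igraph::add_edges(g, t(edges), weight = w)
  best <- -Inf
  for (p in all_partitions(8)) {
    m <- igraph::modularity(g, p, weights = igraph::E(g)$weight)
    if (m > best) { best <- m; bestp <- p }
  }
  out <- cluster_genes(g, seed = 0, min_size = 1)
  expect_equal(igraph::modularity(g, out$cluster,
                                  weights = igraph::E(g)$weight),
               best, tolerance = 1e-12)
  expect_equal(ari(out$cluster, bestp), 1)
})

test_that("scenario-I SVGs cluster by their spatial pattern", {
  set.seed(36)
  sim <- simulate_scenario1(n_spots = 400,
                            effect_grid = seq(1, 2, length.out = 10),
                            seed = 36)
  keig <- kernel_bank_eigen(make_kernel_bank(sim$coords))
  st <- detect_svgs(sim$expr, sim$coords, kernel_eig = keig)
  out <- cluster_svgs(sim$expr, st, keig)
  cc <- out$clusters
  truth <- sim$truth$cluster_label[match(cc$gene_id, sim$truth$gene_id)]
  expect_gte(ari(cc$cluster, truth), 0.8)
  # within-pattern-group edge density exceeds between-group density
  ed <- igraph::as_data_frame(out$graph, what = "edges")
  grp <- function(id) sim$truth$cluster_label[sim$truth$gene_id == id]
  same <- mapply(function(a, b) grp(a) == grp(b), ed$from, ed$to)
  n_nodes <- igraph::vcount(out$graph)
  expect_gt(mean(same), 0.5)
})
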