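test_that("cluster embedding has the requested width and PCA limit", {
  set.seed(41)
  n <- 150
  co <- random_coords(n, seed = 41)
  e <- random_expr(12, n, seed = 41, spot_ids = rownames(co))
  emb <- embed_cluster(e, co)
  expect_equal(ncol(emb), 5L)
  expect_equal(nrow(emb), n)
  # columns ordered by decreasing variance
  expect_true(all(diff(apply(unclass(emb), 2, var)) <= 1e-12))
  # n_pcs truncated when the cluster is small
  expect_warning(emb3 <- embed_cluster(
    expression_matrix(unclass(e)[1:3, ], normalized = TRUE), co), "truncating")
  expect_equal(ncol(emb3), 3L)
  # vanishing bandwidth: smoothing tends to the identity
  emb_pca <- embed_cluster(e, co, method = "pca")
  emb_sm <- embed_cluster(e, co, bandwidth = 1e-4)
  for (j in 1:5) {
    r <- abs(cor(emb_pca[, j], emb_sm[, j]))
    expect_gt(r, 0.999)
  }
})

test_that("first component of a two-domain cluster separates the domains", {
  set.seed(42)
  n <- 300
  co <- random_coords(n, seed = 42)
  left <- as.integer(unclass(co)[, 1] < 0.5)
  Y <- t(sapply(1:8, function(i) left * 2 + rnorm(n, sd = 0.7)))
  rownames(Y) <- paste0("g", 1:8)
  e <- expression_matrix(Y, spot_ids = rownames(co), normalized = TRUE)
  emb <- embed_cluster(e, co)
  expect_gt(abs(cor(emb[, 1], left)), 0.9)
})

test_that("external embeddings are validated and reordered by spot id", {
  n <- 30
  co <- random_coords(n, seed = 43)
  e <- random_expr(5, n, seed = 43, spot_ids = rownames(co))
  sc <- matrix(rnorm(n * 2), n, 2)
  f <- tempfile(fileext = ".tsv")
  perm <- sample(n)
  data.table::fwrite(data.table::data.table(
    spot_id = rownames(co)[perm], a = sc[perm, 1], b = sc[perm, 2]),
    f, sep = "\t")
  emb <- embed_cluster(e, co, method = "external", external_path = f)
  expect_equal(unclass(emb), sc, ignore_attr = TRUE)
  f2 <- tempfile(fileext = ".tsv")
  data.table::fwrite(data.table::data.table(spot_id = "x", a = 1), f2,
                     sep = "\t")
  expect_error(embed_cluster(e, co, method = "external",
                             external_path = f2), "spots")
})

test_that("aggregation concatenates blocks with unit block variance", {
  set.seed(44)
  n <- 100
  embs <- lapply(1:3, function(i)
    structure(matrix(rnorm(n * 5, sd = i * 3), n, 5,
                     dimnames = list(paste0("s", 1:n), NULL)),
              class = c("cluster_embedding", "matrix", "array")))
  names(embs) <- c("c1", "c2", "c3")
  agg <- aggregate_embeddings(embs)
  expect_equal(ncol(agg), 15L)
  prov <- attr(agg, "provenance")
  expect_equal(nrow(prov), 15L)
  expect_equal(unique(prov$cluster), c("c1", "c2", "c3"))
  for (cl in unique(prov$cluster)) {
    block <- unclass(agg)[, prov$cluster == cl, drop = FALSE]
    expect_equal(sum(apply(block, 2, var)), 1, tolerance = 1e-12)
  }
  single <- aggregate_embeddings(embs[1])
  expect_equal(ncol(single), 5L)
  expect_error(aggregate_embeddings(list()), "no embeddings")
})

test_that("spot clustering separates blobs and is deterministic", {
  set.seed(45)
  emb <- rbind(matrix(rnorm(100 * 2, mean = 0, sd = 0.3), ncol = 2),
               matrix(rnorm(80 * 2, mean = 5, sd = 0.3), ncol = 2))
  rownames(emb) <- paste0("s", 1:180)
  truth <- rep(0:1, c(100, 80))
  lab <- cluster_spots(emb, mode = "known_k", k_d = 2)
  expect_equal(attr(lab, "k_d"), 2L)
  expect_equal(ari(as.integer(lab), truth), 1)
  lab2 <- cluster_spots(emb, mode = "known_k", k_d = 2)
  expect_identical(as.integer(lab), as.integer(lab2))
  # identical embedding rows collapse into one domain in unknown_k mode
  flat <- matrix(1, 60, 3, dimnames = list(paste0("s", 1:60), NULL))
  lab3 <- cluster_spots(flat, mode = "unknown_k")
  expect_equal(attr(lab3, "k_d"), 1L)
  # walktrap with a fixed domain count
  lab4 <- cluster_spots(emb, mode = "known_k", k_d = 2,
                        method = "walktrap")
  expect_equal(ari(as.integer(lab4), truth), 1)
  expect_error(cluster_spots(emb, mode = "known_k"), "requires k_d")
})

test_that("permuting cluster order leaves domain labels unchanged", {
  set.seed(46)
  n <- 200
  co <- grid_coords(20, 10)
  band <- as.integer(cut(unclass(co)[, 2], c(0, 4, 7, 10),
                         include.lowest = TRUE))
  embs <- lapply(1:3, function(cl) {
    B <- sapply(1:5, function(j) (band == cl) * 2 + rnorm(n, sd = 0.4))
    rownames(B) <- rownames(co)
    structure(B, class = c("cluster_embedding", "matrix", "array"))
  })
  names(embs) <- c("a", "b", "c")
  l1 <- cluster_spots(aggregate_embeddings(embs),
                      mode = "known_k", k_d = 3)
  l2 <- cluster_spots(aggregate_embeddings(embs[c(3, 1, 2)]),
                      mode = "known_k", k_d = 3)
  expect_equal(ari(as.integer(l1), as.integer(l2)), 1)
})

test_that("baseline arm uses top SVGs and defaults to 20 components", {
  set.seed(47)
  tmpl <- builtin_template(n_spots = 350, n_domains = 3, seed = 47)
  sim <- simulate_domain_dataset(tmpl, n_genes = 60,
                                 svg_counts = c(15, 10, 15), seed = 47)
  keig <- kernel_bank_eigen(make_kernel_bank(sim$coords))
  st <- detect_svgs(sim$expr, sim$coords, kernel_eig = keig)
  expect_warning(bl <- baseline_pipeline(sim$expr, sim$coords, st,
                                         mode = "known_k", k_d = 3),
                 "using all")
  expect_equal(ncol(bl$embedding), 20L)
  expect_equal(length(bl$labels), 350L)
})

test_that("embedding and labels are invariant to rigid motion", {
  set.seed(48)
  n <- 200
  co <- random_coords(n, seed = 48)
  e <- random_expr(10, n, seed = 48, spot_ids = rownames(co))
  emb1 <- embed_cluster(e, co)
  emb2 <- embed_cluster(e, rigid_motion(co))
  for (j in 1:5)
    expect_gt(abs(cor(emb1[, j], emb2[, j])), 0.999)
})
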