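#' Deterministic spatial pattern fields
#'
#' Six smooth fields on the unit square used as simulation ground truth:
#' 1 = linear gradient, 2 = central radial hotspot, 3 = diagonal stripe,
#' 4 = two-hotspot, 5 = periodic bands, 6 = corner quadrant. All are scaled
#' to `[0, 1]` and are pairwise weakly correlated, so the patterns are
#' mutually distinguishable.
#'
#' @param pattern_id integer in 1..6.
#' @param s coordinates: numeric vector of length 2 or an N x 2 matrix with
#'   values in the unit square.
#' @return Field value(s) in `[0, 1]`.
#' @export
pattern_value <- function(pattern_id, s) {
  if (!pattern_id %in% 1:6) stop("unknown pattern_id: ", pattern_id)
  s <- if (is.matrix(s)) s else matrix(s, ncol = 2)
  x <- s[, 1L]; y <- s[, 2L]
  switch(pattern_id,
    x,
    exp(-((x - 0.5)^2 + (y - 0.5)^2) / (2 * 0.15^2)),
    exp(-(x - y)^2 / (2 * 0.12^2)),
    pmax(exp(-((x - 0.15)^2 + (y - 0.5)^2) / (2 * 0.12^2)),
         exp(-((x - 0.85)^2 + (y - 0.5)^2) / (2 * 0.12^2))),
    0.5 * (1 + sin(4 * pi * y)),
    stats::plogis((x - 0.75) / 0.05) * stats::plogis((y - 0.75) / 0.05))
}

# Within-group gene-gene correlation matrix: compound symmetry or AR(1).
group_corr <- function(n, rho, structure = c("CS", "AR1")) {
  structure <- match.arg(structure)
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  if (structure == "CS") {
    R <- matrix(rho, n, n); diag(R) <- 1
  } else {
    R <- rho^abs(outer(seq_len(n), seq_len(n), "-"))
  }
  R
}

# N x n matrix of noise, columns correlated according to R, rows iid.
correlated_noise <- function(N, R, sd = 1) {
  matrix(stats::rnorm(N * ncol(R)), N, ncol(R)) %*% chol(R) * sd
}

#' Simulate the SVG-classification study (scenario I)
#'
#' Generates 53 genes across `n_spots` locations: g1-g10 independent noise,
#' g11-g20 within-group-correlated but non-spatial, g21-g30 / g31-g40 /
#' g41-g50 three patterned groups whose spatial effect strength increases
#' with gene index (the `effect_grid`), and g51-g53 three unique-pattern
#' genes at the strongest effect. Within-group noise follows a compound
#' symmetry or AR(1) correlation structure with parameter `rho`.
#'
#' @param n_spots number of spots; default 2000.
#' @param rho within-group gene correlation; default 0.6.
#' @param structure `"CS"` or `"AR1"`.
#' @param effect_grid strictly increasing spatial-effect multipliers, one
#'   per gene within each patterned group; default 10 values 0.2..2.
#' @param noise_sd residual standard deviation; default 1.
#' @param seed RNG seed.
#' @return A `simulated_dataset` list: `expr` ([expression_matrix()]),
#'   `coords`, and `truth` (data.frame with `gene_id`, `label`,
#'   `cluster_label` for detected-SVG evaluation, and `effect`).
#' @export
simulate_scenario1 <- function(n_spots = 2000, rho = 0.6,
                               structure = c("CS", "AR1"),
                               effect_grid = seq(0.2, 2, length.out = 10),
                               noise_sd = 1, seed = 1L) {
  structure <- match.arg(structure)
  if (is.unsorted(effect_grid, strictly = TRUE))
    stop("effect_grid must be strictly increasing")
  ng <- length(effect_grid)
  set.seed(seed)
  xy <- cbind(x = stats::runif(n_spots), y = stats::runif(n_spots))
  coords <- spatial_coords(xy, paste0("s", seq_len(n_spots)))
  R <- group_corr(ng, rho, structure)
  blocks <- list()
  blocks$noise <- matrix(stats::rnorm(n_spots * 10, sd = noise_sd),
                         n_spots, 10)
  blocks$correlated <- correlated_noise(n_spots, group_corr(10, rho,
                                                            structure),
                                        noise_sd)
  for (p in 1:3) {
    mean_field <- pattern_value(p, xy)
    blocks[[paste0("pattern", p)]] <-
      outer(mean_field, effect_grid) + correlated_noise(n_spots, R, noise_sd)
  }
  uniq <- sapply(4:6, function(p)
    pattern_value(p, xy) * max(effect_grid) +
      stats::rnorm(n_spots, sd = noise_sd))
  Y <- t(cbind(blocks$noise, blocks$correlated, blocks$pattern1,
               blocks$pattern2, blocks$pattern3, uniq))
  rownames(Y) <- paste0("g", seq_len(nrow(Y)))
  labels <- c(rep("noise", 10), rep("correlated", 10),
              rep("pattern1", ng), rep("pattern2", ng), rep("pattern3", ng),
              paste0("unique", 4:6))
  effects <- c(rep(0, 20), rep(effect_grid, 3), rep(max(effect_grid), 3))
  truth <- data.frame(gene_id = rownames(Y), label = labels,
                      cluster_label = labels, effect = effects,
                      stringsAsFactors = FALSE)
  structure(list(expr = expression_matrix(Y,
                                          spot_ids = rownames(coords),
                                          normalized = TRUE),
                 coords = coords, truth = truth,
                 config = list(n_spots = n_spots, rho = rho,
                               structure = structure,
                               effect_grid = effect_grid,
                               noise_sd = noise_sd, seed = seed)),
            class = "simulated_dataset")
}

#' Built-in layered-tissue domain template
#'
#' A synthetic stand-in for an annotated cortical section: spots on a
#' jittered grid in the unit square, partitioned into `n_domains` curved
#' parallel bands of roughly equal area (layers). Gene cluster 1 maps to
#' the first band, cluster 2 to the middle bands, and cluster 3 to the last
#' band (the white-matter analog).
#'
#' @param n_spots number of spots; default 3484.
#' @param n_domains number of layers; default 5.
#' @param seed RNG seed for the grid jitter.
#' @return A `domain_template` list: `coords`, `domains` (integer labels
#'   1..n_domains), and `cluster_map` (list mapping gene clusters to domain
#'   sets).
#' @export
builtin_template <- function(n_spots = 3484, n_domains = 5, seed = 1L) {
  if (n_domains < 2) stop("need at least two domains")
  set.seed(seed)
  g <- ceiling(sqrt(n_spots))
  grid <- expand.grid(x = (seq_len(g) - 0.5) / g, y = (seq_len(g) - 0.5) / g)
  grid <- grid[seq_len(n_spots), ]
  xy <- as.matrix(grid) + matrix(stats::runif(2 * n_spots, -0.3 / g, 0.3 / g),
                                 ncol = 2)
  band_coord <- xy[, 2L] + 0.12 * sin(2 * pi * xy[, 1L])
  domains <- as.integer(cut(band_coord,
                            stats::quantile(band_coord,
                                            seq(0, 1, length.out = n_domains + 1)),
                            include.lowest = TRUE))
  middle <- if (n_domains > 2) 2:(n_domains - 1) else 1L
  structure(list(coords = spatial_coords(xy, paste0("s", seq_len(n_spots))),
                 domains = domains,
                 cluster_map = list(`1` = 1L, `2` = middle,
                                    `3` = n_domains)),
            class = "domain_template")
}

#' Simulate the domain-detection study dataset
#'
#' Emulates a filtered spot-level dataset on a layered-tissue template:
#' gene baselines and dispersions are drawn from log-normal distributions
#' (documented defaults, re-fittable from any real matrix), a random subset
#' of genes is converted to SVGs overexpressed on the domain set of their
#' assigned cluster, and the remaining genes are spatially unstructured
#' noise.
#'
#' @param template a [builtin_template()] (or compatible) object.
#' @param n_genes total genes; default 4865.
#' @param svg_counts SVGs per gene cluster; default `c(800, 150, 1050)`.
#' @param effect overexpression shift in units of the gene's own standard
#'   deviation; default 1.
#' @param mean_meanlog,mean_sdlog log-normal parameters for gene baseline
#'   means; defaults 0 and 0.5.
#' @param sd_meanlog,sd_sdlog log-normal parameters for gene standard
#'   deviations; defaults -0.25 and 0.3.
#' @param seed RNG seed.
#' @return A `simulated_dataset` list: `expr`, `coords`, `truth` (gene
#'   labels: cluster 1..3 or 0 for noise genes), and `domains` (true spot
#'   labels).
#' @export
simulate_domain_dataset <- function(template, n_genes = 4865,
                                    svg_counts = c(800, 150, 1050),
                                    effect = 1,
                                    mean_meanlog = 0, mean_sdlog = 0.5,
                                    sd_meanlog = -0.25, sd_sdlog = 0.3,
                                    seed = 1L) {
  if (sum(svg_counts) > n_genes)
    stop("svg_counts exceed the total number of genes")
  if (any(svg_counts <= 0)) stop("svg_counts must be positive")
  set.seed(seed)
  coords <- template$coords
  N <- nrow(coords)
  domains <- template$domains
  mu <- stats::rlnorm(n_genes, mean_meanlog, mean_sdlog)
  sdg <- stats::rlnorm(n_genes, sd_meanlog, sd_sdlog)
  svg_idx <- sample.int(n_genes, sum(svg_counts))
  cluster <- integer(n_genes)
  cluster[svg_idx] <- rep(seq_along(svg_counts), svg_counts)
  Y <- matrix(stats::rnorm(n_genes * N, sd = rep(sdg, N)), n_genes, N) + mu
  for (cl in seq_along(svg_counts)) {
    on_spots <- domains %in% template$cluster_map[[as.character(cl)]]
    rows <- which(cluster == cl)
    Y[rows, on_spots] <- Y[rows, on_spots] + effect * sdg[rows]
  }
  rownames(Y) <- paste0("g", seq_len(n_genes))
  truth <- data.frame(gene_id = rownames(Y), cluster = cluster,
                      is_svg = cluster > 0, stringsAsFactors = FALSE)
  structure(list(expr = expression_matrix(Y, spot_ids = rownames(coords),
                                          normalized = TRUE),
                 coords = coords, truth = truth, domains = domains,
                 config = list(n_genes = n_genes, svg_counts = svg_counts,
                               effect = effect, seed = seed)),
            class = "simulated_dataset")
}

#' Write a simulated dataset in the formats the pipeline reads
#'
#' Emits `matrix.mtx` + `features.tsv` + `barcodes.tsv`, `coords.tsv`,
#' `truth_genes.tsv`, and (for domain simulations) `truth_domains.tsv`.
#' Simulated values are shifted to be nonnegative before the MTX write so
#' the file round-trips through [load_expression()]; the shift is recorded
#' in `offset.tsv`.
#'
#' @param sim a `simulated_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  v <- unclass(sim$expr)
  offset <- min(0, min(v))
  write_expression(raw_counts(v - offset), file.path(dir, "matrix.mtx"))
  data.table::fwrite(data.table::data.table(offset = offset),
                     file.path(dir, "offset.tsv"), sep = "\t")
  write_coords(sim$coords, file.path(dir, "coords.tsv"))
  data.table::fwrite(sim$truth, file.path(dir, "truth_genes.tsv"),
                     sep = "\t")
  if (!is.null(sim$domains))
    data.table::fwrite(data.table::data.table(
      spot_id = rownames(sim$coords), domain = sim$domains),
      file.path(dir, "truth_domains.tsv"), sep = "\t")
  invisible(dir)
}
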