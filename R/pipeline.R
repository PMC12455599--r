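#' Default pipeline configuration
#'
#' Returns the full nested configuration list with every tunable of the
#' pipeline at its default. Any subset can be overridden by the `config`
#' argument of [run_pipeline()] (lists are merged recursively) or by a YAML
#' file with the same structure.
#'
#' @return A named list of config blocks: `kernel`, `test`, `step2`,
#'   `embed`, `domains`, and `seed`.
#' @export
default_config <- function() {
  list(
    kernel = list(n_each = 5, quantiles = c(0.1, 0.25, 0.5, 0.75, 0.9),
                  families = c("gaussian", "cosine"), eigen_tol = 1e-7),
    test = list(fdr = 0.05, combine = "cauchy"),
    filter = list(min_frac = 0.01),
    normalize = list(method = "lognorm"),
    step2 = list(alpha = 0.05, selection = "cor_test", var_threshold = 0.8,
                 drop_ratio = 0.5, min_size = 5, resolution = 1.0, seed = 0),
    embed = list(method = "smoothed_pca", n_pcs = 5,
                 bandwidth_quantile = 0.05),
    domains = list(method = "leiden", mode = "unknown_k", k_d = NULL,
                   resolution = 1.0, seed = 0, snn_k = 20),
    baseline = list(n_top_svgs = 3000, n_pcs = 20),
    seed = 0
  )
}

merge_config <- function(base, override) {
  if (is.null(override)) return(base)
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

load_config <- function(config) {
  base <- default_config()
  if (is.null(config)) return(base)
  if (is.character(config)) config <- yaml::read_yaml(config)
  merge_config(base, config)
}

#' Run the full SVG-clustering domain-detection pipeline
#'
#' Executes: normalization (unless the input is an [expression_matrix()]
#' already flagged normalized), SVG detection over the kernel bank, SVG
#' clustering by spatial pattern, per-cluster embedding and aggregation,
#' and spot clustering into spatial domains. Optionally also runs the
#' single-embedding baseline arm and, when truth labels are supplied,
#' evaluates both arms with ARI and PAS.
#'
#' @param expr [raw_counts()] or [expression_matrix()] (genes x spots).
#' @param coords [spatial_coords()].
#' @param config nested config list or YAML path; see [default_config()].
#' @param baseline also run the top-SVG single-embedding comparator arm.
#' @param truth_domains optional true spot labels for evaluation.
#' @param truth_gene_clusters optional true gene-cluster labels (named by
#'   gene id) for evaluation of the SVG clustering.
#' @param outdir optional directory; when given, all result tables are
#'   written as TSV plus a `summary.json`.
#' @return A `run_result` list: `svg_table`, `clusters`, `domains`
#'   (main arm), `domains_baseline` (optional), `metrics`, `config`.
#' @export
run_pipeline <- function(expr, coords, config = NULL, baseline = FALSE,
                      truth_domains = NULL, truth_gene_clusters = NULL,
                      outdir = NULL) {
  cfg <- load_config(config)
  t0 <- proc.time()[["elapsed"]]
  if (!inherits(expr, "expression_matrix")) {
    expr <- filter_genes(expr, cfg$filter$min_frac)
    expr <- normalize_counts(expr, cfg$normalize$method)
  }
  al <- align_spots(expr, coords)
  expr <- al$expr; coords <- al$coords

  bank <- make_kernel_bank(coords, n_each = cfg$kernel$n_each,
                           quantiles = cfg$kernel$quantiles,
                           families = cfg$kernel$families)
  keig <- kernel_bank_eigen(bank, tol = cfg$kernel$eigen_tol)
  svg_table <- detect_svgs(expr, coords, fdr = cfg$test$fdr,
                           combine = cfg$test$combine, kernel_eig = keig)
  step2 <- cluster_svgs(expr, svg_table, keig,
                        alpha = cfg$step2$alpha,
                        var_threshold = cfg$step2$var_threshold,
                        drop_ratio = cfg$step2$drop_ratio,
                        selection = cfg$step2$selection,
                        resolution = cfg$step2$resolution,
                        seed = cfg$step2$seed,
                        min_size = cfg$step2$min_size,
                        combine = cfg$test$combine)
  dom_args <- list(mode = cfg$domains$mode, k_d = cfg$domains$k_d,
                   resolution = cfg$domains$resolution,
                   method = cfg$domains$method, seed = cfg$domains$seed,
                   snn_k = cfg$domains$snn_k)
  main <- do.call(detect_domains,
                  c(list(expr = expr, coords = coords,
                         clusters = step2$clusters,
                         n_pcs = cfg$embed$n_pcs,
                         embed_method = cfg$embed$method,
                         bandwidth_quantile = cfg$embed$bandwidth_quantile),
                    dom_args))
  base_arm <- NULL
  if (isTRUE(baseline)) {
    base_arm <- do.call(baseline_pipeline,
                        c(list(expr = expr, coords = coords,
                               svg_table = svg_table,
                               n_top_svgs = cfg$baseline$n_top_svgs,
                               n_pcs = cfg$baseline$n_pcs,
                               embed_method = cfg$embed$method,
                               bandwidth_quantile =
                                 cfg$embed$bandwidth_quantile),
                          dom_args))
  }
  metrics <- list(n_genes = nrow(expr), n_spots = ncol(expr),
                  n_svgs = sum(svg_table$is_svg),
                  n_gene_clusters =
                    length(unique(step2$clusters$cluster[!step2$clusters$singleton])),
                  n_domains = attr(main$labels, "k_d"),
                  pas = pas(as.integer(main$labels), coords))
  if (!is.null(truth_domains)) {
    metrics$ari <- ari(as.integer(main$labels), truth_domains)
    if (!is.null(base_arm)) {
      metrics$ari_baseline <- ari(as.integer(base_arm$labels), truth_domains)
      metrics$pas_baseline <- pas(as.integer(base_arm$labels), coords)
    }
  } else if (!is.null(base_arm)) {
    metrics$pas_baseline <- pas(as.integer(base_arm$labels), coords)
  }
  if (!is.null(truth_gene_clusters)) {
    ids <- step2$clusters$gene_id
    known <- ids %in% names(truth_gene_clusters)
    metrics$ari_gene_clusters <-
      ari(step2$clusters$cluster[known],
          unname(truth_gene_clusters[ids[known]]))
  }
  metrics$elapsed_sec <- round(proc.time()[["elapsed"]] - t0, 2)
  result <- structure(list(svg_table = svg_table, clusters = step2$clusters,
                           graph = step2$graph, domains = main$labels,
                           embedding = main$embedding,
                           domains_baseline =
                             if (is.null(base_arm)) NULL else base_arm$labels,
                           metrics = metrics, config = cfg),
                      class = "run_result")
  if (!is.null(outdir)) write_run_result(result, coords, outdir)
  result
}

# Write every pipeline output table plus a machine-readable summary.
write_run_result <- function(result, coords, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(result$svg_table, file.path(outdir, "svgs.tsv"),
                     sep = "\t")
  data.table::fwrite(result$clusters, file.path(outdir, "gene_clusters.tsv"),
                     sep = "\t")
  ed <- igraph::as_data_frame(result$graph, what = "edges")
  names(ed) <- c("gene_a", "gene_b", "weight")[seq_len(ncol(ed))]
  data.table::fwrite(ed, file.path(outdir, "edges.tsv"), sep = "\t")
  data.table::fwrite(data.table::data.table(
    spot_id = rownames(coords), label = as.integer(result$domains)),
    file.path(outdir, "domains.tsv"), sep = "\t")
  if (!is.null(result$domains_baseline))
    data.table::fwrite(data.table::data.table(
      spot_id = rownames(coords),
      label = as.integer(result$domains_baseline)),
      file.path(outdir, "domains_baseline.tsv"), sep = "\t")
  emb <- unclass(result$embedding)
  data.table::fwrite(cbind(data.table::data.table(spot_id = rownames(coords)),
                           data.table::as.data.table(emb)),
                     file.path(outdir, "embedding.tsv"), sep = "\t")
  jsonlite::write_json(result$metrics, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Generate and write a simulated dataset
#'
#' Thin wrapper combining the two simulators with the dataset writer, so
#' simulator output feeds [run_pipeline()] (or the command-line interface)
#' unchanged.
#'
#' @param which `"scenario1"` or `"domain"`.
#' @param outdir output directory.
#' @param config optional list of simulator arguments (or YAML path)
#'   overriding the defaults of [simulate_scenario1()] /
#'   [simulate_domain_dataset()]; the `domain` branch also honors
#'   `template` sub-options (`n_spots`, `n_domains`).
#' @param seed RNG seed; default 1.
#' @return The `simulated_dataset`, invisibly; files are written to
#'   `outdir`.
#' @export
run_simulate <- function(which = c("scenario1", "domain"), outdir,
                         config = NULL, seed = 1L) {
  which <- match.arg(which)
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- if (is.null(config)) list() else config
  if (which == "scenario1") {
    args <- config[intersect(names(config),
                             names(formals(simulate_scenario1)))]
    args$seed <- if (is.null(config$seed)) seed else config$seed
    sim <- do.call(simulate_scenario1, args)
  } else {
    targs <- config$template
    tmpl <- do.call(builtin_template,
                    c(targs[intersect(names(targs),
                                      names(formals(builtin_template)))],
                      list(seed = seed)))
    args <- config[intersect(names(config),
                             setdiff(names(formals(simulate_domain_dataset)),
                                     "template"))]
    args$template <- tmpl
    args$seed <- if (is.null(config$seed)) seed else config$seed
    sim <- do.call(simulate_domain_dataset, args)
  }
  write_dataset(sim, outdir)
  invisible(sim)
}
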