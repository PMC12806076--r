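# End-to-end benchmark: simulate -> bin -> impute (x4) -> PCA -> kNN ->
# Louvain -> score against the true cell types, over a grid of window
# lengths, imputation strategies and simulation seeds. Within a grid
# cell the region matrix is built once and shared by all strategies, so
# metric differences are attributable to imputation alone.

#' Benchmark configuration
#'
#' @param sim A [sim_config()] giving the base simulation conditions; its
#'   `window_length` and `sites_per_region_mean` anchor the coverage
#'   scaling (the Poisson site mean is rescaled linearly for each
#'   benchmarked window length).
#' @param window_lengths Window lengths (bp) to benchmark
#'   (default `c(100000, 10000)`).
#' @param strategies Imputation strategies (default all four).
#' @param sim_seeds Simulation seeds, one dataset per seed.
#' @param pipeline_seed Seed for the PCA/Louvain stage, separated from
#'   the data seeds so algorithmic and sampling variability are
#'   distinguishable.
#' @param n_components,k_neighbors,resolution Clustering stage
#'   parameters (defaults 50, 15, 1).
#' @param out_dir Optional directory; if given, [run_benchmark()] writes
#'   `report.tsv`, `aggregates.tsv` and `report.json` there.
#' @return An object of class `benchmark_config`.
#' @export
benchmark_config <- function(sim = sim_config(),
                             window_lengths = c(100000, 10000),
                             strategies = IMPUTE_STRATEGIES,
                             sim_seeds = 1:5,
                             pipeline_seed = 1L,
                             n_components = 50L,
                             k_neighbors = 15L,
                             resolution = 1.0,
                             out_dir = NULL) {
  stopifnot(inherits(sim, "sim_config"),
            length(window_lengths) >= 1L,
            length(strategies) >= 1L,
            length(sim_seeds) >= 1L)
  bad <- setdiff(strategies, IMPUTE_STRATEGIES)
  if (length(bad)) {
    stopf("unknown strategy: %s (valid: %s)", paste(bad, collapse = ", "),
          paste(IMPUTE_STRATEGIES, collapse = ", "))
  }
  structure(list(sim = sim, window_lengths = as.numeric(window_lengths),
                 strategies = strategies, sim_seeds = as.integer(sim_seeds),
                 pipeline_seed = as.integer(pipeline_seed),
                 n_components = as.integer(n_components),
                 k_neighbors = as.integer(k_neighbors),
                 resolution = resolution, out_dir = out_dir),
            class = "benchmark_config")
}

# Rescale a sim_config to a benchmarked window length: the Poisson site
# mean scales linearly with window size (same per-bp site density).
rescale_sim <- function(sim, window_length, seed) {
  sim_config(seed = seed,
             n_cell_types = sim$n_cell_types,
             cells_per_type = sim$cells_per_type,
             n_regions = sim$n_regions,
             window_length = window_length,
             context_mode = sim$context_mode,
             baseline_beta = sim$baseline_beta,
             dmr_fraction = sim$dmr_fraction,
             dmr_state_beta = sim$dmr_state_beta,
             dmr_types_affected = sim$dmr_types_affected,
             sites_per_region_mean =
               sim$sites_per_region_mean * window_length / sim$window_length,
             chrom = sim$chrom)
}

#' Run the imputation-strategy benchmark
#'
#' For every (window length, simulation seed): simulate a dataset, build
#' the region matrix once, drop all-missing regions, then for every
#' strategy impute, embed (PCA), build the k-NN graph, cluster (Louvain)
#' and score the predicted partition against the true cell types. A
#' failed grid cell is recorded and reported; aggregates refuse
#' incomplete grids rather than silently averaging over a subset.
#'
#' @param config A [benchmark_config()].
#' @return An object of class `benchmark_report`: list with `results`
#'   (one row per grid cell: window_length, strategy, sim_seed, the four
#'   metrics, n_clusters, na_rate, regions_dropped), `aggregates` (means
#'   over seeds per window x strategy), and the `config`.
#' @export
run_benchmark <- function(config) {
  stopifnot(inherits(config, "benchmark_config"))
  rows <- list()
  failures <- character(0)
  for (L in config$window_lengths) {
    for (sim_seed in config$sim_seeds) {
      cell_res <- tryCatch({
        cfg <- rescale_sim(config$sim, L, sim_seed)
        ds <- simulate_dataset(cfg)
        grid <- make_bins(ds$chrom_sizes, L)
        mat <- build_region_matrix(ds$cells, grid,
                                   context = cfg$context_mode)
        na_rate <- mean(mat$mask)
        kept <- suppressMessages(drop_all_missing_regions(mat))
        dropped <- nrow(mat$regions) - nrow(kept$regions)
        lapply(config$strategies, function(strategy) {
          imp <- impute_matrix(kept, strategy)
          emb <- pca_embed(imp, n_components = config$n_components,
                           seed = config$pipeline_seed)
          ng <- knn_graph(emb, k = config$k_neighbors)
          pred <- louvain_cluster(ng, resolution = config$resolution,
                                  seed = config$pipeline_seed)
          rep <- evaluate_partitions(pred, ds$truth$labels)
          data.frame(window_length = L, strategy = strategy,
                     sim_seed = sim_seed, ari = rep$ari, ami = rep$ami,
                     nmi = rep$nmi, fmi = rep$fmi,
                     n_clusters = length(unique(pred$labels)),
                     na_rate = na_rate, regions_dropped = dropped)
        })
      }, error = function(e) {
        warning(sprintf("grid cell (L=%g, seed=%d) failed: %s",
                        L, sim_seed, conditionMessage(e)), call. = FALSE)
        conditionMessage(e)
      })
      if (is.character(cell_res)) {
        failures <- c(failures,
                      sprintf("L=%g seed=%d: %s", L, sim_seed, cell_res))
      } else {
        rows <- c(rows, cell_res)
      }
    }
  }
  results <- do.call(rbind, rows)
  aggregates <- NULL
  if (!length(failures) && !is.null(results)) {
    agg <- stats::aggregate(results[c("ari", "ami", "nmi", "fmi")],
                            by = results[c("window_length", "strategy")],
                            FUN = mean)
    aggregates <- agg[order(agg$window_length, agg$strategy), , drop = FALSE]
    rownames(aggregates) <- NULL
  }
  report <- structure(list(results = results, aggregates = aggregates,
                           failures = failures, config = config),
                      class = "benchmark_report")
  if (!is.null(config$out_dir)) write_benchmark_report(report, config$out_dir)
  report
}

#' Write a benchmark report to disk
#'
#' Emits `report.tsv` (per-cell results), `aggregates.tsv` and
#' `report.json`. Output is deterministic: rerunning an identical
#' configuration reproduces the files byte for byte.
#'
#' @param report A [run_benchmark()] report.
#' @param out_dir Output directory (created if needed).
#' @export
write_benchmark_report <- function(report, out_dir) {
  stopifnot(inherits(report, "benchmark_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(report$results, file.path(out_dir, "report.tsv"),
                     sep = "\t", quote = FALSE)
  if (!is.null(report$aggregates)) {
    data.table::fwrite(report$aggregates, file.path(out_dir, "aggregates.tsv"),
                       sep = "\t", quote = FALSE)
  }
  cfg <- report$config
  payload <- list(
    config = list(window_lengths = cfg$window_lengths,
                  strategies = cfg$strategies, sim_seeds = cfg$sim_seeds,
                  pipeline_seed = cfg$pipeline_seed,
                  n_components = cfg$n_components,
                  k_neighbors = cfg$k_neighbors,
                  resolution = cfg$resolution,
                  sim = unclass(cfg$sim)),
    results = report$results, aggregates = report$aggregates,
    failures = report$failures)
  jsonlite::write_json(payload, file.path(out_dir, "report.json"),
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Rank imputation strategies by a metric
#'
#' Per window length, strategies ordered by their mean metric over
#' simulation seeds, with the per-seed spread (standard deviation). Ties
#' in the mean share a rank.
#'
#' @param report A complete [run_benchmark()] report.
#' @param metric One of `"ari"`, `"ami"`, `"nmi"`, `"fmi"`.
#' @return data.frame with columns window_length, strategy, mean, sd,
#'   rank (1 = best; equal means share a rank).
#' @export
compare_strategies <- function(report, metric = c("ari", "ami", "nmi", "fmi")) {
  stopifnot(inherits(report, "benchmark_report"))
  metric <- match.arg(metric)
  if (length(report$failures) || is.null(report$aggregates)) {
    stopf("benchmark grid is incomplete (%d failed cell(s)); cannot rank",
          length(report$failures))
  }
  res <- report$results
  out <- do.call(rbind, lapply(split(res, res$window_length), function(d) {
    m <- vapply(split(d[[metric]], d$strategy), mean, 0)
    s <- vapply(split(d[[metric]], d$strategy), stats::sd, 0)
    s[is.na(s)] <- 0  # single seed
    ord <- order(-m, names(m))
    data.frame(window_length = d$window_length[1L],
               strategy = names(m)[ord], mean = unname(m[ord]),
               sd = unname(s[ord]),
               rank = rank(-round(m[ord], 12), ties.method = "min"))
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("<benchmark_report> %d grid cell(s), %d failure(s)\n",
              if (is.null(x$results)) 0L else nrow(x$results),
              length(x$failures)))
  if (!is.null(x$aggregates)) {
    print(x$aggregates, digits = 4)
  }
  invisible(x)
}
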