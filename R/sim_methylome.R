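# Synthetic single-cell methylome generator. The latent model: every
# region of a single synthetic chromosome carries a per-cell-type
# methylation propensity p; non-DMR regions share one Beta-distributed
# baseline propensity across all types, while differentially methylated
# regions (DMRs) give a sampled subset of types an alternative
# Beta(1.5, 8) state. Against the high CG baseline Beta(8, 2) that state
# is hypo-methylated (the minority low-methylation DMRs that pull
# per-region means below medians); against the near-zero CH baseline
# Beta(0.4, 12) the same state is hyper-methylated, so CH DMRs carry
# signal. Site capture is Poisson per (cell, region): a region with zero
# captured sites becomes a downstream NA, so the NA rate is e^(-lambda)
# and halving the window (lambda scales linearly with window length)
# mechanically deepens the missingness.

#' Simulator configuration
#'
#' Collects and validates all parameters of the synthetic methylome
#' generator. Defaults reproduce the benchmark's standard conditions:
#' three balanced cell types of 60 cells, 2000 regions of 100 kbp on one
#' synthetic chromosome, 10% DMRs each affecting one type, and an
#' expected 8 captured sites per (cell, region) at 100 kbp.
#'
#' @param seed Integer seed; the whole dataset is a pure function of the
#'   configuration.
#' @param n_cell_types Number of latent cell types K (>= 1).
#' @param cells_per_type Integer vector of cells per type (recycled to K).
#' @param n_regions Number of regions G on the synthetic chromosome.
#' @param window_length Region length in bp; the chromosome has length
#'   `n_regions * window_length`.
#' @param context_mode `"CG"` or `"CH"`; sets the baseline Beta and the
#'   context strings written into the calls.
#' @param baseline_beta Length-2 Beta shape parameters for non-DMR
#'   propensities; defaults `c(8, 2)` for CG (high baseline) and
#'   `c(0.4, 12)` for CH (near-zero baseline).
#' @param dmr_fraction Fraction of regions flagged as DMRs (default 0.1).
#' @param dmr_state_beta Beta shapes of the alternative DMR state
#'   (default `c(1.5, 8)`): hypo-methylated relative to the CG baseline,
#'   hyper-methylated relative to the CH baseline.
#' @param dmr_types_affected Number of cell types carrying the alternative
#'   state per DMR (default 1; must be < K).
#' @param sites_per_region_mean Poisson mean of captured sites per
#'   (cell, region); defaults to `8 * window_length / 1e5` so coverage
#'   scales with window size (8 at 100 kbp, 0.8 at 10 kbp).
#' @param chrom Name of the synthetic chromosome.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_cell_types = 3L,
                       cells_per_type = 60L,
                       n_regions = 2000L,
                       window_length = 100000,
                       context_mode = c("CG", "CH"),
                       baseline_beta = NULL,
                       dmr_fraction = 0.1,
                       dmr_state_beta = c(1.5, 8),
                       dmr_types_affected = 1L,
                       sites_per_region_mean = NULL,
                       chrom = "chrS") {
  context_mode <- match.arg(context_mode)
  if (is.null(baseline_beta)) {
    baseline_beta <- if (context_mode == "CG") c(8, 2) else c(0.4, 12)
  }
  if (is.null(sites_per_region_mean)) {
    sites_per_region_mean <- 8 * window_length / 1e5
  }
  n_cell_types <- as.integer(n_cell_types)
  cells_per_type <- as.integer(rep_len(cells_per_type, n_cell_types))
  stopifnot(n_cell_types >= 1L, all(cells_per_type >= 1L),
            n_regions >= 1, window_length >= 1)
  if (any(baseline_beta <= 0) || any(dmr_state_beta <= 0)) {
    stopf("Beta shape parameters must be positive")
  }
  if (dmr_fraction < 0 || dmr_fraction > 1) {
    stopf("dmr_fraction must lie in [0, 1]")
  }
  if (sites_per_region_mean <= 0) {
    stopf("sites_per_region_mean must be positive")
  }
  if (dmr_fraction > 0 && dmr_types_affected >= n_cell_types &&
      n_cell_types > 1L) {
    stopf("dmr_types_affected must be smaller than n_cell_types")
  }
  structure(list(seed = as.integer(seed),
                 n_cell_types = n_cell_types,
                 cells_per_type = cells_per_type,
                 n_regions = as.integer(n_regions),
                 window_length = as.numeric(window_length),
                 context_mode = context_mode,
                 baseline_beta = as.numeric(baseline_beta),
                 dmr_fraction = dmr_fraction,
                 dmr_state_beta = as.numeric(dmr_state_beta),
                 dmr_types_affected = as.integer(dmr_types_affected),
                 sites_per_region_mean = sites_per_region_mean,
                 chrom = chrom),
            class = "sim_config")
}

#' Chromosome sizes implied by a simulator configuration
#' @param config A [sim_config()].
#' @return Named vector suitable for [make_bins()].
#' @export
sim_chrom_sizes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  stats::setNames(config$n_regions * config$window_length, config$chrom)
}

#' Sample the latent ground truth of a simulated dataset
#'
#' Draws the per-type, per-region methylation propensities and the true
#' cell-type labels. `floor(dmr_fraction * G)` regions are flagged as
#' DMRs; each samples its affected types uniformly without replacement
#' and assigns them an alternative propensity from `dmr_state_beta`,
#' while unaffected types keep the region's baseline draw.
#'
#' @param config A [sim_config()].
#' @return An object of class `ground_truth`: list with `labels` (a
#'   [partition] of true types), `propensity` (K x G matrix in (0,1)),
#'   `dmr_regions` (integer indices), `affected_types` (list, per DMR).
#' @export
sample_ground_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  K <- config$n_cell_types
  G <- config$n_regions
  if (K < 2L && config$dmr_fraction > 0) {
    stopf("DMRs require at least 2 cell types (got %d)", K)
  }
  with_seed(config$seed, {
    base_p <- rbeta(G, config$baseline_beta[1L], config$baseline_beta[2L])
    propensity <- matrix(rep(base_p, each = K), nrow = K)
    n_dmr <- floor(config$dmr_fraction * G)
    dmr_regions <- if (n_dmr > 0) sort(sample.int(G, n_dmr)) else integer(0)
    affected <- vector("list", length(dmr_regions))
    for (i in seq_along(dmr_regions)) {
      types <- sort(sample.int(K, config$dmr_types_affected))
      state <- rbeta(1L, config$dmr_state_beta[1L], config$dmr_state_beta[2L])
      propensity[types, dmr_regions[i]] <- state
      affected[[i]] <- types
    }
    propensity <- pmin(pmax(propensity, 1e-9), 1 - 1e-9)
    n <- sum(config$cells_per_type)
    labels <- partition(sprintf("cell_%04d", seq_len(n)),
                        rep(paste0("type_", seq_len(K)),
                            config$cells_per_type))
    structure(list(labels = labels, propensity = propensity,
                   dmr_regions = dmr_regions, affected_types = affected),
              class = "ground_truth")
  })
}

#' Simulate one cell's methylation calls
#'
#' Per region, the number of captured sites is Poisson with mean
#' `sites_per_region_mean`; site positions are uniform within the region
#' (duplicate positions are merged); each site's call is Bernoulli with
#' the cell type's propensity, written as a binary single-read call
#' (`mc_reads` in \{0,1\}, `total_reads` = 1). Regions with zero captured
#' sites contribute no calls and become the downstream NA entries.
#'
#' Deterministic given the configuration seed and `cell_index`.
#'
#' @param truth A [sample_ground_truth()] object.
#' @param config The matching [sim_config()].
#' @param cell_index Index into `truth$labels`.
#' @return A [cell_call_set].
#' @export
simulate_cell_calls <- function(truth, config, cell_index) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  n <- length(truth$labels$cell_ids)
  if (cell_index < 1L || cell_index > n) {
    stopf("cell_index must be in 1..%d", n)
  }
  type <- match(truth$labels$labels[cell_index],
                paste0("type_", seq_len(config$n_cell_types)))
  G <- config$n_regions
  L <- config$window_length
  with_seed(derive_seed(config$seed, cell_index), {
    s <- rpois(G, config$sites_per_region_mean)
    over <- s > L
    if (any(over)) {
      message(sprintf("capping site count to region length in %d region(s)",
                      sum(over)))
      s[over] <- L
    }
    total <- sum(s)
    if (total == 0L) {
      calls <- data.frame(chrom = character(0), pos = integer(0),
                          strand = character(0), context = character(0),
                          mc_reads = integer(0), total_reads = integer(0))
      return(cell_call_set(truth$labels$cell_ids[cell_index], calls))
    }
    region <- rep.int(seq_len(G), s)
    pos <- as.numeric(region - 1L) * L + floor(runif(total) * L)
    keep <- !duplicated(pos)   # merge coincident site draws within a region
    region <- region[keep]
    pos <- pos[keep]
    mc <- rbinom(length(pos), 1L, truth$propensity[type, region])
    ctx <- if (config$context_mode == "CG") "CG" else
      sample(c("CHG", "CHH"), length(pos), replace = TRUE)
    calls <- data.frame(chrom = config$chrom, pos = as.integer(pos),
                        strand = "+", context = ctx,
                        mc_reads = mc, total_reads = 1L)
    cell_call_set(truth$labels$cell_ids[cell_index], calls)
  })
}

#' Simulate a full dataset of single-cell methylomes
#'
#' Draws the ground truth and one [cell_call_set] per cell. Fully
#' reproducible: the same configuration always yields the same dataset.
#'
#' @param config A [sim_config()].
#' @return List with `cells` (list of [cell_call_set]), `truth`
#'   (the [sample_ground_truth()] object) and `chrom_sizes`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  truth <- sample_ground_truth(config)
  n <- length(truth$labels$cell_ids)
  cells <- lapply(seq_len(n), function(i) simulate_cell_calls(truth, config, i))
  list(cells = cells, truth = truth, chrom_sizes = sim_chrom_sizes(config))
}

#' Write a simulated dataset as allc-style files
#'
#' Emits one call file per cell, a chrom.sizes file, and the true cell
#' type labels, so simulated data can round-trip through the standard
#' readers.
#'
#' @param dataset Result of [simulate_dataset()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_sim_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (cell in dataset$cells) {
    write_cell_calls(cell, file.path(out_dir, paste0(cell$cell_id, ".allc.tsv")))
  }
  writeLines(sprintf("%s\t%g", names(dataset$chrom_sizes),
                     dataset$chrom_sizes),
             file.path(out_dir, "chrom.sizes"))
  write_cell_labels(dataset$truth$labels, file.path(out_dir, "labels.tsv"))
  invisible(out_dir)
}

#' Subsample a dataset to a target cell-type composition
#'
#' Finds the largest total cell count N such that `floor(N * p_t)` cells
#' of each type t are available (N = `floor(min(available_t / p_t))` over
#' types with positive proportion), then subsamples each type without
#' replacement to `floor(N * p_t)` cells.
#'
#' @param cells List of [cell_call_set] objects.
#' @param labels A [partition] with the cells' type labels.
#' @param target_proportions Named numeric vector of proportions (summing
#'   to 1) over the type labels.
#' @param seed RNG seed for the subsampling.
#' @return List with subsampled `cells` and `labels` (cells keep their
#'   original relative order).
#' @export
perturb_composition <- function(cells, labels, target_proportions, seed = 1L) {
  stopifnot(inherits(labels, "partition"))
  ids <- vapply(cells, function(c) c$cell_id, "")
  if (!setequal(ids, labels$cell_ids)) {
    stopf("cells and labels cover different cell ids")
  }
  props <- target_proportions
  if (is.null(names(props))) stopf("target_proportions must be named by type")
  if (abs(sum(props) - 1) > 1e-8) stopf("target proportions must sum to 1")
  lab_by_id <- stats::setNames(labels$labels, labels$cell_ids)
  avail <- table(lab_by_id[ids])
  pos <- names(props)[props > 0]
  missing_types <- pos[!(pos %in% names(avail)) | avail[pos] == 0]
  missing_types <- missing_types[!is.na(missing_types)]
  if (length(missing_types)) {
    stopf("no cells available for type(s) with positive proportion: %s",
          paste(missing_types, collapse = ", "))
  }
  n_total <- floor(min(as.numeric(avail[pos]) / props[pos]))
  target_counts <- floor(n_total * props[pos])
  keep_idx <- with_seed(seed, {
    idx <- integer(0)
    for (ty in pos) {
      idx_ty <- which(lab_by_id[ids] == ty)
      idx <- c(idx, idx_ty[sample.int(length(idx_ty), target_counts[ty])])
    }
    idx
  })
  keep_idx <- sort(keep_idx)
  list(cells = cells[keep_idx],
       labels = partition(ids[keep_idx],
                          unname(lab_by_id[ids[keep_idx]])))
}
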