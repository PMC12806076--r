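small_cfg <- function(...) {
  args <- utils::modifyList(
    list(seed = 101, n_cell_types = 3, cells_per_type = 10,
         n_regions = 200, window_length = 1000,
         sites_per_region_mean = 2),
    list(...))
  do.call(sim_config, args)
}

test_that("ground truth structure follows the configuration", {
  cfg <- small_cfg()
  truth <- sample_ground_truth(cfg)
  expect_equal(dim(truth$propensity), c(3L, 200L))
  expect_equal(length(truth$dmr_regions), floor(0.1 * 200))
  # non-DMR regions share one propensity across types; DMRs differ
  non_dmr <- setdiff(seq_len(200), truth$dmr_regions)
  expect_true(all(apply(truth$propensity[, non_dmr], 2,
                        function(p) length(unique(p)) == 1L)))
  for (i in seq_along(truth$dmr_regions)) {
    j <- truth$dmr_regions[i]
    aff <- truth$affected_types[[i]]
    expect_true(all(truth$propensity[aff, j] !=
                      truth$propensity[setdiff(1:3, aff), j][1]))
  }
  # determinism: same config -> identical truth
  expect_identical(truth$propensity, sample_ground_truth(cfg)$propensity)
})

test_that("no DMRs means identical propensities for all types", {
  truth <- sample_ground_truth(small_cfg(dmr_fraction = 0))
  expect_equal(truth$propensity[1, ], truth$propensity[2, ])
  expect_equal(truth$propensity[1, ], truth$propensity[3, ])
})

test_that("CG baseline propensities average near their Beta mean", {
  cfg <- sim_config(seed = 5, n_regions = 5000, dmr_fraction = 0)
  truth <- sample_ground_truth(cfg)
  # Beta(8, 2) has mean 0.8; 5000 draws pin the grand mean tightly
  expect_lt(abs(mean(truth$propensity[1, ]) - 0.8), 0.01)
})

test_that("DMRs require heterogeneity to express", {
  expect_error(sample_ground_truth(
    sim_config(n_cell_types = 1, cells_per_type = 5, dmr_fraction = 0.1)),
    "at least 2")
})

test_that("simulated calls are binary, sorted, and propensity-faithful", {
  cfg <- small_cfg()
  truth <- sample_ground_truth(cfg)
  cell <- simulate_cell_calls(truth, cfg, 1)
  expect_true(all(cell$calls$total_reads == 1L))
  expect_true(all(cell$calls$mc_reads %in% 0:1))
  expect_false(is.unsorted(cell$calls$pos))
  # deterministic per (config, cell index)
  expect_identical(cell$calls, simulate_cell_calls(truth, cfg, 1)$calls)

  # p = 1 everywhere -> every call methylated
  truth1 <- truth
  truth1$propensity[] <- 1 - 1e-12
  expect_true(all(simulate_cell_calls(truth1, cfg, 2)$calls$mc_reads == 1L))

  # vanishing coverage -> almost every region empty
  cfg0 <- small_cfg(sites_per_region_mean = 1e-9)
  truth0 <- sample_ground_truth(cfg0)
  expect_equal(nrow(simulate_cell_calls(truth0, cfg0, 1)$calls), 0L)
})

test_that("datasets are balanced, reproducible, and seed-sensitive", {
  cfg <- small_cfg()
  ds <- simulate_dataset(cfg)
  expect_length(ds$cells, 30L)
  expect_equal(unname(table(ds$truth$labels$labels)), rep(10L, 3L),
               ignore_attr = TRUE)
  ds_again <- simulate_dataset(cfg)
  expect_identical(ds$cells[[7]]$calls, ds_again$cells[[7]]$calls)
  ds_other <- simulate_dataset(small_cfg(seed = 202))
  expect_length(ds_other$cells, 30L)
  expect_false(identical(ds$cells[[1]]$calls, ds_other$cells[[1]]$calls))
})

test_that("simulated datasets round-trip through allc files on disk", {
  cfg <- sim_config(seed = 3, n_cell_types = 2, cells_per_type = 3,
                    n_regions = 50, window_length = 1000,
                    sites_per_region_mean = 3)
  ds <- simulate_dataset(cfg)
  dir <- tempfile()
  write_sim_dataset(ds, dir)
  sizes <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  expect_equal(unname(sizes), 50 * 1000)
  labels <- read_cell_labels(file.path(dir, "labels.tsv"))
  expect_identical(labels$labels, ds$truth$labels$labels)
  cell1 <- read_cell_calls(file.path(dir, "cell_0001.allc.tsv"),
                           cell_id = "cell_0001")
  expect_equal(cell1$calls, ds$cells[[1]]$calls)
})

test_that("region-level call means track the latent propensities", {
  cfg <- sim_config(seed = 17, n_cell_types = 1, cells_per_type = 400,
                    n_regions = 30, window_length = 1000,
                    dmr_fraction = 0, sites_per_region_mean = 4)
  ds <- simulate_dataset(cfg)
  grid <- make_bins(ds$chrom_sizes, 1000)
  tot_mc <- numeric(30)
  tot_n <- numeric(30)
  for (cell in ds$cells) {
    idx <- assign_bin(grid, cell$calls$chrom, cell$calls$pos)
    tot_mc <- tot_mc + tabulate(idx[cell$calls$mc_reads == 1L], 30)
    tot_n <- tot_n + tabulate(idx, 30)
  }
  p <- ds$truth$propensity[1, ]
  se <- sqrt(p * (1 - p) / tot_n)
  expect_true(all(abs(tot_mc / tot_n - p) <= 3 * se))
})

test_that("median exceeds mean in most DMR columns with a minority low state", {
  # CG conditions: high baseline, 10% hypo-DMRs carried by one of three
  # types; across DMR columns the available-value median should exceed
  # the mean in the majority of cases
  cfg <- sim_config(seed = 29, n_cell_types = 3, cells_per_type = 30,
                    n_regions = 400, window_length = 1000,
                    sites_per_region_mean = 6)
  ds <- simulate_dataset(cfg)
  mat <- build_region_matrix(ds$cells, make_bins(ds$chrom_sizes, 1000),
                             context = "CG")
  kept <- suppressMessages(drop_all_missing_regions(mat))
  keep_ids <- which(colSums(!mat$mask) > 0)
  dmr_cols <- match(intersect(ds$truth$dmr_regions, keep_ids), keep_ids)
  meds <- vapply(dmr_cols, function(j) column_available_median(kept, j), 0)
  mns <- vapply(dmr_cols, function(j) column_available_mean(kept, j), 0)
  expect_gt(mean(meds > mns), 0.5)
})

test_that("composition perturbation uses the largest feasible subsample", {
  cfg <- sim_config(seed = 31, n_cell_types = 3, cells_per_type = 60,
                    n_regions = 20, window_length = 1000,
                    sites_per_region_mean = 1)
  ds <- simulate_dataset(cfg)
  props <- c(type_1 = 0.8, type_2 = 0.1, type_3 = 0.1)
  sub <- perturb_composition(ds$cells, ds$truth$labels, props, seed = 2)
  # N = floor(min(60/0.8, 60/0.1)) = 75 -> counts floor(75 * p) = 60, 7, 7
  expect_equal(unname(c(table(sub$labels$labels))), c(60L, 7L, 7L))
  expect_length(sub$cells, 74L)

  # current proportions -> identity up to ordering
  same <- perturb_composition(ds$cells, ds$truth$labels,
                              c(type_1 = 1/3, type_2 = 1/3, type_3 = 1/3),
                              seed = 2)
  expect_setequal(same$labels$cell_ids, ds$truth$labels$cell_ids)

  expect_error(perturb_composition(ds$cells, ds$truth$labels,
                                   c(type_1 = 0.5, ghost = 0.5), seed = 1),
               "ghost")
})
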