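test_that("binning covers each chromosome with a trailing partial bin", {
  grid <- make_bins(c(chr1 = 250), 100)
  expect_equal(nrow(grid$regions), 3L)
  expect_equal(grid$regions$start, c(0, 100, 200))
  expect_equal(grid$regions$end, c(100, 200, 250))

  exact <- make_bins(c(chr1 = 100), 100)
  expect_equal(nrow(exact$regions), 1L)
  expect_equal(exact$regions$end, 100)

  multi <- make_bins(c(chr1 = 100, chr2 = 100), 100)
  expect_equal(assign_bin(multi, "chr1", 0), 1L)
  expect_equal(assign_bin(multi, "chr2", 0), 2L)

  expect_error(make_bins(c(chr1 = 100), 0), "positive")
})

test_that("grid construction is deterministic", {
  sizes <- c(chrA = 1234, chrB = 999)
  expect_identical(make_bins(sizes, 100)$regions, make_bins(sizes, 100)$regions)
})

test_that("window boundaries map to adjacent bins (half-open intervals)", {
  grid <- make_bins(c(chr1 = 300), 100)
  expect_equal(assign_bin(grid, "chr1", 99), 1L)
  expect_equal(assign_bin(grid, "chr1", 100), 2L)
  expect_error(assign_bin(grid, "chr1", 300), "outside")
  expect_error(assign_bin(grid, "chrX", 0), "chrX")
})

test_that("assign_bin matches a linear scan over region coordinates", {
  set.seed(11)
  grid <- make_bins(c(chr1 = 1037, chr2 = 450), 97)
  for (rep in 1:200) {
    chrom <- sample(c("chr1", "chr2"), 1L)
    pos <- sample.int(grid$chrom_sizes[chrom], 1L) - 1L
    scan <- which(grid$regions$chrom == chrom &
                    grid$regions$start <= pos & pos < grid$regions$end)
    expect_length(scan, 1L)
    expect_equal(assign_bin(grid, chrom, pos), scan)
  }
})

test_that("per-region aggregation averages site levels and masks empty bins", {
  grid <- make_bins(c(chr1 = 300), 100)
  cell <- cell_call_set("c1", data.frame(
    chrom = "chr1", pos = c(10L, 50L, 90L, 250L), strand = "+",
    context = "CG", mc_reads = c(1L, 1L, 0L, 1L), total_reads = 1L))
  agg <- aggregate_cell(cell, grid)
  expect_equal(agg$values[1], 2 / 3)        # sites {1,1,0}
  expect_true(agg$mask[2])                  # no captured site
  expect_true(is.na(agg$values[2]))
  expect_equal(agg$values[3], 1)
  expect_equal(agg$n_sites, c(3L, 0L, 1L))
})

test_that("aggregation matches a brute-force per-region accumulation", {
  grid <- make_bins(c(chr1 = 500, chr2 = 210), 100)
  cell <- random_cell_calls(grid, 200, seed = 3)
  agg <- aggregate_cell(cell, grid)
  # oracle: dictionary accumulation over the calls
  sums <- numeric(nrow(grid$regions))
  cnt <- integer(nrow(grid$regions))
  for (i in seq_len(nrow(cell$calls))) {
    row <- cell$calls[i, ]
    j <- which(grid$regions$chrom == row$chrom &
                 grid$regions$start <= row$pos & row$pos < grid$regions$end)
    sums[j] <- sums[j] + row$mc_reads / row$total_reads
    cnt[j] <- cnt[j] + 1L
  }
  expect_equal(agg$n_sites, cnt)            # coverage partition: no call lost
  expect_equal(sum(cnt), nrow(cell$calls))
  want <- ifelse(cnt > 0, sums / pmax(cnt, 1L), NA_real_)
  expect_equal(agg$values, want)
  expect_identical(agg$mask, cnt == 0L)     # NA exactly where no site
  # with binary single-read calls, value * site count is an integer
  obs <- which(cnt > 0)
  expect_equal(agg$values[obs] * cnt[obs], round(agg$values[obs] * cnt[obs]))
})

test_that("calls on chromosomes missing from the grid are rejected", {
  grid <- make_bins(c(chr1 = 100), 50)
  cell <- cell_call_set("c1", data.frame(chrom = "chrUn", pos = 10L,
                                         strand = "+", context = "CG",
                                         mc_reads = 1L, total_reads = 1L))
  expect_error(aggregate_cell(cell, grid), "chrUn")
})

test_that("matrix construction is row-independent and validates cell ids", {
  grid <- make_bins(c(chr1 = 300), 100)
  mk <- function(id, pos, mc) {
    cell_call_set(id, data.frame(chrom = "chr1", pos = pos, strand = "+",
                                 context = "CG", mc_reads = mc,
                                 total_reads = 1L))
  }
  a <- mk("a", c(10L, 110L), c(1L, 0L))
  b <- mk("b", 250L, 1L)
  mat <- build_region_matrix(list(a, b), grid)
  swapped <- build_region_matrix(list(b, a), grid)
  expect_equal(mat$values[c("a", "b"), ], swapped$values[c("a", "b"), ])

  empty <- build_region_matrix(list(), grid)
  expect_equal(dim(empty$values), c(0L, 3L))

  single <- build_region_matrix(list(mk("solo", 10L, 1L)), grid)
  expect_equal(sum(!single$mask), 1L)

  expect_error(build_region_matrix(list(a, a), grid), "duplicate")
})

test_that("CH matrices never include CG calls and vice versa", {
  grid <- make_bins(c(chr1 = 100), 100)
  mixed <- cell_call_set("m", data.frame(
    chrom = "chr1", pos = c(1L, 2L, 3L), strand = "+",
    context = c("CG", "CHG", "CHH"), mc_reads = c(1L, 0L, 0L),
    total_reads = 1L))
  cg <- build_region_matrix(list(mixed), grid, context = "CG")
  ch <- build_region_matrix(list(mixed), grid, context = "CH")
  expect_equal(cg$values[1, 1], 1)   # only the methylated CG call
  expect_equal(ch$values[1, 1], 0)   # mean of the two unmethylated CH calls
})

test_that("dropping all-missing regions counts, preserves coords, idempotent", {
  values <- matrix(c(0.1, 0.2, NA, NA, 0.5, NA, 1, 0.4), nrow = 2)
  mat <- toy_region_matrix(values)
  expect_message(kept <- drop_all_missing_regions(mat), "1 region")
  expect_equal(nrow(kept$regions), 3L)
  expect_equal(kept$regions$start, c(0, 200, 300))  # survivor coords intact

  again <- suppressMessages(drop_all_missing_regions(kept))
  expect_identical(again$values, kept$values)

  no_gap <- toy_region_matrix(matrix(c(0.1, NA, 0.3, 0.4), nrow = 2))
  expect_identical(drop_all_missing_regions(no_gap)$values, no_gap$values)
})
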