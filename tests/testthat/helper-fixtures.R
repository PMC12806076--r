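# Programmatic fixtures shared across test files.

# Region matrix from a plain values matrix (NA entries become the mask).
toy_region_matrix <- function(values, context = "CG", window = 100) {
  values <- as.matrix(values)
  regions <- data.frame(chrom = "chr1",
                        start = (seq_len(ncol(values)) - 1) * window,
                        end = seq_len(ncol(values)) * window)
  region_matrix(values, sprintf("cell_%d", seq_len(nrow(values))),
                regions, context, window)
}

# Random matrix in [0,1] with a target missingness rate, guaranteeing at
# least one observed entry per column.
random_region_matrix <- function(n, R, miss = 0.3, seed = 1L, context = "CG") {
  set.seed(seed)
  values <- matrix(round(runif(n * R), 6), n, R)
  mask <- matrix(runif(n * R) < miss, n, R)
  for (j in which(colSums(!mask) == 0L)) mask[sample.int(n, 1L), j] <- FALSE
  values[mask] <- NA_real_
  toy_region_matrix(values, context = context)
}

# Write a call data.frame (0-based positions) as an allc-style file
# (1-based positions on disk) and return the path.
write_allc_fixture <- function(calls, path = tempfile(fileext = ".tsv")) {
  out <- calls
  out$pos <- out$pos + 1L
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  path
}

# Random call set over a given grid for oracle comparisons.
random_cell_calls <- function(grid, n_calls, cell_id = "cellR", seed = 1L) {
  set.seed(seed)
  chrom <- sample(grid$chrom_order, n_calls, replace = TRUE)
  pos <- floor(runif(n_calls) * grid$chrom_sizes[chrom])
  keep <- !duplicated(paste(chrom, pos))
  cell_call_set(cell_id,
                data.frame(chrom = chrom[keep], pos = as.integer(pos[keep]),
                           strand = "+", context = "CG",
                           mc_reads = sample(0:1, sum(keep), replace = TRUE),
                           total_reads = 1L))
}
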