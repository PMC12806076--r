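# Genome window binning and NA-aware cell-by-region aggregation.

#' Tile the genome into fixed-length windows
#'
#' Bins every chromosome into consecutive non-overlapping windows of
#' `window_length` bp (0-based half-open intervals). The last window of each
#' chromosome may be shorter; it is kept as a region. Global region indices
#' run over chromosomes in the order given by `sizes`, then by position.
#'
#' @param sizes Named vector of chromosome lengths, as from
#'   [read_chrom_sizes()].
#' @param window_length Window size in bp (e.g. `100000` or `10000`).
#' @return An object of class `bin_grid` with elements `window_length`,
#'   `chrom_order`, `chrom_sizes`, `bins_per_chrom`, `offsets` (0-based
#'   global index of each chromosome's first bin) and `regions`
#'   (data.frame `chrom`, `start`, `end`).
#' @examples
#' grid <- make_bins(c(chr1 = 250), 100)
#' grid$regions  # [0,100), [100,200), [200,250)
#' @export
make_bins <- function(sizes, window_length) {
  if (!length(sizes)) stopf("no chromosomes")
  if (is.null(names(sizes)) || any(!nzchar(names(sizes)))) {
    stopf("chromosome sizes must be named")
  }
  if (anyDuplicated(names(sizes))) stopf("duplicate chromosome names")
  if (any(sizes <= 0)) stopf("chromosome lengths must be positive")
  if (length(window_length) != 1L || is.na(window_length) || window_length <= 0) {
    stopf("window_length must be a positive number of bp")
  }
  window_length <- as.numeric(window_length)
  nbins <- ceiling(as.numeric(sizes) / window_length)
  offsets <- c(0, cumsum(nbins))[seq_along(sizes)]
  regions <- do.call(rbind, lapply(seq_along(sizes), function(i) {
    starts <- (seq_len(nbins[i]) - 1) * window_length
    data.frame(chrom = names(sizes)[i], start = starts,
               end = pmin(starts + window_length, as.numeric(sizes[i])))
  }))
  rownames(regions) <- NULL
  structure(list(window_length = window_length,
                 chrom_order = names(sizes),
                 chrom_sizes = stats::setNames(as.numeric(sizes), names(sizes)),
                 bins_per_chrom = stats::setNames(as.integer(nbins), names(sizes)),
                 offsets = stats::setNames(offsets, names(sizes)),
                 regions = regions),
            class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("<bin_grid> %d region(s) of %g bp over %d chromosome(s)\n",
              nrow(x$regions), x$window_length, length(x$chrom_order)))
  invisible(x)
}

#' Map genomic positions to region indices
#'
#' Vectorised over `chrom` and `pos`. Returns the 1-based global index of
#' the unique window satisfying start <= pos < end; for a position `p` in a
#' grid with window length `L` this is the bin with ordinal `floor(p / L)`
#' on its chromosome.
#'
#' @param grid A [make_bins()] grid.
#' @param chrom Chromosome names.
#' @param pos 0-based positions.
#' @return Integer vector of region indices in `1..nrow(grid$regions)`.
#' @export
assign_bin <- function(grid, chrom, pos) {
  stopifnot(inherits(grid, "bin_grid"))
  unknown <- setdiff(unique(chrom), grid$chrom_order)
  if (length(unknown)) {
    stopf("chromosome(s) not in grid: %s", paste(unknown, collapse = ", "))
  }
  len <- grid$chrom_sizes[chrom]
  bad <- pos < 0 | pos >= len
  if (any(bad)) {
    i <- which(bad)[1L]
    stopf("position %g outside chromosome '%s' (length %g)",
          pos[i], chrom[i], len[i])
  }
  as.integer(grid$offsets[chrom] + pos %/% grid$window_length) + 1L
}

#' Aggregate one cell's calls into per-region methylation levels
#'
#' For each region with at least `min_sites` retained calls, the level is
#' the unweighted mean of per-site ratios `mc_reads / total_reads` (with
#' binary single-read calls this is the fraction of methylated sites);
#' regions with no captured site are masked as missing. Setting
#' `weighted = TRUE` switches to the read-weighted ratio
#' `sum(mc) / sum(total)` instead.
#'
#' @param cell A [cell_call_set] (calls assumed already context-filtered).
#' @param grid A [make_bins()] grid covering every call's chromosome.
#' @param min_sites Minimum site count for a region to receive a value;
#'   regions below it are masked. Default 1.
#' @param weighted Use the read-weighted mean instead of the site mean.
#' @return List with `values` (numeric, `NA` where masked), `mask`
#'   (logical, `TRUE` = missing) and `n_sites` (integer site counts), each
#'   of length `nrow(grid$regions)`.
#' @export
aggregate_cell <- function(cell, grid, min_sites = 1L, weighted = FALSE) {
  stopifnot(inherits(cell, "cell_call_set"), inherits(grid, "bin_grid"))
  R <- nrow(grid$regions)
  calls <- cell$calls
  if (!nrow(calls)) {
    return(list(values = rep(NA_real_, R), mask = rep(TRUE, R),
                n_sites = integer(R)))
  }
  idx <- assign_bin(grid, calls$chrom, calls$pos)
  n_sites <- tabulate(idx, nbins = R)
  if (weighted) {
    num <- vapply(split(calls$mc_reads, idx), sum, 0)
    den <- vapply(split(calls$total_reads, idx), sum, 0)
    values <- rep(NA_real_, R)
    values[as.integer(names(num))] <- num / den
  } else {
    lev <- calls$mc_reads / calls$total_reads
    sums <- vapply(split(lev, idx), sum, 0)
    values <- rep(NA_real_, R)
    values[as.integer(names(sums))] <- sums / n_sites[as.integer(names(sums))]
  }
  mask <- n_sites < max(1L, min_sites)
  values[mask] <- NA_real_
  list(values = values, mask = mask, n_sites = n_sites)
}

region_labels <- function(regions) {
  sprintf("%s:%g-%g", regions$chrom, regions$start, regions$end)
}

#' Construct a region matrix object
#'
#' Low-level constructor validating the cells-by-regions container: values
#' lie in \[0,1\] wherever the mask is `FALSE`, and are `NA` exactly where
#' it is `TRUE`.
#'
#' @param values Numeric matrix (cells x regions) with `NA` at masked
#'   entries.
#' @param cell_ids Character vector of unique cell ids (one per row).
#' @param regions data.frame with columns `chrom`, `start`, `end`.
#' @param context `"CG"` or `"CH"`.
#' @param window_length Window size in bp the matrix was built at.
#' @param mask Optional logical matrix; defaults to `is.na(values)`.
#' @return An object of class `region_matrix` with elements `values`,
#'   `mask`, `cell_ids`, `regions`, `context`, `window_length`.
#' @export
region_matrix <- function(values, cell_ids, regions, context,
                          window_length, mask = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(mask)) mask <- is.na(values)
  mask <- as.matrix(mask)
  cell_ids <- as.character(cell_ids)
  if (anyDuplicated(cell_ids)) stopf("duplicate cell ids")
  if (nrow(values) != length(cell_ids)) {
    stopf("values has %d rows but there are %d cell ids",
          nrow(values), length(cell_ids))
  }
  if (ncol(values) != nrow(regions)) {
    stopf("values has %d columns but there are %d regions",
          ncol(values), nrow(regions))
  }
  if (!identical(dim(mask), dim(values))) stopf("mask and values dims differ")
  if (any(is.na(values) != mask)) {
    stopf("mask must be TRUE exactly where values are NA")
  }
  obs <- values[!mask]
  if (length(obs) && (any(obs < 0) || any(obs > 1))) {
    stopf("unmasked values must lie in [0, 1]")
  }
  if (!context %in% c("CG", "CH")) stopf("context must be 'CG' or 'CH'")
  regions <- as.data.frame(regions)[c("chrom", "start", "end")]
  rownames(regions) <- NULL
  dimnames(values) <- list(cell_ids, region_labels(regions))
  dimnames(mask) <- dimnames(values)
  structure(list(values = values, mask = mask, cell_ids = cell_ids,
                 regions = regions, context = context,
                 window_length = as.numeric(window_length)),
            class = "region_matrix")
}

#' @export
print.region_matrix <- function(x, ...) {
  cat(sprintf(
    "<region_matrix> %d cell(s) x %d region(s), context %s, %.1f%% missing\n",
    length(x$cell_ids), nrow(x$regions), x$context,
    if (length(x$mask)) 100 * mean(x$mask) else 0))
  invisible(x)
}

#' Build the cell-by-region average methylation matrix
#'
#' Applies [aggregate_cell()] to every cell over a shared grid, after
#' restricting each cell's calls to the requested context class. Entry
#' (i, j) is cell i's average methylation level over its captured sites in
#' window j; entries with no captured site are `NA` and flagged in the
#' mask.
#'
#' @param cells List of [cell_call_set] objects with unique cell ids.
#' @param grid A [make_bins()] grid.
#' @param context `"CG"` (CpG calls only) or `"CH"` (CHG + CHH).
#' @param min_sites,weighted Passed to [aggregate_cell()].
#' @return A [region_matrix].
#' @export
build_region_matrix <- function(cells, grid, context = c("CG", "CH"),
                                min_sites = 1L, weighted = FALSE) {
  context <- match.arg(context)
  stopifnot(inherits(grid, "bin_grid"))
  ids <- vapply(cells, function(c) c$cell_id, "")
  if (anyDuplicated(ids)) {
    stopf("duplicate cell id(s): %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  R <- nrow(grid$regions)
  values <- matrix(NA_real_, nrow = length(cells), ncol = R)
  for (i in seq_along(cells)) {
    cl <- cells[[i]]
    filtered <- cell_call_set(cl$cell_id, filter_context(cl$calls, context))
    values[i, ] <- aggregate_cell(filtered, grid, min_sites = min_sites,
                                  weighted = weighted)$values
  }
  region_matrix(values, ids, grid$regions, context, grid$window_length)
}

#' Drop regions missing in every cell
#'
#' Regions masked in all cells carry no information and admit no mean or
#' median statistic; this removes them (idempotent) and reports the count.
#'
#' @param mat A [region_matrix].
#' @return A [region_matrix] restricted to regions observed in at least one
#'   cell; surviving region coordinates are unchanged.
#' @export
drop_all_missing_regions <- function(mat) {
  stopifnot(inherits(mat, "region_matrix"))
  if (!length(mat$mask)) return(mat)
  keep <- colSums(!mat$mask) > 0L
  n_drop <- sum(!keep)
  if (n_drop) {
    message(sprintf("dropping %d region(s) with no captured site in any cell",
                    n_drop))
  } else {
    return(mat)
  }
  region_matrix(mat$values[, keep, drop = FALSE], mat$cell_ids,
                mat$regions[keep, , drop = FALSE], mat$context,
                mat$window_length)
}
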