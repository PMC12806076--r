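# The four NA-imputation strategies compared by the package: constant
# zeros, constant ones, and the per-region mean or median of the values
# observed across cells. Statistics use only observed entries (single
# pass, never previously imputed values).

IMPUTE_STRATEGIES <- c("zeros", "ones", "means", "medians")

check_region_index <- function(mat, region) {
  stopifnot(inherits(mat, "region_matrix"))
  if (length(region) != 1L || region < 1L || region > ncol(mat$values)) {
    stopf("region index must be in 1..%d", ncol(mat$values))
  }
}

#' Per-region statistics over available (unmasked) entries
#'
#' `column_available_mean()` is the arithmetic mean of a region's observed
#' values across cells; `column_available_median()` the order-statistic
#' median (mean of the two central order statistics for an even count).
#' These are the fill values used by the `"means"` and `"medians"`
#' imputation strategies.
#'
#' @param mat A [region_matrix] (run [drop_all_missing_regions()] first so
#'   every region has at least one observed value).
#' @param region Region (column) index.
#' @return A value in \[0, 1\].
#' @export
column_available_mean <- function(mat, region) {
  check_region_index(mat, region)
  obs <- mat$values[!mat$mask[, region], region]
  if (!length(obs)) {
    stopf("region %d is missing in every cell; drop it first with drop_all_missing_regions()",
          region)
  }
  mean(obs)
}

#' @rdname column_available_mean
#' @export
column_available_median <- function(mat, region) {
  check_region_index(mat, region)
  obs <- mat$values[!mat$mask[, region], region]
  if (!length(obs)) {
    stopf("region %d is missing in every cell; drop it first with drop_all_missing_regions()",
          region)
  }
  stats::median(obs)
}

#' Impute the missing entries of a region matrix
#'
#' Replaces every masked entry by a strategy-specific fill: `0`, `1`, the
#' region's [column_available_mean()], or its [column_available_median()].
#' Observed entries are passed through bit-identically; the original mask
#' is retained as `source_mask` so downstream code can always tell imputed
#' from observed values.
#'
#' @param mat A [region_matrix] with no all-missing regions.
#' @param strategy One of `"zeros"`, `"ones"`, `"means"`, `"medians"`.
#' @return An object of class `imputed_matrix`: list with `values` (fully
#'   defined cells x regions matrix), `cell_ids`, `regions`, `context`,
#'   `window_length`, `strategy`, `source_mask`.
#' @examples
#' mat <- region_matrix(matrix(c(0.2, NA, 0.8, 1), 4, 1), paste0("c", 1:4),
#'                      data.frame(chrom = "chr1", start = 0, end = 100),
#'                      "CG", 100)
#' impute_matrix(mat, "medians")$values[2, 1]  # 0.8
#' @export
impute_matrix <- function(mat, strategy) {
  stopifnot(inherits(mat, "region_matrix"))
  if (!is.character(strategy) || length(strategy) != 1L ||
      !strategy %in% IMPUTE_STRATEGIES) {
    stopf("unknown imputation strategy '%s'; valid strategies: %s",
          paste(strategy, collapse = ","),
          paste(IMPUTE_STRATEGIES, collapse = ", "))
  }
  values <- mat$values
  mask <- mat$mask
  if (ncol(values) && any(colSums(!mask) == 0L)) {
    stopf("matrix has all-missing region(s); drop them first with drop_all_missing_regions()")
  }
  if (any(mask)) {
    fill <- switch(strategy,
      zeros   = rep(0, ncol(values)),
      ones    = rep(1, ncol(values)),
      means   = colMeans(values, na.rm = TRUE),
      medians = apply(values, 2L, stats::median, na.rm = TRUE))
    values[mask] <- rep(fill, each = nrow(values))[mask]
  }
  structure(list(values = values, cell_ids = mat$cell_ids,
                 regions = mat$regions, context = mat$context,
                 window_length = mat$window_length, strategy = strategy,
                 source_mask = mask),
            class = "imputed_matrix")
}

#' @export
print.imputed_matrix <- function(x, ...) {
  cat(sprintf("<imputed_matrix> %d cell(s) x %d region(s), strategy '%s' (%d entries filled)\n",
              nrow(x$values), ncol(x$values), x$strategy, sum(x$source_mask)))
  invisible(x)
}
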