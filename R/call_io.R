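# Recognised cytosine sequence contexts. "CH" is shorthand for CHG + CHH
# (H = A, C or T), the standard nomenclature for non-CpG methylation.
METH_CONTEXTS <- c("CG", "CHG", "CHH")

#' Construct a per-cell set of methylation calls
#'
#' A `cell_call_set` holds one cell's site-level methylation calls: one row
#' per captured cytosine with its genomic location, strand, sequence context,
#' and methylated / total read counts. In single-cell bisulfite data the
#' total read count is typically 1, so a call is binary (methylated or not),
#' but counts greater than 1 are admitted.
#'
#' @param cell_id Character scalar naming the cell.
#' @param calls `data.frame` with columns `chrom`, `pos` (0-based),
#'   `strand` (`"+"`/`"-"`), `context` (`"CG"`, `"CHG"`, `"CHH"`),
#'   `mc_reads`, `total_reads`. Rows are sorted by (chrom, pos) on
#'   construction.
#' @return An object of class `cell_call_set`: a list with elements
#'   `cell_id` and `calls`.
#' @examples
#' calls <- data.frame(chrom = "chr1", pos = c(10L, 4L), strand = "+",
#'                     context = "CG", mc_reads = c(1L, 0L),
#'                     total_reads = 1L)
#' cs <- cell_call_set("cellA", calls)
#' cs$calls$pos  # sorted: 4, 10
#' @export
cell_call_set <- function(cell_id, calls) {
  stopifnot(is.character(cell_id), length(cell_id) == 1L)
  needed <- c("chrom", "pos", "strand", "context", "mc_reads", "total_reads")
  missing_cols <- setdiff(needed, names(calls))
  if (length(missing_cols)) {
    stopf("calls is missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  calls <- as.data.frame(calls)[needed]
  if (nrow(calls)) {
    bad_ctx <- setdiff(unique(calls$context), METH_CONTEXTS)
    if (length(bad_ctx)) {
      stopf("unknown methylation context(s): %s", paste(bad_ctx, collapse = ", "))
    }
    if (any(calls$pos < 0)) stopf("positions must be >= 0 (0-based)")
    if (any(calls$total_reads < 1)) stopf("total_reads must be >= 1")
    if (any(calls$mc_reads < 0 | calls$mc_reads > calls$total_reads)) {
      stopf("mc_reads must satisfy 0 <= mc_reads <= total_reads")
    }
    key <- paste(calls$chrom, calls$pos, calls$strand)
    if (anyDuplicated(key)) {
      stopf("duplicate (chrom, pos, strand) entries in calls for cell '%s'",
            cell_id)
    }
    calls <- calls[order(calls$chrom, calls$pos), , drop = FALSE]
    rownames(calls) <- NULL
  }
  structure(list(cell_id = cell_id, calls = calls), class = "cell_call_set")
}

#' @export
print.cell_call_set <- function(x, ...) {
  cat(sprintf("<cell_call_set> %s: %d calls on %d chromosome(s)\n",
              x$cell_id, nrow(x$calls), length(unique(x$calls$chrom))))
  invisible(x)
}

#' Read a chromosome-sizes file
#'
#' Parses a two-column tab-separated file (chromosome name, length in bp)
#' into a named integer vector. Chromosome order in the file is preserved,
#' which fixes the global region indexing downstream.
#'
#' @param path Path to a chrom.sizes file (plain or gzipped).
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stopf("no chromosomes in '%s'", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sizes <- numeric(length(lines))
  names_out <- character(length(lines))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 2L) {
      stopf("malformed chrom.sizes line %d: expected 2 tab-separated fields", i)
    }
    len <- suppressWarnings(as.numeric(f[2L]))
    if (is.na(len) || len != floor(len)) {
      stopf("malformed chrom.sizes line %d: length '%s' is not an integer",
            i, f[2L])
    }
    if (len <= 0) {
      stopf("chrom.sizes line %d: chromosome '%s' has non-positive length %s",
            i, f[1L], f[2L])
    }
    names_out[i] <- f[1L]
    sizes[i] <- len
  }
  if (anyDuplicated(names_out)) stopf("duplicate chromosome names in '%s'", path)
  stats::setNames(sizes, names_out)
}

#' Read an allc-style methylation call file for one cell
#'
#' Reads a six-column tab-separated file (chromosome, 1-based position,
#' strand, context, methylated reads, total reads), converts positions to
#' the package-internal 0-based convention, and optionally restricts to a
#' sequence-context class. `"CH"` keeps CHG and CHH calls; `"CG"` keeps CG
#' only.
#'
#' @param path Path to the call file (plain or gzipped; no header).
#' @param context_filter One of `"all"`, `"CG"`, `"CH"`.
#' @param cell_id Cell identifier; defaults to the file name without
#'   extensions.
#' @return A [cell_call_set].
#' @export
read_cell_calls <- function(path, context_filter = c("all", "CG", "CH"),
                            cell_id = NULL) {
  context_filter <- match.arg(context_filter)
  if (is.null(cell_id)) {
    cell_id <- sub("\\.(tsv|txt|allc)(\\.gz)?$", "", basename(path))
  }
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = c(1L, 3L, 4L)))
  if (ncol(dt) < 6L) stopf("'%s': expected 6 tab-separated columns", path)
  calls <- data.frame(chrom = dt[[1L]],
                      pos = as.integer(dt[[2L]]) - 1L,
                      strand = dt[[3L]],
                      context = dt[[4L]],
                      mc_reads = as.integer(dt[[5L]]),
                      total_reads = as.integer(dt[[6L]]))
  calls <- filter_context(calls, context_filter)
  cell_call_set(cell_id, calls)
}

# Restrict calls to a context class; "CH" = CHG + CHH.
filter_context <- function(calls, context_filter) {
  if (nrow(calls)) {
    bad_ctx <- setdiff(unique(calls$context), METH_CONTEXTS)
    if (length(bad_ctx)) {
      stopf("unknown methylation context(s): %s", paste(bad_ctx, collapse = ", "))
    }
  }
  keep <- switch(context_filter,
                 all = rep(TRUE, nrow(calls)),
                 CG  = calls$context == "CG",
                 CH  = calls$context %in% c("CHG", "CHH"))
  calls[keep, , drop = FALSE]
}

#' Write a cell's methylation calls as an allc-style file
#'
#' Inverse of [read_cell_calls()]: positions are written 1-based, six
#' tab-separated columns, no header.
#'
#' @param cell A [cell_call_set].
#' @param path Output path (`.gz` suffix writes gzip).
#' @export
write_cell_calls <- function(cell, path) {
  stopifnot(inherits(cell, "cell_call_set"))
  out <- cell$calls
  out$pos <- out$pos + 1L
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a cell partition
#'
#' A `partition` pairs an ordered vector of cell ids with one categorical
#' label per cell — either annotated cell types or predicted cluster ids.
#'
#' @param cell_ids Character vector of unique cell ids.
#' @param labels Vector of labels, one per cell (coerced to character).
#' @return An object of class `partition`.
#' @export
partition <- function(cell_ids, labels) {
  cell_ids <- as.character(cell_ids)
  labels <- as.character(labels)
  if (length(cell_ids) != length(labels)) {
    stopf("cell_ids (%d) and labels (%d) differ in length",
          length(cell_ids), length(labels))
  }
  if (anyDuplicated(cell_ids)) stopf("duplicate cell ids in partition")
  structure(list(cell_ids = cell_ids, labels = labels), class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d cells, %d label(s)\n",
              length(x$cell_ids), length(unique(x$labels))))
  invisible(x)
}

#' Read / write cell label files
#'
#' Two-column tab-separated files with header `cell_id<TAB>label`.
#'
#' @param path File path.
#' @return `read_cell_labels` returns a [partition].
#' @export
read_cell_labels <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (ncol(dt) < 2L) stopf("'%s': expected columns cell_id, label", path)
  partition(dt[[1L]], dt[[2L]])
}

#' @rdname read_cell_labels
#' @param part A [partition].
#' @export
write_cell_labels <- function(part, path) {
  stopifnot(inherits(part, "partition"))
  data.table::fwrite(data.frame(cell_id = part$cell_ids, label = part$labels),
                     path, sep = "\t", quote = FALSE)
  invisible(path)
}

# File names used by the region-matrix writer/reader pair.
region_matrix_paths <- function(prefix) {
  list(matrix  = paste0(prefix, "_matrix.tsv"),
       regions = paste0(prefix, "_regions.tsv"),
       cells   = paste0(prefix, "_cells.tsv"),
       meta    = paste0(prefix, "_meta.json"))
}

#' Write a region matrix to disk
#'
#' Writes a dense TSV (cells as rows, regions as columns headed
#' `chrom:start-end`, missing entries as the literal token `NA`) plus region
#' and cell metadata sidecars and a small JSON metadata file. Values are
#' serialized with 17 significant digits so the round trip through
#' [read_region_matrix()] is bit-exact.
#'
#' @param mat A [region_matrix].
#' @param prefix Path prefix; files `<prefix>_matrix.tsv`,
#'   `<prefix>_regions.tsv`, `<prefix>_cells.tsv`, `<prefix>_meta.json` are
#'   written.
#' @export
write_region_matrix <- function(mat, prefix) {
  stopifnot(inherits(mat, "region_matrix"))
  paths <- region_matrix_paths(prefix)
  region_names <- region_labels(mat$regions)
  vals <- mat$values
  chr <- matrix(sprintf("%.17g", vals), nrow = nrow(vals), ncol = ncol(vals))
  chr[mat$mask] <- "NA"
  out <- data.table::data.table(cell_id = mat$cell_ids)
  if (ncol(chr)) {
    for (j in seq_len(ncol(chr))) data.table::set(out, j = region_names[j],
                                                  value = chr[, j])
  }
  data.table::fwrite(out, paths$matrix, sep = "\t", quote = FALSE)
  data.table::fwrite(mat$regions, paths$regions, sep = "\t", quote = FALSE)
  data.table::fwrite(data.frame(cell_id = mat$cell_ids), paths$cells,
                     sep = "\t", quote = FALSE)
  jsonlite::write_json(list(context = mat$context,
                            window_length = mat$window_length,
                            n_cells = length(mat$cell_ids),
                            n_regions = nrow(mat$regions)),
                       paths$meta, auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read a region matrix written by [write_region_matrix()]
#'
#' @param prefix Path prefix used when writing.
#' @return A [region_matrix] identical to the one written (values, mask,
#'   region coordinates, cell ids, context).
#' @export
read_region_matrix <- function(prefix) {
  paths <- region_matrix_paths(prefix)
  for (p in unlist(paths)) if (!file.exists(p)) stopf("missing file '%s'", p)
  meta <- jsonlite::read_json(paths$meta, simplifyVector = TRUE)
  regions <- as.data.frame(data.table::fread(paths$regions, sep = "\t"))
  cells <- as.data.frame(data.table::fread(paths$cells, sep = "\t",
                                           colClasses = "character"))
  dt <- data.table::fread(paths$matrix, sep = "\t", header = TRUE,
                          na.strings = "NA")
  cell_ids <- as.character(dt[[1L]])
  if (ncol(dt) > 1L) {
    vals <- as.matrix(dt[, -1L, drop = FALSE])
    storage.mode(vals) <- "double"
  } else {
    vals <- matrix(numeric(0), nrow = nrow(dt), ncol = 0L)
  }
  bad <- !is.na(vals) & (vals < 0 | vals > 1)
  if (any(bad)) {
    stopf("matrix value outside [0,1] at %d entr%s (first: %g)",
          sum(bad), if (sum(bad) == 1L) "y" else "ies", vals[bad][1L])
  }
  region_matrix(values = vals, cell_ids = cell_ids, regions = regions,
                context = meta$context, window_length = meta$window_length)
}
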