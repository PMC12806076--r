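# External clustering agreement metrics, implemented from their
# definitions on the contingency table of two partitions: adjusted Rand
# index (Hubert-Arabie), normalized and adjusted mutual information, and
# the Fowlkes-Mallows index. Natural logarithms throughout (the metrics
# are ratio-normalised so the base cancels); 0 * log 0 := 0.

#' Contingency table of two partitions
#'
#' Counts `n_uv`, the number of cells with label u in `U` and v in `V`,
#' after aligning the two partitions by cell id (order may differ).
#'
#' @param U,V [partition] objects over the same cell id set.
#' @return An object of class `contingency_table`: list with `n`, `counts`
#'   (K_U x K_V matrix), `row_sums`, `col_sums`.
#' @export
contingency_table <- function(U, V) {
  stopifnot(inherits(U, "partition"), inherits(V, "partition"))
  if (!setequal(U$cell_ids, V$cell_ids) ||
      length(U$cell_ids) != length(V$cell_ids)) {
    only_u <- setdiff(U$cell_ids, V$cell_ids)
    only_v <- setdiff(V$cell_ids, U$cell_ids)
    stopf("partitions cover different cells (only in U: %s; only in V: %s)",
          paste(utils::head(only_u, 5L), collapse = ","),
          paste(utils::head(only_v, 5L), collapse = ","))
  }
  v_aligned <- V$labels[match(U$cell_ids, V$cell_ids)]
  counts <- unclass(table(U$labels, v_aligned))
  as_contingency(counts)
}

# Wrap a raw counts matrix (e.g. from table()) as a contingency_table.
as_contingency <- function(counts) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  structure(list(n = sum(counts), counts = counts,
                 row_sums = rowSums(counts), col_sums = colSums(counts)),
            class = "contingency_table")
}

coerce_contingency <- function(t) {
  if (inherits(t, "contingency_table")) t else as_contingency(t)
}

choose2 <- function(x) x * (x - 1) / 2

# Shannon entropy (nats) of a count vector.
count_entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

# Mutual information (nats) of a contingency table.
table_mutual_information <- function(t) {
  nz <- which(t$counts > 0, arr.ind = TRUE)
  if (!nrow(nz)) return(0)
  nij <- t$counts[nz]
  ai <- t$row_sums[nz[, 1L]]
  bj <- t$col_sums[nz[, 2L]]
  sum(nij / t$n * (log(t$n) + log(nij) - log(ai) - log(bj)))
}

entropy_normalizer <- function(h_u, h_v,
                               average = c("arithmetic", "geometric",
                                           "min", "max")) {
  switch(match.arg(average),
         arithmetic = (h_u + h_v) / 2,
         geometric = sqrt(h_u * h_v),
         min = min(h_u, h_v),
         max = max(h_u, h_v))
}

#' Adjusted Rand index
#'
#' Hubert-Arabie chance-corrected pair-counting agreement:
#' `(sum_uv C(n_uv,2) - E) / ((sum_u C(a_u,2) + sum_v C(b_v,2))/2 - E)`
#' with `E = sum_u C(a_u,2) * sum_v C(b_v,2) / C(n,2)`. Equals 1 iff the
#' partitions are identical up to label renaming and has expectation ~0
#' under independent random labelings with the same marginals.
#'
#' @param t A [contingency_table()] (or a raw counts matrix).
#' @return The ARI (<= 1).
#' @export
adjusted_rand_index <- function(t) {
  t <- coerce_contingency(t)
  if (t$n < 2) stopf("ARI needs at least 2 items")
  sum_comb <- sum(choose2(t$counts))
  comb_a <- sum(choose2(t$row_sums))
  comb_b <- sum(choose2(t$col_sums))
  expected <- comb_a * comb_b / choose2(t$n)
  max_index <- (comb_a + comb_b) / 2
  if (max_index == expected) return(1)  # both partitions degenerate
  (sum_comb - expected) / (max_index - expected)
}

#' Normalized mutual information
#'
#' `I(U;V)` divided by a mean of the two label entropies (arithmetic by
#' default). In \[0,1\]; 1 iff the partitions are identical up to
#' renaming; 0 when the mutual information is zero (e.g. one partition is
#' a single cluster and the other is not).
#'
#' @param t A [contingency_table()] (or a raw counts matrix).
#' @param average Entropy normalizer: `"arithmetic"` (default),
#'   `"geometric"`, `"min"` or `"max"`.
#' @return The NMI in \[0, 1\].
#' @export
normalized_mutual_information <- function(t, average = "arithmetic") {
  t <- coerce_contingency(t)
  if (t$n < 1) stopf("empty contingency table")
  h_u <- count_entropy(t$row_sums)
  h_v <- count_entropy(t$col_sums)
  if (h_u == 0 && h_v == 0) return(1)  # both single-cluster: identical
  mi <- table_mutual_information(t)
  if (mi <= 0) return(0)
  mi / entropy_normalizer(h_u, h_v, average)
}

#' Expected mutual information under the permutation (hypergeometric) model
#'
#' Exact finite sum of `E[I(U;V)]` over all feasible cell counts for fixed
#' marginals, used by the AMI's chance correction.
#'
#' @param row_sums,col_sums Cluster sizes of the two partitions.
#' @param n Total number of items.
#' @return Expected mutual information in nats.
#' @export
expected_mutual_information <- function(row_sums, col_sums, n) {
  lg <- lgamma(seq_len(n + 1))  # lg[x] = lgamma(x) = log((x-1)!)
  lgam <- function(x) lg[x + 1L]
  emi <- 0
  for (ai in row_sums) {
    for (bj in col_sums) {
      lo <- max(1, ai + bj - n)
      hi <- min(ai, bj)
      if (hi < lo) next
      nij <- lo:hi
      log_term <- log(n) + log(nij) - log(ai) - log(bj)
      log_pmf <- lgam(ai) + lgam(bj) + lgam(n - ai) + lgam(n - bj) -
        lgam(n) - lgam(nij) - lgam(ai - nij) - lgam(bj - nij) -
        lgam(n - ai - bj + nij)
      emi <- emi + sum(nij / n * log_term * exp(log_pmf))
    }
  }
  emi
}

#' Adjusted mutual information
#'
#' `(I - E[I]) / (mean(H(U), H(V)) - E[I])` with the exact
#' hypergeometric-model [expected_mutual_information()]. Equals 1 iff the
#' partitions are identical up to renaming and has expectation ~0 under
#' independent random labelings.
#'
#' @inheritParams normalized_mutual_information
#' @return The AMI (<= 1).
#' @export
adjusted_mutual_information <- function(t, average = "arithmetic") {
  t <- coerce_contingency(t)
  if (t$n < 2) stopf("AMI needs at least 2 items")
  h_u <- count_entropy(t$row_sums)
  h_v <- count_entropy(t$col_sums)
  if (h_u == 0 && h_v == 0) {
    message("both partitions are single clusters; AMI defined as 1")
    return(1)
  }
  mi <- table_mutual_information(t)
  emi <- expected_mutual_information(t$row_sums, t$col_sums, as.integer(t$n))
  normalizer <- entropy_normalizer(h_u, h_v, average)
  denom <- normalizer - emi
  # guard against cancellation when the denominator is (numerically) zero
  if (abs(denom) < .Machine$double.eps) {
    denom <- if (denom >= 0) .Machine$double.eps else -.Machine$double.eps
  }
  (mi - emi) / denom
}

#' Fowlkes-Mallows index
#'
#' Pair-counting index `TP / sqrt((TP + FP) * (TP + FN))`, where TP counts
#' cell pairs co-clustered in both partitions, TP + FP pairs co-clustered
#' in the first, and TP + FN pairs co-clustered in the second. In \[0,1\];
#' 1 iff identical up to renaming. Defined as 0 (with a message) when a
#' partition has no co-clustered pair at all.
#'
#' @param t A [contingency_table()] (or a raw counts matrix).
#' @return The FMI in \[0, 1\].
#' @export
fowlkes_mallows_index <- function(t) {
  t <- coerce_contingency(t)
  tp <- sum(choose2(t$counts))
  pairs_u <- sum(choose2(t$row_sums))
  pairs_v <- sum(choose2(t$col_sums))
  if (pairs_u == 0 || pairs_v == 0) {
    message("a partition has no co-clustered pair; FMI defined as 0")
    return(0)
  }
  tp / sqrt(pairs_u * pairs_v)
}

#' Score the agreement of two partitions with all four metrics
#'
#' Builds one shared contingency table and evaluates ARI, AMI, NMI and
#' FMI on it. All four are symmetric in (U, V).
#'
#' @param U,V [partition] objects over the same cells (typically predicted
#'   clusters vs annotated cell types).
#' @param average Entropy normalizer for NMI/AMI (default arithmetic).
#' @param metadata Named list carried through to the report (e.g. the
#'   imputation strategy, window length, seed).
#' @return An object of class `metric_report`: list with `ari`, `ami`,
#'   `nmi`, `fmi`, `n`, `metadata`.
#' @export
evaluate_partitions <- function(U, V, average = "arithmetic",
                                metadata = list()) {
  t <- contingency_table(U, V)
  structure(list(ari = adjusted_rand_index(t),
                 ami = adjusted_mutual_information(t, average),
                 nmi = normalized_mutual_information(t, average),
                 fmi = fowlkes_mallows_index(t),
                 n = t$n, metadata = metadata),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> n=%d  ARI=%.4f  AMI=%.4f  NMI=%.4f  FMI=%.4f\n",
              x$n, x$ari, x$ami, x$nmi, x$fmi))
  invisible(x)
}
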