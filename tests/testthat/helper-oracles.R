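# Independent brute-force oracles for the clustering metrics. These
# enumerate cell pairs or probability terms with explicit loops and never
# call the package's contingency-formula implementations.

# Classify every unordered pair of items as co-clustered in u and/or v.
oracle_pair_counts <- function(u, v) {
  n <- length(u)
  tp <- fp <- fn <- tn <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      su <- u[i] == u[j]
      sv <- v[i] == v[j]
      if (su && sv) tp <- tp + 1
      else if (su && !sv) fp <- fp + 1
      else if (!su && sv) fn <- fn + 1
      else tn <- tn + 1
    }
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# Hubert-Arabie ARI in its pair-count form.
oracle_ari <- function(u, v) {
  p <- oracle_pair_counts(u, v)
  num <- 2 * (p$tp * p$tn - p$fp * p$fn)
  den <- (p$tp + p$fp) * (p$fp + p$tn) + (p$tp + p$fn) * (p$fn + p$tn)
  if (den == 0) return(1)
  num / den
}

oracle_fmi <- function(u, v) {
  p <- oracle_pair_counts(u, v)
  if (p$tp + p$fp == 0 || p$tp + p$fn == 0) return(0)
  p$tp / sqrt((p$tp + p$fp) * (p$tp + p$fn))
}

# Entropy / mutual information by explicit p*log(p) summation.
oracle_entropy <- function(labels) {
  h <- 0
  n <- length(labels)
  for (lv in unique(labels)) {
    p <- sum(labels == lv) / n
    h <- h - p * log(p)
  }
  h
}

oracle_mi <- function(u, v) {
  n <- length(u)
  mi <- 0
  for (a in unique(u)) {
    for (b in unique(v)) {
      nab <- sum(u == a & v == b)
      if (nab > 0) {
        mi <- mi + nab / n * log(n * nab / (sum(u == a) * sum(v == b)))
      }
    }
  }
  mi
}

oracle_nmi <- function(u, v) {
  hu <- oracle_entropy(u)
  hv <- oracle_entropy(v)
  if (hu == 0 && hv == 0) return(1)
  mi <- oracle_mi(u, v)
  if (mi <= 0) return(0)
  mi / ((hu + hv) / 2)
}

# Expected MI over the hypergeometric model, with exact choose() ratios
# (valid for the small n used in tests).
oracle_emi <- function(a, b, n) {
  s <- 0
  for (ai in a) {
    for (bj in b) {
      lo <- max(1, ai + bj - n)
      hi <- min(ai, bj)
      if (hi < lo) next
      for (nij in lo:hi) {
        p <- choose(ai, nij) * choose(n - ai, bj - nij) / choose(n, bj)
        if (p > 0) s <- s + p * (nij / n) * log(n * nij / (ai * bj))
      }
    }
  }
  s
}

oracle_ami <- function(u, v) {
  n <- length(u)
  hu <- oracle_entropy(u)
  hv <- oracle_entropy(v)
  if (hu == 0 && hv == 0) return(1)
  mi <- oracle_mi(u, v)
  a <- as.vector(table(u))
  b <- as.vector(table(v))
  emi <- oracle_emi(a, b, n)
  (mi - emi) / ((hu + hv) / 2 - emi)
}

# Average MI over every permutation of v's labels: the permutation-model
# expectation, feasible for tiny n.
oracle_emi_by_permutation <- function(u, v) {
  n <- length(u)
  perms <- function(x) {
    if (length(x) <= 1L) return(list(x))
    out <- list()
    for (i in seq_along(x)) {
      for (rest in perms(x[-i])) out <- c(out, list(c(x[i], rest)))
    }
    out
  }
  mis <- vapply(perms(v), function(vp) oracle_mi(u, vp), 0)
  mean(mis)
}

random_partition_pair <- function(n, max_k = 4L) {
  u <- sample.int(sample(2:max_k, 1L), n, replace = TRUE)
  v <- sample.int(sample(2:max_k, 1L), n, replace = TRUE)
  list(u = u, v = v)
}
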