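# Independent brute-force oracles used by the unit and acceptance tests.
# These deliberately avoid the package's own closed-form code paths.

# All set partitions of {1, ..., n} as lists of integer blocks.
enumerate_set_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  smaller <- enumerate_set_partitions(n - 1)
  out <- list()
  for (p in smaller) {
    for (b in seq_along(p)) {
      q <- p
      q[[b]] <- c(q[[b]], n)
      out[[length(out) + 1]] <- q
    }
    out[[length(out) + 1]] <- c(p, list(n))
  }
  out
}

# Exact CRP probability of a specific (ordered-block) set partition,
# computed by sequential seating without the package's EPPF code.
crp_partition_probability <- function(blocks, d, alpha) {
  n <- sum(lengths(blocks))
  member_of <- integer(n)
  for (b in seq_along(blocks)) member_of[blocks[[b]]] <- b
  sizes <- integer(length(blocks))
  prob <- 1
  for (i in seq_len(n)) {
    b <- member_of[i]
    if (i > 1) {
      prob <- prob * if (sizes[b] == 0) {
        (alpha + sum(sizes > 0) * d) / (alpha + i - 1)
      } else {
        (sizes[b] - d) / (alpha + i - 1)
      }
    }
    sizes[b] <- sizes[b] + 1L
  }
  prob
}

# Exhaustive expectation of a partition metric over all assignments of n
# iid records to categories with probabilities p (M^n outcomes).
enumerate_multinomial <- function(p, n, metric) {
  M <- length(p)
  grid <- as.matrix(expand.grid(rep(list(seq_len(M)), n)))
  tot <- 0
  for (r in seq_len(nrow(grid))) {
    occ <- tabulate(grid[r, ], nbins = M)
    w <- prod(p[grid[r, ]])
    tot <- tot + w * metric(occ[occ > 0], n)
  }
  tot
}

# Partition metrics on a vector of occupied set sizes.
metric_correctness <- function(sizes, n) length(sizes) / n
metric_uniqueness <- function(sizes, n) sum(sizes == 1) / n
metric_kanon <- function(k) function(sizes, n) sum(sizes[sizes < k]) / n

# Exhaustive subsample expectation over all size-m subsets of a small
# gallery given per-record set labels.
enumerate_subsamples <- function(labels, m, metric) {
  idx <- utils::combn(length(labels), m)
  vals <- apply(idx, 2, function(cols) {
    occ <- table(labels[cols])
    metric(as.numeric(occ), m)
  })
  mean(vals)
}
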