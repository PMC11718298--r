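#' Anonymity-set size counts
#'
#' The multiset of anonymity-set sizes summarizing the partition of a
#' gallery: a table mapping each distinct set size `s` to its multiplicity
#' `m_s`. This is the sufficient statistic for all empirical privacy
#' metrics and for the exchangeable-partition likelihood.
#'
#' @param sizes Either an integer vector of individual set sizes (one entry
#'   per set), or the distinct sizes when `counts` is given.
#' @param counts Optional multiplicities matching `sizes`.
#' @return An object of class `"anonymity_counts"`: a list with `table`
#'   (data.frame with columns `size`, `m`, ordered by size), `N` (number of
#'   records) and `K` (number of sets).
#' @examples
#' anonymity_counts(c(2, 1, 1))           # sizes of three sets
#' anonymity_counts(c(1, 2), c(2, 1))     # same, as size/multiplicity
#' @export
anonymity_counts <- function(sizes, counts = NULL) {
  if (is.null(counts)) {
    sizes <- as.numeric(sizes)
    if (length(sizes) < 1 || any(!is.finite(sizes)) || any(sizes < 1) ||
        any(sizes != round(sizes))) {
      stop("anonymity_counts: set sizes must be positive integers", call. = FALSE)
    }
    tab <- table(sizes)
    df <- data.frame(size = as.numeric(names(tab)), m = as.numeric(tab))
  } else {
    sizes <- as.numeric(sizes); counts <- as.numeric(counts)
    if (length(sizes) != length(counts) || length(sizes) < 1 ||
        any(sizes < 1) || any(sizes != round(sizes)) ||
        any(counts < 1) || any(counts != round(counts))) {
      stop("anonymity_counts: sizes and counts must be positive integers of equal length",
           call. = FALSE)
    }
    df <- stats::aggregate(m ~ size, data.frame(size = sizes, m = counts), sum)
  }
  df <- df[order(df$size), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(table = df, N = sum(df$size * df$m), K = sum(df$m)),
            class = "anonymity_counts")
}

#' @export
print.anonymity_counts <- function(x, ...) {
  cat(sprintf("Anonymity-set counts: N = %d records in K = %d sets\n",
              as.integer(x$N), as.integer(x$K)))
  print(x$table, row.names = FALSE)
  invisible(x)
}

# Expand counts to one entry per set (vector of set sizes).
.set_sizes <- function(counts) rep(counts$table$size, counts$table$m)

#' Partition a gallery into anonymity sets
#'
#' Groups the rows of a tabular gallery by exact equality on the selected
#' quasi-identifier columns and returns the multiset of group sizes.
#' Missing values form their own category (dropping them would silently
#' change the gallery size). Numeric columns with non-integer values are
#' refused unless an explicit binning is supplied, since exact matching is
#' defined on discrete equality.
#'
#' @param table A data.frame of records.
#' @param qid_columns Character vector of quasi-identifier column names.
#' @param bins Optional named list of numeric break vectors, passed to
#'   [cut()], for pre-discretizing continuous columns.
#' @return An [anonymity_counts()] object.
#' @examples
#' g <- data.frame(zip = c("02138", "02138", "02139"), sex = c("F", "F", "M"))
#' partition_gallery(g, c("zip", "sex"))
#' @export
partition_gallery <- function(table, qid_columns, bins = NULL) {
  if (!is.data.frame(table) || nrow(table) < 1) {
    stop("partition_gallery: table must be a data.frame with at least one row",
         call. = FALSE)
  }
  if (length(qid_columns) < 1) {
    stop("partition_gallery: at least one quasi-identifier column is required",
         call. = FALSE)
  }
  missing_cols <- setdiff(qid_columns, names(table))
  if (length(missing_cols) > 0) {
    stop(sprintf("partition_gallery: unknown column(s) %s; available: %s",
                 paste(missing_cols, collapse = ", "),
                 paste(names(table), collapse = ", ")), call. = FALSE)
  }
  keys <- lapply(qid_columns, function(cn) {
    col <- table[[cn]]
    if (is.double(col) && any(col != round(col), na.rm = TRUE)) {
      if (is.null(bins) || is.null(bins[[cn]])) {
        stop(sprintf(
          "partition_gallery: column '%s' is continuous; supply bins[['%s']] to discretize it",
          cn, cn), call. = FALSE)
      }
      col <- cut(col, breaks = bins[[cn]], include.lowest = TRUE)
    }
    v <- as.character(col)
    v[is.na(v)] <- "\x01<missing>"
    v
  })
  key <- do.call(paste, c(keys, sep = "\x1f"))
  anonymity_counts(as.integer(table(key)))
}

#' Empirical correctness of a partitioned gallery
#'
#' The per-record probability of a correct match under exact matching is
#' the reciprocal of the record's anonymity-set size; averaging over all
#' records gives exactly (number of sets) / (number of records), `K / N`.
#'
#' @param counts An [anonymity_counts()] object.
#' @return Correctness in `(0, 1]`.
#' @examples
#' empirical_correctness(anonymity_counts(4)) # one set of 4 records: 0.25
#' @export
empirical_correctness <- function(counts) {
  stopifnot(inherits(counts, "anonymity_counts"))
  counts$K / counts$N
}

#' Empirical uniqueness of a partitioned gallery
#'
#' Fraction of records lying in singleton anonymity sets.
#'
#' @inheritParams empirical_correctness
#' @return Uniqueness in `[0, 1]`.
#' @export
empirical_uniqueness <- function(counts) {
  stopifnot(inherits(counts, "anonymity_counts"))
  m1 <- counts$table$m[counts$table$size == 1]
  if (length(m1) == 0) 0 else m1 / counts$N
}

#' Empirical k-anonymity violations of a partitioned gallery
#'
#' Fraction of records whose anonymity set contains fewer than `k` records.
#'
#' @inheritParams empirical_correctness
#' @param k Anonymity threshold, `k >= 1`.
#' @return Probability in `[0, 1]`; 0 at `k = 1`.
#' @export
empirical_kanon_violations <- function(counts, k) {
  stopifnot(inherits(counts, "anonymity_counts"), is.numeric(k), k >= 1)
  with(counts$table, sum(size[size < k] * m[size < k])) / counts$N
}

#' Correctness curve under subsampling of a finite gallery
#'
#' Expected correctness when `m` of the gallery's `N` records are drawn
#' uniformly without replacement, for each requested subsample size. In
#' `"exact"` mode the hypergeometric expectation is used: the expected
#' number of anonymity sets represented in the subsample is
#' \eqn{\sum_{\mathrm{sets}} [1 - \binom{N-s}{m}/\binom{N}{m}]}, divided by
#' `m` (computed with log-binomials). In `"montecarlo"` mode, `reps`
#' subsamples are drawn and the set-count ratio averaged.
#'
#' @param counts An [anonymity_counts()] object.
#' @param sizes Integer subsample sizes, each between 1 and `N`.
#' @param method `"exact"` (default) or `"montecarlo"`.
#' @param reps Number of Monte-Carlo replicates.
#' @param seed Seed for the Monte-Carlo draws.
#' @return A [correctness_curve()] with one point per subsample size.
#' @examples
#' subsampled_correctness_curve(anonymity_counts(c(2, 2)), c(1, 2, 4))
#' @export
subsampled_correctness_curve <- function(counts, sizes,
                                         method = c("exact", "montecarlo"),
                                         reps = 100L, seed = NULL) {
  method <- match.arg(method)
  .check_subsizes(counts, sizes)
  kappa <- if (method == "exact") {
    vapply(sizes, function(m) .exact_sub_correctness(counts, m), numeric(1))
  } else {
    .mc_subsample(counts, sizes, reps, seed,
                  function(sub) sub$K / sub$N)
  }
  correctness_curve(sizes, kappa)
}

#' Uniqueness curve under subsampling of a finite gallery
#'
#' Expected fraction of subsampled records that are unique within the
#' subsample, under uniform sampling without replacement. In `"exact"` mode
#' a set of size `s` contributes a singleton with hypergeometric
#' probability \eqn{s\binom{N-s}{m-1}/\binom{N}{m}}.
#'
#' @inheritParams subsampled_correctness_curve
#' @return A data.frame with columns `n` and `uniqueness`.
#' @export
subsampled_uniqueness_curve <- function(counts, sizes,
                                        method = c("exact", "montecarlo"),
                                        reps = 100L, seed = NULL) {
  method <- match.arg(method)
  .check_subsizes(counts, sizes)
  xi <- if (method == "exact") {
    s <- counts$table$size; mult <- counts$table$m
    vapply(sizes, function(m) {
      lp <- log(s) + lchoose(counts$N - s, m - 1) - lchoose(counts$N, m)
      min(max(sum(exp(lp) * mult) / m, 0), 1)
    }, numeric(1))
  } else {
    .mc_subsample(counts, sizes, reps, seed, empirical_uniqueness)
  }
  data.frame(n = sizes, uniqueness = xi)
}

#' k-anonymity violation curve under subsampling of a finite gallery
#'
#' Expected fraction of subsampled records in subsample anonymity sets of
#' fewer than `k` records, under uniform sampling without replacement. In
#' `"exact"` mode, a set of size `s` contributes `j` violating records with
#' hypergeometric probability `dhyper(j, s, N - s, m)` for each
#' `j = 1, ..., min(k - 1, s)`.
#'
#' @inheritParams subsampled_correctness_curve
#' @param k Anonymity threshold, `k >= 1`.
#' @return A data.frame with columns `n` and `violations`.
#' @export
subsampled_kanon_curve <- function(counts, sizes, k,
                                   method = c("exact", "montecarlo"),
                                   reps = 100L, seed = NULL) {
  method <- match.arg(method)
  stopifnot(is.numeric(k), length(k) == 1, k >= 1)
  .check_subsizes(counts, sizes)
  v <- if (method == "exact") {
    vapply(sizes, function(m) {
      if (k == 1) return(0)
      tot <- 0
      for (r in seq_len(nrow(counts$table))) {
        s <- counts$table$size[r]; mult <- counts$table$m[r]
        j <- seq_len(min(k - 1, s))
        tot <- tot + mult * sum(j * stats::dhyper(j, s, counts$N - s, m))
      }
      tot / m
    }, numeric(1))
  } else {
    .mc_subsample(counts, sizes, reps, seed,
                  function(sub) empirical_kanon_violations(sub, k))
  }
  data.frame(n = sizes, violations = v)
}

.check_subsizes <- function(counts, sizes) {
  stopifnot(inherits(counts, "anonymity_counts"))
  if (any(sizes < 1) || any(sizes != round(sizes))) {
    stop("subsample sizes must be positive integers", call. = FALSE)
  }
  if (any(sizes > counts$N)) {
    stop(sprintf("subsample sizes must not exceed the gallery size N = %d",
                 as.integer(counts$N)), call. = FALSE)
  }
}

.exact_sub_correctness <- function(counts, m) {
  s <- counts$table$size; mult <- counts$table$m
  l_absent <- lchoose(counts$N - s, m) - lchoose(counts$N, m)
  # clip roundoff at the m = 1 / m = N endpoints
  min(max(sum((1 - exp(l_absent)) * mult) / m, 0), 1)
}

# Draw subsamples of record indices and apply `metric` to the induced counts.
.mc_subsample <- function(counts, sizes, reps, seed, metric) {
  set_of_record <- rep(seq_len(counts$K), times = .set_sizes(counts))
  withr::with_seed(if (is.null(seed)) 1L else seed, {
    vapply(sizes, function(m) {
      mean(vapply(seq_len(reps), function(r) {
        idx <- sample.int(counts$N, m)
        metric(anonymity_counts(as.integer(table(set_of_record[idx]))))
      }, numeric(1)))
    }, numeric(1))
  })
}
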