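# Distribution-free two-group comparison by label randomisation with a
# median-difference statistic. Two computational routes give the same null
# distribution: "shuffle" permutes the pooled values directly; "tabulate"
# draws the group allocation of each distinct value from the multivariate
# hypergeometric (a label shuffle of a multiset is exactly that), which
# makes year-scale minute-level tests cheap. The route is chosen
# deterministically from the input size, so a given seed always reproduces
# the same null values.

#' Difference in group medians
#'
#' @param a,b numeric vectors (non-empty). Even-length medians are the mean
#'   of the two central order statistics.
#' @return `median(a) - median(b)`.
#' @export
median_difference <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  stats::median(a) - stats::median(b)
}

#' Two-group randomisation test on the median difference
#'
#' Pools the two groups, reassigns values to group labels uniformly at
#' random preserving group sizes, and recomputes the median difference for
#' each of `B` replicates. The two-tailed p-value is
#' `(1 + #\{|null| >= |observed|\}) / (B + 1)` by default, so it is never
#' exactly zero and the test is valid; `raw_proportion = TRUE` gives the
#' plain proportion `#\{|null| >= |observed|\} / B` instead (at B = 5000 the
#' two differ by at most 2e-4).
#'
#' @param a,b numeric vectors (non-empty).
#' @param B number of replicates (default 5000).
#' @param seed integer seed recorded in the result; same seed, same null.
#' @param raw_proportion use the plain-proportion p-value convention.
#' @param method `"auto"` (default), `"shuffle"` or `"tabulate"`; `"auto"`
#'   uses tabulation when the pooled sample is large with few distinct
#'   values, and direct shuffling otherwise.
#' @return object of class `"randomisation_result"`: list with `observed`,
#'   `null_values` (length `B`), `p_value`, `B`, `seed`, `n_a`, `n_b`,
#'   `method`. If all pooled values are identical the test is degenerate:
#'   p = 1 with a warning.
#' @examples
#' r <- randomisation_test(rpois(30, 5), rpois(30, 9), B = 999, seed = 1)
#' r$p_value
#' @export
randomisation_test <- function(a, b, B = 5000, seed = NULL,
                               raw_proportion = FALSE,
                               method = c("auto", "shuffle", "tabulate")) {
  method <- match.arg(method)
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  stopifnot(B >= 1)
  observed <- median_difference(a, b)
  pooled <- c(a, b)
  n_a <- length(a); n_b <- length(b); n <- n_a + n_b
  if (length(unique(pooled)) == 1L) {
    warning("all pooled values identical: degenerate randomisation test, p = 1")
    return(structure(list(observed = 0, null_values = rep(0, B),
                          p_value = 1, B = as.integer(B), seed = seed,
                          n_a = n_a, n_b = n_b, method = "degenerate"),
                     class = "randomisation_result"))
  }
  if (method == "auto") {
    method <- if (n >= 10000L && length(unique(pooled)) <= 2000L)
      "tabulate" else "shuffle"
  }
  if (!is.null(seed)) set.seed(seed)
  null_values <- if (method == "shuffle") {
    null_shuffle(pooled, n_a, B)
  } else {
    null_tabulate(pooled, n_a, B)
  }
  k <- sum(abs(null_values) >= abs(observed) - 1e-12)
  p <- if (raw_proportion) k / B else (1 + k) / (B + 1)
  structure(list(observed = observed, null_values = null_values,
                 p_value = p, B = as.integer(B), seed = seed,
                 n_a = n_a, n_b = n_b, method = method),
            class = "randomisation_result")
}

null_shuffle <- function(pooled, n_a, B) {
  n <- length(pooled)
  vapply(seq_len(B), function(i) {
    take <- sample.int(n, n_a)
    inb <- rep(TRUE, n); inb[take] <- FALSE
    stats::median(pooled[take]) - stats::median(pooled[inb])
  }, numeric(1))
}

# Multivariate-hypergeometric route: allocate the count of each distinct
# value to group A by chained rhyper draws (vectorised over replicates),
# then read both group medians off cumulative counts.
null_tabulate <- function(pooled, n_a, B) {
  vals <- sort(unique(pooled))
  cnt <- tabulate(match(pooled, vals), nbins = length(vals))
  K <- length(vals)
  n <- length(pooled)
  XA <- matrix(0L, nrow = B, ncol = K)
  remaining_draws <- rep.int(n_a, B)
  remaining_pop <- n
  for (k in seq_len(K)) {
    rest <- remaining_pop - cnt[k]
    XA[, k] <- if (rest == 0L) remaining_draws else
      stats::rhyper(B, cnt[k], rest, remaining_draws)
    remaining_draws <- remaining_draws - XA[, k]
    remaining_pop <- rest
  }
  med_a <- median_from_counts(XA, vals, n_a)
  XB <- matrix(rep(cnt, each = B), nrow = B) - XA
  med_b <- median_from_counts(XB, vals, n - n_a)
  med_a - med_b
}

# row-wise median of count vectors over the common support `vals`
median_from_counts <- function(X, vals, n) {
  cum <- X
  for (k in seq_len(ncol(X))[-1L]) cum[, k] <- cum[, k - 1L] + X[, k]
  pick <- function(pos) vals[rowSums(cum < pos) + 1L]
  if (n %% 2L == 1L) {
    pick((n + 1L) / 2L)
  } else {
    (pick(n / 2L) + pick(n / 2L + 1L)) / 2
  }
}

#' @export
print.randomisation_result <- function(x, ...) {
  cat(sprintf(
    "<randomisation test: observed median diff %.4g, p = %.4g (B = %d, n = %d + %d)>\n",
    x$observed, x$p_value, x$B, x$n_a, x$n_b))
  invisible(x)
}

#' Pairwise randomisation tests across covariate groups
#'
#' Runs [randomisation_test()] for every unordered pair of groups. P-values
#' are reported raw, without multiplicity correction (noted in the result's
#' metadata).
#'
#' @param values numeric vector of observations.
#' @param labels group labels (factor or coercible), at least two non-empty
#'   groups.
#' @param B,seed,raw_proportion as in [randomisation_test()]; each pair gets
#'   its own sub-seed derived deterministically from `seed`.
#' @return list of class `"pairwise_randomisation"`, one
#'   `"randomisation_result"` per pair, named `"A|B"`; attribute
#'   `multiplicity_correction = "none"`.
#' @export
pairwise_randomisation <- function(values, labels, B = 5000, seed = NULL,
                                   raw_proportion = FALSE) {
  labels <- factor(labels)
  groups <- split(values, labels, drop = TRUE)
  if (length(groups) < 2L) stop("need at least two non-empty groups")
  pairs <- utils::combn(names(groups), 2L)
  if (!is.null(seed)) set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, ncol(pairs))
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    randomisation_test(groups[[pairs[1L, j]]], groups[[pairs[2L, j]]],
                       B = B, seed = sub_seeds[j],
                       raw_proportion = raw_proportion)
  })
  names(out) <- paste(pairs[1L, ], pairs[2L, ], sep = "|")
  structure(out, class = "pairwise_randomisation",
            multiplicity_correction = "none")
}

#' @export
print.pairwise_randomisation <- function(x, ...) {
  cat("<pairwise randomisation tests (uncorrected p-values)>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-20s observed %8.4g  p = %.4g\n",
                nm, x[[nm]]$observed, x[[nm]]$p_value))
  }
  invisible(x)
}

#' @export
as.data.frame.pairwise_randomisation <- function(x, ...) {
  do.call(rbind, lapply(names(x), function(nm) {
    r <- x[[nm]]
    g <- strsplit(nm, "|", fixed = TRUE)[[1L]]
    data.frame(group_a = g[1L], group_b = g[2L], n_a = r$n_a, n_b = r$n_b,
               observed = r$observed, p_value = r$p_value, B = r$B,
               seed = if (is.null(r$seed)) NA_integer_ else r$seed)
  }))
}
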