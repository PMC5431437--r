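# Hypergeometric co-occurrence scoring of herb-disease associations from
# literature document counts.
#
# With N papers in total, K of them linked to the disease, n about the herb
# and k about both, the association score is the upper-tail probability
#   P(X >= k) = 1 - sum_{i=0}^{k-1} C(K,i) C(N-K,n-i) / C(N,n)
# of a hypergeometric variable X. Small P means the herb co-occurs with the
# disease more often than chance sampling of the literature would produce.

#' Literature document counts for one herb-disease pair
#'
#' @param n_total total number of papers in the corpus (N).
#' @param n_disease number of papers linked to the disease (K).
#' @param n_herb number of papers about the herb (n).
#' @param n_joint number of papers linking the herb and the disease (k).
#' @return a validated `corpus_counts` object.
#' @export
#' @examples
#' corpus_counts(10, 5, 4, 2)
corpus_counts <- function(n_total, n_disease, n_herb, n_joint) {
  if (!is_count(n_total) || !is_count(n_disease) ||
      !is_count(n_herb) || !is_count(n_joint)) {
    stop("domain error: counts must be single non-negative integers")
  }
  if (n_disease > n_total || n_herb > n_total) {
    stop("domain error: n_disease and n_herb cannot exceed n_total")
  }
  if (n_joint > min(n_disease, n_herb)) {
    stop("domain error: n_joint cannot exceed min(n_disease, n_herb)")
  }
  structure(list(n_total = n_total, n_disease = n_disease,
                 n_herb = n_herb, n_joint = n_joint),
            class = "corpus_counts")
}

as_corpus_counts <- function(x) {
  if (inherits(x, "corpus_counts")) return(x)
  if (is.list(x) &&
      all(c("n_total", "n_disease", "n_herb", "n_joint") %in% names(x))) {
    return(corpus_counts(x$n_total, x$n_disease, x$n_herb, x$n_joint))
  }
  stop("domain error: expected corpus_counts or a compatible named list")
}

#' Upper-tail hypergeometric co-occurrence probability
#'
#' Probability of observing at least the recorded number of joint
#' herb-disease papers under hypergeometric sampling of the corpus. Computed
#' from log-space binomial coefficients with log-sum-exp over whichever tail
#' has fewer terms, so corpora up to ~1e7 documents neither overflow nor lose
#' precision. `n_joint = 0` gives exactly 1.
#'
#' @param counts a [corpus_counts()] object (or compatible named list).
#' @return the probability P(X >= k), a number in \[0, 1\].
#' @export
#' @examples
#' hypergeom_pvalue(corpus_counts(10, 5, 4, 2)) # 155/210
hypergeom_pvalue <- function(counts) {
  counts <- as_corpus_counts(counts)
  N <- counts$n_total
  K <- counts$n_disease
  n <- counts$n_herb
  k <- counts$n_joint
  if (k == 0) return(1)
  lo <- max(0, n - (N - K))          # smallest i with positive pmf
  hi <- min(K, n)                    # largest i with positive pmf
  lpmf <- function(i) lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  n_upper <- hi - k + 1
  n_lower <- k - lo                  # terms strictly below k within support
  p <- if (n_upper <= n_lower) {
    exp(logsumexp(lpmf(k:hi)))
  } else if (n_lower <= 0) {
    1                                # the whole support is >= k
  } else {
    1 - exp(logsumexp(lpmf(lo:(k - 1))))
  }
  min(max(p, 0), 1)
}

#' Significance decision for a co-occurrence probability
#'
#' Strict comparison against the significance level: an association is called
#' significant iff `p < alpha`.
#'
#' @param p probability (vectorized), each in \[0, 1\].
#' @param alpha significance level, default 0.01.
#' @return logical vector.
#' @export
is_significant <- function(p, alpha = 0.01) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("domain error: p must lie in [0, 1]")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    stop("domain error: alpha must lie in (0, 1]")
  }
  p < alpha
}

#' Rank herbs by disease co-occurrence probability
#'
#' Batch wrapper: scores every herb and returns the association table sorted
#' ascending by probability, ties broken lexicographically by herb name.
#'
#' @param counts_table data.frame with columns `herb`, `n_total`,
#'   `n_disease`, `n_herb`, `n_joint` (one row per herb; a TSV with these
#'   columns read via [utils::read.delim()] works directly).
#' @param alpha significance level passed to [is_significant()].
#' @return the input columns plus `p_value` and `significant`, sorted.
#' @export
rank_herbs <- function(counts_table, alpha = 0.01) {
  stopifnot(is.data.frame(counts_table))
  need <- c("herb", "n_total", "n_disease", "n_herb", "n_joint")
  missing_cols <- setdiff(need, names(counts_table))
  if (length(missing_cols)) {
    stop("schema error: missing column '", missing_cols[1], "'")
  }
  if (anyDuplicated(counts_table$herb)) {
    stop("validation error: duplicate herb name(s): ",
         paste(unique(counts_table$herb[duplicated(counts_table$herb)]),
               collapse = ", "))
  }
  p <- vapply(seq_len(nrow(counts_table)), function(i) {
    hypergeom_pvalue(corpus_counts(counts_table$n_total[i],
                                   counts_table$n_disease[i],
                                   counts_table$n_herb[i],
                                   counts_table$n_joint[i]))
  }, numeric(1))
  out <- counts_table[need]
  out$p_value <- p
  out$significant <- is_significant(p, alpha)
  out <- out[order(out$p_value, out$herb), , drop = FALSE]
  rownames(out) <- NULL
  out
}
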