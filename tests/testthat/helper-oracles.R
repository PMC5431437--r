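# Independent oracles used across the suite. These deliberately take the
# naive route (direct pmf summation, per-row scans, per-target set
# membership) so they share no code with the implementation they check.

# upper-tail hypergeometric by direct pmf summation with choose()
hyper_oracle <- function(N, K, n, k) {
  i <- seq.int(k, min(K, n))
  if (length(i) == 0L || k > min(K, n)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# per-target membership scan for shared/specific classification
partition_oracle <- function(net, groups) {
  hit <- function(g, t) {
    for (cid in unique(net$edges$compound_id[net$edges$target_id == t])) {
      if (g %in% net$groups[[cid]]) return(TRUE)
    }
    FALSE
  }
  res <- list(shared = character(),
              specific = stats::setNames(
                rep(list(character()), length(groups)), groups),
              other = character())
  for (t in net$targets) {
    hits <- groups[vapply(groups, hit, logical(1), t = t)]
    if (length(hits) == length(groups) && length(groups) > 1L) {
      res$shared <- c(res$shared, t)
    } else if (length(hits) == 1L && length(groups) > 1L) {
      res$specific[[hits]] <- c(res$specific[[hits]], t)
    } else if (length(groups) == 1L && length(hits) == 1L) {
      res$shared <- c(res$shared, t)
    } else {
      res$other <- c(res$other, t)
    }
  }
  res
}

# small literal library for round-trip and screening tests
tiny_library <- function() {
  compound_library(
    compound_id = c("X1", "X2", "X3"),
    name = c("one, with comma", "two", "three"),
    ob = c(55.5, 12.0, 30.0),
    dl = c(0.5, 0.9, 0.18),
    herbs = list("Herb A", c("Herb A", "Herb B"), "Herb B"),
    rescued = c(FALSE, TRUE, FALSE),
    descriptors = list(c(1, 2, 0), NULL, c(0, 1, 1))
  )
}

# random valid score table with known kept rows
random_scores <- function(n, seed) {
  set.seed(seed)
  data.frame(
    compound_id = sprintf("C%05d", seq_len(n)),
    target_id = sprintf("T%05d", sample.int(n, n, replace = FALSE)),
    rf_score = runif(n),
    svm_score = runif(n),
    stringsAsFactors = FALSE
  )
}
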