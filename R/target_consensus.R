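# Dual-model consensus filtering of compound-target prediction scores.
#
# An interaction is kept only when both the random-forest and the
# support-vector-machine scores clear the positive-prediction level (0.5)
# AND their model-specific final cutoffs (RF > 0.7, SVM > 0.8), all strict.

#' Consensus-filter thresholds
#'
#' @param positive_min positive-prediction level both scores must exceed;
#'   default 0.5.
#' @param rf_min final random-forest cutoff; default 0.7.
#' @param svm_min final support-vector-machine cutoff; default 0.8.
#' @return a `consensus_config` object.
#' @export
consensus_config <- function(positive_min = 0.5, rf_min = 0.7,
                             svm_min = 0.8) {
  vals <- c(positive_min = positive_min, rf_min = rf_min, svm_min = svm_min)
  if (!is.numeric(vals) || any(is.na(vals)) || any(vals < 0 | vals > 1)) {
    stop("domain error: thresholds must lie in [0, 1]")
  }
  if (positive_min > rf_min || positive_min > svm_min) {
    stop("domain error: positive_min must not exceed rf_min or svm_min")
  }
  structure(list(positive_min = positive_min, rf_min = rf_min,
                 svm_min = svm_min),
            class = "consensus_config")
}

check_scores <- function(rf, svm) {
  if (is.null(rf) || is.null(svm)) {
    stop("domain error: rf_score and svm_score are required")
  }
  if (any(is.na(rf)) || any(is.na(svm)) ||
      any(rf < 0 | rf > 1) || any(svm < 0 | svm > 1)) {
    stop("domain error: scores must lie in [0, 1]")
  }
  invisible(TRUE)
}

#' Decide whether one scored interaction is kept
#'
#' Strict conjunctive rule: kept iff both scores exceed `positive_min` and
#' additionally `rf_score > rf_min` and `svm_score > svm_min`. Vectorized.
#'
#' @param x list or data.frame with numeric `rf_score` and `svm_score`.
#' @param config a [consensus_config()].
#' @return logical vector.
#' @export
#' @examples
#' keep_interaction(list(rf_score = 0.9, svm_score = 0.9))   # TRUE
#' keep_interaction(list(rf_score = 0.75, svm_score = 0.75)) # FALSE
keep_interaction <- function(x, config = consensus_config()) {
  stopifnot(inherits(config, "consensus_config"))
  check_scores(x$rf_score, x$svm_score)
  x$rf_score > config$positive_min & x$svm_score > config$positive_min &
    x$rf_score > config$rf_min & x$svm_score > config$svm_min
}

#' Filter a table of scored interactions
#'
#' Row-local, order-stable application of [keep_interaction()]: returns
#' exactly the rows passing the rule, in their input order.
#'
#' @param interactions data.frame with columns `compound_id`, `target_id`,
#'   `rf_score`, `svm_score`; (compound, target) pairs must be unique.
#' @param config a [consensus_config()].
#' @return the kept subset of `interactions`.
#' @export
consensus_filter <- function(interactions, config = consensus_config()) {
  stopifnot(is.data.frame(interactions))
  need <- c("compound_id", "target_id", "rf_score", "svm_score")
  missing_cols <- setdiff(need, names(interactions))
  if (length(missing_cols)) {
    stop("schema error: missing column '", missing_cols[1], "'")
  }
  key <- paste(interactions$compound_id, interactions$target_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("validation error: duplicate (compound, target) pair: ",
         gsub("\r", " / ", dup, fixed = TRUE))
  }
  kept <- keep_interaction(interactions, config)
  out <- interactions[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}
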