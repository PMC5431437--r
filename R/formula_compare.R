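# The alternative-removing comparison: partition the target union of two
# formula-variant networks into shared and variant-specific sets, then judge
# whether the removed component set is dispensable for the disease.

#' Compare the target coverage of two formula networks
#'
#' Partitions the union of both networks' targets into `shared` (hit by
#' both), `a_specific` (only network A) and `b_specific` (only network B);
#' `shared_fraction` is `|shared| / |union|`. Target annotations supply the
#' disease-association flag: annotated `TRUE` targets among `b_specific` are
#' returned as `b_specific_disease_linked`; targets with `NA` or missing
#' annotation are reported separately as `b_specific_unknown` rather than
#' silently treated as safe.
#'
#' @param net_a `ct_network` of the retained formula (e.g. the modified
#'   formula).
#' @param net_b `ct_network` of the removed component set (e.g. the animal
#'   drugs).
#' @param annotations data.frame with columns `target_id` and
#'   `disease_associated` (logical; `NA` = unknown). Optional columns
#'   (`gene_name`, `pathways`) are carried along untouched.
#' @param labels length-2 character labels for the two networks (used in
#'   printing).
#' @return a `formula_comparison` object.
#' @export
compare_formulae <- function(net_a, net_b, annotations = NULL,
                             labels = c("a", "b")) {
  stopifnot(inherits(net_a, "ct_network"), inherits(net_b, "ct_network"),
            is.character(labels), length(labels) == 2L)
  ta <- net_a$targets
  tb <- net_b$targets
  all_targets <- union(ta, tb)
  if (length(all_targets) == 0L) {
    stop("domain error: both networks have empty target sets")
  }
  shared <- intersect(ta, tb)
  a_specific <- setdiff(ta, tb)
  b_specific <- setdiff(tb, ta)
  status <- rep(NA, length(b_specific))   # disease association, NA = unknown
  if (!is.null(annotations)) {
    stopifnot(is.data.frame(annotations),
              all(c("target_id", "disease_associated") %in%
                    names(annotations)))
    if (anyDuplicated(annotations$target_id)) {
      stop("validation error: duplicate target_id in annotations")
    }
    idx <- match(b_specific, annotations$target_id)
    status <- as.logical(annotations$disease_associated)[idx]
  }
  structure(list(
    labels = labels,
    shared_targets = shared,
    a_specific = a_specific,
    b_specific = b_specific,
    shared_fraction = length(shared) / length(all_targets),
    b_specific_disease_linked = b_specific[!is.na(status) & status],
    b_specific_unknown = b_specific[is.na(status)],
    n_union = length(all_targets)
  ), class = "formula_comparison")
}

#' Compare an original formula against its modified (reduced) version
#'
#' [compare_formulae()] with role labels fixed to modified/original: the
#' modified formula plays network A, the original plays network B, so
#' `b_specific` holds the targets the reduction loses.
#'
#' @param net_modified,net_original `ct_network` objects.
#' @param annotations as in [compare_formulae()].
#' @return a `formula_comparison` object.
#' @export
compare_original_vs_modified <- function(net_modified, net_original,
                                         annotations = NULL) {
  compare_formulae(net_modified, net_original, annotations,
                   labels = c("modified", "original"))
}

#' @export
print.formula_comparison <- function(x, ...) {
  cat(sprintf("<formula_comparison> %s vs %s: %d target(s) in union\n",
              x$labels[1], x$labels[2], x$n_union))
  cat(sprintf("  shared: %d (%.2f%%)\n", length(x$shared_targets),
              100 * x$shared_fraction))
  cat(sprintf("  %s-specific: %d\n", x$labels[1], length(x$a_specific)))
  cat(sprintf("  %s-specific: %d (%d disease-linked, %d unknown)\n",
              x$labels[2], length(x$b_specific),
              length(x$b_specific_disease_linked),
              length(x$b_specific_unknown)))
  invisible(x)
}

#' Removability verdict for a formula comparison
#'
#' Two rules, reported independently: (i) coverage — the shared fraction of
#' the target union must reach the threshold; (ii) disease link — no target
#' specific to the removed component set may be disease-associated. The
#' component set is `removable` only when both rules pass. Removed-specific
#' targets of unknown disease status make the verdict *indeterminate*
#' (removable = `NA`) rather than falsely reassuring, unless the comparison
#' already fails on a known rule.
#'
#' @param report a [compare_formulae()] result.
#' @param shared_fraction_threshold minimum shared fraction, default 0.90.
#' @return a `removal_verdict`: list with `removable` (`TRUE`/`FALSE`/`NA`),
#'   `status` (`"removable"`, `"not removable"`, `"indeterminate"`) and
#'   per-rule `reasons`.
#' @export
removal_verdict <- function(report, shared_fraction_threshold = 0.90) {
  stopifnot(inherits(report, "formula_comparison"),
            is.numeric(shared_fraction_threshold),
            length(shared_fraction_threshold) == 1L,
            shared_fraction_threshold >= 0, shared_fraction_threshold <= 1)
  coverage_pass <- report$shared_fraction >= shared_fraction_threshold
  n_linked <- length(report$b_specific_disease_linked)
  n_unknown <- length(report$b_specific_unknown)
  disease_pass <- if (n_linked > 0) FALSE else if (n_unknown > 0) NA else TRUE
  removable <- if (!coverage_pass || isFALSE(disease_pass)) {
    FALSE
  } else if (is.na(disease_pass)) {
    NA
  } else {
    TRUE
  }
  status <- if (is.na(removable)) "indeterminate"
            else if (removable) "removable" else "not removable"
  structure(list(
    removable = removable,
    status = status,
    shared_fraction_threshold = shared_fraction_threshold,
    reasons = list(
      coverage = list(pass = coverage_pass,
                      shared_fraction = report$shared_fraction,
                      threshold = shared_fraction_threshold),
      disease_link = list(pass = disease_pass,
                          n_disease_linked = n_linked,
                          n_unknown = n_unknown)
    )
  ), class = "removal_verdict")
}

#' @export
print.removal_verdict <- function(x, ...) {
  cat(sprintf("<removal_verdict> %s\n", x$status))
  cat(sprintf("  coverage rule: %s (shared fraction %.4f, threshold %.2f)\n",
              if (x$reasons$coverage$pass) "pass" else "fail",
              x$reasons$coverage$shared_fraction,
              x$reasons$coverage$threshold))
  dp <- x$reasons$disease_link$pass
  cat(sprintf("  disease-link rule: %s (%d disease-linked, %d unknown among removed-specific targets)\n",
              if (is.na(dp)) "indeterminate" else if (dp) "pass" else "fail",
              x$reasons$disease_link$n_disease_linked,
              x$reasons$disease_link$n_unknown))
  invisible(x)
}
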