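# ADME candidate screening: oral bioavailability (OB, %) and Tanimoto
# drug-likeness (DL) thresholds, plus an explicit whitelist that rescues
# literature-supported compounds failing the numeric filter.

#' Screening thresholds
#'
#' Defaults follow the standard systems-pharmacology cutoffs: OB >= 30% and
#' DL >= 0.18, the latter being the mean drug-likeness of the DrugBank
#' collection. Boundaries are inclusive by default, so a compound sitting
#' exactly at DL = 0.18 is kept.
#'
#' @param ob_min OB threshold in percent, in \[0, 100\]. Default 30.
#' @param dl_min DL threshold, in \[0, 1\]. Default 0.18.
#' @param inclusive logical; if `TRUE` (default) the comparison is `>=`,
#'   otherwise strict `>`.
#' @return a `screen_config` object.
#' @export
screen_config <- function(ob_min = 30, dl_min = 0.18, inclusive = TRUE) {
  stopifnot(is.numeric(ob_min), length(ob_min) == 1L,
            ob_min >= 0, ob_min <= 100,
            is.numeric(dl_min), length(dl_min) == 1L,
            dl_min >= 0, dl_min <= 1,
            is.logical(inclusive), length(inclusive) == 1L, !is.na(inclusive))
  structure(list(ob_min = ob_min, dl_min = dl_min, inclusive = inclusive),
            class = "screen_config")
}

#' Continuous Tanimoto similarity
#'
#' `T(a, b) = sum(a*b) / (sum(a^2) + sum(b^2) - sum(a*b))` for non-negative
#' descriptor vectors; symmetric, in \[0, 1\], and 1 exactly when `a == b`.
#'
#' @param a,b non-negative numeric vectors of equal length, not both
#'   all-zero.
#' @return similarity score in \[0, 1\].
#' @export
#' @examples
#' tanimoto_similarity(c(1, 1, 0), c(1, 0, 1)) # 1/3
tanimoto_similarity <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b)) {
    stop("domain error: descriptor vectors must be numeric")
  }
  if (length(a) != length(b)) {
    stop("domain error: descriptor vectors differ in length (",
         length(a), " vs ", length(b), ")")
  }
  if (any(!is.finite(a)) || any(!is.finite(b)) || any(a < 0) || any(b < 0)) {
    stop("domain error: descriptor vectors must be finite and non-negative")
  }
  ab <- sum(a * b)
  denom <- sum(a^2) + sum(b^2) - ab
  if (denom == 0) {
    stop("undefined-input error: both descriptor vectors are all-zero")
  }
  ab / denom
}

#' Drug-likeness of a compound against a reference mean vector
#'
#' The DL score is the Tanimoto similarity between the compound's descriptor
#' vector and the mean descriptor vector of a reference drug collection.
#' When the compound carries no descriptors the score is not computable and
#' `NA` is returned, signalling that the tabulated DL value must be used
#' instead.
#'
#' @param descriptors the compound's non-negative descriptor vector, or
#'   `NULL`/empty when unavailable.
#' @param reference_mean mean descriptor vector of the reference drugs.
#' @return DL score in \[0, 1\], or `NA_real_` when not computable.
#' @export
#' @examples
#' drug_likeness(c(2, 0, 1), c(1, 1, 1)) # 0.6
drug_likeness <- function(descriptors, reference_mean) {
  if (is.null(descriptors) || length(descriptors) == 0L ||
      all(is.na(descriptors))) {
    return(NA_real_)
  }
  tanimoto_similarity(descriptors, reference_mean)
}

#' OB/DL filter decision for compounds
#'
#' @param record a `compound_library` (vectorized over rows) or any
#'   list/data.frame with numeric `ob` and `dl` entries.
#' @param config a [screen_config()].
#' @return logical vector, `TRUE` where the compound meets both thresholds.
#' @export
#' @examples
#' passes_filter(list(ob = 46.43, dl = 0.28)) # TRUE  (quercetin)
#' passes_filter(list(ob = 7.60, dl = 0.41))  # FALSE (brucine: low OB)
passes_filter <- function(record, config = screen_config()) {
  stopifnot(inherits(config, "screen_config"))
  ob <- record$ob
  dl <- record$dl
  if (is.null(ob) || is.null(dl)) {
    stop("not-evaluable error: record lacks ob/dl fields")
  }
  if (any(is.na(ob)) || any(is.na(dl))) {
    stop("not-evaluable error: OB or DL missing for ",
         sum(is.na(ob) | is.na(dl)), " compound(s)")
  }
  if (config$inclusive) {
    ob >= config$ob_min & dl >= config$dl_min
  } else {
    ob > config$ob_min & dl > config$dl_min
  }
}

#' Screen a compound library with a rescue whitelist
#'
#' Partitions the library into strict passes (both thresholds met), rescued
#' compounds (whitelisted despite failing at least one threshold) and
#' rejected compounds. The three sets are disjoint; retained = strict union
#' rescued. Per-herb counts are computed over each compound's full herb
#' attribution set, deduped by compound id.
#'
#' @param library a [compound_library()] with non-missing OB and DL.
#' @param whitelist character vector of compound ids to retain regardless of
#'   their scores; must all exist in the library. Default: none.
#' @param config a [screen_config()].
#' @return a `screen_result`: list with `strict_pass`, `rescued`, `retained`,
#'   `rejected` (character id vectors), `per_herb_counts` (data.frame with
#'   `herb`, `n_strict`, `n_retained`) and the `config` used.
#' @export
#' @examples
#' lib <- load_fixture("table1")
#' res <- screen_library(lib, whitelist = lib$compound_id[lib$rescued])
#' length(res$retained) # 66
screen_library <- function(library, whitelist = character(),
                           config = screen_config()) {
  stopifnot(inherits(library, "compound_library"))
  whitelist <- unique(as.character(whitelist))
  unknown <- setdiff(whitelist, library$compound_id)
  if (length(unknown)) {
    stop("validation error: whitelist id(s) absent from library: ",
         paste(unknown, collapse = ", "))
  }
  ids <- library$compound_id
  ok <- if (nrow(library)) passes_filter(library, config) else logical(0)
  strict_pass <- ids[ok]
  rescued <- setdiff(whitelist, strict_pass)
  retained <- ids[ok | ids %in% rescued]   # keep library order
  rejected <- setdiff(ids, retained)
  herbs_all <- sort(unique(unlist(library$herbs)))
  per_herb <- if (length(herbs_all)) {
    counts <- t(vapply(herbs_all, function(h) {
      in_h <- vapply(library$herbs, function(hs) h %in% hs, logical(1))
      c(sum(in_h & ids %in% strict_pass), sum(in_h & ids %in% retained))
    }, numeric(2)))
    data.frame(herb = herbs_all, n_strict = as.integer(counts[, 1]),
               n_retained = as.integer(counts[, 2]),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(herb = character(), n_strict = integer(),
               n_retained = integer(), stringsAsFactors = FALSE)
  }
  structure(list(strict_pass = strict_pass, rescued = rescued,
                 retained = retained, rejected = rejected,
                 per_herb_counts = per_herb, config = config,
                 n_input = nrow(library)),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf(paste0("<screen_result> %d compound(s): %d strict pass, ",
                     "%d rescued, %d rejected (OB >= %g, DL >= %g)\n"),
              x$n_input, length(x$strict_pass), length(x$rescued),
              length(x$rejected), x$config$ob_min, x$config$dl_min))
  print(x$per_herb_counts, row.names = FALSE)
  invisible(x)
}
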