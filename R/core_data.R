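# Domain container for screened molecules and its TSV plumbing.
#
# A compound library is a data.frame (one row per unique compound) with
# columns:
#   compound_id  character, unique
#   name         character
#   ob           numeric in [0, 100], NA when not predicted
#   dl           numeric in [0, 1],   NA when not predicted
#   herbs        list of character vectors (non-empty herb attribution sets)
#   rescued      logical, literature-justified retention despite filter failure
#   descriptors  list of numeric vectors (or NULL entries) of one fixed length

#' Construct a compound library
#'
#' Builds and validates the tabular container used throughout the package for
#' screened molecules. A compound appearing in several herbs is stored once,
#' with its full herb attribution set, so that per-herb counts can be deduped
#' by compound id.
#'
#' @param compound_id character vector of unique short identifiers.
#' @param name character vector of compound names.
#' @param ob numeric oral bioavailability percentages in \[0, 100\]; `NA`
#'   marks an unknown (not predicted) value.
#' @param dl numeric drug-likeness scores in \[0, 1\]; `NA` allowed as for
#'   `ob`.
#' @param herbs list of non-empty character vectors (herb attribution sets),
#'   or a single character vector recycled element-wise.
#' @param rescued logical; whitelist flag for compounds retained despite
#'   failing the screen. Default `FALSE`.
#' @param descriptors optional list of non-negative numeric vectors of one
#'   common length (per-compound descriptor vectors); `NULL` entries allowed.
#' @return a `compound_library` (classed data.frame).
#' @export
#' @examples
#' lib <- compound_library(
#'   compound_id = c("A1", "A2"),
#'   name = c("alpha", "beta"),
#'   ob = c(45, 12), dl = c(0.3, 0.4),
#'   herbs = list("Herb One", c("Herb One", "Herb Two"))
#' )
#' nrow(lib)
compound_library <- function(compound_id, name, ob, dl, herbs,
                             rescued = FALSE, descriptors = NULL) {
  compound_id <- as.character(compound_id)
  n <- length(compound_id)
  if (anyDuplicated(compound_id)) {
    stop("validation error: duplicate compound_id(s): ",
         paste(unique(compound_id[duplicated(compound_id)]), collapse = ", "))
  }
  name <- rep_len(as.character(name), n)
  ob <- rep_len(as.numeric(ob), n)
  dl <- rep_len(as.numeric(dl), n)
  if (any(!is.na(ob) & (ob < 0 | ob > 100))) {
    stop("validation error: ob outside [0, 100]")
  }
  if (any(!is.na(dl) & (dl < 0 | dl > 1))) {
    stop("validation error: dl outside [0, 1]")
  }
  if (!is.list(herbs)) herbs <- as.list(rep_len(as.character(herbs), n))
  herbs <- rep_len(herbs, n)
  herbs <- lapply(herbs, function(h) unique(trimws(as.character(h))))
  if (n > 0 && any(vapply(herbs, length, 1L) == 0L)) {
    stop("validation error: every compound needs a non-empty herb set")
  }
  rescued <- rep_len(as.logical(rescued), n)
  if (is.null(descriptors)) {
    descriptors <- vector("list", n)
  } else {
    descriptors <- rep_len(descriptors, n)
    lens <- unique(vapply(Filter(Negate(is.null), descriptors), length, 1L))
    if (length(lens) > 1L) {
      stop("validation error: descriptor vectors must share one length")
    }
    bad <- vapply(descriptors,
                  function(d) !is.null(d) && any(!is.finite(d) | d < 0),
                  logical(1))
    if (any(bad)) stop("validation error: descriptors must be non-negative")
  }
  out <- data.frame(compound_id = compound_id, name = name,
                    ob = ob, dl = dl, stringsAsFactors = FALSE)
  out$herbs <- herbs
  out$rescued <- rescued
  out$descriptors <- descriptors
  class(out) <- c("compound_library", "data.frame")
  out
}

#' @export
print.compound_library <- function(x, ...) {
  cat(sprintf("<compound_library> %d compound(s), %d herb(s)\n",
              nrow(x), length(unique(unlist(x$herbs)))))
  if (nrow(x) > 0) {
    shown <- utils::head(data.frame(
      compound_id = x$compound_id, name = x$name, ob = x$ob, dl = x$dl,
      herbs = vapply(x$herbs, paste, "", collapse = ", "),
      stringsAsFactors = FALSE), 10)
    print(shown, row.names = FALSE)
    if (nrow(x) > 10) cat(sprintf("... %d more row(s)\n", nrow(x) - 10))
  }
  invisible(x)
}

.default_dialect <- c(id = "id", name = "name", ob = "ob", dl = "dl",
                      herbs = "herbs", rescued = "rescued",
                      descriptors = "descriptors")

#' Read a compound table from TSV
#'
#' Reads a tab-separated compound table (header row; herb attributions as a
#' comma-separated list inside one, optionally quoted, cell) into a validated
#' [compound_library()]. Column names in the file can differ from the
#' canonical ones via `dialect`.
#'
#' @param path path to a TSV file.
#' @param dialect named character vector mapping canonical column names
#'   (`id`, `name`, `ob`, `dl`, `herbs`, and optionally `rescued`,
#'   `descriptors`) to the names used in the file. Unmentioned columns keep
#'   their canonical names.
#' @return a `compound_library`; row order of the file is preserved.
#' @export
read_compound_table <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  map <- .default_dialect
  if (!is.null(dialect)) {
    unknown <- setdiff(names(dialect), names(map))
    if (length(unknown)) {
      stop("schema error: unknown dialect key(s): ",
           paste(unknown, collapse = ", "))
    }
    map[names(dialect)] <- dialect
  }
  raw <- utils::read.delim(path, sep = "\t", quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = NULL)
  for (col in c("id", "name", "ob", "dl", "herbs")) {
    if (!map[[col]] %in% names(raw)) {
      stop(sprintf("schema error: missing column '%s'", map[[col]]))
    }
  }
  parse_num <- function(v, what) {
    v[v %in% c("", "NA")] <- NA_character_
    out <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(out) & !is.na(v))
    if (length(bad)) {
      stop(sprintf("parse error: non-numeric %s in row %d ('%s')",
                   what, bad[1], v[bad[1]]))
    }
    out
  }
  herbs <- lapply(strsplit(raw[[map[["herbs"]]]], ",", fixed = TRUE), trimws)
  rescued <- if (map[["rescued"]] %in% names(raw)) {
    as.logical(raw[[map[["rescued"]]]])
  } else FALSE
  descriptors <- if (map[["descriptors"]] %in% names(raw)) {
    lapply(raw[[map[["descriptors"]]]], function(s) {
      if (is.na(s) || !nzchar(s)) NULL
      else as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
    })
  } else NULL
  compound_library(
    compound_id = raw[[map[["id"]]]],
    name = raw[[map[["name"]]]],
    ob = parse_num(raw[[map[["ob"]]]], "OB"),
    dl = parse_num(raw[[map[["dl"]]]], "DL"),
    herbs = herbs,
    rescued = rescued,
    descriptors = descriptors
  )
}

#' Write a compound library to TSV
#'
#' Inverse of [read_compound_table()]: `read_compound_table(write_compound_table(x, f))`
#' reproduces `x` field for field. Herb sets are serialized as a
#' comma-separated list inside a quoted cell; descriptor vectors as
#' semicolon-separated numbers.
#'
#' @param library a `compound_library`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_compound_table <- function(library, path) {
  stopifnot(inherits(library, "compound_library"))
  fmt_num <- function(v) ifelse(is.na(v), "NA", as.character(v))
  out <- data.frame(
    id = library$compound_id,
    name = library$name,
    ob = fmt_num(library$ob),
    dl = fmt_num(library$dl),
    herbs = vapply(library$herbs, paste, "", collapse = ", "),
    rescued = as.character(library$rescued),
    stringsAsFactors = FALSE
  )
  if (any(!vapply(library$descriptors, is.null, logical(1)))) {
    out$descriptors <- vapply(library$descriptors, function(d) {
      if (is.null(d)) "" else paste(d, collapse = ";")
    }, "")
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = c(2L, 5L),
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("I/O error: cannot write ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Load a packaged compound-table fixture
#'
#' `"table1"` is the published table of the 66 candidate compounds of the
#' modified Yimusake formula (ids M001--M066, with OB, DL, herb attribution
#' and the 10-compound rescue flag). `"table3"` is the published table of the
#' 37 compounds of the three animal drugs Moschus, Ambra Grisea and Bullwhip
#' (ids S01--S21, L01--L09, N01--N07); their OB/DL were not published and are
#' stored as `NA`.
#'
#' @param name `"table1"` or `"table3"`.
#' @return a `compound_library`.
#' @export
#' @examples
#' nrow(load_fixture("table1")) # 66
#' nrow(load_fixture("table3")) # 37
load_fixture <- function(name = c("table1", "table3")) {
  name <- tryCatch(match.arg(name),
                   error = function(e) stop("lookup error: unknown fixture '",
                                            name[1], "'"))
  fname <- switch(name,
                  table1 = "table1_compounds.tsv",
                  table3 = "table3_compounds.tsv")
  path <- system.file("extdata", fname, package = "formulanet",
                      mustWork = TRUE)
  read_compound_table(path)
}
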