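# Stage-chaining pipeline: screen -> targets -> network -> compare ->
# pathways, with a manifest (config hash, seed, output checksums) and a
# structured run log so per-stage record attrition is machine-readable.

#' Pipeline configuration
#'
#' Collects the inputs and per-stage settings for [run_pipeline()]. Tabular
#' inputs may be given as in-memory objects or as TSV paths; when `simulate`
#' is set, the synthetic-data generators provide whatever the requested
#' stages still lack (scores, comparison networks, annotations, a
#' three-pathway table).
#'
#' @param out_dir output directory (created if absent).
#' @param seed integer seed used for any simulated input; default 1.
#' @param stages character subset of
#'   `c("screen", "targets", "network", "compare", "pathways")`, in the order
#'   they should run. `character(0)` writes the manifest only.
#' @param library a [compound_library()], a fixture name (`"table1"` /
#'   `"table3"`) or a TSV path. Default `"table1"`.
#' @param whitelist rescue whitelist: character ids, a path to a one-id-per-
#'   line file, or `NULL` (default) to use the library's `rescued` flags.
#' @param scores scored-interaction data.frame or TSV path (columns
#'   `compound_id`, `target_id`, `rf_score`, `svm_score`); `NULL` to
#'   simulate when `simulate` is set.
#' @param annotations target-annotation data.frame or TSV path (columns
#'   `target_id`, `disease_associated`).
#' @param pathways pathway table (named list or long data.frame) or TSV path
#'   with columns `pathway`, `target_id`.
#' @param screen a [screen_config()].
#' @param consensus a [consensus_config()].
#' @param comparison_threshold shared-fraction threshold for
#'   [removal_verdict()]; default 0.90.
#' @param simulate `NULL`, `TRUE` (build a [simulation_config()] from
#'   `seed`) or a ready [simulation_config()].
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            stages = c("screen", "targets", "network",
                                       "compare", "pathways"),
                            library = "table1",
                            whitelist = NULL,
                            scores = NULL,
                            annotations = NULL,
                            pathways = NULL,
                            screen = screen_config(),
                            consensus = consensus_config(),
                            comparison_threshold = 0.90,
                            simulate = NULL) {
  stopifnot(is.character(out_dir), length(out_dir) == 1L)
  known <- c("screen", "targets", "network", "compare", "pathways")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("config error: unknown stage(s): ",
                        paste(bad, collapse = ", "))
  if (!is_count(seed)) stop("config error: seed must be an integer")
  if (isTRUE(simulate)) simulate <- simulation_config(seed = seed)
  if (!is.null(simulate)) stopifnot(inherits(simulate, "simulation_config"))
  stopifnot(inherits(screen, "screen_config"),
            inherits(consensus, "consensus_config"),
            is.numeric(comparison_threshold),
            comparison_threshold >= 0, comparison_threshold <= 1)
  for (input in list(library, scores, annotations, pathways)) {
    if (is.character(input) && length(input) == 1L &&
        !input %in% c("table1", "table3") && !file.exists(input)) {
      stop("config error: input file does not exist: ", input)
    }
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 stages = stages, library = library, whitelist = whitelist,
                 scores = scores, annotations = annotations,
                 pathways = pathways, screen = screen, consensus = consensus,
                 comparison_threshold = comparison_threshold,
                 simulate = simulate),
            class = "pipeline_config")
}

resolve_library <- function(x) {
  if (inherits(x, "compound_library")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (x %in% c("table1", "table3")) return(load_fixture(x))
    return(read_compound_table(x))
  }
  stop("config error: library must be a compound_library, fixture name or path")
}

resolve_table <- function(x, reader = utils::read.delim) {
  if (is.null(x) || is.data.frame(x)) return(x)
  if (is.character(x) && length(x) == 1L) {
    return(reader(x, sep = "\t", stringsAsFactors = FALSE))
  }
  x
}

# stable hash of the user-settable configuration (timestamps excluded)
config_hash <- function(config) {
  keep <- config[setdiff(names(config), "out_dir")]
  json <- jsonlite::toJSON(keep, auto_unbox = TRUE, digits = NA,
                           force = TRUE, null = "null")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(json), f)
  unname(tools::md5sum(f))
}

#' Run the screening / network / comparison pipeline
#'
#' Executes the requested stages in order and writes every artifact to
#' `config$out_dir`: `screen_report.tsv` + `per_herb_summary.tsv` (screen),
#' `kept_interactions.tsv` (targets), `network_edges.tsv` + `network.sif` +
#' `overlap_summary.tsv` (network), `comparison_report.tsv` + `verdict.txt`
#' (compare), `pathway_counts.tsv` (pathways), plus `run_log.tsv` (stage,
#' records in/out) and `manifest.json` (config hash, seed, per-file MD5
#' checksums). Reruns with an identical configuration are bit-identical
#' except for the manifest timestamp. Any stage failure aborts with the
#' stage name.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory stage results and
#'   `manifest` (the manifest path).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  log_rows <- list()
  written <- character()
  results <- list()
  note <- function(stage, n_in, n_out) {
    log_rows[[length(log_rows) + 1L]] <<-
      data.frame(stage = stage, n_in = n_in, n_out = n_out,
                 stringsAsFactors = FALSE)
  }
  emit <- function(df, f) {
    utils::write.table(df, out(f), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    written <<- c(written, f)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  library <- run_stage("input", resolve_library(config$library))
  scores <- resolve_table(config$scores)
  annotations <- resolve_table(config$annotations)
  pathways <- if (is.character(config$pathways)) {
    resolve_table(config$pathways)
  } else {
    config$pathways
  }
  sim <- config$simulate
  pair <- NULL
  if (!is.null(sim)) {
    if (is.null(scores) && "targets" %in% config$stages) {
      scores <- generate_scores(library, config = sim)$scores
      emit(scores, "simulated_scores.tsv")
    }
    if (any(c("compare", "pathways") %in% config$stages)) {
      pair <- generate_formula_pair(sim)
      if (is.null(annotations)) annotations <- pair$annotations
    }
  }

  screen_res <- NULL
  if ("screen" %in% config$stages) {
    screen_res <- run_stage("screen", {
      wl <- config$whitelist
      if (is.null(wl)) {
        wl <- library$compound_id[library$rescued]
      } else if (is.character(wl) && length(wl) == 1L && file.exists(wl)) {
        wl <- readLines(wl)
        wl <- wl[nzchar(trimws(wl))]
      }
      screen_library(library, whitelist = wl, config = config$screen)
    })
    ids <- library$compound_id
    emit(data.frame(id = ids, ob = library$ob, dl = library$dl,
                    strict_pass = ids %in% screen_res$strict_pass,
                    rescued = ids %in% screen_res$rescued,
                    retained = ids %in% screen_res$retained,
                    stringsAsFactors = FALSE),
         "screen_report.tsv")
    emit(screen_res$per_herb_counts, "per_herb_summary.tsv")
    note("screen", nrow(library), length(screen_res$retained))
    results$screen <- screen_res
  }

  kept <- NULL
  if ("targets" %in% config$stages) {
    kept <- run_stage("targets", {
      if (is.null(scores)) {
        stop("no score table supplied (set `scores` or `simulate`)")
      }
      consensus_filter(scores, config$consensus)
    })
    emit(kept, "kept_interactions.tsv")
    note("targets", nrow(scores), nrow(kept))
    results$kept <- kept
  }

  net <- NULL
  if ("network" %in% config$stages) {
    net <- run_stage("network", {
      if (is.null(kept)) stop("network stage needs the targets stage output")
      keep_ids <- if (!is.null(screen_res)) screen_res$retained else
        library$compound_id
      build_network(kept[kept$compound_id %in% keep_ids, , drop = FALSE],
                    library = library)
    })
    export_network(net, "edge-tsv", out("network_edges.tsv"))
    export_network(net, "sif", out("network.sif"))
    written <- c(written, "network_edges.tsv", "network.sif")
    groups <- sort(unique(unlist(net$groups)))
    overlap <- if (length(groups) && length(net$targets)) {
      part <- partition_targets(net, groups)
      data.frame(
        group = c("(all)", groups),
        shared = length(part$shared),
        specific = c(NA_integer_,
                     vapply(part$specific, length, integer(1))),
        overlap_pct = overlap_percentage(length(part$shared),
                                         length(net$targets)),
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(group = character(), shared = integer(),
                 specific = integer(), overlap_pct = numeric(),
                 stringsAsFactors = FALSE)
    }
    emit(overlap, "overlap_summary.tsv")
    note("network", nrow(kept), nrow(net$edges))
    results$network <- net
  }

  if ("compare" %in% config$stages) {
    cmp <- run_stage("compare", {
      if (is.null(pair)) {
        stop("comparison networks unavailable (set `simulate`)")
      }
      compare_formulae(pair$net_a, pair$net_b, annotations,
                       labels = c("modified", "removed"))
    })
    verdict <- removal_verdict(cmp, config$comparison_threshold)
    emit(data.frame(
      class = c("shared", "modified_specific", "removed_specific",
                "removed_specific_disease_linked"),
      n = c(length(cmp$shared_targets), length(cmp$a_specific),
            length(cmp$b_specific), length(cmp$b_specific_disease_linked)),
      stringsAsFactors = FALSE), "comparison_report.tsv")
    writeLines(sprintf(
      "%s\tshared_fraction=%.6f\tthreshold=%.2f\tdisease_linked_removed_specific=%d",
      verdict$status, cmp$shared_fraction, config$comparison_threshold,
      length(cmp$b_specific_disease_linked)), out("verdict.txt"))
    written <- c(written, "verdict.txt")
    note("compare", cmp$n_union, length(cmp$shared_targets))
    results$comparison <- cmp
    results$verdict <- verdict
  }

  if ("pathways" %in% config$stages) {
    counts <- run_stage("pathways", {
      pnet <- results$network %||% (if (!is.null(pair)) pair$net_a else NULL)
      if (is.null(pnet)) stop("pathway stage needs a network or `simulate`")
      if (is.null(pathways)) {
        if (is.null(sim)) stop("no pathway table supplied")
        # three illustrative pathway sets over the simulated target universe
        set.seed(sim$seed + 3L)
        tgts <- pnet$targets
        pathways <- list(
          "NO/cGMP" = sample(tgts, max(1L, round(length(tgts) * 0.2))),
          "Ras" = sample(tgts, max(1L, round(length(tgts) * 0.15))),
          "VEGF" = sample(tgts, max(1L, round(length(tgts) * 0.25)))
        )
      }
      compounds_per_pathway(pnet, pathways)
    })
    emit(data.frame(pathway = names(counts), n_compounds = unname(counts),
                    stringsAsFactors = FALSE), "pathway_counts.tsv")
    note("pathways", length(counts), sum(counts))
    results$pathway_counts <- counts
  }

  log_df <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(stage = character(), n_in = integer(), n_out = integer(),
               stringsAsFactors = FALSE)
  emit(log_df, "run_log.tsv")
  checksums <- tools::md5sum(file.path(config$out_dir, written))
  manifest <- list(
    package = "formulanet",
    version = as.character(utils::packageVersion("formulanet")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    stages = config$stages,
    config_hash = config_hash(config),
    files = as.list(stats::setNames(unname(checksums), written))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  results$manifest <- out("manifest.json")
  invisible(results)
}
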