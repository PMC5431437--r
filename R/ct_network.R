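# Bipartite compound-target networks and the degree / shared-specific /
# overlap statistics computed on them.

#' Build a bipartite compound-target network
#'
#' Nodes are compound ids and target ids; edges are the (deduplicated) kept
#' interactions. Each compound carries a non-empty group set (its herb or
#' component attribution), used by [partition_targets()]. Compounds declared
#' in the library but hitting no target are kept as isolated nodes only when
#' `keep_isolated = TRUE`.
#'
#' @param interactions data.frame with columns `compound_id`, `target_id`
#'   (extra columns, e.g. scores, are ignored).
#' @param library optional [compound_library()]; supplies group membership
#'   (herb sets) and is used to validate that every interaction references a
#'   known compound.
#' @param groups optional named list mapping compound id to a character
#'   vector of group names; overrides/extends the library-derived groups.
#' @param keep_isolated logical; retain library compounds without edges.
#' @return a `ct_network`: list with `compounds`, `targets` (character
#'   vectors), `edges` (two-column data.frame) and `groups` (named list).
#' @export
build_network <- function(interactions, library = NULL, groups = NULL,
                          keep_isolated = FALSE) {
  stopifnot(is.data.frame(interactions))
  if (nrow(interactions) > 0 &&
      !all(c("compound_id", "target_id") %in% names(interactions))) {
    stop("schema error: interactions need compound_id and target_id columns")
  }
  edges <- if (nrow(interactions)) {
    unique(data.frame(compound_id = as.character(interactions$compound_id),
                      target_id = as.character(interactions$target_id),
                      stringsAsFactors = FALSE))
  } else {
    data.frame(compound_id = character(), target_id = character(),
               stringsAsFactors = FALSE)
  }
  rownames(edges) <- NULL
  group_map <- list()
  if (!is.null(library)) {
    stopifnot(inherits(library, "compound_library"))
    group_map <- stats::setNames(library$herbs, library$compound_id)
    unknown <- setdiff(edges$compound_id, library$compound_id)
    if (length(unknown)) {
      stop("validation error: interaction references unknown compound(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  if (!is.null(groups)) {
    stopifnot(is.list(groups), !is.null(names(groups)))
    group_map[names(groups)] <- groups
  }
  compounds <- unique(edges$compound_id)
  if (keep_isolated && !is.null(library)) {
    compounds <- unique(c(compounds, library$compound_id))
  }
  if (length(compounds)) {
    missing_grp <- compounds[!compounds %in% names(group_map)]
    if (is.null(library) && is.null(groups)) {
      # no group source: every compound forms its own singleton group
      group_map <- stats::setNames(as.list(compounds), compounds)
    } else if (length(missing_grp)) {
      stop("validation error: no group for compound(s): ",
           paste(missing_grp, collapse = ", "))
    }
  }
  structure(list(compounds = compounds,
                 targets = unique(edges$target_id),
                 edges = edges,
                 groups = group_map[compounds]),
            class = "ct_network")
}

#' @export
print.ct_network <- function(x, ...) {
  cat(sprintf("<ct_network> %d compound(s), %d target(s), %d edge(s), %d group(s)\n",
              length(x$compounds), length(x$targets), nrow(x$edges),
              length(unique(unlist(x$groups)))))
  invisible(x)
}

#' Degree statistics of a compound-target network
#'
#' @param net a `ct_network` with at least one compound.
#' @return list with `compound_degrees` and `target_degrees` (named integer
#'   vectors), `mean_targets_per_compound` (edges per compound, rounded half
#'   up to 2 decimals), and the maximum-degree `top_compound` / `top_target`
#'   (ties broken by node name).
#' @export
degree_stats <- function(net) {
  stopifnot(inherits(net, "ct_network"))
  if (length(net$compounds) == 0L) {
    stop("undefined-mean error: network has no compounds")
  }
  cdeg <- table(factor(net$edges$compound_id, levels = net$compounds))
  tdeg <- table(factor(net$edges$target_id, levels = net$targets))
  cdeg <- stats::setNames(as.integer(cdeg), names(cdeg))
  tdeg <- stats::setNames(as.integer(tdeg), names(tdeg))
  pick_top <- function(d) {
    if (!length(d)) return(NA_character_)
    cand <- names(d)[d == max(d)]
    sort(cand)[1]
  }
  list(compound_degrees = cdeg,
       target_degrees = tdeg,
       mean_targets_per_compound =
         round_half_up(nrow(net$edges) / length(net$compounds), 2),
       top_compound = pick_top(cdeg),
       top_target = pick_top(tdeg))
}

#' Shared / specific target partition across groups
#'
#' A target is *shared* when every listed group has at least one compound
#' hitting it, and *specific to g* when, among the listed groups, only
#' compounds of `g` hit it. Targets hit by several but not all groups (or
#' only by compounds outside the listed groups) fall into `other`. The three
#' parts are disjoint and cover the network's target side.
#'
#' @param net a `ct_network`.
#' @param groups character vector of group names to compare; each must have
#'   at least one compound in the network.
#' @return an `overlap_partition`: list with `groups`, `shared`,
#'   `specific` (named list per group) and `other`.
#' @export
partition_targets <- function(net, groups) {
  stopifnot(inherits(net, "ct_network"), is.character(groups),
            length(groups) >= 1L)
  if (anyDuplicated(groups)) stop("validation error: duplicate group names")
  present <- unique(unlist(net$groups))
  unknown <- setdiff(groups, present)
  if (length(unknown)) {
    stop("lookup error: group(s) with no compound in the network: ",
         paste(unknown, collapse = ", "))
  }
  # targets hit by each group
  hit_by <- lapply(groups, function(g) {
    cids <- names(net$groups)[vapply(net$groups, function(gs) g %in% gs,
                                     logical(1))]
    unique(net$edges$target_id[net$edges$compound_id %in% cids])
  })
  names(hit_by) <- groups
  n_hits <- vapply(net$targets,
                   function(t) sum(vapply(hit_by, function(s) t %in% s,
                                          logical(1))),
                   integer(1))
  shared <- net$targets[n_hits == length(groups)]
  specific <- lapply(groups, function(g) {
    net$targets[n_hits == 1L &
                  vapply(net$targets, function(t) t %in% hit_by[[g]],
                         logical(1))]
  })
  names(specific) <- groups
  if (length(groups) == 1L) {
    # a single group: "shared" and "specific" coincide; keep them disjoint
    specific[[1]] <- character(0)
  }
  other <- setdiff(net$targets, c(shared, unlist(specific)))
  structure(list(groups = groups, shared = shared, specific = specific,
                 other = other),
            class = "overlap_partition")
}

#' @export
print.overlap_partition <- function(x, ...) {
  total <- length(x$shared) + length(unlist(x$specific)) + length(x$other)
  cat(sprintf("<overlap_partition> %d target(s): %d shared by all %d group(s)",
              total, length(x$shared), length(x$groups)))
  if (total > 0) {
    cat(sprintf(" (%s%%)", format(overlap_percentage(length(x$shared), total))))
  }
  cat("\n")
  for (g in x$groups) {
    cat(sprintf("  specific to %s: %d\n", g, length(x$specific[[g]])))
  }
  cat(sprintf("  other: %d\n", length(x$other)))
  invisible(x)
}

#' Overlap percentage
#'
#' `100 * shared_count / total_count`, rounded half up to the requested
#' number of decimals (so 67 of 132 reports as 50.76).
#'
#' @param shared_count count of shared items, `0 <= shared_count <=
#'   total_count`.
#' @param total_count positive total.
#' @param decimals decimal places; default 2.
#' @return the percentage as a number.
#' @export
#' @examples
#' overlap_percentage(67, 132)       # 50.76
#' overlap_percentage(135, 139, 0)   # 97
overlap_percentage <- function(shared_count, total_count, decimals = 2) {
  if (!is_count(shared_count) || !is_count(total_count) || total_count == 0) {
    stop("domain error: counts must be non-negative integers, total > 0")
  }
  if (shared_count > total_count) {
    stop("domain error: shared_count exceeds total_count")
  }
  round_half_up(100 * shared_count / total_count, decimals)
}

#' Export a network for external tools
#'
#' Writes the network as Cytoscape SIF (`compound <tab> ct <tab> target`),
#' GraphML (node `side` and `group` attributes included) or a plain edge-list
#' TSV that round-trips through [build_network()].
#'
#' @param net a `ct_network`.
#' @param format one of `"sif"`, `"graphml"`, `"edge-tsv"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, format = c("sif", "graphml", "edge-tsv"),
                           path) {
  stopifnot(inherits(net, "ct_network"))
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("usage error: unknown format '",
                                              format[1], "'"))
  if (format == "sif") {
    writeLines(paste(net$edges$compound_id, "ct", net$edges$target_id,
                     sep = "\t"), path)
  } else if (format == "edge-tsv") {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    vertices <- data.frame(
      name = c(net$compounds, net$targets),
      side = c(rep("compound", length(net$compounds)),
               rep("target", length(net$targets))),
      group = c(vapply(net$groups, paste, "", collapse = ";"),
                rep("", length(net$targets))),
      stringsAsFactors = FALSE
    )
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = vertices)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read an edge-list TSV
#'
#' Companion to `export_network(format = "edge-tsv")`.
#'
#' @param path TSV file with columns `compound_id`, `target_id`.
#' @return data.frame of edges, suitable for [build_network()].
#' @export
read_edge_table <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  out <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character")
  missing_cols <- setdiff(c("compound_id", "target_id"), names(out))
  if (length(missing_cols)) {
    stop("schema error: missing column '", missing_cols[1], "'")
  }
  out
}
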