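# Target-to-pathway mapping and the tripartite compound-target-pathway view.
# Pathway membership is a caller-supplied annotation table (e.g. curated from
# KEGG); no live database is queried.

as_pathway_table <- function(pathways) {
  if (is.data.frame(pathways)) {
    missing_cols <- setdiff(c("pathway", "target_id"), names(pathways))
    if (length(missing_cols)) {
      stop("schema error: missing column '", missing_cols[1], "'")
    }
    pathways <- split(as.character(pathways$target_id),
                      as.character(pathways$pathway))
  }
  if (!is.list(pathways) || is.null(names(pathways)) ||
      anyDuplicated(names(pathways))) {
    stop("validation error: pathways must be a uniquely named list or a ",
         "(pathway, target_id) data.frame")
  }
  lapply(pathways, function(t) unique(as.character(t)))
}

#' Map targets onto pathways
#'
#' Intersects a target set with each pathway's membership; targets belonging
#' to no listed pathway are returned separately.
#'
#' @param targets character vector of target ids.
#' @param pathways pathway table: named list `pathway -> target ids`, or a
#'   data.frame with columns `pathway`, `target_id` (long form, one row per
#'   membership; a target may belong to several pathways).
#' @return list with `by_pathway` (named list of present targets per pathway)
#'   and `unmapped` (targets in no pathway).
#' @export
map_targets <- function(targets, pathways) {
  targets <- unique(as.character(targets))
  tab <- as_pathway_table(pathways)
  by_pathway <- lapply(tab, intersect, x = targets)
  list(by_pathway = by_pathway,
       unmapped = setdiff(targets, unlist(tab)))
}

#' Count compounds reaching each pathway
#'
#' A compound participates in a pathway when it has at least one edge to one
#' of the pathway's targets; each compound is counted once per pathway.
#'
#' @param net a `ct_network`.
#' @param mapping a [map_targets()] result, or a pathway table accepted by
#'   [map_targets()] (it is then intersected with the network's targets).
#' @return named integer vector, one count per pathway.
#' @export
compounds_per_pathway <- function(net, mapping) {
  stopifnot(inherits(net, "ct_network"))
  by_pathway <- if (is.list(mapping) && !is.data.frame(mapping) &&
                    identical(sort(names(mapping)),
                              sort(c("by_pathway", "unmapped")))) {
    mapping$by_pathway
  } else {
    map_targets(net$targets, mapping)$by_pathway
  }
  vapply(by_pathway, function(t) {
    length(unique(net$edges$compound_id[net$edges$target_id %in% t]))
  }, integer(1))
}

#' Build (and optionally export) a compound-target-pathway network
#'
#' Overlays the compound-target network onto the target-pathway memberships:
#' nodes carry a role (`compound`, `target`, `pathway`) and edges a role
#' (`ct`, `tp`). Only targets present in the network receive target-pathway
#' edges; pathway members absent from the network are returned as
#' `unconnected_targets`.
#'
#' @param net a `ct_network`.
#' @param pathways pathway table as in [map_targets()].
#' @param path optional output file; written when non-`NULL`.
#' @param format `"edge-tsv"` (long form: `from`, `to`, `role`) or
#'   `"graphml"` (node/edge roles as attributes).
#' @return invisibly, a list with `nodes` (`id`, `role`), `edges`
#'   (`from`, `to`, `role`) and `unconnected_targets`.
#' @export
build_ctp_network <- function(net, pathways, path = NULL,
                              format = c("edge-tsv", "graphml")) {
  stopifnot(inherits(net, "ct_network"))
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("usage error: unknown format '",
                                              format[1], "'"))
  tab <- as_pathway_table(pathways)
  tp <- do.call(rbind, lapply(names(tab), function(p) {
    hit <- intersect(tab[[p]], net$targets)
    if (!length(hit)) return(NULL)
    data.frame(from = hit, to = p, role = "tp", stringsAsFactors = FALSE)
  }))
  if (is.null(tp)) {
    tp <- data.frame(from = character(), to = character(),
                     role = character(), stringsAsFactors = FALSE)
  }
  ct <- data.frame(from = net$edges$compound_id, to = net$edges$target_id,
                   role = "ct", stringsAsFactors = FALSE)
  edges <- rbind(ct, tp)
  rownames(edges) <- NULL
  pathways_used <- unique(tp$to)
  nodes <- data.frame(
    id = c(net$compounds, net$targets, pathways_used),
    role = c(rep("compound", length(net$compounds)),
             rep("target", length(net$targets)),
             rep("pathway", length(pathways_used))),
    stringsAsFactors = FALSE
  )
  out <- list(nodes = nodes, edges = edges,
              unconnected_targets = setdiff(unlist(tab), net$targets))
  if (!is.null(path)) {
    if (format == "edge-tsv") {
      utils::write.table(edges, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = TRUE)
    } else {
      g <- igraph::graph_from_data_frame(
        edges, directed = FALSE,
        vertices = stats::setNames(nodes, c("name", "role"))
      )
      igraph::write_graph(g, path, format = "graphml")
    }
  }
  invisible(out)
}
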