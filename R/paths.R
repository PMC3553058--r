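# Directed bipartite species-reaction graph: edges s -> r for every reactant s
# of r, and r -> p for every product p. Vertex names are prefixed "s:" / "r:"
# (":" cannot occur in species or reaction ids).
.sr_graph <- function(network) {
  edges <- character(0)
  for (r in network$reactions) {
    rid <- paste0("r:", r$id)
    if (length(r$reactants)) {
      edges <- c(edges, rbind(paste0("s:", r$reactants), rid))
    }
    if (length(r$products)) {
      edges <- c(edges, rbind(rid, paste0("s:", r$products)))
    }
  }
  igraph::make_graph(edges = edges, directed = TRUE,
                     isolates = setdiff(paste0("s:", network$species),
                                        edges[startsWith(edges, "s:")]))
}

.vpath_to_path <- function(nodes_pref) {
  nodes <- sub("^[sr]:", "", nodes_pref)
  is_rx <- startsWith(nodes_pref, "r:")
  structure(list(nodes = nodes,
                 species = nodes[!is_rx],
                 reactions = nodes[is_rx],
                 source = nodes[1],
                 target = nodes[length(nodes)],
                 length = sum(is_rx)),
            class = "rn_path")
}

#' @export
print.rn_path <- function(x, ...) {
  cat(sprintf("<path> %s (%d reaction%s)\n",
              paste(x$nodes, collapse = " -> "), x$length,
              if (x$length == 1L) "" else "s"))
  invisible(x)
}

.sort_paths <- function(paths) {
  if (length(paths) <= 1L) return(paths)
  len <- vapply(paths, `[[`, integer(1), "length")
  key <- vapply(paths, function(p) paste(p$nodes, collapse = "\x01"), character(1))
  paths[order(len, key, method = "radix")]
}

.k_paths_raw <- function(g, source, target, k) {
  from <- paste0("s:", source)
  to <- paste0("s:", target)
  res <- tryCatch(
    suppressWarnings(igraph::k_shortest_paths(g, from = from, to = to, k = k)),
    error = function(e) NULL)
  if (is.null(res) || length(res$vpaths) == 0L) return(list())
  .sort_paths(lapply(res$vpaths, function(v) .vpath_to_path(names(v))))
}

#' k shortest loopless paths between two species
#'
#' Paths run through the directed bipartite species-reaction graph: a
#' species points to every reaction that consumes it, and a reaction points
#' to every species it produces. Paths are simple (loopless), alternate
#' species and reactions, and their length is the number of reaction nodes.
#' Up to `k` shortest paths are returned (Yen's algorithm via igraph),
#' re-sorted by length and then by lexicographic node sequence so results
#' are reproducible.
#'
#' @inheritParams closure
#' @param source,target distinct species ids.
#' @param k maximum number of paths (>= 1).
#' @return A list of path objects (class `rn_path`), possibly empty. Each
#'   has fields `nodes`, `species`, `reactions`, `source`, `target`,
#'   `length`.
#' @examples
#' net <- parse_reaction_list("A + C -> B")
#' k_shortest_paths(net, "A", "B", k = 5)
#' @export
k_shortest_paths <- function(network, source, target, k = 20L) {
  stopifnot(inherits(network, "reaction_network"), k >= 1L)
  source <- .check_species(network, source, "source")
  target <- .check_species(network, target, "target")
  if (identical(source, target)) stop("source and target must differ", call. = FALSE)
  g <- .sr_graph(network)
  .k_paths_raw(g, source, target, as.integer(k))
}

#' Candidate context of a path
#'
#' The context a path suggests for realizing the mapping source -> target:
#' the union of all reactant species of the reactions along the path, minus
#' the species nodes of the path itself (source, intermediates, target).
#' These are the co-reactants one has to supply for the path to fire.
#'
#' @inheritParams closure
#' @param path an `rn_path` as returned by [k_shortest_paths()].
#' @return Character vector of species ids (possibly empty), sorted.
#' @export
path_context <- function(network, path) {
  stopifnot(inherits(path, "rn_path"))
  rids <- vapply(network$reactions, `[[`, character(1), "id")
  hit <- match(path$reactions, rids)
  if (anyNA(hit)) stop("path reactions not found in network", call. = FALSE)
  reac <- unlist(lapply(network$reactions[hit], `[[`, "reactants"),
                 use.names = FALSE)
  .csort(setdiff(reac, path$species))
}
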