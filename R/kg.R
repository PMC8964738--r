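#' Construct a typed knowledge graph
#'
#' A heterogeneous biomedical graph as a typed edge list: entities (genes,
#' diseases, compounds, ...) connected by typed relations. Duplicate
#' (source, relation, target) triples are collapsed with a warning. When a
#' node table is supplied, every edge endpoint must appear in it; otherwise
#' node identities are inferred from the edges with unknown type.
#'
#' @param edges data.frame with character columns `source`, `relation`,
#'   `target`.
#' @param nodes optional data.frame with columns `id` and `type`.
#' @return An object of class `knowledge_graph`: list with elements `nodes`
#'   and `edges`.
#' @export
knowledge_graph <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges))
  need <- c("source", "relation", "target")
  if (!all(need %in% names(edges))) {
    stop("edge list needs columns source, relation, target")
  }
  edges <- data.frame(lapply(edges[, need], as.character))
  if (!nrow(edges)) stop("a knowledge graph needs at least one edge")
  dup <- duplicated(edges)
  if (any(dup)) {
    warning(sprintf("removed %d duplicated triple(s)", sum(dup)))
    edges <- edges[!dup, ]
  }
  endpoint_ids <- unique(c(edges$source, edges$target))
  if (is.null(nodes)) {
    nodes <- data.frame(id = endpoint_ids, type = "unknown")
  } else {
    stopifnot(is.data.frame(nodes), all(c("id", "type") %in% names(nodes)))
    nodes <- data.frame(id = as.character(nodes$id),
                        type = as.character(nodes$type))
    if (anyDuplicated(nodes$id)) stop("node ids must be unique")
    dangling <- setdiff(endpoint_ids, nodes$id)
    if (length(dangling)) {
      stop(sprintf("edge endpoint(s) missing from the node table: %s",
                   paste(head(dangling, 5L), collapse = ", ")))
    }
  }
  structure(list(nodes = nodes, edges = edges), class = "knowledge_graph")
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat(sprintf("<knowledge_graph> %d nodes, %d edges, %d relation type(s)\n",
              nrow(x$nodes), nrow(x$edges), length(unique(x$edges$relation))))
  invisible(x)
}

#' Read a knowledge graph from a TSV edge list
#'
#' @param path TSV with header columns `source`, `relation`, `target`
#'   (Hetionet-style typed edge export).
#' @param node_path optional TSV with columns `id`, `type`; when given,
#'   dangling edge endpoints are an error.
#' @return A [knowledge_graph()].
#' @export
read_kg <- function(path, node_path = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  edges <- read.delim(path, colClasses = "character", check.names = FALSE)
  nodes <- NULL
  if (!is.null(node_path)) {
    if (!file.exists(node_path)) stop(sprintf("no such file: %s", node_path))
    nodes <- read.delim(node_path, colClasses = "character",
                        check.names = FALSE)
  }
  knowledge_graph(edges, nodes)
}

#' Write a knowledge graph to TSV
#' @param kg a [knowledge_graph()]
#' @param path edge-list output path.
#' @param node_path optional node-table output path.
#' @return `path`, invisibly.
#' @export
write_kg <- function(kg, path, node_path = NULL) {
  stopifnot(inherits(kg, "knowledge_graph"))
  write.table(kg$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(node_path)) {
    write.table(kg$nodes, node_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Descriptive structural metrics per node
#'
#' `degree` counts incident edges across all relation types (parallel edges
#' under different relations each count); `unique_neighbors` counts distinct
#' adjacent node identities. Hence `degree >= unique_neighbors` everywhere.
#'
#' @param kg a [knowledge_graph()]
#' @return data.frame with columns `node`, `degree`, `unique_neighbors`,
#'   covering every node in the graph (isolated nodes score 0).
#' @export
structural_metrics <- function(kg) {
  stopifnot(inherits(kg, "knowledge_graph"))
  ids <- kg$nodes$id
  ends <- c(kg$edges$source, kg$edges$target)
  deg <- table(factor(ends, levels = ids))
  pairs <- unique(data.frame(a = c(kg$edges$source, kg$edges$target),
                             b = c(kg$edges$target, kg$edges$source)))
  uniq <- table(factor(pairs$a, levels = ids))
  data.frame(node = ids, degree = as.integer(deg),
             unique_neighbors = as.integer(uniq), row.names = NULL)
}

#' Extract a single-relation subgraph
#'
#' The protein-protein interaction view of the graph: the node-induced
#' subgraph over edges of one relation (canonically `"interacts"`), treated
#' as undirected. Centrality features ([kg_pagerank()], [kg_betweenness()])
#' are computed on this subgraph; embeddings use the full graph.
#'
#' @param kg a [knowledge_graph()]
#' @param relation relation name; must exist in the graph.
#' @return A [knowledge_graph()] restricted to that relation.
#' @export
ppi_subgraph <- function(kg, relation = "interacts") {
  stopifnot(inherits(kg, "knowledge_graph"))
  if (!relation %in% kg$edges$relation) {
    stop(sprintf("relation '%s' not present in the graph", relation))
  }
  edges <- kg$edges[kg$edges$relation == relation, ]
  ids <- unique(c(edges$source, edges$target))
  nodes <- kg$nodes[kg$nodes$id %in% ids, ]
  knowledge_graph(edges, nodes)
}

# Undirected simple adjacency (0/1) over the graph's nodes; parallel and
# reciprocal edges collapse to a single undirected link.
undirected_adjacency <- function(kg) {
  ids <- kg$nodes$id
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  i <- match(kg$edges$source, ids)
  j <- match(kg$edges$target, ids)
  keep <- i != j
  A[cbind(i[keep], j[keep])] <- 1
  A[cbind(j[keep], i[keep])] <- 1
  A
}

#' PageRank on an undirected graph
#'
#' Power iteration with uniform teleportation: at each step a walker follows
#' a uniformly chosen incident edge with probability `damping` and teleports
#' uniformly otherwise; mass on isolated nodes is redistributed uniformly.
#' Iteration stops when the L1 change drops below `tol`; scores always sum
#' to 1.
#'
#' @param kg a [knowledge_graph()] (typically a [ppi_subgraph()]).
#' @param damping damping factor in (0, 1); default 0.85.
#' @param tol L1 convergence tolerance; default 1e-9.
#' @param max_iter iteration cap; non-convergence is an error naming the
#'   iteration count.
#' @return named numeric vector of PageRank scores, one per node.
#' @export
kg_pagerank <- function(kg, damping = 0.85, tol = 1e-9, max_iter = 200L) {
  stopifnot(inherits(kg, "knowledge_graph"),
            damping > 0, damping < 1)
  A <- undirected_adjacency(kg)
  n <- nrow(A)
  deg <- rowSums(A)
  r <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    share <- ifelse(deg > 0, r / deg, 0)
    dangling <- sum(r[deg == 0])
    r_new <- (1 - damping) / n + damping * (as.vector(A %*% share) + dangling / n)
    if (sum(abs(r_new - r)) < tol) {
      return(setNames(r_new, rownames(A)))
    }
    r <- r_new
  }
  stop(sprintf("PageRank did not converge within %d iterations", max_iter))
}

#' Shortest-path betweenness centrality
#'
#' Exact betweenness on the undirected simple graph (Brandes' algorithm via
#' igraph): for each node, the number of shortest paths between other node
#' pairs passing through it, weighted by the fraction of shortest paths used.
#' Endpoints are excluded and, by default, counts are unnormalised.
#'
#' @param kg a [knowledge_graph()] (typically a [ppi_subgraph()]).
#' @param normalized divide by the number of orderable pairs; default FALSE.
#' @return named numeric vector of betweenness scores, one per node.
#' @export
kg_betweenness <- function(kg, normalized = FALSE) {
  stopifnot(inherits(kg, "knowledge_graph"))
  g <- igraph_from_kg(kg)
  b <- igraph::betweenness(g, directed = FALSE, normalized = normalized)
  # igraph counts each unordered pair once on undirected graphs
  b[kg$nodes$id]
}

igraph_from_kg <- function(kg) {
  el <- unique(kg$edges[, c("source", "target")])
  el <- el[el$source != el$target, ]
  g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                     vertices = kg$nodes$id)
  igraph::simplify(g)
}
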