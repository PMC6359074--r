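#' Undirected metabolite network
#'
#' A set of unordered node pairs with an optional per-edge weight. Edges are
#' canonicalized so that \code{node_a < node_b} lexicographically and stored
#' sorted, making two networks with the same edge set identical objects.
#' This is the common currency of the network-inference and
#' network-comparison functions.
#'
#' @param node_a,node_b character vectors of node names (surrounding
#'   whitespace is trimmed; names are matched case-sensitively).
#' @param weight optional numeric per-edge weight.
#' @return An object of class \code{metab_network}: a data frame with columns
#'   \code{node_a}, \code{node_b} and optionally \code{weight}.
#' @examples
#' undirected_network(c("A", "B"), c("B", "A"))  # collapses to one edge
#' @export
undirected_network <- function(node_a, node_b, weight = NULL) {
  node_a <- trimws(as.character(node_a))
  node_b <- trimws(as.character(node_b))
  if (length(node_a) != length(node_b))
    stop("node_a and node_b must have equal length")
  if (any(node_a == "") || any(node_b == ""))
    stop("empty node name")
  loops <- node_a == node_b
  if (any(loops))
    stop("self-loops not allowed: ", paste(unique(node_a[loops]), collapse = ", "))
  swap <- node_a > node_b
  tmp <- node_a[swap]; node_a[swap] <- node_b[swap]; node_b[swap] <- tmp
  net <- data.frame(node_a = node_a, node_b = node_b,
                    stringsAsFactors = FALSE)
  if (!is.null(weight)) {
    if (length(weight) != length(node_a))
      stop("weight must have one value per edge")
    net$weight <- as.numeric(weight)
  }
  key <- paste(net$node_a, net$node_b, sep = "\r")
  if (anyDuplicated(key)) {
    if (!is.null(weight)) {
      w_by_key <- split(net$weight, key)
      conflict <- names(w_by_key)[vapply(w_by_key, function(w)
        length(unique(w)) > 1L, logical(1))]
      if (length(conflict))
        stop("repeated edge with conflicting weights: ",
             paste(gsub("\r", "--", conflict), collapse = ", "))
    }
    net <- net[!duplicated(key), , drop = FALSE]
    key <- key[!duplicated(key)]
  }
  net <- net[order(net$node_a, net$node_b), , drop = FALSE]
  rownames(net) <- NULL
  class(net) <- c("metab_network", "data.frame")
  net
}

#' @export
print.metab_network <- function(x, ...) {
  cat("Undirected network:", nrow(x), "edges,",
      length(network_nodes(x)), "nodes\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more edges\n")
  invisible(x)
}

#' Nodes incident to at least one edge
#' @param net a \code{metab_network}
#' @return character vector of node names, sorted
#' @export
network_nodes <- function(net) sort(unique(c(net$node_a, net$node_b)))

#' Number of edges
#' @param net a \code{metab_network}
#' @export
n_edges <- function(net) nrow(net)

edge_keys <- function(net) paste(net$node_a, net$node_b, sep = "\r")

#' Edge-set operations
#'
#' Set operations on the edge sets of two networks (weights are dropped;
#' edge identity is the unordered node pair).
#' @param a,b \code{metab_network} objects
#' @return a \code{metab_network}
#' @export
edge_intersect <- function(a, b) {
  keep <- edge_keys(a) %in% edge_keys(b)
  undirected_network(a$node_a[keep], a$node_b[keep])
}

#' @rdname edge_intersect
#' @export
edge_setdiff <- function(a, b) {
  keep <- !(edge_keys(a) %in% edge_keys(b))
  undirected_network(a$node_a[keep], a$node_b[keep])
}

#' @rdname edge_intersect
#' @export
edge_union <- function(a, b) {
  undirected_network(c(a$node_a, b$node_a), c(a$node_b, b$node_b))
}

#' Per-node degrees
#' @param net a \code{metab_network}
#' @param nodes optional node universe; nodes absent from the network get 0
#' @return named integer vector
#' @export
network_degrees <- function(net, nodes = network_nodes(net)) {
  d <- table(factor(c(net$node_a, net$node_b), levels = nodes))
  stats::setNames(as.integer(d), nodes)
}

#' Read / write an edge list
#'
#' TSV with header columns \code{node_a}, \code{node_b} and optionally
#' \code{weight}. Edges are canonicalized on read; \code{read_edge_list(
#' write_edge_list(net, f))} returns a network identical to \code{net}.
#'
#' @param path file path
#' @return \code{read_edge_list}: a \code{metab_network}.
#' @export
read_edge_list <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2)
    stop("edge list must have at least two columns (node_a, node_b): ", path)
  names(df)[1:2] <- c("node_a", "node_b")
  w <- if ("weight" %in% names(df)) as.numeric(df$weight) else NULL
  undirected_network(df$node_a, df$node_b, w)
}

#' @rdname read_edge_list
#' @param net a \code{metab_network}
#' @export
write_edge_list <- function(net, path) {
  utils::write.table(as.data.frame(net), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a network as GraphML
#'
#' Thin wrapper over \pkg{igraph} for interoperability with network viewers.
#' @param net a \code{metab_network}
#' @param path output file
#' @export
write_graphml <- function(net, path) {
  g <- igraph::graph_from_data_frame(as.data.frame(net), directed = FALSE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Warn when two networks use non-overlapping node vocabularies
#' @param a,b \code{metab_network} objects
#' @return invisibly, the character vector of non-shared node names
#' @export
check_node_vocabulary <- function(a, b) {
  na <- network_nodes(a); nb <- network_nodes(b)
  odd <- c(setdiff(na, nb), setdiff(nb, na))
  if (length(odd) && (length(intersect(na, nb)) == 0))
    warning("networks share no node names; first mismatches: ",
            paste(utils::head(odd, 5), collapse = ", "))
  invisible(odd)
}
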