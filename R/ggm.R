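#' GGM selection configuration
#'
#' Parameters of the two-step Gaussian-graphical-model estimator: per-node
#' Lasso paths generate candidate neighborhoods; a penalized residual
#' criterion selects one graph from the family they span.
#'
#' @param K scalar penalty multiplier; sparsity increases with K. The
#'   customary range is 2 to 5 — values outside it are allowed with a
#'   warning.
#' @param dmax maximum node degree in the selected graph
#' @param lasso_path_length number of penalties on each per-node Lasso path
#' @param symmetrize \code{"and"} (edge requires each endpoint in the
#'   other's candidate neighborhood; the conservative default) or
#'   \code{"or"}
#' @param standardize standardize columns before regression (recommended and
#'   assumed by the criterion's scaling)
#' @return object of class \code{ggm_config}
#' @export
ggm_config <- function(K = 2, dmax = 5, lasso_path_length = 100,
                       symmetrize = c("and", "or"), standardize = TRUE) {
  symmetrize <- match.arg(symmetrize)
  stopifnot(dmax >= 1, lasso_path_length >= 10, K > 0)
  if (K < 2 || K > 5)
    warning("K = ", K, " is outside the customary [2, 5] range")
  structure(list(K = K, dmax = as.integer(dmax),
                 lasso_path_length = as.integer(lasso_path_length),
                 symmetrize = symmetrize, standardize = standardize),
            class = "ggm_config")
}

# standardized design matrix from an abundance table or matrix; zero-variance
# columns are dropped with a warning
ggm_design_matrix <- function(table, standardize = TRUE) {
  x <- if (inherits(table, "abundance_table")) {
    if (!table$log_transformed)
      warning("table is not log-transformed; GGM assumes Gaussian columns")
    table$values
  } else as.matrix(table)
  if (anyNA(x)) stop("table has missing values; impute first")
  if (nrow(x) < 3) stop("need at least 3 samples")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance column(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  if (standardize) x <- scale(x)
  x
}

# per-node Lasso entry orders: for each node, the order in which the other
# variables first become active along its regularization path
nodewise_entry_orders <- function(x, dmax, path_length = 100) {
  n <- nrow(x); p <- ncol(x)
  nodes <- colnames(x)
  orders <- vector("list", p)
  names(orders) <- nodes
  for (a in seq_len(p)) {
    xa <- x[, -a, drop = FALSE]
    fit <- glmnet::glmnet(xa, x[, a], family = "gaussian",
                          nlambda = path_length,
                          standardize = FALSE, intercept = TRUE,
                          dfmax = min(dmax + 5L, p - 1L, n - 1L))
    beta <- as.matrix(fit$beta)
    entry <- apply(beta != 0, 1, function(z) if (any(z)) which(z)[1] else Inf)
    entered <- which(is.finite(entry))
    if (length(entered)) {
      # ties at a knot broken by coefficient magnitude at that knot
      mag <- vapply(entered, function(i) abs(beta[i, entry[i]]), numeric(1))
      ord <- entered[order(entry[entered], -mag)]
    } else ord <- integer(0)
    orders[[a]] <- utils::head(colnames(xa)[ord], dmax)
  }
  orders
}

#' Candidate graph family from nodewise Lasso paths
#'
#' Step one of the estimator: regress each node on all others with the
#' Lasso, record the order in which variables enter each node's path, and
#' assemble one graph per shared path-position index \code{d = 0..dmax} —
#' node \code{a}'s candidate neighborhood at level \code{d} is its first
#' \code{d} entries, and an edge (a,b) is kept when the symmetrization rule
#' holds (\code{"and"}: each node in the other's candidates). Under the
#' and-rule the levels are nested, so the family is a chain of at most
#' \code{dmax + 1} graphs, deduplicated; the empty graph (level 0) is always
#' a member, and every member respects the degree cap.
#'
#' @param table \code{abundance_table} (imputed, log scale) or numeric
#'   matrix, samples in rows
#' @param config a \code{ggm_config}
#' @return object of class \code{ggm_family}: \code{graphs} (list of
#'   \code{metab_network}), \code{levels}, \code{entry_orders}, \code{x}
#'   (standardized design), \code{config}
#' @export
nodewise_lasso_family <- function(table, config = ggm_config()) {
  x <- ggm_design_matrix(table, config$standardize)
  n <- nrow(x); p <- ncol(x)
  dmax <- config$dmax
  if (dmax >= n - 2) {
    warning("dmax >= n - 2: neighborhood regressions ill-posed; ",
            "capping candidate neighborhoods at n - 3 = ", n - 3)
    dmax <- max(1L, n - 3L)
  }
  dmax <- min(dmax, p - 1L)
  orders <- nodewise_entry_orders(x, dmax, config$lasso_path_length)
  nodes <- colnames(x)
  graphs <- list(); levels <- integer(0); seen <- character(0)
  for (d in 0:dmax) {
    g <- assemble_level_graph(orders, nodes, d, dmax, config$symmetrize)
    sig <- paste(edge_keys(g), collapse = ";")
    if (!(sig %in% seen)) {
      graphs[[length(graphs) + 1L]] <- g
      levels <- c(levels, d)
      seen <- c(seen, sig)
    }
  }
  structure(list(graphs = graphs, levels = levels, entry_orders = orders,
                 x = x, config = config, dmax_effective = dmax),
            class = "ggm_family")
}

assemble_level_graph <- function(orders, nodes, d, dmax, symmetrize) {
  empty <- undirected_network(character(0), character(0))
  if (d == 0) return(empty)
  nb <- lapply(orders, utils::head, d)
  from <- rep(names(nb), lengths(nb))
  to <- unlist(nb, use.names = FALSE)
  if (!length(from)) return(empty)
  a <- pmin(from, to); b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  # each direction occurs at most once, so a count of 2 means mutual
  cnt <- table(key)
  keep <- if (symmetrize == "and") names(cnt)[cnt == 2L] else names(cnt)
  if (!length(keep)) return(empty)
  parts <- strsplit(keep, "\r", fixed = TRUE)
  g <- undirected_network(vapply(parts, `[`, "", 1),
                          vapply(parts, `[`, "", 2))
  if (symmetrize == "or") g <- trim_to_degree_cap(g, orders, dmax)
  g
}

# or-rule graphs can exceed the degree cap; keep, per node, the edges with
# the best (smallest) path-entry rank until every degree fits
trim_to_degree_cap <- function(g, orders, dmax) {
  if (n_edges(g) == 0) return(g)
  rank_of <- function(a, b) {
    r <- match(b, orders[[a]])
    if (is.na(r)) Inf else r
  }
  score <- mapply(function(a, b) min(rank_of(a, b), rank_of(b, a)),
                  g$node_a, g$node_b)
  ord <- order(score)
  deg <- stats::setNames(integer(length(orders)), names(orders))
  keep <- logical(nrow(g))
  for (i in ord) {
    a <- g$node_a[i]; b <- g$node_b[i]
    if (deg[a] < dmax && deg[b] < dmax) {
      keep[i] <- TRUE
      deg[a] <- deg[a] + 1L; deg[b] <- deg[b] + 1L
    }
  }
  undirected_network(g$node_a[keep], g$node_b[keep])
}

#' Penalized selection criterion for a graph
#'
#' Step two's score: \deqn{Crit(G) = \sum_a RSS_a(G) \,
#' \left(1 + \frac{pen(d_a)}{n - d_a}\right), \qquad
#' pen(d) = \frac{K}{2} \, d \, \left(1 + \sqrt{2 \log(p - 1)}\right)^2
#' \frac{n}{n - d - 1},}
#' where \eqn{RSS_a(G)} is the residual sum of squares of the least-squares
#' regression of node \eqn{a} on its neighbors in \eqn{G} (standardized
#' columns) and \eqn{d_a} its degree. The \eqn{(1+\sqrt{2\log(p-1)})^2}
#' constant accounts for each neighbor being the best of \eqn{p-1}
#' candidates (the multiple-testing-aware constant of penalized model
#' selection), so selection stays sparse on null data even at K = 2; the
#' \eqn{n/(n-d-1)} factor is the small-sample inflation that keeps
#' near-saturated regressions (d close to n, where greedy subsets can push
#' RSS toward zero by chance) from collapsing the multiplicative penalty,
#' and is negligible when \eqn{n \gg d}. Larger K penalizes edges more, so
#' the selected graph is sparser.
#'
#' @param x standardized design matrix (as stored in a \code{ggm_family}),
#'   or an \code{abundance_table}/matrix to be standardized
#' @param graph a \code{metab_network} whose nodes are columns of \code{x}
#' @param K penalty multiplier
#' @return the criterion value (numeric scalar)
#' @export
selection_criterion <- function(x, graph, K = 2) {
  if (!is.matrix(x)) x <- ggm_design_matrix(x)
  n <- nrow(x); p <- ncol(x)
  nodes <- colnames(x)
  deg <- network_degrees(graph, nodes)
  if (any(n - deg <= 0)) stop("node degree >= n; criterion undefined")
  nbrs <- split_neighbors(graph, nodes)
  pen_unit <- ggm_pen_unit(p)
  crit <- 0
  for (a in nodes) {
    crit <- crit + node_criterion_term(x, a, nbrs[[a]], K, pen_unit)
  }
  crit
}

split_neighbors <- function(graph, nodes) {
  nbrs <- stats::setNames(vector("list", length(nodes)), nodes)
  for (a in nodes) nbrs[[a]] <- character(0)
  if (n_edges(graph)) {
    for (i in seq_len(nrow(graph))) {
      a <- graph$node_a[i]; b <- graph$node_b[i]
      nbrs[[a]] <- c(nbrs[[a]], b)
      nbrs[[b]] <- c(nbrs[[b]], a)
    }
  }
  nbrs
}

ggm_pen_unit <- function(p) 0.5 * (1 + sqrt(2 * log(p - 1)))^2

node_criterion_term <- function(x, a, nb, K, pen_unit) {
  n <- nrow(x)
  d <- length(nb)
  if (n - d - 1 <= 0) return(Inf)
  y <- x[, a]
  rss <- if (d == 0) sum((y - mean(y))^2) else {
    f <- stats::lm.fit(cbind(1, x[, nb, drop = FALSE]), y)
    sum(f$residuals^2)
  }
  rss * (1 + K * d * pen_unit * n / ((n - d - 1) * (n - d)))
}

# backward-pruning trajectory: starting from `graph`, repeatedly remove the
# edge whose removal most decreases the criterion; returns every graph
# visited (including the start). Edge removal only touches the two endpoint
# node terms, so steps are evaluated incrementally.
prune_graph_path <- function(x, graph, K) {
  p <- ncol(x); nodes <- colnames(x)
  pen_unit <- ggm_pen_unit(p)
  nbrs <- split_neighbors(graph, nodes)
  terms <- vapply(nodes, function(a)
    node_criterion_term(x, a, nbrs[[a]], K, pen_unit), numeric(1))
  ea <- graph$node_a; eb <- graph$node_b
  active <- rep(TRUE, length(ea))
  edge_delta <- function(i) {
    a <- ea[i]; b <- eb[i]
    new_a <- node_criterion_term(x, a, setdiff(nbrs[[a]], b), K, pen_unit)
    new_b <- node_criterion_term(x, b, setdiff(nbrs[[b]], a), K, pen_unit)
    (new_a + new_b) - (terms[a] + terms[b])
  }
  deltas <- vapply(seq_along(ea), function(i)
    if (active[i]) edge_delta(i) else Inf, numeric(1))
  path <- list(graph)
  crits <- sum(terms)
  while (any(active)) {
    i <- which.min(deltas)
    if (deltas[i] >= 0) break
    a <- ea[i]; b <- eb[i]
    active[i] <- FALSE; deltas[i] <- Inf
    nbrs[[a]] <- setdiff(nbrs[[a]], b)
    nbrs[[b]] <- setdiff(nbrs[[b]], a)
    terms[a] <- node_criterion_term(x, a, nbrs[[a]], K, pen_unit)
    terms[b] <- node_criterion_term(x, b, nbrs[[b]], K, pen_unit)
    # only edges sharing an endpoint with the removed one change score
    touch <- which(active & (ea == a | eb == a | ea == b | eb == b))
    for (j in touch) deltas[j] <- edge_delta(j)
    path[[length(path) + 1L]] <- undirected_network(ea[active], eb[active])
    crits <- c(crits, sum(terms))
  }
  list(graphs = path, crits = crits)
}

#' Select a Gaussian graphical model
#'
#' Runs both steps: builds the Lasso-derived candidate family, extends it
#' with the backward-pruning trajectory of its best member (edges whose
#' removal lowers the criterion are greedily removed — the shared-level
#' graphs bundle late-entering true edges with path-order false positives,
#' and pruning separates them), and returns the member minimizing the
#' penalized criterion. Ties are broken toward fewer edges, then toward the
#' lexicographically smallest edge set.
#'
#' @inheritParams nodewise_lasso_family
#' @param family optionally a prebuilt \code{ggm_family} (its design matrix
#'   is reused; \code{config$K} still governs selection)
#' @return object of class \code{ggm_fit}: \code{graph},
#'   \code{neighborhoods}, \code{criterion_value}, \code{family_size},
#'   \code{family_table} (level, edges, criterion), \code{config}
#' @export
select_graph <- function(table, config = ggm_config(), family = NULL) {
  if (is.null(family)) family <- nodewise_lasso_family(table, config)
  x <- family$x
  graphs <- family$graphs
  levels <- family$levels
  crits <- vapply(graphs, function(g)
    selection_criterion(x, g, config$K), numeric(1))
  # refine by backward pruning from the best level and from the largest
  # member (the levels bundle edges, so the strong subset of a rejected
  # level can still beat the empty graph); pruned graphs join the family
  starts <- unique(c(which.min(crits), length(graphs)))
  sigs_have <- vapply(graphs, function(g)
    paste(edge_keys(g), collapse = ";"), character(1))
  for (st in starts) {
    pruned <- prune_graph_path(x, graphs[[st]], config$K)
    for (k in seq_along(pruned$graphs)[-1]) {
      g <- pruned$graphs[[k]]
      sig <- paste(edge_keys(g), collapse = ";")
      if (!(sig %in% sigs_have)) {
        graphs[[length(graphs) + 1L]] <- g
        levels <- c(levels, NA_integer_)
        crits <- c(crits, pruned$crits[k])
        sigs_have <- c(sigs_have, sig)
      }
    }
  }
  sizes <- vapply(graphs, n_edges, integer(1))
  sigs <- vapply(graphs, function(g)
    paste(edge_keys(g), collapse = ";"), character(1))
  best <- order(crits, sizes, sigs)[1]
  graph <- graphs[[best]]
  structure(list(graph = graph,
                 neighborhoods = split_neighbors(graph, colnames(x)),
                 criterion_value = crits[best],
                 family_size = length(graphs),
                 family_table = data.frame(level = levels,
                                           edges = sizes,
                                           criterion = crits),
                 config = config),
            class = "ggm_fit")
}

#' @export
print.ggm_fit <- function(x, ...) {
  cat(sprintf(
    "GGM fit: %d edges (K = %g, dmax = %d, %s-rule); criterion %.4g over %d-graph family\n",
    n_edges(x$graph), x$config$K, x$config$dmax, x$config$symmetrize,
    x$criterion_value, x$family_size))
  invisible(x)
}

#' Sweep the (K, dmax) grid and report edge-count plateaus
#'
#' Fits every combination and, per K, reports the longest run of
#' consecutive dmax values over which the selected edge count is constant —
#' the diagnostic used to fix default penalty settings.
#'
#' @param table \code{abundance_table} or matrix
#' @param K_values,dmax_values grids (defaults 2..5 and 1..10)
#' @param config base \code{ggm_config} (symmetrize/path settings)
#' @return list: \code{edge_counts} (K x dmax matrix) and \code{plateaus}
#'   (data frame K, dmax_from, dmax_to, edges)
#' @export
sweep_k_dmax <- function(table, K_values = 2:5, dmax_values = 1:10,
                         config = ggm_config()) {
  dmax_values <- sort(unique(as.integer(dmax_values)))
  counts <- matrix(NA_integer_, length(K_values), length(dmax_values),
                   dimnames = list(paste0("K=", K_values),
                                   paste0("dmax=", dmax_values)))
  # entry orders depend only on dmax: build once at the largest and reuse
  fam_cache <- list()
  for (j in seq_along(dmax_values)) {
    cfg <- config; cfg$dmax <- dmax_values[j]
    fam <- nodewise_lasso_family(table, cfg)
    for (i in seq_along(K_values)) {
      cfg_k <- cfg; cfg_k$K <- K_values[i]
      counts[i, j] <- n_edges(select_graph(table, cfg_k, family = fam)$graph)
    }
  }
  plateaus <- do.call(rbind, lapply(seq_along(K_values), function(i) {
    r <- rle(as.integer(counts[i, ]))
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    k <- which.max(r$lengths)
    data.frame(K = K_values[i],
               dmax_from = dmax_values[starts[k]],
               dmax_to = dmax_values[ends[k]],
               edges = r$values[k])
  }))
  list(edge_counts = counts, plateaus = plateaus)
}
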