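#' Edge symmetric difference between two networks
#'
#' The proportion of edges not shared between two networks,
#' \deqn{esd(A,B) = \frac{|E(A) \setminus E(B)| + |E(B) \setminus E(A)|}
#' {|E(A)| + |E(B)|},}
#' ranging from 0 (identical edge sets) to 1 (disjoint). Weights are
#' ignored; edge identity is the unordered node pair. The statistic is
#' symmetric in its arguments.
#'
#' @param network_a,network_b \code{metab_network} objects
#' @return object of class \code{esd_result}: \code{value},
#'   \code{only_in_first}, \code{only_in_second}, \code{size_first},
#'   \code{size_second}, \code{shared}
#' @examples
#' a <- undirected_network(c("x", "y"), c("y", "z"))
#' esd(a, a)$value  # 0
#' @export
esd <- function(network_a, network_b) {
  ka <- edge_keys(network_a); kb <- edge_keys(network_b)
  if (length(ka) + length(kb) == 0)
    stop("esd undefined: both networks are empty (0/0)")
  shared <- sum(ka %in% kb)
  only_a <- length(ka) - shared
  only_b <- length(kb) - shared
  structure(list(value = (only_a + only_b) / (length(ka) + length(kb)),
                 only_in_first = only_a, only_in_second = only_b,
                 size_first = length(ka), size_second = length(kb),
                 shared = shared),
            class = "esd_result")
}

#' @export
print.esd_result <- function(x, ...) {
  cat(sprintf(
    "esd = %.4f  (|A| = %d, |B| = %d, shared = %d, A-only = %d, B-only = %d)\n",
    x$value, x$size_first, x$size_second, x$shared,
    x$only_in_first, x$only_in_second))
  invisible(x)
}

# absolute pairwise correlations of a preprocessed table, long format
all_pair_correlations <- function(table) {
  x <- if (inherits(table, "abundance_table")) table$values else
    as.matrix(table)
  if (nrow(x) < 3) stop("need at least 3 samples for correlations")
  sds <- apply(x, 2, stats::sd, na.rm = TRUE)
  if (any(sds == 0 | is.na(sds))) {
    warning("excluding zero-variance metabolite(s): ",
            paste(colnames(x)[sds == 0 | is.na(sds)], collapse = ", "))
    x <- x[, !(sds == 0 | is.na(sds)), drop = FALSE]
  }
  r <- stats::cor(x, use = "pairwise.complete.obs")
  idx <- which(upper.tri(r), arr.ind = TRUE)
  data.frame(node_a = colnames(x)[idx[, 1]],
             node_b = colnames(x)[idx[, 2]],
             r = r[idx], stringsAsFactors = FALSE)
}

#' Pearson correlation network at a threshold
#'
#' An edge joins two metabolites iff the absolute Pearson correlation of
#' their (preprocessed) abundances strictly exceeds the threshold; the edge
#' weight is the signed r.
#'
#' @param table preprocessed \code{abundance_table} or matrix
#' @param threshold absolute-correlation cutoff (strict inequality)
#' @return \code{metab_network} with a \code{weight} column
#' @export
correlation_network <- function(table, threshold) {
  pr <- all_pair_correlations(table)
  keep <- abs(pr$r) > threshold
  undirected_network(pr$node_a[keep], pr$node_b[keep], pr$r[keep])
}

#' Correlation threshold matching a target edge count
#'
#' Sorts all pairwise absolute correlations and returns the cutoff under
#' which exactly \code{target_edge_count} pairs strictly exceed it — the
#' (target+1)-th largest |r| when values are distinct. Under ties at the
#' boundary the nearest achievable count is returned, preferring the larger.
#'
#' @param table preprocessed \code{abundance_table} or matrix
#' @param target_edge_count requested number of edges
#' @return list: \code{threshold}, \code{network}, \code{achieved_edges}
#' @export
match_edge_count_threshold <- function(table, target_edge_count) {
  pr <- all_pair_correlations(table)
  npairs <- nrow(pr)
  if (target_edge_count > npairs)
    stop("target exceeds the number of metabolite pairs (", npairs, ")")
  absr <- sort(abs(pr$r), decreasing = TRUE)
  if (target_edge_count == 0) {
    thr <- absr[1]
    return(list(threshold = thr,
                network = correlation_network(table, thr),
                achieved_edges = 0L))
  }
  # achievable counts are the numbers of |r| strictly above each distinct value
  cand_thr <- unique(absr)
  cand_cnt <- vapply(cand_thr, function(v) sum(absr > v), integer(1))
  d <- abs(cand_cnt - target_edge_count)
  best <- which(d == min(d))
  if (length(best) > 1) best <- best[which.max(cand_cnt[best])]
  thr <- cand_thr[best]
  net <- correlation_network(table, thr)
  list(threshold = thr, network = net, achieved_edges = n_edges(net))
}

#' Two-sided p-value of a Pearson correlation
#'
#' Exact t-distribution tail: \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on
#' \eqn{n - 2} degrees of freedom.
#'
#' @param r correlation coefficient(s), |r| <= 1
#' @param n sample size, at least 3
#' @return two-sided p-value(s); for |r| = 1 the value 0 is returned with a
#'   \code{degenerate} attribute
#' @examples
#' correlation_pvalue(0.9235, 31)  # ~1.4e-13
#' @export
correlation_pvalue <- function(r, n) {
  if (any(n < 3)) stop("need n >= 3")
  if (any(abs(r) > 1)) stop("|r| > 1")
  degenerate <- abs(r) == 1
  p <- numeric(length(r))
  ok <- !degenerate
  t <- r[ok] * sqrt((n - 2) / (1 - r[ok]^2))
  p[ok] <- 2 * stats::pt(-abs(t), df = n - 2)
  p[degenerate] <- 0
  if (any(degenerate)) attr(p, "degenerate") <- which(degenerate)
  p
}

#' Three-way edge overlap with per-edge correlation shifts
#'
#' Partitions the union of three edge sets (condition A, condition B, and
#' the pooled dataset) into its 7 exclusive regions, computes for every
#' union edge the Pearson correlation of its two metabolites within each of
#' the three datasets, and flags edges whose dataset of membership does not
#' carry the highest absolute correlation.
#'
#' @param net_hfd,net_nd,net_complete \code{metab_network}s
#' @param tables named list of preprocessed tables (\code{HFD}, \code{ND},
#'   \code{complete}) whose metabolite columns cover the networks' nodes
#' @return object of class \code{overlap_result}: \code{region_counts}
#'   (named integer vector over the 7 regions), \code{per_edge}
#'   (data frame: edge, membership, r in each dataset, flags)
#' @export
overlap3 <- function(net_hfd, net_nd, net_complete, tables = NULL) {
  nets <- list(HFD = net_hfd, ND = net_nd, complete = net_complete)
  u <- edge_union(edge_union(net_hfd, net_nd), net_complete)
  ku <- edge_keys(u)
  inset <- matrix(FALSE, length(ku), length(nets),
                  dimnames = list(NULL, names(nets)))
  for (nm in names(nets)) inset[, nm] <- ku %in% edge_keys(nets[[nm]])
  region <- apply(inset, 1, function(z)
    paste(names(nets)[z], collapse = "&"))
  region <- as.character(region)
  region_levels <- c("HFD", "ND", "complete", "HFD&ND", "HFD&complete",
                     "ND&complete", "HFD&ND&complete")
  region_counts <- table(factor(region, levels = region_levels))
  per_edge <- data.frame(node_a = u$node_a, node_b = u$node_b,
                         membership = region, stringsAsFactors = FALSE)
  if (!is.null(tables)) {
    need <- c("HFD", "ND", "complete")
    if (!all(need %in% names(tables)))
      stop("tables must be a named list with HFD, ND and complete")
    nodes_needed <- network_nodes(u)
    for (nm in need) {
      mets <- if (inherits(tables[[nm]], "abundance_table"))
        tables[[nm]]$metabolite_ids else colnames(tables[[nm]])
      missing_nodes <- setdiff(nodes_needed, mets)
      if (length(missing_nodes))
        stop("table '", nm, "' lacks metabolite(s): ",
             paste(utils::head(missing_nodes, 5), collapse = ", "))
    }
    for (nm in need) {
      x <- if (inherits(tables[[nm]], "abundance_table"))
        tables[[nm]]$values else as.matrix(tables[[nm]])
      per_edge[[paste0("r_", nm)]] <- mapply(function(a, b)
        stats::cor(x[, a], x[, b], use = "pairwise.complete.obs"),
        u$node_a, u$node_b, USE.NAMES = FALSE)
    }
    rmat <- abs(as.matrix(per_edge[, paste0("r_", need)]))
    top <- need[max.col(rmat, ties.method = "first")]
    # an edge unique to one dataset "should" have its highest |r| there
    in_one <- per_edge$membership %in% need
    per_edge$highest_r_dataset <- top
    per_edge$membership_not_highest_r <- in_one & (top != per_edge$membership)
  }
  structure(list(region_counts = stats::setNames(as.integer(region_counts),
                                                 region_levels),
                 per_edge = per_edge),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("Three-way edge overlap (exclusive regions):\n")
  print(x$region_counts)
  invisible(x)
}
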