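# shared fixture builders; everything is generated in code at test time

edge_key_set <- function(net) paste(net$node_a, net$node_b, sep = "|")

edge_f1 <- function(estimated, truth) {
  tp <- length(intersect(edge_key_set(estimated), edge_key_set(truth)))
  denom <- n_edges(estimated) + n_edges(truth)
  if (denom == 0) return(NA_real_)
  2 * tp / denom
}

chain_network <- function(nodes) {
  undirected_network(nodes[-length(nodes)], nodes[-1])
}

# draw n multivariate-normal rows with covariance = inverse of `omega`
sample_mvn_from_precision <- function(omega, n, seed) {
  set.seed(seed)
  sigma <- chol2inv(chol(omega))
  x <- matrix(stats::rnorm(n * ncol(omega)), n) %*% chol(sigma)
  colnames(x) <- colnames(omega)
  x
}

write_tmp_lines <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# small raw-scale abundance table with optional missing cells
toy_table <- function(values, sample_ids = NULL, metabolite_ids = NULL) {
  m <- as.matrix(values)
  rownames(m) <- sample_ids %||% sprintf("s%02d", seq_len(nrow(m)))
  colnames(m) <- metabolite_ids %||% sprintf("m%02d", seq_len(ncol(m)))
  abundance_table(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent-criterion oracle: the documented formula evaluated with lm()
brute_force_criterion <- function(x, net, K) {
  x <- scale(x)
  n <- nrow(x); p <- ncol(x)
  pen_unit <- 0.5 * (1 + sqrt(2 * log(p - 1)))^2
  total <- 0
  for (a in colnames(x)) {
    nb <- unique(c(net$node_b[net$node_a == a], net$node_a[net$node_b == a]))
    rss <- if (length(nb)) {
      sum(stats::residuals(stats::lm(x[, a] ~ x[, nb, drop = FALSE]))^2)
    } else sum((x[, a] - mean(x[, a]))^2)
    d <- length(nb)
    total <- total +
      rss * (1 + K * d * pen_unit * n / ((n - d - 1) * (n - d)))
  }
  total
}

# every graph on a small node set, as a list of metab_networks
all_graphs <- function(nodes) {
  pairs <- t(utils::combn(nodes, 2))
  m <- nrow(pairs)
  lapply(0:(2^m - 1), function(mask) {
    keep <- bitwAnd(mask, 2^(seq_len(m) - 1)) > 0
    undirected_network(pairs[keep, 1], pairs[keep, 2])
  })
}
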