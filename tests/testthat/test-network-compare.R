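test_that("esd follows its formula and axioms on fixed cases", {
  a <- undirected_network(c("x", "y", "z"), c("y", "z", "w"))
  expect_equal(esd(a, a)$value, 0)
  b <- undirected_network(c("p", "q"), c("q", "r"))
  e <- esd(a, b)
  expect_equal(e$value, 1)
  expect_equal(e$size_first, 3L); expect_equal(e$size_second, 2L)
  # the emulated study's counts: 93 and 57 edges sharing 16
  nodes <- sprintf("n%03d", 1:200)
  shared <- undirected_network(nodes[1:16], nodes[17:32])
  hfd <- edge_union(shared, undirected_network(nodes[33:109], nodes[110:186]))
  nd <- edge_union(shared, undirected_network(nodes[1:41], nodes[160:200]))
  expect_equal(n_edges(hfd), 93L); expect_equal(n_edges(nd), 57L)
  r <- esd(hfd, nd)
  expect_equal(r$shared, 16L)
  expect_equal(r$value, 118 / 150)
  expect_equal(round(r$value, 3), 0.787)  # prints as 0.786|7
  expect_equal(esd(nd, hfd)$value, r$value)
  empty <- undirected_network(character(0), character(0))
  expect_error(esd(empty, empty), "0/0")
  expect_equal(esd(a, empty)$value, 1)
})

test_that("correlation networks match a brute-force all-pairs oracle", {
  set.seed(4)
  x <- matrix(rnorm(50 * 5), 50, 5, dimnames = list(NULL, letters[1:5]))
  x[, 2] <- x[, 1]                       # duplicated variable
  net <- correlation_network(x, 0.9)
  expect_equal(n_edges(net), 1L)
  expect_equal(net$node_a, "a"); expect_equal(net$node_b, "b")
  expect_equal(net$weight, 1)
  expect_equal(n_edges(correlation_network(x, 1)), 0L)

  y <- matrix(rnorm(30 * 5), 30, 5, dimnames = list(NULL, letters[1:5]))
  y[, 3] <- y[, 1] * 0.9 + rnorm(30, sd = 0.2)
  thr <- 0.4
  net2 <- correlation_network(y, thr)
  cm <- cor(y)
  oracle <- which(abs(cm) > thr & upper.tri(cm), arr.ind = TRUE)
  expect_equal(n_edges(net2), nrow(oracle))
  expect_setequal(edge_key_set(net2),
                  paste(rownames(cm)[pmin(oracle[, 1], oracle[, 2])],
                        colnames(cm)[pmax(oracle[, 1], oracle[, 2])],
                        sep = "|"))
  expect_error(correlation_network(y[1:2, ], 0.5), "3 samples")
  yz <- cbind(y, zv = 1)
  expect_warning(correlation_network(yz, 0.5), "zero-variance")
})

test_that("edge-count matching finds the exact threshold in generic position", {
  set.seed(5)
  x <- matrix(rnorm(40 * 4), 40, 4, dimnames = list(NULL, letters[1:4]))
  res <- match_edge_count_threshold(x, 2)
  absr <- sort(abs(cor(x)[upper.tri(cor(x))]), decreasing = TRUE)
  expect_equal(res$threshold, absr[3])   # (target+1)-th largest |r|
  expect_equal(res$achieved_edges, 2L)
  expect_equal(n_edges(res$network), 2L)

  expect_equal(match_edge_count_threshold(x, 0)$achieved_edges, 0L)
  expect_error(match_edge_count_threshold(x, 7), "pairs")

  # generic exactness over random targets
  set.seed(6)
  z <- matrix(rnorm(60 * 8), 60, 8, dimnames = list(NULL, letters[1:8]))
  for (target in c(1, 5, 13, 27)) {
    expect_equal(match_edge_count_threshold(z, target)$achieved_edges,
                 as.integer(target))
  }
})

test_that("boundary ties prefer the larger achievable edge count", {
  set.seed(7)
  base <- rnorm(25)
  x <- cbind(a = base, b = base, c = base, d = rnorm(25))
  # pairs (a,b), (a,c), (b,c) all have |r| = 1: counts jump 0 -> 3
  res <- match_edge_count_threshold(x, 2)
  expect_equal(res$achieved_edges, 3L)
})

test_that("correlation p-values reproduce the t closed form and null calibration", {
  expect_equal(correlation_pvalue(0, 25), 1)
  p <- correlation_pvalue(0.9235, 31)
  expect_equal(as.numeric(p), 2 * pt(-0.9235 * sqrt(29 / (1 - 0.9235^2)), 29))
  expect_error(correlation_pvalue(0.5, 2), "n >= 3")
  p1 <- correlation_pvalue(1, 10)
  expect_equal(as.numeric(p1), 0)
  expect_false(is.null(attr(p1, "degenerate")))

  # strict monotonicity in |r| and n
  rs <- seq(0.1, 0.9, by = 0.1)
  expect_true(all(diff(correlation_pvalue(rs, 20)) < 0))
  ns <- c(5, 10, 30, 100)
  expect_true(all(diff(sapply(ns, function(n)
    correlation_pvalue(0.4, n))) < 0))

  # permutation-null oracle at r = 0.5, n = 30
  set.seed(11)
  n <- 30; B <- 100000
  x0 <- as.numeric(scale(rnorm(n))); y0 <- as.numeric(scale(rnorm(n)))
  rs_null <- replicate(B, abs(cor(x0, sample(y0))))
  p_perm <- mean(rs_null >= 0.5)
  p_t <- as.numeric(correlation_pvalue(0.5, n))
  mc_se <- sqrt(p_t * (1 - p_t) / B)
  expect_lt(abs(p_perm - p_t), 4 * mc_se + 1e-3)
})

test_that("three-way overlap partitions edges into exclusive regions", {
  a <- undirected_network(c("x", "y"), c("y", "z"))
  ov_same <- overlap3(a, a, a)
  expect_equal(unname(ov_same$region_counts["HFD&ND&complete"]), 2L)
  expect_equal(sum(ov_same$region_counts), 2L)

  b <- undirected_network("p", "q"); cc <- undirected_network("u", "v")
  ov_dis <- overlap3(a, b, cc)
  expect_equal(unname(ov_dis$region_counts[c("HFD", "ND", "complete")]),
               c(2L, 1L, 1L))
  expect_equal(sum(ov_dis$region_counts[4:7]), 0L)
})

test_that("per-edge correlations flag membership without the highest |r|", {
  set.seed(12)
  n <- 20
  x_h <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, letters[1:4]))
  x_h[, 2] <- x_h[, 1] + rnorm(n, sd = 0.2)           # strong only in HFD
  x_n <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, letters[1:4]))
  x_n[, 3] <- x_n[, 4] + rnorm(n, sd = 0.2)           # strong only in ND
  x_c <- rbind(x_h, x_n)
  net_h <- undirected_network("a", "b")
  net_n <- undirected_network("c", "d")
  net_c <- undirected_network(c("a", "c"), c("b", "d"))
  ov <- overlap3(net_h, net_n, net_c,
                 tables = list(HFD = x_h, ND = x_n, complete = x_c))
  pe <- ov$per_edge
  expect_equal(pe$highest_r_dataset[pe$node_a == "a"], "HFD")
  expect_equal(pe$highest_r_dataset[pe$node_a == "c"], "ND")
  expect_error(overlap3(undirected_network("zz", "ww"), net_n, net_c,
                        tables = list(HFD = x_h, ND = x_n, complete = x_c)),
               "lacks metabolite")
})
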