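#' Specification of a synthetic metabolomics study
#'
#' Collects the generative parameters for a two-diet untargeted-metabolomics
#' study: two sparse condition-specific conditional-dependence graphs with a
#' controlled edge overlap, a block of diet-shifted differentiator
#' metabolites (medium-chain fatty-acid analogs, shifted under the high-fat
#' diet), a correlated phenotype-linked block (dipeptide analogs, shifted by
#' reaction-norm class), genotypes nested in reaction-norm classes, and
#' left-censoring of low values to mimic a detection floor.
#'
#' Defaults reproduce the scale of the emulated study: 350 metabolites,
#' 16 normal-diet and 15 high-fat-diet samples over 16 genotypes in three
#' reaction-norm classes, condition graphs of 57 and 93 edges with edge
#' symmetric difference 0.786, and node degree capped at 5.
#'
#' @param p number of metabolites
#' @param n_per_condition named counts \code{c(ND=, HFD=)}
#' @param n_edges named target edge counts per condition graph
#' @param target_esd target edge symmetric difference between the two graphs
#' @param degree_cap maximum node degree in each condition graph
#' @param differentiator_size,differentiator_shift_sd size of the
#'   diet-differentiator block and its mean shift under HFD, in units of the
#'   metabolite's within-condition SD
#' @param phenotype_size,phenotype_rho,phenotype_shift_sd size, within-block
#'   correlation, and reaction-norm mean shift (SD units) of the
#'   phenotype-linked block
#' @param detection_floor_quantile fraction of each metabolite's lowest
#'   values censored to missing
#' @param partial_corr_magnitude target magnitude of nonzero partial
#'   correlations implied by the precision matrices
#' @param n_genotypes number of genotypes, split across the three
#'   reaction-norm classes
#' @param genotype_sd SD of an optional per-genotype random intercept
#'   (0 = off, the default)
#' @param seed integer seed controlling all randomness downstream
#' @return object of class \code{synthetic_spec}
#' @export
synthetic_spec <- function(p = 350,
                           n_per_condition = c(ND = 16, HFD = 15),
                           n_edges = c(ND = 57, HFD = 93),
                           target_esd = 0.786,
                           degree_cap = 5,
                           differentiator_size = 10,
                           differentiator_shift_sd = 3,
                           phenotype_size = 8,
                           phenotype_rho = 0.6,
                           phenotype_shift_sd = 1.5,
                           detection_floor_quantile = 0.05,
                           partial_corr_magnitude = 0.35,
                           n_genotypes = 16,
                           genotype_sd = 0,
                           seed = 1L) {
  stopifnot(p >= 3, all(n_per_condition >= 2), all(n_edges >= 1),
            target_esd >= 0, target_esd <= 1, degree_cap >= 1,
            detection_floor_quantile >= 0, detection_floor_quantile < 1)
  if (differentiator_size + phenotype_size > p)
    stop("planted blocks larger than p")
  spec <- list(p = p, n_per_condition = n_per_condition, n_edges = n_edges,
               target_esd = target_esd, degree_cap = degree_cap,
               differentiator_size = differentiator_size,
               differentiator_shift_sd = differentiator_shift_sd,
               phenotype_size = phenotype_size,
               phenotype_rho = phenotype_rho,
               phenotype_shift_sd = phenotype_shift_sd,
               detection_floor_quantile = detection_floor_quantile,
               partial_corr_magnitude = partial_corr_magnitude,
               n_genotypes = n_genotypes, genotype_sd = genotype_sd,
               seed = as.integer(seed))
  class(spec) <- "synthetic_spec"
  spec
}

#' Metabolite names used by the generator
#'
#' Planted diet differentiators are named \code{mcfa_analog_*} (medium-chain
#' fatty-acid analogs), the phenotype-linked block \code{dipeptide_analog_*},
#' the rest \code{met_*}.
#' @param spec a \code{synthetic_spec}
#' @return character vector of length \code{spec$p}
#' @export
synthetic_metabolite_ids <- function(spec) {
  c(sprintf("mcfa_analog_%02d", seq_len(spec$differentiator_size)),
    sprintf("dipeptide_analog_%02d", seq_len(spec$phenotype_size)),
    sprintf("met_%03d",
            seq_len(spec$p - spec$differentiator_size - spec$phenotype_size)))
}

# nearest feasible shared-edge count for a target esd given two edge counts
feasible_shared_edges <- function(e1, e2, target_esd) {
  total <- e1 + e2
  smax <- min(e1, e2)
  esd_min <- (total - 2 * smax) / total
  if (target_esd < esd_min - .Machine$double.eps^0.5)
    stop(sprintf(paste0("target_esd %.4f infeasible: with edge counts %d and",
                        " %d the minimum achievable esd is %.4f ",
                        "(shared edges cannot exceed min(|E1|,|E2|) = %d)"),
                 target_esd, e1, e2, esd_min, smax))
  s_cand <- 0:smax
  esd_cand <- (total - 2 * s_cand) / total
  s <- s_cand[which.min(abs(esd_cand - target_esd))]
  list(s = s, realized_esd = (total - 2 * s) / total)
}

# sample n_new edges among `nodes`, respecting a per-node degree cap within
# each of the graphs listed in `deg` (a list of named degree vectors) and
# avoiding `taken` edge keys
sample_edges_capped <- function(nodes, n_new, deg_list, cap, taken) {
  p <- length(nodes)
  edges_a <- character(n_new); edges_b <- character(n_new)
  got <- 0L; tries <- 0L; max_tries <- 500L * max(n_new, 1L)
  while (got < n_new) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("could not place requested edges under the degree cap; ",
           "raise degree_cap or p, or lower the edge counts")
    ij <- sample.int(p, 2L)
    a <- nodes[min(ij)]; b <- nodes[max(ij)]
    key <- paste(a, b, sep = "\r")
    if (key %in% taken) next
    ok <- all(vapply(deg_list, function(d) d[a] < cap && d[b] < cap,
                     logical(1)))
    if (!ok) next
    got <- got + 1L
    edges_a[got] <- a; edges_b[got] <- b
    taken <- c(taken, key)
    for (k in seq_along(deg_list)) {
      deg_list[[k]][a] <- deg_list[[k]][a] + 1L
      deg_list[[k]][b] <- deg_list[[k]][b] + 1L
    }
  }
  list(node_a = edges_a, node_b = edges_b, deg_list = deg_list,
       taken = taken)
}

#' Build two condition graphs with a controlled edge overlap
#'
#' Draws two random graphs on the same node set with the requested edge
#' counts, a per-node degree cap in each graph, and a shared-edge count
#' \code{s} chosen so that the realized edge symmetric difference
#' \eqn{(|E_1|+|E_2|-2s)/(|E_1|+|E_2|)} is the feasible value nearest
#' \code{target_esd} — exactly, by construction.
#'
#' @param spec a \code{synthetic_spec}
#' @return list with \code{graph_ND}, \code{graph_HFD}
#'   (\code{metab_network}s), \code{shared_edges}, \code{realized_esd}
#' @export
make_condition_graphs <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  e_nd <- spec$n_edges[["ND"]]; e_hfd <- spec$n_edges[["HFD"]]
  if (max(e_nd, e_hfd) > spec$p * spec$degree_cap / 2)
    stop(sprintf("edge count %d exceeds degree-cap capacity p*cap/2 = %.0f",
                 max(e_nd, e_hfd), spec$p * spec$degree_cap / 2))
  feas <- feasible_shared_edges(e_nd, e_hfd, spec$target_esd)
  nodes <- synthetic_metabolite_ids(spec)
  set.seed(spec$seed)
  deg0 <- stats::setNames(integer(spec$p), nodes)
  # shared edges count against both graphs' caps
  sh <- sample_edges_capped(nodes, feas$s,
                            list(ND = deg0, HFD = deg0),
                            spec$degree_cap, character(0))
  u_nd <- sample_edges_capped(nodes, e_nd - feas$s,
                              list(ND = sh$deg_list$ND),
                              spec$degree_cap, sh$taken)
  u_hfd <- sample_edges_capped(nodes, e_hfd - feas$s,
                               list(HFD = sh$deg_list$HFD),
                               spec$degree_cap, u_nd$taken)
  g_nd <- undirected_network(c(sh$node_a, u_nd$node_a),
                             c(sh$node_b, u_nd$node_b))
  g_hfd <- undirected_network(c(sh$node_a, u_hfd$node_a),
                              c(sh$node_b, u_hfd$node_b))
  list(graph_ND = g_nd, graph_HFD = g_hfd,
       shared_edges = feas$s, realized_esd = feas$realized_esd)
}

#' Precision matrix with support on a given graph
#'
#' The standard simulation device for Gaussian graphical models: place
#' random-sign entries of magnitude governed by \code{partial_corr_magnitude}
#' on the graph's edges, make the matrix strictly diagonally dominant
#' (hence symmetric positive definite), and rescale to unit diagonal. The
#' off-diagonal support of the result equals the graph exactly, and the
#' implied partial correlations \eqn{-\omega_{ab}/\sqrt{\omega_{aa}
#' \omega_{bb}}} on edges are reported.
#'
#' @param graph a \code{metab_network}
#' @param nodes full node universe (isolated nodes allowed)
#' @param partial_corr_magnitude nominal edge-entry magnitude before
#'   dominance rescaling
#' @param seed integer seed
#' @return list with \code{omega} (p x p precision matrix, dimnames =
#'   nodes) and \code{partial_corr_range} over edges
#' @export
graph_to_precision <- function(graph, nodes,
                               partial_corr_magnitude = 0.35, seed = 1L) {
  p <- length(nodes)
  if (p == 0) stop("empty node set")
  set.seed(seed)
  omega <- diag(1, p)
  dimnames(omega) <- list(nodes, nodes)
  m <- n_edges(graph)
  if (m > 0) {
    ia <- match(graph$node_a, nodes); ib <- match(graph$node_b, nodes)
    if (anyNA(ia) || anyNA(ib)) stop("graph has nodes outside `nodes`")
    vals <- sample(c(-1, 1), m, replace = TRUE) *
      stats::runif(m, 0.9, 1.1) * partial_corr_magnitude
    omega[cbind(ia, ib)] <- vals
    omega[cbind(ib, ia)] <- vals
    # strict diagonal dominance guarantees positive definiteness
    rs <- rowSums(abs(omega)) - diag(omega)
    diag(omega) <- pmax(1, 1.05 * rs)
    d <- 1 / sqrt(diag(omega))
    omega <- omega * tcrossprod(d)
  }
  pc <- if (m > 0) {
    ia <- match(graph$node_a, nodes); ib <- match(graph$node_b, nodes)
    abs(-omega[cbind(ia, ib)] /
          sqrt(diag(omega)[ia] * diag(omega)[ib]))
  } else numeric(0)
  ev_min <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 0) stop("precision matrix not positive definite")
  list(omega = omega,
       partial_corr_range = if (m) range(pc) else c(NA_real_, NA_real_))
}

# genotype design: n_genotypes split across the three reaction-norm classes,
# one sample per genotype per diet, minus dropped genotypes under HFD so the
# condition sample counts are honored
genotype_design <- function(spec) {
  classes <- c("N_lt_HF", "N_gt_HF", "zero")
  sizes <- diff(round(seq(0, spec$n_genotypes, length.out = 4)))
  geno <- sprintf("G%02d", seq_len(spec$n_genotypes))
  cls <- rep(classes, sizes)
  # triglyceride phenotypes consistent with the 25% reaction-norm rule
  trig_nd <- stats::rlnorm(spec$n_genotypes, meanlog = log(100), sdlog = 0.15)
  ratio <- vapply(cls, function(cl) switch(cl,
    N_lt_HF = 1.25 + stats::runif(1, 0.05, 0.5),
    N_gt_HF = 1 / (1.25 + stats::runif(1, 0.05, 0.5)),
    zero = exp(stats::runif(1, log(1 / 1.2), log(1.2)))), numeric(1))
  data.frame(genotype = geno, reaction_norm = cls,
             trig_ND = trig_nd, trig_HFD = trig_nd * ratio,
             stringsAsFactors = FALSE)
}

#' Draw a synthetic abundance table with annotated ground truth
#'
#' Per condition, draws latent Gaussian vectors with covariance equal to the
#' inverse of that condition's precision matrix, adds the planted mean
#' structure (diet differentiator shift under HFD; phenotype-block shift by
#' reaction-norm class, plus a shared within-block factor inducing the block
#' correlation), exponentiates to a positive abundance scale (so the
#' pipeline's log transform returns to Gaussianity), and censors each
#' metabolite's lowest \code{detection_floor_quantile} fraction of values to
#' missing. All randomness derives from \code{spec$seed}.
#'
#' @param spec a \code{synthetic_spec}
#' @param truth output of \code{\link{make_synthetic_truth}} (built if
#'   omitted)
#' @return list with \code{table} (raw-scale \code{abundance_table} with
#'   missing cells), \code{meta} (sample metadata data frame), and
#'   \code{truth}
#' @export
sample_table <- function(spec, truth = make_synthetic_truth(spec)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (any(spec$n_per_condition < 2)) stop("need >= 2 samples per condition")
  nodes <- synthetic_metabolite_ids(spec)
  p <- spec$p
  set.seed(spec$seed + 211L)
  design <- genotype_design(spec)
  # one sample per genotype per diet; drop genotypes under HFD (from the
  # largest class) until the requested condition counts are met
  meta <- rbind(
    data.frame(diet = "ND", design[rep(seq_len(nrow(design)),
                                       length.out = spec$n_per_condition[["ND"]]), ],
               stringsAsFactors = FALSE),
    local({
      drop_n <- nrow(design) - spec$n_per_condition[["HFD"]]
      keep <- design
      if (drop_n > 0) {
        zero_rows <- which(keep$reaction_norm == "zero")
        keep <- keep[-utils::tail(zero_rows, drop_n), , drop = FALSE]
      }
      data.frame(diet = "HFD",
                 keep[rep(seq_len(nrow(keep)),
                          length.out = spec$n_per_condition[["HFD"]]), ],
                 stringsAsFactors = FALSE)
    }))
  meta$triglyceride <- ifelse(meta$diet == "ND", meta$trig_ND, meta$trig_HFD)
  meta$sample_id <- sprintf("S%02d_%s_%s", seq_len(nrow(meta)),
                            meta$diet, meta$genotype)
  meta <- meta[, c("sample_id", "diet", "genotype", "reaction_norm",
                   "triglyceride")]
  rownames(meta) <- NULL

  diff_idx <- seq_len(spec$differentiator_size)
  pheno_idx <- spec$differentiator_size + seq_len(spec$phenotype_size)
  gen_int <- if (spec$genotype_sd > 0)
    stats::setNames(stats::rnorm(nrow(design), 0, spec$genotype_sd),
                    design$genotype)
  else stats::setNames(numeric(nrow(design)), design$genotype)

  latent <- matrix(NA_real_, nrow(meta), p,
                   dimnames = list(meta$sample_id, nodes))
  for (cond in c("ND", "HFD")) {
    rows <- which(meta$diet == cond)
    sigma <- chol2inv(chol(truth$precision[[cond]]))
    sdv <- sqrt(diag(sigma))
    z <- matrix(stats::rnorm(length(rows) * p), length(rows), p)
    x <- z %*% chol(sigma)
    if (cond == "HFD")
      x[, diff_idx] <- x[, diff_idx] +
        rep(spec$differentiator_shift_sd * sdv[diff_idx],
            each = length(rows))
    # phenotype block: class mean shift + shared factor for block correlation
    shift <- ifelse(meta$reaction_norm[rows] == "N_gt_HF",
                    spec$phenotype_shift_sd,
                    ifelse(meta$reaction_norm[rows] == "N_lt_HF",
                           -spec$phenotype_shift_sd, 0))
    rho <- spec$phenotype_rho
    fac <- stats::rnorm(length(rows))
    x[, pheno_idx] <- x[, pheno_idx] +
      outer(shift, sdv[pheno_idx]) +
      outer(sqrt(rho / (1 - rho)) * fac, sdv[pheno_idx])
    x <- x + gen_int[meta$genotype[rows]]
    latent[rows, ] <- x
  }
  abund <- exp(latent)
  if (spec$detection_floor_quantile > 0) {
    k <- floor(spec$detection_floor_quantile * nrow(abund))
    if (k >= nrow(abund)) k <- nrow(abund) - 1L
    if (k > 0) {
      for (j in seq_len(p)) {
        ord <- order(abund[, j])[seq_len(k)]
        abund[ord, j] <- NA_real_
      }
    }
  }
  tab <- abundance_table(abund, annotations = data.frame(
    metabolite_id = nodes, display_name = nodes,
    id_status = ifelse(grepl("^met_", nodes) &
                         (seq_len(p) %% 5 == 0), "unknown", "known"),
    class_label = ifelse(grepl("^mcfa", nodes), "medium-chain fatty acid",
                         ifelse(grepl("^dipeptide", nodes), "dipeptide",
                                "other")),
    stringsAsFactors = FALSE))
  meta$diet <- factor(meta$diet, levels = c("ND", "HFD"))
  meta$reaction_norm <- factor(meta$reaction_norm,
                               levels = c("N_gt_HF", "zero", "N_lt_HF"))
  list(table = tab, meta = meta, truth = truth)
}

#' Ground truth for a synthetic study
#'
#' Builds the condition graphs and their precision matrices and records the
#' planted block memberships.
#' @param spec a \code{synthetic_spec}
#' @return object of class \code{synthetic_truth}: \code{graphs} (per
#'   condition), \code{precision} (per condition), \code{differentiator_ids},
#'   \code{phenotype_block_ids}, \code{shared_edges}, \code{realized_esd},
#'   \code{partial_corr_range}
#' @export
make_synthetic_truth <- function(spec) {
  g <- make_condition_graphs(spec)
  nodes <- synthetic_metabolite_ids(spec)
  pr_nd <- graph_to_precision(g$graph_ND, nodes,
                              spec$partial_corr_magnitude,
                              seed = spec$seed + 17L)
  pr_hfd <- graph_to_precision(g$graph_HFD, nodes,
                               spec$partial_corr_magnitude,
                               seed = spec$seed + 29L)
  structure(list(
    graphs = list(ND = g$graph_ND, HFD = g$graph_HFD),
    precision = list(ND = pr_nd$omega, HFD = pr_hfd$omega),
    differentiator_ids = nodes[seq_len(spec$differentiator_size)],
    phenotype_block_ids = nodes[spec$differentiator_size +
                                  seq_len(spec$phenotype_size)],
    shared_edges = g$shared_edges,
    realized_esd = g$realized_esd,
    partial_corr_range = range(c(pr_nd$partial_corr_range,
                                 pr_hfd$partial_corr_range), na.rm = TRUE)),
    class = "synthetic_truth")
}

#' One-call synthetic study
#'
#' Convenience wrapper: truth + table + metadata from a single spec.
#' @param spec a \code{synthetic_spec}
#' @return see \code{\link{sample_table}}
#' @export
simulate_study <- function(spec = synthetic_spec()) {
  sample_table(spec, make_synthetic_truth(spec))
}
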