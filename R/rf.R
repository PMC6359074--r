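#' Random-forest configuration
#'
#' @param ntree number of trees (default 1000)
#' @param mtry_grid candidate values for the number of variables tried at
#'   each split; tuning picks the grid value with the lowest out-of-bag
#'   error, breaking ties toward the value nearest
#'   \code{floor(sqrt(M))} (Breiman's recommendation) where M is the number
#'   of metabolites
#' @param mtry_selected chosen mtry (filled by \code{\link{tune_mtry}})
#' @param seed base seed; tuning uses \code{seed + grid index} per value
#' @return object of class \code{rf_config}
#' @export
rf_config <- function(ntree = 1000, mtry_grid = c(5, 18, 100, 250, 350),
                      mtry_selected = NULL, seed = 1L) {
  stopifnot(ntree >= 1, all(mtry_grid >= 1))
  structure(list(ntree = as.integer(ntree),
                 mtry_grid = as.integer(mtry_grid),
                 mtry_selected = if (is.null(mtry_selected)) NULL
                 else as.integer(mtry_selected),
                 seed = as.integer(seed),
                 tuning = NULL),
            class = "rf_config")
}

rf_xy <- function(table, labels) {
  x <- if (inherits(table, "abundance_table")) table$values else
    as.matrix(table)
  if (anyNA(x)) stop("table has missing values; impute first")
  y <- droplevels(factor(labels))
  if (length(y) != nrow(x)) stop("labels not aligned with table rows")
  if (nlevels(y) < 2) stop("need at least 2 classes")
  if (any(table(y) < 2))
    stop("class with a single sample; out-of-bag error undefined")
  list(x = x, y = y)
}

#' Tune mtry by out-of-bag error over a grid
#'
#' Fits one forest per grid value (seed offset by grid position so runs are
#' reproducible) and selects the value with minimal OOB error; ties are
#' broken toward the grid value nearest \code{floor(sqrt(M))}, then toward
#' the smaller value.
#'
#' @param table \code{abundance_table} (imputed, log scale) or numeric matrix
#' @param labels class labels aligned with rows
#' @param config an \code{rf_config}
#' @return the config with \code{mtry_selected} set and a \code{tuning}
#'   data frame (\code{mtry}, \code{oob_error}, \code{seed})
#' @export
tune_mtry <- function(table, labels, config = rf_config()) {
  d <- rf_xy(table, labels)
  M <- ncol(d$x)
  if (any(config$mtry_grid > M))
    stop("mtry grid value exceeds number of metabolites (",
         paste(config$mtry_grid[config$mtry_grid > M], collapse = ", "),
         " > ", M, ")")
  oob <- numeric(length(config$mtry_grid))
  for (i in seq_along(config$mtry_grid)) {
    set.seed(config$seed + i)
    fit <- randomForest::randomForest(d$x, d$y, ntree = config$ntree,
                                      mtry = config$mtry_grid[i])
    oob[i] <- fit$err.rate[config$ntree, "OOB"]
  }
  anchor <- floor(sqrt(M))
  best <- which(oob == min(oob))
  if (length(best) > 1) {
    dist <- abs(config$mtry_grid[best] - anchor)
    best <- best[dist == min(dist)]
    best <- best[which.min(config$mtry_grid[best])]
  }
  config$mtry_selected <- config$mtry_grid[best]
  config$tuning <- data.frame(mtry = config$mtry_grid, oob_error = oob,
                              seed = config$seed + seq_along(config$mtry_grid))
  config
}

#' Fit a random-forest classifier with OOB error and permutation importance
#'
#' Bootstrap-per-tree ensemble via \pkg{randomForest}; the out-of-bag error
#' uses, for each sample, only the trees whose bootstrap excluded it, so no
#' validation set is needed. Permutation importance (mean decrease in OOB
#' accuracy when a variable's values are shuffled among a tree's out-of-bag
#' samples) is computed during fitting, both raw and divided by its standard
#' error.
#'
#' @inheritParams tune_mtry
#' @return object of class \code{rf_fit}: \code{oob_error},
#'   \code{per_class_error}, \code{confusion}, \code{importance} (data
#'   frame: \code{metabolite}, \code{raw}, \code{scaled}, \code{rank}),
#'   \code{oob_votes}, \code{config}, and the underlying \code{forest}.
#' @export
fit_forest <- function(table, labels, config = rf_config()) {
  d <- rf_xy(table, labels)
  mtry <- if (!is.null(config$mtry_selected)) config$mtry_selected else
    max(1L, floor(sqrt(ncol(d$x))))
  if (mtry > ncol(d$x)) stop("mtry exceeds number of metabolites")
  set.seed(config$seed)
  fit <- randomForest::randomForest(d$x, d$y, ntree = config$ntree,
                                    mtry = mtry, importance = TRUE,
                                    keep.inbag = TRUE)
  conf <- fit$confusion
  k <- nlevels(d$y)
  per_class <- conf[, "class.error"]
  raw <- randomForest::importance(fit, type = 1, scale = FALSE)[, 1]
  scaled <- randomForest::importance(fit, type = 1, scale = TRUE)[, 1]
  imp <- data.frame(metabolite = names(raw),
                    raw = unname(raw), scaled = unname(scaled),
                    stringsAsFactors = FALSE)
  imp <- imp[order(-imp$scaled), ]
  imp$rank <- seq_len(nrow(imp))
  rownames(imp) <- NULL
  structure(list(oob_error = unname(fit$err.rate[config$ntree, "OOB"]),
                 per_class_error = per_class,
                 confusion = conf[, seq_len(k), drop = FALSE],
                 importance = imp,
                 oob_votes = fit$votes,
                 config = config,
                 mtry = mtry,
                 forest = fit),
            class = "rf_fit")
}

#' @export
print.rf_fit <- function(x, ...) {
  cat(sprintf("Random forest: %d trees, mtry = %d, OOB error = %.2f%%\n",
              x$config$ntree, x$mtry, 100 * x$oob_error))
  cat("Per-class error:",
      paste(sprintf("%s = %.3f", names(x$per_class_error),
                    x$per_class_error), collapse = ", "), "\n")
  invisible(x)
}

#' Permutation importance table of a fitted forest
#'
#' Mean decrease in out-of-bag accuracy under per-tree permutation of each
#' metabolite among that tree's OOB samples; reported raw and SD-scaled
#' (raw divided by its standard error over trees). Ranking is by the scaled
#' variant, the customary display.
#'
#' @param fit an \code{rf_fit}
#' @param k optionally return only the top k metabolites
#' @return data frame \code{metabolite}, \code{raw}, \code{scaled},
#'   \code{rank}
#' @export
permutation_importance <- function(fit, k = NULL) {
  stopifnot(inherits(fit, "rf_fit"))
  imp <- fit$importance
  if (!is.null(k)) imp <- imp[seq_len(min(k, nrow(imp))), , drop = FALSE]
  imp
}

#' Ward clustering of the top-k important metabolites
#'
#' Z-scores the selected metabolites' log abundances across samples and
#' applies Ward agglomeration (on Euclidean distance) to both the metabolite
#' and the sample axis — the heat-map layout — with a cut into
#' \code{n_clusters} metabolite clusters.
#'
#' @param table \code{abundance_table} (imputed, log scale) or matrix
#' @param importance importance data frame from
#'   \code{\link{permutation_importance}} (or a character vector of
#'   metabolite names)
#' @param k number of top metabolites to cluster (default 10)
#' @param n_clusters number of metabolite clusters to cut (default 3)
#' @return list: \code{z} (samples x k z-score matrix),
#'   \code{metabolite_hclust}, \code{sample_hclust}, \code{metabolite_order},
#'   \code{sample_order}, \code{metabolite_clusters}, \code{sample_clusters}
#' @export
top_k_and_ward <- function(table, importance, k = 10, n_clusters = 3) {
  x <- if (inherits(table, "abundance_table")) table$values else
    as.matrix(table)
  if (k < 2) stop("k must be at least 2")
  if (k > ncol(x)) stop("k exceeds number of metabolites")
  sel <- if (is.character(importance)) importance else
    importance$metabolite[order(importance$rank)]
  sel <- utils::head(sel, k)
  z <- scale(x[, sel, drop = FALSE])
  z[, attr(z, "scaled:scale") == 0] <- 0  # constant columns: z-score 0
  dm <- stats::dist(t(z)); ds <- stats::dist(z)
  if (all(dm < .Machine$double.eps^0.5) || all(ds < .Machine$double.eps^0.5))
    warning("degenerate zero-distance configuration; clustering arbitrary")
  hm <- stats::hclust(dm, method = "ward.D2")
  hs <- stats::hclust(ds, method = "ward.D2")
  list(z = z,
       metabolite_hclust = hm, sample_hclust = hs,
       metabolite_order = hm$labels[hm$order],
       sample_order = hs$labels[hs$order],
       metabolite_clusters = stats::cutree(hm, k = min(n_clusters, k)),
       sample_clusters = stats::cutree(hs, k = min(n_clusters, nrow(z))))
}

#' Restrict to the two extreme reaction-norm classes
#'
#' The phenotype contrast uses only samples in the \code{N_gt_HF} and
#' \code{N_lt_HF} classes; the no-change class is excluded.
#' @param table an \code{abundance_table}
#' @param meta metadata with \code{reaction_norm}
#' @return list of aligned \code{table} and \code{meta}
#' @export
extreme_reaction_norms <- function(table, meta) {
  if (!"reaction_norm" %in% names(meta))
    stop("metadata lacks reaction_norm")
  keep <- meta$reaction_norm %in% c("N_gt_HF", "N_lt_HF")
  out <- subset_samples(table, meta, keep)
  out$meta$reaction_norm <- droplevels(out$meta$reaction_norm)
  out
}
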