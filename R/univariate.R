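#' Per-metabolite two-way ANOVA with post hoc reaction-norm contrast
#'
#' Fixed-effects two-way ANOVA of each metabolite's log abundance on diet,
#' reaction-norm class and their interaction, with Type-II sums of squares
#' (appropriate for the unbalanced genotype design), plus a post hoc
#' two-sample t-test between the two extreme reaction-norm classes.
#' Benjamini-Hochberg q-values are reported alongside every raw p.
#'
#' @param table imputed, log-scale \code{abundance_table} or matrix
#' @param meta metadata with \code{diet} and \code{reaction_norm} aligned to
#'   rows (matched by \code{sample_id} when present)
#' @return data frame, one row per metabolite: F and p for diet,
#'   reaction_norm and interaction, the post hoc t and p, and \code{q_*}
#'   columns
#' @export
anova_two_way <- function(table, meta) {
  x <- if (inherits(table, "abundance_table")) table$values else
    as.matrix(table)
  meta <- align_meta(x, meta)
  diet <- droplevels(factor(meta$diet))
  rn <- droplevels(factor(meta$reaction_norm))
  if (nlevels(diet) < 2) stop("diet has a single level")
  if (nlevels(rn) < 2) stop("reaction_norm has a single level")
  ext <- rn %in% c("N_gt_HF", "N_lt_HF")
  res <- lapply(colnames(x), function(m) {
    y <- x[, m]
    fit <- stats::lm(y ~ diet * rn)
    a2 <- car::Anova(fit, type = 2)
    rn_t <- if (sum(ext) >= 4 && length(unique(rn[ext])) == 2) {
      tt <- stats::t.test(y[ext & rn == "N_gt_HF"],
                          y[ext & rn == "N_lt_HF"])
      c(tt$statistic, tt$p.value)
    } else c(NA_real_, NA_real_)
    data.frame(metabolite = m,
               F_diet = a2["diet", "F value"],
               p_diet = a2["diet", "Pr(>F)"],
               F_rn = a2["rn", "F value"],
               p_rn = a2["rn", "Pr(>F)"],
               F_interaction = a2["diet:rn", "F value"],
               p_interaction = a2["diet:rn", "Pr(>F)"],
               t_posthoc = rn_t[1], p_posthoc = rn_t[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  for (col in c("p_diet", "p_rn", "p_interaction", "p_posthoc"))
    out[[sub("^p_", "q_", col)]] <- stats::p.adjust(out[[col]], "BH")
  rownames(out) <- NULL
  out
}

align_meta <- function(x, meta) {
  if ("sample_id" %in% names(meta) && !is.null(rownames(x))) {
    if (!all(rownames(x) %in% meta$sample_id))
      stop("samples missing from metadata: ",
           paste(utils::head(setdiff(rownames(x), meta$sample_id), 5),
                 collapse = ", "))
    meta <- meta[match(rownames(x), meta$sample_id), , drop = FALSE]
  } else if (nrow(meta) != nrow(x))
    stop("metadata not aligned with table rows")
  meta
}

#' Per-metabolite regression on triglyceride level
#'
#' Ordinary least squares of each metabolite's log abundance on the
#' sample-level triglyceride concentration, across all treatments; the sign
#' of r identifies negatively correlated compounds.
#'
#' @inheritParams anova_two_way
#' @return data frame: \code{metabolite}, \code{slope}, \code{r}, \code{p},
#'   \code{q}
#' @export
triglyceride_regression <- function(table, meta) {
  x <- if (inherits(table, "abundance_table")) table$values else
    as.matrix(table)
  meta <- align_meta(x, meta)
  trig <- meta$triglyceride
  if (is.null(trig) || anyNA(trig))
    stop("triglyceride must be present for all samples used")
  if (stats::sd(trig) == 0) stop("triglyceride is constant; regression undefined")
  n <- length(trig)
  res <- lapply(colnames(x), function(m) {
    y <- x[, m]
    if (stats::sd(y) == 0)
      return(data.frame(metabolite = m, slope = 0, r = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    fit <- stats::lm(y ~ trig)
    r <- stats::cor(y, trig)
    p <- if (abs(r) < 1) correlation_pvalue(r, n) else 0
    data.frame(metabolite = m, slope = unname(stats::coef(fit)[2]),
               r = r, p = as.numeric(p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, "BH")
  rownames(out) <- NULL
  out
}

#' Assign a reaction-norm class from paired triglyceride phenotypes
#'
#' A genotype is classed \code{N_lt_HF} when it stores at least
#' \code{100*threshold_fraction}\% more triglyceride on the high-fat diet
#' than on the normal diet, \code{N_gt_HF} for the reverse, and \code{zero}
#' when neither diet changes storage by that much.
#'
#' @param trig_nd,trig_hfd positive triglyceride levels on each diet
#'   (vectorized)
#' @param threshold_fraction relative-change rule (default 0.25)
#' @return factor with levels \code{N_gt_HF}, \code{zero}, \code{N_lt_HF}
#' @examples
#' assign_reaction_norm(100, 130)  # N_lt_HF: 130 >= 125
#' @export
assign_reaction_norm <- function(trig_nd, trig_hfd,
                                 threshold_fraction = 0.25) {
  if (any(trig_nd <= 0) || any(trig_hfd <= 0))
    stop("triglyceride levels must be positive")
  f <- 1 + threshold_fraction
  cls <- ifelse(trig_hfd >= f * trig_nd, "N_lt_HF",
                ifelse(trig_nd >= f * trig_hfd, "N_gt_HF", "zero"))
  factor(cls, levels = c("N_gt_HF", "zero", "N_lt_HF"))
}

#' PCA of samples over a metabolite subset
#'
#' Centered (and by default scaled, i.e. correlation-matrix) principal
#' component analysis of the samples, optionally restricted to a metabolite
#' subset such as the top importance hits.
#'
#' @param table imputed, log-scale \code{abundance_table} or matrix
#' @param subset_metabolites optional character vector of metabolite ids
#' @param scale. scale columns to unit variance (default TRUE)
#' @return list: \code{scores} (samples x components), \code{loadings},
#'   \code{variance_fraction}
#' @export
pca_scores <- function(table, subset_metabolites = NULL, scale. = TRUE) {
  x <- if (inherits(table, "abundance_table")) table$values else
    as.matrix(table)
  if (!is.null(subset_metabolites)) {
    missing_m <- setdiff(subset_metabolites, colnames(x))
    if (length(missing_m))
      stop("unknown metabolite(s): ",
           paste(utils::head(missing_m, 5), collapse = ", "))
    x <- x[, subset_metabolites, drop = FALSE]
  }
  if (ncol(x) < 2) stop("need at least 2 metabolites")
  if (nrow(x) < 2) stop("need at least 2 samples")
  sds <- apply(x, 2, stats::sd)
  if (scale. && any(sds == 0)) {
    warning("dropping zero-variance column(s) before scaled PCA")
    x <- x[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = scale.)
  list(scores = pc$x, loadings = pc$rotation,
       variance_fraction = pc$sdev^2 / sum(pc$sdev^2))
}

#' Overlap between importance and significance hit lists
#'
#' The set comparison used to contrast the forest's top-importance
#' metabolites with the ANOVA-significant ones: of the k significant
#' metabolites, how many are absent from the k most important.
#'
#' @param importance importance data frame (\code{metabolite}, \code{rank})
#' @param pvalues named vector of per-metabolite raw p-values
#' @param alpha raw significance threshold (default 0.05)
#' @return list: \code{n_significant}, \code{n_important_considered},
#'   \code{significant_not_important}, \code{overlap}
#' @export
importance_significance_overlap <- function(importance, pvalues,
                                            alpha = 0.05) {
  sig <- names(pvalues)[!is.na(pvalues) & pvalues < alpha]
  k <- length(sig)
  top <- importance$metabolite[order(importance$rank)][seq_len(min(k, nrow(importance)))]
  list(n_significant = k,
       n_important_considered = length(top),
       significant_not_important = sum(!(sig %in% top)),
       overlap = sum(sig %in% top))
}
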