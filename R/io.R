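#' Sample-by-metabolite abundance table
#'
#' Container for an untargeted-metabolomics feature table: an n x p matrix of
#' relative abundances (arbitrary units, nonnegative; missing values allowed
#' and kept as \code{NA}, never silently zeroed) plus per-metabolite
#' annotation.
#'
#' @param values numeric matrix, samples in rows, metabolites in columns,
#'   with row and column names.
#' @param annotations optional data frame with one row per metabolite
#'   (columns such as \code{display_name}, \code{id_status} in
#'   \{"known","unknown"\}, \code{class_label}).
#' @param log_transformed has the table been log-transformed already?
#' @return object of class \code{abundance_table} with fields
#'   \code{values}, \code{sample_ids}, \code{metabolite_ids},
#'   \code{annotations}, \code{log_transformed}, \code{log_base}.
#' @export
abundance_table <- function(values, annotations = NULL,
                            log_transformed = FALSE) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry sample (row) and metabolite (column) names")
  sample_ids <- trimws(rownames(values))
  metabolite_ids <- trimws(colnames(values))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(metabolite_ids))
    stop("duplicate metabolite ids: ",
         paste(unique(metabolite_ids[duplicated(metabolite_ids)]),
               collapse = ", "))
  storage.mode(values) <- "double"
  rownames(values) <- sample_ids
  colnames(values) <- metabolite_ids
  if (!log_transformed && any(values < 0, na.rm = TRUE))
    stop("negative abundance values in a non-log table")
  if (is.null(annotations)) {
    annotations <- data.frame(metabolite_id = metabolite_ids,
                              display_name = metabolite_ids,
                              id_status = "known",
                              class_label = NA_character_,
                              stringsAsFactors = FALSE)
  } else {
    if (nrow(annotations) != length(metabolite_ids))
      stop("annotations must have one row per metabolite")
  }
  structure(list(values = values,
                 sample_ids = sample_ids,
                 metabolite_ids = metabolite_ids,
                 annotations = annotations,
                 log_transformed = log_transformed,
                 log_base = NA_real_),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("Abundance table:", length(x$sample_ids), "samples x",
      length(x$metabolite_ids), "metabolites;",
      sum(is.na(x$values)), "missing cells;",
      if (x$log_transformed) sprintf("log base %.4g", x$log_base)
      else "raw scale", "\n")
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Read an abundance table from TSV/CSV
#'
#' Expects a header row and a first column of identifiers
#' (\code{sample_id} when samples are in rows, the default; set
#' \code{orientation = "metabolites_in_rows"} for the transposed layout).
#' Cells matching \code{missing_token} (or empty) are recorded as missing,
#' not zero. The delimiter is inferred from the file extension
#' (\code{.csv} vs anything else = TSV) unless given.
#'
#' @param path file path
#' @param orientation \code{"samples_in_rows"} or \code{"metabolites_in_rows"}
#' @param missing_token strings to treat as missing (empty cells always are)
#' @param sep field delimiter; \code{NULL} to infer from the extension
#' @param log_transformed set when the file holds already log-transformed
#'   values (negative entries allowed)
#' @return an \code{abundance_table}
#' @export
read_abundance_table <- function(path,
                                 orientation = c("samples_in_rows",
                                                 "metabolites_in_rows"),
                                 missing_token = c("NA", "NaN"),
                                 sep = NULL, log_transformed = FALSE) {
  orientation <- match.arg(orientation)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c(missing_token, ""),
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  if (ncol(df) < 2) stop("malformed header in ", path)
  ids <- trimws(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate row ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cn <- trimws(names(df)[-1])
  if (anyDuplicated(cn))
    stop("duplicate column ids in ", path, ": ",
         paste(unique(cn[duplicated(cn)]), collapse = ", "))
  cells <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(is.na(num) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell at row '%s', column '%s' in %s",
                 ids[bad[1, 1]], cn[bad[1, 2]], path))
  dimnames(num) <- list(ids, cn)
  if (orientation == "metabolites_in_rows") num <- t(num)
  abundance_table(num, log_transformed = log_transformed)
}

#' @rdname read_abundance_table
#' @param table an \code{abundance_table}
#' @export
write_abundance_table <- function(table, path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(sample_id = table$sample_ids,
                   table$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read sample metadata
#'
#' TSV with columns \code{sample_id}, \code{diet} (ND/HFD) and optionally
#' \code{genotype}, \code{reaction_norm} (N_gt_HF / zero / N_lt_HF),
#' \code{triglyceride}.
#' @param path file path
#' @return data frame with those columns, \code{diet} and
#'   \code{reaction_norm} as factors
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("sample_id", "diet")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metadata missing required column(s): ", paste(miss, collapse = ", "))
  df$sample_id <- trimws(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in metadata")
  if (!all(df$diet %in% c("ND", "HFD")))
    stop("diet must be ND or HFD")
  df$diet <- factor(df$diet, levels = c("ND", "HFD"))
  if ("reaction_norm" %in% names(df)) {
    ok <- is.na(df$reaction_norm) |
      df$reaction_norm %in% c("N_gt_HF", "zero", "N_lt_HF")
    if (!all(ok)) stop("reaction_norm must be N_gt_HF, zero or N_lt_HF")
    df$reaction_norm <- factor(df$reaction_norm,
                               levels = c("N_gt_HF", "zero", "N_lt_HF"))
  }
  df
}

#' @rdname read_sample_metadata
#' @param meta metadata data frame
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Minimum-value imputation and log transform
#'
#' Each missing cell is imputed to the minimum observed (non-missing) value
#' of that metabolite across all retained samples — the conventional
#' stand-in for values below the instrument detection limit — and the whole
#' table is then log-transformed.
#'
#' @param table an \code{abundance_table} on the raw (positive) scale
#' @param log_base base of the logarithm (default natural log)
#' @return a list with \code{table} (imputed, log scale) and \code{report},
#'   a \code{preprocess_report} recording every imputed cell and the
#'   per-metabolite imputation value.
#' @export
impute_min_and_log <- function(table, log_base = exp(1)) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$log_transformed) stop("table is already log-transformed")
  v <- table$values
  all_missing <- colSums(!is.na(v)) == 0L
  if (any(all_missing))
    stop("metabolite(s) with no observed values: ",
         paste(table$metabolite_ids[all_missing], collapse = ", "))
  if (any(v <= 0, na.rm = TRUE))
    stop("nonpositive observed abundance; log transform undefined")
  col_min <- apply(v, 2, min, na.rm = TRUE)
  na_idx <- which(is.na(v), arr.ind = TRUE)
  if (nrow(na_idx)) v[na_idx] <- col_min[na_idx[, 2]]
  v <- log(v, base = log_base)
  out <- table
  out$values <- v
  out$log_transformed <- TRUE
  out$log_base <- log_base
  report <- structure(list(
    imputed_cell_count = nrow(na_idx),
    imputed_cells = data.frame(
      sample_id = table$sample_ids[na_idx[, 1]],
      metabolite_id = table$metabolite_ids[na_idx[, 2]],
      imputed_value = unname(col_min[na_idx[, 2]]),
      stringsAsFactors = FALSE),
    imputation_value_per_metabolite = col_min,
    removed_samples = data.frame(sample_id = character(0),
                                 outlier_score = numeric(0)),
    log_base = log_base), class = "preprocess_report")
  list(table = out, report = report)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("Preprocess report:", x$imputed_cell_count, "cells imputed;",
      nrow(x$removed_samples), "samples flagged/removed; log base",
      format(x$log_base, digits = 4), "\n")
  invisible(x)
}

#' Flag outlier samples by robust z-score of per-sample median abundance
#'
#' Scores each sample by the robust z-score (median/MAD across samples) of
#' its median log abundance. Samples with score above the cutoff are
#' flagged; nothing is removed — removal is an explicit caller action via
#' \code{\link{drop_samples}}.
#'
#' @param table an imputed, log-transformed \code{abundance_table}
#' @param robust_z_cutoff flag threshold (default 5)
#' @return data frame with \code{sample_id}, \code{outlier_score},
#'   \code{flagged}
#' @export
flag_outlier_samples <- function(table, robust_z_cutoff = 5) {
  stopifnot(inherits(table, "abundance_table"))
  if (!table$log_transformed)
    stop("flag_outlier_samples expects an imputed, log-transformed table")
  n <- length(table$sample_ids)
  if (n < 4) stop("need at least 4 samples for robust outlier scores")
  med <- apply(table$values, 1, stats::median, na.rm = TRUE)
  ctr <- stats::median(med)
  scale <- stats::mad(med)
  score <- if (scale == 0) ifelse(med == ctr, 0, Inf) else
    abs(med - ctr) / scale
  data.frame(sample_id = table$sample_ids,
             outlier_score = unname(score),
             flagged = unname(score > robust_z_cutoff),
             stringsAsFactors = FALSE)
}

#' Drop samples from a table (explicit removal step)
#' @param table an \code{abundance_table}
#' @param sample_ids ids to remove
#' @return the table without those samples
#' @export
drop_samples <- function(table, sample_ids) {
  keep <- !(table$sample_ids %in% sample_ids)
  out <- table
  out$values <- table$values[keep, , drop = FALSE]
  out$sample_ids <- table$sample_ids[keep]
  out
}

#' Subset a table's samples and align metadata
#' @param table an \code{abundance_table}
#' @param meta metadata data frame with \code{sample_id}
#' @param keep logical or character selector over metadata rows
#' @return list of \code{table} and \code{meta}, samples aligned and in the
#'   same order
#' @export
subset_samples <- function(table, meta, keep = rep(TRUE, nrow(meta))) {
  meta <- meta[keep, , drop = FALSE]
  ids <- intersect(table$sample_ids, meta$sample_id)
  meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
  out <- table
  sel <- match(ids, table$sample_ids)
  out$values <- table$values[sel, , drop = FALSE]
  out$sample_ids <- ids
  rownames(meta) <- NULL
  list(table = out, meta = meta)
}
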