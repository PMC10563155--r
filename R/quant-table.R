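# The quant_table container: a feature x sample intensity matrix with
# feature annotation (protein mapping, peptide support, contaminant/ligand
# flags) and a sample design (condition, replicate). Missing values are NA,
# never zero; zeros in input files are read as missing, following the
# convention of label-free search-engine output tables.

.parse_sample_names <- function(x) {
  m <- regmatches(x, regexec("^(.+)_rep([0-9]+)$", x))
  bad <- x[vapply(m, length, integer(1L)) == 0L]
  if (length(bad) > 0L) {
    stop("unparsable sample column name(s): ", paste(bad, collapse = ", "),
         " (expected <condition>_rep<k>)", call. = FALSE)
  }
  data.frame(
    sample = x,
    condition = vapply(m, `[[`, character(1L), 2L),
    replicate = as.integer(vapply(m, `[[`, character(1L), 3L)),
    stringsAsFactors = FALSE
  )
}

#' Construct a quantification table
#'
#' Bundles a features-by-samples intensity matrix with feature annotation and
#' the experimental design. Sample columns are named `<condition>_rep<k>` and
#' the design is parsed from those names unless given explicitly.
#'
#' @param features Data frame with columns `feature_id`, `protein_id`,
#'   `n_peptides`, `is_contaminant`, `is_ligand` (missing annotation columns
#'   are filled with defaults).
#' @param intensities Numeric matrix, features x samples; `NA` = missing.
#'   Must be strictly positive where observed on the linear scale.
#' @param samples Optional data frame with columns `sample`, `condition`,
#'   `replicate`; derived from `colnames(intensities)` when `NULL`.
#' @param level `"protein"` or `"peptide"`.
#' @param log2 Whether `intensities` are already log2-transformed.
#' @return An object of class `quant_table`.
#' @export
quant_table <- function(features, intensities, samples = NULL,
                        level = c("protein", "peptide"), log2 = FALSE) {
  level <- match.arg(level)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (is.null(features$feature_id)) {
    stop("features must have a feature_id column", call. = FALSE)
  }
  if (anyDuplicated(features$feature_id)) {
    dup <- unique(features$feature_id[duplicated(features$feature_id)])
    stop("duplicate feature id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(features$protein_id)) features$protein_id <- features$feature_id
  if (is.null(features$n_peptides)) features$n_peptides <- 1L
  if (is.null(features$is_contaminant)) features$is_contaminant <- FALSE
  if (is.null(features$is_ligand)) features$is_ligand <- FALSE
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (nrow(intensities) != nrow(features)) {
    stop("features and intensities disagree on the number of rows",
         call. = FALSE)
  }
  if (!log2 && any(intensities <= 0, na.rm = TRUE)) {
    stop("linear-scale intensities must be positive where observed",
         call. = FALSE)
  }
  if (is.null(samples)) {
    if (is.null(colnames(intensities))) {
      stop("intensities need sample column names or an explicit design",
           call. = FALSE)
    }
    samples <- .parse_sample_names(colnames(intensities))
  } else {
    samples <- as.data.frame(samples, stringsAsFactors = FALSE)
    stopifnot(all(c("sample", "condition", "replicate") %in% names(samples)),
              nrow(samples) == ncol(intensities))
  }
  if (anyDuplicated(samples[c("condition", "replicate")])) {
    stop("replicate indices must be distinct within a condition",
         call. = FALSE)
  }
  rownames(intensities) <- features$feature_id
  colnames(intensities) <- samples$sample
  rownames(features) <- NULL
  rownames(samples) <- NULL
  structure(
    list(features = features, intensities = intensities, samples = samples,
         level = level, log2 = log2),
    class = "quant_table"
  )
}

#' @export
print.quant_table <- function(x, ...) {
  n_missing <- sum(is.na(x$intensities))
  cat(sprintf(
    "<quant_table> %s-level, %d features x %d samples (%s scale)\n",
    x$level, nrow(x$intensities), ncol(x$intensities),
    if (x$log2) "log2" else "linear"
  ))
  cat(sprintf("  conditions: %s\n",
              paste(sprintf("%s (n=%d)",
                            unique(x$samples$condition),
                            tabulate(factor(x$samples$condition,
                                            unique(x$samples$condition)))),
                    collapse = ", ")))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", n_missing,
              100 * n_missing / length(x$intensities)))
  cat(sprintf("  contaminants: %d, ligand features: %d\n",
              sum(x$features$is_contaminant), sum(x$features$is_ligand)))
  invisible(x)
}

#' @export
dim.quant_table <- function(x) dim(x$intensities)

#' @export
summary.quant_table <- function(object, ...) {
  obs <- colSums(!is.na(object$intensities))
  data.frame(
    sample = object$samples$sample,
    condition = object$samples$condition,
    replicate = object$samples$replicate,
    n_observed = as.integer(obs),
    median_intensity = apply(object$intensities, 2, stats::median, na.rm = TRUE),
    row.names = NULL
  )
}

#' Restrict a quant table to a set of conditions
#'
#' @param x A [quant_table()].
#' @param conditions Character vector of condition labels to keep.
#' @param drop_empty Drop features unobserved in every kept sample.
#' @return A [quant_table()] with only the selected samples.
#' @export
subset_samples <- function(x, conditions, drop_empty = FALSE) {
  stopifnot(inherits(x, "quant_table"))
  keep <- x$samples$condition %in% conditions
  if (!any(keep)) {
    stop("no samples in condition(s): ", paste(conditions, collapse = ", "),
         call. = FALSE)
  }
  out <- x
  out$samples <- x$samples[keep, , drop = FALSE]
  rownames(out$samples) <- NULL
  out$intensities <- x$intensities[, keep, drop = FALSE]
  if (drop_empty) {
    nonempty <- rowSums(!is.na(out$intensities)) > 0L
    out$features <- out$features[nonempty, , drop = FALSE]
    rownames(out$features) <- NULL
    out$intensities <- out$intensities[nonempty, , drop = FALSE]
  }
  out
}

#' Log2-transform a quant table
#'
#' @param x A linear-scale [quant_table()].
#' @return The table with log2 intensities.
#' @export
log2_transform <- function(x) {
  stopifnot(inherits(x, "quant_table"))
  if (x$log2) {
    stop("table is already log2-transformed", call. = FALSE)
  }
  x$intensities <- log2(x$intensities)
  x$log2 <- TRUE
  x
}

# Linear-scale intensities of a table regardless of its stored scale.
.linear_intensities <- function(x) {
  if (x$log2) 2^x$intensities else x$intensities
}

#' Read a quantification TSV
#'
#' Reads the package's tab-separated quantification dialect (modelled on
#' label-free search-engine summary tables): annotation columns
#' `feature_id`, `protein_id`, `n_peptides`, `is_contaminant`, `is_ligand`,
#' followed by one intensity column per sample named `<condition>_rep<k>`.
#' Zeros and blanks are read as missing.
#'
#' @param path File path.
#' @param level `"protein"` or `"peptide"`.
#' @param col_map Optional named character vector mapping this dialect's
#'   annotation column names to the names used in the file, e.g.
#'   `c(feature_id = "Protein", protein_id = "Protein ID")`, for ingesting
#'   third-party tables.
#' @return A linear-scale [quant_table()].
#' @export
read_quant_tsv <- function(path, level = c("protein", "peptide"),
                           col_map = NULL) {
  level <- match.arg(level)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      if (col_map[[std]] %in% names(df)) {
        names(df)[names(df) == col_map[[std]]] <- std
      }
    }
  }
  anno_cols <- c("feature_id", "protein_id", "n_peptides",
                 "is_contaminant", "is_ligand")
  if (!"feature_id" %in% names(df)) {
    stop("'", path, "' has no feature_id column", call. = FALSE)
  }
  sample_cols <- setdiff(names(df), anno_cols)
  ints <- as.matrix(df[, sample_cols, drop = FALSE])
  storage.mode(ints) <- "double"
  ints[!is.na(ints) & ints == 0] <- NA_real_
  features <- df[, intersect(anno_cols, names(df)), drop = FALSE]
  if (!is.null(features$is_contaminant)) {
    features$is_contaminant <- as.logical(features$is_contaminant)
  }
  if (!is.null(features$is_ligand)) {
    features$is_ligand <- as.logical(features$is_ligand)
  }
  quant_table(features, ints, level = level)
}

#' Write a quantification TSV
#'
#' Inverse of [read_quant_tsv()]: writes annotation columns followed by one
#' intensity column per sample; missing cells are written as 0 and floats at
#' 6 significant digits, so a write/read round trip is lossless at that
#' precision.
#'
#' @param x A linear-scale [quant_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_quant_tsv <- function(x, path) {
  stopifnot(inherits(x, "quant_table"))
  if (x$log2) {
    stop("write_quant_tsv expects a linear-scale table", call. = FALSE)
  }
  ints <- signif(x$intensities, 6)
  ints[is.na(ints)] <- 0
  df <- cbind(
    x$features[c("feature_id", "protein_id", "n_peptides",
                 "is_contaminant", "is_ligand")],
    as.data.frame(ints, check.names = FALSE)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
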