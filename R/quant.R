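# Label-free quantification post-processing: protein filtering, pairwise
# ratio-mode normalization, downshifted-Gaussian imputation, replicate
# metrics and ligand contamination accounting.

#' Filter a protein table for quantification
#'
#' Keeps proteins that are not contaminants, were identified with at least
#' `min_peptides` peptides, and were quantified in at least `min_reps`
#' replicates of at least one condition. Row order is preserved; the filter
#' is idempotent.
#'
#' @param x A protein-level [quant_table()].
#' @param min_peptides Minimum peptide support per protein (default 2).
#' @param min_reps Minimum observed replicates in some condition (default 2).
#' @return The filtered [quant_table()].
#' @export
filter_proteins <- function(x, min_peptides = 2L, min_reps = 2L) {
  stopifnot(inherits(x, "quant_table"))
  if (x$level != "protein") {
    stop("filter_proteins requires a protein-level table", call. = FALSE)
  }
  observed <- !is.na(x$intensities)
  conds <- unique(x$samples$condition)
  reps_per_cond <- vapply(conds, function(cc) {
    apply(observed[, x$samples$condition == cc, drop = FALSE], 1, sum)
  }, numeric(nrow(observed)))
  if (is.null(dim(reps_per_cond))) {
    reps_per_cond <- matrix(reps_per_cond, nrow = nrow(observed))
  }
  keep <- !x$features$is_contaminant &
    x$features$n_peptides >= min_peptides &
    apply(reps_per_cond, 1, max) >= min_reps
  out <- x
  out$features <- x$features[keep, , drop = FALSE]
  rownames(out$features) <- NULL
  out$intensities <- x$intensities[keep, , drop = FALSE]
  out
}

# KDE mode of a numeric vector: Gaussian kernel, Silverman's rule-of-thumb
# bandwidth, argmax on a 512-point grid over the data range.
.kde_mode <- function(x) {
  # (near-)constant ratio vectors: the mode is the common value; the KDE
  # grid machinery degenerates there
  if (diff(range(x)) < 1e-8) {
    return(stats::median(x))
  }
  d <- stats::density(x, bw = "nrd0", n = 512L)
  d$x[[which.max(d$y)]]
}

#' Modes of all pairwise log2-ratio distributions
#'
#' For every ordered sample pair (i, j), the mode of the distribution of
#' per-protein log2 ratios `x[p, i] - x[p, j]` over proteins observed in
#' both samples, estimated by Gaussian kernel density (Silverman bandwidth)
#' maximized on a 512-point grid. The mode of the ratio distribution is the
#' systematic abundance offset between the two runs, robust to the minority
#' of genuinely changing proteins.
#'
#' @param x A log2-scale [quant_table()].
#' @param min_shared Pairs sharing fewer co-observed proteins than this are
#'   flagged with a warning (default 10); fewer than 2 is an error.
#' @return An antisymmetric (within grid tolerance) numeric matrix of modes,
#'   samples x samples.
#' @export
pairwise_ratio_modes <- function(x, min_shared = 10L) {
  stopifnot(inherits(x, "quant_table"))
  if (!x$log2) {
    stop("pairwise_ratio_modes requires a log2-transformed table",
         call. = FALSE)
  }
  s <- ncol(x$intensities)
  if (s < 2L) {
    stop("at least two samples are required", call. = FALSE)
  }
  modes <- matrix(0, s, s,
                  dimnames = list(x$samples$sample, x$samples$sample))
  for (i in seq_len(s)) {
    for (j in seq_len(s)) {
      if (i == j) next
      both <- !is.na(x$intensities[, i]) & !is.na(x$intensities[, j])
      if (sum(both) < 2L) {
        stop("samples ", x$samples$sample[[i]], " and ",
             x$samples$sample[[j]], " share fewer than 2 observed proteins",
             call. = FALSE)
      }
      if (sum(both) < min_shared) {
        warning("samples ", x$samples$sample[[i]], " and ",
                x$samples$sample[[j]], " share only ", sum(both),
                " observed proteins; mode estimate may be unstable",
                call. = FALSE)
      }
      modes[i, j] <- .kde_mode(x$intensities[both, i] - x$intensities[both, j])
    }
  }
  modes
}

#' Solve per-sample normalization factors from pairwise ratio modes
#'
#' Finds additive log2 factors f minimizing
#' `sum over pairs (f_i - f_j - m_ij)^2` subject to `sum(f) = 0`, i.e. the
#' global least-squares reconciliation of all pairwise offsets. Normalized
#' intensities are `x - f[sample]`.
#'
#' @param modes Square matrix of pairwise ratio modes as returned by
#'   [pairwise_ratio_modes()]; `NA` entries mark unavailable pairs. Only the
#'   upper triangle is used.
#' @return An object of class `mode_normalization` with components
#'   `factors` (named, zero-sum) and `modes`.
#' @export
solve_normalization_factors <- function(modes) {
  modes <- as.matrix(modes)
  s <- nrow(modes)
  stopifnot(ncol(modes) == s, s >= 2L)
  rows <- list()
  rhs <- numeric(0)
  for (i in seq_len(s - 1L)) {
    for (j in (i + 1L):s) {
      if (is.na(modes[i, j])) next
      r <- numeric(s)
      r[[i]] <- 1
      r[[j]] <- -1
      rows[[length(rows) + 1L]] <- r
      rhs <- c(rhs, modes[i, j])
    }
  }
  if (length(rows) == 0L) {
    stop("no usable pairwise modes", call. = FALSE)
  }
  a <- rbind(do.call(rbind, rows), rep(1, s))
  b <- c(rhs, 0)
  if (qr(a)$rank < s) {
    stop("pairwise modes do not connect all samples; ",
         "normalization factors are not identifiable", call. = FALSE)
  }
  f <- qr.solve(a, b)
  f <- f - mean(f)  # enforce the zero-sum constraint exactly
  names(f) <- colnames(modes)
  structure(list(factors = f, modes = modes), class = "mode_normalization")
}

#' @export
print.mode_normalization <- function(x, ...) {
  cat("<mode_normalization> per-sample log2 factors:\n")
  print(round(x$factors, 4))
  invisible(x)
}

#' Mode-normalize a quant table
#'
#' Runs [pairwise_ratio_modes()] and [solve_normalization_factors()] and
#' subtracts each sample's factor from its log2 intensities. The fitted
#' `mode_normalization` is stored in the returned table's `normalization`
#' element.
#'
#' @inheritParams pairwise_ratio_modes
#' @return The normalized [quant_table()].
#' @export
normalize_quant <- function(x, min_shared = 10L) {
  norm <- solve_normalization_factors(pairwise_ratio_modes(x, min_shared))
  x$intensities <- sweep(x$intensities, 2L, norm$factors)
  x$normalization <- norm
  x
}

#' Impute missing values from a downshifted Gaussian
#'
#' Left-censored (missing-not-at-random) imputation: for each sample,
#' missing values are drawn from
#' `Normal(median_s - downshift * sd_s, (width * sd_s)^2)` where `median_s`
#' and `sd_s` are the median and standard deviation of that sample's
#' observed log2 intensities. Observed cells are untouched.
#'
#' @param x A log2-scale (typically normalized) [quant_table()].
#' @param downshift Distribution center shift below the sample median, in
#'   sample standard deviations (default 1.8).
#' @param width Distribution width as a fraction of the sample standard
#'   deviation (default 0.3).
#' @param seed Optional integer seed for reproducible draws.
#' @return The table with no remaining missing cells.
#' @export
impute_missing <- function(x, downshift = 1.8, width = 0.3, seed = NULL) {
  stopifnot(inherits(x, "quant_table"), downshift >= 0, width > 0)
  if (!x$log2) {
    stop("impute_missing requires a log2-transformed table", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  for (s in seq_len(ncol(x$intensities))) {
    col <- x$intensities[, s]
    obs <- col[!is.na(col)]
    if (length(obs) < 3L) {
      stop("sample ", x$samples$sample[[s]], " has fewer than 3 observed ",
           "values; imputation parameters are undefined", call. = FALSE)
    }
    n_miss <- sum(is.na(col))
    if (n_miss > 0L) {
      mu <- stats::median(obs) - downshift * stats::sd(obs)
      sigma <- width * stats::sd(obs)
      x$intensities[is.na(col), s] <- stats::rnorm(n_miss, mu, sigma)
    }
  }
  x
}

# Match the samples of two tables into comparison pairs. Tables with the
# same condition set are matched on (condition, replicate); two
# single-condition tables are matched on replicate rank.
.match_sample_pairs <- function(a, b) {
  ca <- unique(a$samples$condition)
  cb <- unique(b$samples$condition)
  if (setequal(ca, cb)) {
    key_a <- paste(a$samples$condition, a$samples$replicate)
    key_b <- paste(b$samples$condition, b$samples$replicate)
    if (!setequal(key_a, key_b)) {
      stop("tables have the same conditions but different replicate layouts",
           call. = FALSE)
    }
    idx_b <- match(key_a, key_b)
    labels <- a$samples$sample
  } else if (length(ca) == 1L && length(cb) == 1L) {
    if (nrow(a$samples) != nrow(b$samples)) {
      stop("single-condition tables must have equal replicate counts",
           call. = FALSE)
    }
    ord_a <- order(a$samples$replicate)
    ord_b <- order(b$samples$replicate)
    idx_b <- integer(nrow(a$samples))
    idx_b[ord_a] <- ord_b
    labels <- paste0("rep", a$samples$replicate)
  } else {
    stop("cannot pair samples: condition sets differ", call. = FALSE)
  }
  list(idx_b = idx_b, labels = labels)
}

#' Log2 ratios between matched replicate pairs of two experiments
#'
#' Pairs each sample of `a` with the corresponding sample of `b` (replicate
#' 1 vs 1, 2 vs 2, ...) and returns per-protein log2 ratios `a - b` for
#' every pair in which both members were observed.
#'
#' @param a,b Protein-level log2-scale [quant_table()]s with matching
#'   designs (same conditions, or one condition each with equal replicate
#'   counts). Features are matched by `feature_id`.
#' @return Numeric matrix of ratios, shared features x replicate pairs;
#'   `NA` where either member of a pair was missing.
#' @export
replicate_pair_ratios <- function(a, b) {
  stopifnot(inherits(a, "quant_table"), inherits(b, "quant_table"))
  if (!a$log2 || !b$log2) {
    stop("replicate_pair_ratios requires log2-transformed tables",
         call. = FALSE)
  }
  shared <- intersect(a$features$feature_id, b$features$feature_id)
  pairing <- .match_sample_pairs(a, b)
  ia <- match(shared, a$features$feature_id)
  ib <- match(shared, b$features$feature_id)
  ratios <- a$intensities[ia, , drop = FALSE] -
    b$intensities[ib, pairing$idx_b, drop = FALSE]
  dimnames(ratios) <- list(shared, pairing$labels)
  ratios
}

#' Median of per-protein mean replicate ratios
#'
#' Summarizes a replicate-ratio matrix to one number: each protein's ratios
#' are averaged across replicate pairs, and the median over proteins is
#' returned. With `require_all_replicates = TRUE` (the default), proteins
#' missing any replicate pair are excluded before taking the median.
#'
#' @param ratios Matrix from [replicate_pair_ratios()].
#' @param require_all_replicates Exclude proteins not quantified in every
#'   replicate pair.
#' @return The median log2 ratio (scalar).
#' @export
median_ratio <- function(ratios, require_all_replicates = TRUE) {
  ratios <- as.matrix(ratios)
  if (require_all_replicates) {
    ratios <- ratios[stats::complete.cases(ratios), , drop = FALSE]
  }
  means <- rowMeans(ratios, na.rm = TRUE)
  stats::median(means[is.finite(means)])
}

#' Per-protein coefficient of variation across replicates
#'
#' CV = SD / mean of linear-scale intensities across a condition's
#' replicates (log2 tables are de-transformed first). Proteins observed in
#' fewer than two replicates of the condition are excluded.
#'
#' @param x A protein-level [quant_table()].
#' @param condition Condition label.
#' @return Named numeric vector of CVs for the eligible proteins.
#' @export
protein_cv <- function(x, condition) {
  stopifnot(inherits(x, "quant_table"))
  cols <- x$samples$condition == condition
  if (!any(cols)) {
    stop("no samples in condition '", condition, "'", call. = FALSE)
  }
  lin <- .linear_intensities(x)[, cols, drop = FALSE]
  n_obs <- rowSums(!is.na(lin))
  eligible <- n_obs >= 2L
  cv <- apply(lin[eligible, , drop = FALSE], 1, function(v) {
    v <- v[!is.na(v)]
    stats::sd(v) / mean(v)
  })
  names(cv) <- x$features$feature_id[eligible]
  cv
}

#' Count quantified proteins per condition
#'
#' Number of non-ligand, non-contaminant proteins observed in at least
#' `min_reps` replicates of each condition.
#'
#' @param x A protein-level [quant_table()].
#' @param min_reps Minimum observed replicates (default 2).
#' @return Named integer vector, one count per condition.
#' @export
count_quantified <- function(x, min_reps = 2L) {
  stopifnot(inherits(x, "quant_table"))
  real <- !x$features$is_ligand & !x$features$is_contaminant
  observed <- !is.na(x$intensities[real, , drop = FALSE])
  conds <- unique(x$samples$condition)
  counts <- vapply(conds, function(cc) {
    sum(rowSums(observed[, x$samples$condition == cc, drop = FALSE]) >=
          min_reps)
  }, integer(1L))
  names(counts) <- conds
  counts
}

#' Relative ligand peptide intensity per condition
#'
#' Quantifies ligand contamination: the `top_n` ligand peptides with the
#' highest mean intensity in the reference condition are selected, their
#' intensities are summed per sample (missing = 0), averaged across each
#' condition's replicates, and reported relative to the reference condition
#' (which is 1 by construction).
#'
#' @param x A peptide-level [quant_table()] with `is_ligand` flags
#'   (linear scale; log2 tables are de-transformed).
#' @param reference Reference condition label (e.g. the mock treatment).
#' @param top_n Number of top ligand peptides to track (default 5; 1 tracks
#'   only the most prominent peptide).
#' @return Named numeric vector of relative intensities, one per condition.
#' @export
ligand_contamination_report <- function(x, reference, top_n = 5L) {
  stopifnot(inherits(x, "quant_table"))
  if (x$level != "peptide") {
    stop("ligand_contamination_report requires a peptide-level table",
         call. = FALSE)
  }
  if (!reference %in% x$samples$condition) {
    stop("reference condition '", reference, "' not present", call. = FALSE)
  }
  lig <- which(x$features$is_ligand)
  if (length(lig) == 0L) {
    stop("table has no ligand peptides", call. = FALSE)
  }
  lin <- .linear_intensities(x)[lig, , drop = FALSE]
  lin[is.na(lin)] <- 0
  ref_cols <- x$samples$condition == reference
  ref_mean <- rowMeans(lin[, ref_cols, drop = FALSE])
  top <- order(ref_mean, decreasing = TRUE)[seq_len(min(top_n, length(lig)))]
  per_sample <- colSums(lin[top, , drop = FALSE])
  conds <- unique(x$samples$condition)
  per_cond <- vapply(conds, function(cc) {
    mean(per_sample[x$samples$condition == cc])
  }, numeric(1L))
  names(per_cond) <- conds
  ref_value <- per_cond[[reference]]
  if (ref_value == 0) {
    stop("reference condition has zero summed ligand intensity",
         call. = FALSE)
  }
  per_cond / ref_value
}

#' Roll peptide intensities up to protein intensities
#'
#' Protein intensity is the sum of the intensities of the peptides uniquely
#' mapped to it; peptides mapped to multiple proteins (';'-separated
#' `protein_id`) are dropped. A protein is missing in a sample when all of
#' its peptides are.
#'
#' @param x A peptide-level linear-scale [quant_table()].
#' @return A protein-level linear-scale [quant_table()]; `n_peptides` is the
#'   number of unique peptides per protein and the contaminant/ligand flags
#'   are inherited (any peptide flagged flags the protein).
#' @export
protein_from_peptides <- function(x) {
  stopifnot(inherits(x, "quant_table"))
  if (x$level != "peptide") {
    stop("protein_from_peptides requires a peptide-level table",
         call. = FALSE)
  }
  if (x$log2) {
    stop("peptide intensities must be on the linear scale for summation",
         call. = FALSE)
  }
  unique_map <- !grepl(";", x$features$protein_id, fixed = TRUE)
  feats <- x$features[unique_map, , drop = FALSE]
  ints <- x$intensities[unique_map, , drop = FALSE]
  prot_ids <- unique(feats$protein_id)
  prot_ints <- matrix(NA_real_, length(prot_ids), ncol(ints),
                      dimnames = list(prot_ids, colnames(ints)))
  for (k in seq_along(prot_ids)) {
    rows <- feats$protein_id == prot_ids[[k]]
    sub <- ints[rows, , drop = FALSE]
    sums <- colSums(sub, na.rm = TRUE)
    sums[colSums(!is.na(sub)) == 0L] <- NA_real_
    prot_ints[k, ] <- sums
  }
  prot_feats <- data.frame(
    feature_id = prot_ids,
    protein_id = prot_ids,
    n_peptides = vapply(prot_ids, function(p) {
      sum(feats$protein_id == p)
    }, integer(1L)),
    is_contaminant = vapply(prot_ids, function(p) {
      any(feats$is_contaminant[feats$protein_id == p])
    }, logical(1L)),
    is_ligand = vapply(prot_ids, function(p) {
      any(feats$is_ligand[feats$protein_id == p])
    }, logical(1L)),
    stringsAsFactors = FALSE
  )
  quant_table(prot_feats, prot_ints, samples = x$samples, level = "protein")
}
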