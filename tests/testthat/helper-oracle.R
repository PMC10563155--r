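# Independent brute-force oracles and small fixture builders. These
# re-derive expected results directly from the definitions, without using
# the package's digestion or normalization code paths.

# Cleavage sites straight from the definition: position k (1-based, k < L)
# is a site iff residue k is a target, is not acetylated, and (under the
# proline restriction) residue k+1 is not P.
oracle_sites <- function(seq, targets, acetyl = integer(0),
                         proline_restriction = FALSE) {
  aa <- strsplit(seq, "")[[1]]
  n <- length(aa)
  out <- integer(0)
  for (k in seq_len(max(n - 1L, 0L))) {
    if (!aa[k] %in% targets) next
    if (k %in% acetyl) next
    if (proline_restriction && aa[k + 1L] == "P") next
    out <- c(out, k)
  }
  out
}

# Every substring (i..j) that is a digestion product: both ends fall on
# cleavage boundaries (terminus or site) and it spans at most max_missed
# internal sites. Returns "start:end:mc" keys.
oracle_digest_keys <- function(seq, targets, acetyl = integer(0),
                               proline_restriction = FALSE, max_missed = 0L) {
  n <- nchar(seq)
  sites <- oracle_sites(seq, targets, acetyl, proline_restriction)
  boundary <- function(b) b == 0L || b == n || b %in% sites
  keys <- character(0)
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (!boundary(i - 1L) || !boundary(j)) next
      internal <- sum(sites >= i & sites < j)
      if (internal > max_missed) next
      keys <- c(keys, sprintf("%d:%d:%d", i, j, internal))
    }
  }
  sort(keys)
}

# Random K/R/P-rich sequences so cleavage, missed-cleavage and proline
# edge cases all get exercised.
random_protein <- function(len) {
  pool <- c("A", "G", "S", "T", "V", "L", "P", "D", "E", "K", "K", "R", "R")
  paste(sample(pool, len, replace = TRUE), collapse = "")
}

# A quant_table built from an explicit matrix; NA = missing.
toy_table <- function(mat, level = "protein", log2 = FALSE,
                      n_peptides = NULL, is_contaminant = NULL,
                      is_ligand = NULL, feature_id = NULL) {
  n <- nrow(mat)
  feats <- data.frame(
    feature_id = if (is.null(feature_id)) sprintf("P%03d", seq_len(n))
                 else feature_id,
    protein_id = if (is.null(feature_id)) sprintf("P%03d", seq_len(n))
                 else feature_id,
    n_peptides = if (is.null(n_peptides)) rep(2L, n) else n_peptides,
    is_contaminant = if (is.null(is_contaminant)) rep(FALSE, n)
                     else is_contaminant,
    is_ligand = if (is.null(is_ligand)) rep(FALSE, n) else is_ligand
  )
  quant_table(feats, mat, level = level, log2 = log2)
}
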