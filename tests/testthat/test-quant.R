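test_that("protein filter applies the three quantification rules", {
  # 6 proteins: contaminant, single-peptide, never >= 2 replicates anywhere,
  # one failing two rules, and two that pass.
  mat <- rbind(
    c(10, 11, 12, 10, 11, 12),   # contaminant, otherwise fine
    c(10, 11, 12, 10, 11, 12),   # only 1 peptide
    c(10, NA, NA, 11, NA, NA),   # quantified once per condition
    c(NA, 10, NA, NA, NA, 11),   # 1 peptide AND < 2 replicates
    c(10, 11, NA, NA, NA, NA),   # passes via condition A
    c(10, 11, 12, 10, 11, 12)    # passes everywhere
  )
  colnames(mat) <- c(paste0("a_rep", 1:3), paste0("b_rep", 1:3))
  tab <- toy_table(mat,
                   n_peptides = c(5L, 1L, 3L, 1L, 2L, 2L),
                   is_contaminant = c(TRUE, rep(FALSE, 5)))
  kept <- filter_proteins(tab)
  expect_identical(kept$features$feature_id, c("P005", "P006"))
  # idempotent, never grows
  again <- filter_proteins(kept)
  expect_identical(again$features, kept$features)
  expect_identical(again$intensities, kept$intensities)
  expect_error(filter_proteins(log2_transform(tab), min_reps = 1),
               NA)  # scale-independent
  pep <- toy_table(mat, level = "peptide")
  expect_error(filter_proteins(pep), "protein-level")
})

test_that("pairwise ratio modes recover constant shifts", {
  set.seed(101)
  x <- rnorm(200, 20, 2)
  mat <- cbind(a_rep1 = x, a_rep2 = x + 0.5)
  tab <- toy_table(mat, log2 = TRUE)
  m <- pairwise_ratio_modes(tab)
  expect_equal(m["a_rep2", "a_rep1"], 0.5, tolerance = 0.02)
  expect_equal(m["a_rep1", "a_rep2"], -0.5, tolerance = 0.02)
  # identical samples: mode 0
  tab0 <- toy_table(cbind(a_rep1 = x, a_rep2 = x), log2 = TRUE)
  expect_equal(pairwise_ratio_modes(tab0)["a_rep1", "a_rep2"], 0,
               tolerance = 1e-8)
})

test_that("the ratio mode is robust to a minority of changing proteins", {
  set.seed(102)
  base <- rnorm(500, 0, 1)
  shifted <- base + 1.2
  out <- sample(500, 50)
  shifted[out] <- base[out] - 3       # 10% outliers at a different shift
  tab <- toy_table(cbind(a_rep1 = shifted, a_rep2 = base), log2 = TRUE)
  m <- pairwise_ratio_modes(tab)
  expect_equal(m["a_rep1", "a_rep2"], 1.2, tolerance = 0.1)
})

test_that("ratio modes are antisymmetric and guard sparse pairs", {
  set.seed(103)
  mat <- matrix(rnorm(300 * 4, 20, 2), ncol = 4)
  mat[sample(length(mat), 150)] <- NA
  colnames(mat) <- c("a_rep1", "a_rep2", "b_rep1", "b_rep2")
  m <- pairwise_ratio_modes(toy_table(mat, log2 = TRUE))
  expect_equal(m, -t(m), tolerance = 0.05)
  # < 2 co-observed proteins is an error
  sparse <- rbind(c(1, NA), c(2, NA), c(NA, 3), c(20, 21))
  colnames(sparse) <- c("a_rep1", "a_rep2")
  expect_error(
    suppressWarnings(pairwise_ratio_modes(toy_table(sparse, log2 = TRUE))),
    "fewer than 2"
  )
})

test_that("normalization factors solve the zero-sum least squares", {
  # S = 2: symmetric split of the single mode
  m2 <- matrix(c(0, 0.8, -0.8, 0), 2, 2, byrow = TRUE,
               dimnames = rep(list(c("a_rep1", "a_rep2")), 2))
  f2 <- solve_normalization_factors(m2)$factors
  expect_equal(unname(f2), c(0.4, -0.4))
  # consistent modes from exact shifts are recovered exactly
  shifts <- c(0, 1, -1)
  m3 <- outer(shifts, shifts, "-")
  dimnames(m3) <- rep(list(c("s1_rep1", "s1_rep2", "s1_rep3")), 2)
  expect_equal(unname(solve_normalization_factors(m3)$factors), shifts)
  # all-zero modes give all-zero factors
  m0 <- matrix(0, 3, 3, dimnames = dimnames(m3))
  expect_equal(unname(solve_normalization_factors(m0)$factors), rep(0, 3))
  expect_equal(sum(solve_normalization_factors(m2)$factors), 0)
  # disconnected pair graph is singular
  m_disc <- matrix(NA_real_, 4, 4)
  diag(m_disc) <- 0
  m_disc[1, 2] <- 0.5
  m_disc[3, 4] <- -0.2
  expect_error(solve_normalization_factors(m_disc), "connect")
})

test_that("normalization is idempotent on synthetic shifted tables", {
  set.seed(104)
  shifts <- c(-0.6, 0.1, 0.5, -0.4, 0.4, 0)
  base <- rnorm(400, 20, 2)   # shared protein effect across samples
  mat <- outer(base, rep(1, 6)) + rep(shifts, each = 400) +
    rnorm(400 * 6, 0, 0.1)
  mat[sample(length(mat), 0.1 * length(mat))] <- NA
  colnames(mat) <- c(paste0("a_rep", 1:3), paste0("b_rep", 1:3))
  norm1 <- normalize_quant(toy_table(mat, log2 = TRUE))
  expect_lt(max(abs(norm1$normalization$factors - shifts)), 0.05)
  norm2 <- normalize_quant(norm1)
  expect_true(all(abs(norm2$normalization$factors) < 0.01))
})

test_that("imputation draws from the downshifted per-sample Gaussian", {
  # observed values with median exactly 20 and sd exactly 2
  obs <- c(18, 20, 22)
  mat <- matrix(c(obs, rep(NA_real_, 1e5)), ncol = 1,
                dimnames = list(NULL, "a_rep1"))
  tab <- toy_table(mat, log2 = TRUE)
  imp <- impute_missing(tab, seed = 105)
  drawn <- imp$intensities[-(1:3), 1]
  expect_equal(mean(drawn), 20 - 1.8 * 2, tolerance = 0.01)
  expect_equal(sd(drawn), 0.3 * 2, tolerance = 0.01)
  # observed cells bit-identical, nothing missing afterwards
  expect_identical(imp$intensities[1:3, 1], tab$intensities[1:3, 1])
  expect_identical(sum(is.na(imp$intensities)), 0L)
  # a complete table passes through unchanged
  full <- toy_table(matrix(rnorm(30, 20, 1), ncol = 2,
                           dimnames = list(NULL, c("a_rep1", "a_rep2"))),
                    log2 = TRUE)
  expect_identical(impute_missing(full, seed = 1)$intensities,
                   full$intensities)
  # same seed, same draws
  expect_identical(impute_missing(tab, seed = 7)$intensities,
                   impute_missing(tab, seed = 7)$intensities)
  # too few observed values per sample
  tiny <- toy_table(matrix(c(20, NA, NA, NA), ncol = 1,
                           dimnames = list(NULL, "a_rep1")), log2 = TRUE)
  expect_error(impute_missing(tiny), "fewer than 3")
})

test_that("replicate pair ratios compare matched replicates only", {
  mat <- matrix(rnorm(20, 20, 1), ncol = 2)
  colnames(mat) <- c("x_rep1", "x_rep2")
  a <- toy_table(mat, log2 = TRUE)
  expect_true(all(replicate_pair_ratios(a, a) == 0))
  b <- a
  b$intensities <- a$intensities - 2
  expect_true(all(replicate_pair_ratios(a, b) == 2))
  # a missing member drops the pair, not the protein
  c_ <- a
  c_$intensities[1, 2] <- NA
  rr <- replicate_pair_ratios(a, c_)
  expect_true(is.na(rr[1, 2]) && !is.na(rr[1, 1]))
})

test_that("median ratio honours the all-replicates rule", {
  ratios <- rbind(c(1, 1, 1))
  expect_equal(median_ratio(ratios), 1)
  ratios3 <- rbind(c(0.5, 0.5, 0.5), c(1, 1, 1), c(3, 3, 3))
  expect_equal(median_ratio(ratios3), 1)
  # protein with a missing pair excluded under the flag, included without
  with_na <- rbind(c(0.5, 0.5, 0.5), c(1, 1, 1), c(10, 10, NA))
  expect_equal(median_ratio(with_na, require_all_replicates = TRUE), 0.75)
  expect_equal(median_ratio(with_na, require_all_replicates = FALSE), 1)
})

test_that("protein CV is computed on linear intensities", {
  mat <- rbind(c(100, 100, 100), c(90, 100, 110), c(50, NA, NA))
  colnames(mat) <- paste0("a_rep", 1:3)
  tab <- toy_table(mat)
  cv <- protein_cv(tab, "a")
  expect_equal(unname(cv["P001"]), 0)
  expect_equal(unname(cv["P002"]), 0.1)
  expect_false("P003" %in% names(cv))  # single replicate: excluded
  # log2 tables are de-transformed first
  cv_log <- protein_cv(log2_transform(tab), "a")
  expect_equal(cv_log, cv)
})

test_that("quantified-protein counting excludes ligand and contaminants", {
  mat <- rbind(c(10, 11, NA), c(10, NA, NA), c(10, 11, 12), c(10, 11, 12))
  colnames(mat) <- paste0("a_rep", 1:3)
  tab <- toy_table(mat,
                   is_contaminant = c(FALSE, FALSE, TRUE, FALSE),
                   is_ligand = c(FALSE, FALSE, FALSE, TRUE))
  expect_identical(count_quantified(tab), c(a = 1L))
  expect_identical(count_quantified(tab, min_reps = 1), c(a = 2L))
  empty <- toy_table(mat[0, , drop = FALSE])
  expect_identical(count_quantified(empty), c(a = 0L))
})

test_that("ligand contamination report is relative to the reference", {
  mat <- rbind(
    c(100, 100, 50, 50),
    c(80, 80, 40, 40),
    c(10, 10, 5, 5),
    c(1000, 1000, 1000, 1000)  # background peptide, must be ignored
  )
  colnames(mat) <- c("mock_rep1", "mock_rep2", "ac_rep1", "ac_rep2")
  tab <- toy_table(mat, level = "peptide",
                   is_ligand = c(TRUE, TRUE, TRUE, FALSE))
  rel <- ligand_contamination_report(tab, reference = "mock")
  expect_equal(unname(rel["mock"]), 1)
  expect_equal(unname(rel["ac"]), 0.5)
  # top_n = 1 tracks only the most prominent ligand peptide
  mat2 <- mat
  mat2[1, c("ac_rep1", "ac_rep2")] <- 25   # top peptide down 4x
  tab2 <- toy_table(mat2, level = "peptide",
                    is_ligand = c(TRUE, TRUE, TRUE, FALSE))
  rel1 <- ligand_contamination_report(tab2, reference = "mock", top_n = 1)
  expect_equal(unname(rel1["ac"]), 0.25)
  expect_error(ligand_contamination_report(toy_table(mat), "mock"),
               "peptide-level")
})

test_that("protein intensities are sums of unique peptide intensities", {
  mat <- rbind(c(10, 20), c(20, NA), c(30, 5), c(99, 99))
  colnames(mat) <- c("a_rep1", "a_rep2")
  feats <- data.frame(
    feature_id = paste0("pep", 1:4),
    protein_id = c("P1", "P1", "P1", "P1;P2"),  # last is shared -> dropped
    n_peptides = 1L, is_contaminant = FALSE, is_ligand = FALSE
  )
  tab <- quant_table(feats, mat, level = "peptide")
  prot <- protein_from_peptides(tab)
  expect_identical(prot$features$feature_id, "P1")
  expect_identical(prot$features$n_peptides, 3L)
  expect_equal(unname(prot$intensities["P1", ]), c(60, 25))
  # all peptides missing in a sample leaves the protein missing
  mat_na <- rbind(c(10, NA), c(20, NA))
  colnames(mat_na) <- c("a_rep1", "a_rep2")
  feats2 <- data.frame(feature_id = c("q1", "q2"),
                       protein_id = "Q", n_peptides = 1L,
                       is_contaminant = FALSE, is_ligand = FALSE)
  prot2 <- protein_from_peptides(quant_table(feats2, mat_na,
                                             level = "peptide"))
  expect_true(is.na(prot2$intensities["Q", "a_rep2"]))
})
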