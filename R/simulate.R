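# Synthetic AP-MS experiment generator with known ground truth.
#
# Emulates the pull-down design of a GFP-tagged bait purified from a
# background proteome on ligand-coated beads: log-normal background
# intensities, bait/interactor enrichment in the tagged condition only,
# ligand peptides produced mechanistically by the two-step digestion engine
# at the arm's acetylation probability, per-sample abundance shifts, and
# intensity-dependent (left-censored, MNAR) missingness.

# Synthetic nanobody-like VHH sequence used as the default bead ligand.
# This is NOT a database sequence; it is an invented single-domain-antibody-
# like chain with a realistic length and lysine content, anchored at its
# N-terminus.
.SYNTHETIC_NANOBODY <- paste0(
  "QVQLVESGGGLVQAGGSLRLSCAASGRTFSKYAMGWFRQAPGKEREFVAAISWSGGSTYYADSVKGRF",
  "TISRDNAKNTVYLQMNSLKPEDTAVYYCAADRKSYYYTGSYDYWGQGTQVTVSS"
)

#' Default synthetic ligand protein
#'
#' A synthetic nanobody-like VHH sequence (122 aa, 6 lysines) used as the
#' default bead-bound ligand in simulations, anchored at residue 1. It is an
#' invented sequence with realistic composition, not a database entry.
#'
#' @return A [protein_sequence()] with role `"ligand"`.
#' @export
synthetic_nanobody <- function() {
  protein_sequence("SYNTHETIC_NANOBODY", .SYNTHETIC_NANOBODY,
                   role = "ligand", attachment = 1L)
}

#' Simulation configuration
#'
#' Parameters of the synthetic AP-MS experiment. Defaults emulate a
#' two-condition (bait-tagged vs untagged) pull-down in three replicates
#' with a bead-anchored nanobody ligand.
#'
#' @param n_background Number of background proteins (default 300).
#' @param n_interactors Number of bait interactors enriched in the tagged
#'   condition (default 10).
#' @param n_contaminants Number of flagged contaminant proteins (default 5).
#' @param bait_enrichment Bait log2 enrichment in the tagged condition
#'   (default 4).
#' @param interactor_enrichment Interactor log2 enrichment (default 2).
#' @param ligand Bead-bound ligand as a [protein_sequence()]; default
#'   [synthetic_nanobody()].
#' @param ligand_log2_abundance Total log2 abundance of the ligand protein
#'   when fully released (default 27, dominating the background as ligand
#'   codigestion does on untreated beads).
#' @param acetylation_p Per-lysine acetylation probability of the arm being
#'   simulated (0 = mock beads).
#' @param tagged_condition,untagged_condition Condition labels.
#' @param n_replicates Replicates per condition (>= 2, default 3).
#' @param sample_shifts Per-sample additive log2 offsets (length
#'   `2 * n_replicates`, zero-sum); a fixed default is used when `NULL`.
#' @param intensity_location,intensity_scale Location and scale of the
#'   per-protein log2 abundance distribution (i.e. log-normal intensities;
#'   defaults 20 and 2).
#' @param replicate_sd Replicate-to-replicate log2 noise SD (default 0.25).
#' @param missing_threshold,missing_steepness Logistic missingness model on
#'   log2 intensity: a cell is dropped with probability
#'   `plogis((threshold - x) / steepness)` (defaults 16 and 1).
#' @param peptides_per_protein Peptides simulated per non-ligand protein
#'   (>= 2, default 5).
#' @param seed Optional integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_background = 300L,
                       n_interactors = 10L,
                       n_contaminants = 5L,
                       bait_enrichment = 4,
                       interactor_enrichment = 2,
                       ligand = synthetic_nanobody(),
                       ligand_log2_abundance = 27,
                       acetylation_p = 0,
                       tagged_condition = "gfp",
                       untagged_condition = "wt",
                       n_replicates = 3L,
                       sample_shifts = NULL,
                       intensity_location = 20,
                       intensity_scale = 2,
                       replicate_sd = 0.25,
                       missing_threshold = 16,
                       missing_steepness = 1,
                       peptides_per_protein = 5L,
                       seed = NULL) {
  cfg <- list(
    n_background = as.integer(n_background),
    n_interactors = as.integer(n_interactors),
    n_contaminants = as.integer(n_contaminants),
    bait_enrichment = bait_enrichment,
    interactor_enrichment = interactor_enrichment,
    ligand = ligand,
    ligand_log2_abundance = ligand_log2_abundance,
    acetylation_p = acetylation_p,
    tagged_condition = tagged_condition,
    untagged_condition = untagged_condition,
    n_replicates = as.integer(n_replicates),
    sample_shifts = sample_shifts,
    intensity_location = intensity_location,
    intensity_scale = intensity_scale,
    replicate_sd = replicate_sd,
    missing_threshold = missing_threshold,
    missing_steepness = missing_steepness,
    peptides_per_protein = as.integer(peptides_per_protein),
    seed = seed
  )
  n_samples <- 2L * cfg$n_replicates
  if (is.null(cfg$sample_shifts)) {
    raw <- seq(-0.4, 0.4, length.out = n_samples)
    cfg$sample_shifts <- raw - mean(raw)
  }
  if (cfg$n_replicates < 2L) {
    stop("sim_config: n_replicates must be >= 2", call. = FALSE)
  }
  if (length(cfg$sample_shifts) != n_samples) {
    stop("sim_config: sample_shifts must have length 2 * n_replicates",
         call. = FALSE)
  }
  if (abs(sum(cfg$sample_shifts)) > 1e-8) {
    stop("sim_config: sample_shifts must sum to 0", call. = FALSE)
  }
  if (cfg$acetylation_p < 0 || cfg$acetylation_p > 1) {
    stop("sim_config: acetylation_p must be in [0, 1]", call. = FALSE)
  }
  if (cfg$peptides_per_protein < 2L) {
    stop("sim_config: peptides_per_protein must be >= 2", call. = FALSE)
  }
  if (!inherits(cfg$ligand, "protein_seq")) {
    stop("sim_config: ligand must be a protein_sequence", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0("<sim_config> %d background + %d interactors + bait, ",
           "%s/%s x %d reps, acetylation p = %.2f\n"),
    x$n_background, x$n_interactors, x$tagged_condition,
    x$untagged_condition, x$n_replicates, x$acetylation_p
  ))
  invisible(x)
}

# Released ligand peptides of one acetylation draw, with per-peptide log2
# intensity apportioned by residue length out of the full ligand abundance.
.draw_ligand_peptides <- function(ligand, p, log2_abundance) {
  acetyl <- acetylate(ligand, p)
  released <- two_step_digest(ligand, acetyl,
                              max_missed_lysc = 0L,
                              max_missed_trypsin = 0L)$released
  if (nrow(released) == 0L) {
    return(data.frame(key = character(0), sequence = character(0),
                      log2_intensity = numeric(0)))
  }
  len <- released$end - released$start + 1L
  data.frame(
    key = sprintf("%s_%d_%d", ligand$id, released$start, released$end),
    sequence = released$sequence,
    log2_intensity = log2_abundance + log2(len / nchar(ligand$residues)),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic AP-MS experiment
#'
#' Draws a complete two-condition pull-down dataset at peptide and protein
#' level together with its ground truth. Background/interactor/bait/
#' contaminant peptide intensities are log-normal with fixed per-protein
#' peptide weights; the bait and interactors are enriched in the tagged
#' condition only; ligand peptides are produced by [two_step_digest()] under
#' a fresh acetylation draw per sample; per-sample shifts are added to every
#' cell; cells are then dropped by a logistic left-censoring model.
#'
#' @param config A [sim_config()].
#' @return A list with elements `peptides` and `proteins` (linear-scale
#'   [quant_table()]s) and `truth` (class `sim_truth`: the simulated shifts,
#'   enrichments, expected released ligand fraction, the complete
#'   pre-censoring log2 matrix and the dropout indicators).
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)

  n_rep <- config$n_replicates
  samples <- data.frame(
    sample = c(sprintf("%s_rep%d", config$tagged_condition, seq_len(n_rep)),
               sprintf("%s_rep%d", config$untagged_condition, seq_len(n_rep))),
    condition = rep(c(config$tagged_condition, config$untagged_condition),
                    each = n_rep),
    replicate = rep(seq_len(n_rep), 2L),
    stringsAsFactors = FALSE
  )
  shifts <- config$sample_shifts
  names(shifts) <- samples$sample
  tagged <- samples$condition == config$tagged_condition

  # Protein catalogue (non-ligand).
  prot <- data.frame(
    protein_id = c(
      sprintf("BG%04d", seq_len(config$n_background)),
      sprintf("INT%03d", seq_len(config$n_interactors)),
      "BAIT",
      sprintf("CONT%03d", seq_len(config$n_contaminants))
    ),
    class = c(rep("background", config$n_background),
              rep("interactor", config$n_interactors),
              "bait",
              rep("contaminant", config$n_contaminants)),
    stringsAsFactors = FALSE
  )
  prot$base <- stats::rnorm(nrow(prot), config$intensity_location,
                            config$intensity_scale)
  prot$base[prot$class == "bait"] <- config$intensity_location
  prot$enrichment <- ifelse(prot$class == "bait", config$bait_enrichment,
                            ifelse(prot$class == "interactor",
                                   config$interactor_enrichment, 0))

  # Per-protein fixed peptide weights (which peptide carries which share of
  # the protein's signal is a property of the peptide, not of the sample).
  k <- config$peptides_per_protein
  pep_rows <- data.frame(
    feature_id = as.vector(t(outer(prot$protein_id, seq_len(k),
                                   function(p, i) sprintf("%s_pep%d", p, i)))),
    protein_id = rep(prot$protein_id, each = k),
    is_contaminant = rep(prot$class == "contaminant", each = k),
    is_ligand = FALSE,
    stringsAsFactors = FALSE
  )
  w <- stats::rexp(nrow(pep_rows))
  w <- w / rep(tapply(w, pep_rows$protein_id, sum)[pep_rows$protein_id], 1)
  pep_rows$log2_weight <- log2(w)

  # Noise-free peptide log2 intensity per sample.
  prot_level <- outer(prot$base, rep(1, nrow(samples))) +
    outer(prot$enrichment, as.numeric(tagged))
  pep_mu <- prot_level[rep(seq_len(nrow(prot)), each = k), , drop = FALSE] +
    pep_rows$log2_weight

  # Ligand peptides: a fresh acetylation draw per sample.
  ligand_draws <- lapply(seq_len(nrow(samples)), function(s) {
    .draw_ligand_peptides(config$ligand, config$acetylation_p,
                          config$ligand_log2_abundance)
  })
  lig_keys <- unique(unlist(lapply(ligand_draws, `[[`, "key")))
  lig_mu <- matrix(NA_real_, length(lig_keys), nrow(samples))
  for (s in seq_len(nrow(samples))) {
    d <- ligand_draws[[s]]
    lig_mu[match(d$key, lig_keys), s] <- d$log2_intensity
  }

  mu <- rbind(pep_mu, lig_mu)
  features <- data.frame(
    feature_id = c(pep_rows$feature_id, lig_keys),
    protein_id = c(pep_rows$protein_id, rep(config$ligand$id,
                                            length(lig_keys))),
    n_peptides = 1L,
    is_contaminant = c(pep_rows$is_contaminant, rep(FALSE, length(lig_keys))),
    is_ligand = c(pep_rows$is_ligand, rep(TRUE, length(lig_keys))),
    stringsAsFactors = FALSE
  )

  # Replicate noise and per-sample shifts; then logistic left-censoring.
  noise <- matrix(stats::rnorm(length(mu), 0, config$replicate_sd),
                  nrow(mu), ncol(mu))
  complete <- mu + noise + rep(shifts, each = nrow(mu))
  p_miss <- stats::plogis((config$missing_threshold - complete) /
                            config$missing_steepness)
  dropped <- matrix(stats::runif(length(complete)) < p_miss,
                    nrow(complete), ncol(complete)) & !is.na(complete)
  observed_log2 <- complete
  observed_log2[dropped] <- NA_real_

  peptides <- quant_table(features, 2^observed_log2, samples = samples,
                          level = "peptide")
  proteins <- protein_from_peptides(peptides)

  truth <- structure(list(
    sample_shifts = shifts,
    bait_enrichment = config$bait_enrichment,
    interactor_enrichment = config$interactor_enrichment,
    acetylation_p = config$acetylation_p,
    ligand_signal_fraction = ligand_signal_fraction(
      config$ligand, config$acetylation_p, n_reps = 2000L
    ),
    bait_id = "BAIT",
    interactor_ids = prot$protein_id[prot$class == "interactor"],
    complete_log2 = complete,
    dropped = dropped
  ), class = "sim_truth")

  list(peptides = peptides, proteins = proteins, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(
    paste0("<sim_truth> bait enrichment %.2f log2, acetylation p %.2f, ",
           "ligand fraction %.3f, %d dropped cells\n"),
    x$bait_enrichment, x$acetylation_p, x$ligand_signal_fraction,
    sum(x$dropped)
  ))
  invisible(x)
}

#' Simulate an acetylation titration of the bead ligand
#'
#' For each acetylation probability, simulates replicate two-step digests of
#' the ligand and reports the relative intensity of the top ligand peptides
#' against the untreated reference (p = 0), mirroring a bead-treatment
#' titration read out by label-free LC-MS in duplicate.
#'
#' @param config A [sim_config()]; only the ligand, its abundance, the
#'   replicate noise SD and the seed are used.
#' @param p_values Acetylation probabilities to titrate; 0 is added as the
#'   reference when absent.
#' @param n_replicates Simulated replicates per probability (default 2).
#' @param top_n Top ligand peptides tracked (default 5).
#' @return A data frame with columns `p` and `relative_intensity`
#'   (reference = 1).
#' @export
simulate_titration <- function(config, p_values, n_replicates = 2L,
                               top_n = 5L) {
  stopifnot(inherits(config, "sim_config"), length(p_values) >= 1L,
            all(p_values >= 0 & p_values <= 1))
  if (!is.null(config$seed)) set.seed(config$seed)
  p_values <- sort(unique(c(0, p_values)))
  cond_of <- function(p) sprintf("p%g", p)

  draws <- list()
  for (p in p_values) {
    for (r in seq_len(n_replicates)) {
      d <- .draw_ligand_peptides(config$ligand, p,
                                 config$ligand_log2_abundance)
      d$sample <- rep(sprintf("%s_rep%d", cond_of(p), r), nrow(d))
      draws[[length(draws) + 1L]] <- d
    }
  }
  all_keys <- unique(unlist(lapply(draws, `[[`, "key")))
  samples <- data.frame(
    sample = unlist(lapply(p_values, function(p) {
      sprintf("%s_rep%d", cond_of(p), seq_len(n_replicates))
    })),
    condition = rep(vapply(p_values, cond_of, character(1L)),
                    each = n_replicates),
    replicate = rep(seq_len(n_replicates), length(p_values)),
    stringsAsFactors = FALSE
  )
  mu <- matrix(NA_real_, length(all_keys), nrow(samples),
               dimnames = list(all_keys, samples$sample))
  for (d in draws) {
    if (nrow(d) > 0L) {
      mu[match(d$key, all_keys), d$sample[[1L]]] <- d$log2_intensity
    }
  }
  mu <- mu + matrix(stats::rnorm(length(mu), 0, config$replicate_sd),
                    nrow(mu), ncol(mu))
  features <- data.frame(
    feature_id = all_keys,
    protein_id = config$ligand$id,
    n_peptides = 1L,
    is_contaminant = FALSE,
    is_ligand = TRUE,
    stringsAsFactors = FALSE
  )
  tab <- quant_table(features, 2^mu, samples = samples, level = "peptide")
  rel <- ligand_contamination_report(tab, reference = cond_of(0),
                                     top_n = top_n)
  data.frame(
    p = p_values,
    relative_intensity = as.numeric(rel[vapply(p_values, cond_of,
                                               character(1L))]),
    row.names = NULL
  )
}
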