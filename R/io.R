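# Readers and writers: FASTA protein input, peptide TSV output, simulation
# config files, and the ground-truth table.

#' Read protein sequences from FASTA
#'
#' Reads a single- or multi-record FASTA file. The description line may
#' carry `role=<ligand|bait|background>` and `attachment=<index>` tokens;
#' the role defaults to `background`.
#'
#' @param path FASTA file path.
#' @return List of [protein_sequence()] objects in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) {
      stop("malformed FASTA '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (length(set) == 0L) {
    stop("FASTA '", path, "' contains no records", call. = FALSE)
  }
  lapply(seq_along(set), function(i) {
    desc <- names(set)[[i]]
    fields <- strsplit(desc, "[[:space:]]+")[[1L]]
    id <- fields[[1L]]
    role <- "background"
    attachment <- NA_integer_
    role_tok <- grep("^role=", fields, value = TRUE)
    if (length(role_tok) > 0L) {
      role <- sub("^role=", "", role_tok[[1L]])
      if (!role %in% c("ligand", "bait", "background")) {
        stop("record '", id, "': unknown role '", role, "'", call. = FALSE)
      }
    }
    att_tok <- grep("^attachment=", fields, value = TRUE)
    if (length(att_tok) > 0L) {
      attachment <- as.integer(sub("^attachment=", "", att_tok[[1L]]))
    }
    protein_sequence(id, as.character(set[[i]]), role = role,
                     attachment = attachment)
  })
}

#' Write protein sequences to FASTA
#'
#' @param proteins List of [protein_sequence()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  stopifnot(length(proteins) > 0L,
            all(vapply(proteins, inherits, logical(1L), "protein_seq")))
  lines <- unlist(lapply(proteins, function(p) {
    header <- sprintf(">%s role=%s%s", p$id, p$role,
                      if (is.na(p$attachment)) ""
                      else sprintf(" attachment=%d", p$attachment))
    c(header, p$residues)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Write a peptide table to TSV
#'
#' Writes a digestion result (from [digest()] or [two_step_digest()]) with
#' monoisotopic peptide masses appended.
#'
#' @param peptides Peptide data frame.
#' @param path Output path.
#' @param fixed_cys Fixed cysteine modification for the mass column.
#' @return `path`, invisibly.
#' @export
write_peptides_tsv <- function(peptides, path, fixed_cys = "none") {
  peptides <- as.data.frame(peptides)
  peptides$mass <- if (nrow(peptides) > 0L) {
    round(peptide_mass(peptides$sequence, fixed_cys = fixed_cys), 5)
  } else {
    numeric(0)
  }
  utils::write.table(peptides, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a simulation configuration file
#'
#' Reads a YAML file whose keys are [sim_config()] arguments. The ligand may
#' be given inline as `ligand: {id, residues, attachment}` or by
#' `ligand_fasta: <path>` (first record with `role=ligand`, or the first
#' record).
#'
#' @param path YAML config path.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) {
    stop("config '", path, "' is not a key-value mapping", call. = FALSE)
  }
  if (!is.null(raw$ligand_fasta)) {
    prots <- read_fasta(raw$ligand_fasta)
    roles <- vapply(prots, `[[`, character(1L), "role")
    lig <- if (any(roles == "ligand")) {
      prots[[which(roles == "ligand")[[1L]]]]
    } else {
      prots[[1L]]
    }
    if (is.na(lig$attachment)) lig$attachment <- 1L
    raw$ligand <- lig
    raw$ligand_fasta <- NULL
  } else if (is.list(raw$ligand)) {
    raw$ligand <- protein_sequence(
      raw$ligand$id, raw$ligand$residues, role = "ligand",
      attachment = if (is.null(raw$ligand$attachment)) 1L
                   else raw$ligand$attachment
    )
  }
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("config '", path, "': unknown field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(sim_config, raw)
}

#' Write the simulation ground truth to TSV
#'
#' One row per truth item (`item`, `key`, `value`): per-sample shifts, the
#' enrichments, the acetylation probability and the expected released ligand
#' fraction. The full pre-censoring matrix is not written.
#'
#' @param truth A `sim_truth` from [generate_experiment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  rows <- rbind(
    data.frame(item = "sample_shift", key = names(truth$sample_shifts),
               value = as.numeric(truth$sample_shifts)),
    data.frame(item = "bait_enrichment", key = truth$bait_id,
               value = truth$bait_enrichment),
    data.frame(item = "interactor_enrichment", key = truth$interactor_ids,
               value = truth$interactor_enrichment),
    data.frame(item = "acetylation_p", key = "arm",
               value = truth$acetylation_p),
    data.frame(item = "ligand_signal_fraction", key = "arm",
               value = truth$ligand_signal_fraction)
  )
  rows$value <- signif(rows$value, 6)
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
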