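# Modification-aware in-silico proteolysis.
#
# The model: Lys-C cleaves C-terminal to lysine, trypsin/P C-terminal to
# lysine or arginine with no proline restriction. Acetylation of a lysine's
# epsilon-amine blocks cleavage after that residue for both proteases. In the
# two-step protocol the bead-anchored ligand is eluted by Lys-C (fragments
# not containing the anchor are released into the supernatant), the beads are
# removed, and released material is digested to completion with trypsin.
#
# Coordinates are 1-based and inclusive ([start, end]), the R/Bioconductor
# convention; a cleavage site at position i means cleavage after residue i.

.AA_CODES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Protein sequence with an AP-MS role
#'
#' Construct a protein record for the digestion and simulation machinery:
#' an amino-acid sequence annotated with its role in the pull-down (the
#' bead-bound `ligand`, the `bait`, or a `background` protein) and, for
#' bead-bound ligands, the residue through which it is anchored to the bead.
#'
#' @param id Protein identifier.
#' @param residues Amino-acid sequence (one-letter codes; case-insensitive).
#' @param role One of `"background"`, `"ligand"`, `"bait"`.
#' @param attachment 1-based residue index anchoring the protein to the bead,
#'   or `NA` for proteins free in solution.
#' @return An object of class `protein_seq`.
#' @examples
#' protein_sequence("nb1", "MKGGRGGK", role = "ligand", attachment = 1)
#' @export
protein_sequence <- function(id, residues,
                             role = c("background", "ligand", "bait"),
                             attachment = NA_integer_) {
  role <- match.arg(role)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (!nzchar(residues)) {
    stop("protein '", id, "': empty sequence", call. = FALSE)
  }
  aa <- strsplit(residues, "", fixed = TRUE)[[1L]]
  bad <- setdiff(aa, .AA_CODES)
  if (length(bad) > 0L) {
    stop("protein '", id, "': invalid residue code(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  attachment <- as.integer(attachment)
  if (!is.na(attachment) &&
      (attachment < 1L || attachment > nchar(residues))) {
    stop("protein '", id, "': attachment index out of range", call. = FALSE)
  }
  structure(
    list(id = id, residues = residues, role = role, attachment = attachment),
    class = "protein_seq"
  )
}

#' @export
print.protein_seq <- function(x, ...) {
  cat(sprintf("<protein_seq> %s (%s), %d aa%s\n", x$id, x$role,
              nchar(x$residues),
              if (is.na(x$attachment)) ""
              else sprintf(", bead-anchored at residue %d", x$attachment)))
  invisible(x)
}

#' Lysine acetylation state of a protein
#'
#' Records which lysines of a protein carry an epsilon-amine acetyl group
#' (e.g. after S-NHS-Ac treatment of bead-bound ligand). Acetylated lysines
#' are refractory to Lys-C and trypsin cleavage.
#'
#' @param protein A [protein_sequence()] object.
#' @param positions Integer vector of 1-based residue indices; every index
#'   must point at a lysine (K).
#' @return An object of class `acetylation_state`.
#' @examples
#' p <- protein_sequence("x", "AKGGRGGK")
#' acetylation_state(p, c(2, 8))
#' @export
acetylation_state <- function(protein, positions = integer(0)) {
  stopifnot(inherits(protein, "protein_seq"))
  positions <- sort(unique(as.integer(positions)))
  if (length(positions) > 0L) {
    if (any(positions < 1L | positions > nchar(protein$residues))) {
      stop("acetylation position out of range for '", protein$id, "'",
           call. = FALSE)
    }
    aa <- substring(protein$residues, positions, positions)
    if (any(aa != "K")) {
      stop("acetylation positions must be lysines; offending position(s): ",
           paste(positions[aa != "K"], collapse = ", "), call. = FALSE)
    }
  }
  structure(list(protein_id = protein$id, positions = positions),
            class = "acetylation_state")
}

#' @export
print.acetylation_state <- function(x, ...) {
  cat(sprintf("<acetylation_state> %s: %d acetyl-K (%s)\n", x$protein_id,
              length(x$positions),
              if (length(x$positions) == 0) "none"
              else paste(x$positions, collapse = ", ")))
  invisible(x)
}

# Resolve an acetylation argument (NULL, integer vector, or state object)
# into a validated integer position vector for `protein`.
.acetyl_positions <- function(protein, acetyl) {
  if (is.null(acetyl)) {
    return(integer(0))
  }
  if (inherits(acetyl, "acetylation_state")) {
    if (!identical(acetyl$protein_id, protein$id)) {
      stop("acetylation state refers to protein '", acetyl$protein_id,
           "', not '", protein$id, "'", call. = FALSE)
    }
    return(acetyl$positions)
  }
  acetylation_state(protein, acetyl)$positions
}

#' Protease cleavage rule
#'
#' Cleavage specificities used in the two-step protocol. `lys_c` cleaves
#' C-terminal to K; `trypsin_p` cleaves C-terminal to K or R with no proline
#' restriction (the "/P" specificity); `trypsin` is classic trypsin with the
#' proline restriction. All rules are blocked by acetyl-lysine.
#'
#' @param name One of `"trypsin_p"`, `"lys_c"`, `"trypsin"`.
#' @param proline_restriction Override the rule's default proline behaviour
#'   (no cleavage before P when `TRUE`).
#' @return An object of class `cleavage_rule`.
#' @export
cleavage_rule <- function(name = c("trypsin_p", "lys_c", "trypsin"),
                          proline_restriction = NULL) {
  name <- match.arg(name)
  rule <- switch(name,
    trypsin_p = list(name = "trypsin_p", targets = c("K", "R"),
                     proline_restriction = FALSE),
    trypsin = list(name = "trypsin", targets = c("K", "R"),
                   proline_restriction = TRUE),
    lys_c = list(name = "lys_c", targets = "K", proline_restriction = FALSE)
  )
  if (!is.null(proline_restriction)) {
    rule$proline_restriction <- isTRUE(proline_restriction)
  }
  rule$blocked_by_acetyl <- TRUE
  structure(rule, class = "cleavage_rule")
}

#' Find cleavage sites in a protein
#'
#' Positions after which the protease cuts: residue `i` is a site iff it is a
#' target residue of the rule, not the last residue, not acetylated, and (for
#' proline-restricted rules) not followed by P.
#'
#' @param protein A [protein_sequence()].
#' @param rule A [cleavage_rule()] (or its name).
#' @param acetyl Acetylated lysine positions: an [acetylation_state()], an
#'   integer vector, or `NULL` for none.
#' @return Strictly increasing integer vector of 1-based site positions
#'   (cleavage occurs after each).
#' @examples
#' p <- protein_sequence("x", "AKGGRGG")
#' cleavage_sites(p, "trypsin_p")           # 2, 5
#' cleavage_sites(p, "trypsin_p", acetyl = 2) # 5
#' cleavage_sites(p, "lys_c")               # 2
#' @export
cleavage_sites <- function(protein, rule = cleavage_rule("trypsin_p"),
                           acetyl = NULL) {
  stopifnot(inherits(protein, "protein_seq"))
  if (is.character(rule)) rule <- cleavage_rule(rule)
  stopifnot(inherits(rule, "cleavage_rule"))
  acetyl <- .acetyl_positions(protein, acetyl)
  aa <- strsplit(protein$residues, "", fixed = TRUE)[[1L]]
  n <- length(aa)
  sites <- which(aa %in% rule$targets)
  sites <- sites[sites < n]
  if (rule$blocked_by_acetyl && length(acetyl) > 0L) {
    sites <- setdiff(sites, acetyl)
  }
  if (rule$proline_restriction) {
    sites <- sites[aa[sites + 1L] != "P"]
  }
  as.integer(sites)
}

# Peptides between cleavage boundaries. `boundaries` are positions after
# which cuts occur, i.e. a peptide runs (b_i + 1) .. b_j.
.peptides_from_sites <- function(protein, sites, max_missed, acetyl) {
  n <- nchar(protein$residues)
  bounds <- c(0L, sites, n)
  k <- length(bounds)
  out <- list()
  for (i in seq_len(k - 1L)) {
    jmax <- min(k, i + 1L + max_missed)
    for (j in (i + 1L):jmax) {
      start <- bounds[[i]] + 1L
      end <- bounds[[j]]
      out[[length(out) + 1L]] <- c(start, end, j - i - 1L)
    }
  }
  m <- do.call(rbind, out)
  data.frame(
    parent_id = protein$id,
    start = m[, 1L],
    end = m[, 2L],
    sequence = substring(protein$residues, m[, 1L], m[, 2L]),
    missed_cleavages = m[, 3L],
    carries_acetyl = vapply(seq_len(nrow(m)), function(r) {
      any(acetyl >= m[r, 1L] & acetyl <= m[r, 2L])
    }, logical(1L)),
    stringsAsFactors = FALSE
  )
}

#' In-silico digest of a protein
#'
#' Enumerates the peptides a protease produces from a protein, allowing up to
#' `max_missed` missed cleavages. Acetylated lysines do not cleave.
#'
#' @inheritParams cleavage_sites
#' @param max_missed Maximum number of internal (missed) cleavage sites a
#'   peptide may span; default 2, the usual database-search setting.
#' @return A data frame with one row per peptide: `parent_id`, `start`,
#'   `end` (1-based inclusive), `sequence`, `missed_cleavages`,
#'   `carries_acetyl`.
#' @examples
#' p <- protein_sequence("x", "AKGK")
#' digest(p, "trypsin_p", max_missed = 2)  # AK, GK, AKGK
#' @export
digest <- function(protein, rule = cleavage_rule("trypsin_p"), acetyl = NULL,
                   max_missed = 2L) {
  stopifnot(inherits(protein, "protein_seq"))
  max_missed <- as.integer(max_missed)
  if (is.na(max_missed) || max_missed < 0L) {
    stop("max_missed must be a non-negative integer", call. = FALSE)
  }
  if (is.character(rule)) rule <- cleavage_rule(rule)
  acetyl_pos <- .acetyl_positions(protein, acetyl)
  sites <- cleavage_sites(protein, rule, acetyl_pos)
  .peptides_from_sites(protein, sites, max_missed, acetyl_pos)
}

#' Two-step on-bead Lys-C / in-solution trypsin digestion
#'
#' Simulates the elution protocol for bead-anchored proteins: Lys-C digestion
#' on the bead releases every fragment that does not contain the anchor
#' residue; the beads (with all anchor-containing fragments) are removed; the
#' released fragments are then digested with trypsin/P. Acetyl-lysines block
#' both steps, so a fully acetylated ligand is not eluted at all.
#'
#' @inheritParams cleavage_sites
#' @param max_missed_lysc,max_missed_trypsin Missed cleavages allowed in the
#'   Lys-C and trypsin steps.
#' @return A list with components `released` (tryptic peptides reaching the
#'   LC-MS sample) and `retained` (bead-retained Lys-C fragments), both as
#'   peptide data frames in parent-protein coordinates.
#' @examples
#' nb <- protein_sequence("nb", "AKGGRGGK", role = "ligand", attachment = 1)
#' two_step_digest(nb, max_missed_lysc = 0, max_missed_trypsin = 0)
#' @export
two_step_digest <- function(protein, acetyl = NULL,
                            max_missed_lysc = 2L, max_missed_trypsin = 2L) {
  stopifnot(inherits(protein, "protein_seq"))
  acetyl_pos <- .acetyl_positions(protein, acetyl)
  step1 <- digest(protein, cleavage_rule("lys_c"), acetyl_pos,
                  max_missed = max_missed_lysc)
  anchored <- if (is.na(protein$attachment)) {
    rep(FALSE, nrow(step1))
  } else {
    step1$start <= protein$attachment & step1$end >= protein$attachment
  }
  retained <- step1[anchored, , drop = FALSE]
  fragments <- step1[!anchored, , drop = FALSE]

  released <- vector("list", nrow(fragments))
  for (i in seq_len(nrow(fragments))) {
    frag <- fragments[i, ]
    sub <- protein_sequence(protein$id,
                            substr(protein$residues, frag$start, frag$end))
    sub_acetyl <- acetyl_pos[acetyl_pos >= frag$start & acetyl_pos <= frag$end] -
      frag$start + 1L
    peps <- digest(sub, cleavage_rule("trypsin_p"), sub_acetyl,
                   max_missed = max_missed_trypsin)
    peps$start <- peps$start + frag$start - 1L
    peps$end <- peps$end + frag$start - 1L
    released[[i]] <- peps
  }
  released <- if (length(released) > 0L) {
    do.call(rbind, released)
  } else {
    step1[0, , drop = FALSE]
  }
  released <- released[!duplicated(released[c("start", "end")]), , drop = FALSE]
  released <- released[order(released$start, released$end), , drop = FALSE]
  rownames(released) <- NULL
  rownames(retained) <- NULL
  list(released = released, retained = retained)
}

#' Stochastic lysine acetylation
#'
#' Draws an acetylation state in which each lysine of the protein is
#' independently acetylated with probability `p` (an all-or-none Bernoulli
#' model of S-NHS-Ac treatment; no site-specific reactivity).
#'
#' @inheritParams cleavage_sites
#' @param p Per-lysine acetylation probability in \[0, 1\].
#' @param seed Optional integer seed for reproducible draws.
#' @return An [acetylation_state()].
#' @export
acetylate <- function(protein, p, seed = NULL) {
  stopifnot(inherits(protein, "protein_seq"),
            is.numeric(p), length(p) == 1L, p >= 0, p <= 1)
  if (!is.null(seed)) set.seed(seed)
  aa <- strsplit(protein$residues, "", fixed = TRUE)[[1L]]
  lys <- which(aa == "K")
  hit <- lys[stats::runif(length(lys)) < p]
  acetylation_state(protein, hit)
}

# Length of the zero-missed-cleavage Lys-C fragment containing the anchor,
# given the active (unblocked) site positions. 0 when there is no anchor.
.retained_length <- function(sites, attachment, n) {
  if (is.na(attachment)) {
    return(0L)
  }
  lower <- sites[sites < attachment]
  upper <- sites[sites >= attachment]
  start <- if (length(lower) > 0L) max(lower) + 1L else 1L
  end <- if (length(upper) > 0L) min(upper) else n
  end - start + 1L
}

#' Expected released ligand signal as a function of acetylation
#'
#' Monte-Carlo estimate of the ligand signal reaching the sample after the
#' two-step digestion, relative to untreated (mock) beads. The signal proxy
#' is the total residue length of Lys-C-released material (its subsequent
#' tryptic digestion does not change the total); the reported value is the
#' mean over `n_reps` independent acetylation draws at probability `p`,
#' divided by the released length at `p = 0`.
#'
#' A protein with no Lys-C-released material even at `p = 0` (no cleavable
#' lysine outside the anchor fragment) is degenerate; the intact protein
#' length is then used as the reference and a warning is issued.
#'
#' @inheritParams acetylate
#' @param n_reps Number of Monte-Carlo acetylation draws (>= 1).
#' @return Relative released signal in \[0, 1\]; exactly 1 at `p = 0`.
#' @examples
#' nb <- protein_sequence("nb", "GGKGG", role = "ligand", attachment = 1)
#' ligand_signal_fraction(nb, p = 0)    # 1
#' ligand_signal_fraction(nb, p = 1)    # 0
#' @export
ligand_signal_fraction <- function(protein, p, n_reps = 1000L, seed = NULL) {
  stopifnot(inherits(protein, "protein_seq"),
            is.numeric(p), length(p) == 1L, p >= 0, p <= 1,
            n_reps >= 1L)
  if (!is.null(seed)) set.seed(seed)
  n <- nchar(protein$residues)
  sites0 <- cleavage_sites(protein, cleavage_rule("lys_c"))
  denom <- n - .retained_length(sites0, protein$attachment, n)
  if (denom == 0L) {
    warning("protein '", protein$id,
            "' releases nothing even without acetylation; ",
            "using intact length as reference", call. = FALSE)
    denom <- n
  }
  if (p == 0) {
    released0 <- n - .retained_length(sites0, protein$attachment, n)
    return(released0 / denom)
  }
  released <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    blocked <- stats::runif(length(sites0)) < p
    active <- sites0[!blocked]
    released[[r]] <- n - .retained_length(active, protein$attachment, n)
  }
  mean(released) / denom
}
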