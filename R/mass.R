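# Monoisotopic mass utilities.
#
# Atomic masses are IUPAC monoisotopic values, hard-coded at 6-decimal
# precision so that mass arithmetic is reproducible without a runtime lookup.

.MONO_MASS <- c(
  C = 12.000000,
  H = 1.007825,
  N = 14.003074,
  O = 15.994915,
  S = 31.972071,
  P = 30.973762
)

# Residue (not free amino acid) elemental compositions of the 20 standard
# amino acids, as counts of C, H, N, O, S.
.AA_COMPOSITION <- matrix(
  c(
    # C   H  N  O  S
    3,  5, 1, 1, 0, # A
    6, 12, 4, 1, 0, # R
    4,  6, 2, 2, 0, # N
    4,  5, 1, 3, 0, # D
    3,  5, 1, 1, 1, # C
    5,  8, 2, 2, 0, # Q
    5,  7, 1, 3, 0, # E
    2,  3, 1, 1, 0, # G
    6,  7, 3, 1, 0, # H
    6, 11, 1, 1, 0, # I
    6, 11, 1, 1, 0, # L
    6, 12, 2, 1, 0, # K
    5,  9, 1, 1, 1, # M
    9,  9, 1, 1, 0, # F
    5,  7, 1, 1, 0, # P
    3,  5, 1, 2, 0, # S
    4,  7, 1, 2, 0, # T
   11, 10, 2, 1, 0, # W
    9,  9, 1, 2, 0, # Y
    5,  9, 1, 1, 0  # V
  ),
  ncol = 5, byrow = TRUE,
  dimnames = list(
    c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
      "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
    c("C", "H", "N", "O", "S")
  )
)

.WATER <- c(C = 0, H = 2, N = 0, O = 1, S = 0)

.parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1L]]
  tokens <- regmatches(formula, list(m))[[1L]]
  if (sum(nchar(tokens)) != nchar(formula)) {
    stop("malformed chemical formula: '", formula, "'", call. = FALSE)
  }
  elements <- sub("[0-9]+$", "", tokens)
  counts <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                              sub("^[A-Za-z]+", "", tokens), "1"))
  tapply(counts, elements, sum)
}

#' Monoisotopic mass of an elemental composition
#'
#' Computes the monoisotopic mass of a molecule or fragment given its
#' elemental composition, using IUPAC monoisotopic atomic masses for
#' C, H, N, O, S and P. The composition may be given either as a named
#' count vector (e.g. `c(C = 2, H = 3, N = 1, O = 1)`) or as a chemical
#' formula string (e.g. `"C2H3NO"`).
#'
#' @param composition Named numeric vector of non-negative element counts,
#'   or a single chemical formula string.
#' @return Monoisotopic mass in Dalton. The empty composition has mass 0.
#' @examples
#' monoisotopic_mass("C2H3NO")             # carbamidomethyl, 57.02146
#' monoisotopic_mass(c(C = 1, H = 2, S = 1)) # methylthio, 45.98772
#' @export
monoisotopic_mass <- function(composition) {
  if (is.character(composition)) {
    composition <- .parse_formula(composition)
  }
  if (length(composition) == 0L) {
    return(0)
  }
  if (is.null(names(composition)) || any(!nzchar(names(composition)))) {
    stop("composition must be a named count vector or formula string",
         call. = FALSE)
  }
  unknown <- setdiff(names(composition), names(.MONO_MASS))
  if (length(unknown) > 0L) {
    stop("unknown element(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(composition < 0)) {
    stop("element counts must be non-negative", call. = FALSE)
  }
  sum(.MONO_MASS[names(composition)] * composition)
}

#' Fixed cysteine modification masses
#'
#' Monoisotopic mass deltas of the two fixed cysteine modifications commonly
#' used in the workflow: carbamidomethylation (iodoacetamide chemistry,
#' C2H3NO) and methylthiolation (MMTS chemistry, CH2S). Both are computed
#' from their elemental compositions at run time.
#'
#' @return Named numeric vector with elements `carbamidomethyl` and
#'   `methylthio`, in Dalton.
#' @examples
#' modification_masses()
#' @export
modification_masses <- function() {
  c(
    carbamidomethyl = monoisotopic_mass("C2H3NO"),
    methylthio = monoisotopic_mass("CH2S")
  )
}

#' Monoisotopic peptide mass
#'
#' Mass of an unmodified (or fixed-Cys-modified) peptide: the sum of its
#' residue masses plus one water. Acetyl-lysine is not added here; use
#' `n_acetyl` to account for acetylated lysines (+C2H2O each).
#'
#' @param sequence Character vector of peptide sequences (one-letter codes).
#' @param fixed_cys Fixed cysteine modification applied to every C residue:
#'   `"none"`, `"carbamidomethyl"` or `"methylthio"`.
#' @param n_acetyl Integer vector (recycled): number of acetylated lysines
#'   per peptide.
#' @return Numeric vector of monoisotopic masses in Dalton.
#' @examples
#' peptide_mass("ACDEFGHIK")
#' peptide_mass("ACDEFGHIK", fixed_cys = "carbamidomethyl")
#' @export
peptide_mass <- function(sequence,
                         fixed_cys = c("none", "carbamidomethyl", "methylthio"),
                         n_acetyl = 0L) {
  fixed_cys <- match.arg(fixed_cys)
  stopifnot(is.character(sequence))
  residue_mass <- as.vector(.AA_COMPOSITION %*% .MONO_MASS[colnames(.AA_COMPOSITION)])
  names(residue_mass) <- rownames(.AA_COMPOSITION)
  water <- monoisotopic_mass(.WATER[.WATER > 0])
  acetyl <- monoisotopic_mass("C2H2O")
  mods <- modification_masses()
  cys_delta <- switch(fixed_cys, none = 0,
                      carbamidomethyl = mods[["carbamidomethyl"]],
                      methylthio = mods[["methylthio"]])
  n_acetyl <- rep_len(as.integer(n_acetyl), length(sequence))
  vapply(seq_along(sequence), function(i) {
    aa <- strsplit(sequence[[i]], "", fixed = TRUE)[[1L]]
    bad <- setdiff(aa, names(residue_mass))
    if (length(bad) > 0L) {
      stop("unknown residue(s) in '", sequence[[i]], "': ",
           paste(unique(bad), collapse = ", "), call. = FALSE)
    }
    sum(residue_mass[aa]) + water +
      cys_delta * sum(aa == "C") + acetyl * n_acetyl[[i]]
  }, numeric(1L))
}
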