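---
title: "Modelling ligand-acetylation two-step digestion and its label-free quantification pipeline"
author: "acetylAPMS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ligand-acetylation two-step digestion and its label-free quantification pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acetylAPMS)
```

## The problem

In affinity-purification mass spectrometry (AP-MS), a bait protein and its
interaction partners are captured on beads coated with a proteinaceous
ligand — an anti-GFP nanobody, streptavidin, or an antibody. When bead-bound
material is eluted by on-bead proteolysis, the ligand is digested along with
everything else, and because the ligand is present in vast molar excess its
peptides can dominate the LC-MS signal, limiting how much sample can be
injected and burying the proteins of interest.

A chemical countermeasure is to acetylate the ligand's lysines (e.g. with
Sulfo-NHS-Acetate) before the pull-down. Acetyl-lysine is refractory to
Lys-C and trypsin, so the ligand becomes proteolytically protected. Elution
is then done in two steps: Lys-C releases captured proteins from the beads,
the beads (with the protected ligand) are removed, and the eluate is
digested to completion with trypsin. This package models that protocol in
silico and implements the label-free quantification (LFQ) post-processing
used to evaluate it.

## The digestion model

Proteins are plain amino-acid strings with a role (`ligand`, `bait`,
`background`) and, for ligands, a bead-attachment residue. Coordinates are
1-based and inclusive, the R/Bioconductor convention; "cleavage site at
position $i$" means the peptide bond after residue $i$ is cut.

Cleavage rules are the standard specificities: Lys-C cuts after K; trypsin/P
cuts after K or R with no proline restriction (classic trypsin, with the
restriction, is also available). Both are blocked at acetylated lysines.
Site finding is therefore:

$$ i \in \mathrm{sites} \iff r_i \in \mathrm{targets},\; i < L,\;
   i \notin \mathrm{acetyl},\; (\neg\mathrm{proline\ rule} \lor r_{i+1} \neq P) $$

`digest()` enumerates all peptides bounded by two cleavage boundaries
(including the termini) spanning at most `max_missed` internal sites — the
usual missed-cleavage enumeration of database search engines, with
`max_missed = 2` as the default. Two invariants pin the implementation
down: the zero-missed-cleavage peptides concatenate exactly to the parent,
and the full enumeration matches a brute-force boundary-pair oracle on
random sequences.

`two_step_digest()` composes the protocol: a Lys-C digest of the anchored
protein; every fragment whose span covers the attachment residue is
*retained* on the bead, the rest are *released*; released fragments are
then digested with trypsin/P. Retained fragments never reach the trypsin
step, because the beads are physically removed before it. The bead anchor
is modelled as a single residue index (default 1): the real coupling
chemistry and topology are unknown, and a single-anchor model is the
simplest contract that captures "one fragment stays behind".

Acetylation is stochastic and all-or-none per lysine: `acetylate()` draws
each lysine independently with probability `p` (no site-specific
reactivity model — there is no data to support one).

### Released-signal prediction

`ligand_signal_fraction()` predicts the relative ligand signal reaching the
sample as a function of `p`. The proxy for "signal" is the summed residue
length of Lys-C-released material under the zero-missed-cleavage partition
(the physical outcome of complete digestion; the subsequent tryptic step
re-cuts but does not change the total). The value is a Monte-Carlo mean
over acetylation draws, normalized to `p = 0`, so it is 1 for mock
treatment and declines to 0 when every Lys-C site the release depends on is
blocked. Residue length is a deliberately crude intensity proxy: it is
deterministic and avoids inventing ionization efficiencies; it is also the
first thing to swap out if peptide-level response factors ever matter.

The mapping from reagent concentration to per-lysine probability is not
modelled at all; titrations are parameterized by `p` directly, so simulated
titration curves are qualitative (monotone decline, endpoints 1 and 0), not
a numerical reproduction of any particular bead-treatment series.

### Masses

`monoisotopic_mass()` sums IUPAC monoisotopic atomic masses (C, H, N, O, S,
P), hard-coded at 6-decimal precision so results are reproducible without a
runtime lookup. The two fixed cysteine modifications used in this workflow
come out at their catalogue values: carbamidomethyl (C2H3NO) = 57.02146 Da
and methylthio (CH2S) = 45.98772 Da. Peptide masses are residue masses plus
one water.

## The quantification pipeline

The pipeline operates on `quant_table` objects: a features × samples
intensity matrix (missing = `NA`, never zero; zeros in input TSVs are read
as missing), feature annotation (protein mapping, peptide support,
contaminant and ligand flags) and a condition × replicate design parsed
from `<condition>_rep<k>` column names.

**Filtering.** `filter_proteins()` keeps proteins that are (i) not
contaminants, (ii) identified with ≥ 2 peptides and (iii) quantified in
≥ 2 replicates of at least one condition. The filter is idempotent and
order-preserving.

**Normalization.** Log2 intensities are aligned across runs by the mode of
pairwise ratio distributions: for samples $i, j$, $m_{ij}$ is the mode of
$\{x_{pi} - x_{pj}\}$ over co-observed proteins, estimated by a Gaussian
kernel density with Silverman's rule-of-thumb bandwidth, maximized on a
512-point grid. The mode, unlike the mean or median, ignores the asymmetric
minority of genuinely changing proteins. Per-sample factors $f$ solve

$$ \min_f \sum_{i<j} (f_i - f_j - m_{ij})^2 \quad \text{s.t.} \sum_s f_s = 0 $$

a global least squares over all pairs. Solving jointly (rather than against
a reference sample) uses every pair symmetrically and has a closed-form
solution; disconnected pair graphs are rejected as unidentifiable. Because
the kernel density estimate is translation-equivariant, normalizing an
already-normalized table returns factors that are zero to numerical
precision — a useful self-check. The mode estimator itself carries sampling
noise of roughly 0.02–0.05 log2 units per factor at a few hundred
co-observed proteins and typical replicate scatter; recovery checks in the
test suite are designed around that floor (they assert typical error, not
single-draw error, when the scatter is large).

**Imputation.** Missing LFQ values are left-censored — low-abundance
proteins drop below the detection limit — so they are imputed from a
downshifted Gaussian: per sample, draws from
$\mathcal{N}(\tilde{x}_s - 1.8\,\sigma_s,\ (0.3\,\sigma_s)^2)$ with
$\tilde{x}_s$ and $\sigma_s$ the median and SD of that sample's *observed*
values. Defaults `downshift = 1.8` and `width = 0.3` are the standard
proteomics choice. Medians and SDs are computed per sample from observed
values only, after normalization: imputing post-normalization avoids
re-shifting imputed cells. Observed cells are never touched, and a sample
with fewer than 3 observed values is an error (its SD is not meaningful).

**Replicate metrics.** `replicate_pair_ratios()` pairs samples replicate-
by-replicate (1 vs 1, 2 vs 2, ...) and returns per-protein log2 ratios
where both members are observed; `median_ratio()` summarizes them with the
median over per-protein means, by default restricted to proteins quantified
in every replicate pair. `protein_cv()` computes SD/mean on *linear*
intensities (de-logging first) — the standard proteomics reading of a CV;
`count_quantified()` counts non-ligand, non-contaminant proteins observed
in ≥ 2 replicates per condition. `protein_from_peptides()` sums uniquely
mapped peptide intensities per protein; shared peptides are dropped
entirely (razor assignment is out of scope), which undercounts shared
signal but never double-counts.

**Ligand accounting.** `ligand_contamination_report()` ranks ligand
peptides by mean intensity in a reference condition, sums the top 5 (or
`top_n`) per sample, averages within conditions and reports relative to the
reference — the same readout used to quantify how much ligand survives a
bead treatment.

No statistical testing is performed anywhere: the pipeline reports ratios,
counts and CVs, and adding a test procedure would be scope invention.

## The synthetic experiment generator

`generate_experiment()` draws a complete two-condition pull-down with known
ground truth, so every pipeline operation is testable without any external
data:

* per-protein log2 abundances $\sim \mathcal{N}(20, 2^2)$ (log-normal
  intensities), split across 5 peptides per protein with fixed random
  weights;
* a bait at the distribution centre plus 4 log2 units of enrichment in the
  tagged condition only, and 10 interactors at +2 (the bait's base
  abundance is fixed, not drawn, so it is observable in both conditions and
  its enrichment recoverable);
* ligand peptides produced *mechanistically*: each sample gets a fresh
  acetylation draw at the arm's `acetylation_p`, is two-step digested, and
  each released peptide carries a share of the ligand abundance (log2 27 by
  default — dominating the background, as untreated-bead ligand codigestion
  does) proportional to its residue length;
* per-sample zero-sum log2 shifts (defaults spanning ±0.4) and replicate
  noise of 0.25 log2 — the replicate variance is a documented constant, not
  a literature-derived value;
* left-censored missingness: each cell is dropped with probability
  $\mathrm{logit}^{-1}((16 - x)/1)$ in log2 intensity — the standard MNAR
  model that downshifted imputation presumes.

The truth object records the shifts, enrichments, acetylation probability,
expected released-ligand fraction, the complete pre-censoring matrix and
the dropout indicators, which is sufficient to score recovery of every
quantity the pipeline estimates. `simulate_titration()` reuses the ligand
machinery over a grid of `p` values with duplicate simulated replicates.

What the generator does *not* emulate: peptide-level ionization and
digestion-efficiency variation, correlated (batch) noise, interference
between co-eluting peptides, razor/shared peptide structure, or any
concentration-to-`p` calibration. Non-ligand proteins are abstract
intensity carriers without sequences — only the ligand's peptides are
mechanistic. Passing tests on generated data therefore demonstrate that the
pipeline recovers what it claims *under its own noise model*, not
instrument-grade realism.

## Numerical and design choices

* **Coordinates** are 1-based inclusive throughout, matching R and
  Bioconductor; concatenation invariants are tested in that convention.
* **Mode estimation** uses `stats::density(bw = "nrd0", n = 512)`; constant
  ratio vectors short-circuit to their common value before the KDE grid
  machinery can degenerate.
* **Ties and degenerate input**: a ligand that releases nothing even
  unmodified falls back to intact length as the reference and warns; pairs
  with < 2 co-observed proteins error, pairs with < 10 warn.
* **Determinism**: every stochastic function takes an optional `seed`;
  the generator and CLI are byte-reproducible given config + seed.
* **Problem sizes** used by the test suite (300–400 proteins, 10^4
  Monte-Carlo digestion draws, 10^5 imputation draws) were chosen so that
  Monte-Carlo standard errors sit an order of magnitude below the asserted
  tolerances; the whole suite runs in well under a minute.

## Known limitations

* Protein N-terminal amine acetylation by the acetylating reagent is not
  modelled; only lysine side chains are. If the ligand's N-terminal
  fragment is release-relevant, the protection is slightly overestimated.
* The length proxy for peptide signal ignores ionization efficiency; the
  titration curve's *shape* between its endpoints should not be
  over-interpreted.
* Shared peptides are discarded rather than razor-assigned, which biases
  protein intensities low for homologous families.
* The CV is defined on linear intensities; if a log-scale CV convention is
  needed, compute it from the table directly.
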