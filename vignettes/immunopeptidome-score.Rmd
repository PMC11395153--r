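---
title: "Scoring HLA class I immunopeptidomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring HLA class I immunopeptidomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunopepscore)
```

## The problem

Immunopeptidomics characterizes the repertoire of peptides presented by HLA
class I molecules at the cell surface. After immunoprecipitation of HLA-I
complexes and LC-MS/MS acquisition, a search engine produces identification
tables: thousands of peptide sequences with charge, m/z, ion mobility, and
protein assignments, plus de novo identifications carrying an average local
confidence (ALC). Only a fraction of these identifications have the
properties of genuine, therapeutically interesting HLA-I ligands. This
package implements a reproducible prioritization of that fraction: quality
control of the identification table, interfaces to MHC binding and
immunogenicity predictors, and a three-stage decision-tree score -- the
Immunopeptidome Score -- that selects candidate immunopeptides.

## The decision tree

Each unique, non-contaminant peptide is scored in three ordered stages:

1. **Length.** One point if the peptide is 8--12 residues long (inclusive),
   the canonical window for peptides anchored in the HLA-I groove. Peptides
   outside the window are dismissed: later stages are not evaluated and
   contribute 0.
2. **Binding.** One point if a strong predicted binding is reported for at
   least one of the sample's class I alleles. "Strong" means a percentile
   rank at or below 0.5%, "weak" at or below 2%; weak or absent binding
   dismisses the peptide.
3. **Immunogenicity.** One point for a strictly positive predicted
   immunogenicity score.

The final score is the sum of stage points (0--3); peptides scoring 3 are
the selected set. Because the stages form a conjunction, the selected set is
invariant to stage order -- a property the test suite verifies against a
brute-force filter -- while the intermediate scores and the funnel depend on
the canonical order above. Per-sample funnels report the percentage of
peptides surviving each stage, starting from 100% of the unique
identifications, together with the most restrictive stage (largest relative
loss among peptides reaching it; ties resolve to the earlier stage).

Boundary semantics are inclusive everywhere a threshold is stated: rank
0.5 is strong, rank 2.0 is weak, ALC exactly 80 is retained, CRAPome
Ave SC exactly 5 is "expected", lengths 8 and 12 both pass. An
immunogenicity score of exactly 0 fails the strict-positivity requirement
and scores no point.

## Quality control

Three table-level summaries describe a run before scoring:

- **Length and charge distributions.** Exact histograms, plus the charge
  histogram conditioned on 8--12-mers, where charges are expected to remain
  within +1..+4.
- **Ion-mobility geometry.** Trapped-ion-mobility runs show two clouds in
  the (m/z, 1/K0) plane: singly charged, high-m/z peptides with higher
  reduced mobility, and multiply charged peptides at lower m/z. The
  published description of these groups is qualitative, so the partition is
  recovered with a deterministic 2-means surrogate: both coordinates are
  scaled to unit variance, centroids are initialized at the data points
  sitting at the 10th and 90th percentile of m/z (no randomness), Lloyd
  iterations run to convergence, and the group with larger mean m/z is
  always labeled as the single-charge group. With fewer than two distinct
  points the function returns a single group with a warning rather than
  failing.
- **CRAPome expected fraction.** Proteins are flagged "expected" when their
  CRAPome Average Spectral Count is at most 5 (inclusive). Proteins absent
  from the CRAPome table are treated as Ave SC 0 and therefore expected:
  CRAPome catalogs frequent affinity-purification contaminants, so absence
  is evidence of specificity.

Deduplication collapses the table to one record per unique bare sequence --
charge variants and modification variants of the same sequence count once,
matching ID counting "without repetitions". Records whose every protein
accession is on the contaminant list are removed first; de novo records,
which carry no accessions, are never flagged as contaminants. De novo
records are filtered at ALC >= 80 before scoring, and database-search and
de novo peptides are scored and reported as separate funnels throughout.

Two open points were settled as follows. Leucine and isoleucine are kept
distinct in uniqueness and overlap computations (mass spectrometry cannot
distinguish them, but collapsing them would change counts irreversibly;
callers can collapse upstream if desired). The FDR level of the originating
search (5% discovery mode or 1% standard) is trusted metadata of the input
table: comparing FDR regimes means reading two tables, never rescoring.

## Predictors: adapters and stand-ins

Real predictions enter through file adapters: the whitespace-aligned text
report or TSV export of NetMHCpan-4.1, and the CSV of the IEDB class I
immunogenicity tool. Two adapter decisions matter. When both eluted-ligand
(EL) and binding-affinity (BA) percentile ranks are present, the EL rank is
used -- it is the server default's headline quantity; this is configurable
at read time by the file supplied. And the strong/weak/non classification
is always recomputed from the rank with the package's thresholds, never
trusted from the file's SB/WB annotations; disagreements are counted and
surfaced.

The built-in stand-ins exist so the whole pipeline is testable offline.
They are deliberately simple, clearly named surrogates -- not
re-implementations of the neural-network predictors -- and the command line
requires asking for them explicitly (`--backend standin`).

- **Binding.** A per-allele position-weight model scores a peptide as the
  sum of position weights; the percentile rank against `background_n`
  random background peptides of the same length is
  `100 * (1 + #{background >= score}) / (background_n + 1)`, an estimator
  that avoids rank 0, stays in (0, 100], and is non-increasing in the
  score. The weights live only on position 1, the position-2 anchor, and
  the C-terminal anchor (two preferred residues per anchor receive a +2.5
  log-odds bonus; internal positions carry weight exactly zero). This
  anchor-block design has two consequences exploited throughout: the score
  distribution over the 20^3 anchor combinations is exactly enumerable, and
  binding is statistically independent of anything encoded in the internal
  positions. One caveat of a degenerate configuration is worth noting: if
  all weights are zero every peptide scores alike, and the estimator
  correctly assigns everyone rank 100; uniformity of ranks holds for
  score distributions without mass points, which the default motifs
  guarantee.
- **Immunogenicity.** The score is a position-weighted sum of per-residue
  propensities with positions 1, 2 and the C-terminus masked to zero --
  those are the MHC anchors, facing the groove rather than the T-cell
  receptor, mirroring the masking of the predictor this stands in for. The
  default propensity scale is Kyte--Doolittle hydropathy centered to sum to
  zero, putting the immunogenic/non-immunogenic boundary at score 0.

Peptides shorter than 8 or longer than 12 residues are never sent to
predictors: the length stage dismisses them first, and the prediction
window matches the 8--12-mer submission used with binding servers.

## The synthetic generator and its expected funnel

`generate_sample()` draws identification tables that emulate the reported
structure of real HLA-I runs, with full planted truth, so parameter
recovery can be tested end to end. Defaults (all overridable in
`synth_config()`):

- **Length**: mode at 9, 78% of mass on 8--12, 4% 7-mers, geometric tail to
  40 residues. Real tables occasionally reach beyond 60 residues, but the
  tail is always dismissed at stage 1, so a shorter cap merely speeds
  simulation.
- **Charge**: banded categorical distributions over +1..+6; 8--12-mers stay
  in +1..+4 and peak at +2.
- **m/z** is computed exactly from the monoisotopic mass and charge, and
  **1/K0** from a two-cluster linear model conditioned on charge, which
  reproduces the two clouds the QC step must find.
- **De novo rows**: 8% of records, with ALC drawn from Beta(5, 1.5) scaled
  to [50, 100], putting roughly a quarter of them below the 80% filter so
  the filter is exercised in both directions.
- **Contaminants**: 3% of database rows carry a bundled contaminant
  accession (the published decontamination removes a few percent of IDs).
  De novo rows cannot be contaminants (no accessions), so the fraction is
  defined over database rows.
- **Duplicates**: 2% extra rows re-emit earlier peptides as charge variants
  or methionine-oxidation variants; the printed mass delta is the delta
  used, so m/z remains exactly re-derivable from the raw sequence.
- **Planted binders**: 30% of window-length peptides take their three
  anchor residues from combinations in the extreme tail of their allele's
  exact score distribution (background tail probability at most 0.8 x
  0.5%), making their stand-in rank fall at or below 0.5% with
  near-certainty under an independent prediction background -- the
  calibration is verified, not assumed, in the test suite (>= 95%
  required, ~100% realized).
- **Planted immunogenicity**: 50% of peptides draw their internal residues
  from positive-propensity letters, the rest from negative ones. Because
  binding reads only the anchor block and immunogenicity only the internal
  block, the two planted properties are exactly independent.

`expected_funnel()` turns a configuration into closed-form stage
expectations. Length is the window mass of the length distribution. For
binding, planted peptides pass with probability ~1; a non-planted peptide
can still pass when its rank against a finite background lands at or below
0.5% by chance, and with the anchor-block design this probability is
computed exactly: enumerate all 20^3 anchor combinations with their
background probabilities and tail probabilities T, and average
P(Binomial(background_n, T) <= k) over combinations, where k is the
largest background count still classified strong. Alleles are combined as
independent (their anchor preferences are drawn independently; residual
correlation through shared residues is well inside the test tolerance), and
selection multiplies by the planted immunogenic fraction. The recovery test
then requires the pipeline-observed funnel at n = 5000 to sit within 3
binomial standard deviations of these expectations per stage, and the
dedup/decontamination counts to match the realized planted truth exactly.

What the generator does **not** emulate: spectra, retention time, FDR
mechanics (decoy competition), real allele-specific motif biology, homology
between peptides, or shared peptides across samples. Passing the recovery
test therefore demonstrates that the pipeline's bookkeeping and decision
rules are correct under known truth -- it says nothing about predictor
accuracy on real data, which belongs to the external tools behind the
adapters.

## Overlap reports

Cross-sample comparisons (proteins, peptides, de novo peptides) use exact
Venn region counts for 2--3 labeled sets. The headline "percent common"
uses the union as denominator -- the only choice comparable between 2-set
and 3-set reports -- and per-set percentages (intersection over each set's
own size) are emitted alongside, since published percent-common figures are
sometimes set-relative. Region names follow the order in which sets are
given; swapping labels permutes names, not counts.

## Problem sizes and runtime choices

The test suite generates all fixtures in code. Property tests use 10^4
random prediction bundles for the oracle-equivalence check, n = 5000
synthetic records with a 10^5-peptide background per allele and length for
parameter recovery, and 10^4 background-distributed peptides for the
rank-uniformity check (Kolmogorov--Smirnov distance below 0.02). These
sizes keep each acceptance property well-powered at 3-sigma tolerances
while the full suite runs in under a minute.

## Known limitations

- The stand-in predictors are surrogates for interface testing; scientific
  conclusions about real peptides require the adapter backends.
- Published per-sample selected percentages depend on the original deposited
  raw data and live predictor services; they are context for interpreting
  funnels, not quantities this package can recompute from scratch.
- The NetMHCpan text parser targets the version 4.1 report layout; other
  versions may need the TSV export instead.
- Percentile ranks from the stand-in are background-sample dependent;
  reproducibility requires fixing `background_n` and the seed, which all
  entry points expose.
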