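---
title: "Scoring alternative gene models with protein-structure evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring alternative gene models with protein-structure evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scoring model

`structscore` decides between two structural annotations of one locus
by comparing the proteins they encode, using only computable evidence:
per-residue confidence from an AlphaFold-3-class predictor, structure
search against the PDB, and protein domain matches. The premise is
mechanistic: annotation errors that matter — a translated intron, a
missing exon, a frameshifted tail, a spurious start — produce protein
sequence that cannot fold consistently with the rest of the molecule,
which depresses local confidence (pLDDT), weakens similarity to known
structures (Foldseek bitscore), and breaks domain matches (InterPro
coverage). Errors confined to intrinsically disordered regions are
largely invisible to all three channels; that is an assumption and a
known limitation, not an oversight.

### Per-model metrics

For each model the package computes eleven canonical variables plus
auxiliaries (`build_score_vector()`):

| group | variables | notes |
|---|---|---|
| predictor | median pLDDT, pTM, mean PAE, n(pLDDT>80), n(pLDDT>90) | counts use strict `>`, configurable to `>=`; the full threshold grid {50,60,70,80,90} and banded counts are kept as auxiliaries |
| Foldseek | E-value, bitscore, LDDT, alntmscore of the top hit | top hit = lowest E-value, ties by higher bitscore then lexicographic target id; masked to (10, 0, 0, 0) when E ≥ 0.05 |
| InterPro | max domain length, total domain length | integrated (IPR-assigned) matches only; lengths are end − start + 1; the total is a plain sum (overlaps double-count), with a union-of-intervals mode available |

Counts above a threshold outperform the median and pTM because
disordered residues lower whole-protein summaries while leaving the
count of confidently folded residues untouched; pTM in particular is
strongly depressed by disordered content.

Missing values (no PAE matrix emitted, no pTM in a summary file, no
disorder track) are represented as explicit absence, never as 0. The
Foldseek sentinel is different: a non-significant hit is *evidence of
absence* of a structural neighbour, and the masking values (E = 10,
other scores 0) deliberately encode that.

### Pair scoring

`score_pairs()` computes Δ = new − old per metric, a sign score (+1
when the delta moves in the metric's good direction, −1 against, 0 at
exactly zero or missing), MaxAbs-scaled deltas (x / max|x|, fitted on
the dataset at hand, never pooled across datasets), combined sums over
four contexts (all 11 variables; and the best single variable per tool
— n(pLDDT>80), bitscore, IPR total length — in the three pairwise/
triple combinations), and win/lose calls (strict sign of the sum; an
exact zero is neither a win nor a lose and is tallied as its own
class). Decrease-good metrics enter sums with their scaled value
negated, so every term contributes positively when it favours the new
model; without this the masked E-value sentinel (10) would dominate
the all-variable sum.

### Ranking and AUC

`pair_confidences()` pools both members of every pair, MaxAbs-scales
the three best single variables on the pooled per-model values (old and
new must share a scale to be rank-compared), sums them into per-model
scores, and takes the pair confidence s_new − s_old. The ROC
construction treats every pair's ground truth as "the curated model is
better": pairs are ordered by |confidence| descending, a pair ranking
the new model first counts as a true positive and one ranking the old
model first as a false positive; tied pairs (confidence exactly 0) are
excluded from the curve and reported separately. Equal-|confidence|
groups advance as a block (diagonal segment), and the trapezoidal AUC
then equals the rank-sum probability that a correctly ranked pair has
larger |confidence| than an incorrectly ranked one —
`auc_oracle()` verifies this identity by exhaustive pairwise
comparison, and the test suite holds the two estimators to 1e-9
agreement. An alternative model-level formulation (each model an
instance labelled new/old, `auc_model_level()`) is provided for
sensitivity analysis; the pair-level formulation is the default
because it matches the true-positive / false-positive counting rule
stated above.

### Dataset construction

`pair_identities()` aligns old and new translations globally
(Needleman–Wunsch via Biostrings) and `filter_pairs()` retains pairs
with strictly less than 80% identity and change class `changed` —
substantial structural edits, where structure evidence can be
informative. Defaults: BLOSUM62, gap open −10, gap extend −0.5 (the
opening penalty includes the first extension), identity denominator =
full alignment length including gapped columns. All three choices are
exposed because published pair counts depend on them and the
convention is rarely stated; the shorter-sequence and aligned-columns
denominators are available. Note that with the alignment-length
denominator, purely terminal gaps are excluded, so a terminal
truncation or extension can still yield 100% identity.

## The synthetic generator

`synthetic_config()` defines the study conditions; `generate_pair()`
builds the curated (new) model first and derives the old model by
applying at most one error mode.

* **Architecture** — 1–3 ordered domains of 80–300 residues with
  disordered linkers/termini making up 20–50% of the protein, the
  disorder range seen across well- and poorly-ordered proteomes
  (apicomplexans sit at the high end, fungi lower).
* **Confidence emission** — ordered residues ~ N(88, 5) pLDDT,
  disordered ~ N(40, 8), clamped to [0, 100] and printed at 2 decimals
  (the precision predictors emit, which is what makes file round-trips
  exact). Each model additionally receives independent run-to-run
  variability: per-residue jitter (sd 2) plus a per-40-residue-block
  regional offset (sd 3). The regional term reflects alignment-depth
  effects that move whole helices or termini together; it is what makes
  wrong-direction changes of tens of high-confidence residues occur by
  chance, as real old/new comparisons show, and without it the count
  above 80 would be an implausibly clean signal.
* **Error modes** (weights 0.40/0.25/0.20/0.15, applied with
  probability `error_probability` = 0.8): *intron insertion* adds
  20–120 disordered-level residues inside a domain and depresses 15
  flanking residues on each side by 10 pLDDT units — the magnifying
  effect by which the neighbourhood of an erroneous insertion also
  loses confidence; *truncation* removes 20–120 residues from a
  domain; *terminal extension* prepends/appends 20–120 spurious
  low-confidence residues and depresses the adjacent genuine terminus;
  *frameshift tail* rewrites a 20–120 residue suffix at
  disordered-level confidence.
* **Downstream scores are mechanistic, not sampled** — bitscore = 0.5
  bits per intact ordered residue + N(0, 10) noise; LDDT/alntmscore
  are noisy monotone transforms of the intact fraction; pTM is a
  clamped function of the intact ordered fraction minus a damage
  penalty. InterPro matches cover maximal intact ordered runs of ≥ 30
  residues with boundary jitter (sd 5 residues, alignment-shift
  variability) and a 1% per-domain dropout (profile scores crossing
  the reporting threshold). Because scores are derived from the
  residue layout and written to files, the generator exercises the
  parsers and the metric code, not just the delta arithmetic.
* **Gene-level properties** — whether a protein family has an InterPro
  entry (missing probability 1/3, matching the observation that about
  a third of models lack IPR domains) and whether its fold is
  represented in the PDB (baseline non-significant probability 0.1)
  are drawn once per gene and shared by both annotation versions;
  corruption adds a further 0.2 chance of losing the structure hit.
  Drawing these per model instead would inject large spurious
  confidences into uncorrupted pairs and destroy the null calibration
  — a deliberate design decision.
* **Determinism** — each pair draws from an RNG substream derived from
  (seed, pair index), so datasets are byte-identical across runs and
  individual pairs can be regenerated alone.

The calibration of the noise scales was chosen so that the synthetic
regime reproduces the qualitative structure of real curation studies:
the combined three-score AUC sits in the ~0.8 band, exceeds each
single-score AUC on the same data, is near 0.5 when no errors are
injected, and grows monotonically with the error rate. The test suite
asserts exactly these properties (null calibration on 3 seeds at 500
pairs; discrimination and monotonicity at 300 pairs — sizes chosen to
keep the full suite comfortably under a minute and a half on one core).

What the generator does **not** emulate: real MSA-depth structure
(confidence variability is Gaussian, not depth-driven), correlations
between Foldseek LDDT/alntmscore and bitscore beyond a shared monotone
driver, compositional realism of sequences (uniform residue usage),
PAE matrices at scale (emitted only behind `emit_pae` for small test
proteins), split/merged/deleted/created change classes (recorded in
metadata but never generated), and predictor-family offsets between
alternative structure predictors. Passing tests therefore demonstrate
the correctness and calibration of the scoring machinery under
controlled error modes, not performance on any real proteome.

## Numerical choices and degenerate inputs

* Strict inequalities throughout: counts use pLDDT > t; the win/lose
  rule is > 0 / < 0 with exact zero its own class; the identity filter
  is < 80; masking triggers at E ≥ 0.05.
* Per-atom pLDDT reduces to residues by the arithmetic mean over the
  residue's atoms (CA-only available); the reduction is
  permutation-invariant within a residue and identical for the JSON
  and mmCIF carriers.
* MaxAbs factors for all-zero (or all-missing) metrics are set to 1 so
  scaled values stay 0; empty datasets are an error.
* `roc_from_pairs()` refuses datasets with no non-tied pairs or with
  only one class, naming the condition rather than returning a
  degenerate curve.
* Mean PAE averages the full matrix including the diagonal (≈ 0, so
  the choice is near-neutral); off-diagonal-only is available.
* CSV round-trips write doubles at 17 significant digits; readers
  treat empty cells as missing.

## Known limitations

Errors inside disordered regions are nearly invisible to all three
channels. pTM and median pLDDT are confounded by disorder content and
are retained for completeness, not recommendation. The Foldseek
channel is only informative for folds represented in the PDB, the
InterPro channel only where a family model exists. Score magnitudes
matter — small wrong-direction changes arise by chance — but the
win/lose calls deliberately use only the sign, mirroring the simple
tally analysis; the ROC ranking is where magnitude information is
used. No learned weighting of metrics is attempted: the combined sums
weight each scaled variable equally.
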