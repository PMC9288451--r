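---
title: "Coupling longitudinal transcriptomes to lung-function decline: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupling longitudinal transcriptomes to lung-function decline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrocouple)
```

# The analysis problem

Two mouse models of pulmonary fibrosis are profiled in parallel over a
four-week time course: bleomycin instillation, where epithelial injury
triggers acute inflammation that transitions into (partially resolving)
fibrosis, and AAV-delivered TGFβ1 overexpression, where fibrosis develops
only after roughly a week of sustained cytokine exposure but then persists.
At days 3, 7, 14, 21 and 28 after administration, treated animals (AAV:
n = 5 per day; bleomycin: n = 8) and their same-day controls (stuffer
vector: n = 5; NaCl: n = 6) contribute bulk mRNA and miRNA counts plus a
lung-compliance measurement. Compliance — volume change per unit pressure —
falls as fibrotic tissue stiffens, and is the phenotype that every
expression trajectory is judged against.

The package answers three questions: which genes and miRNAs *track* the
phenotype rather than merely differing somewhere; which deregulated mouse
miRNAs are actionable in humans (seed-conserved); and which miRNA–mRNA
regulatory interactions are supported jointly by expression anticorrelation
and sequence-based target prediction.

# Differential expression engine

Counts are transformed to `log2(count / library_size * 1e6 + 0.5)`. The
prior count of 0.5 is the conventional stabiliser: a zero count maps to
−1 on the log2-CPM scale and the transform is everywhere finite. Features
with CPM < 1 in more samples than `n - min_samples` are removed first,
where `min_samples` defaults to the size of the smallest (model, arm, day)
group, so a feature cleanly expressed in one full experimental group
survives.

Each model × day contrast compares treated vs the same-day, same-model
control by a per-feature Welch *t*-test on log-CPM; the effect estimate is
the difference of group means, i.e. the log2 fold change. *p*-values are
Benjamini–Hochberg adjusted **within one contrast** (all features at one
model × day), mirroring per-contrast moderation conventions. The DE call is
|log2FC| ≥ 0.6 and adjusted *p* ≤ 0.05; both thresholds are arguments
everywhere they appear.

Design notes:

* A Welch test on log-CPM replaces moderated-variance linear modelling.
  With five or more replicates per arm and desk-scale feature counts the
  moderation gain is modest; the contrast structure, thresholds and BH
  family are preserved, and a moderated engine could be added behind the
  same contract.
* Plain CPM normalisation is deliberately simple and carries a known
  limitation: strong one-sided induction inflates the library and shifts
  all other features' CPM downwards (composition bias). The simulator's
  default feature-space sizes keep planted signal a small fraction of the
  library, as in real data; with few features and large effects the bias
  becomes visible, which is a property of CPM itself, not of the test.
* The DE threshold appears once in the source text as 0.5 and elsewhere as
  0.6; 0.6 is used throughout the results being emulated, so 0.6 is the
  default.

# Phenotype coupling

The compliance trajectory is the treated-arm group mean at each of the five
days — log2FC is itself a group-level quantity, so correlating group-level
trajectories is the consistent choice; per-animal correlation is not
attempted. For each feature and model, Pearson *r* is computed between the
five per-day log2FCs and the five compliance values; `mean_r` averages the
two models. With only five points *r* is granular and no *p*-value is
attached — selection uses the threshold alone (default |mean *r*| ≥ 0.85;
a strict mode requires the threshold per model instead, since the source
is ambiguous about which was applied).

Selection for the "up" direction keeps features with mean *r* ≤ −0.85
(expression rises as compliance falls), adjusted *p* ≤ 0.05 at day 21 in
*both* models, and day-21 log2FC ≥ 0 in both; ranking is by mean day-21
log2FC. "Down" mirrors all signs. Degenerate (constant) trajectories yield
an explicit undefined-correlation flag and can never be selected silently.

The model-specificity partition at a day classifies features as exclusive
to one model or common by the magnitude-only cutoff |log2FC| ≥ 0.6; signs
are left free because the emulated analysis states only an "expression
cutoff", and direction consistency is enforced later during selection
where it is explicit. Per-set agreement is reported as the squared Pearson
correlation of the two models' log2FC vectors, undefined below three
members.

# Seed conservation

Seeds are mature positions 2–7 (1-based, inclusive). Mouse–human pairs are
matched by base name after stripping the species prefix, case-insensitively
and arm-sensitively (-5p vs -3p must agree). Both seeds and full matures
are scored by Needleman–Wunsch global alignment with match 1 and mismatch
0. No gap penalty is stated in the source; the package uses a linear −2
per gapped symbol. For equal-length 6-nt seeds any gap pair costs 4 to gain
at most 1, so gaps are never optimal and the conservation rule —
*conserved* ⇔ seed score 6 ⇔ character-identical seeds — is provably
gap-insensitive (and asserted as a property test). The mature score's mild
gap sensitivity is surfaced as a configurable parameter.

The mature-similarity flag defaults to score ≥ 20 ("at least 20 matched
base pairs"); the stricter reading "above 20" is available via
`inclusive = FALSE`. Mouse miRNAs without a human partner are categorised
`unpaired` and treated as non-conserved by every downstream filter.

# Target pairing and the network

Spearman's ρ (average ranks for ties) is computed for every miRNA–mRNA
combination across *all* samples of both models and all days, on filtered
log-CPM. The high-confidence set intersects ρ ≤ −0.6 with prediction by at
least 2 of the 5 tool columns of the prediction table; all comparisons are
inclusive, matching the printed symbols. A built-in seed-match predictor
(reverse complement of the seed occurring in a transcript) exists solely so
synthetic runs need no external prediction databases; real analyses should
supply tables from the established tools.

The network contains the selected miRNAs and their first-neighbour mRNAs;
repression edges carry the pair's ρ, and coexpression edges connect
included mRNAs with correlation ≥ 0.75 (same correlation kind as the
pairing, Spearman, by default — the source does not name the kind for
mRNA–mRNA edges, so it is configurable). Every node is annotated with its
day-21 log2FC in the AAV model, its number of significant contrasts and
its lung-function correlation; export is SIF (`represses` / `coexpr`
relations) or GraphML with all attributes.

# Staged miRNA selection

Stages, in order: (1) |mean *r*| ≥ 0.85, direction UP if anti-correlated
with compliance; (2) DE at ≥ 1 time point in each model (configurable to
either-model); (3) day-21 log2FC signs must agree between models *and*
with the correlation direction; (4) UP ∧ non-conserved candidates are
excluded — an upregulated miRNA would need inhibition in patients, which
requires the human ortholog to share the seed; (5) high-confidence targets
are attached for reporting. The graphic describing this cascade prints no
numbers, so stages 1–2 reuse the mRNA pipeline's thresholds; everything is
configurable, and the audit table records each candidate's first failing
stage, making the per-stage counts auditable where the original counts are
not recoverable.

# The synthetic study generator

`generate_study()` emulates the study conditions: the exact group sizes and
days above, negative-binomial counts via a gamma–Poisson mixture
(dispersion 0.05, typical for bulk RNA-seq), log-normal baseline
abundances (sdlog 1.2), and log-normal library sizes (CV 0.1, means 2×10⁵
mRNA / 6×10⁴ miRNA). Compliance declines from a 0.06 mL/cmH₂O baseline by
40% at day 21 along a logistic ramp; the AAV ramp is shifted by the 7-day
onset delay so day-3 AAV compliance is near baseline while bleomycin
already declines — the time-shift seen in the phenotype data. A smooth ramp
rather than a hard step avoids discontinuities the real trajectories do not
show.

Planted structure, all recorded in `truth`:

* 30 UP and 20 DOWN tracking genes whose treated-arm log2 mean shift is the
  model's normalised compliance deficit times the day-21 effect size
  (default 2.0, a typical magnitude for fibrosis marker genes).
* 16 tracking miRNAs (8 up, 8 down); 3 per direction receive a human
  ortholog with ≥ 1 mutated seed position, the rest share the seed exactly.
  Non-planted miRNAs get a human partner with probability 0.6 and a random
  seed status, so the conservation corpus is non-trivial.
* 3 repression targets per planted miRNA, drawn from non-planted genes.
  Repression is log-linear: the target's log2 mean moves by
  −`repression_strength` (default 0.8) times the regulator's log2 shift,
  so induced miRNAs repress and depleted miRNAs de-repress symmetrically.
  (A literal multiplicative `1 − strength × induction` was considered and
  rejected: it caps de-repression at +0.85 log2 units, too weak for
  planted pairs to exhibit the anticorrelation they are meant to carry.)
* The prediction table lists every planted pair under 2–3 random tools and
  ~200 single-tool decoy pairs, so the ≥ 2-tool filter has real work to do.

Feature-space sizes (500 genes, 300 miRNAs) are chosen so that a full
20-seed recovery experiment runs in well under a minute while planted
features remain a small fraction of each library — with very few simulated
miRNAs, CPM composition bias couples every null miRNA to the planted
signal, which is unrealistic for a miRBase-scale universe of detected
miRNAs.

All randomness flows from `rng_seed`; identical configurations reproduce
byte-identical artifacts, which the test suite asserts.

What the generator does **not** emulate: batch effects, sample dropout/QC
exclusions, mean–variance trends beyond a constant dispersion, correlated
null genes, isoform structure, and sequence composition of real 3'UTRs.
Passing recovery tests therefore demonstrate that the pipeline's logic
recovers planted structure under its stated noise model — not that the
thresholds have the same operating characteristics on any real dataset.

# Numerical and degenerate-input conventions

* Undefined correlations (zero variance, all ties) are explicit `NA`s with
  an `undefined` flag; they are excluded from selections, never coerced to
  zero.
* BH adjustment, Pearson/Spearman and the alignment DP are each checked
  against independent brute-force oracles (step-up from the definition,
  the covariance formula, exhaustive alignment enumeration) in the test
  suite.
* All thresholds compare inclusively (≥ / ≤), matching the printed
  symbols; boundary behaviour is pinned by tests.
* Ranking ties (e.g. identical rank keys) fall back to input order; with
  continuous data exact ties have measure zero.
* `run_full_pipeline()` stamps every table artifact with the MD5 hash of
  the YAML-serialised configuration; the run log records every threshold
  and each stage's in/out counts. Network files (SIF/GraphML) are listed
  in the log rather than stamped, since comment lines are not part of
  either format's contract.

# Known limitations

* The DE engine is unmoderated; at n = 2–3 replicates its power drops
  faster than a shrinkage estimator's would.
* Five correlation points make the |r| ≥ 0.85 filter coarse: the smallest
  step between achievable values is large, and no significance is attached.
* CPM normalisation is composition-sensitive (discussed above).
* The seed-match predictor ignores site context, pairing stability and
  conservation of the target site; it is a plumbing stand-in, not a
  biological predictor.
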