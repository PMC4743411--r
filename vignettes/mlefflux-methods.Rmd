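---
title: "Methods: collation rules, multi-label strategies, and the synthetic study design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: collation rules, multi-label strategies, and the synthetic study design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

BCRP (ABCG2) and P-glycoprotein (ABCB1) are promiscuous ABC efflux pumps
with overlapping inhibitor profiles. Profiling a compound against both at
once is a *multi-label* problem, and the data situation is characteristic:
a small core of compounds measured on both targets (the *dense* dataset)
inside a much larger set with annotation for only one (the *sparse*
dataset). An absence of annotation is **not** an absence of activity — the
pumps are too promiscuous for that assumption — so all modelling here
treats unannotated cells as missing, never as negatives.

# Collation model

Raw records are (compound, target, endpoint, value, relation, assay,
source) tuples. The pipeline applies, in order:

1. **Endpoint/unit gate.** Only IC50, EC50 and Ki in nanomolar are
   accepted; other rows are logged with a reason, never silently dropped.
2. **Sanity cap.** Values strictly above 10^8 nM are discarded as probable
   unit errors; exactly 10^8 is kept (the cap is strict).
3. **Log transform.** pActivity = −log10(value · 10⁻⁹); 10 µM ⇔ 5.0.
4. **Binarization at pActivity > 5 (strict).** Relation signs are handled
   conservatively: a `<`/`<=` record makes the computed pActivity a lower
   bound, so it is called active only when the bound itself is ≥ 5 and is
   otherwise *ambiguous*; `>`/`>=` mirrors this for inactives. Ambiguous
   records are removed before pivoting — a record that only says
   "weaker than 1 µM" decides nothing at a 10 µM cutoff.
5. **Pivot by InChIKey × target.** The full 27-character standard InChIKey
   is the merge key. The first block alone would merge stereoisomers;
   transporter inhibition can be stereo-sensitive, so the full key is the
   safer default.
6. **Consensus per cell.** Pre-curated labels win outright (they encode
   assay-by-assay expert thresholds); conflicting pre-curated labels drop
   the cell, since no principled precedence exists between two experts.
   Otherwise the median of the measurement labels decides, and a median of
   exactly 0.5 — equal numbers of 0s and 1s — drops the cell. The drop is
   applied per cell, not per compound: a compound with a conflicted BCRP
   cell keeps its clean P-gp annotation and remains in the sparse dataset.
   Consensus operates on binarized labels, not on pooled pActivity values,
   so one outlying potency measurement cannot flip a cell by itself.

Re-running the collation on the same input is bit-identical; no stage uses
randomness.

## Structure standardisation

Washing is rule-based and open: keep the largest organic fragment of a
multi-fragment input (salt stripping), reject when the two largest
fragments tie in heavy-atom count (no defensible winner), neutralize simple
protonation states (OpenBabel's neutralize transform: protonated amines,
deprotonated acids), reject organometallics (metal–carbon bond) and any
fragment containing an element outside {H, B, C, N, O, F, Si, P, S, Cl,
Br, I}. Standardisation is idempotent, and the InChIKey is computed only
from the standardized structure. Pre-curated entries whose structures
cannot generate an InChI are rejected and logged rather than guessed at.

# Descriptor panel

The interpretable panel deliberately reimplements classical 2D descriptors
with open, auditable rules (the proprietary originals are not
redistributable; values are equivalents, not bit-identical copies):

- **a_aro** — atoms in rings flagged aromatic by the ring perceiver.
- **a_hyd** — carbons with no N/O/P/S neighbour, plus halogens on carbon.
- **SlogP** — Wildman–Crippen atomic-contribution logP (OpenBabel); additive
  over fragments by construction.
- **vsa_acc** (Å²) — exposed van der Waals sphere surface of H-bond
  acceptors, with neighbour caps computed from covalent-radius bond-length
  estimates (a Labute-style approximation).
- **a_donacc** — |donors ∪ acceptors|; an amphiprotic oxygen counts once.
- **weinerPath** — sum of heavy-atom shortest-path lengths (hydrogens
  suppressed).
- **BalabanJ** — J = q/(µ+1) Σ_edges (s_i s_j)^(−1/2) on the heavy-atom
  graph; defined as 0 for a single atom, and as an error for disconnected
  graphs (standardisation guarantees one fragment upstream).
- **apol** (Å³) — tabulated element polarizabilities summed over all atoms
  *including* implicit hydrogens.

Fingerprints: MACCS keys truncated to the canonical 166 bits, and Morgan
(ECFP-like) circular fingerprints of diameter 8 folded to 1024 bits by
OR-ing hash blocks. Bemis–Murcko scaffolds are the 2-core of the heavy-atom
graph (rings plus ring–ring linkers) with multiply-bonded attachments
retained, canonicalized as SMILES; acyclic molecules get the empty scaffold
`""`, which the profiler treats as one cluster of its own.

# Multi-label strategies

With labels ordered (P-gp, BCRP), the label-powerset class is
`y_Pgp + 2·y_BCRP`; encode/decode are exact inverses, and encoding a matrix
with missing cells is an error by design. Binary relevance trains one model
per label on that label's annotated rows. The classifiers chain shuffles
the label order under the run seed (or takes an explicit order), trains the
first submodel on its annotated rows, scores *every* compound — including
unannotated ones — and appends the score (a probability, never a hard
label) as a feature for the next submodel.

Two leakage decisions deserve explicit statement:

- At **prediction** time (including held-out folds), the chain always
  propagates its own predicted scores, never the truth — anything else
  would leak test labels into features.
- At **training** time the default augmentation uses in-sample fitted
  scores, the literal reading of the chain procedure. An alternative
  out-of-fold mode (`augment = "oof"`, internal 3-fold) is available for
  users worried about optimistic augmentation, default off.

Cross-validation assigns whole compounds to folds, stratified by
annotation pattern so no fold loses a class entirely (plain random folds
by flag). Metrics (accuracy, MCC, Cohen's kappa, AUC) are computed per fold
per label on held-out annotated cells, averaged over folds, repeats, then
labels (macro-averaging, unweighted). A fold whose held-out truth for a
label is single-class has no defined AUC; it is excluded from that label's
mean with a warning. MCC with a zero denominator is defined as 0.
Multi-class AUC (for powerset models) is the unweighted one-vs-rest mean —
other conventions exist, so cross-toolkit AUC comparisons on the powerset
task carry a caveat. Because binary relevance and the chain share the fold
assignment under a common seed, their comparison is paired.

Base learners are off-the-shelf: `stats::glm` logistic regression
(`nnet::multinom` beyond two classes), `randomForest` (100 trees),
`e1071::svm` (polynomial kernel, degree 2, probability outputs), and
bootstrap-aggregated `rpart` trees (50 by default) — the last doubling as
the interpretable ensemble whose importance measure is the mean fraction
of training samples passing through a feature's split nodes (a root split
sees 100 % of the data and scores exactly 1).

# Interpretation tools

The MCC threshold scan evaluates the rule "value ≤ t ⇒ first-listed class"
at every midpoint between consecutive distinct observed values and reports
the signed curve plus the |MCC|-maximal peak; a negative peak means the
inverse orientation separates better. The printed two-descriptor
selectivity rule (a_hyd ≤ 21 → BCRP-selective; else a_aro ≥ 24 →
BCRP-selective; else P-gp-selective) ships as a fixed, executable model;
`derive_selectivity_thresholds()` fits a plain classification tree on the
two descriptors and reports its primary split points for comparison with
the constants. Scaffold "enrichment" is reported descriptively as
per-cluster label proportions — with clusters of a handful of compounds a
hypothesis test would suggest more rigour than the data supports.

# The synthetic study

The generator's defaults *are* the study conditions the analyses assume,
chosen once:

- **Class proportions (27, 48, 39, 47)/161** over the four powerset
  classes — the composition of the curated dense two-transporter panel.
- **n = 1000 compounds, annotation overlap 0.5, label noise 0.1** for the
  modelling experiments: overlap 0.5 gives both strategies enough dense
  rows to differ meaningfully, and a 10 % flip rate represents
  inter-assay disagreement near the 10 µM cutoff without drowning the
  signal. The curated-panel geometry (n = 2191, overlap 161/2191) is used
  where the sparse/dense split itself is under test.
- **Descriptor distributions** are per-class Gaussian mixtures encoding
  the qualitative trends the interpretation stage must recover:
  P-gp-selective compounds have many hydrophobic atoms and mid-range
  SlogP; BCRP-selective compounds split into a low-hydrophobicity/low-logP
  component and an aromatic-rich/high-logP component (so the class is
  deliberately *not* linearly separable on SlogP alone, and the fixed rule
  holds for ≥ 90 % of class-2 draws and ≤ 10 % of class-1 draws); dual
  inhibitors straddle both selective groups in SlogP and carry a slightly
  higher mean polarizability sum (78.2 vs ≈ 76.9). The component means are
  placed so the class-density crossings sit near the rule constants
  (≈ 21 hydrophobic atoms, ≈ 24 aromatic atoms), which is what makes a
  tree inducer's re-derived thresholds land near the printed ones rather
  than anywhere inside an empty margin. Count descriptors are rounded and
  clamped at zero.
- **Records**: each annotated cell expands to ≥ 1 measurements (Poisson
  multiplicity around 2), with 10 % relation-signed records, a 15 %
  pre-curated subset, and 5 % conflict cells that receive exactly
  balanced 0/1 measurements — dropped by consensus unless a pre-curated
  record rescues them. Active values are drawn log-uniformly on
  pActivity (5.1, 9), inactives on (1.1, 4.9), leaving a margin at the
  cutoff so relation records never become ambiguous by accident.
- **Template structures**: SMILES assembled from a small scaffold library
  (quinoline, naphthalene, phenylpiperazine, xanthone, indole, biphenyl,
  benzimidazole, benzene) plus acyclic substituents — long alkyl chains
  for P-gp-selective compounds, short polar heads on aromatic-rich
  frameworks for BCRP-selective ones. Substituents are acyclic by
  construction so every compound's Murcko scaffold is exactly its
  template, making planted cluster sizes exactly recoverable.

The **label-dependence scenario** used to demonstrate the chain's value is
constructed around annotation asymmetry: label A is a lightly noised XOR
of its two informative features and fully annotated; label B is a noisy
copy of A, its own features pure noise, annotated for only 10 % of
compounds. A tree ensemble cannot learn the XOR from B's few rows, but the
chain hands B's model A's propagated score — a single near-sufficient
feature distilled from A's full annotation. This is the regime where
chaining should help: few annotations on one label, exploitable dependence
on another. When both labels are densely annotated and the dependence is
linear, binary relevance matches the chain — which is itself an
informative negative result.

What the generator does **not** emulate: real descriptor covariance
structure, activity cliffs, assay-family batch effects, series-level
redundancy between train and test compounds, or medicinal-chemistry
diversity. Passing the recovery tests therefore demonstrates that the
machinery is correct and that the planted signal is recoverable — not that
comparable performance would be reached on prospective real data.

# Numerical choices and degenerate inputs

Strict inequalities at both decision boundaries (pActivity > 5,
value > 10^8), per the collation rules. Scan thresholds are midpoints, so
ties in observed values are handled without arbitrary jitter. Seeds are
derived per stage and per label from the run seed via a fixed integer
recurrence (kept below 2³¹), so binary relevance and a one-label chain are
bit-identical under the same seed, and repeats never share an RNG stream.
Empty provenance lists, single-class label columns, missing cells in a
powerset encoding, empty class subsets, and single-class scans all raise
errors naming the offending label or input rather than returning NA.

Problem sizes in the shipped tests and acceptance script — n = 1000 for
parameter recovery, 10 × 400 for the chain-benefit replicates, 2191 for
the sparse/dense geometry, 40 template structures for scaffold recovery —
are the sizes at which the targeted effects are comfortably resolved by
the corresponding statistical checks (binomial 3σ bounds, paired AUC
comparisons).

# Known limitations

- Descriptor values are open equivalents, not reproductions of the
  proprietary originals; models trained on one panel are not transferable
  to values computed by the other.
- OpenBabel's aromaticity and neutralization conventions differ at the
  margins from other toolkits; InChIKeys are computed post-standardisation
  and shared keys require shared washing rules.
- The chain implementation covers a single chain; ensembles of chains
  (averaging over random orders) are out of scope.
- Quaternary ammonium and other permanently charged centres survive
  neutralization and are retained, not rejected.
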