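---
title: "Methods: two-entropy scanning and docked-pose counting for transferase-specific residues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-entropy scanning and docked-pose counting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gelpscan)
```

## The scientific problem

Most GDSL-motif esterase/lipase family proteins (GELPs) are hydrolases, but
a few — TciGLIP of *Tanacetum cinerariifolium*, which assembles the
insecticide pyrethrin I from chrysanthemoyl-CoA and pyrethrolone, and its
relatives TcoGLIP, TaXAT and SlCGT — act predominantly as acyltransferases.
The catalytic triad (Ser40, Asp318, His321 in TciGLIP numbering) is shared
by both activities, so the residues that *switch* a GELP from hydrolysis to
acyl transfer must lie elsewhere. `gelpscan` implements the two
computational instruments used to hunt for them:

1. a **two-entropy scan** of a group-labelled multiple sequence alignment
   that ranks columns conserved preferentially in the small transferase
   group against a large esterase + putative background, and
2. a **geometric "reasonable model" count** over docked substrate poses —
   how many docked configurations put both substrates close to the
   catalytic triad — compared across protein variants with a many-to-one
   Dunnett test against the native enzyme.

## The two-entropy model

For alignment column $p$ and a sequence group $g$, the conservation score is
the Shannon entropy in log10 units,

$$E_p^{(g)} = -\sum_{a=1}^{20} f_{a,p}^{(g)} \log_{10} f_{a,p}^{(g)},$$

computed over exactly the 20 standard amino acids; $0\log 0 \equiv 0$. A
fully conserved column scores 0, a uniform column scores
$\log_{10} 20 \approx 1.301$. The profile reports $E_p^{tr}$ (transferase
group), $E_p^{other}$ (esterase plus putative sequences) and their
difference $\Delta_p = E_p^{other} - E_p^{tr}$: a large positive $\Delta_p$
marks a column that is variable in the family at large but fixed in the
transferase group — a candidate specificity-determining position.

### Pseudo-counts

With only four transferase sequences, raw frequencies are degenerate, so
counts are regularised with BLOSUM62 substitution pseudo-counts. With
observed counts $N_{a,p}$, $N_{obs} = \sum_b N_{b,p}$ countable residues and
pseudo-count mass $B$ (default **2.0**),

$$f_{a,p} = \frac{N_{a,p} + B \sum_b (N_{b,p}/N_{obs})\, P(a \mid b)}
                 {N_{obs} + B},$$

where $P(a \mid b) = q_{ab} / \sum_c q_{cb}$ is the conditional
substitution probability from the BLOSUM62 target frequencies $q_{ab}$
(vendored as a checksummed data file; the conditional table is derived at
load). $B = 0$ recovers raw frequencies exactly, which is how the analytic
test values (0, $\log_{10} 20$, the 0.9/0.1 column) are checked.

### Gaps, ambiguity codes and the denominator

Gaps and ambiguity codes (B, Z, X, J, U, O) contribute no counts: the
entropy sums over 20 residues only. The frequency denominator is $N_{obs}$,
the number of countable residues in the group at that column, because an
entropy requires a probability distribution; a literal variant that divides
by the full group size (gaps included) is available as
`strict_nall = TRUE` for sensitivity analysis — on gapped columns its
frequencies sum to less than one, which depresses the entropy of gappy
columns rather than normalising them. A column with no countable residue in
a group takes the pure BLOSUM62 background distribution when $B > 0$ and is
an error at $B = 0$.

### Ranking and the eligibility rule

`rank_candidates()` takes the `k` (default 10) columns with largest
$\Delta_p$, ties broken by the smaller column index for determinism. Two
eligibility controls matter:

* **Transferase-group coverage** (`max_gap_tr`, default 0). A residue can
  only be conserved in *all* transferase sequences if every transferase
  sequence actually carries a residue at the column. Without this rule,
  columns where three of four transferase cells are gaps and the lone
  observed residues agree (e.g. `G-GG`, `G---`) masquerade as perfectly
  conserved under the $N_{obs}$ denominator and crowd out genuine
  candidates; with 20% gaps and 500 columns such artifacts outnumber the
  real signal in roughly half of simulated data sets. Requiring full
  coverage is the direct reading of "conserved in all transferase members"
  and removes the artifact without touching the entropy itself.
* **Column exclusion** (`exclude_columns`, default none). Signal-peptide
  regions show elevated transferase-group variability; they produce
  *negative* $\Delta$ and cannot contaminate the top ranks, so no region is
  excluded by default — the option exists for users who want to mask a
  declared N-terminal region anyway.

An optional ceiling on $E^{tr}$ (`max_E_tr`) implements the alternative
reading in which candidates must be absolutely, not just relatively,
conserved in the transferase group; it has no default threshold.

### Esterase absence and downstream classification

`est_absence_filter()` flags a candidate column when no esterase-labelled
sequence carries any residue of the transferase set there (gaps never count
as presence). `classify_sequences()` then assigns every sequence
`both` / `pos1_only` / `pos2_only` / `neither` for a chosen pair of
candidate columns, and `annotate_tree()` writes those statuses onto the
tips of a user-supplied phylogeny (NHX comments plus a TSV; the topology is
never altered).

## The geometric pose filter

Docking produces up to 20 ranked poses per substrate per receptor model.
The two-stage acceptance mirrors the order of the chemistry:

* **Stage 1** (acyl donor): the thioester **sulfur** of the CoA substrate
  must lie within `cutoff1` of the His321 imidazole C-2 carbon. In PDB
  nomenclature the imidazole carbon between the two ring nitrogens is
  `CE1`; because naming conventions vary, the selector is configurable and
  a `CD2|CE1` fallback can be supplied.
* **Stage 2** (acyl acceptor): the reactive **hydroxyl oxygen** of the
  alcohol substrate must lie within `cutoff2` of *any heavy atom* of the
  three triad residues.

A (pose 1, pose 2) pair passing both stages on the same structure model is
a *reasonable model*; `count_reasonable()` tallies them per model and
reports mean ± sample sd per variant, with a full per-pair audit table
(both distances for every pair, accepted or not). Acceptance is
`distance <= cutoff`, so the boundary is deterministic. No published cutoff
exists for "close to the triad", so both default to **5.0 Å** — the scale
of near-attack geometries — and every output records the cutoffs and
selectors actually used. Because the cutoffs are not pinned by the source
analysis, absolute published count values are not reproduction targets;
the comparisons across variants are.

## The Dunnett comparison

Per-variant counts (one per structure model, typically $n = 5$) are
compared against the native control with the classical Dunnett many-to-one
procedure: pooled-variance $t$ statistics and family-wise adjusted
p-values $P(\max_j |T_j| \ge |t_i|)$ under the equicorrelated
multivariate-$t$ reference with $\rho_{ij} = \lambda_i \lambda_j$,
$\lambda_i = \sqrt{n_i/(n_i + n_0)}$. The reference distribution is
evaluated by Monte Carlo (default 100,000 draws) with a **mandatory seed**,
so every p-value is exactly reproducible and carries a Monte-Carlo standard
error. Tests are two-sided (both decreased and unchanged counts are of
interest); adjusted p-values are floored at the unadjusted two-sample p so
the adjustment can never be anti-conservative. With a single treatment the
procedure reduces to the pooled two-sample $t$ test, which is one of the
test suite's oracles; an independent implementation (`multcomp::glht`) is
the other.

`dunnett_from_summary()` re-analyses published mean ± sd tables. The
published count summaries do not state the per-group $n$ nor whether ± is
sd or sem; the re-analysis assumes one count per retained structure model
($n = 5$, ± read as sd) and carries that assumption in its output rather
than hiding it. Under that assumption the reported decision pattern is
recovered: the activity-neutral S339A mutant is not separable from native,
while G64A, D336A and R153A all fall significantly below it.

## The simulators — what they emulate and what they do not

`simulate_msa()` emulates the study corpus: 4 transferase, 6 esterase and
100 putative sequences, 500 columns, background residues drawn iid from the
BLOSUM62 marginal distribution (so background entropies spread realistically
below the $\log_{10} 20$ ceiling), 20% gaps, a 25-column N-terminal stretch
of elevated transferase-group variability mimicking a signal peptide, and
planted transferase-specific columns (default: a two-residue {N,R} column
and a single-residue {D} column, esterase-excluded). Columns are
independent: there is no phylogenetic correlation, no indel structure, no
alignment error. Passing the recovery test therefore shows the scan finds
planted conservation against a realistic *composition* background — not
that it is robust to tree-correlated sequences or misalignment.

`simulate_poses()` builds idealised receptors (triad residue templates plus
filler residues, small per-model jitter) and places each pose's criterion
atom at a controlled minimum distance from its anchor — inside the
acceptance shell (Uniform(1, cutoff)) or outside it
(Uniform(cutoff + 2, cutoff + 30)). The 2 Å guard gap around the cutoff
makes truth labels immune to floating-point and file-precision (0.001 Å)
round-off. Placement anchors at the triad atom with maximal projection onto
a random direction, which makes the realised minimum distance *exactly* the
sampled one. The ligands are three-atom caricatures; nothing about docking
energetics, sterics or conformer realism is simulated — the generator
validates the geometry and counting machinery, not docking itself.

## Numerical and design choices

* Alignment columns and residue indices are both 1-based, matching standard
  position numbering (alignment column 208 ↔ TciGLIP residue 153).
* log base 10 throughout the entropy; label-swap antisymmetry of $\Delta$
  and the $B = 0$ bounds $0 \le E \le \log_{10} 20$ are tested invariants.
* The summary-input and raw-input Dunnett paths share one engine, so
  sufficiency (identical results from raw data and their summaries) holds
  to machine precision.
* Pipeline runs write a JSON manifest (inputs with md5 checksums, config,
  seed, package version); deterministic stages re-run bit-identically, and
  a failing stage removes partial outputs and names itself in the error.
* Problem sizes used by the test suite: 100 random 30×200 alignments for
  the oracle-equivalence check; 100 seeds at the full generator defaults
  for recovery; 2,000 replicates (k = 4, n = 5, 20,000 Monte-Carlo draws
  each) for the family-wise-error calibration; 20 seeds of 5 models × 20 ×
  20 poses for filter/generator agreement.

## Known limitations

* The pseudo-count algebra is the standard substitution-matrix mixing rule;
  the original description of the BLOSUM62-based strategy admits variants
  (e.g. different mixing weights), which is why `B` and `strict_nall` are
  exposed rather than hard-coded.
* Sequence-redundancy weighting, alternative divergence measures
  (relative entropy, Jensen–Shannon) and alignment-quality weighting are
  deliberately out of scope.
* The stage-2 criterion uses "any triad heavy atom" because no more
  specific published geometry exists; users with a mechanistic atom in mind
  should supply their own selector.
* With $n = 5$ counts per variant the Dunnett test has limited power;
  product-of-acceptance counts are strongly overdispersed across structure
  models, so only large differences in access geometry separate variants.
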