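---
title: "Identifying dysregulated TF-miRNA feed-forward loops"
author: "dysFFL package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying dysregulated TF-miRNA feed-forward loops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dysFFL)
```

## The model

A feed-forward loop (FFL) is a three-node motif over one transcription
factor (TF), one miRNA and one target gene: both regulators regulate the
gene, and one regulates the other. The direction of the TF–miRNA link
defines the type: **TF-FFL** (TF→miRNA), **miRNA-FFL** (miRNA→TF) and
**FB-FFL** (both directions — the regulators form a feedback pair). Each
(TF, miRNA, gene) triple is reported once with exactly one type; the FB
condition absorbs the other two.

Dysregulation of an FFL between two conditions is quantified by combining
per-node differential expression with per-edge differential coexpression:

* Node score. `Diff = (−log10 p) · |log2FC|`, with p and log2FC from a
  paired empirical-Bayes moderated t-test, is mapped through
  `S_node = Φ⁻¹(1 − 2(1 − Φ(Diff))) = Φ⁻¹(2Φ(Diff) − 1)`. The transform is
  strictly increasing, so larger expression changes always raise the score.
* Edge score. For each of the three pairs (TF–miRNA, TF–gene, miRNA–gene),
  Spearman correlations are computed within each condition, Fisher-z
  transformed (`F(r) = ½ ln((1+r)/(1−r))`) and standardised:
  `D = (F(r_case) − F(r_ctrl)) / √(1.06/(n_case−3) + 1.06/(n_ctrl−3))`.
  The 1.06 constant is the conventional variance inflation for a Fisher-z
  transformed *Spearman* (rather than Pearson) correlation. The edge score
  applies the same inverse-normal transform to |D|, so a coexpression change
  in either direction scores high.
* Combined score. `s_FFL = γ · mean(3 node scores) + (1−γ) · mean(3 edge
  scores)`, γ = 0.5 by default (nodes and edges weighted equally). An
  FB-FFL contributes its mutual TF–miRNA pair *once* — pairwise
  coexpression carries no direction — so every FFL has exactly 3 node and 3
  edge terms, and retyping a triple cannot change its score.

Significance is empirical. Random triples — by default
composition-matched: one TF, one miRNA, one gene, drawn uniformly from the
network's classes — are scored by the identical machinery whether or not
their edges exist (the score needs only expression). One shared null serves
all FFLs; the p-value is the plain proportion of null scores strictly
exceeding the observed score, and FFLs at p ≤ 0.05 are flagged
dysregulated. A `+1/(N+1)` pseudocount variant is available for callers who
need p-values bounded away from zero.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `gamma` | 0.5 | node-vs-edge weight in `s_FFL` (unitless, (0,1)) |
| `n_draws` | 100,000 | permutation draws; tests/acceptance use 5–10k |
| `alpha_ffl` | 0.05 | empirical-p cutoff for "dysregulated" |
| `de_p_max`, `de_lfc_min` | 0.05, 1 | DE-set thresholds (p, log2 units) |
| `min_degree` | 10 | hub-FFL degree threshold (inclusive) |
| `general_min` | 3 | systems shared for a "system-general" FFL |
| `alpha_pattern` | 0.1 | one-sided rank-shift significance |
| `min_reversed` | 3 | genes a drug must reverse to pass |
| `clamp_eps` | 1e−15 | probability floor in the Φ⁻¹ transforms |

The DE thresholds are configurable because the upstream study design this
package targets (five donors, paired conditions) does not pin a unique
choice; p ≤ 0.05 with |log2FC| ≥ 1 is the conventional microarray default.

## Numerical choices

* **Clamping.** `Φ⁻¹` diverges as its argument reaches 0 or 1; the inner
  probability is clamped to `[1e−15, 1−1e−15]`, so a fully null node
  (`Diff = 0`) scores the finite floor `qnorm(1e−15) ≈ −7.94` rather than
  −∞, and all scores stay finite and order-preserving. Similarly |r| is
  clamped below 1 (at `1 − 1e−9`) before the Fisher transform.
* **p = 0.** Before `−log10 p`, p is floored at the smallest positive
  double, so `Diff` is finite for p-values that underflow.
* **Ties.** Spearman uses average ranks; quantile normalisation gives tied
  values the mean of their tied ranks' reference values; rank signatures
  and all drug/degree rankings break ties lexicographically by identifier
  (radix/C-locale order), which makes every output deterministic across
  platforms.
* **Exactness.** The rank-shift Wilcoxon uses the exact distribution
  whenever the smaller group has ≤ 25 members (signature ranks are
  distinct, so ties never block exactness) and the tie/continuity-corrected
  normal approximation otherwise. Fisher's exact test and the
  hypergeometric enrichment use exact hypergeometric summation.
* **Degenerate inputs.** A feature constant across all samples gets
  log2FC = 0, p = 1. A feature constant *within one condition* has an
  undefined Spearman correlation; it is scored as r = 0 with a warning. A
  DE set equal to the whole signature universe makes the rank-shift test
  undefined and is an error; an empty up or down set yields p = 1 for its
  two patterns, flagged as undefined rather than silently significant.
* **Seeds.** Every stochastic stage takes an explicit seed and restores the
  caller's RNG state. The pipeline expands one master seed into per-stage
  seeds by a fixed counter scheme (the k-th draw of `sample.int(2³¹−2)`
  under the master seed), so stages can be re-run independently and still
  reproduce the one-shot run byte for byte.

## Design decisions

* **Moderated t.** The paired design (each donor measured in both
  conditions) is analysed on within-donor differences with an
  empirical-Bayes variance squeeze (via `limma::squeezeVar` behind the
  package's own surface). `prior_df = 0` recovers the ordinary paired t
  and `prior_df = Inf` the pooled-variance z-test, which the unit tests use
  as limiting-case oracles; the default estimated prior is cross-checked
  against `limma::eBayes` directly. BH FDR is computed separately for genes
  and miRNAs, which arrive from separate platforms.
* **Node classes are disjoint and conflicts are errors.** A TF targeted by
  a miRNA keeps node class TF via the dedicated `mirna_tf` edge class;
  silent reclassification would corrupt motif typing. The one sanctioned
  exception: a TF appearing as a `tf_gene` *target* (TF–TF transcriptional
  regulation) stays a TF.
* **Null composition.** "Random triples" is read as composition-matched
  (one node per class), keeping the null on the same score scale as real
  FFLs; a `composition = "free"` flag draws unconstrained triples. Null
  triples are drawn from nodes that have expression and DE records — the
  same eligibility an FFL needs to be scored at all.
* **Web services replaced.** Pathway enrichment is a local upper-tail
  hypergeometric test over user-supplied GMT collections (the same
  mechanism annotates genes and miRNAs), and body systems are defined by a
  user-supplied system→pathway map. Module-extraction tooling is out of
  scope; the sharing analysis reports FFL/node/edge overlaps instead.
* **Drug screens.** Contradictory (drug, miRNA) records count as no
  evidence of inhibition. Gene-signature reversal ranks by reversed-gene
  count only; connectivity-map-style KS statistics are out of scope.

## What the synthetic data emulates — and what it does not

`synthNetwork()` draws edges per regulation class with heavy-tailed
source/target popularity (degree distributions approximate a power law, as
real regulatory catalogues do) and injects guaranteed motifs round-robin
over the three types, stripping any opposite regulator link that would
retype a planted TF-FFL or miRNA-FFL. `synthExpression()` emulates a
paired microarray design: log2 intensities ~ N(8, 1.5) per feature, a
donor baseline ~ N(0, 0.3) shared between the donor's two samples,
residual noise N(0, 0.5), planted nodes shifted by ±2 log2 units in the
case condition, and a per-FFL latent factor inducing within-condition
coexpression ≈ +0.8 among the triple in the case condition. In the control
condition the factor loads (+, −, −) on (TF, miRNA, gene): the TF–miRNA
and TF–gene pairs sit near −0.8 while the miRNA–gene pair stays positive —
a one-factor construction cannot make all three pairwise correlations
negative (their sign product is forced positive), a constraint worth
remembering when interpreting per-edge recovery.

Defaults (50 TFs, 80 miRNAs, 300 genes, density 0.05, 10 planted FFLs, 5
donor pairs) are sized so a full run with 10,000 permutations takes
seconds. The generator does **not** simulate probe-level artefacts,
background correction, batch effects, miRNA-name drift or RNA-seq counts;
a green recovery test establishes that the scoring machinery ranks truly
rewired motifs above background under idealised paired Gaussian data, not
that any particular biological dataset will behave as cleanly.

One calibration subtlety: FFLs that share nodes have strongly dependent
p-values (a hub miRNA's one realised expression vector enters every FFL it
belongs to), so a Kolmogorov–Smirnov uniformity test applied to *all* FFLs
of a dense network rejects even though each p-value is marginally uniform.
The null-calibration test therefore uses node-disjoint planted motifs
(each node in one FFL), where the KS test's independence assumption
approximately holds. This is a property of the test, not of the scores.

## Known limitations

* With five donor pairs, Spearman correlations take few distinct values;
  edge scores are correspondingly coarse, and the permutation p-values
  inherit that granularity (resolution 1/n_draws).
* The score treats the three edges symmetrically and ignores regulation
  sign (activation vs repression), as the underlying catalogues rarely
  provide it.
* Identifiers are opaque, case-sensitive strings; harmonising gene symbols
  and miRNA names across resource versions is the caller's responsibility.
* The rank-shift reference group is the full signature universe minus the
  DE set; genes unmeasured in the perturbation are dropped (and counted),
  not imputed. No multiple-testing correction is applied across cancers ×
  patterns by default, matching the raw p ≤ 0.1 convention; a BH option is
  available downstream of `patternTest()` by adjusting its four p-values.
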