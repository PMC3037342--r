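---
title: "Correlation-based Scatter Search biclustering: models and methods"
author: "corrbic"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

A gene expression matrix M has N gene rows and L condition columns; a
bicluster B selects nG genes and nC conditions and is equivalently a binary
string of length N + L (first the gene bits, then the condition bits; a
bicluster of a 10 × 5 matrix selecting genes {3, 5, 6} and conditions
{2, 3} is the string `0010110000|01100`, the separator being display only).

corrbic targets *shifting-and-scaling patterns*: gene pairs related by
g_Y = α·g_X + β with α > 0. Such pairs have Pearson correlation exactly +1,
so coherence is measured by the **average correlation**

ρ(B) = mean over the C(nG, 2) unordered gene pairs of ρ(g_i, g_j),

with each coefficient computed **only over the bicluster's selected
conditions** (the bicluster is a submatrix; correlations over unselected
conditions would mix in unrelated signal). The search minimizes

f(B) = (1 − ρ(B)) + σ_ρ + M1/nG + M2/nC,

where σ_ρ is the standard deviation of the pairwise coefficients. The σ_ρ
term prevents a bicluster from hiding a few uncorrelated genes behind a
high mean; the penalty terms trade correlation against volume. Two
reporting measures complete each result record: the mean squared residue
(mean of (a_ij − a_iJ − a_Ij + a_IJ)² over cells), which is 0 for constant
and pure-shifting biclusters but grows with the spread of scaling factors,
and the gene (row) variance (mean of (a_ij − a_iJ)²), which indicates the
scaling magnitude. Together they document the regime in which a
correlation objective accepts biclusters that an MSR objective would
reject.

# The search procedure

One restart of the Scatter Search proceeds as follows.

1. **Diversification.** A seed string is drawn with each bit 1 with
   probability 1/2. For every stride h with 1 ≤ h < (N + L)/5 the rule
   "complement positions 1, 1 + h, 1 + 2h, … and copy the rest" emits one
   solution; the last emitted solution becomes the next seed, until
   `populationSize` pairwise-distinct strings exist (a sterile full pass
   draws a fresh random seed to avoid cycling).
2. **Improvement.** Every solution is repaired: scanning genes in index
   order from the first (which is always retained), a gene is kept only if
   its correlation with *every* already-kept gene is strictly positive.
   Conditions are untouched. The default `"contract"` mode enforces the
   method's output guarantee — all retained pairs non-negatively
   correlated; a `"literal"` mode reproduces the classical pseudocode
   sweep, which can retain a gene that a later comparison finds negative
   against an earlier one, and exists for traceability. Zero-correlation
   pairs (including genes constant over the selected conditions) fail the
   strict test and are dropped.
3. **Reference set.** S/2 members by lowest fitness (quality half R1) plus
   S/2 members chosen greedily to maximize the minimum Hamming distance to
   R1 and to each other (diversity half R2); the population loses the
   chosen members.
4. **Update to stability.** All S(S − 1)/2 member pairs are crossed with a
   uniform random mask, children are improved, and the S best of the union
   of reference set and children survive. This repeats until the set no
   longer changes. Ties are broken by first appearance with incumbents
   listed first, so a child must *strictly* improve on some member to
   enter — which also guarantees termination.
5. **Rebuild.** The quality half is kept; the diversity half is re-drawn
   from the remaining population by the same max-min rule (a fresh
   population is generated when it runs short). Steps 4–5 repeat
   `numIterations` times; the restart returns the best member of the final
   reference set.

A full run (`scatterSearch()`) performs `numBiclusters` independent
restarts, each from its own population and RNG substream, and reports each
restart's best bicluster; overlap between results is not controlled.
Degenerate solutions (fewer than 2 genes or 2 conditions), which uniform
crossover can produce, stay representable and receive fitness +∞ so the
selection never propagates them.

# Parameters

| parameter | default | meaning |
|---|---|---|
| `numBiclusters` | 100 | independent restarts / results per run |
| `numIterations` | 20 | stability-then-rebuild cycles per restart |
| `refSetSize` (S) | 10 | reference-set size, half quality, half diversity |
| `populationSize` | 200 | diversification population per restart |
| `M1`, `M2` | 1 | volume penalty weights (per-gene, per-condition) |
| `hMaxDivisor` | 5 | stride bound of the diversification schedule |
| `improveMode` | contract | gene-pruning rule (see above) |

The defaults are the published study settings. M1 = M2 = 1 favours small,
visually crisp biclusters; M1 = M2 = 10 favours volume, which matters when
downstream analyses (e.g. functional enrichment) need large gene sets. The
units of M1 and M2 are fitness units per reciprocal gene (condition): with
M1 = 1, going from 5 to 10 genes buys 0.1 of fitness.

# The synthetic test bed

`makeSyntheticMatrix()` emulates a preprocessed expression matrix:
background entries are i.i.d. Normal(0, 1) (preprocessed microarray data
are routinely variance-stabilized to roughly unit scale), and each
implanted bicluster is built from a base profile p drawn from the same
background distribution, with gene i set to α_i·p + β_i + ε. The defaults
α ~ U(0.5, 2) and β ~ U(−2, 2) put per-gene scaling within a factor ~4 and
shifts within ±2 background SDs — patterns of realistic, not inflated,
contrast — and ε has `noiseSd` = 0 by default so every pairwise implant
correlation is exactly 1. Implants occupy contiguous disjoint blocks from
the matrix's top-left corner, keeping the ground truth unambiguous.
Recovery is scored by the cell-level Jaccard overlap between a found and an
implanted bicluster.

What the generator does **not** emulate: correlated background structure
(real expression matrices contain pervasive co-expression beyond any one
bicluster), heavy-tailed noise, missing values, overlapping biclusters and
condition-dependent variance. Tests passing on this generator therefore
show the machinery is correct and can retrieve a planted signal; they do
not certify performance on real microarray data.

# Numerical and design choices

- Correlation uses the population (divide-by-n) moment form; as a ratio it
  is identical to the sample form, and a test asserts equality with
  `stats::cor`. Coefficients are clamped to [−1, 1] against rounding
  excursions.
- A gene with zero variance over the selected conditions gets coefficient
  0 (uncorrelated) rather than NaN; the improvement then removes it.
- σ_ρ is the *population* standard deviation of the pairwise coefficients,
  so a 2-gene bicluster (one coefficient) has σ_ρ = 0 and stays
  well-defined.
- The diversification rule itself accepts any stride 1 ≤ h < n; the
  h < n/5 bound applies to the population schedule. Flip positions beyond
  the string end are skipped.
- All tie-breaks (fitness sorting, max-min distance) use first appearance
  in the candidate list, making every run reproducible from its seed.
  Exact duplicate bit strings are removed before any selection.
- Stability is re-assessed after every rebuild (a rebuild introduces new
  members, so the updated set must settle again before the next rebuild).
- Restart seeds are drawn once from the run's seed, so `numBiclusters`
  restarts are independent but jointly reproducible.

# Problem sizes used by the test suite

Unit tests run on matrices up to 25 × 12 with reduced search settings
(population ≤ 60, ≤ 5 iterations); the end-to-end checks use the full
published settings (population 200, S = 10, 20 iterations) on 50 × 20
matrices with one noiseless 8 × 6 implant, and brute-force oracle
comparisons on 200 random biclusters of up to 6 × 6. These sizes keep the
full suite under half a minute while exercising every code path at the
study's parameter settings.

# Known limitations

- **Desk-scale recovery is signal-to-background limited.** With the
  generator's default α ~ U(0.5, 2) against unit background noise, a
  single restart recovers the planted 8 × 6 bicluster in only part of the
  seeded runs: small chance-correlated gene triples with many background
  conditions reach competitive fitness (the M2/nC term rewards their extra
  conditions) and can crowd implant fragments out of the quality half
  before condition cleaning begins. Recovery improves with stronger
  scaling contrast, with more restarts (`numBiclusters` > 1 and keeping
  the best-matching result), and with larger implants.
- The improvement anchors on the bicluster's first gene; a badly chosen
  anchor can prune well-correlated genes. This is the method's stated
  rule, not an implementation accident.
- The fitness treats a two-condition bicluster's trivial collinearity as
  ρ(B) = 1; interpret high-ρ results jointly with nC, σ(B) and volume.
- Results from different restarts may overlap arbitrarily; no overlap
  penalty is applied.
- MSR and gene variance are reported, not optimized; they serve to compare
  against residue-based methods.
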