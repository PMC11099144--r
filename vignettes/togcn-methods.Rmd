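---
title: "TO-GCN methods: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TO-GCN methods: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(togcn)
```

## The problem and the model

Bulk time-course transcriptomes of a developing tissue — for example
posterior dorsal chicken skin sampled at five ordered stages for each of
two feather programs (embryonic natal down and juvenile feather) — carry
the order in which transcription factors (TFs) switch on, but no single
sample resolves it. A time-ordered gene co-expression network (TO-GCN)
recovers that order with three ingredients:

1. an **empirical co-expression cutoff** *C*: the nearest-rank 95th
   percentile of the Pearson correlation coefficients (PCCs) of all TF–TF
   pairs, i.e. the smallest realized pair value whose right-tail
   probability is at most $\alpha = 0.05$;
2. a **gene co-expression network (GCN)** whose edges are TF pairs with
   $\mathrm{PCC} \ge C$;
3. a **breadth-first search (BFS)** from a seed TF believed to act first.
   The seed and its direct neighbors form level 1; nodes at graph distance
   $k \ge 2$ form level $k$. Levels approximate activation time.

The model's assumptions are worth stating plainly: activation order is
assumed to be expressed as a *chain of correlation neighborhoods* (genes
active at adjacent times correlate above *C*, genes far apart in time do
not); the seed must genuinely be among the earliest-activated TFs, because
every level is a distance *from the seed*; and only positive co-expression
is used — the cutoff is a right-tail quantile, and repressive (negative
PCC) relationships do not create edges.

Downstream of the levels:

* each level's **co-expressed gene set** collects candidate (typically
  non-TF) genes with $\mathrm{PCC} \ge C$ to at least one TF of that
  level; a gene may appear in several neighboring sets;
* per level, the sets are tested for functional over-representation with
  the one-sided Fisher's exact test (hypergeometric upper tail,
  $P(X \ge k)$) against the background of all expressed genes, with
  Benjamini–Hochberg FDR control;
* for two programs, the per-TF level difference $d = L_A - L_B$ is
  classified **changed** when $|d| \ge t$, with
  $t = \lceil 1.5 \times \widehat{\sigma}(d)\rceil$ (population SD), and
  **type-specific** TFs are those reaching the late "keratinization
  window" of levels 8–11 in exactly one program.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `tpm_min` | 1 | TPM | a gene is expressed if it reaches this in ≥ 1 sample |
| `alpha` | 0.05 | probability | right-tail mass above the PCC cutoff |
| `window` | [8, 11] | levels | late keratinization window for specific-TF calling |
| `multiplier` | 1.5 | — | SD multiple behind the changed/unchanged threshold |
| `padj_max`, `lfc_min` | 0.05, 1 | —, log2 | strict DEG filter on a supplied table |
| `use_replicates` | FALSE | — | correlate condition means (5 points) vs replicate columns |

Correlating condition means is the default because the design being
emulated has five ordered conditions; whether correlations should instead
be taken over replicate-level columns is genuinely open, so both modes are
supported behind one switch.

## Numerical choices

* **Quantile conventions.** The cutoff uses the *nearest-rank* quantile
  (ascending rank $\lceil (1-\alpha) n \rceil$) so it is attainable by at
  least one pair; note that when $(1-\alpha)n$ is an integer the fraction
  of pairs strictly above the cutoff equals $\alpha$ exactly, so the tail
  bound is "≤", not "<". The upper quartile in normalization uses linear
  interpolation between order statistics, computed on *strictly positive*
  values only — zeros dominate RNA-seq matrices and would collapse the
  quartile — and samples are scaled to the geometric mean of their upper
  quartiles, which keeps the output near the input scale.
* **Ties at the cutoff** are kept (edges use $\ge$, a closed threshold).
* **The seed's level.** BFS wording places the seed's neighbors in level
  1; the seed itself is also assigned level 1 (not a level 0), so the
  first level contains the earliest co-activated group. This is a
  convention, not a claim about other implementations.
* **Unreachable and constant genes** are never silently dropped:
  unreachable nodes are listed per TO-GCN, constant-profile genes are
  excluded from PCC with an explicit report, and a constant TF is excluded
  from z-score profiles with a warning.
* **Population SD** (not sample SD) is used both for z-score profiles and
  for the $d$ threshold; with the ceiling rule, any
  $\widehat{\sigma}(d) \in (4/3, 2]$ yields $t = 3$, reproducing the
  "≥ 3 changed / ≤ 2 unchanged" boundary; the acceptance checks confirm
  $t = 3$ on rounded $\mathcal{N}(0, 1.7)$ draws in ≥ 95 of 100 seeds.
* **FDR scope.** BH is applied within each level (enriched functions are
  reported per level); a global-adjustment switch exists. Odds ratios use
  a 0.5 continuity correction when any 2×2 cell is zero. Terms smaller
  than 2 in-background genes and overlaps below 1 are suppressed as
  vacuous (configurable).
* **Absence and the window rule.** A TF missing from one network is
  treated as "not expressed at the window levels" there, hence eligible
  for type-specificity; `allow_absent = FALSE` restores the stricter
  reading that requires presence in both networks. The window includes
  level 8 (the looser "greater than 8" reading is available by passing
  `window = c(9, 11)`).

## The synthetic world

`simulate_timecourse()` generates the world the package is tested in: two
programs × 5 conditions × 3 replicates; 8 TF activation waves × 15 TFs;
wave $w$ TFs follow a Gaussian bump
$a_g \exp\{-(c - c_w)^2 / (2\,0.8^2)\}$ over condition index $c$, with
wave centers spaced uniformly across and slightly beyond the condition
range (0.5 to 5.5) so the first and last waves are monotone — genes still
rising at the final stage. Replicate values add
$\mathcal{N}(0, 0.05 \times \text{amplitude})$ noise truncated at zero.
Background genes co-vary with a randomly assigned wave (populating level
gene sets and the wave-term GMT written by `write_fixture()`), and a
fixed fraction stays uniform in $[0, 0.9]$ TPM — below the expression
filter in both programs. A single integer seed drives everything;
program-specific noise uses substreams derived from it, so generation is a
pure function of the configuration.

Per-gene peak heights are drawn uniformly from $[0.5, 1.5]$ × the
reference amplitude. This choice resolves an internal tension in the
stated design: the recommended BFS seed is defined as "the wave-1 TF with
the highest amplitude", which presupposes amplitude heterogeneity, while
the bump formula alone has a single shared amplitude. Mild uniform
heterogeneity is the smallest change that makes the seed definition
meaningful, and it mimics the real spread of TF expression levels. Noise
SD stays anchored to the *reference* amplitude (an absolute noise floor),
not to each gene's own peak.

What the generator deliberately does **not** emulate: read counts and
their mean–variance structure, library-size artifacts (all samples are
generated on a common scale, so upper-quartile normalization is nearly
neutral on it), sequencing error, genuinely high-dimensional profile
diversity (every profile is a scaled Gaussian bump), and any real TF
catalogue. A green test on this world therefore establishes correctness
of the *mechanics* — filtering, normalization conventions, cutoff rank,
thresholding, BFS strata, set membership, test statistics, classification
rules, determinism — not biological fidelity.

## Known limitations: why end-to-end wave recovery fails in this world

The package's acceptance checks include an end-to-end recovery target: on
the default synthetic world, ≥ 90% of TFs should be leveled within ±1 of
their planted wave. We keep this check honest and report that the stated
world **cannot** reach it, for a structural reason worth understanding
before trusting any TO-GCN on few time points:

* With 8 discrete waves of 15 TFs, 840 of the 7140 TF pairs (11.8%) are
  within-wave. The $\alpha = 0.05$ cutoff, by construction, admits only
  the top ~5% of pairs as edges. Since same-wave pairs share an identical
  underlying profile (PCC ≈ 0.997 at 5% noise), the 95th percentile falls
  *inside* the within-wave PCC band: the thresholded graph is a partial
  union of within-wave cliques with no cross-wave edges, and BFS never
  leaves the seed's wave.
* Making within-wave correlations heterogeneous (low-amplitude genes with
  relatively larger noise, hub-and-spoke structures) cannot rescue this at
  $n = 5$ condition points: the sampling SD of a 5-point PCC is ~0.2–0.4,
  so any cutoff low enough for reliable attachment admits hundreds of
  spuriously correlated cross-wave pairs, destroying the level order.
* Deterministic shape diversity saturates: 5-point Gaussian-bump profiles
  span a small manifold (e.g. all bumps with width ≥ 1.2 conditions are
  mutually correlated ≥ 0.99), and for any smooth one-dimensional profile
  continuum the 5% edge budget pins the BFS hop radius to ~1/20 of the
  time span — forcing ~20–40 levels rather than 8.

Real data escape this because TF profiles are high-dimensional and most
pairs are genuinely uncorrelated, so the top-5% tail *is* the co-expressed
minority. Emulating that would require either many more time points or
abandoning the planted-wave ground truth the recovery check is scored
against. We chose to keep the stated world and report the honest scores
(`scripts/acceptance.R`, criteria 5 and 6) rather than tune the generator
toward a pass; the practical lesson for users is that TO-GCN leveling
needs either dense time sampling or a large, diverse TF complement before
the empirical-quantile cutoff becomes meaningful.

All other acceptance checks — BFS against an independent shortest-path
oracle, the cutoff against a sort oracle, Fisher p-values against
exhaustive hypergeometric enumeration, the BH worked example, the
threshold-rule consistency, and byte determinism of the full pipeline —
pass at their stated tolerances.
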