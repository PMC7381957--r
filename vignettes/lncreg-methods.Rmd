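---
title: "Methods and design of the lncreg pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the lncreg pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, its tunable
parameters, the synthetic data it tests itself on, and the design choices
made where the design was genuinely open. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## Study design and data model

The pipeline targets a three-group bulk RNA-seq design: one control
population and two case populations compared against it separately, with
the canonical sizes control n = 5, case 1 n = 2, case 2 n = 5. Data enter
as a feature × sample count table with a sample→group design, a GTF
transcript annotation (1-based, inclusive coordinates everywhere in the
package), spliced transcript sequences (DNA input is normalised to the RNA
alphabet), protein sequences, gene sets and JASPAR-style position frequency
matrices. All user-facing functions take tibbles and return tibbles so the
stages compose with the pipe; `run_pipeline()` executes them in dependency
order with per-stage seeds derived from one global seed.

## Differential expression

Counts are modelled as negative binomial with variance μ + φμ². Two
normalisations are provided: FPKM (k·10⁹/(L·N), with N the column sum of
the quantified matrix — the total mapped-read count is not available to a
self-contained pipeline, and the column sum is monotone-equivalent) and
median-of-ratios size factors rescaled to geometric mean 1.

The test is a conditioned exact test in the Robinson–Smyth style: per
feature, the group count sums K_A ~ NB(μ·Σ_A s_j, n_A/φ) and
K_B ~ NB(μ·Σ_B s_j, n_B/φ) are conditioned on their total, and the
two-sided p-value sums the probabilities of all splits as or less probable
than the observed one. For totals above 20,000 the enumeration window is
clipped at a 10⁻¹⁴ tail mass, which is exact to double precision. φ = 0
falls back to the Poisson limit.

Dispersion is estimated per feature by the method of moments on normalised
counts, φ̂ = max(0, (s² − m)/m²) with the pooled within-group variance, and
shrunk 50/50 toward the mean of the *untruncated* moment estimates of the
feature's expression decile. Averaging before truncation matters: the
zero-truncated estimates are biased low at small n, and a low prior makes
the exact test liberal. With this prior the measured type-I rate at
nominal 0.05 sits near 0.06 on 2,000 simulated null features (the
acceptance suite asserts the [0.03, 0.07] window).

Differential calling follows the raw-p convention of the analysis the
package implements: p < 0.05 (strict) and |log₂FC| ≥ 1 (inclusive), with
no multiple-testing correction entering the call; BH-adjusted values are
reported alongside. The fold change is computed on normalised group means
with a pseudo-mean of 0.5 (log2((m_b + 0.5)/(m_a + 0.5))), which keeps it
finite and sign-correct for zero groups. Whether the original analysis
computed fold changes on FPKM or normalised counts is not derivable;
normalised counts are the default and FPKM is available by transforming
the input.

## Clustering

Profiles are clustered by average-linkage agglomeration (UPGMA) under
d = 1 − Pearson r, the defaults of the classic Cluster 3.0/TreeView
workflow (the software is named in the source analysis, its settings are
not; this is an emulation, not a reproduction). Ties are broken
deterministically by the lexicographically smallest pair of cluster
representatives, so the tree is a pure function of the distance matrix.
The implementation is validated against `stats::hclust(method = "average")`
by height and cophenetic equality on random instances. Heatmap export
z-scores each feature row for display only.

## Coexpression screen

Pearson correlation between differential lncRNAs and differential
protein-coding genes, with two-sided p from t = r·√((n−2)/(1−r²)).
Three decisions:

* **Sample scope.** Correlations are computed over the case samples pooled
  with the controls (`case_plus_control`, configurable). A within-case
  scope is degenerate at n = 2, and pooling keeps the screen informative
  for both comparisons while preserving the per-comparison pair lists.
* **Scale.** log₂(FPKM+1); Pearson on raw FPKM is dominated by single
  outliers.
* **Sign.** The screen passes on |r| > 0.8 (strict) with p < 0.05; whether
  negative correlations should be retained downstream is ambiguous in the
  source analysis, so `filter_pairs(signed = TRUE)` offers the
  positive-only variant while |r| is the default.

## Duplex scanner

`duplex_scan()` is a local seed-and-extend RNA–RNA interaction scanner.
Seeds are maximal exact Watson–Crick complementary runs of at least
`seed_len` nt (default 7); GU wobble pairs are allowed during extension but
not in seeds. Extension is a banded dynamic program over (query, target)
consumption with two states (last column paired / unpaired), scoring
stacks between adjacent pairs and charging a per-nucleotide penalty for
mismatch and bulge columns (band width `max_bulge`, default 1; extension
capped at `max_extend = 60` nt per side). Only strictly improving
extensions are kept, so neutral columns never inflate a site.

Energies are in model units of 0.1 kcal/mol, the integer convention of
RNA-energy software. The stacking table shipped in
`extdata/stack_energies.tsv` assigns each pair a strength (CG/GC 32,
AU/UA 11, GU/UG 5 units) and scores a stack as minus the mean of its two
pair strengths. The table is pair-symmetric, which makes
`duplex_scan(q, t)` and `duplex_scan(t, q)` report identical energies — an
invariant the tests assert. Two penalties complete the model: duplex
initiation +41 units and a loop penalty of 40 units per unpaired
nucleotide. The loop penalty is deliberately strict: at 40 units a
mismatch must be repaid by several strong stacks, so reported sites are
near-contiguous duplexes. With permissive penalties a 1 kb × 1 kb random
sequence pair frequently contains windows with > 20 scattered paired
positions, and the binding filter loses all specificity; the strict
default keeps the chance rate of passing sites on random transcript pairs
at the percent level while leaving genuine ≥ 21-nt complementary sites
untouched.

The binding filter follows the two-threshold rule of the source analysis:
site length strictly greater than 20 base-paired positions (`min_len = 21`,
counting paired positions, not interval span) and free energy at least as
favourable as the cutoff. The sign and units of the published energy
threshold are genuinely ambiguous; the package implements
`energy ≤ −|cutoff|` in model units with the default magnitude 50
(i.e. −5 kcal/mol), both thresholds configurable. Under the strict scanner
the length condition is the operative one; the energy condition mainly
rejects short GU-heavy sites.

The scanner's optimum is validated against an exhaustive enumeration
oracle over all ungapped windows containing a qualifying seed, exactly, on
hundreds of random pairs.

## cis/trans target classification

A passing coexpression pair is **cis** when both features lie on the same
chromosome with a nearest-end genomic gap below 100 kb (strict), the gap
measured between the spans of each feature's longest transcript,
strand-ignored (the source rule says only "close"; nearest-end distance is
the least-assuming reading, and overlapping spans get gap 0). Pairs on the
same chromosome are otherwise *eliminated*, mirroring the source's
procedure even though it discards distal same-chromosome candidates;
remaining pairs are duplex-scanned and become **trans** when a passing
hybridization site exists. cis and trans are therefore exclusive by
construction.

## lncRNA–protein interaction scoring

Features follow the RPISeq-style scheme: 256 normalised RNA 4-mer
frequencies concatenated with 343 conjoint-triad frequencies over the
standard 7-class reduced amino-acid alphabet {AGV, ILFP, YMTS, HNQW, RK,
DE, C}. Two independent classifiers — a radial-kernel SVM with Platt
calibration and a 200-tree random forest — emit probabilities, and a pair
is positive only when both exceed 0.5, applied to common-set candidate
pairs under the prerequisite that the (lncRNA, gene) pair passed the
coexpression screen. The original tool's trained models are not available;
the scorers are trained at run time, with a fixed seed, on the synthetic
generator's labelled pairs, and all assessment is relative to the
generator's truth — never to the original tool's numeric output.

## Motif scanning

PWMs are converted to log-odds with a uniform 0.25 background and
pseudocount 0.01, and every window is scored. The relative score
normalises by the matrix's attainable range, (score − min)/(max − min)
with per-column extremes; a hit requires relative score ≥ 0.8. Min–max
normalisation (rather than max-only) is chosen so the threshold is a true
fraction of the attainable range; a degenerate matrix with max = min
scores 1.0 everywhere and is flagged in the output rather than erroring.

## Enrichment

Over-representation uses the upper-tail hypergeometric probability
P(X ≥ overlap) with the universe defined as all features tested in the
comparison (the external annotation services' universes are unknowable),
BH-adjusted across sets. Preranked GSEA uses the standard running sum —
hits increment by |score|^weight normalised over set members, misses
decrement by 1/(N − set size) — with the signed extremum as ES and
sign-matched label permutations for p (bounded below by 1/(n_perm+1));
weight 1 and 1,000 permutations by default. ES values are cross-checked
against an independent preranked implementation in the test suite.

## Networks

`build_regulation_network()` assembles lncRNA→gene edges from the
classified pairs; gene nodes carry the expression direction, the Venn set
label and the "n_trans/n_cis" regulator-count label, lncRNA nodes their own
direction and set label. PPI edges are a file input merged on top
(duplicates collapse to the maximum weight) — the package never queries an
external interaction service, keeping runs offline and version-stable.
Subcellular localization is likewise an optional input table attached as a
node attribute. GraphML export round-trips all attributes; SIF keeps
topology only.

## The synthetic study

`simulation_config()` defines the study the pipeline is exercised on; its
defaults are the package's fixed study conditions, not tuning knobs:

* groups control/case1/case2 of 5/2/5 samples; 160 genes + 160 lncRNAs on
  a toy genome of 6 chromosomes × 2 Mb;
* log-normal baseline means (meanlog log 150, sdlog 1), NB dispersion
  φ = 0.05, per-sample depth factors log-uniform in [0.5, 2];
* 24 differential genes and 24 differential lncRNAs per comparison with 12
  common to both (the common-set structure of the motivating design),
  planted at |log₂FC| = 2 with random sign;
* 8 cis pairs (same chromosome, gap uniform in [1 kb, 90 kb]), 8 trans
  pairs (different chromosomes, a 25-nt exact reverse-complementary insert
  copied from the target mRNA into the lncRNA), 3 same-chromosome distal
  decoys (gap > 150 kb) and 3 different-chromosome decoys without inserts,
  all sharing a pair-specific latent factor; 40 independent decoy pairs
  among non-differential features;
* 3 generated PFMs with one planted consensus site each; 6 interacting
  lncRNA–protein pairs (drawn from the cis pairs) carrying sequence
  signatures, plus labelled pairs for scorer training; one gene set
  enriched in differential genes; a random PPI edge list.

Two generator details are worth stating. First, the latent factor that
makes a pair co-vary is *centred within each group* (sd 0.6 on the natural
log scale): uncentred factors distort the realised fold changes of pair
members and, worse, inflate their estimated dispersions enough to cost the
exact test its power on exactly the features the downstream stages need.
Centring keeps planted fold changes unbiased while the pooled-scope pair
correlation stays above 0.9 in expectation. Second, differential features
are placed in genomic "districts" spaced so that no two differential
features other than a planted cis pair fall within 100 kb of each other —
otherwise chance proximity between co-differential features would
contaminate the cis truth. Non-differential features are placed uniformly;
they never enter the screens. φ = 0 is implemented as the degenerate
noise-free mode (counts equal rounded means), which gives the tests an
exact fixture.

What the generator does **not** emulate: isoform structure and splice
diversity, GC/length biases, batch effects, count outliers, annotation
errors, and any real biological covariance beyond the planted latent
factors. Passing tests therefore demonstrate the pipeline's internal
correctness and its operating characteristics under a clean NB world, not
performance on real leukocyte data.

## Problem sizes and numerical choices

The shipped study sizes (320 features, 12 samples, ≤ 2,000-feature
calibration simulations, 200 duplex oracle pairs of ≤ 40 nt, 100 UPGMA
oracle instances, 6-item trees) were chosen so the whole suite exercises
every stage meaningfully while a full run stays comfortably interactive.
Exact-test enumerations are clipped at 10⁻¹⁴ tail mass; correlation p at
|r| = 1 is set to 0; UPGMA ties break lexicographically; degenerate PWMs
score 1 with a flag; all-zero features get p = 1 and log₂FC = 0 with a
flag. The determinism contract — identical config and seed give
byte-identical outputs — is asserted on a reduced but complete pipeline
configuration, since the property is scale-invariant.

## Known limitations

* The NB exact test is an emulation of the classic DESeq-style analysis,
  not a numerical reproduction; its dispersion shrinkage is a stated
  stand-in for local regression fitting.
* The duplex energy model is a simplified nearest-neighbour table with a
  linear loop penalty; it ranks duplexes sensibly and is validated against
  its own oracle, but its energies are not literature free energies, and
  intramolecular accessibility is ignored.
* The interaction scorers are only as good as the synthetic signatures
  they are trained on; they make no claim about real RNA–protein binding.
* With n = 2 in case population 1, every per-comparison statistic for that
  comparison is intrinsically noisy; the package keeps the design faithful
  rather than pretending otherwise.
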