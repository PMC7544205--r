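---
title: "rnpscreen: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rnpscreen: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnpscreen)
```

This vignette documents the statistical models behind the three analysis
arms of `rnpscreen`, the parameters that matter and their defaults, what
the synthetic-data generators do and do not emulate, and the numerical
conventions chosen where several readings were defensible.

# IP-MS enrichment and stoichiometry

## Preprocessing model

MaxQuant-style proteinGroups tables are reduced to a proteins × samples
LFQ intensity matrix. Rows flagged "only identified by site", "reverse"
or "potential contaminant" are removed at load time; intensities of 0 or
blank become explicit missing values, never zeros — LFQ non-detection is
informative (left-censored), not a measurement of zero.

After log2 transformation, proteins are kept if observed in at least
`min_valid` (default 2) replicates of **at least one** sample group.
The alternative whole-row scope is available via
`filter_valid_values(scope = "whole-row")`; the per-group default is the
more permissive reading and keeps proteins detected consistently in only
the bait IP — exactly the candidates an interaction screen is after.

Missing values are imputed per sample column from
$N(m_j - 1.8\,s_j,\ (0.3\,s_j)^2)$, with $m_j$, $s_j$ the observed mean
and standard deviation of column $j$. This is the classic left-shifted
("downshifted") normal used for left-censored proteomics data; width 0.3
and downshift 1.8 are the conventional defaults and are exposed as
arguments. A column with fewer than two observed values has no usable
moments; this is an error unless `fallback_global = TRUE`, which
substitutes whole-matrix moments.

## The moderated test

For each protein, with bait group $A$ and control group $B$,

$$d = \frac{\bar x_A - \bar x_B}{s + s_0}, \qquad
s = \sqrt{s_p^2 \left(\tfrac1{n_A} + \tfrac1{n_B}\right)},$$

where $s_p^2$ is the pooled within-group variance. $s_0 \ge 0$ (default
1, log2 scale) is the SAM-style fudge factor: it suppresses proteins
whose tiny variance would otherwise make negligible fold changes look
significant. At $s_0 = 0$, $d$ is the classical two-sample t statistic
(asserted against `t.test` in the test suite). The phrase "S0 (log2 fold
changes) > 1" in common Perseus workflows is read here as this fudge
factor set to 1, not as an extra fold-change filter; a hard
$|\log_2 FC|$ cutoff can be applied afterwards by filtering the result
table if desired.

## Permutation FDR

Sample labels are permuted (`n_permutations`, default 250, or
`"exhaustive"`); for each observed $|d|$ cutoff,

$$\widehat{FDR}(c) =
  \frac{\text{mean}_\pi\,\#\{|d^\pi| > c\}}{\#\{|d| \ge c\}},$$

clipped to $[0,1]$ and made monotone non-increasing in $|d|$ (ties in
$|d|$ broken by input row order; this tie-break has no semantic
content). Two conventions matter and are deliberate:

* Permuted counts use **strict** inequality. The observed statistics sit
  exactly at their own cutoffs; counting them as permuted discoveries
  would bias the estimate upward by construction.
* Label assignments equivalent to the observed grouping — the identity
  and, for equal group sizes, the complete swap — are **excluded** from
  the permutation set. They reproduce the observed statistics exactly
  and do not represent the null; keeping them places a hard floor of
  $(r-1)/(B\,r)$ under the $r$-th ranked q-value, so in a 4-vs-4 design
  no protein beyond the first could ever reach FDR < 0.01, which
  contradicts how this test is used in practice.

A request for more permutations than exist is silently capped at
exhaustive enumeration. Significance is one-sided: `q` below the
threshold **and** positive fold change — depletion relative to a mock
control has no interpretation as an interaction.

Under a fully null matrix the procedure is validated to keep the
fraction of proteins called at nominal FDR 0.01 below 0.02 on average
(100 simulated null screens of 150 proteins, 4 + 4 replicates, in the
test suite).

## Stoichiometric abundance

For each significant protein (plus the bait), on **raw** (un-logged)
intensities:

1. mean LFQ over replicates divided by the protein's molecular weight
   (LFQ scales with molar amount × MW, so this recovers molar amount);
2. the same quantity in the control IP subtracted;
3. normalised to the bait, set to 100.

Missing intensities enter the replicate mean as 0 by default
(`missing_as_zero = TRUE`): on the raw scale, absence means "not
detected", and averaging only observed replicates would inflate
abundances of sporadically detected proteins. The mean-of-observed
alternative is available. Non-positive background-subtracted values are
reported ND (`NA`), displayed grey in heatmaps. A bait not enriched over
its control makes the whole condition unusable and is a hard error.

One algebraic caveat: the bait's molecular weight enters $A_{bait}$ and
therefore rescales every prey's $S$ by a common factor; it cancels in
prey-to-prey ratios (and in the simulator, where planted interactor
intensities carry the factor $MW_p/MW_{bait}$). The invariants tested
are scale invariance of $S$ under global intensity scaling, invariance
of prey ratios to bait MW, and bait $\equiv$ 100.

For display and clustering, $S$ is transformed to
$\log_2(S \times 10^3)$: stoichiometries spanning 0.001–100% of the bait
then occupy a convenient 0–17 range. Conditions are clustered with
average linkage on Euclidean distances (the common default for such
heatmaps). ND handling: distances are computed pairwise-complete and
rescaled by $\sqrt{n_{total}/n_{shared}}$; column pairs sharing no
defined entries get the maximum observed distance; fully-ND columns are
dropped with a warning. Three-bait comparisons report per-bait unions of
significant proteins across conditions, the seven disjoint Venn region
counts, and pairwise shared fractions $|U_i \cap U_j|/|U_j|$.

# CLIP metagene analysis

## Coordinates and conventions

Internally all intervals are 0-based half-open; GTF input (1-based
closed) is converted at the boundary. Exon rank counts 5′→3′ in
transcript orientation, so rank 1 of a minus-strand transcript is the
genomically rightmost exon. Categories: `monoexonic`, `first`,
`internal`, `last`. For genes with several annotated transcripts the
loader can keep only the longest mature transcript per gene
(`representative = "longest"`); the default keeps all.

Conversion calling follows the PAR-CLIP logic: at a reference T,
uppercase `C` read bases are forward-strand T>C conversions; at a
reference A, lowercase `g` read bases are the same event observed on
reverse reads. All other mismatches are ignored. The mpileup base-string
grammar (`^` + mapping quality, `$`, `+n`/`-n` indel tokens, `*`, `<`,
`>`) is parsed so that the token count must reconcile with the depth
field; any inconsistency is a hard error naming the line.

## Profiles

* **Transcript metagene**: exonic signal is mapped to mature-transcript
  coordinates (introns excised), each transcript's axis is rescaled to
  `n_bins` with fractional-overlap binning (a base overlapping two bins
  splits its score proportionally — transcripts shorter than the bin
  count are handled by the same rule, no special case), and bins are
  averaged across transcripts with equal weight per transcript.
  Expression weighting is deliberately absent: profiles describe where
  on a transcript a factor sits, not how much of the transcriptome it
  occupies.
* **Exon-anchored**: exons of one category, strictly longer than
  `min_exon_len` (default 200 nt — strict, so a 200 nt exon is
  excluded), contribute an axis of `flank_bins` unscaled nt at the 5′
  end, a body rescaled to `body_bins`, and `flank_bins` unscaled nt at
  the 3′ end. Unscaled anchors preserve nucleotide-resolution structure
  near exon ends, where junction-associated factors concentrate.
* **Junction offsets**: every exon followed by a junction (first and
  internal) accumulates signal at offset = mature distance to its 3′
  end, offset 1 being the last exonic base. Offsets are therefore
  integers ≥ 1; an "offset 0" does not exist in this convention.

All three profile builders iterate features in a canonical order
(transcript order, then exon rank) and sort hits by mature position
before accumulating, so results are bit-identical under genome
reflection plus strand flip — an invariant the test suite asserts
exactly, not approximately.

# Exon-count bias in differential expression

DESeq2-format tables are consumed as-is (`id`, `baseMean`,
`log2FoldChange`, `padj`); the model fitting itself is upstream.
Directions at `fdr_level` (default 0.1): `up` if `padj` below the level
and positive fold change, `down` symmetric, otherwise `unchanged` —
including transcripts with `padj = NA` (removed by DESeq2's independent
filtering). Exon counts are taken per transcript id from the annotation;
ids missing from it are dropped with a message. Counting exons per
transcript isoform (not per gene) matches the granularity of the DE
table itself.

The Mann–Whitney U test uses midranks for ties. For
$n_x + n_y \le 12$ (or `mode = "exact"`, refused above 20 total) the
null is enumerated exactly over all $\binom{n}{n_x}$ assignments, with
the two-sided p-value $P(|U - n_x n_y/2| \ge |U_{obs} - n_x n_y/2|)$;
for tie-free data this equals the classic doubled one-sided exact
p-value (asserted against `wilcox.test`). Otherwise a normal
approximation with tie-corrected variance and continuity correction is
used. $U_x + U_y = n_x n_y$ always.

Expression matching is greedy 1:1 nearest-neighbour matching on
$\log_{10}$ baseMean without replacement: the smaller direction is
visited in a seeded random order and each transcript takes the closest
unmatched partner within `caliper_log10` (default 0.1, i.e. a 1.26-fold
expression window). Greedy matching was chosen over optimal matching for
determinism and auditability — the pairing can be inspected via
`attr(matched, "pairs")` — and the caliper guarantees no pair differs by
more than the stated amount, which is what the confounder check needs.

# What the simulators emulate — and what they do not

**IP-MS** (`simulate_ipms`): a bait detected only in bait IPs; true
interactors at configured molar stoichiometries whose mean intensity is
$\text{stoich} \times I_{bait} \times MW_p / MW_{bait}$, so the
stoichiometry score is recoverable by construction (and exactly so in
the noise-free limit); a nonspecific background present at equal means
in both IPs; molecular weights uniform on 10–300 kDa; mean-preserving
lognormal replicate noise at the configured CV (default 0.2, a typical
replicate spread for optimised IP screens); and left-censored
missingness — dropout probability logistic in log2 intensity around a
detection limit, the missingness structure the downshifted-normal
imputation presumes. Defaults use 4 bait + 4 control replicates,
matching screens run in triplicate or quadruplicate. Three flagged decoy
rows exercise load-time filtering. Not emulated: peptide-level
quantification, shared peptides, ratio compression, between-run
normalisation artefacts — so passing tests validate the analysis logic,
not robustness to those upstream effects.

**Annotation** (`simulate_annotation`): one synthetic chromosome with
non-overlapping, single-isoform genes; exon counts for multiexonic
transcripts from a negative-binomial-shaped distribution with mean ~8
(human-like), 10% monoexonic, exon lengths 80–400 nt, intron lengths
100–2000 nt, strands random. No overlapping genes, alternative isoforms,
or chromosome ends — deliberately, since the analysis operates per
transcript.

**CLIP** (`simulate_clip`): crosslink events at junction-bearing exons
with offsets drawn from a configurable distribution; the default places
45% of mass in each of the 10–20 nt and 25–35 nt bands upstream of the
junction with a 10% diffuse background over 1–45 nt, emulating a
junction-associated deposition pattern. Per event, read depth is Poisson
(mean 30) and conversions binomial (rate 0.25, a typical PAR-CLIP
conversion efficiency). Events are projected to the genome respecting
strand and emitted as 6-column mpileup text (uppercase forward /
lowercase reverse, no indel tokens — the parser still handles them) plus
a BED6 of conversion sites. Offsets exceeding their exon are skipped and
reported. Not emulated: sequencing errors, non-crosslink mismatches,
multimapping, library-size differences between factors.

**Differential expression** (`simulate_de_table`): lognormal baseMeans;
a constant up-regulation probability and a down-regulation probability
that may depend on exon count (the planted effect); significant
transcripts receive `padj` uniform below the FDR level and fold changes
of the configured magnitude, unchanged transcripts `padj` above it or
`NA` for a configurable untested fraction. This generates the *results
table* distribution needed to test the downstream comparison; it does
not model counts, dispersion estimation or shrinkage. baseMean is
independent of exon count by default, so expression matching can be
validated against instances where the confounding is introduced
explicitly.

# Numerical choices and degenerate inputs

* Seeds: every stochastic routine takes an explicit seed and restores
  the caller's RNG state; identical configs give byte-identical output.
* `d` with zero pooled error and `s0 = 0`: defined 0 when the mean
  difference is also 0; otherwise infinite, which orders correctly.
* Empty results propagate as empty (zero-row tables, empty significance
  sets); profiles over zero qualifying features return all-`NA` means
  with a warning; an all-flagged proteinGroups file loads as an empty
  matrix with a warning.
* Problem sizes in the validation suite were chosen to make the checks
  sharp but quick: e.g. 100 replicate screens for FDR control and
  stoichiometry error, 10⁴ imputation draws and ≥10⁴ planted crosslink
  events, 200 simulated DE screens for null uniformity and 100 for
  power.

# Known limitations

* The permutation FDR is conservative when many proteins are truly
  enriched (their signal leaks into the permuted null); with only a few
  hundred proteins and 3–4 replicates the discrete permutation space
  limits how fine q-value resolution can be.
* Stoichiometries assume LFQ intensity proportional to molar amount ×
  MW; deviations (ionisation efficiency, sequence coverage) propagate
  directly into $S$.
* CLIP profiles are per-factor; no cross-factor normalisation is
  attempted, so comparisons between factors should be qualitative.
* Greedy matching does not guarantee the maximum number of matched
  pairs; with a tight caliper on strongly shifted expression
  distributions it can discard many transcripts (it errors only if no
  pair fits).
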