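---
title: "Methods: lineage-specific SV inference on simulated catarrhine genomes"
author: "lineageSV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lineage-specific SV inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models and procedures behind `lineageSV`, the
assumptions they make, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical
choices taken where the design was genuinely open.

## 1. The inference problem

Given one Old World monkey assembly (the *reference frame*, "macaque") and
several ape assemblies, the package infers structural variants (SVs,
deletions and insertions ≥ 50 bp) that arose on the ape stem. The chain of
evidence is:

* an SV is *called* in each macaque–ape pairwise comparison, in both
  directions, and kept only when the two directions agree;
* it is a *candidate* when every ape comparison contains a type-matched
  partner with > 50 % reciprocal overlap (strict inequality on both
  lengths);
* it is *polarized* by an outgroup: if the marmoset-role genome carries the
  macaque-like allele at the locus, the variant is ape-derived
  (`high_confident`); if it carries the ape allele, the "shared" variant is
  actually a macaque-lineage change (`false`); anything unresolvable is
  `uncertain`. A gibbon-role genome applied the same way separates ape-wide
  (`ASSV`) from great-ape-specific (`GASSV`) variants.

Duplications and inversions are represented in the data model and the
simulator but are not called by the pairwise engine: the lineage inference
is restricted to deletions and insertions, the two types that dominate
assembly comparisons and that the polarization rule handles cleanly.

SV polarity is ape-centric throughout: a `DEL` means sequence present in
macaque and absent in (some) apes; a macaque-branch deletion therefore
surfaces as an `INS` in the comparison frame. This matches how a
macaque-referenced comparison reads and keeps one convention across truth
tables, callsets, and classification.

## 2. The alignment layer: unique k-mer anchors and LIS chains

The package deliberately does not wrap an external aligner. Its alignment
primitive is the *unique k-mer anchor*: a k-mer (default k = 31, odd, ≤ 31
because k-mers are packed two bits per base into one 64-bit word) that
occurs exactly once in each of the two genomes, counted in canonical
(strand-collapsed) form. Anchor orientation records whether the two
occurrences are on the same strand.

Anchors are chained per (reference chromosome, query chromosome,
orientation) group by longest increasing subsequence (LIS) on query
position ordered by reference position — the maximum-cardinality colinear
subset. Successive LIS rounds on the remaining anchors let rearranged
blocks form their own chains instead of being discarded; chains split
where the inter-anchor distance on either genome exceeds `max_chain_gap`
(default 100 kb). Chains with fewer than `min_chain_anchors` (default 5)
anchors are never used for SV calling, so stray off-diagonal anchors
cannot imply giant indels.

For adjacent anchors in a forward chain with reference gap `g_r` and query
gap `g_q` between k-mer footprints, `d = g_q − g_r` is the exact net indel
size between the anchors regardless of whether the footprints overlap
(adjacent anchors typically overlap by up to k − 1 bp; the overlap cancels
in the difference). `d ≥ min_len` (default 50) is an insertion in the
query, `d ≤ −min_len` a deletion. Breakpoints are placed at the end of the
upstream anchor footprint and are exact when anchors reach the junction;
in repeat-degenerate neighbourhoods they can be off by up to k bp, and
insertion placement is additionally ambiguous up to junction homology (a
called insertion may be a rotation of the planted one that reconstructs
the identical query sequence — the tests assert reconstruction, not string
identity, for exactly this reason).

Both calling directions share one anchor relation (it is symmetric by
construction); the reverse direction re-derives chains and gaps from the
query ordering, and its calls are projected back into the forward frame
using the query-side footprints the anchors provide. Forward/reverse
concordance then keeps forward calls with a > 50 % reciprocal-overlap,
type-matched partner in the projected reverse set.

## 3. Outgroup polarization

For each candidate, the macaque flanks (default 1 kb) on either side of
the SV are located in the outgroup genome via the same anchor machinery,
restricted to the flanks. Two coverages are computed per flank:

* *placement* uses unique anchors only — the chain decides where the flank
  sits and projects the exact gap-facing boundary through the anchor
  nearest the junction (substitutions do not shift coordinates, so the
  projected span is exact under substitution-only divergence);
* *identity* is the flank footprint covered by k-mers that occur anywhere
  in the outgroup (no uniqueness requirement). This is the
  alignment-identity proxy for the 0.85 pre-filter: repeat-resident flanks
  align fine in a real aligner even though their k-mers are not unique, so
  uniqueness must not be part of the identity test.

The outgroup inter-flank span is then compared against the two allele
spans (macaque allele: SV length for a deletion, 0 for an insertion; ape
allele: the reverse). The span is assigned to the nearer allele if within
`span_tol` (default ±10 % of the SV length, floored at 10 % of 50 bp);
ties, negative spans, ambiguous placements, cross-chromosome or
cross-orientation flank pairs, and identity below 0.85 all yield
`uncertain`. Flank contamination — a *different* SV landing within 1 kb of
the candidate — legitimately produces `uncertain`, which is the same
failure mode manual curation hits on real data; with the default event
load (180 events on 2 Mb) a few percent of loci are affected, which is why
seeded sensitivity is 1.0 on some seeds and ~0.98 on others.

## 4. Assembly QC

A *gap* is a maximal run of ≥ 2 Ns (a lone N is not a gap; `minRun` is
configurable). Gap closure extracts up to 5 kb of flanking sequence on
each side, maps each flank onto the new assembly (same machinery as
above), and requires the presence-footprint on the flank to exceed
`min_aligned` (default 2.5 kb). If both flanks map unambiguously to the
same assembly chromosome in one orientation, the boundary coordinates LC
(projected end of the upstream flank) and RC (projected start of the
downstream flank) define the closed-gap length RC − LC, accepted only when
LC < RC and the assembly bases between them contain no N. Neither flank
mapping, or an ambiguous best mapping, is `flank_fail`; a single mapped
flank or an inconsistent pair is `unclosed`. Reverse-complemented loci are
closed via minus-orientation chains, with the fill reverse-complemented.

`QV = −10·log10(P)` with `P` the homozygous-variant rate per assembly
base; zero variants give an infinite sentinel, flagged rather than capped.
N50 is the largest L such that segments ≥ L sum to at least half the
total; contigs are scaffold segments split at N-runs.

## 5. Statistical modules

**ADE calling.** Counts are tested on the log2(count + 1) scale — the
variance-stabilizing choice is stated here because the upstream count
definition leaves the transform open. Tests are pooled-variance Student t
(the chimp group has n = 2, where Welch degrees of freedom are unstable;
Welch is available via `varEqual = FALSE`). An enhancer is an ADE when
macaque–human and macaque–chimp are both significant (raw p < 0.05) in the
same direction while human–chimp is not (p > 0.05); no multiple-testing
correction by default, mirroring the raw-threshold criterion (a BH mode
exists). The reported fold change is log2 of (mean human + mean chimp)/2
over mean macaque on the raw scale. Under the all-null simulator at
CV 0.15 the compound criterion fires at ≤ 1 % — well under the nominal 5 %
of each component because both cross-species tests must agree in
direction while sharing the macaque samples.

**Subtelomeric enrichment and gene-set enrichment.** Both use the same
null form: re-draw positions uniformly (per chromosome for SV starts;
uniform subsets of the SV universe for the gene statistic) and report the
add-one estimator `(1 + #{null ≥ observed}) / (1 + n_iter)`, which can
never be 0 — extreme published p-values are treated as bounds, not
targets. With discrete count statistics the estimator is conservative:
ties count toward p, so p is stochastically ≥ uniform under the null.
Calibration is therefore checked one-sided (no excess of small p-values at
any threshold); a two-sided uniformity test would reject any conservative
estimator by construction. The gene statistic counts distinct trait genes
hit within ± 5 kb (an SV–gene pair-count mode exists). Fisher's exact test
on the 2×2 table (subset membership × gene hit) is reported alongside as
the analytic alternative.

**Genotype summaries.** *Fixed* defaults to homozygous-alt in every
individual (the "carrier" reading — every individual carries ≥ 1 alt — is
available via `fixedRule`); *present*, *absent* and *invalidated*
partition the callset, and fixed/polymorphic partition the present set.

## 6. The simulator: what it emulates, and what it does not

`generateAncestralGenome` draws i.i.d. background bases at GC 0.41 and
plants two repeat families — a 300 bp SINE-like monomer and 1–4 kb
fragments of a 4 kb LINE-like consensus (5'-truncation style) — to a
target 15 % of bases, each copy independently mutated at 15 % per base.
The divergence level matters: near-identical copies would make repeat
interiors anchor-deserts, while 15 % (an old repeat complement) leaves
most 31-mers unique and makes dense anchoring possible, which is the
regime the default conditions assume.

`evolveGenomes` plants per-branch events on the fixed topology. Defaults
define the study conditions: 60 ape-stem events (40 DEL + 20 INS — the
roughly 2:1 deletion bias reported for ape-specific SV sets), 40
macaque-branch events (27 + 13), 20 per great-ape tip (13 + 7), lengths
log-normal with medians 319 bp (DEL) and 231 bp (INS) and σ_log = 1,
floored at 50 bp and capped at 10 kb so desk-scale chromosomes stay
tileable; 0.002 substitutions per base per branch on every branch. The
marmoset and gibbon branches carry substitution divergence but no planted
SVs by default: outgroup SVs would only perturb flank spans at candidate
loci, and modelling them is not needed for any inference the package
makes. Events are rejected within ±50 bp of *any* previously placed event
(not just same-lineage): cross-lineage overlap would make truth projection
onto the macaque frame ill-defined, and the conservative rule keeps the
projection-soundness invariant (the macaque genome contains every ape-stem
deletion verbatim at its recorded coordinates) exactly testable.
Substitutions are drawn per branch in ancestor coordinates and applied to
every descendant tip, so shared branches diverge identically; inserted
sequences do not accumulate later substitutions — a simplification that
only softens the noise level on insertions.

The simulator does **not** emulate: read-level errors or coverage (no
FASTQ), recurrent mutation, segmental duplications or translocations,
within-species polymorphism beyond the genotype-table abstraction, GC or
replication-timing biases, or realistic repeat phylogenies. Passing the
end-to-end tests therefore shows the inference logic is correct under
substitution-plus-indel divergence with diverged repeats — not that the
engine matches a production aligner on raw long reads.

`makeGappedReference` replaces sequence with equal-length N-runs, ≥ 6 kb
apart and from ends (room for 5 kb flanks). `simulateEnhancerMatrix` draws
per-enhancer log-normal baselines (meanlog log 100, sdlog 1), multiplies
the human and chimp means by 2^±2 for planted gains/losses, and applies
mean-one log-normal noise at CV 0.15 over (3, 2, 3) human/chimp/macaque
samples. `simulateGenotypes` fixes a 0.134 fraction, draws the rest at
Uniform(0.1, 0.9) allele frequency under Hardy–Weinberg, and invalidates
repeat-resident insertions with probability 0.6 — the failure signature of
short-read genotyping.

## 7. Problem sizes, seeds, and reproducibility

The default pipeline world is 2 chromosomes × 1 Mb. At that scale the
full ASSV stage (4 apes, both directions, outgroup classification) runs in
about a minute; the packaged test suite and the acceptance script use this
size for end-to-end checks and smaller worlds (150–300 kb) for unit
tests. The subtelomeric margin scales with the world: 100 kb on 1 Mb
chromosomes plays the role the 5 Mb margin plays on real chromosomes.
Permutation defaults are 1000 (subtelomeric) and 2000 (gene sets) in the
pipeline, with the full 10^6-scale counts reachable through `n_iter`.

Every exported stochastic function takes a seed; `runPipeline` derives a
named substream per stage from the single top-level seed, so partial
re-runs reproduce and two runs with the same config are identical down to
the serialized report. A draft-assembly error model (substitutions planted
at 1.11 × 10⁻⁵ per base) feeds the QV stage with a genuinely computed
homozygous-variant count, standing in for the read-mapping pipeline that
is out of scope.

## 8. Known limitations

* Anchor uniqueness is genome-wide; very recent (near-identical) repeat
  expansions would create anchor deserts and degrade breakpoint precision
  to the distance of the nearest unique flank.
* Insertion breakpoints are ambiguous up to junction homology; reported
  inserted sequences are rotations of the planted ones in those cases.
* Outgroup classification is span-based, not base-level alignment;
  balanced events at a locus (equal-length replacement) would be
  mis-read as the macaque-like allele.
* Flanks contaminated by neighbouring SVs yield `uncertain`, reducing
  seeded sensitivity by a few percent at the default event density.
* The t tests assume log-scale normality of enhancer counts; heavy-tailed
  real ChIP-seq counts would need the BH-adjusted mode and larger n.
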