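---
title: "Methods: genome-resolved CAZyme annotation, clusters, and expression ecology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-resolved CAZyme annotation, clusters, and expression ecology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cazyscape)
```

This vignette documents the models and procedures the package implements,
the parameters that matter, the design choices that were genuinely open,
and what the synthetic-data tests do and do not establish about real
data.

## The analysis model

The package treats a community study as a fixed set of population
genomes (MAGs), each a bag of contigs carrying ordered genes. Four layers
of inference sit on top:

1. **Family annotation** decides which genes encode carbohydrate-active
   enzymes, from profile-HMM domain hits.
2. **Functional resolution** attaches Enzyme Commission numbers and then
   substrate categories to those genes.
3. **Cluster detection** finds operon-like CAZyme gene clusters (CGCs;
   polysaccharide utilization loci in *Bacteroidota*) from gene order.
4. **Quantification** decides which populations are present where, and
   which of their CAZyme genes are transcribed, from coverage and
   read-count tables.

All inputs are plain tables in the formats the field's tools emit
(HMMER per-domain tables, BLAST/DIAMOND outfmt-6 TSV, GFF3 or a
7-column gene TSV, TSV matrices). The package never runs the searches
itself; it consumes their outputs.

## Domain-hit filtering and overlap resolution

A domain hit survives when its independent domain E-value is strictly
below `e_max = 1e-18` and its profile coverage is at least
`cov_min = 0.35`. Two deliberate readings are baked in:

* **Coverage is measured on the HMM profile**, not the query protein:
  `(hmm_to − hmm_from + 1)/hmm_length`. That is what "domain coverage"
  means in the dbCAN lineage of tools this stage emulates.
* **The E-value filtered is the independent domain E-value**, not the
  full-sequence one, since a multi-domain protein can carry one genuine
  and several spurious domains.

Overlap resolution then enforces that no two retained domains on one
protein overlap by more than 50% of the shorter alignment. The published
parser scripts in this tool lineage do not document their tie-breaking,
so the package fixes a fully deterministic procedure: candidates are
ordered by ascending E-value, then descending alignment length, then
family label, then start coordinate, and accepted greedily when
compatible with everything already accepted. Two properties of this
choice are enforced by tests: it is idempotent, and it equals an
exhaustive subset-enumeration oracle under the same priority order. The
comparison against *the shorter* hit's length (rather than either hit's)
is the stricter reading and is flagged as a sensitivity point; the
threshold itself is exposed, so the choice is auditable.

Filtering runs **before** overlap resolution. The order matters: a
high-scoring but low-coverage decoy could otherwise displace a genuine
overlapping hit during resolution and then be removed by the filter,
leaving the gene unannotated. A regression test pins this order.

## The EC cascade

EC numbers come from four evidence sources applied strictly in order,
stopping at the first that yields at least one EC: subfamily-hit
metadata; DRAM-style KO annotations; protein-database alignments of the
same family (`E < 1e-102`, percent identity ≥ 35, query coverage ≥ 70);
and BLAST-KEGG KO annotations. Rules 2 and 4 accept a KO's EC only when
it also appears in the curated EC list of at least one of the gene's
families — "agreement" is set membership, checked against any assigned
family. Three further choices:

* When a rule yields several ECs, **all are kept**; downstream substrate
  matching unions over them.
* Partial EC strings (`3.2.1.-`) are legal and compared literally;
  wildcard semantics are not defined anywhere in the source databases'
  dumps, so inventing them would be over-interpretation.
* When several subfamily hits carry conflicting ECs, the union is taken
  (rule 1 does not arbitrate between its own evidence rows).

An exhaustive test over all sixteen presence/absence patterns of the
four evidence types confirms the cascade always reports the
lowest-numbered firing rule.

## Substrates

A gene maps to a substrate only through a **joint** `(family, EC)` key of
the curated map — the stricter of the two readings of matching families
and ECs "against" a substrate table, and the one that avoids annotating,
say, a GH13 amylase with a substrate curated for the same EC in an
unrelated family. Family-only (EC-less) rows are deliberately not
supported. The package ships a small default map of well-characterized
triples under `inst/extdata` as a documented starting point; any real
study should supply its own curated file, because published substrate
maps undergo manual curation that cannot be reproduced mechanically.

## Cluster detection and cluster substrates

"Distanced at most two genes apart" is read as **at most two intervening
non-signature genes** between consecutive signature genes — the
CGC-Finder semantics this definition paraphrases. A maximal chain is a
cluster iff it contains at least one CAZyme and at least one other
signature role; the span runs from the first to the last signature
member, so interior unannotated genes belong to the cluster while
flanking ones do not. When several evidence types hit one gene, role
precedence is CAZyme > transporter > transcription factor >
signal-transduction protein, because CAZyme membership is the
cluster-defining property.

The signature databases publish no thresholds, so dbCAN3-style defaults
are used and exposed as parameters: TF/STP HMM hits at `E < 1e-4` with
coverage ≥ 0.35; transporter alignments at `E ≤ 1e-10` with query
coverage ≥ 35%; transporter-domain HMM hits at `E < 1e-4`.

Cluster substrates are predicted two ways. **Homology**: alignments of
member proteins to a PUL database are kept below `E = 1e-102`; per
candidate PUL only the best hit per (member gene, PUL) pair is summed,
so multi-HSP matches cannot inflate a PUL's score; eligible PULs must be
matched at a CAZyme subject and at another signature subject; the
highest summed bitscore wins, ties resolved by ascending PUL identifier.
**Voting**: each member gene votes once per distinct substrate in its
set; winners need at least `vote_min = 2` votes, because a single-vote
"majority" carries no information; co-winners are all reported. The susC/susD
tandem tally is generalized as a count of adjacent tagged gene pairs
(indices differing by exactly one — an intervening gene breaks the pair).

## Quantification conventions

* Genome breadth per sample is the **contig-length-weighted** mean of
  contig breadths; presence requires breadth ≥ 0.10 (inclusive). Depth
  is summarized the same way, matching genome-level conventions of the
  depth summarizers in common use.
* The `< 5` read-pair exclusion is applied **per gene per sample**
  (cell-wise). The alternative — dropping a gene in all samples when any
  sample is shallow — would couple samples and contradict the per-sample
  TPM framing; the threshold is a parameter for users who want the other
  reading.
* The TPM denominator runs over **all genes** of the quality-passing
  genome set mapped in the sample, not CAZyme genes only: TPM is defined
  against the full transcriptome, and normalization happens before
  subsetting. Filtering precedes normalization, and a regression test
  pins a case where the reverse order differs.
* Per-capita expression is genome-summed TPM divided by that genome's
  mean depth in the same sample; depth 0 leaves the value missing rather
  than zero, because "no detectable population" is not "present but
  silent".
* When TPM is aggregated by EC (or family, or substrate), a gene
  carrying several keys contributes its full TPM to each — the keys are
  alternative descriptions of the same transcripts, not shares of them.

## Ecology statistics

Inverse Simpson diversity is computed as `S²/Σx²` (algebraically
`1/Σp²`, but exact for integer abundances, so the uniform-vector
identity holds without tolerance). Bray–Curtis is `Σ|x−y|/Σ(x+y)`.
Spearman correlation uses average ranks and the t-approximation for its
two-sided p-value. The rank-sum comparison enumerates all group
assignments exactly (ties included) when both groups have at most eight
observations, and otherwise uses the normal approximation with tie
correction and no continuity correction; an independent
pair-counting/bitmask oracle verifies the exact path. No multiple-testing
correction is applied to habitat comparisons, because the statistics are
reported as machinery (statistic plus p-value), not as a screened
discovery list — differential-expression modelling is out of scope. The
abundance unit feeding diversity is per-MAG summed TPM of the genes
sharing a key, the default grouping of `aggregate_tpm()`.

The expressing fraction counts, per substrate and habitat, genomes that
are present in at least one habitat sample and encode the substrate, and
the subset of those with at least one such gene expressed there;
fractions are classified against the 0.5 line and left undefined when no
encoding genome is present.

## What the generator emulates — and what it does not

`simulate_community()` emits identifiers, coordinates and hit tables,
never sequences. It emulates the statistical structure the analysis
relies on:

* **Margin-based decoys.** True CAZyme hits draw
  `E ∈ [1e-40, 1e-19]` and coverage in `[0.4, 1]`; decoys draw
  `E ∈ [1e-17, 1e-5]` or coverage ≤ 0.30 — at least one decade in E or
  0.05 in coverage away from the thresholds on the failing side, so
  threshold tests cannot flake. Decoys are therefore *not*
  distribution-matched to real noise; the tests establish the filters'
  decision boundaries, not their real-world error rates.
* **Planted clusters with padding.** Each planted cluster (and each
  decoy violating the gap rule or lacking a second signature role) sits
  alone on its contig with at least three non-signature genes on either
  side, so detected spans are comparable to the ledger exactly. Real
  genomes have tangent and nested arrangements the generator avoids.
* **Operon-like expression.** Expression states are drawn once per
  (genome, substrate, sample) and inherited by that genome's genes for
  the substrate. This makes the expressing fraction of encoding genomes
  an exact Bernoulli sample of the configured probability, which is what
  the calibration test checks; per-gene independent expression would
  make the target a gene-count-dependent function of it. Genes without a
  substrate express independently at a background probability.
* **Overdispersed counts.** Read pairs are negative binomial
  (`mean_expressed = 50`, `mean_silent = 1`, dispersion 5 by default) —
  Poisson counts would understate the flag-error rate of the ≥ 5
  read-pair rule. In `noise_free` mode counts are deterministic
  (expressed cells get `max(5, round(mean))`, silent cells 0), so the
  expressed flags recover the planted states exactly.
* **Family richness with headroom.** Substrate-linked genes draw from
  ten curated archetype families; background CAZymes additionally draw
  from a 150-strong rare-family pool with no EC (exercising the
  no-evidence branch of the cascade). Without the rare pool, every
  sample would saturate all families and habitat richness contrasts
  would be invisible.
* **One RNG stream per fixture type**, all derived from the master seed,
  so adding a fixture type never perturbs existing ones, and the same
  seed yields byte-identical fixture files.

The estuary scenario (`scenario_estuary()`) fixes the study-shaped
contrasts: sediment communities carry a higher CAZyme gene fraction than
water (0.25 vs 0.12), and water populations express substrate genes with
higher probability (0.9 vs 0.35). Default problem sizes are 30
quality-passing genomes plus 2 low-quality ones per habitat, 2–4 contigs
per genome, 14–30 genes per contig, three samples per habitat, and 12
planted clusters against 12 decoys; the cluster-recovery check scales to
200 planted against 200 decoys, and the expression-calibration check to
200 genomes per habitat with one sample each. These sizes give every
per-gene statistic thousands of observations while each simulated study
builds in about a second.

Passing on this generator shows the *logic* of every stage is exact
under its stated assumptions. It does not validate HMM search
sensitivity, chimeric bins, strain heterogeneity, mapping bias, or any
other upstream artifact — those enter through the input tables, which
real studies must quality-control upstream.

## Calibration of the noisy expression check

Under noise, each (substrate, habitat) expressing fraction is an
approximately binomial estimate of its configured probability, mildly
perturbed by count noise around the read-pair floor. Checking a dozen
such estimates against individual 95% bands simultaneously would fail a
correctly calibrated pipeline almost half the time, so the test asserts
calibration properly: no estimate may fall outside the 99.9% band, and
at most the multiplicity-expected number may exceed the 95% band. The
acceptance script reports the maximum absolute deviation and the number
of encoding genomes behind it, leaving the judgment quantitative.

## Interfaces and scope

The exported functions are the interface: `run_pipeline()` executes the
whole chain on a simulation object or a fixture directory with one
parameter list (`pipeline_params()`, unknown names rejected), and
`simulate_community(dir = ...)` writes a complete fixture set with a
checksum manifest; each stage function runs standalone on the previous
stage's tables. Genes are accepted as given (no partial-gene filtering —
that belongs to the gene caller's quality control). Out of scope by
design: read processing, assembly, binning, dereplication, read mapping
and counting, signal-peptide prediction (consumed as a gene attribute),
ordination plotting, differential-expression model fitting, and taxonomy.

## Known limitations

* Subfamily labels are kept distinct from parent families (`GH16_3` is
  not `GH16`); no reconciliation of subfamily/parent double counting is
  attempted.
* The overlap rule's comparison against the shorter alignment is a
  documented choice, not a published fact; sensitivity to it can be
  probed through the exposed threshold but is not reported by default.
* The substrate map is data, not code: the 45-category vocabulary of a
  full study, and its manual curation, are inputs the package cannot
  reconstruct.
* Rank-sum p-values switch from exact enumeration to a normal
  approximation above group size eight; near that boundary with heavy
  ties the two can differ in the third decimal.
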