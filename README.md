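# cazyscape

Genome-resolved analysis of carbohydrate-active enzymes (CAZymes) in
microbial communities, for microbial ecologists working with
metagenome-assembled genomes (MAGs) and paired metatranscriptomes.
Starting from standard search outputs — HMMER per-domain tables against
CAZyme HMM databases, DIAMOND/BLAST tabular alignments against protein,
transporter and PUL databases, gene tables, coverage and read-count
matrices — the package answers: which populations *carry* genes for which
polysaccharide substrates, which populations actually *express* them, and
how carbohydrate-degradation potential and activity partition between
habitats.

## What it computes

**CAZy family annotation.** Domain hits are kept when the independent
domain E-value is `< 1e-18` and the profile coverage
`(hmm_to − hmm_from + 1)/hmm_length ≥ 0.35`, then reduced to a
non-overlapping set: no retained pair of domains may overlap by more than
50% of the shorter alignment, with a deterministic greedy priority
(E-value, then alignment length, family, position). A gene's families are
the families of its surviving hits; genes can carry several.

**EC assignment.** An ordered four-rule cascade, stopping at the first
rule that yields an EC: (1) ECs on surviving subfamily (dbCAN-sub style)
hits; (2) DRAM KO ECs that agree with the gene's family's curated EC
list; (3) ECs of protein-database hits of the same family
(`E < 1e-102`, identity ≥ 35%, query coverage ≥ 70%); (4) BLAST-KEGG KO
ECs under the rule-2 agreement test.

**Substrates.** A gene maps to a substrate category when one of its
`(family, EC)` pairs is a curated key of the substrate map (joint match;
a small documented default map ships in `inst/extdata`).

**CAZyme gene clusters (CGCs / PULs).** Signature genes (CAZymes,
transcription factors, signal-transduction proteins, transporters) are
chained along contig gene order with at most two intervening
non-signature genes; a chain is a cluster iff it holds ≥ 1 CAZyme and
≥ 1 other signature gene. Cluster substrates come from PUL homology
(summed best-hit bitscores over `E < 1e-102` alignments, eligibility
requiring a matched CAZyme plus another signature subject) and from
majority voting over member-gene substrates (support ≥ 2 votes).

**Quantification.** MAGs pass quality at completeness ≥ 50% and
contamination ≤ 5%; a MAG is present in a sample when its
contig-length-weighted coverage breadth is ≥ 10%. Gene read-pair counts
below 5 are zeroed per cell, then TPM-normalized
(`tpm_g = 1e6 · rate_g / Σ rate`, `rate_g = counts_g/(len_g/1000)`);
per-capita expression divides genome-summed TPM by genome mean depth.
A gene is *expressed* in a sample when it keeps ≥ 5 read pairs.

**Ecology.** Richness partitions between habitats, inverse Simpson
diversity (`S²/Σx²`), Bray–Curtis dissimilarity (`Σ|x−y|/Σ(x+y)`),
Spearman rank correlation, exact/normal-approximation rank-sum
comparisons, and the expressing fraction of substrate-encoding
populations with its classification against the 0.5 line.

**Synthetic communities.** `sim_config()` / `scenario_estuary()` and
`simulate_community()` generate a seeded mock study — genomes, gene
tables, true and decoy hits, planted clusters and cluster decoys,
coverage and negative-binomial counts — together with a complete truth
ledger, so the whole pipeline is testable without any downloads.

## Worked example

```r
library(cazyscape)

cfg <- scenario_estuary(seed = 1, noise_free = TRUE)
sim <- simulate_community(cfg)
res <- run_pipeline(sim)

nrow(res$annotations)                        # 798 CAZyme genes
sum(nzchar(res$annotations$ec_numbers))      # 423 with an EC number

head(res$annotations[nzchar(res$annotations$substrates), ], 3)
#                    gene_id families ec_numbers ec_source substrates
# 1 MAG_sediment_001_c1_g011     GH10    3.2.1.8     RULE3      xylan
# 4 MAG_sediment_001_c2_g001      PL1    4.2.2.2     RULE4     pectin
# 6 MAG_sediment_001_c2_g008      PL1    4.2.2.2     RULE1     pectin

res$cgc_table[1:2, c("cgc_id", "roles", "substrate_B", "substrate_C")]
#                       cgc_id                      roles substrate_B substrate_C
# 1 MAG_sediment_025_c2_CGC001    CAZYME,NULL,TRANSPORTER beta-glucan
# 2 MAG_sediment_026_c1_CGC001 CAZYME,CAZYME,NULL,NULL,TF   cellulose   cellulose

head(res$expressing[res$expressing$n_present > 0, ], 3)
#     substrate  habitat n_present n_expressing  fraction above_half
# 1 beta-glucan sediment        27           13 0.4814815      FALSE
# 2   cellulose sediment        23           12 0.5217391       TRUE
# 3      chitin sediment        23           17 0.7391304       TRUE

res$richness          # families unique to water/sediment or shared, per site
#    site water_only sediment_only shared
# 1 site1         18            46     78
# 2 site2         16            55     66
# 3 site3         19            49     72

unlist(compare_to_ledger(res, sim))   # every agreement metric equals 1
```

The first lines say: of 4,274 simulated genes, 798 survive the CAZyme
filters, 423 receive an EC through the cascade, and those resolve to
substrate categories; the cluster table shows each detected CGC with its
member roles and both substrate predictions (the single-CAZyme cluster
gets no voting call — one vote is not a majority); the expressing table
counts, per substrate and habitat, how many present MAGs encode genes for
the substrate and how many of those express them. On noise-free input the
final comparison shows the pipeline recovering the generator's truth
exactly.

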