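---
title: "Models and methods: simulating and rediscovering copia-type retrotransposon families"
author: "copiascan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: simulating and rediscovering copia-type retrotransposon families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`copiascan` chains seven analysis stages — simulation, degenerate-primer
PCR, clone classification, homology search, consensus extension, structural
annotation, context profiling and RBIP genotyping — into one validated
workflow. This vignette documents the models behind each stage, the
parameters that matter, the numerical choices, and what the synthetic
benchmark does and does not demonstrate about real data.

## 1. The element model

A copia-type element is modelled as

```
5'LTR | PBS | leader | GAG-POL ORF | trailer | PPT | 3'LTR
```

with identical LTR copies, the PBS (tRNA-Met core complement
`TGGTATCAGAGC`, optionally preceded by spacer nucleotides) immediately after
the 5' LTR, and the PPT immediately before the 3' LTR. The bundled
nine-family parameter set (`copia_families()`) carries per-family total
length, LTR length, GAG–POL length in amino acids, and the PBS/PPT strings;
lowercase letters in those strings mark spacer or variable positions. The
two-nucleotide PBS spacer of lineage I/II families versus none in lineage
III is reproduced exactly by the templates and is one of the structural
invariants the tests assert.

One family (Jc8) has a GAG–POL ORF too long for its internal region; its
ORF legitimately runs over the PPT and into the 3' LTR. The builder
supports this: PPT-overlapped codons are constrained to the PPT string
(which is purine-only and therefore stop-free in frame), and the 5' LTR
copy inherits the overlapping ORF bases so the LTR pair stays identical.

**ORF content.** The polyprotein carries sentinel peptide anchors for GAG,
protease, integrase and RNase H at fixed relative positions, and a 220-aa
RT core whose nucleotide sequence embeds exact binding sites for all three
degenerate RT primer sets (F, V, H). The F/V/H sites are placed so that the
F product is 302 bp (the canonical "~300 bp" RT fragment), the V product
225 bp, and the three-set overlap 73 aa — the "about 75 amino acid" core
block that classification trims to. Because the sites are written in the
primers' own IUPAC alphabet and resolved to stop-free codons shared by all
families, every primer matches every family with zero mismatches, while
family identity lives in the free codons around them.

**RT-core divergence structure.** Real RT domains are alignable across
families (conserved blocks every ~20 residues) yet family-diagnostic.  The
generator reproduces both properties: six fixed 4-aa scaffold anchors are
conserved pan-family, and the free codons derive from three
lineage-ancestral cores with per-family codon retention
(`ancestor_keep = 0.45`). The resulting peptide p-distances are ~0.15–0.25
within a family (at 5% per-site copy divergence), ~0.55–0.70 between
families, comfortably straddling the 0.40 single-linkage family cut, while
within-lineage similarity remains detectable for bootstrap lineage
assignment. These retention values were fixed once at design time as the
generator's definition of "distinct families within recognisable lineages".

## 2. The genome simulator

The background is i.i.d. uniform ACGT (GC 0.5): a deliberately neutral
substrate in which any implanted homology is unambiguous. Copies are
implanted with a host-derived TSD (default 5 bp — the TSD's existence, not
its length, is documented for these families; 4–6 bp is the canonical range
and 5 bp the fixed default), i.i.d. substitutions at the requested
divergence (LTR pairs mutate independently), and optional 5'/3'
truncation. Divergence is substitution-only by default so that ground-truth
coordinates remain exact; this is the main idealisation (see §8).

Placement keeps a `min_gap` (default 14 kb) between copies so that a gene
planted within 5 kb of one copy can never sit within 6 kb of another —
making the per-family flank-gene probability an exact Bernoulli parameter
that the context stage must recover. Genes are 0.5–2 kb intervals with the
near edge uniform in [0, 5 kb).

Accession panels share the reference coordinate space; an accession lacking
an insertion carries the pre-insertion allele (element plus one TSD copy
excised), which is exactly the empty-site allele an RBIP assay scores.

Internally all coordinates are 1-based closed intervals, the
Bioconductor/IRanges convention; GFF3 output is therefore written without
translation. Identities quoted as "end − start" elsewhere become
"end − start + 1" here.

## 3. In-silico PCR

Degenerate matching treats each IUPAC code as a character class (zero cost
within the class) plus `max_mismatch` substitutions per primer (default 1 —
wet PCR tolerance is not documented, so this is a free parameter).
Matching delegates to `Biostrings::matchPattern(fixed = "subject")`.
Products pair any plus-strand site with any downstream minus-strand site in
inward orientation within the product range (default 100–1500 bp, wide
because diverged family members shift product length); sequences are
normalised to read 5'→3' from the set's forward primer, which makes
amplification strand-symmetric. Thermodynamics, multiplexing and chimera
formation are out of scope. PCR amplification bias across families is not
modelled beyond clone subsampling in the pipeline.

## 4. Translation with frameshift recovery

RT clones are translated by dynamic programming over reading positions:
each emitted residue consumes 3 nt (normal), 2 nt (recovering a deleted
base) or 4 nt (skipping an inserted base). Frame switches cost 4 codons;
reading through a stop codon in frame costs 2 and emits `X`. The
stop-read-through cost is deliberately *below* the frameshift cost: a
point-mutated (pseudogenised) stop should be crossed in frame, because a
detour through a shifted frame emits out-of-frame residues that corrupt
downstream distances. Conversely a true indel makes the original frame
stop-rich, so a single frame switch wins there. Clones needing more than
two read-throughs, or yielding under 20 aa, are classified non-RT and
dropped; clones whose peptide lacks the YVDD RT-core motif (one mismatch
allowed) are likewise discarded as spurious products — the in-silico
analogue of keeping only fragments "identifiable as the RT region".

Junction residues at a recovered frameshift are ambiguous by nature: the
switch may settle a few codons away from the true indel when the
neighbouring shifted frame happens to be stop-free, so a small window
around the junction (not just two residues) can differ from the clean
translation.

## 5. Classification

Clone peptides are aligned with mafft (the one external binary used; no R
MSA engine is available in the target environment) and trimmed to columns
with ≥95% coverage — with mixed F/V/H products this is the ~73-aa shared
core. Distances are peptide p-distances with pairwise gap deletion: on a
75-aa block, model-based corrections are unstable, so the uncorrected
proportion is the defensible choice. Neighbor joining is implemented
directly (Saitou–Nei Q-criterion, lowest-index tie-break for determinism,
negative branch lengths clamped to zero with the deficit moved to the
sister edge) and is cross-checked in the tests against an independent
implementation and against brute-force recovery of additive metrics.
Families are single-linkage clusters at p-distance 0.40 (the figure-based
cut of the original analysis, exposed as `family_cut`); labels `Jc1..Jck`
follow descending clone count. Homogeneity of family distributions across
accessions uses the Pearson chi-square with df = (r−1)(c−1), refusing
tables with zero expected counts rather than silently pooling.

## 6. Homology search and consensus extension

The search engine is a seeded local aligner: exact 11-mer seeding, X-drop
ungapped extension, then banded gapped extension (band 16), with
Karlin–Altschul E-values (λ solved from the score-generating equality at
uniform composition; K = 0.35 calibrated on the uniform background) and the
E < 1e-20 significance convention. Scores are +1/−2 with gaps −5/−2,
megablast-like stringency. "Copy number" is the count of non-overlapping
subject loci after collapsing overlapping hits to the best. The tests hold
the engine to full Smith–Waterman enumeration (iterated best-alignment with
subject masking) on 20-kb instances.

Consensus building starts from the family's RT majority consensus and
alternates: collect member loci by search, extend each member ±500 bp on
unfinished sides, recompute the column majority (ties alphabetical). A side
is declared finished at the first 20-column window where mean member
agreement falls below 0.6 — outside the element the members' flanks are
unrelated, so agreement collapses to ~0.25. The exact boundary column is
then a change-point: the column maximising the cumulative sum of
(agreement − 0.75), innermost on ties. A plain threshold rule misplaces the
edge because a random flank column still reaches 3/5 agreement ~40% of the
time; the change-point estimator is exact at zero divergence and within a
few bp at 5%. Members whose overall agreement drops below 0.6 (truncated
copies) are dropped. Fewer than three member loci is an error — the
low-copy-family failure mode (one family of the original ten could not be
assembled for exactly this reason). Members are anchored by their initial
hit coordinates, which assumes collinear (gapless) alignments; this matches
the substitution-only generator and is the stated no-indel assumption.

## 7. Annotation, context and RBIP

LTR pairs are found by a diagonal scan anchored within 25 bp of the
sequence ends (score = matches − 2·mismatches along the repeat diagonal;
identity ≥ 0.85, length ≥ 100 bp), which is linear-in-diagonals rather than
a full quadratic self-comparison and reports equal-length repeats — again
matching the substitution-only model. PBS: tRNA core within 30 bp after the
5' LTR, ≤1 mismatch; its offset is the spacer. PPT: the highest
purine-fraction window (≥9 bp, ≥0.8) ending within 50 bp of the 3' LTR,
leftmost-then-longest on ties. The GAG–POL ORF is the longest ATG-to-stop
ORF downstream of the 5' LTR (so Jc8's LTR overrun is caught); domain order
is verified via the sentinel anchors with the copia check INT-before-RT.
The TG…CA terminal dinucleotide is not asserted — it is advisory only.
Restriction maps cut at recognition-site starts; fragments always partition
the length.

Context profiling treats both flanks of a copy as separate observations
(doubling n per family; the source convention is ambiguous and this is the
declared choice), counts qualifying hit loci of the 500-bp flank against
the whole genome — self-hit included, so the minimum count is 1, matching a
lowest bin of 1–10 — and tests genes edge-to-edge within 5 kb. Families
need ≥20 flank observations to be reported; >60% gene-positive flags a
marker candidate.

RBIP markers require identical LTRs, full length and a detected TSD
(recency), plus both flanks in the low-copy bin. Flank primers are placed
as far from the TSD as the 100–400 bp junction bound allows and stepped
inward until their exact genomic site is unique; LTR primers are inherently
family-wide, so assay specificity rests on the flank primers and the
expected product sizes. Genotypes are called haploid: occupied = both
junction products and no empty product; empty = the flank–flank product
only; both classes together is flagged "mixed" (a heterozygote pattern);
anything else "ambiguous". On a simulated panel with zero background SNPs
the calls equal the generating presence matrix exactly.

## 8. What the benchmark shows — and what it does not

Passing the simulated-recovery tests demonstrates that every stage is
internally consistent and that the pipeline inverts its own generator: the
structural table equals the family parameters, the family count equals the
number implanted (in ≥9/10 seeds at 5% divergence, 3 copies per family),
the flank-gene probabilities are recovered within binomial error, and
genotype calls equal the presence matrix. It does not demonstrate
performance on real genomes: the neutral background has no repeats other
than the implants, divergence is substitution-only (no indels, no solo
LTRs, no nested insertions deeper than one level), gene structure is a bare
interval, and PCR is modelled without amplification bias or thermodynamics.
Those gaps are listed as non-goals; the module interfaces accept real FASTA
input so each stage can be applied to real data where its assumptions
allow.

## 9. Problem sizes and determinism

The shipped tests run the classification recovery on 0.8-Mb genomes with
three copies per family (ten seeds), search-oracle comparisons on 20-kb
instances, and the exact structural recovery on a 2-Mb genome — sizes
chosen so the whole suite completes in a few minutes on one CPU while
leaving every statistical check well-powered. All stochastic steps draw
from explicit seeds; the pipeline derives per-stage seeds from one master
seed, and identical configurations produce byte-identical FASTA/GFF3/CSV
artifacts.
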