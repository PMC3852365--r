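# copiascan

Tools for discovering, classifying, structurally characterizing and
marker-izing **copia-type LTR retrotransposon families** in plant genomes —
implemented fully in silico, with a synthetic-genome generator that provides
exact ground truth for every stage.

## The problem

Copia-type LTR retrotransposons are a major, highly heterogeneous component
of plant genomes (in *Jatropha curcas* they fall into families such as
Jc1–Jc10, grouped into three deeper lineages). The classic wet-lab workflow
for characterizing them runs:

1. **Degenerate-primer PCR** against the conserved reverse-transcriptase
   (RT) domain isolates ~300-bp RT fragments from genomic DNA.
2. Cloned RT fragments are translated (tolerating spontaneous frameshift
   mutations), trimmed to their ~75-aa shared core, and classified into
   **families** on a neighbor-joining (NJ) tree; a chi-square test compares
   family distributions across accessions.
3. Per family, a BLAST-style search of the genome collects copies, and
   **iterative consensus extension** ("search again with the new consensus
   until it reaches both element ends") reconstructs the full-length
   element: LTR pair, primer binding site (PBS), polypurine tract (PPT),
   GAG–POL ORF, target site duplication (TSD).
4. Flank analysis (copy-number class of 500-bp flanks; genes within 5 kb)
   identifies families living in gene-rich, low-copy regions — the best
   **marker candidates**.
5. For a recently inserted copy (identical LTRs, intact TSD), a
   three-primer-set **RBIP assay** (FLKL×LTRL, LTRR×FLKR for the occupied
   allele; FLKL×FLKR for the empty allele) genotypes the insertion across
   accessions.

`copiascan` re-implements every computational step of this workflow as
tested, reusable R functions, and adds a simulator that builds genomes with
implanted element copies, gene tracks and accession panels whose ground
truth is known exactly — so each stage (and the pipeline end-to-end) can be
validated against the truth.

## Core methods

* **In-silico PCR** — IUPAC-degenerate primer matching (the published F/V/H
  RT primer sets are built in) with per-primer mismatch tolerance and
  inward-orientation product calling.
* **Frameshift-tolerant translation** — dynamic programming over reading
  positions (3/2/4-nt consumes, penalized frame switches, penalized
  read-through of point-mutated stop codons).
* **NJ classification** — peptide p-distances on the trimmed core block,
  Saitou–Nei neighbor joining (lowest-index tie-break, negative branch
  clamping), single-linkage family cut at p-distance 0.40, Pearson
  chi-square homogeneity test.
* **Seeded local-alignment search** — an exact-word seed / X-drop ungapped /
  banded gapped extension engine (Rcpp) with Karlin–Altschul E-values at the
  E < 1e-20 significance convention; a full Smith–Waterman enumerator serves
  as its oracle in the tests.
* **Structural annotation** — anchored direct-repeat scan for the LTR pair,
  tRNA-Met core (`TGGTATCAGAGC`) PBS search, best-purine-window PPT, longest
  ORF with copia domain order (INT before RT), TSD detection, restriction
  maps, bootstrap NJ lineage assignment.
* **RBIP design & genotyping** — three primer sets per locus with expected
  occupied/empty product sizes, genotype calls per accession.

## Worked example

Build the Jc1 family template (5,398 bp, 510-bp LTRs, 1,339-aa GAG–POL),
implant five identical copies into a 500-kb random background, and recover
everything:

```r
library(copiascan)
fams <- copia_families()

tpl <- build_family_template(fams$Jc1, seed = 1)
genome <- new_genome(5e5, seed = 2)
genome <- implant_copies(genome, tpl, n = 5, divergence = 0, seed = 3)
genome
#> annotated_genome: 1 contig(s), 527,015 bp, 5 element copies, 0 genes

# in-silico PCR with the degenerate F primer set
amplify(genome, rt_primer_set("F"))$length
#> [1] 302 302 302 302 302

# rebuild the full element from its RT core by iterative extension
rt <- substr(tpl$seq, tpl$annotation$rt_core_nt[1], tpl$annotation$rt_core_nt[2])
st <- iterative_extend(rt, genome)
identical(st$consensus, tpl$seq)
#> [1] TRUE

# structural annotation of the recovered consensus
annotate_element(st$consensus)
#> element_annotation: total 5398 bp, LTR 510 bp (identity 1.000),
#>   GAG-POL 1339 aa, PBS spacer 2, PPT purine 1.00
```

The recovered numbers are exactly the family's structural parameters: total
length 5,398 bp, LTR 510 bp, GAG–POL 1,339 aa, and the two-nucleotide PBS
spacer characteristic of lineage I/II families (lineage III families have
none).

A full simulated study — nine families, clone isolation across accessions,
classification, consensus building, context profiling and RBIP genotyping —
runs as one call:

```r
report <- run_pipeline(pipeline_config(seed = 7))
```

or from the shell via the bundled CLI:

```sh
copiascan run-all --genome-size 2000000 --seed 7 --out run1/
```

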