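---
title: "Predicting Spo0 pathway components and architecture from genome context"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting Spo0 pathway components and architecture from genome context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Endospore formation in Firmicutes is initiated by phosphorylation of Spo0A,
the master regulator of sporulation. Two signal transduction architectures
deliver that phosphoryl group: a **phosphorelay** (sensor kinase → Spo0F →
Spo0B → Spo0A, as in *Bacillus subtilis*) and **direct phosphorylation**
(sensor kinases phosphorylate Spo0A themselves, as in *Clostridium
acetobutylicum*). Deciding which architecture a genome encodes reduces to
detecting the two relay intermediates — and that is hard by sequence alone:

* Spo0F is a stand-alone receiver (REC) domain, indistinguishable from other
  single-domain response regulators such as CheY;
* Spo0B is poorly conserved and in many lineages carries no informative Pfam
  domain at all.

`spo0scan` implements a genome-context solution. Both proteins sit in deeply
conserved gene neighborhoods, so they can be found by locating marker genes
and then applying weak, local criteria inside the resulting window.

## The procedure

For each genome (a `GenomeAnnotation`: ordered CDS, protein sequences, domain
hits):

1. **Spo0A** — genome-wide: any protein with a Spo0A_C DNA-binding domain
   hit. Spo0A_C uniquely distinguishes Spo0A from all other response
   regulators; a candidate without a REC hit is flagged rather than dropped.
2. **Marker neighborhoods** — genes hitting the marker domains
   (Spo0F: F_bp_aldolase, Transaldolase, CTP_Synth_N;
   Spo0B: GTP1_OBG, Ribosomal_L21p, Ribosomal_L27) seed windows of ±4 ORFs.
   Windows are merged transitively when they share a gene or when their
   marker genes are separated by at most `mergeGap` (default 4) intervening
   ORFs, irrespective of intergenic distances in bp. Among merged sets, the
   marker neighborhood is chosen by: contains a candidate-like gene; else
   most distinct markers; else lowest ORF index (a deterministic tie-break).
3. **Spo0F** — within the chosen neighborhood, the protein whose domain hits
   are exactly one REC hit covering ≥ 90% of the protein (inclusive).
4. **Spo0B** — within its neighborhood, a protein with zero Pfam hits whose
   local alignment (BLOSUM62, affine gaps 10/0.5) to the first 50 aa of the
   reference Spo0B reaches ≥ 25% identity over ≥ 40 aligned columns *and* a
   raw score ≥ 90 (see "Numerical choices"). Placement between the L27 and
   ObgE genes is recorded as supporting evidence, not required.
5. **Kinase inventory** — proteins with both a HisKA-family and a catalytic
   (HATPase_c / Agfam HK_CA) hit; hybrid kinases are those with a fused REC.
   A kinase is an *orphan* when no other two-component gene lies within ±4
   ORFs. Orphans with an N-terminal PAS domain (a PAS/PAC hit starting before
   the HisKA hit) are the primary sporulation-kinase candidates; PAS-less
   orphans form a secondary tier, since verified PAS-less sporulation kinases
   exist. Hybrids are excluded from the primary tier because the fused
   receiver insulates them from the pathway.
6. **Specificity signatures** — the handful of co-evolving interface residues
   that govern phosphotransfer partner choice: six kinase-side positions in
   the HisKA domain (also applied to Spo0B, whose interaction surface is
   equivalent) and seven receiver positions in the REC domain. The target is
   locally aligned to three reference domains; the best-scoring alignment
   maps the conserved phospho-accepting His/Asp anchor onto the target, and
   residues are read at fixed signed offsets from the anchor (offsets applied
   in reference coordinates and mapped through the alignment; gaps yield
   `-` plus a flag). Signatures are compared by Hamming distance, summarized
   as position frequency matrices (logo-ready), and by within/between-group
   mean pairwise distances.
7. **Architecture call** — Spo0A ∧ Spo0F ∧ Spo0B → `PHOSPHORELAY`;
   Spo0A alone → `DIRECT`; Spo0A with exactly one intermediate →
   `PARTIAL_RELAY`; no Spo0A → `NO_SPO0`.
8. **Phylogenetic summary** — presence/absence per genome ordered along a
   user-supplied tree, and the minimum number of architecture transitions
   under Fitch small parsimony (`NO_SPO0` leaves pruned; optional two-state
   mode mapping `PARTIAL_RELAY` to `PHOSPHORELAY`).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `radius` | 4 ORFs | half-width of a marker window |
| `mergeGap` | 4 ORFs | max intervening ORFs between markers to merge |
| `minRecCoverage` | 0.90 | REC coverage for Spo0F (inclusive) |
| `minIdentity` / `minAligned` | 0.25 / 40 | Spo0B alignability vs reference N-terminus |
| `minScore` | 90 (raw BLOSUM62) | Spo0B alignment significance cutoff |
| `orphanWindow` | 4 ORFs | co-location window for orphan status |
| `minScore` (signatures) | 60 | minimum alignment score to accept an anchor |

All domain-name sets (REC aliases, HisKA family, catalytic, PAS, generic
two-component domains) are options (`spo0scan.*_domains`), so alternative
HMM libraries can be accommodated without code changes.

## Design choices where the method was genuinely open

* **ORF ranking.** Public annotation databases do not document how genes on
  opposite strands are ordered; we rank strictly by start coordinate per
  replicon (0-based `orf_index`).
* **"Separated by no more than four ORFs"** is read as ≤ 4 *intervening*
  ORFs between marker genes (indices 10 and 15 merge; 10 and 16 do not);
  `mergeGap` absorbs the alternative inclusive reading.
* **Circularity.** Windows wrap around the origin on circular replicons
  (bacterial chromosomes are circular, and Spo0F typically lies near the
  origin); neighborhoods never span replicons.
* **Determinism.** Every "choose arbitrarily" in the neighborhood-selection
  cascade is replaced by the lowest-ORF-index tie-break, and alignment ties
  by reference order, so runs are exactly reproducible.
* **`PARTIAL_RELAY`** is this package's label for genomes carrying Spo0A and
  exactly one intermediate (e.g. the Spo0B-like proteins of some
  *Clostridium sensu stricto* species); forcing them into either class would
  overstate the evidence. Both partial cases (Spo0F-only and Spo0B-only) map
  to the same label.
* **Specificity offsets are data, not code.** The shipped profile sidecar
  (`inst/extdata/specificity_profiles.tsv`) holds the anchors and offsets;
  they are calibrated so that extraction from the shipped construct
  sequences reproduces the published residue strings exactly, and they can
  be replaced wholesale for other reference sets.

## Numerical choices

* **Spo0B significance cutoff.** Bare identity/length thresholds on local
  alignments are unreliable against random background: over 3000 random
  150–450 aa proteins aligned to the 50 aa reference, the best null scores
  reached 70 (raw BLOSUM62) with 25–29% identity over 40+ columns. The
  score cutoff of 90 sits above that null maximum while planted true Spo0B
  N-termini score ≥ 207 at the generator's default 20% divergence (≥ 130 at
  35%). Identity and aligned-length thresholds are kept as declared.
* **Anchor acceptance.** Signature extraction rejects alignments scoring
  below 60 (all-gap signature, `no_anchor` flag); an anchored target residue
  other than His/Asp yields `low_confidence_anchor` rather than rejection.
* **Degenerate inputs.** Empty domain tables, marker-free genomes, empty
  signature lists and singleton groups all return well-defined empty/NA
  results rather than errors; truncated Spo0F proteins (< 100 aa) are
  flagged `truncated`.

## The synthetic-genome generator

Real cohort inputs (annotated RefSeq genomes with precomputed domain calls)
cannot be bundled, so `generateGenome()` emulates their statistical
structure: 2000–4000 ordered ORFs on a circular replicon; planted marker
trios with configurable spacing; a Spo0F planted immediately upstream of the
aldolase marker; a domain-free Spo0B (N-terminus a mutated copy of the
reference) planted between L27 and ObgE; a Spo0A; five orphan kinases (four
with N-terminal PAS); decoy stand-alone receivers outside marker
neighborhoods; paired (non-orphan) two-component operons; and a majority of
domain-free background proteins. Protein sequences are random except where a
stage aligns them — Spo0B N-termini and the signature-bearing domains, which
are mutated copies of the shipped references with planted signature
residues. Noise knobs: marker-deletion probability, independent domain-call
dropout, and signature mutation rate. All randomness flows from one seed;
the genome index perturbs the stream deterministically.

What passing tests on these genomes **do** show: the neighborhood algebra,
classifier criteria, orphan/PAS logic, anchored extraction and the
architecture/parsimony layers are correct against planted truth, including
designed failure modes (total marker deletion degrades a planted relay to a
`DIRECT` call). What they **cannot** show: performance against real
annotation noise — mis-called domain boundaries, split/fused ORFs,
contaminated assemblies, lineage-specific marker rearrangements — or the
biological validity of the marker choice itself.

## Problem sizes used by the test suite

Property tests run on toy replicons of 25–125 ORFs; classifier calibration
uses 50 zero-noise genomes at the full 2000–4000 ORF scale; the dropout
monotonicity property uses 800-ORF genomes at 50 genomes per noise level;
parsimony is cross-checked against brute-force enumeration on 200 random
trees of up to 8 leaves; end-to-end recovery uses a 16-leaf clade with mixed
architectures.

## Known limitations

* The shipped reference sequences (Spo0B N-terminus, HisKA/REC profile
  references, construct sequences) are synthetic stand-ins, labelled as such
  in their filenames; production use requires supplying the corresponding
  real sequences, after which every interface stays the same.
* Spo0F/Spo0B detection is only as good as the marker annotation; a genome
  whose marker genes lack domain calls is invisible to the method (this is
  the designed false-negative mode, not a crash).
* The Agfam catalytic-family label (`HK_CA:2`/`HK_CA:3`) is a pass-through
  annotation column, never computed.
* Ancestral-state claims beyond the parsimony transition count (e.g. which
  architecture is ancestral) are interpretation, not computation, and are
  out of scope.

## A minimal run

```{r, eval = FALSE}
library(spo0scan)
cfg <- simulationConfig(seed = 1, nGenomes = 4,
                        architectures = c("PHOSPHORELAY", "DIRECT"))
genomes <- lapply(1:4, function(i) generateGenome(cfg, i)$annotation)
tree <- ape::read.tree(text = "((sim_genome_1,sim_genome_2),(sim_genome_3,sim_genome_4));")
res <- runScan(genomes, "scan_out", tree = tree)
res$report
res$transitions
```
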