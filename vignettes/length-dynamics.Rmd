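---
title: "Transcript length dynamics, isoform switching and splice-mechanism calls"
author: "lengthome package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcript length dynamics, isoform switching and splice-mechanism calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lengthome)
```

## The problem this package addresses

Messenger RNAs of one gene can differ in the lengths of their functional
regions — the 5' untranslated region (5'UTR), the coding sequence (CDS,
start through stop codon), and the 3'UTR. Because UTRs carry microRNA- and
RNA-binding-protein sites, region length changes rewire post-transcriptional
regulation. Isoform-resolved expression platforms report each transcript
under two identifiers: a gene symbol shared by all isoforms and a
RefSeq-style isoform identifier ("seqname"). Comparing the isoform
complements of a gene between two biological conditions therefore reveals
*isoform switching* — one variant replaced by another — and comparing the
transcript structures of the switching pair reveals the splicing mechanism
behind the length change (alternative donors/acceptors, cassette exons,
mutually exclusive terminal exons, alternative start codons, alternative
polyadenylation, or cryptic-site activation).

`lengthome` implements this analysis as a tested pipeline:

1. **Volcano filtering** of per-condition differential-expression tables
   (absolute fold change ≥ 2.0 and p ≤ 0.05 by default, both boundaries
   inclusive; fold changes are kept on the absolute, non-log scale the
   arrays report).
2. **Region lengths** from a genome annotation: for a coding transcript
   `len_5utr = cds_start − 1`, `len_cds = cds_end − cds_start + 1`,
   `len_3utr = spliced_length − cds_end`, so the regions always sum to the
   full length. The stored CDS *includes the stop codon* (RefSeq
   convention), so the 3'UTR begins at the base after the stop. Poly-A
   tails are never part of the 3'UTR. Non-coding transcripts are retained
   but excluded from region statistics.
3. **Length-distribution comparisons** of a query list against the
   reference exome (all coding transcripts of the annotation), with a
   kernel-density overlay per region and a two-sample test.
4. **Exon-count spectra**: per-gene mean exon counts binned into 1..9 and
   "10+", tested against reference proportions by chi-squared goodness of
   fit.
5. **Switch detection** between two conditions of one experimental arm, and
   per-pair S/L/= length codes.
6. **Mechanism classification** of each switching pair, with splice-signal
   extraction and consensus scoring when a genome sequence is available.

## Statistical choices

**Test and scale.** The length comparison defaults to a Welch
(unequal-variance) two-sample t-test on log10 lengths. Transcript region
lengths are strongly right-skewed and query and reference lists differ in
size and spread, so the log scale and the unequal-variance form are the
defensible defaults; both are knobs (`test = "student"`,
`scale = "linear"`) for users who want the classical Student form or linear
lengths. No multiple-testing correction is applied across regions — each
region comparison is reported as its own test.

**Direction.** `direction` is "longer"/"shorter" only when p ≤ alpha
(default 0.05), "none" otherwise, so a direction claim always carries
significance.

**Zeros.** Zero-length UTRs cannot enter a log-scale test; they are
excluded and reported in separate `nZero*` counters rather than silently
dropped.

**KDE.** Densities use Silverman's rule-of-thumb bandwidth per sample on a
shared 256-point grid padded by three bandwidths, so each curve integrates
to 1 (within 1%) over its own grid.

**Chi-squared spectrum.** Per-gene mean exon counts (fractional for genes
with several isoforms) are rounded half-up before binning. Bins whose
expected count is zero are merged upward so the statistic is always
defined; the statistic is the plain Σ(O−E)²/E against reference proportions
scaled to the query total.

## The mechanism cascade

`classifyMechanism(old, new)` decides the event class from the two exon
chains and CDS annotations, first match wins: identical → alternative
polyadenylation (same junctions, 3'-terminal end differs, stop codon
shared) → alternative start codon (same junctions, different CDS start;
this also covers a shifted transcription start combined with a downstream
start codon, which changes the full length as well) → cassette exon
(exactly one internal exon absent from one isoform) → single changed
junction pair (shared acceptor → alternative 5' donor; shared donor →
alternative 3' acceptor, unless the two downstream exons are terminal and
genomically disjoint, which is called mutually exclusive terminal exons) →
junctions private to one isoform extending past the other's structure
(classified by which endpoint falls strictly inside a partner exon) →
`complex` as the honest fallback.

Two orderings here were genuinely open and were fixed as follows. First,
disjointness is checked *before* the acceptor-shift call: a shared-donor
junction change onto a disjoint terminal exon is a mutually-exclusive-
terminal-exon event, not an acceptor shift of the same exon. Second, the
*cryptic* tag is direction-aware: it fires when an endpoint of a junction
private to the **new** isoform lies strictly inside an exon of the **old**
isoform — the signature of a latent site activated inside a previously
intact exon. Outward boundary extensions (the new boundary falls in the
partner's intron) are not tagged, which keeps the tag informative instead
of marking every boundary shift.

The `=` code in S/L/= tables requires exact nucleotide equality — published
tables treat even a 4-nt difference as a real change, so no tolerance is
defensible. When a switching gene has several old and several new isoforms,
the table pairs silenced isoforms (if any, else all old-condition isoforms)
with de novo isoforms (if any, else all new-condition isoforms); this
reproduces single old→new rows for de novo switches and
silenced-versus-survivor rows for isoform losses, without self-pairs.

One container-level relaxation: CDS lengths are not forced to be multiples
of 3. Isoform records in microarray-era annotations are not always
codon-exact, and the worked Mta3 example itself (CDS 1542 → 1757 nt) is
not. The simulator, in contrast, always generates codon-exact CDSs, and the
test suite asserts that on generated output.

## The synthetic-data generator

Real microarray expression tables of this kind are generally not public, so
the package ships a generator whose defaults *are* the study conditions the
pipeline is validated against:

* four downregulated lists of 489 / 1285 / 300 / 690 transcripts (C10, C24,
  T10, T24),
* 114 and 153 genes shared within the C and T pairs, with 7 and 3 planted
  isoform switches,
* a two-component log10-normal 3'UTR mixture with modes near 100 and
  1000 bp (`meanlog10 = 2, 3`; `sdlog10 = 0.22`), a 5'UTR distribution
  peaking near 100 bp, and a log-normal CDS around 1.3 kb,
* a per-condition multiplier on the long-3'UTR component weight
  (C10 0.6, C24 1.6, T10/T24 1.0), so the later control condition shows a
  detectable 3'UTR lengthening while the treated arm stays near the
  reference,
* introns drawn uniformly from 60–2000 nt (irrelevant to mRNA-level
  statistics, present so models live on a genome),
* a mechanism mix over planted switch classes, defaulting to splice-site
  and exon-level events with *zero* alternative-polyadenylation weight,
  matching the observation the fixture encodes (no APA among the worked
  examples).

The effect size of the 3'UTR shift is not documented anywhere; the 1.6
multiplier was chosen once as a realistic planted effect detectable at the
configured list sizes and is a config knob, not a fitted value. Planted
switch pairs are built on a fixed six-segment scaffold (5'UTR exon, two
internal CDS exons, a CDS/stop exon, a 3'UTR exon, and a spare downstream
terminal exon) so that each event class is realised by a local, unambiguous
structural edit with a consistent CDS. Generated sequences physically carry
ATG at the CDS start, a stop codon at its end, and GT..AG at every intron,
which the sequence-level oracle tests check.

What the generator does **not** emulate: probe-level intensities and
normalisation, biological co-expression structure, shared exon content
between genes, non-canonical splice sites, or overlap of gene sets between
the C and T arms (the arms draw from disjoint gene pools). Passing tests on
generated data therefore demonstrate the correctness of the algorithms
under the stated statistical structure, not robustness to annotation noise
in real genomes.

Simulated problem sizes in the test suite are scaled (tens to a few
thousand genes, chosen to exercise every code path at comfortable runtime);
the full-size defaults are used by the reproduction script.

## The packaged worked-example fixture

`switchFixture()` loads `inst/extdata/synthetic_switch_models.tsv`, a
*synthetic reconstruction* of the nine published switching genes (19
isoforms): invented coordinates engineered so that every published
per-region S/L/= code, every mechanism label, and the Mta3 region lengths
(3'UTR 93 → 820 nt, CDS 1542 → 1757 nt) are reproduced exactly. It is not
the true genomic structure of those genes; sequence-level work on real
genes needs a real annotation and genome. Two encodings were fixed by
interpretation: the "METEs" annotation of Ilf3 is encoded as mutually
exclusive terminal exons, and the 4-nt 5'UTR difference of Srsf5 as a 4-nt
acceptor shift. For the six de novo switches the fixture keeps the old
isoform expressed in the later condition alongside the new one (the
published table is ambiguous on persistence; the de-novo class requires
it).

## A worked run

```{r example, message = FALSE}
fx <- switchFixture()
ev <- detectSwitches(fx$lists$C10, fx$lists$C24)
table(ev$switch_class)

rl <- regionLengths(fx$models)
switchTable(ev[ev$switch_class != "no_switch", ], rl)

classifyMechanism(fx$models[["NM_001171053"]], fx$models[["NM_001171052"]])
```

And the simulate-then-analyse loop:

```{r simulate, message = FALSE}
cfg <- simulationConfig(seed = 1, nGenes = 400,
                        listSizes = c(C10 = 80L, C24 = 160L,
                                      T10 = 50L, T24 = 90L),
                        sharedGenes = c(C10_C24 = 30L, T10_T24 = 20L),
                        plantedSwitches = c(C10_C24 = 4L, T10_T24 = 2L))
sim <- simulateGenomeAndAnnotation(cfg, sequence = FALSE)
deg <- simulateDegLists(cfg, sim)
res <- runPipeline(pipelineConfig(annotation = sim$models,
                                  degTables = deg$lists,
                                  outDir = tempdir(), seed = 1L))
sum(res$switches$C10_C24$switch_class != "no_switch")
res$apaCount
```

## Degenerate inputs and numerical corner cases

* Length comparisons refuse to run with fewer than 3 usable values per
  side and name the region in the error.
* Empty expression tables run cleanly through the pipeline, logging
  "0 records" per stage and producing empty outputs.
* Duplicate seqnames within one table keep the smallest p-value row, with
  a warning (the de-duplication rule is a package choice; the source
  platforms are silent on it).
* Gene-symbol sorting is case-insensitive with condition and seqname as
  tie-breaks, making the merged ordering fully deterministic.
* Ties in the S/L/= codes are impossible by construction: codes compare
  exact integer lengths.

## Known limitations

* Switch detection is presence/absence-based; the platform reports a
  filtered list, not isoform-usage fractions, so no usage-proportion
  switch score is computed.
* Splice-signal scoring is a fixed-window IUPAC consensus match (donor
  `MAG|GTRAGT`, acceptor polypyrimidine + `YAG|G`), not a trained
  position-weight or maximum-entropy model; window sizes are exposed as
  parameters.
* The mechanism cascade assigns one class per pair (plus the cryptic tag);
  genuinely composite events fall into `complex` rather than being forced
  into a single label.
* The upregulated direction is supported (`direction = "up"`) but all
  validation targets the downregulated analysis.
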