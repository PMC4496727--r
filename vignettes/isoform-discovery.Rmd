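---
title: "Isoform discovery with a k-best gene model: methods and design notes"
author: "isoscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isoform discovery with a k-best gene model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoscan)
```

This vignette is the package's own account of the science it
implements: the generative gene model and its assumptions, the k-best
decoder, the RNA-seq validation rules, the event classifier, the
proteogenomic filter and the transcript census, together with the
numerical choices made where the design was genuinely open.

## 1. The gene model

`isoscan` models a genomic sequence as the output of a generalized
(explicit-duration) hidden Markov model with a GENSCAN-like topology:

```
N -> Esingle -> N
N -> Einit -> I -> (Eint -> I)* -> Eterm -> N
```

* **N** (intergenic) emits one base at a time with a geometric
  stay/leave decision; `p_stay` fixes the mean intergenic run length
  (default world: 200 nt).
* **Exon states** (`Einit`, `Eint`, `Eterm`, `Esingle`) and **introns**
  (`I`, three phases) are explicit-duration segments.  Exon durations
  follow an empirical histogram with a geometric-shaped tail; introns a
  shifted geometric with a hard minimum of 20 nt.  All duration
  supports are truncated at a finite cap, and the cap is part of the
  model: sampler, scalar scorer and decoder share the identical
  support, so closed-loop tests can demand exact agreement.  The cost
  is that segments longer than the cap are impossible rather than
  merely improbable; for desk-scale worlds (exons ≲ 200 nt, introns
  ≲ 200 nt) this is immaterial.
* **Coding emissions** are a 3-periodic Markov chain of order *k*
  (default 2) over the *genomic* context; noncoding emissions
  (intergenic and intron interiors) a homogeneous chain of the same
  order.  Positions without a full context (sequence start, ambiguity
  codes) fall back to marginal base distributions.
* **Signals** are position weight matrices with hard consensus
  columns: GT/AG at the intron ends, ATG at the translation start, and
  a categorical distribution over TAA/TAG/TGA.  Hard columns make
  illegal splice or translation sites impossible (score `-Inf`), not
  merely unlikely.

**Signal window ownership.**  PWMs factorise over columns, so a signal
spanning a boundary can be split between the two adjacent segments
without changing the model: the donor site contributes its 3 exonic
columns to the exon segment and its 6 intronic columns to the intron
segment; the acceptor contributes 13 intronic and 2 exonic columns; the
start signal (ATG + 3 context columns) lies wholly inside the first
coding exon.  Every base is emitted by exactly one segment, which keeps
both the dynamic program and the generative sampler exact.  A
consequence worth noting: the intron minimum of 20 nt is exactly the
6 + 13 signal columns plus one chain base.

**Phase bookkeeping.**  Each intron carries the codon position at which
coding resumes; terminal and single exons must close the reading frame
(`(phase + length) mod 3 = 0`).  In-frame stop codons lying fully
inside an exon are forbidden by the scorer and decoder.  Stops split
across an intron are *not* forbidden at decode time — tracking them
needs split-codon bases in the state — and are instead removed by the
complete-ORF postfilter; the sampler rejection-samples genes so truth
structures never contain them.  This division of labour is a known
limitation, shared with desk-scale reimplementations of this model
family.

**Training** (`ghmm_train()`) is maximum likelihood with additive
pseudocounts (default 1): chain counts per codon position, PWM column
counts (consensus columns re-imposed afterwards), duration histograms,
and the three transition probabilities (`p_stay`, `p_single`,
`p_term`).  Signal windows that would cross a sequence boundary are
skipped and counted.

**The default world** (`ghmm_default_spec()`) is a hand-specified
parameterisation for simulation and testing, not a claim about any
genome.  Its signal PWMs are deliberately sharp — information content
near that of real splice sites (~7–9 bits) — because an early, softer
draft made the world unidentifiable: sampled gene structures often
ranked below hundreds of alternative parses of the same sequence,
contradicting the intended closed-loop behaviour of the generator.
Sharpness was fixed at generator-design time and not revisited.

## 2. k-best decoding

`kbest_decode()` realises the extended Viterbi algorithm as a list
decoder: every cell of the dynamic program — indexed by position, state
and (where needed) phase — keeps the top-N partial path scores instead
of the single best.  Exon and intron segments enter as arcs whose
emission terms are O(1) after cumulative-sum precomputation (per-frame
coding sums, noncoding sums, per-frame stop-codon counts, per-position
PWM scores), so one decode costs
O(L × max-segment-length × states × N).

Design points:

* **Distinctness** is at the state-path level: two returned paths
  always differ in some segment boundary or state.  Merging paths with
  identical coding sequences is deliberately deferred to
  `postfilter()`, so both conventions remain observable.
* **Tie-breaking** is deterministic: candidates of equal score order by
  predecessor cell, then segment start, then predecessor rank.  The
  top-k list is always a prefix of the top-N list.
* Paths must start and end in the intergenic state, with at least one
  intergenic base between genes — matching the generative process.
* All arithmetic is in log space; hard constraints are `-Inf`, and a
  duration outside the support is impossible rather than penalised.
* The decoder is validated against exhaustive enumeration: on toy
  sequences (≤ 30 nt, reduced duration supports) every legal
  segmentation is generated recursively, scored with the scalar kernel
  `log_score_path()`, and the decoder's top-5 must match in set and
  order (ties excepted) across hundreds of seeds.

`postfilter()` then applies the published post-processing: keep only
complete ORFs (ATG start, terminal stop, no internal in-frame stop,
length divisible by three), drop transcripts with introns below 20 nt,
and deduplicate by exact CDS coordinates keeping the highest-scoring
representative.  `cluster_loci()` performs single-linkage clustering on
≥ 1 bp exonic overlap (same sequence and strand), so a long transcript
bridges otherwise-separate clusters into one locus.
`evaluate_predictions()` scores exact CDS-chain matches, greedily 1–1,
at transcript and gene level.

The reverse strand is decoded on the reverse complement with the same
forward model and coordinates mirrored back — halving the state count
at the price of decoding each region twice.

## 3. RNA-seq validation

Candidate transcripts are validated in *transcript space*: the CDS is
spliced and extended with 100 nt genomic flanks (`build_mature()`), and
reads are assumed to have been aligned unspliced to these mature
sequences upstream of this package, so junctions appear as contiguous
matches.  Only single-run match CIGARs are consumed; everything else is
rejected and counted.

The junction rule: a read at `[s, s + len)` covers the junction at
mature offset `j` iff `s ≤ j − L` and `s + len ≥ j + L` — at least
*L* nt on **each** side.  A junction is validated when at least *M*
reads cover it.  Two strategies are built in:

| strategy  | L  | M | note                              |
|-----------|----|---|-----------------------------------|
| standard  | 10 | 1 | fixed                             |
| stringent | ≥8 | ≥6 | strict-integer reading of "M > 5, L > 7"; defaults 8/6 |

A multi-exon transcript validates in a dataset iff **all** its internal
CDS junctions are covered there.  Tiering of novel transcripts (CDS
absent from the known set) combines the two strategies with the
novel-internal-junction (NIJ) filter:

* **VHC** — validated under the stringent rule in ≥ 1 dataset *and*
  carries ≥ 1 junction absent from every known transcript;
* **VMC** — as above with the standard rule;
* **VLC** — validated under the standard rule but single-exon or with
  all junctions already known;
* known transcripts become **KNOWN_VALIDATED**.

Open points resolved here (both flagged stand-ins): single-exon
transcripts, which have no junctions, validate iff ≥ 90% of their CDS
bases are covered by at least one read; and the transcript-coverage
(TC) requirement seen alongside the junction rule in the source design
is exposed as an optional knob (`min_tc`) defaulting to off.  A
transcript validated in 1–4 datasets is flagged tissue-specific
(`< 5` datasets, treating one merged dataset as one sample).

`saturation_curve()` bootstraps dataset orderings and reports the mean
number of newly validated transcripts contributed by the k-th dataset;
`pcr_panel_summary()` turns per-tier PCR outcomes into success rates.

## 4. Alternative-splicing events

`classify_pair()` compares the CDS exon chains of two isoforms of a
gene (differences outside the coding region are ignored) and emits
events in seven categories keyed by their *signature* — the set of
distinguishing splice-site (or CDS-boundary) genomic offsets:

* **exon skipping** — an internal exon of one isoform absent from the
  other, whose flanking junctions appear fused there; signature = the
  skipped exon's two sites.
* **alternative donor / acceptor** — two junctions sharing one site
  while the other differs, *with the differing sites on overlapping
  exons*.  The overlap requirement is the package's reconstruction
  choice: without it, every exon-skipping pair would also be counted
  as one alternative-donor plus one alternative-acceptor event.
  Donor/acceptor are assigned biologically (strand-aware).
* **intron retention** — an intron of one isoform fully exonic in the
  other.
* **mutually exclusive exons** — two non-overlapping internal exons,
  one per isoform, spliced between the same flanking sites, neither
  present in the other isoform; signature = all four sites.
* **alternative translation start / stop** — differing CDS boundary;
  signature = the two boundary offsets.

`count_events()` unions all isoform pairs per gene and deduplicates by
(gene, category, signature), so an event seen in many pairs counts
once; both event counts and splice-site tallies (each event
contributing its signature size) are reported, the latter matching the
"counted by splice sites" convention.  The seven-category definitions
are reconstructions — the source's formal definitions are not in the
main text — which is why every definition above is also pinned by
hand-constructed cases and an all-pairs brute-force oracle in the test
suite.

## 5. Proteogenomic filter

Downstream of a spectral search against a combined database (reference
proteome + predicted VMC isoforms), taken as given:

1. preliminary novel peptides score against ≥ 1 VMC protein and no
   reference protein;
2. candidate novel proteins have ≥ 2 unique peptides (unique = mapping
   to exactly one protein in the combined database) including ≥ 1
   novel;
3. candidates are filtered against external databases: a candidate
   counts as annotated in a database iff *all* its novel peptides occur
   as exact substrings of some sequence there.  Exact substring
   matching replaces a blastp search — deterministic, dependency-free,
   and conservative at tryptic-peptide lengths (8–12 aa), where a
   full-length exact hit is essentially what a high-identity blastp
   alignment would report.

The worked-example fixture reproduces the published partition: 61
candidates, 9 annotated in both databases, 5 in one, 11 in the other,
36 final novel proteins.  (The source also prints 62 in prose; the
arithmetic line "61 − 9 − 5 − 11 = 36" is preserved as printed.)
Optionally, peptides are mapped back to transcript coordinates to flag
calls whose novel peptide spans a novel splice junction.

## 6. The transcript census

Let `I + II` be the predictions whose CDS matches the known annotation
(II of them RNA-seq validated — only the sum enters), `K` the known-set
size, `III` the expected number of *true* novel validated transcripts,
and `IV` the novel unvalidated true transcripts.  Sensitivity on the
known set is `Sn = (I + II) / K`.  The single modelling assumption —
defensible because an ab initio predictor's sensitivity does not depend
on expression level — is that the same `Sn` applies to undiscovered
transcripts, giving

```
T = (I + II + III + IV) / Sn,         III = VMC count × PCR precision.
```

With `III = IV = 0` the estimate collapses to `K` exactly (a built-in
consistency check).  `IV` defaults to 0, making `T` a lower bound; the
saturation behaviour of multi-dataset validation suggests `IV` is
small.  Two conventions for the PCR precision are supported: the exact
ratio 74/88 or the percentage rounded to one decimal (84.1%); the
rounded form is the default because it reproduces the published
intermediate `III = 26,547` exactly.  The known-set size is recovered
from the printed pair (40,797 multi-exon = 73.94%) as
`round(40797 / 0.7394) = 55,176`; running the estimator then prints
204,947–204,948, within 0.1% of the published 204,950 (the residue is
the source's own rounding of the percentage).

## 7. The synthetic world, and what a green test establishes

The simulators generate: genomes by sampling the gene model locus by
locus (optionally alternating strands), junction-spanning reads with
controllable per-junction coverage and side-overhangs plus background
CDS reads, and peptide tables with truth flags.  Defaults: 50 nt reads
(short-read scale), 10 reads per junction, minimum overhang 10 nt
(matching the standard L), 100 nt flanks, error-free reads.  All
randomness flows from one integer seed; fixed seed gives byte-identical
outputs.

What the world deliberately does **not** emulate: expression-level
variation, sequencing errors beyond a bookkeeping mismatch field,
mapping ambiguity, splice-junction discovery from spliced genomic
alignment, UTRs and non-coding transcription, and GC heterogeneity.  A
green closed-loop test therefore establishes that the algorithms are
mutually consistent and match their independent oracles — decoder
against exhaustive enumeration, junction tallies against per-read brute
force, tiering against its defining predicates, estimator against its
closed form — not that the default parameterisation describes any real
genome.

## 8. Numerical choices and known limitations

* Log-space throughout; no scaling tricks are needed at desk scale.
  Decoder and scalar scorer agree to ~1e-9 (different summation
  orders).
* Deterministic tie-breaks everywhere a ranking is exposed (decoder
  candidates, CDS dedup by score then rank, locus ids by leftmost
  coordinate).
* Degenerate inputs: empty exon lists, zero-exon transcripts, empty
  reference sets and zero denominators raise errors; unmapped or
  gapped SAM records and alignments to unknown targets are skipped and
  counted; mature flanks running past a sequence end are truncated
  with a warning.
* The decoder cannot represent genes at the extreme sequence ends
  (paths start/end intergenic) — pad regions accordingly (the region
  predictor does).
* Split-codon stops pass the decoder and are removed by the ORF
  postfilter (section 2).
* `read_gtf()` accepts the GENCODE attribute dialect via rtracklayer;
  the writer emits exon + CDS rows only.  BAM, GFF3 and FASTQ quality
  handling are out of scope.
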