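---
title: "Reconstructing segmented RNA virus genomes from dsRNA read-stop evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing segmented RNA virus genomes from dsRNA read-stop evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segvir)
library(dplyr)
```

## The inference problem

Double-stranded RNA is a hallmark of RNA virus replication, and dsRNA-seq
library protocols that physically fragment the dsRNA and ligate an adapter
(U2, `GACGTAAGAACGTCGCACCA`) to every fragment's 3' end have a valuable side
effect: the terminal fragment of each genome molecule ends *exactly* at the
true segment terminus. After sequencing and mapping, a genuine segment end
therefore shows up as a large number of read alignments stopping at one and
the same position, while internal fragmentation breakpoints scatter their
stops broadly. segvir turns that signal into genome reconstruction in five
stages:

1. **Preprocess** — remove U2/U2-comp adapter read-through and low-quality
   reads (`trim_adapter()`, `quality_filter()`).
2. **Align and pile up** — map reads to assembled contigs (external SAM via
   `read_sam()`, or the built-in minimal mapper `map_reads()`) and count
   per-position alignment starts, ends and coverage
   (`build_stop_profile()`).
3. **Call termini and classify** — a position near a contig boundary is a
   terminus when *strictly more than* `min_stop_reads` (default 10)
   alignments stop exactly there and those stops are a dominant fraction
   (`min_dominance`, default 0.2) of the local coverage; contigs with both
   termini confirmed are complete genome segments, and complete segments
   with mean coverage *strictly above* 1,000x are flagged "major"
   (`call_termini()`, `classify_segments()`).
4. **Bin and pair** — segments of one multipartite virus share
   (near-)identical 5' and 3' terminal sequences; single-linkage clustering
   over pairs whose terminal windows align at identity at or above
   `link_threshold` groups segments into virus genome bins, and segments of
   different classes are assigned to one virus strain when they co-occur in
   the same sample at similar abundance (`cluster_segments()`,
   `pair_by_abundance()`).
5. **Annotate** — ORFs under the bacterial/archaeal genetic code, SD-like
   ribosome-binding motifs (prokaryotic host evidence), RdRP catalytic
   motifs A/B/C, and a hydropathy-based transmembrane flag
   (`annotate_bin()`).

A synthetic virome generator (`simulate_virome()`, `simulate_flds_reads()`)
produces genomes and read libraries with full ground truth, so every stage
is validated by parameter recovery rather than by eyeballing.

## The simulator: what it emulates, and what it does not

`sim_params()` fixes the study conditions. Each virus receives a 5' and a 3'
terminal sequence (default 25 nt) shared by its 2-3 segments at identity
`terminal_identity_within` (default 1.0); terminal sequences of different
viruses are constrained to pairwise identity at most
`terminal_identity_between` (default 0.3), which the generator enforces by
greedy repair of chance matches. Segment bodies are built from planted genes:
each ORF is preceded by a stop-in-all-frames cassette (so the maximal ORF
starts exactly at the planted start codon), an `AGGAGG` SD consensus for a
`sd_fraction` (default 0.95) of genes at a spacer of 4-14 nt, and a body of
non-stop codons. The first ORF of each virus's first segment encodes the RdRP
catalytic arrangement — motif A aspartate with its partner 13 residues
downstream (the extended spacing), motif B `SGxxxT`, motif C `GDD` — so each
simulated genome bin has exactly one RdRP segment.

Read simulation follows the library chemistry: each genome copy is broken
into ~`fragment_length_mean` (default 1,500 nt) pieces, drawn from a normal
with 20% relative standard deviation, truncated below at the read length;
the terminal remainder may be as short as 50 nt. Both strands of every
fragment are read from their own 5' end with the U2 adapter appended before
truncation to `read_length` (default 300 nt), so short terminal fragments
yield the adapter read-through the trimmer must remove. Substitution errors
are applied at `error_rate` (default 0.005). The depth parameter is the
target mean read coverage; at 200x a 3 kb segment receives roughly 500
molecules, hence hundreds of reads stopping exactly at each true end —
orders of magnitude above the >10-read calling threshold, which is why the
recovery tests demand *exact* coordinate recovery, not proximity.

Degraded molecules are modelled by `truncate_fraction`: a truncated segment
has lost a substantial, variable portion of one end — each molecule stops at
a random offset of up to a quarter of the segment length (at least 500 nt)
inside it — so with the molecule counts the depth model produces, degraded
ends share no common stop position and no complete segment may be called.
This is a deliberate choice of degradation regime: a population nibbled by
only a few nucleotides concentrates its ends on a handful of positions and
presents a genuine new terminus that any count-based rule (including the
published one) would call; such lightly-shortened molecules are a real
variant end, not a missing end, and are outside what the truncation flag
models.
`terminal_capture_rate` (default 1.0) models end retention through library
construction; the protocol's actual capture efficiency is not published, so
the default assumes faithful capture and the parameter is exposed for
sensitivity analysis.

The simulator deliberately omits rRNA background, chimeras, PCR duplicates,
indel errors (exposed as `indel_rate`, default 0) and assembly itself —
contigs given to the pipeline are the true segment sequences. Passing the
recovery tests therefore demonstrates that the *inference rules* are
implemented correctly under the stated read model; it does not certify
performance on real libraries with assembly artefacts, strain mixtures or
low-complexity regions.

## Numerical and design choices

* **Strict thresholds.** The terminus rule is strictly more than 10 stop
  reads, and the major-segment rule strictly above 1,000x mean coverage;
  both are asserted exactly in the tests (10 stops must not call, 11 must).
* **Dominance.** The stop-count rule alone would fire on noise positions
  under very deep coverage; the caller additionally requires
  stop_count / local coverage >= 0.2. The quantification of "dominant" is
  ours; it is configurable and echoed in the run manifest.
* **End window.** Termini are searched within 50 nt of a contig boundary
  (configurable). Internal stop pileups are retained in the profile table
  but never produce termini.
* **Tie-breaks.** Within a window the highest stop count wins; ties go to
  the position closest to the boundary. At most one call per side.
* **Mapper.** The built-in mapper is exact-seed (k = 21) plus gapless
  extension at mismatch rate <= 5%, with soft-clipping only at contig
  boundaries so genuine terminal stops survive. Multi-mapping reads are
  dropped, not randomly placed, because terminus calling is count-based and
  random placement would fabricate stop signal. Reads retaining an adapter
  remnant shorter than the trimmer's minimum overlap (8 nt) map with their
  start shifted by the remnant length; the stop coordinate at the contig
  end is unaffected. Real data should be aligned externally and ingested as
  SAM.
* **Strand orientation.** The coding strand is the one whose forward
  frames carry the greater total ORF length, after cross-strand shadow
  resolution: candidate ORFs from both strands are accepted longest-first
  and a candidate overlapping a longer accepted ORF of the other strand by
  more than half its length is discarded. Without this step, reverse-strand
  "shadow" ORFs — stop codons are depleted on both strands of a genuine
  gene — occasionally out-score the true strand on gene-sparse segments and
  a flipped segment cannot be binned by its termini.
* **Terminal identity.** Windows of 30 nt are aligned globally (match 1,
  mismatch -1, gap open 5, extend 2 — stiff gaps, since spurious gaps
  inflate identity); identity is matches over alignment columns. The link
  threshold 0.6 reflects that published terminal-conservation figures shade
  columns above 50% identity without stating a linking cutoff; both ends
  must pass by default, with a `require_ends = "5p"` mode for virus groups
  conserving only the 5' end.
* **Classes and alternatives.** Within a bin, members at full-length
  identity >= 0.9, length difference < 10% and ORF count within 1 are
  variants of one segment class; distinct classes of similar length in one
  bin are flagged "alternative" (homologous segments sharing termini, the
  RNA2/RNA2*-like pattern). Gene content acts as a guard, not a score.
* **Strain pairing.** Pairs require the same sample and
  |log2 coverage ratio| <= 1; matching is greedy from the most similar
  ratio, one partner per other class (a strain carries one segment of each
  class, so a segment may pair with partners from several classes but never
  with two variants of the same class).
* **SD scanner.** The full `AGGAGG` consensus slides over the 20 nt
  upstream of a start codon; a call requires >= 4 consecutive matching
  bases whose run ends 4-14 nt before the start. On uniform random
  sequence this rule has a false-positive rate just under 0.1 (measured by
  Monte Carlo), and perfect recall on planted motifs. It is a consensus
  matcher, not a trained RBS model, and output is labelled "SD-like".
* **Motif A localisation.** Aspartates 80-200 residues upstream of a GDD
  are classified canonical (partner Asp 4-5 downstream) or extended
  (12-14 downstream). This is a sequence-window heuristic standing in for
  structural superposition, which is out of scope.
* **TMD flag.** Classic Kyte-Doolittle: any 19-residue window with mean
  hydropathy >= 1.6. A heuristic, not an HMM topology model.
* **ORF caller.** Maximal ORFs on the coding strand's three forward frames,
  starts ATG/GTG/TTG, minimum 150 nt including the stop codon. The floor is
  our choice (no published value); gene maps on fixtures are reproducible
  at this setting and the parameter is exposed.

## Determinism and problem sizes

All randomness flows from the integer seed in `sim_params()`; identical
parameters give byte-identical fixtures, and `run_pipeline()` reruns produce
identical manifests (content hashes over every stage output). The validation
suite exercises: a 10-seed sweep of 5-virus viromes at 200x depth and 0.5%
substitution error for terminus recovery (with a quarter of segments
truncated to prove no false complete calls); a two-sample virome for binning
(adjusted Rand index 1.0 expected) and strain pairing; 100 random sequences
against a brute-force ORF oracle, 1,000 random proteins against a regex
motif oracle, and 1,000 constructed reads against an exhaustive trim oracle;
and a ~60-ORF planted genome set for SD recovery within +/-0.05. These sizes
were chosen as the smallest at which the stochastic criteria are stable
across seeds.

## A worked run

```{r pipeline, eval = FALSE}
p <- sim_params(n_viruses = 3, n_samples = 1, seed = 7)
truth <- simulate_virome(p)
reads <- simulate_flds_reads(truth, p)
contigs <- tibble::tibble(contig_id = truth$genomes$segment_id,
                          seq = truth$genomes$seq)
res <- run_pipeline(reads, contigs)
glance(res)
tidy(res, "bins")
summary_report(res)
```

## Known limitations

* Assembly is out of scope; the pipeline consumes contigs and cannot repair
  mis-assemblies or detect internal deletion variants.
* The built-in mapper is gapless; data with indel errors need an external
  aligner.
* Single-linkage binning links transitively: if two viruses ever shared a
  terminus above threshold they would chain into one bin. The threshold
  monotonicity property (raising it never merges bins) is tested, but
  chaining on real mixed communities remains a caveat.
* Strain assignment is only attempted via co-abundance within a sample;
  when terminal conservation makes variant assignment ambiguous the tool
  flags alternatives rather than forcing a decision.
* The SD and TMD scanners are declared heuristics; they do not claim
  equivalence with trained gene callers or topology predictors.
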