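# segvir

Reconstruction of complete multipartite RNA virus genomes from
double-stranded RNA sequencing libraries that preserve genome segment
termini.

## The problem

RNA viruses replicate through dsRNA, and dsRNA-seq protocols that fragment
the duplex and ligate an adapter (U2, `GACGTAAGAACGTCGCACCA`) to every
fragment's 3' end retain the true ends of each genome segment: the terminal
fragment of every molecule stops exactly at the segment terminus. After
mapping, a real terminus is visible as a stack of read alignments ending at
one position. segvir implements the inference built on that signal, for
virologists and microbiome researchers reconstructing segmented RNA virus
genomes from such libraries:

* **Terminus calling** — a position within 50 nt of a contig boundary is a
  segment end when strictly more than 10 reads stop exactly there and those
  stops dominate local coverage (`call_termini()`).
* **Full-length classification** — contigs with both termini confirmed are
  complete segments; complete segments above 1,000× mean coverage are
  flagged major (`classify_segments()`).
* **Genome binning** — segments of one multipartite virus share
  (near-)identical 5'/3' terminal sequences; single-linkage clustering over
  global terminal-window alignments (30 nt, identity ≥ 0.6 at both ends)
  groups segments into virus bins, with variant classes and
  alternative-segment flags (`terminal_identities()`, `cluster_segments()`).
* **Strain pairing** — segments of different classes are assigned to one
  virus strain when they co-occur in the same sample at similar abundance,
  |log2 coverage ratio| ≤ 1 (`pair_by_abundance()`).
* **Annotation** — ORFs under genetic code 11, Shine–Dalgarno-like motifs
  (`AGGAGG` within 4–14 nt of the start codon; prokaryotic host evidence),
  RdRP catalytic motifs B (`SGxxxT`) and C (`GDD`) plus motif A aspartates
  at canonical (4–5) or extended (12–14) spacing, and a Kyte–Doolittle
  transmembrane flag (`annotate_bin()`).
* **Simulation** — a synthetic segmented virome and read-library generator
  with complete ground truth (`simulate_virome()`, `simulate_flds_reads()`)
  drives parameter-recovery validation of every stage.

Everything is tibble-in/tibble-out and pipes cleanly; results carry
broom-style `tidy()`/`glance()` methods and ggplot2 `autoplot()`/
`plot_stop_profile()` graphics.

## Worked example

```r
library(segvir)

p <- sim_params(n_viruses = 3, seed = 7)
truth <- simulate_virome(p)
reads <- simulate_flds_reads(truth, p)
contigs <- tibble::tibble(contig_id = truth$genomes$segment_id,
                          seq = truth$genomes$seq)

res <- run_pipeline(reads, contigs)
res
#> <segvir_result>
#>   contigs: 7 (7 complete segments, 0 major)
#>   bins: 3   strain pairs: 5   ORFs: 48
```

All 7 simulated segments are recovered full-length with termini at the exact
true coordinates, they bin into the 3 simulated viruses, and each bin's
RdRP-motif-bearing member is labelled:

```r
glance(res)
#> # A tibble: 1 x 7
#>   n_contigs n_complete n_major n_bins n_strain_pairs n_orfs sd_fraction
#> 1         7          7       0      3              5     48       0.396

res$bin_summary
#> # A tibble: 3 x 5
#>   bin_id n_members n_orfs sd_fraction rdrp_segment
#> 1 bin01          3     21       0.381 V01_RNA1
#> 2 bin02          2     13       0.231 V02_RNA1
#> 3 bin03          2     14       0.571 V03_RNA1
```

`n_orfs` counts every called ORF ≥ 150 nt, including chance ORFs in the
simulated intergenic filler, which dilutes the overall SD fraction; measured
on the planted genes alone the SD fraction matches the simulated 0.95 (see
the validation suite). `tidy(res, "strain_pairs")` lists the same-sample,
similar-abundance segment pairs; `autoplot(res)` draws the genome map of a
bin with SD and TMD marks.

Real libraries enter the same way: `read_fastq()` + `trim_adapter()` +
`quality_filter()`, an external aligner's SAM via `read_sam()`, and
assembled contigs via `read_contigs()`.

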