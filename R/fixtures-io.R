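#' Write a simulated virome and its reads to plain-text files
#'
#' Writes paired reads as FASTQ (Sanger quality encoding), genome segments as
#' FASTA, and the ground-truth tables (segments, termini, ORFs, bins,
#' coverages, per-read provenance) as TSV. All coordinates in the truth
#' tables are 0-based half-open on the coding strand. Given a fixed
#' simulation seed the files are byte-identical across runs.
#'
#' @param truth A `segvir_truth` from [simulate_virome()].
#' @param reads Read tibble from [simulate_flds_reads()] (may be `NULL` to
#'   write genomes and truth only).
#' @param dir Output directory; created if missing.
#' @return Invisibly, a named character vector of the files written.
#' @export
write_fixture <- function(truth, reads, dir) {
  stopifnot(inherits(truth, "segvir_truth"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2) != 0) abort(sprintf("directory not writable: %s", dir))
  paths <- c(
    genomes = file.path(dir, "genomes.fasta"),
    reads_1 = file.path(dir, "reads_1.fastq"),
    reads_2 = file.path(dir, "reads_2.fastq"),
    segments = file.path(dir, "truth_segments.tsv"),
    termini = file.path(dir, "truth_termini.tsv"),
    orfs = file.path(dir, "truth_orfs.tsv"),
    bins = file.path(dir, "truth_bins.tsv"),
    provenance = file.path(dir, "truth_provenance.tsv")
  )
  dna <- Biostrings::DNAStringSet(setNames(truth$genomes$seq,
                                           truth$genomes$segment_id))
  Biostrings::writeXStringSet(dna, paths[["genomes"]])
  if (is.null(reads)) {
    reads <- tibble(read_id = character(), mate = integer(), seq = character(),
                    qual = character())
  }
  for (m in 1:2) {
    sub <- filter(reads, .data$mate == m)
    write_fastq(sub, paths[[paste0("reads_", m)]])
  }
  readr::write_tsv(select(truth$genomes, -"seq"), paths[["segments"]])
  readr::write_tsv(truth$termini, paths[["termini"]])
  readr::write_tsv(truth$orfs, paths[["orfs"]])
  readr::write_tsv(truth$bins, paths[["bins"]])
  prov_cols <- setdiff(names(reads), c("seq", "qual"))
  readr::write_tsv(reads[, prov_cols], paths[["provenance"]])
  invisible(paths)
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param dir Directory holding the fixture files.
#' @return A list with `truth` (a `segvir_truth` without `params`) and
#'   `reads` (tibble with sequence, quality and provenance columns).
#' @export
read_fixture <- function(dir) {
  p <- function(f) file.path(dir, f)
  for (f in c("genomes.fasta", "truth_segments.tsv")) {
    if (!file.exists(p(f))) abort(sprintf("missing fixture file: %s", p(f)))
  }
  dna <- Biostrings::readDNAStringSet(p("genomes.fasta"))
  seg <- readr::read_tsv(p("truth_segments.tsv"), show_col_types = FALSE)
  genomes <- as_tibble(seg)
  genomes$seq <- unname(as.character(dna)[genomes$segment_id])
  genomes <- select(genomes, "virus_id", "segment_id", "sample_id", "seq",
                    everything())
  r1 <- read_fastq(p("reads_1.fastq"))
  r2 <- read_fastq(p("reads_2.fastq"))
  prov <- readr::read_tsv(p("truth_provenance.tsv"), show_col_types = FALSE)
  reads <- bind_rows(mutate(r1, mate = 1L), mutate(r2, mate = 2L))
  reads <- left_join(reads, prov, by = c("read_id", "mate"))
  truth <- structure(list(
    genomes = genomes,
    termini = readr::read_tsv(p("truth_termini.tsv"), show_col_types = FALSE),
    orfs = readr::read_tsv(p("truth_orfs.tsv"), show_col_types = FALSE),
    bins = readr::read_tsv(p("truth_bins.tsv"), show_col_types = FALSE),
    coverages = select(genomes, "segment_id", depth = "depth")
  ), class = "segvir_truth")
  list(truth = truth, reads = reads)
}

#' Write reads to FASTQ (Sanger encoding)
#'
#' @param reads Tibble with `read_id`, `seq`, `qual`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  dna <- Biostrings::DNAStringSet(setNames(reads$seq, reads$read_id))
  Biostrings::writeXStringSet(dna, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Read a FASTQ file into a tibble
#'
#' @param path FASTQ path (Sanger quality encoding).
#' @return Tibble with `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(read_id = names(x), seq = unname(as.character(x)),
         qual = unname(as.character(S4Vectors::mcols(x)$qualities)))
}

#' Read contigs from a FASTA file
#'
#' @param path FASTA path.
#' @return Tibble with `contig_id`, `seq`.
#' @export
read_contigs <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(contig_id = sub("\\s.*$", "", names(x)), seq = as.character(x))
}
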