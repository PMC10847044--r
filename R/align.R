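#' Read alignments from a SAM file
#'
#' Ingests a plain-text SAM file (with header), keeping primary mapped
#' records only; unmapped, secondary and supplementary alignments are
#' excluded. Coordinates are converted from 1-based SAM to 0-based half-open;
#' the reported interval is the reference span of the aligned portion
#' (soft-clips excluded).
#'
#' @param path Path to a SAM file.
#' @return Tibble with `read_id`, `contig_id`, `start`, `end`, `strand`,
#'   `n_mismatches` (from the NM tag where present, otherwise `NA`).
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  header <- readLines(path, n = 200L)
  if (!any(startsWith(header, "@SQ"))) {
    abort("SAM file has no @SQ header lines", class = "segvir_format_error")
  }
  bam <- tryCatch(
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE),
    error = function(e) {
      abort(sprintf("failed to parse SAM %s: %s", path, conditionMessage(e)),
            class = "segvir_format_error")
    }
  )
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag, what = "qname", tag = "NM")
  aln <- GenomicAlignments::readGAlignments(bam, param = param, use.names = FALSE)
  nm <- S4Vectors::mcols(aln)$NM
  tibble(
    read_id = S4Vectors::mcols(aln)$qname,
    contig_id = as.character(GenomicAlignments::seqnames(aln)),
    start = GenomicAlignments::start(aln) - 1L,
    end = GenomicAlignments::end(aln),
    strand = as.character(GenomicAlignments::strand(aln)),
    n_mismatches = if (is.null(nm)) NA_integer_ else as.integer(nm)
  )
}

# k-mer index over all contigs; positions are encoded as
# contig_index * ENC + 0-based position + ENC_SHIFT so that shifting a hit
# by a seed offset is plain integer arithmetic.
ENC <- 1e9
ENC_SHIFT <- 1e4

build_kmer_index <- function(contigs, k) {
  kmers <- character(0)
  codes <- numeric(0)
  for (i in seq_len(nrow(contigs))) {
    s <- contigs$seq[i]
    L <- nchar(s)
    if (L < k) next
    pos <- seq_len(L - k + 1L)
    kmers <- c(kmers, substring(s, pos, pos + k - 1L))
    codes <- c(codes, i * ENC + (pos - 1L) + ENC_SHIFT)
  }
  list2env(split(codes, kmers), hash = TRUE, size = length(kmers))
}

# Gapless end-to-end check of `read` against contig `cseq` with read base 1
# at 0-based contig position `pos`; clipped at contig bounds. Returns NULL or
# a list(start, end, clip5, clip3, mm, aligned).
extend_placement <- function(read, cseq, clen, pos, max_mismatch_rate) {
  rl <- nchar(read)
  clip5 <- max(0L, -pos)
  clip3 <- max(0L, pos + rl - clen)
  aligned <- rl - clip5 - clip3
  if (aligned < 1L) return(NULL)
  start <- pos + clip5
  frag <- substr(cseq, start + 1L, start + aligned)
  sub <- if (clip5 > 0L || clip3 > 0L) substr(read, clip5 + 1L, clip5 + aligned) else read
  mm <- str_mismatches(sub, frag)
  if (mm > max_mismatch_rate * aligned) return(NULL)
  list(start = start, end = start + aligned, clip5 = clip5, clip3 = clip3,
       mm = mm, aligned = aligned)
}

#' Map reads to contigs with a minimal exact-seed, gapless mapper
#'
#' A deliberately simple mapper adequate for low-error, indel-free reads
#' (such as the built-in simulator's): a k-mer seed anchors each read, which
#' is then extended end-to-end without gaps; placements with a mismatch rate
#' above `max_mismatch_rate` are rejected. Reads whose placement would extend
#' past a contig boundary are soft-clipped at the boundary (never beyond), so
#' genuine terminal read stops are preserved. Reads passing at more than one
#' locus are discarded as ambiguous rather than placed arbitrarily, because
#' downstream terminus calling is count-based. Real data should be aligned
#' externally and ingested with [read_sam()].
#'
#' @param reads Tibble with `read_id` and `seq` (trimmed reads).
#' @param contigs Contigs as a tibble (`contig_id`, `seq`), named character
#'   vector or `DNAStringSet`.
#' @param k Seed k-mer length.
#' @param max_mismatch_rate Maximum mismatch fraction over the aligned part.
#' @param seed_tries Number of non-overlapping seed offsets attempted.
#' @return Tibble with `read_id`, `contig_id`, `start`, `end` (0-based
#'   half-open), `strand`, `n_mismatches`, `clip5`, `clip3`; counts of
#'   mapped/ambiguous/unmapped reads in attribute `"counts"`.
#' @export
map_reads <- function(reads, contigs, k = 21L, max_mismatch_rate = 0.05,
                      seed_tries = 4L) {
  contigs <- as_contig_tbl(contigs)
  if (any(nchar(reads$seq) < k)) {
    abort("`k` is larger than the shortest read; trim or filter first")
  }
  index <- build_kmer_index(contigs, k)
  clen <- nchar(contigs$seq)
  n_reads <- nrow(reads)
  res <- vector("list", n_reads)
  status <- character(n_reads)
  rc_all <- revcomp(reads$seq)
  for (i in seq_len(n_reads)) {
    placements <- list()
    for (strand in c("+", "-")) {
      rseq <- if (strand == "+") reads$seq[i] else rc_all[i]
      rl <- nchar(rseq)
      offsets <- unique(pmin(seq(0L, by = k, length.out = seed_tries), rl - k))
      cand <- numeric(0)
      for (off in offsets) {
        hits <- get0(substr(rseq, off + 1L, off + k), envir = index,
                     inherits = FALSE)
        if (!is.null(hits)) cand <- c(cand, hits - off)
      }
      for (code in unique(cand)) {
        ci <- code %/% ENC
        pos <- code %% ENC - ENC_SHIFT
        pl <- extend_placement(rseq, contigs$seq[ci], clen[ci], pos,
                               max_mismatch_rate)
        if (!is.null(pl)) {
          pl$contig <- ci
          pl$strand <- strand
          placements[[length(placements) + 1L]] <- pl
        }
      }
      if (length(placements) > 1L) break
    }
    if (length(placements) == 1L) {
      p <- placements[[1L]]
      res[[i]] <- c(p$contig, p$start, p$end, p$mm, p$clip5, p$clip3,
                    if (p$strand == "+") 1L else -1L)
      status[i] <- "mapped"
    } else if (length(placements) > 1L) {
      status[i] <- "ambiguous"
    } else {
      status[i] <- "unmapped"
    }
  }
  ok <- which(status == "mapped")
  m <- do.call(rbind, res[ok])
  out <- if (length(ok)) {
    tibble(
      read_id = reads$read_id[ok],
      contig_id = contigs$contig_id[m[, 1]],
      start = as.integer(m[, 2]),
      end = as.integer(m[, 3]),
      strand = ifelse(m[, 7] > 0, "+", "-"),
      n_mismatches = as.integer(m[, 4]),
      clip5 = as.integer(m[, 5]),
      clip3 = as.integer(m[, 6])
    )
  } else {
    tibble(read_id = character(), contig_id = character(), start = integer(),
           end = integer(), strand = character(), n_mismatches = integer(),
           clip5 = integer(), clip3 = integer())
  }
  attr(out, "counts") <- c(mapped = sum(status == "mapped"),
                           ambiguous = sum(status == "ambiguous"),
                           unmapped = sum(status == "unmapped"))
  out
}

#' Per-position coverage and read start/stop pileup
#'
#' Computes, for each contig, the number of alignments starting at every
#' position, the number ending (exclusive end coordinate) at every position,
#' and the coverage depth. These counts house the evidence for terminus
#' calling: dominant read stops shared at one position around a contig end
#' mark a true segment terminus.
#'
#' @param alignments Alignment tibble from [map_reads()] or [read_sam()].
#' @param contigs Contigs (tibble, named character vector or `DNAStringSet`);
#'   every alignment must reference one of them and lie within its bounds.
#' @return Tibble with `contig_id`, `pos` (0..contig length), `starts`,
#'   `ends`, `coverage` (coverage at the final position, where no base
#'   exists, is 0).
#' @export
build_stop_profile <- function(alignments, contigs) {
  contigs <- as_contig_tbl(contigs)
  bad <- !alignments$contig_id %in% contigs$contig_id
  if (any(bad)) {
    abort(sprintf("alignments reference unknown contig: %s",
                  alignments$contig_id[which(bad)[1]]))
  }
  out <- vector("list", nrow(contigs))
  for (i in seq_len(nrow(contigs))) {
    L <- nchar(contigs$seq[i])
    a <- alignments[alignments$contig_id == contigs$contig_id[i], , drop = FALSE]
    if (nrow(a) > 0L &&
        (min(a$start) < 0L || max(a$end) > L || any(a$start >= a$end))) {
      abort(sprintf("alignment out of bounds on contig %s",
                    contigs$contig_id[i]), class = "segvir_invariant_error")
    }
    starts <- tabulate(a$start + 1L, nbins = L + 1L)
    ends <- tabulate(a$end + 1L, nbins = L + 1L)
    # an alignment [s, e) covers p iff s <= p < e, so coverage at p is
    # #(starts <= p) - #(ends <= p)
    coverage <- cumsum(starts - ends)
    out[[i]] <- tibble(contig_id = contigs$contig_id[i], pos = 0:L,
                       starts = starts, ends = ends, coverage = coverage)
  }
  list_rbind(out)
}
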