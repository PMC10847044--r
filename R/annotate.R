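GENETIC_CODE_11 <- Biostrings::getGeneticCode("11")

translate_cds <- function(dna) {
  aa <- Biostrings::translate(Biostrings::DNAString(dna),
                              genetic.code = GENETIC_CODE_11,
                              if.fuzzy.codon = "X")
  sub("\\*$", "", as.character(aa))
}

#' Find ORFs on the coding strand (genetic code 11)
#'
#' Maximal open reading frames on the three forward frames: each ORF starts
#' at the first ATG/GTG/TTG after the preceding in-frame stop and runs to
#' the next in-frame stop (coordinates include the stop codon) or, when no
#' stop follows, to the last complete codon before the segment end (flagged
#' `open_3p`). Nested ORFs are suppressed: only the longest ORF per stop
#' position is reported.
#'
#' @param seq Coding-strand nucleotide sequence (ACGTN).
#' @param min_orf_len Minimum ORF length in nt (start to stop inclusive).
#' @return Tibble with `start`, `end` (0-based half-open), `frame` (0-2),
#'   `strand` (always "+"), `start_codon`, `open_3p`, `protein`, ordered by
#'   `start`.
#' @export
find_orfs <- function(seq, min_orf_len = 150L) {
  seq <- check_dna(seq, "seq", allow_n = TRUE)
  L <- nchar(seq)
  out <- list()
  for (frame in 0:2) {
    n_cod <- (L - frame) %/% 3L
    if (n_cod < 2L) next
    starts_nt <- frame + 3L * (seq_len(n_cod) - 1L)
    codons <- substring(seq, starts_nt + 1L, starts_nt + 3L)
    is_stop <- codons %in% STOP_CODONS
    is_start <- codons %in% START_CODONS
    # segment the codon sequence at stops; within each inter-stop stretch
    # the maximal ORF begins at the first start codon
    stop_idx <- which(is_stop)
    bounds <- c(0L, stop_idx, n_cod + 1L)
    for (b in seq_len(length(bounds) - 1L)) {
      lo <- bounds[b] + 1L
      hi <- bounds[b + 1L] - 1L  # last codon before the stop (or seq end)
      cand <- which(is_start[seq.int(lo, length.out = max(0L, hi - lo + 1L))])
      if (!length(cand)) next
      first_start <- lo + cand[1L] - 1L
      has_stop <- bounds[b + 1L] <= n_cod
      end_cod <- if (has_stop) bounds[b + 1L] else hi
      start_nt <- starts_nt[first_start]
      end_nt <- starts_nt[end_cod] + 3L
      if (end_nt - start_nt < min_orf_len) next
      cds <- substr(seq, start_nt + 1L, end_nt)
      out[[length(out) + 1L]] <- tibble(
        start = start_nt, end = end_nt, frame = frame, strand = "+",
        start_codon = codons[first_start], open_3p = !has_stop,
        protein = translate_cds(cds)
      )
    }
  }
  if (!length(out)) {
    return(tibble(start = integer(), end = integer(), frame = integer(),
                  strand = character(), start_codon = character(),
                  open_3p = logical(), protein = character()))
  }
  arrange(list_rbind(out), .data$start)
}

#' Detect a Shine-Dalgarno-like motif upstream of an ORF
#'
#' Slides the SD consensus (AGGAGG) over the 20 nt immediately upstream of
#' the ORF start codon and looks, within each placement, for the longest run
#' of consecutive matching bases. An SD-like motif is called when a run of
#' at least `min_match` bases ends 4-14 nt before the start codon. The
#' scanner is a consensus matcher, not a trained ribosome-binding-site
#' model, and its calls are labelled SD-like accordingly.
#'
#' @param seq Segment sequence (coding strand).
#' @param orf_start 0-based start coordinate of the ORF.
#' @param consensus SD consensus sequence.
#' @param min_match Minimum consecutive matching bases.
#' @param upstream Window length examined upstream of the start codon
#'   (clipped at the segment start).
#' @return One-row tibble: `sd_found`, `sd_seq` (matched bases), `sd_spacer`
#'   (nt between match end and start codon), `sd_match_len`.
#' @export
detect_sd <- function(seq, orf_start, consensus = SD_CONSENSUS,
                      min_match = 4L, upstream = 20L) {
  w0 <- max(0L, orf_start - upstream)
  win <- substr(seq, w0 + 1L, orf_start)
  Lw <- nchar(win)
  clen <- nchar(consensus)
  best <- list(len = 0L, spacer = NA_integer_, seq = NA_character_)
  if (Lw >= clen) {
    cons_raw <- charToRaw(consensus)
    for (s in 0:(Lw - clen)) {
      m <- charToRaw(substr(win, s + 1L, s + clen)) == cons_raw
      r <- rle(m)
      if (!any(r$values)) next
      run_ends <- cumsum(r$lengths)
      for (j in which(r$values)) {
        len <- r$lengths[j]
        end_in_win <- s + run_ends[j]
        spacer <- Lw - end_in_win
        if (len >= min_match && spacer >= 4L && spacer <= 14L) {
          if (len > best$len || (len == best$len && !is.na(best$spacer) &&
                                   spacer < best$spacer)) {
            best <- list(len = len, spacer = spacer,
                         seq = substr(win, end_in_win - len + 1L, end_in_win))
          }
        }
      }
    }
  }
  tibble(sd_found = best$len >= min_match, sd_seq = best$seq,
         sd_spacer = best$spacer, sd_match_len = best$len)
}

#' Scan a protein for RdRP catalytic motifs A, B and C
#'
#' Reports all occurrences of motif C (GDD) and motif B (SGxxxT, x = any
#' residue); a B hit is flagged "ordered" when it lies 10-60 residues before
#' a C hit, the arrangement diagnostic of an RdRP palm domain. Motif A
#' candidates are aspartates 80-200 residues upstream of a C hit with a
#' partner aspartate 4-5 residues downstream (canonical spacing) or 12-14
#' residues downstream (the extended arrangement seen in highly divergent
#' RdRPs). Non-standard residues never match S, G, T or D.
#'
#' @param protein Amino-acid sequence (one-letter code).
#' @return Tibble with `motif` ("A", "B" or "C"), `position` (0-based
#'   residue index), `matched` (matched residues), `ordered` (B only),
#'   `partner_spacing` and `spacing_class` ("canonical" or "extended",
#'   A only), ordered by position.
#' @export
scan_rdrp_motifs <- function(protein) {
  if (nchar(protein) < 30L) abort("protein must be at least 30 residues")
  aa <- strsplit(protein, "")[[1]]
  n <- length(aa)
  c_pos <- which(aa[seq_len(max(0L, n - 2L))] == "G" &
                   aa[seq_len(max(0L, n - 2L)) + 1L] == "D" &
                   aa[seq_len(max(0L, n - 2L)) + 2L] == "D") - 1L
  b_pos <- integer(0)
  if (n >= 6L) {
    i <- seq_len(n - 5L)
    b_pos <- which(aa[i] == "S" & aa[i + 1L] == "G" & aa[i + 5L] == "T") - 1L
  }
  hits <- list()
  for (p in c_pos) {
    hits[[length(hits) + 1L]] <- tibble(
      motif = "C", position = p, matched = "GDD", ordered = NA,
      partner_spacing = NA_integer_, spacing_class = NA_character_)
  }
  for (p in b_pos) {
    ordered <- any(c_pos - p >= 10L & c_pos - p <= 60L)
    hits[[length(hits) + 1L]] <- tibble(
      motif = "B", position = p,
      matched = substr(protein, p + 1L, p + 6L), ordered = ordered,
      partner_spacing = NA_integer_, spacing_class = NA_character_)
  }
  d_pos <- which(aa == "D") - 1L
  a_seen <- integer(0)
  for (cp in c_pos) {
    cands <- d_pos[cp - d_pos >= 80L & cp - d_pos <= 200L]
    for (dp in cands) {
      if (dp %in% a_seen) next
      spacing <- d_pos - dp
      cls <- if (any(spacing >= 4L & spacing <= 5L)) "canonical"
             else if (any(spacing >= 12L & spacing <= 14L)) "extended"
             else NA_character_
      if (is.na(cls)) next
      a_seen <- c(a_seen, dp)
      hits[[length(hits) + 1L]] <- tibble(
        motif = "A", position = dp, matched = "D", ordered = NA,
        partner_spacing = if (cls == "canonical") {
          min(spacing[spacing >= 4L & spacing <= 5L])
        } else {
          min(spacing[spacing >= 12L & spacing <= 14L])
        },
        spacing_class = cls)
    }
  }
  if (!length(hits)) {
    return(tibble(motif = character(), position = integer(),
                  matched = character(), ordered = logical(),
                  partner_spacing = integer(), spacing_class = character()))
  }
  arrange(list_rbind(hits), .data$position, .data$motif)
}

# Kyte-Doolittle hydropathy values; non-standard residues score 0.
KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

#' Flag transmembrane-domain candidates by hydropathy
#'
#' Classic sliding-window heuristic: a protein is flagged when any window of
#' `window` residues has mean Kyte-Doolittle hydropathy at or above
#' `threshold`.
#'
#' @param protein Amino-acid sequence; must be at least `window` residues.
#' @param window Window length in residues.
#' @param threshold Mean hydropathy at or above which a window qualifies.
#' @return One-row tibble: `tmd` (logical), `best_score`, `best_start`
#'   (0-based window start).
#' @export
flag_tmd <- function(protein, window = 19L, threshold = 1.6) {
  n <- nchar(protein)
  if (n < window) abort("protein shorter than the hydropathy window")
  h <- unname(KD_HYDROPATHY[strsplit(protein, "")[[1]]])
  h[is.na(h)] <- 0
  cs <- c(0, cumsum(h))
  means <- (cs[(window + 1L):(n + 1L)] - cs[seq_len(n - window + 1L)]) / window
  best <- which.max(means)
  tibble(tmd = means[best] >= threshold, best_score = means[best],
         best_start = best - 1L)
}

#' Annotate all ORFs of a segment
#'
#' Runs [find_orfs()], [detect_sd()], [flag_tmd()] and [scan_rdrp_motifs()]
#' on one coding-strand sequence.
#'
#' @param seq Coding-strand sequence.
#' @param segment_id Identifier recorded in the output.
#' @param min_orf_len Minimum ORF length in nt.
#' @param sd_min_match Minimum consecutive SD-consensus matches.
#' @return ORF tibble with added columns `segment_id`, `sd_found`,
#'   `sd_seq`, `sd_spacer`, `tmd`, `rdrp_b`, `rdrp_c`, `rdrp_ordered`,
#'   `rdrp_a_class`.
#' @export
annotate_segment <- function(seq, segment_id = "segment", min_orf_len = 150L,
                             sd_min_match = 4L) {
  orfs <- find_orfs(seq, min_orf_len)
  if (nrow(orfs) == 0L) {
    return(bind_cols(tibble(segment_id = character()), orfs,
                     tibble(sd_found = logical(), sd_seq = character(),
                            sd_spacer = integer(), tmd = logical(),
                            rdrp_b = integer(), rdrp_c = integer(),
                            rdrp_ordered = logical(),
                            rdrp_a_class = character())))
  }
  sd <- list_rbind(map(orfs$start, function(s) detect_sd(seq, s,
                                                         min_match = sd_min_match)))
  extra <- list_rbind(map(orfs$protein, function(p) {
    tmd <- if (nchar(p) >= 19L) flag_tmd(p)$tmd else FALSE
    if (nchar(p) >= 30L) {
      m <- scan_rdrp_motifs(p)
      a_cls <- m$spacing_class[m$motif == "A"]
      tibble(tmd = tmd,
             rdrp_b = sum(m$motif == "B"),
             rdrp_c = sum(m$motif == "C"),
             rdrp_ordered = any(m$ordered %in% TRUE),
             rdrp_a_class = if (length(a_cls)) a_cls[1] else NA_character_)
    } else {
      tibble(tmd = tmd, rdrp_b = 0L, rdrp_c = 0L, rdrp_ordered = FALSE,
             rdrp_a_class = NA_character_)
    }
  }))
  bind_cols(tibble(segment_id = segment_id), orfs,
            select(sd, "sd_found", "sd_seq", "sd_spacer"), extra)
}

#' Annotate a virus genome bin
#'
#' Annotates every member segment of a bin and summarises the bin: ORF
#' count, fraction of ORFs with an SD-like motif, and the member carrying an
#' ordered B-C RdRP motif pair (labelled the RdRP segment). Optionally
#' writes per-bin GFF3 and protein FASTA.
#'
#' @param bins Bin membership from [cluster_segments()].
#' @param segments Oriented segment tibble (`contig_id`, `seq`).
#' @param min_orf_len Minimum ORF length in nt.
#' @param gff_dir,protein_dir Optional output directories for per-bin GFF3
#'   and protein FASTA files.
#' @return List with `orfs` (annotation tibble over all members) and
#'   `summary` (per bin: `bin_id`, `n_members`, `n_orfs`, `sd_fraction`,
#'   `rdrp_segment`).
#' @export
annotate_bin <- function(bins, segments, min_orf_len = 150L,
                         gff_dir = NULL, protein_dir = NULL) {
  seqs <- setNames(segments$seq, segments$contig_id)
  ann <- list_rbind(map(bins$contig_id, function(id) {
    annotate_segment(seqs[[id]], id, min_orf_len)
  }))
  ann <- left_join(ann, select(bins, "contig_id", "bin_id"),
                   by = c(segment_id = "contig_id"))
  summary <- ann |>
    group_by(.data$bin_id) |>
    summarise(
      n_members = dplyr::n_distinct(.data$segment_id),
      n_orfs = n(),
      sd_fraction = mean(.data$sd_found),
      rdrp_segment = {
        r <- unique(.data$segment_id[.data$rdrp_ordered])
        if (length(r)) paste(r, collapse = ",") else NA_character_
      }
    )
  if (!is.null(gff_dir)) {
    if (!dir.exists(gff_dir)) dir.create(gff_dir, recursive = TRUE)
    for (b in unique(bins$bin_id)) {
      members <- bins$contig_id[bins$bin_id == b]
      sub <- ann[ann$segment_id %in% members, , drop = FALSE]
      write_orf_gff3(sub, seqs[members],
                     file.path(gff_dir, paste0(b, ".gff3")))
    }
  }
  if (!is.null(protein_dir)) {
    if (!dir.exists(protein_dir)) dir.create(protein_dir, recursive = TRUE)
    for (b in unique(bins$bin_id)) {
      sub <- ann[ann$bin_id == b, , drop = FALSE]
      aa <- Biostrings::AAStringSet(setNames(sub$protein, sprintf(
        "%s_ORF%d", sub$segment_id, stats::ave(seq_len(nrow(sub)),
                                               sub$segment_id, FUN = seq_along))))
      Biostrings::writeXStringSet(aa, file.path(protein_dir,
                                                paste0(b, "_proteins.fasta")))
    }
  }
  list(orfs = ann, summary = summary)
}

#' Write ORF annotations as GFF3
#'
#' Coordinates follow the GFF3 convention (1-based, inclusive).
#'
#' @param orfs Annotation tibble from [annotate_segment()]/[annotate_bin()].
#' @param seqs Named character vector of the annotated sequences (for
#'   sequence-region lengths).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_orf_gff3 <- function(orfs, seqs, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = orfs$segment_id,
    ranges = IRanges::IRanges(start = orfs$start + 1L, end = orfs$end),
    strand = orfs$strand
  )
  GenomeInfoDb::seqlengths(gr) <- nchar(seqs)[GenomeInfoDb::seqlevels(gr)]
  gr$type <- "CDS"
  gr$phase <- 0L
  gr$ID <- sprintf("%s_ORF%d", orfs$segment_id,
                   stats::ave(seq_len(nrow(orfs)), orfs$segment_id,
                              FUN = seq_along))
  gr$sd_like <- ifelse(orfs$sd_found, "yes", "no")
  gr$tmd <- ifelse(orfs$tmd, "yes", "no")
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
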