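#' Simulation parameters for a synthetic segmented dsRNA virome
#'
#' Bundles and validates every knob of the synthetic virome and FLDS-read
#' simulator. Defaults describe the library structure the terminus-calling
#' pipeline assumes: multipartite viruses whose 2-3 genome segments share
#' (near-)identical 5' and 3' terminal sequences on the coding strand,
#' polycistronic ORFs mostly preceded by a Shine-Dalgarno motif, ~1.5 kb
#' physical fragmentation with U2 adapter ligation at fragment 3' ends, and
#' read stacks that terminate exactly at true segment ends.
#'
#' @param n_viruses Number of viruses to simulate.
#' @param segments_per_virus Range (scalar or length 2) of segments per virus.
#' @param segment_length Range of segment lengths in nt.
#' @param terminal_length Length in nt of the conserved terminal sequence
#'   shared by segments of one virus.
#' @param terminal_identity_within Identity of terminal sequences between
#'   segments of the same virus (1 = identical).
#' @param terminal_identity_between Maximum allowed identity between terminal
#'   sequences of different viruses.
#' @param orfs_per_segment Range of ORFs planted per segment.
#' @param sd_fraction Fraction of planted ORFs preceded by a Shine-Dalgarno
#'   motif (consensus AGGAGG, spacer 4-14 nt).
#' @param fragment_length_mean Mean physical fragment length in nt (the
#'   protocol fragments dsRNA to roughly 1.5 kb); fragment lengths are drawn
#'   from a normal with sd = 20% of the mean, truncated to
#'   `[read_length, molecule length]`.
#' @param read_length Read length in nt.
#' @param depth_per_virus Range of mean fold-coverage per virus.
#' @param error_rate Per-base substitution error probability.
#' @param indel_rate Per-base indel probability (default 0; substitutions
#'   only keeps the built-in gapless mapper adequate).
#' @param terminal_capture_rate Probability that a fragment edge falling on a
#'   true segment end retains that exact end through library construction.
#' @param plant_rdrp When `TRUE`, the first ORF of each virus's first
#'   segment encodes the RdRP catalytic motif arrangement (extended motif A,
#'   B, C), so exactly one member of each genome bin is an RdRP segment.
#' @param truncate_fraction Fraction of segments simulated as degraded
#'   molecules missing one true end (ragged, no common stop position); used
#'   to verify that no complete segment is called where an end is absent.
#' @param n_samples Number of samples the viruses are distributed over
#'   (round-robin); strain pairing requires sample co-occurrence.
#' @param seed Integer seed; all outputs are deterministic given the params.
#'
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_viruses = 3,
                       segments_per_virus = c(2, 3),
                       segment_length = c(1500, 6000),
                       terminal_length = 25,
                       terminal_identity_within = 1.0,
                       terminal_identity_between = 0.3,
                       orfs_per_segment = c(2, 4),
                       sd_fraction = 0.95,
                       fragment_length_mean = 1500,
                       read_length = 300,
                       depth_per_virus = c(100, 300),
                       error_rate = 0.005,
                       indel_rate = 0,
                       terminal_capture_rate = 1.0,
                       truncate_fraction = 0,
                       plant_rdrp = TRUE,
                       n_samples = 1,
                       seed = 1L) {
  assert_scalar_count(n_viruses, "n_viruses")
  assert_scalar_count(terminal_length, "terminal_length")
  assert_scalar_count(fragment_length_mean, "fragment_length_mean")
  assert_scalar_count(read_length, "read_length")
  assert_scalar_count(n_samples, "n_samples")
  assert_scalar_count(seed, "seed", positive = FALSE)
  assert_fraction(terminal_identity_within, "terminal_identity_within")
  assert_fraction(terminal_identity_between, "terminal_identity_between")
  assert_fraction(sd_fraction, "sd_fraction")
  assert_fraction(error_rate, "error_rate")
  assert_fraction(indel_rate, "indel_rate")
  assert_fraction(terminal_capture_rate, "terminal_capture_rate")
  assert_fraction(truncate_fraction, "truncate_fraction")
  p <- list(
    n_viruses = as.integer(n_viruses),
    segments_per_virus = as_range(segments_per_virus, "segments_per_virus"),
    segment_length = as_range(segment_length, "segment_length"),
    terminal_length = as.integer(terminal_length),
    terminal_identity_within = terminal_identity_within,
    terminal_identity_between = terminal_identity_between,
    orfs_per_segment = as_range(orfs_per_segment, "orfs_per_segment"),
    sd_fraction = sd_fraction,
    fragment_length_mean = as.integer(fragment_length_mean),
    read_length = as.integer(read_length),
    depth_per_virus = as_range(depth_per_virus, "depth_per_virus"),
    error_rate = error_rate,
    indel_rate = indel_rate,
    terminal_capture_rate = terminal_capture_rate,
    truncate_fraction = truncate_fraction,
    plant_rdrp = isTRUE(plant_rdrp),
    n_samples = as.integer(n_samples),
    seed = as.integer(seed)
  )
  if (p$terminal_length < 10) {
    abort("`terminal_length` must be at least 10 nt")
  }
  if (p$terminal_length >= p$segment_length[1] / 2) {
    abort("`terminal_length` must be shorter than half the minimum segment length")
  }
  if (p$read_length > p$fragment_length_mean) {
    abort("`read_length` must not exceed `fragment_length_mean`")
  }
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-26s %s\n", nm, paste(x[[nm]], collapse = "-")))
  }
  invisible(x)
}

# Stop cassette with a stop codon in all three frames and no start codon in
# any frame; placed immediately upstream of each planted gene so the maximal
# ORF begins exactly at the planted start codon.
STOP_CASSETTE <- "TAACTAACTAAC"
SD_CONSENSUS <- "AGGAGG"

START_CODONS <- c("ATG", "GTG", "TTG")
STOP_CODONS <- c("TAA", "TAG", "TGA")

all_codons <- function() {
  g <- expand.grid(DNA_BASES, DNA_BASES, DNA_BASES, stringsAsFactors = FALSE)
  paste0(g[[3]], g[[2]], g[[1]])
}

random_orf_seq <- function(len_nt) {
  stopifnot(len_nt %% 3 == 0, len_nt >= 9)
  sense <- setdiff(all_codons(), STOP_CODONS)
  n_body <- len_nt / 3 - 2
  paste0(
    sample(START_CODONS, 1L, prob = c(0.8, 0.1, 0.1)),
    paste(sample(sense, n_body, replace = TRUE), collapse = ""),
    sample(STOP_CODONS, 1L)
  )
}

# Reverse-translate one amino acid to a random synonymous codon (code 11).
aa_to_codon <- local({
  tbl <- NULL
  function(aa) {
    if (is.null(tbl)) {
      code <- GENETIC_CODE_11
      tbl <<- split(names(code), unname(code))
    }
    vapply(aa, function(a) sample(tbl[[a]], 1L), "", USE.NAMES = FALSE)
  }
})

# ORF whose protein carries the RdRP palm-domain motif arrangement: motif A
# first Asp with its partner Asp 13 residues downstream (the extended
# arrangement), motif B (SGxxxT) 80 residues later, motif C (GDD) 110
# residues after motif A, i.e. 24 residues after motif B ends.
rdrp_orf_seq <- function(len_nt) {
  stopifnot(len_nt %% 3 == 0, len_nt >= 480)
  n_res <- len_nt / 3L - 2L
  aa <- sample(names(KD_HYDROPATHY), n_res, replace = TRUE)
  d0 <- 31L  # 1-based index of the first motif-A Asp
  aa[d0] <- "D"
  # keep the inter-Asp stretch free of chance aspartates so the planted
  # spacing (13, the extended arrangement) is unambiguous
  between <- d0 + seq_len(12L)
  aa[between][aa[between] == "D"] <- "A"
  aa[d0 + 13L] <- "D"
  b0 <- d0 + 80L
  aa[b0] <- "S"; aa[b0 + 1L] <- "G"; aa[b0 + 5L] <- "T"
  c0 <- d0 + 110L
  aa[c0] <- "G"; aa[c0 + 1L] <- "D"; aa[c0 + 2L] <- "D"
  paste0("ATG", paste(aa_to_codon(aa), collapse = ""), sample(STOP_CODONS, 1L))
}

# Spacer drawn from {A,C} only: cannot create a start codon or an SD match.
random_spacer <- function(n) paste(sample(c("A", "C"), n, replace = TRUE), collapse = "")

# Generate a pool of terminal sequences with all pairwise identities at or
# below `max_ident`, by greedy repair of chance matches.
generate_termini_pool <- function(n, len, max_ident) {
  allowed <- floor(max_ident * len)
  pool <- character(0)
  for (i in seq_len(n)) {
    cand <- random_dna(len)
    for (iter in 1:200) {
      offender <- NULL
      for (u in pool) {
        m <- which(charToRaw(cand) == charToRaw(u))
        if (length(m) > allowed) { offender <- m; break }
      }
      if (is.null(offender)) break
      fix <- sample(offender, length(offender) - allowed)
      cand <- mutate_positions(cand, fix)
    }
    pool <- c(pool, cand)
  }
  # verify
  if (length(pool) > 1) {
    for (i in seq_len(length(pool) - 1)) {
      for (j in (i + 1):length(pool)) {
        if (hamming_identity(pool[i], pool[j]) > max_ident) {
          abort("failed to generate terminal pool within identity constraint")
        }
      }
    }
  }
  pool
}

# Introduce mismatches so that identity to the template is ~`ident`.
degrade_terminal <- function(seq, ident) {
  if (ident >= 1) return(seq)
  n_mut <- round((1 - ident) * nchar(seq))
  if (n_mut == 0) return(seq)
  mutate_positions(seq, sample(nchar(seq), n_mut))
}

build_segment <- function(target_len, term5, term3, n_orfs, sd_fraction,
                          min_filler = 8L, orf_min = 156L, rdrp_orf = 0L) {
  tlen <- nchar(term5)
  has_sd <- runif(n_orfs) < sd_fraction
  spacer <- ifelse(has_sd, sample(4:14, n_orfs, replace = TRUE), 0L)
  overhead <- nchar(STOP_CASSETTE) + ifelse(has_sd, nchar(SD_CONSENSUS) + spacer, 0L)
  orf_min_vec <- rep(orf_min, n_orfs)
  if (rdrp_orf > 0L) orf_min_vec[rdrp_orf] <- 480L
  budget <- target_len - 2L * tlen - sum(overhead) - (n_orfs + 1L) * min_filler
  if (budget < sum(orf_min_vec)) {
    abort(sprintf(
      "infeasible parameters: %d ORFs (min total %d nt) cannot fit in a %d nt segment",
      n_orfs, sum(orf_min_vec), target_len), class = "segvir_infeasible")
  }
  # split extra codons over ORFs (roughly 70%), the remainder widens fillers
  extra_codons <- (budget - sum(orf_min_vec)) %/% 3L
  orf_extra <- floor(extra_codons * 0.7)
  shares <- if (n_orfs == 1L) orf_extra else {
    cuts <- sort(sample(0:orf_extra, n_orfs - 1L, replace = TRUE))
    diff(c(0L, cuts, orf_extra))
  }
  orf_len <- orf_min_vec + 3L * shares
  fill_total <- target_len - 2L * tlen - sum(overhead) - sum(orf_len)
  stopifnot(fill_total >= (n_orfs + 1L) * min_filler)
  fill_extra <- fill_total - (n_orfs + 1L) * min_filler
  fcuts <- if (n_orfs == 0L) integer(0) else sort(sample(0:fill_extra, n_orfs, replace = TRUE))
  fill_len <- min_filler + diff(c(0L, fcuts, fill_extra))

  parts <- character(0)
  cursor <- 0L
  push <- function(s) {
    parts[[length(parts) + 1L]] <<- s
    cursor <<- cursor + nchar(s)
  }
  push(term5)
  orfs <- vector("list", n_orfs)
  for (i in seq_len(n_orfs)) {
    push(random_dna(fill_len[i]))
    push(STOP_CASSETTE)
    if (has_sd[i]) {
      push(SD_CONSENSUS)
      push(random_spacer(spacer[i]))
    }
    start <- cursor
    push(if (i == rdrp_orf) rdrp_orf_seq(orf_len[i]) else random_orf_seq(orf_len[i]))
    sp <- if (has_sd[i]) spacer[i] else NA_integer_
    orfs[[i]] <- tibble(
      start = start, end = cursor, strand = "+",
      has_sd = has_sd[i], sd_spacer = as.integer(sp),
      is_rdrp = i == rdrp_orf
    )
  }
  push(random_dna(fill_len[n_orfs + 1L]))
  push(term3)
  seq <- paste(parts, collapse = "")
  stopifnot(nchar(seq) == target_len)
  list(seq = seq, orfs = list_rbind(orfs))
}

#' Simulate a synthetic multipartite dsRNA virome with ground truth
#'
#' Generates coding-strand genome segments for `n_viruses` viruses. Segments
#' of one virus share a 5' terminal sequence and a 3' terminal sequence at
#' identity >= `terminal_identity_within`; terminal sequences of different
#' viruses agree at no more than `terminal_identity_between`. Each segment
#' carries the requested number of non-overlapping ORFs on the coding strand;
#' SD-flagged ORFs are preceded by the AGGAGG consensus at a spacer of 4-14
#' nt before the start codon (genetic code 11 starts ATG/GTG/TTG).
#'
#' @param params A [sim_params()] object.
#' @return A list of class `segvir_truth` with tibbles `genomes` (virus_id,
#'   segment_id, sample_id, seq, length, depth, complete_5p, complete_3p),
#'   `termini` (segment_id, end5, end3; 0-based, half-open), `orfs`
#'   (segment_id, start, end, strand, has_sd, sd_spacer), `bins`
#'   (segment_id, virus_id) and `coverages` (segment_id, depth), plus the
#'   generating `params`.
#' @export
simulate_virome <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  nv <- params$n_viruses
  tl <- params$terminal_length
  pool <- generate_termini_pool(2L * nv, tl, params$terminal_identity_between)
  term5 <- pool[seq_len(nv)]
  term3 <- pool[nv + seq_len(nv)]

  genomes <- list()
  orfs <- list()
  for (v in seq_len(nv)) {
    n_seg <- sample_range_int(params$segments_per_virus)
    sample_id <- sprintf("S%d", ((v - 1L) %% params$n_samples) + 1L)
    virus_depth <- runif(1, params$depth_per_virus[1], params$depth_per_virus[2])
    for (s in seq_len(n_seg)) {
      seg_id <- sprintf("V%02d_RNA%d", v, s)
      L <- sample_range_int(params$segment_length)
      n_orfs <- sample_range_int(params$orfs_per_segment)
      t5 <- degrade_terminal(term5[v], params$terminal_identity_within)
      t3 <- degrade_terminal(term3[v], params$terminal_identity_within)
      built <- build_segment(L, t5, t3, n_orfs, params$sd_fraction,
                             rdrp_orf = if (params$plant_rdrp && s == 1L) 1L else 0L)
      truncated <- runif(1) < params$truncate_fraction
      side <- if (truncated) sample(c("5p", "3p"), 1L) else NA_character_
      genomes[[seg_id]] <- tibble(
        virus_id = sprintf("V%02d", v),
        segment_id = seg_id,
        sample_id = sample_id,
        seq = built$seq,
        length = L,
        depth = round(virus_depth * 2^runif(1, -0.4, 0.4), 3),
        complete_5p = !(truncated && side == "5p"),
        complete_3p = !(truncated && side == "3p")
      )
      orfs[[seg_id]] <- mutate(built$orfs, segment_id = seg_id, .before = 1)
    }
  }
  genomes <- list_rbind(genomes)
  orfs <- list_rbind(orfs)
  truth <- list(
    genomes = genomes,
    termini = tibble(segment_id = genomes$segment_id, end5 = 0L,
                     end3 = genomes$length),
    orfs = orfs,
    bins = select(genomes, "segment_id", "virus_id"),
    coverages = select(genomes, "segment_id", depth = "depth"),
    params = params
  )
  structure(truth, class = "segvir_truth")
}

#' @export
print.segvir_truth <- function(x, ...) {
  cat(sprintf("<segvir_truth> %d viruses, %d segments, %d planted ORFs\n",
              dplyr::n_distinct(x$genomes$virus_id), nrow(x$genomes),
              nrow(x$orfs)))
  invisible(x)
}

# One molecule's fragment breakpoints within [mol_start, mol_end). Interior
# fragments are at least a read long; the terminal remainder may be shorter
# (down to 50 nt, smaller slivers are absorbed), producing the short
# fragments whose reads run through into the ligated adapter.
fragment_molecule <- function(mol_start, mol_end, frag_mean, read_length) {
  sdv <- 0.2 * frag_mean
  cuts <- mol_start
  pos <- mol_start
  while (pos < mol_end) {
    len <- max(read_length, round(rnorm(1, frag_mean, sdv)))
    nxt <- min(pos + len, mol_end)
    if (mol_end - nxt < 50L) nxt <- mol_end
    cuts <- c(cuts, nxt)
    pos <- nxt
  }
  cbind(head(cuts, -1L), tail(cuts, -1L))
}

#' Simulate FLDS-like paired reads from a synthetic virome
#'
#' Emulates the library structure of fragmented, adapter-ligated dsRNA
#' sequencing. Each genome copy (molecule) is broken at random positions into
#' ~`fragment_length_mean` fragments; the first and last fragments of a
#' complete molecule end exactly at the true segment termini, which is the
#' read-stop signal the terminus caller detects. Both strands of every
#' fragment are read from their own 5' end; the U2 adapter
#' (GACGTAAGAACGTCGCACCA) is appended at each strand's 3' end before
#' truncation to `read_length`, so reads from fragments shorter than the read
#' length carry an adapter suffix. Substitution errors are applied at
#' `error_rate`. Provenance columns record the true source interval of every
#' read on its segment.
#'
#' @param truth A `segvir_truth` from [simulate_virome()].
#' @param params The same [sim_params()] used to build `truth`.
#' @return A tibble with one row per read: `read_id`, `mate` (1 = plus
#'   strand of the fragment, 2 = minus strand), `seq`, `qual`, `segment_id`,
#'   `strand`, `src_start`, `src_end` (0-based half-open on the coding
#'   strand), `frag_start`, `frag_end`, `has_adapter`, `n_errors`.
#' @export
simulate_flds_reads <- function(truth, params) {
  stopifnot(inherits(truth, "segvir_truth"), inherits(params, "sim_params"))
  if (nrow(truth$genomes) == 0L) abort("`truth` contains no segments")
  set.seed(params$seed + 1L)
  rl <- params$read_length
  out <- vector("list", nrow(truth$genomes))
  for (g in seq_len(nrow(truth$genomes))) {
    row <- truth$genomes[g, ]
    L <- row$length
    # draw molecules until the realised read bases reach the target depth,
    # so the simulated mean coverage tracks the declared per-segment depth
    target_bases <- row$depth * L
    got_bases <- 0
    frags <- list()
    m <- 0L
    # a truncated segment models a molecule population that has lost a
    # substantial, variable portion of one end (up to a quarter of its
    # length), the regime in which degraded ends share no common stop
    # position; lightly nibbled ends would present a genuine new terminus
    # and are not what the truncation flag means
    ragged_span <- max(500L, round(L / 4))
    while (got_bases < target_bases) {
      m <- m + 1L
      mol_start <- 0L
      mol_end <- L
      if (!row$complete_5p) mol_start <- sample(seq_len(ragged_span), 1L)
      if (!row$complete_3p) mol_end <- L - sample(seq_len(ragged_span), 1L)
      if (row$complete_5p && runif(1) > params$terminal_capture_rate) {
        mol_start <- mol_start + sample(1:8, 1L)
      }
      if (row$complete_3p && runif(1) > params$terminal_capture_rate) {
        mol_end <- mol_end - sample(1:8, 1L)
      }
      if (mol_end - mol_start < rl) next
      fr <- fragment_molecule(mol_start, mol_end, params$fragment_length_mean, rl)
      got_bases <- got_bases + sum(2L * pmin(rl, fr[, 2] - fr[, 1]))
      frags[[length(frags) + 1L]] <- cbind(fr, m)
    }
    fr <- do.call(rbind, frags)
    if (is.null(fr)) next
    f0 <- fr[, 1]; f1 <- fr[, 2]; mol <- fr[, 3]
    flen <- f1 - f0
    short <- flen < rl
    # plus-strand read: fragment 5'->3' on the coding strand
    p_src0 <- f0
    p_src1 <- ifelse(short, f1, f0 + rl)
    p_core <- substring(row$seq, p_src0 + 1L, p_src1)
    p_seq <- ifelse(short,
                    substr(paste0(p_core, U2_SEQ), 1L, rl),
                    p_core)
    # minus-strand read: reverse complement, read from the fragment's other end
    m_src0 <- ifelse(short, f0, f1 - rl)
    m_src1 <- f1
    m_core <- revcomp(substring(row$seq, m_src0 + 1L, m_src1))
    m_seq <- ifelse(short,
                    substr(paste0(m_core, U2_SEQ), 1L, rl),
                    m_core)
    frag_idx <- stats::ave(mol, mol, FUN = seq_along)
    ids <- sprintf("%s_m%04d_f%02d", row$segment_id, mol, frag_idx)
    seg_tbl <- tibble(
      read_id = c(paste0(ids, "/1"), paste0(ids, "/2")),
      mate = rep(c(1L, 2L), each = length(ids)),
      seq = c(p_seq, m_seq),
      segment_id = row$segment_id,
      strand = rep(c("+", "-"), each = length(ids)),
      src_start = c(p_src0, m_src0),
      src_end = c(p_src1, m_src1),
      frag_start = rep(f0, 2L),
      frag_end = rep(f1, 2L),
      has_adapter = rep(short, 2L)
    )
    out[[g]] <- seg_tbl
  }
  reads <- list_rbind(out)
  if (nrow(reads) == 0L) abort("no reads simulated; increase depth or lengths")
  # substitution errors
  n_err <- rbinom(nrow(reads), nchar(reads$seq), params$error_rate)
  idx <- which(n_err > 0L)
  if (length(idx)) {
    reads$seq[idx] <- vapply(idx, function(i) {
      mutate_positions(reads$seq[i], sample(nchar(reads$seq[i]), n_err[i]))
    }, "")
  }
  reads$n_errors <- n_err
  reads$qual <- strrep("F", nchar(reads$seq))
  select(reads, "read_id", "mate", "seq", "qual", "segment_id", "strand",
         "src_start", "src_end", "frag_start", "frag_end", "has_adapter",
         "n_errors")
}
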