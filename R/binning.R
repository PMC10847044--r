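global_align <- function(x, y) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  Biostrings::pairwiseAlignment(Biostrings::DNAString(x),
                                Biostrings::DNAString(y),
                                type = "global", substitutionMatrix = mat,
                                gapOpening = 5, gapExtension = 2)
}

# matches / alignment columns of a global alignment
global_identity <- function(x, y) {
  aln <- global_align(x, y)
  Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

#' Orient a segment to its coding strand
#'
#' The coding strand of a dsRNA segment is taken to be the strand whose
#' three forward reading frames carry the greater total length of ORFs
#' (genetic code 11 starts, minimum ORF `min_orf_len` nt), after shadow
#' resolution: candidate ORFs from both strands are accepted longest-first,
#' and a candidate overlapping an already accepted, longer ORF of the other
#' strand by more than half its length is discarded. Stop codons are
#' depleted on both strands of a genuine gene, so unresolved reverse-strand
#' "shadow" ORFs would otherwise inflate the wrong strand's score. Ties
#' keep the input orientation; segments with no ORF on either strand are
#' kept as input and flagged low-confidence.
#'
#' @param segments Segment tibble with `contig_id` and `seq` columns (e.g.
#'   from [classify_segments()]).
#' @param min_orf_len Minimum ORF length in nt used for the comparison.
#' @return The tibble with `seq` possibly reverse-complemented and added
#'   columns `flipped` and `orient_confidence` ("ok" or "low").
#' @export
orient_coding_strand <- function(segments, min_orf_len = 150L) {
  stopifnot(all(c("contig_id", "seq") %in% names(segments)))
  score <- function(seq) strand_orf_scores(seq, min_orf_len)
  sc <- lapply(segments$seq, score)
  fwd <- vapply(sc, `[[`, 0, "fwd")
  rev <- vapply(sc, `[[`, 0, "rev")
  rc <- revcomp(segments$seq)
  flip <- rev > fwd
  out <- segments
  out$seq <- ifelse(flip, rc, segments$seq)
  out$flipped <- flip
  out$orient_confidence <- ifelse(fwd == 0 & rev == 0, "low", "ok")
  out
}

# Per-strand total ORF length after cross-strand shadow resolution.
strand_orf_scores <- function(seq, min_orf_len = 150L) {
  L <- nchar(seq)
  f <- find_orfs(seq, min_orf_len)
  r <- find_orfs(revcomp(seq), min_orf_len)
  cand <- rbind(
    if (nrow(f)) data.frame(start = f$start, end = f$end, strand = "+"),
    if (nrow(r)) data.frame(start = L - r$end, end = L - r$start,
                            strand = "-")
  )
  if (is.null(cand) || nrow(cand) == 0L) return(list(fwd = 0, rev = 0))
  cand <- cand[order(-(cand$end - cand$start)), , drop = FALSE]
  acc <- cand[0, ]
  for (i in seq_len(nrow(cand))) {
    len_i <- cand$end[i] - cand$start[i]
    other <- acc[acc$strand != cand$strand[i], , drop = FALSE]
    ov <- 0
    if (nrow(other)) {
      ov <- max(pmin(other$end, cand$end[i]) - pmax(other$start, cand$start[i]))
    }
    if (ov <= 0.5 * len_i) acc <- rbind(acc, cand[i, ])
  }
  lens <- acc$end - acc$start
  list(fwd = sum(lens[acc$strand == "+"]), rev = sum(lens[acc$strand == "-"]))
}

#' Terminal sequence identity between two oriented segments
#'
#' Globally aligns the first `window` nt (5' side) and the last `window` nt
#' (3' side) of the two coding strands; identity is matches over alignment
#' columns. If a segment is shorter than `window` the window is shrunk to
#' the shorter length and recorded.
#'
#' @param a,b Coding-strand sequences.
#' @param window Terminal window length in nt.
#' @param link_threshold Minimum identity for the pair to be linked.
#' @param require_ends `"both"` links a pair only when both the 5' and 3'
#'   identities reach the threshold; `"5p"` uses the 5' side only (for
#'   virus groups that conserve only the 5' terminus).
#' @return One-row tibble: `identity_5`, `identity_3`, `linked`,
#'   `window_used`.
#' @export
terminal_identity <- function(a, b, window = 30L, link_threshold = 0.6,
                              require_ends = c("both", "5p")) {
  require_ends <- match.arg(require_ends)
  w <- min(window, nchar(a), nchar(b))
  id5 <- global_identity(substr(a, 1L, w), substr(b, 1L, w))
  id3 <- global_identity(substr(a, nchar(a) - w + 1L, nchar(a)),
                         substr(b, nchar(b) - w + 1L, nchar(b)))
  crit <- if (require_ends == "both") min(id5, id3) else id5
  tibble(identity_5 = id5, identity_3 = id3,
         linked = crit >= link_threshold, window_used = w)
}

#' All pairwise terminal identities among segments
#'
#' @param segments Oriented segment tibble (`contig_id`, `seq`).
#' @inheritParams terminal_identity
#' @return Tibble with `a`, `b` (contig ids, a < b), `identity_5`,
#'   `identity_3`, `linked`, `window_used`.
#' @export
terminal_identities <- function(segments, window = 30L, link_threshold = 0.6,
                                require_ends = c("both", "5p")) {
  require_ends <- match.arg(require_ends)
  ids <- sort(segments$contig_id)
  seqs <- setNames(segments$seq, segments$contig_id)
  if (length(ids) < 2L) {
    return(tibble(a = character(), b = character(), identity_5 = double(),
                  identity_3 = double(), linked = logical(),
                  window_used = integer()))
  }
  pairs <- utils::combn(ids, 2L)
  scores <- map(seq_len(ncol(pairs)), function(j) {
    terminal_identity(seqs[[pairs[1, j]]], seqs[[pairs[2, j]]], window,
                      link_threshold, require_ends)
  })
  bind_cols(tibble(a = pairs[1, ], b = pairs[2, ]), list_rbind(scores))
}

#' Group segments into multipartite virus genome bins
#'
#' Single-linkage clustering of complete segments over pairs whose terminal
#' identities pass `link_threshold`: shared (near-)identical 5'/3' terminal
#' sequences are the hallmark by which segments of one multipartite virus
#' are recognised. Within a bin, members with full-length nucleotide
#' identity >= 0.9, lengths within 10% and ORF counts within +/-1 are
#' grouped as variants of one segment class; distinct classes of similar
#' length in the same bin are flagged as alternative segments (the
#' RNA2/RNA2*-like pattern of homologous segments sharing termini).
#'
#' @param segments Oriented segment tibble (`contig_id`, `seq`, and
#'   optionally `mean_coverage`).
#' @param scores Pairwise identity tibble from [terminal_identities()].
#' @param link_threshold Minimum terminal identity to link a pair.
#' @param require_ends See [terminal_identity()].
#' @param variant_identity Full-length identity at or above which two
#'   same-bin segments are variants of one class.
#' @param min_orf_len Minimum ORF length for the gene-content guard.
#' @return Tibble with `bin_id`, `contig_id`, `class_id`, `is_alternative`.
#' @export
cluster_segments <- function(segments, scores, link_threshold = 0.6,
                             require_ends = c("both", "5p"),
                             variant_identity = 0.9, min_orf_len = 150L) {
  require_ends <- match.arg(require_ends)
  ids <- sort(segments$contig_id)
  crit <- if (require_ends == "both") {
    pmin(scores$identity_5, scores$identity_3)
  } else {
    scores$identity_5
  }
  edges <- scores[crit >= link_threshold, c("a", "b"), drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership
  # canonical bin ids: ordered by smallest member contig id
  first_member <- tapply(names(comp), comp, min)
  bin_rank <- rank(first_member)
  membership <- tibble(
    contig_id = names(comp),
    bin_id = sprintf("bin%02d", bin_rank[as.character(comp)])
  )
  seqs <- setNames(segments$seq, segments$contig_id)
  covs <- if ("mean_coverage" %in% names(segments)) {
    setNames(segments$mean_coverage, segments$contig_id)
  } else {
    setNames(rep(NA_real_, nrow(segments)), segments$contig_id)
  }
  orf_counts <- vapply(seqs, function(s) nrow(find_orfs(s, min_orf_len)), 0L)
  out <- list()
  for (b in sort(unique(membership$bin_id))) {
    members <- sort(membership$contig_id[membership$bin_id == b])
    n <- length(members)
    # variant grouping: single linkage over near-identical same-length pairs
    vg <- igraph::make_empty_graph(n = n, directed = FALSE)
    igraph::V(vg)$name <- members
    if (n > 1L) {
      for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
          la <- nchar(seqs[[members[i]]]); lb <- nchar(seqs[[members[j]]])
          if (abs(la - lb) / max(la, lb) >= 0.1) next
          if (abs(orf_counts[[members[i]]] - orf_counts[[members[j]]]) > 1L) next
          if (global_identity(seqs[[members[i]]], seqs[[members[j]]]) >=
                variant_identity) {
            vg <- igraph::add_edges(vg, c(i, j))
          }
        }
      }
    }
    cls <- igraph::components(vg)$membership
    cls_first <- tapply(members, cls, min)
    cls_rank <- rank(cls_first)
    class_id <- sprintf("%s_c%d", b, cls_rank[as.character(cls)])
    # alternative-segment flag: classes of similar length ranked by coverage
    cls_tbl <- tibble(contig_id = members, class_id = class_id) |>
      mutate(len = nchar(seqs[.data$contig_id]),
             cov = covs[.data$contig_id])
    cls_sum <- cls_tbl |>
      group_by(.data$class_id) |>
      summarise(med_len = stats::median(.data$len),
                tot_cov = sum(.data$cov, na.rm = TRUE), n = n()) |>
      arrange(desc(.data$n), desc(.data$tot_cov), .data$class_id)
    alt <- rep(FALSE, nrow(cls_sum))
    for (i in seq_len(nrow(cls_sum))[-1]) {
      prior <- cls_sum$med_len[seq_len(i - 1L)]
      alt[i] <- any(abs(cls_sum$med_len[i] - prior) / pmax(cls_sum$med_len[i], prior) < 0.1)
    }
    alt_classes <- cls_sum$class_id[alt]
    out[[b]] <- tibble(bin_id = b, contig_id = members, class_id = class_id,
                       is_alternative = class_id %in% alt_classes)
  }
  list_rbind(out)
}

#' Pair segments into virus strains by sample co-occurrence and abundance
#'
#' Segments of different classes in one bin are assigned to the same virus
#' strain when they come from the same sample and have similar abundances:
#' `|log2(coverage_a / coverage_b)| <= max_log2_ratio`. For each pair of
#' classes, candidates are matched greedily from the most similar coverage
#' ratio downward, and a segment is paired with at most one partner per
#' other class (it may pair with partners from several classes, as a strain
#' has one segment of each class). Segments without coverage are excluded
#' with a warning.
#'
#' @param bins Bin membership from [cluster_segments()].
#' @param segments Segment tibble with `contig_id`, `mean_coverage`,
#'   `sample_id`.
#' @param max_log2_ratio Maximum absolute log2 coverage ratio.
#' @return Tibble with `bin_id`, `sample_id`, `a`, `b`, `class_a`,
#'   `class_b`, `coverage_a`, `coverage_b`, `log2_ratio`; unpaired members
#'   are listed in attribute `"unpaired"`.
#' @export
pair_by_abundance <- function(bins, segments, max_log2_ratio = 1.0) {
  info <- left_join(bins, select(segments, "contig_id", "mean_coverage",
                                 "sample_id"), by = "contig_id")
  no_cov <- is.na(info$mean_coverage)
  if (any(no_cov)) {
    warn(sprintf("%d segment(s) lack coverage and are excluded from pairing",
                 sum(no_cov)))
    info <- info[!no_cov, , drop = FALSE]
  }
  pairs <- list()
  for (b in unique(info$bin_id)) {
    for (s in unique(info$sample_id[info$bin_id == b])) {
      sub <- info[info$bin_id == b & info$sample_id == s, , drop = FALSE]
      classes <- sort(unique(sub$class_id))
      if (length(classes) < 2L) next
      for (ci in seq_len(length(classes) - 1L)) {
        for (cj in (ci + 1L):length(classes)) {
          xa <- sub[sub$class_id == classes[ci], , drop = FALSE]
          xb <- sub[sub$class_id == classes[cj], , drop = FALSE]
          cand <- crossing(ia = seq_len(nrow(xa)), ib = seq_len(nrow(xb))) |>
            mutate(ratio = abs(log2(xa$mean_coverage[.data$ia] /
                                      xb$mean_coverage[.data$ib]))) |>
            filter(.data$ratio <= max_log2_ratio) |>
            arrange(.data$ratio)
          used_a <- used_b <- integer(0)
          for (r in seq_len(nrow(cand))) {
            ia <- cand$ia[r]; ib <- cand$ib[r]
            if (ia %in% used_a || ib %in% used_b) next
            used_a <- c(used_a, ia); used_b <- c(used_b, ib)
            pairs[[length(pairs) + 1L]] <- tibble(
              bin_id = b, sample_id = s,
              a = xa$contig_id[ia], b = xb$contig_id[ib],
              class_a = classes[ci], class_b = classes[cj],
              coverage_a = xa$mean_coverage[ia],
              coverage_b = xb$mean_coverage[ib],
              log2_ratio = log2(xa$mean_coverage[ia] / xb$mean_coverage[ib])
            )
          }
        }
      }
    }
  }
  out <- if (length(pairs)) list_rbind(pairs) else {
    tibble(bin_id = character(), sample_id = character(), a = character(),
           b = character(), class_a = character(), class_b = character(),
           coverage_a = double(), coverage_b = double(),
           log2_ratio = double())
  }
  paired_ids <- unique(c(out$a, out$b))
  attr(out, "unpaired") <- setdiff(info$contig_id, paired_ids)
  out
}

#' Center-star alignment of the terminal windows of a bin's members
#'
#' Aligns the 5' windows (and, separately, the 3' windows) of all members of
#' a bin against the longest member (the star), merging pairwise alignments
#' into one multiple alignment, and annotates column-wise conservation (the
#' fraction of members carrying the modal character).
#'
#' @param segments Oriented members of one bin (`contig_id`, `seq`);
#'   at least 2 required.
#' @param window Terminal window length in nt.
#' @return A list of class `segvir_terminal_msa` with elements `"5p"` and
#'   `"3p"`, each holding `alignment` (named character vector of gapped
#'   sequences) and `conservation` (numeric per column).
#' @export
terminal_alignment_view <- function(segments, window = 30L) {
  if (nrow(segments) < 2L) {
    abort("terminal alignment view needs at least 2 bin members")
  }
  star_i <- which.max(nchar(segments$seq))
  take <- function(side) {
    w <- pmin(window, nchar(segments$seq))
    if (side == "5p") substr(segments$seq, 1L, w)
    else substr(segments$seq, nchar(segments$seq) - w + 1L, nchar(segments$seq))
  }
  one_side <- function(side) {
    seqs <- setNames(take(side), segments$contig_id)
    star <- seqs[[star_i]]
    others <- setdiff(seq_along(seqs), star_i)
    alns <- map(others, function(i) {
      a <- global_align(seqs[[i]], star)
      list(mem = as.character(Biostrings::alignedPattern(a)),
           star = as.character(Biostrings::alignedSubject(a)))
    })
    # insertions relative to star coordinates: ins[i] = gap columns before
    # star base i (i = 1..n+1)
    n <- nchar(star)
    ins <- integer(n + 1L)
    per_aln_ins <- map(alns, function(al) {
      ch <- strsplit(al$star, "")[[1]]
      v <- integer(n + 1L)
      bi <- 1L
      run <- 0L
      for (c in ch) {
        if (c == "-") run <- run + 1L
        else { v[bi] <- run; run <- 0L; bi <- bi + 1L }
      }
      v[n + 1L] <- run
      v
    })
    for (v in per_aln_ins) ins <- pmax(ins, v)
    expand <- function(gapped_star, gapped_mem) {
      ch_s <- strsplit(gapped_star, "")[[1]]
      ch_m <- strsplit(gapped_mem, "")[[1]]
      out <- character(0)
      bi <- 1L
      run_cols <- character(0)
      for (k in seq_along(ch_s)) {
        if (ch_s[k] == "-") {
          run_cols <- c(run_cols, ch_m[k])
        } else {
          out <- c(out, run_cols, strrep("-", ins[bi] - length(run_cols)),
                   ch_m[k])
          run_cols <- character(0)
          bi <- bi + 1L
        }
      }
      out <- c(out, run_cols, strrep("-", ins[n + 1L] - length(run_cols)))
      paste(out, collapse = "")
    }
    rows <- setNames(vector("character", length(seqs)), names(seqs))
    rows[[star_i]] <- expand(star, star)
    for (j in seq_along(others)) {
      rows[[others[j]]] <- expand(alns[[j]]$star, alns[[j]]$mem)
    }
    mat <- do.call(rbind, strsplit(rows, ""))
    conservation <- apply(mat, 2, function(col) max(table(col)) / length(col))
    list(alignment = rows, conservation = as.numeric(conservation))
  }
  structure(list(`5p` = one_side("5p"), `3p` = one_side("3p")),
            class = "segvir_terminal_msa")
}

#' @export
print.segvir_terminal_msa <- function(x, ...) {
  for (side in names(x)) {
    cat(sprintf("== %s terminal windows ==\n", side))
    for (nm in names(x[[side]]$alignment)) {
      cat(sprintf("  %-20s %s\n", nm, x[[side]]$alignment[[nm]]))
    }
    cat(sprintf("  conserved columns (>=0.9): %d / %d\n",
                sum(x[[side]]$conservation >= 0.9),
                length(x[[side]]$conservation)))
  }
  invisible(x)
}
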