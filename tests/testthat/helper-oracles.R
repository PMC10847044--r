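# Independent oracle implementations used only to cross-check the package.
# Each deliberately uses a different algorithm/route than the implementation.

# Needleman-Wunsch with linear gap penalty; returns identity
# (matches / alignment columns) of one optimal alignment. Gap penalty 7
# mirrors the package's affine 5+2 cost for a single-base gap.
oracle_nw_identity <- function(a, b, match = 1, mismatch = -1, gap = -7) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- gap * (0:n)
  S[1, ] <- gap * (0:m)
  for (i in 1:n) {
    for (j in 1:m) {
      d <- S[i, j] + if (x[i] == y[j]) match else mismatch
      S[i + 1, j + 1] <- max(d, S[i, j + 1] + gap, S[i + 1, j] + gap)
    }
  }
  # traceback
  i <- n; j <- m; matches <- 0L; cols <- 0L
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + (if (x[i] == y[j]) match else mismatch)) {
      matches <- matches + (x[i] == y[j])
      i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] + gap) {
      i <- i - 1
    } else {
      j <- j - 1
    }
    cols <- cols + 1L
  }
  matches / cols
}

# Hamming identity over equal-length strings (for generated termini).
oracle_hamming_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  mean(ca == cb)
}

# Naive ORF scan: every position with a start codon is extended to the first
# in-frame stop (or the last full codon); then keep ORFs >= min_len and, per
# end position, the longest (earliest start).
oracle_find_orfs <- function(seq, min_len = 150L) {
  starts <- c("ATG", "GTG", "TTG")
  stops <- c("TAA", "TAG", "TGA")
  L <- nchar(seq)
  cand <- list()
  for (p in 0:(L - 3)) {
    cod <- substr(seq, p + 1, p + 3)
    if (!cod %in% starts) next
    q <- p
    end <- NA
    open <- TRUE
    while (q + 3 <= L) {
      cq <- substr(seq, q + 1, q + 3)
      if (cq %in% stops && q > p) { end <- q + 3; open <- FALSE; break }
      if (cq %in% stops && q == p) break  # start codon is never a stop; safety
      q <- q + 3
    }
    if (open) end <- p + 3 * ((L - p) %/% 3)
    if (!is.na(end) && end - p >= min_len) {
      cand[[length(cand) + 1]] <- data.frame(start = p, end = end, open_3p = open)
    }
  }
  if (!length(cand)) {
    return(data.frame(start = integer(), end = integer(), open_3p = logical()))
  }
  df <- do.call(rbind, cand)
  # longest per stop position = smallest start per (end, frame)
  df$frame <- df$start %% 3
  keep <- do.call(rbind, lapply(split(df, paste(df$end, df$frame)), function(g) {
    g[which.min(g$start), ]
  }))
  keep <- keep[order(keep$start), c("start", "end", "open_3p")]
  rownames(keep) <- NULL
  keep
}

# Regex-based motif oracle with overlap-aware lookahead.
oracle_motif_positions <- function(protein, pattern) {
  m <- gregexpr(paste0("(?=", pattern, ")"), protein, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

# Exhaustive adapter-trim oracle: consider every full-adapter internal match
# and every suffix/prefix overlap; the cut is the leftmost/minimum over all
# qualifying candidates and adapters.
oracle_trim_cut <- function(seq, adapters) {
  n <- nchar(seq)
  cuts <- n
  for (ad in adapters) {
    a <- ad$sequence
    alen <- nchar(a)
    mm_full <- floor(ad$max_mismatch_rate * alen)
    if (n >= alen) {
      for (p in 0:(n - alen)) {
        d <- sum(strsplit(substr(seq, p + 1, p + alen), "")[[1]] !=
                   strsplit(a, "")[[1]])
        if (d <= mm_full) cuts <- c(cuts, p)
      }
    }
    for (ov in ad$min_overlap:min(n, alen)) {
      d <- sum(strsplit(substr(seq, n - ov + 1, n), "")[[1]] !=
                 strsplit(substr(a, 1, ov), "")[[1]])
      if (d / ov <= ad$max_mismatch_rate) cuts <- c(cuts, n - ov)
    }
  }
  min(cuts)
}

# All-window Kyte-Doolittle means by direct summation.
oracle_kd_windows <- function(protein, window = 19L) {
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
          G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
          P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
  aa <- strsplit(protein, "")[[1]]
  v <- kd[aa]
  v[is.na(v)] <- 0
  n <- length(v)
  vapply(seq_len(n - window + 1L), function(i) mean(v[i:(i + window - 1L)]), 0)
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein_str <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
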