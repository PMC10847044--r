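DNA_BASES <- c("A", "C", "G", "T")

# U2 adapter ligated to the 3' end of fragmented dsRNA, and its reverse
# complement primer; both occur as read suffixes depending on cDNA strand.
U2_SEQ <- "GACGTAAGAACGTCGCACCA"
U2_COMP_SEQ <- "TGGTGCGACGTTCTTACGTC"

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Count mismatches between two equal-length strings
#' @noRd
str_mismatches <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  sum(ra != rb)
}

# Fraction of identical positions between equal-length strings.
hamming_identity <- function(a, b) {
  n <- nchar(a)
  if (n == 0L) return(NA_real_)
  1 - str_mismatches(a, b) / n
}

# Substitute bases at given 1-based positions with a different random base.
mutate_positions <- function(seq, pos) {
  if (length(pos) == 0L) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(DNA_BASES, b), 1L), "")
  paste(ch, collapse = "")
}

assert_scalar_count <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) ||
      (positive && x <= 0)) {
    abort(sprintf("`%s` must be a single positive integer", name))
  }
  invisible(as.integer(x))
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single value in [0, 1]", name))
  }
  invisible(as.numeric(x))
}

# Normalise a scalar-or-length-2 numeric into an inclusive range.
as_range <- function(x, name) {
  if (!is.numeric(x) || !length(x) %in% 1:2 || anyNA(x)) {
    abort(sprintf("`%s` must be a numeric scalar or length-2 range", name))
  }
  r <- range(x)
  if (r[1] <= 0) abort(sprintf("`%s` must be positive", name))
  r
}

sample_range_int <- function(r) {
  if (r[1] == r[2]) return(as.integer(r[1]))
  sample(seq.int(r[1], r[2]), 1L)
}

check_dna <- function(x, name = "sequence", allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !str_detect(str_to_upper(x), pat)
  if (any(bad)) {
    abort(sprintf("`%s` contains non-ACGT%s characters (first offender: %s)",
                  name, if (allow_n) "N" else "", which(bad)[1]))
  }
  invisible(str_to_upper(x))
}

# tibble of contigs from a named character vector or tibble/data.frame
as_contig_tbl <- function(contigs) {
  if (is.data.frame(contigs)) {
    stopifnot(all(c("contig_id", "seq") %in% names(contigs)))
    return(as_tibble(contigs[, c("contig_id", "seq")]))
  }
  if (inherits(contigs, "DNAStringSet")) {
    return(tibble(contig_id = names(contigs), seq = as.character(contigs)))
  }
  if (is.character(contigs)) {
    if (is.null(names(contigs))) abort("character contigs must be named")
    return(tibble(contig_id = names(contigs), seq = unname(contigs)))
  }
  abort("`contigs` must be a tibble with contig_id/seq, a named character vector or a DNAStringSet")
}
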