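# Construct a stop profile directly from alignment stacks on a random contig.
mk_profile <- function(L = 2000L, stacks = list(), background = 0L,
                       seed = 301L) {
  set.seed(seed)
  contigs <- tibble::tibble(contig_id = "c1", seq = random_dna_str(L))
  aln <- list(tibble::tibble(read_id = character(), contig_id = character(),
                             start = integer(), end = integer(),
                             strand = character(), n_mismatches = integer()))
  for (s in stacks) {
    aln[[length(aln) + 1L]] <- tibble::tibble(
      read_id = sprintf("stk%d_%d", s$start, seq_len(s$n)),
      contig_id = "c1",
      start = rep(s$start, s$n), end = rep(s$end, s$n),
      strand = "+", n_mismatches = 0L)
  }
  if (background > 0L) {
    st <- sample(0:(L - 301L), background, replace = TRUE)
    aln[[length(aln) + 1L]] <- tibble::tibble(
      read_id = sprintf("bg%d", seq_len(background)), contig_id = "c1",
      start = st, end = st + 300L, strand = "+", n_mismatches = 0L)
  }
  list(contigs = contigs,
       profile = build_stop_profile(dplyr::bind_rows(aln), contigs))
}

# Brute-force terminus caller: scan every candidate position on both sides.
oracle_call <- function(profile, min_stop_reads = 10, end_window = 50,
                        min_dominance = 0.2) {
  out <- list()
  for (cid in unique(profile$contig_id)) {
    p <- profile[profile$contig_id == cid, ]
    L <- max(p$pos)
    best <- list(`5p` = NULL, `3p` = NULL)
    for (pos in p$pos) {
      for (side in c("5p", "3p")) {
        count <- if (side == "5p") p$starts[p$pos == pos] else p$ends[p$pos == pos]
        dist <- if (side == "5p") pos else L - pos
        if (dist >= end_window) next
        cov <- if (side == "5p") p$coverage[p$pos == pos]
               else p$coverage[p$pos == pos - 1]
        dom <- min(1, count / max(cov, 1))
        if (count > min_stop_reads && dom >= min_dominance) {
          b <- best[[side]]
          if (is.null(b) || count > b$count ||
              (count == b$count && dist < b$dist)) {
            best[[side]] <- list(pos = pos, count = count, dist = dist)
          }
        }
      }
    }
    for (side in c("5p", "3p")) {
      if (!is.null(best[[side]])) {
        out[[length(out) + 1L]] <- data.frame(contig_id = cid, side = side,
                                              position = best[[side]]$pos)
      }
    }
  }
  if (!length(out)) return(data.frame(contig_id = character(),
                                      side = character(),
                                      position = integer()))
  do.call(rbind, out)
}

test_that("the stop-count threshold is strict: 10 stops no call, 11 and 12 call", {
  for (n in c(10L, 11L, 12L)) {
    px <- mk_profile(stacks = list(list(start = 1700L, end = 2000L, n = n)),
                     background = 30L)
    calls <- call_termini(px$profile)
    got3 <- calls[calls$side == "3p", ]
    if (n == 10L) {
      expect_equal(nrow(got3), 0)
    } else {
      expect_equal(got3$position, 2000)
      expect_equal(got3$stop_count, n)
    }
  }
})

test_that("the strongest stack wins within the window", {
  px <- mk_profile(stacks = list(
    list(start = 1690L, end = 1990L, n = 15),
    list(start = 1660L, end = 1960L, n = 40)
  ))
  calls <- call_termini(px$profile)
  got3 <- calls[calls$side == "3p", ]
  expect_equal(got3$position, 1960)
  expect_equal(got3$stop_count, 40)
})

test_that("dominance suppresses minor stacks under deep local coverage", {
  # 12 stops under ~300x local coverage: dominance ~0.04 < 0.2
  px <- mk_profile(stacks = list(list(start = 1650L, end = 1950L, n = 12)),
                   background = 2000L)
  calls <- call_termini(px$profile)
  expect_equal(nrow(calls[calls$side == "3p" & calls$position == 1950, ]), 0)
})

test_that("call_termini equals the brute-force scan on simulated fixtures", {
  fx <- get_fixture("small")
  got <- call_termini(fx$profile)
  want <- oracle_call(fx$profile)
  got_key <- sort(paste(got$contig_id, got$side, got$position))
  want_key <- sort(paste(want$contig_id, want$side, want$position))
  expect_equal(got_key, want_key)
})

test_that("raising min_stop_reads only removes calls (monotonicity)", {
  fx <- get_fixture("small")
  thresholds <- c(5, 10, 50, 200, 1000)
  prev <- NULL
  for (th in thresholds) {
    calls <- call_termini(fx$profile, min_stop_reads = th)
    key <- paste(calls$contig_id, calls$side, calls$position)
    if (!is.null(prev)) expect_true(all(key %in% prev))
    prev <- key
  }
})

test_that("an oversized end window is a parameter error", {
  px <- mk_profile(L = 300L)
  expect_error(call_termini(px$profile, end_window = 150L), "end_window")
})

test_that("segment status follows the two-termini rule", {
  px <- mk_profile(stacks = list(
    list(start = 0L, end = 300L, n = 20),
    list(start = 1700L, end = 2000L, n = 20)
  ), background = 50L)
  calls <- call_termini(px$profile)
  seg <- classify_segments(px$contigs, calls, px$profile)
  expect_equal(seg$status, "complete")
  expect_equal(nchar(seg$seq), 2000)

  only5 <- call_termini(px$profile)
  only5 <- only5[only5$side == "5p", ]
  seg5 <- classify_segments(px$contigs, only5, px$profile)
  expect_equal(seg5$status, "partial_3")
  only3 <- calls[calls$side == "3p", ]
  seg3 <- classify_segments(px$contigs, only3, px$profile)
  expect_equal(seg3$status, "partial_5")
  none <- calls[0, ]
  seg0 <- classify_segments(px$contigs, none, px$profile)
  expect_equal(seg0$status, "incomplete")
  # termini from an unknown contig are a consistency error
  alien <- calls
  alien$contig_id <- "nope"
  expect_error(classify_segments(px$contigs, alien, px$profile),
               class = "segvir_consistency_error")
})

test_that("complete segments are trimmed to the called terminus interval", {
  px <- mk_profile(stacks = list(
    list(start = 5L, end = 305L, n = 30),
    list(start = 1660L, end = 1960L, n = 30)
  ), background = 50L)
  calls <- call_termini(px$profile)
  seg <- classify_segments(px$contigs, calls, px$profile)
  expect_equal(seg$status, "complete")
  expect_equal(seg$seq, substr(px$contigs$seq, 6, 1960))
})

test_that("the major flag uses a strict 1000x mean-coverage bound", {
  mk_cov_profile <- function(cov) {
    L <- 2000L
    n <- ceiling(cov * L / 300)
    starts <- rep(seq(0L, L - 300L, length.out = n) |> round(), 1)
    aln <- tibble::tibble(read_id = sprintf("r%d", seq_len(n)),
                          contig_id = "c1", start = as.integer(starts),
                          end = as.integer(starts + 300L), strand = "+",
                          n_mismatches = 0L)
    stack5 <- tibble::tibble(read_id = sprintf("t5_%d", 1:30),
                             contig_id = "c1", start = 0L, end = 300L,
                             strand = "+", n_mismatches = 0L)
    stack3 <- tibble::tibble(read_id = sprintf("t3_%d", 1:30),
                             contig_id = "c1", start = 1700L, end = 2000L,
                             strand = "+", n_mismatches = 0L)
    contigs <- tibble::tibble(contig_id = "c1", seq = strrep("A", 2000L))
    build_stop_profile(dplyr::bind_rows(aln, stack5, stack3), contigs)
  }
  contigs <- tibble::tibble(contig_id = "c1", seq = strrep("A", 2000L))
  for (cov in c(1500, 800)) {
    prof <- mk_cov_profile(cov)
    calls <- call_termini(prof, min_dominance = 0)
    seg <- classify_segments(contigs, calls, prof)
    expect_equal(seg$status, "complete")
    expect_equal(seg$is_major, cov > 1000, label = sprintf("cov %d", cov))
  }
})

test_that("termini are recovered exactly on simulated data", {
  fx <- get_fixture("small")
  g <- fx$truth$genomes
  seg <- fx$segments
  expect_equal(sum(seg$status == "complete"), nrow(g))
  expect_true(all(seg$t5 == 0))
  expect_equal(seg$t3, g$length[match(seg$contig_id, g$segment_id)])
  # recovered complete sequence equals the truth sequence
  expect_equal(seg$seq, g$seq[match(seg$contig_id, g$segment_id)])
})

test_that("segments with one ragged end are never called complete", {
  p <- small_sim_params(seed = 57L, truncate_fraction = 0.5)
  fx <- build_processed_fixture(p)
  g <- fx$truth$genomes
  truncated <- g$segment_id[!(g$complete_5p & g$complete_3p)]
  expect_gt(length(truncated), 0)
  called <- fx$segments
  expect_true(all(called$status[called$contig_id %in% truncated] != "complete"))
  # the intact side is still found
  g3 <- g[!g$complete_5p & g$complete_3p, ]
  if (nrow(g3)) {
    st <- called[called$contig_id %in% g3$segment_id, ]
    expect_true(all(st$status == "partial_5"))
  }
})

test_that("segment report rows are internally consistent", {
  fx <- get_fixture("small")
  path <- tempfile(fileext = ".tsv")
  rep <- segment_report(fx$segments, path)
  expect_true(file.exists(path))
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(fx$segments))
  expect_equal(sum(back$status == "complete"),
               sum(fx$segments$status == "complete"))
  empty <- segment_report(fx$segments[0, ])
  expect_equal(nrow(empty), 0)
})
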