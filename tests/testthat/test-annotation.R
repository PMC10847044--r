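test_that("a constructed ORF is found at exact coordinates", {
  set.seed(601)
  # padding free of start codons (pyrimidine-rich), then a clean ORF
  pad <- strrep("TCC", 60)
  orf <- paste0("ATG", strrep("GCA", 60), "TAA")
  seq <- paste0(pad, orf, pad)
  got <- find_orfs(seq, min_orf_len = 150)
  expect_equal(nrow(got), 1)
  expect_equal(got$start, nchar(pad))
  expect_equal(got$end, nchar(pad) + nchar(orf))
  expect_equal(got$start_codon, "ATG")
  expect_false(got$open_3p)
  expect_equal(got$protein, paste0("M", strrep("A", 60)))
  expect_error(find_orfs("ACGTXN"), "non-ACGT")
})

test_that("ORF finder equals the brute-force three-frame oracle", {
  set.seed(602)
  got_all <- list()
  want_all <- list()
  for (i in 1:100) {
    seq <- random_dna_str(sample(300:1200, 1))
    got <- find_orfs(seq, min_orf_len = 90)
    want <- oracle_find_orfs(seq, min_len = 90)
    got_all[[i]] <- data.frame(case = rep(i, nrow(got)), start = got$start,
                               end = got$end, open_3p = got$open_3p)
    want_all[[i]] <- data.frame(case = rep(i, nrow(want)), start = want$start,
                                end = want$end, open_3p = want$open_3p)
  }
  expect_equal(do.call(rbind, got_all), do.call(rbind, want_all),
               ignore_attr = TRUE)
})

test_that("planted ORFs are recovered exactly on simulated genomes", {
  truth <- get_sd_truth()$truth
  recovered <- 0L
  for (sid in truth$genomes$segment_id) {
    seq <- truth$genomes$seq[truth$genomes$segment_id == sid]
    called <- find_orfs(seq)
    key <- paste(called$start, called$end)
    planted <- truth$orfs[truth$orfs$segment_id == sid, ]
    recovered <- recovered + sum(paste(planted$start, planted$end) %in% key)
  }
  expect_gte(recovered / nrow(truth$orfs), 0.95)
})

test_that("ORF calls are consistent after reverse-complement re-orientation", {
  truth <- get_fixture("small")$truth
  seq <- truth$genomes$seq[1]
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  ori <- orient_coding_strand(tibble::tibble(contig_id = "s", seq = rc))
  expect_true(ori$flipped)
  expect_equal(find_orfs(ori$seq), find_orfs(seq))
})

test_that("SD detection matches constructed cases", {
  set.seed(603)
  # AGGAGG ending 8 nt before the start codon; spacer from {C,A} only
  up <- paste0(random_dna_str(20), "AGGAGG", "CACCACAC")
  seq <- paste0(up, "ATG", strrep("GCA", 60), "TAA")
  sd <- detect_sd(seq, nchar(up))
  expect_true(sd$sd_found)
  expect_equal(sd$sd_spacer, 8)
  expect_equal(sd$sd_match_len, 6)
  expect_equal(sd$sd_seq, "AGGAGG")
  # pyrimidine upstream cannot contain any AGGAGG 4-mer
  seq2 <- paste0(strrep("CT", 30), "ATGGCAGCATAA")
  sd2 <- detect_sd(seq2, 60)
  expect_false(sd2$sd_found)
})

test_that("SD fraction is recovered within 0.05 on a large planted set", {
  sdfx <- get_sd_truth()
  truth <- sdfx$truth
  expect_gte(nrow(truth$orfs), 50)
  found <- vapply(seq_len(nrow(truth$orfs)), function(k) {
    o <- truth$orfs[k, ]
    seq <- truth$genomes$seq[truth$genomes$segment_id == o$segment_id]
    detect_sd(seq, o$start)$sd_found
  }, TRUE)
  expect_lt(abs(mean(found) - sdfx$params$sd_fraction), 0.05)
  # recall on SD-planted ORFs is perfect; false calls on SD-free ORFs rare
  expect_equal(mean(found[truth$orfs$has_sd]), 1)
  if (any(!truth$orfs$has_sd)) {
    expect_lte(mean(found[!truth$orfs$has_sd]), 0.5)
  }
})

test_that("RdRP motif scanner matches regex oracles on random proteins", {
  set.seed(604)
  got <- vector("list", 1000)
  want <- vector("list", 1000)
  for (i in 1:1000) {
    prot <- random_protein_str(sample(40:200, 1))
    hits <- scan_rdrp_motifs(prot)
    got[[i]] <- list(c = hits$position[hits$motif == "C"],
                     b = hits$position[hits$motif == "B"])
    want[[i]] <- list(c = oracle_motif_positions(prot, "GDD"),
                      b = oracle_motif_positions(prot, "SG...T"))
  }
  expect_equal(got, want)
})

test_that("ordered B-C pairs and motif A spacing classes are detected", {
  pad <- function(n) strrep("A", n)
  # B at 40, C at 70: gap 30 within [10, 60] -> ordered
  prot <- paste0(pad(40), "SGKLMT", pad(24), "GDD", pad(60))
  hits <- scan_rdrp_motifs(prot)
  expect_true(hits$ordered[hits$motif == "B"])
  # motif A: D at 140 residues before C with partner D 13 downstream -> extended
  prot2 <- paste0(pad(30), "D", pad(12), "D", pad(96), "GDD", pad(40))
  h2 <- scan_rdrp_motifs(prot2)
  a <- h2[h2$motif == "A", ]
  expect_equal(a$position, 30)
  expect_equal(a$partner_spacing, 13)
  expect_equal(a$spacing_class, "extended")
  # canonical spacing 4-5
  prot3 <- paste0(pad(30), "D", pad(3), "D", pad(105), "GDD", pad(40))
  h3 <- scan_rdrp_motifs(prot3)
  a3 <- h3[h3$motif == "A" & h3$position == 30, ]
  expect_equal(a3$spacing_class, "canonical")
  # a motif-free protein yields an empty hit list
  expect_equal(nrow(scan_rdrp_motifs(strrep("A", 100))), 0)
  expect_error(scan_rdrp_motifs("SHORT"), "at least 30")
})

test_that("hydropathy flag matches the exhaustive window oracle", {
  set.seed(605)
  poly_l <- paste0(random_protein_str(30), strrep("L", 19),
                   random_protein_str(30))
  expect_true(flag_tmd(poly_l)$tmd)
  expect_false(flag_tmd(strrep("D", 40))$tmd)
  ok <- vapply(1:50, function(i) {
    prot <- random_protein_str(sample(25:150, 1))
    got <- flag_tmd(prot)
    means <- oracle_kd_windows(prot)
    isTRUE(all.equal(got$best_score, max(means), tolerance = 1e-9)) &&
      got$tmd == (max(means) >= 1.6) &&
      # the reported window attains the maximum (ties may resolve either way)
      isTRUE(all.equal(means[got$best_start + 1L], max(means),
                       tolerance = 1e-9))
  }, TRUE)
  expect_true(all(ok))
  expect_error(flag_tmd("ACD"), "shorter than")
})

test_that("the RdRP-bearing member of each bin is labelled", {
  fx <- get_fixture("small")
  ori <- orient_coding_strand(dplyr::filter(fx$segments, status == "complete"))
  bins <- cluster_segments(ori, terminal_identities(ori))
  ann <- annotate_bin(bins, ori)
  truth_rdrp <- fx$truth$orfs[fx$truth$orfs$is_rdrp, ]
  for (b in unique(bins$bin_id)) {
    members <- bins$contig_id[bins$bin_id == b]
    want <- intersect(unique(truth_rdrp$segment_id), members)
    got <- ann$summary$rdrp_segment[ann$summary$bin_id == b]
    expect_equal(got, want)
  }
  # a bin without motif hits reports no RdRP segment
  plain <- tibble::tibble(
    contig_id = c("p1", "p2"),
    seq = c(paste0(strrep("TCC", 80), "ATG", strrep("GCA", 80), "TAA",
                   strrep("TCC", 80)),
            paste0(strrep("TCC", 80), "ATG", strrep("GCU", 0),
                   strrep("GCA", 80), "TAA", strrep("TCC", 80))))
  plain_bins <- tibble::tibble(bin_id = "binX", contig_id = c("p1", "p2"),
                               class_id = c("binX_c1", "binX_c2"),
                               is_alternative = FALSE)
  ann2 <- annotate_bin(plain_bins, plain)
  expect_true(is.na(ann2$summary$rdrp_segment))
})

test_that("GFF3 export round-trips coordinates exactly", {
  fx <- get_fixture("small")
  ori <- orient_coding_strand(dplyr::filter(fx$segments, status == "complete"))
  bins <- cluster_segments(ori, terminal_identities(ori))
  d <- withr::local_tempdir()
  ann <- annotate_bin(bins, ori, gff_dir = d, protein_dir = d)
  b1 <- bins$bin_id[1]
  gff <- rtracklayer::import(file.path(d, paste0(b1, ".gff3")))
  sub <- ann$orfs[ann$orfs$bin_id == b1, ]
  expect_equal(length(gff), nrow(sub))
  expect_equal(BiocGenerics::start(gff), sub$start + 1L)
  expect_equal(BiocGenerics::end(gff), sub$end)
  expect_true(file.exists(file.path(d, paste0(b1, "_proteins.fasta"))))
})
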