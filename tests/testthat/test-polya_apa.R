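test_that("polyA windows are centred, clipped, and strand-aware", {
  set.seed(20)
  chr <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  genome <- c(chr1 = chr)
  tx <- transcript_model("t1", "chr1", "+",
                         data.frame(start = 100, end = 500))
  w <- extract_polya_window(genome, tx)   # polya_site = 500
  expect_equal(w$g_start, 400); expect_equal(w$g_end, 600)
  expect_equal(w$site_offset, 100)
  expect_equal(w$sequence, substr(chr, 401, 600))
  # near-start clipping
  tx2 <- transcript_model("t2", "chr1", "+",
                          data.frame(start = 10, end = 50))
  w2 <- extract_polya_window(genome, tx2)
  expect_equal(nchar(w2$sequence), 150)
  expect_equal(w2$site_offset, 50)
  # minus strand reads sense: reverse complement of the plus extraction
  tx3 <- transcript_model("t3", "chr1", "-",
                          data.frame(start = 500, end = 800))
  w3 <- extract_polya_window(genome, tx3)  # polya_site = 500
  expect_equal(w3$sequence, revcomp(substr(chr, 401, 600)))
  expect_equal(w3$site_offset, 100)
  tx4 <- transcript_model("t4", "chr1", "+",
                          data.frame(start = 1, end = 20))
  tx4$polya_site <- NA
  expect_error(extract_polya_window(genome, tx4), "polya_site")
})

test_that("consensus alignment maps positions and measures identity", {
  set.seed(22)
  cons <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  win <- substr(cons, 38, 137)  # consensus offset 37, length 100
  m <- align_to_consensus(win, cons)
  expect_equal(m$identity, 1)
  expect_equal(m$pairs$consensus_pos, m$pairs$window_pos + 37)
  expect_equal(m$consensus_region, c(37, 137))
  # one substitution: same coordinate map, identity (L-1)/L
  win1 <- win
  substr(win1, 50, 50) <- if (substr(win1, 50, 50) == "A") "C" else "A"
  m1 <- align_to_consensus(win1, cons)
  expect_equal(m1$pairs$consensus_pos, m1$pairs$window_pos + 37)
  expect_equal(m1$identity, 99 / 100)
  expect_false(m1$low_confidence)
})

test_that("simulated 8% divergence recovers the truth alignment", {
  sim <- simulate_polya_instances(NULL, 6, 0.08, 1, seed = 23)
  for (i in seq_along(sim$sequences)) {
    m <- align_to_consensus(sim$sequences[[i]], sim$consensus)
    off <- sim$truth$offset[i]
    # interior columns must follow the truth diagonal; the last few
    # columns of a free-end-gap alignment may legitimately wobble when
    # terminal mismatches make a shifted end score higher
    interior <- m$pairs$window_pos >= 10 & m$pairs$window_pos < 190
    expect_gt(sum(interior), 150)
    expect_equal(m$pairs$consensus_pos[interior],
                 m$pairs$window_pos[interior] + off)
    # lifting the planted hexamer recovers the consensus position
    expect_equal(
      lift_to_consensus(m, sim$truth$hexamer_window_pos[i]),
      sim$truth$hexamer_consensus_pos[i])
  }
})

test_that("hexamer scanning reports all overlapping occurrences", {
  h <- scan_polya_hexamers("GGAATAAAGG")
  expect_equal(h$position, 2L)
  expect_true(h$is_core)
  h2 <- scan_polya_hexamers("AATAATAAA")
  expect_equal(h2$position, 3L)  # AATAAT is not the motif
  expect_equal(nrow(scan_polya_hexamers("GGGGGGGG")), 0)
  # property: equals the sliding-window oracle, overlapping hits included
  set.seed(24)
  for (rep in 1:10) {
    s <- paste(sample(c("A", "T"), 60, TRUE, prob = c(.7, .3)),
               collapse = "")
    for (motif in c("AATAAA", "ATTAAA")) {
      got <- scan_polya_hexamers(s, motif_set = motif)
      expect_equal(got$position, brute_motif_scan(s, motif))
    }
  }
})

test_that("the extended PAS motif set is scanned and reported per motif", {
  h <- scan_polya_hexamers("GGATTAAAGG", motif_set = extended_pas_motifs())
  expect_equal(h$hexamer, "ATTAAA")
  expect_false(any(h$is_core))
})

test_that("paired co-occurrence test matches the closed form", {
  # construct 4 windows with motif counts (1, 0, 1, 0), consensus count 0
  sim <- simulate_polya_instances(NULL, 4, 0, 0, seed = 25)
  seqs <- sim$sequences
  for (i in c(1, 3)) {
    s <- seqs[[i]]
    substr(s, 51, 56) <- "AATAAA"
    seqs[[i]] <- s
  }
  maps <- lapply(seqs, align_to_consensus, consensus_seq = sim$consensus)
  res <- cooccurrence_paired_test(seqs, maps, sim$consensus)
  expect_equal(res$pairs$window_count, c(1, 0, 1, 0))
  expect_equal(res$pairs$consensus_count, rep(0, 4))
  expect_equal(res$t, 1.732051, tolerance = 1e-6)
  expect_equal(res$df, 3)
  expect_equal(res$p, 0.1816901, tolerance = 1e-6)
  # matches the textbook implementation to near machine precision
  tt <- stats::t.test(res$pairs$window_count,
                      res$pairs$consensus_count, paired = TRUE)
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
})

test_that("all-zero differences give p = 1 with a warning", {
  sim <- simulate_polya_instances(NULL, 4, 0, 0, seed = 26)
  maps <- lapply(sim$sequences, align_to_consensus,
                 consensus_seq = sim$consensus)
  expect_warning(res <- cooccurrence_paired_test(sim$sequences, maps,
                                                 sim$consensus),
                 "zero")
  expect_equal(res$p, 1)
  expect_error(cooccurrence_paired_test(sim$sequences[1:2], maps[1:2],
                                        sim$consensus), ">= 3")
})

test_that("motif-free fixtures never reject (type-I behaviour)", {
  rejections <- vapply(1:10, function(s) {
    sim <- simulate_polya_instances(NULL, 8, 0.08, 0, seed = s)
    maps <- lapply(sim$sequences, align_to_consensus,
                   consensus_seq = sim$consensus)
    res <- suppressWarnings(
      cooccurrence_paired_test(sim$sequences, maps, sim$consensus))
    res$p < 0.05
  }, NA)
  expect_lte(mean(rejections), 0.05)
})

test_that("isoforms are grouped by which TE copy the terminal exon hits", {
  te <- data.frame(chrom = "chr1",
                   start = c(5000, 9000), end = c(5400, 9400),
                   family = "MER65", id = c("copy1", "copy2"))
  mk_tx <- function(id, last_start, last_end)
    transcript_model(id, "chr1", "+",
                     data.frame(start = c(1000, last_start),
                                end = c(1500, last_end)))
  txs <- list(mk_tx("iso-prox", 4900, 5100),   # hits proximal copy
              mk_tx("iso-dist", 8900, 9100),   # hits distal copy
              mk_tx("iso-none", 3000, 3400))   # membrane-isoform analog
  got <- classify_isoform_groups(txs, te, family_filter = "MER65")
  expect_equal(got$group, c("TE-proximal", "TE-distal", "no-TE"))
  expect_equal(got$te_id, c("copy1", "copy2", NA))
})

test_that("minus-strand genes rank copies along transcription direction", {
  te <- data.frame(chrom = "chr1",
                   start = c(5000, 9000), end = c(5400, 9400),
                   family = "MER65", id = c("left", "right"))
  # minus strand: transcription runs right to left, terminal exon is the
  # leftmost; the 'right' copy is proximal
  tx <- transcript_model("m1", "chr1", "-",
                         data.frame(start = c(9100, 12000),
                                    end = c(9500, 12500)))
  got <- classify_isoform_groups(list(tx), te)
  expect_equal(got$group, "TE-proximal")
  expect_equal(got$te_id, "right")
})

test_that("a terminal exon over two copies takes the larger overlap", {
  te <- data.frame(chrom = "chr1", start = c(1000, 1500),
                   end = c(1400, 2000), family = "F",
                   id = c("small", "big"))
  tx <- transcript_model("t", "chr1", "+",
                         data.frame(start = 1300, end = 1900))
  expect_message(got <- classify_isoform_groups(list(tx), te),
                 "largest overlap")
  expect_equal(got$te_id, "big")  # 400 bp vs 100 bp
})
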