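# Motif scanning and enrichment.

test_that("build_pssm preserves consensus and validates input", {
  counts <- sapply(strsplit("CACGTG", "")[[1]], function(b) {
    p <- setNames(numeric(4), c("A", "C", "G", "T")); p[b] <- 1; p
  })
  pssm <- build_pssm(counts, pseudocount = 0.01, name = "ebox")
  consensus <- paste(rownames(pssm$prob)[apply(pssm$prob, 2, which.max)],
                     collapse = "")
  expect_equal(consensus, "CACGTG")
  expect_equal(colSums(pssm$prob), setNames(rep(1, 6), colnames(counts)),
               tolerance = 1e-9)
  expect_true(all(pssm$prob > 0))

  probs <- matrix(0.25, 4, 5)
  expect_equal(build_pssm(probs, pseudocount = 0)$prob,
               matrix(0.25, 4, 5, dimnames = list(c("A", "C", "G", "T"),
                                                  NULL)))
  bad <- counts; bad[, 3] <- 0
  expect_error(build_pssm(bad), "all-zero position")
  expect_error(build_pssm(counts[1:3, ]), "4 rows")
})

test_that("promoter extraction does the coordinate arithmetic", {
  chrom <- paste(rep("ACGT", 2500), collapse = "")   # 10 kb
  res <- extract_promoter(chrom, exon_starts = c(6001, 7201),
                          exon_ends = c(7000, 7500), strand = "+",
                          upstream = 5000)
  expect_equal(res$start, 1001)
  expect_equal(res$end, 7200)
  expect_equal(nchar(res$sequence), 6200)
  expect_equal(res$sequence, substr(chrom, 1001, 7200))

  # minus strand: reverse complement of the corresponding genomic window
  resm <- extract_promoter(chrom, exon_starts = c(5001, 3001),
                           exon_ends = c(5500, 3800), strand = "-",
                           upstream = 1000)
  expect_equal(resm$start, 3801)
  expect_equal(resm$end, 6500)
  expect_equal(resm$sequence, revcomp_chr(substr(chrom, 3801, 6500)))

  expect_warning(extract_promoter(chrom, c(2001, 4001), c(3000, 4500),
                                  strand = "+", upstream = 5000),
                 "truncated")
  expect_error(extract_promoter(chrom, 100, 200), ">= 2 exons")

  seqs <- c(m1 = "ACGT", m2 = "ACGT", m3 = "AAAA")
  expect_equal(names(dedup_sequences(seqs)), c("m1", "m3"))
})

test_that("palindromic E-box hits land on both strands at one position", {
  hits <- scan_sequence("TTCACGTGTT", clock_pssms()$Ebox, threshold = 6)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$position, c(3L, 3L))
  expect_setequal(hits$strand, c("+", "-"))
  expect_equal(hits$score[1], hits$score[2], tolerance = 1e-12)
})

test_that("scan matches the brute-force oracle on random sequences", {
  set.seed(55)
  pssms <- clock_pssms()
  for (i in 1:3) {
    s <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
               collapse = "")
    for (p in pssms[c("Ebox", "Dbox")]) {
      mine <- scan_sequence(s, p, threshold = 3)
      orc <- oracle_scan(s, p, threshold = 3)
      expect_equal(mine$position, orc$position)
      expect_equal(mine$strand, orc$strand)
      expect_equal(mine$score, orc$score, tolerance = 1e-10)
    }
  }
})

test_that("scan edge cases: N windows, short sequences, infinite threshold", {
  pssm <- clock_pssms()$Ebox
  # every width-6 window of this 10-mer covers the N at position 5: all skip
  expect_equal(nrow(scan_sequence("TTCANGTGTT", pssm, threshold = -1e6)),
               0L)
  # N outside a window leaves it scoreable
  withN <- scan_sequence("NTTCACGTGTTN", pssm, threshold = 6)
  expect_equal(withN$position, c(4L, 4L))
  expect_equal(nrow(scan_sequence("ACGT", pssm)), 0L)
  expect_equal(nrow(scan_sequence("TTCACGTGTT", pssm, threshold = Inf)),
               0L)
})

test_that("reverse-complement symmetry holds with non-uniform background", {
  set.seed(14)
  s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE,
                    prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
  pssm <- clock_pssms()$Dbox
  bg <- c(0.3, 0.2, 0.2, 0.3)
  fwd <- scan_sequence(s, pssm, background = bg, threshold = 2)
  rc_pssm <- pssm
  rc_pssm$prob <- pssm$prob[4:1, pssm$width:1, drop = FALSE]
  rownames(rc_pssm$prob) <- c("A", "C", "G", "T")
  rc_bg <- rev(bg)   # background seen by the complemented read
  rev_scan <- scan_sequence(revcomp_chr(s), rc_pssm, background = rc_bg,
                            threshold = 2)
  # reverse-complementing both sequence and PSSM mirrors positions to
  # n - w - i + 2 and leaves the strand unchanged
  n <- nchar(s); w <- pssm$width
  mapped <- data.frame(position = n - w - rev_scan$position + 2L,
                       strand = rev_scan$strand,
                       score = rev_scan$score)
  mapped <- mapped[order(mapped$position, mapped$strand), ]
  fwd_s <- fwd[order(fwd$position, fwd$strand), ]
  expect_equal(fwd_s$position, mapped$position)
  expect_equal(fwd_s$strand, mapped$strand)
  expect_equal(fwd_s$score, mapped$score, tolerance = 1e-10)
})

test_that("per-gene presence uses any-hit semantics", {
  hits <- data.frame(seq_id = "m1", motif = "Ebox", position = 1L,
                     strand = "+", score = 10)
  map <- c(m1 = "geneA", m2 = "geneA", m3 = "geneB")
  flags <- gene_motif_presence(hits, map)
  expect_true(flags[["geneA"]])
  expect_false(flags[["geneB"]])
  expect_error(gene_motif_presence(
    data.frame(seq_id = "mX", motif = "Ebox", position = 1L, strand = "+",
               score = 1), map), "not mapped")
})

test_that("control-set sampling is seeded and exhaustive at n = pool", {
  pool <- sprintf("g%03d", 1:165)
  s1 <- sample_control_set(pool, 62, seed = 10)
  expect_length(s1, 62L)
  expect_false(anyDuplicated(s1) > 0)
  expect_identical(s1, sample_control_set(pool, 62, seed = 10))
  expect_setequal(sample_control_set(pool, 165, seed = 2), pool)
  expect_error(sample_control_set(pool, 200, seed = 1), "exceeds")
})

test_that("fisher enrichment matches hand and brute-force computation", {
  res <- enrichment_test(rep(TRUE, 5), rep(FALSE, 5))
  expect_equal(res$p, 1 / 252, tolerance = 1e-12)
  expect_equal(res$odds_ratio, Inf)

  same <- enrichment_test(c(rep(TRUE, 3), rep(FALSE, 3)),
                          c(rep(TRUE, 3), rep(FALSE, 3)))
  expect_gte(same$p, 0.5)

  # exhaustive check over small tables, plus row/column-swap invariance
  for (a in 0:4) for (b in 0:3) for (c in 0:4) for (d in 0:3) {
    if (a + b == 0 || c + d == 0) next
    fr <- c(rep(TRUE, a), rep(FALSE, b))
    fc <- c(rep(TRUE, c), rep(FALSE, d))
    p <- enrichment_test(fr, fc)$p
    expect_equal(p, oracle_fisher_onetail(a, b, c, d), tolerance = 1e-10)
    expect_equal(p,
                 fisher.test(matrix(c(a, b, c, d), 2),
                             alternative = "greater")$p.value,
                 tolerance = 1e-8)
  }
})

test_that("planted-motif enrichment is detected in seeded replicates", {
  pssm <- clock_pssms()$Ebox
  detected <- 0
  n_rep <- 8
  for (rep_i in seq_len(n_rep)) {
    pr <- generate_promoters(30, 30, length = 500,
                             frac_fg_with_motif = 0.8,
                             frac_bg_with_motif = 0.1, seed = 100 + rep_i)
    flag_set <- function(seqs) {
      vapply(names(seqs), function(id) {
        nrow(scan_sequence(seqs[[id]], pssm, threshold = 8, seq_id = id)) > 0
      }, logical(1))
    }
    p <- enrichment_test(flag_set(pr$fg), flag_set(pr$bg))$p
    if (p < 0.05) detected <- detected + 1
  }
  expect_equal(detected, n_rep)
})
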