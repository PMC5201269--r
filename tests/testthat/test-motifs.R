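test_that("consensus scanning finds E-boxes with TSS-relative coordinates", {
  hits <- scan_consensus("TTCAGGTGAA")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$match, "CAGGTG")
  expect_equal(hits$position, 2)
  expect_equal(hits$tss_rel, -8)       # leftmost base, -1 = last base
  expect_equal(hits$strand, "±")       # palindromic pattern class
  # the mutagenesis replacement word contains no E-box
  expect_equal(nrow(scan_consensus("TTACGCGTAA")), 0)
  # overlapping matches are all reported
  expect_equal(scan_consensus("CACATGTG")$position, c(0, 2))
  # non-palindromic consensus reports stranded hits
  h <- scan_consensus("AAGGGTTT", "GGGT")
  expect_equal(h$strand, "+")
  h2 <- scan_consensus("AAACCCTT", "GGGT")
  expect_equal(h2$strand, "-")
  expect_error(scan_consensus("ACGT", "CAXTG"), "IUPAC")
})

test_that("consensus hit positions equal the regex oracle on random sequence", {
  set.seed(33)
  seq <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
  hits <- scan_consensus(seq)
  expect_equal(hits$position, oracle_ebox_starts(seq))
  # case invariance
  expect_equal(scan_consensus(tolower(seq))$position, hits$position)
})

test_that("consensus_to_pwm concentrates mass as specified", {
  m <- consensus_to_pwm("CANNTG", alpha = 0.01)
  expect_equal(colSums(m$prob), rep(1, 6), tolerance = 1e-12)
  # N column scores 0 against a uniform background
  expect_equal(unname(m$logodds[, 3]), rep(0, 4))
  # C column: 0.97 on C, pseudocount elsewhere
  expect_equal(unname(m$prob["C", 1]), 0.97)
  expect_equal(unname(m$prob["A", 1]), 0.01)
  # max-scoring words are exactly the CANNTG matches, equal across Ns
  expect_equal(sum(apply(m$logodds, 2, max)),
               4 * log2(0.97 / 0.25))
})

test_that("DP null distribution equals 4^w brute force (within one bin)", {
  # width-1 uniform case: each score carries mass 1/4
  m1 <- consensus_to_pwm("C")
  n1 <- pwm_null_distribution(m1)
  expect_equal(sum(n1$pmf), 1, tolerance = 1e-9)
  expect_equal(pwm_pvalue(n1, log2(0.97 / 0.25)), 0.25)
  expect_equal(pwm_pvalue(n1, log2(0.01 / 0.25)), 1)
  # random-ish PWMs up to width 6, non-uniform background
  set.seed(14)
  for (cons in c("CANNTG", "RYSWKM", "ACG")) {
    bg <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
    m <- consensus_to_pwm(cons, alpha = 0.02, background = bg)
    null <- pwm_null_distribution(m)
    expect_equal(sum(null$pmf), 1, tolerance = 1e-9)
    w <- m$width
    for (s in quantile(null$support * null$bin, c(0, .3, .7, 1))) {
      p_dp <- pwm_pvalue(null, s)
      # exact agreement with enumeration of the same discretized model
      expect_equal(p_dp, oracle_pwm_tail(m, s), tolerance = 1e-9)
      # and bracketed by exact-score enumeration within one bin per column
      expect_lte(oracle_pwm_tail(m, s + w * null$bin, discretize = FALSE),
                 p_dp + 1e-12)
      expect_gte(oracle_pwm_tail(m, s - w * null$bin, discretize = FALSE),
                 p_dp - 1e-12)
    }
  }
  # the consensus-PWM design tension: a perfect CANNTG match has
  # p = 1/256 = 0.0039 > 0.001, so the FIMO-style default threshold
  # rejects consensus sites under a uniform background
  m6 <- consensus_to_pwm("CANNTG")
  n6 <- pwm_null_distribution(m6)
  pmax6 <- pwm_pvalue(n6, sum(apply(m6$logodds, 2, max)))
  expect_equal(pmax6, 1 / 256, tolerance = 1e-9)
  expect_gt(pmax6, 0.001)
})

test_that("scan_pwm respects thresholds, strands and degenerate input", {
  m <- consensus_to_pwm("CANNTG")
  null <- pwm_null_distribution(m)
  seq <- "TTTTCAGGTGTTTTT"
  hits <- scan_pwm(seq, m, p_threshold = 1 / 256 + 1e-9, null = null)
  expect_equal(hits$position, 4)
  expect_equal(hits$strand, "±")
  # vacuous threshold: every ACGT window hits (palindromes deduplicated)
  all_hits <- scan_pwm(seq, m, p_threshold = 1, null = null)
  n_win <- nchar(seq) - m$width + 1
  expect_equal(nrow(all_hits) + sum(all_hits$strand == "±"), 2 * n_win)
  # strand symmetry: scanning the reverse complement mirrors positions
  rc_hits <- scan_pwm(revcomp(seq), m, p_threshold = 1 / 256 + 1e-9,
                      null = null)
  expect_equal(rc_hits$position, nchar(seq) - m$width - hits$position)
  expect_warning(short <- scan_pwm("ACG", m), "shorter")
  expect_equal(nrow(short), 0)
  # default FIMO-style cut rejects a bare consensus site under uniform bg
  expect_equal(nrow(scan_pwm(seq, m, null = null)), 0)
})

test_that("promoter extraction is strand-aware with truncation flags", {
  genome <- c(chrI = paste(rep("ACGT", 500), collapse = ""))  # 2000 bp
  # + gene, TSS at 1-based 1001: promoter = first 1000 bases
  pp <- extract_promoter(genome, list(gene_id = "gp", seqid = "chrI",
                                      start = 1001, end = 1500,
                                      strand = "+"))
  expect_equal(nchar(pp$sequence), 1000)
  expect_equal(pp$sequence, substr(genome[[1]], 1, 1000))
  expect_false(pp$truncated)
  # - gene: promoter is revcomp of the bases 3' of the TSS (gene end)
  pm <- extract_promoter(genome, list(gene_id = "gm", seqid = "chrI",
                                      start = 1, end = 900, strand = "-"),
                         length = 100)
  expect_equal(pm$sequence,
               revcomp(substr(genome[[1]], 901, 1000)))
  # a known 6-mer just 3' of a minus-strand TSS ends the promoter
  g2 <- c(c1 = paste0("AAAA", "CACGTG", paste(rep("A", 20), collapse = "")))
  pm2 <- extract_promoter(g2, list(gene_id = "x", seqid = "c1",
                                   start = 1, end = 4, strand = "-"),
                          length = 10)
  expect_equal(substr(pm2$sequence, 5, 10), revcomp("CACGTG"))
  # truncation at the contig start
  pt <- extract_promoter(genome, list(gene_id = "gt", seqid = "chrI",
                                      start = 501, end = 600,
                                      strand = "+"))
  expect_equal(nchar(pt$sequence), 500)
  expect_true(pt$truncated)
  expect_error(extract_promoter(genome, list(gene_id = "z", seqid = "nope",
                                             start = 1, end = 2,
                                             strand = "+")), "contig")
})

test_that("mutation_effect abolishes sites locally and only locally", {
  set.seed(77)
  sim <- simulate_promoters(sim_config(seed = 77))
  seq <- sim$sequences[["daf-21"]]
  me <- mutation_effect(seq, -432, "ACGCGT")
  expect_true(-432 %in% me$hits_before$tss_rel)
  expect_false(-432 %in% me$hits_after$tss_rel)
  expect_equal(me$lost, -432)
  # identity substitution changes nothing
  w <- substr(seq, nchar(seq) - 432 + 1, nchar(seq) - 432 + 6)
  me_id <- mutation_effect(seq, -432, w)
  expect_identical(me_id$hits_before, me_id$hits_after)
  # locality: random substitutions only change windows within w-1 of the
  # edit
  for (i in 1:20) {
    pos <- -sample(10:990, 1)
    repl <- paste(sample(c("A", "C", "G", "T"), 6, TRUE), collapse = "")
    mm <- mutation_effect(seq, pos, repl)
    changed <- c(mm$lost, mm$gained)
    if (length(changed))
      expect_true(all(changed > pos - 6 & changed < pos + 6))
  }
  expect_error(mutation_effect(seq, -3, "ACGCGT"), "bounds")
})
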